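---
title: "Methods: simulating and mapping four epistatic leaf-colour loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping four epistatic leaf-colour loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthomap)
```

## The genetic model

Red pigmentation of lettuce leaves is controlled in this package by four
interacting loci, named after the cloned genes:

* **RLL1** (bHLH activator): the null allele *rll1* is fully recessive and
  epistatic over everything — an *rll1/rll1* plant is green no matter what
  the other loci carry, because the anthocyanin pathway cannot be activated.
* **RLL2** (R2R3-MYB activator): one functional (highly expressed) copy
  suffices for visible red colour — fully dominant.
* **rll3**, **rll4** (defective alleles of an R3-MYB competitor and a
  RUP-like WD40 suppressor): each is a recessive intensifier; a plant
  homozygous for the defective allele loses one layer of repression and
  darkens by one step.

`latent_score()` encodes this as an integer score:

$$
s = \begin{cases}
0 & \text{if } g_{RLL1} = 0\\
2\,[g_{RLL2} \ge 1] + [g_{RLL3} = 0] + [g_{RLL4} = 0] + b\,[\text{stress}] & \text{otherwise,}
\end{cases}
$$

where $g$ counts functional alleles and the stress bonus $b$ (default 1)
models the red blush wild lettuce develops under cold or drought.
Thresholds at 1, 2 and 3 cut the score into the ordinal classes
green / light red / red / dark red. The weights are a design choice — the
source material for the model is ordinal, not quantitative — picked so that
the documented family contrasts fall into distinct classes: a 2 for the
dominant MYB keeps every RLL2 carrier at least "red-class" distance above
the rll2-null genotypes, while each intensifier adds a single step
(light red to red, red to dark red). Class labels are absolute here; in a
family that segregates only an intensifier, the lighter class may print as
"red" even where a field notebook would say "light red" relative to its
dark siblings.

Two leniencies of real phenotyping are exposed as parameters and default to
off: Gaussian noise on the latent score before thresholding (`noise_sd`)
and a penetrance leak (`penetrance_green`), the probability that a
red-class plant is scored green. The leak exists because the reference F2
(113 green of 218) shows more green plants than any fully penetrant
four-locus model predicts (91/256 ≈ 35.5%); it is deliberately not
calibrated — no stated mechanism pins its value — so the default generator
reproduces the Mendelian expectation, not the printed excess.

## The cross simulator

`simulate_f2()` and `self_generation()` generate gametes by a Markov walk
along each chromosome: the haplotype source at the first locus is uniform,
and switches between adjacent loci occur with the Haldane recombination
fraction $r = (1 - e^{-2d/100})/2$ of their cM distance (no interference;
Kosambi could be substituted by changing one function). The default map
carries 200 evenly spaced markers on each of nine chromosomes with lengths
on the v8 assembly scale and a uniform 0.5 cM/Mb expansion; the causal loci
sit on chromosomes 5 (RLL1, inside its fine-mapped 335.69–337.92 Mb
interval), 5 (RLL2), 4 (RLL3) and 9 (RLL4). Parents are opposite
homozygotes everywhere, so marker phase is known and dosages are counted as
copies of the red-parent allele.

`select_pools()` builds the contrasting pools: the high pool takes the
`k_high` most intense non-green plants ranked by latent score plus optional
`score_noise_sd` (ties broken by a seeded shuffle); the low pool is either
a random draw among green-class plants — the classic design — or the bottom
of the same ranking for families with no green class. The campaign default
`score_noise_sd = 1` reflects that visually ranking redness among dozens of
red plants confuses adjacent intensity steps routinely; one latent unit is
exactly one intensifier step, so the noise is of the same magnitude as the
smallest genetic effect being ranked.

`sample_pool_reads()` models pooled RNA-seq coverage as negative binomial
per SNP and pool (mean 50, size 10 by default; Poisson at `dispersion =
Inf`) and draws alternate-allele reads binomially at the error-perturbed
pool frequency $p(1-\varepsilon) + (1-p)\varepsilon$, with
$\varepsilon = 0.002$ by default. Allele-specific expression bias is not
modelled.

## The scan statistic and its null bands

The per-pool SNP index is the alternate-read fraction (SNPs below
`min_depth = 10` in either pool are dropped); the signed
$\Delta$ SNP-index is high-pool minus low-pool with the red-parent allele
as alternate. Windows of 20 Mb advanced by 5 Mb average the per-SNP
$\Delta$; windows need at least 5 SNPs. These window defaults are larger
than the 2 Mb / 500 kb that a dense whole-genome SNP set would invite
because the default map supplies roughly one marker per 1–1.8 Mb; a 2-Mb
window would hold fewer SNPs than its own `min_snps` floor.

`simulate_null_ci()` draws the null distribution the way the scan sees it:
each replicate samples every pooled individual's dosage from the
generation's Mendelian law (F2: 1/4, 1/2, 1/4; selfed-family pools can use
3/8, 1/4, 3/8), converts pool frequencies to binomial reads at the
scheduled depth, and recomputes $\Delta$. The `snps_per_window` argument is
the load-bearing subtlety: linked SNPs inside one window are read noise
around a *shared* pool composition, so a null replicate of the windowed
statistic must reuse one composition across its $m$ SNPs and average only
the read noise. Bands built this way are calibrated for the windowed track
(5% of null windows fall outside the 95% band); per-SNP bands
(`snps_per_window = 1`) would be conservative for window means. Bands are
tabulated on a depth grid and interpolated at each window's mean depth.
`call_regions()` merges runs of at least 3 consecutive exceeding windows
into candidate regions, using $|\Delta|$.

## The end-to-end campaign and epistatic masking

`run_bsa_campaign()` reproduces the whole mapping strategy: an F2 of 218
with pools of 50 (most intense red vs random green, depth 50), then four
sequential fixed-background rounds. Each round selects an F2 plant whose
genotype is heterozygous at one target locus and fixed at the other three
(`select_fixed_background()`), selfs it into a family of 300, scans
top-vs-bottom pools of 50 and asks whether a 0.01-level region covers the
target.

In the F2 scan the two qualitative loci dominate: the green pool is devoid
of functional RLL1 contrast and depleted of RLL2, giving locus contrasts of
roughly 0.45 and 0.3, far above the 0.01 band. The intensifiers are
*partially* masked: because the reddest plants are disproportionately
intensifier homozygotes, ranking the red pool by intensity leaks an
expected contrast of 0.1–0.27 onto chromosomes 4 and 9 (the size depends on
the scoring noise), which straddles the 0.05 band rather than sitting
safely below it. Simulated campaigns accordingly show the intensifiers
escaping detection in only about half of replicates — they surface as
moderate, sub-qualitative peaks in the rest — while the fixed-background
rounds recover each masked locus essentially always. The package reports
this honestly rather than forcing complete masking: complete invisibility
of a recessive intensifier in an intensity-ranked extreme pool is not a
property this model (or, we would argue, the underlying experiment) can
guarantee.

## Recessive-class fine mapping

`fine_map_recessive()` implements breakpoint exclusion: among individuals
selected for the recessive class, any marker at which an individual is not
homozygous for the donor allele excludes the locus from that marker
outward. Exclusion is computed at sub-marker resolution — a marker is
excluded when its recombinant count exceeds `max_errors`, and the *gap*
between two adjacent markers is excluded only when a single individual is
recombinant at both flanks (only then does a foreign segment span the
gap). The reported interval is the hull of all unexcluded cells, extended
to the innermost excluded flanking markers. This makes the coverage
guarantee exact: with error-free phenotyping and `max_errors = 0`, the
causal locus lies inside the interval in every replicate, including the
rare configurations where breakpoints fall in the two gaps immediately
flanking the locus, or where a clean stretch elsewhere is wider than the
locus's own. `max_errors` exists because late-onset light-red phenotypes
carry real misclassification risk.

Fine-mapping simulations use a dense local panel (100-kb marker spacing
over a 40-Mb region) with a locally suppressed recombination rate of
0.05 cM/Mb. That rate is implied by the published resolution of such
campaigns — mapping a gene to ~358 kb with 3100 plants, or ~2.2 Mb with
1751, is only possible where a megabase corresponds to a few hundredths of
a centiMorgan, as in the recombination-poor interior of these very large
chromosomes. On a genome-average 0.5 cM/Mb map, 864 recessive plants would
recombine at every marker more than ~0.1 Mb from the locus and no
zero-recombinant core could exist. At the published campaign size (864
recessives) the simulated median interval is ~2.3 Mb, matching the scale of
the printed intervals.

## Statistics

Segregation ratios use the Pearson chi-square goodness of fit
($\chi^2 = \sum (O-E)^2/E$, df = classes − 1) without continuity
correction; the worked example 4058:1372 against 3:1 gives
$\chi^2 = 0.207$, $p = 0.65$, comfortably satisfying the reported
$p > 0.5$, and the conclusion is unchanged with the Yates correction
(exposed as a flag). Marker–trait association is the chi-square test of
independence on the genotype × phenotype table. Family segregation is
declared when at least two phenotype classes each reach 3 plants and 5%
frequency — thresholds chosen for robustness to single mis-scored plants,
not taken from any source.

## Variant annotation

Gene models are minimal (ordered exons, CDS span, reference sequence) and
validated (spliced CDS starts ATG, ends with a stop, length divisible by
three). Variants are VCF-style (indels anchored on the preceding base) and
left-normalized before classification. Coding SNVs are translated with the
standard code and reported as residue-numbered substitutions; coding indels
are frameshift exactly when their length change is not a multiple of three;
intronic variants within 2 bp of an exon boundary are splice-adjacent;
upstream indels within the promoter window (default 2000 bp) are reported
with a negative offset where the base adjacent to the A of ATG is −1 (the
reference point of published promoter positions is not stated; this
convention is ours and documented). Minus-strand genes are handled by
reverse complementation, and annotation of a variant on a minus-strand
gene equals annotation of its mirror on the plus strand.
`group_haplotypes()` groups amplicon sequences by exact identity after
uppercasing; IUPAC ambiguity codes (double peaks from direct Sanger
sequencing) flag a genotype as carrying multiple homologs.

## Problem sizes, seeds and reproducibility

Every stochastic function takes a `seed` and is bit-reproducible given one;
the campaign derives per-stage seeds from its master seed. The shipped
tests run the complete pipeline at the sizes of the original study design
(F2 of 218, pools of 50, families of hundreds to thousands, 10,000-replicate
null bands, 50-replicate campaign ensembles, 100-replicate fine-mapping
coverage) — sizes chosen to match the study conditions while keeping each
property estimable within tight Monte-Carlo error.

## Known limitations

* RNA-seq allele-specific expression and pooling-by-tissue (rather than by
  RNA) biases are not modelled.
* The F2 green excess (113/218) is representable via `penetrance_green`
  but off by default; no value is asserted.
* Only two-pool designs, mean-based smoothing and empirical-quantile bands
  are provided (no G′ statistic, tricube weighting or Bayesian
  alternatives).
* The uniform cM/Mb map is a simplification; fine mapping requires the
  locally realistic rate described above, supplied as a local panel rather
  than a genome-wide recombination landscape.
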