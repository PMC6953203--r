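# Shared fixtures, all built in code.

# A small map: n markers per chromosome on the standard nine chromosomes.
small_map <- function(n_markers = 20) marker_map(n_markers = n_markers)

# A single-chromosome map (useful for fine-mapping tests). Chromosome 4 by
# default so the default architecture's RLL3 sits on it.
one_chrom_map <- function(chrom = 4, n_markers = 200) {
  lens <- lettuce_chrom_lengths()[as.character(chrom)]
  marker_map(n_markers = n_markers, chrom_lengths_bp = lens)
}

# Dense local marker panel for recessive-class fine mapping around the
# intensifier locus on chromosome 4, with the locally suppressed
# recombination rate implied by sub-Mb fine-mapping resolution in a
# several-hundred-Mb chromosome (0.05 cM/Mb). Markers are offset so none
# coincides with the causal position.
fine_map_panel <- function(region = c(1.8e8, 2.2e8), spacing = 1e5,
                           local_cm_per_mb = 0.05) {
  pos <- seq(region[1] + spacing / 2, region[2], by = spacing)
  map <- tibble::tibble(
    chrom = 4L, id = sprintf("fm_%05d", seq_along(pos)), pos_bp = pos,
    pos_cM = 100 + (pos - region[1]) / 1e6 * local_cm_per_mb,
    red_allele = "A", green_allele = "T"
  )
  map <- structure(map, chrom_lengths = c("4" = 3.69e8),
                   cm_per_mb = local_cm_per_mb,
                   class = c("anthomap_map", class(map)))
  loci <- rll_loci()
  i <- loci$name == "RLL3"
  loci$pos_cM[i] <- 100 + (loci$pos_bp[i] - region[1]) / 1e6 * local_cm_per_mb
  list(map = map, arch = genetic_architecture(loci = loci))
}

# Build a population directly from haplotype matrices (columns follow
# sim_loci(map, arch) order).
manual_pop <- function(hapA, hapB, map = small_map(), arch = genetic_architecture()) {
  loci <- anthomap:::sim_loci(map, arch)
  stopifnot(ncol(hapA) == nrow(loci))
  anthomap:::new_population(loci, hapA, hapB, arch,
                            generation = "F2", family = "")
}

manual_pools <- function(high, low) {
  structure(list(high = high, low = low), class = "anthomap_pools")
}

# Deterministic pool-count table for scan unit tests.
toy_counts <- function(n = 10, chrom = 1L, high_alt = 30, high_ref = 10,
                       low_alt = 5, low_ref = 35) {
  tibble::tibble(
    chrom = chrom,
    pos_bp = seq(1e6, by = 1e6, length.out = n),
    id = sprintf("m%03d", seq_len(n)),
    ref = "A", alt = "T",
    high_ref = high_ref, high_alt = high_alt,
    low_ref = low_ref, low_alt = low_alt
  )
}

# Toy single-exon gene: CDS of `n_codons` codons starting at genomic
# `cds_start`, 'GCT' filler with chosen codons overridden, CG-repeat
# upstream sequence (no homopolymers, so indels do not left-shift).
toy_gene <- function(n_codons = 60, cds_start = 1001,
                     codons = list(), gene_id = "toy") {
  body <- rep("GCT", n_codons)
  body[1] <- "ATG"
  body[n_codons] <- "TAA"
  for (k in names(codons)) body[as.integer(k)] <- codons[[k]]
  cds <- paste(body, collapse = "")
  upstream <- strrep("CG", (cds_start - 1) / 2)
  seq <- paste0(substr(upstream, 1, cds_start - 1), cds, strrep("CG", 50))
  gene_model(gene_id,
             exons = data.frame(start = cds_start,
                                end = cds_start + nchar(cds) - 1),
             cds_start = cds_start, cds_end = cds_start + nchar(cds) - 1,
             seq = seq, seq_start = 1L)
}

# Toy seven-exon gene, fully coding, 30-bp exons separated by 20-bp
# T-homopolymer introns.
toy_multiexon_gene <- function(n_exons = 7, exon_len = 30, intron_len = 20,
                               cds_start0 = 501) {
  n_codons <- n_exons * exon_len / 3
  body <- rep("GCT", n_codons)
  body[1] <- "ATG"
  body[n_codons] <- "TAA"
  cds <- paste(body, collapse = "")
  starts <- cds_start0 + (seq_len(n_exons) - 1) * (exon_len + intron_len)
  ends <- starts + exon_len - 1
  seq <- strrep("C", max(ends) + 100)
  for (i in seq_len(n_exons)) {
    piece <- substr(cds, (i - 1) * exon_len + 1, i * exon_len)
    substr(seq, starts[i], ends[i]) <- piece
  }
  for (i in seq_len(n_exons - 1)) {
    substr(seq, ends[i] + 1, ends[i] + intron_len) <- strrep("T", intron_len)
  }
  gene_model("toy7", exons = data.frame(start = starts, end = ends),
             cds_start = starts[1], cds_end = ends[n_exons],
             seq = seq, seq_start = 1L)
}
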