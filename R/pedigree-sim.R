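# Pedigree simulation: gametes with Haldane recombination, F2 populations,
# selfed families, contrasting pools and pooled read sampling.

# Random haplotype-source walk along one chromosome: n gametes x L loci of
# 0/1 indicators, switching between adjacent loci with probability r[j].
sim_gamete_sources <- function(n, r) {
  L <- length(r) + 1L
  S <- matrix(0L, n, L)
  S[, 1L] <- rbinom(n, 1L, 0.5)
  for (j in seq_len(L - 1L)) {
    S[, j + 1L] <- (S[, j] + rbinom(n, 1L, r[j])) %% 2L
  }
  S
}

# Draw n gametes from a parent's two haplotypes (vectors over all loci),
# chromosome by chromosome.
sim_gametes <- function(h1, h2, n, loci) {
  out <- matrix(0L, n, length(h1))
  for (chr in unique(loci$chrom)) {
    idx <- which(loci$chrom == chr)
    r <- haldane(diff(loci$pos_cM[idx]))
    S <- sim_gamete_sources(n, r)
    g <- matrix(h1[idx], n, length(idx), byrow = TRUE)
    m2 <- matrix(h2[idx], n, length(idx), byrow = TRUE)
    g[S == 1L] <- m2[S == 1L]
    out[, idx] <- g
  }
  out
}

new_population <- function(loci, hapA, hapB, arch, generation, family,
                           noise_sd = 0, stress = FALSE, seed = NULL) {
  n <- nrow(hapA)
  ids <- sprintf("%s_%s%04d", generation, ifelse(family == "", "", paste0(family, "_")), seq_len(n))
  pheno <- phenotype_individuals(loci, hapA, hapB, arch,
                                 noise_sd = noise_sd, stress = stress,
                                 seed = seed)
  structure(
    list(
      loci = loci, hapA = hapA, hapB = hapB, arch = arch,
      generation = generation, family = family,
      phenotype = bind_cols(tibble(id = ids), pheno)
    ),
    class = "anthomap_pop"
  )
}

phenotype_individuals <- function(loci, hapA, hapB, arch, noise_sd = 0,
                                  stress = FALSE, seed = NULL) {
  dos <- causal_dosage_matrix(loci, hapA, hapB)
  score <- latent_score(as_tibble(dos), stress = stress, arch = arch)
  cls <- classify_colour(score, arch, noise_sd = noise_sd, seed = seed)
  bind_cols(as_tibble(dos), tibble(score = score), cls)
}

# n x 4 matrix of functional-allele dosages at the causal loci.
causal_dosage_matrix <- function(loci, hapA, hapB) {
  causal <- loci[loci$is_causal, ]
  red <- hapA[, causal$.locus, drop = FALSE] + hapB[, causal$.locus, drop = FALSE]
  fun <- red
  flip <- causal$functional_source == "green_parent"
  fun[, flip] <- 2L - red[, flip, drop = FALSE]
  colnames(fun) <- causal$locus_name
  fun
}

#' Simulate an F2 population from a red x green cross
#'
#' The parents are opposite homozygotes at every marker and causal locus, so
#' the F1 is uniformly heterozygous and each F2 results from two independent
#' F1 gametes. Gametes follow a Markov walk along each chromosome with
#' inter-locus recombination fractions from the Haldane map function.
#' Phenotypes are assigned with the epistatic trait model.
#'
#' @param n Number of F2 individuals.
#' @param map Marker map from [marker_map()].
#' @param arch Causal architecture from [genetic_architecture()].
#' @param noise_sd Phenotype noise passed to [classify_colour()]. Default 0.
#' @param stress Stressed growth conditions. Default FALSE.
#' @param seed Optional integer seed.
#' @return An `anthomap_pop`: list with the locus table (`loci`), two n x L
#'   haplotype matrices of red-parent-allele indicators (`hapA`, `hapB`),
#'   the architecture, and a `phenotype` tibble (id, causal dosages, latent
#'   score, colour class).
#' @examples
#' pop <- simulate_f2(50, marker_map(n_markers = 20), seed = 1)
#' dplyr::count(pop$phenotype, colour_class)
#' @export
simulate_f2 <- function(n, map = marker_map(), arch = genetic_architecture(),
                        noise_sd = 0, stress = FALSE, seed = NULL) {
  if (nrow(map) == 0) abort("empty marker map")
  loci <- sim_loci(map, arch)
  run <- function() {
    # F1 haplotypes are all-red (1) / all-green (0); a gamete is then just
    # the source-walk indicator itself.
    hapA <- matrix(0L, n, nrow(loci))
    hapB <- matrix(0L, n, nrow(loci))
    if (n > 0) {
      for (chr in unique(loci$chrom)) {
        idx <- which(loci$chrom == chr)
        r <- haldane(diff(loci$pos_cM[idx]))
        hapA[, idx] <- sim_gamete_sources(n, r)
        hapB[, idx] <- sim_gamete_sources(n, r)
      }
    }
    new_population(loci, hapA, hapB, arch, generation = "F2", family = "",
                   noise_sd = noise_sd, stress = stress)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Self one individual to produce a family
#'
#' Generates `n_offspring` progeny of a single parent by drawing two
#' independent recombinant gametes per offspring from the parent's
#' haplotypes. Heterozygosity halves in expectation with each round of
#' selfing.
#'
#' @param pop An `anthomap_pop`.
#' @param parent Id (character) or row index of the parent individual.
#' @param n_offspring Family size.
#' @param generation Label for the offspring generation (e.g. `"F3"`).
#'   Default increments the numeric suffix of the parent generation.
#' @param family Family label; defaults to the parent id.
#' @inheritParams simulate_f2
#' @return An `anthomap_pop` for the selfed family.
#' @export
self_generation <- function(pop, parent, n_offspring, generation = NULL,
                            family = NULL, noise_sd = 0, stress = FALSE,
                            seed = NULL) {
  i <- if (is.character(parent)) match(parent, pop$phenotype$id) else parent
  if (is.na(i) || i < 1 || i > nrow(pop$hapA)) abort("unknown parent")
  if (is.null(generation)) {
    g <- suppressWarnings(as.integer(sub("^F", "", strsplit(pop$generation, "_")[[1]][1])))
    generation <- if (is.na(g)) "self" else paste0("F", g + 1L)
  }
  family <- family %||% pop$phenotype$id[i]
  h1 <- pop$hapA[i, ]
  h2 <- pop$hapB[i, ]
  run <- function() {
    gamA <- sim_gametes(h1, h2, n_offspring, pop$loci)
    gamB <- sim_gametes(h1, h2, n_offspring, pop$loci)
    new_population(pop$loci, gamA, gamB, pop$arch, generation = generation,
                   family = family, noise_sd = noise_sd, stress = stress)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Red-parent allele dosages of a population
#'
#' @param pop An `anthomap_pop`.
#' @param loci_ids Optional character vector of locus ids to extract.
#' @return Tibble: one row per individual (`id` column), one column per locus
#'   with the 0/1/2 dosage of the red-parent allele.
#' @export
dosages <- function(pop, loci_ids = NULL) {
  d <- pop$hapA + pop$hapB
  colnames(d) <- pop$loci$id
  if (!is.null(loci_ids)) {
    miss <- setdiff(loci_ids, colnames(d))
    if (length(miss)) abort(paste("unknown loci:", paste(miss, collapse = ", ")))
    d <- d[, loci_ids, drop = FALSE]
  }
  bind_cols(tibble(id = pop$phenotype$id), as_tibble(d))
}

#' @export
print.anthomap_pop <- function(x, ...) {
  cat("<anthomap_pop>", x$generation,
      if (nzchar(x$family)) paste0("family ", x$family) else "",
      "-", nrow(x$hapA), "individuals x", nrow(x$loci), "loci\n")
  print(dplyr::count(x$phenotype, .data$colour_class))
  invisible(x)
}

#' Choose contrasting pools from a phenotyped population
#'
#' The high (red) pool collects the `k_high` most intensely pigmented
#' non-green plants, ranked by latent score plus optional scoring noise
#' (visual intensity ranking is imprecise in the field); ties are broken by a
#' seeded shuffle. The low pool is either a random draw from the green-class
#' plants (`extreme_vs_random`, the classic design) or the bottom `k_low` of
#' the same ranking (`extreme_vs_extreme`, used for families that segregate
#' two red intensities and have no green class).
#'
#' @param pop An `anthomap_pop`.
#' @param k_high,k_low Pool sizes. Default 50 each.
#' @param mode `"extreme_vs_random"` or `"extreme_vs_extreme"`.
#' @param score_noise_sd Gaussian noise added to the latent score before
#'   ranking. Default 0.
#' @param seed Optional integer seed.
#' @return List with class `anthomap_pools`: character vectors `high`, `low`.
#' @export
select_pools <- function(pop, k_high = 50, k_low = 50,
                         mode = c("extreme_vs_random", "extreme_vs_extreme"),
                         score_noise_sd = 0, seed = NULL) {
  mode <- match.arg(mode)
  ph <- pop$phenotype
  run <- function() {
    rank_score <- ph$latent + rnorm(nrow(ph), 0, score_noise_sd) +
      runif(nrow(ph), 0, 1e-9) # seeded tie-break
    non_green <- which(ph$colour_class != "green")
    if (length(non_green) < k_high) {
      abort(sprintf(
        "cannot fill the high pool: %d non-green plants available, %d needed",
        length(non_green), k_high
      ))
    }
    high <- non_green[order(rank_score[non_green], decreasing = TRUE)][seq_len(k_high)]
    if (mode == "extreme_vs_random") {
      greens <- which(ph$colour_class == "green")
      if (length(greens) < k_low) {
        abort(sprintf(
          "cannot fill the green pool: %d green plants available, %d needed",
          length(greens), k_low
        ))
      }
      low <- sample(greens, k_low)
    } else {
      rest <- setdiff(seq_len(nrow(ph)), high)
      if (length(rest) < k_low) abort("not enough plants for the low pool")
      low <- rest[order(rank_score[rest])][seq_len(k_low)]
    }
    structure(list(high = ph$id[high], low = ph$id[low]),
              class = "anthomap_pools")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Sample pooled sequencing read counts at every marker
#'
#' For each SNP the pooled alternate-allele (red-parent allele) frequency is
#' the mean allele dosage of the pooled individuals. Read depth is drawn per
#' SNP and pool from a negative binomial with mean `mean_depth` and the given
#' `dispersion` (Poisson when `dispersion = Inf`), emulating the uneven
#' coverage of pooled RNA-seq. Alternate read counts are binomial at the
#' error-perturbed frequency `p (1 - e) + (1 - p) e`.
#'
#' @param pop An `anthomap_pop`.
#' @param pools An `anthomap_pools` from [select_pools()].
#' @param mean_depth Mean read depth per SNP and pool. Default 50.
#' @param dispersion Negative-binomial size parameter. Default 10.
#' @param error_rate Per-read error rate, in `[0, 0.5)`. Default 0.002.
#' @param seed Optional integer seed.
#' @return Pool-count tibble with columns `chrom`, `pos_bp`, `id`, `ref`,
#'   `alt`, `high_ref`, `high_alt`, `low_ref`, `low_alt`. The alternate
#'   allele is the red-parent allele.
#' @export
sample_pool_reads <- function(pop, pools, mean_depth = 50, dispersion = 10,
                              error_rate = 0.002, seed = NULL) {
  if (length(pools$high) == 0 || length(pools$low) == 0) {
    abort("pools must be non-empty")
  }
  if (error_rate < 0 || error_rate >= 0.5) abort("`error_rate` must be in [0, 0.5)")
  if (mean_depth <= 0) abort("`mean_depth` must be positive")
  idx <- function(ids) match(ids, pop$phenotype$id)
  pool_freq <- function(ids) {
    i <- idx(ids)
    colSums(pop$hapA[i, , drop = FALSE] + pop$hapB[i, , drop = FALSE]) /
      (2 * length(i))
  }
  p_high <- pool_freq(pools$high)
  p_low <- pool_freq(pools$low)
  L <- nrow(pop$loci)
  run <- function() {
    draw_depth <- function() {
      if (is.infinite(dispersion)) rpois(L, mean_depth)
      else rnbinom(L, mu = mean_depth, size = dispersion)
    }
    one_pool <- function(p) {
      d <- draw_depth()
      a <- rbinom(L, d, p * (1 - error_rate) + (1 - p) * error_rate)
      list(ref = d - a, alt = a)
    }
    hi <- one_pool(p_high)
    lo <- one_pool(p_low)
    tibble(
      chrom = pop$loci$chrom,
      pos_bp = pop$loci$pos_bp,
      id = pop$loci$id,
      ref = pop$loci$green_allele,
      alt = pop$loci$red_allele,
      high_ref = hi$ref, high_alt = hi$alt,
      low_ref = lo$ref, low_alt = lo$alt
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
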