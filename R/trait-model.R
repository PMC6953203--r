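#' Latent anthocyanin score of a four-locus genotype
#'
#' Implements the epistatic genotype-to-colour model. Dosages count copies of
#' the *functional* allele at each locus (0, 1 or 2). A plant homozygous for
#' the null RLL1 allele cannot make anthocyanin at all and scores 0 (green)
#' regardless of the other three loci. Otherwise the dominant MYB activator
#' RLL2 contributes 2 when at least one functional copy is present, and each
#' intensifier locus contributes 1 when its suppressing allele is *absent*
#' (dosage 0, i.e. homozygous rll3 or rll4). Stress adds `stress_bonus` to any
#' plant with an intact pathway.
#'
#' @param dosage Data frame (or named list/vector for a single genotype) with
#'   columns/elements `RLL1`, `RLL2`, `RLL3`, `RLL4`, each in `{0, 1, 2}`:
#'   functional-allele dosages.
#' @param stress Logical (scalar or per-row): stressed growth conditions.
#' @param arch A [genetic_architecture()].
#' @return Integer vector of latent scores, one per row of `dosage`.
#' @examples
#' latent_score(data.frame(RLL1 = 0, RLL2 = 2, RLL3 = 0, RLL4 = 0)) # 0, green
#' latent_score(data.frame(RLL1 = 2, RLL2 = 2, RLL3 = 0, RLL4 = 0)) # 4
#' @export
latent_score <- function(dosage, stress = FALSE, arch = genetic_architecture()) {
  if (!is.data.frame(dosage)) dosage <- as_tibble(as.list(dosage))
  loci <- c("RLL1", "RLL2", "RLL3", "RLL4")
  if (!all(loci %in% names(dosage))) {
    abort("`dosage` needs columns RLL1, RLL2, RLL3, RLL4")
  }
  d <- as.matrix(dosage[loci])
  if (!all(d %in% 0:2)) abort("dosages must be 0, 1 or 2")
  stress <- rep_len(as.logical(stress), nrow(d))
  s <- 2L * (d[, "RLL2"] >= 1L) +
    1L * (d[, "RLL3"] == 0L) +
    1L * (d[, "RLL4"] == 0L) +
    arch$stress_bonus * stress
  s[d[, "RLL1"] == 0L] <- 0L
  as.integer(s)
}

#' Ordinal colour class from a latent score
#'
#' Thresholds the (optionally noise-perturbed) latent score into the four
#' ordinal classes. A plant is green when its latent value falls below the
#' first threshold; the remaining thresholds separate light_red, red and
#' dark_red. With `noise_sd = 0` the map is deterministic. The architecture's
#' `penetrance_green` leak, if non-zero, re-labels red-class plants green with
#' that probability (mis-phenotyping of weakly pigmented plants).
#'
#' @param score Integer latent scores, e.g. from [latent_score()].
#' @param arch A [genetic_architecture()].
#' @param noise_sd Standard deviation of Gaussian noise added to the score
#'   before thresholding. Must be >= 0. Default 0.
#' @param seed Optional integer seed for reproducible noise.
#' @return Tibble with columns `latent` (numeric, post-noise) and
#'   `colour_class` (ordered factor green < light_red < red < dark_red).
#' @examples
#' classify_colour(c(0, 1, 2, 3))
#' @export
classify_colour <- function(score, arch = genetic_architecture(),
                            noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  draw <- function() {
    latent <- score + if (noise_sd > 0) rnorm(length(score), 0, noise_sd) else 0
    cls <- cut(latent,
      breaks = c(-Inf, arch$class_thresholds, Inf),
      labels = colour_levels(), right = FALSE
    )
    if (arch$penetrance_green > 0) {
      leak <- runif(length(score)) < arch$penetrance_green & cls != "green"
      cls[leak] <- "green"
    }
    tibble(latent = latent,
           colour_class = factor(cls, levels = colour_levels(), ordered = TRUE))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Exhaustive genotype-to-phenotype table
#'
#' Enumerates all `3^4` dosage combinations at the four loci, under stressed
#' and unstressed conditions (162 rows), with the noise-free latent score and
#' colour class of each. Useful as documentation of the epistasis rules and as
#' a test surface: every row with RLL1 dosage 0 is green.
#'
#' @param arch A [genetic_architecture()].
#' @return Tibble with columns `RLL1`-`RLL4`, `stress`, `score`, `colour_class`.
#' @export
enumerate_phenotype_table <- function(arch = genetic_architecture()) {
  grid <- expand_grid(
    RLL1 = 0:2, RLL2 = 0:2, RLL3 = 0:2, RLL4 = 0:2,
    stress = c(FALSE, TRUE)
  )
  # penetrance/noise intentionally off: this is the deterministic map
  arch0 <- arch
  arch0$penetrance_green <- 0
  grid$score <- latent_score(grid, stress = grid$stress, arch = arch0)
  grid$colour_class <- classify_colour(grid$score, arch0)$colour_class
  grid
}
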