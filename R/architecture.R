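#' Define a four-locus leaf-colour genetic architecture
#'
#' An architecture bundles the positions and parental origin of the four
#' causal loci together with the parameters of the genotype-to-colour map:
#' the stress bonus added when the anthocyanin pathway is intact, and the
#' latent-score thresholds that separate the four ordinal colour classes.
#'
#' @param loci Data frame with one row per causal locus and columns
#'   `name` (`"RLL1"`, `"RLL2"`, `"RLL3"`, `"RLL4"`), `chrom` (integer 1-9),
#'   `pos_bp`, `pos_cM`, and `functional_source` (`"red_parent"` or
#'   `"green_parent"`): which parent carries the *functional* allele.
#'   Defaults to [rll_loci()].
#' @param stress_bonus Integer added to the latent score of plants with an
#'   intact pathway (functional RLL1) under stress conditions. Default 1.
#' @param class_thresholds Three strictly increasing numbers cutting the
#'   latent score into green / light_red / red / dark_red. Default `c(1, 2, 3)`.
#' @param penetrance_green Probability that a plant with a red-class latent
#'   score is nonetheless phenotyped green (mis-scoring of weakly pigmented
#'   plants). Default 0 (complete penetrance).
#'
#' @return An object of class `anthomap_arch`: a list with elements `loci`
#'   (tibble), `stress_bonus`, `class_thresholds`, `penetrance_green`.
#' @examples
#' arch <- genetic_architecture()
#' arch$loci
#' @export
genetic_architecture <- function(loci = rll_loci(),
                                 stress_bonus = 1L,
                                 class_thresholds = c(1, 2, 3),
                                 penetrance_green = 0) {
  loci <- as_tibble(loci)
  required <- c("name", "chrom", "pos_bp", "pos_cM", "functional_source")
  if (!all(required %in% names(loci))) {
    abort(paste0("`loci` must have columns: ", paste(required, collapse = ", ")))
  }
  if (nrow(loci) != 4L || anyDuplicated(loci$name) > 0L) {
    abort("an architecture needs exactly four causal loci with distinct names")
  }
  if (!setequal(loci$name, c("RLL1", "RLL2", "RLL3", "RLL4"))) {
    abort("locus names must be RLL1, RLL2, RLL3 and RLL4")
  }
  if (!all(loci$functional_source %in% c("red_parent", "green_parent"))) {
    abort("`functional_source` must be 'red_parent' or 'green_parent'")
  }
  if (!all(loci$chrom %in% 1:9) || any(loci$pos_bp < 0) || any(loci$pos_cM < 0)) {
    abort("locus positions must be non-negative and on chromosomes 1-9")
  }
  if (length(class_thresholds) != 3L || any(diff(class_thresholds) <= 0)) {
    abort("`class_thresholds` must be three strictly increasing numbers")
  }
  if (penetrance_green < 0 || penetrance_green > 1) {
    abort("`penetrance_green` must be in [0, 1]")
  }
  structure(
    list(
      loci = loci[order(match(loci$name, c("RLL1", "RLL2", "RLL3", "RLL4"))), ],
      stress_bonus = as.integer(stress_bonus),
      class_thresholds = as.numeric(class_thresholds),
      penetrance_green = penetrance_green
    ),
    class = "anthomap_arch"
  )
}

#' Default placement of the four leaf-colour loci
#'
#' RLL1 sits in its fine-mapped interval on chromosome 5 (335.69-337.92 Mb),
#' RLL2 elsewhere on chromosome 5, RLL3 on chromosome 4 and RLL4 on
#' chromosome 9. The red parent donates the functional alleles of the two
#' activators (RLL1, RLL2) and the *defective* alleles of the two
#' intensifier-suppressors, i.e. the green parent carries functional RLL3
#' and RLL4.
#'
#' @return Tibble with one row per locus.
#' @export
rll_loci <- function() {
  tibble(
    name = c("RLL1", "RLL2", "RLL3", "RLL4"),
    chrom = c(5L, 5L, 4L, 9L),
    pos_bp = c(336800000, 120000000, 200000000, 100000000),
    pos_cM = NA_real_, # filled from the map scale below
    functional_source = c("red_parent", "red_parent",
                          "green_parent", "green_parent")
  ) |>
    mutate(pos_cM = .data$pos_bp / 1e6 * 0.5)
}

#' @export
print.anthomap_arch <- function(x, ...) {
  cat("<anthomap_arch> four-locus leaf-colour architecture\n")
  cat("  stress bonus:", x$stress_bonus,
      " thresholds:", paste(x$class_thresholds, collapse = "/"),
      " green penetrance leak:", x$penetrance_green, "\n")
  print(x$loci)
  invisible(x)
}

colour_levels <- function() c("green", "light_red", "red", "dark_red")
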