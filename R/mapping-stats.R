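# Segregation statistics, marker-trait association, segregating-family
# classification, fixed-background family selection and recessive-class
# fine mapping.

new_seg_test <- function(statistic, df, p.value, method, observed,
                         expected = NULL) {
  structure(
    list(statistic = statistic, df = df, p.value = p.value, method = method,
         observed = observed, expected = expected),
    class = "anthomap_seg_test"
  )
}

#' @export
print.anthomap_seg_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  X-squared = %.4f, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
tidy.anthomap_seg_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method)
}

#' @export
glance.anthomap_seg_test <- function(x, ...) tidy(x)

#' Chi-square goodness of fit to a Mendelian ratio
#'
#' Tests observed phenotype class counts against a hypothesized segregation
#' ratio (such as 3:1) with the Pearson chi-square statistic,
#' `sum((obs - exp)^2 / exp)`, on `classes - 1` degrees of freedom. No
#' continuity correction is applied by default; `correct = TRUE` enables the
#' Yates correction for two classes.
#'
#' @param counts Non-negative integer counts, one per phenotype class.
#' @param ratio Positive ratio terms of the same length, e.g. `c(3, 1)`.
#' @param correct Apply the Yates continuity correction (two classes only).
#' @return An `anthomap_seg_test` with `tidy()`/`glance()` methods.
#' @examples
#' chisq_ratio(c(4058, 1372), c(3, 1)) # p ~ 0.65
#' @export
chisq_ratio <- function(counts, ratio = c(3, 1), correct = FALSE) {
  if (length(counts) != length(ratio)) abort("ratio arity mismatch")
  if (any(ratio <= 0)) abort("ratio terms must be positive")
  total <- sum(counts)
  if (total <= 0) abort("total count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected < 1)) abort("expected count below 1 in some class")
  if (any(expected < 5)) warn("expected count below 5 in some class")
  dev <- abs(counts - expected)
  if (correct) {
    if (length(counts) != 2) abort("Yates correction applies to two classes only")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- length(counts) - 1L
  new_seg_test(stat, df, pchisq(stat, df, lower.tail = FALSE),
               sprintf("Chi-square goodness of fit to a %s ratio",
                       paste(ratio, collapse = ":")),
               observed = counts, expected = expected)
}

#' Chi-square test of marker-trait association
#'
#' Pearson chi-square test of independence on the genotype x phenotype
#' contingency table, with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param data Data frame with one row per individual.
#' @param genotype,phenotype Columns (tidy-eval) holding the marker genotype
#'   and the phenotype class of each individual.
#' @param correct Yates continuity correction for 2 x 2 tables. Default FALSE.
#' @return An `anthomap_seg_test`.
#' @examples
#' df <- data.frame(g = rep(c("AA", "Aa", "aa"), c(50, 100, 50)),
#'                  ph = rep(c("red", "red", "green"), c(50, 100, 50)))
#' marker_association(df, g, ph)
#' @export
marker_association <- function(data, genotype, phenotype, correct = FALSE) {
  g <- factor(pull(data, {{ genotype }}))
  p <- factor(pull(data, {{ phenotype }}))
  tab <- table(g, p)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("degenerate table: need at least two genotype and two phenotype classes")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("empty row or column in the contingency table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - expected)
  if (correct) {
    if (!all(dim(tab) == 2)) abort("Yates correction applies to 2 x 2 tables only")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  new_seg_test(stat, df, pchisq(stat, df, lower.tail = FALSE),
               "Chi-square test of marker-trait independence",
               observed = tab, expected = expected)
}

#' Is a family segregating for leaf colour?
#'
#' A family counts as segregating when at least two phenotype classes each
#' reach both a minimum count and a minimum frequency, which keeps rare
#' mis-phenotyped plants from flagging a fixed family.
#'
#' @param counts Named or unnamed non-negative counts per phenotype class.
#' @param min_minor_count Minimum plants in a minor class. Default 3.
#' @param min_minor_freq Minimum frequency of a minor class. Default 0.05.
#' @return Logical flag.
#' @examples
#' classify_segregating(c(light_red = 195, dark_red = 75)) # TRUE
#' classify_segregating(c(red = 99, green = 1)) # FALSE
#' @export
classify_segregating <- function(counts, min_minor_count = 3,
                                 min_minor_freq = 0.05) {
  total <- sum(counts)
  if (total <= 0) abort("total count must be positive")
  ok <- counts >= min_minor_count & counts / total >= min_minor_freq
  sum(ok) >= 2
}

#' Select individuals with a fixed genetic background
#'
#' Filters a population to the individuals whose functional-allele dosage at
#' each constrained causal locus matches the requested state. This is the
#' family-selection step of a sequential mapping campaign: fixing the loci
#' already cloned isolates the segregation of the next one.
#'
#' @param pop An `anthomap_pop`.
#' @param constraints Named list/character vector mapping locus names to one
#'   of `"homozygous_functional"`, `"homozygous_null"`, `"homozygous"` (either
#'   homozygote) or `"heterozygous"`.
#' @return Character vector of individual ids, in population order.
#' @examples
#' pop <- simulate_f2(100, marker_map(n_markers = 10), seed = 1)
#' select_fixed_background(pop, list(RLL1 = "heterozygous",
#'                                   RLL2 = "homozygous_functional"))
#' @export
select_fixed_background <- function(pop, constraints) {
  states <- c("homozygous_functional", "homozygous_null", "homozygous",
              "heterozygous")
  constraints <- as.list(constraints)
  unknown <- setdiff(names(constraints), pop$loci$locus_name[pop$loci$is_causal])
  if (length(unknown)) {
    abort(paste("unknown locus name(s):", paste(unknown, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(pop$phenotype))
  for (locus in names(constraints)) {
    state <- match.arg(constraints[[locus]], states)
    d <- pop$phenotype[[locus]]
    keep <- keep & switch(state,
      homozygous_functional = d == 2L,
      homozygous_null = d == 0L,
      homozygous = d != 1L,
      heterozygous = d == 1L
    )
  }
  pop$phenotype$id[keep]
}

#' Fine mapping from recessive-class individuals
#'
#' Given individuals selected for the recessive phenotype class, any marker
#' at which an individual is not homozygous for the donor (recessive-parent)
#' allele carries a recombination breakpoint that excludes the causal locus.
#' The candidate region is found at sub-marker resolution: a marker is
#' excluded when more than `max_errors` individuals are recombinant there,
#' and the gap between two adjacent markers is excluded when more than
#' `max_errors` single individuals are recombinant at *both* its flanks (only
#' then does some individual's foreign segment span the gap). The reported
#' interval is the widest run of unexcluded markers/gaps, extended outward to
#' the innermost excluded flanking markers (the locus cannot lie beyond
#' them). With zero phenotyping error and `max_errors = 0` the interval is
#' guaranteed to contain the causal locus, even when breakpoints fall in the
#' two gaps immediately flanking it.
#'
#' @param geno Matrix or data frame of donor-allele dosages (0/1/2), one row
#'   per recessive-class individual, columns ordered by marker position.
#' @param positions Marker positions in bp (same order as columns).
#' @param chrom Chromosome label carried into the result. Default `NA`.
#' @param max_errors Tolerated recombinant count inside the interval
#'   (allowance for mis-phenotyped plants). Default 0.
#' @return An `anthomap_fine_map`: list with `interval` (tibble: chrom,
#'   start_bp, end_bp, n_markers_core) and `markers` (tibble of per-marker
#'   recombinant counts).
#' @export
fine_map_recessive <- function(geno, positions, chrom = NA_integer_,
                               max_errors = 0) {
  geno <- as.matrix(geno)
  if (nrow(geno) < 1) abort("need at least one recessive-class individual")
  if (ncol(geno) != length(positions)) {
    abort("`positions` must match the marker columns")
  }
  if (is.unsorted(positions)) abort("markers must be ordered by position")
  rec_mat <- geno != 2L
  M <- length(positions)
  recomb <- colSums(rec_mat)
  ok_marker <- recomb <= max_errors
  if (M > 1) {
    spans <- colSums(rec_mat[, -M, drop = FALSE] & rec_mat[, -1, drop = FALSE])
    ok_gap <- spans <= max_errors
  } else {
    ok_gap <- logical(0)
  }
  # interleave markers and gaps: cells m1 g1 m2 g2 ... mM
  cells <- logical(2L * M - 1L)
  cells[seq(1L, 2L * M - 1L, by = 2L)] <- ok_marker
  if (M > 1) cells[seq(2L, 2L * M - 2L, by = 2L)] <- ok_gap
  if (!any(cells)) {
    abort("every marker carries recombinants: phenotype and genotype are inconsistent")
  }
  # hull over every unexcluded cell: the minimal interval the exclusion
  # logic can certify to contain the locus
  a <- min(which(cells)); b <- max(which(cells))
  left <- if (a == 1L) 1L else as.integer(ceiling((a - 1L) / 2L))
  right <- if (b == 2L * M - 1L) M else as.integer(floor((b + 1L) / 2L) + 1L)
  core <- which(ok_marker)
  structure(
    list(
      interval = tibble(
        chrom = chrom,
        start_bp = positions[left],
        end_bp = positions[right],
        n_markers_core = length(core)
      ),
      markers = tibble(
        chrom = chrom, pos_bp = positions, recombinants = recomb,
        in_core = seq_len(M) %in% core
      )
    ),
    class = "anthomap_fine_map"
  )
}

#' @export
print.anthomap_fine_map <- function(x, ...) {
  cat("<anthomap_fine_map>\n")
  print(x$interval)
  invisible(x)
}

#' @export
tidy.anthomap_fine_map <- function(x, ...) x$markers

#' @export
glance.anthomap_fine_map <- function(x, ...) {
  mutate(x$interval, width_bp = .data$end_bp - .data$start_bp)
}
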