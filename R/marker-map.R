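#' Haldane map function
#'
#' Converts a map distance in centiMorgans into a recombination fraction
#' assuming no crossover interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM Non-negative map distance(s) in cM.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane(10) # ~0.0906
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) abort("map distances must be non-negative")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Chromosome lengths on the lettuce v8 assembly scale
#'
#' @return Named numeric vector (bp) for chromosomes "1".."9".
#' @export
lettuce_chrom_lengths <- function() {
  stats::setNames(
    c(215, 240, 258, 369, 360, 182, 194, 306, 203) * 1e6,
    as.character(1:9)
  )
}

#' Build a nine-chromosome marker map
#'
#' Evenly spaces `n_markers` biallelic markers along each of the nine lettuce
#' chromosomes (lengths on the v8 assembly scale) and assigns genetic
#' positions with a constant bp-to-cM scaling. Each marker records the red-
#' and green-parent alleles; parents are opposite homozygotes everywhere.
#'
#' @param n_markers Markers per chromosome. Default 200.
#' @param cm_per_mb Genetic map expansion, cM per Mb. Default 0.5.
#' @param chrom_lengths_bp Named numeric vector of chromosome lengths in bp
#'   (names "1".."9"). Defaults to the v8-scale lengths.
#' @return An `anthomap_map`: tibble with columns `chrom`, `id`, `pos_bp`,
#'   `pos_cM`, `red_allele`, `green_allele`, plus a `chrom_lengths` attribute.
#' @examples
#' map <- marker_map(n_markers = 50)
#' dplyr::count(map, chrom)
#' @export
marker_map <- function(n_markers = 200,
                       cm_per_mb = 0.5,
                       chrom_lengths_bp = lettuce_chrom_lengths()) {
  if (n_markers < 1) abort("`n_markers` must be at least 1")
  bases <- c("A", "C", "G", "T")
  map <- imap(chrom_lengths_bp, function(len, chrom) {
    pos <- round(seq(len / n_markers / 2, len - len / n_markers / 2,
                     length.out = n_markers))
    k <- seq_len(n_markers)
    tibble(
      chrom = as.integer(chrom),
      id = sprintf("chr%s_%04d", chrom, k),
      pos_bp = pos,
      pos_cM = pos / 1e6 * cm_per_mb,
      red_allele = bases[(k - 1L) %% 4L + 1L],
      green_allele = bases[k %% 4L + 1L]
    )
  }) |> list_rbind()
  structure(map, chrom_lengths = chrom_lengths_bp, cm_per_mb = cm_per_mb,
            class = c("anthomap_map", class(map)))
}

# Merge causal loci from an architecture into a marker map, producing the
# full ordered locus table used by the simulator. Causal loci get dedicated
# rows (is_causal = TRUE) inserted at their map position.
sim_loci <- function(map, arch) {
  cm_per_mb <- attr(map, "cm_per_mb") %||% 0.5
  causal <- arch$loci |>
    mutate(
      id = .data$name,
      pos_cM = if_else(is.na(.data$pos_cM), .data$pos_bp / 1e6 * cm_per_mb,
                       .data$pos_cM),
      red_allele = "A", green_allele = "T",
      is_causal = TRUE
    ) |>
    select("chrom", "id", "pos_bp", "pos_cM", "red_allele", "green_allele",
           "is_causal", locus_name = "name",
           functional_source = "functional_source")
  lens <- attr(map, "chrom_lengths")
  if (!is.null(lens)) {
    known <- lens[as.character(causal$chrom)]
    bad <- !is.na(known) & causal$pos_bp > known
    if (any(bad)) abort("causal locus position outside its chromosome")
  }
  markers <- as_tibble(map) |>
    mutate(is_causal = FALSE, locus_name = NA_character_,
           functional_source = NA_character_)
  bind_rows(markers, causal) |>
    arrange(.data$chrom, .data$pos_bp) |>
    mutate(.locus = row_number())
}
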