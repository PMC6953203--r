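# The delta SNP-index scan: per-pool SNP indices, pool differences, window
# smoothing, Monte-Carlo null confidence bands and candidate-region calling.

#' Per-pool SNP index
#'
#' The SNP index of a pool at a SNP is the fraction of reads carrying the
#' alternate (red-parent) allele. SNPs with depth below `min_depth` in a pool
#' are flagged `filtered` and excluded downstream.
#'
#' @param counts Pool-count tibble as produced by [sample_pool_reads()] or
#'   [read_allele_counts()].
#' @param min_depth Minimum per-pool depth. Default 10.
#' @return Tibble with one row per SNP and pool: `chrom`, `pos_bp`, `id`,
#'   `pool` ("high"/"low"), `depth`, `index`, `filtered`.
#' @examples
#' counts <- tibble::tibble(chrom = 1, pos_bp = 100, id = "m1",
#'   ref = "A", alt = "T", high_ref = 10, high_alt = 30,
#'   low_ref = 35, low_alt = 5)
#' snp_index(counts)
#' @export
snp_index <- function(counts, min_depth = 10) {
  if (min_depth < 1) abort("`min_depth` must be >= 1")
  counts |>
    select("chrom", "pos_bp", "id", "high_ref", "high_alt", "low_ref", "low_alt") |>
    pivot_longer(c("high_ref", "high_alt", "low_ref", "low_alt"),
                 names_to = c("pool", "allele"), names_sep = "_") |>
    pivot_wider(names_from = "allele", values_from = "value") |>
    mutate(
      depth = .data$ref + .data$alt,
      index = if_else(.data$depth > 0, .data$alt / .data$depth, NA_real_),
      filtered = .data$depth < min_depth
    ) |>
    select("chrom", "pos_bp", "id", "pool", "depth", "index", "filtered")
}

#' Delta SNP-index between the two pools
#'
#' `delta = index_high - index_low`, signed with the red-parent allele as the
#' alternate allele: positive values mean the red pool is enriched for the
#' red-parent allele. Only SNPs unfiltered in both pools are retained.
#'
#' @param index Output of [snp_index()] containing both pools, or the high
#'   pool track if `low` is given.
#' @param low Optional low-pool track when the two pools come as separate
#'   tibbles (must share SNP coordinates).
#' @return Tibble: `chrom`, `pos_bp`, `id`, `depth_high`, `depth_low`,
#'   `index_high`, `index_low`, `delta`.
#' @export
delta_index <- function(index, low = NULL) {
  if (!is.null(low)) {
    index <- bind_rows(mutate(index, pool = "high"), mutate(low, pool = "low"))
  }
  wide <- index |>
    pivot_wider(
      id_cols = c("chrom", "pos_bp", "id"),
      names_from = "pool",
      values_from = c("depth", "index", "filtered")
    )
  if (!all(c("filtered_high", "filtered_low") %in% names(wide)) ||
      anyNA(wide$filtered_high) || anyNA(wide$filtered_low)) {
    abort("the two pool tracks do not share SNP coordinates")
  }
  wide |>
    filter(!.data$filtered_high, !.data$filtered_low) |>
    mutate(delta = .data$index_high - .data$index_low) |>
    select("chrom", "pos_bp", "id", "depth_high", "depth_low",
           "index_high", "index_low", "delta")
}

#' Sliding-window smoothing of the delta-index track
#'
#' Tiles each chromosome with windows of `window_bp` advanced by `step_bp`
#' and averages the per-SNP delta inside each window. Windows with fewer than
#' `min_snps` SNPs are flagged unusable. Defaults suit the default marker
#' density (about one marker per 1-2 Mb).
#'
#' @param track Per-SNP delta tibble from [delta_index()].
#' @param window_bp Window width in bp. Default 2e7.
#' @param step_bp Step between window starts in bp. Default 5e6.
#' @param min_snps Minimum SNPs per usable window. Default 5.
#' @return Tibble: `chrom`, `start_bp`, `end_bp` (1-based inclusive), `mid_bp`,
#'   `n_snps`, `mean_delta`, `mean_depth` (per-pool mean of the pooled mean
#'   depth), `usable`.
#' @export
window_smooth <- function(track, window_bp = 2e7, step_bp = 5e6, min_snps = 5) {
  if (!(window_bp >= step_bp && step_bp > 0)) {
    abort("need window_bp >= step_bp > 0")
  }
  one_chrom <- function(tr) {
    span_end <- max(tr$pos_bp)
    starts <- seq(1, max(1, span_end - window_bp + 1), by = step_bp)
    purrr::map(starts, function(s) {
      e <- s + window_bp - 1
      inside <- tr[tr$pos_bp >= s & tr$pos_bp <= e, ]
      tibble(
        chrom = tr$chrom[1], start_bp = s, end_bp = e, mid_bp = (s + e) / 2,
        n_snps = nrow(inside),
        mean_delta = if (nrow(inside)) mean(inside$delta) else NA_real_,
        mean_depth = if (nrow(inside)) {
          mean((inside$depth_high + inside$depth_low) / 2)
        } else NA_real_
      )
    }) |> list_rbind()
  }
  track |>
    group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map(one_chrom) |>
    list_rbind() |>
    mutate(usable = .data$n_snps >= min_snps)
}

# Null replicates of the windowed delta statistic at one depth: each
# replicate draws a fresh pair of pool compositions (the individuals are
# shared by all linked SNPs of a window) and averages binomial read noise
# over `m` SNPs.
r_null_delta <- function(n_reps, pool_n_high, pool_n_low, depth,
                         dosage_probs, m = 1, error_rate = 0) {
  pool_freq <- function(n_pool) {
    cnt <- rmultinom(n_reps, n_pool, dosage_probs)
    (cnt[2, ] + 2 * cnt[3, ]) / (2 * n_pool)
  }
  p_h <- pool_freq(pool_n_high)
  p_l <- pool_freq(pool_n_low)
  adj <- function(p) p * (1 - error_rate) + (1 - p) * error_rate
  idx_mean <- function(p) {
    reads <- matrix(rbinom(n_reps * m, depth, rep(adj(p), m)), n_reps, m)
    rowMeans(reads) / depth
  }
  idx_mean(p_h) - idx_mean(p_l)
}

#' Monte-Carlo null confidence bands for the delta index
#'
#' Simulates the distribution of the (windowed) delta index under the null
#' hypothesis of no trait locus: every pooled individual draws its dosage at
#' a null SNP from the generation's Mendelian distribution (F2: 1/4, 1/2,
#' 1/4; a selfed F2:3 generation: 3/8, 1/4, 3/8), pool frequencies produce
#' binomial read counts at each scheduled depth, and the delta statistic is
#' computed exactly as in the scan. Bands are empirical two-sided quantiles.
#' `snps_per_window` matches the band to the windowed statistic: the null
#' replicate shares one pool composition across the window's SNPs and
#' averages the read noise, which is how linked SNPs behave in a real pool.
#'
#' @param pool_n_high,pool_n_low Individuals per pool. Default 50.
#' @param generation `"F2"` or `"F2:3"`.
#' @param depths Numeric vector of depths at which to tabulate the band
#'   (interpolated between, clamped outside).
#' @param n_reps Null replicates per depth. Default 10000.
#' @param levels Two-sided confidence probabilities. Default `c(0.05, 0.01)`.
#' @param snps_per_window SNPs averaged per window in the statistic the band
#'   will be compared to; 1 gives the per-SNP band. Default 1.
#' @param error_rate Per-read error rate used in the null. Default 0.
#' @param seed Optional integer seed.
#' @return An `anthomap_ci` tibble: `depth`, `level`, `lower`, `upper`, with
#'   the simulation parameters stored as attributes.
#' @examples
#' simulate_null_ci(depths = 100, n_reps = 2000, seed = 1)
#' @export
simulate_null_ci <- function(pool_n_high = 50, pool_n_low = 50,
                             generation = c("F2", "F2:3"),
                             depths = c(20, 35, 50, 75, 100),
                             n_reps = 10000, levels = c(0.05, 0.01),
                             snps_per_window = 1, error_rate = 0,
                             seed = NULL) {
  generation <- match.arg(generation)
  if (n_reps < 1000) abort("`n_reps` must be at least 1000")
  if (pool_n_high < 1 || pool_n_low < 1) abort("pool sizes must be >= 1")
  if (any(depths <= 0)) abort("zero or negative depth in the schedule")
  probs <- switch(generation,
    "F2" = c(1, 2, 1) / 4,
    "F2:3" = c(3, 2, 3) / 8
  )
  run <- function() {
    purrr::map(sort(unique(depths)), function(d) {
      delta <- r_null_delta(n_reps, pool_n_high, pool_n_low, d, probs,
                            m = snps_per_window, error_rate = error_rate)
      purrr::map(levels, function(a) {
        q <- unname(quantile(delta, c(a / 2, 1 - a / 2), names = FALSE))
        tibble(depth = d, level = a, lower = q[1], upper = q[2])
      }) |> list_rbind()
    }) |> list_rbind()
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out,
    pool_n_high = pool_n_high, pool_n_low = pool_n_low,
    generation = generation, n_reps = n_reps,
    snps_per_window = snps_per_window, seed = seed,
    class = c("anthomap_ci", class(out))
  )
}

# Interpolate the band half-widths of one level at arbitrary depths.
band_at <- function(bands, depth, level) {
  b <- bands[abs(bands$level - level) < 1e-12, ]
  if (nrow(b) == 0) abort(sprintf("no band at level %s", format(level)))
  if (nrow(b) == 1) {
    return(tibble(lower = rep(b$lower, length(depth)),
                  upper = rep(b$upper, length(depth))))
  }
  tibble(
    lower = approx(b$depth, b$lower, xout = depth, rule = 2)$y,
    upper = approx(b$depth, b$upper, xout = depth, rule = 2)$y
  )
}

#' Call candidate regions from a windowed scan
#'
#' Flags windows whose |mean delta| exceeds the confidence band interpolated
#' at the window's mean depth, then merges maximal runs of at least
#' `min_consecutive` consecutive usable exceeding windows into candidate
#' regions. Unusable windows (too few SNPs) break runs.
#'
#' @param windows Windowed track from [window_smooth()].
#' @param bands An `anthomap_ci` from [simulate_null_ci()].
#' @param level Band level used for calling. Default 0.05.
#' @param min_consecutive Minimum run length. Default 3.
#' @return Tibble of regions: `chrom`, `start_bp`, `end_bp` (1-based
#'   inclusive), `peak_delta` (signed delta of largest magnitude),
#'   `n_windows`, `level`.
#' @export
call_regions <- function(windows, bands, level = 0.05, min_consecutive = 3) {
  thr <- band_at(bands, windows$mean_depth, level)
  w <- windows |>
    mutate(exceeds = .data$usable &
             (.data$mean_delta > thr$upper | .data$mean_delta < thr$lower)) |>
    mutate(exceeds = if_else(is.na(.data$exceeds), FALSE, .data$exceeds))
  out <- w |>
    group_by(.data$chrom) |>
    dplyr::group_split() |>
    purrr::map(function(wc) {
      r <- rle(wc$exceeds)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- which(r$values & r$lengths >= min_consecutive)
      purrr::map(keep, function(k) {
        block <- wc[starts[k]:ends[k], ]
        tibble(
          chrom = block$chrom[1],
          start_bp = min(block$start_bp),
          end_bp = max(block$end_bp),
          peak_delta = block$mean_delta[which.max(abs(block$mean_delta))],
          n_windows = nrow(block)
        )
      }) |> list_rbind()
    }) |>
    list_rbind()
  if (nrow(out) == 0) {
    return(tibble(chrom = integer(), start_bp = numeric(), end_bp = numeric(),
                  peak_delta = numeric(), n_windows = integer(),
                  level = numeric()))
  }
  mutate(out, level = level)
}
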