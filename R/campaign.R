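# The packaged end-to-end scenario: F2 scan, then sequential fixed-background
# family rounds that recover the loci masked by epistasis.

# Which causal loci fall inside called regions, and the windowed delta at
# each locus position.
locus_scan_summary <- function(arch, windows, regions_005, regions_001) {
  covered <- function(regions, chrom, pos) {
    any(regions$chrom == chrom & regions$start_bp <= pos & regions$end_bp >= pos)
  }
  arch$loci |>
    mutate(
      delta_at_locus = map_dbl(seq_len(dplyr::n()), function(i) {
        w <- windows |>
          filter(.data$chrom == arch$loci$chrom[i], .data$usable,
                 .data$start_bp <= arch$loci$pos_bp[i],
                 .data$end_bp >= arch$loci$pos_bp[i])
        if (nrow(w) == 0) NA_real_ else w$mean_delta[which.max(abs(w$mean_delta))]
      }),
      detected_005 = map_lgl(seq_len(dplyr::n()), function(i) {
        covered(regions_005, arch$loci$chrom[i], arch$loci$pos_bp[i])
      }),
      detected_001 = map_lgl(seq_len(dplyr::n()), function(i) {
        covered(regions_001, arch$loci$chrom[i], arch$loci$pos_bp[i])
      })
    ) |>
    select("name", "chrom", "pos_bp", "delta_at_locus",
           "detected_005", "detected_001")
}

scan_counts <- function(counts, bands, min_depth, window_bp, step_bp,
                        min_snps, min_consecutive) {
  windows <- counts |>
    snp_index(min_depth = min_depth) |>
    delta_index() |>
    window_smooth(window_bp = window_bp, step_bp = step_bp,
                  min_snps = min_snps)
  list(
    windows = windows,
    regions_005 = call_regions(windows, bands, level = 0.05,
                               min_consecutive = min_consecutive),
    regions_001 = call_regions(windows, bands, level = 0.01,
                               min_consecutive = min_consecutive)
  )
}

# Fixed-background round definitions for the sequential campaign. Each round
# fixes the already-mapped loci (either homozygote is acceptable where only
# segregation of the target must be prevented) and keeps the target locus
# heterozygous in the family parent.
campaign_rounds <- function() {
  list(
    S9 = list(target = "RLL1",
              constraints = list(RLL1 = "heterozygous",
                                 RLL2 = "homozygous_functional",
                                 RLL3 = "homozygous", RLL4 = "homozygous")),
    Q16 = list(target = "RLL2",
               constraints = list(RLL1 = "homozygous_functional",
                                  RLL2 = "heterozygous",
                                  RLL3 = "homozygous", RLL4 = "homozygous")),
    R3 = list(target = "RLL3",
              constraints = list(RLL1 = "homozygous_functional",
                                 RLL2 = "homozygous_null",
                                 RLL3 = "heterozygous",
                                 RLL4 = "homozygous")),
    Q54 = list(target = "RLL4",
               constraints = list(RLL1 = "homozygous_functional",
                                  RLL2 = "homozygous",
                                  RLL3 = "homozygous",
                                  RLL4 = "heterozygous"))
  )
}

#' Run the full sequential mapping campaign on simulated data
#'
#' Emulates the mapping study end to end: (1) simulate an F2 from the
#' red x green cross and scan contrasting pools (most intense red vs random
#' green) with the delta SNP-index; (2) for each of four sequential rounds,
#' pick an F2 plant whose genotype fixes the previously mapped loci and
#' leaves one target locus heterozygous, self it into a family, scan
#' contrasting pools from that family, and record whether the target locus
#' is recovered. The F2 scan shows the epistatic masking of the two
#' intensifier loci; the fixed-background rounds recover them one at a time.
#'
#' @param n_f2 F2 population size. Default 218.
#' @param n_family Individuals per selfed family. Default 300.
#' @param pool_size Individuals per pool. Default 50.
#' @param mean_depth Mean read depth per SNP and pool. Default 50.
#' @param dispersion,error_rate Read-sampling parameters
#'   (see [sample_pool_reads()]).
#' @param score_noise_sd Intensity-scoring noise used when ranking the F2
#'   red pool (field scoring of red intensity is imprecise). Default 1.
#' @param map,arch Marker map and architecture.
#' @param bands Optional precomputed [simulate_null_ci()] bands; computed
#'   when `NULL`.
#' @param window_bp,step_bp,min_snps,min_consecutive,min_depth Scan
#'   parameters.
#' @param n_reps Null replicates for the bands when computed here.
#' @param seed Integer seed; every stage derives its stream from it.
#' @return An `anthomap_campaign`: list with `f2` (phenotype counts, windowed
#'   track, regions, per-locus summary), `rounds` (per-round details and a
#'   `summary` tibble), and `bands`.
#' @export
run_bsa_campaign <- function(n_f2 = 218, n_family = 300, pool_size = 50,
                             mean_depth = 50, dispersion = 10,
                             error_rate = 0.002, score_noise_sd = 1,
                             map = marker_map(), arch = genetic_architecture(),
                             bands = NULL, window_bp = 2e7, step_bp = 5e6,
                             min_snps = 5, min_consecutive = 3, min_depth = 10,
                             n_reps = 10000, seed = 1) {
  seed <- as.integer(seed)
  if (is.null(bands)) {
    bands <- simulate_null_ci(
      pool_n_high = pool_size, pool_n_low = pool_size, generation = "F2",
      depths = c(20, 35, 50, 75, 100), n_reps = n_reps,
      snps_per_window = max(1, floor(window_bp / 1.8e6)),
      seed = seed + 1000L
    )
  }

  f2 <- simulate_f2(n_f2, map = map, arch = arch, seed = seed)
  pools <- select_pools(f2, k_high = pool_size, k_low = pool_size,
                        mode = "extreme_vs_random",
                        score_noise_sd = score_noise_sd, seed = seed + 1L)
  counts <- sample_pool_reads(f2, pools, mean_depth = mean_depth,
                              dispersion = dispersion,
                              error_rate = error_rate, seed = seed + 2L)
  scan <- scan_counts(counts, bands, min_depth, window_bp, step_bp,
                      min_snps, min_consecutive)
  f2_summary <- locus_scan_summary(arch, scan$windows,
                                   scan$regions_005, scan$regions_001)

  rounds <- imap(campaign_rounds(), function(rd, rname) {
    offset <- 10L * match(rname, names(campaign_rounds()))
    candidates <- select_fixed_background(f2, rd$constraints)
    if (length(candidates) == 0) {
      return(list(round = rname, target = rd$target, parent = NA_character_,
                  n_candidates = 0L, recovered = FALSE, regions = NULL))
    }
    parent <- withr::with_seed(seed + offset,
                               candidates[sample.int(length(candidates), 1)])
    fam <- self_generation(f2, parent, n_family, family = rname,
                           seed = seed + offset + 1L)
    fam_pools <- select_pools(fam, k_high = pool_size, k_low = pool_size,
                              mode = "extreme_vs_extreme",
                              seed = seed + offset + 2L)
    fam_counts <- sample_pool_reads(fam, fam_pools, mean_depth = mean_depth,
                                    dispersion = dispersion,
                                    error_rate = error_rate,
                                    seed = seed + offset + 3L)
    fam_scan <- scan_counts(fam_counts, bands, min_depth, window_bp, step_bp,
                            min_snps, min_consecutive)
    target <- arch$loci[arch$loci$name == rd$target, ]
    hit <- fam_scan$regions_001 |>
      filter(.data$chrom == target$chrom,
             .data$start_bp <= target$pos_bp,
             .data$end_bp >= target$pos_bp)
    list(round = rname, target = rd$target, parent = parent,
         n_candidates = length(candidates), recovered = nrow(hit) == 1L,
         regions = fam_scan$regions_001, windows = fam_scan$windows,
         class_counts = dplyr::count(fam$phenotype, .data$colour_class))
  })

  summary <- purrr::map(rounds, function(r) {
    tibble(round = r$round, target = r$target, parent = r$parent,
           n_candidates = r$n_candidates, recovered = r$recovered)
  }) |> list_rbind()

  structure(
    list(
      f2 = list(
        class_counts = dplyr::count(f2$phenotype, .data$colour_class),
        windows = scan$windows,
        regions_005 = scan$regions_005,
        regions_001 = scan$regions_001,
        summary = f2_summary
      ),
      rounds = rounds,
      rounds_summary = summary,
      bands = bands,
      seed = seed
    ),
    class = "anthomap_campaign"
  )
}

#' @export
print.anthomap_campaign <- function(x, ...) {
  cat("<anthomap_campaign> seed", x$seed, "\n\nF2 colour classes:\n")
  print(x$f2$class_counts)
  cat("\nF2 scan, per causal locus:\n")
  print(x$f2$summary)
  cat("\nSequential fixed-background rounds:\n")
  print(x$rounds_summary)
  invisible(x)
}
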