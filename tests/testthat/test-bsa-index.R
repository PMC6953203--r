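# The delta SNP-index scan statistic and its Monte-Carlo confidence bands.

test_that("snp_index computes allele fractions and applies the depth filter", {
  cnt <- toy_counts(1, high_alt = 30, high_ref = 0, low_alt = 0, low_ref = 30)
  si <- snp_index(cnt)
  expect_equal(si$index[si$pool == "high"], 1.0)
  expect_equal(si$index[si$pool == "low"], 0.0)
  cnt2 <- toy_counts(1, high_alt = 5, high_ref = 3, low_alt = 10, low_ref = 10)
  si2 <- snp_index(cnt2, min_depth = 10)
  expect_true(si2$filtered[si2$pool == "high"])
  expect_false(si2$filtered[si2$pool == "low"])
  expect_error(snp_index(cnt, min_depth = 0), ">= 1")
})

test_that("delta_index is the signed pool difference and demands shared coordinates", {
  cnt <- toy_counts(5, high_alt = 90, high_ref = 10, low_alt = 10, low_ref = 90)
  d <- delta_index(snp_index(cnt))
  expect_equal(d$delta, rep(0.8, 5))
  same <- toy_counts(5)
  same$low_ref <- same$high_ref
  same$low_alt <- same$high_alt
  expect_equal(delta_index(snp_index(same))$delta, rep(0, 5))
  # filtered SNPs drop out
  cnt$low_ref[3] <- 2; cnt$low_alt[3] <- 2
  expect_equal(nrow(delta_index(snp_index(cnt))), 4)
  # mismatched coordinates
  a <- snp_index(toy_counts(3))
  b <- snp_index(dplyr::mutate(toy_counts(3), pos_bp = pos_bp + 1))
  expect_error(delta_index(dplyr::filter(a, pool == "high"),
                           dplyr::filter(b, pool == "low")),
               "share SNP coordinates")
})

test_that("window means agree with a brute-force recomputation", {
  set.seed(31)
  track <- tibble::tibble(
    chrom = 1L,
    pos_bp = sort(sample(1:5e7, 100)),
    id = sprintf("s%03d", 1:100),
    depth_high = 50, depth_low = 50,
    index_high = runif(100), index_low = runif(100)
  ) |> dplyr::mutate(delta = index_high - index_low)
  w <- window_smooth(track, window_bp = 5e6, step_bp = 1e6, min_snps = 1)
  # independent oracle: explicit loop
  for (i in sample(nrow(w), 20)) {
    inside <- track$delta[track$pos_bp >= w$start_bp[i] &
                            track$pos_bp <= w$end_bp[i]]
    if (length(inside) == 0) {
      expect_true(is.na(w$mean_delta[i]))
    } else {
      expect_equal(w$mean_delta[i], mean(inside))
      expect_equal(w$n_snps[i], length(inside))
    }
  }
  # constant track: every usable window equals the constant
  track$delta <- 0.25
  w2 <- window_smooth(track, window_bp = 5e6, step_bp = 1e6, min_snps = 1)
  expect_true(all(abs(w2$mean_delta[w2$usable] - 0.25) < 1e-12))
  expect_error(window_smooth(track, window_bp = 1e6, step_bp = 2e6), "window_bp")
})

test_that("null bands nest, reproduce, and match the F2 closed form", {
  b <- simulate_null_ci(50, 50, "F2", depths = c(50, 10000), n_reps = 6000,
                        seed = 5)
  b2 <- simulate_null_ci(50, 50, "F2", depths = c(50, 10000), n_reps = 6000,
                         seed = 5)
  expect_identical(as.data.frame(b), as.data.frame(b2))
  # band(0.01) strictly contains band(0.05) at every depth
  wide <- tidyr::pivot_wider(as.data.frame(b), names_from = level,
                             values_from = c(lower, upper))
  expect_true(all(wide$`upper_0.01` > wide$`upper_0.05`))
  expect_true(all(wide$`lower_0.01` < wide$`lower_0.05`))
  # at saturating depth the half-width is the normal-approximation value:
  # var(delta) = 2 / (8 n) for F2 pools of n, so 1.96 / sqrt(4 n) at 95%
  hw <- wide[wide$depth == 10000, ]
  expect_equal(hw$`upper_0.05`, 1.96 / sqrt(4 * 50), tolerance = 0.08)
  expect_equal(-hw$`lower_0.05`, 1.96 / sqrt(4 * 50), tolerance = 0.08)
  # bands are roughly symmetric under the symmetric null
  expect_lt(abs(hw$`upper_0.05` + hw$`lower_0.05`), 0.02)
  expect_error(simulate_null_ci(depths = 0), "depth")
  expect_error(simulate_null_ci(n_reps = 10), "1000")
})

test_that("region calling returns nothing on a flat track and finds a planted peak", {
  b <- simulate_null_ci(50, 50, depths = c(40, 60), n_reps = 2000, seed = 2)
  flat <- toy_counts(60)
  flat$low_ref <- flat$high_ref <- 25
  flat$low_alt <- flat$high_alt <- 25
  w <- window_smooth(delta_index(snp_index(flat)), 5e6, 5e6, min_snps = 1)
  expect_equal(nrow(call_regions(w, b, 0.05)), 0)
  # plant a strong peak across SNPs 20..40
  sig <- flat
  sig$high_alt[20:40] <- 45; sig$high_ref[20:40] <- 5
  ws <- window_smooth(delta_index(snp_index(sig)), 5e6, 5e6, min_snps = 1)
  reg <- call_regions(ws, b, 0.05, min_consecutive = 3)
  expect_equal(nrow(reg), 1)
  expect_true(reg$start_bp <= 21e6 && reg$end_bp >= 40e6)
  expect_equal(reg$peak_delta, 0.4, tolerance = 1e-9)
})

test_that("swapping the pools negates the scan and mirrors the regions", {
  pop <- simulate_f2(218, small_map(30), seed = 77)
  pools <- select_pools(pop, 50, 50, mode = "extreme_vs_extreme", seed = 78)
  cnt <- sample_pool_reads(pop, pools, seed = 79)
  swapped <- cnt |>
    dplyr::rename(high_ref = low_ref, high_alt = low_alt,
                  low_ref = high_ref, low_alt = high_alt)
  d1 <- delta_index(snp_index(cnt))
  d2 <- delta_index(snp_index(swapped))
  expect_equal(d2$delta, -d1$delta)
  b <- simulate_null_ci(50, 50, depths = c(30, 50, 80), n_reps = 2000,
                        snps_per_window = 10, seed = 80)
  w1 <- window_smooth(d1); w2 <- window_smooth(d2)
  r1 <- call_regions(w1, b, 0.05); r2 <- call_regions(w2, b, 0.05)
  expect_equal(r1[c("chrom", "start_bp", "end_bp")],
               r2[c("chrom", "start_bp", "end_bp")])
  expect_equal(r1$peak_delta, -r2$peak_delta)
})
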