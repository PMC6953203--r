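# Segregation statistics, marker association, family selection and
# recessive-class fine mapping.

test_that("chisq_ratio reproduces worked segregation examples", {
  q16 <- chisq_ratio(c(4058, 1372), c(3, 1))
  expect_equal(q16$statistic, 0.2065, tolerance = 1e-3)
  expect_gt(q16$p.value, 0.5)
  exact <- chisq_ratio(c(75, 25), c(3, 1))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p.value, 1)
  q54 <- chisq_ratio(c(195, 75), c(3, 1))
  expect_equal(q54$statistic, 10 / 9, tolerance = 1e-9)
  expect_equal(q54$p.value, 0.2918, tolerance = 1e-3)
  expect_error(chisq_ratio(c(0, 0), c(3, 1)), "positive")
  expect_error(chisq_ratio(c(10, 10, 10), c(3, 1)), "arity")
  td <- tidy(q16)
  expect_equal(td$p.value, q16$p.value)
})

test_that("chisq_ratio matches stats::chisq.test on random tables", {
  set.seed(99)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    ratio <- sample(1:4, k, replace = TRUE)
    counts <- as.vector(rmultinom(1, 500, ratio / sum(ratio)))
    counts <- pmax(counts, 1)
    ours <- chisq_ratio(counts, ratio)
    base <- suppressWarnings(chisq.test(counts, p = ratio / sum(ratio)))
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, unname(base$p.value), tolerance = 1e-8)
  }
  # Yates-corrected two-class variant matches the closed form
  y <- chisq_ratio(c(80, 20), c(3, 1), correct = TRUE)
  expect_equal(y$statistic, (abs(80 - 75) - 0.5)^2 / 75 + (abs(20 - 25) - 0.5)^2 / 25)
})

test_that("p-values are uniform under a true 3:1 ratio", {
  set.seed(7)
  n_fam <- 10000
  reds <- rbinom(n_fam, 5000, 0.75)
  p <- vapply(reds, function(r) chisq_ratio(c(r, 5000 - r), c(3, 1))$p.value, 0)
  # Kolmogorov-Smirnov distance to U(0,1), allowing for count discreteness
  d <- max(abs(sort(p) - (seq_len(n_fam) / n_fam)))
  expect_lt(d, 0.03)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.012)
})

test_that("marker association detects cosegregation and stays calibrated", {
  # perfect cosegregation in an F2-sized sample
  df <- data.frame(
    g = rep(c("AA", "Aa", "aa"), c(50, 100, 50)),
    ph = rep(c("red", "red", "green"), c(50, 100, 50))
  )
  strong <- marker_association(df, g, ph)
  expect_lt(strong$p.value, 1e-6)
  expect_equal(strong$df, 2L)
  # agreement with the base-R implementation
  base <- chisq.test(table(df$g, df$ph), correct = FALSE)
  expect_equal(strong$statistic, unname(base$statistic), tolerance = 1e-10)

  # type-I calibration for an unlinked marker
  set.seed(21)
  n_reps <- 10000
  hits <- vapply(seq_len(n_reps), function(i) {
    d <- data.frame(
      g = sample(c("AA", "Aa", "aa"), 200, TRUE, prob = c(1, 2, 1) / 4),
      ph = sample(c("red", "green"), 200, TRUE, prob = c(3, 1) / 4)
    )
    marker_association(d, g, ph)$p.value < 0.05
  }, TRUE)
  expect_lt(abs(mean(hits) - 0.05), 0.01)

  # degenerate tables are rejected
  empty_level <- data.frame(
    g = factor(rep("AA", 10), levels = c("AA", "aa")),
    ph = rep(c("red", "green"), 5)
  )
  expect_error(marker_association(empty_level, g, ph), "empty|degenerate")
  expect_error(marker_association(data.frame(g = rep("AA", 10),
                                             ph = rep(c("a", "b"), 5)),
                                  g, ph), "degenerate")
})

test_that("segregating-family classification applies both minor-class thresholds", {
  expect_true(classify_segregating(c(195, 75)))
  expect_false(classify_segregating(c(270, 0)))
  expect_false(classify_segregating(c(99, 1)))        # count threshold
  expect_false(classify_segregating(c(990, 10)))      # frequency threshold
  expect_true(classify_segregating(c(30, 3), min_minor_freq = 0.05))
  expect_error(classify_segregating(c(0, 0)), "positive")
})

test_that("fixed-background selection mirrors the family-screening design", {
  pop <- simulate_f2(600, small_map(5), seed = 13)
  ids <- select_fixed_background(pop, list(RLL1 = "heterozygous",
                                           RLL2 = "homozygous_functional"))
  ph <- pop$phenotype
  expect_true(all(ph$RLL1[match(ids, ph$id)] == 1))
  expect_true(all(ph$RLL2[match(ids, ph$id)] == 2))
  # selfing such a plant segregates ~3:1 red:green (only RLL1 segregates in
  # a fully fixed background)
  ids4 <- select_fixed_background(pop, list(RLL1 = "heterozygous",
                                            RLL2 = "homozygous_functional",
                                            RLL3 = "homozygous",
                                            RLL4 = "homozygous"))
  expect_gt(length(ids4), 0)
  fam <- self_generation(pop, ids4[1], 800, seed = 14)
  n_green <- sum(fam$phenotype$colour_class == "green")
  expect_lt(abs(n_green - 200), 3 * sqrt(800 * 0.25 * 0.75))
  expect_error(select_fixed_background(pop, list(RLL9 = "heterozygous")),
               "unknown locus")
  none <- simulate_f2(3, small_map(3), seed = 15)
  res <- select_fixed_background(none, list(RLL1 = "heterozygous",
                                            RLL2 = "heterozygous",
                                            RLL3 = "heterozygous",
                                            RLL4 = "heterozygous"))
  expect_true(length(res) == 0 || all(res %in% none$phenotype$id))
})

test_that("the fine-map interval is the zero-recombinant core plus flanks", {
  # five markers with recombinant counts (2, 1, 0, 0, 3)
  pos <- c(10, 20, 30, 40, 50) * 1e6
  geno <- rbind(
    c(1, 2, 2, 2, 2),
    c(1, 1, 2, 2, 0),
    c(2, 2, 2, 2, 1),
    c(2, 2, 2, 2, 1)
  )
  fm <- fine_map_recessive(geno, pos, chrom = 4)
  expect_equal(fm$markers$recombinants, c(2, 1, 0, 0, 3))
  expect_equal(fm$interval$start_bp, 20e6) # flank where recombinants reappear
  expect_equal(fm$interval$end_bp, 50e6)
  expect_equal(glance(fm)$width_bp, 30e6)
  # all-donor genotypes: interval spans all markers
  all_donor <- matrix(2, 3, 5)
  fm2 <- fine_map_recessive(all_donor, pos)
  expect_equal(fm2$interval$start_bp, pos[1])
  expect_equal(fm2$interval$end_bp, pos[5])
  # max_errors tolerance widens the acceptable core
  fm3 <- fine_map_recessive(geno, pos, max_errors = 1)
  expect_equal(fm3$interval$start_bp, 10e6)
  expect_equal(fm3$interval$end_bp, 50e6)
  expect_error(fine_map_recessive(matrix(0, 2, 5), pos), "inconsistent")
  expect_error(fine_map_recessive(geno, rev(pos)), "ordered")
})
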