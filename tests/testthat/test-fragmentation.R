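# Per-bin counts, GC correction, ratio/fraction profiles, cohort similarity.

test_that("bin size counts split lengths into disjoint windows", {
  bins <- make_bins(c(chr1 = 5e6), 5e6)
  s <- frags_of_lengths(c(120, 150, 180), gap = 1000)
  counts <- bin_size_counts(s, bins)
  expect_equal(counts$short, 2)  # 150 belongs to the short window
  expect_equal(counts$long, 1)
  expect_equal(counts$total, 3)

  expect_error(bin_size_counts(s, bins, short_range = c(100, 160),
                               long_range = c(150, 220)), "overlap")
})

test_that("empty bins carry zero counts", {
  bins <- make_bins(c(chr1 = 10e6), 5e6)
  s <- make_frags("chr1", 100, 267)  # only first bin
  counts <- bin_size_counts(s, bins)
  expect_equal(counts$total, c(1, 0))
})

test_that("per-bin short share matches the configured mixture mass", {
  cfg <- sim_config(ratio_amplitude = 0, n_fragments = 40000)
  s <- simulate_sample(cfg, "healthy", seed = 4)$sample
  bins <- make_bins(cfg$genome, cfg$bin_size)
  counts <- bin_size_counts(s, bins)
  m <- cfg$mixtures$healthy
  p_short <- mixture_mass(m, 100, 150) /
    (mixture_mass(m, 100, 150) + mixture_mass(m, 151, 220))
  n <- counts$short + counts$long
  se <- sqrt(p_short * (1 - p_short) / n)
  expect_true(all(abs(counts$short / n - p_short) < 3.5 * se))
})

test_that("GC correction matches a weighted-regression oracle on linear data", {
  set.seed(3)
  gc <- seq(0.35, 0.6, length.out = 40)[sample.int(40)]
  values <- 100 + 200 * (gc - mean(gc))  # exactly linear in GC
  corrected <- gc_correct(values, gc)
  # oracle: weighted least squares recovers the linear trend exactly, so
  # the corrected values must all collapse to the mean level of 100
  ols <- lm(values ~ gc, weights = rep(1, length(gc)))
  expect_lt(max(abs(fitted(ols) - values)), 1e-8)
  expect_true(all(abs(corrected - 100) < 2))
  # total is preserved
  expect_equal(sum(corrected), sum(values), tolerance = 1e-3)
})

test_that("GC correction is the identity for degenerate inputs", {
  values <- rep(100, 20)
  gc <- seq(0.3, 0.7, length.out = 20)
  expect_equal(gc_correct(values, gc), values, tolerance = 1e-6)
  # identical GC everywhere: nothing to remove
  set.seed(1)
  v2 <- rnorm(20, 100, 10)
  expect_identical(gc_correct(v2, rep(0.5, 20)), v2)
})

test_that("GC correction preserves totals on simulated counts", {
  co <- default_cohort()
  p <- co$profiles[[1]]
  expect_equal(sum(p$corrected_total, na.rm = TRUE),
               sum(p$total[!is.na(p$corrected_total)]),
               tolerance = 1e-3 * sum(p$total))
})

test_that("ratio and fraction profiles satisfy their identities", {
  rp <- ratio_profile(short = c(50, 30, 40), long = c(100, 100, 100))
  expect_equal(rp$ratio, c(0.5, 0.3, 0.4))
  expect_equal(mean(rp$normalized_ratio), 0, tolerance = 1e-12)
  expect_equal(ratio_profile(c(2, 3, 4), c(10, 10, 10))$normalized_ratio,
               c(-0.1, 0, 0.1))

  # zero/negative long counts are masked
  rp2 <- ratio_profile(c(5, 5), c(10, 0))
  expect_true(rp2$masked[2])
  expect_true(is.na(rp2$ratio[2]))

  expect_equal(fraction_profile(c(10, 30, 60)), c(0.1, 0.3, 0.6))
  expect_equal(fraction_profile(100), 1)
  expect_error(fraction_profile(c(0, 0)), "no unmasked")
})

test_that("sample profiles keep their invariants on simulated data", {
  for (p in default_cohort()$profiles[c(1, 25)]) {
    expect_equal(sum(p$fraction, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_equal(mean(p$normalized_ratio, na.rm = TRUE), 0, tolerance = 1e-9)
    expect_true(all(p$ratio[!p$masked] >= 0))
  }
})

fake_profile <- function(ratio) {
  data.frame(ratio = ratio, fraction = abs(ratio) / sum(abs(ratio)),
             masked = FALSE)
}

test_that("cohort similarity has unit diagonal, symmetry, and exact anchors", {
  r <- c(0.2, 0.5, 0.3, 0.6, 0.4)
  profs <- list(a = fake_profile(r), b = fake_profile(r),
                c = fake_profile(2 * mean(r) - r))  # negation about the mean
  cs <- cohort_similarity(profs, healthy_ids = c("a", "b"))
  expect_equal(diag(cs$matrix), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cs$matrix, t(cs$matrix))
  expect_true(all(cs$matrix >= -1 - 1e-12 & cs$matrix <= 1 + 1e-12))
  # sample identical to the healthy median: r = 1; its negation: r = -1
  expect_equal(unname(cs$r_to_reference[["a"]]), 1)
  expect_equal(unname(cs$r_to_reference[["c"]]), -1)
})

test_that("cohort similarity demands shared support and flags zero variance", {
  profs <- list(a = fake_profile(c(1, 2)), b = fake_profile(c(1, 2)))
  expect_error(cohort_similarity(profs, healthy_ids = "a"), "3 shared")
  profs2 <- list(a = fake_profile(c(1, 2, 3, 4)),
                 b = fake_profile(rep(1, 4)))
  expect_warning(cohort_similarity(profs2, healthy_ids = "a"),
                 "zero-variance")
})
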