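# The seeded simulator: determinism, analytic size masses, spatial placement.

test_that("simulation is byte-identical for a fixed seed", {
  cfg <- sim_config(n_fragments = 5000)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  co1 <- simulate_cohort(cfg, n_cancer = 1, n_healthy = 1, seed = 99,
                         out_dir = d1)
  co2 <- simulate_cohort(cfg, n_cancer = 1, n_healthy = 1, seed = 99,
                         out_dir = d2)
  for (f in names(co1$files$fragments)) {
    expect_identical(readLines(co1$files$fragments[[f]]),
                     readLines(co2$files$fragments[[f]]))
  }
  expect_identical(co1$truth, co2$truth)
  # a different seed changes the fragments
  co3 <- simulate_cohort(cfg, n_cancer = 1, n_healthy = 1, seed = 100)
  expect_false(identical(co1$samples[[1]]$fragments,
                         co3$samples[[1]]$fragments))
})

test_that("config validation rejects inconsistent settings", {
  mixtures <- cffeatures:::default_mixtures()
  mixtures$healthy$weight <- mixtures$healthy$weight * 2
  expect_error(sim_config(mixtures = mixtures), "sum to 1")
  expect_error(sim_config(ndr_depletion = 0), "ndr_depletion")
  expect_error(sim_config(tumor_fraction = 2), "tumor_fraction")
  expect_error(sim_config(amplified_bins = 99), "available bins")
})

test_that("observed size-range fractions match the analytic mixture mass", {
  co <- default_cohort()$cohort
  cfg <- default_cohort()$config
  ranges <- list(c(30, 79), c(80, 149), c(150, 219), c(220, 999),
                 c(1000, Inf))
  for (id in c("healthy_04", "cancer_04", "hemolysis_01")) {
    s <- co$samples[[id]]
    label <- co$truth$label[co$truth$sample_id == id]
    f <- size_fractions(size_histogram(s))
    masses <- vapply(ranges, function(r)
      mixture_mass(cfg$mixtures[[label]], r[1], r[2]), 0)
    se <- sqrt(masses * (1 - masses) / s$n_after_filters)
    expect_true(all(abs(f - masses) < 3 * se + 1e-4),
                label = sprintf("size masses for %s", id))
  }
})

test_that("per-bin fragment counts follow the placement weights", {
  cfg <- default_cohort()$config
  co <- default_cohort()$cohort
  bins <- default_cohort()$bins
  s <- co$samples[["cancer_02"]]
  truth_bins <- co$bins
  gc_pref <- exp(cfg$gc_strength * (truth_bins$gc - mean(truth_bins$gc)))
  w <- (truth_bins$end - truth_bins$start) * truth_bins$multiplier * gc_pref
  p <- w / sum(w)
  idx <- assign_to_bins(s, bins)
  counts <- tabulate(idx, nrow(truth_bins))
  n <- sum(counts)
  # 3.5 sigma: promoter/TF thinning perturbs the first bins slightly
  expect_true(all(abs(counts - n * p) < 3.5 * sqrt(n * p * (1 - p)) + 25))
})

test_that("cancer samples have systematically higher short/long ratios", {
  co <- default_cohort()
  ratios <- vapply(co$cohort$samples, function(s)
    hemolysis_flag(s)$ratio, 0)
  labels <- co$labels[names(ratios)]
  cancer <- ratios[labels == "cancer"]
  healthy <- ratios[labels == "healthy"]
  expect_gt(min(cancer), max(healthy) * 0.9)
  expect_lt(wilcox.test(cancer, healthy)$p.value, 0.01)
})

test_that("cohort truth covers every simulated entity", {
  co <- default_cohort()$cohort
  expect_equal(nrow(co$truth), 42)
  expect_setequal(unique(co$truth$label), c("cancer", "healthy", "hemolysis"))
  expect_equal(nrow(co$bins), 18)
  expect_true(all(co$bins$multiplier > 0))
  expect_true(all(co$genes$state %in% c("open", "closed", "neutral")))
  expect_setequal(names(co$tf_sites), c("TF1", "TF2"))
})

test_that("zero-sample cohorts are rejected", {
  cfg <- sim_config(n_fragments = 1000)
  expect_error(simulate_cohort(cfg, 0, 0, 0), "zero total samples")
})
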