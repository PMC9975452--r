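# Size histograms, size-range fractions, hemolysis flag, chromosome stats.

test_that("size histogram counts lengths and pools the overflow class", {
  s <- frags_of_lengths(c(167, 167, 334))
  h <- size_histogram(s)
  expect_equal(h$count[h$length == 167], 2)
  expect_equal(h$count[h$length == 334], 1)

  h2 <- size_histogram(frags_of_lengths(c(167, 1200, 5000)))
  expect_equal(h2$count[h2$length == 1000], 2)  # overflow class

  expect_warning(h3 <- size_histogram(frags_of_lengths(numeric())), "empty")
  expect_equal(nrow(h3), 0)
})

test_that("simulated healthy size distribution peaks at the mononucleosome mode", {
  s <- default_cohort()$cohort$samples[["healthy_01"]]
  h <- size_histogram(s)
  mode <- h$length[which.max(h$count)]
  expect_gte(mode, 160)
  expect_lte(mode, 174)
})

test_that("size fractions use half-open ranges and sum to one", {
  f <- size_fractions(size_histogram(frags_of_lengths(
    rep(c(100, 160, 300), c(50, 30, 20)))))
  expect_equal(unname(f), c(0, 0.5, 0.3, 0.2, 0), tolerance = 1e-12)

  # 150 bp belongs to the third (150-220) range under the half-open rule
  f2 <- size_fractions(size_histogram(frags_of_lengths(rep(150, 10))))
  expect_equal(unname(f2[["f_150_220"]]), 1)

  f3 <- size_fractions(size_histogram(frags_of_lengths(rep(1000, 4))))
  expect_equal(unname(f3[["f_ge_1000"]]), 1)

  expect_error(size_fractions(suppressWarnings(
    size_histogram(frags_of_lengths(numeric())))), "empty")
})

test_that("size fractions sum to one for arbitrary non-empty samples", {
  set.seed(42)
  for (i in 1:20) {
    lens <- sample(30:2000, sample(1:300, 1), replace = TRUE)
    f <- size_fractions(size_histogram(frags_of_lengths(lens)))
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
})

test_that("hemolysis flag uses a strict threshold on the short/long ratio", {
  # 4 short (100-150) vs 100 long (151-220): ratio 0.04 -> flagged
  s <- frags_of_lengths(rep(c(120, 180), c(4, 100)))
  r <- hemolysis_flag(s)
  expect_equal(r$ratio, 0.04)
  expect_true(r$flag)

  # ratio exactly 0.05 is NOT flagged (strict <)
  s2 <- frags_of_lengths(rep(c(120, 180), c(5, 100)))
  expect_false(hemolysis_flag(s2)$flag)

  s3 <- frags_of_lengths(rep(c(120, 180), c(20, 100)))
  expect_false(hemolysis_flag(s3)$flag)

  # no long fragments: degenerate profile is flagged with a reason
  s4 <- frags_of_lengths(rep(120, 10))
  r4 <- hemolysis_flag(s4)
  expect_true(r4$flag)
  expect_true(is.na(r4$ratio))
  expect_match(r4$reason, "degenerate")
})

test_that("hemolysis flagging is monotone in the short and long counts", {
  base_long <- rep(180, 100)
  flagged_at <- function(n_short) {
    hemolysis_flag(frags_of_lengths(c(rep(120, n_short), base_long)))$flag
  }
  flags <- vapply(1:10, flagged_at, TRUE)
  # once unflagged, adding short fragments never re-flags
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("chromosome stats zero-fill annotated chromosomes", {
  sizes <- setNames(rep(1e6, 24), c(paste0("chr", 1:22), "chrX", "chrY"))
  s <- make_frags(c("chr1", "chr2", "chr2"), c(0, 0, 500),
                  c(167, 100, 700), mapq = c(60, 50, 40))
  st <- chromosome_stats(s, sizes)
  expect_equal(nrow(st), 24)
  expect_equal(st$n_fragments[st$chrom == "chr1"], 1)
  expect_equal(st$n_fragments[st$chrom == "chr3"], 0)
  expect_equal(st$mean_length[st$chrom == "chr2"], 150)
  expect_equal(st$mean_mapq[st$chrom == "chr2"], 45)
})

test_that("simulated per-chromosome counts track chromosome length", {
  # no GC bias, flat copy number: counts are multinomial on length shares
  cfg <- sim_config(gc_strength = 0, n_fragments = 30000)
  s <- simulate_sample(cfg, "healthy", seed = 9)$sample
  st <- chromosome_stats(s, cfg$genome)
  n <- sum(st$n_fragments)
  p <- cfg$genome / sum(cfg$genome)
  expected <- n * p[st$chrom]
  expect_true(all(abs(st$n_fragments - expected) <
                    3 * sqrt(n * p[st$chrom] * (1 - p[st$chrom]))))
})

test_that("qc_report ties the pieces together", {
  s <- default_cohort()$cohort$samples[["healthy_02"]]
  r <- qc_report(s, default_cohort()$config$genome)
  expect_s3_class(r, "qc_report")
  expect_equal(sum(r$fractions), 1, tolerance = 1e-9)
  expect_identical(r$hemolysis, r$ratio < 0.05)
  expect_equal(nrow(r$chrom_stats), 3)
})
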