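# TSS relative coverage and chromatin-state calls.

test_that("region depth counts mean per-base fragment coverage", {
  sizes <- c(chr1 = 10000)
  expect_equal(region_depth(make_frags("chr1", 5000, 5100), "chr1", 0, 10000,
                            chrom_sizes = sizes), 0.01)
  # no fragments in the interval
  expect_equal(region_depth(make_frags("chr1", 5000, 5100), "chr1", 0, 100,
                            chrom_sizes = sizes), 0)
  # one fragment covering the whole interval
  expect_equal(region_depth(make_frags("chr1", 0, 10000), "chr1", 2000, 2200,
                            chrom_sizes = sizes), 1)
  # two fragments each covering exactly half of a 200 bp interval
  expect_equal(region_depth(make_frags("chr1", c(1000, 1100), c(1100, 1200)),
                            "chr1", 1000, 1200, chrom_sizes = sizes), 1)
  expect_error(region_depth(make_frags("chr1", 0, 100), "chr1", 50, 50,
                            chrom_sizes = sizes), "length")
})

test_that("uniform coverage gives relative coverages of one", {
  s <- uniform_frags(chrom_len = 1e6, len = 100, step = 20)
  tss <- data.frame(gene = c("A", "B"), chrom = "chrP", strand = c("+", "-"),
                    tss = c(3e5, 7e5))
  cov <- tss_relative_coverages(s, tss, c(chrP = 1e6))
  expect_equal(cov$ndr_rc, c(1, 1), tolerance = 1e-6)
  expect_equal(cov$k2_rc, c(1, 1), tolerance = 1e-6)
  expect_equal(cov$conventional_rc, c(1, 1), tolerance = 1e-2)
})

test_that("strand mirroring leaves all three coverages unchanged", {
  cfg <- default_cohort()$config
  s <- default_cohort()$cohort$samples[["healthy_03"]]
  tss_pos <- 2e6
  tss_fwd <- data.frame(gene = "G", chrom = "chr1", strand = "+", tss = tss_pos)
  tss_rev <- data.frame(gene = "G", chrom = "chr1", strand = "-", tss = tss_pos)
  # mirror fragments about the TSS: covered base x -> 2*tss - x
  df <- s$fragments
  mirrored <- sample_fragments(data.frame(
    chrom = df$chrom,
    start = 2 * tss_pos - df$end + 1,
    end = 2 * tss_pos - df$start + 1), sample_id = "mirror")
  cov_f <- tss_relative_coverages(s, tss_fwd, cfg$genome)
  cov_r <- tss_relative_coverages(mirrored, tss_rev, cfg$genome)
  expect_equal(cov_f$ndr_rc, cov_r$ndr_rc)
  expect_equal(cov_f$k2_rc, cov_r$k2_rc)
  expect_equal(cov_f$conventional_rc, cov_r$conventional_rc)
})

test_that("zero NDR coverage with covered flanks gives ndr_rc of zero", {
  # fragments only in the reference flanks
  start <- c(seq(1e5 - 2800, 1e5 - 1400, by = 100),
             seq(1e5 + 1400, 1e5 + 2800, by = 100))
  s <- make_frags("chrP", start, start + 100)
  tss <- data.frame(gene = "A", chrom = "chrP", strand = "+", tss = 1e5)
  cov <- tss_relative_coverages(s, tss, c(chrP = 1e6))
  expect_equal(cov$ndr_rc, 0)
})

test_that("genes near chromosome edges are skipped and reported", {
  s <- uniform_frags()
  tss <- data.frame(gene = c("edge", "ok"), chrom = "chrP",
                    strand = "+", tss = c(1000, 5e5))
  cov <- tss_relative_coverages(s, tss, c(chrP = 1e6))
  expect_equal(cov$gene, "ok")
  expect_equal(attr(cov, "skipped"), "edge")
})

test_that("duplicate TSS annotations collapse to the most upstream", {
  tss <- data.frame(gene = c("G", "G", "H", "H"), chrom = "c",
                    strand = c("+", "+", "-", "-"),
                    tss = c(5000, 4000, 5000, 6000))
  collapsed <- cffeatures:::collapse_tss(tss)
  expect_equal(collapsed$tss[collapsed$gene == "G"], 4000)
  expect_equal(collapsed$tss[collapsed$gene == "H"], 6000)
})

state_table <- function(gene, ndr, k2, n) {
  data.frame(sample_id = paste0("s", seq_len(n)), gene = gene,
             ndr_rc = ndr, k2_rc = k2)
}

test_that("chromatin states follow the strict-majority conjunction rule", {
  # both coverages < 1 in 8/10 samples: permissive
  t1 <- state_table("G", c(rep(0.5, 8), 1.2, 1.3), c(rep(0.6, 8), 1.2, 1.3), 10)
  expect_equal(classify_chromatin_state(t1)$state, "permissive")
  expect_equal(classify_chromatin_state(t1)$freq_open, 0.8)

  # both > 1.5 in 9/10: nonpermissive
  t2 <- state_table("G", c(rep(1.6, 9), 1.0), c(rep(1.8, 9), 1.0), 10)
  expect_equal(classify_chromatin_state(t2)$state, "nonpermissive")

  # NDR low but 2K not: the conjunction fails -> indeterminate
  t3 <- state_table("G", rep(0.5, 10), rep(1.2, 10), 10)
  expect_equal(classify_chromatin_state(t3)$state, "indeterminate")
})

test_that("expression concordance reports direction and handles nulls", {
  states <- data.frame(gene = paste0("g", 1:40),
                       state = rep(c("permissive", "nonpermissive"), 20))
  set.seed(7)
  # identical distributions: p should be large
  expr0 <- data.frame(gene = states$gene, expression = rnorm(40, 5))
  r0 <- expression_concordance(states, expr0)
  expect_gt(r0$expression_by_state$p, 0.05)

  # permissive genes expressed higher
  expr1 <- expr0
  expr1$expression[states$state == "permissive"] <- rnorm(20, 12)
  r1 <- expression_concordance(states, expr1)
  expect_lt(r1$expression_by_state$p, 0.01)
  expect_match(r1$expression_by_state$direction, ">")

  # single gene per group: test skipped with a warning
  expect_warning(
    r2 <- expression_concordance(states[1:2, ], expr1[1:2, ]),
    "skipped")
  expect_null(r2$expression_by_state)
})

test_that("coverage of upregulated genes is lower than downregulated", {
  pc <- promoter_cohort()
  s <- pc$cohort$samples[[1]]
  cov <- tss_relative_coverages(s, pc$genes, pc$config$genome)
  cov$sample_id <- s$sample_id
  groups <- data.frame(gene = pc$genes$gene,
                       expression = pc$genes$expression,
                       group = pc$genes$expr_label)
  r <- expression_concordance(NULL, groups[groups$group != "neutral", ],
                              coverages = cov)
  expect_lt(r$coverage_by_group$p, 0.01)
  expect_equal(r$coverage_by_group$direction, "up < down")
})
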