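# Fragment loading, genome binning, midpoint assignment.

test_that("BED fragments load with lengths and filters applied", {
  bed <- write_bed(data.frame(chrom = c("chr1", "chr1", "chr2"),
                              start = c(100, 300, 0),
                              end = c(250, 480, 167)))
  s <- load_fragments(bed, length_range = c(30, Inf), min_mapq = 0)
  expect_s3_class(s, "sample_fragments")
  expect_equal(s$n_after_filters, 3)
  expect_setequal(s$fragments$length, c(150, 180, 167))

  s2 <- load_fragments(bed, length_range = c(160, 220), min_mapq = 0)
  expect_equal(s2$n_total, 3)
  expect_equal(s2$n_after_filters, 2)
  expect_setequal(s2$fragments$length, c(180, 167))
})

test_that("empty and malformed BED input is handled", {
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_warning(s <- load_fragments(empty), "no fragments")
  expect_equal(s$n_after_filters, 0)
  expect_equal(s$n_total, 0)

  bad <- write_bed(data.frame(chrom = c("chr1", "chr1", "chr1"),
                              start = c(100, 500, 900),
                              end = c(250, 400, 1000)))  # line 2 reversed
  expect_warning(s <- load_fragments(bad, min_mapq = 0), "malformed")
  expect_equal(s$n_rejected, 1)
  expect_equal(s$n_after_filters, 2)
})

test_that("BED mapq column and dedup filters work", {
  bed <- write_bed(data.frame(chrom = "chr1", start = c(0, 0, 500),
                              end = c(167, 167, 667), mapq = c(60, 60, 10)))
  s <- load_fragments(bed, min_mapq = 30, dedup = TRUE)
  expect_equal(s$n_after_filters, 1)  # duplicate removed, low mapq removed
  s2 <- load_fragments(bed, min_mapq = 0, dedup = FALSE)
  expect_equal(s2$n_after_filters, 3)
})

test_that("loading is deterministic and BAM matches the equivalent BED", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    # proper pair spanning [100, 250): pos 101, TLEN 150
    "r1\t99\tchr1\t101\t60\t50M\t=\t201\t150\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    "r1\t147\tchr1\t201\t60\t50M\t=\t101\t-150\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    # proper pair spanning [300, 480)
    "r2\t99\tchr1\t301\t60\t50M\t=\t431\t180\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    "r2\t147\tchr1\t431\t60\t50M\t=\t301\t-180\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    # improperly paired: must be excluded
    "r3\t97\tchr1\t601\t60\t50M\t=\t901\t350\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*",
    "r3\t145\tchr1\t901\t60\t50M\t=\t601\t-350\tAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA\t*"
  )
  writeLines(lines, sam)
  bam <- suppressWarnings(Rsamtools::asBam(sam, tempfile(), overwrite = TRUE))
  s <- load_fragments(bam, length_range = c(30, Inf))
  expect_equal(s$fragments$start, c(100, 300))
  expect_equal(s$fragments$end, c(250, 480))
  expect_equal(s$fragments$length, c(150, 180))

  s2 <- load_fragments(bam, length_range = c(30, Inf))
  expect_identical(s$fragments, s2$fragments)
})

test_that("make_bins tiles chromosomes with the 50% partial-bin rule", {
  b1 <- make_bins(c(chrA = 5e6), 5e6)
  expect_equal(nrow(b1$bins), 1)
  expect_equal(b1$bins$end, 5e6)

  b2 <- make_bins(c(chrA = 12e6), 5e6)
  expect_equal(nrow(b2$bins), 2)  # 2 Mb remainder < 2.5 Mb: dropped

  b3 <- make_bins(c(chrA = 13e6), 5e6)
  expect_equal(nrow(b3$bins), 3)
  expect_equal(b3$bins$end[3], 13e6)
  expect_true(b3$bins$partial[3])
})

test_that("bins tile each chromosome contiguously from zero", {
  sizes <- c(a = 17.2e6, b = 5e6, c = 9.9e6)
  b <- make_bins(sizes, 3e6)
  for (ch in names(sizes)) {
    rows <- b$bins[b$bins$chrom == ch, ]
    expect_equal(rows$start[1], 0)
    if (nrow(rows) > 1) {
      expect_equal(rows$start[-1], rows$end[-nrow(rows)])
    }
    expect_true(all(diff(rows$end) > 0))
  }
})

test_that("GC attachment validates chromosomes and bounds", {
  gc <- data.frame(chrom = c("chrA", "chrOops"), start = c(0, 0),
                   gc = c(0.4, 0.5))
  expect_error(make_bins(c(chrA = 10e6), 5e6, gc = gc), "chrOops")
  gc_ok <- data.frame(chrom = "chrA", start = c(0, 5e6), gc = c(0.4, 0.6))
  b <- make_bins(c(chrA = 10e6), 5e6, gc = gc_ok)
  expect_equal(b$bins$gc, c(0.4, 0.6))
})

test_that("GC can be derived from a genome sequence", {
  seqs <- Biostrings::DNAStringSet(c(chrA = paste(
    c(strrep("AT", 2500), strrep("GC", 2500)), collapse = "")))
  b <- make_bins(c(chrA = 10000), 5000, gc = seqs)
  expect_equal(b$bins$gc, c(0, 1))
})

test_that("midpoint assignment respects half-open bin boundaries", {
  bins <- make_bins(c(chr1 = 10e6), 5e6)
  s <- make_frags("chr1", c(4999900, 1000), c(5000100, 1200))
  idx <- assign_to_bins(s, bins)
  # fragment [4999900, 5000100) has midpoint 5000000 -> second bin
  expect_equal(unname(idx[s$fragments$start == 4999900]), 2L)
  expect_equal(unname(idx[s$fragments$start == 1000]), 1L)
})

test_that("assignment conserves fragments and excludes alien chromosomes", {
  bins <- make_bins(c(chr1 = 10e6), 5e6)
  s <- make_frags(c("chr1", "chr1", "chrUn"), c(0, 6e6, 100),
                  c(167, 6e6 + 167, 267))
  idx <- assign_to_bins(s, bins)
  expect_equal(sum(!is.na(idx)) + attr(idx, "n_excluded"), s$n_after_filters)
  expect_equal(attr(idx, "n_excluded"), 1L)
})

test_that("uniform fragments split evenly between two bins", {
  bins <- make_bins(c(chr1 = 10e6), 5e6)
  set.seed(1)
  start <- sort(floor(runif(1000, 0, 10e6 - 167)))
  s <- make_frags("chr1", start, start + 167)
  idx <- assign_to_bins(s, bins)
  counts <- tabulate(idx, 2)
  # binomial oracle: 500 +- 3 * sqrt(1000 * 0.25)
  expect_true(all(abs(counts - 500) < 3 * sqrt(1000 * 0.25)))
})
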