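# Per-sample fragment-size QC: histograms, size-range fractions,
# per-chromosome read stats, and the hemolysis risk flag.

#' Fragment-size histogram at 1-bp resolution
#'
#' Lengths at or above `overflow_at` are pooled into a single overflow
#' class, so the histogram covers at least 30-1000 bp plus ">= 1000".
#' Load fragments with `length_range = c(30, Inf)` so that long
#' (hemolysis-derived) fragments are visible here.
#'
#' @param sample a [sample_fragments()] object.
#' @param overflow_at lengths `>= overflow_at` are pooled (default 1000 bp).
#' @return `size_histogram`: data frame with columns `length`, `count`;
#'   the row with `length == overflow_at` is the pooled overflow class.
#' @export
size_histogram <- function(sample, overflow_at = 1000) {
  stopifnot(inherits(sample, "sample_fragments"))
  len <- sample$fragments$length
  if (!length(len)) {
    warnf("empty sample '%s': empty histogram", sample$sample_id)
    out <- data.frame(length = integer(), count = integer())
  } else {
    tab <- table(pmin(len, overflow_at))
    out <- data.frame(length = as.integer(names(tab)),
                      count = as.integer(tab))
    out <- out[order(out$length), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, overflow_at = overflow_at, class = c("size_histogram", "data.frame"))
}

#' Fragment counts of a histogram within an integer length window
#' @noRd
hist_count <- function(hist, lo, hi, include_overflow = FALSE) {
  sel <- hist$length >= lo & hist$length <= hi
  if (!include_overflow) sel <- sel & hist$length < attr(hist, "overflow_at")
  sum(hist$count[sel])
}

#' Five canonical fragment-size-range fractions
#'
#' Fractions of fragments in the 30-80, 80-150, 150-220, 220-1000 and
#' ">= 1000" bp ranges. The printed ranges share endpoints, so each range is
#' half-open `[lo, hi)`: a 150 bp fragment belongs to the 150-220 range.
#' Fragments shorter than 30 bp are expected to be excluded at load time;
#' any present are dropped here with a warning. The five fractions sum to 1.
#'
#' @param hist a [size_histogram()].
#' @param breaks ascending cut points; default `c(30, 80, 150, 220, 1000)`,
#'   the last opening the unbounded overflow range.
#' @return Named numeric vector (`f_30_80`, `f_80_150`, `f_150_220`,
#'   `f_220_1000`, `f_ge_1000`) summing to 1.
#' @export
size_fractions <- function(hist, breaks = c(30, 80, 150, 220, 1000)) {
  stopifnot(inherits(hist, "size_histogram"), length(breaks) >= 2)
  if (!nrow(hist) || sum(hist$count) == 0) stopf("empty histogram")
  below <- hist$length < breaks[1]
  if (any(below & hist$count > 0)) {
    warnf("dropping %d fragment(s) below %d bp", sum(hist$count[below]), breaks[1])
    hist <- hist[!below, , drop = FALSE]
  }
  edges <- c(breaks, Inf)
  counts <- vapply(seq_len(length(edges) - 1L), function(i) {
    sum(hist$count[hist$length >= edges[i] & hist$length < edges[i + 1L]])
  }, 0)
  nm <- c(paste0("f_", breaks[-length(breaks)], "_", breaks[-1]),
          paste0("f_ge_", breaks[length(breaks)]))
  setNames(counts / sum(counts), nm)
}

#' Hemolysis risk flag from the genome-wide short/long fragment ratio
#'
#' Hemolysis (red-blood-cell rupture during handling) floods plasma with
#' long genomic DNA, collapsing the ratio of short (100-150 bp) to long
#' (151-220 bp) cfDNA fragments. A sample is flagged as at high risk of
#' hemolysis when this genome-wide ratio falls strictly below `threshold`
#' (default 0.05). When the long-window count is zero the ratio is
#' undefined and the sample is flagged with reason "degenerate size
#' profile".
#'
#' @param x a [sample_fragments()] object or a [size_histogram()].
#' @param threshold flag when ratio `< threshold` (strict).
#' @param short_range,long_range inclusive length windows in bp.
#' @return List with `ratio` (may be `NA`), `flag` (logical), `reason`.
#' @export
hemolysis_flag <- function(x, threshold = 0.05,
                           short_range = c(100, 150),
                           long_range = c(151, 220)) {
  hist <- if (inherits(x, "size_histogram")) x else size_histogram(x)
  short_n <- hist_count(hist, short_range[1], short_range[2])
  long_n <- hist_count(hist, long_range[1], long_range[2])
  if (long_n == 0) {
    return(list(ratio = NA_real_, flag = TRUE,
                reason = "degenerate size profile"))
  }
  ratio <- short_n / long_n
  list(ratio = ratio, flag = ratio < threshold,
       reason = if (ratio < threshold) "short/long ratio below threshold" else "")
}

#' Per-chromosome fragment statistics
#'
#' One row per chromosome in `chrom_sizes` (zero-filled when no fragments
#' map there), or per observed chromosome when `chrom_sizes` is `NULL`.
#' For a standard human genome (chr1-22, X, Y) this yields 24 rows.
#'
#' @param sample a [sample_fragments()] object.
#' @param chrom_sizes optional named vector / data frame / file path.
#' @return Data frame: `chrom`, `n_fragments`, `mean_length`, `mean_mapq`.
#' @export
chromosome_stats <- function(sample, chrom_sizes = NULL) {
  stopifnot(inherits(sample, "sample_fragments"))
  df <- sample$fragments
  chroms <- if (is.null(chrom_sizes)) {
    unique(df$chrom)
  } else {
    names(as_chrom_sizes(chrom_sizes))
  }
  rows <- lapply(chroms, function(ch) {
    sel <- df$chrom == ch
    n <- sum(sel)
    data.frame(chrom = ch, n_fragments = n,
               mean_length = if (n) mean(df$length[sel]) else NA_real_,
               mean_mapq = if (n && any(!is.na(df$mapq[sel])))
                 mean(df$mapq[sel], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full per-sample QC report
#'
#' Combines the size histogram, the five size-range fractions, the
#' hemolysis flag and per-chromosome statistics.
#'
#' @inheritParams chromosome_stats
#' @param hemolysis_threshold flag threshold, see [hemolysis_flag()].
#' @return `qc_report`: list with `sample_id`, `fractions`, `ratio`,
#'   `hemolysis` (logical), `reason`, `histogram`, `chrom_stats`,
#'   `n_total`, `n_after_filters`.
#' @export
qc_report <- function(sample, chrom_sizes = NULL, hemolysis_threshold = 0.05) {
  hist <- size_histogram(sample)
  hemo <- hemolysis_flag(hist, threshold = hemolysis_threshold)
  structure(list(
    sample_id = sample$sample_id,
    fractions = size_fractions(hist),
    ratio = hemo$ratio,
    hemolysis = hemo$flag,
    reason = hemo$reason,
    histogram = hist,
    chrom_stats = chromosome_stats(sample, chrom_sizes),
    n_total = sample$n_total,
    n_after_filters = sample$n_after_filters
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %d fragments; short/long ratio %.4f; hemolysis flag: %s\n",
              x$sample_id, x$n_after_filters,
              if (is.na(x$ratio)) NaN else x$ratio,
              if (x$hemolysis) "YES" else "no"))
  print(round(x$fractions, 4))
  invisible(x)
}
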