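# TSS relative coverage and chromatin-state calls.
#
# Around the transcription start site of an active gene, nucleosome
# depletion lowers cfDNA fragment coverage; three relative-coverage
# summaries quantify this per gene:
#   ndr_rc          = depth(NDR window)   / depth(reference flanks)
#   k2_rc           = depth(2K window)    / depth(reference flanks)
#   conventional_rc = depth(2K window)    / genome-wide mean depth
# Windows are offsets relative to the strand-oriented TSS; the defaults
# (NDR -150..+50, 2K -1000..+1000, reference flanks +-(1000..3000)) follow
# common TSS-coverage practice and are configurable.

#' Per-chromosome fragment coverage
#'
#' @param sample a [sample_fragments()] object.
#' @param chrom_sizes named vector / data frame / path of chromosome sizes.
#' @return Named list of [S4Vectors::Rle] coverage vectors, one per
#'   chromosome in `chrom_sizes`.
#' @export
fragment_coverage <- function(sample, chrom_sizes) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  df <- sample$fragments
  out <- lapply(names(chrom_sizes), function(ch) {
    sel <- df$chrom == ch
    ir <- IRanges::IRanges(start = df$start[sel] + 1L, end = df$end[sel])
    IRanges::coverage(ir, width = as.integer(chrom_sizes[[ch]]))
  })
  names(out) <- names(chrom_sizes)
  out
}

#' Mean per-base fragment coverage over an interval
#'
#' @param cov coverage list from [fragment_coverage()], or a
#'   [sample_fragments()] object (then `chrom_sizes` is required).
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param chrom_sizes needed only when `cov` is a fragment set.
#' @return Mean number of fragments overlapping each base of the interval.
#' @export
region_depth <- function(cov, chrom, start, end, chrom_sizes = NULL) {
  if (inherits(cov, "sample_fragments")) {
    cov <- fragment_coverage(cov, chrom_sizes)
  }
  if (end <= start) stopf("interval of non-positive length")
  if (!chrom %in% names(cov)) return(0)
  window_depth_sum(cov[[chrom]], c(start, end)) / (end - start)
}

# strand-oriented window: offsets [a, b) around tss; for "-" genes mirrored
oriented_window <- function(tss, strand, a, b) {
  if (strand == "-") c(tss - b + 1, tss - a + 1) else c(tss + a, tss + b)
}

window_depth_sum <- function(r, win) {
  s <- max(win[1] + 1, 1)
  e <- min(win[2], length(r))
  if (e < s) return(0)
  v <- IRanges::Views(r, s, e)
  sum(S4Vectors::runValue(v) * S4Vectors::runLength(v))
}

collapse_tss <- function(tss) {
  stopifnot(all(c("gene", "chrom", "strand", "tss") %in% names(tss)))
  if (!anyDuplicated(tss$gene)) return(tss)
  # duplicates collapse to the most upstream TSS by strand
  parts <- split(tss, tss$gene)
  out <- do.call(rbind, lapply(parts, function(p) {
    if (nrow(p) == 1) return(p)
    i <- if (p$strand[1] == "-") which.max(p$tss) else which.min(p$tss)
    p[i, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' TSS relative coverages per gene for one sample
#'
#' @param sample a [sample_fragments()] object.
#' @param tss data frame with columns `gene`, `chrom`, `strand` (`+`/`-`),
#'   `tss` (0-based position). Multiple TSSs per gene collapse to the most
#'   upstream by strand.
#' @param chrom_sizes chromosome sizes (vector / data frame / path).
#' @param ndr_window,k2_window integer offsets `c(a, b)` defining the
#'   half-open strand-oriented window `[tss + a, tss + b)`.
#' @param ref_offsets `c(inner, outer)`: the reference is the union of the
#'   upstream and downstream flanks at offsets `(-outer, -inner)` and
#'   `(inner, outer)`.
#' @return Data frame per gene: `gene`, `chrom`, `strand`, `tss`,
#'   `conventional_rc`, `ndr_rc`, `k2_rc` (NA when the reference depth is
#'   zero). Genes within `outer` of a chromosome edge are skipped and
#'   listed in attribute `skipped`. Attribute `sample_id` records the
#'   sample.
#' @export
tss_relative_coverages <- function(sample, tss, chrom_sizes,
                                   ndr_window = c(-150, 50),
                                   k2_window = c(-1000, 1000),
                                   ref_offsets = c(1000, 3000)) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  tss <- collapse_tss(tss)
  cov <- fragment_coverage(sample, chrom_sizes)
  genome_size <- sum(chrom_sizes)
  genome_mean <- sum(sample$fragments$length) / genome_size
  outer <- ref_offsets[2]
  edge <- tss$tss < outer |
    tss$tss + outer > chrom_sizes[tss$chrom] |
    !(tss$chrom %in% names(chrom_sizes))
  skipped <- tss$gene[edge | is.na(edge)]
  keep <- tss[!(edge | is.na(edge)), , drop = FALSE]
  # vectorised half-open strand-oriented windows: offsets [a, b) around tss
  win <- function(tss_pos, strand, a, b) {
    cbind(start = ifelse(strand == "-", tss_pos - b + 1, tss_pos + a),
          end = ifelse(strand == "-", tss_pos - a + 1, tss_pos + b))
  }
  sums <- function(r, w) IRanges::viewSums(IRanges::Views(r, w[, 1] + 1, w[, 2]))
  keep$conventional_rc <- keep$ndr_rc <- keep$k2_rc <- NA_real_
  for (ch in unique(keep$chrom)) {
    sel <- keep$chrom == ch
    r <- cov[[ch]]
    g <- keep[sel, ]
    d_ndr <- sums(r, win(g$tss, g$strand, ndr_window[1], ndr_window[2])) /
      (ndr_window[2] - ndr_window[1])
    d_k2 <- sums(r, win(g$tss, g$strand, k2_window[1], k2_window[2])) /
      (k2_window[2] - k2_window[1])
    ref_w <- 2 * (ref_offsets[2] - ref_offsets[1])
    d_ref <- (sums(r, win(g$tss, g$strand, -ref_offsets[2], -ref_offsets[1])) +
                sums(r, win(g$tss, g$strand, ref_offsets[1], ref_offsets[2]))) /
      ref_w
    keep$conventional_rc[sel] <- if (genome_mean > 0) d_k2 / genome_mean else NA_real_
    keep$ndr_rc[sel] <- ifelse(d_ref > 0, d_ndr / d_ref, NA_real_)
    keep$k2_rc[sel] <- ifelse(d_ref > 0, d_k2 / d_ref, NA_real_)
  }
  out <- keep[c("gene", "chrom", "strand", "tss", "conventional_rc",
                "ndr_rc", "k2_rc")]
  rownames(out) <- NULL
  attr(out, "skipped") <- as.character(skipped)
  attr(out, "sample_id") <- sample$sample_id
  out
}

#' Cohort chromatin-state call per gene
#'
#' A gene is called permissive (open chromatin) when both its NDR and 2K
#' relative coverages are below `open_threshold` in a strict majority of
#' samples, nonpermissive (closed) when both exceed `closed_threshold` in a
#' strict majority, and indeterminate otherwise.
#'
#' @param coverages long data frame with columns `sample_id`, `gene`,
#'   `ndr_rc`, `k2_rc` (e.g. stacked [tss_relative_coverages()] results),
#'   or a list of per-sample tables.
#' @param open_threshold both coverages `<` this for an "open" vote
#'   (default 1).
#' @param closed_threshold both coverages `>` this for a "closed" vote
#'   (default 1.5).
#' @param freq_min strict majority fraction (default 0.5).
#' @return Data frame per gene: `gene`, `n_samples`, `median_ndr_rc`,
#'   `median_k2_rc`, `freq_open`, `freq_closed`, `state`.
#' @export
classify_chromatin_state <- function(coverages, open_threshold = 1.0,
                                     closed_threshold = 1.5, freq_min = 0.5) {
  if (is.list(coverages) && !is.data.frame(coverages)) {
    coverages <- do.call(rbind, lapply(names(coverages), function(id) {
      cbind(sample_id = id, coverages[[id]][c("gene", "ndr_rc", "k2_rc")],
            stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("gene", "ndr_rc", "k2_rc") %in% names(coverages)))
  if (!nrow(coverages)) stopf("no coverage rows")
  parts <- split(coverages, coverages$gene)
  out <- do.call(rbind, lapply(names(parts), function(gname) {
    p <- parts[[gname]]
    ok <- !is.na(p$ndr_rc) & !is.na(p$k2_rc)
    p <- p[ok, , drop = FALSE]
    n <- nrow(p)
    fo <- if (n) mean(p$ndr_rc < open_threshold & p$k2_rc < open_threshold) else NA_real_
    fc <- if (n) mean(p$ndr_rc > closed_threshold & p$k2_rc > closed_threshold) else NA_real_
    state <- if (!n) "indeterminate"
    else if (fo > freq_min) "permissive"
    else if (fc > freq_min) "nonpermissive"
    else "indeterminate"
    data.frame(gene = gname, n_samples = n,
               median_ndr_rc = if (n) median(p$ndr_rc) else NA_real_,
               median_k2_rc = if (n) median(p$k2_rc) else NA_real_,
               freq_open = fo, freq_closed = fc, state = state,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Concordance between chromatin-state calls and expression
#'
#' Two complementary rank-sum checks: (1) expression of permissive vs
#' nonpermissive genes; (2) relative coverage of genes labelled up- vs
#' downregulated. Both two-sided Wilcoxon; groups with fewer than 2 genes
#' skip the test with a warning.
#'
#' @param states output of [classify_chromatin_state()] (or `NULL`).
#' @param expression data frame with `gene` and `expression`, and
#'   optionally `group` (`"up"`/`"down"`) for the coverage comparison.
#' @param coverages optional long coverage table (as in
#'   [classify_chromatin_state()]) for the up/down coverage test, compared
#'   on per-gene median `ndr_rc`.
#' @return List with elements `expression_by_state` and `coverage_by_group`,
#'   each either `NULL` or a list with `p`, `medians`, `direction`.
#' @export
expression_concordance <- function(states = NULL, expression, coverages = NULL) {
  res <- list(expression_by_state = NULL, coverage_by_group = NULL)
  if (!is.null(states)) {
    m <- merge(states[c("gene", "state")], expression, by = "gene")
    perm <- m$expression[m$state == "permissive"]
    nonp <- m$expression[m$state == "nonpermissive"]
    if (length(perm) >= 2 && length(nonp) >= 2) {
      wt <- wilcox.test(perm, nonp, alternative = "two.sided", exact = FALSE)
      res$expression_by_state <- list(
        p = wt$p.value,
        medians = c(permissive = median(perm), nonpermissive = median(nonp)),
        direction = if (median(perm) > median(nonp)) "permissive > nonpermissive"
                    else "permissive <= nonpermissive")
    } else {
      warnf("fewer than 2 genes in a state group; expression test skipped")
    }
  }
  if (!is.null(coverages) && "group" %in% names(expression)) {
    med <- aggregate(ndr_rc ~ gene, data = coverages, FUN = median)
    m <- merge(med, expression[c("gene", "group")], by = "gene")
    up <- m$ndr_rc[m$group == "up"]
    down <- m$ndr_rc[m$group == "down"]
    if (length(up) >= 2 && length(down) >= 2) {
      wt <- wilcox.test(up, down, alternative = "two.sided", exact = FALSE)
      res$coverage_by_group <- list(
        p = wt$p.value,
        medians = c(up = median(up), down = median(down)),
        direction = if (median(up) < median(down)) "up < down"
                    else "up >= down")
    } else {
      warnf("fewer than 2 genes in an expression group; coverage test skipped")
    }
  }
  res
}
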