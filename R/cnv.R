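# Bin-level copy-number scores against a healthy reference panel and
# gene-level amplification calls.
#
# The per-bin score is the log2 ratio of the sample's GC-corrected bin
# fraction to the panel median fraction (shallow-WGS practice), with a
# panel z-score as the significance scale. Because bin fractions sum to 1,
# the score is invariant to library size.

#' Per-bin copy-number scores for one sample
#'
#' @param sample_fractions numeric per-bin corrected fractions for the
#'   sample (see [sample_profile()], column `fraction`).
#' @param panel numeric matrix of per-bin fractions for the healthy panel,
#'   bins in rows (same order as `sample_fractions`), samples in columns;
#'   at least 3 panel samples.
#' @return `cnv_profile` data frame: `log2_ratio`, `z`, `masked` per bin.
#'   Bins with zero/NA panel median or zero panel standard deviation are
#'   masked.
#' @export
cnv_scores <- function(sample_fractions, panel) {
  panel <- as.matrix(panel)
  if (ncol(panel) < 3) stopf("healthy panel needs >= 3 samples")
  if (nrow(panel) != length(sample_fractions)) {
    stopf("bin count mismatch: sample has %d bins, panel has %d",
          length(sample_fractions), nrow(panel))
  }
  med <- apply(panel, 1, median)
  mu <- rowMeans(panel)
  sdev <- apply(panel, 1, sd)
  masked <- is.na(sample_fractions) | is.na(med) | med <= 0 |
    is.na(sdev) | sdev == 0
  log2_ratio <- ifelse(masked, NA_real_, log2(sample_fractions / med))
  z <- ifelse(masked, NA_real_, (sample_fractions - mu) / sdev)
  structure(data.frame(log2_ratio = log2_ratio, z = z, masked = masked),
            class = c("cnv_profile", "data.frame"))
}

#' Bind per-sample fraction profiles into a bins-by-samples matrix
#'
#' @param profiles list of [sample_profile()] objects (their `fraction`
#'   columns are used), a list of numeric vectors, or an existing matrix
#'   (returned unchanged).
#' @return Numeric matrix, bins in rows, samples in columns.
#' @export
fraction_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1)
  vapply(profiles, function(p) {
    if (is.data.frame(p)) p$fraction else as.numeric(p)
  }, numeric(if (is.data.frame(profiles[[1]])) nrow(profiles[[1]])
             else length(profiles[[1]])))
}

#' Compare per-sample copy-number score variance between groups
#'
#' In healthy plasma the bin scores concentrate around zero; copy-number
#' altered tumours disperse them. Per sample, the variance of `log2_ratio`
#' over unmasked bins is computed against the healthy panel median, and the
#' two groups are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param cancer,healthy per-bin fraction matrices (bins x samples) or
#'   named lists of [sample_profile()] objects. The healthy group doubles
#'   as the reference panel.
#' @return List with `variance` (named list of per-sample variances by
#'   group), `p` and `statistic` (NULL when a group has < 2 samples).
#' @export
cohort_variance_test <- function(cancer, healthy) {
  cancer <- fraction_matrix(cancer)
  healthy <- fraction_matrix(healthy)
  per_sample_var <- function(mat) {
    apply(mat, 2, function(fr) {
      sc <- cnv_scores(fr, healthy)
      var(sc$log2_ratio[!sc$masked])
    })
  }
  v <- list(cancer = per_sample_var(cancer), healthy = per_sample_var(healthy))
  if (length(v$cancer) < 2 || length(v$healthy) < 2) {
    warnf("a group has fewer than 2 samples; variance test skipped")
    return(list(variance = v, p = NULL, statistic = NULL))
  }
  wt <- wilcox.test(v$cancer, v$healthy, alternative = "two.sided",
                    exact = FALSE)
  list(variance = v, p = wt$p.value, statistic = unname(wt$statistic))
}

#' Call amplified genes from bin-level copy-number scores
#'
#' Maps each gene to the bins overlapping its span, scores every sample at
#' every gene by the mean `log2_ratio` over those bins (computed against the
#' healthy panel median), compares cancer vs healthy per gene with a
#' two-sided Wilcoxon rank-sum test, adjusts with Benjamini-Hochberg across
#' genes, and calls a gene amplified when `q < alpha` and the cancer group
#' mean exceeds the healthy group mean.
#'
#' @param cancer,healthy per-bin fraction matrices (bins x samples) or
#'   lists of [sample_profile()] objects; `healthy` is also the panel.
#' @param bins the [make_bins()] object the fractions were computed on.
#' @param genes data frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open spans).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return Data frame, one row per gene: `gene`, `chrom`, `n_bins`,
#'   `cancer_mean`, `healthy_mean`, `statistic`, `p`, `q`, `call`
#'   (`"amplified"`/`"not_called"`), `reason`.
#' @export
call_amplified_genes <- function(cancer, healthy, bins, genes, alpha = 0.05) {
  stopifnot(inherits(bins, "genome_bins"),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  cancer <- fraction_matrix(cancer)
  healthy <- fraction_matrix(healthy)
  scores_c <- lapply(seq_len(ncol(cancer)), function(j)
    cnv_scores(cancer[, j], healthy))
  scores_h <- lapply(seq_len(ncol(healthy)), function(j)
    cnv_scores(healthy[, j], healthy))
  masked <- Reduce(`|`, lapply(c(scores_c, scores_h), function(s) s$masked))
  l2_c <- vapply(scores_c, function(s) s$log2_ratio, numeric(nrow(bins$bins)))
  l2_h <- vapply(scores_h, function(s) s$log2_ratio, numeric(nrow(bins$bins)))

  bin_rows_for <- function(chrom, start, end) {
    which(bins$bins$chrom == chrom & bins$bins$start < end &
            bins$bins$end > start & !masked)
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    b <- bin_rows_for(g$chrom, g$start, g$end)
    if (!length(b)) {
      return(data.frame(gene = g$gene, chrom = g$chrom, n_bins = 0L,
                        cancer_mean = NA_real_, healthy_mean = NA_real_,
                        statistic = NA_real_, p = NA_real_,
                        reason = "all bins masked or unmapped",
                        stringsAsFactors = FALSE))
    }
    gs_c <- colMeans(l2_c[b, , drop = FALSE])
    gs_h <- colMeans(l2_h[b, , drop = FALSE])
    wt <- wilcox.test(gs_c, gs_h, alternative = "two.sided", exact = FALSE)
    data.frame(gene = g$gene, chrom = g$chrom, n_bins = length(b),
               cancer_mean = mean(gs_c), healthy_mean = mean(gs_h),
               statistic = unname(wt$statistic), p = wt$p.value,
               reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out$call <- ifelse(tested & out$q < alpha & out$cancer_mean > out$healthy_mean,
                     "amplified", "not_called")
  rownames(out) <- NULL
  out[c("gene", "chrom", "n_bins", "cancer_mean", "healthy_mean",
        "statistic", "p", "q", "call", "reason")]
}
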