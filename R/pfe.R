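# Promoter fragmentation entropy (PFE): Shannon entropy of the fragment
# length distribution around each TSS. Actively transcribed promoters show
# a more diverse (less strictly mononucleosomal) length mix, hence higher
# entropy.

#' Shannon entropy of a count vector, in bits
#'
#' A pseudocount is added to every bin before normalising, acting as a mild
#' shrinkage toward uniform for sparse promoters; with `pseudocount = 0`,
#' empty bins contribute zero (the `0 log 0 = 0` convention).
#'
#' @param counts non-negative counts over the length bins.
#' @param pseudocount added to every bin (default 0).
#' @return Entropy in bits, in `[0, log2(length(counts))]`.
#' @export
shannon_entropy <- function(counts, pseudocount = 0) {
  stopifnot(all(counts >= 0))
  x <- counts + pseudocount
  tot <- sum(x)
  if (tot <= 0) stopf("entropy undefined for all-zero counts without pseudocount")
  p <- x / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Promoter fragmentation entropy per gene
#'
#' Fragments whose midpoint falls within `window` bp of the strand-oriented
#' TSS and whose length lies in `length_range` are tallied into
#' `bin_width`-bp length bins; the Shannon entropy of that distribution is
#' the gene's PFE. Genes with fewer than `min_fragments` supporting
#' fragments report `NA` (the pseudocount would otherwise dominate).
#'
#' @param sample a [sample_fragments()] object.
#' @param tss TSS annotation data frame (`gene`, `chrom`, `strand`, `tss`).
#' @param window half-width of the promoter window in bp (default 1000).
#' @param length_range inclusive fragment-length range (default 100-220 bp).
#' @param bin_width length-bin width in bp (default 5; 24 bins for the
#'   default range).
#' @param pseudocount per-bin pseudocount (default 0.5).
#' @param min_fragments support floor below which PFE is missing
#'   (default 20).
#' @return Data frame per gene: `gene`, `n_fragments`, `entropy` (bits),
#'   `normalized_entropy` (`entropy / log2(K)`), `reason`.
#' @export
promoter_entropy <- function(sample, tss, window = 1000,
                             length_range = c(100, 220), bin_width = 5,
                             pseudocount = 0.5, min_fragments = 20) {
  stopifnot(inherits(sample, "sample_fragments"))
  tss <- collapse_tss(tss)
  k <- as.integer(floor((length_range[2] - length_range[1]) / bin_width))
  if (k < 2) stopf("need at least 2 length bins")
  df <- sample$fragments
  df <- df[df$length >= length_range[1] & df$length <= length_range[2], ,
           drop = FALSE]
  counts <- matrix(0L, nrow = nrow(tss), ncol = k)
  if (nrow(df)) {
    mid <- floor((df$start + df$end) / 2)
    lbin <- pmin(((df$length - length_range[1]) %/% bin_width) + 1L, k)
    for (ch in unique(tss$chrom)) {
      gi <- which(tss$chrom == ch)
      fi <- which(df$chrom == ch)
      if (!length(fi)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = mid[fi] + 1L, width = 1L),
        IRanges::IRanges(start = tss$tss[gi] - window + 1L,
                         end = tss$tss[gi] + window)
      )
      if (!length(hits)) next
      gidx <- gi[S4Vectors::subjectHits(hits)]
      bidx <- lbin[fi[S4Vectors::queryHits(hits)]]
      tab <- table(factor(gidx, levels = seq_len(nrow(tss))),
                   factor(bidx, levels = seq_len(k)))
      counts <- counts + unclass(tab)
    }
  }
  n <- rowSums(counts)
  entropy <- rep(NA_real_, nrow(tss))
  ok <- n >= min_fragments
  entropy[ok] <- apply(counts[ok, , drop = FALSE], 1, shannon_entropy,
                       pseudocount = pseudocount)
  data.frame(
    gene = tss$gene, n_fragments = as.integer(n),
    entropy = entropy,
    normalized_entropy = entropy / log2(k),
    reason = ifelse(ok, "", sprintf("fewer than %d fragments", min_fragments)),
    stringsAsFactors = FALSE
  )
}

#' Compare mean PFE between gene groups
#'
#' Per-gene mean PFE across samples (non-missing values), compared between
#' up- and downregulated gene sets with a two-sided Wilcoxon rank-sum test.
#'
#' @param pfe long data frame with columns `sample_id`, `gene`, `entropy`
#'   (stacked [promoter_entropy()] results), or a named list of per-sample
#'   tables.
#' @param groups data frame with `gene` and `group` (`"up"`/`"down"`).
#' @return List with `p`, `medians`, `direction`, `n` per group; or a list
#'   with `reason = "insufficient support"` when fewer than 2 genes per
#'   group have non-missing PFE.
#' @export
pfe_group_comparison <- function(pfe, groups) {
  if (is.list(pfe) && !is.data.frame(pfe)) {
    pfe <- do.call(rbind, lapply(names(pfe), function(id) {
      cbind(sample_id = id, pfe[[id]][c("gene", "entropy")],
            stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("gene", "entropy") %in% names(pfe)),
            all(c("gene", "group") %in% names(groups)))
  ok <- !is.na(pfe$entropy)
  if (!any(ok)) {
    warnf("all PFE values missing")
    return(list(p = NULL, reason = "insufficient support"))
  }
  mean_pfe <- aggregate(entropy ~ gene, data = pfe[ok, ], FUN = mean)
  m <- merge(mean_pfe, groups, by = "gene")
  up <- m$entropy[m$group == "up"]
  down <- m$entropy[m$group == "down"]
  if (length(up) < 2 || length(down) < 2) {
    warnf("fewer than 2 genes per group with non-missing PFE")
    return(list(p = NULL, reason = "insufficient support"))
  }
  wt <- wilcox.test(up, down, alternative = "two.sided", exact = FALSE)
  list(p = wt$p.value,
       medians = c(up = median(up), down = median(down)),
       direction = if (median(up) > median(down)) "up > down" else "up <= down",
       n = c(up = length(up), down = length(down)))
}
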