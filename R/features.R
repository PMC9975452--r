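# In-memory assembly of the per-modality feature blocks from a cohort of
# fragment sets. The pipeline builds the same blocks from its stage TSVs;
# this path serves programmatic use on cohorts held in memory.

#' Build per-modality feature blocks for a cohort
#'
#' Computes, per sample: the five size fractions; per-bin normalized
#' fragment ratios plus the Pearson r to the healthy-median ratio profile;
#' the r to the healthy-median fraction profile; copy-number summaries
#' (variance of `log2_ratio`, mean `|z|`) against the healthy panel; mean
#' NDR/2K relative coverage over the gene panel; mean promoter
#' fragmentation entropy; and per-TF central occupancy scores.
#'
#' @param samples named list of [sample_fragments()] objects.
#' @param labels named vector of `"cancer"`/`"healthy"` labels (samples with
#'   other labels are ignored).
#' @param bins a [make_bins()] object with GC attached.
#' @param tss optional TSS annotation data frame (enables the `tss` and
#'   `pfe` blocks).
#' @param tf_sites optional named list of TF site data frames (enables the
#'   `tf` block).
#' @param chrom_sizes chromosome sizes; defaults to the bin frame's.
#' @param short_range,long_range,gc_span see [sample_profile()].
#' @param pfe_min_fragments see [promoter_entropy()].
#' @return Named list of feature matrices (rows = samples), ready for
#'   [assemble_features()].
#' @export
build_feature_blocks <- function(samples, labels, bins, tss = NULL,
                                 tf_sites = NULL, chrom_sizes = NULL,
                                 short_range = c(100, 150),
                                 long_range = c(151, 220), gc_span = 0.75,
                                 pfe_min_fragments = 20) {
  chrom_sizes <- chrom_sizes %||% bins$chrom_sizes
  ids <- names(samples)[names(samples) %in%
                          names(labels)[labels %in% c("cancer", "healthy")]]
  samples <- samples[ids]
  healthy <- ids[labels[ids] == "healthy"]
  if (!length(healthy)) stopf("no healthy samples for the reference panel")
  blocks <- list()

  hists <- lapply(samples, size_histogram)
  blocks$size_fractions <- t(vapply(hists, size_fractions, numeric(5)))

  profiles <- lapply(samples, sample_profile, bins = bins,
                     short_range = short_range, long_range = long_range,
                     gc_span = gc_span)
  sim_r <- cohort_similarity(profiles, healthy_ids = healthy, on = "ratio")
  sim_f <- cohort_similarity(profiles, healthy_ids = healthy, on = "fraction")
  ratio_mat <- t(vapply(profiles, function(p) p$normalized_ratio,
                        numeric(nrow(bins$bins))))
  colnames(ratio_mat) <- paste0(bins$bins$chrom, ":", bins$bins$start)
  blocks$fragment_ratio <- cbind(ratio_mat,
                                 r_to_reference = sim_r$r_to_reference[ids])
  blocks$fragment_fraction <- matrix(
    sim_f$r_to_reference[ids], ncol = 1,
    dimnames = list(ids, "r_to_reference"))

  panel <- fraction_matrix(profiles[healthy])
  blocks$cnv <- t(vapply(profiles, function(p) {
    sc <- cnv_scores(p$fraction, panel)
    c(log2_var = var(sc$log2_ratio[!sc$masked]),
      mean_abs_z = mean(abs(sc$z[!sc$masked])))
  }, numeric(2)))

  if (!is.null(tss)) {
    tss_stats <- t(vapply(samples, function(s) {
      cov <- tss_relative_coverages(s, tss, chrom_sizes)
      c(mean_ndr_rc = mean(cov$ndr_rc, na.rm = TRUE),
        mean_k2_rc = mean(cov$k2_rc, na.rm = TRUE))
    }, numeric(2)))
    blocks$tss <- tss_stats
    pfe_stats <- vapply(samples, function(s) {
      pfe <- promoter_entropy(s, tss, min_fragments = pfe_min_fragments)
      mean(pfe$entropy, na.rm = TRUE)
    }, 0)
    blocks$pfe <- matrix(pfe_stats, ncol = 1,
                         dimnames = list(ids, "mean_entropy"))
  }

  if (!is.null(tf_sites)) {
    blocks$tf <- t(vapply(samples, function(s) {
      tf_feature_vector(lapply(
        setNames(names(tf_sites), names(tf_sites)),
        function(tf) tryCatch(
          composite_profile(s, tf_sites[[tf]], chrom_sizes, tf_name = tf),
          error = function(e) NA)))
    }, numeric(length(tf_sites))))
  }
  lapply(blocks, function(b) {
    rownames(b) <- ids
    b
  })
}
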