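# Composite nucleosome-occupancy profiles around transcription-factor
# binding sites. Coverage is averaged across sites, normalised to the outer
# flanks, and summarised by a central score: occupied (nucleosome-bound)
# site sets stay near 1, active sites show central depletion well below 1.

#' Composite coverage profile around a set of TF binding sites
#'
#' @param sample a [sample_fragments()] object.
#' @param sites data frame of binding sites: `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand`; the profile is computed
#'   around each site's midpoint, strand-oriented when strand is given.
#' @param chrom_sizes chromosome sizes (vector / data frame / path).
#' @param window profile half-width in bp (default 1000).
#' @param step position step in bp (default 10).
#' @param min_sites minimum usable sites (default 10).
#' @param flank_fraction fraction of positions on each end treated as
#'   normalising flank (default 0.25).
#' @param central_halfwidth half-width of the central score window in bp
#'   (default 50).
#' @param tf_name label carried into the result.
#' @return `composite_profile`: list with `tf`, `offsets`, `mean_coverage`
#'   (flank-normalised), `raw_coverage`, `n_sites`, `central_score`.
#' @export
composite_profile <- function(sample, sites, chrom_sizes, window = 1000,
                              step = 10, min_sites = 10,
                              flank_fraction = 0.25, central_halfwidth = 50,
                              tf_name = "TF") {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (!nrow(sites)) stopf("empty site list for %s", tf_name)
  center <- floor((sites$start + sites$end) / 2)
  usable <- sites$chrom %in% names(chrom_sizes) &
    center - window >= 0 &
    center + window < chrom_sizes[sites$chrom]
  usable[is.na(usable)] <- FALSE
  if (!any(usable)) stopf("all sites skipped (chromosome edges) for %s", tf_name)
  if (sum(usable) < min_sites) {
    stopf("too few sites for %s: %d usable, %d required",
          tf_name, sum(usable), min_sites)
  }
  sites <- sites[usable, , drop = FALSE]
  center <- center[usable]
  strand <- if ("strand" %in% names(sites)) as.character(sites$strand)
            else rep("+", nrow(sites))
  cov <- fragment_coverage(sample, chrom_sizes)
  offsets <- seq(-window, window, by = step)
  acc <- numeric(length(offsets))
  for (ch in unique(sites$chrom)) {
    sel <- which(sites$chrom == ch)
    r <- cov[[ch]]
    v <- IRanges::Views(r, start = center[sel] - window + 1L,
                        end = center[sel] + window + 1L)
    m <- t(IRanges::viewApply(v, as.numeric))  # sites x positions
    rev_rows <- strand[sel] == "-"
    if (any(rev_rows)) m[rev_rows, ] <- m[rev_rows, ncol(m):1, drop = FALSE]
    keep_cols <- seq(1L, ncol(m), by = step)
    acc <- acc + colSums(m[, keep_cols, drop = FALSE])
  }
  raw <- acc / nrow(sites)
  n_flank <- max(1L, floor(flank_fraction * length(offsets)))
  flank_mean <- mean(c(head(raw, n_flank), tail(raw, n_flank)))
  if (flank_mean <= 0) stopf("no flank coverage for %s", tf_name)
  norm <- raw / flank_mean
  central <- abs(offsets) <= central_halfwidth
  structure(list(tf = tf_name, offsets = offsets, mean_coverage = norm,
                 raw_coverage = raw, n_sites = nrow(sites),
                 central_score = mean(norm[central])),
            class = "composite_profile")
}

#' @export
print.composite_profile <- function(x, ...) {
  cat(sprintf("<composite_profile> %s: %d sites, central score %.3f\n",
              x$tf, x$n_sites, x$central_score))
  invisible(x)
}

#' Per-sample vector of TF central occupancy scores
#'
#' @param profiles named list of [composite_profile()] results (or `NA` for
#'   TFs that failed for this sample).
#' @return Named numeric vector of central scores, `NA` where missing.
#' @export
tf_feature_vector <- function(profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  vapply(profiles, function(p) {
    if (inherits(p, "composite_profile")) p$central_score else NA_real_
  }, 0)
}
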