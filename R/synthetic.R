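# Seeded simulator of cfDNA fragment cohorts with the statistical structure
# the feature modules assume: nucleosomal size mixtures, per-bin copy-number
# multipliers, a smooth GC sampling bias, promoter nucleosome depletion
# coupled to expression labels, TF-site central depletion, and a hemolysis
# contamination mode. Ground truth for every simulated entity is returned
# alongside the fragments.

size_mixture <- function(role, dist, p1, p2, shift, weight) {
  data.frame(role = role, dist = dist, p1 = p1, p2 = p2, shift = shift,
             weight = weight, stringsAsFactors = FALSE)
}

default_mixtures <- function() {
  list(
    # healthy plasma: dominant ~167 bp mononucleosome peak, dinucleosomal
    # shoulder, sub-mononucleosomal ladder, traces of short and very long DNA
    healthy = size_mixture(
      role = c("mono", "di", "short", "sub", "tail"),
      dist = c("norm", "norm", "norm", "norm", "expshift"),
      p1 = c(167, 334, 145, 60, 600), p2 = c(10, 20, 10, 12, NA),
      shift = c(0, 0, 0, 0, 150),
      weight = c(0.76, 0.07, 0.10, 0.05, 0.02)),
    # cancer: enriched short (~145 bp) tumour-derived fragments
    cancer = size_mixture(
      role = c("mono", "di", "short", "sub", "tail"),
      dist = c("norm", "norm", "norm", "norm", "expshift"),
      p1 = c(167, 334, 145, 60, 600), p2 = c(10, 20, 10, 12, NA),
      shift = c(0, 0, 0, 0, 150),
      weight = c(0.63, 0.06, 0.22, 0.05, 0.04)),
    # hemolysis: genomic DNA rising steeply from 150 bp plus excess
    # 30-60 bp reads; the short cfDNA component collapses
    hemolysis = size_mixture(
      role = c("mono", "di", "sub", "gdna"),
      dist = c("norm", "norm", "norm", "gammashift"),
      p1 = c(167, 334, 45, 2), p2 = c(10, 20, 8, 120),
      shift = c(0, 0, 0, 150),
      weight = c(0.33, 0.04, 0.06, 0.57))
  )
}

# reweight the "short" component by a per-bin multiplier, keeping the
# weights normalised
adjust_short_weight <- function(mixture, m) {
  i <- which(mixture$role == "short")
  if (!length(i) || m == 1) return(mixture)
  mixture$weight[i] <- mixture$weight[i] * m
  mixture$weight <- mixture$weight / sum(mixture$weight)
  mixture
}

draw_lengths <- function(n, mixture, min_len = 30) {
  comp <- sample.int(nrow(mixture), n, replace = TRUE, prob = mixture$weight)
  len <- numeric(n)
  for (i in seq_len(nrow(mixture))) {
    sel <- comp == i
    m <- sum(sel)
    if (!m) next
    len[sel] <- switch(mixture$dist[i],
      norm = rnorm(m, mixture$p1[i], mixture$p2[i]),
      expshift = mixture$shift[i] + stats::rexp(m, rate = 1 / mixture$p1[i]),
      gammashift = mixture$shift[i] +
        rgamma(m, shape = mixture$p1[i], scale = mixture$p2[i]),
      stopf("unknown mixture component '%s'", mixture$dist[i]))
  }
  len <- round(len)
  while (any(bad <- len < min_len)) {
    len[bad] <- round(draw_lengths(sum(bad), mixture, min_len = -Inf))
    len[bad][len[bad] < min_len] <- min_len
  }
  len
}

#' Analytic probability mass of a size mixture over an integer length range
#'
#' Probability that a simulated (rounded) fragment length falls in
#' `[lo, hi]`, computed by integrating each mixture component with a 0.5 bp
#' continuity correction. Truncation below `min_len` is accounted for.
#'
#' @param mixture a mixture table from [sim_config()]
#'   (`config$mixtures[[label]]`).
#' @param lo,hi inclusive integer bounds (`hi` may be `Inf`).
#' @param min_len lower truncation applied at simulation time.
#' @return Probability in `[0, 1]`.
#' @export
mixture_mass <- function(mixture, lo, hi, min_len = 30) {
  comp_cdf <- function(i, q) {
    switch(mixture$dist[i],
      norm = stats::pnorm(q, mixture$p1[i], mixture$p2[i]),
      expshift = stats::pexp(pmax(q - mixture$shift[i], 0),
                             rate = 1 / mixture$p1[i]),
      gammashift = stats::pgamma(pmax(q - mixture$shift[i], 0),
                                 shape = mixture$p1[i],
                                 scale = mixture$p2[i]))
  }
  mass <- function(a, b) {
    sum(vapply(seq_len(nrow(mixture)), function(i) {
      mixture$weight[i] * (comp_cdf(i, b) - comp_cdf(i, a))
    }, 0))
  }
  lo_q <- lo - 0.5
  hi_q <- if (is.infinite(hi)) Inf else hi + 0.5
  trunc_q <- min_len - 0.5
  mass(max(lo_q, trunc_q), hi_q) / mass(trunc_q, Inf)
}

#' Simulator configuration
#'
#' Defines the study conditions for a synthetic cfDNA cohort on a miniature
#' genome: three 30 Mb chromosomes tiled into 5 Mb bins, 180 genes (equal
#' thirds labelled up / down / neutral, with upregulated genes open and
#' depleted around the TSS and downregulated genes closed and
#' over-protected), two TF site sets with deeper central depletion in
#' cancer, a smooth GC gradient across bins with an exponential sampling
#' bias, and per-bin copy-number multipliers corresponding to a 1.5x
#' amplification at 25% tumour fraction in a subset of bins.
#'
#' @param genome named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp.
#' @param n_fragments fragments per sample.
#' @param mixtures named list (`healthy`, `cancer`, `hemolysis`) of size
#'   mixture tables; weights must sum to 1.
#' @param gc_range per-bin GC gradient range across the genome. The
#'   gradient is assigned to bins in a fixed scrambled order so GC and
#'   genomic position are decoupled.
#' @param gc_strength exponential GC-preference strength (0 disables bias).
#' @param ratio_amplitude relative amplitude of the shared sinusoidal
#'   per-bin modulation of the short-fragment weight (the "fragmentation
#'   landscape" all samples have in common).
#' @param cancer_ratio_noise standard deviation of the per-sample
#'   log-normal per-bin distortion of the short-fragment weight in cancer
#'   samples (mean-one, so genome-wide size masses are preserved to first
#'   order); this is what makes cancer ratio profiles heterogeneous.
#' @param n_genes number of genes (spaced `gene_spacing` bp apart).
#' @param gene_spacing distance between consecutive TSSs in bp.
#' @param ndr_depletion promoter thinning factor for upregulated genes
#'   (fragment keep probability in the 2K window; < 1).
#' @param occupancy_factor promoter coverage multiplier for downregulated
#'   genes (> 1, at most 2).
#' @param pfe_spread probability that a promoter fragment of an upregulated
#'   gene redraws its length uniformly on 100-220 bp (entropy coupling).
#' @param tss_window promoter half-width in bp for all promoter effects.
#' @param amplified_bins indices of bins amplified in cancer samples.
#' @param copy_ratio amplified copy ratio (1.5 = 3 copies vs 2).
#' @param tumor_fraction tumour DNA fraction in cancer plasma.
#' @param tf_sites number of binding sites per TF.
#' @param tf_depletion data frame with `tf`, `healthy`, `cancer` central
#'   depletion factors (fragment keep probability within +-100 bp of a
#'   site).
#' @param min_len minimum simulated fragment length (bp).
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(genome = c(chr1 = 30e6, chr2 = 30e6, chr3 = 30e6),
                       bin_size = 5e6,
                       n_fragments = 30000,
                       mixtures = default_mixtures(),
                       gc_range = c(0.35, 0.60),
                       gc_strength = 1.0,
                       ratio_amplitude = 0.3,
                       cancer_ratio_noise = 0.25,
                       n_genes = 180,
                       gene_spacing = 20000,
                       ndr_depletion = 0.4,
                       occupancy_factor = 1.8,
                       pfe_spread = 0.35,
                       tss_window = 1000,
                       amplified_bins = c(4, 10, 16),
                       copy_ratio = 1.5,
                       tumor_fraction = 0.25,
                       tf_sites = 200,
                       tf_depletion = data.frame(
                         tf = c("TF1", "TF2"),
                         healthy = c(0.70, 0.80),
                         cancer = c(0.45, 0.55),
                         stringsAsFactors = FALSE),
                       min_len = 30) {
  config <- list(genome = genome, bin_size = bin_size,
                 n_fragments = n_fragments, mixtures = mixtures,
                 gc_range = gc_range, gc_strength = gc_strength,
                 ratio_amplitude = ratio_amplitude,
                 cancer_ratio_noise = cancer_ratio_noise,
                 n_genes = n_genes, gene_spacing = gene_spacing,
                 ndr_depletion = ndr_depletion,
                 occupancy_factor = occupancy_factor,
                 pfe_spread = pfe_spread, tss_window = tss_window,
                 amplified_bins = amplified_bins, copy_ratio = copy_ratio,
                 tumor_fraction = tumor_fraction, tf_sites = tf_sites,
                 tf_depletion = tf_depletion, min_len = min_len)
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  for (label in names(config$mixtures)) {
    w <- config$mixtures[[label]]$weight
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stopf("mixture weights for '%s' must be non-negative and sum to 1", label)
    }
  }
  if (config$ndr_depletion <= 0 || config$ndr_depletion > 1) {
    stopf("ndr_depletion must lie in (0, 1]")
  }
  if (config$occupancy_factor < 1 || config$occupancy_factor > 2) {
    stopf("occupancy_factor must lie in [1, 2]")
  }
  if (config$tumor_fraction < 0 || config$tumor_fraction > 1) {
    stopf("tumor_fraction must lie in [0, 1]")
  }
  if (any(config$gc_range < 0) || any(config$gc_range > 1)) {
    stopf("gc_range must lie in [0, 1]")
  }
  nb <- sum(vapply(config$genome, function(s) {
    floor(s / config$bin_size) +
      ((s %% config$bin_size) >= config$bin_size / 2)
  }, 0))
  if (any(config$amplified_bins < 1 | config$amplified_bins > nb)) {
    stopf("amplified_bins outside the %d available bins", nb)
  }
  invisible(TRUE)
}

# deterministic per-bin GC gradient + derived layout tables; the gradient
# is assigned in a scrambled (coprime-stride) bin order so that GC is not a
# monotone function of genomic position
sim_layout <- function(config) {
  bins <- make_bins(config$genome, config$bin_size)
  nb <- nrow(bins$bins)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  stride <- 7L
  while (gcd(stride, nb) != 1L) stride <- stride + 1L
  perm <- ((seq_len(nb) - 1L) * stride) %% nb + 1L
  gc <- seq(config$gc_range[1], config$gc_range[2], length.out = nb)[perm]
  bins$bins$gc <- gc
  multipliers <- rep(1, nb)
  multipliers[config$amplified_bins] <-
    1 + config$tumor_fraction * (config$copy_ratio - 1)

  # genes: evenly spaced TSSs, alternating strand, label in equal thirds
  n <- config$n_genes
  chroms <- names(config$genome)
  per_chrom <- ceiling(n / length(chroms))
  gene_rows <- list()
  g <- 0
  for (ch in chroms) {
    for (i in seq_len(per_chrom)) {
      if (g >= n) break
      g <- g + 1
      gene_rows[[g]] <- data.frame(
        gene = sprintf("G%03d", g), chrom = ch,
        strand = if (g %% 2 == 0) "-" else "+",
        tss = 50000 + (i - 1) * config$gene_spacing,
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  if (any(genes$tss + config$tss_window + 3000 > config$genome[genes$chrom])) {
    stopf("gene layout exceeds chromosome length; reduce n_genes or gene_spacing")
  }
  expr_label <- rep(c("up", "down", "neutral"), length.out = nrow(genes))
  genes$expr_label <- expr_label
  genes$state <- c(up = "open", down = "closed", neutral = "neutral")[expr_label]
  # reference expression levels (arbitrary units): level set by label with a
  # deterministic within-group spread so rank tests see variation
  base <- c(up = 50, down = 2, neutral = 10)[expr_label]
  genes$expression <- base * exp(0.6 * sin(seq_len(nrow(genes)) * 2.39996))

  list(bins = bins, multipliers = multipliers, genes = genes)
}

# TF sites are part of the fixed study layout: deterministic placement
sim_tf_sites <- function(config) {
  chroms <- names(config$genome)
  per_tf <- config$tf_sites
  if (per_tf == 0) return(list())
  lapply(setNames(config$tf_depletion$tf, config$tf_depletion$tf), function(tf) {
    k <- match(tf, config$tf_depletion$tf)
    rows <- lapply(seq_along(chroms), function(ci) {
      m <- ceiling(per_tf / length(chroms))
      # offset TFs from each other and start past the gene zone so TF and
      # promoter effects do not overlap
      gene_zone <- 60000 + ceiling(config$n_genes / length(chroms)) *
        config$gene_spacing
      centers <- round(seq(gene_zone + k * 31000,
                           config$genome[chroms[ci]] - 2e5,
                           length.out = m))
      data.frame(chrom = chroms[ci], start = centers - 10, end = centers + 10,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[seq_len(min(per_tf, nrow(out))), , drop = FALSE]
  })
}

#' Simulate one cfDNA sample
#'
#' Fragment midpoints are placed proportionally to bin width x copy-number
#' multiplier x GC preference; lengths are drawn from the label's size
#' mixture; promoter windows of upregulated genes are thinned (and their
#' fragment lengths broadened), promoter windows of downregulated genes are
#' over-covered; TF-site centers are depleted. Deterministic for a fixed
#' seed.
#'
#' @param config a [sim_config()] object.
#' @param label `"cancer"`, `"healthy"` or `"hemolysis"`.
#' @param seed RNG seed.
#' @param sample_id sample identifier.
#' @return List with `sample` (a [sample_fragments()] object) and `truth`
#'   (list: `label`, `hemolysis`, `bin_multipliers`, `genes`, `tf_depletion`).
#' @export
simulate_sample <- function(config, label = c("healthy", "cancer", "hemolysis"),
                            seed = 1, sample_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  label <- match.arg(label)
  sample_id <- sample_id %||% sprintf("%s_%d", label, seed)
  layout <- sim_layout(config)
  bins <- layout$bins$bins
  multipliers <- if (label == "cancer") layout$multipliers else rep(1, nrow(bins))
  tf_sites <- sim_tf_sites(config)
  tf_col <- if (label == "cancer") "cancer" else "healthy"

  frag <- with_seed(seed, {
    gc_pref <- exp(config$gc_strength * (bins$gc - mean(bins$gc)))
    w <- (bins$end - bins$start) * multipliers * gc_pref
    n <- config$n_fragments
    bidx <- sample.int(nrow(bins), n, replace = TRUE, prob = w)
    mid <- bins$start[bidx] +
      floor(runif(n) * (bins$end[bidx] - bins$start[bidx]))
    chrom <- bins$chrom[bidx]

    # promoter effects, applied per chromosome on global keep/boost masks
    genes <- layout$genes
    win <- config$tss_window
    keep <- rep(TRUE, n)
    boost <- rep(FALSE, n)
    in_up_promoter <- rep(FALSE, n)
    for (ch in unique(genes$chrom)) {
      gi <- genes[genes$chrom == ch, , drop = FALSE]
      fi <- which(chrom == ch)
      if (!length(fi)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = mid[fi] + 1L, width = 1L),
        IRanges::IRanges(start = gi$tss - win + 1L, end = gi$tss + win))
      if (!length(hits)) next
      q <- fi[S4Vectors::queryHits(hits)]
      st <- gi$state[S4Vectors::subjectHits(hits)]
      open_q <- q[st == "open"]
      keep[open_q] <- runif(length(open_q)) < config$ndr_depletion
      in_up_promoter[open_q] <- TRUE
      closed_q <- q[st == "closed"]
      boost[closed_q] <- runif(length(closed_q)) <
        (config$occupancy_factor - 1)
    }
    # TF central depletion
    for (tf in names(tf_sites)) {
      s <- tf_sites[[tf]]
      d <- config$tf_depletion[[tf_col]][match(tf, config$tf_depletion$tf)]
      ctr <- floor((s$start + s$end) / 2)
      for (ch in unique(s$chrom)) {
        fi <- which(chrom == ch)
        if (!length(fi)) next
        hits <- IRanges::findOverlaps(
          IRanges::IRanges(start = mid[fi] + 1L, width = 1L),
          IRanges::IRanges(start = ctr[s$chrom == ch] - 99L,
                           end = ctr[s$chrom == ch] + 100L))
        q <- fi[unique(S4Vectors::queryHits(hits))]
        keep[q] <- keep[q] & (runif(length(q)) < d)
      }
    }

    idx <- c(which(keep), which(keep & boost))
    mid <- mid[idx]
    chrom <- chrom[idx]
    in_up <- in_up_promoter[idx]
    bin_of <- bidx[idx]

    # per-bin short-fragment weight field: a sinusoidal landscape shared by
    # every sample, plus (cancer only) mean-one log-normal per-bin
    # distortions that make the ratio profile heterogeneous
    nb <- nrow(bins)
    short_field <- 1 + config$ratio_amplitude *
      sin(2 * pi * (seq_len(nb) - 1) / nb)
    if (label == "cancer" && config$cancer_ratio_noise > 0) {
      s <- config$cancer_ratio_noise
      short_field <- short_field * exp(rnorm(nb, -s^2 / 2, s))
    }
    # pin the field mean at 1 so the genome-wide size mixture stays at its
    # configured masses for every sample
    short_field <- short_field / mean(short_field)
    len <- numeric(length(idx))
    for (b in seq_len(nb)) {
      sel <- bin_of == b
      if (!any(sel)) next
      len[sel] <- draw_lengths(sum(sel),
                               adjust_short_weight(config$mixtures[[label]],
                                                   short_field[b]),
                               min_len = config$min_len)
    }
    if (label != "hemolysis" && any(in_up)) {
      spread <- in_up & runif(length(idx)) < config$pfe_spread
      len[spread] <- floor(runif(sum(spread), 100, 221))
    }
    start <- mid - floor(len / 2)
    end <- start + len
    # shift fragments protruding past the chromosome ends back inside
    size <- config$genome[chrom]
    shift_r <- pmax(0, -start)
    start <- start + shift_r
    end <- end + shift_r
    shift_l <- pmax(0, end - size)
    start <- pmax(0, start - shift_l)
    end <- end - shift_l
    data.frame(chrom = chrom, start = start, end = end,
               mapq = 60, stringsAsFactors = FALSE)
  })

  truth <- list(
    label = label,
    hemolysis = label == "hemolysis",
    bin_multipliers = data.frame(bins[c("chrom", "start", "end")],
                                 gc = bins$gc, multiplier = multipliers),
    genes = layout$genes,
    tf_depletion = data.frame(tf = config$tf_depletion$tf,
                              depletion = config$tf_depletion[[tf_col]])
  )
  list(sample = sample_fragments(frag, sample_id = sample_id),
       truth = truth)
}

#' Simulate a labelled cohort
#'
#' Per-sample seeds are derived deterministically from the master seed, so
#' the same master seed reproduces the identical cohort. When `out_dir` is
#' given, fragment BEDs, the chrom-sizes file, the per-bin GC table, the
#' TSS/gene table, per-TF site BEDs and the truth tables are written as
#' plain text.
#'
#' @param config a [sim_config()] object.
#' @param n_cancer,n_healthy,n_hemolysis sample counts per group.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return List with `samples` (named list of [sample_fragments()]),
#'   `truth` (data frame: `sample_id`, `label`, `hemolysis`, `seed`),
#'   `bins` (truth bin table with multipliers), `genes`, `tf_sites`,
#'   `config`, and `files` (when written).
#' @export
simulate_cohort <- function(config, n_cancer = 50, n_healthy = 50,
                            n_hemolysis = 0, seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_cancer + n_healthy + n_hemolysis <= 0) stopf("zero total samples")
  labels <- c(rep("cancer", n_cancer), rep("healthy", n_healthy),
              rep("hemolysis", n_hemolysis))
  ids <- unlist(lapply(unique(labels), function(l) {
    sprintf("%s_%02d", l, seq_len(sum(labels == l)))
  }))
  seeds <- vapply(seq_along(labels), function(i) derive_seed(seed, i), 0L)
  sims <- lapply(seq_along(labels), function(i) {
    simulate_sample(config, labels[i], seed = seeds[i], sample_id = ids[i])
  })
  samples <- lapply(sims, `[[`, "sample")
  names(samples) <- ids
  truth <- data.frame(sample_id = ids, label = labels,
                      hemolysis = labels == "hemolysis", seed = seeds,
                      stringsAsFactors = FALSE)
  layout <- sim_layout(config)
  cancer_truth <- if (n_cancer > 0) sims[[1]]$truth else
    simulate_sample(config, "cancer", seed = 1)$truth
  out <- list(samples = samples, truth = truth,
              bins = cancer_truth$bin_multipliers,
              genes = layout$genes, tf_sites = sim_tf_sites(config),
              config = config)
  if (!is.null(out_dir)) out$files <- write_cohort(out, out_dir)
  out
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  files$chrom_sizes <- file.path(out_dir, "chrom.sizes")
  write.table(data.frame(names(cohort$config$genome),
                         format(cohort$config$genome, scientific = FALSE,
                                trim = TRUE)),
              files$chrom_sizes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  files$gc_bins <- file.path(out_dir, "gc_bins.tsv")
  write_tsv(cohort$bins[c("chrom", "start", "end", "gc")], files$gc_bins)
  files$tss <- file.path(out_dir, "tss.tsv")
  write_tsv(cohort$genes[c("gene", "chrom", "strand", "tss")], files$tss)
  files$truth_samples <- file.path(out_dir, "truth_samples.tsv")
  write_tsv(cohort$truth, files$truth_samples)
  files$truth_bins <- file.path(out_dir, "truth_bins.tsv")
  write_tsv(cohort$bins, files$truth_bins)
  files$truth_genes <- file.path(out_dir, "truth_genes.tsv")
  write_tsv(cohort$genes, files$truth_genes)
  files$tf_sites <- character()
  for (tf in names(cohort$tf_sites)) {
    p <- file.path(out_dir, sprintf("sites_%s.bed", tf))
    write.table(cohort$tf_sites[[tf]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    files$tf_sites[tf] <- p
  }
  files$fragments <- character()
  for (id in names(cohort$samples)) {
    p <- file.path(out_dir, sprintf("fragments_%s.bed", id))
    df <- cohort$samples[[id]]$fragments
    write.table(data.frame(df$chrom,
                           format(df$start, scientific = FALSE, trim = TRUE),
                           format(df$end, scientific = FALSE, trim = TRUE),
                           df$mapq),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    files$fragments[id] <- p
  }
  files
}
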