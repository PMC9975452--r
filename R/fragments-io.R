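# Loading, filtering and binning cfDNA fragments.
#
# Coordinates are 0-based half-open (BED convention) throughout; BAM's
# 1-based positions are converted on read. A fragment is the outer span of a
# properly paired sequencing template.

#' Construct a sample fragment set
#'
#' Low-level constructor used by [load_fragments()] and the simulator. The
#' fragment table is sorted by chromosome and start, and invariants
#' (`start < end`, `length == end - start`) are enforced.
#'
#' @param fragments data frame with columns `chrom`, `start`, `end` and
#'   optionally `mapq`. Coordinates 0-based half-open.
#' @param sample_id sample identifier.
#' @param n_total number of fragments seen before filtering; defaults to
#'   `nrow(fragments)`.
#' @param n_rejected number of malformed input records dropped at parse time.
#' @return An object of class `sample_fragments`: a list with elements
#'   `sample_id`, `fragments` (data frame with `chrom`, `start`, `end`,
#'   `length`, `mapq`), `n_total`, `n_after_filters`, `n_rejected`.
#' @export
sample_fragments <- function(fragments, sample_id = "sample",
                             n_total = nrow(fragments), n_rejected = 0L) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  df <- data.frame(
    chrom = as.character(fragments$chrom),
    start = as.numeric(fragments$start),
    end = as.numeric(fragments$end),
    stringsAsFactors = FALSE
  )
  df$length <- df$end - df$start
  df$mapq <- if ("mapq" %in% names(fragments)) {
    as.numeric(fragments$mapq)
  } else {
    rep(NA_real_, nrow(df))
  }
  if (nrow(df) && any(df$length <= 0)) {
    stopf("%d fragment(s) with start >= end", sum(df$length <= 0))
  }
  if (nrow(df) && any(df$length > 1e7)) {
    stopf("fragment length above 10 Mb; input is unlikely to be a fragment file")
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(sample_id = sample_id, fragments = df,
         n_total = as.integer(n_total),
         n_after_filters = nrow(df),
         n_rejected = as.integer(n_rejected)),
    class = "sample_fragments"
  )
}

#' @export
print.sample_fragments <- function(x, ...) {
  cat(sprintf("<sample_fragments> %s: %d fragments (%d before filters, %d rejected lines)\n",
              x$sample_id, x$n_after_filters, x$n_total, x$n_rejected))
  if (x$n_after_filters > 0) {
    cat(sprintf("  chromosomes: %s; median length %.0f bp\n",
                paste(unique(x$fragments$chrom), collapse = ", "),
                median(x$fragments$length)))
  }
  invisible(x)
}

#' Load cfDNA fragments from a BAM or fragment BED file
#'
#' For BAM input one fragment per properly paired template is emitted, using
#' the template length (outer span of the pair); single-end and improper
#' pairs are excluded, as are marked duplicates when `dedup = TRUE`. For BED
#' input the columns are `chrom`, `start`, `end` and optionally `mapq`;
#' malformed lines (`start >= end`, non-numeric coordinates) are rejected,
#' counted and reported with a warning.
#'
#' The default length window keeps 30-1000 bp fragments, suitable for the
#' binned profiles. For QC size histograms use `length_range = c(30, Inf)`
#' so that very long (e.g. hemolysis-derived) fragments remain visible.
#'
#' @param path BAM (indexed, coordinate-sorted) or BED file.
#' @param format `"auto"` (by extension), `"bed"` or `"bam"`.
#' @param min_mapq minimum mapping quality; fragments without a recorded
#'   mapping quality are kept.
#' @param dedup drop marked duplicates (BAM flag) or exact-coordinate
#'   duplicates (BED).
#' @param length_range inclusive fragment length window in bp.
#' @param sample_id sample identifier; defaults to the file name.
#' @return A [sample_fragments()] object.
#' @export
load_fragments <- function(path, format = c("auto", "bed", "bam"),
                           min_mapq = 30, dedup = TRUE,
                           length_range = c(30, 1000),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("cannot read fragment file '%s'", path)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  sample_id <- sample_id %||% sub("\\.(bed|bam)(\\.gz)?$", "",
                                  basename(path), ignore.case = TRUE)
  raw <- switch(format,
    bed = read_fragment_bed(path),
    bam = read_fragment_bam(path, min_mapq = min_mapq, dedup = dedup)
  )
  df <- raw$fragments
  n_total <- nrow(df)
  if (format == "bed") {
    if (dedup && nrow(df)) {
      df <- df[!duplicated(df[c("chrom", "start", "end")]), , drop = FALSE]
    }
    if (min_mapq > 0 && nrow(df)) {
      keep <- is.na(df$mapq) | df$mapq >= min_mapq
      df <- df[keep, , drop = FALSE]
    }
  }
  if (nrow(df)) {
    len <- df$end - df$start
    df <- df[len >= length_range[1] & len <= length_range[2], , drop = FALSE]
  }
  if (!nrow(df)) {
    warnf("no fragments survive filtering in '%s'", path)
    df <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), mapq = numeric())
  }
  sample_fragments(df, sample_id = sample_id, n_total = n_total,
                   n_rejected = raw$n_rejected)
}

read_fragment_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(list(fragments = data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), mapq = numeric()),
                n_rejected = 0L))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  bad <- ncol < 3L
  chrom <- vapply(parts, function(p) p[1], "", USE.NAMES = FALSE)
  start <- suppressWarnings(as.numeric(vapply(parts, function(p) p[2], "")))
  end <- suppressWarnings(as.numeric(vapply(parts, function(p) p[3], "")))
  mapq <- suppressWarnings(as.numeric(vapply(parts, function(p)
    if (length(p) >= 4L) p[4] else NA_character_, "")))
  bad <- bad | is.na(start) | is.na(end) | start >= end
  if (any(bad)) {
    warnf("rejected %d malformed BED line(s) in '%s'", sum(bad), path)
  }
  keep <- !bad
  list(fragments = data.frame(chrom = chrom[keep], start = start[keep],
                              end = end[keep], mapq = mapq[keep],
                              stringsAsFactors = FALSE),
       n_rejected = sum(bad))
}

read_fragment_bam <- function(path, min_mapq = 30, dedup = TRUE) {
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = if (dedup) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "isize", "mapq"),
    mapqFilter = as.integer(max(min_mapq, 0))
  )
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  # leftmost read of each template carries a positive template length
  keep <- !is.na(rec$isize) & rec$isize > 0L & !is.na(rec$pos)
  start <- rec$pos[keep] - 1L   # 1-based -> 0-based
  list(fragments = data.frame(
         chrom = as.character(rec$rname[keep]),
         start = start,
         end = start + rec$isize[keep],
         mapq = as.numeric(rec$mapq[keep]),
         stringsAsFactors = FALSE),
       n_rejected = 0L)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path plain-text file: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "size"),
                   stringsAsFactors = FALSE)
  if (any(df$size <= 0)) stopf("non-positive chromosome size in '%s'", path)
  setNames(as.numeric(df$size), df$chrom)
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L &&
      file.exists(chrom_sizes)) {
    return(read_chrom_sizes(chrom_sizes))
  }
  if (is.data.frame(chrom_sizes)) {
    return(setNames(as.numeric(chrom_sizes[[2]]),
                    as.character(chrom_sizes[[1]])))
  }
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  chrom_sizes
}

#' Tile a genome into fixed-size bins
#'
#' Each chromosome is tiled from position 0 into adjacent, non-overlapping,
#' half-open bins of `bin_size` bp (5 Mb by default). A final partial bin is
#' kept, and flagged as partial, when it spans at least 50% of `bin_size`;
#' shorter remainders are dropped to avoid high-variance tiny bins.
#'
#' @param chrom_sizes named numeric vector, two-column data frame, or path
#'   to a chrom-sizes file.
#' @param bin_size bin width in bp.
#' @param gc optional GC source: a data frame with columns `chrom`, `start`,
#'   `gc` (per-bin GC fraction, matched on `chrom` + `start`), a
#'   [Biostrings::DNAStringSet] of chromosome sequences, or a path to a
#'   genome FASTA.
#' @return An object of class `genome_bins`: list with `bins` (data frame
#'   `chrom`, `start`, `end`, `gc`, `partial`), `bin_size`, `chrom_sizes`.
#' @export
make_bins <- function(chrom_sizes, bin_size = 5e6, gc = NULL) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (!is_count(bin_size) || bin_size <= 0) stopf("bin_size must be positive")
  per_chrom <- lapply(names(chrom_sizes), function(ch) {
    size <- chrom_sizes[[ch]]
    n_full <- floor(size / bin_size)
    starts <- seq_len(n_full) * bin_size - bin_size
    ends <- starts + bin_size
    partial <- rep(FALSE, n_full)
    rem <- size - n_full * bin_size
    if (rem >= bin_size / 2) {
      starts <- c(starts, n_full * bin_size)
      ends <- c(ends, size)
      partial <- c(partial, TRUE)
    }
    if (!length(starts)) return(NULL)
    data.frame(chrom = ch, start = starts, end = ends, partial = partial,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_chrom)
  if (is.null(bins) || !nrow(bins)) stopf("no bins: chromosomes too short for bin_size")
  rownames(bins) <- NULL
  bins$gc <- NA_real_
  obj <- structure(list(bins = bins, bin_size = bin_size,
                        chrom_sizes = chrom_sizes),
                   class = "genome_bins")
  if (!is.null(gc)) obj <- attach_gc(obj, gc)
  obj
}

attach_gc <- function(bins_obj, gc) {
  bins <- bins_obj$bins
  if (is.character(gc) && length(gc) == 1L) {
    gc <- Biostrings::readDNAStringSet(gc)
    names(gc) <- sub("\\s.*$", "", names(gc))
  }
  if (methods::is(gc, "DNAStringSet")) {
    missing <- setdiff(unique(bins$chrom), names(gc))
    if (length(missing)) {
      stopf("chromosome(s) missing from genome sequence: %s",
            paste(missing, collapse = ", "))
    }
    bins$gc <- vapply(seq_len(nrow(bins)), function(i) {
      seq <- Biostrings::subseq(gc[[bins$chrom[i]]],
                                bins$start[i] + 1L, bins$end[i])
      gc_n <- Biostrings::letterFrequency(seq, "GC")
      acgt_n <- Biostrings::letterFrequency(seq, "ACGT")
      if (acgt_n == 0) NA_real_ else gc_n / acgt_n
    }, 0)
  } else if (is.data.frame(gc)) {
    stopifnot(all(c("chrom", "start", "gc") %in% names(gc)))
    missing <- setdiff(unique(gc$chrom), names(bins_obj$chrom_sizes))
    if (length(missing)) {
      stopf("chromosome(s) in GC table missing from chrom_sizes: %s",
            paste(missing, collapse = ", "))
    }
    key_bins <- paste(bins$chrom, bins$start)
    key_gc <- paste(gc$chrom, gc$start)
    idx <- match(key_bins, key_gc)
    bins$gc <- gc$gc[idx]
  } else {
    stopf("unsupported GC source")
  }
  if (any(!is.na(bins$gc) & (bins$gc < 0 | bins$gc > 1))) {
    stopf("GC fractions must lie in [0, 1]")
  }
  bins_obj$bins <- bins
  bins_obj
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("<genome_bins> %d bins of %.3g bp on %d chromosome(s); %d partial; GC %s\n",
              nrow(x$bins), x$bin_size, length(unique(x$bins$chrom)),
              sum(x$bins$partial),
              if (all(is.na(x$bins$gc))) "absent" else "attached"))
  invisible(x)
}

#' Assign fragments to genome bins by midpoint
#'
#' Each fragment is assigned to the unique half-open bin containing its
#' midpoint `floor((start + end) / 2)`. Fragments on chromosomes absent
#' from the bin frame, or whose midpoint falls in a dropped terminal
#' remainder, are excluded and counted.
#'
#' @param sample a [sample_fragments()] object.
#' @param bins a [make_bins()] object.
#' @return Integer vector of bin row indices (one per fragment, `NA` when
#'   excluded) with attribute `n_excluded`.
#' @export
assign_to_bins <- function(sample, bins) {
  stopifnot(inherits(sample, "sample_fragments"), inherits(bins, "genome_bins"))
  df <- sample$fragments
  out <- rep(NA_integer_, nrow(df))
  if (nrow(df)) {
    mid <- floor((df$start + df$end) / 2)
    for (ch in unique(df$chrom)) {
      rows <- which(bins$bins$chrom == ch)
      if (!length(rows)) next
      sel <- df$chrom == ch
      j <- floor(mid[sel] / bins$bin_size) + 1
      ok <- j >= 1 & j <= length(rows)
      ok[ok] <- mid[sel][ok] < bins$bins$end[rows[j[ok]]]
      idx <- rep(NA_integer_, sum(sel))
      idx[ok] <- rows[j[ok]]
      out[sel] <- idx
    }
  }
  structure(out, n_excluded = sum(is.na(out)))
}
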