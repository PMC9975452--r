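# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as TSV with optional header comments
#'
#' Column definitions are carried as `#`-prefixed comment lines above the
#' header so downstream tools can re-read the table with standard parsers.
#'
#' @param df data frame.
#' @param path output path.
#' @param comments optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, quote = "")
}

# md5 of an arbitrary R object via an uncompressed serialization
checksum_obj <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

checksum_file <- function(path) {
  out <- rep(NA_character_, length(path))
  ok <- file.exists(path)
  out[ok] <- unname(tools::md5sum(path[ok]))
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# derive a reproducible child seed (< 2^31) from a master seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %%
               2147483563) + 1L
}
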