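# Shared fixtures: small hand-built fragment sets and reusable simulated
# cohorts (built once per test run, seeded).

make_frags <- function(chrom, start, end, mapq = NULL, id = "s") {
  if (!length(start)) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric())
  } else {
    df <- data.frame(chrom = chrom, start = start, end = end)
    if (!is.null(mapq)) df$mapq <- mapq
  }
  sample_fragments(df, sample_id = id)
}

# fragments with given lengths, placed consecutively on one chromosome
frags_of_lengths <- function(lengths, chrom = "chr1", gap = 5000, id = "s") {
  start <- seq(0, by = gap, length.out = length(lengths))
  make_frags(chrom, start, start + lengths, id = id)
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# uniform "flat coverage" fragment set: identical-length fragments tiling a
# chromosome with constant overlap, giving exactly uniform coverage away
# from the edges
uniform_frags <- function(chrom_len = 1e6, len = 100, step = 20,
                          chrom = "chrP", id = "uniform") {
  start <- seq(0, chrom_len - len, by = step)
  make_frags(chrom, start, start + len, id = id)
}

# default-condition cohort, shared across tests that only read it
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config()
      co <- simulate_cohort(cfg, n_cancer = 20, n_healthy = 20, n_hemolysis = 2,
                            seed = 20260101)
      bins <- make_bins(cfg$genome, cfg$bin_size,
                        gc = co$bins[c("chrom", "start", "end", "gc")])
      profiles <- lapply(co$samples[co$truth$label != "hemolysis"],
                         sample_profile, bins = bins)
      cache <<- list(config = cfg, cohort = co, bins = bins,
                     profiles = profiles,
                     labels = setNames(co$truth$label, co$truth$sample_id))
    }
    cache
  }
})

# promoter-focused conditions: small dense-gene genome at high depth for
# TSS / PFE analyses
promoter_config <- function(n_fragments = 300000) {
  sim_config(genome = c(chrP = 4.5e6), bin_size = 1e6,
             n_fragments = n_fragments, n_genes = 600, gene_spacing = 7000,
             amplified_bins = 2, tf_sites = 0)
}

promoter_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- promoter_config()
      co <- simulate_cohort(cfg, n_cancer = 0, n_healthy = 30,
                            seed = 20260102)
      cache <<- list(config = cfg, cohort = co,
                     genes = co$genes)
    }
    cache
  }
})
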