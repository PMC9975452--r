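# Config-driven pipeline: wires the modules together in dependency order
# (io -> qc -> fragmentation -> cnv/tss/pfe/tfbs -> ml), writes every stage
# as TSV, and records a manifest with input checksums and per-stage
# signatures so unchanged stages are skipped on rerun.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_cancer = 12L, n_healthy = 12L,
                    n_hemolysis = 0L, n_fragments = 30000L),
    inputs = list(samples = NULL, chrom_sizes = NULL, gc_bins = NULL,
                  tss = NULL, tf_sites = NULL, genes = NULL),
    stages = list(qc = TRUE, fragmentation = TRUE, cnv = TRUE, tss = TRUE,
                  pfe = TRUE, tfbs = TRUE, ml = TRUE),
    params = list(
      bin_size = 5e6,
      min_mapq = 30L, dedup = TRUE,
      hemolysis_threshold = 0.05,
      short_range = c(100, 150), long_range = c(151, 220),
      gc_span = 0.75,
      open_threshold = 1.0, closed_threshold = 1.5,
      cnv_alpha = 0.05,
      pfe_min_fragments = 20L,
      tf_window = 1000L, tf_step = 10L,
      folds = 10L, test_fraction = 0.3,
      benchmark = FALSE
    )
  )
}

config_schema <- function() {
  list(
    seed = "number",
    simulate = list(enabled = "logical", n_cancer = "number",
                    n_healthy = "number", n_hemolysis = "number",
                    n_fragments = "number"),
    inputs = list(samples = "character", chrom_sizes = "character",
                  gc_bins = "character", tss = "character",
                  tf_sites = "character", genes = "character"),
    stages = list(qc = "logical", fragmentation = "logical",
                  cnv = "logical", tss = "logical", pfe = "logical",
                  tfbs = "logical", ml = "logical"),
    params = list(bin_size = "number", min_mapq = "number",
                  dedup = "logical", hemolysis_threshold = "number",
                  short_range = "number", long_range = "number",
                  gc_span = "number", open_threshold = "number",
                  closed_threshold = "number", cnv_alpha = "number",
                  pfe_min_fragments = "number", tf_window = "number",
                  tf_step = "number", folds = "number",
                  test_fraction = "number", benchmark = "logical")
  )
}

check_type <- function(value, type) {
  switch(type,
         number = is.numeric(value) && !anyNA(value),
         logical = is.logical(value) && !anyNA(value),
         character = is.character(value),
         FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks every key against the documented schema and reports all
#' violations (unknown keys, wrong types) in a single error.
#'
#' @param config configuration list (e.g. parsed from YAML).
#' @return The config merged over the defaults, invisibly-valid.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  problems <- character()
  walk <- function(cfg, sch, prefix) {
    for (key in names(cfg)) {
      path <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
      if (!key %in% names(sch)) {
        problems <<- c(problems, sprintf("unknown key '%s'", path))
        next
      }
      expected <- sch[[key]]
      if (is.list(expected)) {
        if (!is.list(cfg[[key]])) {
          problems <<- c(problems, sprintf("'%s' must be a section", path))
        } else {
          walk(cfg[[key]], expected, path)
        }
      } else if (!is.null(cfg[[key]]) && !check_type(cfg[[key]], expected)) {
        problems <<- c(problems,
                       sprintf("'%s' must be of type %s", path, expected))
      }
    }
  }
  walk(config, schema, "")
  if (length(problems)) {
    stopf("invalid configuration:\n  %s", paste(problems, collapse = "\n  "))
  }
  merged <- default_pipeline_config()
  for (section in names(config)) {
    if (is.list(config[[section]])) {
      for (key in names(config[[section]])) {
        merged[[section]][[key]] <- config[[section]][[key]]
      }
    } else {
      merged[[section]] <- config[[section]]
    }
  }
  merged
}

stage_signature <- function(params, input_files = character()) {
  checksum_obj(list(params = params, inputs = checksum_file(input_files)))
}

stage_up_to_date <- function(manifest, stage, signature, outputs) {
  !is.null(manifest$stages[[stage]]) &&
    identical(manifest$stages[[stage]]$signature, signature) &&
    all(file.exists(outputs))
}

#' Run the full cfDNA feature pipeline
#'
#' Executes the enabled stages in dependency order on either a simulated
#' cohort (when `simulate.enabled`) or user-supplied fragment files, writing
#' per-stage TSVs under `out_dir` and a `manifest.json` with the config
#' snapshot, input checksums, per-stage signatures and runtimes, and output
#' checksums. Rerunning with an unchanged config over unchanged inputs
#' skips every stage and changes no output file.
#'
#' @param config configuration list or path to a YAML file; see
#'   `default_pipeline_config()` (internal) for the full schema and
#'   defaults.
#' @param out_dir output directory (created if needed).
#' @param force rerun all stages even when up to date.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list()
  }
  new_manifest <- list(
    tool = "cffeatures",
    version = as.character(packageVersion("cffeatures")),
    seed = config$seed,
    config = config,
    stages = list(),
    warnings = character()
  )
  note_warning <- function(w) {
    new_manifest$warnings <<- c(new_manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(name, params, input_files, outputs, fun) {
    sig <- stage_signature(params, input_files)
    rel <- file.path(out_dir, outputs)
    if (!force && stage_up_to_date(manifest, name, sig, rel)) {
      entry <- manifest$stages[[name]]
      entry$skipped <- TRUE
      new_manifest$stages[[name]] <<- entry
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(fun(), warning = note_warning)
    missing <- rel[!file.exists(rel)]
    if (length(missing)) {
      stopf("stage '%s' did not produce: %s", name,
            paste(missing, collapse = ", "))
    }
    new_manifest$stages[[name]] <<- list(
      signature = sig, outputs = outputs,
      output_checksums = setNames(as.list(checksum_file(rel)), outputs),
      runtime_s = round(proc.time()[["elapsed"]] - t0, 3),
      skipped = FALSE)
    invisible(NULL)
  }
  env <- new.env(parent = emptyenv())
  pipeline_io_stage(config, out_dir, env, run_stage)
  if (isTRUE(config$stages$qc)) pipeline_qc_stage(config, out_dir, env, run_stage)
  if (isTRUE(config$stages$fragmentation)) {
    pipeline_fragmentation_stage(config, out_dir, env, run_stage)
  }
  if (isTRUE(config$stages$cnv)) pipeline_cnv_stage(config, out_dir, env, run_stage)
  if (isTRUE(config$stages$tss)) pipeline_tss_stage(config, out_dir, env, run_stage)
  if (isTRUE(config$stages$pfe)) pipeline_pfe_stage(config, out_dir, env, run_stage)
  if (isTRUE(config$stages$tfbs)) pipeline_tfbs_stage(config, out_dir, env, run_stage)
  if (isTRUE(config$stages$ml)) pipeline_ml_stage(config, out_dir, env, run_stage)
  jsonlite::write_json(new_manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(new_manifest)
}

pipeline_io_stage <- function(config, out_dir, env, run_stage) {
  if (isTRUE(config$simulate$enabled)) {
    sim_dir <- file.path(out_dir, "simulate")
    cfg <- sim_config(n_fragments = config$simulate$n_fragments,
                      bin_size = config$params$bin_size)
    run_stage("simulate",
              params = list(sim = unclass(cfg), n = config$simulate,
                            seed = config$seed),
              input_files = character(),
              outputs = file.path("simulate", "truth_samples.tsv"),
              fun = function() {
                simulate_cohort(cfg,
                                n_cancer = config$simulate$n_cancer,
                                n_healthy = config$simulate$n_healthy,
                                n_hemolysis = config$simulate$n_hemolysis,
                                seed = config$seed, out_dir = sim_dir)
              })
    truth <- read_tsv(file.path(sim_dir, "truth_samples.tsv"))
    env$sample_files <- setNames(
      file.path(sim_dir, sprintf("fragments_%s.bed", truth$sample_id)),
      truth$sample_id)
    env$labels <- setNames(truth$label, truth$sample_id)
    env$chrom_sizes_file <- file.path(sim_dir, "chrom.sizes")
    env$gc_file <- file.path(sim_dir, "gc_bins.tsv")
    env$tss_file <- file.path(sim_dir, "tss.tsv")
    env$tf_files <- setNames(
      file.path(sim_dir, sprintf("sites_%s.bed", cfg$tf_depletion$tf)),
      cfg$tf_depletion$tf)
    genes <- read_tsv(file.path(sim_dir, "truth_genes.tsv"))
    env$genes <- data.frame(gene = genes$gene, chrom = genes$chrom,
                            start = pmax(0, genes$tss - 1000),
                            end = genes$tss + 1000,
                            stringsAsFactors = FALSE)
  } else {
    inp <- config$inputs
    for (need in c("samples", "chrom_sizes")) {
      if (is.null(inp[[need]])) {
        stopf("stage 'io': missing required input '%s'", need)
      }
    }
    st <- read_tsv(inp$samples)  # sample_id, path, label
    if (!all(c("sample_id", "path", "label") %in% names(st))) {
      stopf("stage 'io': samples table needs sample_id, path, label")
    }
    missing <- st$path[!file.exists(st$path)]
    if (length(missing)) {
      stopf("stage 'io': missing fragment file(s): %s",
            paste(missing, collapse = ", "))
    }
    env$sample_files <- setNames(st$path, st$sample_id)
    env$labels <- setNames(st$label, st$sample_id)
    env$chrom_sizes_file <- inp$chrom_sizes
    env$gc_file <- inp$gc_bins
    env$tss_file <- inp$tss
    env$tf_files <- if (!is.null(inp$tf_sites)) {
      setNames(inp$tf_sites, sub("\\.bed$", "", basename(inp$tf_sites)))
    }
    env$genes <- if (!is.null(inp$genes)) {
      g <- read.table(inp$genes, sep = "\t", stringsAsFactors = FALSE)
      data.frame(gene = g[[4]], chrom = g[[1]], start = g[[2]], end = g[[3]])
    }
  }
  env$chrom_sizes <- read_chrom_sizes(env$chrom_sizes_file)
  env$load_qc <- function(id) {
    load_fragments(env$sample_files[[id]], min_mapq = config$params$min_mapq,
                   dedup = config$params$dedup, length_range = c(30, Inf),
                   sample_id = id)
  }
  env$load_binned <- function(id) {
    load_fragments(env$sample_files[[id]], min_mapq = config$params$min_mapq,
                   dedup = config$params$dedup, length_range = c(30, 1000),
                   sample_id = id)
  }
  invisible(env)
}

pipeline_qc_stage <- function(config, out_dir, env, run_stage) {
  dir.create(file.path(out_dir, "qc"), showWarnings = FALSE)
  outs <- file.path("qc", c("qc_report.tsv", "size_histograms.tsv",
                            "chrom_stats.tsv"))
  run_stage("qc",
            params = config$params[c("min_mapq", "dedup", "hemolysis_threshold")],
            input_files = c(env$sample_files, env$chrom_sizes_file),
            outputs = outs, fun = function() {
    reports <- lapply(names(env$sample_files), function(id) {
      qc_report(env$load_qc(id), env$chrom_sizes,
                hemolysis_threshold = config$params$hemolysis_threshold)
    })
    tab <- do.call(rbind, lapply(reports, function(r) {
      data.frame(sample_id = r$sample_id, t(r$fractions),
                 short_long_ratio = r$ratio, hemolysis_flag = r$hemolysis,
                 n_total = r$n_total, n_after_filters = r$n_after_filters,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(tab, file.path(out_dir, outs[1]),
              comments = "per-sample size fractions and hemolysis flag")
    hist_long <- do.call(rbind, lapply(reports, function(r) {
      cbind(sample_id = r$sample_id, as.data.frame(r$histogram))
    }))
    write_tsv(hist_long, file.path(out_dir, outs[2]),
              comments = "1-bp size histograms; length 1000 pools >= 1000 bp")
    cs_long <- do.call(rbind, lapply(reports, function(r) {
      cbind(sample_id = r$sample_id, r$chrom_stats)
    }))
    write_tsv(cs_long, file.path(out_dir, outs[3]))
  })
}

pipeline_bins <- function(config, env) {
  gc <- if (!is.null(env$gc_file)) read_tsv(env$gc_file)
  make_bins(env$chrom_sizes, bin_size = config$params$bin_size, gc = gc)
}

pipeline_profiles <- function(config, env) {
  if (!is.null(env$profiles)) return(env$profiles)
  bins <- pipeline_bins(config, env)
  env$profiles <- lapply(names(env$sample_files), function(id) {
    sample_profile(env$load_binned(id), bins,
                   short_range = config$params$short_range,
                   long_range = config$params$long_range,
                   gc_span = config$params$gc_span)
  })
  names(env$profiles) <- names(env$sample_files)
  env$bins <- bins
  env$profiles
}

profile_long <- function(profiles) {
  do.call(rbind, lapply(names(profiles), function(id) {
    cbind(sample_id = id, as.data.frame(profiles[[id]]))
  }))
}

pipeline_fragmentation_stage <- function(config, out_dir, env, run_stage) {
  dir.create(file.path(out_dir, "fragmentation"), showWarnings = FALSE)
  outs <- file.path("fragmentation",
                    c("profiles.tsv", "similarity_ratio.tsv",
                      "similarity_fraction.tsv", "r_to_reference.tsv"))
  run_stage("fragmentation",
            params = config$params[c("bin_size", "short_range", "long_range",
                                     "gc_span")],
            input_files = c(env$sample_files, env$chrom_sizes_file,
                            env$gc_file),
            outputs = outs, fun = function() {
    profiles <- pipeline_profiles(config, env)
    write_tsv(profile_long(profiles), file.path(out_dir, outs[1]),
              comments = "per-bin fragmentation profiles (counts, GC-corrected, ratio, fraction)")
    non_hemo <- names(env$labels)[env$labels != "hemolysis"]
    healthy <- names(env$labels)[env$labels == "healthy"]
    sim_r <- cohort_similarity(profiles[non_hemo], healthy_ids = healthy,
                               on = "ratio", labels = env$labels[non_hemo])
    sim_f <- cohort_similarity(profiles[non_hemo], healthy_ids = healthy,
                               on = "fraction", labels = env$labels[non_hemo])
    write_tsv(cbind(sample_id = rownames(sim_r$matrix),
                    as.data.frame(sim_r$matrix)),
              file.path(out_dir, outs[2]))
    write_tsv(cbind(sample_id = rownames(sim_f$matrix),
                    as.data.frame(sim_f$matrix)),
              file.path(out_dir, outs[3]))
    write_tsv(data.frame(sample_id = non_hemo,
                         label = env$labels[non_hemo],
                         r_ratio = sim_r$r_to_reference,
                         r_fraction = sim_f$r_to_reference),
              file.path(out_dir, outs[4]),
              comments = "Pearson r to the healthy-median profile")
    env$similarity <- list(ratio = sim_r, fraction = sim_f)
  })
}

pipeline_cnv_stage <- function(config, out_dir, env, run_stage) {
  dir.create(file.path(out_dir, "cnv"), showWarnings = FALSE)
  outs <- file.path("cnv", c("scores.tsv", "variance_test.tsv",
                             "amplified_genes.tsv"))
  run_stage("cnv",
            params = config$params[c("bin_size", "gc_span", "cnv_alpha")],
            input_files = c(env$sample_files, env$chrom_sizes_file,
                            env$gc_file),
            outputs = outs, fun = function() {
    profiles <- pipeline_profiles(config, env)
    healthy <- names(env$labels)[env$labels == "healthy"]
    cancer <- names(env$labels)[env$labels == "cancer"]
    panel <- fraction_matrix(profiles[healthy])
    all_ids <- c(cancer, healthy)
    scores_long <- do.call(rbind, lapply(all_ids, function(id) {
      sc <- cnv_scores(profiles[[id]]$fraction, panel)
      cbind(sample_id = id, env$bins$bins[c("chrom", "start", "end")], sc)
    }))
    write_tsv(scores_long, file.path(out_dir, outs[1]),
              comments = "per-bin log2 ratio and z-score vs healthy panel")
    vt <- cohort_variance_test(fraction_matrix(profiles[cancer]), panel)
    write_tsv(data.frame(
      group = rep(c("cancer", "healthy"), c(length(cancer), length(healthy))),
      sample_id = c(cancer, healthy),
      log2_ratio_variance = c(vt$variance$cancer, vt$variance$healthy),
      wilcoxon_p = vt$p %||% NA_real_),
      file.path(out_dir, outs[2]))
    calls <- call_amplified_genes(fraction_matrix(profiles[cancer]), panel,
                                  env$bins, env$genes,
                                  alpha = config$params$cnv_alpha)
    write_tsv(calls, file.path(out_dir, outs[3]))
    env$cnv_variance <- vt
  })
}

pipeline_tss_stage <- function(config, out_dir, env, run_stage) {
  dir.create(file.path(out_dir, "tss"), showWarnings = FALSE)
  outs <- file.path("tss", c("coverages.tsv", "states.tsv"))
  run_stage("tss",
            params = config$params[c("open_threshold", "closed_threshold")],
            input_files = c(env$sample_files, env$chrom_sizes_file,
                            env$tss_file),
            outputs = outs, fun = function() {
    if (is.null(env$tss_file)) stopf("stage 'tss': missing TSS annotation input")
    tss <- read_tsv(env$tss_file)
    ids <- names(env$labels)[env$labels != "hemolysis"]
    cov_long <- do.call(rbind, lapply(ids, function(id) {
      cbind(sample_id = id,
            tss_relative_coverages(env$load_binned(id), tss, env$chrom_sizes))
    }))
    write_tsv(cov_long, file.path(out_dir, outs[1]),
              comments = "per-gene conventional/NDR/2K relative coverages")
    states <- classify_chromatin_state(
      cov_long, open_threshold = config$params$open_threshold,
      closed_threshold = config$params$closed_threshold)
    write_tsv(states, file.path(out_dir, outs[2]))
    env$tss_cov <- cov_long
  })
}

pipeline_pfe_stage <- function(config, out_dir, env, run_stage) {
  dir.create(file.path(out_dir, "pfe"), showWarnings = FALSE)
  outs <- file.path("pfe", "pfe.tsv")
  run_stage("pfe",
            params = config$params["pfe_min_fragments"],
            input_files = c(env$sample_files, env$tss_file),
            outputs = outs, fun = function() {
    if (is.null(env$tss_file)) stopf("stage 'pfe': missing TSS annotation input")
    tss <- read_tsv(env$tss_file)
    ids <- names(env$labels)[env$labels != "hemolysis"]
    pfe_long <- do.call(rbind, lapply(ids, function(id) {
      cbind(sample_id = id,
            promoter_entropy(env$load_binned(id), tss,
                             min_fragments = config$params$pfe_min_fragments))
    }))
    write_tsv(pfe_long, file.path(out_dir, outs),
              comments = "promoter fragmentation entropy (bits)")
    env$pfe <- pfe_long
  })
}

pipeline_tfbs_stage <- function(config, out_dir, env, run_stage) {
  if (is.null(env$tf_files)) return(invisible(NULL))
  dir.create(file.path(out_dir, "tfbs"), showWarnings = FALSE)
  outs <- file.path("tfbs", c("tf_scores.tsv", "tf_profiles.tsv"))
  run_stage("tfbs",
            params = config$params[c("tf_window", "tf_step")],
            input_files = c(env$sample_files, env$chrom_sizes_file,
                            env$tf_files),
            outputs = outs, fun = function() {
    sites <- lapply(env$tf_files, function(p) {
      s <- read.table(p, sep = "\t", stringsAsFactors = FALSE)
      names(s)[1:3] <- c("chrom", "start", "end")
      s
    })
    ids <- names(env$labels)[env$labels != "hemolysis"]
    rows <- list()
    profs <- list()
    for (id in ids) {
      sm <- env$load_binned(id)
      pl <- lapply(names(sites), function(tf) {
        tryCatch(composite_profile(sm, sites[[tf]], env$chrom_sizes,
                                   window = config$params$tf_window,
                                   step = config$params$tf_step,
                                   tf_name = tf),
                 error = function(e) NA)
      })
      names(pl) <- names(sites)
      rows[[id]] <- data.frame(sample_id = id, t(tf_feature_vector(pl)),
                               stringsAsFactors = FALSE)
      profs[[id]] <- do.call(rbind, lapply(names(pl), function(tf) {
        if (!inherits(pl[[tf]], "composite_profile")) return(NULL)
        data.frame(sample_id = id, tf = tf, offset = pl[[tf]]$offsets,
                   coverage = pl[[tf]]$mean_coverage)
      }))
    }
    write_tsv(do.call(rbind, rows), file.path(out_dir, outs[1]),
              comments = "central occupancy score per TF (flank-normalised)")
    write_tsv(do.call(rbind, profs), file.path(out_dir, outs[2]))
  })
}

pipeline_ml_stage <- function(config, out_dir, env, run_stage) {
  dir.create(file.path(out_dir, "ml"), showWarnings = FALSE)
  outs <- file.path("ml", c("auc.tsv", "predictions.tsv", "roc_cv.tsv",
                            "confusion.tsv", "consistency.tsv"))
  if (isTRUE(config$params$benchmark)) {
    outs <- c(outs, file.path("ml", "benchmark.tsv"))
  }
  prev <- c(file.path(out_dir, "qc", "qc_report.tsv"),
            file.path(out_dir, "fragmentation",
                      c("profiles.tsv", "r_to_reference.tsv")),
            file.path(out_dir, "cnv", "scores.tsv"),
            file.path(out_dir, "tss", "coverages.tsv"),
            file.path(out_dir, "pfe", "pfe.tsv"),
            file.path(out_dir, "tfbs", "tf_scores.tsv"))
  prev <- prev[file.exists(prev)]
  run_stage("ml",
            params = config$params[c("folds", "test_fraction", "benchmark")],
            input_files = prev, outputs = outs, fun = function() {
    blocks <- pipeline_feature_blocks(out_dir, env)
    labels <- env$labels[env$labels != "hemolysis"]
    blocks <- lapply(blocks, function(b) {
      b[intersect(rownames(b), names(labels)), , drop = FALSE]
    })
    fm <- assemble_features(blocks, labels, impute = "mean")
    report <- train_eval_sgd(fm, folds = config$params$folds,
                             seed = config$seed,
                             test_fraction = config$params$test_fraction)
    write_tsv(data.frame(metric = c("train_auc", "test_auc", "cv_auc"),
                         value = c(report$train_auc, report$test_auc,
                                   report$cv_auc)),
              file.path(out_dir, outs[1]))
    write_tsv(report$predictions, file.path(out_dir, outs[2]))
    write_tsv(report$roc_cv, file.path(out_dir, outs[3]))
    write_tsv(as.data.frame(report$confusion), file.path(out_dir, outs[4]))
    cons <- per_modality_consistency(fm, folds = config$params$folds,
                                     seed = config$seed)
    write_tsv(cons$per_sample, file.path(out_dir, outs[5]))
    if (isTRUE(config$params$benchmark)) {
      bm <- benchmark_methods(fm, folds = config$params$folds,
                              seed = config$seed)
      write_tsv(bm, file.path(out_dir, outs[6]))
    }
    env$ml_report <- report
  })
}

# per-modality summary blocks assembled from the stage TSVs
pipeline_feature_blocks <- function(out_dir, env) {
  blocks <- list()
  qc_path <- file.path(out_dir, "qc", "qc_report.tsv")
  if (file.exists(qc_path)) {
    qc <- read_tsv(qc_path)
    m <- as.matrix(qc[grep("^f_", names(qc))])
    rownames(m) <- qc$sample_id
    blocks$size_fractions <- m
  }
  prof_path <- file.path(out_dir, "fragmentation", "profiles.tsv")
  rref_path <- file.path(out_dir, "fragmentation", "r_to_reference.tsv")
  if (file.exists(prof_path)) {
    prof <- read_tsv(prof_path)
    wide <- tapply(prof$normalized_ratio,
                   list(prof$sample_id,
                        paste0(prof$chrom, ":", prof$start)), identity)
    blocks$fragment_ratio <- wide
  }
  if (file.exists(rref_path)) {
    rref <- read_tsv(rref_path)
    if (!is.null(blocks$fragment_ratio)) {
      idx <- match(rownames(blocks$fragment_ratio), rref$sample_id)
      blocks$fragment_ratio <- cbind(blocks$fragment_ratio,
                                     r_to_reference = rref$r_ratio[idx])
    }
    blocks$fragment_fraction <- matrix(
      rref$r_fraction, ncol = 1,
      dimnames = list(rref$sample_id, "r_to_reference"))
  }
  cnv_path <- file.path(out_dir, "cnv", "scores.tsv")
  if (file.exists(cnv_path)) {
    sc <- read_tsv(cnv_path)
    agg <- do.call(rbind, lapply(split(sc, sc$sample_id), function(p) {
      data.frame(log2_var = var(p$log2_ratio, na.rm = TRUE),
                 mean_abs_z = mean(abs(p$z), na.rm = TRUE))
    }))
    blocks$cnv <- as.matrix(agg)
  }
  tss_path <- file.path(out_dir, "tss", "coverages.tsv")
  if (file.exists(tss_path)) {
    cov <- read_tsv(tss_path)
    agg <- vapply(split(cov, cov$sample_id), function(p) {
      c(mean_ndr_rc = mean(p$ndr_rc, na.rm = TRUE),
        mean_k2_rc = mean(p$k2_rc, na.rm = TRUE))
    }, numeric(2))
    blocks$tss <- t(agg)
  }
  pfe_path <- file.path(out_dir, "pfe", "pfe.tsv")
  if (file.exists(pfe_path)) {
    pfe <- read_tsv(pfe_path)
    agg <- vapply(split(pfe, pfe$sample_id), function(p) {
      mean(p$entropy, na.rm = TRUE)
    }, 0)
    blocks$pfe <- matrix(agg, ncol = 1,
                         dimnames = list(names(agg), "mean_entropy"))
  }
  tf_path <- file.path(out_dir, "tfbs", "tf_scores.tsv")
  if (file.exists(tf_path)) {
    tf <- read_tsv(tf_path)
    m <- as.matrix(tf[setdiff(names(tf), "sample_id")])
    rownames(m) <- tf$sample_id
    blocks$tf <- m
  }
  blocks
}
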