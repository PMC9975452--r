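# Multimodal feature assembly and cross-validated classification.

#' Assemble per-modality feature blocks into a cohort feature matrix
#'
#' @param blocks named list of numeric matrices / data frames, one per
#'   modality (e.g. `size_fractions`, `fragment_ratio`, `cnv`, `tss`,
#'   `pfe`, `tf`), rows named by sample id.
#' @param labels named vector/factor of class labels
#'   (`"cancer"`/`"healthy"`) covering every sample.
#' @param impute `"drop"` removes samples with any missing value (with a
#'   report); `"mean"` imputes column means.
#' @param drop_constant drop zero-variance columns with a warning.
#' @return `cohort_features`: list with `x` (matrix, samples x features),
#'   `labels` (factor, aligned), `blocks` (named list of column indices),
#'   `dropped_samples`, `dropped_columns`.
#' @export
assemble_features <- function(blocks, labels, impute = c("drop", "mean"),
                              drop_constant = TRUE) {
  impute <- match.arg(impute)
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)))
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    if (is.null(rownames(b))) stopf("every block needs sample ids as rownames")
    b
  })
  ids <- Reduce(union, lapply(blocks, rownames))
  aligned <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    if (is.null(colnames(b))) colnames(b) <- paste0(nm, seq_len(ncol(b)))
    out <- matrix(NA_real_, length(ids), ncol(b),
                  dimnames = list(ids, paste(nm, colnames(b), sep = ".")))
    out[rownames(b), ] <- b
    out
  })
  x <- do.call(cbind, aligned)
  block_cols <- split(seq_len(ncol(x)),
                      rep(names(blocks), vapply(aligned, ncol, 0L)))
  block_cols <- block_cols[names(blocks)]
  all_na <- apply(x, 2, function(col) all(is.na(col)))
  if (any(all_na)) {
    warnf("dropping %d all-missing feature column(s)", sum(all_na))
    keep <- which(!all_na)
    block_cols <- lapply(block_cols, function(cols) match(intersect(cols, keep), keep))
    x <- x[, keep, drop = FALSE]
  }
  dropped_samples <- character()
  if (anyNA(x)) {
    if (impute == "drop") {
      bad <- !complete.cases(x)
      dropped_samples <- ids[bad]
      if (length(dropped_samples)) {
        warnf("dropping %d sample(s) with missing modality values: %s",
              length(dropped_samples),
              paste(dropped_samples, collapse = ", "))
      }
      x <- x[!bad, , drop = FALSE]
      ids <- ids[!bad]
    } else {
      for (j in seq_len(ncol(x))) {
        nas <- is.na(x[, j])
        if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
      }
    }
  }
  dropped_columns <- character()
  if (drop_constant && nrow(x) > 1) {
    sds <- apply(x, 2, sd)
    const <- is.na(sds) | sds == 0
    if (any(const)) {
      dropped_columns <- colnames(x)[const]
      warnf("dropping %d zero-variance feature column(s)", sum(const))
      keep <- which(!const)
      block_cols <- lapply(block_cols, function(cols) {
        match(intersect(cols, keep), keep)
      })
      x <- x[, keep, drop = FALSE]
    }
  }
  block_cols <- block_cols[vapply(block_cols, length, 0L) > 0]
  if (is.null(names(labels))) stopf("labels must be named by sample id")
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab)) {
    stopf("no label for sample(s): %s", paste(missing_lab, collapse = ", "))
  }
  structure(list(x = x, labels = factor(as.character(labels[ids])),
                 blocks = block_cols,
                 dropped_samples = dropped_samples,
                 dropped_columns = dropped_columns),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("<cohort_features> %d samples x %d features in %d blocks (%s)\n",
              nrow(x$x), ncol(x$x), length(x$blocks),
              paste(names(x$blocks), collapse = ", ")))
  print(table(x$labels))
  invisible(x)
}

binary_response <- function(labels, positive = "cancer") {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stopf("single-class input")
  if (!positive %in% levels(labels)) positive <- levels(labels)[2]
  as.numeric(labels == positive)
}

#' Train and evaluate the SGD classifier
#'
#' Two complementary evaluations of a logistic-loss linear model trained by
#' stochastic gradient descent:
#' a stratified train/test split (default 70/30) reporting train and test
#' ROC/AUC plus a confusion matrix at probability 0.5, and stratified
#' k-fold cross-validation pooling out-of-fold scores into a single ROC/AUC.
#' Standardisation is fitted on training data only (per split and per
#' fold), so no test information leaks into the model. A fixed seed makes
#' the whole report bit-reproducible.
#'
#' @param features a [assemble_features()] object, or a numeric matrix
#'   (then `labels` is required).
#' @param labels class labels when `features` is a matrix.
#' @param folds number of CV folds (default 10); reduced with a warning
#'   when a class has fewer members.
#' @param seed RNG seed (folds, split, SGD shuffling).
#' @param test_fraction held-out fraction for the split evaluation.
#' @param positive label treated as the positive class (default
#'   `"cancer"`).
#' @param epochs,eta0,lambda SGD hyperparameters, see [sgd_logistic()].
#' @return `classifier_report`: list with `train_auc`, `test_auc`,
#'   `cv_auc`, `fold_auc`, `roc_train`, `roc_test`, `roc_cv`, `confusion`,
#'   `predictions` (per-sample split membership, test score, out-of-fold CV
#'   score), and `settings`.
#' @export
train_eval_sgd <- function(features, labels = NULL, folds = 10, seed = 1,
                           test_fraction = 0.3, positive = "cancer",
                           epochs = 50, eta0 = 0.1, lambda = 1e-3) {
  if (inherits(features, "cohort_features")) {
    x <- features$x
    labels <- features$labels
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stopf("labels required with a plain matrix")
  }
  y <- binary_response(labels, positive)
  n <- length(y)
  min_class <- min(table(y))
  if (folds > min_class) {
    warnf("reducing folds from %d to %d (smallest class size)", folds, min_class)
    folds <- max(2L, min_class)
  }
  fit_fun <- function(xt, yt, s) sgd_logistic(xt, yt, epochs = epochs,
                                              eta0 = eta0, lambda = lambda,
                                              seed = s)
  pred_fun <- function(m, xt) predict(m, xt)

  # stratified train/test split
  test_idx <- logical(n)
  with_seed(derive_seed(seed, 1L), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_test <- max(1L, round(test_fraction * length(idx)))
      test_idx[sample(idx, n_test)] <- TRUE
    }
  })
  std <- standardizer(x[!test_idx, , drop = FALSE])
  model <- fit_fun(std$apply(x[!test_idx, , drop = FALSE]), y[!test_idx],
                   derive_seed(seed, 2L))
  score_train <- pred_fun(model, std$apply(x[!test_idx, , drop = FALSE]))
  score_test <- pred_fun(model, std$apply(x[test_idx, , drop = FALSE]))
  confusion <- table(
    predicted = factor(ifelse(score_test >= 0.5, "positive", "negative"),
                       levels = c("negative", "positive")),
    truth = factor(ifelse(y[test_idx] == 1, "positive", "negative"),
                   levels = c("negative", "positive"))
  )

  # pooled k-fold cross-validation on all samples
  oof <- cv_scores(x, y, folds, derive_seed(seed, 3L), fit_fun, pred_fun)
  fold <- attr(oof, "fold")
  fold_auc <- vapply(sort(unique(fold)), function(f) {
    sel <- fold == f
    if (length(unique(y[sel])) < 2) return(NA_real_)
    auc_score(oof[sel], y[sel])
  }, 0)

  preds <- data.frame(
    sample_id = rownames(x) %||% as.character(seq_len(n)),
    label = as.character(labels),
    split = ifelse(test_idx, "test", "train"),
    test_score = NA_real_,
    cv_score = as.vector(oof),
    cv_fold = fold,
    stringsAsFactors = FALSE
  )
  preds$test_score[test_idx] <- score_test

  structure(list(
    train_auc = auc_score(score_train, y[!test_idx]),
    test_auc = auc_score(score_test, y[test_idx]),
    cv_auc = auc_score(as.vector(oof), y),
    fold_auc = fold_auc,
    roc_train = roc_curve(score_train, y[!test_idx]),
    roc_test = roc_curve(score_test, y[test_idx]),
    roc_cv = roc_curve(as.vector(oof), y),
    confusion = confusion,
    predictions = preds,
    settings = list(folds = folds, seed = seed,
                    test_fraction = test_fraction, positive = positive,
                    epochs = epochs, eta0 = eta0, lambda = lambda)
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> train AUC %.3f | test AUC %.3f | pooled %d-fold CV AUC %.3f\n",
              x$train_auc, x$test_auc, x$settings$folds, x$cv_auc))
  cat("test confusion matrix (threshold 0.5):\n")
  print(x$confusion)
  invisible(x)
}

#' Per-modality out-of-fold prediction consistency
#'
#' Trains one SGD classifier per feature block with identical folds and
#' reports, per sample, every block's out-of-fold predicted label, the
#' number of blocks agreeing with the truth, and the majority-vote label
#' (ties broken toward the higher mean predicted probability).
#'
#' @inheritParams train_eval_sgd
#' @return List with `per_sample` (data frame) and `block_accuracy`
#'   (named vector).
#' @export
per_modality_consistency <- function(features, folds = 10, seed = 1,
                                     positive = "cancer", epochs = 50,
                                     eta0 = 0.1, lambda = 1e-3) {
  stopifnot(inherits(features, "cohort_features"))
  if (length(features$blocks) < 2) stopf("need at least 2 feature blocks")
  y <- binary_response(features$labels, positive)
  folds <- min(folds, min(table(y)))
  fit_fun <- function(xt, yt, s) sgd_logistic(xt, yt, epochs = epochs,
                                              eta0 = eta0, lambda = lambda,
                                              seed = s)
  scores <- lapply(names(features$blocks), function(nm) {
    cols <- features$blocks[[nm]]
    if (!length(cols)) return(NULL)
    cv_scores(features$x[, cols, drop = FALSE], y, folds,
              derive_seed(seed, 3L), fit_fun, function(m, xt) predict(m, xt))
  })
  names(scores) <- names(features$blocks)
  scores <- scores[!vapply(scores, is.null, TRUE)]
  pred_mat <- vapply(scores, function(s) as.numeric(s >= 0.5),
                     numeric(length(y)))
  prob_mat <- vapply(scores, as.vector, numeric(length(y)))
  n_correct <- rowSums(pred_mat == y)
  majority <- ifelse(rowMeans(pred_mat) > 0.5, 1,
                     ifelse(rowMeans(pred_mat) < 0.5, 0,
                            as.numeric(rowMeans(prob_mat) >= 0.5)))
  to_label <- function(v) ifelse(v == 1, positive, paste0("not_", positive))
  per_sample <- data.frame(
    sample_id = rownames(features$x) %||% as.character(seq_along(y)),
    label = as.character(features$labels),
    stringsAsFactors = FALSE
  )
  for (nm in colnames(pred_mat)) per_sample[[paste0("pred_", nm)]] <- to_label(pred_mat[, nm])
  per_sample$n_blocks_correct <- as.integer(n_correct)
  per_sample$majority_label <- to_label(majority)
  list(per_sample = per_sample,
       block_accuracy = colMeans(pred_mat == y),
       majority_accuracy = mean(majority == y))
}

#' Built-in classifier specifications for [benchmark_methods()]
#'
#' Each specification is a list with `fit(x, y, seed)` returning a model
#' and `predict(model, x)` returning positive-class probabilities.
#' Methods whose backing package is not installed are omitted.
#'
#' @return Named list of classifier specifications.
#' @export
default_methods <- function() {
  methods <- list(
    sgd = list(
      fit = function(x, y, seed) sgd_logistic(x, y, seed = seed),
      predict = function(m, x) predict(m, x)
    ),
    logistic = list(
      fit = function(x, y, seed) {
        suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))
      },
      predict = function(m, x) {
        z <- cbind(1, x) %*% m$coefficients
        as.vector(1 / (1 + exp(-z)))
      }
    )
  )
  if (requireNamespace("glmnet", quietly = TRUE)) {
    methods$lasso <- list(
      fit = function(x, y, seed) glmnet::glmnet(x, y, family = "binomial",
                                                lambda = 0.01),
      predict = function(m, x) as.vector(predict(m, x, type = "response"))
    )
  }
  if (requireNamespace("randomForest", quietly = TRUE)) {
    methods$random_forest <- list(
      fit = function(x, y, seed) with_seed(seed,
        randomForest::randomForest(x, factor(y), ntree = 200)),
      predict = function(m, x) predict(m, x, type = "prob")[, "1"]
    )
  }
  if (requireNamespace("e1071", quietly = TRUE)) {
    methods$svm_radial <- list(
      fit = function(x, y, seed) with_seed(seed,
        e1071::svm(x, factor(y), kernel = "radial", probability = TRUE)),
      predict = function(m, x) {
        attr(predict(m, x, probability = TRUE), "probabilities")[, "1"]
      }
    )
  }
  methods
}

#' Benchmark several classifiers with identical folds
#'
#' @inheritParams train_eval_sgd
#' @param methods named list of classifier specifications (see
#'   [default_methods()]).
#' @return Data frame: `method`, `cv_auc` (pooled out-of-fold AUC over the
#'   folds that succeeded), `n_folds_failed`.
#' @export
benchmark_methods <- function(features, labels = NULL,
                              methods = default_methods(), folds = 10,
                              seed = 1, positive = "cancer") {
  if (inherits(features, "cohort_features")) {
    x <- features$x
    labels <- features$labels
  } else {
    x <- as.matrix(features)
  }
  y <- binary_response(labels, positive)
  folds <- min(folds, min(table(y)))
  rows <- lapply(names(methods), function(nm) {
    sp <- methods[[nm]]
    oof <- cv_scores(x, y, folds, derive_seed(seed, 3L), sp$fit, sp$predict)
    ok <- !is.na(oof)
    auc <- if (sum(ok) && length(unique(y[ok])) == 2) {
      auc_score(oof[ok], y[ok])
    } else NA_real_
    data.frame(method = nm, cv_auc = auc,
               n_folds_failed = attr(oof, "n_failed"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
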