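# Linear classifier with logistic loss trained by stochastic gradient
# descent. Written for determinism: a fixed seed fixes the shuffling order,
# so the fitted weights are bit-identical across runs on the same platform.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Logistic regression by stochastic gradient descent
#'
#' Minimises the L2-regularised logistic loss with per-example updates and
#' the standard decaying learning rate
#' `eta_t = eta0 / (1 + eta0 * lambda * t)`. Features should be
#' standardised by the caller; the intercept is not regularised.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y 0/1 response vector.
#' @param epochs passes over the data (default 50).
#' @param eta0 initial learning rate (default 0.1).
#' @param lambda L2 regularisation strength (default 1e-3).
#' @param seed RNG seed controlling the shuffle order; fixed seed gives
#'   bit-identical fits.
#' @return `sgd_logistic` object with `weights`, `intercept` and the
#'   hyperparameters.
#' @export
sgd_logistic <- function(x, y, epochs = 50, eta0 = 0.1, lambda = 1e-3,
                         seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stopf("single-class input")
  n <- nrow(x)
  w <- numeric(ncol(x))
  b <- 0
  t <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- eta0 / (1 + eta0 * lambda * t)
        z <- sum(x[i, ] * w) + b
        p <- 1 / (1 + exp(-z))
        g <- p - y[i]
        w <- w - eta * (g * x[i, ] + lambda * w)
        b <- b - eta * g
      }
    }
  })
  structure(list(weights = w, intercept = b, epochs = epochs, eta0 = eta0,
                 lambda = lambda, seed = seed),
            class = "sgd_logistic")
}

#' @param object fitted [sgd_logistic()] model.
#' @param newdata feature matrix on the training scale.
#' @param ... unused.
#' @return Predicted probabilities of the positive class.
#' @rdname sgd_logistic
#' @export
predict.sgd_logistic <- function(object, newdata, ...) {
  z <- as.matrix(newdata) %*% object$weights + object$intercept
  as.vector(1 / (1 + exp(-z)))
}

#' ROC curve by threshold sweep
#'
#' @param scores predicted scores (higher = more positive).
#' @param labels 0/1 truth.
#' @return Data frame of ROC points (`fpr`, `tpr`), non-decreasing in both
#'   coordinates, from (0,0) to (1,1).
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  tp <- cumsum(labels)
  fp <- cumsum(1 - labels)
  # collapse tied scores to a single operating point
  keep <- c(diff(scores[ord]) != 0, TRUE)
  np <- sum(labels)
  nn <- length(labels) - np
  data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
}

#' Area under the ROC curve (trapezoid rule)
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  r <- roc_curve(scores, labels)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

# stratified fold assignment: seeded shuffle within class, then round-robin
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[is.na(sdev) | sdev == 0] <- 1
  list(apply = function(m) sweep(sweep(as.matrix(m), 2, mu), 2, sdev, "/"),
       mu = mu, sd = sdev)
}

# out-of-fold scores: standardisation refit inside each training fold so no
# test-fold information leaks into the model
cv_scores <- function(x, y, folds, seed, fit_fun, predict_fun) {
  fold <- make_folds(y, folds, seed)
  scores <- rep(NA_real_, length(y))
  failed <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    res <- tryCatch({
      std <- standardizer(x[tr, , drop = FALSE])
      model <- fit_fun(std$apply(x[tr, , drop = FALSE]), y[tr],
                       derive_seed(seed, f))
      predict_fun(model, std$apply(x[!tr, , drop = FALSE]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
    } else {
      scores[!tr] <- res
    }
  }
  structure(scores, fold = fold, n_failed = failed)
}
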