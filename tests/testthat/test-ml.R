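# Feature assembly, the SGD classifier, consistency and benchmarking.

sim_features <- function(n = 40, p = 4, shift = 2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)), NULL))
  labels <- setNames(rep(c("cancer", "healthy"), each = n / 2), rownames(x))
  x[labels == "cancer", 1] <- x[labels == "cancer", 1] + shift
  list(x = x, labels = labels)
}

test_that("assemble_features aligns blocks and records membership", {
  b1 <- matrix(1:10, 2, 5, dimnames = list(c("a", "b"), paste0("f", 1:5)))
  b2 <- matrix(c(1, 2, 3, 4, 5, 7), 2, 3, dimnames = list(c("a", "b"), NULL))
  fm <- assemble_features(list(frac = b1, cnv = b2),
                          labels = c(a = "cancer", b = "healthy"),
                          drop_constant = FALSE)
  expect_equal(dim(fm$x), c(2, 8))
  expect_equal(lengths(fm$blocks), c(frac = 5L, cnv = 3L))
  expect_equal(levels(fm$labels), c("cancer", "healthy"))
})

test_that("constant columns are dropped and missing samples handled", {
  b <- matrix(c(1, 1, 2, 5), 2, 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_warning(fm <- assemble_features(list(m = b),
                                         c(a = "cancer", b = "healthy")),
                 "zero-variance")
  expect_equal(colnames(fm$x), "m.c2")

  b2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), NULL))
  b3 <- matrix(5:6, 1, 2, dimnames = list("a", NULL))  # sample b missing
  expect_warning(fm2 <- assemble_features(
    list(x = b2, y = b3), c(a = "cancer", b = "healthy"), impute = "drop"),
    "dropping 1 sample")
  expect_equal(rownames(fm2$x), "a")
  fm3 <- suppressWarnings(assemble_features(
    list(x = b2, y = b3), c(a = "cancer", b = "healthy"), impute = "mean"))
  expect_equal(nrow(fm3$x), 2)
  expect_false(anyNA(fm3$x))
})

test_that("a perfectly separable feature gives AUC 1 and clean confusion", {
  sf <- sim_features(n = 40, p = 1, shift = 10)
  r <- train_eval_sgd(sf$x, sf$labels, folds = 5, seed = 3)
  expect_equal(r$test_auc, 1)
  expect_equal(r$cv_auc, 1)
  expect_equal(sum(r$confusion) , sum(r$predictions$split == "test"))
  expect_equal(r$confusion["positive", "negative"][[1]] +
                 r$confusion["negative", "positive"][[1]], 0)
})

test_that("reports are bit-reproducible under a fixed seed", {
  sf <- sim_features(n = 30, p = 5, shift = 1)
  r1 <- train_eval_sgd(sf$x, sf$labels, folds = 5, seed = 11)
  r2 <- train_eval_sgd(sf$x, sf$labels, folds = 5, seed = 11)
  expect_identical(r1, r2)
  r3 <- train_eval_sgd(sf$x, sf$labels, folds = 5, seed = 12)
  expect_false(identical(r1$cv_auc, r3$cv_auc))
})

test_that("ROC points are monotone and AUC matches an independent oracle", {
  set.seed(9)
  scores <- rnorm(60)
  y <- rbinom(60, 1, plogis(2 * scores))
  roc <- roc_curve(scores, y)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(range(roc$fpr), c(0, 1))
  skip_if_not_installed("pROC")
  oracle <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(auc_score(scores, y), oracle, tolerance = 1e-12)
})

test_that("permuted labels give chance-level out-of-fold AUC", {
  set.seed(21)
  n <- 100
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("s", 1:n), NULL))
  labels <- setNames(sample(rep(c("cancer", "healthy"), each = n / 2)),
                     rownames(x))
  r <- train_eval_sgd(x, labels, folds = 10, seed = 5)
  expect_gte(r$cv_auc, 0.35)
  expect_lte(r$cv_auc, 0.65)
})

test_that("fold-internal standardisation does not leak; a deliberate leak does", {
  set.seed(33)
  n <- 60; p <- 200
  x <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("s", 1:n), NULL))
  y <- rep(c(1, 0), each = n / 2)
  labels <- setNames(ifelse(y == 1, "cancer", "healthy"), rownames(x))
  # deliberate leak: select the 10 features most correlated with the labels
  # on ALL data, then cross-validate on the selected matrix
  cors <- abs(cor(x, y))
  x_leak <- x[, order(-cors)[1:10]]
  r_leak <- train_eval_sgd(x_leak, labels, folds = 5, seed = 2)
  # shipped path on the full matrix, selection-free
  r_clean <- train_eval_sgd(x, labels, folds = 5, seed = 2)
  expect_gt(r_leak$cv_auc, 0.75)
  expect_lte(r_clean$cv_auc, 0.7)
  expect_gt(r_leak$cv_auc - r_clean$cv_auc, 0.15)
})

test_that("single-class input and fold reduction are handled", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  expect_error(train_eval_sgd(x, setNames(rep("cancer", 10), rownames(x))),
               "single-class")
  labels <- setNames(rep(c("cancer", "healthy"), each = 5), rownames(x))
  expect_warning(r <- train_eval_sgd(x, labels, folds = 10, seed = 1),
                 "reducing folds")
  expect_equal(r$settings$folds, 5)
})

test_that("per-modality consistency: identical blocks agree, noise is chance", {
  sf <- sim_features(n = 40, p = 3, shift = 3, seed = 8)
  set.seed(88)
  noise <- matrix(rnorm(40 * 3), 40, 3, dimnames = dimnames(sf$x))
  fm <- assemble_features(list(a = sf$x, b = sf$x, noise = noise), sf$labels)
  cons <- per_modality_consistency(fm, folds = 5, seed = 4)
  expect_identical(cons$per_sample$pred_a, cons$per_sample$pred_b)
  expect_gte(cons$block_accuracy[["noise"]], 0.25)
  expect_lte(cons$block_accuracy[["noise"]], 0.75)
  # majority vote is no worse than the best block minus a small margin
  expect_gte(cons$majority_accuracy, max(cons$block_accuracy) - 0.05)
})

test_that("benchmarking runs every method on identical folds", {
  sf <- sim_features(n = 40, p = 3, shift = 5, seed = 10)
  methods <- default_methods()
  methods$dummy <- list(fit = function(x, y, seed) NULL,
                        predict = function(m, x) rep(0.5, nrow(x)))
  methods$sgd_again <- methods$sgd
  bm <- benchmark_methods(sf$x, sf$labels, methods = methods, folds = 5,
                          seed = 6)
  expect_equal(bm$cv_auc[bm$method == "sgd"],
               bm$cv_auc[bm$method == "sgd_again"])
  expect_equal(bm$cv_auc[bm$method == "dummy"], 0.5)
  sane <- setdiff(bm$method, "dummy")
  expect_true(all(bm$cv_auc[bm$method %in% sane] >= 0.9))
  expect_true(all(bm$n_folds_failed == 0))
})

test_that("failing methods are recorded as missing without stopping the run", {
  sf <- sim_features(n = 20, p = 2, shift = 5)
  methods <- list(broken = list(fit = function(x, y, seed) stop("boom"),
                                predict = function(m, x) NULL),
                  sgd = default_methods()$sgd)
  bm <- benchmark_methods(sf$x, sf$labels, methods = methods, folds = 4,
                          seed = 1)
  expect_true(is.na(bm$cv_auc[bm$method == "broken"]))
  expect_equal(bm$n_folds_failed[bm$method == "broken"], 4)
  expect_false(is.na(bm$cv_auc[bm$method == "sgd"]))
})
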