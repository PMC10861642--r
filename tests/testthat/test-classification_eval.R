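# toy linearly separable 2-D feature table
toy_table <- function(n = 20, centers = list(A = c(0, 0), B = c(10, 10)),
                      spread = 0.1, seed = 5) {
  with_seed_local <- function(s, e) { set.seed(s); e }
  set.seed(seed)
  rows <- lapply(names(centers), function(k) {
    X <- cbind(stats::rnorm(n, centers[[k]][1], spread),
               stats::rnorm(n, centers[[k]][2], spread))
    colnames(X) <- c("f1", "f2")
    feature_table(sprintf("%s%02d", k, 1:n), rep(k, n), X)
  })
  do.call(rbind, rows)
}

test_that("stratified split preserves class ratios and is seed-reproducible", {
  tab <- make_synth_table(n_per_class = 10, seed = 3, size = c(32, 32))
  sp <- split_spec(test_fraction = 0.2, seed = 9)
  parts <- stratified_split(tab, sp)
  expect_identical(nrow(parts$train) + nrow(parts$test), nrow(tab))
  expect_length(intersect(parts$train$source_id, parts$test$source_id), 0L)
  for (k in unique(tab$label))
    expect_lte(abs(sum(parts$test$label == k) - 0.2 * 10), 1)
  parts2 <- stratified_split(tab, sp)
  expect_identical(parts$test$source_id, parts2$test$source_id)
  expect_error(split_spec(test_fraction = 0), "test_fraction")
  one <- tab[c(1, 11, 12, 21, 22), ]
  expect_error(stratified_split(one, sp), "2 samples")
})

test_that("linear SVM separates a separable toy problem deterministically", {
  tab <- toy_table()
  fit <- fit_linear_svm(tab, C = 1, seed = 1)
  pred <- predict(fit, tab)
  expect_equal(mean(pred$labels == tab$label), 1.0)
  # duplicating every training point leaves the decision function unchanged
  # same separating hyperplane up to the solver's convergence tolerance
  fit2 <- fit_linear_svm(rbind(tab, tab), C = 1, seed = 1)
  norm1 <- sqrt(colSums(fit$W^2)); norm2 <- sqrt(colSums(fit2$W^2))
  expect_equal(sweep(fit$W, 2, norm1, "/"), sweep(fit2$W, 2, norm2, "/"),
               tolerance = 1e-2)
  expect_equal(fit$b / norm1, fit2$b / norm2, tolerance = 1e-2)
  expect_identical(predict(fit2, tab)$labels, pred$labels)
  expect_error(fit_linear_svm(tab[tab$label == "A", ]), "2 classes")
  # layout mismatch is rejected
  bad <- tab
  names(bad)[3] <- "zz"
  expect_error(predict(fit, bad), "layout")
})

test_that("evaluate reproduces hand-computed binary metrics", {
  # TP=50 TN=40 FP=5 FN=5 for class "pos"
  cm <- matrix(c(50L, 5L, 5L, 40L), 2, 2, byrow = TRUE,
               dimnames = list(truth = c("pos", "neg"),
                               predicted = c("pos", "neg")))
  rep <- metrics_report(cm)
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$accuracy, 0.9)
  expect_equal(pos$precision, 50 / 55)
  expect_equal(pos$recall, 50 / 55)
  expect_equal(pos$specificity, 40 / 45)
  expect_equal(pos$FPR, 5 / 45)
  expect_equal(pos$FNR, 5 / 55)
  expect_equal(pos$dice, 100 / 110)
  expect_equal(rep$micro_accuracy, 0.9)
})

test_that("perfect and degenerate predictors give the expected battery", {
  labs <- rep(c("a", "b", "c"), each = 10)
  cm <- confusion_matrix(labs, labs)
  rep <- metrics_report(cm)
  expect_equal(unname(rep$macro[c("accuracy", "precision", "recall", "f1",
                                  "specificity")]), rep(1, 5))
  expect_equal(unname(rep$macro[c("FPR", "FNR")]), c(0, 0))
  # all-one-class predictor on balanced 3-class truth
  cm1 <- confusion_matrix(labs, rep("a", 30))
  expect_equal(metrics_report(cm1)$micro_accuracy, 1 / 3)
})

test_that("metric identities hold on fuzzed confusion matrices", {
  set.seed(29)
  for (i in 1:500) {
    cm <- random_confusion(K = sample(2:5, 1))
    if (sum(cm) == 0) next
    per <- metrics_report(cm)$per_class
    expect_identical(per$recall, per$sensitivity)
    expect_identical(per$recall, per$TPR)
    expect_equal(per$FNR, 1 - per$TPR, tolerance = 1e-12)
    expect_equal(per$specificity, 1 - per$FPR, tolerance = 1e-12)
    expect_identical(per$specificity, per$TNR)
    expect_identical(per$dice, per$f1)
    expect_equal(metrics_report(cm)$micro_accuracy, sum(diag(cm)) / sum(cm))
  }
})

test_that("per-class Dice matches the formula and flags empty classes", {
  cm <- matrix(c(50L, 5L, 5L, 40L), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  d <- dice_per_class(cm)
  expect_equal(d[["pos"]], 100 / 110)
  cm_empty <- matrix(c(10L, 0L, 0L, 0L), 2, 2,
                     dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(d2 <- dice_per_class(cm_empty), "empty|absent|1")
  expect_equal(d2[["b"]], 1)
  expect_true(attr(d2, "empty")[2])
})

test_that("trapezoidal AUC equals the brute-force pairwise win rate", {
  # 4-point hand example: positives 0.9/0.8, negatives 0.7/0.95
  s <- c(0.9, 0.8, 0.7, 0.95)
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  S <- cbind(p = s, q = -s)
  labs <- ifelse(pos, "p", "q")
  r <- roc_ovr(S, labs)
  expect_equal(r$auc[["p"]], 0.5)
  expect_equal(r$auc[["p"]], oracle_pairwise_auc(s, pos))

  set.seed(41)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    scores <- round(stats::rnorm(n), 1)   # rounding forces ties
    pos <- stats::runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    S <- cbind(p = scores, q = -scores)
    r <- roc_ovr(S, ifelse(pos, "p", "q"))
    expect_equal(r$auc[["p"]], oracle_pairwise_auc(scores, pos),
                 tolerance = 1e-12)
    # micro curve pools both columns
    expect_equal(r$micro$auc,
                 oracle_pairwise_auc(c(scores, -scores), c(pos, !pos)),
                 tolerance = 1e-12)
  }
})

test_that("ROC extremes: perfect separation gives AUC 1, noise about 0.5", {
  scores <- c(stats::runif(25, 0.8, 1), stats::runif(25, 0, 0.2))
  pos <- rep(c(TRUE, FALSE), each = 25)
  r <- roc_ovr(cbind(p = scores, q = -scores), ifelse(pos, "p", "q"))
  expect_equal(r$auc[["p"]], 1)
  expect_equal(r$auc[["q"]], 1)
  set.seed(59)
  scores <- stats::rnorm(2000)
  pos <- stats::runif(2000) < 0.5
  r <- roc_ovr(cbind(p = scores, q = -scores), ifelse(pos, "p", "q"))
  expect_lt(abs(r$auc[["p"]] - 0.5), 0.05)
  # degenerate class: no positives
  expect_warning(
    r3 <- roc_ovr(cbind(p = 1:4, q = 4:1, z = rep(0, 4)),
                  c("p", "p", "q", "q")), "lacks")
  expect_true(is.na(r3$auc[["z"]]))
})

test_that("learning curve reports perfect train accuracy on separable data", {
  tab <- toy_table(n = 30)
  lc <- learning_curve(tab, sizes = c(0.5, 1), spec = split_spec(folds = 3))
  expect_equal(lc$train_mean, rep(1, 2))
  expect_true(all(lc$val_mean > 0.9))
  expect_identical(lc$n, c(30L, 60L))
  # SD over folds matches its definition on the recorded scores
  expect_true(all(lc$val_sd >= 0))
  expect_warning(
    learning_curve(tab[c(1:4, 31:34), ], sizes = 0.3,
                   spec = split_spec(folds = 3)), "skipped|fewer")
})
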