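# Linear-SVM training on feature tables and the full confusion-matrix
# metric battery: Table-style rates, per-class Dice, one-vs-rest ROC/AUC,
# and learning curves.

#' Train/test split specification
#'
#' @param test_fraction Fraction held out, in (0, 1). Default 0.2.
#' @param folds Cross-validation folds for [learning_curve()], >= 2.
#' @param seed Integer seed making every split reproducible.
#' @param stratified Preserve per-class proportions (default `TRUE`).
#' @return A `split_spec` list.
#' @export
split_spec <- function(test_fraction = 0.2, folds = 5L, seed = 1L,
                       stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  structure(list(test_fraction = test_fraction, folds = as.integer(folds),
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

#' Stratified train/test split of a feature table
#'
#' Disjoint, exhaustive partition; with stratification each class's test
#' count is `round(n_k * test_fraction)` (at least 1), so class
#' proportions are preserved within rounding. Reproducible for a fixed
#' `spec$seed`.
#'
#' @param table A [feature_table()].
#' @param spec A [split_spec()].
#' @return List with `train` and `test` feature tables.
#' @export
stratified_split <- function(table, spec = split_spec()) {
  labs <- table$label
  cnt <- table(labs)
  if (any(cnt < 2L))
    stop("every class needs at least 2 samples to split", call. = FALSE)
  test_idx <- with_local_seed(spec$seed, {
    if (spec$stratified) {
      unlist(lapply(names(cnt), function(k) {
        idx <- which(labs == k)
        n_test <- max(1L, min(length(idx) - 1L,
                              round(length(idx) * spec$test_fraction)))
        sample(idx, n_test)
      }))
    } else {
      sample(nrow(table), max(1L, round(nrow(table) * spec$test_fraction)))
    }
  })
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

#' Fit a one-vs-rest linear-kernel SVM
#'
#' Features are z-scored with statistics of the training set only
#' (constant features get unit scale), then one binary linear SVM is fit
#' per class against the rest. The stored model keeps, per class, the
#' explicit weight vector and bias of the decision function, so prediction
#' is a deterministic matrix product.
#'
#' @param train A [feature_table()] with >= 2 classes.
#' @param C Regularization (cost) parameter of the soft-margin SVM.
#' @param seed Integer recorded with the model; the underlying solver is
#'   itself deterministic given the data.
#' @return A `linear_svm` object: `W` (features x classes weight matrix),
#'   `b` (per-class bias), `center`/`scale` (standardization), `classes`,
#'   `C`, `seed`.
#' @export
fit_linear_svm <- function(train, C = 1.0, seed = 1L) {
  X <- feature_matrix(train)
  y <- train$label
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("training data must contain at least 2 classes", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- scale(X, center = ctr, scale = scl)

  W <- matrix(0, ncol(X), length(classes),
              dimnames = list(colnames(X), classes))
  b <- stats::setNames(numeric(length(classes)), classes)
  for (k in classes) {
    yk <- factor(ifelse(y == k, "pos", "rest"), levels = c("pos", "rest"))
    fit <- e1071::svm(Z, yk, kernel = "linear", cost = C, scale = FALSE)
    w <- crossprod(fit$SV, fit$coefs)[, 1L]
    # libsvm's decision value is positive for its first internal label,
    # which follows order of appearance in the data, not factor order
    flip <- if (fit$labels[1L] == 1L) 1 else -1
    W[, k] <- flip * w
    b[k] <- flip * -fit$rho
  }
  structure(list(W = W, b = b, center = ctr, scale = scl,
                 classes = classes, C = C, seed = as.integer(seed)),
            class = "linear_svm")
}

#' Per-class decision scores and predicted labels
#'
#' @param object A `linear_svm` from [fit_linear_svm()].
#' @param newdata A [feature_table()] (or bare feature matrix) with the
#'   training feature layout.
#' @param ... Unused.
#' @return List with `scores` (n x classes decision-value matrix) and
#'   `labels` (argmax class per row).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "data.frame")) feature_matrix(newdata)
       else as.matrix(newdata)
  if (ncol(X) != nrow(object$W) ||
      !identical(colnames(X), rownames(object$W)))
    stop("feature layout does not match the trained model", call. = FALSE)
  Z <- scale(X, center = object$center, scale = object$scale)
  S <- Z %*% object$W + rep(object$b, each = nrow(Z))
  list(scores = S, labels = object$classes[max.col(S, ties.method = "first")])
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted Character vectors of class labels.
#' @param classes Optional class ordering; defaults to the sorted union.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

# one-vs-rest TP/FP/FN/TN per class
ovr_counts <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- sum(cm) - tp - fp - fn
  data.frame(class = colnames(cm), TP = tp, FP = fp, FN = fn, TN = tn,
             row.names = NULL)
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Full metric battery from a confusion matrix
#'
#' Computes, per class one-vs-rest and macro-averaged: accuracy, precision,
#' recall, F1, sensitivity (= recall = TPR), specificity (= TNR = 1 - FPR),
#' TPR, FPR, FNR, TNR, and Dice (= per-class F1 by the identity
#' `2TP / (2TP + FP + FN)`). Also reports the pooled (micro) accuracy
#' `trace(cm) / n`. Rates with a zero denominator are reported as 0.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return A `metrics_report`: list with `per_class` (data.frame), `macro`
#'   (named vector), `micro_accuracy`, `confusion`.
#' @export
metrics_report <- function(cm) {
  ct <- ovr_counts(cm)
  with(ct, {
    tpr <- safe_div(TP, TP + FN)
    fpr <- safe_div(FP, FP + TN)
    tnr <- safe_div(TN, FP + TN)
    f1 <- safe_div(2 * TP, 2 * TP + FP + FN)
    per <- data.frame(
      class = class,
      accuracy = (TP + TN) / (TP + TN + FP + FN),
      precision = safe_div(TP, TP + FP),
      recall = tpr,
      f1 = f1,
      sensitivity = tpr,
      specificity = tnr,
      TPR = tpr,
      FPR = fpr,
      FNR = safe_div(FN, TP + FN),
      TNR = tnr,
      dice = f1,
      row.names = NULL)
    macro <- colMeans(per[, -1L])
    structure(list(per_class = per, macro = macro,
                   micro_accuracy = sum(diag(cm)) / sum(cm),
                   confusion = cm),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Macro-averaged metrics over", nrow(x$per_class), "classes:\n")
  print(round(x$macro, 4))
  cat(sprintf("Micro (pooled) accuracy: %.4f\n", x$micro_accuracy))
  invisible(x)
}

#' Evaluate a trained classifier on a held-out feature table
#'
#' @param model A `linear_svm`.
#' @param test A [feature_table()] with the training feature layout.
#' @return List with `confusion`, `metrics` (a [metrics_report()]), `roc`
#'   (from [roc_ovr()]) and the raw `scores`.
#' @export
evaluate <- function(model, test) {
  pred <- predict(model, test)
  cm <- confusion_matrix(test$label, pred$labels, classes = model$classes)
  list(confusion = cm, metrics = metrics_report(cm),
       roc = roc_ovr(pred$scores, test$label), scores = pred$scores)
}

#' Per-class Dice similarity coefficient
#'
#' `dice_k = 2 TP_k / (2 TP_k + FP_k + FN_k)`, identical to the per-class
#' F1 score. A class with `2TP + FP + FN = 0` (absent from both truth and
#' predictions) gets Dice 1 by the empty-vs-empty convention and is
#' flagged.
#'
#' @param cm Confusion matrix.
#' @return Named per-class vector with attributes `macro` (mean) and
#'   `empty` (logical flags).
#' @export
dice_per_class <- function(cm) {
  ct <- ovr_counts(cm)
  den <- 2 * ct$TP + ct$FP + ct$FN
  empty <- den == 0
  if (any(empty))
    warning("Dice for class(es) absent from truth and predictions ",
            "defined as 1: ", paste(ct$class[empty], collapse = ", "))
  d <- ifelse(empty, 1, 2 * ct$TP / ifelse(empty, 1, den))
  names(d) <- ct$class
  attr(d, "macro") <- mean(d)
  attr(d, "empty") <- empty
  d
}

# binary ROC by threshold sweep over unique scores; trapezoidal AUC
binary_roc <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  # cumulative counts at each distinct threshold (ties collapse)
  keep <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(p)[keep]; fp <- cumsum(!p)[keep]
  P <- sum(positive); N <- sum(!positive)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps a threshold over that class's decision scores
#' against binary is-that-class labels (trapezoidal AUC; tied scores
#' collapse to one operating point, equivalent to counting ties as half
#' wins). The micro-average pools all (score, binary label) pairs across
#' classes into one curve.
#'
#' @param scores n x K matrix of per-class decision values with class
#'   column names.
#' @param labels Length-n true class labels.
#' @return List with `per_class` (each `fpr`, `tpr`, `auc`), `auc` (named
#'   per-class vector), `macro_auc` (mean over classes with both
#'   positives and negatives) and `micro` (pooled curve and `auc`).
#' @export
roc_ovr <- function(scores, labels) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)),
            nrow(scores) == length(labels), all(is.finite(scores)))
  classes <- colnames(scores)
  per <- list(); aucs <- stats::setNames(rep(NA_real_, length(classes)), classes)
  pool_s <- c(); pool_p <- c()
  for (k in classes) {
    pos <- labels == k
    pool_s <- c(pool_s, scores[, k]); pool_p <- c(pool_p, pos)
    if (!any(pos) || all(pos)) {
      warning("class ", k, " lacks positives or negatives; AUC undefined")
      per[[k]] <- list(fpr = NA, tpr = NA, auc = NA_real_)
      next
    }
    per[[k]] <- binary_roc(scores[, k], pos)
    aucs[k] <- per[[k]]$auc
  }
  micro <- binary_roc(pool_s, pool_p)
  list(per_class = per, auc = aucs,
       macro_auc = mean(aucs, na.rm = TRUE), micro = micro)
}

#' Learning curve by cross-validated subsampling
#'
#' For each training-set fraction, stratified-subsamples the table, runs
#' k-fold cross-validation, and records the accuracy on the training folds
#' and on the validation fold (mean and SD over folds).
#'
#' @param table A [feature_table()].
#' @param sizes Fractions of the table to use, each in (0, 1].
#' @param spec A [split_spec()] (supplies `folds` and `seed`).
#' @param C SVM cost parameter.
#' @return data.frame with columns `size`, `n`, `train_mean`, `train_sd`,
#'   `val_mean`, `val_sd`.
#' @export
learning_curve <- function(table, sizes = c(0.25, 0.5, 0.75, 1),
                           spec = split_spec(), C = 1.0) {
  stopifnot(all(sizes > 0), all(sizes <= 1))
  classes <- sort(unique(table$label))
  rows <- list()
  for (s in sizes) {
    sub_idx <- with_local_seed(spec$seed + round(1000 * s), {
      unlist(lapply(classes, function(k) {
        idx <- which(table$label == k)
        sample(idx, max(1L, round(length(idx) * s)))
      }))
    })
    sub <- table[sub_idx, , drop = FALSE]
    if (any(table(sub$label) < spec$folds)) {
      warning("size ", s, " leaves a class with fewer samples than folds; skipped")
      next
    }
    folds <- with_local_seed(spec$seed, {      # stratified fold assignment
      f <- integer(nrow(sub))
      for (k in classes) {
        idx <- which(sub$label == k)
        f[idx] <- sample(rep_len(seq_len(spec$folds), length(idx)))
      }
      f
    })
    tr_acc <- val_acc <- numeric(spec$folds)
    for (i in seq_len(spec$folds)) {
      tr <- sub[folds != i, , drop = FALSE]
      va <- sub[folds == i, , drop = FALSE]
      fit <- fit_linear_svm(tr, C = C, seed = spec$seed)
      tr_acc[i] <- mean(predict(fit, tr)$labels == tr$label)
      val_acc[i] <- mean(predict(fit, va)$labels == va$label)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      size = s, n = nrow(sub),
      train_mean = mean(tr_acc), train_sd = stats::sd(tr_acc),
      val_mean = mean(val_acc), val_sd = stats::sd(val_acc))
  }
  do.call(rbind, rows)
}
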