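# Classification and evaluation: Gaussian-kernel SVM and random forest,
# stratified train/test splitting, k-fold and jackknife cross-validation,
# and the four confusion-matrix metrics (SN, SP, ACC, MCC).

#' Gaussian (RBF) kernel
#'
#' \eqn{K(x_1, x_2) = \exp(-\lVert x_1 - x_2 \rVert^2 / (2\sigma^2))}.
#' Symmetric, with values in `(0, 1]` and `K(x, x) = 1`.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param sigma Kernel width, positive.
#' @return A scalar kernel value.
#' @export
gaussian_kernel <- function(x1, x2, sigma) {
  if (length(x1) != length(x2)) {
    abort("kernel arguments must have equal dimension")
  }
  if (sigma <= 0) abort("sigma must be positive")
  exp(-sum((x1 - x2)^2) / (2 * sigma^2))
}

#' Train a DNA-binding protein classifier
#'
#' Fits a Gaussian-kernel soft-margin SVM (via e1071) or a random forest
#' (via randomForest) on a labelled feature table. Features are
#' standardized to training-set mean 0 / variance 1 before an SVM fit (the
#' same transform is reapplied at prediction time); random forests use the
#' raw features.
#'
#' @param data Labelled feature table (`sample_id`, `label` 0/1, feature
#'   columns); both classes must be present.
#' @param classifier `"svm"` or `"rf"`.
#' @param cost SVM soft-margin penalty C (default 1).
#' @param sigma Gaussian kernel width; default `sqrt(d/2)` for d features
#'   (the `gamma = 1/d` heuristic).
#' @param ntree Random-forest tree count (default 500).
#' @param seed Integer seed; fits are deterministic given it.
#' @return A `dbp_model` object.
#' @export
train_classifier <- function(data, classifier = c("svm", "rf"),
                             cost = 1, sigma = NULL, ntree = 500, seed = 1) {
  classifier <- match.arg(classifier)
  assert_labeled(data)
  m <- feature_matrix(data)
  y <- factor(as.integer(data$label > 0), levels = c(0, 1))
  center <- colMeans(m)
  scale <- apply(m, 2, sd)
  scale[scale == 0] <- 1
  set.seed(seed)
  if (classifier == "svm") {
    sigma <- sigma %||% sqrt(ncol(m) / 2)
    if (sigma <= 0) abort("sigma must be positive")
    z <- scale(m, center = center, scale = scale)
    fit <- e1071::svm(x = z, y = y, kernel = "radial",
                      gamma = 1 / (2 * sigma^2), cost = cost, scale = FALSE)
  } else {
    sigma <- NA_real_
    fit <- randomForest::randomForest(x = m, y = y, ntree = ntree)
  }
  structure(
    list(classifier = classifier, fit = fit,
         feature_names = colnames(m), center = center, scale = scale,
         cost = cost, sigma = sigma, ntree = ntree, seed = seed,
         n_train = nrow(m)),
    class = "dbp_model")
}

#' @export
print.dbp_model <- function(x, ...) {
  cat(sprintf("<dbp_model: %s, %d features, %d training samples>\n",
              x$classifier, length(x$feature_names), x$n_train))
  invisible(x)
}

#' Predict class labels for new samples
#'
#' @param object A `dbp_model`.
#' @param newdata Feature table with exactly the features the model was
#'   trained on (any column order).
#' @param ... Unused.
#' @return Integer vector of 0/1 labels (1 = binding), named by
#'   `sample_id`.
#' @export
predict.dbp_model <- function(object, newdata, ...) {
  fn <- feature_names(newdata)
  missing_f <- setdiff(object$feature_names, fn)
  extra_f <- setdiff(fn, object$feature_names)
  if (length(missing_f) || length(extra_f)) {
    abort(paste0(
      "feature mismatch with training data;",
      if (length(missing_f)) paste0(" missing: ",
        paste(head(missing_f, 5), collapse = ", ")),
      if (length(extra_f)) paste0(" extra: ",
        paste(head(extra_f, 5), collapse = ", "))))
  }
  if (nrow(newdata) == 0) {
    return(setNames(integer(0), character(0)))
  }
  m <- feature_matrix(newdata)[, object$feature_names, drop = FALSE]
  if (object$classifier == "svm") {
    m <- scale(m, center = object$center, scale = object$scale)
  }
  pred <- predict(object$fit, m)
  setNames(as.integer(as.character(pred)), newdata$sample_id)
}

confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth > 0)
  pred <- as.integer(pred > 0)
  c(tp = sum(truth == 1 & pred == 1), fp = sum(truth == 0 & pred == 1),
    tn = sum(truth == 0 & pred == 0), fn = sum(truth == 1 & pred == 0))
}

#' Evaluation metrics from confusion counts
#'
#' Computes sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' accuracy `ACC = (TP+TN)/(TP+FP+TN+FN)` and the Matthews correlation
#' coefficient
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' with `MCC = 0` when any denominator factor vanishes.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts, total > 0.
#' @return A `dbp_eval` object with the counts and the four metrics.
#' @export
#' @examples
#' compute_metrics(14, 3, 16, 5)  # SN 0.7368, SP 0.8421, ACC 0.7895, MCC 0.58
compute_metrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    abort("confusion counts must be non-negative integers")
  }
  if (sum(cnt) == 0) abort("confusion counts are all zero")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / sum(cnt)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
         fn = as.integer(fn), sn = sn, sp = sp, acc = acc, mcc = mcc),
    class = "dbp_eval")
}

#' @export
print.dbp_eval <- function(x, ...) {
  cat(sprintf(
    "<dbp_eval: TP=%d FP=%d TN=%d FN=%d | SN=%.4f SP=%.4f ACC=%.4f MCC=%.4f>\n",
    x$tp, x$fp, x$tn, x$fn, x$sn, x$sp, x$acc, x$mcc))
  invisible(x)
}

#' Evaluate a fitted model on labelled data
#'
#' @param model A `dbp_model`.
#' @param data Labelled feature table.
#' @return A `dbp_eval` report.
#' @export
evaluate_model <- function(model, data) {
  assert_labeled(data)
  pred <- predict(model, data)
  cc <- confusion_counts(data$label, pred)
  compute_metrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"])
}

stratified_folds <- function(label, k, seed) {
  set.seed(seed)
  fold <- integer(length(label))
  for (cl in unique(label)) {
    idx <- which(label == cl)
    if (length(idx) < k) {
      abort(sprintf("class %s has %d samples, fewer than k = %d folds",
                    cl, length(idx), k))
    }
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Assigns samples to `k` folds stratified by class, trains on `k - 1`
#' folds and scores the held-out fold, and reports the mean of the fold
#' accuracies together with per-fold confusion counts and the pooled
#' evaluation.
#'
#' When `mrmd_m` is given, MRMD feature selection is refit on every
#' training fold and applied to its held-out fold, so the selection never
#' sees test labels (selection performed once on the full data before
#' cross-validation would bias the estimate upward).
#'
#' @param data Labelled feature table; each class needs at least `k`
#'   samples.
#' @param k Number of folds (default 10).
#' @param mrmd_m Optional per-fold MRMD selection size (integer or
#'   `"auto"`, see [mrmd_select()]); `NULL` disables selection.
#' @param classifier,seed,... Passed to [train_classifier()]; `seed` also
#'   fixes the fold assignment.
#' @return A `dbp_cv` object with `mean_accuracy`, a per-fold tibble
#'   `folds`, and the pooled `dbp_eval`.
#' @export
k_fold_cv <- function(data, k = 10, classifier = "svm", seed = 1,
                      mrmd_m = NULL, ...) {
  assert_labeled(data)
  if (k < 2) abort("k must be at least 2")
  fold <- stratified_folds(as.integer(data$label > 0), k, seed)
  per_fold <- purrr::map(seq_len(k), function(f) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    if (!is.null(mrmd_m)) {
      train <- mrmd_select(train, m = mrmd_m, classifier = classifier,
                           seed = seed)
      test <- test[, names(train), drop = FALSE]
    }
    model <- train_classifier(train, classifier = classifier,
                              seed = seed, ...)
    cc <- confusion_counts(test$label, predict(model, test))
    c(fold = f, cc, accuracy = unname((cc["tp"] + cc["tn"]) / sum(cc)))
  })
  folds <- as_tibble(do.call(rbind, per_fold))
  pooled <- compute_metrics(sum(folds$tp), sum(folds$fp),
                            sum(folds$tn), sum(folds$fn))
  structure(
    list(mean_accuracy = mean(folds$accuracy), folds = folds,
         pooled = pooled, k = k, classifier = classifier, seed = seed),
    class = "dbp_cv")
}

#' @export
print.dbp_cv <- function(x, ...) {
  cat(sprintf("<dbp_cv: %d-fold, %s, mean accuracy %.4f>\n",
              x$k, x$classifier, x$mean_accuracy))
  invisible(x)
}

#' Jackknife (leave-one-out) validation
#'
#' Each sample is predicted by a model trained on all other samples; the
#' pooled predictions form one confusion matrix.
#'
#' @param data Labelled feature table with at least 3 samples.
#' @param classifier,seed,... Passed to [train_classifier()].
#' @return A `dbp_eval` report over the pooled leave-one-out predictions.
#' @export
jackknife_cv <- function(data, classifier = "svm", seed = 1, ...) {
  assert_labeled(data)
  n <- nrow(data)
  if (n < 3) abort("jackknife validation needs at least 3 samples")
  pred <- vapply(seq_len(n), function(i) {
    model <- train_classifier(data[-i, , drop = FALSE],
                              classifier = classifier, seed = seed, ...)
    unname(predict(model, data[i, , drop = FALSE]))
  }, integer(1))
  cc <- confusion_counts(data$label, pred)
  compute_metrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"])
}

#' Stratified train/test split
#'
#' Randomly assigns `floor(train_fraction * n_class)` samples of each
#' class to the training partition, the rest to the test partition, so the
#' class balance is preserved (e.g. a balanced 186-sample set at fraction
#' 0.8 gives 74+74 training and 19+19 test samples).
#'
#' @param data Labelled feature table.
#' @param train_fraction Fraction in (0, 1) of each class for training.
#' @param seed Integer seed fixing the random membership.
#' @return A list with elements `train` and `test`, disjoint feature
#'   tables whose union is `data`.
#' @export
train_test_split_stratified <- function(data, train_fraction = 0.8,
                                        seed = 1) {
  assert_labeled(data)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be strictly between 0 and 1")
  }
  set.seed(seed)
  lab <- as.integer(data$label > 0)
  train_idx <- integer(0)
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    n_train <- floor(train_fraction * length(idx))
    if (n_train == 0 || n_train == length(idx)) {
      abort(sprintf("split empties class %d (size %d, fraction %.2f)",
                    cl, length(idx), train_fraction))
    }
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = data[train_idx, , drop = FALSE],
       test = data[-train_idx, , drop = FALSE])
}

#' Save / load a fitted classifier
#'
#' Persists a `dbp_model` together with a format version and the package
#' version that wrote it.
#'
#' @param model A `dbp_model`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `dbp_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "dbp_model")) abort("not a dbp_model")
  saveRDS(list(format = "dbpmix-model/1",
               package_version = as.character(utils::packageVersion("dbpmix")),
               model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "dbpmix-model/1")) {
    abort("not a dbpmix model file")
  }
  obj$model
}
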