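# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' @param x A `dbp_eval` object.
#' @param ... Unused.
#' @return A tibble with columns `metric` (`sn`, `sp`, `acc`, `mcc`) and
#'   `value`.
#' @method tidy dbp_eval
#' @export
tidy.dbp_eval <- function(x, ...) {
  tibble(metric = c("sn", "sp", "acc", "mcc"),
         value = c(x$sn, x$sp, x$acc, x$mcc))
}

#' @rdname tidy.dbp_eval
#' @return `glance()` returns a one-row tibble with the confusion counts
#'   and all four metrics.
#' @method glance dbp_eval
#' @export
glance.dbp_eval <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
         sn = x$sn, sp = x$sp, acc = x$acc, mcc = x$mcc)
}

#' Tidy a cross-validation result
#'
#' @param x A `dbp_cv` object.
#' @param ... Unused.
#' @return Per-fold tibble (`fold`, confusion counts, `accuracy`).
#' @method tidy dbp_cv
#' @export
tidy.dbp_cv <- function(x, ...) {
  x$folds
}

#' @rdname tidy.dbp_cv
#' @return `glance()` returns a one-row tibble with `k`, `classifier`,
#'   `mean_accuracy` and the pooled metrics.
#' @method glance dbp_cv
#' @export
glance.dbp_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(k = x$k, classifier = x$classifier,
           mean_accuracy = x$mean_accuracy),
    dplyr::rename_with(glance(x$pooled), ~ paste0("pooled_", .x)))
}

#' Tidy a fitted classifier
#'
#' @param x A `dbp_model`.
#' @param ... Unused.
#' @return `glance()` returns a one-row tibble of the model settings
#'   (classifier kind, feature count, hyperparameters, training size);
#'   `tidy()` returns one row per training feature with its
#'   standardization parameters.
#' @method glance dbp_model
#' @export
glance.dbp_model <- function(x, ...) {
  tibble(classifier = x$classifier,
         n_features = length(x$feature_names),
         n_train = x$n_train,
         cost = x$cost, sigma = x$sigma,
         ntree = if (x$classifier == "rf") x$ntree else NA_integer_,
         seed = x$seed)
}

#' @rdname glance.dbp_model
#' @method tidy dbp_model
#' @export
tidy.dbp_model <- function(x, ...) {
  tibble(feature = x$feature_names,
         center = unname(x$center), scale = unname(x$scale))
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object A `dbp_cv` object.
#' @param ... Unused.
#' @return A ggplot: fold accuracies as columns with the mean as a dashed
#'   line.
#' @method autoplot dbp_cv
#' @export
autoplot.dbp_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = sprintf("%d-fold CV (%s): mean accuracy %.3f",
                                  object$k, object$classifier,
                                  object$mean_accuracy)) +
    ggplot2::ylim(0, 1)
}

#' Plot an evaluation report
#'
#' @param object A `dbp_eval` object.
#' @param ... Unused.
#' @return A ggplot of SN, SP, ACC and MCC as columns.
#' @method autoplot dbp_eval
#' @export
autoplot.dbp_eval <- function(object, ...) {
  d <- tidy(object)
  d$metric <- factor(toupper(d$metric), levels = c("SN", "SP", "ACC", "MCC"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::labs(x = NULL, y = "value")
}

#' Plot an MRMD ranking
#'
#' @param object An `mrmd_ranking` tibble.
#' @param top Number of leading features to show (default 30).
#' @param ... Unused.
#' @return A ggplot of the relevance and distance components, stacked per
#'   feature in rank order.
#' @method autoplot mrmd_ranking
#' @export
autoplot.mrmd_ranking <- function(object, top = 30, ...) {
  d <- head(object, top)
  long <- tidyr::pivot_longer(
    d[, c("feature", "rank", "relevance", "distance")],
    c("relevance", "distance"),
    names_to = "component", values_to = "score")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$feature, -.data$rank),
                               y = .data$score, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "combined score contribution")
}

#' Accuracy report table for several feature sets
#'
#' Assembles a table in the usual benchmarking layout — one row per
#' method, its cross-validation mean accuracy and the test-set SN, SP,
#' MCC and ACC (percentages except MCC).
#'
#' @param results Named list; each element a list with components `cv` (a
#'   `dbp_cv`) and `test` (a `dbp_eval`).
#' @return A tibble with columns `method`, `cv_accuracy_pct`, `sn_pct`,
#'   `sp_pct`, `mcc`, `acc_pct`.
#' @export
report_table <- function(results) {
  purrr::imap_dfr(results, function(r, nm) {
    tibble(method = nm,
           cv_accuracy_pct = round(100 * r$cv$mean_accuracy, 2),
           sn_pct = round(100 * r$test$sn, 2),
           sp_pct = round(100 * r$test$sp, 2),
           mcc = round(r$test$mcc, 2),
           acc_pct = round(100 * r$test$acc, 2))
  })
}
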