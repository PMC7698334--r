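#' Tidy a nested cross-validation result
#'
#' @param x A `nested_loocv` object.
#' @param ... Unused.
#' @return One row per sample: `sample_id`, `truth`, `predicted`, `decision`,
#'   `k`.
#' @export
tidy.nested_loocv <- function(x, ...) x$predictions

#' One-row performance summary of a nested cross-validation result
#'
#' @param x A `nested_loocv` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `mean_k`.
#' @export
glance.nested_loocv <- function(x, ...) {
  cm <- confusion_metrics(x, x$positive_class)
  tibble::tibble(
    n = x$n, accuracy = cm$accuracy, sensitivity = cm$sensitivity,
    specificity = cm$specificity, auc = roc_auc(x, x$positive_class),
    mean_k = mean(x$predictions$k)
  )
}

#' Tidy a fitted linear SVM
#'
#' @param x A `linear_svm` object.
#' @param ... Unused.
#' @return One row per model feature: `bin`, `ppm_mid`, `weight` (on the
#'   standardized scale), `weight_raw` (on the raw feature scale).
#' @export
tidy.linear_svm <- function(x, ...) {
  tibble::tibble(
    bin = x$selected,
    ppm_mid = x$bins$ppm_mid,
    weight = x$w,
    weight_raw = x$w_raw
  )
}

#' @rdname tidy.linear_svm
#' @export
glance.linear_svm <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$selected),
    cost = x$config$cost,
    bias = x$b,
    n_support = sum(x$alpha > 1e-12)
  )
}

#' Tidy a performance report
#'
#' @param x An `mrs_performance` object.
#' @param ... Unused.
#' @return One row per reported statistic: `metric`, `estimate`, `lower`,
#'   `upper` (CI bounds where defined).
#' @export
tidy.mrs_performance <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "auc", "mean_k"),
    estimate = c(cm$accuracy, cm$sensitivity, cm$specificity, x$auc, x$mean_k),
    lower = c(NA, x$sensitivity_ci$lower, x$specificity_ci$lower, NA, NA),
    upper = c(NA, x$sensitivity_ci$upper, x$specificity_ci$upper, NA, NA)
  )
}

#' @rdname tidy.mrs_performance
#' @export
glance.mrs_performance <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(
    n = x$n, tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
    accuracy = cm$accuracy, sensitivity = cm$sensitivity,
    specificity = cm$specificity, auc = x$auc, mean_k = x$mean_k
  )
}
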