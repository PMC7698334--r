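#' Round half away from zero
#'
#' Reporting convention for percentages: 88.235 -> 88.2 (usual rounding) but
#' exact halves go away from zero, e.g. 95.45 -> 95.5, unlike base R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Confusion counts and derived proportions from a cross-validation result
#'
#' Tallies true/false positives and negatives with the positive class fixed to
#' IDH-mutant (so sensitivity is the mutation detection rate) and derives
#' accuracy, sensitivity and specificity. Percentages are also reported
#' rounded to one decimal, half away from zero.
#'
#' @param cv A `nested_loocv` object, or any data frame with `truth` and
#'   `predicted` columns.
#' @param positive_class Positive class label (default `"IDHmut"`).
#' @return A one-row tibble: `tp`, `fn`, `tn`, `fp`, `accuracy`,
#'   `sensitivity`, `specificity` (proportions) and `accuracy_pct`,
#'   `sensitivity_pct`, `specificity_pct` (one-decimal percentages).
#' @export
confusion_metrics <- function(cv, positive_class = "IDHmut") {
  df <- if (inherits(cv, "nested_loocv")) cv$predictions else tibble::as_tibble(cv)
  stopifnot(all(c("truth", "predicted") %in% names(df)), nrow(df) > 0)
  pos <- df$truth == positive_class
  pred_pos <- df$predicted == positive_class
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = acc, sensitivity = sens, specificity = spec,
    accuracy_pct = round_half_away(100 * acc),
    sensitivity_pct = round_half_away(100 * sens),
    specificity_pct = round_half_away(100 * spec)
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval by the beta-quantile formulation: the lower bound
#' is `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), the upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). These invert the
#' binomial tail sums, so e.g. 21 successes in 22 trials give the interval
#' 0.772-0.999 at the 95% level.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (>= 1).
#' @param alpha Two-sided error level (default 0.05 for a 95% interval).
#' @return A one-row tibble: `successes`, `trials`, `alpha`, `estimate`,
#'   `lower`, `upper`.
#' @export
clopper_pearson <- function(successes, trials, alpha = 0.05) {
  if (length(successes) != 1L || length(trials) != 1L ||
      is.na(successes) || is.na(trials) ||
      successes < 0 || trials < 1 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    abort("need integer counts with 0 <= successes <= trials, trials >= 1.",
          class = "gliomrs_invalid_parameter")
  }
  stopifnot(alpha > 0, alpha < 1)
  x <- successes; n <- trials
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  tibble::tibble(successes = x, trials = n, alpha = alpha,
                 estimate = x / n, lower = lower, upper = upper)
}

#' Area under the ROC curve from pooled decision values
#'
#' Mann-Whitney construction: the probability that a random positive-class
#' sample has a higher decision value than a random negative-class sample,
#' with ties counted one half.
#'
#' @param cv A `nested_loocv` object, or a data frame with `truth` and
#'   `decision` columns.
#' @param positive_class Positive class label (default `"IDHmut"`).
#' @return AUC as a single number in \[0, 1\].
#' @export
roc_auc <- function(cv, positive_class = "IDHmut") {
  df <- if (inherits(cv, "nested_loocv")) cv$predictions else tibble::as_tibble(cv)
  stopifnot(all(c("truth", "decision") %in% names(df)))
  pos <- df$truth == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present to compute an AUC.",
          class = "gliomrs_class_count_error")
  }
  r <- rank(df$decision, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from pooled decision values
#'
#' @inheritParams roc_auc
#' @return A tibble with `threshold`, `tpr` and `fpr`, ordered from the
#'   (0, 0) to the (1, 1) corner.
#' @export
roc_curve <- function(cv, positive_class = "IDHmut") {
  df <- if (inherits(cv, "nested_loocv")) cv$predictions else tibble::as_tibble(cv)
  pos <- df$truth == positive_class
  thr <- c(Inf, sort(unique(df$decision), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(df$decision[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(df$decision[!pos] >= t), numeric(1))
  )
}

#' Class-averaged spectra and their difference
#'
#' Pointwise means of the normalized (pre-log) feature vectors per class plus
#' the mutant-minus-wildtype difference; the inputs should be at stage
#' `"normalized"` so the averages are on the scale on which class differences
#' in the 4.1-3.5 ppm region are visible.
#'
#' @param features An `mrs_features` tibble with both classes present.
#' @param positive_class Positive class (default `"IDHmut"`).
#' @return A tibble with `bin`, `ppm_mid`, `mean_mut`, `mean_wt`, `diff`
#'   (`mean_mut - mean_wt`).
#' @export
average_class_spectra <- function(features, positive_class = "IDHmut") {
  stopifnot(inherits(features, "mrs_features"))
  classes <- unique(features$label)
  if (!positive_class %in% classes || length(setdiff(classes, positive_class)) == 0) {
    abort("both classes must be present.", class = "gliomrs_class_count_error")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(features, .data$bin, .data$ppm_mid,
                    grp = ifelse(.data$label == positive_class, "mean_mut", "mean_wt")),
    value = mean(.data$value), .groups = "drop"
  )
  out <- tidyr::pivot_wider(agg, names_from = "grp", values_from = "value")
  out$diff <- out$mean_mut - out$mean_wt
  dplyr::arrange(out, .data$bin)
}

#' Default ppm-to-metabolite assignment table
#'
#' Derived from the simulator basis: each resonance contributes an interval of
#' about one in vivo linewidth (default 0.04 ppm half-width) around its
#' chemical shift.
#'
#' @param basis A basis tibble ([default_basis()]).
#' @param halfwidth_ppm Half-width of each assignment interval.
#' @return A tibble with `metabolite`, `ppm_lower`, `ppm_upper`.
#' @export
assignment_table <- function(basis = default_basis(), halfwidth_ppm = 0.04) {
  tibble::tibble(
    metabolite = basis$metabolite,
    ppm_lower = basis$shift_ppm - halfwidth_ppm,
    ppm_upper = basis$shift_ppm + halfwidth_ppm
  )
}

#' Annotate selected bins with candidate metabolites
#'
#' Labels each bin with every metabolite whose assignment interval overlaps
#' the bin's ppm interval; bins matching nothing are labeled `"unassigned"`.
#'
#' @param selection A tibble with `bin`, `ppm_upper`, `ppm_lower` (and
#'   typically `freq`), e.g. the `selection` element of a [nested_loocv()]
#'   result.
#' @param table An assignment table ([assignment_table()]).
#' @return `selection` with a `metabolites` character column
#'   (comma-separated).
#' @export
annotate_features <- function(selection, table = assignment_table()) {
  mets <- vapply(seq_len(nrow(selection)), function(i) {
    hit <- table$metabolite[table$ppm_lower <= selection$ppm_upper[i] &
                              table$ppm_upper >= selection$ppm_lower[i]]
    if (length(hit)) paste(unique(hit), collapse = ", ") else "unassigned"
  }, character(1))
  out <- tibble::as_tibble(selection)
  out$metabolites <- mets
  out
}

#' Full performance report
#'
#' Combines confusion-derived proportions, exact Clopper-Pearson confidence
#' intervals for sensitivity and specificity, the AUC from pooled outer-fold
#' decision values, the per-fold feature counts and the annotated feature
#' selection frequencies.
#'
#' @param cv A `nested_loocv` result.
#' @param alpha Two-sided error level for the confidence intervals.
#' @param table Metabolite assignment table for feature annotation.
#' @return An object of class `mrs_performance`.
#' @export
performance_report <- function(cv, alpha = 0.05, table = assignment_table()) {
  stopifnot(inherits(cv, "nested_loocv"))
  cm <- confusion_metrics(cv, cv$positive_class)
  sens_ci <- clopper_pearson(cm$tp, cm$tp + cm$fn, alpha)
  spec_ci <- clopper_pearson(cm$tn, cm$tn + cm$fp, alpha)
  structure(
    list(
      confusion = cm,
      sensitivity_ci = sens_ci,
      specificity_ci = spec_ci,
      auc = roc_auc(cv, cv$positive_class),
      mean_k = mean(cv$predictions$k),
      k_per_fold = cv$predictions$k,
      selection = annotate_features(cv$selection, table),
      positive_class = cv$positive_class,
      alpha = alpha,
      n = cv$n
    ),
    class = "mrs_performance"
  )
}

#' @export
print.mrs_performance <- function(x, ...) {
  cm <- x$confusion
  lvl <- 100 * (1 - x$alpha)
  cat(sprintf("IDH-status prediction, %d samples (positive class %s)\n",
              x$n, x$positive_class))
  cat(sprintf("  accuracy    %5.1f%%  (%d/%d)\n", cm$accuracy_pct,
              cm$tp + cm$tn, x$n))
  cat(sprintf("  sensitivity %5.1f%%  (%.0f%% CI %.1f-%.1f%%)\n",
              cm$sensitivity_pct, lvl,
              100 * x$sensitivity_ci$lower, 100 * x$sensitivity_ci$upper))
  cat(sprintf("  specificity %5.1f%%  (%.0f%% CI %.1f-%.1f%%)\n",
              cm$specificity_pct, lvl,
              100 * x$specificity_ci$lower, 100 * x$specificity_ci$upper))
  cat(sprintf("  AUC         %5.2f\n", x$auc))
  cat(sprintf("  mean features per fold: %.1f\n", x$mean_k))
  top <- dplyr::arrange(x$selection[x$selection$n_selected > 0, ],
                        dplyr::desc(.data$freq))
  if (nrow(top)) {
    cat("  most selected bins:\n")
    for (i in seq_len(min(5, nrow(top)))) {
      cat(sprintf("    %5.2f-%.2f ppm  %3.0f%%  %s\n",
                  top$ppm_upper[i], top$ppm_lower[i], 100 * top$freq[i],
                  top$metabolites[i]))
    }
  }
  invisible(x)
}

#' Serialize a performance report to JSON
#'
#' @param report An `mrs_performance` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "mrs_performance"))
  payload <- list(
    n = report$n,
    positive_class = report$positive_class,
    confusion = as.list(report$confusion),
    sensitivity_ci = as.list(report$sensitivity_ci),
    specificity_ci = as.list(report$specificity_ci),
    auc = report$auc,
    mean_k = report$mean_k,
    k_per_fold = report$k_per_fold,
    selection = report$selection
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
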