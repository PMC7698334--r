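#' Classifier configuration
#'
#' @param cost Soft-margin cost parameter C of the linear SVM; left at its
#'   default value of 1.
#' @param standardize Standardize features by training-fold mean and standard
#'   deviation before fitting (default `TRUE`).
#' @param k_max Largest number of top-ranked features tried by the inner
#'   cross-validation (default 15).
#' @param positive_class Class treated as positive for decision values,
#'   sensitivity and ROC analysis (default `"IDHmut"`, so sensitivity refers
#'   to mutation detection).
#' @param k_rule How the inner loop picks the feature count: `"global_max"`
#'   (default) takes the k with maximal inner leave-one-out accuracy, smallest
#'   k on ties; `"first_local_max"` stops at the first k whose accuracy is not
#'   improved by k + 1.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(cost = 1, standardize = TRUE, k_max = 15L,
                       positive_class = "IDHmut",
                       k_rule = c("global_max", "first_local_max")) {
  stopifnot(cost > 0, k_max >= 1L)
  k_rule <- match.arg(k_rule)
  structure(list(cost = as.numeric(cost), standardize = isTRUE(standardize),
                 k_max = as.integer(k_max), positive_class = positive_class,
                 k_rule = k_rule),
            class = "svm_config")
}

# ---- matrix internals (hot path) -------------------------------------------

# features tibble -> list(X [samples x bins], pos [logical], ids, bins tibble)
features_to_matrix <- function(features, positive_class = "IDHmut") {
  stopifnot(inherits(features, "mrs_features"))
  ids <- unique(features$sample_id)
  bins <- dplyr::distinct(features[, c("bin", "ppm_upper", "ppm_lower", "ppm_mid")])
  bins <- bins[order(bins$bin), ]
  X <- matrix(features$value[order(match(features$sample_id, ids), features$bin)],
              nrow = length(ids), ncol = nrow(bins), byrow = TRUE,
              dimnames = list(ids, paste0("bin", bins$bin)))
  lab <- features$label[match(ids, features$sample_id)]
  list(X = X, pos = lab == positive_class, labels = lab, ids = ids, bins = bins)
}

label_of <- function(pos, positive_class, labels) {
  neg <- setdiff(unique(labels), positive_class)
  neg <- if (length(neg)) neg[1] else "other"
  ifelse(pos, positive_class, neg)
}

# Welch t statistic per column; zero-variance denominators get |t| = 0
welch_t_matrix <- function(X, pos) {
  n1 <- sum(pos); n2 <- sum(!pos)
  p <- ncol(X)
  X1 <- X[pos, , drop = FALSE]; X2 <- X[!pos, , drop = FALSE]
  m1 <- .colMeans(X1, n1, p); m2 <- .colMeans(X2, n2, p)
  v1 <- pmax(.colSums(X1 * X1, n1, p) - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax(.colSums(X2 * X2, n2, p) - n2 * m2^2, 0) / (n2 - 1)
  den <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / den
  t[den <= 0] <- 0
  t
}

rank_ttest_matrix <- function(X, pos) {
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    abort("t-test ranking needs at least 2 samples per class.",
          class = "gliomrs_class_count_error")
  }
  t <- welch_t_matrix(X, pos)
  order(-abs(t), seq_along(t))
}

fit_svm_matrix <- function(X, pos, cost, standardize = TRUE) {
  if (all(pos) || !any(pos)) {
    abort("training set must contain both classes.",
          class = "gliomrs_class_count_error")
  }
  if (nrow(X) >= 2L && all(abs(sweep(X, 2L, X[1L, ])) < 1e-300)) {
    abort("degenerate training set: all rows identical.",
          class = "gliomrs_degenerate_error")
  }
  n <- nrow(X); p <- ncol(X)
  if (standardize) {
    mu <- .colMeans(X, n, p)
    v <- pmax(.colSums(X * X, n, p) - n * mu^2, 0) / (n - 1)
    sg <- sqrt(v)
    sg[sg < 1e-12] <- 1
  } else {
    mu <- numeric(p); sg <- rep(1, p)
  }
  Xs <- (X - rep(mu, each = n)) / rep(sg, each = n)
  ypm <- ifelse(pos, 1, -1)
  fit <- .svm_smo(Xs, ypm, cost)
  # fold the standardization into the raw-scale weights
  w_raw <- fit$w / sg
  list(w = fit$w, b = fit$b, mu = mu, sigma = sg,
       w_raw = w_raw, b_raw = fit$b - sum(mu * w_raw),
       alpha = fit$alpha)
}

decision_matrix <- function(fit, X) {
  drop(X %*% fit$w_raw) + fit$b_raw
}

choose_k_matrix <- function(X, pos, config) {
  res <- .choose_k_cpp(X, ifelse(pos, 1, -1), config$cost, config$k_max,
                       config$standardize, config$k_rule == "first_local_max")
  list(k = as.integer(res$k), inner_accuracy = res$inner_accuracy)
}

nested_fold_matrix <- function(X, pos, s, config) {
  res <- .nested_fold_cpp(X, ifelse(pos, 1, -1), s, config$cost, config$k_max,
                          config$standardize,
                          config$k_rule == "first_local_max")
  list(k = as.integer(res$k), selected = res$selected,
       fit = res[c("w", "b", "w_raw", "b_raw", "mu", "sigma")],
       inner_accuracy = res$inner_accuracy,
       decision = res$decision, predicted_pos = res$predicted_pos)
}

# ---- tidy user-facing surface ----------------------------------------------

#' Rank features by a two-sample Welch t-test
#'
#' Features are ordered by descending absolute Welch (unequal-variance) t
#' statistic comparing the two classes; features with a zero-variance
#' denominator are ranked last (|t| treated as 0) and ties break toward the
#' lower bin index.
#'
#' @param features An `mrs_features` tibble with both classes present
#'   (at least 2 samples each).
#' @param positive_class Class whose mean enters the t statistic with positive
#'   sign.
#' @return A tibble with one row per feature in rank order: `rank`, `bin`,
#'   `ppm_mid`, `statistic`.
#' @export
rank_features_ttest <- function(features, positive_class = "IDHmut") {
  m <- features_to_matrix(features, positive_class)
  ord <- rank_ttest_matrix(m$X, m$pos)
  t <- welch_t_matrix(m$X, m$pos)
  tibble::tibble(
    rank = seq_along(ord),
    bin = m$bins$bin[ord],
    ppm_mid = m$bins$ppm_mid[ord],
    statistic = t[ord]
  )
}

#' Train a linear soft-margin SVM on selected features
#'
#' Minimizes the standard C-SVM objective (hinge loss plus `1/(2C) * ||w||^2`)
#' with a package-native SMO solver on features standardized by training-set
#' mean and standard deviation (stored in the model, so prediction applies the
#' identical transform). Decision values are positive on the
#' `positive_class` side; an exact zero decision value is classified as the
#' positive class.
#'
#' @param features An `mrs_features` tibble with class labels.
#' @param selected Integer vector of bin ids to train on; `NULL` uses all bins.
#' @param config An [svm_config()].
#' @return An object of class `linear_svm`.
#' @export
train_linear_svm <- function(features, selected = NULL, config = svm_config()) {
  m <- features_to_matrix(features, config$positive_class)
  cols <- if (is.null(selected)) seq_len(ncol(m$X)) else match(selected, m$bins$bin)
  if (anyNA(cols)) abort("`selected` contains bin ids absent from `features`.")
  fit <- fit_svm_matrix(m$X[, cols, drop = FALSE], m$pos, config$cost,
                        config$standardize)
  structure(
    c(fit, list(
      selected = m$bins$bin[cols],
      bins = m$bins[cols, ],
      positive_class = config$positive_class,
      negative_class = setdiff(unique(m$labels), config$positive_class)[1],
      config = config
    )),
    class = "linear_svm"
  )
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d features, cost %g, positive class %s\n",
              length(x$selected), x$config$cost, x$positive_class))
  invisible(x)
}

#' Predict class labels for new feature vectors
#'
#' @param object A `linear_svm` model.
#' @param newdata An `mrs_features` tibble containing (at least) the bins the
#'   model was trained on.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `decision` (signed decision value,
#'   positive means `positive_class`) and `predicted`.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  m <- features_to_matrix(newdata, object$positive_class)
  cols <- match(object$selected, m$bins$bin)
  if (anyNA(cols)) {
    abort(sprintf("new data lacks model feature bin(s): %s",
                  paste(object$selected[is.na(cols)], collapse = ", ")),
          class = "gliomrs_feature_mismatch")
  }
  d <- unname(decision_matrix(object, m$X[, cols, drop = FALSE]))
  neg <- if (is.na(object$negative_class)) "IDHwt" else object$negative_class
  tibble::tibble(
    sample_id = m$ids,
    decision = d,
    predicted = ifelse(d >= 0, object$positive_class, neg)
  )
}

#' Choose the number of features by inner leave-one-out cross-validation
#'
#' For each candidate k from 1 to `k_max`, runs a leave-one-out loop over the
#' training set in which features are re-ranked on every inner training subset
#' ([rank_features_ttest()]), the top k are kept, and a model is trained and
#' applied to the held-out inner sample. The feature count starts at one and
#' is increased in steps of one; the k with the best inner accuracy is
#' returned (smallest k on ties under the default `"global_max"` rule).
#'
#' @param features Training `mrs_features` tibble.
#' @param config An [svm_config()].
#' @return A list with `k` (chosen count) and `inner_accuracy` (accuracy per
#'   candidate k).
#' @export
choose_k_inner_cv <- function(features, config = svm_config()) {
  m <- features_to_matrix(features, config$positive_class)
  choose_k_matrix(m$X, m$pos, config)
}

#' Recompute one outer fold of the nested cross-validation
#'
#' Exposes the complete decision path of a single outer fold — inner-loop
#' choice of k, feature ranking on the outer-training set, model fit and
#' held-out prediction — so the strict train/test separation can be audited:
#' the held-out sample's values must have no influence on the returned model.
#'
#' @param features An `mrs_features` tibble.
#' @param holdout `sample_id` of the held-out sample.
#' @param config An [svm_config()].
#' @return A list with `k`, `selected` (bin ids), `fit` (weights, bias,
#'   standardization), `decision` and `predicted`.
#' @export
nested_fold <- function(features, holdout, config = svm_config()) {
  m <- features_to_matrix(features, config$positive_class)
  s <- match(holdout, m$ids)
  if (is.na(s)) abort(sprintf("holdout sample '%s' not found.", holdout))
  res <- nested_fold_matrix(m$X, m$pos, s, config)
  res$selected <- m$bins$bin[res$selected]
  res$predicted <- label_of(res$predicted_pos, config$positive_class, m$labels)
  res
}

#' Nested leave-one-out cross-validation with t-test feature selection
#'
#' Iteratively holds out one sample; on the remaining samples the inner
#' leave-one-out loop ([choose_k_inner_cv()]) picks the number of features,
#' features are ranked on the full remainder, the top k are kept, a linear
#' SVM is trained, and the held-out sample is predicted. The held-out sample
#' never influences ranking, k selection, standardization or training, giving
#' an (almost) unbiased estimate of the true classification error. The
#' procedure is fully deterministic.
#'
#' @param features An `mrs_features` tibble (typically stage `"log2"`) with at
#'   least 3 samples per class.
#' @param config An [svm_config()].
#' @return An object of class `nested_loocv` with per-sample predictions and
#'   decision values, per-fold chosen k and selected bins, and per-bin
#'   selection frequencies. See [tidy()] and [glance()] methods.
#' @export
nested_loocv <- function(features, config = svm_config()) {
  m <- features_to_matrix(features, config$positive_class)
  n <- nrow(m$X)
  if (sum(m$pos) < 3L || sum(!m$pos) < 3L) {
    abort("nested leave-one-out needs at least 3 samples per class.",
          class = "gliomrs_class_count_error")
  }
  folds <- lapply(seq_len(n), function(s) nested_fold_matrix(m$X, m$pos, s, config))
  predictions <- tibble::tibble(
    sample_id = m$ids,
    truth = m$labels,
    predicted = label_of(vapply(folds, `[[`, logical(1), "predicted_pos"),
                         config$positive_class, m$labels),
    decision = vapply(folds, `[[`, numeric(1), "decision"),
    k = vapply(folds, `[[`, integer(1), "k")
  )
  sel_counts <- tabulate(unlist(lapply(folds, `[[`, "selected")),
                         nbins = nrow(m$bins))
  selection <- m$bins
  selection$n_selected <- sel_counts
  selection$freq <- sel_counts / n
  structure(
    list(predictions = predictions, selection = selection,
         folds = lapply(folds, function(f) {
           list(k = f$k, selected = m$bins$bin[f$selected])
         }),
         config = config, n = n, positive_class = config$positive_class),
    class = "nested_loocv"
  )
}

#' @export
print.nested_loocv <- function(x, ...) {
  acc <- mean(x$predictions$predicted == x$predictions$truth)
  cat(sprintf(
    "<nested_loocv> %d samples, accuracy %.1f%%, mean k = %.1f\n",
    x$n, 100 * acc, mean(x$predictions$k)
  ))
  invisible(x)
}
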