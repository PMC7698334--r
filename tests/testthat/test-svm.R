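test_that("t-test ranking puts a strong effect first and constants last", {
  set.seed(3)
  X <- matrix(rnorm(20 * 10), 20, 10)
  X[1:10, 4] <- rnorm(10, 10, 1) # means 0 vs 10, sd 1
  X[, 7] <- 2.5 # constant feature
  labels <- rep(c("IDHmut", "IDHwt"), each = 10)
  r <- rank_features_ttest(toy_features(X, labels))
  expect_identical(r$bin[1], 4L)
  expect_identical(r$bin[10], 7L)
  expect_identical(r$statistic[10], 0)

  # permutation invariance in the sample order
  perm <- sample(20)
  r2 <- rank_features_ttest(toy_features(X[perm, ], labels[perm]))
  expect_identical(r$bin, r2$bin)

  expect_error(rank_features_ttest(toy_features(X[c(1, 11:20), ], labels[c(1, 11:20)])),
               class = "gliomrs_class_count_error")
})

test_that("the linear SVM separates separable clouds with the sign convention", {
  f <- toy_classes(n_pos = 8, n_neg = 8, p = 5, effect = 6, seed = 2)
  m <- train_linear_svm(f)
  pred <- predict(m, f)
  truth <- f$label[match(pred$sample_id, f$sample_id)]
  expect_identical(pred$predicted, truth)
  expect_true(all(pred$decision[truth == "IDHmut"] > 0))
  expect_true(all(pred$decision[truth == "IDHwt"] < 0))

  # flipping every label negates the decision values
  flipped <- f
  flipped$label <- ifelse(f$label == "IDHmut", "IDHwt", "IDHmut")
  m2 <- train_linear_svm(flipped)
  expect_equal(predict(m2, f)$decision, -pred$decision, tolerance = 1e-6)

  # all-identical rows are degenerate
  same <- toy_features(matrix(1, 6, 3), rep(c("IDHmut", "IDHwt"), 3))
  expect_error(train_linear_svm(same), class = "gliomrs_degenerate_error")
})

test_that("the SMO solution matches a brute-force hinge-objective search", {
  # 4-point 2D toy problem; objective (1/(2C))||w||^2 + sum hinge
  X <- matrix(c(1, 1, 2, 0.5, -1, -1.5, -0.5, -1.2,
                0.5, 1.5, 1, 2, -1, -0.3, -1.5, -0.8), 8, 2)
  y <- rep(c(1, -1), each = 4)
  C <- 1
  obj <- function(w1, w2, b) {
    margins <- 1 - y * (X[, 1] * w1 + X[, 2] * w2 + b)
    (w1^2 + w2^2) / (2 * C) + sum(pmax(margins, 0))
  }
  grid <- seq(-3, 3, by = 0.05)
  best <- c(0, 0, 0); best_val <- Inf
  for (w1 in grid) for (w2 in grid) {
    # optimal b for fixed w is piecewise linear; search a coarse b grid
    for (b in seq(-2, 2, by = 0.05)) {
      v <- obj(w1, w2, b)
      if (v < best_val) { best_val <- v; best <- c(w1, w2, b) }
    }
  }
  fit <- gliomrs:::.svm_smo(X, y, C)
  expect_lte((sum(fit$w^2)) / (2 * C) +
               sum(pmax(1 - y * (drop(X %*% fit$w) + fit$b), 0)),
             best_val + 1e-6)
  cosine <- sum(fit$w * best[1:2]) / sqrt(sum(fit$w^2) * sum(best[1:2]^2))
  expect_gt(cosine, 0.99)
})

test_that("SMO agrees with the reference SVM library on random problems", {
  library(e1071)
  primal <- function(w, b, X, y, C) {
    0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(X %*% w) + b)))
  }
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(6:30, 1); p <- sample(1:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, -1), length.out = n)[sample(n)]
    X[y > 0, ] <- X[y > 0, ] + 0.8
    C <- sample(c(0.5, 1, 2), 1)
    mine <- gliomrs:::.svm_smo(X, y, C)
    ref <- svm(X, factor(y, levels = c(1, -1)), kernel = "linear", cost = C,
               scale = FALSE, type = "C-classification", tolerance = 1e-8)
    w_ref <- drop(t(ref$coefs) %*% ref$SV); b_ref <- -ref$rho
    d_ref <- drop(X %*% w_ref) + b_ref
    if (cor(d_ref, y) < 0) { w_ref <- -w_ref; b_ref <- -b_ref; d_ref <- -d_ref }
    # at least as optimal as the reference, and same decision surface
    expect_lte(primal(mine$w, mine$b, X, y, C),
               primal(w_ref, b_ref, X, y, C) + 1e-6)
    expect_equal(drop(X %*% mine$w) + mine$b, d_ref, tolerance = 1e-3)
  }
})

test_that("prediction applies the training-fold standardization", {
  f <- toy_classes(n_pos = 6, n_neg = 6, p = 4, effect = 2, seed = 5)
  m <- train_linear_svm(f)
  ids <- unique(f$sample_id)
  one <- gliomrs:::new_mrs_features(f[f$sample_id == ids[1], ], stage = "log2")
  p_all <- predict(m, f)
  p_one <- predict(m, one)
  expect_equal(p_one$decision, p_all$decision[p_all$sample_id == ids[1]],
               tolerance = 1e-12)

  # a sample at the midpoint of two symmetric clusters scores ~0
  Xs <- rbind(matrix(2, 4, 2), matrix(-2, 4, 2))
  Xs <- Xs + matrix(rep(c(0.1, -0.1), 8), 8, 2) # break exact degeneracy
  fs <- toy_features(Xs, rep(c("IDHmut", "IDHwt"), each = 4))
  ms <- train_linear_svm(fs)
  mid <- toy_features(matrix(0, 1, 2), "unknown")
  expect_lt(abs(predict(ms, mid)$decision), 0.1)

  short <- toy_features(matrix(0, 1, 2), "unknown")
  short$bin <- c(98L, 99L)
  expect_error(predict(m, gliomrs:::new_mrs_features(short, stage = "log2")),
               class = "gliomrs_feature_mismatch")
})

test_that("the inner loop picks a feature count matching the signal structure", {
  # one perfectly informative feature: k = 1
  f1 <- toy_classes(n_pos = 8, n_neg = 8, p = 12, informative = 1,
                    effect = 8, seed = 1)
  expect_identical(choose_k_inner_cv(f1)$k, 1L)

  # two features that only separate jointly: chosen k concentrates near 2
  ks <- vapply(1:8, function(seed) {
    set.seed(seed)
    n <- 16
    X <- matrix(rnorm(n * 15), n, 15)
    u <- rnorm(n, rep(c(2.2, -2.2), each = n / 2), 1)
    X[, 3] <- u + rnorm(n, 0, 1.4) # two noisy views of the latent class axis
    X[, 9] <- u + rnorm(n, 0, 1.4)
    f <- toy_features(X, rep(c("IDHmut", "IDHwt"), each = n / 2))
    choose_k_inner_cv(f)$k
  }, integer(1))
  expect_lte(median(ks), 3)
  expect_gte(sum(ks >= 2), 4) # a single view is rarely enough

  # pure noise with permuted labels: inner accuracy hovers at chance
  set.seed(99)
  accs <- replicate(6, {
    X <- matrix(rnorm(16 * 20), 16, 20)
    f <- toy_features(X, sample(rep(c("IDHmut", "IDHwt"), each = 8)))
    mean(choose_k_inner_cv(f)$inner_accuracy)
  })
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("nested LOOCV is exact on separable data and fully deterministic", {
  f <- toy_classes(n_pos = 17, n_neg = 17, p = 30, informative = 2,
                   effect = 5, seed = 4)
  cv <- nested_loocv(f)
  expect_identical(nrow(cv$predictions), 34L)
  expect_true(all(cv$predictions$predicted == cv$predictions$truth))
  expect_true(all(sign(cv$predictions$decision) ==
                    ifelse(cv$predictions$truth == "IDHmut", 1, -1)))
  cv2 <- nested_loocv(f)
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(cv$folds, cv2$folds)

  few <- toy_classes(n_pos = 2, n_neg = 8, p = 5, seed = 1)
  expect_error(nested_loocv(few), class = "gliomrs_class_count_error")
})

test_that("decision values agree in sign with predicted labels", {
  co <- quick_cohort(n_mut = 5, n_wt = 5, seed = 6)
  cv <- nested_loocv(preprocess_cohort(co))
  expect_true(all((cv$predictions$decision >= 0) ==
                    (cv$predictions$predicted == "IDHmut")))
  expect_identical(sort(unique(unlist(lapply(cv$folds, `[[`, "selected")))),
                   sort(cv$selection$bin[cv$selection$n_selected > 0]))
})

test_that("the held-out sample cannot influence its own fold's model", {
  f <- toy_classes(n_pos = 10, n_neg = 10, p = 25, informative = 2,
                   effect = 2, seed = 8)
  ids <- unique(f$sample_id)
  for (s in ids[c(1, 5, 12, 20)]) {
    ref <- nested_fold(f, s)
    poisoned <- f
    poisoned$value[poisoned$sample_id == s] <-
      rnorm(sum(poisoned$sample_id == s), 50, 10)
    poisoned <- gliomrs:::new_mrs_features(poisoned, stage = "log2")
    alt <- nested_fold(poisoned, s)
    expect_identical(alt$k, ref$k)
    expect_identical(alt$selected, ref$selected)
    expect_identical(alt$fit$w, ref$fit$w)
    expect_identical(alt$fit$b, ref$fit$b)
  }
})
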