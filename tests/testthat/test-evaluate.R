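test_that("confusion metrics reproduce the printed-rate arithmetic", {
  # 22 positives with one miss, 12 negatives with three false alarms
  preds <- tibble::tibble(
    truth = c(rep("IDHmut", 22), rep("IDHwt", 12)),
    predicted = c(rep("IDHmut", 21), "IDHwt",
                  rep("IDHwt", 9), rep("IDHmut", 3))
  )
  cm <- confusion_metrics(preds)
  expect_identical(c(cm$tp, cm$fn, cm$tn, cm$fp), c(21L, 1L, 9L, 3L))
  expect_identical(cm$accuracy_pct, 88.2)
  expect_identical(cm$sensitivity_pct, 95.5)
  expect_identical(cm$specificity_pct, 75.0)

  all_right <- tibble::tibble(truth = preds$truth, predicted = preds$truth)
  expect_identical(confusion_metrics(all_right)$accuracy_pct, 100)

  all_pos <- tibble::tibble(truth = preds$truth, predicted = "IDHmut")
  cm2 <- confusion_metrics(all_pos)
  expect_identical(cm2$sensitivity_pct, 100)
  expect_identical(cm2$specificity_pct, 0)
})

test_that("report percentages round half away from zero", {
  expect_identical(round_half_away(88.235), 88.2)
  expect_identical(round_half_away(95.45), 95.5)
  expect_identical(round_half_away(100 * 21 / 22), 95.5)
  expect_identical(round_half_away(-1.25), -1.3)
  expect_identical(round_half_away(2.5, 0), 3)
})

test_that("Clopper-Pearson intervals reproduce the published bounds", {
  sens <- clopper_pearson(21, 22, 0.05)
  expect_equal(round(sens$lower, 3), 0.772)
  expect_equal(round(sens$upper, 3), 0.999)
  spec <- clopper_pearson(9, 12, 0.05)
  expect_equal(round(spec$upper, 3), 0.945)
  expect_equal(round(spec$lower, 3), 0.428)

  # closed-form boundary cases
  expect_identical(clopper_pearson(0, 7, 0.05)$lower, 0)
  top <- clopper_pearson(7, 7, 0.05)
  expect_identical(top$upper, 1)
  expect_equal(top$lower, (0.05 / 2)^(1 / 7), tolerance = 1e-12)

  expect_error(clopper_pearson(5, 4), class = "gliomrs_invalid_parameter")
  expect_error(clopper_pearson(-1, 4), class = "gliomrs_invalid_parameter")
})

# independent oracle: invert the exact binomial tail sums by bisection
cp_bisect <- function(x, n, alpha) {
  bis <- function(f) {
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else bis(function(p) 1 - pbinom(x - 1, n, p) > alpha / 2)
  upper <- if (x == n) 1 else bis(function(p) pbinom(x, n, p) < alpha / 2)
  c(lower, upper)
}

test_that("the beta-quantile interval inverts the binomial tails exactly", {
  for (n in c(1, 2, 5, 12, 22, 33, 40)) {
    for (x in 0:n) {
      got <- clopper_pearson(x, n, 0.05)
      want <- cp_bisect(x, n, 0.05)
      expect_equal(c(got$lower, got$upper), want, tolerance = 1e-9)
    }
  }
  # agreement with the stats::binom.test implementation
  bt <- binom.test(17, 29)$conf.int
  got <- clopper_pearson(17, 29, 0.05)
  expect_equal(c(got$lower, got$upper), as.numeric(bt), tolerance = 1e-12)
})

test_that("confidence intervals nest as alpha decreases", {
  for (case in list(c(3, 10), c(21, 22), c(9, 12), c(0, 5), c(5, 5))) {
    wide <- clopper_pearson(case[1], case[2], 0.01)
    narrow <- clopper_pearson(case[1], case[2], 0.05)
    expect_lte(wide$lower, narrow$lower)
    expect_gte(wide$upper, narrow$upper)
    expect_lte(narrow$lower, narrow$estimate)
    expect_gte(narrow$upper, narrow$estimate)
  }
})

auc_pairs <- function(truth, score, positive = "IDHmut") {
  pos <- score[truth == positive]
  neg <- score[truth != positive]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

test_that("AUC equals the Mann-Whitney pair-counting probability", {
  perfect <- tibble::tibble(truth = rep(c("IDHmut", "IDHwt"), each = 4),
                            decision = c(4, 3, 2, 1, -1, -2, -3, -4))
  expect_identical(roc_auc(perfect), 1)
  ties <- tibble::tibble(truth = rep(c("IDHmut", "IDHwt"), each = 4),
                         decision = rep(0, 8))
  expect_identical(roc_auc(ties), 0.5)
  mixed <- tibble::tibble(truth = c(rep("IDHmut", 3), rep("IDHwt", 2)),
                          decision = c(0.9, 0.8, 0.3, 0.7, 0.2))
  expect_equal(roc_auc(mixed), 5 / 6)

  set.seed(7)
  for (i in 1:200) {
    n1 <- sample(1:15, 1); n0 <- sample(1:15, 1)
    truth <- c(rep("IDHmut", n1), rep("IDHwt", n0))
    score <- round(rnorm(n1 + n0), sample(0:2, 1)) # rounding induces ties
    df <- tibble::tibble(truth = truth, decision = score)
    expect_equal(roc_auc(df), auc_pairs(truth, score), tolerance = 1e-12)
  }

  one_class <- tibble::tibble(truth = rep("IDHmut", 4), decision = rnorm(4))
  expect_error(roc_auc(one_class), class = "gliomrs_class_count_error")
})

test_that("the ROC curve starts at (0,0), ends at (1,1) and matches the AUC", {
  set.seed(11)
  df <- tibble::tibble(truth = rep(c("IDHmut", "IDHwt"), c(12, 9)),
                       decision = rnorm(21))
  rc <- roc_curve(df)
  expect_identical(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_identical(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
  expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
  trapz <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
  expect_equal(trapz, roc_auc(df), tolerance = 1e-12)
})

test_that("class-averaged spectra localize the discriminative window", {
  X <- rbind(matrix(1, 3, 4), matrix(1, 2, 4))
  X[4:5, 2] <- 3
  f <- toy_features(X, c(rep("IDHmut", 3), rep("IDHwt", 2)), stage = "normalized")
  avg <- average_class_spectra(f)
  expect_equal(avg$mean_mut, rep(1, 4))
  expect_equal(avg$diff, c(0, -2, 0, 0))

  single <- toy_features(rbind(c(1, 2), c(5, 3)), c("IDHmut", "IDHwt"),
                         stage = "normalized")
  expect_equal(average_class_spectra(single)$diff, c(1 - 5, 2 - 3))

  # simulated cohorts put the largest class difference in 3.5-4.1 ppm
  cfg <- clean_config(n_mut = 50, n_wt = 50, seed = 21)
  co <- simulate_cohort(default_basis(), cfg)
  pre <- normalize_total(select_region(bin_spectrum(
    align_to_reference(phase_correct(co))
  )))
  avg2 <- average_class_spectra(pre)
  top_bin <- avg2$ppm_mid[which.max(abs(avg2$diff))]
  expect_gte(top_bin, 3.5)
  expect_lte(top_bin, 4.1)

  expect_error(average_class_spectra(
    toy_features(matrix(1, 2, 2), c("IDHmut", "IDHmut"), stage = "normalized")
  ), class = "gliomrs_class_count_error")
})

test_that("selected bins are annotated with overlapping metabolites", {
  sel <- tibble::tibble(
    bin = 1:3,
    ppm_upper = c(3.57, 3.22, 6.0),
    ppm_lower = c(3.53, 3.18, 5.9),
    ppm_mid = c(3.55, 3.20, 5.95),
    freq = c(0.9, 0.5, 0.1)
  )
  ann <- annotate_features(sel)
  expect_true(grepl("Gly", ann$metabolites[1]) && grepl("M-ins", ann$metabolites[1]))
  expect_identical(ann$metabolites[2], "Cho")
  expect_identical(ann$metabolites[3], "unassigned")
})

test_that("the performance report assembles consistently and serializes", {
  f <- toy_classes(n_pos = 8, n_neg = 6, p = 15, effect = 2, seed = 13)
  cv <- nested_loocv(f)
  rep <- performance_report(cv)
  cm <- rep$confusion
  expect_identical(cm$tp + cm$fn, 8L)
  expect_identical(cm$tn + cm$fp, 6L)
  expect_equal(cm$accuracy, (cm$tp + cm$tn) / 14)
  expect_identical(rep$sensitivity_ci$successes, cm$tp)
  expect_gte(rep$auc, 0)
  expect_lte(rep$auc, 1)

  g <- glance(cv)
  expect_identical(g$accuracy, cm$accuracy)
  td <- tidy(rep)
  expect_identical(td$metric[1:3], c("accuracy", "sensitivity", "specificity"))

  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$confusion$tp, cm$tp)
  expect_equal(parsed$auc, rep$auc, tolerance = 1e-12)
})
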