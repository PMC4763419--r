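test_that("AUROCC equals pairwise concordance on worked examples", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both outcome classes")
})

test_that("AUROCC matches brute force and an independent ROC library", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    y <- runif(n) < plogis(3 * (p - 0.5))
    if (length(unique(y)) < 2) next
    a <- auroc(p, y)
    expect_equal(a, brute_auc(p, y))
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(
      as.integer(y), p, levels = c(0, 1), direction = "<", quiet = TRUE))))
  }
})

test_that("AUROCC is invariant under strictly increasing transforms", {
  set.seed(72)
  p <- runif(300)
  y <- runif(300) < p
  a <- auroc(p, y)
  expect_equal(auroc(qlogis(p), y), a)
  expect_equal(auroc(p^3 + 2 * p, y), a)
  expect_equal(auroc(rank(p), y), a)
})

test_that("comparing a model to itself is never significant", {
  set.seed(73)
  p <- runif(500)
  y <- runif(500) < p
  expect_equal(compare_auroc(p, p, y), 1)
  expect_equal(compare_calibration_slope(qlogis(p), qlogis(p), y), 1)
})

test_that("an informative model beats pure noise decisively", {
  set.seed(74)
  pvals <- replicate(5, {
    n <- 2000
    x <- rnorm(n)
    y <- runif(n) < plogis(-2 + 1.5 * x)
    compare_auroc(plogis(-2 + 1.5 * x), runif(n), y)
  })
  expect_gte(mean(pvals < 0.001), 0.8)
})

test_that("ROC comparison holds its size under the null", {
  set.seed(75)
  rejections <- replicate(200, {
    n <- 300
    x <- rnorm(n)
    z <- rnorm(n)  # equally informative independent predictor
    y <- runif(n) < plogis(-1.5 + x + z)
    compare_auroc(plogis(x), plogis(z), y) < 0.05
  })
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("calibration slope obeys its exact identities", {
  co <- small_cohort(seed = 76)
  fit <- fit_logit(co, builtin_model("basic"))
  lp <- linear_predictor(fit$model, co)
  expect_equal(calibration_slope(lp, co$early_death), 1, tolerance = 1e-6)
  # doubling the linear predictor exactly halves the slope
  expect_equal(calibration_slope(2 * lp, co$early_death), 0.5,
               tolerance = 1e-6)
})

test_that("overfit models show slopes below 1 on fresh data", {
  # ~12 events against 8 parameters: substantial overfitting by design
  set.seed(77)
  below <- replicate(10, {
    train <- generate_cohort(cohort_spec(
      n_per_hospital = c(A = 60, B = 60, C = 60),
      seed = sample.int(1e6, 1)))
    test <- generate_cohort(cohort_spec(
      n_per_hospital = c(A = 1000, B = 1000, C = 1000),
      seed = sample.int(1e6, 1)))
    fit <- tryCatch(fit_logit(train, builtin_model("basic_hr")),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA)
    calibration_slope(linear_predictor(fit$model, test),
                      test$early_death) < 1
  })
  expect_gte(mean(below, na.rm = TRUE), 0.8)
})

test_that("slope comparison separates well- from badly-scaled predictors", {
  set.seed(78)
  hits <- replicate(5, {
    n <- 5000
    x <- rnorm(n)
    lp <- -2.5 + 1.2 * x
    y <- runif(n) < plogis(lp)
    compare_calibration_slope(lp, 2 * lp, y, n_boot = 200,
                              seed = sample.int(1e6, 1)) < 0.01
  })
  expect_gte(mean(hits), 0.8)
})

test_that("sensitivity and specificity follow the confusion table", {
  p <- c(0.01, 0.2, 0.04, 0.9)
  y <- c(0, 1, 0, 1)
  ss <- sens_spec(p, y, threshold = 0.05)
  expect_equal(unname(ss), c(1, 1))
  expect_equal(unname(sens_spec(p, y, threshold = 0))[1], 1)       # everyone positive
  expect_equal(unname(sens_spec(p, y, threshold = 1 + 1e-9))[2], 1) # everyone negative
  set.seed(79)
  p <- runif(100); y <- runif(100) < p
  ss <- sens_spec(p, y, 0.3)
  tab <- table(pred = factor(p >= 0.3, c(FALSE, TRUE)),
               truth = factor(y, c(FALSE, TRUE)))
  expect_equal(unname(ss["sensitivity"]), tab["TRUE", "TRUE"] / sum(tab[, "TRUE"]))
  expect_equal(unname(ss["specificity"]), tab["FALSE", "FALSE"] / sum(tab[, "FALSE"]))
})

test_that("risk deciles of calibrated predictions match observed fractions", {
  set.seed(80)
  n <- 50000
  p <- rbeta(n, 1.2, 12)
  y <- runif(n) < p
  cal <- calibration_plot_data(p, y)
  expect_equal(nrow(cal$groups), 10L)
  expect_true(all(abs(diff(cal$groups$n)) <= 1))
  expect_equal(sum(cal$groups$n), n)
  expect_lt(max(abs(cal$groups$observed - cal$groups$mean_predicted)), 0.02)
  expect_equal(cal$slope, 1, tolerance = 0.1)
})

test_that("degenerate grouping still partitions the sample", {
  # constant predictions collapse to a single effective group
  y <- rep(c(TRUE, FALSE), c(3, 17))
  cal <- calibration_plot_data(rep(0.15, 20), y)
  expect_equal(nrow(cal$groups), 1L)
  expect_equal(cal$groups$observed, 0.15)
  # one patient per group at n = groups
  set.seed(81)
  cal10 <- calibration_plot_data(runif(10), runif(10) < 0.5, n_groups = 10)
  expect_equal(cal10$groups$n, rep(1L, 10))
  expect_true(all(cal10$groups$observed %in% c(0, 1)))
})

test_that("pooled metrics report median and quartiles", {
  pm <- pool_metric(c(0.84, 0.85, 0.86, 0.90))
  expect_equal(pm$median, 0.855)
  expect_equal(pm$iqr, unname(quantile(c(0.84, 0.85, 0.86, 0.90), c(0.25, 0.75))))
  expect_error(pool_metric(numeric(0)), "no values")
})

test_that("performance summaries pool per-imputation metrics coherently", {
  co <- small_cohort(n_per_hospital = c(A = 500, B = 500, C = 500), seed = 82)
  fit_b <- fit_logit(co, builtin_model("basic"))
  fit_g <- fit_logit(co, builtin_model("gcs_only"))
  masked <- impose_missingness(co, c(sbp = 0.15, gcs = 0.1), seed = 83)
  imp <- impute_cohort(masked, m = 3, seed = 84)
  perf <- assess_performance(list(basic = fit_b$model, gcs_only = fit_g$model),
                             imp, reference = "basic", n_boot = 50, seed = 85)
  expect_equal(nrow(perf$per_imputation), 2 * 3)
  expect_true(all(perf$pooled$median >= perf$pooled$q1 - 1e-12 &
                    perf$pooled$median <= perf$pooled$q3 + 1e-12))
  aucs <- perf$per_imputation$auroc
  expect_true(all(aucs > 0.5 & aucs < 1))
  expect_equal(nrow(perf$comparisons), 1L)
  expect_true(perf$comparisons$auroc_p_median >= 0 &&
                perf$comparisons$auroc_p_median <= 1)
})
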