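test_that("the imputation-count rule follows the worst hospital", {
  expect_identical(choose_m(c(A = 0.51, B = 0.40, C = 0.22)), 51L)
  expect_identical(choose_m(c(A = 0.33, B = 0.10, C = 0.05)), 33L)
  expect_identical(choose_m(c(A = 0, B = 0, C = 0)), 0L)
  # any missingness at all still yields multiple imputations
  expect_identical(choose_m(c(A = 0.005, B = 0)), 2L)
  # monotone in the maximum fraction
  ms <- vapply(seq(0.02, 0.9, by = 0.02), function(f) choose_m(c(f, 0.01)),
               integer(1))
  expect_true(all(diff(ms) >= 0))
  expect_error(choose_m(c(1.2, 0.1)), "\\[0, 1\\]")
})

test_that("a complete cohort passes through imputation unchanged", {
  co <- small_cohort(n_per_hospital = c(A = 80, B = 80, C = 80), seed = 2)
  res <- impute_cohort(co, m = 2, seed = 3)
  expect_identical(res$datasets[[1]], co)
  expect_identical(res$datasets[[2]], co)
})

test_that("only originally-missing cells differ across completed datasets", {
  co <- small_cohort(n_per_hospital = c(A = 250, B = 250, C = 250), seed = 4)
  masked <- impose_missingness(co, c(sbp = 0.2, hr = 0.15, gcs = 0.2), seed = 5)
  res <- impute_cohort(masked, m = 3, seed = 6)
  for (v in c("sbp", "hr", "gcs")) {
    obs <- !is.na(masked[[v]])
    for (d in 1:3) {
      expect_false(anyNA(res$datasets[[d]][[v]]))
      expect_identical(res$datasets[[d]][[v]][obs], masked[[v]][obs])
    }
  }
  # untouched columns are identical everywhere
  for (v in c("age", "male", "early_death", "arrival_time")) {
    expect_identical(res$datasets[[1]][[v]], masked[[v]])
    expect_identical(res$datasets[[2]][[v]], masked[[v]])
  }
  # coma-scale imputations stay integers on the observed 3-15 scale
  expect_true(all(res$datasets[[1]]$gcs %in% 3:15))
  expect_true(all(res$datasets[[2]]$sbp > 0))
})

test_that("hospitals are imputed in isolation", {
  co <- small_cohort(n_per_hospital = c(A = 220, B = 220, C = 220), seed = 7)
  masked <- impose_missingness(co, c(sbp = 0.25, gcs = 0.25), seed = 8)
  res1 <- impute_cohort(masked, m = 2, seed = 9)

  # shuffle the rows of hospitals B and C; hospital A must be unaffected
  rows_a <- which(masked$hospital_id == "A")
  rows_bc <- which(masked$hospital_id != "A")
  set.seed(1)
  shuffled <- rbind(masked[rows_a, ], masked[sample(rows_bc), ])
  rownames(shuffled) <- NULL
  res2 <- impute_cohort(shuffled, m = 2, seed = 9)
  for (d in 1:2) {
    a1 <- res1$datasets[[d]][res1$datasets[[d]]$hospital_id == "A", ]
    a2 <- res2$datasets[[d]][res2$datasets[[d]]$hospital_id == "A", ]
    rownames(a1) <- rownames(a2) <- NULL
    expect_identical(a1, a2)
  }
})

test_that("a hospital with a fully missing variable fails loudly", {
  co <- small_cohort(n_per_hospital = c(A = 50, B = 50, C = 50), seed = 10)
  co$sbp[co$hospital_id == "B"] <- NA
  expect_error(impute_cohort(co, m = 2, seed = 1), "hospital 'B'.*'sbp'")
})

test_that("imputation under MCAR recovers the pre-masking mean", {
  co <- small_cohort(n_per_hospital = c(A = 3400, B = 3300, C = 3300), seed = 11)
  masked <- impose_missingness(co, c(sbp = 0.2), mechanism = "MCAR", seed = 12)
  res <- impute_cohort(masked, m = 10, seed = 13)
  pooled_mean <- mean(vapply(res$datasets, function(d) mean(d$sbp), numeric(1)))
  se <- sd(co$sbp) / sqrt(sum(is.na(masked$sbp)))
  expect_lt(abs(pooled_mean - mean(co$sbp)), 3 * se)
})

test_that("complete-case and imputed discrimination agree under MCAR", {
  aucs <- vapply(1:6, function(r) {
    co <- small_cohort(n_per_hospital = c(A = 1700, B = 1700, C = 1600),
                       seed = 100 + r)
    masked <- impose_missingness(co, c(sbp = 0.2, gcs = 0.2),
                                 mechanism = "MCAR", seed = 200 + r)
    fit <- fit_logit(co, builtin_model("basic"))
    cc <- masked[!is.na(masked$sbp) & !is.na(masked$gcs), ]
    auc_cc <- auroc(predict(fit$model, cc), cc$early_death)
    res <- impute_cohort(masked, m = 10, seed = 300 + r)
    auc_mi <- median(vapply(res$datasets, function(d)
      auroc(predict(fit$model, d), d$early_death), numeric(1)))
    auc_mi - auc_cc
  }, numeric(1))
  expect_lt(abs(mean(aucs)), 0.02)
})

test_that("P-values pool by the median with the 0.05 significance rule", {
  out <- pool_pvalues(c(0.01, 0.02, 0.03))
  expect_equal(out$median, 0.02)
  expect_true(out$significant)

  single <- pool_pvalues(0.2)
  expect_equal(single$median, 0.2)
  expect_equal(single$iqr, c(0.2, 0.2))
  expect_false(single$significant)

  set.seed(33)
  ps <- runif(33)
  out33 <- pool_pvalues(ps)
  # brute-force order-statistic check of the median
  s <- sort(ps)
  expect_equal(out33$median, s[17])
  expect_equal(out33$iqr, unname(quantile(ps, c(0.25, 0.75))))

  expect_error(pool_pvalues(numeric(0)), "no P-values")
  expect_error(pool_pvalues(c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("imputation stacks carry the index column convention", {
  co <- small_cohort(n_per_hospital = c(A = 40, B = 40, C = 40), seed = 14)
  masked <- impose_missingness(co, c(sbp = 0.3), seed = 15)
  res <- impute_cohort(masked, m = 2, seed = 16)
  stacked <- stack_imputations(res, original = masked)
  expect_equal(unique(stacked$.imp), c(0L, 1L, 2L))
  expect_equal(nrow(stacked), 3 * nrow(masked))
  expect_true(anyNA(stacked$sbp[stacked$.imp == 0]))
  expect_false(anyNA(stacked$sbp[stacked$.imp > 0]))
})
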