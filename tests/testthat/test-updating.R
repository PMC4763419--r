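test_that("logistic fit on a 2x2 table equals closed-form log-odds", {
  dat <- data.frame(
    exposed = rep(c(1, 0), each = 50),
    early_death = c(rep(c(TRUE, FALSE), c(10, 40)),
                    rep(c(TRUE, FALSE), c(5, 45)))
  )
  fit <- fit_logit(dat, list(term_linear("exposed")))
  expect_equal(unname(fit$model$coefficients["exposed"]),
               log((10 / 40) / (5 / 45)), tolerance = 1e-6)
  expect_equal(unname(fit$model$coefficients["intercept"]),
               log(5 / 45), tolerance = 1e-6)
})

test_that("degenerate outcomes and designs raise explicit errors", {
  dat <- data.frame(x = rnorm(50), early_death = FALSE)
  expect_error(fit_logit(dat, list(term_linear("x"))), "single class")
  # perfectly separated data must not return silently huge coefficients
  sep <- data.frame(x = c(1:20, 31:50),
                    early_death = rep(c(FALSE, TRUE), each = 20))
  expect_error(fit_logit(sep, list(term_linear("x"))), "separation|converge")
  # rank-deficient design
  dd <- data.frame(x = rnorm(100), early_death = runif(100) < 0.4)
  dd$z <- 2 * dd$x
  expect_error(fit_logit(dd, list(term_linear("x"), term_linear("z"))),
               "full rank")
})

test_that("the generating coefficients are recovered from a large cohort", {
  co <- generate_cohort(cohort_spec(
    n_per_hospital = c(A = 6700, B = 6700, C = 6600), seed = 51))
  truth <- generating_model()
  fit <- fit_logit(co, truth)  # same frozen knots as the truth
  expect_equal(fit$model$terms[[1]]$knots, truth$terms[[1]]$knots)
  dev <- abs(fit$model$coefficients - truth$coefficients) / fit$se
  expect_true(all(dev < 3))
})

test_that("regressing the outcome on its own full-data lp is the identity", {
  co <- small_cohort(seed = 52)
  fit <- fit_logit(co, builtin_model("basic"))
  lp <- linear_predictor(fit$model, co)
  refit <- glm(co$early_death ~ lp, family = binomial())
  expect_equal(unname(coef(refit)[2]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(refit)[1]), 0, tolerance = 1e-6)
})

test_that("bootstrap shrinkage is deterministic and averages its slopes", {
  co <- small_cohort(seed = 53)
  u1 <- bootstrap_shrinkage(co, builtin_model("gcs_only"), n_bootstrap = 40,
                            seed = 7)
  u2 <- bootstrap_shrinkage(co, builtin_model("gcs_only"), n_bootstrap = 40,
                            seed = 7)
  expect_identical(u1$bootstrap_slopes, u2$bootstrap_slopes)
  expect_length(u1$bootstrap_slopes, 40L)
  expect_equal(u1$shrinkage_factor, mean(u1$bootstrap_slopes))
  u3 <- bootstrap_shrinkage(co, builtin_model("gcs_only"), n_bootstrap = 40,
                            seed = 8)
  expect_false(identical(u1$bootstrap_slopes, u3$bootstrap_slopes))
})

test_that("shrinkage approaches 1 as events per parameter grow", {
  sfs <- vapply(c(400, 1600, 6400), function(n) {
    co <- generate_cohort(cohort_spec(
      n_per_hospital = c(A = ceiling(n / 3), B = ceiling(n / 3),
                         C = ceiling(n / 3)),
      seed = n))
    bootstrap_shrinkage(co, builtin_model("basic"), n_bootstrap = 60,
                        seed = 1)$shrinkage_factor
  }, numeric(1))
  expect_true(all(diff(sfs) > 0) || all(sfs > 0.9))
  expect_lt(sfs[1], 1)
  expect_gt(sfs[3], 0.95)
})

test_that("applying shrinkage scales slopes and recalibrates the base rate", {
  co <- small_cohort(seed = 54)
  fit <- fit_logit(co, builtin_model("basic"))

  # identity factor changes nothing material
  same <- apply_shrinkage(fit$model, 1.0, data = co)
  expect_equal(same$coefficients[-1], fit$model$coefficients[-1])
  expect_equal(same$coefficients[1], fit$model$coefficients[1],
               tolerance = 1e-6)

  # slopes scale linearly
  toy <- model_spec("toy", list(term_linear("gcs"), term_linear("sbp")),
                    coefficients = c(1, 2, -4))
  half <- apply_shrinkage(toy, 0.5, recalibrate_intercept = FALSE)
  expect_equal(unname(half$coefficients), c(0.5, 1, -2))
  half2 <- apply_shrinkage(toy, 0.5, data = co)
  expect_equal(unname(half2$coefficients[-1]), c(1, -2))

  # recalibrated intercept restores the observed event rate exactly
  shr <- apply_shrinkage(fit$model, 0.8, data = co)
  expect_equal(mean(predict(shr, co)), mean(co$early_death),
               tolerance = 1e-6)
  expect_equal(shr$shrinkage_factor, 0.8)
})

test_that("intercept recalibration requires data unless literal mode", {
  toy <- model_spec("toy", list(term_linear("gcs")), coefficients = c(1, -0.2))
  expect_error(apply_shrinkage(toy, 0.9), "data")
  expect_error(apply_shrinkage(toy, -1, recalibrate_intercept = FALSE),
               "positive")
})
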