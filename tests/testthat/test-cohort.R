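test_that("generation is deterministic given spec and seed", {
  a <- generate_cohort(cohort_spec(n_per_hospital = c(A = 150, B = 150, C = 150), seed = 5))
  b <- generate_cohort(cohort_spec(n_per_hospital = c(A = 150, B = 150, C = 150), seed = 5))
  expect_identical(a, b)
  c <- generate_cohort(cohort_spec(n_per_hospital = c(A = 150, B = 150, C = 150), seed = 6))
  expect_false(identical(a, c))
})

test_that("marginals track the registry targets", {
  co <- generate_cohort(cohort_spec(
    n_per_hospital = c(A = 937, B = 937, C = 937), seed = 21))
  expect_true(all(co$age >= 15))
  expect_true(all(co$gcs %in% 3:15))
  expect_false(anyNA(co))
  expect_equal(median(co$gcs), 15)
  expect_equal(unname(quantile(co$gcs, 0.25)), 9, tolerance = 1)
  expect_equal(median(co$sbp), 120, tolerance = 2)
  expect_equal(mean(co$male), 0.80, tolerance = 0.025)
  expect_equal(mean(co$transferred), 0.71, tolerance = 0.03)
  expect_equal(median(co$delay_h), 7, tolerance = 1)
  # 24-h mortality near 7 % as in the validation column (3 binomial SE)
  expect_lt(abs(mean(co$early_death) - 0.068),
            3 * sqrt(0.068 * 0.932 / nrow(co)))
})

test_that("a very large negative intercept produces no deaths", {
  m <- generating_model()
  m$coefficients["intercept"] <- -50
  co <- generate_cohort(cohort_spec(n_per_hospital = c(A = 300, B = 300, C = 300),
                                    model = m, seed = 2))
  expect_equal(sum(co$early_death), 0)
})

test_that("empirical event rate matches the generating model analytically", {
  spec <- cohort_spec(n_per_hospital = c(A = 3400, B = 3300, C = 3300), seed = 31)
  co <- generate_cohort(spec)
  p <- predict_probability(linear_predictor(generating_model(), co))
  se <- sqrt(mean(p) * (1 - mean(p)) / nrow(co))
  expect_lt(abs(mean(co$early_death) - mean(p)), 3 * se)
})

test_that("the true linear predictor is calibrated in large samples", {
  spec <- cohort_spec(n_per_hospital = c(A = 17000, B = 17000, C = 16000),
                      seed = 41)
  co <- generate_cohort(spec)
  lp <- linear_predictor(generating_model(), co)
  expect_gt(calibration_slope(lp, co$early_death), 0.95)
  expect_lt(calibration_slope(lp, co$early_death), 1.05)
})

test_that("imposed missingness hits the requested fractions", {
  co <- small_cohort(n_per_hospital = c(A = 550, B = 550, C = 529), seed = 8)
  rates <- c(sbp = 0.20, hr = 0.18, gcs = 0.20, delay_h = 0.06)
  for (mech in c("MCAR", "MAR")) {
    masked <- impose_missingness(co, rates, mechanism = mech, seed = 9)
    for (v in names(rates)) {
      se <- sqrt(rates[[v]] * (1 - rates[[v]]) / nrow(co))
      expect_lt(abs(mean(is.na(masked[[v]])) - rates[[v]]), 3 * se)
    }
    expect_false(anyNA(masked$early_death))
    expect_false(anyNA(masked$age))
  }
})

test_that("masking changes designated fields only, and only to NA", {
  co <- small_cohort(seed = 12)
  masked <- impose_missingness(co, c(sbp = 0.3, gcs = 0.2), seed = 13)
  for (v in setdiff(names(co), c("sbp", "gcs"))) {
    expect_identical(masked[[v]], co[[v]])
  }
  for (v in c("sbp", "gcs")) {
    ok <- !is.na(masked[[v]])
    expect_identical(masked[[v]][ok], co[[v]][ok])
    expect_gt(sum(!ok), 0)
  }
  # zero rates are the identity
  expect_identical(impose_missingness(co, c(sbp = 0, hr = 0), seed = 1), co)
  # the outcome can never be masked
  expect_error(impose_missingness(co, c(early_death = 0.1)), "early_death")
})

test_that("MCAR masking leaves the observed distribution unbiased", {
  co <- small_cohort(n_per_hospital = c(A = 3400, B = 3300, C = 3300), seed = 14)
  masked <- impose_missingness(co, c(sbp = 0.5), mechanism = "MCAR", seed = 15)
  obs <- masked$sbp[!is.na(masked$sbp)]
  se <- sd(co$sbp) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - mean(co$sbp)), 3 * se)
})

test_that("MAR masking depends on always-observed fields", {
  co <- small_cohort(n_per_hospital = c(A = 2000, B = 2000, C = 2000), seed = 16)
  masked <- impose_missingness(co, c(sbp = 0.2), mechanism = "MAR", seed = 17)
  miss <- is.na(masked$sbp)
  # transferred patients lose more measurements by design
  expect_gt(mean(miss[co$transferred]), mean(miss[!co$transferred]))
})

test_that("cohorts survive the CSV round trip", {
  co <- small_cohort(n_per_hospital = c(A = 60, B = 60, C = 60), seed = 18)
  masked <- impose_missingness(co, c(sbp = 0.2, gcs = 0.2), seed = 19)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(masked, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(masked))
  expect_equal(back$sbp, masked$sbp, tolerance = 1e-6)
  expect_identical(is.na(back$gcs), is.na(masked$gcs))
  expect_identical(back$early_death, masked$early_death)
  expect_equal(as.numeric(back$arrival_time), as.numeric(masked$arrival_time),
               tolerance = 1)
  # header line is a plain RFC-4180 CSV header
  expect_match(readLines(path, n = 1), "^hospital_id,arrival_time,")
})
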