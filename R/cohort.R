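#' Synthetic multi-hospital trauma cohorts
#'
#' Generates patient-level cohorts with the statistical structure of an urban
#' trauma registry: three referral hospitals, adult (>= 15 years) patients,
#' vitals on arrival (systolic blood pressure, heart rate, Glasgow coma
#' scale), mechanism of injury, transfer status, delay from injury, and death
#' within 24 h of the first recorded vitals. The outcome is drawn from a
#' known logistic model in an SBP spline and linear GCS, so the generating
#' truth is available to every downstream test.
#'
#' @name synthetic_cohort
NULL

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# seed for a sub-task, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# log-normal parameters from a median and quartiles
lnorm_params <- function(median, q1, q3) {
  sdlog <- mean(c(log(median / q1), log(q3 / median))) / stats::qnorm(0.75)
  c(meanlog = log(median), sdlog = sdlog)
}

#' The data-generating risk model shipped with the package
#'
#' A fully specified logistic model (4-knot restricted cubic spline of SBP
#' plus linear GCS) whose coefficients are read from a plain-text model file
#' installed with the package. The intercept is calibrated so that a default
#' cohort has an early-mortality rate of about 6--7 %.
#'
#' @return A `"model_spec"`.
#' @export
generating_model <- function() {
  path <- system.file("extdata", "generating-model.yaml", package = "trauma24",
                      mustWork = TRUE)
  read_model_spec(path)
}

#' Specify a synthetic cohort
#'
#' Collects everything the generator needs: per-hospital sizes, the arrival
#' window, marginal targets (medians and quartiles for continuous variables,
#' proportions for categorical ones), a latent correlation among the vitals,
#' and the true outcome model. Defaults emulate the validation-period column
#' of the registry's sample-characteristics table.
#'
#' @param n_per_hospital Named integer vector of cohort sizes (>= 1 each).
#' @param window Length-2 character/Date vector, arrival window (UTC days).
#' @param marginals List of marginal targets; see Details of
#'   [generate_cohort()].
#' @param vitals_correlation Named numeric vector with entries `sbp_hr`,
#'   `sbp_gcs`, `hr_gcs`: latent Gaussian-copula correlations among the
#'   vitals. Defaults encode mild clinical structure (shock: lower SBP with
#'   higher HR; head injury: lower GCS with lower SBP).
#' @param model The true outcome `"model_spec"`; default [generating_model()].
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `"cohort_spec"` list.
#' @export
cohort_spec <- function(n_per_hospital = c(A = 1480L, B = 1480L, C = 1480L),
                        window = c("2013-10-01", "2014-07-23"),
                        marginals = list(
                          age = c(median = 35, q1 = 25, q3 = 46),
                          male = 0.80,
                          mechanism = c(fall = 0.26, railway = 0.06,
                                        road_traffic = 0.46, assault = 0.11,
                                        burn = 0.07, other = 0.04),
                          delay_h = c(median = 7, q1 = 2, q3 = 26),
                          transferred = 0.71,
                          sbp = c(median = 120, q1 = 110, q3 = 130),
                          sbp_shock = c(median = 65, q1 = 55, q3 = 80),
                          shock_fraction = 0.03,
                          hr = c(median = 89, q1 = 80, q3 = 98),
                          gcs15_mass = 0.55
                        ),
                        vitals_correlation = c(sbp_hr = -0.2, sbp_gcs = 0.3,
                                               hr_gcs = -0.1),
                        model = NULL,
                        seed = 1L) {
  if (any(n_per_hospital < 1L)) stop("each hospital needs n >= 1")
  if (is.null(names(n_per_hospital))) {
    names(n_per_hospital) <- LETTERS[seq_along(n_per_hospital)]
  }
  mech <- marginals$mechanism
  marginals$mechanism <- mech / sum(mech)
  if (marginals$gcs15_mass <= 0 || marginals$gcs15_mass >= 1) {
    stop("'gcs15_mass' must lie in (0, 1)")
  }
  structure(
    list(n_per_hospital = n_per_hospital,
         window = as.Date(window),
         marginals = marginals,
         vitals_correlation = vitals_correlation,
         model = model,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

vitals_sigma <- function(r) {
  S <- diag(3)
  dimnames(S) <- list(c("sbp", "hr", "gcs"), c("sbp", "hr", "gcs"))
  S["sbp", "hr"] <- S["hr", "sbp"] <- r[["sbp_hr"]]
  S["sbp", "gcs"] <- S["gcs", "sbp"] <- r[["sbp_gcs"]]
  S["hr", "gcs"] <- S["gcs", "hr"] <- r[["hr_gcs"]]
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) stop("'vitals_correlation' is not positive definite")
  S
}

# GCS quantile function: point mass at 15, uniform tail over 3..14
q_gcs <- function(u, p15) {
  out <- rep.int(15L, length(u))
  tail <- u < (1 - p15)
  out[tail] <- 3L + pmin(11L, as.integer(floor(u[tail] / (1 - p15) * 12)))
  out
}

#' Generate a complete synthetic cohort
#'
#' Draws a complete (no missing values) cohort. Continuous variables come
#' from log-normal distributions matched to the target median and quartiles;
#' SBP is a mixture with a small haemorrhagic-shock component
#' (`shock_fraction`, default 3 %) supplying the clinically expected
#' hypotensive tail below 60 mmHg; GCS comes from a two-component mixture (a
#' point mass at 15 plus a uniform severe/moderate tail over 3--14, giving
#' median 15 and lower quartile near 9); the three vitals are coupled
#' through a Gaussian copula. Age is
#' truncated at 15 (eligibility) and rounded; arrival times are uniform over
#' the window so a temporal split is meaningful. The outcome `early_death`
#' is Bernoulli with probability from the spec's true model applied to each
#' patient's SBP and GCS.
#'
#' @param spec A `"cohort_spec"`.
#' @return A data frame sorted by arrival time with columns `hospital_id`,
#'   `arrival_time` (POSIXct, UTC), `age`, `male`, `mechanism`, `delay_h`,
#'   `transferred`, `sbp`, `hr`, `gcs`, `early_death`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  model <- if (is.null(spec$model)) generating_model() else spec$model
  mg <- spec$marginals
  n <- sum(spec$n_per_hospital)

  with_seed(spec$seed, {
    hospital_id <- factor(rep(names(spec$n_per_hospital), spec$n_per_hospital),
                          levels = names(spec$n_per_hospital))

    t0 <- as.POSIXct(paste(spec$window[1], "00:00:00"), tz = "UTC")
    t1 <- as.POSIXct(paste(spec$window[2], "23:59:59"), tz = "UTC")
    arrival_time <- t0 + stats::runif(n) * as.numeric(difftime(t1, t0, units = "secs"))

    ap <- lnorm_params(mg$age[["median"]], mg$age[["q1"]], mg$age[["q3"]])
    age <- pmax(15L, as.integer(round(stats::rlnorm(n, ap[1], ap[2]))))
    male <- stats::runif(n) < mg$male
    mechanism <- factor(
      sample(names(mg$mechanism), n, replace = TRUE, prob = mg$mechanism),
      levels = names(mg$mechanism)
    )
    dp <- lnorm_params(mg$delay_h[["median"]], mg$delay_h[["q1"]], mg$delay_h[["q3"]])
    delay_h <- stats::rlnorm(n, dp[1], dp[2])
    transferred <- stats::runif(n) < mg$transferred

    # correlated vitals through a Gaussian copula
    L <- chol(vitals_sigma(spec$vitals_correlation))
    z <- matrix(stats::rnorm(3L * n), ncol = 3L) %*% L
    u <- stats::pnorm(z)
    sp <- lnorm_params(mg$sbp[["median"]], mg$sbp[["q1"]], mg$sbp[["q3"]])
    sk <- lnorm_params(mg$sbp_shock[["median"]], mg$sbp_shock[["q1"]],
                       mg$sbp_shock[["q3"]])
    hp <- lnorm_params(mg$hr[["median"]], mg$hr[["q1"]], mg$hr[["q3"]])
    # small haemorrhagic-shock subpopulation gives SBP its hypotensive tail
    shock <- stats::runif(n) < mg$shock_fraction
    sbp <- pmin(300, ifelse(shock,
                            stats::qlnorm(u[, 1L], sk[1], sk[2]),
                            stats::qlnorm(u[, 1L], sp[1], sp[2])))
    hr <- pmin(250, stats::qlnorm(u[, 2L], hp[1], hp[2]))
    gcs <- q_gcs(u[, 3L], mg$gcs15_mass)

    cohort <- data.frame(
      hospital_id = hospital_id, arrival_time = arrival_time,
      age = age, male = male, mechanism = mechanism, delay_h = delay_h,
      transferred = transferred, sbp = sbp, hr = hr, gcs = gcs,
      early_death = FALSE
    )
    p <- predict_probability(linear_predictor(model, cohort))
    cohort$early_death <- stats::runif(n) < p

    cohort <- cohort[order(cohort$arrival_time), , drop = FALSE]
    rownames(cohort) <- NULL
    cohort
  })
}

MASKABLE_FIELDS <- c("sbp", "hr", "gcs", "delay_h")

#' Impose missing values on a complete cohort
#'
#' Masks entries of `sbp`, `hr`, `gcs` and/or `delay_h` (the only fields
#' with missingness in the emulated registry; demographics, mechanism,
#' transfer status and the outcome are always observed). Under `"MCAR"`
#' every record has equal masking probability. Under `"MAR"` the masking
#' probability depends only on always-observed fields (hospital, transfer
#' status, mechanism) through a logistic model whose intercept is solved so
#' the marginal masking fraction equals the requested rate.
#'
#' No value is ever altered: cells either keep their value or become `NA`.
#'
#' @param cohort Complete cohort data frame.
#' @param rates Named numeric vector of masking fractions in `[0, 1)`; names
#'   must be among `sbp`, `hr`, `gcs`, `delay_h`.
#' @param mechanism `"MAR"` (default) or `"MCAR"`.
#' @param seed Integer seed.
#' @return The cohort with `NA`s inserted.
#' @export
impose_missingness <- function(cohort, rates, mechanism = c("MAR", "MCAR"),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  bad <- setdiff(names(rates), MASKABLE_FIELDS)
  if (length(bad)) {
    stop("missingness requested for field(s) not allowed to be missing: ",
         paste(bad, collapse = ", "))
  }
  if (any(rates < 0 | rates >= 1)) stop("missingness rates must lie in [0, 1)")
  n <- nrow(cohort)

  # MAR score from always-observed fields only
  hosp_eff <- stats::setNames(
    seq_along(levels(cohort$hospital_id)) * 0.3 - 0.3,
    levels(cohort$hospital_id)
  )
  score <- 0.6 * cohort$transferred +
    0.4 * (cohort$mechanism %in% c("road_traffic", "railway")) +
    hosp_eff[as.character(cohort$hospital_id)]

  with_seed(seed, {
    for (v in names(rates)) {
      r <- rates[[v]]
      if (r == 0) next
      p <- if (mechanism == "MCAR") {
        rep.int(r, n)
      } else {
        a <- stats::uniroot(
          function(a) mean(stats::plogis(a + score)) - r,
          interval = c(-20, 20), tol = 1e-10
        )$root
        stats::plogis(a + score)
      }
      cohort[[v]][stats::runif(n) < p] <- NA
    }
    cohort
  })
}

#' Generate a study cohort with period-specific missingness
#'
#' Convenience wrapper reproducing the full study's data conditions:
#' generates a complete cohort, splits it at `split_date`, and imposes the
#' registry's period-specific missingness fractions (updating period: 20 %
#' SBP, 18 % HR, 20 % GCS, 6 % delay; validation period: 9 %, 3 %, 8 %,
#' 4 %) under the chosen mechanism.
#'
#' @param spec A `"cohort_spec"`.
#' @param split_date Date separating updating from validation arrivals.
#' @param updating_rates,validation_rates Named masking fractions per period.
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @return List with `cohort` (with missing values), `complete` (the
#'   pre-masking cohort) and `split_date`.
#' @export
simulate_study_cohort <- function(spec,
                                  split_date = as.Date("2014-01-12"),
                                  updating_rates = c(sbp = 0.20, hr = 0.18,
                                                     gcs = 0.20, delay_h = 0.06),
                                  validation_rates = c(sbp = 0.09, hr = 0.03,
                                                       gcs = 0.08, delay_h = 0.04),
                                  mechanism = "MAR") {
  complete <- generate_cohort(spec)
  split_date <- as.Date(split_date)
  before <- as.Date(complete$arrival_time, tz = "UTC") < split_date
  upd <- impose_missingness(complete[before, , drop = FALSE], updating_rates,
                            mechanism = mechanism,
                            seed = derive_seed(spec$seed, 101L))
  val <- impose_missingness(complete[!before, , drop = FALSE], validation_rates,
                            mechanism = mechanism,
                            seed = derive_seed(spec$seed, 202L))
  cohort <- rbind(upd, val)
  cohort <- cohort[order(cohort$arrival_time), , drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort, complete = complete, split_date = split_date)
}

#' Read and write cohort files
#'
#' Cohorts are exchanged as RFC-4180 CSV with a header row, ISO-8601 UTC
#' timestamps, lower-case `true`/`false` booleans and empty fields for
#' missing values.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   cohort data frame typed as produced by [generate_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$arrival_time <- format(out$arrival_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (v in c("male", "transferred", "early_death")) {
    out[[v]] <- ifelse(out[[v]], "true", "false")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  raw$arrival_time <- as.POSIXct(raw$arrival_time, tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%OS")
  raw$hospital_id <- factor(raw$hospital_id)
  raw$mechanism <- factor(raw$mechanism)
  for (v in c("male", "transferred", "early_death")) {
    raw[[v]] <- raw[[v]] == "true"
  }
  raw$gcs <- as.integer(raw$gcs)
  raw$age <- as.integer(raw$age)
  raw
}
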