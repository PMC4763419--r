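#' Multiple imputation by chained equations, per hospital
#'
#' Missing vitals are handled by multiple imputation under a
#' missing-at-random assumption. Each hospital is imputed separately with
#' the same imputation model and the completed hospitals are recombined, so
#' hospital-specific measurement practices never leak across sites. The
#' chained-equation conditionals use predictive mean matching (PMM), which
#' keeps every imputed value inside the observed support: coma-scale
#' imputations are integers in 3--15 and vitals stay on plausible positive
#' scales by construction. The outcome (early death) is always part of the
#' imputation model.
#'
#' @name imputation
NULL

MODEL_VARS <- c("sbp", "hr", "gcs", "age")

#' Per-hospital fraction of incomplete observations
#'
#' An observation counts as incomplete when it is missing at least one of
#' the variables required to apply the compared risk models (`sbp`, `hr`,
#' `gcs`, `age` by default); missing delay does not count.
#'
#' @param cohort Cohort data frame with a `hospital_id` column.
#' @param vars Variables whose missingness defines incompleteness.
#' @return Named numeric vector, fraction in `[0, 1]` per hospital.
#' @export
incomplete_fractions <- function(cohort, vars = MODEL_VARS) {
  vars <- intersect(vars, names(cohort))
  inc <- rowSums(is.na(cohort[, vars, drop = FALSE])) > 0
  tapply(inc, cohort$hospital_id, mean)
}

#' Number of imputed datasets from the incompleteness rule
#'
#' The number of imputed datasets equals the percentage of incomplete
#' observations in the hospital with the highest percentage of incomplete
#' observations, rounded to the nearest integer. With any missing data at
#' all the result is floored at 2 (a single imputation is not multiple
#' imputation); with fully complete data the result is 0 (no imputation).
#'
#' @param per_hospital_incomplete_fraction Numeric fractions in `[0, 1]`.
#' @return Integer `m`.
#' @examples
#' choose_m(c(A = 0.51, B = 0.40, C = 0.22))  # 51
#' @export
choose_m <- function(per_hospital_incomplete_fraction) {
  f <- per_hospital_incomplete_fraction
  if (any(f < 0 | f > 1)) stop("incomplete fractions must lie in [0, 1]")
  worst <- max(f)
  if (worst == 0) return(0L)
  max(2L, as.integer(round(100 * worst)))
}

# design matrix of imputation predictors for one hospital's rows;
# 'current' holds working copies of the other imputed variables
imputation_design <- function(dat, exclude) {
  mech <- stats::model.matrix(~mechanism, dat)[, -1L, drop = FALSE]
  vit <- setdiff(c("sbp", "hr", "gcs", "delay_h"), exclude)
  X <- cbind(
    1,
    early_death = as.numeric(dat$early_death),
    age = dat$age,
    male = as.numeric(dat$male),
    transferred = as.numeric(dat$transferred),
    mech,
    as.matrix(dat[, vit, drop = FALSE])
  )
  storage.mode(X) <- "double"
  X
}

# one PMM draw: linear fit on observed rows, donor matching on fitted values.
# Donors are pre-sorted by fitted value so each missing row only inspects the
# 2k-neighbourhood around its insertion point (O(n log n) overall).
pmm_draw <- function(X, y, obs, mis, k = 5L) {
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  yhat <- drop(X %*% beta)
  ord <- order(yhat[obs])
  donors_hat <- yhat[obs][ord]
  donors_y <- y[obs][ord]
  n_d <- length(donors_y)
  kk <- min(k, n_d)
  pos <- findInterval(yhat[mis], donors_hat)
  vapply(seq_along(mis), function(i) {
    lo <- max(1L, pos[i] - kk + 1L)
    hi <- min(n_d, pos[i] + kk)
    win <- lo:hi
    near <- win[order(abs(donors_hat[win] - yhat[mis[i]]))[seq_len(kk)]]
    donors_y[near[sample.int(kk, 1L)]]
  }, numeric(1))
}

impute_one_hospital <- function(dat, impute_vars, seed, n_cycles, k = 5L) {
  miss_idx <- lapply(dat[impute_vars], function(col) which(is.na(col)))
  active <- impute_vars[vapply(miss_idx, length, integer(1)) > 0]
  if (!length(active)) return(dat)
  with_seed(seed, {
    # initialise missing cells from the observed marginal
    for (v in active) {
      obs_vals <- dat[[v]][!is.na(dat[[v]])]
      dat[[v]][miss_idx[[v]]] <- sample(obs_vals, length(miss_idx[[v]]),
                                        replace = TRUE)
    }
    for (cycle in seq_len(n_cycles)) {
      for (v in active) {
        X <- imputation_design(dat, exclude = v)
        mis <- miss_idx[[v]]
        obs <- setdiff(seq_len(nrow(dat)), mis)
        draws <- pmm_draw(X, dat[[v]], obs, mis, k = k)
        # donors come from the observed column, so integer columns stay integer
        if (is.integer(dat[[v]])) draws <- as.integer(draws)
        dat[[v]][mis] <- draws
      }
    }
    dat
  })
}

#' Impute a cohort
#'
#' Produces `m` completed copies of the cohort. Imputation runs separately
#' within each hospital (the completed hospitals are then recombined), uses
#' chained equations with predictive mean matching, and includes early
#' mortality among the predictors. Observed values are never modified and
#' are identical across all completed datasets. Per-hospital,
#' per-dataset seeds are derived deterministically from the master seed, so
#' one hospital's imputations are unaffected by any change to the others.
#'
#' @param cohort Cohort data frame (may contain missing `sbp`, `hr`, `gcs`,
#'   `delay_h`).
#' @param m Number of completed datasets (>= 2); default applies the
#'   incompleteness rule of [choose_m()].
#' @param seed Master integer seed.
#' @param n_cycles Chained-equation burn-in cycles (default 10).
#' @param impute_vars Variables eligible for imputation.
#' @return An object of class `"imputation_result"`: list with `m`,
#'   `datasets` (list of `m` complete data frames),
#'   `per_hospital_incomplete_fraction`, `imputed_vars` and `seed`.
#' @export
impute_cohort <- function(cohort, m = NULL, seed = 1L, n_cycles = 10L,
                          impute_vars = c("sbp", "hr", "gcs", "delay_h")) {
  impute_vars <- intersect(impute_vars, names(cohort))
  frac <- incomplete_fractions(cohort)
  if (is.null(m)) m <- choose_m(frac)
  m <- as.integer(m)
  any_missing <- anyNA(cohort[, impute_vars, drop = FALSE])
  if (any_missing && m < 2L) {
    stop("m must be >= 2 when the cohort has missing values")
  }
  if (!any_missing) {
    m <- max(m, 2L)
    return(structure(
      list(m = m, datasets = rep(list(cohort), m),
           per_hospital_incomplete_fraction = frac,
           imputed_vars = impute_vars, seed = as.integer(seed)),
      class = "imputation_result"
    ))
  }
  hospitals <- levels(droplevels(cohort$hospital_id))
  for (h in hospitals) {
    rows <- cohort$hospital_id == h
    for (v in impute_vars) {
      if (all(is.na(cohort[[v]][rows]))) {
        stop(sprintf("hospital '%s' has no observed values of '%s'; cannot fit its imputation model",
                     h, v))
      }
    }
  }
  datasets <- vector("list", m)
  for (d in seq_len(m)) {
    completed <- cohort
    for (hi in seq_along(hospitals)) {
      rows <- which(cohort$hospital_id == hospitals[hi])
      sub <- cohort[rows, , drop = FALSE]
      sub_seed <- derive_seed(seed, d * 997L + hi)
      completed[rows, ] <- impute_one_hospital(sub, impute_vars, sub_seed,
                                               n_cycles)
    }
    datasets[[d]] <- completed
  }
  structure(
    list(m = m, datasets = datasets,
         per_hospital_incomplete_fraction = frac,
         imputed_vars = impute_vars, seed = as.integer(seed)),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> m = %d completed datasets, n = %d rows\n",
              x$m, nrow(x$datasets[[1]])))
  cat("  incomplete fraction by hospital:",
      paste(sprintf("%s=%.2f", names(x$per_hospital_incomplete_fraction),
                    x$per_hospital_incomplete_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Stack completed datasets into one long table
#'
#' Follows the long-standing imputation-stack convention: one delimited
#' table with an imputation-index column `.imp` where 0 is the original
#' data (with its missing values) and 1..m are the completed copies.
#'
#' @param result An `"imputation_result"`.
#' @param original The original cohort to include as `.imp = 0` (optional).
#' @return A data frame with a leading `.imp` column.
#' @export
stack_imputations <- function(result, original = NULL) {
  pieces <- list()
  if (!is.null(original)) {
    pieces[[1]] <- cbind(.imp = 0L, original)
  }
  for (d in seq_len(result$m)) {
    pieces[[length(pieces) + 1L]] <- cbind(.imp = d, result$datasets[[d]])
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write an imputation stack to delimited text
#'
#' @param result An `"imputation_result"`.
#' @param path File path (CSV).
#' @param original Optional original cohort written as `.imp = 0`.
#' @return `path`, invisibly.
#' @export
write_imputations <- function(result, path, original = NULL) {
  stacked <- stack_imputations(result, original)
  stacked$arrival_time <- format(stacked$arrival_time, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC")
  utils::write.csv(stacked, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pool per-imputation P-values by the median
#'
#' Tests are run once per completed dataset and summarised by the median
#' P-value with its inter-quartile range; a median P-value below 0.05 is
#' deemed significant.
#'
#' @param p_values Numeric vector, one P-value per imputed dataset.
#' @return List with `median`, `iqr` (25th and 75th percentiles) and
#'   `significant`.
#' @export
pool_pvalues <- function(p_values) {
  if (!length(p_values)) stop("no P-values supplied")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("P-values must lie in [0, 1]")
  }
  med <- stats::median(p_values)
  list(median = med,
       iqr = unname(stats::quantile(p_values, c(0.25, 0.75))),
       significant = med < 0.05)
}

#' Pool a per-imputation performance metric
#'
#' Median and inter-quartile range across imputed datasets, the pooling
#' convention used for every performance measure in this package.
#'
#' @param values Numeric vector, one value per imputed dataset.
#' @return List with `median` and `iqr`.
#' @export
pool_metric <- function(values) {
  if (!length(values)) stop("no values supplied")
  list(median = stats::median(values),
       iqr = unname(stats::quantile(values, c(0.25, 0.75))))
}
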