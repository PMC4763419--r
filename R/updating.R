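#' Model updating by re-estimation with bootstrap shrinkage
#'
#' Step 1 of the two-step design: existing models are updated by
#' re-estimating their coefficients on the updating sample (keeping every
#' parameter regardless of significance), single-predictor models are
#' fitted fresh, and a linear shrinkage factor is estimated from 300
#' bootstrap resamples to protect the re-estimated coefficients against
#' overfitting before they are carried to the validation period.
#'
#' @name updating
NULL

# logistic fit on a prebuilt design matrix (intercept included in X);
# returns NULL on non-convergence, rank deficiency, or complete separation
fast_logit <- function(X, y, epsilon = 1e-8, maxit = 100L) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      X, y, family = stats::binomial(),
      control = stats::glm.control(epsilon = epsilon, maxit = maxit)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) return(NULL)
  mu <- fit$fitted.values
  if (all(mu[y == 1] > 1 - 1e-8) && all(mu[y == 0] < 1e-8)) return(NULL)
  fit
}

#' Fit a logistic risk model by maximum likelihood
#'
#' Re-estimates (or fits fresh) the coefficients of a model structure on a
#' complete cohort. Unfrozen spline knots are first placed at percentiles of
#' this sample and frozen into the returned model. Convergence requires
#' successive deviance changes below `1e-8` within 100 iterations; a
#' single-class outcome, a rank-deficient design, or complete separation
#' raise explicit errors rather than returning silently huge coefficients.
#'
#' @param data Complete cohort data frame (no missing model variables).
#' @param model A `"model_spec"` (its coefficients, if any, are ignored) or
#'   a list of [risk_term] definitions.
#' @param outcome Name of the binary outcome column.
#' @param knot_scheme Percentile scheme for any unfrozen spline knots.
#' @return A `"logit_fit"`: list with `model` (fitted `"model_spec"` with
#'   frozen knots), `se` (coefficient standard errors), `vcov`, `loglik`
#'   and `n`.
#' @export
fit_logit <- function(data, model, outcome = "early_death",
                      knot_scheme = "equal") {
  if (!inherits(model, "model_spec")) {
    model <- model_spec("custom", model)
  }
  y <- as.numeric(data[[outcome]])
  if (length(unique(y)) < 2L) {
    stop("outcome '", outcome, "' has a single class; cannot fit a logistic model")
  }
  model <- freeze_knots(model, data, scheme = knot_scheme)
  X <- cbind(intercept = 1, model_matrix(model, data))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix for model '", model$name, "' is not full rank")
  }
  fit <- fast_logit(X, y)
  if (is.null(fit)) {
    stop("logistic fit for model '", model$name,
         "' did not converge (possible complete separation)")
  }
  # covariance from the IRLS QR decomposition (stable for ill-scaled bases
  # such as raw cubic terms)
  piv <- fit$qr$pivot
  vcov <- matrix(NA_real_, ncol(X), ncol(X),
                 dimnames = list(colnames(X), colnames(X)))
  vcov[piv, piv] <- chol2inv(qr.R(fit$qr))
  model$coefficients[] <- fit$coefficients
  model$provenance <- sprintf("fitted by maximum likelihood on n = %d", nrow(data))
  structure(
    list(model = model, se = sqrt(diag(vcov)), vcov = vcov,
         loglik = -fit$deviance / 2, n = nrow(data)),
    class = "logit_fit"
  )
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> %s on n = %d\n", x$model$name, x$n))
  tab <- cbind(estimate = x$model$coefficients, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

# slope of a logistic regression of y on a single linear predictor
lp_slope <- function(lp, y) {
  fit <- fast_logit(cbind(1, lp), y)
  if (is.null(fit)) return(NA_real_)
  fit$coefficients[2L]
}

#' Bootstrap linear shrinkage factor
#'
#' Repeats the estimation process in `n_bootstrap` bootstrap samples drawn
#' with replacement (same size as the data). Each bootstrap model generates
#' a linear predictor in the original, not bootstrapped, sample; that linear
#' predictor is entered into a logistic model with early mortality as the
#' dependent variable, and the shrinkage factor is the mean of the resulting
#' slope coefficients. Bootstrap fits that fail (non-convergence, rank
#' deficiency, separation) are redrawn; more than 10 % failures aborts with
#' a diagnostic.
#'
#' @inheritParams fit_logit
#' @param n_bootstrap Number of bootstrap resamples (default 300).
#' @param seed Integer seed; identical data and seed give identical slopes.
#' @return An `"update_result"`: list with `model` (the full-data fit),
#'   `shrinkage_factor` (mean of the slopes), `bootstrap_slopes`,
#'   `n_bootstrap`, `n_redrawn` and `seed`.
#' @export
bootstrap_shrinkage <- function(data, model, n_bootstrap = 300L, seed = 1L,
                                outcome = "early_death") {
  full <- fit_logit(data, model, outcome = outcome)
  y <- as.numeric(data[[outcome]])
  X <- cbind(1, model_matrix(full$model, data))  # knots now frozen
  n <- nrow(X)
  slopes <- numeric(n_bootstrap)
  n_redrawn <- 0L
  max_failures <- ceiling(0.1 * n_bootstrap)
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        bfit <- if (length(unique(y[idx])) < 2L) NULL else
          fast_logit(X[idx, , drop = FALSE], y[idx])
        if (!is.null(bfit)) {
          lp <- drop(X %*% bfit$coefficients)
          s <- lp_slope(lp, y)
          if (!is.na(s)) {
            slopes[b] <- s
            break
          }
        }
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_failures) {
          stop(sprintf("more than 10%% of bootstrap fits failed for model '%s' (%d failures); the sample is too small or too sparse for this model",
                       full$model$name, n_redrawn))
        }
      }
    }
  })
  structure(
    list(model = full$model, shrinkage_factor = mean(slopes),
         bootstrap_slopes = slopes, n_bootstrap = as.integer(n_bootstrap),
         n_redrawn = n_redrawn, seed = as.integer(seed)),
    class = "update_result"
  )
}

#' @export
print.update_result <- function(x, ...) {
  cat(sprintf("<update_result> %s: shrinkage factor %.3f (from %d bootstrap slopes%s)\n",
              x$model$name, x$shrinkage_factor, x$n_bootstrap,
              if (x$n_redrawn > 0) sprintf(", %d redrawn", x$n_redrawn) else ""))
  invisible(x)
}

#' Apply a linear shrinkage factor to a fitted model
#'
#' Multiplies the non-intercept coefficients by `factor`. By default the
#' intercept is then re-estimated (a logistic fit of the outcome on an
#' offset of the shrunken linear predictor) so that the mean predicted
#' probability on the supplied data equals the observed event rate; this is
#' the standard companion to uniform shrinkage, since scaling the intercept
#' would distort the base rate. `recalibrate_intercept = FALSE` gives the
#' literal mode in which every coefficient, intercept included, is scaled.
#'
#' @param model A fitted `"model_spec"`.
#' @param factor Positive shrinkage factor.
#' @param data Complete cohort used to re-estimate the intercept (required
#'   unless `recalibrate_intercept = FALSE`).
#' @param recalibrate_intercept Logical, default `TRUE`.
#' @param outcome Outcome column name.
#' @return The shrunken `"model_spec"` with `shrinkage_factor` recorded.
#' @export
apply_shrinkage <- function(model, factor, data = NULL,
                            recalibrate_intercept = TRUE,
                            outcome = "early_death") {
  if (!(is.numeric(factor) && length(factor) == 1L && factor > 0)) {
    stop("'factor' must be a single positive number")
  }
  out <- model
  if (recalibrate_intercept) {
    if (is.null(data)) {
      stop("'data' is required to re-estimate the intercept after shrinkage")
    }
    X <- model_matrix(model, data)
    off <- drop(X %*% (model$coefficients[-1L] * factor))
    y <- as.numeric(data[[outcome]])
    fit <- suppressWarnings(stats::glm.fit(
      matrix(1, nrow(X)), y, family = stats::binomial(), offset = off,
      control = stats::glm.control(epsilon = 1e-10, maxit = 100L)
    ))
    out$coefficients[1L] <- fit$coefficients[1L]
    out$coefficients[-1L] <- model$coefficients[-1L] * factor
  } else {
    out$coefficients <- model$coefficients * factor
  }
  out$shrinkage_factor <- factor
  out$provenance <- paste0(model$provenance, "; shrinkage factor ",
                           format(factor, digits = 4),
                           if (recalibrate_intercept) " (intercept re-estimated)"
                           else " (literal, intercept scaled)")
  out
}
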