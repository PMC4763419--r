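#' Discrimination and calibration assessment
#'
#' Step 2 of the two-step design: each model is applied to the temporally
#' independent validation sample and assessed for discrimination (AUROCC,
#' sensitivity, specificity) and calibration (calibration slope, calibration
#' plots over risk deciles). Metrics are computed once per imputed dataset
#' and pooled by median and inter-quartile range; model-to-model comparisons
#' use a paired test for correlated ROC curves and a paired bootstrap for
#' calibration-slope differences, summarised by the median P-value.
#'
#' @name performance
NULL

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present")
  }
}

#' Area under the ROC curve
#'
#' The Mann--Whitney concordance probability: the chance that a randomly
#' chosen case has a higher predicted risk than a randomly chosen non-case,
#' with ties counting one half. Invariant under any strictly increasing
#' transform of the predictions.
#'
#' @param p Predicted risks (any monotone score).
#' @param y Binary outcomes (0/1 or logical).
#' @return AUROCC in `[0, 1]`.
#' @export
auroc <- function(p, y) {
  y <- as.logical(y)
  check_two_classes(y)
  r <- rank(p, ties.method = "average")
  n1 <- sum(y)
  n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare two correlated ROC curves
#'
#' Two-sided paired test (DeLong) for the difference in AUROCC between two
#' models evaluated on the same patients. Identical prediction vectors make
#' the test degenerate; by convention the P-value is then 1.
#'
#' @param p_a,p_b Predicted risks from the two models on the same patients.
#' @param y Binary outcomes.
#' @return Two-sided P-value in `[0, 1]`.
#' @export
compare_auroc <- function(p_a, p_b, y) {
  if (length(p_a) != length(p_b) || length(p_a) != length(y)) {
    stop("'p_a', 'p_b' and 'y' must have the same length")
  }
  y <- as.integer(as.logical(y))
  check_two_classes(y)
  if (isTRUE(all.equal(as.numeric(p_a), as.numeric(p_b)))) return(1)
  roc_a <- pROC::roc(y, p_a, levels = c(0, 1), direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(y, p_b, levels = c(0, 1), direction = "<", quiet = TRUE)
  out <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
  pv <- as.numeric(out$p.value)
  if (is.na(pv)) 1 else min(max(pv, 0), 1)
}

#' Calibration slope
#'
#' Slope coefficient from a logistic regression of the outcome on a model's
#' linear predictor (with intercept). 1 is ideal; below 1 the predictions
#' are too extreme (overfitting), above 1 too moderate.
#'
#' @param lp Linear predictor (log-odds) values.
#' @param y Binary outcomes.
#' @return The slope.
#' @export
calibration_slope <- function(lp, y) {
  y <- as.numeric(as.logical(y))
  check_two_classes(y)
  if (any(!is.finite(lp))) stop("linear predictor must be finite")
  s <- lp_slope(lp, y)
  if (is.na(s)) stop("calibration-slope regression did not converge")
  unname(s)
}

#' Compare calibration slopes by paired bootstrap
#'
#' Resamples patients with replacement, recomputes both calibration slopes
#' on each resample, and derives a two-sided P-value for a zero slope
#' difference from the bootstrap distribution of the difference (twice the
#' smaller tail fraction). Identical linear predictors give a difference of
#' exactly zero in every resample and a P-value of 1.
#'
#' @param lp_a,lp_b Linear predictors of the two models on the same patients.
#' @param y Binary outcomes.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Two-sided P-value in `[0, 1]`.
#' @export
compare_calibration_slope <- function(lp_a, lp_b, y, n_boot = 1000L,
                                      seed = 1L) {
  if (length(lp_a) != length(lp_b) || length(lp_a) != length(y)) {
    stop("'lp_a', 'lp_b' and 'y' must have the same length")
  }
  y <- as.numeric(as.logical(y))
  check_two_classes(y)
  if (isTRUE(all.equal(as.numeric(lp_a), as.numeric(lp_b)))) return(1)
  n <- length(y)
  deltas <- rep(NA_real_, n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) next
      sa <- lp_slope(lp_a[idx], y[idx])
      sb <- lp_slope(lp_b[idx], y[idx])
      if (!is.na(sa) && !is.na(sb)) deltas[b] <- sa - sb
    }
  })
  deltas <- deltas[!is.na(deltas)]
  if (!length(deltas)) stop("all bootstrap slope fits failed")
  lo <- mean(deltas <= 0)
  hi <- mean(deltas >= 0)
  min(1, 2 * min(lo, hi))
}

#' Sensitivity and specificity at a risk threshold
#'
#' Classifies a patient as positive when the predicted risk is at or above
#' the threshold (default 0.05, the threshold probability emphasised in the
#' decision-curve scenario).
#'
#' @param p Predicted risks.
#' @param y Binary outcomes.
#' @param threshold Classification threshold in probability units.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(p, y, threshold = 0.05) {
  y <- as.logical(y)
  check_two_classes(y)
  pos <- p >= threshold
  c(sensitivity = sum(pos & y) / sum(y),
    specificity = sum(!pos & !y) / sum(!y))
}

#' Calibration plot data over risk deciles
#'
#' Groups patients into `n_groups` quantile groups of predicted risk (stable
#' order, group sizes differing by at most one), and returns per-group mean
#' predicted probability and observed event fraction, a locally smoothed
#' observed-vs-predicted curve, and the calibration-slope line, as
#' plain-text-exportable tables.
#'
#' @param p Predicted risks.
#' @param y Binary outcomes.
#' @param n_groups Number of quantile groups (default 10).
#' @param span Span of the local-regression smoother (default 0.75).
#' @return An object of class `"calibration_data"`: list with `groups`
#'   (data frame: `group`, `n`, `mean_predicted`, `observed`), `smooth`
#'   (data frame: `predicted`, `observed`), `slope` and `intercept` of the
#'   logistic recalibration line, and `n`.
#' @export
calibration_plot_data <- function(p, y, n_groups = 10L, span = 0.75) {
  y <- as.numeric(as.logical(y))
  n <- length(p)
  if (n < n_groups) stop("need at least as many patients as groups")
  if (length(unique(p)) == 1L) {
    # a constant predictor has a single effective risk group
    groups <- data.frame(group = 1L, n = n, mean_predicted = p[1L],
                         observed = mean(y))
  } else {
    ord <- order(p)  # stable: ties keep original order
    grp <- integer(n)
    grp[ord] <- as.integer(ceiling(seq_len(n) / (n / n_groups)))
    groups <- data.frame(
      group = seq_len(n_groups),
      n = as.integer(tabulate(grp, n_groups)),
      mean_predicted = as.numeric(tapply(p, grp, mean)),
      observed = as.numeric(tapply(y, grp, mean))
    )
  }
  smooth <- tryCatch({
    lo <- suppressWarnings(stats::loess(y ~ p, span = span, degree = 2,
                                        family = "gaussian"))
    grid <- seq(min(p), max(p), length.out = 100L)
    data.frame(
      predicted = grid,
      observed = pmin(1, pmax(0, stats::predict(lo, newdata = data.frame(p = grid))))
    )
  }, error = function(e) {
    data.frame(predicted = groups$mean_predicted, observed = groups$observed)
  })
  lp <- stats::qlogis(pmin(1 - 1e-12, pmax(1e-12, p)))
  cal <- if (length(unique(y)) >= 2L && length(unique(lp)) >= 2L) {
    fit <- fast_logit(cbind(1, lp), y)
    if (is.null(fit)) c(NA_real_, NA_real_) else fit$coefficients
  } else c(NA_real_, NA_real_)
  structure(
    list(groups = groups, smooth = smooth,
         intercept = unname(cal[1L]), slope = unname(cal[2L]), n = n),
    class = "calibration_data"
  )
}

#' @export
print.calibration_data <- function(x, ...) {
  cat(sprintf("<calibration_data> n = %d, %d groups, calibration slope %.3f\n",
              x$n, nrow(x$groups), x$slope))
  print(round(x$groups, 4))
  invisible(x)
}

#' Plot observed versus predicted risk
#'
#' @param x A `"calibration_data"`.
#' @param ... Unused.
#' @return A ggplot object: decile points, smoothed curve, the logistic
#'   recalibration line (dashed) and the identity (dotted).
#' @export
plot.calibration_data <- function(x, ...) {
  rng <- range(c(x$groups$mean_predicted, x$groups$observed))
  line_grid <- data.frame(predicted = seq(max(1e-6, rng[1]),
                                          min(1 - 1e-6, rng[2]),
                                          length.out = 100))
  line_grid$observed <- stats::plogis(x$intercept +
                                        x$slope * stats::qlogis(line_grid$predicted))
  ggplot2::ggplot(x$groups,
                  ggplot2::aes(x = .data$mean_predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line(data = x$smooth,
                       ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_line(data = line_grid,
                       ggplot2::aes(x = .data$predicted, y = .data$observed),
                       linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Predicted probability of early mortality",
                  y = "Observed probability of early mortality") +
    ggplot2::theme_minimal()
}

#' Validation performance pooled across imputations
#'
#' Applies each fitted model to every completed validation dataset and pools
#' AUROCC, calibration slope, sensitivity and specificity by median and IQR.
#' When a reference model is named, each other model is compared against it
#' (paired ROC test and paired bootstrap slope test per imputed dataset,
#' pooled by median P-value).
#'
#' @param models Named list of fitted `"model_spec"` objects.
#' @param imputations An `"imputation_result"` for the validation sample, or
#'   a list of complete data frames.
#' @param reference Name of the reference model for comparisons, or `NULL`.
#' @param threshold Risk threshold for sensitivity/specificity.
#' @param n_boot Bootstrap resamples for slope comparisons.
#' @param seed Integer seed for the bootstrap comparisons.
#' @param outcome Outcome column name.
#' @return An object of class `"performance_summary"`: list with
#'   `per_imputation` (long data frame of metrics), `pooled` (data frame of
#'   medians and IQRs per model and metric), `comparisons` (median-P data
#'   frame or `NULL`), `predicted` (pooled median/IQR of predicted risk per
#'   model) and `m`.
#' @export
assess_performance <- function(models, imputations, reference = NULL,
                               threshold = 0.05, n_boot = 1000L, seed = 1L,
                               outcome = "early_death") {
  datasets <- if (inherits(imputations, "imputation_result")) {
    imputations$datasets
  } else if (is.data.frame(imputations)) {
    list(imputations)
  } else imputations
  m <- length(datasets)
  stopifnot(m >= 1L, length(names(models)) == length(models))

  per <- list()
  pred_pool <- list()
  lps <- lapply(models, function(mod) lapply(datasets, function(d)
    linear_predictor(mod, d)))
  for (nm in names(models)) {
    for (d in seq_len(m)) {
      y <- datasets[[d]][[outcome]]
      lp <- lps[[nm]][[d]]
      p <- predict_probability(lp)
      ss <- sens_spec(p, y, threshold)
      per[[length(per) + 1L]] <- data.frame(
        model = nm, imputation = d,
        auroc = auroc(p, y),
        calibration_slope = calibration_slope(lp, y),
        sensitivity = ss[["sensitivity"]],
        specificity = ss[["specificity"]]
      )
      pred_pool[[length(pred_pool) + 1L]] <- data.frame(
        model = nm, imputation = d,
        median_p = stats::median(p),
        q1_p = unname(stats::quantile(p, 0.25)),
        q3_p = unname(stats::quantile(p, 0.75))
      )
    }
  }
  per <- do.call(rbind, per)
  pred_pool <- do.call(rbind, pred_pool)

  pool_rows <- list()
  for (nm in names(models)) {
    sub <- per[per$model == nm, ]
    for (metric in c("auroc", "calibration_slope", "sensitivity", "specificity")) {
      pm <- pool_metric(sub[[metric]])
      pool_rows[[length(pool_rows) + 1L]] <- data.frame(
        model = nm, metric = metric,
        median = pm$median, q1 = pm$iqr[1], q3 = pm$iqr[2]
      )
    }
  }
  pooled <- do.call(rbind, pool_rows)

  predicted <- do.call(rbind, lapply(split(pred_pool, pred_pool$model), function(s) {
    data.frame(model = s$model[1],
               median = stats::median(s$median_p),
               q1 = stats::median(s$q1_p),
               q3 = stats::median(s$q3_p))
  }))
  rownames(predicted) <- NULL

  comparisons <- NULL
  if (!is.null(reference)) {
    stopifnot(reference %in% names(models))
    others <- setdiff(names(models), reference)
    comp_rows <- list()
    for (nm in others) {
      p_auc <- p_cs <- numeric(m)
      for (d in seq_len(m)) {
        y <- datasets[[d]][[outcome]]
        lp_r <- lps[[reference]][[d]]
        lp_o <- lps[[nm]][[d]]
        p_auc[d] <- compare_auroc(predict_probability(lp_r),
                                  predict_probability(lp_o), y)
        p_cs[d] <- compare_calibration_slope(lp_r, lp_o, y, n_boot = n_boot,
                                             seed = derive_seed(seed, d))
      }
      pa <- pool_pvalues(p_auc)
      pc <- pool_pvalues(p_cs)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        model = nm, reference = reference,
        auroc_p_median = pa$median, auroc_p_q1 = pa$iqr[1], auroc_p_q3 = pa$iqr[2],
        slope_p_median = pc$median, slope_p_q1 = pc$iqr[1], slope_p_q3 = pc$iqr[2]
      )
    }
    comparisons <- do.call(rbind, comp_rows)
  }

  structure(
    list(per_imputation = per, pooled = pooled, comparisons = comparisons,
         predicted = predicted, m = m, threshold = threshold),
    class = "performance_summary"
  )
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("<performance_summary> %d models x %d imputations\n",
              length(unique(x$pooled$model)), x$m))
  wide <- x$pooled[x$pooled$metric %in% c("auroc", "calibration_slope"), ]
  wide$label <- sprintf("%.3f (%.3f-%.3f)", wide$median, wide$q1, wide$q3)
  print(stats::reshape(wide[, c("model", "metric", "label")],
                       idvar = "model", timevar = "metric",
                       direction = "wide"), row.names = FALSE)
  invisible(x)
}
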