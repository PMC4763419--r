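#' Decision curve analysis
#'
#' Quantifies the clinical consequences of acting on model predictions. The
#' scenario: several surveyed trauma patients are being monitored, and the
#' clinician may repeat the survey on everyone, on no one, or on those whose
#' predicted early-mortality risk reaches a threshold probability `p_t`. Net
#' benefit at `p_t` weighs true positives against false positives at the
#' odds of the threshold:
#' \deqn{NB(p_t) = \frac{TP}{n} - \frac{FP}{n} \cdot \frac{p_t}{1 - p_t}}
#'
#' @name decision_curves
NULL

#' Net benefit of a prediction strategy at a threshold
#'
#' A patient is treated as positive when the predicted risk is at or above
#' the threshold (ties treat).
#'
#' @param p Predicted risks.
#' @param y Binary outcomes.
#' @param p_t Threshold probability, strictly inside (0, 1).
#' @return Net benefit (true positives per patient, net of false positives
#'   weighted by the threshold odds).
#' @export
net_benefit <- function(p, y, p_t) {
  if (!(is.numeric(p_t) && length(p_t) == 1L && p_t > 0 && p_t < 1)) {
    stop("'p_t' must lie strictly inside (0, 1)")
  }
  y <- as.logical(y)
  n <- length(y)
  pos <- p >= p_t
  tp <- sum(pos & y)
  fp <- sum(pos & !y)
  tp / n - fp / n * p_t / (1 - p_t)
}

# closed form for the survey-everyone strategy
net_benefit_all <- function(prevalence, p_t) {
  prevalence - (1 - prevalence) * p_t / (1 - p_t)
}

#' Decision curves for a set of models
#'
#' Net benefit per threshold probability for each model plus the
#' survey-everyone (`treat_all`) and survey-no-one (`treat_none`)
#' strategies. Predictions can be supplied directly (named list of risk
#' vectors) or as fitted models applied to a complete cohort. When a list of
#' imputed datasets is supplied the per-dataset curves are pooled by the
#' median, consistent with the median-based pooling used elsewhere.
#'
#' @param models Named list of fitted `"model_spec"` objects (may be empty
#'   for a baseline-only curve), or a named list of numeric risk vectors
#'   when `cohort` rows match their length.
#' @param cohort A complete cohort data frame, an `"imputation_result"`, or
#'   a list of complete data frames.
#' @param thresholds Threshold-probability grid (default 0.01--0.50 by
#'   0.01, always including 0.05).
#' @param outcome Outcome column name.
#' @return An object of class `"decision_curve"`: list with `table` (data
#'   frame `threshold`, `strategy`, `net_benefit`), `prevalence` and
#'   `thresholds`.
#' @export
decision_curve <- function(models, cohort,
                           thresholds = seq(0.01, 0.50, by = 0.01),
                           outcome = "early_death") {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  thresholds <- sort(unique(thresholds))
  datasets <- if (inherits(cohort, "imputation_result")) cohort$datasets
              else if (is.data.frame(cohort)) list(cohort)
              else cohort
  m <- length(datasets)
  strategies <- c(names(models), "treat_all", "treat_none")

  nb <- array(NA_real_, dim = c(length(thresholds), length(strategies), m),
              dimnames = list(NULL, strategies, NULL))
  prev <- numeric(m)
  for (d in seq_len(m)) {
    dat <- datasets[[d]]
    y <- as.logical(dat[[outcome]])
    prev[d] <- mean(y)
    preds <- lapply(models, function(mod) {
      if (is.numeric(mod)) mod else predict_probability(linear_predictor(mod, dat))
    })
    for (ti in seq_along(thresholds)) {
      pt <- thresholds[ti]
      for (nm in names(models)) {
        nb[ti, nm, d] <- net_benefit(preds[[nm]], y, pt)
      }
      nb[ti, "treat_all", d] <- net_benefit_all(prev[d], pt)
      nb[ti, "treat_none", d] <- 0
    }
  }
  pooled <- apply(nb, c(1, 2), stats::median)
  table <- data.frame(
    threshold = rep(thresholds, times = length(strategies)),
    strategy = rep(strategies, each = length(thresholds)),
    net_benefit = as.vector(pooled)
  )
  structure(
    list(table = table, prevalence = stats::median(prev),
         thresholds = thresholds, m = m),
    class = "decision_curve"
  )
}

#' @export
print.decision_curve <- function(x, ...) {
  cat(sprintf("<decision_curve> %d strategies over %d thresholds (prevalence %.3f, %d dataset%s)\n",
              length(unique(x$table$strategy)), length(x$thresholds),
              x$prevalence, x$m, if (x$m > 1) "s" else ""))
  at <- x$table[x$table$threshold == 0.05, ]
  if (nrow(at)) {
    cat("  net benefit at p_t = 0.05:\n")
    for (i in seq_len(nrow(at))) {
      cat(sprintf("    %-12s %.4f\n", at$strategy[i], at$net_benefit[i]))
    }
  }
  invisible(x)
}

#' Plot decision curves
#'
#' @param x A `"decision_curve"`.
#' @param ... Unused.
#' @return A ggplot object, net benefit against threshold probability.
#' @export
plot.decision_curve <- function(x, ...) {
  ggplot2::ggplot(x$table,
                  ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.01, max(x$table$net_benefit) * 1.05)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Unnecessary surveys avoided per 100 patients
#'
#' Converts a net-benefit advantage of a model over the survey-everyone
#' strategy into the number of avoidable repeated surveys per 100 patients
#' at the same number of true positives:
#' \deqn{(NB_{model} - NB_{all}) \cdot \frac{1 - p_t}{p_t} \cdot 100}
#' Reported both as the real value and truncated to an integer count.
#'
#' @param nb_model Net benefit of the model strategy at `p_t`.
#' @param nb_all Net benefit of the survey-everyone strategy at `p_t`.
#' @param p_t Threshold probability in (0, 1).
#' @return List with `real` and `count` (integer, truncated toward zero).
#' @examples
#' net_reduction_per_100(0.045, 0.07 - 0.93 * (0.05 / 0.95), 0.05)
#' @export
net_reduction_per_100 <- function(nb_model, nb_all, p_t) {
  if (!(p_t > 0 && p_t < 1)) stop("'p_t' must lie strictly inside (0, 1)")
  real <- (nb_model - nb_all) * (1 - p_t) / p_t * 100
  list(real = real, count = as.integer(trunc(real)))
}
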