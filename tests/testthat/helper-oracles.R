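# Independent oracles, deliberately written from first principles and not
# sharing code with the package implementation.

# concordance probability by exhaustive case/non-case pair counting
brute_auc <- function(p, y) {
  y <- as.logical(y)
  cases <- p[y]
  controls <- p[!y]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(cases) * length(controls))
}

# restricted truncated-power cubic basis, direct textbook transcription
brute_rcs <- function(x, knots) {
  k <- length(knots)
  plus3 <- function(u) ifelse(u > 0, u^3, 0)
  out <- matrix(NA_real_, length(x), k - 1)
  out[, 1] <- x
  for (j in 1:(k - 2)) {
    num <- plus3(x - knots[j]) -
      plus3(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
      plus3(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])
    out[, j + 1] <- num / (knots[k] - knots[1])^2
  }
  out
}

# net benefit from an explicitly tabulated confusion matrix
brute_nb <- function(p, y, pt) {
  y <- as.logical(y)
  pred_pos <- p >= pt
  tp <- sum(pred_pos & y)
  fp <- sum(pred_pos & !y)
  n <- length(y)
  (tp / n) - (fp / n) * (pt / (1 - pt))
}

is_fitted_for_test <- function(model) !anyNA(model$coefficients)

terms_to_model_for_test <- function(terms) model_spec("test", terms)

# a small complete cohort from the default generator
small_cohort <- function(n_per_hospital = c(A = 200L, B = 200L, C = 200L),
                         seed = 1L, ...) {
  generate_cohort(cohort_spec(n_per_hospital = n_per_hospital,
                              seed = seed, ...))
}
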