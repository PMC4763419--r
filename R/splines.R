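#' Restricted cubic spline basis
#'
#' Knot placement and basis evaluation for restricted cubic splines (natural
#' cubic splines): piecewise cubic between knots, constrained to be linear
#' beyond the boundary knots. With \eqn{k} knots the basis has \eqn{k - 1}
#' columns: the variable itself plus \eqn{k - 2} nonlinear terms, the "spline
#' basis functions" (SBF) reported for systolic blood pressure and heart rate
#' in the bedside risk models.
#'
#' @name rcs
NULL

#' Place spline knots at sample percentiles
#'
#' Computes knot locations for a restricted cubic spline from the observed
#' (non-missing) values of a predictor. The default scheme places the knots
#' at equally spaced percentiles: for four knots, the 20th/40th/60th/80th
#' percentiles. The conventional alternative that pushes the boundary knots
#' outward (5th/35th/65th/95th for four knots) is available as
#' `scheme = "outer"`.
#'
#' @param x Numeric vector; missing values are dropped.
#' @param n_knots Number of knots (>= 3), default 4.
#' @param scheme `"equal"` for equally spaced interior percentiles
#'   (`p_j = j / (k + 1)`), `"outer"` for percentiles spanning 5--95.
#' @param varname Variable name used in error messages.
#' @return An object of class `"rcs_basis"`: a list with `knots` (strictly
#'   increasing numeric vector) and `basis_dimension` (`n_knots - 1`).
#' @examples
#' b <- compute_knots(1:100, n_knots = 4)
#' b$knots  # 20th/40th/60th/80th percentiles
#' @export
compute_knots <- function(x, n_knots = 4L,
                          scheme = c("equal", "outer"),
                          varname = deparse(substitute(x))) {
  scheme <- match.arg(scheme)
  x <- x[is.finite(x)]
  if (n_knots < 3L) {
    stop("at least 3 knots are required for a restricted cubic spline")
  }
  if (length(unique(x)) < n_knots) {
    stop(sprintf("'%s' has fewer than %d distinct finite values; cannot place spline knots",
                 varname, n_knots))
  }
  probs <- switch(scheme,
    equal = seq_len(n_knots) / (n_knots + 1),
    outer = seq(0.05, 0.95, length.out = n_knots)
  )
  knots <- unname(stats::quantile(x, probs = probs, type = 7))
  if (any(diff(knots) <= 0)) {
    stop(sprintf("knots for '%s' are not strictly increasing (heavily tied data); use fewer knots",
                 varname))
  }
  new_rcs_basis(knots)
}

new_rcs_basis <- function(knots) {
  knots <- as.numeric(knots)
  stopifnot(length(knots) >= 3L, all(diff(knots) > 0))
  structure(
    list(knots = knots, basis_dimension = length(knots) - 1L),
    class = "rcs_basis"
  )
}

#' @export
print.rcs_basis <- function(x, ...) {
  cat("Restricted cubic spline basis\n")
  cat("  knots:", paste(format(x$knots), collapse = ", "), "\n")
  cat("  basis dimension:", x$basis_dimension, "\n")
  invisible(x)
}

#' Evaluate the restricted cubic spline basis
#'
#' Returns the n x (k - 1) design matrix for a restricted cubic spline with
#' the given knots. Column 1 is the variable itself; the remaining k - 2
#' columns are the restricted truncated-power cubic terms, scaled by the
#' squared knot range so their coefficients are on a magnitude comparable to
#' the linear term. The basis is exactly linear beyond the boundary knots
#' (extrapolation outside the knot range is therefore linear, never cubic).
#'
#' For knots \eqn{t_1 < \dots < t_k} and \eqn{j = 1, \dots, k - 2}:
#' \deqn{f_j(x) = \frac{(x - t_j)_+^3
#'   - (x - t_{k-1})_+^3 \, (t_k - t_j) / (t_k - t_{k-1})
#'   + (x - t_k)_+^3 \, (t_{k-1} - t_j) / (t_k - t_{k-1})}{(t_k - t_1)^2}}
#'
#' @param x Numeric vector (values outside the knot range are valid).
#' @param basis An `"rcs_basis"` from [compute_knots()], or a numeric vector
#'   of knots.
#' @return Numeric matrix, `length(x)` rows and `k - 1` columns, with column
#'   names `sbf1` (linear) ... `sbf<k-1>`.
#' @export
rcs_basis <- function(x, basis) {
  knots <- if (inherits(basis, "rcs_basis")) basis$knots else as.numeric(basis)
  if (length(knots) < 3L || any(diff(knots) <= 0)) {
    stop("'basis' must supply at least 3 strictly increasing knots")
  }
  k <- length(knots)
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  scale <- (tk - knots[1L])^2
  out <- matrix(0, nrow = length(x), ncol = k - 1L)
  out[, 1L] <- x
  pos3 <- function(u) pmax(u, 0)^3
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                        pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                        pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / scale
  }
  colnames(out) <- paste0("sbf", seq_len(k - 1L))
  out
}
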