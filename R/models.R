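#' Model term constructors
#'
#' A risk model is a list of term definitions over patient-level variables.
#' Each term expands into one or more design-matrix columns:
#' \describe{
#'   \item{`term_linear(var)`}{one column, the variable itself.}
#'   \item{`term_spline(var, knots)`}{a restricted cubic spline; `knots` may
#'     be `NULL` for an unfitted structure whose knots are frozen on the
#'     updating sample via [freeze_knots()]. Expands to `k - 1` columns.}
#'   \item{`term_polynomial(var, degree)`}{raw polynomial columns
#'     \eqn{x, x^2, \dots, x^d}.}
#'   \item{`term_indicator(var, op, cutoff)`}{one 0/1 column, e.g.
#'     age < 60 years.}
#'   \item{`term_categories(var, cutpoints, reference)`}{ordered bands over a
#'     continuous variable. With cutpoints \eqn{c_1 < \dots < c_m} the bands
#'     are \eqn{x < c_1}; \eqn{c_{i-1} \le x \le c_i} for interior bands; and
#'     \eqn{x > c_m}. Boundary values belong to the interior band (so a band
#'     printed "60 <= SBP <= 120" is closed on both sides). The reference
#'     band contributes no column.}
#' }
#'
#' @param var Variable (column) name.
#' @param knots Numeric knot vector or `NULL` (unfitted spline).
#' @param n_knots Knot count used when freezing an unfitted spline.
#' @param degree Polynomial degree (>= 1).
#' @param op Comparison operator, one of `"<"`, `"<="`, `">"`, `">="`.
#' @param cutoff Numeric threshold for the indicator.
#' @param cutpoints Strictly increasing numeric vector of band boundaries.
#' @param reference Index of the reference band (default 1, the lowest).
#' @return A `"risk_term"` list.
#' @name risk_term
NULL

new_term <- function(var, form, ...) {
  structure(list(variable = var, form = form, ...), class = "risk_term")
}

#' @rdname risk_term
#' @export
term_linear <- function(var) new_term(var, "linear")

#' @rdname risk_term
#' @export
term_spline <- function(var, knots = NULL, n_knots = 4L) {
  if (!is.null(knots)) {
    knots <- as.numeric(knots)
    stopifnot(length(knots) >= 3L, all(diff(knots) > 0))
    n_knots <- length(knots)
  }
  new_term(var, "spline", knots = knots, n_knots = as.integer(n_knots))
}

#' @rdname risk_term
#' @export
term_polynomial <- function(var, degree) {
  stopifnot(degree >= 1L)
  new_term(var, "polynomial", degree = as.integer(degree))
}

#' @rdname risk_term
#' @export
term_indicator <- function(var, op, cutoff) {
  op <- match.arg(op, c("<", "<=", ">", ">="))
  new_term(var, "indicator", op = op, cutoff = as.numeric(cutoff))
}

#' @rdname risk_term
#' @export
term_categories <- function(var, cutpoints, reference = 1L) {
  cutpoints <- as.numeric(cutpoints)
  stopifnot(length(cutpoints) >= 1L, all(diff(cutpoints) > 0))
  n_bands <- length(cutpoints) + 1L
  stopifnot(reference >= 1L, reference <= n_bands)
  new_term(var, "categories", cutpoints = cutpoints,
           reference = as.integer(reference))
}

term_width <- function(term) {
  switch(term$form,
    linear = 1L,
    spline = term$n_knots - 1L,
    polynomial = term$degree,
    indicator = 1L,
    categories = length(term$cutpoints)
  )
}

term_labels <- function(term) {
  v <- term$variable
  switch(term$form,
    linear = v,
    spline = paste0(v, "_sbf", seq_len(term_width(term))),
    polynomial = if (term$degree == 1L) v else
      c(v, paste0(v, "^", 2:term$degree)),
    indicator = paste0(v, term$op, term$cutoff),
    categories = {
      cp <- term$cutpoints
      bands <- band_labels(v, cp)
      bands[-term$reference]
    }
  )
}

band_labels <- function(v, cp) {
  m <- length(cp)
  labs <- character(m + 1L)
  labs[1L] <- paste0(v, "<", cp[1L])
  if (m >= 2L) {
    for (i in 2:m) labs[i] <- paste0(cp[i - 1L], "<=", v, "<=", cp[i])
  }
  labs[m + 1L] <- paste0(v, ">", cp[m])
  labs
}

band_index <- function(x, cutpoints) {
  # band 1: x < c1; band i (2..m): c_{i-1} <= x <= c_i; band m+1: x > c_m
  m <- length(cutpoints)
  idx <- rep.int(m + 1L, length(x))
  idx[x < cutpoints[1L]] <- 1L
  if (m >= 2L) {
    for (i in 2:m) {
      idx[x >= cutpoints[i - 1L] & x <= cutpoints[i]] <- i
    }
  } else {
    # with a single cutpoint the printed convention keeps the boundary below
    idx[x >= cutpoints[1L] & x <= cutpoints[1L]] <- 1L
  }
  idx
}

term_columns <- function(term, x) {
  switch(term$form,
    linear = matrix(x, ncol = 1L),
    spline = {
      if (is.null(term$knots)) {
        stop(sprintf("spline term on '%s' has no knots; call freeze_knots() on the updating sample first",
                     term$variable))
      }
      rcs_basis(x, term$knots)
    },
    polynomial = matrix(vapply(seq_len(term$degree), function(d) x^d,
                               numeric(length(x))), nrow = length(x)),
    indicator = {
      f <- switch(term$op, "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`)
      matrix(as.numeric(f(x, term$cutoff)), ncol = 1L)
    },
    categories = {
      idx <- band_index(x, term$cutpoints)
      keep <- setdiff(seq_len(length(term$cutpoints) + 1L), term$reference)
      out <- vapply(keep, function(b) as.numeric(idx == b),
                    numeric(length(x)))
      matrix(out, nrow = length(x))
    }
  )
}

#' Define a risk model
#'
#' Bundles a model name, its term definitions, coefficients (intercept first)
#' and a multiplicative shrinkage factor into a portable specification.
#' Coefficients may be `NA` for a structure-only (unfitted) model.
#'
#' @param name Model name.
#' @param terms List of [risk_term] objects.
#' @param coefficients Numeric vector, intercept followed by one value per
#'   design column, or `NULL` for an unfitted structure.
#' @param shrinkage_factor Positive multiplier recorded with the model
#'   (applied explicitly via [apply_shrinkage()], never implicitly).
#' @param provenance Free-text note on where the coefficients come from.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(name, terms, coefficients = NULL,
                       shrinkage_factor = 1, provenance = "") {
  stopifnot(is.list(terms), length(terms) >= 1L,
            all(vapply(terms, inherits, logical(1), "risk_term")))
  if (!(is.numeric(shrinkage_factor) && length(shrinkage_factor) == 1L &&
        shrinkage_factor > 0)) {
    stop("'shrinkage_factor' must be a single positive number")
  }
  labels <- c("intercept", unlist(lapply(terms, term_labels)))
  n_coef <- length(labels)
  if (is.null(coefficients)) coefficients <- rep(NA_real_, n_coef)
  if (length(coefficients) != n_coef) {
    stop(sprintf("model '%s' needs %d coefficients (intercept + %d basis columns), got %d",
                 name, n_coef, n_coef - 1L, length(coefficients)))
  }
  coefficients <- stats::setNames(as.numeric(coefficients), labels)
  structure(
    list(name = name, terms = terms, coefficients = coefficients,
         shrinkage_factor = shrinkage_factor, provenance = provenance),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s)\n", x$name,
              if (is_fitted(x)) "fitted" else "structure only"))
  for (tm in x$terms) {
    extra <- switch(tm$form,
      spline = if (is.null(tm$knots)) sprintf("%d knots, unfrozen", tm$n_knots)
               else paste("knots", paste(format(tm$knots, digits = 4), collapse = ", ")),
      polynomial = paste("degree", tm$degree),
      indicator = paste(tm$op, tm$cutoff),
      categories = paste("cutpoints", paste(tm$cutpoints, collapse = ", ")),
      ""
    )
    cat(sprintf("  %s [%s] %s\n", tm$variable, tm$form, extra))
  }
  if (is_fitted(x)) {
    print(round(x$coefficients, 4))
  }
  cat("  shrinkage factor:", format(x$shrinkage_factor, digits = 4), "\n")
  invisible(x)
}

is_fitted <- function(model) !anyNA(model$coefficients)

#' Variables required by a model
#' @param model A `"model_spec"`.
#' @return Character vector of variable names.
#' @export
model_variables <- function(model) {
  unique(vapply(model$terms, `[[`, character(1), "variable"))
}

#' Built-in bedside trauma risk models
#'
#' Returns one of the six compared model structures:
#' \describe{
#'   \item{`basic`}{SBP as a 4-knot restricted cubic spline + linear GCS
#'     (structure only; knots and coefficients are fitted on an updating
#'     sample because no published knot locations exist).}
#'   \item{`basic_hr`}{`basic` plus a 4-knot spline of heart rate
#'     (structure only).}
#'   \item{`kondo`}{GCS linear, an age < 60 indicator, and SBP in three bands
#'     (reference SBP < 60 mmHg; 60--120 inclusive; > 120), with the
#'     published re-estimated coefficients as fixture values.}
#'   \item{`perel`}{age and SBP as cubic polynomials, GCS quadratic, with
#'     published re-estimated coefficients as fixture values (the original
#'     trial model's tranexamic-acid term and random intercept are dropped).}
#'   \item{`sbp_only`}{4-knot SBP spline, structure only.}
#'   \item{`gcs_only`}{linear GCS, structure only.}
#' }
#' Published coefficient sets are fixtures for format and arithmetic checks;
#' fitting on your own updating sample is the supported workflow.
#'
#' @param name One of `"basic"`, `"basic_hr"`, `"kondo"`, `"perel"`,
#'   `"sbp_only"`, `"gcs_only"`.
#' @return A `"model_spec"`.
#' @examples
#' m <- builtin_model("kondo")
#' linear_predictor(m, data.frame(gcs = 15, age = 35, sbp = 120))
#' @export
builtin_model <- function(name) {
  name <- match.arg(name, c("basic", "basic_hr", "kondo", "perel",
                            "sbp_only", "gcs_only"))
  switch(name,
    basic = model_spec(
      "basic",
      list(term_spline("sbp"), term_linear("gcs")),
      provenance = "SBP spline + GCS structure; fit on an updating sample"
    ),
    basic_hr = model_spec(
      "basic_hr",
      list(term_spline("sbp"), term_spline("hr"), term_linear("gcs")),
      provenance = "SBP + HR splines + GCS structure; fit on an updating sample"
    ),
    kondo = model_spec(
      "kondo",
      list(term_linear("gcs"), term_indicator("age", "<", 60),
           term_categories("sbp", c(60, 120), reference = 1L)),
      coefficients = c(1.919, -0.254, -0.225, -2.067, -2.511),
      provenance = "published re-estimated coefficients (fixture)"
    ),
    perel = model_spec(
      "perel",
      list(term_polynomial("age", 3L), term_polynomial("sbp", 3L),
           term_polynomial("gcs", 2L)),
      coefficients = c(3.678,
                       -0.067, 0.002, -1.3e-5,
                       0.019, -0.001, 2.3e-6,
                       -0.679, 0.024),
      provenance = "published re-estimated coefficients (fixture)"
    ),
    sbp_only = model_spec(
      "sbp_only",
      list(term_spline("sbp")),
      provenance = "single-predictor SBP spline; fit on an updating sample"
    ),
    gcs_only = model_spec(
      "gcs_only",
      list(term_linear("gcs")),
      provenance = "single-predictor linear GCS; fit on an updating sample"
    )
  )
}

#' Freeze spline knots on an updating sample
#'
#' Computes percentile knots for every unfrozen spline term from the
#' non-missing values of the supplied data and stores them in the model.
#' Knots are computed once, on the updating sample, and reused unchanged for
#' validation and charting: a prediction model must be fully specified before
#' it is validated.
#'
#' @param model A `"model_spec"`.
#' @param data Data frame holding the spline variables.
#' @param scheme Knot-placement scheme, see [compute_knots()].
#' @return The model with all spline knots set.
#' @export
freeze_knots <- function(model, data, scheme = c("equal", "outer")) {
  scheme <- match.arg(scheme)
  model$terms <- lapply(model$terms, function(tm) {
    if (tm$form == "spline" && is.null(tm$knots)) {
      b <- compute_knots(data[[tm$variable]], n_knots = tm$n_knots,
                         scheme = scheme, varname = tm$variable)
      tm$knots <- b$knots
    }
    tm
  })
  model
}

#' Design matrix for a risk model
#'
#' Expands each model term into its basis columns. Records with a missing
#' value in any required variable raise an explicit error: prediction on
#' incomplete records is never silently imputed.
#'
#' @param model A `"model_spec"`.
#' @param data Data frame with one row per patient.
#' @return Numeric matrix (no intercept column), labelled per basis column.
#' @export
model_matrix <- function(model, data) {
  for (v in model_variables(model)) {
    if (is.null(data[[v]])) {
      stop(sprintf("variable '%s' required by model '%s' is absent", v, model$name))
    }
    if (anyNA(data[[v]])) {
      stop(sprintf("variable '%s' required by model '%s' has missing values; impute or complete the data first",
                   v, model$name))
    }
  }
  cols <- lapply(model$terms, function(tm) term_columns(tm, as.numeric(data[[tm$variable]])))
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(lapply(model$terms, term_labels))
  X
}

#' Linear predictor (log-odds) of a risk model
#'
#' `lp = intercept + X beta` on the model's own (unshrunken) coefficients.
#' Shrinkage is applied only explicitly, via [apply_shrinkage()].
#'
#' @inheritParams model_matrix
#' @return Numeric vector of log-odds, one per row of `data`.
#' @export
linear_predictor <- function(model, data) {
  if (!is_fitted(model)) {
    stop(sprintf("model '%s' has unfitted (NA) coefficients", model$name))
  }
  X <- model_matrix(model, data)
  drop(model$coefficients[1L] + X %*% model$coefficients[-1L])
}

#' Convert log-odds to probability
#'
#' The inverse logit \eqn{p = 1 / (1 + e^{-lp})}; strictly increasing in the
#' linear predictor.
#'
#' @param lp Numeric vector of finite log-odds.
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(lp) {
  if (any(!is.finite(lp))) stop("linear predictor must be finite")
  stats::plogis(lp)
}

#' Predicted early-mortality probability for a cohort
#'
#' @param object A `"model_spec"`.
#' @param newdata Data frame of complete patient records.
#' @param type `"response"` for probabilities, `"lp"` for log-odds.
#' @param ... Unused.
#' @export
predict.model_spec <- function(object, newdata, type = c("response", "lp"), ...) {
  type <- match.arg(type)
  lp <- linear_predictor(object, newdata)
  if (type == "lp") lp else predict_probability(lp)
}

term_to_list <- function(tm) {
  out <- unclass(tm)
  out[!vapply(out, is.null, logical(1))]
}

term_from_list <- function(lst) {
  tm <- switch(lst$form,
    linear = term_linear(lst$variable),
    spline = term_spline(lst$variable, knots = lst$knots,
                         n_knots = if (is.null(lst$n_knots)) 4L else lst$n_knots),
    polynomial = term_polynomial(lst$variable, lst$degree),
    indicator = term_indicator(lst$variable, lst$op, lst$cutoff),
    categories = term_categories(lst$variable, lst$cutpoints, lst$reference),
    stop("unknown term form: ", lst$form)
  )
  tm
}

#' Read and write model-specification files
#'
#' Models round-trip through a versioned plain-text YAML file holding the
#' name, term definitions (including frozen spline knots), coefficients and
#' shrinkage factor, so a validated model is a portable artefact.
#'
#' @param model A `"model_spec"`.
#' @param path File path.
#' @return `write_model_spec` returns `path` invisibly; `read_model_spec`
#'   returns a `"model_spec"`.
#' @export
write_model_spec <- function(model, path) {
  payload <- list(
    format = "trauma24-model/1",
    name = model$name,
    provenance = model$provenance,
    shrinkage_factor = model$shrinkage_factor,
    terms = lapply(model$terms, term_to_list),
    coefficients = as.list(model$coefficients)
  )
  yaml::write_yaml(payload, path, precision = 17L)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  payload <- yaml::read_yaml(path)
  if (!identical(payload$format, "trauma24-model/1")) {
    stop("not a trauma24 model-specification file: ", path)
  }
  terms <- lapply(payload$terms, term_from_list)
  model_spec(payload$name, terms,
             coefficients = unlist(payload$coefficients),
             shrinkage_factor = payload$shrinkage_factor,
             provenance = payload$provenance)
}
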