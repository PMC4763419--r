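#' Two-step updating/validation study pipeline
#'
#' Orchestrates the full design: split the cohort into a temporally earlier
#' updating period and a later validation period, stop the validation sample
#' at the first `event_cap` deaths, impute each period separately, update or
#' fit every model on the updating imputations with bootstrap shrinkage,
#' then validate, compare, run the decision curve analysis and build the
#' bedside chart. Every model artefact records that its coefficients, knots
#' and shrinkage factor come from the updating period only.
#'
#' @name pipeline
NULL

#' Study design parameters
#'
#' @param split_date Date separating updating from validation arrivals.
#' @param event_cap Validation sampling stops after this many events
#'   (default 200, sized to detect a 0.05 drop in discrimination).
#' @param models Character vector of model roster names for
#'   [builtin_model()].
#' @param m Imputations per period: an integer (default 10, a reduced
#'   default for routine runs) or `"rule"` for the incompleteness rule of
#'   [choose_m()].
#' @param n_bootstrap Bootstrap resamples for the shrinkage factor
#'   (default 300).
#' @param compare_boot Bootstrap resamples per calibration-slope comparison.
#' @param thresholds Decision-curve threshold grid.
#' @param threshold Highlighted threshold probability (classification and
#'   survey cutoff; default 0.05).
#' @param reference Reference model for comparisons.
#' @param knot_scheme Spline knot-placement scheme.
#' @param seed Master seed; the whole run is deterministic given it.
#' @return A `"study_design"` list.
#' @export
study_design <- function(split_date = as.Date("2014-01-12"),
                         event_cap = 200L,
                         models = c("basic", "basic_hr", "kondo", "perel",
                                    "sbp_only", "gcs_only"),
                         m = 10L,
                         n_bootstrap = 300L,
                         compare_boot = 1000L,
                         thresholds = seq(0.01, 0.50, by = 0.01),
                         threshold = 0.05,
                         reference = "basic",
                         knot_scheme = "equal",
                         seed = 1L) {
  stopifnot(event_cap >= 1L, reference %in% models,
            threshold %in% thresholds || (threshold > 0 && threshold < 1))
  structure(
    list(split_date = as.Date(split_date), event_cap = as.integer(event_cap),
         models = models, m = m, n_bootstrap = as.integer(n_bootstrap),
         compare_boot = as.integer(compare_boot),
         thresholds = sort(unique(c(thresholds, threshold))),
         threshold = threshold, reference = reference,
         knot_scheme = knot_scheme, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Split a cohort into updating and validation periods by arrival time
#'
#' @param cohort Cohort data frame with complete `arrival_time`.
#' @param split_date Date (arrivals strictly before midnight UTC of this day
#'   form the updating period).
#' @return List with `updating` and `validation` data frames.
#' @export
temporal_split <- function(cohort, split_date) {
  if (anyNA(cohort$arrival_time)) stop("arrival_time must be complete")
  cut <- as.POSIXct(paste(as.Date(split_date), "00:00:00"), tz = "UTC")
  before <- cohort$arrival_time < cut
  if (!any(before)) stop("updating period is empty: split date precedes every arrival")
  if (all(before)) stop("validation period is empty: split date follows every arrival")
  list(updating = cohort[before, , drop = FALSE],
       validation = cohort[!before, , drop = FALSE])
}

#' Truncate a validation sample at the event cap
#'
#' Includes the first `event_cap` consecutive events and all non-events
#' arriving during the same time period: every patient whose arrival time is
#' at or before the arrival time of the `event_cap`-th death. With fewer
#' events than the cap the full cohort is returned with a warning.
#'
#' @param cohort Cohort data frame (will be sorted by arrival time).
#' @param event_cap Maximum number of events (default 200).
#' @param outcome Outcome column name.
#' @return The truncated cohort, sorted by arrival time.
#' @export
select_validation_sample <- function(cohort, event_cap = 200L,
                                     outcome = "early_death") {
  cohort <- cohort[order(cohort$arrival_time), , drop = FALSE]
  events <- which(cohort[[outcome]])
  if (length(events) < event_cap) {
    warning(sprintf("only %d events available, below the cap of %d; returning the full cohort",
                    length(events), event_cap))
    return(cohort)
  }
  cap_time <- cohort$arrival_time[events[event_cap]]
  cohort[cohort$arrival_time <= cap_time, , drop = FALSE]
}

update_roster_model <- function(name, datasets, design, upd_observed) {
  structure0 <- builtin_model(name)
  structure0 <- freeze_knots(structure0, upd_observed, scheme = design$knot_scheme)
  m <- length(datasets)
  coefs <- NULL
  sfs <- numeric(m)
  for (d in seq_len(m)) {
    ur <- bootstrap_shrinkage(datasets[[d]], structure0,
                              n_bootstrap = design$n_bootstrap,
                              seed = derive_seed(design$seed, 37L * d +
                                                   match(name, design$models)))
    shrunk <- apply_shrinkage(ur$model, ur$shrinkage_factor,
                              data = datasets[[d]])
    coefs <- cbind(coefs, shrunk$coefficients)
    sfs[d] <- ur$shrinkage_factor
  }
  final <- structure0
  final$coefficients[] <- rowMeans(coefs)
  final$shrinkage_factor <- mean(sfs)
  final$provenance <- sprintf(
    "re-estimated on the updating period only (%d imputations, %d bootstrap resamples; knots and shrinkage from updating period)",
    m, design$n_bootstrap)
  list(model = final, shrinkage_factors = sfs)
}

#' Run the full two-step study
#'
#' @param cohort Cohort data frame (optionally with missing vitals) or a
#'   path to a cohort CSV readable by [read_cohort()].
#' @param design A `"study_design"`.
#' @return An object of class `"study_report"`: list with `design`,
#'   `samples` (period sizes, event counts, incomplete fractions, m),
#'   `models` (final fitted/shrunken `"model_spec"`s), `shrinkage` (per
#'   imputation factors), `performance` (a `"performance_summary"`),
#'   `calibration` (per-model `"calibration_data"` on the stacked validation
#'   imputations), `decision` (a `"decision_curve"`), `net_reduction`
#'   (surveys avoided per 100 patients at the design threshold), `chart`
#'   (a `"risk_chart"` for the reference model) and `log`.
#' @export
run_study <- function(cohort, design = study_design()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(design, "study_design"))
  rng <- range(cohort$arrival_time)
  if (design$split_date <= as.Date(rng[1], tz = "UTC") ||
      design$split_date > as.Date(rng[2], tz = "UTC")) {
    stop("split date must fall inside the cohort's arrival range")
  }

  split <- temporal_split(cohort, design$split_date)
  validation <- select_validation_sample(split$validation, design$event_cap)
  updating <- split$updating

  frac_u <- incomplete_fractions(updating)
  frac_v <- incomplete_fractions(validation)
  m_u <- if (identical(design$m, "rule")) choose_m(frac_u) else design$m
  m_v <- if (identical(design$m, "rule")) choose_m(frac_v) else design$m
  imp_u <- impute_cohort(updating, m = m_u, seed = derive_seed(design$seed, 11L))
  imp_v <- impute_cohort(validation, m = m_v, seed = derive_seed(design$seed, 13L))

  updated <- lapply(design$models, update_roster_model,
                    datasets = imp_u$datasets, design = design,
                    upd_observed = updating)
  names(updated) <- design$models
  models <- lapply(updated, `[[`, "model")
  shrinkage <- lapply(updated, `[[`, "shrinkage_factors")

  performance <- assess_performance(models, imp_v,
                                    reference = design$reference,
                                    threshold = design$threshold,
                                    n_boot = design$compare_boot,
                                    seed = derive_seed(design$seed, 17L))

  stacked <- do.call(rbind, imp_v$datasets)
  calibration <- lapply(models, function(mod) {
    calibration_plot_data(predict_probability(linear_predictor(mod, stacked)),
                          stacked$early_death)
  })

  decision <- decision_curve(models, imp_v, thresholds = design$thresholds)
  nb_tab <- decision$table[decision$table$threshold == design$threshold, ]
  nb_ref <- nb_tab$net_benefit[nb_tab$strategy == design$reference]
  nb_all <- nb_tab$net_benefit[nb_tab$strategy == "treat_all"]
  net_reduction <- net_reduction_per_100(nb_ref, nb_all, design$threshold)

  chart_model <- models[[design$reference]]
  chart <- if (length(setdiff(model_variables(chart_model), c("sbp", "gcs")))) {
    NULL
  } else {
    build_chart(chart_model, cutoff = design$threshold)
  }

  log <- list(
    seed = design$seed,
    split_date = as.character(design$split_date),
    knot_scheme = design$knot_scheme,
    event_cap = design$event_cap,
    m = list(updating = imp_u$m, validation = imp_v$m,
             rule = identical(design$m, "rule")),
    n_bootstrap = design$n_bootstrap,
    compare_boot = design$compare_boot,
    threshold = design$threshold,
    intercept_handling = "re-estimated after uniform shrinkage of the slopes",
    pooling = "median and IQR across imputations; coefficients pooled by mean",
    provenance = "all coefficients, knots and shrinkage factors estimated on the updating period only"
  )

  structure(
    list(design = design,
         samples = list(
           n_updating = nrow(updating), n_validation = nrow(validation),
           events_updating = sum(updating$early_death),
           events_validation = sum(validation$early_death),
           incomplete_updating = frac_u, incomplete_validation = frac_v,
           m_updating = imp_u$m, m_validation = imp_v$m
         ),
         models = models, shrinkage = shrinkage,
         performance = performance, calibration = calibration,
         decision = decision, net_reduction = net_reduction,
         chart = chart, log = log),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  s <- x$samples
  cat("<study_report>\n")
  cat(sprintf("  updating: n = %d (%d events), m = %d imputations\n",
              s$n_updating, s$events_updating, s$m_updating))
  cat(sprintf("  validation: n = %d (%d events), m = %d imputations\n",
              s$n_validation, s$events_validation, s$m_validation))
  cat(sprintf("  shrinkage factors: %s\n",
              paste(sprintf("%s=%.3f", names(x$models),
                            vapply(x$models, `[[`, numeric(1), "shrinkage_factor")),
                    collapse = ", ")))
  print(x$performance)
  cat(sprintf("  net benefit (reference) at p_t = %.2f: %.4f; %d unnecessary surveys avoided per 100 patients\n",
              x$design$threshold,
              x$decision$table$net_benefit[
                x$decision$table$threshold == x$design$threshold &
                  x$decision$table$strategy == x$design$reference],
              x$net_reduction$count))
  invisible(x)
}

#' Write a study report bundle to a directory
#'
#' Emits, as plain text: one model-specification file per model, the pooled
#' and per-imputation performance tables, the comparison table, the
#' predicted-probability summary, per-model calibration tables, the
#' decision-curve table, the chart grid (plus PNG) and a YAML run log.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory (created if needed).
#' @param image Also render the chart PNG (default `TRUE`).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir, image = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "models"), showWarnings = FALSE)
  for (nm in names(report$models)) {
    write_model_spec(report$models[[nm]],
                     file.path(dir, "models", paste0(nm, ".yaml")))
  }
  utils::write.csv(report$performance$pooled,
                   file.path(dir, "performance_pooled.csv"), row.names = FALSE)
  utils::write.csv(report$performance$per_imputation,
                   file.path(dir, "performance_per_imputation.csv"),
                   row.names = FALSE)
  if (!is.null(report$performance$comparisons)) {
    utils::write.csv(report$performance$comparisons,
                     file.path(dir, "comparisons.csv"), row.names = FALSE)
  }
  utils::write.csv(report$performance$predicted,
                   file.path(dir, "predicted_probabilities.csv"),
                   row.names = FALSE)
  for (nm in names(report$calibration)) {
    utils::write.csv(report$calibration[[nm]]$groups,
                     file.path(dir, paste0("calibration_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$decision$table,
                   file.path(dir, "decision_curve.csv"), row.names = FALSE)
  if (!is.null(report$chart)) {
    render_chart(report$chart, file.path(dir, "risk_chart"), image = image)
  }
  yaml::write_yaml(c(report$log, list(
    n_updating = report$samples$n_updating,
    n_validation = report$samples$n_validation,
    events_validation = report$samples$events_validation,
    net_reduction_per_100 = report$net_reduction$count
  )), file.path(dir, "run_log.yaml"))
  invisible(dir)
}
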