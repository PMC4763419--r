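#' Colour-coded bedside risk chart
#'
#' A two-predictor model (systolic blood pressure and Glasgow coma scale)
#' can be turned into a lookup chart usable by anyone in the trauma
#' receiving area without calculation: predicted early-mortality probability
#' and a colour-coded triage category for every SBP-bin / GCS cell. A binary
#' variant flags the cells whose predicted probability reaches the survey
#' cutoff (default 0.05).
#'
#' @name charting
NULL

#' Build a risk chart from a two-predictor model
#'
#' Evaluates the model at every (SBP bin midpoint, GCS value) cell. Chart
#' probabilities are exactly `predict_probability(linear_predictor(...))` at
#' the cell: the chart is a cache of the model, never a reimplementation.
#'
#' @param model A fitted `"model_spec"` depending only on `sbp` and `gcs`.
#' @param sbp_bins Ordered bin edges in mmHg (default 10-mmHg bins, 50--220).
#' @param gcs_values Integer GCS axis (default 3--15).
#' @param cutoff Probability cutoff for the binary survey flag.
#' @param bands Increasing interior band edges for the colour categories
#'   (default 0.05 and 0.20).
#' @param band_labels One label per band (default green/yellow/red: below
#'   0.05; 0.05 to below 0.20; 0.20 and above).
#' @return An object of class `"risk_chart"`: list with `sbp_edges`,
#'   `sbp_mid`, `gcs`, `probability` (matrix, rows = GCS, columns = SBP
#'   bins), `category` (character matrix), `survey` (logical matrix),
#'   `cutoff`, `bands`, `band_labels`, `model_name`.
#' @export
build_chart <- function(model, sbp_bins = seq(50, 220, by = 10),
                        gcs_values = 3:15, cutoff = 0.05,
                        bands = c(0.05, 0.20),
                        band_labels = c("green", "yellow", "red")) {
  extra <- setdiff(model_variables(model), c("sbp", "gcs"))
  if (length(extra)) {
    stop("a risk chart is only defined for models in SBP and GCS; model '",
         model$name, "' also requires: ", paste(extra, collapse = ", "))
  }
  if (!is_fitted(model)) stop("model must be fitted before charting")
  stopifnot(length(sbp_bins) >= 2L, all(diff(sbp_bins) > 0),
            all(diff(bands) > 0), length(band_labels) == length(bands) + 1L)
  mids <- (sbp_bins[-1] + sbp_bins[-length(sbp_bins)]) / 2
  cells <- expand.grid(gcs = gcs_values, sbp = mids)
  p <- predict_probability(linear_predictor(model, cells))
  prob <- matrix(p, nrow = length(gcs_values), ncol = length(mids),
                 dimnames = list(
                   gcs = gcs_values,
                   sbp = sprintf("%g-%g", sbp_bins[-length(sbp_bins)], sbp_bins[-1])
                 ))
  category <- matrix(
    as.character(cut(prob, breaks = c(0, bands, 1), labels = band_labels,
                     right = FALSE, include.lowest = TRUE)),
    nrow = nrow(prob), dimnames = dimnames(prob)
  )
  structure(
    list(sbp_edges = sbp_bins, sbp_mid = mids, gcs = gcs_values,
         probability = prob, category = category,
         survey = prob >= cutoff, cutoff = cutoff,
         bands = bands, band_labels = band_labels,
         model_name = model$name),
    class = "risk_chart"
  )
}

#' @export
print.risk_chart <- function(x, ...) {
  cat(sprintf("<risk_chart> model '%s': %d GCS rows x %d SBP bins, cutoff %.2f\n",
              x$model_name, length(x$gcs), length(x$sbp_mid), x$cutoff))
  cat("  categories:", paste(x$band_labels, collapse = " / "),
      "at edges", paste(x$bands, collapse = ", "), "\n")
  invisible(x)
}

# text form: one row per GCS (high to low), cells "probability|category"
chart_grid <- function(chart) {
  ord <- order(chart$gcs, decreasing = TRUE)
  cells <- matrix(
    sprintf("%.6f|%s", chart$probability[ord, , drop = FALSE],
            chart$category[ord, , drop = FALSE]),
    nrow = length(chart$gcs), dimnames = list(NULL, colnames(chart$probability))
  )
  data.frame(gcs = chart$gcs[ord], cells, check.names = FALSE)
}

#' Render a chart to an image and a plain-text grid
#'
#' Writes a colour-tile image (`<path>.png`) and a lossless tab-separated
#' grid (`<path>.tsv`, rows = GCS from 15 down, columns = SBP bins, cells =
#' `probability|category`) that [parse_chart_grid()] reads back.
#'
#' @param chart A `"risk_chart"`.
#' @param path Output path without extension.
#' @param image Logical; also write the PNG (default `TRUE`).
#' @return Named character vector of the files written, invisibly.
#' @export
render_chart <- function(chart, path, image = TRUE) {
  grid_path <- paste0(path, ".tsv")
  utils::write.table(chart_grid(chart), grid_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  written <- c(grid = grid_path)
  if (image) {
    img_path <- paste0(path, ".png")
    ggplot2::ggsave(img_path, plot = plot(chart), width = 9, height = 5,
                    dpi = 150)
    written <- c(written, image = img_path)
  }
  invisible(written)
}

#' Read back a rendered chart grid
#'
#' @param path Path to a `.tsv` written by [render_chart()].
#' @return Data frame in the same layout as the rendered grid.
#' @export
parse_chart_grid <- function(path) {
  utils::read.delim(path, check.names = FALSE, colClasses = "character")
}

#' Plot a risk chart as colour-coded tiles
#'
#' @param x A `"risk_chart"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.risk_chart <- function(x, ...) {
  df <- expand.grid(gcs = x$gcs, bin = seq_along(x$sbp_mid))
  df$probability <- as.vector(x$probability)
  df$category <- factor(as.vector(x$category), levels = x$band_labels)
  df$bin_label <- factor(colnames(x$probability)[df$bin],
                         levels = colnames(x$probability))
  fills <- stats::setNames(
    grDevices::hcl.colors(length(x$band_labels), "RdYlGn", rev = TRUE),
    x$band_labels
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_label, y = .data$gcs,
                                   fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$probability)),
                       size = 2.4) +
    ggplot2::scale_fill_manual(values = fills) +
    ggplot2::scale_y_continuous(breaks = x$gcs) +
    ggplot2::labs(x = "Systolic blood pressure (mmHg)",
                  y = "Glasgow coma scale",
                  fill = "Triage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
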