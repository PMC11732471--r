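# Figures and formatted tables for a fitted curve. Interval plots show, per
# candidate sample size, a random handful of individual permutation HDCIs
# next to the average interval; proportion plots show the fraction of the k
# intervals excluding zero. Default colours are from the Okabe-Ito palette.

#' Interval plot: individual and average HDCIs per sample size
#'
#' For each grid sample size, plots the `display_count` randomly selected
#' individual intervals (light colour) beside the average of all k intervals
#' (dark colour, larger glyph), with a horizontal reference line at zero.
#'
#' @param curve An `hdci_curve` from [run_curve()].
#' @param color_cells,color_mean Colours for individual and average
#'   intervals.
#' @return A ggplot object.
#' @export
plot_intervals <- function(curve, color_cells = "#56B4E9",
                           color_mean = "#D55E00") {
  grid <- curve$grid
  gpos <- stats::setNames(seq_along(grid), grid)
  disp <- curve$display
  m <- curve$config$display_count
  layers <- list()
  if (nrow(disp) > 0) {
    disp <- disp |>
      dplyr::group_by(.data$n) |>
      dplyr::mutate(slot = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::mutate(x = gpos[as.character(.data$n)] - 0.38 +
                      0.6 * (.data$slot - 1) / max(1, m - 1))
    layers <- c(layers, list(
      ggplot2::geom_pointrange(
        data = disp,
        ggplot2::aes(x = .data$x, y = .data$point,
                     ymin = .data$lower, ymax = .data$upper),
        colour = color_cells, linewidth = 0.4, size = 0.25)))
  }
  avg <- curve$summary |>
    dplyr::mutate(x = gpos[as.character(.data$n)] + 0.32)
  ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    layers +
    ggplot2::geom_pointrange(
      data = avg,
      ggplot2::aes(x = .data$x, y = .data$mean_point,
                   ymin = .data$mean_lower, ymax = .data$mean_upper),
      colour = color_mean, linewidth = 0.8, size = 0.5) +
    ggplot2::scale_x_continuous(breaks = seq_along(grid), labels = grid) +
    ggplot2::labs(x = "sample size", y = estimator_label(curve),
                  title = curve$name) +
    ggplot2::theme_minimal()
}

#' Proportion plot: fraction of intervals excluding zero per sample size
#'
#' @inheritParams plot_intervals
#' @param color Line/point colour.
#' @return A ggplot object with the y axis fixed to \[0, 1\].
#' @export
plot_proportions <- function(curve, color = "#D55E00") {
  ggplot2::ggplot(curve$summary,
                  ggplot2::aes(x = .data$n, y = .data$prop_excluding_zero)) +
    ggplot2::geom_line(colour = color) +
    ggplot2::geom_point(colour = color, size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "sample size", y = "proportion of intervals excluding 0",
                  title = curve$name) +
    ggplot2::theme_minimal()
}

estimator_label <- function(curve) {
  if (curve$config$estimator == "corr") {
    "Pearson correlation with covariate"
  } else if (curve$config$boot$statistic == "mean_diff") {
    "mean condition difference"
  } else {
    "Cohen's d"
  }
}

#' Formatted summary table of a curve
#'
#' One row per grid sample size with the printed-style cell text
#' `"P (L, U), n = <n>"` — values rounded to two decimals, half away from
#' zero, trailing zeros dropped (0.80 renders "0.8") — alongside the
#' full-precision numeric columns.
#'
#' @param curve An `hdci_curve`.
#' @return A tibble with columns `n`, `label`, `mean_point`, `mean_lower`,
#'   `mean_upper`, `prop_excluding_zero`.
#' @export
summary_table <- function(curve) {
  s <- curve$summary
  if (nrow(s) == 0) abort_hdcurve("empty curve", "config_error")
  tibble::tibble(
    n = s$n,
    label = mapply(format_estimate, s$mean_point, s$mean_lower, s$mean_upper,
                   s$n),
    mean_point = s$mean_point,
    mean_lower = s$mean_lower,
    mean_upper = s$mean_upper,
    prop_excluding_zero = s$prop_excluding_zero)
}

#' Format an interval the way results tables print it
#'
#' @param point,lower,upper Estimate and interval bounds.
#' @param n Optional sample size appended as `", n = <n>"`.
#' @return A string such as `"0.46 (0.22, 0.7), n = 72"`.
#' @export
format_estimate <- function(point, lower, upper, n = NULL) {
  txt <- sprintf("%s (%s, %s)", fmt_num(point), fmt_num(lower),
                 fmt_num(upper))
  if (!is.null(n)) txt <- sprintf("%s, n = %d", txt, as.integer(n))
  txt
}

# two decimals, half away from zero, trailing zeros dropped
fmt_num <- function(x) {
  r <- sign(x) * floor(abs(x) * 100 + 0.5) / 100
  if (r == 0) return("0")
  s <- sprintf("%.2f", r)
  s <- sub("0$", "", s)
  sub("\\.0$", "", s)
}

#' Write curve results to CSV
#'
#' Writes `"<prefix>_summary.csv"` (one row per grid n: `n`, `mean_point`,
#' `mean_lower`, `mean_upper`, `prop_excluding_zero`) and
#' `"<prefix>_cells.csv"` (`perm`, `n`, `point`, `lower`, `upper`), both with
#' headers at full precision.
#'
#' @param curve An `hdci_curve`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"curve"`.
#' @return Invisibly, the two file paths.
#' @export
write_curve_csvs <- function(curve, dir, prefix = "curve") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(dir, paste0(prefix, "_summary.csv"))
  cells_path <- file.path(dir, paste0(prefix, "_cells.csv"))
  readr::write_csv(curve$summary[, c("n", "mean_point", "mean_lower",
                                     "mean_upper", "prop_excluding_zero")],
                   summary_path, progress = FALSE)
  readr::write_csv(curve$cells[, c("perm", "n", "point", "lower", "upper")],
                   cells_path, progress = FALSE)
  invisible(c(summary = summary_path, cells = cells_path))
}
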