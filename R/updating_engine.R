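# The core procedure: to account for the arbitrary order of participants in
# an existing dataset, participant order is permuted k times; within each
# permutation the first n records emulate a study that stopped at sample size
# n (subsets are nested across n, mirroring accrual). Per grid size the k
# HDCIs are averaged and the proportion excluding zero is recorded.

#' Engine configuration
#'
#' @param n_min Smallest sample size on the grid (default 20; must be >= 2,
#'   or >= 4 for the correlation estimator).
#' @param grid Ordered integer vector of candidate sample sizes; defaults to
#'   [default_grid()] over `n_min..N` when `NULL`.
#' @param k Number of participant-order permutations (default 1000).
#' @param seed Master seed. Independent substreams are derived from it for
#'   (a) the permutations, (b) the per-cell bootstraps and (c) the display
#'   selection, so changing `display_count` cannot perturb the estimates.
#' @param estimator `"diff"` (paired condition difference; Cohen's d or raw
#'   mean difference per `boot`) or `"corr"` (Pearson correlation of the
#'   condition difference with the covariate).
#' @param display_count Number of individual intervals per sample size kept
#'   for display (default 10).
#' @param boot A [bootstrap_config()] used by the `"diff"` estimator.
#' @param nested If `TRUE` (default) the n-subset is the first n records of
#'   the same shuffled order for every grid size; if `FALSE` each cell draws
#'   an independent subsample of size n.
#' @param n_max Optional maximum achievable sample size, used by
#'   [monitor_update()] to flag that updating is finished.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(n_min = 20L, grid = NULL, k = 1000L, seed = 1L,
                          estimator = c("diff", "corr"), display_count = 10L,
                          boot = bootstrap_config(), nested = TRUE,
                          n_max = NULL) {
  estimator <- match.arg(estimator)
  n_min <- as.integer(n_min)
  k <- as.integer(k)
  floor_n <- if (estimator == "corr") 4L else 2L
  if (n_min < floor_n) {
    abort_hdcurve(sprintf("n_min must be >= %d for estimator '%s'",
                          floor_n, estimator), "config_error")
  }
  if (k < 1) abort_hdcurve("k must be >= 1", "config_error")
  if (!is.null(grid)) {
    grid <- as.integer(grid)
    if (length(grid) < 1 || any(diff(grid) <= 0)) {
      abort_hdcurve("grid must be strictly increasing", "config_error")
    }
    if (min(grid) < floor_n) {
      abort_hdcurve("grid entries are too small for the estimator",
                    "config_error")
    }
  }
  if (display_count < 0) abort_hdcurve("display_count must be >= 0",
                                       "config_error")
  structure(list(n_min = n_min, grid = grid, k = k, seed = as.integer(seed),
                 estimator = estimator,
                 display_count = as.integer(display_count),
                 boot = boot, nested = isTRUE(nested),
                 n_max = if (!is.null(n_max)) as.integer(n_max)),
            class = "engine_config")
}

#' Default sample-size grid
#'
#' Five candidate sizes: the minimum, then steps of one fifth of the
#' remaining range (`s = round((N - n_min) / 5)`, half away from zero), ending
#' at the full sample. For example `default_grid(20, 271)` gives
#' 20, 70, 120, 170, 271.
#'
#' @param n_min Smallest size (default 20).
#' @param N Total sample size available.
#' @return Strictly increasing integer vector (duplicates collapsed).
#' @export
default_grid <- function(n_min = 20L, N) {
  n_min <- as.integer(n_min); N <- as.integer(N)
  if (n_min >= N) abort_hdcurve("n_min must be smaller than N", "config_error")
  s <- round_half_away((N - n_min) / 5)
  unique(as.integer(c(n_min + s * 0:3, N)))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Run the permutation-subsampling curve
#'
#' Draws `cfg$k` uniform random permutations of the participants; for each
#' permutation and each grid size n computes the HDCI on the first n records
#' of that permutation (so at `n = N` every permutation contains the same
#' records). Cells on which the estimator is degenerate are flagged, logged
#' and excluded from the per-size averages.
#'
#' @param ds An [roi_dataset()] (the `"corr"` estimator requires a fully
#'   present covariate channel; run [validate_covariate()] first if needed).
#' @param cfg An [engine_config()].
#' @return An object of class `hdci_curve`: a list with
#'   \describe{
#'     \item{summary}{tibble, one row per grid n: `n`, `mean_point`,
#'       `mean_lower`, `mean_upper`, `prop_excluding_zero`, `n_degenerate`.}
#'     \item{cells}{tibble of all k x length(grid) cells: `perm`, `n`,
#'       `point`, `lower`, `upper`, `excludes_zero`, `degenerate`.}
#'     \item{display}{the reproducible random subset of `display_count` cells
#'       per n used for plotting.}
#'     \item{config, name}{the configuration and dataset label.}
#'   }
#' @export
run_curve <- function(ds, cfg = engine_config()) {
  N <- nrow(ds)
  if (cfg$estimator == "corr") ds <- require_covariate(ds)
  grid <- cfg$grid %||% default_grid(cfg$n_min, N)
  if (max(grid) > N) {
    abort_hdcurve("grid exceeds the available sample size", "config_error")
  }
  seeds <- derive_substream_seeds(cfg$seed)
  k <- cfg$k
  ng <- length(grid)

  set.seed(seeds[["perm"]])
  perms <- replicate(k, sample.int(N))
  dim(perms) <- c(N, k)

  x <- ds$value_a
  y <- ds$value_b
  dvec <- x - y
  cov <- if (cfg$estimator == "corr") ds$covariate

  n_cells <- k * ng
  point <- lower <- upper <- rep(NA_real_, n_cells)
  degen <- logical(n_cells)

  set.seed(seeds[["boot"]])
  cell <- 0L
  for (p in seq_len(k)) {
    ord <- perms[, p]
    for (j in seq_len(ng)) {
      n <- grid[j]
      idx <- if (cfg$nested) ord[seq_len(n)] else sample.int(N, n)
      cell <- cell + 1L
      est <- tryCatch({
        if (cfg$estimator == "diff") {
          bootstrap_hdci(x[idx], y[idx], cfg$boot)
        } else {
          flat_prior_hdci_r(pearson_r(dvec[idx], cov[idx]), n,
                            level = cfg$boot$level)
        }
      }, hdcurve_degenerate_data_error = function(e) NULL)
      if (is.null(est)) {
        degen[cell] <- TRUE
      } else {
        point[cell] <- est$point
        lower[cell] <- est$lower
        upper[cell] <- est$upper
      }
    }
  }

  cells <- tibble::tibble(
    perm = rep(seq_len(k), each = ng),
    n = rep(grid, times = k),
    point = point, lower = lower, upper = upper,
    excludes_zero = !degen & (lower > 0 | upper < 0),
    degenerate = degen)

  n_degenerate_total <- sum(degen)
  if (n_degenerate_total > 0) {
    message(sprintf(
      "run_curve: %d degenerate cell(s) excluded from aggregation",
      n_degenerate_total))
  }

  summary <- cells |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(
      mean_point = mean(.data$point[!.data$degenerate]),
      mean_lower = mean(.data$lower[!.data$degenerate]),
      mean_upper = mean(.data$upper[!.data$degenerate]),
      prop_excluding_zero = sum(.data$excludes_zero) / k,
      n_degenerate = sum(.data$degenerate),
      .groups = "drop") |>
    dplyr::arrange(.data$n)

  set.seed(seeds[["display"]])
  display <- if (cfg$display_count > 0) {
    chosen <- lapply(grid, function(n) {
      tibble::tibble(n = n,
                     perm = sort(select_display_perms(k, cfg$display_count)))
    })
    dplyr::inner_join(dplyr::bind_rows(chosen), cells, by = c("perm", "n"))
  } else {
    cells[0, ]
  }

  structure(list(summary = summary, cells = cells, display = display,
                 config = cfg, grid = grid, name = roi_name(ds)),
            class = "hdci_curve")
}

# One master seed spawns named substreams so that options affecting one stage
# (e.g. display_count) cannot perturb another.
derive_substream_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  names(s) <- c("perm", "boot", "display")
  s
}

select_display_perms <- function(k, m) {
  if (m > k) abort_hdcurve("display_count cannot exceed k", "config_error")
  sample.int(k, m)
}

#' @export
print.hdci_curve <- function(x, ...) {
  cat(sprintf("<hdci_curve> %s (estimator: %s, k = %d)\n",
              x$name, x$config$estimator, x$config$k))
  print(summary_table(x))
  invisible(x)
}

#' Proportion of intervals excluding zero
#'
#' The empirical analogue of power used throughout: the fraction of
#' permutation HDCIs at one sample size whose bounds both lie on one side of
#' zero (strict inequalities; degenerate cells never count as excluding).
#'
#' @param cells A tibble of cells with `lower` and `upper` columns (e.g., a
#'   single-n slice of `curve$cells`).
#' @return Fraction in \[0, 1\].
#' @export
proportion_excluding_zero <- function(cells) {
  if (nrow(cells) == 0) {
    abort_hdcurve("no cells supplied", "config_error")
  }
  ok <- !is.na(cells$lower) & !is.na(cells$upper)
  sum(ok & (cells$lower > 0 | cells$upper < 0)) / nrow(cells)
}

#' Select display cells
#'
#' Uniform sample without replacement of `m` of the k cells at one sample
#' size, reproducible from the seed in force.
#'
#' @param cells Tibble of cells at a single n.
#' @param m Number of cells to select (`m <= nrow(cells)`).
#' @param seed Optional integer seed.
#' @return A tibble of `m` rows.
#' @export
select_display <- function(cells, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (m > nrow(cells)) {
    abort_hdcurve("cannot display more cells than were computed",
                  "config_error")
  }
  cells[sort(sample.int(nrow(cells), m)), , drop = FALSE]
}

#' Monitoring update: recompute the current HDCI as data accrue
#'
#' The sequential use of the method during data collection: append newly
#' collected records to the accumulated sample and recompute the single
#' current-data HDCI (no permutation). Updating is finished when the interval
#' excludes zero or the maximum achievable sample size (`cfg$n_max`) has been
#' reached.
#'
#' @param accumulated An [roi_dataset()] of the data so far.
#' @param new_records A data frame with columns `value_a`, `value_b` and,
#'   when the correlation estimator is used, `covariate`; may be empty.
#' @param cfg An [engine_config()]; `seed`, `estimator`, `boot` and `n_max`
#'   are used.
#' @return A list of class `monitor_result`: `interval` (the current
#'   [interval_estimate()]), `excludes_zero`, `max_reached`, `finished`, and
#'   `data` (the combined `roi_dataset` for the next update).
#' @export
monitor_update <- function(accumulated, new_records, cfg = engine_config()) {
  need <- c("value_a", "value_b",
            if (cfg$estimator == "corr") "covariate")
  new_records <- tibble::as_tibble(new_records)
  if (nrow(new_records) > 0 && !all(need %in% names(new_records))) {
    abort_hdcurve(sprintf("new records must carry columns: %s",
                          paste(need, collapse = ", ")), "pairing_error")
  }
  old <- tibble::as_tibble(accumulated)
  if (cfg$estimator == "corr" && !"covariate" %in% names(old)) {
    abort_hdcurve("accumulated data lack the covariate the estimator needs",
                  "config_error")
  }
  if (nrow(new_records) > 0) {
    ids <- if ("participant_id" %in% names(new_records)) {
      new_records$participant_id
    } else {
      paste0("new_", nrow(old) + seq_len(nrow(new_records)))
    }
    new_records <- new_records[, intersect(names(old), names(new_records))]
    new_records$participant_id <- as.character(ids)
    combined <- dplyr::bind_rows(old, new_records)
  } else {
    combined <- old
  }
  ds <- roi_dataset(combined$value_a, combined$value_b,
                    covariate = if ("covariate" %in% names(combined))
                      combined$covariate,
                    participant_id = combined$participant_id,
                    name = roi_name(accumulated))
  n <- nrow(ds)
  set.seed(cfg$seed)
  interval <- if (cfg$estimator == "diff") {
    bootstrap_hdci(ds$value_a, ds$value_b, cfg$boot)
  } else {
    flat_prior_hdci_r(pearson_r(ds$value_a - ds$value_b, ds$covariate), n,
                      level = cfg$boot$level)
  }
  excl <- excludes_zero(interval)
  max_reached <- !is.null(cfg$n_max) && n >= cfg$n_max
  structure(list(interval = interval, excludes_zero = excl,
                 max_reached = max_reached,
                 finished = excl || max_reached, data = ds),
            class = "monitor_result")
}

#' @export
print.monitor_result <- function(x, ...) {
  print(x$interval)
  cat(sprintf("updating %s\n",
              if (x$finished) "finished" else "continues: collect more data"))
  invisible(x)
}
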