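# Participant-level ROI summary data: one row per participant, a mean
# activation value for each of two task conditions, and an optional covariate
# (typically age in years). Everything downstream consumes this container.

#' Construct an ROI summary dataset
#'
#' Builds the participant-level container used throughout the package: one row
#' per participant with a mean region-of-interest activation value for each of
#' two task conditions (e.g., GLM parameter estimates for a learning and an
#' application phase) and, optionally, a covariate such as age.
#'
#' @param value_a Numeric vector of condition-A values (finite).
#' @param value_b Numeric vector of condition-B values (finite, same length).
#' @param covariate Optional numeric vector of covariate values. May contain
#'   `NA`; [validate_covariate()] resolves partially observed covariates.
#' @param participant_id Optional vector of unique participant labels.
#'   Synthesised as `1..N` in row order when absent.
#' @param name Free-text label for the dataset (used in plot titles and logs).
#'
#' @return A tibble of class `roi_dataset` with columns `participant_id`,
#'   `value_a`, `value_b` and (if supplied) `covariate`, carrying attributes
#'   `roi_name`, `covariate_status` (`"present"`, `"absent"` or `"mixed"`)
#'   and `n_dropped`.
#' @seealso [read_roi_table()], [validate_covariate()]
#' @export
#' @examples
#' ds <- roi_dataset(value_a = c(1.2, 0.8, 1.5), value_b = c(0.3, 0.4, 0.2))
#' ds
roi_dataset <- function(value_a, value_b, covariate = NULL,
                        participant_id = NULL, name = "ROI dataset") {
  if (length(value_a) != length(value_b)) {
    abort_hdcurve("value_a and value_b must have the same length",
                  "pairing_error")
  }
  value_a <- as.double(value_a)
  value_b <- as.double(value_b)
  if (!all(is.finite(value_a)) || !all(is.finite(value_b))) {
    abort_hdcurve("condition values must be finite", "input_error")
  }
  n <- length(value_a)
  if (n < 2) {
    abort_hdcurve("an ROI dataset needs at least 2 participants",
                  "insufficient_data_error")
  }
  if (is.null(participant_id)) {
    participant_id <- as.character(seq_len(n))
  } else {
    participant_id <- as.character(participant_id)
    if (length(participant_id) != n) {
      abort_hdcurve("participant_id length does not match the data",
                    "pairing_error")
    }
    if (anyDuplicated(participant_id)) {
      abort_hdcurve("participant_id values must be unique", "input_error")
    }
  }
  df <- tibble::tibble(participant_id = participant_id,
                       value_a = value_a, value_b = value_b)
  status <- "absent"
  if (!is.null(covariate)) {
    covariate <- as.double(covariate)
    if (length(covariate) != n) {
      abort_hdcurve("covariate length does not match the data",
                    "pairing_error")
    }
    if (any(is.infinite(covariate))) {
      abort_hdcurve("covariate values must be finite or NA", "input_error")
    }
    n_obs <- sum(!is.na(covariate))
    if (n_obs == 0L) {
      status <- "absent"
    } else {
      df$covariate <- covariate
      status <- if (n_obs == n) "present" else "mixed"
    }
  }
  new_roi_dataset(df, name = name, covariate_status = status)
}

new_roi_dataset <- function(df, name, covariate_status, n_dropped = 0L) {
  structure(df,
            class = c("roi_dataset", class(tibble::tibble())),
            roi_name = name,
            covariate_status = covariate_status,
            n_dropped = as.integer(n_dropped))
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> %s: N = %d, covariate %s\n",
              roi_name(x), nrow(x), covariate_status(x)))
  NextMethod()
}

#' Dataset label
#' @param ds An `roi_dataset`.
#' @return The free-text label the dataset was constructed with.
#' @export
roi_name <- function(ds) attr(ds, "roi_name") %||% "ROI dataset"

#' Covariate channel status
#' @param ds An `roi_dataset`.
#' @return `"present"`, `"absent"`, or `"mixed"` (some rows lack the
#'   covariate; run [validate_covariate()] to resolve).
#' @export
covariate_status <- function(ds) attr(ds, "covariate_status") %||% "absent"

#' Read an ROI summary table from a delimited file
#'
#' Reads a comma-separated table (header row required, `.` decimal separator)
#' of per-participant ROI condition summaries. Rows whose condition values are
#' missing or non-numeric are dropped listwise and the drop count is reported
#' via [message()]. File row order is preserved: the permutation engine, not
#' the reader, randomises participant order.
#'
#' @param path Path to a CSV file.
#' @param col_a,col_b Names of the two condition-value columns.
#' @param col_cov Optional name of a covariate column (e.g., age).
#' @param col_id Optional name of a participant-id column; ids are synthesised
#'   as `1..N` in file order when absent.
#' @param name Dataset label; defaults to the file name.
#' @return An [roi_dataset()].
#' @export
read_roi_table <- function(path, col_a, col_b, col_cov = NULL, col_id = NULL,
                           name = NULL) {
  if (!file.exists(path)) {
    abort_hdcurve(sprintf("input file not found: %s", path), "input_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c(col_a, col_b, col_cov, col_id)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort_hdcurve(sprintf("column(s) not found in %s: %s", path,
                          paste(missing_cols, collapse = ", ")),
                  "schema_error")
  }
  a <- suppressWarnings(as.numeric(raw[[col_a]]))
  b <- suppressWarnings(as.numeric(raw[[col_b]]))
  if (nrow(raw) > 0 && !any(is.finite(a))) {
    abort_hdcurve(sprintf("column '%s' contains no numeric values", col_a),
                  "schema_error")
  }
  if (nrow(raw) > 0 && !any(is.finite(b))) {
    abort_hdcurve(sprintf("column '%s' contains no numeric values", col_b),
                  "schema_error")
  }
  keep <- is.finite(a) & is.finite(b)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("read_roi_table: dropped %d row(s) with missing or ",
                    n_dropped),
            sprintf("non-numeric values in '%s'/'%s'", col_a, col_b))
  }
  if (sum(keep) < 2) {
    abort_hdcurve("fewer than 2 valid rows after filtering",
                  "insufficient_data_error")
  }
  covariate <- if (!is.null(col_cov)) {
    suppressWarnings(as.numeric(raw[[col_cov]]))[keep]
  }
  ids <- if (!is.null(col_id)) raw[[col_id]][keep]
  ds <- roi_dataset(value_a = a[keep], value_b = b[keep],
                    covariate = covariate, participant_id = ids,
                    name = name %||% basename(path))
  attr(ds, "n_dropped") <- as.integer(n_dropped)
  ds
}

#' Write an ROI dataset to CSV
#'
#' Writes the retained records in the same dialect [read_roi_table()] reads
#' (comma-separated, header, full numeric precision), so a write/read round
#' trip reproduces all values exactly.
#'
#' @param ds An `roi_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(ds, path) {
  readr::write_csv(tibble::as_tibble(ds), path, progress = FALSE)
  invisible(path)
}

#' Resolve a partially observed covariate channel
#'
#' If some retained records carry a covariate value and others do not, records
#' lacking it are dropped (listwise, with a logged count); if no record
#' carries one, the channel is marked absent; otherwise the dataset is
#' returned unchanged.
#'
#' @param ds An `roi_dataset`.
#' @return An `roi_dataset` whose covariate channel is either fully present
#'   or absent; the number of rows removed is stored in the
#'   `n_dropped_covariate` attribute.
#' @export
validate_covariate <- function(ds) {
  status <- covariate_status(ds)
  if (status != "mixed") {
    attr(ds, "n_dropped_covariate") <- 0L
    return(ds)
  }
  keep <- !is.na(ds$covariate)
  n_drop <- sum(!keep)
  message(sprintf(
    "validate_covariate: dropped %d record(s) lacking a covariate", n_drop))
  out <- tibble::as_tibble(ds)[keep, , drop = FALSE]
  if (nrow(out) < 2) {
    abort_hdcurve("fewer than 2 records remain with a covariate",
                  "insufficient_data_error")
  }
  out <- new_roi_dataset(out, name = roi_name(ds),
                         covariate_status = "present",
                         n_dropped = attr(ds, "n_dropped") %||% 0L)
  attr(out, "n_dropped_covariate") <- as.integer(n_drop)
  out
}

require_covariate <- function(ds) {
  ds <- validate_covariate(ds)
  if (covariate_status(ds) != "present") {
    abort_hdcurve(
      "a covariate analysis was requested but the dataset has no covariate",
      "config_error")
  }
  ds
}

# Classed conditions so callers can distinguish data problems from usage
# problems; every error the package raises goes through here.
abort_hdcurve <- function(msg, class) {
  rlang::abort(msg, class = c(paste0("hdcurve_", class), "hdcurve_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
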