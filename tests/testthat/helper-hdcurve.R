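# Shared fixture helpers: all test data are generated in code.

write_temp_csv <- function(df, dir = tempdir()) {
  path <- tempfile("roi_", tmpdir = dir, fileext = ".csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}

# a small complete ROI table on disk
small_roi_csv <- function(n = 30, d_true = 0.8, seed = 11, covariate = TRUE) {
  ds <- if (covariate) {
    gen_with_covariate(n, d_true = d_true, r_true = 0.3, seed = seed)
  } else {
    gen_paired(n, d_true = d_true, seed = seed)
  }
  write_temp_csv(tibble::as_tibble(ds))
}
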