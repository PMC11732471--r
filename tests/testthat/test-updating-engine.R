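test_that("default grid steps by one fifth of the remaining range", {
  expect_equal(default_grid(20, 271), c(20, 70, 120, 170, 271))
  expect_equal(default_grid(20, 221), c(20, 60, 100, 140, 221))
  expect_equal(default_grid(20, 149), c(20, 46, 72, 98, 149))
  expect_equal(default_grid(20, 156), c(20, 47, 74, 101, 156))
  expect_equal(default_grid(20, 25), c(20, 21, 22, 23, 25))
  expect_error(default_grid(20, 20), class = "hdcurve_config_error")
})

test_that("a single full-sample cell reproduces the plain estimator", {
  ds <- gen_with_covariate(40, d_true = 0.6, r_true = 0.3, seed = 21)
  # correlation is closed-form and order invariant: exact equality
  cv <- run_curve(ds, engine_config(k = 1, grid = 40L, seed = 5,
                                    estimator = "corr", display_count = 1))
  r_full <- pearson_r(ds$value_a - ds$value_b, ds$covariate)
  expect_identical(cv$summary$mean_point, r_full)
  expect_identical(cv$summary$mean_lower, flat_prior_hdci_r(r_full, 40)$lower)
  # diff estimator: the single cell is the summary
  cv <- run_curve(ds, engine_config(k = 1, grid = 40L, seed = 5,
                                    display_count = 1))
  expect_identical(cv$summary$mean_point, cv$cells$point)
})

test_that("per-size aggregates are exact means of the cells", {
  ds <- gen_paired(60, d_true = 0.5, seed = 3)
  cv <- run_curve(ds, engine_config(k = 30, seed = 9))
  for (nn in cv$grid) {
    sl <- cv$cells[cv$cells$n == nn, ]
    srow <- cv$summary[cv$summary$n == nn, ]
    expect_equal(srow$mean_point, mean(sl$point))
    expect_equal(srow$mean_lower, mean(sl$lower))
    expect_equal(srow$mean_upper, mean(sl$upper))
    expect_equal(srow$prop_excluding_zero,
                 sum(sl$lower > 0 | sl$upper < 0) / 30)
    expect_equal(srow$prop_excluding_zero, proportion_excluding_zero(sl))
  }
})

test_that("proportion excluding zero uses strict one-sided exclusion", {
  cells <- tibble::tibble(lower = c(0.1, -0.1, -0.5, 0, 0.2),
                          upper = c(0.5, 0.5, -0.1, 0.4, 0.9))
  expect_equal(proportion_excluding_zero(cells), 3 / 5)
  expect_equal(proportion_excluding_zero(
    tibble::tibble(lower = rep(0.1, 4), upper = rep(0.5, 4))), 1)
  expect_equal(proportion_excluding_zero(
    tibble::tibble(lower = rep(-0.1, 4), upper = rep(0.5, 4))), 0)
  expect_error(proportion_excluding_zero(cells[0, ]),
               class = "hdcurve_config_error")
})

test_that("display selection is a reproducible sample without replacement", {
  ds <- gen_paired(50, d_true = 0.5, seed = 13)
  cv <- run_curve(ds, engine_config(k = 20, seed = 4, display_count = 10))
  counts <- table(cv$display$n)
  expect_true(all(counts == 10))
  for (nn in cv$grid) {
    expect_false(anyDuplicated(cv$display$perm[cv$display$n == nn]) > 0)
  }
  # asking to display all cells returns all of them
  cells_n <- cv$cells[cv$cells$n == cv$grid[1], ]
  expect_equal(nrow(select_display(cells_n, 20, seed = 1)), 20)
  expect_error(select_display(cells_n, 21), class = "hdcurve_config_error")
  expect_identical(select_display(cells_n, 5, seed = 2),
                   select_display(cells_n, 5, seed = 2))
})

test_that("at the full sample size all correlation cells coincide", {
  ds <- gen_with_covariate(45, d_true = 0.5, r_true = 0.5, seed = 17)
  cv <- run_curve(ds, engine_config(k = 40, seed = 2, estimator = "corr",
                                    display_count = 0))
  full <- cv$cells[cv$cells$n == 45, ]
  expect_equal(length(unique(full$point)), 1)
  expect_equal(length(unique(full$lower)), 1)
  expect_true(cv$summary$prop_excluding_zero[cv$summary$n == 45] %in% c(0, 1))
})

test_that("mean interval width is non-increasing in the sample size", {
  ds <- gen_paired(150, d_true = 0.6, seed = 23)
  cv <- run_curve(ds, engine_config(k = 100, seed = 6, display_count = 0))
  widths <- cv$summary$mean_upper - cv$summary$mean_lower
  expect_true(all(diff(widths) < 0.02))  # strictly shrinking up to MC noise
})

test_that("identical configuration gives a bit-identical curve", {
  ds <- gen_with_covariate(50, d_true = 0.5, r_true = 0.3, seed = 29)
  cfg <- engine_config(k = 25, seed = 77)
  expect_identical(run_curve(ds, cfg), run_curve(ds, cfg))
  # and the estimates do not depend on the display count
  a <- run_curve(ds, engine_config(k = 25, seed = 77, display_count = 0))
  b <- run_curve(ds, engine_config(k = 25, seed = 77, display_count = 5))
  expect_identical(a$summary, b$summary)
})

test_that("engine configuration is validated", {
  expect_error(engine_config(k = 0), class = "hdcurve_config_error")
  expect_error(engine_config(n_min = 1), class = "hdcurve_config_error")
  expect_error(engine_config(n_min = 3, estimator = "corr"),
               class = "hdcurve_config_error")
  expect_error(engine_config(grid = c(20, 20, 30)),
               class = "hdcurve_config_error")
  ds <- gen_paired(30, d_true = 0.5, seed = 1)
  expect_error(run_curve(ds, engine_config(grid = c(20, 40), k = 2)),
               class = "hdcurve_config_error")
  expect_error(run_curve(ds, engine_config(k = 2, estimator = "corr")),
               class = "hdcurve_config_error")  # no covariate channel
})

test_that("monitoring updates recompute the current interval as data accrue", {
  ds <- gen_paired(20, d_true = 0.8, seed = 41)
  cfg <- engine_config(seed = 10, n_max = 30)

  same <- monitor_update(ds, ds[0, ], cfg)
  again <- monitor_update(ds, ds[0, ], cfg)
  expect_identical(same$interval, again$interval)  # identity update
  expect_equal(same$interval$n, 20)
  expect_false(same$max_reached)

  more <- gen_paired(10, d_true = 0.8, seed = 42)
  grown <- monitor_update(ds, tibble::as_tibble(more)[, c("value_a", "value_b")],
                          cfg)
  expect_equal(grown$interval$n, 30)
  expect_true(grown$max_reached)
  expect_true(grown$finished)
  expect_equal(grown$excludes_zero, excludes_zero(grown$interval))

  expect_error(monitor_update(ds, tibble::tibble(value_a = 1), cfg),
               class = "hdcurve_pairing_error")
})

test_that("updates narrow the interval in expectation on a growing stream", {
  set.seed(55)
  widths <- replicate(30, {
    ds <- gen_paired(20, d_true = 0.5, seed = sample.int(1e6, 1))
    add <- gen_paired(10, d_true = 0.5, seed = sample.int(1e6, 1))
    cfg <- engine_config(seed = 1)
    w20 <- with(monitor_update(ds, ds[0, ], cfg)$interval, upper - lower)
    w30 <- with(monitor_update(
      ds, tibble::as_tibble(add)[, c("value_a", "value_b")],
      cfg)$interval, upper - lower)
    c(w20, w30)
  })
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
})
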