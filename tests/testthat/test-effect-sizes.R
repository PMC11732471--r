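test_that("paired Cohen's d matches direct arithmetic", {
  # dz: differences (1, 2, 3) have mean 2 and sample SD 1
  expect_equal(cohens_d_paired(c(2, 4, 6), c(1, 2, 3)), 2.0)
  # symmetric differences give zero under either standardiser
  expect_equal(cohens_d_paired(c(0, 2), c(1, 1), "dz"), 0)
  expect_equal(cohens_d_paired(c(0, 2), c(1, 1), "dav"), 0)

  # dav oracle: independent evaluation of the formula
  x <- c(3, 5, 4, 6); y <- c(1, 2, 2, 3)
  sx <- sqrt(sum((x - mean(x))^2) / 3)
  sy <- sqrt(sum((y - mean(y))^2) / 3)
  expect_equal(cohens_d_paired(x, y, "dav"),
               mean(x - y) / ((sx + sy) / 2))
})

test_that("Cohen's d is shift invariant, and dz scale invariant", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(cohens_d_paired(x + 3.7, y + 3.7),
                 cohens_d_paired(x, y))
    expect_equal(cohens_d_paired(x + 3.7, y + 3.7, "dav"),
                 cohens_d_paired(x, y, "dav"))
    expect_equal(cohens_d_paired(2.5 * x, 2.5 * y),
                 cohens_d_paired(x, y))
  }
})

test_that("Cohen's d raises classed errors on degenerate or unpaired data", {
  expect_error(cohens_d_paired(c(1, 2, 3), c(0, 1, 2)),
               class = "hdcurve_degenerate_data_error")
  expect_error(cohens_d_paired(1:4, 1:3), class = "hdcurve_pairing_error")
  expect_error(cohens_d_paired(1, 2), class = "hdcurve_insufficient_data_error")
})

test_that("bootstrap interval is symmetric around the bootstrap mean", {
  set.seed(7)
  for (stat in c("cohens_d", "mean_diff")) {
    for (i in 1:8) {
      n <- sample(5:40, 1)
      x <- rnorm(n, 0.5); y <- rnorm(n)
      est <- bootstrap_hdci(x, y, bootstrap_config(statistic = stat))
      expect_lt(abs((est$lower + est$upper) / 2 - est$point), 1e-12)
      expect_true(est$lower <= est$point && est$point <= est$upper)
      expect_equal(est$n, n)
    }
  }
})

test_that("bootstrap errors when the statistic is undefined on the data", {
  y <- rnorm(10)
  expect_error(bootstrap_hdci(y + 2, y), # all differences identical
               class = "hdcurve_degenerate_data_error")
})

test_that("bootstrap point estimate is consistent for a known population dz", {
  ds <- gen_paired(5000, d_true = 0.5, seed = 31)
  est <- bootstrap_hdci(ds$value_a, ds$value_b, seed = 32)
  expect_lt(abs(est$point - 0.5), 0.05)
  expect_equal(est$method, "bootstrap_d")
})

test_that("Pearson correlation matches the product-moment formula", {
  u <- rnorm(20)
  expect_equal(pearson_r(u, 2 * u + 1), 1.0)
  # independent arithmetic oracle
  u <- c(1, 2, 3, 4, 5); v <- c(2, 1, 4, 3, 5)
  num <- sum((u - mean(u)) * (v - mean(v)))
  den <- sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(pearson_r(u, v), num / den)
  expect_equal(num / den, 0.8)
  expect_error(pearson_r(u, rep(1, 5)),
               class = "hdcurve_degenerate_data_error")
  expect_error(pearson_r(1:2, 2:1), class = "hdcurve_insufficient_data_error")
})

test_that("flat-prior correlation interval equals the Fisher closed form", {
  z975 <- qnorm(0.975)
  # symmetry at r = 0
  est <- flat_prior_hdci_r(0, 403)
  expect_equal(est$upper, tanh(z975 / 20), tolerance = 1e-12)
  expect_equal(est$lower, -est$upper, tolerance = 1e-12)
  # closed-form oracle at r = 0.5, n = 30
  est <- flat_prior_hdci_r(0.5, 30)
  expect_equal(est$lower, tanh(atanh(0.5) - z975 / sqrt(27)),
               tolerance = 1e-12)
  expect_equal(est$upper, tanh(atanh(0.5) + z975 / sqrt(27)),
               tolerance = 1e-12)
  expect_equal(est$point, 0.5)
  # the full-sample interval before any permutation averaging
  est <- flat_prior_hdci_r(0.38, 271)
  expect_equal(round(est$lower, 2), 0.27)
  expect_equal(round(est$upper, 2), 0.48)
  expect_error(flat_prior_hdci_r(1, 30),
               class = "hdcurve_degenerate_data_error")
  expect_error(flat_prior_hdci_r(0.5, 3),
               class = "hdcurve_insufficient_data_error")
})

test_that("Fisher interval width shrinks with n and grows with level", {
  widths_n <- sapply(c(10, 30, 100, 400), function(n) {
    e <- flat_prior_hdci_r(0.3, n); e$upper - e$lower
  })
  expect_true(all(diff(widths_n) < 0))
  widths_l <- sapply(c(0.8, 0.9, 0.95, 0.99), function(l) {
    e <- flat_prior_hdci_r(0.3, 50, level = l); e$upper - e$lower
  })
  expect_true(all(diff(widths_l) > 0))
})

test_that("bootstrap correlation interval mirrors the d construction", {
  ds <- gen_with_covariate(200, d_true = 0.4, r_true = 0.4, seed = 8)
  est <- bootstrap_hdci_r(ds$value_a - ds$value_b, ds$covariate, seed = 9)
  expect_equal(est$method, "bootstrap_r")
  expect_lt(abs((est$lower + est$upper) / 2 - est$point), 1e-12)
  # agrees with the Fisher interval to within sampling noise
  fisher <- flat_prior_hdci_r(pearson_r(ds$value_a - ds$value_b,
                                        ds$covariate), 200)
  expect_lt(abs(est$point - fisher$point), 0.1)
})
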