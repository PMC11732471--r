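# Seeded generators for synthetic ROI datasets with known population effect
# sizes, structured like extracted per-participant condition summaries: two
# correlated bivariate-normal condition values per participant and an
# optional uniformly distributed covariate (e.g., age) with a controlled
# population correlation to the condition difference.

#' Generate a paired-condition ROI dataset with known population Cohen's d
#'
#' Draws `n` bivariate-normal condition pairs with the requested standard
#' deviations and between-condition correlation, and shifts the condition-A
#' mean by `d_true` times the population SD of the differences, so that the
#' population value of paired Cohen's d (dz variant) equals `d_true` exactly.
#'
#' @param n Number of participants.
#' @param d_true Population dz (mean difference over SD of differences).
#' @param sd_a,sd_b Condition standard deviations (default 1).
#' @param rho_ab Correlation between the two conditions, in (-1, 1)
#'   (default 0.5; repeated measures on the same region are typically
#'   positively correlated, which shrinks the difference SD).
#' @param mean_b Baseline (condition-B) mean, default 0.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param name Dataset label.
#' @return An [roi_dataset()] without covariate.
#' @export
#' @examples
#' ds <- gen_paired(n = 50, d_true = 0.5, seed = 1)
#' cohens_d_paired(ds$value_a, ds$value_b)
gen_paired <- function(n, d_true, sd_a = 1, sd_b = 1, rho_ab = 0.5,
                       mean_b = 0, seed = 1L, name = "synthetic paired") {
  check_paired_spec(sd_a, sd_b, rho_ab)
  set.seed(seed)
  sim <- draw_pairs(n, d_true, sd_a, sd_b, rho_ab, mean_b)
  roi_dataset(sim$a, sim$b, name = name)
}

check_paired_spec <- function(sd_a, sd_b, rho_ab) {
  if (sd_a <= 0 || sd_b <= 0 || abs(rho_ab) >= 1) {
    abort_hdcurve("need sd_a, sd_b > 0 and |rho_ab| < 1", "config_error")
  }
  sd_d <- sqrt(sd_a^2 + sd_b^2 - 2 * rho_ab * sd_a * sd_b)
  if (!is.finite(sd_d) || sd_d <= 0) {
    abort_hdcurve("implied SD of differences is not positive", "config_error")
  }
  sd_d
}

draw_pairs <- function(n, d_true, sd_a, sd_b, rho_ab, mean_b) {
  sd_d <- check_paired_spec(sd_a, sd_b, rho_ab)
  mu <- c(mean_b + d_true * sd_d, mean_b)
  sigma <- matrix(c(sd_a^2, rho_ab * sd_a * sd_b,
                    rho_ab * sd_a * sd_b, sd_b^2), 2, 2)
  ab <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  list(a = ab[, 1], b = ab[, 2], sd_d = sd_d, mu_d = d_true * sd_d)
}

#' Generate a paired dataset with a covariate of known correlation
#'
#' Generates condition pairs as in [gen_paired()], then a covariate that is
#' marginally uniform on `[cov_min, cov_max]` (think ages sampled evenly
#' across a developmental range) and whose population Pearson correlation
#' with the condition difference equals `r_true` exactly. The covariate is
#' built through a Gaussian copula: a latent standard normal mixes the
#' population-standardised condition difference with independent noise at
#' latent correlation `r_true * sqrt(pi / 3)` (the factor undoing the
#' attenuation of the normal-to-uniform transform), and is then mapped
#' through the normal CDF onto the requested range.
#'
#' @inheritParams gen_paired
#' @param r_true Population correlation between the condition difference and
#'   the covariate; attainable range is `|r_true| < sqrt(3 / pi)` (about
#'   0.977).
#' @param cov_min,cov_max Covariate range (default ages 11 and 21).
#' @return An [roi_dataset()] with a fully present covariate channel.
#' @export
gen_with_covariate <- function(n, d_true, r_true, sd_a = 1, sd_b = 1,
                               rho_ab = 0.5, mean_b = 0, cov_min = 11,
                               cov_max = 21, seed = 1L,
                               name = "synthetic paired + covariate") {
  if (abs(r_true) >= 1) {
    abort_hdcurve("|r_true| must be < 1", "config_error")
  }
  attain <- sqrt(3 / pi)
  if (abs(r_true) >= attain) {
    abort_hdcurve(sprintf(
      "|r_true| must be < %.4f for a uniform covariate", attain),
      "config_error")
  }
  if (cov_min >= cov_max) {
    abort_hdcurve("cov_min must be smaller than cov_max", "config_error")
  }
  check_paired_spec(sd_a, sd_b, rho_ab)
  set.seed(seed)
  sim <- draw_pairs(n, d_true, sd_a, sd_b, rho_ab, mean_b)
  dstd <- (sim$a - sim$b - sim$mu_d) / sim$sd_d  # population-standardised
  rho_lat <- r_true * sqrt(pi / 3)
  w <- rho_lat * dstd + sqrt(1 - rho_lat^2) * stats::rnorm(n)
  covariate <- cov_min + (cov_max - cov_min) * stats::pnorm(w)
  roi_dataset(sim$a, sim$b, covariate = covariate, name = name)
}

#' Four synthetic datasets mirroring typical developmental ROI studies
#'
#' A fixed suite of four datasets emulating the structure of commonly studied
#' task/region combinations — feedback learning in the DLPFC, gambling reward
#' in the NAcc, self-evaluation in the mPFC and vicarious reward in the NAcc —
#' with sample sizes 271, 221, 149 and 156, population Cohen's d of 1.87,
#' 0.73, 0.46 and 0.57, population age correlations of 0.38, -0.04, 0.06 and
#' -0.17, and age ranges 8-25, 12-28, 11-21 and 11-21 years.
#'
#' These are synthetic stand-ins whose population parameters match the scale
#' of real effects in that literature; they support end-to-end smoke tests
#' without any data download.
#'
#' @param seed Master seed; each dataset gets an independent derived seed.
#' @return A named list of four [roi_dataset()]s with covariates:
#'   `feedback_dlpfc`, `gambling_nacc`, `self_evaluations_mpfc`,
#'   `vicarious_charity_nacc`.
#' @export
fixture_suite <- function(seed = 1L) {
  specs <- tibble::tibble(
    key = c("feedback_dlpfc", "gambling_nacc", "self_evaluations_mpfc",
            "vicarious_charity_nacc"),
    name = c("Feedback DLPFC (synthetic)", "Gambling NAcc (synthetic)",
             "Self-evaluations mPFC (synthetic)",
             "Vicarious charity NAcc (synthetic)"),
    n = c(271L, 221L, 149L, 156L),
    d_true = c(1.87, 0.73, 0.46, 0.57),
    r_true = c(0.38, -0.04, 0.06, -0.17),
    cov_min = c(8, 12, 11, 11),
    cov_max = c(25, 28, 21, 21))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(specs))
  out <- lapply(seq_len(nrow(specs)), function(i) {
    gen_with_covariate(n = specs$n[i], d_true = specs$d_true[i],
                       r_true = specs$r_true[i], cov_min = specs$cov_min[i],
                       cov_max = specs$cov_max[i], seed = sub_seeds[i],
                       name = specs$name[i])
  })
  names(out) <- specs$key
  out
}
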