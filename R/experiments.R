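# Verification experiments: repeated-simulation studies that close the loop
# between the generator and the analysis layer. These back the analysis
# scripts and the acceptance checks; problem sizes are arguments so desk-scale
# runs and full runs share one code path.

# deterministic sub-seeds derived from one base seed (kept below 2^31)
derive_seeds <- function(base_seed, n) {
  set.seed(base_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Mixed-model parameter recovery under the default experiment
#'
#' Repeatedly simulates the full experiment, runs the needle-trait pipeline,
#' fits the climate mixed model for branch-year mean needle length on the
#' standardized premonsoon/monsoon water-input predictors, and rescales the
#' fixed-effect slopes to mm of needle per mm of water. The recovery target
#' is the unweighted mean of the three generating treatment slopes (random
#' effects are centred on the fixed effect).
#'
#' @param n_seeds number of simulated replicates.
#' @param cfg generator configuration.
#' @param base_seed seed from which per-replicate seeds are derived.
#' @return list with `estimates` (n_seeds x 2), `truth`, `bias_pct`
#'   (percent bias of the mean estimate per predictor).
#' @export
experiment_lmem_recovery <- function(n_seeds = 200L, cfg = sim_config(),
                                     base_seed = 1L) {
  seeds <- derive_seeds(base_seed, n_seeds)
  est <- t(vapply(seeds, function(s) {
    d <- generate_dataset(cfg, seed = s)
    tr <- summarize_traits(d$needles)
    dd <- merge_climate_predictors(tr, d$seasonal)
    f <- fit_lmem(dd, "mean_length_mm", c("ppt_premonsoon", "ppt_monsoon"))
    f$coefficients$estimate[2:3] / f$scaling$sd
  }, numeric(2)))
  colnames(est) <- c("ppt_premonsoon", "ppt_monsoon")
  truth <- c(ppt_premonsoon = mean(cfg$l_coefs$b_pre),
             ppt_monsoon = mean(cfg$l_coefs$b_mon))
  bias <- 100 * (colMeans(est) / truth - 1)
  list(estimates = est, truth = truth, bias_pct = bias)
}

#' Bootstrap confirmation rate of the treatment slope ordering
#'
#' For each simulated replicate, fits the per-treatment needle-length
#' response to its own seasonal water input and runs the branch-resampling
#' bootstrap ordering test for the premonsoon coefficient against the
#' hypothesized ordering (irrigated < ambient < droughted, the buffering of
#' interannual variability by wetter soil).
#'
#' @inheritParams experiment_lmem_recovery
#' @param b bootstrap replicates per treatment per replicate.
#' @param ordering hypothesized increasing ordering of treatments.
#' @return list with `confirmed` (logical per seed), `rate`, and the mean
#'   per-treatment slopes.
#' @export
experiment_slope_ordering <- function(n_seeds = 50L, cfg = sim_config(),
                                      base_seed = 1L, b = 400L,
                                      ordering = c("irrigated", "ambient", "droughted")) {
  seeds <- derive_seeds(base_seed + 1L, n_seeds)
  slopes <- matrix(NA_real_, n_seeds, 3, dimnames = list(NULL, ordering))
  confirmed <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    d <- generate_dataset(cfg, seed = seeds[i])
    tr <- summarize_traits(d$needles)
    dd <- merge_climate_predictors(tr, d$seasonal)
    r <- bootstrap_coef_between_treatments(
      dd, "mean_length_mm", c("ppt_premonsoon", "ppt_monsoon"),
      coef = "ppt_premonsoon", ordering = ordering, b = b, seed = seeds[i] %% 1000L + 1L
    )
    slopes[i, ] <- r$slopes[ordering]
    confirmed[i] <- r$ordering_confirmed
  }
  list(confirmed = confirmed, rate = mean(confirmed),
       mean_slopes = colMeans(slopes))
}

#' Type-I error calibration of the nonparametric tests
#'
#' Simulates the three tests under their null hypotheses and reports the
#' empirical rejection rate at alpha = 0.05: rank-sum on two same-
#' distribution groups, two-sample KS of a year sample against a pooled
#' sample from the same distribution, and the bootstrap zero-intercept slope
#' comparison on two groups generated with identical slopes. Sample sizes
#' are chosen large enough that the discreteness of the exact small-sample
#' tests does not distort the nominal level.
#'
#' @param n_reps replicates per test.
#' @param base_seed RNG seed.
#' @param b bootstrap replicates inside the slope test.
#' @return named numeric vector of empirical type-I rates.
#' @export
experiment_type1 <- function(n_reps = 1000L, base_seed = 1L, b = 999L) {
  set.seed(base_seed + 2L)
  ranksum <- mean(replicate(n_reps, {
    ranksum_pairs(c(stats::rnorm(20), stats::rnorm(20)),
                  rep(c("a", "b"), each = 20))$p_value < 0.05
  }))
  ks <- mean(replicate(n_reps, {
    ks_year_vs_pooled(stats::rnorm(60), stats::rnorm(300))$p_value < 0.05
  }))
  boot <- mean(replicate(n_reps, {
    x1 <- stats::runif(120, 0.5, 1.5); y1 <- 1.5 * x1 + stats::rnorm(120, 0, 0.3)
    x2 <- stats::runif(120, 0.5, 1.5); y2 <- 1.5 * x2 + stats::rnorm(120, 0, 0.3)
    bootstrap_slope_difference(x1, y1, x2, y2, b = b)$significant
  }))
  c(ranksum = ranksum, ks = ks, bootstrap_slope = boot)
}

#' Treatment ordering of mean SA:LA and the extreme-year needle collapse
#'
#' For each simulated replicate, runs the ratio pipeline and checks whether
#' the experiment-period mean SA:LA is ordered irrigated > ambient >
#' droughted; also records, for the droughted treatment, the ratio of mean
#' needle length in the collapse year (2011-like) to the preceding year.
#'
#' @inheritParams experiment_lmem_recovery
#' @return list with `ordering_ok` (logical per seed), `rate`,
#'   `mean_sa_la` (per treatment, averaged over seeds), `collapse_ratio`
#'   (per-seed droughted 2011/2010 needle-length ratio), and
#'   `collapse_drop_pct` (mean percent decline).
#' @export
experiment_sa_la_ordering <- function(n_seeds = 20L, cfg = sim_config(),
                                      base_seed = 1L) {
  seeds <- derive_seeds(base_seed + 3L, n_seeds)
  ord_ok <- logical(n_seeds)
  sal <- matrix(NA_real_, n_seeds, 3,
                dimnames = list(NULL, c("irrigated", "ambient", "droughted")))
  cratio <- rep(NA_real_, n_seeds)
  collapse_year <- 2011
  for (i in seq_len(n_seeds)) {
    d <- generate_dataset(cfg, seed = seeds[i])
    am <- fit_area_model(d$needles)
    audit <- ratio_audit(d$rings, d$needles, am, segments = d$segments)
    ratios <- branch_year_means(audit)
    m <- tapply(ratios$sa_la, ratios$treatment, mean)
    sal[i, ] <- m[colnames(sal)]
    ord_ok[i] <- m[["irrigated"]] > m[["ambient"]] && m[["ambient"]] > m[["droughted"]]
    nd <- d$needles[d$needles$treatment == "droughted", ]
    l11 <- mean(nd$length_mm[nd$year == collapse_year])
    l10 <- mean(nd$length_mm[nd$year == collapse_year - 1])
    if (is.finite(l11) && is.finite(l10) && l10 > 0) cratio[i] <- l11 / l10
  }
  list(ordering_ok = ord_ok, rate = mean(ord_ok), mean_sa_la = colMeans(sal),
       collapse_ratio = cratio,
       collapse_drop_pct = 100 * (1 - mean(cratio, na.rm = TRUE)))
}
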