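# Mixed models: recovery, invariances, R2 decomposition, model search,
# cross-treatment bootstrap.

sim_lmm_data <- function(n_branch = 24, years = 7, beta = c(10, 2, -1),
                         group_dev = c(0, 0, 0), sigma = 0.5, seed = 1) {
  set.seed(seed)
  groups <- rep(c("irrigated", "ambient", "droughted"), length.out = n_branch)
  x1y <- rnorm(years); x2y <- rnorm(years)
  rows <- lapply(seq_len(n_branch), function(b) {
    g <- groups[b]
    gi <- match(g, c("irrigated", "ambient", "droughted"))
    data.frame(branch_id = paste0("b", b), treatment = g, year = seq_len(years),
               x1 = x1y, x2 = x2y,
               y = beta[1] + (beta[2] + group_dev[gi]) * x1y +
                 (beta[3] - group_dev[gi]) * x2y + rnorm(years, 0, sigma))
  })
  do.call(rbind, rows)
}

test_that("fixed effects are recovered within 3 SE when random variance is zero", {
  d <- sim_lmm_data(beta = c(10, 2, -1), sigma = 0.4, seed = 2)
  f <- fit_lmem(d, "y", c("x1", "x2"), standardize = FALSE)
  expect_equal(nrow(d), 168)
  for (k in 2:3) {
    expect_lt(abs(f$coefficients$estimate[k] - c(10, 2, -1)[k]),
              3 * f$coefficients$se[k] + 1e-8)
  }
  expect_lte(f$r2_marginal, f$r2_conditional)
  expect_lte(f$r2_conditional, 1)
})

test_that("fits are invariant to row order and equivariant to response scaling", {
  d <- sim_lmm_data(seed = 3)
  f <- fit_lmem(d, "y", c("x1", "x2"))
  set.seed(4)
  f_perm <- fit_lmem(d[sample(nrow(d)), ], "y", c("x1", "x2"))
  expect_equal(f_perm$coefficients$estimate, f$coefficients$estimate,
               tolerance = 1e-6)
  d10 <- d; d10$y <- 10 * d10$y
  f10 <- fit_lmem(d10, "y", c("x1", "x2"))
  expect_equal(f10$coefficients$estimate, 10 * f$coefficients$estimate,
               tolerance = 1e-4)
})

test_that("variance-partition R2 handles the degenerate corners", {
  # no random structure in the data: marginal ~ conditional
  d <- sim_lmm_data(group_dev = c(0, 0, 0), sigma = 0.3, seed = 5)
  f <- fit_lmem(d, "y", c("x1", "x2"))
  expect_lt(f$r2_conditional - f$r2_marginal, 0.05)
  expect_gt(f$r2_marginal, 0.8)  # strong fixed effects by construction
  # no fixed effects in the data: marginal ~ 0
  d0 <- d; d0$y <- rnorm(nrow(d0))
  f0 <- fit_lmem(d0, "y", c("x1", "x2"))
  expect_lt(f0$r2_marginal, 0.05)
  # strong group structure: conditional clearly above marginal
  dg <- sim_lmm_data(group_dev = c(-2, 0, 2), sigma = 0.3, seed = 6)
  fg <- fit_lmem(dg, "y", c("x1", "x2"))
  expect_gt(fg$r2_conditional, fg$r2_marginal + 0.05)
  # known variance decomposition, zero random variance:
  # R2m = var_fixed / (var_fixed + sigma^2), here ~ (4+1)/(5 + 0.09)
  expect_equal(f$r2_marginal,
               with(list(vf = var(2 * d$x1 - 1 * d$x2)), vf / (vf + 0.3^2)),
               tolerance = 0.08)
})

test_that("the AIC search prefers the generating predictor pair", {
  set.seed(7)
  wins <- 0L; n_rep <- 30L
  for (i in 1:n_rep) {
    cfg <- sim_config()
    d <- generate_dataset(cfg, seed = 7000 + i)
    tr <- summarize_traits(d$needles)
    dd <- merge_climate_predictors(tr, d$seasonal)
    ms <- model_search(dd, "mean_length_mm", lrt = FALSE)
    top <- sort(c(ms$predictor1[1], ms$predictor2[1]))
    wins <- wins + identical(top, c("ppt_monsoon", "ppt_premonsoon"))
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("a pure-noise predictor does not beat AIC's complexity penalty", {
  set.seed(19)
  deltas <- replicate(15, {
    d <- sim_lmm_data(beta = c(5, 1.5, 0), sigma = 0.5,
                      seed = sample.int(1e6, 1))
    d$noise <- rnorm(nrow(d))
    f1 <- lme4::lmer(y ~ x1 + (1 + x1 || treatment), data = d, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    f2 <- fit_lmem(d, "y", c("x1", "noise"), standardize = FALSE)
    f2$aic - AIC(f1)
  })
  expect_gt(mean(deltas), -2)
})

test_that("model_search reports collinearity and ranks by AIC", {
  d <- sim_lmm_data(seed = 8)
  d$x3 <- d$x1 + rnorm(nrow(d), 0, 0.1)  # near-duplicate of x1
  expect_message(
    ms <- model_search(d, "y", candidates = list(c("x1", "x2"), c("x1", "x3"))),
    "collinear"
  )
  expect_true(all(diff(ms$aic) >= 0))
  expect_equal(ms$delta_aic[1], 0)
  expect_true(any(ms$collinear))
  one <- model_search(d, "y", candidates = list(c("x1", "x2")), lrt = FALSE)
  expect_equal(nrow(one), 1)
})

test_that("cross-treatment bootstrap confirms true orderings, not false ones", {
  # true ordering in the generating slopes
  d <- sim_lmm_data(group_dev = c(-1, 0, 1), sigma = 0.3, seed = 9)
  r <- bootstrap_coef_between_treatments(
    d, "y", c("x1", "x2"), coef = "x1",
    ordering = c("irrigated", "ambient", "droughted"), b = 500, seed = 10
  )
  expect_true(r$ordering_confirmed)
  expect_true(all(diff(r$slopes[c("irrigated", "ambient", "droughted")]) > 0))
  # equal generating slopes: rarely confirmed
  set.seed(11)
  hits <- replicate(20, {
    d0 <- sim_lmm_data(group_dev = c(0, 0, 0), sigma = 0.5,
                       seed = sample.int(1e6, 1))
    bootstrap_coef_between_treatments(
      d0, "y", c("x1", "x2"), coef = "x1",
      ordering = c("irrigated", "ambient", "droughted"), b = 199,
      seed = sample.int(1e6, 1)
    )$ordering_confirmed
  })
  expect_lte(mean(hits), 0.1)
  # deterministic under a fixed seed
  r2 <- bootstrap_coef_between_treatments(
    d, "y", c("x1", "x2"), coef = "x1",
    ordering = c("irrigated", "ambient", "droughted"), b = 500, seed = 10
  )
  expect_identical(r$pairs, r2$pairs)
})
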