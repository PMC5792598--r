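# Synthetic experiment generator: construction guarantees, treatment water
# rules, determinism, and the noiseless identifiability of the responses.

test_that("climatology mode with noise off hits the seasonal shares exactly", {
  cfg <- sim_config(climate_mode = "climatology", noise = FALSE)
  set.seed(1)
  daily <- simulate_daily_climate(cfg)
  mo <- as.integer(format(daily$date, "%m"))
  hy <- hydro_year(daily$date)
  for (y in cfg$years) {
    winter <- sum(daily$precip_mm[hy == y & (mo >= 11 | mo <= 2)])
    jassep <- sum(daily$precip_mm[hy == y & mo >= 7 & mo <= 9])
    total <- sum(daily$precip_mm[hy == y])
    expect_equal(total, 355.3, tolerance = 1e-9)
    expect_equal(winter / total, 0.18, tolerance = 1e-9)
    expect_equal(jassep / total, 0.52, tolerance = 1e-9)
  }
})

test_that("climatology mode reproduces the long-run annual mean", {
  cfg <- sim_config(climate_mode = "climatology", years = 1801:2000)
  set.seed(2)
  daily <- simulate_daily_climate(cfg)
  s <- summarize_seasons(daily)
  expect_equal(nrow(s), 200)
  # MC error ~ 83.4/sqrt(200) ~ 5.9 mm; allow 3 SE
  expect_lt(abs(mean(s$ppt_yearly) - 355.3), 18)
})

test_that("anchored mode tracks the per-year anchors and exceedance counts", {
  cfg <- sim_config(noise = FALSE)
  set.seed(3)
  daily <- simulate_daily_climate(cfg)
  s <- summarize_seasons(daily)
  expect_equal(s$ppt_premonsoon, cfg$anchor_ppt_premonsoon, tolerance = 1e-9)
  expect_equal(s$ppt_monsoon, cfg$anchor_ppt_monsoon, tolerance = 1e-9)
  expect_identical(s$vpd_days_dry, cfg$anchor_vpd_days_dry)
  expect_identical(s$vpd_days_monsoon, cfg$anchor_vpd_days_monsoon)
  expect_equal(s$vpd_mean_max_monsoon, cfg$anchor_vpd_monsoon, tolerance = 0.15)
})

test_that("treatment water rules scale, add, and pass through", {
  cfg <- sim_config(noise = FALSE)
  set.seed(4)
  amb <- simulate_daily_climate(cfg)
  expect_identical(apply_treatment_water(amb, "ambient", cfg), amb)
  dro <- apply_treatment_water(amb, "droughted", cfg)
  post <- amb$date >= cfg$exclusion_start
  expect_equal(dro$precip_mm[post], amb$precip_mm[post] * 0.55, tolerance = 1e-12)
  expect_equal(dro$precip_mm[!post], amb$precip_mm[!post])
  expect_equal(dro$vpd_max_kpa, amb$vpd_max_kpa)  # VPD is atmospheric, shared
  irr <- apply_treatment_water(amb, "irrigated", cfg)
  s_amb <- summarize_seasons(amb); s_irr <- summarize_seasons(irr)
  added <- s_irr$ppt_yearly - s_amb$ppt_yearly
  expect_equal(added[s_amb$hydro_year == 2010], 112, tolerance = 1e-9)
  expect_equal(added[s_amb$hydro_year == 2008], 57, tolerance = 1e-9)
  expect_equal(added[s_amb$hydro_year == 2007], 0)
})

test_that("generated tables satisfy the structural invariants", {
  cfg <- sim_config()
  d <- generate_dataset(cfg, seed = 5)
  expect_true(all(d$rings$section_genesis_year <= d$rings$ring_year))
  # apical ring exists for every section
  sections <- unique(d$rings[c("branch_id", "section_genesis_year")])
  has_apical <- mapply(function(b, g) {
    any(d$rings$branch_id == b & d$rings$section_genesis_year == g &
          d$rings$ring_year == g)
  }, sections$branch_id, sections$section_genesis_year)
  expect_true(all(has_apical))
  # cohort arithmetic: measured branches = 10 + 10 + 4*3
  expect_equal(length(unique(d$needles$branch_id)), 32)
  yrs_per_branch <- tapply(d$needles$year, d$needles$branch_id,
                           function(y) length(unique(y)))
  expect_true(all(yrs_per_branch >= 4 & yrs_per_branch <= 7))
  npy <- tapply(d$needles$length_mm,
                paste(d$needles$branch_id, d$needles$year), length)
  expect_true(all(npy >= 1 & npy <= 15))
  # identical VPD series across the three treatment files
  expect_equal(d$climate$irrigated$vpd_max_kpa, d$climate$ambient$vpd_max_kpa)
  expect_equal(d$climate$droughted$vpd_max_kpa, d$climate$ambient$vpd_max_kpa)
})

test_that("the cohort-depth distribution centres near 5.5 years", {
  cfg <- sim_config()
  set.seed(6)
  depths <- replicate(300, {
    as.integer(sample(names(cfg$needle_year_probs), 1,
                      prob = cfg$needle_year_probs))
  })
  expect_lt(abs(mean(depths) - 5.5), 0.2)
})

test_that("the same seed reproduces the dataset and its files byte-identically", {
  cfg <- sim_config()
  d1 <- generate_dataset(cfg, seed = 7)
  d2 <- generate_dataset(cfg, seed = 7)
  expect_identical(d1$needles, d2$needles)
  expect_identical(d1$rings, d2$rings)
  expect_identical(d1$climate, d2$climate)
  o1 <- file.path(tempdir(), "simA"); o2 <- file.path(tempdir(), "simB")
  generate_dataset(cfg, seed = 7, outdir = o1)
  generate_dataset(cfg, seed = 7, outdir = o2)
  for (f in list.files(o1)) {
    expect_identical(unname(tools::md5sum(file.path(o1, f))),
                     unname(tools::md5sum(file.path(o2, f))))
  }
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("noise off + collapse off makes every response exactly linear", {
  cfg <- sim_config(noise = FALSE, collapse_vpd_days_min = Inf,
                    missing_ring_prob = 0)
  d <- generate_dataset(cfg, seed = 8)
  tr <- summarize_traits(d$needles)
  dd <- merge_climate_predictors(tr, d$seasonal)
  # per-treatment OLS recovers the generating needle-length coefficients
  for (t in cfg$treatments) {
    sub <- dd[dd$treatment == t, ]
    fit <- lm(mean_length_mm ~ ppt_premonsoon + ppt_monsoon, data = sub)
    truth <- cfg$l_coefs[cfg$l_coefs$treatment == t, ]
    expect_equal(unname(coef(fit)), c(truth$b0, truth$b_pre, truth$b_mon),
                 tolerance = 1e-9)
    expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)  # noiseless fit
  }
})

test_that("a 2011-like year triggers collapse flags only where water input is low", {
  cfg <- sim_config()
  d <- generate_dataset(cfg, seed = 9)
  flags <- lapply(d$truth$collapse, function(x) x$year[x$collapse])
  expect_identical(flags$ambient, 2011L)
  expect_identical(flags$droughted, 2011L)
  expect_identical(flags$irrigated, integer(0))
  # missing rings occur only in collapse years
  miss <- d$rings[d$rings$missing, ]
  expect_true(all(miss$ring_year == 2011))
})
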