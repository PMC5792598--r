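# Hydro-year labelling, VPD derivation, seasonal aggregation.

test_that("hydro-year boundaries follow the Nov-Oct convention", {
  expect_identical(hydro_year(as.Date("2010-11-01")), 2011L)
  expect_identical(hydro_year(as.Date("2011-10-31")), 2011L)
  expect_identical(hydro_year(as.Date("2011-11-01")), 2012L)
  # a full year maps to exactly two labels, split at Nov 1
  days <- seq(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "day")
  expect_setequal(unique(hydro_year(days)), c(2011L, 2012L))
})

test_that("Tetens-based VPD matches hand-evaluated cases and rejects bad RH", {
  expect_equal(vpd_from_trh(25, 100), 0)
  expect_equal(vpd_from_trh(25, 50), 0.6108 * exp(17.27 * 25 / 262.3) / 2,
               tolerance = 1e-12)
  expect_equal(vpd_from_trh(25, 50), 1.584, tolerance = 1e-3)
  expect_equal(vpd_from_trh(0, 0), 0.6108, tolerance = 1e-12)
  expect_error(vpd_from_trh(25, 120), "rhmin")
  expect_error(vpd_from_trh(80, 50), "tmax")
})

make_daily <- function(from, to, precip = 0, vpd = 1) {
  d <- seq(as.Date(from), as.Date(to), by = "day")
  data.frame(date = d, precip_mm = rep_len(precip, length(d)),
             vpd_max_kpa = rep_len(vpd, length(d)))
}

test_that("cumulative precipitation sums the right windows and flags empties", {
  daily <- make_daily("2010-11-01", "2011-10-31")
  # one premonsoon and one monsoon event
  daily$precip_mm[daily$date == as.Date("2011-01-15")] <- 34.5
  daily$precip_mm[daily$date == as.Date("2011-08-15")] <- 128.5
  expect_equal(as.numeric(cumulative_precip(daily, 2011, "premonsoon")), 34.5)
  expect_equal(as.numeric(cumulative_precip(daily, 2011, "monsoon")), 128.5)
  expect_equal(as.numeric(cumulative_precip(daily, 2011, "yearly")), 163)
  expect_equal(as.numeric(cumulative_precip(make_daily("2010-11-01", "2011-10-31"),
                                            2011, "yearly")), 0)
  expect_error(cumulative_precip(daily, 1999, "yearly"), "no daily records")
})

test_that("VPD exceedance is strict and windows have the right lengths", {
  daily <- make_daily("2010-11-01", "2011-10-31", vpd = 4.5)
  expect_identical(count_vpd_exceedance(daily, 2011, "monsoon"), 0L)
  daily$vpd_max_kpa[] <- 5
  expect_identical(count_vpd_exceedance(daily, 2011, "monsoon"), 123L)  # JASO
  expect_identical(count_vpd_exceedance(daily, 2011, "dry"), 122L)      # MAMJ
  # monotone in the threshold
  set.seed(1)
  daily$vpd_max_kpa <- runif(nrow(daily), 0, 8)
  counts <- vapply(c(2, 4, 4.5, 6), function(th) {
    count_vpd_exceedance(daily, 2011, "monsoon", threshold = th)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(count_vpd_exceedance(daily, 2011, "dry", threshold = -1), "threshold")
})

test_that("summarize_seasons matches a brute-force day classification", {
  set.seed(42)
  daily <- make_daily("2008-11-01", "2011-10-31")
  daily$precip_mm <- rexp(nrow(daily), 1)
  daily$vpd_max_kpa <- runif(nrow(daily), 0, 6)
  s <- summarize_seasons(daily)
  # brute force: loop over days, classify by month
  for (y in s$hydro_year) {
    pre <- 0; mon <- 0; kd <- 0L; km <- 0L
    for (i in seq_len(nrow(daily))) {
      if (hydro_year(daily$date[i]) != y) next
      m <- as.integer(format(daily$date[i], "%m"))
      if (m >= 7 && m <= 10) mon <- mon + daily$precip_mm[i] else pre <- pre + daily$precip_mm[i]
      if (m >= 3 && m <= 6 && daily$vpd_max_kpa[i] > 4.5) kd <- kd + 1L
      if (m >= 7 && m <= 10 && daily$vpd_max_kpa[i] > 4.5) km <- km + 1L
    }
    row <- s[s$hydro_year == y, ]
    expect_equal(row$ppt_premonsoon, pre, tolerance = 1e-12)
    expect_equal(row$ppt_monsoon, mon, tolerance = 1e-12)
    expect_equal(row$ppt_yearly, pre + mon, tolerance = 1e-12)
    expect_identical(row$vpd_days_dry, kd)
    expect_identical(row$vpd_days_monsoon, km)
  }
  # additivity + window partition already implied; coverage flag:
  expect_true(all(s$complete))
  short <- daily[daily$date <= as.Date("2011-03-01"), ]
  s2 <- summarize_seasons(short)
  expect_false(s2$complete[s2$hydro_year == 2011])
})

test_that("period_stats uses complete years and the n-1 SD convention", {
  s <- data.frame(hydro_year = 2007:2009,
                  ppt_premonsoon = c(10, 20, 30),
                  ppt_monsoon = c(5, 5, 5),
                  ppt_yearly = c(15, 25, 35),
                  vpd_days_dry = 0L, vpd_days_monsoon = 0L,
                  vpd_mean_max_dry = 2, vpd_mean_max_monsoon = 3,
                  complete = c(TRUE, TRUE, FALSE))
  p <- period_stats(s)
  expect_equal(p$ppt_premonsoon, c(15, sd(c(10, 20))))
  expect_identical(attr(p, "n_years"), 2L)
  one <- period_stats(s[1, ])
  expect_true(is.na(one$ppt_premonsoon[2]))  # single year: SD undefined
})

test_that("standardization centres on the experimental period and inverts", {
  z <- standardize_series(c(1, 2, 3))
  expect_equal(z$z, c(-1, 0, 1))
  expect_equal(z$z * z$sd + z$mean, c(1, 2, 3))
  expect_error(standardize_series(rep(2, 5)), "constant")
  expect_error(standardize_series(1), "two values")
  vpd <- c(2.92, 2.48, 2.87, 2.90, 3.07, 3.06, 2.42)
  expect_equal(standardize_series(vpd)$mean, 2.82, tolerance = 0.005)
  expect_equal(mean(standardize_series(vpd)$z), 0, tolerance = 1e-12)
  expect_equal(sd(standardize_series(vpd)$z), 1, tolerance = 1e-12)
})
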