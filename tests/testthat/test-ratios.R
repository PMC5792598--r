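# Annual functional ratios: leaf-area cohorts, apical discard, distances,
# branch means, and the brute-force equivalence of the whole chain.

test_that("cohort leaf area doubles areas, converts units, and flags empty years", {
  nd <- toy_needles(years = 2011, n = 4)
  nd$area_adaxial_mm2 <- 50
  m <- structure(list(gamma = 0, alpha = 1, r2 = 1, n = 3), class = "area_model")
  la <- leaf_area_cohort(nd, 2011, m)
  expect_equal(as.numeric(la), 4 * 2 * 50 * 1e-6)
  empty <- leaf_area_cohort(nd, 1999, m)
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "flagged"))
  # additivity: doubling the needle count doubles LA
  la2 <- leaf_area_cohort(rbind(nd, nd), 2011, m)
  expect_equal(as.numeric(la2), 2 * as.numeric(la))
})

test_that("the per-cell ratio converts mm2 to cm2 and rejects zero leaf area", {
  expect_equal(ratio_year_section(0.8, 0.006), 4 / 3, tolerance = 1e-12)
  expect_equal(ratio_year_section(2 * 0.8, 0.006) / 2, ratio_year_section(0.8, 0.006))
  expect_error(ratio_year_section(0.8, 0), "excluded")
})

test_that("apical discard removes exactly the y == Gamma rings", {
  r <- toy_rings(genesis_years = c(2010, 2012), last_year = 2012)
  kept <- drop_apical(r)
  expect_true(all(kept$ring_year > kept$section_genesis_year))
  expect_equal(nrow(r) - nrow(kept), 2)  # one apical per section
  single <- toy_rings(genesis_years = 2012, last_year = 2012)
  expect_equal(nrow(drop_apical(single)), 0)
})

test_that("distance to tip sums segments Gamma..y with the chosen placement", {
  seg <- toy_segments(years = 2008:2012, length_mm = 20)
  expect_equal(distance_to_tip(seg, "t1_b1", 2012, 2010), 0.060)
  expect_equal(distance_to_tip(seg, "t1_b1", 2012, 2012), 0.020)  # apical case
  expect_equal(distance_to_tip(seg, "t1_b1", 2012, 2010, position = "midpoint"),
               0.050)
  # non-decreasing in y at fixed Gamma
  ds <- vapply(2010:2012, distance_to_tip, numeric(1),
               segments = seg, branch_id = "t1_b1", genesis_year = 2010)
  expect_true(all(diff(ds) >= 0))
  expect_error(distance_to_tip(seg, "t1_b1", 2012, 2005), "missing segment")
  expect_error(distance_to_tip(seg, "t1_b1", 2010, 2012), "<=")
})

test_that("branch means average quotients, not quotient of averages", {
  # two sections, same year, unequal distances
  nd <- toy_needles(years = 2012, n = 2)
  nd$area_adaxial_mm2 <- 50  # LA = 2*2*50e-6 = 2e-4 m2
  seg <- data.frame(branch_id = "t1_b1", year = 2008:2012,
                    length_mm = c(50, 50, 50, 100, 50))
  # ratios: SA chosen so sa_la is 1 and 2 cm2/m2
  r <- data.frame(tree_id = "t1", branch_id = "t1_b1",
                  section_genesis_year = c(2011, 2010, 2011, 2010),
                  ring_year = c(2011, 2010, 2012, 2012),
                  ring_area_mm2 = c(9, 9, 1e-4 * 2e-4 * 1e6 / 1e-2, 2e-4 * 2 * 100),
                  missing = FALSE)
  r$ring_area_mm2[3] <- 1 * 2e-4 * 100  # sa_la = 1 for section 2011
  m <- structure(list(gamma = 0, alpha = 1, r2 = 1, n = 3), class = "area_model")
  audit <- ratio_audit(r, nd, m, segments = seg)
  by <- branch_year_means(audit)
  row <- by[by$year == 2012, ]
  expect_equal(row$sa_la, mean(c(1, 2)))
  # d(2012, 2011) = 0.100 + 0.050 = 0.150; d(2012, 2010) = 0.050+0.100+0.050 = 0.200
  avg_quot <- mean(c(1e-4 * 1 / 0.15, 1e-4 * 2 / 0.20))
  quot_avg <- (1e-4 * mean(c(1, 2))) / mean(c(0.15, 0.20))
  expect_equal(row$sa_la_per_d, avg_quot, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(avg_quot, quot_avg)))  # the two conventions differ here
})

test_that("missing rings propagate as absent cells, never zeros", {
  nd <- toy_needles(years = 2010:2012, n = 3)
  r <- toy_rings(genesis_years = 2009, last_year = 2012,
                 area_fun = function(y, g) 1)
  r$missing[r$ring_year == 2011] <- TRUE
  r$ring_area_mm2[r$ring_year == 2011] <- NA
  m <- fit_area_model(nd)
  audit <- ratio_audit(r, nd, m)
  expect_false(2011 %in% audit$ring_year)
  by <- branch_year_means(audit)
  expect_false(2011 %in% by$year)          # omitted, not zero
  expect_true(all(by$sa_la > 0))
})

test_that("pipeline ratios equal a naive triple-loop oracle on random branches", {
  set.seed(23)
  for (rep in 1:100) {
    br <- random_branch(branch_id = paste0("rb", rep))
    m <- structure(list(gamma = 0.1, alpha = 0.7, r2 = 1, n = 10),
                   class = "area_model")
    expected <- oracle_branch_ratios(br$needles, br$rings, br$segments)
    non_apical <- br$rings$ring_year != br$rings$section_genesis_year &
      !br$rings$missing
    if (is.null(expected)) {
      expect_error(ratio_audit(br$rings, br$needles, m, segments = br$segments))
      next
    }
    audit <- ratio_audit(br$rings, br$needles, m, segments = br$segments)
    got <- branch_year_means(audit)
    expect_equal(got$year, expected$year)
    expect_equal(got$sa_la, expected$sa_la, tolerance = 1e-12)
    expect_equal(got$sa_la_per_d, expected$sa_la_per_d, tolerance = 1e-12)
    # post-discard Gamma-consistency
    expect_true(all(audit$ring_year > audit$section_genesis_year))
  }
})

test_that("ratio magnitudes land where the field data does, on defaults", {
  d <- generate_dataset(sim_config(), seed = 31)
  audit <- ratio_audit(d$rings, d$needles, fit_area_model(d$needles),
                       segments = d$segments)
  by <- branch_year_means(audit)
  expect_gt(mean(by$sa_la), 0.5)          # ~1.5 cm2/m2 scale
  expect_lt(mean(by$sa_la), 4)
  expect_gt(mean(by$sa_la_per_d), 5e-4)   # ~1e-3 m2/m3 scale
  expect_lt(mean(by$sa_la_per_d), 1e-2)
})

test_that("the hydraulic gradient diagnostic follows E / (k_S * A_S:A_L)", {
  expect_equal(potential_gradient(0, 2, 0.25), 0)
  expect_equal(potential_gradient(1, 2, 0.25), 2)
  expect_equal(potential_gradient(1, 2, 0.5), 1)  # doubling as_al halves it
  expect_error(potential_gradient(1, 0, 0.5), "> 0")
})
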