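# Shared fixture builders. Everything is generated in code; no stored data.

# A deterministic toy needle table: `n` needles per year, exact allometry
# A_ad = gamma + alpha * l * w unless noise_sd > 0.
toy_needles <- function(years = 2010:2012, n = 6, branch_id = "t1_b1",
                        tree_id = "t1", treatment = "ambient",
                        gamma = 0.1, alpha = 0.7, noise_sd = 0,
                        measured_frac = 1) {
  rows <- lapply(years, function(y) {
    l <- seq(25, 40, length.out = n) + (y - min(years))
    w <- seq(0.9, 1.2, length.out = n)
    a <- gamma + alpha * l * w + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    measured <- seq_len(n) <= ceiling(measured_frac * n)
    data.frame(tree_id = tree_id, branch_id = branch_id, treatment = treatment,
               year = y, length_mm = l, width_mm = w,
               area_adaxial_mm2 = ifelse(measured, a, NA_real_),
               rows_adaxial = 6, rows_abaxial = 6,
               stomata_per_mm = 8, stomatal_diameter_um = 20)
  })
  do.call(rbind, rows)
}

# Matching segment table: constant annual elongation.
toy_segments <- function(years = 2008:2012, branch_id = "t1_b1", length_mm = 20) {
  data.frame(branch_id = branch_id, year = years, length_mm = length_mm)
}

# Ring table for sections with the given genesis years, one ring per year up
# to `last_year`; `area_fun(y, gamma)` supplies ring areas.
toy_rings <- function(genesis_years = c(2010, 2011), last_year = 2012,
                      branch_id = "t1_b1", tree_id = "t1",
                      area_fun = function(y, g) 0.5) {
  rows <- lapply(genesis_years, function(g) {
    ys <- g:last_year
    data.frame(tree_id = tree_id, branch_id = branch_id,
               section_genesis_year = g, ring_year = ys,
               ring_area_mm2 = vapply(ys, area_fun, numeric(1), g = g),
               missing = FALSE)
  })
  do.call(rbind, rows)
}

# Random small branch (needles + segments + rings) for brute-force oracle
# comparisons; uses the session RNG.
random_branch <- function(branch_id = "rb1", max_sections = 4, max_years = 6) {
  last <- 2012
  n_years <- sample(2:max_years, 1)
  years <- (last - n_years + 1):last
  needles <- do.call(rbind, lapply(years, function(y) {
    n <- sample(2:8, 1)
    l <- runif(n, 15, 45)
    w <- runif(n, 0.8, 1.3)
    data.frame(tree_id = "rt", branch_id = branch_id, treatment = "ambient",
               year = y, length_mm = l, width_mm = w,
               area_adaxial_mm2 = 0.1 + 0.7 * l * w,
               rows_adaxial = 6, rows_abaxial = 6,
               stomata_per_mm = 8, stomatal_diameter_um = 20)
  }))
  segments <- data.frame(branch_id = branch_id, year = years,
                         length_mm = runif(n_years, 5, 40))
  n_sec <- sample(seq_len(min(max_sections, n_years)), 1)
  genesis <- sort(sample(years, n_sec))
  rings <- do.call(rbind, lapply(genesis, function(g) {
    ys <- g:last
    miss <- runif(length(ys)) < 0.15
    data.frame(tree_id = "rt", branch_id = branch_id,
               section_genesis_year = g, ring_year = ys,
               ring_area_mm2 = ifelse(miss, NA_real_, runif(length(ys), 0.1, 2)),
               missing = miss)
  }))
  list(needles = needles, segments = segments, rings = rings)
}

# Independent brute-force evaluation of the annual-ratio equations on one
# branch: plain loops over sections and years, no shared code with the
# pipeline. Returns per-(branch, year) means of SA:LA and SA:LA/d.
oracle_branch_ratios <- function(needles, rings, segments) {
  years <- sort(unique(rings$ring_year))
  out <- NULL
  for (y in years) {
    vals <- c(); vals_d <- c()
    for (i in seq_len(nrow(rings))) {
      if (rings$ring_year[i] != y) next
      g <- rings$section_genesis_year[i]
      if (g == y) next                                  # apical discard
      if (rings$missing[i] || is.na(rings$ring_area_mm2[i])) next
      la <- 0
      for (j in seq_len(nrow(needles))) {
        if (needles$year[j] == y) {
          la <- la + 2 * needles$area_adaxial_mm2[j] * 1e-6
        }
      }
      if (la <= 0) next
      ratio <- (rings$ring_area_mm2[i] / 100) / la
      d <- 0
      for (t in g:y) d <- d + segments$length_mm[segments$year == t] / 1000
      vals <- c(vals, ratio)
      vals_d <- c(vals_d, (ratio * 1e-4) / d)
    }
    if (length(vals)) {
      out <- rbind(out, data.frame(year = y, sa_la = mean(vals),
                                   sa_la_per_d = mean(vals_d)))
    }
  }
  out
}

# Independent unit-checked evaluation of the anatomical-conductance formula
# working entirely in field units (stomata/mm2, micrometres), collecting the
# mm/um -> SI conversions into a single factor derived by hand:
#   a_max[um2] * D[mm-2] = a_max*D * 1e-12 * 1e6 m2/m2 = a_max*D * 1e-6
#   denominator[um]      = 1e-6 m
#   => g = (d/v) * a_max * D / denom_um
oracle_gsmax <- function(d_s_um, ds_per_mm2, d = 2.49e-5, v = 2.446e-2) {
  a_max_um2 <- pi * (d_s_um / 2)^2
  p_um <- d_s_um / 2
  denom_um <- p_um + (pi / 2) * sqrt(a_max_um2 / pi)
  (d / v) * a_max_um2 * ds_per_mm2 / denom_um
}
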