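#' Simulation configuration for the synthetic drought experiment
#'
#' Builds the default configuration emulating the 7-year field experiment:
#' three watering treatments (irrigated / ambient / droughted) with 10, 10
#' and 4 trees, three branches collected per tree of which one (three for the
#' droughted treatment) is measured; bimodal monsoonal climate with per-year
#' seasonal anchors taken from the site's meteorological record; a ~45%
#' rainfall exclusion and scheduled ~19 mm irrigation events; treatment-
#' specific linear needle-length and SA:LA responses to premonsoon and
#' monsoon water input; and an extreme-year collapse rule (many high-VPD
#' monsoon days combined with a dry year) that governs missing rings.
#'
#' All values are configuration, not hard-coded truth: any element can be
#' overridden via `...`.
#'
#' @param ... named overrides of any default element.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(...) {
  treatments <- c("irrigated", "ambient", "droughted")
  cfg <- list(
    years = 2007:2013,
    treatments = treatments,
    trees = c(irrigated = 10, ambient = 10, droughted = 4),
    branches_per_tree = 3,
    branches_measured = c(irrigated = 1, ambient = 1, droughted = 3),
    needle_year_probs = c(`4` = 0.12, `5` = 0.38, `6` = 0.38, `7` = 0.12),
    needles_per_year_mean = 13.2,
    needles_per_year_sd = 3.1,
    needles_per_year_range = c(1L, 15L),
    stomatal_subsample = 5L,

    # --- climate -----------------------------------------------------------
    climate_mode = c("anchored", "climatology"),
    # per-year seasonal anchors (experimental period, field-site record)
    anchor_ppt_premonsoon = c(174.3, 96.8, 105.9, 202.7, 34.5, 159.2, 85.3),
    anchor_ppt_monsoon = c(149.3, 253.8, 175.8, 149.6, 128.5, 193.4, 292.1),
    anchor_vpd_dry = c(2.35, 2.61, 2.35, 2.49, 2.87, 2.91, 2.80),
    anchor_vpd_monsoon = c(2.92, 2.48, 2.87, 2.90, 3.07, 3.06, 2.42),
    anchor_vpd_days_dry = c(8L, 14L, 8L, 11L, 20L, 21L, 18L),
    anchor_vpd_days_monsoon = c(6L, 2L, 5L, 6L, 14L, 12L, 1L),
    ppt_season_noise_sd = 15,
    # climatology mode: stationary draws around the long-term record
    annual_ppt_mean = 355.3,
    annual_ppt_sd = 83.4,
    winter_share = 0.18,   # Nov-Feb share of the hydro-year total
    jas_share = 0.52,      # Jul-Sep share
    oct_share = 0.09,      # Oct share (rest falls Mar-Jun)
    climatology_vpd_dry = 2.43,
    climatology_vpd_monsoon = 2.57,
    climatology_vpd_days = c(dry = 10L, monsoon = 4L),
    rain_event_mm = 8,
    vpd_day_sd = 0.45,
    vpd_offseason_mean = 1.0,
    vpd_threshold = 4.5,

    # --- treatment water rules --------------------------------------------
    exclusion_fraction = 0.45,
    exclusion_start = as.Date("2007-08-01"),
    irrigation_annual_mm = c(`2008` = 57, `2009` = 69.5, `2010` = 112,
                             `2011` = 107, `2012` = 95, `2013` = 95),
    irrigation_event_mm = 19,

    # --- branch growth responses (slopes per mm of own seasonal input) ----
    l_coefs = data.frame(
      treatment = treatments,
      b0 = c(18, 0.4, 2),
      b_pre = c(0.051, 0.126, 0.236),
      b_mon = c(0.05, 0.096, 0.171)
    ),
    r_coefs = data.frame(  # SA:LA targets, cm2/m2
      treatment = treatments,
      b0 = c(0.11, -0.09, -0.21),
      b_pre = c(4.2e-3, 6.5e-3, 6.5e-3),
      b_mon = c(3.8e-3, 4.1e-3, 8.0e-3)
    ),
    branch_intercept_sd = 1.5,
    needle_length_sd = 3,
    width_mean = 1.0, width_sd = 0.07,
    area_gamma = 0.1, area_alpha = 0.7, area_noise_sd = 0.3,
    area_measured_frac = 0.2,
    rows_mean = 6, rows_sd = 0.8,
    dlin_mean = 6, dlin_sd = 0.5,
    dlin_mult = c(irrigated = 0.93, ambient = 1, droughted = 1.05),
    ds_mean = 20, ds_sd = 1,
    ds_mult = c(irrigated = 1.03, ambient = 1, droughted = 0.98),
    segment_slope = 0.9, segment_sd = 2, segment_min = 2,
    section_genesis_years = c(2007, 2009, 2011),
    sa_noise_cv = 0.2,

    # --- extreme-year collapse rule ---------------------------------------
    collapse_vpd_days_min = 10,
    collapse_ppt_max = 200,
    collapse_factor_l = 1.0,
    collapse_factor_sa = 1.0,
    missing_ring_prob = 0.25,

    noise = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  cfg$climate_mode <- match.arg(cfg$climate_mode, c("anchored", "climatology"))
  stopifnot(cfg$winter_share >= 0, cfg$jas_share >= 0, cfg$oct_share >= 0,
            cfg$winter_share + cfg$jas_share + cfg$oct_share <= 1,
            cfg$exclusion_fraction > 0, cfg$exclusion_fraction < 1)
  structure(cfg, class = "sim_config")
}

# noise-aware sd
nz <- function(cfg, sd) if (isTRUE(cfg$noise)) sd else 0

# scatter a seasonal precipitation total over event days inside a window
scatter_rain <- function(cfg, dates, total) {
  out <- numeric(length(dates))
  if (total <= 0) return(out)
  n_ev <- max(1L, min(length(dates), round(total / cfg$rain_event_mm)))
  days <- sample.int(length(dates), n_ev)
  w <- if (isTRUE(cfg$noise)) stats::rexp(n_ev) else rep(1, n_ev)
  out[days] <- total * w / sum(w)
  out
}

# fill a VPD window: `k` exceedance days above the threshold, the remaining
# days drawn below it with the window mean steered toward `target_mean`
fill_vpd <- function(cfg, n, target_mean, k) {
  k <- min(k, n)
  v <- numeric(n)
  spikes <- if (k > 0) {
    cfg$vpd_threshold + 0.1 +
      (if (isTRUE(cfg$noise)) stats::rexp(k, rate = 1 / 0.35) else rep(0.35, k))
  } else numeric(0)
  rest_n <- n - k
  if (rest_n > 0) {
    rest_mean <- (target_mean * n - sum(spikes)) / rest_n
    rest_mean <- min(max(rest_mean, 0.2), cfg$vpd_threshold - 0.3)
    rest <- stats::rnorm(rest_n, rest_mean, nz(cfg, cfg$vpd_day_sd))
    rest <- pmin(pmax(rest, 0.05), cfg$vpd_threshold - 0.05)
    v[] <- 0
    idx <- if (k > 0) sample.int(n, k) else integer(0)
    v[idx] <- spikes
    v[setdiff(seq_len(n), idx)] <- rest
  } else {
    v[] <- spikes
  }
  v
}

#' Simulate an ambient daily climate series
#'
#' Generates daily precipitation and daily-maximum VPD over the configured
#' hydrological years. In `"anchored"` mode (the default) each year's
#' premonsoon/monsoon precipitation totals, seasonal mean VPD, and
#' high-VPD-day counts follow the configured per-year anchors (plus noise);
#' in `"climatology"` mode years are stationary draws around the long-term
#' record (annual mean, winter and monsoon shares). Rain falls in discrete
#' events; VPD exceedance days are placed explicitly inside each window so
#' the seasonal exceedance predictors are well controlled.
#'
#' Randomness is taken from the current RNG state; call [set.seed()] (or use
#' [generate_dataset()]) for reproducibility.
#'
#' @param cfg a [sim_config()] object.
#' @return data frame with `date`, `precip_mm`, `vpd_max_kpa` covering
#'   Nov 1 of the year before the first configured year through Oct 31 of
#'   the last.
#' @export
simulate_daily_climate <- function(cfg = sim_config()) {
  years <- cfg$years
  dates <- seq(as.Date(sprintf("%d-11-01", min(years) - 1L)),
               as.Date(sprintf("%d-10-31", max(years))), by = "day")
  precip <- numeric(length(dates))
  vpd <- numeric(length(dates))
  hy <- hydro_year(dates)
  mo <- as.integer(format(dates, "%m"))
  # within-season splits shared by both modes
  pre_share <- cfg$winter_share + (1 - cfg$winter_share - cfg$jas_share - cfg$oct_share)
  winter_within_pre <- cfg$winter_share / pre_share
  mon_share <- cfg$jas_share + cfg$oct_share
  oct_within_mon <- cfg$oct_share / mon_share
  for (i in seq_along(years)) {
    y <- years[i]
    if (cfg$climate_mode == "anchored") {
      pre_tot <- max(2, cfg$anchor_ppt_premonsoon[i] +
                       stats::rnorm(1, 0, nz(cfg, cfg$ppt_season_noise_sd)))
      mon_tot <- max(2, cfg$anchor_ppt_monsoon[i] +
                       stats::rnorm(1, 0, nz(cfg, cfg$ppt_season_noise_sd)))
      v_dry <- cfg$anchor_vpd_dry[i]
      v_mon <- cfg$anchor_vpd_monsoon[i]
      k_dry <- cfg$anchor_vpd_days_dry[i]
      k_mon <- cfg$anchor_vpd_days_monsoon[i]
    } else {
      annual <- max(30, stats::rnorm(1, cfg$annual_ppt_mean,
                                     nz(cfg, cfg$annual_ppt_sd)))
      pre_tot <- annual * pre_share
      mon_tot <- annual * mon_share
      v_dry <- cfg$climatology_vpd_dry
      v_mon <- cfg$climatology_vpd_monsoon
      k_dry <- cfg$climatology_vpd_days[["dry"]]
      k_mon <- cfg$climatology_vpd_days[["monsoon"]]
    }
    sel_y <- hy == y
    winter <- sel_y & (mo >= 11L | mo <= 2L)
    marjun <- sel_y & mo >= 3L & mo <= 6L
    jassep <- sel_y & mo >= 7L & mo <= 9L
    octb <- sel_y & mo == 10L
    precip[winter] <- scatter_rain(cfg, dates[winter], pre_tot * winter_within_pre)
    precip[marjun] <- scatter_rain(cfg, dates[marjun], pre_tot * (1 - winter_within_pre))
    precip[jassep] <- scatter_rain(cfg, dates[jassep], mon_tot * (1 - oct_within_mon))
    precip[octb] <- scatter_rain(cfg, dates[octb], mon_tot * oct_within_mon)
    dry_win <- sel_y & mo >= 3L & mo <= 6L       # MAMJ
    mon_win <- sel_y & mo >= 7L & mo <= 10L      # JASO
    off_win <- sel_y & (mo >= 11L | mo <= 2L)
    vpd[dry_win] <- fill_vpd(cfg, sum(dry_win), v_dry, k_dry)
    vpd[mon_win] <- fill_vpd(cfg, sum(mon_win), v_mon, k_mon)
    off <- stats::rnorm(sum(off_win), cfg$vpd_offseason_mean, nz(cfg, 0.3))
    vpd[off_win] <- pmin(pmax(off, 0.05), cfg$vpd_threshold - 0.05)
  }
  data.frame(date = dates, precip_mm = precip, vpd_max_kpa = vpd)
}

#' Apply a treatment's water-input rule to an ambient series
#'
#' Droughted branches sit under a rainfall exclusion removing a fixed
#' fraction of every precipitation event from the exclusion start date;
#' irrigated branches receive scheduled watering events (roughly
#' `irrigation_event_mm` each, April through October) summing to the
#' configured annual addition. VPD is atmospheric and identical across
#' treatments.
#'
#' @param daily ambient daily series (from [simulate_daily_climate()] or
#'   observed data with the same columns).
#' @param treatment `"ambient"`, `"irrigated"` or `"droughted"`.
#' @param cfg a [sim_config()] object.
#' @return daily series with treatment water input applied.
#' @export
apply_treatment_water <- function(daily, treatment, cfg = sim_config()) {
  treatment <- match.arg(treatment, c("ambient", "irrigated", "droughted"))
  out <- daily
  if (treatment == "droughted") {
    sel <- out$date >= cfg$exclusion_start
    out$precip_mm[sel] <- out$precip_mm[sel] * (1 - cfg$exclusion_fraction)
  } else if (treatment == "irrigated") {
    for (ys in names(cfg$irrigation_annual_mm)) {
      y <- as.integer(ys)
      total <- cfg$irrigation_annual_mm[[ys]]
      if (total <= 0) next
      n_ev <- max(1L, round(total / cfg$irrigation_event_mm))
      ev_dates <- as.Date(round(seq(as.numeric(as.Date(sprintf("%d-04-15", y))),
                                    as.numeric(as.Date(sprintf("%d-10-15", y))),
                                    length.out = n_ev)),
                          origin = "1970-01-01")
      idx <- match(ev_dates, out$date)
      idx <- idx[!is.na(idx)]
      out$precip_mm[idx] <- out$precip_mm[idx] + total / length(idx)
    }
  }
  out
}

# linear treatment response evaluated on a seasonal water-input table
.response_means <- function(coefs, treatment, seasonal) {
  cf <- coefs[coefs$treatment == treatment, ]
  cf$b0 + cf$b_pre * seasonal$ppt_premonsoon + cf$b_mon * seasonal$ppt_monsoon
}

#' Simulate one branch: needles, shoot segments, and twig-section rings
#'
#' Draws the branch's annual needle cohorts, shoot elongation segments and
#' per-section ring areas from the treatment's seasonal water input. Yearly
#' mean needle length follows the treatment-specific linear response (plus a
#' branch-level intercept); segment lengths scale with needle length; ring
#' areas are set so the implied SA:LA tracks the treatment's linear SA:LA
#' response against the leaf area actually generated. In collapse years the
#' configured multipliers apply and rings go missing with the configured
#' probability.
#'
#' @param tree_id,branch_id,treatment identifiers.
#' @param seasonal the treatment's seasonal water-input table (one row per
#'   configured year, columns `hydro_year`, `ppt_premonsoon`, `ppt_monsoon`).
#' @param collapse logical vector, one per configured year.
#' @param cfg a [sim_config()] object.
#' @return list with data frames `needles`, `segments`, `rings`, plus
#'   `branch_intercept` and `l_mean` (the latent yearly means).
#' @export
simulate_branch_growth <- function(tree_id, branch_id, treatment, seasonal,
                                   collapse, cfg = sim_config()) {
  years <- cfg$years
  stopifnot(nrow(seasonal) == length(years), length(collapse) == length(years))
  b_br <- stats::rnorm(1, 0, nz(cfg, cfg$branch_intercept_sd))
  l_mean <- .response_means(cfg$l_coefs, treatment, seasonal) + b_br
  l_mean[collapse] <- l_mean[collapse] * cfg$collapse_factor_l
  l_mean <- pmax(l_mean, 1)

  seg_len <- pmax(cfg$segment_min,
                  cfg$segment_slope * l_mean +
                    stats::rnorm(length(years), 0, nz(cfg, cfg$segment_sd)))
  segments <- data.frame(branch_id = branch_id, year = years, length_mm = seg_len)

  n_years <- as.integer(sample(names(cfg$needle_year_probs), 1,
                               prob = cfg$needle_year_probs))
  cohort_years <- utils::tail(years, n_years)
  resampled <- 0L
  needle_rows <- lapply(cohort_years, function(y) {
    i <- match(y, years)
    n <- round(stats::rnorm(1, cfg$needles_per_year_mean, cfg$needles_per_year_sd))
    n <- min(max(n, cfg$needles_per_year_range[1]), cfg$needles_per_year_range[2])
    l <- stats::rnorm(n, l_mean[i], nz(cfg, cfg$needle_length_sd))
    while (any(l <= 0)) {  # nonpositive draws are resampled, counted
      bad <- l <= 0
      resampled <<- resampled + sum(bad)
      l[bad] <- stats::rnorm(sum(bad), l_mean[i], nz(cfg, cfg$needle_length_sd))
    }
    w <- pmax(0.3, stats::rnorm(n, cfg$width_mean, nz(cfg, cfg$width_sd)))
    a_ad <- pmax(0.05, cfg$area_gamma + cfg$area_alpha * l * w +
                   stats::rnorm(n, 0, nz(cfg, cfg$area_noise_sd)))
    measured <- stats::runif(n) < cfg$area_measured_frac
    rows_ad <- pmax(1, round(2 * stats::rnorm(n, cfg$rows_mean, nz(cfg, cfg$rows_sd))) / 2)
    rows_ab <- pmax(1, round(2 * stats::rnorm(n, cfg$rows_mean, nz(cfg, cfg$rows_sd))) / 2)
    sub <- seq_len(min(cfg$stomatal_subsample, n))
    dlin <- rep(NA_real_, n)
    dsd <- rep(NA_real_, n)
    dlin[sub] <- pmax(0.5, stats::rnorm(length(sub),
                                        cfg$dlin_mean * cfg$dlin_mult[[treatment]],
                                        nz(cfg, cfg$dlin_sd)))
    dsd[sub] <- pmax(5, stats::rnorm(length(sub),
                                     cfg$ds_mean * cfg$ds_mult[[treatment]],
                                     nz(cfg, cfg$ds_sd)))
    data.frame(tree_id = tree_id, branch_id = branch_id, treatment = treatment,
               year = y, length_mm = l, width_mm = w,
               area_adaxial_mm2 = ifelse(measured, a_ad, NA_real_),
               rows_adaxial = rows_ad, rows_abaxial = rows_ab,
               stomata_per_mm = dlin, stomatal_diameter_um = dsd,
               area_adaxial_true_mm2 = a_ad)
  })
  needles <- do.call(rbind, needle_rows)

  la_by_year <- vapply(years, function(y) {
    sel <- needles$year == y
    if (!any(sel)) 0 else sum(2 * needles$area_adaxial_true_mm2[sel]) * 1e-6
  }, numeric(1))
  la_typical <- mean(la_by_year[la_by_year > 0])
  ratio_target <- pmax(0.05, .response_means(cfg$r_coefs, treatment, seasonal))
  ratio_target[collapse] <- ratio_target[collapse] * cfg$collapse_factor_sa
  sdlog <- sqrt(log(1 + nz(cfg, cfg$sa_noise_cv)^2))

  ring_rows <- lapply(cfg$section_genesis_years, function(g) {
    ys <- years[years >= g]
    i <- match(ys, years)
    la <- ifelse(la_by_year[i] > 0, la_by_year[i], la_typical)
    sa_cm2 <- ratio_target[i] * la *
      exp(stats::rnorm(length(ys), -sdlog^2 / 2, sdlog))
    miss <- collapse[i] & stats::runif(length(ys)) < cfg$missing_ring_prob
    data.frame(tree_id = tree_id, branch_id = branch_id,
               section_genesis_year = g, ring_year = ys,
               ring_area_mm2 = ifelse(miss, NA_real_, sa_cm2 * 100),
               missing = miss)
  })
  rings <- do.call(rbind, ring_rows)
  needles$area_adaxial_true_mm2 <- NULL
  list(needles = needles, segments = segments, rings = rings,
       branch_intercept = b_br, l_mean = l_mean, resampled = resampled)
}

#' Generate a full synthetic experiment dataset
#'
#' Runs the complete generator: one ambient daily climate series, the three
#' treatment water-input series, seasonal predictor tables, and the needle /
#' ring / segment tables for every measured branch, together with the
#' generating truth (coefficients, branch intercepts, collapse flags).
#' Regenerating with the same seed reproduces the dataset exactly.
#'
#' @param cfg a [sim_config()] object.
#' @param seed integer RNG seed.
#' @param outdir optional directory; when given, writes `needles.csv`,
#'   `rings.csv`, `segments.csv`, `climate_daily_<treatment>.csv` and
#'   `truth.json` there.
#' @return (invisibly when writing) list with `needles`, `rings`, `segments`,
#'   `climate` (list of three daily series), `seasonal` (list of three
#'   seasonal tables), `truth`, `config`.
#' @export
generate_dataset <- function(cfg = sim_config(), seed = 1L, outdir = NULL) {
  set.seed(seed)
  ambient <- simulate_daily_climate(cfg)
  climate <- lapply(stats::setNames(cfg$treatments, cfg$treatments),
                    function(tr) apply_treatment_water(ambient, tr, cfg))
  seasonal <- lapply(climate, function(d) {
    s <- summarize_seasons(d, threshold = cfg$vpd_threshold)
    s[match(cfg$years, s$hydro_year), , drop = FALSE]
  })
  # Extreme-year collapse: regional atmospheric + soil drought (many high-VPD
  # monsoon days and a dry year at the site) combined with low water input for
  # the treatment itself, so irrigation lifts a plot out of the collapse.
  site <- seasonal$ambient
  site_rule <- site$vpd_days_monsoon >= cfg$collapse_vpd_days_min &
    site$ppt_yearly < cfg$collapse_ppt_max
  collapse <- lapply(seasonal, function(s) {
    site_rule & s$ppt_yearly < cfg$collapse_ppt_max
  })
  needles <- list(); rings <- list(); segments <- list()
  intercepts <- list()
  for (tr in cfg$treatments) {
    code <- substr(tr, 1, 1)
    for (t in seq_len(cfg$trees[[tr]])) {
      tree_id <- sprintf("%s%02d", code, t)
      for (b in seq_len(cfg$branches_measured[[tr]])) {
        branch_id <- sprintf("%s_b%d", tree_id, b)
        sim <- simulate_branch_growth(tree_id, branch_id, tr,
                                      seasonal[[tr]], collapse[[tr]], cfg)
        needles[[branch_id]] <- sim$needles
        rings[[branch_id]] <- sim$rings
        segments[[branch_id]] <- sim$segments
        intercepts[[branch_id]] <- sim$branch_intercept
      }
    }
  }
  out <- list(
    needles = do.call(rbind, unname(needles)),
    rings = do.call(rbind, unname(rings)),
    segments = do.call(rbind, unname(segments)),
    climate = climate,
    seasonal = seasonal,
    truth = list(
      seed = seed,
      l_coefs = cfg$l_coefs,
      r_coefs = cfg$r_coefs,
      collapse = lapply(collapse, function(cl) {
        data.frame(year = cfg$years, collapse = cl)
      }),
      branch_intercepts = unlist(intercepts)
    ),
    config = cfg
  )
  rownames(out$needles) <- rownames(out$rings) <- rownames(out$segments) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$needles, file.path(outdir, "needles.csv"), row.names = FALSE)
    utils::write.csv(out$rings, file.path(outdir, "rings.csv"), row.names = FALSE)
    utils::write.csv(out$segments, file.path(outdir, "segments.csv"), row.names = FALSE)
    for (tr in cfg$treatments) {
      utils::write.csv(out$climate[[tr]],
                       file.path(outdir, sprintf("climate_daily_%s.csv", tr)),
                       row.names = FALSE)
    }
    truth <- out$truth
    truth$config <- cfg[setdiff(names(cfg), c("l_coefs", "r_coefs"))]
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, Date = "ISO8601")
    return(invisible(out))
  }
  out
}
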