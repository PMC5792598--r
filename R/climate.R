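#' Hydrological year of a date
#'
#' The hydrological year at the study site runs from November 1 through
#' October 31 and is labelled by the calendar year containing its October 31
#' endpoint, so "2011" spans Nov 1 2010 -- Oct 31 2011.
#'
#' @param date a `Date` vector (or something coercible via [as.Date()]).
#' @return integer vector of hydrological-year labels.
#' @export
#' @examples
#' hydro_year(as.Date(c("2010-11-01", "2011-10-31", "2011-11-01")))
hydro_year <- function(date) {
  d <- as.Date(date)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  ifelse(m >= 11L, y + 1L, y)
}

#' Daily maximum vapour pressure deficit from temperature and humidity
#'
#' Tetens saturation vapour pressure, `e_s = 0.6108 * exp(17.27 T / (T + 237.3))`
#' kPa, evaluated at the daily maximum temperature, times the saturation
#' deficit implied by the daily minimum relative humidity. Pairing Tmax with
#' RHmin approximates the daily maximum VPD.
#'
#' @param tmax_c daily maximum air temperature, degrees C (within -40..60).
#' @param rhmin_pct daily minimum relative humidity, percent (0..100).
#' @return VPD in kPa.
#' @export
#' @examples
#' vpd_from_trh(25, 50)
vpd_from_trh <- function(tmax_c, rhmin_pct) {
  if (any(!is.finite(tmax_c)) || any(tmax_c < -40 | tmax_c > 60)) {
    stop("tmax_c must be finite and within [-40, 60] degrees C")
  }
  if (any(!is.finite(rhmin_pct)) || any(rhmin_pct < 0 | rhmin_pct > 100)) {
    stop("rhmin_pct must be within [0, 100]")
  }
  es <- 0.6108 * exp(17.27 * tmax_c / (tmax_c + 237.3))
  es * (1 - rhmin_pct / 100)
}

# Calendar window (first, last day inclusive) of a season within a hydro year.
# premonsoon: Nov 1 (Y-1) .. Jun 30 (Y); monsoon: Jul 1 .. Oct 31 (Y);
# yearly: the whole hydro year; dry (VPD window): Mar 1 .. Jun 30 (MAMJ);
# monsoon VPD window coincides with the monsoon precipitation window (JASO).
season_window <- function(hydro_year, season) {
  season <- match.arg(season, c("premonsoon", "monsoon", "yearly", "dry"))
  y <- as.integer(hydro_year)
  switch(season,
    premonsoon = c(as.Date(sprintf("%d-11-01", y - 1L)), as.Date(sprintf("%d-06-30", y))),
    monsoon    = c(as.Date(sprintf("%d-07-01", y)),      as.Date(sprintf("%d-10-31", y))),
    yearly     = c(as.Date(sprintf("%d-11-01", y - 1L)), as.Date(sprintf("%d-10-31", y))),
    dry        = c(as.Date(sprintf("%d-03-01", y)),      as.Date(sprintf("%d-06-30", y)))
  )
}

# internal: validate a daily climate table
validate_daily <- function(daily) {
  req <- c("date", "precip_mm", "vpd_max_kpa")
  miss <- setdiff(req, names(daily))
  if (length(miss)) stop("daily climate table lacks column(s): ", paste(miss, collapse = ", "))
  daily$date <- as.Date(daily$date)
  if (anyNA(daily$date)) stop("unparseable dates in daily climate table")
  if (is.unsorted(daily$date, strictly = TRUE)) stop("dates must be strictly increasing")
  if (any(daily$precip_mm < 0, na.rm = TRUE)) stop("precip_mm must be >= 0")
  if (any(daily$vpd_max_kpa < 0, na.rm = TRUE)) stop("vpd_max_kpa must be >= 0")
  daily
}

#' Cumulative precipitation over a seasonal window
#'
#' Sums daily precipitation over the premonsoon (Nov 1 -- Jun 30), monsoon
#' (Jul 1 -- Oct 31) or full hydrological-year window. Days missing from the
#' series are excluded from the sum (reported via the `n_missing` attribute);
#' an entirely uncovered window is an error, distinct from zero rainfall.
#'
#' @param daily data frame with columns `date`, `precip_mm`, `vpd_max_kpa`.
#' @param hydro_year integer hydro-year label.
#' @param season `"premonsoon"`, `"monsoon"` or `"yearly"`.
#' @return precipitation total in mm, with attribute `n_missing`.
#' @export
cumulative_precip <- function(daily, hydro_year,
                              season = c("premonsoon", "monsoon", "yearly")) {
  season <- match.arg(season)
  daily <- validate_daily(daily)
  win <- season_window(hydro_year, season)
  sel <- daily$date >= win[1] & daily$date <= win[2]
  if (!any(sel)) {
    stop("no daily records cover the ", season, " window of hydro year ", hydro_year)
  }
  n_expected <- as.integer(win[2] - win[1]) + 1L
  out <- sum(daily$precip_mm[sel], na.rm = TRUE)
  attr(out, "n_missing") <- n_expected - sum(sel & !is.na(daily$precip_mm))
  out
}

#' Count days whose maximum VPD exceeds a threshold
#'
#' Strict exceedance (`vpd_max > threshold`) counted over the dry-season
#' window (MAMJ, Mar 1 -- Jun 30) or the monsoon window (JASO, Jul 1 -- Oct 31)
#' of a hydrological year.
#'
#' @inheritParams cumulative_precip
#' @param season `"dry"` (MAMJ) or `"monsoon"` (JASO).
#' @param threshold kPa, must be positive; default 4.5.
#' @return integer count of exceedance days.
#' @export
count_vpd_exceedance <- function(daily, hydro_year, season = c("dry", "monsoon"),
                                 threshold = 4.5) {
  season <- match.arg(season)
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be > 0")
  daily <- validate_daily(daily)
  win <- season_window(hydro_year, season)
  sel <- daily$date >= win[1] & daily$date <= win[2]
  sum(daily$vpd_max_kpa[sel] > threshold, na.rm = TRUE)
}

#' Seasonal climate predictors per hydrological year
#'
#' Aggregates a daily series into one row per hydrological year: cumulative
#' premonsoon, monsoon and yearly precipitation; counts of days with maximum
#' VPD above `threshold` in the dry-season (MAMJ) and monsoon (JASO) windows;
#' and mean daily-maximum VPD over those windows. Years whose day coverage
#' falls below `min_coverage` are flagged `complete = FALSE` and are excluded
#' by [period_stats()].
#'
#' @inheritParams cumulative_precip
#' @param threshold VPD exceedance threshold in kPa.
#' @param min_coverage minimum fraction of days that must be present for a
#'   year to count as complete (default 0.95).
#' @return data frame, one row per hydro year present in the series.
#' @seealso [period_stats()] for the experimental-period summary rows.
#' @export
summarize_seasons <- function(daily, threshold = 4.5, min_coverage = 0.95) {
  daily <- validate_daily(daily)
  hy <- hydro_year(daily$date)
  years <- sort(unique(hy))
  rows <- lapply(years, function(y) {
    wy <- season_window(y, "yearly")
    n_expected <- as.integer(wy[2] - wy[1]) + 1L
    sel_y <- hy == y
    n_present <- sum(sel_y & !is.na(daily$precip_mm) & !is.na(daily$vpd_max_kpa))
    d <- daily$date
    in_win <- function(season) {
      w <- season_window(y, season)
      sel_y & d >= w[1] & d <= w[2]
    }
    pre <- sum(daily$precip_mm[in_win("premonsoon")], na.rm = TRUE)
    mon <- sum(daily$precip_mm[in_win("monsoon")], na.rm = TRUE)
    vdry <- daily$vpd_max_kpa[in_win("dry")]
    vmon <- daily$vpd_max_kpa[in_win("monsoon")]
    data.frame(
      hydro_year = y,
      ppt_premonsoon = pre,
      ppt_monsoon = mon,
      ppt_yearly = pre + mon,
      vpd_days_dry = sum(vdry > threshold, na.rm = TRUE),
      vpd_days_monsoon = sum(vmon > threshold, na.rm = TRUE),
      vpd_mean_max_dry = if (length(vdry)) mean(vdry, na.rm = TRUE) else NA_real_,
      vpd_mean_max_monsoon = if (length(vmon)) mean(vmon, na.rm = TRUE) else NA_real_,
      coverage = n_present / n_expected,
      complete = n_present / n_expected >= min_coverage
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Period summary statistics of seasonal climate
#'
#' Mean and sample standard deviation (n - 1) of each seasonal predictor over
#' the complete hydrological years of a [summarize_seasons()] table, mirroring
#' the multi-year summary rows of a long-term climate table. With a single
#' complete year the SD is reported as `NA`.
#'
#' @param seasonal output of [summarize_seasons()] (or a data frame with the
#'   same columns; a missing `complete` column is taken as all-complete).
#' @return data frame with one row per statistic (`mean`, `sd`) and attribute
#'   `n_years`.
#' @export
period_stats <- function(seasonal) {
  if (is.null(seasonal$complete)) seasonal$complete <- TRUE
  use <- seasonal[seasonal$complete, , drop = FALSE]
  if (nrow(use) == 0L) stop("no complete hydro years in the period")
  vars <- c("ppt_premonsoon", "ppt_monsoon", "ppt_yearly",
            "vpd_days_dry", "vpd_days_monsoon",
            "vpd_mean_max_dry", "vpd_mean_max_monsoon")
  vars <- intersect(vars, names(use))
  m <- vapply(use[vars], mean, numeric(1))
  s <- if (nrow(use) >= 2L) vapply(use[vars], stats::sd, numeric(1)) else
    stats::setNames(rep(NA_real_, length(vars)), vars)
  out <- rbind(as.data.frame(as.list(m)), as.data.frame(as.list(s)))
  out <- cbind(statistic = c("mean", "sd"), out)
  attr(out, "n_years") <- nrow(use)
  out
}

#' Standardize a yearly predictor series
#'
#' Centers and scales by the mean and sample standard deviation of the
#' experimental period, the convention used for climate covariates entering
#' the mixed models (yearly value minus experimental mean, divided by SD).
#' The mean and SD are retained so the transform is invertible.
#'
#' @param x numeric vector (length >= 2, non-constant).
#' @param center,scale optional externally supplied mean and SD (e.g. to scale
#'   one treatment's series by the pooled experimental statistics).
#' @return object of class `std_series`: list with `z`, `mean`, `sd`.
#' @export
standardize_series <- function(x, center = NULL, scale = NULL) {
  if (length(x) < 2L) stop("need at least two values to standardize")
  m <- if (is.null(center)) mean(x) else center
  s <- if (is.null(scale)) stats::sd(x) else scale
  if (!is.finite(s) || s <= 0) stop("cannot standardize a constant (zero-variance) series")
  structure(list(z = (x - m) / s, mean = m, sd = s), class = "std_series")
}

#' @export
print.std_series <- function(x, ...) {
  cat(sprintf("standardized series: n = %d, center = %.4g, scale = %.4g\n",
              length(x$z), x$mean, x$sd))
  invisible(x)
}
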