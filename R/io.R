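# Readers, validation, and the orchestrating pipeline. All tabular I/O is
# plain CSV with units encoded in column names (_mm, _mm2, _kpa, _um).

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read and validate a needle table
#'
#' One row per measured needle. Required columns: `tree_id`, `branch_id`,
#' `treatment`, `year`, `length_mm`, `width_mm`, `rows_adaxial`,
#' `rows_abaxial`; optional (nullable): `area_adaxial_mm2`, `stomata_per_mm`,
#' `stomatal_diameter_um`. Row-level invariant violations (nonpositive
#' dimensions, negative densities, row counts off the half-integer grid) are
#' rejected with reasons collected in the `validation` attribute.
#'
#' @param path CSV file path (or a data frame, validated in place).
#' @return validated data frame with attribute `validation`.
#' @export
read_needles <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path)
  check_columns(df, c("tree_id", "branch_id", "treatment", "year", "length_mm",
                      "width_mm", "rows_adaxial", "rows_abaxial"), "needle table")
  for (opt in c("area_adaxial_mm2", "stomata_per_mm", "stomatal_diameter_um")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  bad_tr <- !df$treatment %in% c("irrigated", "ambient", "droughted")
  reasons <- character(nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reasons[cond] <<- ifelse(nzchar(reasons[cond]),
                             paste(reasons[cond], why, sep = "; "), why)
  }
  flag(bad_tr, "unknown treatment")
  flag(df$length_mm <= 0, "nonpositive length")
  flag(df$width_mm <= 0, "nonpositive width")
  flag(!is.na(df$area_adaxial_mm2) & df$area_adaxial_mm2 <= 0, "nonpositive measured area")
  flag(df$rows_adaxial < 0 | df$rows_abaxial < 0, "negative row count")
  flag((df$rows_adaxial * 2) %% 1 != 0 | (df$rows_abaxial * 2) %% 1 != 0,
       "row count not on the half-row grid")
  flag(!is.na(df$stomata_per_mm) & df$stomata_per_mm < 0, "negative linear density")
  flag(!is.na(df$stomatal_diameter_um) & df$stomatal_diameter_um < 0,
       "negative stomatal diameter")
  keep <- !nzchar(reasons)
  out <- df[keep, , drop = FALSE]
  attr(out, "validation") <- data.frame(row = which(!keep), reason = reasons[!keep])
  if (any(!keep)) {
    message(sum(!keep), " needle row(s) rejected; see attr(x, 'validation')")
  }
  out
}

#' Read and validate a ring table
#'
#' One row per annual ring per twig section. Required columns: `tree_id`,
#' `branch_id`, `section_genesis_year`, `ring_year`, `ring_area_mm2`,
#' `missing`. A ring cannot predate its section (`Gamma <= y`: hard error,
#' naming the offending rows); a missing ring carries `missing = TRUE` and
#' `NA` area -- it is absent data, never zero.
#'
#' @inheritParams read_needles
#' @return validated data frame.
#' @export
read_rings <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path)
  check_columns(df, c("tree_id", "branch_id", "section_genesis_year",
                      "ring_year", "ring_area_mm2", "missing"), "ring table")
  df$missing <- as.logical(df$missing)
  bad <- df$section_genesis_year > df$ring_year
  if (any(bad)) {
    stop("ring table violates Gamma <= y at row(s): ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  }
  bad_area <- !df$missing & (is.na(df$ring_area_mm2) | df$ring_area_mm2 <= 0)
  if (any(bad_area)) {
    stop("non-missing rings must have positive area; row(s): ",
         paste(utils::head(which(bad_area), 10), collapse = ", "))
  }
  df
}

#' Read and validate a shoot-segment table
#'
#' One row per branch and elongation year; `length_mm >= 0`, at most one row
#' per branch-year.
#'
#' @inheritParams read_needles
#' @return validated data frame.
#' @export
read_segments <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path)
  check_columns(df, c("branch_id", "year", "length_mm"), "segment table")
  if (any(df$length_mm < 0, na.rm = TRUE)) stop("segment lengths must be >= 0")
  if (anyDuplicated(df[c("branch_id", "year")])) {
    stop("duplicate branch-year rows in segment table")
  }
  df
}

#' Read and validate a daily climate table
#'
#' Columns `date` (ISO-8601), `precip_mm`, and either `vpd_max_kpa` or the
#' pair `tmax_c` + `rhmin_pct` from which VPD is derived via [vpd_from_trh()].
#'
#' @inheritParams read_needles
#' @return validated daily series with a `vpd_max_kpa` column.
#' @export
read_daily_climate <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path)
  check_columns(df, c("date", "precip_mm"), "daily climate table")
  if (!"vpd_max_kpa" %in% names(df)) {
    check_columns(df, c("tmax_c", "rhmin_pct"),
                  "daily climate table (no vpd_max_kpa column)")
    df$vpd_max_kpa <- vpd_from_trh(df$tmax_c, df$rhmin_pct)
  }
  validate_daily(df)
}

#' Attach seasonal climate predictors to a branch-year table
#'
#' Joins each (treatment, year) row to the treatment's seasonal water-input
#' predictors (precipitation windows and VPD-exceedance counts).
#'
#' @param branch_years data frame with `treatment` and `year` columns.
#' @param seasonal_by_treatment named list of [summarize_seasons()] tables,
#'   one per treatment.
#' @return `branch_years` with the predictor columns appended.
#' @export
merge_climate_predictors <- function(branch_years, seasonal_by_treatment) {
  cols <- c("ppt_premonsoon", "ppt_monsoon", "ppt_yearly",
            "vpd_days_dry", "vpd_days_monsoon")
  for (col in cols) branch_years[[col]] <- NA_real_
  for (tr in names(seasonal_by_treatment)) {
    s <- seasonal_by_treatment[[tr]]
    sel <- branch_years$treatment == tr
    idx <- match(branch_years$year[sel], s$hydro_year)
    for (col in cols) branch_years[[col]][sel] <- s[[col]][idx]
  }
  branch_years
}

#' Run the full branch-dissection pipeline
#'
#' Orchestrates climate aggregation, needle traits, functional ratios and the
#' default inference layer on validated input tables, returning every stage's
#' output plus a run manifest (seed, stage row counts). Omitting the segment
#' table disables only the `SA:LA/d` ratio, with a warning.
#'
#' @param needles,rings,climate needle table, ring table, and named list of
#'   per-treatment daily climate tables (paths or data frames).
#' @param segments optional segment table.
#' @param vpd_threshold exceedance threshold, kPa.
#' @param predictors two predictor columns for the mixed models.
#' @param seed RNG seed used by the bootstrap stages.
#' @param bootstrap_b bootstrap replicates for the slope comparisons.
#' @return list with `seasonal`, `period`, `area_model`, `traits`, `audit`,
#'   `ratios`, `lmem`, `slope_tests`, `manifest`.
#' @export
run_pipeline <- function(needles, rings, climate, segments = NULL,
                         vpd_threshold = 4.5,
                         predictors = c("ppt_premonsoon", "ppt_monsoon"),
                         seed = 1L, bootstrap_b = 2000L) {
  needles <- read_needles(needles)
  rings <- read_rings(rings)
  climate <- lapply(climate, read_daily_climate)
  if (!is.null(segments)) {
    segments <- read_segments(segments)
  } else {
    warning("no segment table supplied: SA:LA/d is disabled")
  }
  seasonal <- lapply(climate, summarize_seasons, threshold = vpd_threshold)
  period <- lapply(seasonal, period_stats)
  area_model <- fit_area_model(needles)
  traits <- summarize_traits(needles, area_model)
  audit <- ratio_audit(rings, needles, area_model, segments = segments)
  ratios <- branch_year_means(audit)
  d_l <- merge_climate_predictors(traits, seasonal)
  d_r <- merge_climate_predictors(ratios, seasonal)
  lmem <- list(
    needle_length = fit_lmem(d_l, "mean_length_mm", predictors),
    sa_la = fit_lmem(d_r, "sa_la", predictors)
  )
  if (!is.null(segments)) {
    lmem$sa_la_per_d <- fit_lmem(d_r, "sa_la_per_d", predictors)
  }
  set.seed(seed)
  treatments <- intersect(c("irrigated", "ambient", "droughted"),
                          unique(audit$treatment))
  slope_tests <- NULL
  if (length(treatments) >= 2L) {
    prs <- utils::combn(treatments, 2, simplify = FALSE)
    slope_tests <- do.call(rbind, lapply(prs, function(pr) {
      a <- audit[audit$treatment == pr[1], ]
      b <- audit[audit$treatment == pr[2], ]
      cbind(data.frame(group1 = pr[1], group2 = pr[2]),
            bootstrap_slope_difference(a$la_m2, a$sa_mm2 / 100,
                                       b$la_m2, b$sa_mm2 / 100,
                                       b = bootstrap_b))
    }))
  }
  manifest <- list(
    seed = seed, vpd_threshold = vpd_threshold, predictors = predictors,
    n_needles = nrow(needles), n_rings = nrow(rings),
    n_traits = nrow(traits), n_ratio_cells = nrow(audit),
    n_branch_years = nrow(ratios),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  list(seasonal = seasonal, period = period, area_model = area_model,
       traits = traits, audit = audit, ratios = ratios,
       lmem = lmem, slope_tests = slope_tests, manifest = manifest)
}
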