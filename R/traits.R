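#' Fit the needle adaxial-area allometry
#'
#' Ordinary least squares of measured adaxial area on the length-by-width
#' product, `A_ad = gamma + alpha * l * w`, used to predict the area of
#' needles whose adaxial face was not scanned (about 80% of needles in a
#' typical dissection campaign).
#'
#' @param needles data frame with columns `length_mm`, `width_mm`,
#'   `area_adaxial_mm2` (rows with `NA` area are ignored).
#' @return object of class `area_model`: list with `gamma` (mm2), `alpha`
#'   (dimensionless), `r2`, `n`.
#' @export
fit_area_model <- function(needles) {
  ok <- !is.na(needles$area_adaxial_mm2) &
    !is.na(needles$length_mm) & !is.na(needles$width_mm)
  d <- needles[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 needles with measured adaxial area")
  lw <- d$length_mm * d$width_mm
  if (stats::var(lw) <= 0) stop("degenerate design: l*w is constant across measured needles")
  fit <- stats::lm(d$area_adaxial_mm2 ~ lw)
  # R2 computed directly (summary.lm warns on noiseless fits)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((d$area_adaxial_mm2 - mean(d$area_adaxial_mm2))^2)
  structure(
    list(gamma = unname(stats::coef(fit)[1]),
         alpha = unname(stats::coef(fit)[2]),
         r2 = 1 - sse / sst,
         n = nrow(d)),
    class = "area_model"
  )
}

#' @export
print.area_model <- function(x, ...) {
  cat(sprintf("adaxial-area model: A_ad = %.4g + %.4g * l*w  (R2 = %.3f, n = %d)\n",
              x$gamma, x$alpha, x$r2, x$n))
  invisible(x)
}

#' Predict (or pass through) the adaxial needle area
#'
#' Applies the fitted allometry `gamma + alpha * l * w`; a measured area, when
#' supplied, takes precedence over the prediction. Negative predictions are
#' clamped to zero with a warning.
#'
#' @param model an [fit_area_model()] object.
#' @param length_mm,width_mm needle dimensions, mm.
#' @param measured_mm2 optional vector of measured areas (`NA` = unmeasured).
#' @return adaxial area in mm2.
#' @export
predict_adaxial_area <- function(model, length_mm, width_mm, measured_mm2 = NULL) {
  stopifnot(inherits(model, "area_model"))
  pred <- model$gamma + model$alpha * length_mm * width_mm
  if (any(pred < 0, na.rm = TRUE)) {
    warning(sum(pred < 0, na.rm = TRUE), " negative area prediction(s) clamped to 0")
    pred <- pmax(pred, 0)
  }
  if (!is.null(measured_mm2)) pred <- ifelse(is.na(measured_mm2), pred, measured_mm2)
  pred
}

#' Total needle surface area
#'
#' The abaxial face is taken to equal the adaxial face (the slight curvature
#' of the abaxial side is neglected), so total area is twice the adaxial area.
#'
#' @param area_adaxial_mm2 adaxial area, mm2.
#' @return total (adaxial + abaxial) area, mm2.
#' @export
total_needle_area <- function(area_adaxial_mm2) 2 * area_adaxial_mm2

#' Estimated number of stomata on a needle
#'
#' Linear stomatal density along rows, times needle length, times the total
#' number of rows on the two faces. Row counts are read to the nearest half
#' row, so the estimate need not be an integer.
#'
#' @param dlin_per_mm mean linear density of stomata within rows, stomata/mm.
#' @param length_mm needle length, mm.
#' @param rows_adaxial,rows_abaxial stomatal row counts (steps of 0.5 allowed).
#' @return estimated stomata per needle.
#' @export
stomata_per_needle <- function(dlin_per_mm, length_mm, rows_adaxial, rows_abaxial) {
  if (any(c(dlin_per_mm, length_mm, rows_adaxial, rows_abaxial) < 0, na.rm = TRUE)) {
    stop("stomatal inputs must be non-negative")
  }
  dlin_per_mm * length_mm * (rows_adaxial + rows_abaxial)
}

#' Stomatal density of a needle
#'
#' Stomata per unit needle surface: estimated stomata per needle divided by
#' total needle area `2 * A_ad`.
#'
#' @inheritParams stomata_per_needle
#' @param area_adaxial_mm2 adaxial area, mm2 (must be > 0).
#' @return stomatal density, stomata/mm2.
#' @export
stomatal_density <- function(dlin_per_mm, length_mm, rows_adaxial, rows_abaxial,
                             area_adaxial_mm2) {
  if (any(area_adaxial_mm2 <= 0, na.rm = TRUE)) stop("area_adaxial_mm2 must be > 0")
  stomata_per_needle(dlin_per_mm, length_mm, rows_adaxial, rows_abaxial) /
    (2 * area_adaxial_mm2)
}

#' Half-sphere stomatal pore geometry and gas constants
#'
#' Pinyon stomata are close to circular, so the pore is idealized as a
#' half-sphere of diameter `d_S`: pore depth `p = d_S / 2` and maximum pore
#' area `a_max = pi * (d_S / 2)^2`. Bundled with the physical constants
#' needed by [gsmax()]: diffusivity of water vapour in air and molar volume
#' of air, both at 25 degrees C by default.
#'
#' @param ds_um maximal stomatal diameter, micrometres (>= 0).
#' @param diffusivity_m2s diffusivity of water vapour in air, m2/s.
#' @param molar_volume_m3mol molar volume of air, m3/mol.
#' @return object of class `stomatal_geometry`: list with `a_max_um2`, `p_um`,
#'   `diffusivity_m2s`, `molar_volume_m3mol`.
#' @export
stomatal_geometry <- function(ds_um, diffusivity_m2s = 2.49e-5,
                              molar_volume_m3mol = 2.446e-2) {
  if (any(ds_um < 0, na.rm = TRUE)) stop("ds_um must be >= 0")
  if (diffusivity_m2s <= 0 || molar_volume_m3mol <= 0) {
    stop("diffusivity and molar volume must be > 0")
  }
  structure(
    list(a_max_um2 = pi * (ds_um / 2)^2,
         p_um = ds_um / 2,
         diffusivity_m2s = diffusivity_m2s,
         molar_volume_m3mol = molar_volume_m3mol),
    class = "stomatal_geometry"
  )
}

#' Maximal anatomical stomatal conductance
#'
#' The diffusion-limited upper bound on stomatal conductance implied by the
#' stomatal anatomy:
#' \deqn{g_{smax} = \frac{d}{v} \cdot
#'       \frac{a_{max} D_s}{p + \frac{\pi}{2}\sqrt{a_{max}/\pi}}}
#' with `d` the diffusivity of water vapour, `v` the molar volume of air,
#' `a_max` the maximum pore area, `p` the pore depth, and `D_s` the stomatal
#' density. Inputs arrive in field units (stomata/mm2, micrometres) and are
#' converted to SI internally.
#'
#' @param ds_per_mm2 stomatal density, stomata/mm2.
#' @param geometry a [stomatal_geometry()] object.
#' @return conductance in mol m-2 s-1.
#' @export
#' @examples
#' gsmax(40, stomatal_geometry(20))  # ~0.498 mol m-2 s-1
gsmax <- function(ds_per_mm2, geometry) {
  stopifnot(inherits(geometry, "stomatal_geometry"))
  if (any(ds_per_mm2 < 0, na.rm = TRUE)) stop("ds_per_mm2 must be >= 0")
  a_max_m2 <- geometry$a_max_um2 * 1e-12
  p_m <- geometry$p_um * 1e-6
  ds_m2 <- ds_per_mm2 * 1e6
  out <- numeric(length(ds_m2))
  degenerate <- a_max_m2 == 0
  if (any(degenerate & ds_m2 > 0)) {
    warning("degenerate pore (a_max = 0) with positive stomatal density; g_smax set to 0")
  }
  denom <- p_m + (pi / 2) * sqrt(a_max_m2 / pi)
  ok <- !degenerate
  out[ok] <- (geometry$diffusivity_m2s / geometry$molar_volume_m3mol) *
    (a_max_m2[ok] * ds_m2[ok]) / denom[ok]
  out
}

#' Branch-year evaporative-structure summary
#'
#' Pools needles into branch-by-formation-year cohorts and reports the mean
#' length, mean total needle area, mean stomata per needle, mean stomatal
#' density, and mean stomatal diameter. One maximal anatomical conductance is
#' derived per branch-year from the cohort means of `D_s` and `d_S` (the
#' anatomy enters [gsmax()] after averaging, not per needle). Needles without
#' stomatal subsample values contribute to length/area means only.
#'
#' @param needles needle table (see [read_needles()] for the column contract).
#' @param area_model an [fit_area_model()] object; fitted on `needles` when
#'   omitted.
#' @param geometry_constants list with `diffusivity_m2s`, `molar_volume_m3mol`
#'   overriding the 25 C defaults.
#' @return data frame keyed by `tree_id`, `branch_id`, `treatment`, `year`.
#' @export
summarize_traits <- function(needles, area_model = NULL,
                             geometry_constants = list()) {
  if (is.null(area_model)) area_model <- fit_area_model(needles)
  a_ad <- predict_adaxial_area(area_model, needles$length_mm, needles$width_mm,
                               needles$area_adaxial_mm2)
  has_stomata <- !is.na(needles$stomata_per_mm) &
    !is.na(needles$rows_adaxial) & !is.na(needles$rows_abaxial)
  ds <- rep(NA_real_, nrow(needles))
  ds[has_stomata] <- stomatal_density(
    needles$stomata_per_mm[has_stomata], needles$length_mm[has_stomata],
    needles$rows_adaxial[has_stomata], needles$rows_abaxial[has_stomata],
    a_ad[has_stomata]
  )
  n_stom <- rep(NA_real_, nrow(needles))
  n_stom[has_stomata] <- stomata_per_needle(
    needles$stomata_per_mm[has_stomata], needles$length_mm[has_stomata],
    needles$rows_adaxial[has_stomata], needles$rows_abaxial[has_stomata]
  )
  key <- interaction(needles$tree_id, needles$branch_id, needles$year, drop = TRUE)
  groups <- split(seq_len(nrow(needles)), key)
  const <- utils::modifyList(
    list(diffusivity_m2s = 2.49e-5, molar_volume_m3mol = 2.446e-2),
    geometry_constants
  )
  rows <- lapply(groups, function(idx) {
    g <- needles[idx, , drop = FALSE]
    mean_ds <- if (any(!is.na(ds[idx]))) mean(ds[idx], na.rm = TRUE) else NA_real_
    mean_diam <- if (any(!is.na(g$stomatal_diameter_um))) {
      mean(g$stomatal_diameter_um, na.rm = TRUE)
    } else NA_real_
    g_sm <- if (!is.na(mean_ds) && !is.na(mean_diam)) {
      gsmax(mean_ds, stomatal_geometry(mean_diam,
                                       diffusivity_m2s = const$diffusivity_m2s,
                                       molar_volume_m3mol = const$molar_volume_m3mol))
    } else NA_real_
    data.frame(
      tree_id = g$tree_id[1], branch_id = g$branch_id[1],
      treatment = g$treatment[1], year = g$year[1],
      n_needles = nrow(g),
      mean_length_mm = mean(g$length_mm),
      mean_total_area_mm2 = mean(total_needle_area(a_ad[idx])),
      mean_stomata_per_needle = if (any(!is.na(n_stom[idx]))) {
        mean(n_stom[idx], na.rm = TRUE)
      } else NA_real_,
      stomatal_density_mm2 = mean_ds,
      stomatal_diameter_um = mean_diam,
      gsmax_mol_m2_s = g_sm
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tree_id, out$branch_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
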