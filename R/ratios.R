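#' Leaf area of a year cohort distal to a twig section
#'
#' Total surface area (both faces) of the needles formed in year `y` that sit
#' between the branch tip and the section whose innermost ring dates to year
#' `gamma`. Needles grow on the primary axis, so every year-`y` needle is
#' distal to any section with `gamma < y`; the cohort leaf area therefore
#' depends on the year only. Returned in m2 (needle areas are mm2).
#'
#' @param needles needle table for one branch (or many; filtered by
#'   `branch_id` when given).
#' @param year formation year of the cohort.
#' @param area_model an [fit_area_model()] object used to fill unmeasured
#'   adaxial areas.
#' @param branch_id optional branch filter.
#' @return leaf area in m2; `0` with attribute `flagged = TRUE` when the
#'   branch carries no needles of that year (the downstream ratio is then
#'   undefined, not zero).
#' @export
leaf_area_cohort <- function(needles, year, area_model, branch_id = NULL) {
  if (!is.null(branch_id)) needles <- needles[needles$branch_id == branch_id, , drop = FALSE]
  sel <- needles$year == year
  if (!any(sel)) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  a_ad <- predict_adaxial_area(area_model, needles$length_mm[sel],
                               needles$width_mm[sel], needles$area_adaxial_mm2[sel])
  sum(total_needle_area(a_ad)) * 1e-6
}

#' Annual sapwood-to-leaf-area ratio for one (year, section) cell
#'
#' `SA:LA_{y,Gamma}`: the ring area added in year `y` on the section of
#' genesis year `Gamma`, over the leaf area of the year-`y` needle cohort
#' distal to that section. Ring areas arrive in mm2 and are reported per cm2
#' (divided by 100); leaf area is in m2, so the ratio is in cm2/m2.
#'
#' @param sa_mm2 ring area, mm2.
#' @param la_m2 cohort leaf area, m2 (> 0; a zero leaf area means the ratio is
#'   undefined and the cell must be excluded, not set to zero).
#' @return ratio in cm2/m2.
#' @export
ratio_year_section <- function(sa_mm2, la_m2) {
  if (any(la_m2 <= 0, na.rm = TRUE)) {
    stop("leaf area must be > 0; cells with no needle cohort are excluded, not zeroed")
  }
  (sa_mm2 / 100) / la_m2
}

#' Discard apical ring values
#'
#' Removes the innermost ring of every twig section (the `y == Gamma` cells,
#' primary xylem); these never contribute to the branch averages.
#'
#' @param rings ring table with columns `ring_year` and `section_genesis_year`.
#' @return the table without apical rows.
#' @export
drop_apical <- function(rings) {
  rings[rings$ring_year != rings$section_genesis_year, , drop = FALSE]
}

#' Distance from a twig section to the tip as of year y
#'
#' The section cut in the year-`Gamma` elongation segment is placed at that
#' segment's proximal end (`position = "proximal"`, the default), so the
#' distance to the tip as of year `y` is the sum of the annual segment
#' lengths for years `Gamma..y`; `"midpoint"` instead counts half of the
#' genesis-year segment. Converted mm to m.
#'
#' @param segments segment table with columns `branch_id`, `year`, `length_mm`.
#' @param branch_id branch key.
#' @param year ring year `y`.
#' @param genesis_year section genesis year `Gamma` (`<= year`).
#' @param position `"proximal"` or `"midpoint"` section placement.
#' @return distance in m.
#' @export
distance_to_tip <- function(segments, branch_id, year, genesis_year,
                            position = c("proximal", "midpoint")) {
  position <- match.arg(position)
  if (genesis_year > year) stop("genesis_year must be <= year")
  segs <- segments[segments$branch_id == branch_id, , drop = FALSE]
  need <- genesis_year:year
  len <- segs$length_mm[match(need, segs$year)]
  if (anyNA(len)) {
    stop("missing segment length(s) for branch ", branch_id, ", year(s) ",
         paste(need[is.na(len)], collapse = ", "))
  }
  if (position == "midpoint") len[1] <- len[1] / 2
  sum(len) / 1000
}

#' Per-(year, section) ratio audit table
#'
#' Builds every defined `SA:LA_{y,Gamma}` cell for the supplied branches:
#' apical cells (`y == Gamma`) are discarded, missing rings propagate as
#' absent cells (never zeros), and cells whose year has no needle cohort are
#' excluded and flagged. When segment lengths are available the per-cell
#' `SA:LA/d` quotient is added.
#'
#' @param rings ring table (see [read_rings()]).
#' @param needles needle table.
#' @param area_model an [fit_area_model()] object (fitted on `needles` when
#'   omitted).
#' @param segments optional segment table; when `NULL`, `sa_la_per_d` is
#'   omitted.
#' @param position section placement passed to [distance_to_tip()].
#' @return data frame with one row per retained (branch, y, Gamma) cell:
#'   `sa_mm2`, `la_m2`, `sa_la` (cm2/m2), `d_m`, `sa_la_per_d` (m2/m3).
#' @export
ratio_audit <- function(rings, needles, area_model = NULL, segments = NULL,
                        position = "proximal") {
  if (is.null(area_model)) area_model <- fit_area_model(needles)
  bad <- rings$section_genesis_year > rings$ring_year
  if (any(bad)) {
    stop("ring(s) predate their section (Gamma > y) at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  rings <- drop_apical(rings)
  rings <- rings[!rings$missing & !is.na(rings$ring_area_mm2), , drop = FALSE]
  if (nrow(rings) == 0L) {
    stop("no non-apical, non-missing rings to compute ratios from")
  }
  # leaf area per (branch, year) cohort; identical across sections on the
  # primary axis, so computed once per pair
  keys <- unique(rings[c("branch_id", "ring_year")])
  keys$la_m2 <- mapply(function(b, y) {
    as.numeric(leaf_area_cohort(needles, y, area_model, branch_id = b))
  }, keys$branch_id, keys$ring_year)
  la <- keys$la_m2[match(paste(rings$branch_id, rings$ring_year),
                         paste(keys$branch_id, keys$ring_year))]
  defined <- la > 0
  n_flagged <- sum(!defined)
  out <- rings[defined, , drop = FALSE]
  out$la_m2 <- la[defined]
  out$sa_la <- ratio_year_section(out$ring_area_mm2, out$la_m2)
  if (!is.null(segments)) {
    out$d_m <- mapply(function(b, y, g) {
      distance_to_tip(segments, b, y, g, position = position)
    }, out$branch_id, out$ring_year, out$section_genesis_year)
    out$sa_la_per_d <- (out$sa_la * 1e-4) / out$d_m  # cm2/m2 -> m2/m2, per m
  }
  names(out)[names(out) == "ring_area_mm2"] <- "sa_mm2"
  # treatment lives on the needle table; carry it over by branch
  if (!"treatment" %in% names(out) && "treatment" %in% names(needles)) {
    out$treatment <- needles$treatment[match(out$branch_id, needles$branch_id)]
  }
  attr(out, "n_flagged_no_cohort") <- n_flagged
  rownames(out) <- NULL
  out
}

#' Branch-year means of the functional ratios
#'
#' Averages `SA:LA_{y,Gamma}` arithmetically across the sections (`Gamma`) of
#' each branch for each year, and likewise averages the per-section quotients
#' `SA:LA_{y,Gamma} / d_{y,Gamma}` (mean of quotients, not quotient of
#' means). Only post-apical-discard, defined cells contribute; a branch-year
#' with no valid section is omitted.
#'
#' @param audit output of [ratio_audit()].
#' @return data frame keyed by `tree_id`, `branch_id`, `treatment`, `year`
#'   with `sa_la` (cm2/m2), `sa_la_per_d` (m2/m3, when distances were
#'   available) and `n_sections`.
#' @export
branch_year_means <- function(audit) {
  key <- interaction(audit$branch_id, audit$ring_year, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(audit)), key), function(idx) {
    g <- audit[idx, , drop = FALSE]
    data.frame(
      tree_id = g$tree_id[1], branch_id = g$branch_id[1],
      treatment = g$treatment[1], year = g$ring_year[1],
      sa_la = mean(g$sa_la),
      sa_la_per_d = if ("sa_la_per_d" %in% names(g)) mean(g$sa_la_per_d) else NA_real_,
      n_sections = nrow(g)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tree_id, out$branch_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Steady-state xylem water-potential gradient
#'
#' Diagnostic helper for the hydraulic framing: under steady state the
#' gradient along the pathway is `dPsi/dx = E / k_L` with the leaf-specific
#' conductivity decomposed as `k_L = k_S * A_S:A_L`.
#'
#' @param e evaporative flux density.
#' @param k_s specific hydraulic conductivity (> 0).
#' @param as_al sapwood-to-leaf-area ratio (> 0).
#' @return the water-potential gradient, same unit system as the inputs.
#' @export
potential_gradient <- function(e, k_s, as_al) {
  if (any(k_s * as_al <= 0, na.rm = TRUE)) stop("k_s * as_al must be > 0")
  e / (k_s * as_al)
}
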