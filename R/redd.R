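#' Project geometry: project area and leakage belt
#'
#' @param project_mask Logical matrix: pixels inside the project
#'   implementation area.
#' @param leakage_mask Logical matrix: pixels in the surrounding leakage
#'   belt. Must be disjoint from the project area and on the same grid.
#' @return A `project_geometry`.
#' @export
project_geometry <- function(project_mask, leakage_mask) {
  if (!identical(dim(project_mask), dim(leakage_mask))) {
    stop("masks are not on the same grid")
  }
  if (any(project_mask & leakage_mask, na.rm = TRUE)) {
    stop("project area and leakage belt overlap")
  }
  structure(list(project = project_mask, leakage = leakage_mask),
            class = "project_geometry")
}

#' Build a leakage belt as a buffer around the project area
#'
#' Dilates the project mask by `width_px` pixels (Chebyshev distance) and
#' takes the ring outside the project area, a simple stand-in for a
#' GIS buffer.
#'
#' @param project_mask Logical matrix.
#' @param width_px Belt width in pixels.
#' @export
leakage_belt_buffer <- function(project_mask, width_px = 5) {
  m <- project_mask
  for (k in seq_len(width_px)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m <- m | up | dn | lf | rt |
      rbind(lf[-1, , drop = FALSE], FALSE) | rbind(FALSE, lf[-nrow(m), , drop = FALSE]) |
      rbind(rt[-1, , drop = FALSE], FALSE) | rbind(FALSE, rt[-nrow(m), , drop = FALSE])
  }
  project_geometry(project_mask, m & !project_mask)
}

zone_forest_ha <- function(mask_map, zone) {
  px_ha <- mask_map$pixel_size^2 / 1e4
  sum(mask_map$values[zone] == 1, na.rm = TRUE) * px_ha
}

#' Annual deforestation series per accounting zone
#'
#' Converts forest/non-forest masks at projection epochs into annual
#' hectares of forest loss per zone (project area and leakage belt) by
#' linear interpolation of forest area between epochs; the last interval's
#' rate is carried forward if the horizon extends beyond the final mask.
#' Negative values (net recovery) are permitted and flagged.
#'
#' @param forest_masks_by_year Named (by year) list of binary forest
#'   [lulc_map()]s from [binarize_forest()], >= 2 epochs.
#' @param geometry A [project_geometry()] on the same grid.
#' @param horizon Number of accounting years (default 30), starting the
#'   year after the first epoch.
#' @return Data frame: `zone`, `year`, `deforestation_ha` (one row per
#'   zone-year), with attribute `has_recovery`.
#' @export
deforestation_series <- function(forest_masks_by_year, geometry,
                                 horizon = 30) {
  if (length(forest_masks_by_year) < 2) stop("need >= 2 forest masks")
  years <- suppressWarnings(as.numeric(names(forest_masks_by_year)))
  if (anyNA(years)) stop("forest masks must be named by calendar year")
  for (m in forest_masks_by_year) {
    if (!identical(dim(m$values), dim(geometry$project))) {
      stop("mask grids are not aligned with the project geometry")
    }
  }
  zones <- list(project = geometry$project, leakage = geometry$leakage)
  out <- list()
  for (zn in names(zones)) {
    areas <- vapply(forest_masks_by_year, zone_forest_ha, zone = zones[[zn]],
                    numeric(1))
    # annual loss rate within each observed interval (ha/yr, loss positive)
    rates <- -diff(areas) / diff(years)
    yr <- years[1] + seq_len(horizon)
    iv <- findInterval(yr, years[-1], left.open = TRUE) + 1
    iv[iv > length(rates)] <- length(rates) # carry last rate forward
    out[[zn]] <- data.frame(zone = zn, year = yr,
                            deforestation_ha = rates[iv])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "has_recovery") <- any(res$deforestation_ha < 0)
  res
}

#' Emission factor
#'
#' tCO2e released per hectare of forest converted to non-forest. The
#' default of 10 tCO2e/ha is the ratio implied by the headline baseline
#' figures of the case study this package emulates (about 2.0 MtCO2e from
#' about 0.2 Mha); it is a reporting convention, not a biome carbon
#' density, and should be replaced with a site-appropriate value for real
#' accounting.
#'
#' @param tCO2e_per_ha Nonnegative factor (default 10).
#' @export
emission_factor <- function(tCO2e_per_ha = 10) {
  if (tCO2e_per_ha < 0) stop("emission factor must be >= 0")
  structure(list(tCO2e_per_ha = tCO2e_per_ha), class = "emission_factor")
}

#' Convert a deforestation series to annual emissions
#'
#' emissions = hectares x factor per year; the sign follows the series
#' (negative = net sequestration from recovery).
#'
#' @param series Data frame with `deforestation_ha` (from
#'   [deforestation_series()]) or a plain numeric vector of ha/yr.
#' @param ef An [emission_factor()] or a plain nonnegative number.
#' @return The series with an `emissions_tCO2e` column (or a numeric
#'   vector when the input was a vector).
#' @export
emissions_from_deforestation <- function(series, ef = emission_factor()) {
  f <- if (inherits(ef, "emission_factor")) ef$tCO2e_per_ha else ef
  if (f < 0) stop("emission factor must be >= 0")
  if (is.numeric(series)) return(series * f)
  series$emissions_tCO2e <- series$deforestation_ha * f
  series
}

#' With-project scenario: actual and leakage series
#'
#' Project effectiveness e removes a fraction of baseline deforestation
#' inside the project area (actual = (1 - e) baseline) and a fraction d of
#' the avoided deforestation is displaced into the leakage belt
#' (leakage = d e baseline).
#'
#' @param baseline_series Numeric vector of annual baseline values
#'   (hectares or emissions) in the project area.
#' @param effectiveness e in [0, 1].
#' @param displacement d in [0, 1].
#' @return List with `actual` and `leakage` vectors.
#' @export
scenario_with_project <- function(baseline_series, effectiveness,
                                  displacement) {
  if (effectiveness < 0 || effectiveness > 1) stop("effectiveness not in [0,1]")
  if (displacement < 0 || displacement > 1) stop("displacement not in [0,1]")
  list(actual = (1 - effectiveness) * baseline_series,
       leakage = displacement * effectiveness * baseline_series)
}

#' Net REDD emission reduction
#'
#' C_REDD = C_Baseline - C_Actual - C_Leakage, the exact accounting
#' identity of avoided-deforestation crediting (all terms tCO2e).
#'
#' @param c_baseline,c_actual,c_leakage Scenario totals in tCO2e.
#' @export
compute_c_redd <- function(c_baseline, c_actual, c_leakage = 0) {
  stopifnot(is.finite(c_baseline), is.finite(c_actual),
            is.finite(c_leakage))
  c_baseline - c_actual - c_leakage
}

#' Assemble the REDD accounting ledger
#'
#' From a baseline annual deforestation series in the project area, applies
#' the with-project scenario, converts to emissions, and accumulates the
#' BioCF-style scenario terms over the horizon.
#'
#' @param baseline_def_ha Numeric vector: annual baseline deforestation in
#'   the project area (ha/yr), one entry per horizon year.
#' @param years Calendar years parallel to `baseline_def_ha`.
#' @param ef An [emission_factor()].
#' @param effectiveness,displacement Scenario parameters (see
#'   [scenario_with_project()]).
#' @param reporting_period_years Reporting interval (default 5).
#' @return A `redd_ledger`: `annual` data frame (zone, year, deforestation,
#'   emissions, cumulative emissions), totals `C_Baseline`, `C_Actual`,
#'   `C_Leakage`, `C_REDD`, and the configuration.
#' @export
redd_ledger <- function(baseline_def_ha, years = seq_along(baseline_def_ha),
                        ef = emission_factor(), effectiveness = 0.8,
                        displacement = 0.1, reporting_period_years = 5) {
  sc <- scenario_with_project(baseline_def_ha, effectiveness, displacement)
  f <- if (inherits(ef, "emission_factor")) ef$tCO2e_per_ha else ef
  zones <- list(baseline = baseline_def_ha, actual = sc$actual,
                leakage = sc$leakage)
  annual <- do.call(rbind, lapply(names(zones), function(zn) {
    em <- zones[[zn]] * f
    data.frame(zone = zn, year = years, deforestation_ha = zones[[zn]],
               emissions_tCO2e = em, cumulative_tCO2e = cumsum(em))
  }))
  rownames(annual) <- NULL
  totals <- vapply(zones, function(z) sum(z) * f, numeric(1))
  structure(list(annual = annual,
                 C_Baseline = totals[["baseline"]],
                 C_Actual = totals[["actual"]],
                 C_Leakage = totals[["leakage"]],
                 C_REDD = compute_c_redd(totals[["baseline"]],
                                         totals[["actual"]],
                                         totals[["leakage"]]),
                 horizon_years = length(years),
                 reporting_period_years = reporting_period_years,
                 emission_factor = f,
                 effectiveness = effectiveness,
                 displacement = displacement),
            class = "redd_ledger")
}

#' @export
print.redd_ledger <- function(x, ...) {
  cat(sprintf(paste0("<redd_ledger> %d-year horizon, EF = %g tCO2e/ha, ",
                     "e = %g, d = %g\n"),
              x$horizon_years, x$emission_factor, x$effectiveness,
              x$displacement))
  fmt <- function(v) format(round(v), big.mark = ",", scientific = FALSE)
  cat("  C_Baseline =", fmt(x$C_Baseline), "tCO2e\n")
  cat("  C_Actual   =", fmt(x$C_Actual), "tCO2e\n")
  cat("  C_Leakage  =", fmt(x$C_Leakage), "tCO2e\n")
  cat("  C_REDD     =", fmt(x$C_REDD), "tCO2e\n")
  invisible(x)
}

#' Periodic (default 5-year) reporting table
#'
#' Per-zone period sums and averages of deforestation and emissions, with
#' a cumulative emissions column; a horizon not divisible by the period
#' yields a short final period.
#'
#' @param ledger A [redd_ledger()].
#' @param period_years Reporting interval; defaults to the ledger's.
#' @return Data frame, one row per zone-period.
#' @export
five_year_report <- function(ledger, period_years =
                               ledger$reporting_period_years) {
  ann <- ledger$annual
  out <- list()
  for (zn in unique(ann$zone)) {
    z <- ann[ann$zone == zn, ]
    n <- nrow(z)
    pid <- (seq_len(n) - 1) %/% period_years + 1
    for (pp in unique(pid)) {
      rows <- z[pid == pp, ]
      out[[length(out) + 1]] <- data.frame(
        zone = zn, period = pp,
        from_year = min(rows$year), to_year = max(rows$year),
        years = nrow(rows),
        deforestation_ha = sum(rows$deforestation_ha),
        mean_deforestation_ha_yr = mean(rows$deforestation_ha),
        emissions_tCO2e = sum(rows$emissions_tCO2e),
        mean_emissions_tCO2e_yr = mean(rows$emissions_tCO2e),
        cumulative_tCO2e = rows$cumulative_tCO2e[nrow(rows)])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
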