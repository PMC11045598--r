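#' Cross-tabulate two categorical maps
#'
#' Counts pixels by (class at t1, class at t2); pixels nodata in either map
#' are excluded so transition estimates are not biased by masking.
#'
#' @param map_t1,map_t2 [lulc_map()]s on the same grid with the same legend.
#' @return A `crosstab`: `counts` (rows = earlier class, cols = later
#'   class), `class_codes`, `pixel_area` (m^2).
#' @export
crosstab <- function(map_t1, map_t2) {
  check_same_grid(map_t1, map_t2)
  ok <- !is.na(map_t1$values) & !is.na(map_t2$values)
  lev <- map_t1$class_codes
  cm <- table(factor(map_t1$values[ok], levels = lev),
              factor(map_t2$values[ok], levels = lev))
  counts <- matrix(as.integer(cm), length(lev), length(lev),
                   dimnames = list(map_t1$class_names, map_t1$class_names))
  structure(list(counts = counts, class_codes = lev,
                 class_names = map_t1$class_names,
                 pixel_area = map_t1$pixel_size^2),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("<crosstab> (rows = earlier, cols = later), pixel area",
      x$pixel_area, "m^2\n")
  print(x$counts)
  invisible(x)
}

#' Per-class areas of a categorical map
#'
#' @param map A [lulc_map()].
#' @param pixel_area Pixel area in m^2 (default from the map's pixel size).
#' @return Named numeric vector of areas in hectares.
#' @export
area_stats <- function(map, pixel_area = map$pixel_size^2) {
  if (pixel_area <= 0) stop("pixel_area must be positive")
  counts <- tabulate(match(map$values[!is.na(map$values)], map$class_codes),
                     nbins = length(map$class_codes))
  stats::setNames(counts * pixel_area / 1e4, map$class_names)
}

#' Multi-epoch change report
#'
#' Per-epoch class areas (ha) plus per-interval absolute (ha) and percent
#' change with gain/loss direction labels. Percent change is
#' 100 (A2 - A1)/A1 and is `NA` (flagged undefined) when the baseline area
#' is zero.
#'
#' @param maps_by_year Named (by year) list of [lulc_map()]s, >= 2 epochs.
#' @param pixel_area Pixel area in m^2.
#' @return A `change_report`: `areas` (epoch x class data frame, ha) and
#'   `intervals` (long data frame of changes).
#' @export
change_report <- function(maps_by_year,
                          pixel_area = maps_by_year[[1]]$pixel_size^2) {
  if (length(maps_by_year) < 2) stop("need >= 2 epochs")
  years <- names(maps_by_year)
  if (is.null(years)) years <- as.character(seq_along(maps_by_year))
  areas <- t(vapply(maps_by_year, area_stats, pixel_area = pixel_area,
                    numeric(length(maps_by_year[[1]]$class_codes))))
  rownames(areas) <- years
  iv <- list()
  for (k in seq_len(length(maps_by_year) - 1)) {
    a1 <- areas[k, ]
    a2 <- areas[k + 1, ]
    delta <- a2 - a1
    pct <- ifelse(a1 > 0, 100 * delta / a1, NA_real_)
    iv[[k]] <- data.frame(
      from_year = years[k], to_year = years[k + 1],
      class = colnames(areas), area_t1_ha = as.numeric(a1),
      area_t2_ha = as.numeric(a2), change_ha = as.numeric(delta),
      change_pct = as.numeric(pct),
      direction = ifelse(delta > 0, "gain", ifelse(delta < 0, "loss",
                                                   "stable")),
      row.names = NULL)
  }
  structure(list(areas = as.data.frame(areas),
                 intervals = do.call(rbind, iv)),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat("<change_report> class areas (ha):\n")
  print(round(x$areas))
  cat("\nintervals:\n")
  print(x$intervals)
  invisible(x)
}
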