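#' Categorical land-cover raster
#'
#' In-memory container for a single-layer categorical map: an integer matrix
#' of class codes (row-major grid, top-left origin) with `NA` marking nodata,
#' the legal class codes, optional class names, and the pixel edge length in
#' metres. Every stage of the pipeline consumes and produces this type.
#'
#' @param values Integer matrix of class codes; `NA` = nodata.
#' @param class_codes Integer vector of legal codes (order defines matrix
#'   row/column order in crosstabs and transition matrices).
#' @param class_names Optional character vector parallel to `class_codes`.
#' @param pixel_size Pixel edge length in metres (default 30, Landsat scale).
#' @return An object of class `lulc_map`.
#' @export
lulc_map <- function(values, class_codes, class_names = NULL, pixel_size = 30) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  class_codes <- as.integer(class_codes)
  if (anyDuplicated(class_codes)) stop("duplicate class codes")
  bad <- setdiff(unique(values[!is.na(values)]), class_codes)
  if (length(bad) > 0) {
    stop("values contain codes outside class_codes: ", paste(bad, collapse = ", "))
  }
  if (is.null(class_names)) class_names <- as.character(class_codes)
  if (length(class_names) != length(class_codes)) {
    stop("class_names must be parallel to class_codes")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a positive scalar (metres)")
  }
  structure(
    list(values = values, class_codes = class_codes,
         class_names = as.character(class_names), pixel_size = pixel_size),
    class = "lulc_map"
  )
}

#' @export
print.lulc_map <- function(x, ...) {
  cat(sprintf("<lulc_map> %d x %d pixels @ %g m, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              length(x$class_codes), paste(x$class_names, collapse = ", ")))
  tab <- table(factor(x$values, levels = x$class_codes))
  names(tab) <- x$class_names
  print(tab)
  nd <- sum(is.na(x$values))
  if (nd > 0) cat(nd, "nodata pixels\n")
  invisible(x)
}

#' @export
dim.lulc_map <- function(x) dim(x$values)

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size))
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("maps are not on the same grid")
  if (!identical(a$class_codes, b$class_codes)) {
    stop("maps do not share a class set")
  }
  invisible(TRUE)
}

#' Continuous driver raster
#'
#' A named continuous surface (elevation, slope, aspect or a distance field)
#' used as an explanatory variable for transition-potential modelling.
#' Distance fields must be nonnegative; all valid pixels must be finite.
#'
#' @param name Driver name, e.g. `"elevation"` or `"dist_road"`.
#' @param values Numeric matrix; `NA` = nodata.
#' @param units Unit string (default `"m"`).
#' @return An object of class `driver_field`.
#' @export
driver_field <- function(name, values, units = "m") {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  v <- values[!is.na(values)]
  if (any(!is.finite(v))) stop("driver '", name, "' has non-finite valid pixels")
  if (grepl("^dist", name) && any(v < 0)) {
    stop("distance driver '", name, "' has negative values")
  }
  structure(list(name = name, values = values, units = units),
            class = "driver_field")
}

#' @export
print.driver_field <- function(x, ...) {
  cat(sprintf("<driver_field> %s [%s], %d x %d, range %.3g..%.3g\n",
              x$name, x$units, nrow(x$values), ncol(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

# ---- ASCII-grid serialization ------------------------------------------------
# Plain-text raster format (ESRI ASCII grid). Categorical maps use an integer
# nodata code (255); continuous layers use -9999. This replaces binary GeoTIFF
# so that all artifacts are text.

#' Write a raster to an ESRI ASCII grid file
#'
#' @param x A `lulc_map`, `driver_field`, or plain matrix.
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Nodata sentinel written in place of `NA`.
#' @export
write_asc <- function(x, path, nodata = if (inherits(x, "lulc_map")) 255 else -9999) {
  m <- if (is.matrix(x)) x else x$values
  px <- if (inherits(x, "lulc_map")) x$pixel_size else 30
  hdr <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", 0),
    paste("yllcorner", 0),
    paste("cellsize", px),
    paste("NODATA_value", nodata)
  )
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path Input file path.
#' @param class_codes If given, the result is a [lulc_map()] with these codes;
#'   otherwise a plain numeric matrix with `NA` nodata is returned.
#' @param class_names Optional class names for the categorical case.
#' @export
read_asc <- function(path, class_codes = NULL, class_names = NULL) {
  lines <- readLines(path, n = 6)
  hdr <- strsplit(trimws(lines), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != val[["nrows"]] || ncol(m) != val[["ncols"]]) {
    stop("grid dimensions disagree with header in ", path)
  }
  m[m == val[["nodata_value"]]] <- NA
  if (is.null(class_codes)) return(m)
  lulc_map(m, class_codes, class_names, pixel_size = val[["cellsize"]])
}
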