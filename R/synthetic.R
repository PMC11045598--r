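#' Seeded synthetic landscape scenario
#'
#' Bundles everything needed to generate a multitemporal categorical
#' land-cover world with known ground truth: grid geometry, the six-class
#' legend, per-interval true transition matrices, driver-field models with
#' their effect weights on transition odds, per-class spectral signatures,
#' and a single integer seed that fans out to per-operation substreams.
#'
#' The defaults describe a temperate mountain-forest watershed: forest is the
#' dominant class, epochs span 1985-2020 with a deforestation phase
#' (1985-2000) followed by a recovery phase (2000-2020), elevation spans
#' 432-3800 m, and conversion pressure concentrates at low elevation and
#' near roads.
#'
#' @param grid_rows,grid_cols Grid size in pixels.
#' @param pixel_size Pixel edge (m), default 30.
#' @param class_codes Integer codes for the classes (>= 2 required).
#' @param class_names Class names parallel to `class_codes`.
#' @param class_weights Initial-epoch prevalence weights (sum 1).
#' @param epoch_years Strictly increasing calendar years, one map per epoch.
#' @param true_transition_matrices List of row-stochastic matrices, one per
#'   consecutive epoch pair. Default: [default_transition_matrices()].
#' @param driver_spec Driver models and effect weights;
#'   see [default_driver_spec()].
#' @param spectral_signatures Per-class per-band reflectance mean/sd;
#'   see [default_spectral_signatures()].
#' @param burn_in Number of pre-observation intervals the landscape is
#'   evolved under the first transition matrix before the first epoch is
#'   recorded (default 2), so the observed series starts near the regime's
#'   quasi-equilibrium instead of the thresholded initial map's transient.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(grid_rows = 150, grid_cols = 150,
                               pixel_size = 30,
                               class_codes = 1:6,
                               class_names = c("forest", "rangeland",
                                               "cropland", "barren",
                                               "artificial", "water"),
                               class_weights = c(0.45, 0.25, 0.12,
                                                 0.10, 0.05, 0.03),
                               epoch_years = c(1985, 1990, 1995, 2000,
                                               2010, 2015, 2020),
                               true_transition_matrices =
                                 default_transition_matrices(class_names,
                                                             length(epoch_years) - 1),
                               driver_spec = default_driver_spec(class_names),
                               spectral_signatures =
                                 default_spectral_signatures(class_names),
                               burn_in = 2L,
                               seed = 1L) {
  if (length(class_codes) < 2) stop("configuration error: need >= 2 classes")
  if (length(class_weights) != length(class_codes)) {
    stop("class_weights must be parallel to class_codes")
  }
  if (any(class_weights < 0) || sum(class_weights) <= 0) {
    stop("class_weights must be nonnegative with positive sum")
  }
  class_weights <- class_weights / sum(class_weights)
  if (is.unsorted(epoch_years, strictly = TRUE)) {
    stop("epoch_years must be strictly increasing")
  }
  if (length(true_transition_matrices) != length(epoch_years) - 1) {
    stop("need one transition matrix per consecutive epoch pair")
  }
  J <- length(class_codes)
  for (M in true_transition_matrices) {
    check_stochastic(M, J)
  }
  if (any(spectral_signatures$sd < 0)) stop("spectral sds must be >= 0")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         pixel_size = pixel_size, class_codes = as.integer(class_codes),
         class_names = class_names, class_weights = class_weights,
         epoch_years = as.integer(epoch_years),
         true_transition_matrices = true_transition_matrices,
         driver_spec = driver_spec,
         spectral_signatures = spectral_signatures,
         burn_in = as.integer(burn_in),
         seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

check_stochastic <- function(M, J = nrow(M), tol = 1e-9) {
  if (!is.matrix(M) || nrow(M) != J || ncol(M) != J) {
    stop("transition matrix must be ", J, "x", J)
  }
  if (any(M < 0) || any(M > 1)) stop("transition probabilities outside [0,1]")
  if (any(abs(rowSums(M) - 1) > tol)) {
    stop("transition matrix rows must sum to 1 (tolerance ", tol, ")")
  }
  invisible(TRUE)
}

#' Default per-interval transition matrices
#'
#' A deforestation phase for the first three intervals (net forest loss to
#' rangeland and cropland) followed by recovery intervals (rangeland and
#' cropland reverting to forest), emulating a watershed that loses forest
#' to 2000 and regains it afterwards. All rows are row-stochastic.
#'
#' @param class_names The six class names in legend order.
#' @param n_intervals Number of consecutive epoch pairs.
#' @export
default_transition_matrices <- function(class_names = c("forest", "rangeland",
                                                        "cropland", "barren",
                                                        "artificial", "water"),
                                        n_intervals = 6) {
  J <- length(class_names)
  decline <- matrix(0, J, J, dimnames = list(class_names, class_names))
  diag(decline) <- 1
  # forest loss to rangeland/cropland, slow urbanisation of cropland;
  # persistence ~0.98 per 5-year interval keeps gross change in the low
  # single-digit percent range typical of classified map series
  decline["forest", ] <- c(0.980, 0.012, 0.007, 0.001, 0, 0)
  decline["rangeland", ] <- c(0.005, 0.985, 0.005, 0.0025, 0.0025, 0)
  decline["cropland", ] <- c(0.003, 0.004, 0.985, 0.003, 0.005, 0)
  decline["barren", ] <- c(0.002, 0.008, 0.004, 0.985, 0.001, 0)
  decline["artificial", ] <- c(0, 0, 0, 0, 1, 0)
  recovery <- matrix(0, J, J, dimnames = list(class_names, class_names))
  diag(recovery) <- 1
  recovery["forest", ] <- c(0.995, 0.003, 0.002, 0, 0, 0)
  recovery["rangeland", ] <- c(0.030, 0.960, 0.005, 0.0025, 0.0025, 0)
  recovery["cropland", ] <- c(0.012, 0.004, 0.980, 0.001, 0.003, 0)
  recovery["barren", ] <- c(0.004, 0.010, 0.002, 0.983, 0.001, 0)
  recovery["artificial", ] <- c(0, 0, 0, 0, 1, 0)
  n_decline <- min(3, n_intervals)
  c(rep(list(decline), n_decline),
    rep(list(recovery), max(0, n_intervals - n_decline)))
}

#' Default driver specification
#'
#' Two smoothed random fields: elevation (432-3800 m, the study-area style
#' altitude range) and distance to road (0-5000 m). Effect weights act on the
#' per-destination log-odds of the transition kernel: conversion to cropland
#' and artificial land is favoured at low elevation and near roads, and
#' reversion to forest is favoured away from them. The weight magnitudes
#' (1.5 per standard deviation on the conversion destinations) concentrate
#' change in space strongly enough that a calibrated projection recovers
#' most conversion locations, while realized per-interval forest change
#' stays in the low single-digit-percent regime.
#'
#' @param class_names The class names in legend order.
#' @export
default_driver_spec <- function(class_names = c("forest", "rangeland",
                                                "cropland", "barren",
                                                "artificial", "water")) {
  J <- length(class_names)
  eff <- function(v) stats::setNames(v, class_names)
  list(
    elevation = list(units = "m", min = 432, max = 3800,
                     effect = eff(c(0.75, 0, -1.5, 0, -1.5, 0))),
    dist_road = list(units = "m", min = 0, max = 5000,
                     effect = eff(c(0.75, 0, -1.5, 0, -1.5, 0)))
  )
}

#' Default per-class spectral signatures
#'
#' Six-band (blue, green, red, NIR, SWIR1, SWIR2) surface-reflectance means
#' typical of each class, with a common per-band noise sd of 0.015 so that
#' forest and barren land are separated by at least 5 sd in every band.
#'
#' @param class_names The class names in legend order.
#' @export
default_spectral_signatures <- function(class_names = c("forest", "rangeland",
                                                        "cropland", "barren",
                                                        "artificial", "water")) {
  bands <- c("blue", "green", "red", "nir", "swir1", "swir2")
  mean <- rbind(
    forest     = c(0.030, 0.050, 0.040, 0.450, 0.200, 0.100),
    rangeland  = c(0.050, 0.080, 0.090, 0.330, 0.260, 0.160),
    cropland   = c(0.060, 0.100, 0.110, 0.520, 0.300, 0.180),
    barren     = c(0.120, 0.160, 0.210, 0.280, 0.360, 0.310),
    artificial = c(0.150, 0.170, 0.180, 0.220, 0.250, 0.230),
    water      = c(0.040, 0.050, 0.030, 0.020, 0.010, 0.005)
  )
  colnames(mean) <- bands
  rownames(mean) <- class_names[seq_len(nrow(mean))]
  sd <- matrix(0.015, nrow(mean), ncol(mean), dimnames = dimnames(mean))
  list(band_names = bands, mean = mean, sd = sd)
}

# Substream scheme: op_seed = (seed * 16807 + op_id) mod (2^31 - 1), op ids
# documented per operation (initial map = 1, interval k evolution = 10 + k,
# image stack = 100 + epoch index, reference samples = 200 + epoch index).
substream <- function(seed, op_id) {
  as.integer((as.numeric(seed) %% 2147483647 * 16807 + op_id) %% 2147483647)
}

# Separable box blur (truncated at edges), `passes` repetitions per axis;
# three passes approximate a Gaussian kernel.
box1d <- function(m, r) {
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(n) - r, 1)
  hi <- pmin(seq_len(n) + r, n)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

smooth_field <- function(m, radius = 3, passes = 3) {
  for (i in seq_len(passes)) {
    m <- box1d(m, radius)
    m <- t(box1d(t(m), radius))
  }
  m
}

# Smoothed standard-normal field on the scenario grid, excluding nothing.
scenario_field <- function(scenario, seed, radius = 4) {
  set.seed(seed)
  raw <- matrix(stats::rnorm(scenario$grid_rows * scenario$grid_cols),
                scenario$grid_rows, scenario$grid_cols)
  smooth_field(raw, radius = radius)
}

#' Generate the initial-epoch land-cover map
#'
#' Thresholds one smoothed Gaussian noise field at the cumulative
#' class-prevalence quantiles, producing spatially contiguous patches with
#' exactly the requested class frequencies (up to integer rounding by
#' largest remainder). Deterministic for a fixed scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param nodata_mask Optional logical matrix; `TRUE` pixels stay nodata.
#' @return A [lulc_map()].
#' @export
generate_initial_lulc <- function(scenario, nodata_mask = NULL) {
  field <- scenario_field(scenario, substream(scenario$seed, 1L))
  vals <- matrix(NA_integer_, scenario$grid_rows, scenario$grid_cols)
  valid <- if (is.null(nodata_mask)) rep(TRUE, length(vals)) else !as.vector(nodata_mask)
  n <- sum(valid)
  counts <- largest_remainder(scenario$class_weights * n)
  ord <- order(field[valid], seq_len(n)) # deterministic tie-break
  lab <- rep.int(scenario$class_codes, counts)
  v <- integer(n)
  v[ord] <- lab
  vals[valid] <- v
  lulc_map(vals, scenario$class_codes, scenario$class_names,
           scenario$pixel_size)
}

# Round nonnegative reals to integers preserving the (rounded) total.
largest_remainder <- function(x) {
  largest_remainder_total(x, round(sum(x)))
}

largest_remainder_total <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    take <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[take] <- fl[take] + 1
  }
  as.integer(fl)
}

#' Realise driver fields on the scenario grid
#'
#' Each driver is a smoothed Gaussian field rescaled through its normal CDF
#' to the configured min-max range, giving spatially coherent surfaces
#' (distance fields are nonnegative by construction).
#'
#' @param scenario A [synthetic_scenario()].
#' @return Named list of [driver_field()] objects.
#' @export
generate_drivers <- function(scenario) {
  out <- list()
  for (k in seq_along(scenario$driver_spec)) {
    nm <- names(scenario$driver_spec)[k]
    spec <- scenario$driver_spec[[k]]
    f <- scenario_field(scenario, substream(scenario$seed, 300L + k))
    u <- stats::pnorm(scale(as.vector(f))[, 1])
    vals <- matrix(spec$min + (spec$max - spec$min) * u,
                   scenario$grid_rows, scenario$grid_cols)
    out[[nm]] <- driver_field(nm, vals, spec$units)
  }
  out
}

#' Advance a land-cover map one interval under a transition kernel
#'
#' Each valid pixel's new class is drawn from its class's row of `M`, with
#' the per-destination log-odds optionally tilted by standardized driver
#' values times their effect weights (all-zero weights recover the pure
#' Markov kernel exactly). Sampling uses the Gumbel-max trick so a
#' deterministic row (a single probability of 1) maps deterministically.
#' Nodata pixels are preserved.
#'
#' @param map A [lulc_map()].
#' @param M Row-stochastic transition matrix in legend order.
#' @param drivers Named list of [driver_field()] (or `NULL`).
#' @param effect_weights Named list (by driver) of per-destination-class
#'   weight vectors, or `NULL` for no tilt.
#' @param seed Integer seed for this step.
#' @return A [lulc_map()] on the same grid.
#' @export
evolve_lulc <- function(map, M, drivers = NULL, effect_weights = NULL,
                        seed = 1L) {
  J <- length(map$class_codes)
  check_stochastic(M, J)
  vals <- map$values
  valid <- which(!is.na(vals))
  cls_idx <- match(vals[valid], map$class_codes)
  logits <- log(M)[cls_idx, , drop = FALSE] # -Inf where P = 0
  if (!is.null(drivers) && !is.null(effect_weights)) {
    for (nm in names(effect_weights)) {
      w <- effect_weights[[nm]]
      if (all(w == 0)) next
      if (is.null(drivers[[nm]])) stop("no driver field named '", nm, "'")
      z <- as.vector(drivers[[nm]]$values)[valid]
      z <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
      logits <- logits + outer(z, as.numeric(w))
    }
  }
  set.seed(seed)
  g <- -log(-log(matrix(stats::runif(length(valid) * J), ncol = J)))
  pick <- max.col(logits + g, ties.method = "first")
  out <- vals
  out[valid] <- map$class_codes[pick]
  lulc_map(out, map$class_codes, map$class_names, map$pixel_size)
}

#' Simulate the full multitemporal map series of a scenario
#'
#' Applies [generate_initial_lulc()] then [evolve_lulc()] per interval with
#' the scenario's true transition matrices and driver effects.
#'
#' @param scenario A [synthetic_scenario()].
#' @param use_drivers Apply the scenario's driver effect weights (default
#'   `TRUE`); `FALSE` gives the pure Markov world.
#' @param nodata_mask Optional logical matrix of nodata pixels.
#' @return List with `maps` (named by epoch year) and `drivers`.
#' @export
simulate_scenario <- function(scenario, use_drivers = TRUE,
                              nodata_mask = NULL) {
  drivers <- generate_drivers(scenario)
  eff <- if (use_drivers) {
    lapply(scenario$driver_spec, function(s) s$effect)
  } else NULL
  maps <- vector("list", length(scenario$epoch_years))
  names(maps) <- scenario$epoch_years
  m0 <- generate_initial_lulc(scenario, nodata_mask)
  for (b in seq_len(scenario$burn_in)) {
    m0 <- evolve_lulc(m0, scenario$true_transition_matrices[[1]],
                      drivers = drivers, effect_weights = eff,
                      seed = substream(scenario$seed, 900L + b))
  }
  maps[[1]] <- m0
  for (k in seq_along(scenario$true_transition_matrices)) {
    maps[[k + 1]] <- evolve_lulc(maps[[k]],
                                 scenario$true_transition_matrices[[k]],
                                 drivers = drivers, effect_weights = eff,
                                 seed = substream(scenario$seed, 10L + k))
  }
  list(maps = maps, drivers = drivers)
}

#' Generate a multiband image stack for one epoch
#'
#' Every scene assigns each valid pixel its class-mean reflectance plus
#' independent Gaussian noise per band and scene; nodata pixels are NA.
#'
#' @param scenario A [synthetic_scenario()].
#' @param lulc The epoch's [lulc_map()].
#' @param n_scenes Number of scenes (>= 1).
#' @param seed Integer seed.
#' @param year Acquisition year used for the growing-season date stamps.
#' @return An `image_collection`: list of 3-D scene arrays
#'   (rows x cols x bands), band names, and dates.
#' @export
generate_image_stack <- function(scenario, lulc, n_scenes = 10, seed = 1L,
                                 year = scenario$epoch_years[1]) {
  if (n_scenes < 1) stop("n_scenes must be >= 1")
  sig <- scenario$spectral_signatures
  present <- unique(lulc$values[!is.na(lulc$values)])
  nm <- scenario$class_names[match(present, scenario$class_codes)]
  missing_sig <- setdiff(nm, rownames(sig$mean))
  if (length(missing_sig) > 0) {
    stop("configuration error: no spectral signature for class ",
         paste(missing_sig, collapse = ", "))
  }
  nb <- length(sig$band_names)
  dims <- dim(lulc$values)
  valid <- which(!is.na(lulc$values))
  ridx <- match(scenario$class_names[match(lulc$values[valid],
                                           scenario$class_codes)],
                rownames(sig$mean))
  set.seed(seed)
  scenes <- vector("list", n_scenes)
  for (s in seq_len(n_scenes)) {
    arr <- array(NA_real_, c(dims, nb), dimnames = list(NULL, NULL,
                                                        sig$band_names))
    for (b in seq_len(nb)) {
      layer <- matrix(NA_real_, dims[1], dims[2])
      layer[valid] <- sig$mean[ridx, b] +
        stats::rnorm(length(valid), 0, sig$sd[ridx, b])
      arr[, , b] <- layer
    }
    scenes[[s]] <- arr
  }
  # spread acquisitions across the April-September growing season
  doy <- round(seq(91, 273, length.out = n_scenes))
  dates <- as.Date(doy - 1, origin = as.Date(paste0(year, "-01-01")))
  image_collection(scenes, sig$band_names, dates)
}

#' Multiband image collection
#'
#' @param scenes List of 3-D arrays (rows x cols x bands) sharing one grid.
#' @param band_names Band names, length = 3rd dimension.
#' @param dates Acquisition dates, one per scene.
#' @export
image_collection <- function(scenes, band_names, dates = NULL) {
  if (length(scenes) < 1) stop("empty image collection")
  d <- dim(scenes[[1]])
  for (s in scenes) {
    if (!identical(dim(s), d)) stop("scenes do not share a grid")
  }
  if (length(band_names) != d[3]) stop("band_names do not match band count")
  structure(list(scenes = scenes, band_names = band_names, dates = dates),
            class = "image_collection")
}

#' @export
print.image_collection <- function(x, ...) {
  d <- dim(x$scenes[[1]])
  cat(sprintf("<image_collection> %d scenes, %d x %d pixels, bands: %s\n",
              length(x$scenes), d[1], d[2], paste(x$band_names,
                                                  collapse = ", ")))
  invisible(x)
}

#' Draw stratified reference samples with true labels
#'
#' Samples valid pixels stratified by class, either proportionally to class
#' area (largest-remainder rounding to hit `n_samples` exactly) or with an
#' explicit per-class allocation.
#'
#' @param lulc A [lulc_map()] supplying the true labels.
#' @param n_samples Total samples (ignored when `per_class` is given).
#' @param seed Integer seed.
#' @param per_class Optional named (by class name) or unnamed vector of
#'   per-class sample counts.
#' @return A `data.frame` with `row`, `col` (1-based), `class_code`,
#'   `class_name`.
#' @export
generate_reference_samples <- function(lulc, n_samples = 800, seed = 1L,
                                       per_class = NULL) {
  valid <- which(!is.na(lulc$values))
  if (is.null(per_class)) {
    if (n_samples > length(valid)) stop("sampling error: n_samples exceeds valid pixels")
    if (n_samples == 0) {
      return(data.frame(row = integer(), col = integer(),
                        class_code = integer(), class_name = character()))
    }
    tab <- tabulate(match(lulc$values[valid], lulc$class_codes),
                    nbins = length(lulc$class_codes))
    alloc <- largest_remainder(n_samples * tab / sum(tab))
  } else {
    alloc <- rep(0L, length(lulc$class_codes))
    idx <- if (!is.null(names(per_class))) {
      match(names(per_class), lulc$class_names)
    } else seq_along(per_class)
    alloc[idx] <- as.integer(per_class)
  }
  set.seed(seed)
  rows <- ((valid - 1) %% nrow(lulc$values)) + 1
  cols <- ((valid - 1) %/% nrow(lulc$values)) + 1
  cls <- lulc$values[valid]
  out <- vector("list", length(lulc$class_codes))
  for (k in seq_along(lulc$class_codes)) {
    if (alloc[k] == 0) next
    pool <- which(cls == lulc$class_codes[k])
    if (length(pool) < alloc[k]) {
      stop("sampling error: class ", lulc$class_names[k],
           " has only ", length(pool), " pixels, ", alloc[k], " requested")
    }
    take <- pool[sample.int(length(pool), alloc[k])]
    out[[k]] <- data.frame(row = rows[take], col = cols[take],
                           class_code = cls[take],
                           class_name = lulc$class_names[k])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
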