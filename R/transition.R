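#' Estimate a Markov transition matrix from a map pair
#'
#' P_ij = n_ij / n_i from the cross-tabulation of the two epochs. Rows with
#' no origin pixels (n_i = 0) are set to identity and flagged in
#' `empty_rows`.
#'
#' @param map_t1,map_t2 [lulc_map()]s on the same grid and legend.
#' @param interval_years Calendar length of the observed interval.
#' @return A `transition_matrix`: `P`, `counts`, `origin_totals`,
#'   `class_codes`, `interval_years`, `empty_rows`.
#' @export
estimate_transition_matrix <- function(map_t1, map_t2, interval_years = 1) {
  ct <- crosstab(map_t1, map_t2)
  if (sum(ct$counts) == 0) stop("all pixels are nodata in one of the maps")
  transition_matrix_from_counts(ct$counts, map_t1$class_codes,
                                interval_years)
}

#' Build a transition matrix from a count matrix
#'
#' @param counts Square matrix of transition pixel counts.
#' @param class_codes Class codes in row/column order.
#' @param interval_years Interval length in years.
#' @export
transition_matrix_from_counts <- function(counts, class_codes =
                                            seq_len(nrow(counts)),
                                          interval_years = 1) {
  n_i <- rowSums(counts)
  P <- counts / ifelse(n_i > 0, n_i, 1)
  empty <- which(n_i == 0)
  for (i in empty) {
    P[i, ] <- 0
    P[i, i] <- 1
  }
  if (length(empty) > 0) {
    warning("empty origin rows set to identity: ",
            paste(rownames(counts)[empty], collapse = ", "))
  }
  structure(list(P = as.matrix(P), counts = as.matrix(counts),
                 origin_totals = n_i, class_codes = as.integer(class_codes),
                 interval_years = interval_years,
                 empty_rows = empty),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes over %g years\n",
              nrow(x$P), x$interval_years))
  print(round(x$P, 4))
  invisible(x)
}

# Matrix power by repeated squaring (n >= 0 integer).
mat_power <- function(M, n) {
  out <- diag(nrow(M))
  base <- M
  while (n > 0) {
    if (n %% 2 == 1) out <- out %*% base
    base <- base %*% base
    n <- n %/% 2
  }
  out
}

#' Project a class-composition vector through the Markov chain
#'
#' v_t2 = v_t1 M^n: the chain composed over `n_steps` calibration
#' intervals. Total mass (pixel count or area) is conserved.
#'
#' @param v Nonnegative class-composition vector (pixel counts or areas).
#' @param M Row-stochastic transition matrix (or `transition_matrix`).
#' @param n_steps Number of whole intervals to compose.
#' @return The projected composition vector.
#' @export
markov_project <- function(v, M, n_steps = 1) {
  if (inherits(M, "transition_matrix")) M <- M$P
  if (length(v) != nrow(M)) stop("dimension mismatch between v and M")
  if (any(v < 0)) stop("v must be nonnegative")
  check_stochastic(M)
  out <- as.numeric(v %*% mat_power(M, n_steps))
  names(out) <- colnames(M)
  out
}

# Row-stochastic kernel over a possibly fractional number of intervals:
# linear interpolation between consecutive whole powers (stochastic roots
# may not exist, so fractional powers are not attempted).
scaled_kernel <- function(P, k) {
  if (k < 0) stop("negative projection interval")
  f <- k - floor(k)
  Mf <- mat_power(P, floor(k))
  if (f == 0) return(Mf)
  (1 - f) * Mf + f * mat_power(P, floor(k) + 1)
}

#' Expected transition-area (pixel-count) matrix
#'
#' Expected number of pixels converting from class i to class j over the
#' projection interval: n_i times the scaled kernel, rounded by largest
#' remainder within each row so row sums equal the current class counts
#' exactly.
#'
#' @param map Current [lulc_map()] (or a named vector of class pixel
#'   counts).
#' @param tm A `transition_matrix` (or plain row-stochastic matrix).
#' @param n_steps Projection length in calibration intervals (fractional
#'   allowed; interpolates between whole powers).
#' @return Integer matrix of expected pixel counts.
#' @export
transition_area_matrix <- function(map, tm, n_steps = 1) {
  P <- if (inherits(tm, "transition_matrix")) tm$P else tm
  v <- if (inherits(map, "lulc_map")) {
    tabulate(match(map$values[!is.na(map$values)], map$class_codes),
             nbins = length(map$class_codes))
  } else as.numeric(map)
  K <- scaled_kernel(P, n_steps)
  A <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
  for (i in seq_len(nrow(P))) {
    A[i, ] <- largest_remainder(v[i] * K[i, ])
  }
  A
}

# ---- MLP transition potential ------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train a multilayer-perceptron transition-potential model
#'
#' Regresses a binary changed/persistent indicator on standardized driver
#' values with a single-hidden-layer perceptron (logistic activations,
#' hidden width `max(4, n_drivers)`), minimising mean squared error with
#' Adam. Training stops when training RMSE falls to `rms_target` or after
#' `max_iterations` iterations. Changed and persistent pixels are drawn in
#' equal numbers (class balance), then split 70/30 into training and
#' testing; both RMSEs are reported.
#'
#' @param drivers Named list of [driver_field()]s.
#' @param change_labels Matrix with 1 = changed, 0 = persistent, `NA` =
#'   not eligible (not of the origin class).
#' @param rms_target Stopping RMSE (default 0.01).
#' @param max_iterations Iteration cap (default 1000).
#' @param seed Integer seed (sampling and weight initialisation).
#' @param hidden Hidden width; default `max(4, n_drivers)`.
#' @param max_per_class Cap on balanced samples per label (default 4000).
#' @param learning_rate Adam step size.
#' @return An `mlp_model` with weights, standardization constants, RMSE
#'   trace, and `rmse_train` / `rmse_test`.
#' @export
train_transition_potential <- function(drivers, change_labels,
                                       rms_target = 0.01,
                                       max_iterations = 1000, seed = 1L,
                                       hidden = NULL, max_per_class = 4000,
                                       learning_rate = 0.05) {
  lab <- as.vector(change_labels)
  D <- vapply(drivers, function(d) as.vector(d$values), numeric(length(lab)))
  ok <- !is.na(lab) & stats::complete.cases(D)
  lab <- lab[ok]
  D <- D[ok, , drop = FALSE]
  if (length(unique(lab)) < 2) {
    stop("labels contain a single class; nothing to learn")
  }
  set.seed(seed)
  pos <- which(lab == 1)
  neg <- which(lab == 0)
  n_bal <- min(length(pos), length(neg), max_per_class)
  take <- c(pos[sample.int(length(pos), n_bal)],
            neg[sample.int(length(neg), n_bal)])
  X <- D[take, , drop = FALSE]
  y <- lab[take]
  n <- nrow(X)
  test <- sample.int(n, floor(0.3 * n))
  train <- setdiff(seq_len(n), test)
  mu <- colMeans(X[train, , drop = FALSE])
  sdv <- pmax(apply(X[train, , drop = FALSE], 2, stats::sd),
              .Machine$double.eps)
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  p <- ncol(Z)
  H <- if (is.null(hidden)) max(4L, p) else as.integer(hidden)
  W1 <- matrix(stats::rnorm(p * H, 0, 0.5), p, H)
  b1 <- rep(0, H)
  W2 <- matrix(stats::rnorm(H, 0, 0.5), H, 1)
  b2 <- 0
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  Ztr <- Z[train, , drop = FALSE]
  ytr <- y[train]
  ntr <- length(ytr)
  trace <- numeric(0)
  for (it in seq_len(max_iterations)) {
    A1 <- sigmoid(sweep(Ztr %*% params$W1, 2, params$b1, "+"))
    yhat <- as.vector(sigmoid(A1 %*% params$W2 + params$b2))
    err <- yhat - ytr
    rmse <- sqrt(mean(err^2))
    trace[it] <- rmse
    if (rmse <= rms_target) break
    d_out <- 2 * err * yhat * (1 - yhat) / ntr
    gW2 <- t(A1) %*% d_out
    gb2 <- sum(d_out)
    d_hid <- (d_out %*% t(params$W2)) * A1 * (1 - A1)
    gW1 <- t(Ztr) %*% d_hid
    gb1 <- colSums(d_hid)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^it)
      vhat <- vel[[nm]] / (1 - beta2^it)
      params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  predict_raw <- function(Zm) {
    A1 <- sigmoid(sweep(Zm %*% params$W1, 2, params$b1, "+"))
    as.vector(sigmoid(A1 %*% params$W2 + params$b2))
  }
  rmse_train <- sqrt(mean((predict_raw(Ztr) - ytr)^2))
  Zte <- Z[test, , drop = FALSE]
  rmse_test <- if (length(test) > 0) {
    sqrt(mean((predict_raw(Zte) - y[test])^2))
  } else NA_real_
  structure(list(params = params, driver_names = names(drivers),
                 mu = mu, sd = sdv, hidden = H,
                 rmse_train = rmse_train, rmse_test = rmse_test,
                 trace = trace, iterations = length(trace),
                 config = list(rms_target = rms_target,
                               max_iterations = max_iterations,
                               seed = seed, learning_rate = learning_rate)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(paste0("<mlp_model> %d drivers -> %d hidden units; %d ",
                     "iterations, RMSE train %.4f / test %.4f\n"),
              length(x$driver_names), x$hidden, x$iterations,
              x$rmse_train, x$rmse_test))
  invisible(x)
}

#' Predict a transition-potential surface
#'
#' @param model An [train_transition_potential()] model.
#' @param drivers Named list of [driver_field()]s covering the model's
#'   driver names.
#' @return Matrix of potentials in [0, 1] (`NA` where any driver is nodata).
#' @export
predict_potential <- function(model, drivers) {
  miss <- setdiff(model$driver_names, names(drivers))
  if (length(miss) > 0) stop("missing drivers: ", paste(miss, collapse = ", "))
  d1 <- drivers[[model$driver_names[1]]]$values
  D <- vapply(model$driver_names,
              function(nm) as.vector(drivers[[nm]]$values),
              numeric(length(d1)))
  out <- rep(NA_real_, nrow(D))
  ok <- stats::complete.cases(D)
  if (any(ok)) {
    Z <- sweep(sweep(D[ok, , drop = FALSE], 2, model$mu), 2, model$sd, "/")
    A1 <- sigmoid(sweep(Z %*% model$params$W1, 2, model$params$b1, "+"))
    out[ok] <- as.vector(sigmoid(A1 %*% model$params$W2 + model$params$b2))
  }
  matrix(out, nrow(d1), ncol(d1))
}

# ---- spatial allocation ------------------------------------------------------

#' Allocate demanded transitions to the highest-potential pixels
#'
#' Greedy ranked selection: transitions are processed in descending-demand
#' order; for each ordered pair (i, j), the `demand[i, j]` still-available
#' pixels of class i with the highest i->j potential convert to j, ties
#' broken by ascending pixel (column-major) index. A pixel converts at most
#' once. Zero demand leaves the map unchanged; class areas after allocation
#' equal the demanded areas exactly.
#'
#' @param current_map A [lulc_map()].
#' @param potentials Named list of potential matrices keyed `"i->j"` by
#'   class code (missing entries fall back to a uniform surface).
#' @param demand Square matrix of pixel counts to convert (diagonal
#'   ignored; rows/cols in legend order).
#' @param seed Unused (allocation is deterministic); kept for interface
#'   stability.
#' @return The allocated [lulc_map()].
#' @export
allocate_change <- function(current_map, potentials, demand, seed = 1L) {
  codes <- current_map$class_codes
  J <- length(codes)
  if (!all(dim(demand) == c(J, J))) stop("demand must be ", J, "x", J)
  vals <- current_map$values
  avail_count <- tabulate(match(vals[!is.na(vals)], codes), nbins = J)
  off <- demand
  diag(off) <- 0
  over <- which(rowSums(off) > avail_count)
  if (length(over) > 0) {
    stop("demand exceeds available pixels for origin class ",
         paste(current_map$class_names[over], collapse = ", "))
  }
  idx <- which(off > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    ord <- order(-off[idx], idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
  }
  out <- vals
  locked <- matrix(FALSE, nrow(vals), ncol(vals))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]
    j <- idx[r, 2]
    need <- off[i, j]
    cand <- which(!is.na(vals) & vals == codes[i] & !locked)
    if (length(cand) < need) {
      stop("demand exceeds available pixels for transition ",
           current_map$class_names[i], "->", current_map$class_names[j])
    }
    key <- paste0(codes[i], "->", codes[j])
    pot <- if (!is.null(potentials[[key]])) potentials[[key]][cand] else
      rep(0, length(cand))
    pot[is.na(pot)] <- -Inf
    pick <- cand[order(-pot, cand)[seq_len(need)]]
    out[pick] <- codes[j]
    locked[pick] <- TRUE
  }
  lulc_map(out, codes, current_map$class_names, current_map$pixel_size)
}

#' Project a future land-cover map from observed epochs
#'
#' The full calibrate-then-forecast pipeline: estimate the transition
#' matrix from a calibration map pair, scale it to the target interval
#' (whole-interval matrix powers, linear interpolation of the transition
#' area matrix for fractional intervals), train per-transition MLP
#' potential surfaces on the calibration interval's observed changes, and
#' allocate the demanded conversions to the highest-potential pixels.
#' Also emits per-class conditional probability images (rows of the scaled
#' kernel indexed by the base map), which sum to 1 per valid pixel.
#'
#' @param maps_by_year Named (by calendar year) list of [lulc_map()]s in
#'   chronological order; at least the two calibration epochs.
#' @param drivers Named list of [driver_field()]s (may be empty: uniform
#'   potentials).
#' @param target_year Projection year (after the base year).
#' @param calibration Character or integer years of the two calibration
#'   epochs (default: the last two observed).
#' @param base_year Year of the map the projection starts from (default:
#'   the last observed).
#' @param seed Integer seed (MLP training).
#' @param rms_target,max_iterations MLP stopping criteria.
#' @return List: `map`, `probabilities` (per-class matrices),
#'   `transition_matrix`, `kernel` (scaled), `demand`,
#'   `potential_models`.
#' @export
project_lulc <- function(maps_by_year, drivers = list(), target_year,
                         calibration = NULL, base_year = NULL, seed = 1L,
                         rms_target = 0.01, max_iterations = 1000,
                         potentials = NULL) {
  years <- as.numeric(names(maps_by_year))
  if (length(years) < 2) stop("need >= 2 observed epochs")
  if (is.null(calibration)) calibration <- years[c(length(years) - 1,
                                                   length(years))]
  calibration <- as.numeric(calibration)
  ci <- match(calibration, years)
  if (anyNA(ci)) stop("calibration years not among observed epochs")
  if (is.null(base_year)) base_year <- years[length(years)]
  bi <- match(as.numeric(base_year), years)
  if (is.na(bi)) stop("base_year not among observed epochs")
  if (target_year <= base_year) {
    stop("target year must be after the base year")
  }
  interval <- calibration[2] - calibration[1]
  tm <- estimate_transition_matrix(maps_by_year[[ci[1]]],
                                   maps_by_year[[ci[2]]], interval)
  base_map <- maps_by_year[[bi]]
  k <- (target_year - as.numeric(base_year)) / interval
  demand <- transition_area_matrix(base_map, tm, k)
  codes <- base_map$class_codes
  # per-transition potential surfaces from the calibration interval
  models <- list()
  off <- demand
  diag(off) <- 0
  if (is.null(potentials)) {
  potentials <- list()
  if (length(drivers) > 0) {
    m1 <- maps_by_year[[ci[1]]]$values
    m2 <- maps_by_year[[ci[2]]]$values
    for (i in seq_along(codes)) {
      for (j in seq_along(codes)) {
        if (i == j || off[i, j] == 0) next
        origin <- !is.na(m1) & m1 == codes[i] & !is.na(m2)
        labels <- matrix(NA_real_, nrow(m1), ncol(m1))
        labels[origin] <- as.numeric(m2[origin] == codes[j])
        key <- paste0(codes[i], "->", codes[j])
        if (length(unique(labels[origin])) < 2) next # uniform fallback
        models[[key]] <- train_transition_potential(
          drivers, labels, rms_target = rms_target,
          max_iterations = max_iterations,
          seed = substream(seed, i * length(codes) + j))
        potentials[[key]] <- predict_potential(models[[key]], drivers)
      }
    }
  }
  }
  projected <- allocate_change(base_map, potentials, demand, seed = seed)
  K <- scaled_kernel(tm$P, k)
  probs <- vector("list", length(codes))
  names(probs) <- base_map$class_names
  for (j in seq_along(codes)) {
    pj <- matrix(NA_real_, nrow(base_map$values), ncol(base_map$values))
    valid <- !is.na(base_map$values)
    pj[valid] <- K[match(base_map$values[valid], codes), j]
    probs[[j]] <- pj
  }
  list(map = projected, probabilities = probs, transition_matrix = tm,
       kernel = K, demand = demand, potential_models = models,
       potentials = potentials)
}

#' Project a series of future maps sharing one calibration
#'
#' Calls [project_lulc()] for each target year, training the
#' transition-potential surfaces once (on the first target) and reusing
#' them for the rest, since the calibration interval is the same.
#'
#' @inheritParams project_lulc
#' @param target_years Increasing projection years, all after the base
#'   year.
#' @return Named (by year) list of [project_lulc()] results.
#' @export
project_series <- function(maps_by_year, drivers = list(), target_years,
                           calibration = NULL, base_year = NULL, seed = 1L,
                           rms_target = 0.01, max_iterations = 1000) {
  out <- vector("list", length(target_years))
  names(out) <- target_years
  pots <- NULL
  for (k in seq_along(target_years)) {
    out[[k]] <- project_lulc(maps_by_year, drivers, target_years[k],
                             calibration = calibration,
                             base_year = base_year, seed = seed,
                             rms_target = rms_target,
                             max_iterations = max_iterations,
                             potentials = pots)
    if (is.null(pots)) pots <- out[[k]]$potentials
  }
  out
}
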