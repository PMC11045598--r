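#' Append vegetation-index bands to a scene
#'
#' Computes NDVI = (NIR - R)/(NIR + R), DVI = NIR - R, and
#' EVI = G (NIR - R)/(NIR + C1 R - C2 B + L) with the standard constants
#' G = 2.5, C1 = 6, C2 = 7.5, L = 1. Pixels where an index denominator is 0
#' are flagged nodata for that index.
#'
#' @param scene 3-D array (rows x cols x bands) with band dimnames.
#' @param bands Named character vector locating `blue`, `red`, `nir` bands.
#' @return The scene with `ndvi`, `dvi`, `evi` bands appended.
#' @export
vegetation_indices <- function(scene,
                               bands = c(blue = "blue", red = "red",
                                         nir = "nir")) {
  bn <- dimnames(scene)[[3]]
  need <- c("red", "nir")
  if (!all(bands[need] %in% bn)) stop("red and near-infrared bands required")
  r <- scene[, , bands[["red"]]]
  n <- scene[, , bands[["nir"]]]
  den <- n + r
  ndvi <- (n - r) / den
  ndvi[!is.na(den) & den == 0] <- NA
  dvi <- n - r
  out_bn <- c(bn, "ndvi", "dvi")
  layers <- list(ndvi, dvi)
  if (bands[["blue"]] %in% bn) {
    b <- scene[, , bands[["blue"]]]
    eden <- n + 6 * r - 7.5 * b + 1
    evi <- 2.5 * (n - r) / eden
    evi[!is.na(eden) & eden == 0] <- NA
    layers <- c(layers, list(evi))
    out_bn <- c(out_bn, "evi")
  }
  d <- dim(scene)
  out <- array(NA_real_, c(d[1], d[2], length(out_bn)),
               dimnames = list(NULL, NULL, out_bn))
  out[, , seq_len(d[3])] <- scene
  for (k in seq_along(layers)) out[, , d[3] + k] <- layers[[k]]
  out
}

#' Append index bands to every scene of a collection
#'
#' @param collection An [image_collection()].
#' @inheritParams vegetation_indices
#' @export
append_indices <- function(collection, bands = c(blue = "blue", red = "red",
                                                 nir = "nir")) {
  scenes <- lapply(collection$scenes, vegetation_indices, bands = bands)
  image_collection(scenes, dimnames(scenes[[1]])[[3]], collection$dates)
}

stm_stat_names <- c("median", "sd", "min", "max", "p25", "p50", "p75")

# Type-7 quantile (linear interpolation between order statistics) on
# row-sorted values; vectorized over rows.
row_quantile7 <- function(sorted, p) {
  n <- ncol(sorted)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  sorted[, lo] + (h - lo) * (sorted[, min(lo + 1, n)] - sorted[, lo])
}

#' Spectral-temporal metric (STM) feature cube
#'
#' Reduces the temporal stack to 7 per-pixel statistics per band/index
#' series: median, sample standard deviation, minimum, maximum, and the
#' 25th/50th/75th percentiles (linear interpolation between order
#' statistics). With 6 spectral bands and 3 indices this yields 63 feature
#' layers. Scenes that are nodata at a pixel are excluded for that pixel;
#' a pixel with no valid scene is nodata in every feature.
#'
#' @param collection An [image_collection()] (indices already appended).
#' @return An `stm_cube`: list with `features` (rows x cols x n_features
#'   array) and `feature_names` like `"ndvi_p25"`.
#' @export
compute_stm <- function(collection) {
  if (length(collection$scenes) < 1) stop("empty image collection")
  bn <- collection$band_names
  d <- dim(collection$scenes[[1]])
  S <- length(collection$scenes)
  nstat <- length(stm_stat_names)
  feature_names <- as.vector(t(outer(bn, stm_stat_names, paste, sep = "_")))
  feats <- array(NA_real_, c(d[1], d[2], length(feature_names)),
                 dimnames = list(NULL, NULL, feature_names))
  for (b in seq_along(bn)) {
    mat <- vapply(collection$scenes, function(s) as.vector(s[, , b]),
                  numeric(d[1] * d[2]))
    if (!is.matrix(mat)) mat <- matrix(mat, nrow = d[1] * d[2])
    nvalid <- rowSums(!is.na(mat))
    stats_mat <- matrix(NA_real_, nrow(mat), nstat)
    full <- nvalid == S
    if (any(full)) {
      sub <- mat[full, , drop = FALSE]
      sorted <- if (S == 1) sub else
        matrix(sub[order(row(sub), sub)], nrow = nrow(sub), byrow = TRUE)
      mu <- rowMeans(sub)
      sdv <- if (S == 1) rep(0, nrow(sub)) else
        sqrt(rowSums((sub - mu)^2) / (S - 1))
      stats_mat[full, ] <- cbind(
        row_quantile7(sorted, 0.5), sdv, sorted[, 1], sorted[, S],
        row_quantile7(sorted, 0.25), row_quantile7(sorted, 0.5),
        row_quantile7(sorted, 0.75))
    }
    part <- which(nvalid > 0 & nvalid < S)
    for (i in part) {
      v <- mat[i, ]
      v <- v[!is.na(v)]
      stats_mat[i, ] <- c(stats::median(v),
                          if (length(v) > 1) stats::sd(v) else 0,
                          min(v), max(v),
                          stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                          type = 7))
    }
    for (k in seq_len(nstat)) {
      feats[, , (b - 1) * nstat + k] <- matrix(stats_mat[, k], d[1], d[2])
    }
  }
  structure(list(features = feats, feature_names = feature_names),
            class = "stm_cube")
}

#' @export
print.stm_cube <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<stm_cube> %d x %d pixels, %d features\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Split reference samples into training and testing subsets
#'
#' Stratified by class: each stratum contributes at least
#' `floor(n_c * train_fraction)` training records, and the remaining
#' training slots needed to reach `round(n * train_fraction)` overall go to
#' the strata with the largest fractional parts (so 800 samples at 0.7
#' yield exactly 560 train / 240 test, and a single stratum of 10 yields
#' 7 / 3). Deterministic for a fixed seed.
#'
#' @param samples Data frame from [generate_reference_samples()].
#' @param train_fraction Fraction in (0, 1] assigned to training.
#' @param seed Integer seed.
#' @return `samples` with a `role` column (`"train"`/`"test"`).
#' @export
split_samples <- function(samples, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction > 1) {
    stop("train_fraction must be in (0, 1]")
  }
  set.seed(seed)
  classes <- unique(samples$class_code)
  sizes <- vapply(classes, function(cc) sum(samples$class_code == cc),
                  integer(1))
  n_train <- largest_remainder_total(sizes * train_fraction,
                                     round(nrow(samples) * train_fraction))
  samples$role <- "test"
  for (k in seq_along(classes)) {
    idx <- which(samples$class_code == classes[k])
    samples$role[idx[sample.int(length(idx), n_train[k])]] <- "train"
  }
  samples
}

cube_matrix_at <- function(cube, rows, cols) {
  d <- dim(cube$features)
  lin <- cbind(rows, cols)
  X <- vapply(seq_len(d[3]),
              function(k) cube$features[, , k][lin],
              numeric(length(rows)))
  if (length(rows) == 1) X <- matrix(X, nrow = 1)
  colnames(X) <- cube$feature_names
  X
}

#' Train the tree-ensemble land-cover classifier
#'
#' Bagged CART forest (Gini splits, per-node random feature subsets of size
#' `floor(sqrt(p))`, bootstrap per tree, majority vote). The ensemble size
#' defaults to 500 trees; other hyperparameters are fixed defaults recorded
#' in the model object.
#'
#' @param cube An [compute_stm()] feature cube.
#' @param train_samples Data frame with `row`, `col`, `class_code` (training
#'   records only, or a `role` column from [split_samples()]).
#' @param n_trees Ensemble size (default 500).
#' @param seed Integer seed.
#' @param classes Optional integer vector of class codes that must all be
#'   represented in training; an absent class is an error naming it.
#' @param min_node,max_depth Tree growth controls.
#' @return An `rf_model`.
#' @export
train_classifier <- function(cube, train_samples, n_trees = 500, seed = 1L,
                             classes = NULL, min_node = 1, max_depth = 25) {
  if (!is.null(train_samples$role)) {
    train_samples <- train_samples[train_samples$role == "train", ]
  }
  present <- sort(unique(train_samples$class_code))
  if (!is.null(classes)) {
    miss <- setdiff(classes, present)
    if (length(miss) > 0) {
      stop("no training pixels for class ", paste(miss, collapse = ", "))
    }
    present <- sort(as.integer(classes))
  }
  if (length(present) < 2) stop("need >= 2 classes in training data")
  X <- cube_matrix_at(cube, train_samples$row, train_samples$col)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  y <- match(train_samples$class_code[keep], present) - 1L
  mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  trees <- .rf_fit(X, y, length(present), as.integer(n_trees), mtry,
                   as.integer(min_node), as.integer(max_depth))
  structure(list(trees = trees, feature_names = cube$feature_names,
                 classes = present,
                 settings = list(n_trees = n_trees, mtry = mtry,
                                 min_node = min_node, max_depth = max_depth,
                                 seed = seed)),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, %d features, classes: %s\n",
              length(x$trees), length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Classify a feature cube into a land-cover map
#'
#' Majority vote over the ensemble; pixels with any missing feature are
#' nodata. The model can only emit classes seen in training.
#'
#' @param model An [train_classifier()] model.
#' @param cube The feature cube to classify (feature names must match
#'   training).
#' @param class_names Optional names for the model's class codes.
#' @param pixel_size Pixel edge (m) for the output map.
#' @return A [lulc_map()].
#' @export
classify <- function(model, cube, class_names = NULL, pixel_size = 30) {
  if (!identical(cube$feature_names, model$feature_names)) {
    stop("feature names do not match the trained model")
  }
  d <- dim(cube$features)
  X <- matrix(cube$features, d[1] * d[2], d[3])
  ok <- stats::complete.cases(X)
  vals <- matrix(NA_integer_, d[1], d[2])
  if (any(ok)) {
    votes <- .rf_predict(model$trees, X[ok, , drop = FALSE],
                         length(model$classes))
    vals[ok] <- model$classes[max.col(votes, ties.method = "first")]
  }
  lulc_map(vals, model$classes, class_names, pixel_size)
}

#' Accuracy assessment of a classified map
#'
#' Confusion matrix over test samples (rows = reference, cols = predicted)
#' with overall accuracy, Cohen's kappa, and per-class F1.
#'
#' @param predicted The classified [lulc_map()].
#' @param test_samples Data frame with `row`, `col`, `class_code` (testing
#'   records only, or a `role` column).
#' @return An `accuracy_report`: `confusion`, `overall_accuracy`, `kappa`,
#'   `per_class_f1`.
#' @export
assess_accuracy <- function(predicted, test_samples) {
  if (!is.null(test_samples$role)) {
    test_samples <- test_samples[test_samples$role == "test", ]
  }
  if (nrow(test_samples) == 0) stop("empty test set")
  pred <- predicted$values[cbind(test_samples$row, test_samples$col)]
  if (anyNA(pred)) stop("test samples fall on nodata pixels")
  lev <- sort(union(test_samples$class_code, pred))
  cm <- table(reference = factor(test_samples$class_code, levels = lev),
              predicted = factor(pred, levels = lev))
  accuracy_from_confusion(unclass(cm))
}

#' Accuracy metrics from a confusion matrix
#'
#' @param cm Square count matrix, rows = reference, cols = predicted.
#' @return An `accuracy_report`.
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  oa <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (oa - pe) / (1 - pe) else 1
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  names(f1) <- rownames(cm)
  structure(list(confusion = cm, overall_accuracy = oa, kappa = kappa,
                 per_class_f1 = f1),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> OA = %.4f, kappa = %.4f\n",
              x$overall_accuracy, x$kappa))
  cat("per-class F1:\n")
  print(round(x$per_class_f1, 4))
  invisible(x)
}

#' Collapse a land-cover map to a forest / non-forest mask
#'
#' @param map A [lulc_map()].
#' @param forest_code The class code representing forest.
#' @return A binary [lulc_map()] (1 = forest, 0 = non-forest), nodata
#'   preserved.
#' @export
binarize_forest <- function(map, forest_code = map$class_codes[1]) {
  if (!forest_code %in% map$class_codes) {
    stop("forest code ", forest_code, " is not in the class set")
  }
  vals <- ifelse(map$values == forest_code, 1L, 0L)
  lulc_map(vals, c(0L, 1L), c("non-forest", "forest"), map$pixel_size)
}
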