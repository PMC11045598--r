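# Shared fixtures, all built in code.

# Small two-class legend map from a plain matrix of 1/2 codes.
toy_map <- function(values, codes = c(1L, 2L),
                    names = c("forest", "cropland")) {
  lulc_map(values, codes, names, pixel_size = 30)
}

# A tiny 6-class scenario that keeps tests fast.
tiny_scenario <- function(seed = 11L, n = 60L, ...) {
  synthetic_scenario(grid_rows = n, grid_cols = n, seed = seed, ...)
}

# Well-separated 3-feature cube with two blocks of classes, for classifier
# tests that do not need the full STM machinery.
toy_cube <- function(nr = 20, nc = 20, noise = 0.05, seed = 1) {
  set.seed(seed)
  cls <- matrix(rep(1:2, each = nr * nc / 2), nr, nc)
  f <- array(NA_real_, c(nr, nc, 3),
             dimnames = list(NULL, NULL, c("a", "b", "c")))
  for (k in 1:3) {
    f[, , k] <- (cls - 1) * k + matrix(rnorm(nr * nc, 0, noise), nr, nc)
  }
  list(cube = structure(list(features = f, feature_names = c("a", "b", "c")),
                        class = "stm_cube"),
       truth = lulc_map(cls, 1:2, c("one", "two")))
}

# All 2x2 maps over `k` classes, as a list of matrices.
all_tiny_maps <- function(k = 3) {
  grid <- expand.grid(rep(list(seq_len(k)), 4))
  lapply(seq_len(nrow(grid)), function(i) {
    matrix(as.integer(grid[i, ]), 2, 2)
  })
}

# Independent direct-counting recomputation of the agreement components,
# kept deliberately separate from the package's closed forms.
oracle_components <- function(ref_vals, sim_vals, k) {
  n <- length(ref_vals)
  P0 <- sum(ref_vals == sim_vals) / n
  q <- vapply(seq_len(k), function(c) sum(ref_vals == c) / n, numeric(1))
  p <- vapply(seq_len(k), function(c) sum(sim_vals == c) / n, numeric(1))
  MQNL <- 0
  MQPL <- 0
  NQPL <- 0
  PQNL <- 0
  for (j in seq_len(k)) {
    MQNL <- MQNL + p[j] * q[j]
    MQPL <- MQPL + min(p[j], q[j])
    NQPL <- NQPL + min(1 / k, q[j])
    PQNL <- PQNL + q[j] * q[j]
  }
  L <- if (MQPL - MQNL > 1e-12) (P0 - MQNL) / (MQPL - MQNL) else
    if (abs(P0 - MQPL) <= 1e-12) 1 else NA_real_
  list(P0 = P0, p = p, q = q, NQNL = 1 / k, MQNL = MQNL, MQPL = MQPL,
       NQPL = NQPL, PQNL = PQNL, L = L,
       NQML = 1 / k + L * (NQPL - 1 / k),
       PQML = PQNL + L * (1 - PQNL))
}
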