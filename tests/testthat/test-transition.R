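test_that("transition estimation matches the counting definition", {
  t1 <- toy_map(matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE))
  t2 <- toy_map(matrix(c(1L, 2L, 2L, 2L), 2, 2, byrow = TRUE))
  tm <- estimate_transition_matrix(t1, t2, 5)
  expect_equal(tm$P["forest", "cropland"], 0.5)
  expect_equal(tm$P["cropland", "cropland"], 1)
  expect_equal(unname(rowSums(tm$P)), c(1, 1))

  # no change: identity
  tmi <- estimate_transition_matrix(t1, t1, 5)
  expect_equal(tmi$P, diag(2), ignore_attr = TRUE)

  # empty origin rows become identity with a warning
  t3 <- toy_map(matrix(2L, 2, 2))
  expect_warning(tm3 <- estimate_transition_matrix(t3, t3, 5), "identity")
  expect_equal(tm3$P[1, ], c(1, 0), ignore_attr = TRUE)
  expect_equal(unname(tm3$empty_rows), 1L)

  tna <- toy_map(matrix(NA_integer_, 2, 2))
  expect_error(estimate_transition_matrix(tna, tna, 5), "nodata")
})

test_that("exhaustive toy pairs match hand-computed row normalization", {
  # every pair of 2x2 maps over 2 classes: estimated P equals n_ij / n_i
  maps <- all_tiny_maps(2)
  for (a in seq_along(maps)) {
    for (b in seq(a, length(maps), by = 7)) { # strided subset of pairs
      m1 <- toy_map(maps[[a]])
      m2 <- toy_map(maps[[b]])
      suppressWarnings(tm <- estimate_transition_matrix(m1, m2, 1))
      counts <- matrix(0, 2, 2)
      for (px in 1:4) {
        counts[maps[[a]][px], maps[[b]][px]] <-
          counts[maps[[a]][px], maps[[b]][px]] + 1
      }
      for (i in 1:2) {
        expected <- if (sum(counts[i, ]) > 0) counts[i, ] / sum(counts[i, ])
          else as.numeric(diag(2)[i, ])
        expect_equal(unname(tm$P[i, ]), expected)
      }
    }
  }
})

test_that("markov projection composes the chain and conserves mass", {
  M <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(unname(markov_project(c(100, 0), M, 1)), c(90, 10))
  expect_equal(unname(markov_project(c(100, 50), diag(2), 10)), c(100, 50))
  expect_equal(sum(markov_project(c(30, 70), M, 7)), 100)
  expect_error(markov_project(c(1, 2, 3), M, 1), "dimension")

  # irreducible aperiodic chain approaches its stationary distribution
  M2 <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  v500 <- markov_project(c(1, 0), M2, 500)
  stationary <- c(0.6, 0.4) # solves pi = pi M2
  expect_lt(max(abs(v500 - stationary)), 1e-6)
})

test_that("transition area matrices preserve row totals", {
  sc <- tiny_scenario(n = 30)
  m <- generate_initial_lulc(sc)
  M <- sc$true_transition_matrices[[1]]
  v <- tabulate(match(m$values[!is.na(m$values)], m$class_codes), 6)
  for (k in c(1, 2, 1.4)) {
    A <- transition_area_matrix(m, M, k)
    expect_true(all(A >= 0))
    expect_equal(unname(rowSums(A)), v)
  }
})

test_that("the MLP learns a separable threshold and is seeded", {
  set.seed(3)
  z <- matrix(rnorm(2500), 50, 50)
  d <- list(x = driver_field("x", z), noise = driver_field("noise",
                                                           matrix(rnorm(2500), 50, 50)))
  labels <- matrix(as.numeric(z > 0.5), 50, 50)
  m <- train_transition_potential(d, labels, seed = 5)
  expect_lt(m$rmse_test, 0.1)
  # potential ranking reproduces the threshold ordering
  pot <- predict_potential(m, d)
  n_pos <- sum(labels == 1)
  top <- order(-pot)[seq_len(n_pos)]
  expect_gt(mean(labels[top] == 1), 0.95)

  m2 <- train_transition_potential(d, labels, seed = 5)
  expect_identical(m$params, m2$params)
  expect_true(all(pot >= 0 & pot <= 1))
})

test_that("pure-noise drivers give a null-model test RMSE", {
  set.seed(4)
  d <- list(x = driver_field("x", matrix(rnorm(3600), 60, 60)))
  labels <- matrix(rbinom(3600, 1, 0.5), 60, 60)
  m <- train_transition_potential(d, labels, max_iterations = 300, seed = 2)
  expect_lt(abs(m$rmse_test - 0.5), 0.06)
})

test_that("single-class labels are rejected", {
  d <- list(x = driver_field("x", matrix(rnorm(100), 10, 10)))
  expect_error(train_transition_potential(d, matrix(1, 10, 10)),
               "single class")
})

test_that("allocation satisfies demand exactly with documented tie-breaks", {
  m <- toy_map(matrix(rep(c(1L, 2L), each = 18), 6, 6))
  zero <- matrix(0, 2, 2)
  expect_identical(allocate_change(m, list(), zero)$values, m$values)

  # uniform potential: exactly 10 convert, lowest pixel indices first
  demand <- matrix(c(0, 10, 0, 0), 2, 2, byrow = TRUE)
  out <- allocate_change(m, list(), demand)
  expect_equal(sum(out$values == 2L), 18 + 10)
  forest_idx <- which(m$values == 1L)
  expect_equal(which(out$values == 2L & m$values == 1L), forest_idx[1:10])

  # monotone potential gradient: converted pixels are the brute-force top-10
  pot <- matrix(seq_len(36) / 36, 6, 6)
  out2 <- allocate_change(m, list("1->2" = pot), demand)
  conv <- which(out2$values == 2L & m$values == 1L)
  brute <- forest_idx[order(-pot[forest_idx], forest_idx)][1:10]
  expect_equal(sort(conv), sort(brute))

  # conservation of total pixel count per class set
  expect_equal(sum(table(out2$values)), 36)

  too_much <- matrix(c(0, 19, 0, 0), 2, 2, byrow = TRUE)
  expect_error(allocate_change(m, list(), too_much), "forest")
})

test_that("projection pipeline composes and conserves", {
  sc <- tiny_scenario(n = 50, seed = 13)
  w <- simulate_scenario(sc)
  yrs <- sc$epoch_years

  # stationary input: identical maps project to themselves
  same <- list(`1985` = w$maps[[1]], `1990` = w$maps[[1]])
  pr0 <- project_lulc(same, list(), target_year = 1995)
  expect_identical(pr0$map$values, w$maps[[1]]$values)

  pr <- project_lulc(stats::setNames(w$maps[1:2], yrs[1:2]), w$drivers,
                     target_year = 1995, seed = 4, max_iterations = 200)
  # pixel-count conservation
  expect_equal(sum(!is.na(pr$map$values)), sum(!is.na(w$maps[[2]]$values)))
  # probability images sum to 1 per valid pixel
  tot <- Reduce(`+`, pr$probabilities)
  expect_true(all(abs(tot[!is.na(tot)] - 1) < 1e-6))
  # demanded areas delivered exactly
  got <- tabulate(match(pr$map$values[!is.na(pr$map$values)],
                        sc$class_codes), 6)
  expect_equal(got, unname(colSums(pr$demand)))

  expect_error(project_lulc(stats::setNames(w$maps[1:2], yrs[1:2]),
                            list(), target_year = 1980),
               "after the base year")
})

test_that("projected areas track the chain under a known kernel", {
  # zero-driver world: evolve twice with known M, calibrate on first pair,
  # project the third epoch; areas must match v M^2 within 3 multinomial SE
  sc <- synthetic_scenario(grid_rows = 120, grid_cols = 120, seed = 17,
                           burn_in = 0)
  M <- sc$true_transition_matrices[[1]]
  m1 <- generate_initial_lulc(sc)
  m2 <- evolve_lulc(m1, M, seed = 21)
  pr <- project_lulc(list(`1985` = m1, `1990` = m2), list(),
                     target_year = 1995)
  v1 <- tabulate(match(m1$values, sc$class_codes), 6)
  expected <- markov_project(v1, M, 2)
  got <- tabulate(match(pr$map$values, sc$class_codes), 6)
  se <- sqrt(pmax(expected * (1 - expected / sum(v1)), 1))
  expect_true(all(abs(got - expected) <= 3 * se + 3))
})

test_that("project_series reuses potentials consistently", {
  sc <- tiny_scenario(n = 40, seed = 19)
  w <- simulate_scenario(sc)
  yrs <- sc$epoch_years
  ser <- project_series(stats::setNames(w$maps, yrs), w$drivers,
                        target_years = c(2025, 2030), seed = 2,
                        max_iterations = 150)
  single <- project_lulc(stats::setNames(w$maps, yrs), w$drivers,
                         target_year = 2025, seed = 2,
                         max_iterations = 150)
  expect_identical(ser[["2025"]]$map$values, single$map$values)
  expect_equal(dim(ser[["2030"]]$map$values), dim(w$maps[[1]]$values))
})
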