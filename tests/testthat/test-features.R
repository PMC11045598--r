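make_scene <- function(blue, red, nir) {
  arr <- array(NA_real_, c(1, 1, 6),
               dimnames = list(NULL, NULL,
                               c("blue", "green", "red", "nir", "swir1",
                                 "swir2")))
  arr[1, 1, ] <- c(blue, 0.1, red, nir, 0.1, 0.1)
  arr
}

test_that("vegetation indices match their closed forms", {
  s <- vegetation_indices(make_scene(0.05, 0.25, 0.5))
  expect_equal(unname(s[1, 1, "ndvi"]), 1 / 3)
  expect_equal(unname(s[1, 1, "dvi"]), 0.25)
  # EVI with G=2.5, C1=6, C2=7.5, L=1
  expect_equal(unname(s[1, 1, "evi"]),
               2.5 * (0.5 - 0.25) / (0.5 + 6 * 0.25 - 7.5 * 0.05 + 1))

  s2 <- vegetation_indices(make_scene(0.05, 0.3, 0.3)) # NIR = R
  expect_equal(unname(s2[1, 1, "ndvi"]), 0)
  expect_equal(unname(s2[1, 1, "dvi"]), 0)

  s3 <- vegetation_indices(make_scene(0.05, 0, 0.4)) # R = 0
  expect_equal(unname(s3[1, 1, "ndvi"]), 1)

  s4 <- vegetation_indices(make_scene(0.05, 0, 0)) # NIR + R = 0
  expect_true(is.na(s4[1, 1, "ndvi"]))
})

test_that("STM cube has the 7 x (bands + indices) layer structure", {
  sc <- tiny_scenario(n = 12)
  m <- generate_initial_lulc(sc)
  coll <- append_indices(generate_image_stack(sc, m, n_scenes = 4, seed = 1))
  expect_equal(length(coll$band_names), 9) # 6 bands + 3 indices
  cube <- compute_stm(coll)
  expect_equal(length(cube$feature_names), 63)
  expect_equal(dim(cube$features)[3], 63)

  # percentile ordering invariant at every valid pixel, every series
  for (b in coll$band_names) {
    mn <- cube$features[, , paste0(b, "_min")]
    p25 <- cube$features[, , paste0(b, "_p25")]
    p50 <- cube$features[, , paste0(b, "_p50")]
    p75 <- cube$features[, , paste0(b, "_p75")]
    mx <- cube$features[, , paste0(b, "_max")]
    expect_true(all(mn <= p25 + 1e-12 & p25 <= p50 + 1e-12 &
                      p50 <= p75 + 1e-12 & p75 <= mx + 1e-12))
    expect_equal(cube$features[, , paste0(b, "_median")], p50)
  }
})

test_that("STM statistics match hand computations", {
  # constant stack
  mk <- function(v) array(v, c(1, 1, 1), dimnames = list(NULL, NULL, "x"))
  coll <- image_collection(lapply(c(5, 5, 5), mk), "x")
  cube <- compute_stm(coll)
  got <- cube$features[1, 1, ]
  expect_equal(unname(got[c("x_median", "x_min", "x_max", "x_p25", "x_p50",
                            "x_p75")]), rep(5, 6))
  expect_equal(unname(got[["x_sd"]]), 0)

  # {1,2,3}: median 2, sample sd 1, p25 = 1.5 under linear interpolation
  coll2 <- image_collection(lapply(c(2, 1, 3), mk), "x")
  g2 <- compute_stm(coll2)$features[1, 1, ]
  expect_equal(unname(g2[["x_median"]]), 2)
  expect_equal(unname(g2[["x_sd"]]), 1)
  expect_equal(unname(g2[["x_p25"]]), 1.5)
  expect_equal(unname(g2[["x_p75"]]), 2.5)

  # nodata scenes excluded pixel-wise
  s1 <- mk(4)
  s2 <- mk(NA_real_)
  s3 <- mk(8)
  g3 <- compute_stm(image_collection(list(s1, s2, s3), "x"))$features[1, 1, ]
  expect_equal(unname(g3[["x_median"]]), 6)
  expect_equal(unname(g3[["x_min"]]), 4)
})

test_that("sample splitting is stratified with the documented rounding", {
  s <- data.frame(row = 1:800, col = 1,
                  class_code = rep(1:6, c(360, 200, 96, 80, 40, 24)))
  sp <- split_samples(s, 0.7, seed = 1)
  expect_equal(sum(sp$role == "train"), 560)
  expect_equal(sum(sp$role == "test"), 240)
  # each stratum within 1 of n_c * 0.7
  for (cc in 1:6) {
    n_c <- sum(s$class_code == cc)
    tr <- sum(sp$role == "train" & sp$class_code == cc)
    expect_lte(abs(tr - n_c * 0.7), 1)
  }

  s10 <- data.frame(row = 1:10, col = 1, class_code = rep(1, 10))
  sp10 <- split_samples(s10, 0.7, seed = 1)
  expect_equal(sum(sp10$role == "train"), 7)

  spall <- split_samples(s, 1, seed = 1)
  expect_true(all(spall$role == "train"))
  expect_error(split_samples(s, 0), "train_fraction")
})

test_that("the tree ensemble separates separable classes and is seeded", {
  tc <- toy_cube(noise = 0.05)
  samples <- data.frame(row = rep(1:20, 4), col = rep(c(1, 5, 12, 18), each = 20))
  samples$class_code <- tc$truth$values[cbind(samples$row, samples$col)]
  m1 <- train_classifier(tc$cube, samples, n_trees = 25, seed = 3)
  m2 <- train_classifier(tc$cube, samples, n_trees = 25, seed = 3)
  pred <- classify(m1, tc$cube)
  # training pixels reproduced exactly on separable data
  expect_equal(pred$values[cbind(samples$row, samples$col)],
               samples$class_code)
  expect_identical(classify(m2, tc$cube)$values, pred$values)

  # closed world: a model trained without class k never emits it
  expect_true(all(pred$values %in% 1:2))

  # absent class errors by name
  expect_error(train_classifier(tc$cube, samples, classes = 1:3),
               "class 3")
})

test_that("larger ensembles do not hurt accuracy on noisy data", {
  set.seed(99)
  wins <- replicate(10, {
    tc <- toy_cube(noise = 1.1, seed = sample.int(1e6, 1))
    idx <- expand.grid(row = 1:20, col = 1:20)
    tr <- sample.int(400, 120)
    te <- setdiff(seq_len(400), tr)[1:120]
    samples <- data.frame(row = idx$row[tr], col = idx$col[tr])
    samples$class_code <- tc$truth$values[cbind(samples$row, samples$col)]
    test_s <- data.frame(row = idx$row[te], col = idx$col[te])
    test_s$class_code <- tc$truth$values[cbind(test_s$row, test_s$col)]
    acc <- function(n_trees) {
      m <- train_classifier(tc$cube, samples, n_trees = n_trees, seed = 1)
      assess_accuracy(classify(m, tc$cube), test_s)$overall_accuracy
    }
    acc(100) - acc(1)
  })
  expect_gte(median(wins), 0)
})

test_that("classify propagates nodata and validates features", {
  tc <- toy_cube()
  samples <- data.frame(row = rep(1:20, 2), col = rep(c(1, 18), each = 20))
  samples$class_code <- tc$truth$values[cbind(samples$row, samples$col)]
  m <- train_classifier(tc$cube, samples, n_trees = 10, seed = 1)
  cube_na <- tc$cube
  cube_na$features[] <- NA_real_
  out <- classify(m, cube_na)
  expect_true(all(is.na(out$values)))
  cube_bad <- tc$cube
  cube_bad$feature_names <- c("x", "y", "z")
  expect_error(classify(m, cube_bad), "feature names")
})

test_that("accuracy metrics match closed forms", {
  rep1 <- accuracy_from_confusion(matrix(c(50, 10, 10, 30), 2, 2,
                                         byrow = TRUE))
  expect_equal(rep1$overall_accuracy, 0.8)
  expect_equal(rep1$kappa, (0.8 - 0.52) / (1 - 0.52))
  expect_equal(unname(rep1$per_class_f1[1]), 50 / 60)

  perfect <- accuracy_from_confusion(diag(c(5, 8, 2)))
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_true(all(perfect$per_class_f1 == 1))

  # independent prediction with identical marginals: kappa ~ 0 in expectation
  set.seed(7)
  ks <- replicate(300, {
    truth <- sample(1:3, 300, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    pred <- sample(1:3, 300, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    cm <- table(factor(truth, levels = 1:3), factor(pred, levels = 1:3))
    accuracy_from_confusion(cm)$kappa
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("forest binarization is consistent with the crosstab", {
  sc <- tiny_scenario(n = 30)
  m <- generate_initial_lulc(sc)
  bin <- binarize_forest(m, 1)
  expect_equal(sum(bin$values == 1L), sum(m$values == 1L))

  allf <- toy_map(matrix(1L, 3, 3))
  expect_true(all(binarize_forest(allf, 1)$values == 1L))
  nof <- toy_map(matrix(2L, 3, 3))
  expect_true(all(binarize_forest(nof, 1)$values == 0L))
  expect_error(binarize_forest(m, 99), "class set")
})
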