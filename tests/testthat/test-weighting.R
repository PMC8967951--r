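paper_geom <- voxel_geometry()

test_that("smoothed class weights reproduce the closed-form examples", {
  # balanced 100/100/100 of 300: each w' = log 6, normalized to 1/3
  w <- class_weights_smoothed(c(100, 100, 100))
  expect_equal(as.vector(attr(w, "w_prime")), rep(log(6), 3))
  expect_equal(as.vector(unclass(w)), rep(1 / 3, 3), ignore_attr = TRUE)
  # all voxels one class: that class gets w' = max(log 2, 1) = 1
  w1 <- class_weights_smoothed(c(50, 0, 0))
  expect_equal(as.vector(attr(w1, "w_prime"))[1], 1)
  # strong imbalance 980/10/10
  w2 <- class_weights_smoothed(c(980, 10, 10))
  expect_equal(as.vector(attr(w2, "w_prime")), c(1, log(200), log(200)))
  expect_equal(as.vector(unclass(w2)), c(1, log(200), log(200)) / (1 + 2 * log(200)), ignore_attr = TRUE)
  expect_equal(round(as.vector(w2), 4), c(0.0862, 0.4569, 0.4569), ignore_attr = TRUE)
})

test_that("smoothed weights normalize to 1 for any composition", {
  set.seed(12)
  for (i in 1:100) {
    counts <- rmultinom(1, sample(10:5000, 1), prob = runif(3, 0.01, 1))[, 1]
    w <- class_weights_smoothed(counts)
    expect_equal(sum(w), 1)
    expect_true(all(is.finite(attr(w, "w_prime"))))
  }
})

test_that("generalized-Dice class weights are inverse squared volumes", {
  expect_equal(as.vector(class_weights_gdl(c(4, 2, 2))), c(1 / 16, 1 / 4, 1 / 4))
  expect_equal(as.vector(class_weights_gdl(c(9, 9, 9))), rep(1 / 81, 3))
  expect_equal(as.vector(class_weights_gdl(c(5, 0, 3)))[2], 0)  # absent class
})

test_that("distance field is an exact anisotropic EDT in um", {
  lab <- array(0L, c(6, 6, 4))
  lab[3, 3, 2] <- 1L
  df <- distance_field(lab, paper_geom)
  expect_equal(df[3, 3, 2], 0)
  expect_equal(df[4, 3, 2], 0.0751562)
  expect_equal(df[3, 3, 3], 0.279911)
  # random mask vs brute-force all-pairs minimum
  set.seed(8)
  d <- c(10L, 10L, 5L)
  lab2 <- array(as.integer(runif(prod(d)) < 0.1), d)
  if (!any(lab2 > 0)) lab2[4, 4, 2] <- 1L
  df2 <- distance_field(lab2, paper_geom)
  pts <- which(lab2 > 0, arr.ind = TRUE)
  vs <- paper_geom$voxel_size
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    bf <- sqrt(min(((x - pts[, 1]) * vs[1])^2 + ((y - pts[, 2]) * vs[2])^2 +
                     ((z - pts[, 3]) * vs[3])^2))
    expect_equal(df2[x, y, z], bf, tolerance = 1e-12)
  }
})

test_that("pixel weights hit their closed forms and decay monotonically", {
  d <- array(c(0, 1, 3, 2.5, 5, 7), c(6, 1, 1))
  we <- pixel_weight_exp(d, 0.5)
  expect_equal(we[1, 1, 1], 1)
  expect_equal(we[2, 1, 1], 0.5)
  expect_equal(we[3, 1, 1], 0.125)
  ww <- pixel_weight_window(d, 5)
  expect_equal(ww[1, 1, 1], 1)
  expect_equal(ww[5, 1, 1], 0)          # d = d_max
  expect_equal(ww[6, 1, 1], 0)          # beyond
  expect_equal(pixel_weight_window(array(2.5, c(1, 1, 1)), 5)[1], 0.5625)
  # both non-increasing in d, equal to 1 at zero
  ds <- seq(0, 8, by = 0.05)
  for (f in list(function(x) pixel_weight_exp(x, 0.3),
                 function(x) pixel_weight_window(x, 5))) {
    v <- f(ds)
    expect_true(all(diff(v) <= 1e-12))
    expect_equal(v[1], 1)
  }
  # continuity at d_max
  expect_lt(pixel_weight_window(5 - 1e-9, 5), 1e-15)
})

test_that("WCEL matches its closed forms and a scalar-loop oracle", {
  d <- c(4L, 3L, 2L)
  set.seed(4)
  gt <- array(sample(0:2, prod(d), TRUE), d)
  onehot <- array(0, c(d, 3))
  for (k in 0:2) onehot[, , , k + 1][gt == k] <- 1
  # perfect prediction: zero
  expect_equal(wcel(onehot, gt, 1), 0)
  # uniform prediction, unit weights: #Omega * log 3
  unif <- array(1 / 3, c(d, 3))
  expect_equal(wcel(unif, gt, 1), prod(d) * log(3), tolerance = 1e-12)
  # random case vs oracle
  pred <- random_probs(d)
  w <- array(runif(prod(d)), d)
  expect_equal(wcel(pred, gt, w), wcel_oracle(pred, gt, w), tolerance = 1e-9)
  # WCEL >= 0 and only 0 when one-hot correct on the weight support
  expect_gt(wcel(pred, gt, w), 0)
  expect_error(wcel(pred, array(0L, c(5, 3, 2)), 1), "mismatch")
})

test_that("GDL matches its oracle and is class-permutation invariant", {
  d <- c(4L, 3L, 2L)
  set.seed(14)
  gt <- array(sample(0:2, prod(d), TRUE), d)
  pred <- random_probs(d)
  expect_equal(gdl(pred, gt), gdl_oracle(pred, gt), tolerance = 1e-12)
  onehot <- array(0, c(d, 3))
  for (k in 0:2) onehot[, , , k + 1][gt == k] <- 1
  expect_equal(gdl(onehot, gt), 0)
  v <- gdl(pred, gt)
  expect_gte(v, 0)
  expect_lte(v, 1)
  # jointly permute class indices of prediction and ground truth
  perm <- c(2L, 0L, 1L)
  gt_p <- array(perm[gt + 1L], d)
  pred_p <- pred[, , , order(perm), drop = FALSE]
  expect_equal(gdl(pred_p, gt_p), v, tolerance = 1e-12)
})

test_that("weight volumes multiply class and pixel factors", {
  d <- c(6L, 6L, 3L)
  lab <- array(rep(0:2, length.out = prod(d)), d)  # perfectly balanced
  cfg <- default_config()$weighting
  w <- build_weight_volume(lab, "patch", cfg, geometry = paper_geom)
  expect_equal(unname(w), array(1 / 3, d))  # mode none + uniform classes
  # exp mode decays monotonically outward from the structures
  lab2 <- array(0L, d)
  lab2[3, 3, 2] <- 1L
  cfg$mode <- "exp"
  w2 <- build_weight_volume(lab2, "patch", cfg, geometry = paper_geom)
  df <- distance_field(lab2, paper_geom)
  ord <- order(as.vector(df))
  ratio <- as.vector(w2) / class_weights_smoothed(lab2)[lab2 + 1L]
  expect_true(all(diff(ratio[ord]) <= 1e-12))
  # dataset scope differs from patch scope iff compositions differ
  w3 <- build_weight_volume(lab2, "dataset", default_config()$weighting,
                            dataset_counts = c(1, 1, 1), geometry = paper_geom)
  expect_false(isTRUE(all.equal(w3, build_weight_volume(
    lab2, "patch", default_config()$weighting, geometry = paper_geom))))
})
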