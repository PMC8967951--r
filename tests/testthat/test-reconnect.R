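rc_default <- default_config()$reconnect
paper_geom <- voxel_geometry()

test_that("connected components match a brute-force BFS oracle", {
  set.seed(7)
  for (i in 1:6) {
    d <- c(sample(5:12, 1), sample(5:12, 1), sample(3:8, 1))
    mask <- array(runif(prod(d)) < 0.35, dim = d)
    lab <- array(0L, d)
    lab[mask] <- 2L
    for (conn in c(6L, 26L)) {
      got <- find_components(lab, 2L, conn)
      want <- components_oracle(mask, conn)
      expect_identical(got$n, max(want))
      # same partition up to label renaming
      both <- table(got$ids[mask], want[mask])
      expect_true(all(rowSums(both > 0) == 1) && all(colSums(both > 0) == 1))
    }
  }
})

test_that("in-plane diagonal voxels: one 26-component, two 6-components", {
  lab <- array(0L, c(4, 4, 1))
  lab[1, 1, 1] <- 2L
  lab[2, 2, 1] <- 2L
  expect_identical(find_components(lab, 2L, 26L)$n, 1L)
  expect_identical(find_components(lab, 2L, 6L)$n, 2L)
  expect_identical(find_components(array(0L, c(4, 4, 2)), 2L)$n, 0L)
})

test_that("clip_bounding_box pads, clamps, and re-embeds losslessly", {
  d <- c(30L, 30L, 10L)
  lab <- array(0L, d)
  lab[5, 5, 2] <- 2L
  img <- array(runif(prod(d)), d)
  cl <- clip_bounding_box(lab, img, lab == 2L, pad = c(6, 6, 2))
  expect_identical(cl$ranges[[1]], 1:11)  # max(1, 5-6) .. 5+6
  expect_identical(cl$ranges[[3]], 1:4)
  expect_identical(cl$offset, c(0L, 0L, 0L))
  full <- clip_bounding_box(lab, img, array(TRUE, d), pad = c(0, 0, 0))
  expect_identical(dim(full$labels), d)
  expect_error(clip_bounding_box(lab, img, lab == 1L), "empty structure")
})

test_that("path_cost evaluates the density + length objective", {
  den <- array(0.5, c(4, 4, 1))
  cfg <- rc_default
  # single voxel with den = 1: both sums vanish
  den1 <- den
  den1[2, 2, 1] <- 1
  expect_equal(path_cost(matrix(c(2, 2, 1), 1), den1, cfg, paper_geom), 0)
  # two in-plane 6-neighbors, den 0.5 each, f_s = 1, physical x step
  p2 <- rbind(c(1, 1, 1), c(2, 1, 1))
  expect_equal(path_cost(p2, den, cfg, paper_geom), 1.0751562)
  # f_s = 0: pure geometric length
  cfg0 <- cfg
  cfg0$f_s <- 0
  expect_equal(path_cost(p2, den, cfg0, paper_geom), 0.0751562)
  # voxel units
  cfgv <- cfg
  cfgv$distance_units <- "voxel"
  expect_equal(path_cost(p2, den, cfgv, paper_geom), 2)
  expect_error(path_cost(rbind(c(1, 1, 1), c(3, 1, 1)), den, cfg, paper_geom),
               "neighbors")
})

test_that("normalized density is min-max with constant clips mapping to zero", {
  expect_true(all(normalized_density(array(7, c(3, 3, 3))) == 0))
  x <- array(0, c(101, 1, 1))
  x[, 1, 1] <- 0:100
  nd <- normalized_density(x)
  expect_equal(nd[51, 1, 1], 0.5)
  expect_equal(range(nd), c(0, 1))
})

test_that("A* equals the Dijkstra oracle and follows bright corridors", {
  skip_if_not_installed("igraph")
  set.seed(3)
  # corridor: two blobs joined by a bright line in a dark field
  d <- c(15L, 9L, 5L)
  den <- array(0.05, d)
  den[4:12, 5, 3] <- 0.95
  source <- array(FALSE, d); source[2:3, 4:6, 2:4] <- TRUE
  target <- array(FALSE, d); target[13:14, 4:6, 2:4] <- TRUE
  res <- astar_connect(den, source, target, NULL, rc_default, paper_geom)
  oc <- dijkstra_cost_oracle(den, source, target, array(FALSE, d), 1,
                             paper_geom$voxel_size)
  expect_equal(res$cost, oc, tolerance = 1e-12)
  mid <- res$path[res$path[, 1] >= 5 & res$path[, 1] <= 11, , drop = FALSE]
  expect_true(all(mid[, 2] == 5 & mid[, 3] == 3))  # rides the corridor
  # adjacent source/target
  d2 <- c(4L, 4L, 2L)
  den2 <- array(runif(prod(d2)), d2)
  s2 <- array(FALSE, d2); s2[1, 1, 1] <- TRUE
  t2 <- array(FALSE, d2); t2[2, 1, 1] <- TRUE
  r2 <- astar_connect(den2, s2, t2, NULL, rc_default, paper_geom)
  expect_lte(nrow(r2$path), 2)
  expect_equal(r2$cost,
               dijkstra_cost_oracle(den2, s2, t2, array(FALSE, d2), 1,
                                    paper_geom$voxel_size), tolerance = 1e-12)
  # uniform density: cost equals the oracle's geodesic cost
  den3 <- array(0.5, d2)
  r3 <- astar_connect(den3, s2, t2, NULL, rc_default, paper_geom)
  expect_equal(r3$cost,
               dijkstra_cost_oracle(den3, s2, t2, array(FALSE, d2), 1,
                                    paper_geom$voxel_size), tolerance = 1e-12)
  # forbidden wall: no admissible path
  d4 <- c(5L, 3L, 1L)
  den4 <- array(0.5, d4)
  s4 <- array(FALSE, d4); s4[1, 2, 1] <- TRUE
  t4 <- array(FALSE, d4); t4[5, 2, 1] <- TRUE
  forb <- array(FALSE, d4); forb[3, , 1] <- TRUE
  expect_error(astar_connect(den4, s4, t4, forb, rc_default, paper_geom),
               class = "spineflow_no_path")
})

test_that("median denoising matches the naive sliding-window oracle", {
  set.seed(5)
  v <- array(runif(8 * 8 * 4), c(8, 8, 4))
  for (w in list(c(3L, 3L, 1L), c(8L, 8L, 2L), c(4L, 2L, 3L))) {
    expect_equal(median_denoise(v, w), median_filter_oracle(v, w))
  }
  # constant volumes are unchanged; a single hot voxel is suppressed
  expect_equal(median_denoise(array(3, c(5, 5, 3)), c(3, 3, 1)),
               array(3, c(5, 5, 3)))
  hot <- array(0, c(7, 7, 3))
  hot[4, 4, 2] <- 100
  expect_true(all(median_denoise(hot, c(3, 3, 1)) == 0))
})

test_that("flood fill obeys min/max ellipsoids and tolerance semantics", {
  d <- c(15L, 11L, 5L)
  cfg <- rc_default
  path <- rbind(c(5, 6, 3), c(6, 6, 3), c(7, 6, 3))
  labels <- array(0L, d)
  # zero-size ellipsoids: exactly the path voxels
  cfg0 <- cfg
  cfg0$min_ellipsoid <- c(0, 0, 0)
  grow0 <- flood_from_path(path, array(5, d), labels, 2L, cfg0, c(0, 0, 0))
  expect_equal(which(grow0),
               sort(path[, 1] + d[1] * (path[, 2] - 1) +
                      d[1] * d[2] * (path[, 3] - 1)))
  # tol = 0, constant intensity: min-dilation plus equal-intensity flood
  cfgc <- cfg
  cfgc$tolerance <- 0
  growc <- flood_from_path(path, array(5, d), labels, 2L, cfgc, c(2, 2, 1))
  # equal intensity everywhere: flood fills the whole max-ellipsoid union
  ns <- asNamespace("spineflow")
  maxu <- ns$stamp_ellipsoids(path, c(2, 2, 1), d)
  expect_identical(growc, maxu)
  # growth never exceeds the max-ellipsoid union
  set.seed(9)
  img <- array(runif(prod(d), 1, 10), d)
  grow <- flood_from_path(path, img, labels, 2L, cfg, c(3, 3, 1))
  expect_true(all(which(grow) %in% which(ns$stamp_ellipsoids(path, c(3, 3, 1), d))))
  # monotone in tolerance
  lo <- cfg; lo$tolerance <- 0.05
  hi <- cfg; hi$tolerance <- 0.4
  g_lo <- flood_from_path(path, img, labels, 2L, lo, c(3, 3, 1))
  g_hi <- flood_from_path(path, img, labels, 2L, hi, c(3, 3, 1))
  expect_true(all(g_hi[g_lo]))
  # never claims voxels of a different structure
  lab2 <- labels
  lab2[6, 7, 3] <- 1L
  g2 <- flood_from_path(path, array(5, d), lab2, 2L, cfgc, c(2, 2, 1))
  expect_false(g2[6, 7, 3])
})

test_that("reconnect_structure joins split structures along bright corridors", {
  d <- c(24L, 11L, 5L)
  labels <- array(0L, d)
  labels[2:5, 5:7, 2:4] <- 2L
  labels[11:13, 5:7, 2:4] <- 2L
  labels[19:22, 5:7, 2:4] <- 2L
  img <- array(500, d)
  img[2:22, 6, 3] <- 40000  # bright corridor through all three blobs
  out <- reconnect_structure(labels, img, 2L, rc_default, paper_geom)
  expect_identical(find_components(out, 2L)$n, 1L)
  # never deletes: output label set contains the input set
  expect_true(all(out[labels == 2L] == 2L))
  added <- which(out == 2L & labels == 0L)
  ijk <- arrayInd(added, d)
  # growth stays within the max-ellipsoid dilation of the corridor paths
  expect_true(all(abs(ijk[, 2] - 6) <= 6 & abs(ijk[, 3] - 3) <= 2))
  rep <- attr(out, "report")
  expect_identical(nrow(rep), 2L)
  # an already-connected structure is returned unchanged
  out2 <- reconnect_structure(out, img, 2L, rc_default, paper_geom)
  expect_identical(array(out2, d), array(out, d))
})

test_that("ground-truth preprocessing attaches spines and is idempotent", {
  cfg <- default_config()
  ph <- generate_phantom(phantom_cfg(neck_break_probability = 1), seed = 21)
  before <- count_unconnected_spine_parts(ph$labels, ph$labels)
  expect_gt(before$unconnected, 0)
  pre <- suppressWarnings(preprocess_ground_truth(ph$labels, ph$intensity, cfg))
  after <- count_unconnected_spine_parts(pre, pre)
  expect_identical(after$unconnected, 0L)
  expect_identical(find_components(pre, 1L)$n, 1L)
  # no voxel loses its label
  expect_true(all(pre$labels[ph$labels$labels > 0L] ==
                    ph$labels$labels[ph$labels$labels > 0L]))
  # idempotent
  pre2 <- suppressWarnings(preprocess_ground_truth(pre, ph$intensity, cfg))
  expect_identical(pre2$labels, pre$labels)
  # fully connected ground truth is a fixed point, shaft count unchanged
  clean <- ph$clean_labels
  pre3 <- preprocess_ground_truth(clean, ph$intensity, cfg)
  expect_identical(pre3$labels, clean$labels)
  expect_identical(find_components(pre3, 1L)$n, 1L)
})

test_that("per-spine fragment reconnection uses instance provenance", {
  cfg <- default_config()
  ph <- generate_phantom(phantom_cfg(neck_break_probability = 0), seed = 33)
  labels <- ph$clean_labels$labels
  # split one spine in half by erasing a mid-neck slab (keep shaft contact)
  inst <- ph$instances$ids
  sp_id <- ph$truth$spines$id[1]
  vox <- which(inst == sp_id)
  ijk <- arrayInd(vox, dim(labels))
  dshaft <- distance_field(array((labels == 1L) * 1L, dim(labels)), paper_geom)
  band <- vox[dshaft[vox] > 0.22 & dshaft[vox] <= 0.38]
  skip_if(length(band) == 0 || length(band) == length(vox))
  cut <- labels
  cut[band] <- 0L
  n_before <- find_components(cut, 2L)$n
  skip_if(n_before <= find_components(labels, 2L)$n)  # cut must split
  pre <- suppressWarnings(preprocess_ground_truth(
    label_volume(cut, paper_geom), ph$intensity, cfg, instances = ph$instances))
  expect_lt(find_components(pre, 2L)$n, n_before)
})
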