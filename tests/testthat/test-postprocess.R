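paper_geom <- voxel_geometry()

test_that("noise removal applies the distance AND size conjunction", {
  d <- c(80L, 80L, 20L)
  lab <- array(0L, d)
  lab[10:70, 28:36, 8:13] <- 1L        # large shaft (>> V_d)
  lab[79, 79, 19] <- 2L                # tiny blob > 3 um away
  lab[72, 33, 10] <- 2L                # tiny blob ~0.15 um away
  lab[2:7, 74:79, 15:18] <- 2L         # large blob (>= V_s): size test fails
  lv <- label_volume(lab, paper_geom)
  out <- remove_noise(lv)
  expect_identical(out$labels[79, 79, 19], 0L)   # far and small: removed
  expect_identical(out$labels[72, 33, 10], 2L)   # near: distance test fails
  expect_true(all(out$labels[2:7, 74:79, 15:18] == 2L))  # big: size test fails
  rem <- attr(out, "removed")
  expect_identical(nrow(rem), 1L)
  expect_gt(rem$distance_um, 3)
  # surviving voxels untouched; deleted volume equals the report's sum
  expect_identical(sum(lv$labels > 0L) - sum(out$labels > 0L),
                   sum(rem$voxels))
  # with no shaft above V_d, every small component is "far"
  lab2 <- array(0L, c(20L, 20L, 8L))
  lab2[3, 3, 2] <- 1L
  lab2[15, 15, 6] <- 2L
  out2 <- remove_noise(label_volume(lab2, paper_geom))
  expect_identical(out2$labels[15, 15, 6], 0L)
})

test_that("relabeling changes exactly the selection and validates bounds", {
  lab <- array(0L, c(6, 6, 3))
  lab[2, 2, 1] <- 1L
  out <- relabel_selection(lab, matrix(numeric(0), ncol = 3), 2L)
  expect_identical(out, lab)  # empty selection: identity
  sel <- rbind(c(2, 2, 1), c(3, 3, 2))
  out2 <- relabel_selection(lab, sel, 2L)
  expect_identical(out2[2, 2, 1], 2L)
  expect_identical(out2[3, 3, 2], 2L)
  expect_identical(sum(out2 != lab), 2L)
  back <- relabel_selection(relabel_selection(out2, sel, 0L), rbind(c(2, 2, 1)), 1L)
  expect_identical(back, lab)  # relabel then inverse relabel
  expect_error(relabel_selection(lab, rbind(c(7, 1, 1)), 1L), "outside")
})

test_that("instance extraction mirrors the component partition", {
  lab <- array(0L, c(12, 12, 4))
  lab[2:4, 2:4, 1:2] <- 2L
  lab[8:10, 8:10, 3:4] <- 2L
  lab[6, 6, 2] <- 1L
  inst <- extract_instances(lab)
  ids <- setdiff(unique(as.vector(inst$ids)), 0L)
  expect_length(ids, 3L)
  expect_identical(sum(inst$class_of == 2L), 2L)
  # merged blobs collapse to one instance
  lab2 <- lab
  lab2[4:8, 4:8, 2] <- 2L
  expect_identical(sum(extract_instances(lab2)$class_of == 2L), 1L)
  # cross-module agreement with find_components
  comp <- find_components(lab, 2L, 26L)
  spine_ids <- names(inst$class_of)[inst$class_of == 2L]
  for (sid in spine_ids) {
    vox <- which(inst$ids == as.integer(sid))
    expect_length(unique(comp$ids[vox]), 1L)
  }
})

test_that("supervised reconnection joins exactly the chosen pair", {
  d <- c(20L, 9L, 5L)
  lab <- array(0L, d)
  lab[2:4, 4:6, 2:4] <- 2L
  lab[16:18, 4:6, 2:4] <- 2L
  img <- array(100, d)
  img[2:18, 5, 3] <- 30000
  out <- connect_components_supervised(lab, img, 2L, 1L, 2L,
                                       geometry = paper_geom)
  expect_identical(find_components(out, 2L)$n, 1L)
  expect_gt(attr(out, "report")$voxels_added, 0)
  expect_error(connect_components_supervised(lab, img, 2L, 1L, 1L,
                                             geometry = paper_geom),
               "identical")
  # overrides are applied and unknown options rejected
  expect_error(connect_components_supervised(lab, img, 2L, 1L, 2L,
                                             geometry = paper_geom,
                                             bogus = 1), "unknown")
})

test_that("watershed splits a dumbbell at the neck and conserves voxels", {
  g <- voxel_geometry(c(1, 1, 1))
  d <- c(24L, 16L, 16L)
  mask <- array(FALSE, d)
  for (x in 1:24) for (y in 1:16) for (z in 1:16) {
    p <- c(x, y, z) - 0.5
    in_s1 <- sqrt(sum((p - c(7, 8, 8))^2)) <= 5
    in_s2 <- sqrt(sum((p - c(17, 8, 8))^2)) <= 5
    in_neck <- p[1] > 7 && p[1] < 17 && sqrt(sum((p[2:3] - 8)^2)) <= 2
    if (in_s1 || in_s2 || in_neck) mask[x, y, z] <- TRUE
  }
  ws <- watershed_split(mask, rbind(c(7, 8, 8), c(17, 8, 8)), g)
  expect_identical(ws$ids > 0L, mask)            # exact conservation
  sizes <- table(ws$ids[ws$ids > 0L])
  expect_length(sizes, 2L)
  expect_equal(as.numeric(sizes[1]), as.numeric(sizes[2]), tolerance = 0.02)
  # the split plane sits at the neck center (x = 12) within one voxel
  b1 <- range(which(apply(ws$ids == 1L, 1, any)))
  expect_lte(abs(b1[2] - 12), 1)
  # determinism
  ws2 <- watershed_split(mask, rbind(c(7, 8, 8), c(17, 8, 8)), g)
  expect_identical(ws$ids, ws2$ids)
  # one seed: identity partition; k seeds: k instances
  one <- watershed_split(mask, rbind(c(7, 8, 8)), g)
  expect_identical(one$ids > 0L, mask)
  expect_length(unique(one$ids[one$ids > 0L]), 1L)
  three <- watershed_split(mask, rbind(c(7, 8, 8), c(17, 8, 8), c(12, 8, 8)), g)
  expect_length(unique(three$ids[three$ids > 0L]), 3L)
  expect_error(watershed_split(mask, rbind(c(1, 1, 1)), g), "inside")
})

test_that("instance surfaces are watertight with near-exact volumes", {
  g <- voxel_geometry(c(1, 1, 1))
  ball <- array(0L, c(20L, 20L, 14L))
  for (x in 1:20) for (y in 1:20) for (z in 1:14)
    if (sum((c(x, y, z) - c(10, 10, 7))^2) <= 20) ball[x, y, z] <- 2L
  meshes <- mesh_from_labels(label_volume(ball, g))
  expect_length(meshes, 1L)
  m <- meshes[[1]]
  expect_true(is_watertight(m))
  expect_identical(mesh_euler_characteristic(m), 2L)
  expect_lt(abs(abs(mesh_volume(m)) - sum(ball > 0)) / sum(ball > 0), 0.1)
  # empty instance: no mesh; disjoint instances yield disjoint AABBs
  two <- ball
  two[1:3, 1:3, 1:2] <- 2L
  mm <- mesh_from_labels(label_volume(two, g))
  expect_length(mm, 2L)
  bb <- lapply(mm, function(x) apply(x$vertices, 2, range))
  sep <- any(bb[[1]][2, ] < bb[[2]][1, ]) || any(bb[[2]][2, ] < bb[[1]][1, ])
  expect_true(sep)
})

test_that("unconnected spine parts are counted against GT overlap", {
  d <- c(20L, 20L, 6L)
  gt <- array(0L, d)
  gt[5:15, 9:11, 2:4] <- 1L
  gt[7:8, 12:13, 3] <- 2L     # GT spine A (near shaft)
  gt[12:13, 14:15, 3] <- 2L   # GT spine B
  pred <- array(0L, d)
  pred[5:15, 9:11, 2:4] <- 1L
  pred[7:8, 12:13, 3] <- 2L       # touches predicted shaft: not counted
  pred[12:13, 14:15, 3] <- 2L     # detached and overlaps GT: counted
  pred[2:3, 2:3, 1] <- 2L         # detached, zero GT overlap: ignored
  res <- count_unconnected_spine_parts(pred, gt)
  expect_identical(res$unconnected, 1L)
  expect_identical(res$considered, 2L)
  expect_identical(res$total, 3L)
  # self-comparison counts exactly the GT spine parts not touching GT shaft
  gt2 <- array(0L, d)
  gt2[5:15, 9:11, 2:4] <- 1L
  gt2[7:8, 12, 3] <- 2L       # touches the shaft
  gt2[17:18, 2:3, 1] <- 2L    # detached part
  self <- count_unconnected_spine_parts(gt2, gt2)
  expect_identical(self$unconnected, 1L)
  expect_identical(self$considered, 2L)
})

test_that("improvement ratios match the percentage definition", {
  expect_equal(improvement_ratio(84, 20), 76.19)
  expect_equal(improvement_ratio(134, 30), 77.61)
  expect_equal(improvement_ratio(57, 57), 0)
  expect_error(improvement_ratio(0, 3), "positive")
})
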