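unit_geom <- voxel_geometry(c(1, 1, 1))

test_that("an axis-aligned cube over voxels [2,6)^3 marks exactly the 56 shell voxels", {
  # inset by 1e-6 so no face lies exactly on a voxel boundary plane
  cube <- generate_mesh_fixture("box", list(lo = rep(2 + 1e-6, 3),
                                            hi = rep(6 - 1e-6, 3)), 1L)
  shell <- rasterize_surface(cube, unit_geom, c(10L, 10L, 10L))
  expect_identical(sum(shell), 56L)
  ijk <- which(shell, arr.ind = TRUE)
  expect_true(all(ijk >= 3 & ijk <= 6))  # 1-based indices of voxels 2..5
  solid <- fill_interior(shell)
  expect_identical(sum(solid), 64L)
})

test_that("a mesh inside a single voxel marks exactly that voxel", {
  tiny <- generate_mesh_fixture("icosphere",
                                list(radius = 0.2, center = c(4.5, 4.5, 4.5)))
  shell <- rasterize_surface(tiny, unit_geom, c(10L, 10L, 10L))
  expect_identical(which(shell), which(array(seq_len(1000), c(10, 10, 10)) ==
                                         (5 + 10 * 4 + 100 * 4)))
  expect_identical(sum(shell), 1L)
})

test_that("a mesh outside the volume reports the offending vertex", {
  big <- generate_mesh_fixture("icosphere", list(radius = 3, center = c(1, 5, 5)))
  expect_error(rasterize_surface(big, unit_geom, c(10L, 10L, 10L)),
               "outside the volume")
})

test_that("interior filling is a border-background complement and idempotent", {
  expect_identical(sum(fill_interior(array(FALSE, c(6, 6, 6)))), 0L)
  cube <- generate_mesh_fixture("box", list(lo = rep(1.5, 3), hi = rep(6.5, 3)))
  shell <- rasterize_surface(cube, unit_geom, c(8L, 8L, 8L))
  solid <- fill_interior(shell)
  expect_true(all(solid[3:6, 3:6, 3:6]))
  expect_identical(fill_interior(solid), solid)
})

test_that("icosphere shell has thickness >= 1 along rays from the center", {
  r <- 8
  n <- 24L
  ico <- generate_mesh_fixture("icosphere", list(radius = r, center = rep(12, 3),
                                                 subdivisions = 3))
  shell <- rasterize_surface(ico, unit_geom, rep(n, 3L))
  # cast rays from the center; each must cross at least one shell voxel
  set.seed(1)
  for (i in 1:50) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    ts <- seq(0, r + 1.5, by = 0.25)
    pts <- t(vapply(ts, function(s) 12 + u * s, numeric(3)))
    vox <- unique(pmin(pmax(floor(pts) + 1L, 1L), n))
    hit <- any(shell[vox[, 1] + n * (vox[, 2] - 1L) + n^2 * (vox[, 3] - 1L)])
    expect_true(hit)
  }
})

test_that("voxelization commutes with integer-voxel translation", {
  ico <- generate_mesh_fixture("icosphere", list(radius = 3, center = c(7, 7, 7),
                                                 subdivisions = 2))
  m1 <- fill_interior(rasterize_surface(ico, unit_geom, c(20L, 20L, 20L)))
  shifted <- ico
  shifted$vertices <- sweep(ico$vertices, 2, c(3, 2, 1), "+")
  m2 <- fill_interior(rasterize_surface(shifted, unit_geom, c(20L, 20L, 20L)))
  expect_identical(m2[4:20, 3:20, 2:20], m1[1:17, 1:18, 1:19])
})

test_that("voxelize_scene: class counts, overlap precedence, provenance", {
  geom <- unit_geom
  shape <- c(20L, 16L, 12L)
  shaft <- generate_mesh_fixture("box", list(lo = c(1.5, 5.5, 4.5),
                                             hi = c(18.5, 9.5, 8.5)), 1L)
  sp1 <- generate_mesh_fixture("icosphere", list(radius = 2, center = c(5, 12.2, 6)))
  # shaft only
  lv <- voxelize_scene(shaft, list(), geom, shape)
  expect_setequal(unique(as.vector(lv$labels)), c(0L, 1L))
  expect_identical(sum(lv$labels == 1L),
                   sum(fill_interior(rasterize_surface(shaft, geom, shape))))
  # disjoint shaft + spine: counts equal the independent fills
  lv2 <- voxelize_scene(shaft, list(sp1), geom, shape)
  expect_identical(sum(lv2$labels == 2L),
                   sum(fill_interior(rasterize_surface(sp1, geom, shape))))
  expect_identical(sum(lv2$labels == 1L), sum(lv$labels == 1L))
  inst <- attr(lv2, "instances")
  expect_identical(unname(inst$class_of[c("1", "2")]), c(1L, 2L))
  # overlapping spine wins on the overlap
  sp2 <- generate_mesh_fixture("icosphere", list(radius = 2, center = c(10, 7, 6)))
  lv3 <- voxelize_scene(shaft, list(sp2), geom, shape)
  overlap <- fill_interior(rasterize_surface(sp2, geom, shape)) &
    fill_interior(rasterize_surface(shaft, geom, shape))
  expect_true(any(overlap))
  expect_true(all(lv3$labels[overlap] == 2L))
  # opposite policy keeps the shaft
  lv4 <- voxelize_scene(shaft, list(sp2), geom, shape, spine_over_shaft = FALSE)
  expect_true(all(lv4$labels[overlap] == 1L))
})

test_that("volume error halves (or better) when resolution doubles", {
  errs <- vapply(c(10, 20), function(r) {
    n <- as.integer(2 * r + 8)
    ico <- generate_mesh_fixture("icosphere",
                                 list(radius = r, center = rep(n / 2, 3),
                                      subdivisions = 3))
    solid <- fill_interior(rasterize_surface(ico, unit_geom, rep(n, 3L)))
    abs(sum(solid) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, numeric(1))
  expect_lt(errs[2], errs[1] * 0.55)
})
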