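# distance from every voxel center to a 3-D segment [p, q], vectorized
# over the voxel grid; cx/cy/cz are per-axis center coordinate vectors
segment_distance <- function(cx, cy, cz, p, q) {
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  gx <- array(cx, dim = c(nx, ny, nz))
  gy <- array(rep(cy, each = nx), dim = c(nx, ny, nz))
  gz <- array(rep(cz, each = nx * ny), dim = c(nx, ny, nz))
  v <- q - p
  L2 <- sum(v^2)
  if (L2 == 0) {
    return(sqrt((gx - p[1])^2 + (gy - p[2])^2 + (gz - p[3])^2))
  }
  t <- ((gx - p[1]) * v[1] + (gy - p[2]) * v[2] + (gz - p[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((gx - (p[1] + t * v[1]))^2 + (gy - (p[2] + t * v[2]))^2 +
         (gz - (p[3] + t * v[3]))^2)
}

polyline_distance <- function(cx, cy, cz, pts) {
  d <- NULL
  for (i in seq_len(nrow(pts) - 1)) {
    di <- segment_distance(cx, cy, cz, pts[i, ], pts[i + 1, ])
    d <- if (is.null(d)) di else pmin(d, di)
  }
  d
}

#' Generate a synthetic dendrite phantom
#'
#' Builds a paired intensity/label volume with the structure the
#' pipeline assumes: a tubular dendritic shaft around a smooth random
#' centerline (class 1), spherical spine heads attached by thin
#' cylindrical necks (class 2, one instance each), an intensity channel
#' equal to the structure indicator scaled to 16-bit range, blurred by
#' an anisotropic Gaussian PSF (axially elongated), plus sensor noise.
#' With `neck_break_probability > 0`, selected spines' neck bases are
#' erased from the labels (the image is left intact), emulating the
#' unattached-component annotation defect; with `missing_branch`, a
#' collateral branch appears in the intensity but not in the labels
#' (missing-reconstruction defect).
#'
#' @param cfg the `phantom` section of [default_config()].
#' @param geometry a [voxel_geometry()] (confocal spacing by default).
#' @param seed integer seed; the generator is fully deterministic per
#'   seed.
#' @return list with `intensity` ([intensity_volume()]), `labels` (the
#'   possibly corrupted [label_volume()]), `clean_labels` (before
#'   defects), `instances` ([instance_volume()] provenance on the clean
#'   labels), and `truth` (per-spine record incl. broken flags and any
#'   skipped placements).
#' @export
generate_phantom <- function(cfg = default_config()$phantom,
                             geometry = voxel_geometry(), seed = 0L) {
  set.seed(seed)
  dims <- as.integer(cfg$shape)
  vs <- geometry$voxel_size
  ext <- dims * vs
  cx <- (seq_len(dims[1]) - 0.5) * vs[1]
  cy <- (seq_len(dims[2]) - 0.5) * vs[2]
  cz <- (seq_len(dims[3]) - 0.5) * vs[3]

  # shaft centerline: gentle random walk along x, kept near the center
  n_ctrl <- 8
  tx <- seq(0.05 * ext[1], 0.95 * ext[1], length.out = n_ctrl)
  wob <- function(extent) {
    w <- cumsum(stats::rnorm(n_ctrl, 0, 0.12))
    w <- w - mean(w)
    extent / 2 + pmin(pmax(w, -0.15 * extent), 0.15 * extent)
  }
  ty <- wob(ext[2])
  tz <- rep(ext[3] / 2, n_ctrl) + pmin(pmax(cumsum(stats::rnorm(n_ctrl, 0, 0.05)) -
    0, -0.1 * ext[3]), 0.1 * ext[3])
  fine_t <- seq(0, 1, length.out = 40)
  ctr <- cbind(stats::spline(seq_len(n_ctrl), tx, xout = 1 + fine_t * (n_ctrl - 1))$y,
               stats::spline(seq_len(n_ctrl), ty, xout = 1 + fine_t * (n_ctrl - 1))$y,
               stats::spline(seq_len(n_ctrl), tz, xout = 1 + fine_t * (n_ctrl - 1))$y)
  shaft_dist <- polyline_distance(cx, cy, cz, ctr)
  shaft_mask <- shaft_dist <= cfg$shaft_radius

  labels <- array(0L, dim = dims)
  labels[shaft_mask] <- 1L
  ids <- array(0L, dim = dims)
  ids[shaft_mask] <- 1L
  class_of <- c("1" = 1L)

  spine_rows <- list()
  skipped <- 0L
  head_centers <- matrix(numeric(0), ncol = 4)  # x, y, z, r
  for (si in seq_len(cfg$spine_count)) {
    placed <- FALSE
    for (attempt in 1:20) {
      ti <- sample(5:(nrow(ctr) - 5), 1)
      base <- ctr[ti, ]
      tangent <- ctr[min(ti + 1, nrow(ctr)), ] - ctr[max(ti - 1, 1), ]
      tangent <- tangent / sqrt(sum(tangent^2))
      theta <- stats::runif(1, 0, 2 * pi)
      raw <- c(0, cos(theta), 0.35 * sin(theta))  # mostly in-plane: z is thin
      dirv <- raw - sum(raw * tangent) * tangent
      dirv <- dirv / sqrt(sum(dirv^2))
      neck_len <- stats::runif(1, cfg$neck_length_range[1], cfg$neck_length_range[2])
      head_r <- stats::runif(1, cfg$head_radius_range[1], cfg$head_radius_range[2])
      hc <- base + dirv * (cfg$shaft_radius + neck_len + 0.6 * head_r)
      lo_ok <- all(hc > head_r + 1.5 * vs)
      hi_ok <- all(hc < ext - head_r - 1.5 * vs)
      if (!lo_ok || !hi_ok) next
      if (nrow(head_centers) > 0) {
        dd <- sqrt(colSums((t(head_centers[, 1:3, drop = FALSE]) - hc)^2))
        if (any(dd < head_centers[, 4] + head_r + 0.15)) next
      }
      neck_from <- base + dirv * (0.5 * cfg$shaft_radius)
      neck_d <- segment_distance(cx, cy, cz, neck_from, hc)
      head_d <- segment_distance(cx, cy, cz, hc, hc)
      sp_mask <- (neck_d <= cfg$neck_radius | head_d <= head_r) & !shaft_mask
      # a neck thinner than the (anisotropic) voxel can fragment when
      # rasterized: stamp the voxel chain under the neck axis so every
      # spine is one connected component attached to the shaft
      npts <- 4L * ceiling(sqrt(sum((hc - neck_from)^2)) / min(vs)) + 2L
      ts <- seq(0, 1, length.out = npts)
      chain <- cbind(neck_from[1] + ts * (hc[1] - neck_from[1]),
                     neck_from[2] + ts * (hc[2] - neck_from[2]),
                     neck_from[3] + ts * (hc[3] - neck_from[3]))
      cvox <- point_to_voxel(geometry, chain)
      clin <- cvox[, 1] + dims[1] * (cvox[, 2] - 1L) +
        dims[1] * dims[2] * (cvox[, 3] - 1L)
      sp_mask[clin[!shaft_mask[clin]]] <- TRUE
      if (!any(sp_mask)) next
      # drop rasterization slivers not connected to the neck chain
      comp <- array(cpp_label_components(as.logical(sp_mask),
                                         as.integer(dims), 26L), dim = dims)
      keep <- unique(comp[clin])
      sp_mask <- sp_mask & array(comp %in% setdiff(keep, 0L), dim = dims)
      labels[sp_mask] <- 2L
      ids[sp_mask] <- 1L + si
      class_of[as.character(1L + si)] <- 2L
      head_centers <- rbind(head_centers, c(hc, head_r))
      spine_rows[[length(spine_rows) + 1]] <- data.frame(
        id = 1L + si, head_x = hc[1], head_y = hc[2], head_z = hc[3],
        head_radius = head_r, neck_length = neck_len, broken = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) skipped <- skipped + 1L
  }
  spines <- if (length(spine_rows)) do.call(rbind, spine_rows) else
    data.frame(id = integer(0), head_x = numeric(0), head_y = numeric(0),
               head_z = numeric(0), head_radius = numeric(0),
               neck_length = numeric(0), broken = logical(0))
  if (skipped > 0)
    warning(sprintf("%d spine(s) could not be placed without overlap", skipped))

  # intensity: indicator -> PSF blur -> noise (image built BEFORE defects)
  signal <- (labels > 0L) * cfg$peak_intensity
  branch_mask <- NULL
  if (isTRUE(cfg$missing_branch)) {
    bi <- max(4, round(nrow(ctr) * 0.3))
    bdir <- c(0.25, -sign(ctr[bi, 2] - ext[2] / 2 + 1e-9), 0)
    bdir <- bdir / sqrt(sum(bdir^2))
    bend <- ctr[bi, ] + bdir * min(0.35 * ext[2], 2.5)
    bd <- segment_distance(cx, cy, cz, ctr[bi, ], bend)
    branch_mask <- bd <= 0.7 * cfg$shaft_radius
    signal[branch_mask & labels == 0L] <- cfg$peak_intensity
  }
  sigma_vox <- cfg$psf_sigma / vs
  img <- if (any(sigma_vox > 0)) {
    array(cpp_gaussian_blur(as.numeric(signal), dims, as.numeric(sigma_vox)),
          dim = dims)
  } else signal
  if (isTRUE(cfg$poisson_noise)) {
    img <- array(stats::rpois(length(img), pmax(img, 0) / 16) * 16, dim = dims)
  }
  if (cfg$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, cfg$noise_sigma)
  }
  img <- round(pmin(pmax(img, 0), 65535))
  dim(img) <- dims

  clean <- label_volume(labels, geometry)
  inst <- instance_volume(ids, class_of, geometry)
  out_labels <- clean
  if (cfg$neck_break_probability > 0 && nrow(spines) > 0) {
    cb <- corrupt_labels(clean, "break_necks",
                         params = list(rate = cfg$neck_break_probability,
                                       gap = cfg$break_gap),
                         seed = seed + 10000L)
    out_labels <- cb
    rec <- attr(cb, "defects")
    if (!is.null(rec) && nrow(rec) > 0) {
      # map broken components back to spine ids via instance overlap
      for (r in seq_len(nrow(rec))) {
        vox <- attr(cb, "defect_voxels")[[r]]
        hit <- unique(ids[vox])
        hit <- hit[hit > 1L]
        spines$broken[spines$id %in% hit] <- TRUE
      }
    }
  }
  truth <- list(spines = spines, skipped = skipped, seed = seed,
                missing_branch_voxels = if (is.null(branch_mask)) 0L
                                        else sum(branch_mask & labels == 0L))
  list(intensity = intensity_volume(img, geometry), labels = out_labels,
       clean_labels = clean, instances = inst, truth = truth)
}

#' Apply an annotation defect to a label volume
#'
#' `break_necks` erases, for each spine component adjacent to the
#' shaft selected with probability `rate`, all spine voxels within
#' `gap` um of the shaft, detaching the spine while leaving the image
#' untouched. `drop_branch` removes one whole connected component of
#' the chosen class (missing-reconstruction defect).
#'
#' @param labels a [label_volume()] or array.
#' @param defect `"break_necks"` or `"drop_branch"`.
#' @param params list: `rate` and `gap` (um) for `break_necks`;
#'   `class` (default 1) and optional `component` id for
#'   `drop_branch`.
#' @param seed integer seed for the defect draw.
#' @param connectivity 6 or 26.
#' @return labels of the input type with attribute `defects`, a
#'   data.frame of affected components, and `defect_voxels`, the erased
#'   voxel indices per record.
#' @export
corrupt_labels <- function(labels, defect = c("break_necks", "drop_branch"),
                           params = list(), seed = 0L, connectivity = 26L) {
  defect <- match.arg(defect)
  arr <- as_array3d(labels)
  geometry <- vol_geometry(labels)
  d <- dim(arr)
  set.seed(seed)
  records <- list()
  voxsets <- list()
  if (defect == "break_necks") {
    rate <- if (is.null(params$rate)) 0.5 else params$rate
    gap <- if (is.null(params$gap)) 0.35 else params$gap
    shaft <- arr == 1L
    if (any(shaft) && any(arr == 2L)) {
      dist_shaft <- array(cpp_edt(as.logical(shaft), as.integer(d),
                                  as.numeric(geometry$voxel_size)), dim = d)
      comps <- find_components(arr, 2L, connectivity, geometry)
      touch <- array(cpp_adjacent_mask(as.logical(comps$ids > 0L),
                                       as.logical(shaft), as.integer(d),
                                       as.integer(connectivity)), dim = d)
      for (ci in seq_len(comps$n)) {
        vox <- comps$voxels[[ci]]
        if (!any(touch[vox])) next
        if (stats::runif(1) >= rate) next
        erase <- vox[dist_shaft[vox] <= gap]
        if (length(erase) == 0 || length(erase) == length(vox)) next
        arr[erase] <- 0L
        records[[length(records) + 1]] <- data.frame(
          defect = "break_necks", component = ci,
          voxels_removed = length(erase))
        voxsets[[length(voxsets) + 1]] <- erase
      }
    }
  } else {
    cls <- if (is.null(params$class)) 1L else as.integer(params$class)
    comps <- find_components(arr, cls, connectivity, geometry)
    if (comps$n > 0) {
      ci <- if (!is.null(params$component)) params$component
            else sample(comps$n, 1)
      vox <- comps$voxels[[ci]]
      arr[vox] <- 0L
      records[[1]] <- data.frame(defect = "drop_branch", component = ci,
                                 voxels_removed = length(vox))
      voxsets[[1]] <- vox
    }
  }
  out <- if (inherits(labels, "label_volume")) label_volume(arr, geometry)
         else arr
  attr(out, "defects") <- if (length(records)) do.call(rbind, records) else
    data.frame(defect = character(0), component = integer(0),
               voxels_removed = integer(0))
  attr(out, "defect_voxels") <- voxsets
  out
}

#' Analytic watertight mesh fixtures
#'
#' `icosphere`: subdivided icosahedron projected to a sphere.
#' `box`: an axis-aligned box. `dumbbell`: two spheres joined by a
#' cylindrical neck, built as a closed surface of revolution.
#'
#' @param kind `"icosphere"`, `"box"`, or `"dumbbell"`.
#' @param params list of parameters: icosphere `radius`, `center`,
#'   `subdivisions`; box `lo`, `hi`; dumbbell `center`, `length`
#'   (between sphere centers), `radius` (spheres), `neck_radius`,
#'   `n_theta`, `n_axis`.
#' @param structure_class class tag (1 or 2).
#' @return A watertight [triangle_mesh()].
#' @export
generate_mesh_fixture <- function(kind = c("icosphere", "box", "dumbbell"),
                                  params = list(), structure_class = 2L) {
  kind <- match.arg(kind)
  switch(kind,
    icosphere = make_icosphere(params, structure_class),
    box = make_box(params, structure_class),
    dumbbell = make_dumbbell(params, structure_class))
}

make_box <- function(params, structure_class) {
  lo <- if (is.null(params$lo)) c(0, 0, 0) else params$lo
  hi <- if (is.null(params$hi)) c(1, 1, 1) else params$hi
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: (x fastest) 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
  #               5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = lo
             c(5, 6, 7), c(6, 8, 7),   # z = hi
             c(1, 2, 5), c(2, 6, 5),   # y = lo
             c(3, 7, 4), c(4, 7, 8),   # y = hi
             c(1, 5, 3), c(3, 5, 7),   # x = lo
             c(2, 4, 6), c(4, 8, 6))   # x = hi
  triangle_mesh(v, f, structure_class)
}

make_icosphere <- function(params, structure_class) {
  radius <- if (is.null(params$radius)) 1 else params$radius
  center <- if (is.null(params$center)) c(0, 0, 0) else params$center
  nsub <- if (is.null(params$subdivisions)) 2L else params$subdivisions
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(nsub)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    verts <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1]] <<- matrix(m, 1)
      nv <<- nv + 1L
      midcache[[key]] <- nv
      nv
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c3, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, verts)
    f <- newf
  }
  v <- sweep(v * radius, 2, center, "+")
  triangle_mesh(v, f, structure_class)
}

make_dumbbell <- function(params, structure_class) {
  center <- if (is.null(params$center)) c(0, 0, 0) else params$center
  L <- if (is.null(params$length)) 2 else params$length
  r <- if (is.null(params$radius)) 0.6 else params$radius
  rn <- if (is.null(params$neck_radius)) 0.25 else params$neck_radius
  n_theta <- if (is.null(params$n_theta)) 24L else params$n_theta
  n_axis <- if (is.null(params$n_axis)) 48L else params$n_axis
  half <- L / 2
  xs <- seq(-half - r, half + r, length.out = n_axis)
  prof <- vapply(xs, function(x) {
    s1 <- if (abs(x + half) < r) sqrt(r^2 - (x + half)^2) else 0
    s2 <- if (abs(x - half) < r) sqrt(r^2 - (x - half)^2) else 0
    nk <- if (abs(x) <= half) rn else 0
    max(s1, s2, nk)
  }, numeric(1))
  prof[1] <- 0
  prof[n_axis] <- 0
  revolve_x(xs, prof, n_theta, center, structure_class)
}

# closed surface of revolution around the x axis; profile must start
# and end at radius 0 (poles)
revolve_x <- function(xs, radii, n_theta, center, structure_class) {
  stopifnot(radii[1] == 0, radii[length(radii)] == 0,
            all(radii[c(-1, -length(radii))] > 0))
  thetas <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- matrix(c(xs[1], 0, 0), 1)  # pole 1
  ring_start <- integer(0)
  for (i in 2:(length(xs) - 1)) {
    ring_start <- c(ring_start, nrow(verts) + 1L)
    ring <- cbind(xs[i], radii[i] * cos(thetas), radii[i] * sin(thetas))
    verts <- rbind(verts, ring)
  }
  pole2 <- nrow(verts) + 1L
  verts <- rbind(verts, c(xs[length(xs)], 0, 0))
  faces <- list()
  first <- ring_start[1]
  for (j in seq_len(n_theta)) {
    jn <- j %% n_theta + 1L
    faces[[length(faces) + 1]] <- c(1L, first + jn - 1L, first + j - 1L)
  }
  for (ri in seq_len(length(ring_start) - 1)) {
    a <- ring_start[ri]
    b <- ring_start[ri + 1]
    for (j in seq_len(n_theta)) {
      jn <- j %% n_theta + 1L
      faces[[length(faces) + 1]] <- c(a + j - 1L, b + jn - 1L, b + j - 1L)
      faces[[length(faces) + 1]] <- c(a + j - 1L, a + jn - 1L, b + jn - 1L)
    }
  }
  last <- ring_start[length(ring_start)]
  for (j in seq_len(n_theta)) {
    jn <- j %% n_theta + 1L
    faces[[length(faces) + 1]] <- c(pole2, last + j - 1L, last + jn - 1L)
  }
  verts <- sweep(verts, 2, center, "+")
  triangle_mesh(verts, do.call(rbind, faces), structure_class)
}
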