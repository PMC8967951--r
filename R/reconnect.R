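#' Connected components of one structure class
#'
#' @param labels a [label_volume()] or integer 3-D array.
#' @param class structure class, 1 (shaft) or 2 (spine).
#' @param connectivity 6 or 26.
#' @param geometry optional [voxel_geometry()] for physical sizes.
#' @return An object of class `component_set`: component id grid,
#'   per-component voxel lists (linear indices), sizes in voxels and
#'   um^3, and bounding boxes.
#' @export
find_components <- function(labels, class = 2L, connectivity = 26L,
                            geometry = NULL) {
  arr <- as_array3d(labels)
  if (is.null(geometry)) geometry <- vol_geometry(labels)
  d <- dim(arr)
  ids <- cpp_label_components(as.logical(arr == class), as.integer(d),
                              as.integer(connectivity))
  n <- attr(ids, "n_components")
  ids <- array(ids, dim = d)
  voxels <- if (n > 0) split(which(ids > 0L), ids[ids > 0L]) else list()
  sizes <- vapply(voxels, length, integer(1))
  vox_um3 <- prod(geometry$voxel_size)
  bbox <- lapply(voxels, function(v) {
    ijk <- arrayInd(v, d)
    rbind(lo = apply(ijk, 2, min), hi = apply(ijk, 2, max))
  })
  structure(list(ids = ids, class = as.integer(class),
                 connectivity = as.integer(connectivity), n = n,
                 voxels = voxels, sizes = sizes,
                 sizes_um3 = sizes * vox_um3, bbox = bbox,
                 geometry = geometry),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> class %d: %d component(s), sizes %s voxels\n",
              x$class, x$n, paste(sort(x$sizes, decreasing = TRUE),
                                  collapse = ", ")))
  invisible(x)
}

#' Clip volumes to a structure's padded bounding box
#'
#' Both volumes are clipped identically to the axis-aligned bounding box
#' of the structure, padded by `pad` voxels per axis and clamped to the
#' volume; the returned offset allows lossless re-embedding.
#'
#' @param labels a [label_volume()] or array.
#' @param intensity an [intensity_volume()] or array (same shape).
#' @param structure logical mask of the structure, or a class code.
#' @param pad integer length-3 padding in voxels.
#' @return list with `labels`, `intensity` (clipped arrays), `offset`
#'   (0-based corner of the clip) and `ranges` (per-axis index ranges).
#' @export
clip_bounding_box <- function(labels, intensity, structure, pad = c(0, 0, 0)) {
  arr <- as_array3d(labels)
  img <- as_array3d(intensity)
  if (length(structure) == 1) structure <- arr == structure
  if (!any(structure)) stop("empty structure: nothing to clip")
  d <- dim(arr)
  ijk <- arrayInd(which(structure), d)
  pad <- ceiling(as.numeric(pad))
  ranges <- lapply(1:3, function(a) {
    max(1L, min(ijk[, a]) - pad[a]):min(d[a], max(ijk[, a]) + pad[a])
  })
  list(labels = arr[ranges[[1]], ranges[[2]], ranges[[3]], drop = FALSE],
       intensity = img[ranges[[1]], ranges[[2]], ranges[[3]], drop = FALSE],
       offset = vapply(ranges, function(r) r[1] - 1L, integer(1)),
       ranges = ranges)
}

#' Min-max normalized density
#'
#' Rescales an intensity clip to `[0, 1]`; a constant clip maps to all
#' zeros.
#'
#' @param intensity an [intensity_volume()] or numeric array.
#' @return numeric array of the same shape with values in `[0, 1]`.
#' @export
normalized_density <- function(intensity) {
  x <- as_array3d(intensity)
  rng <- range(x)
  if (rng[2] == rng[1]) return(array(0, dim = dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Path cost for gap reconnection
#'
#' Evaluates `sum_i (1 - den(p_i)) * f_s + sum_{i>=2} dist(p_{i-1}, p_i)`
#' on an ordered voxel path, where `dist` is the center-to-center
#' distance in physical um (or voxel units, per
#' `config$distance_units`).
#'
#' @param path integer matrix (n x 3) of 1-based voxel indices;
#'   consecutive rows must be neighbors under `config$connectivity`.
#' @param den normalized density array (values in `[0, 1]`).
#' @param config the `reconnect` section of [default_config()].
#' @param geometry a [voxel_geometry()] (used in physical mode).
#' @return numeric scalar cost.
#' @export
path_cost <- function(path, den, config = default_config()$reconnect,
                      geometry = voxel_geometry()) {
  path <- rbind_index(path)
  d <- dim(den)
  if (any(path < 1) || any(sweep(path, 2, d, ">") != 0))
    stop("path voxel outside the volume")
  n <- nrow(path)
  if (n > 1) {
    steps <- abs(diff(path))
    if (any(steps > 1))
      stop("consecutive path voxels must be neighbors")
    if (config$connectivity == 6 && any(rowSums(steps) > 1))
      stop("consecutive path voxels must be 6-neighbors")
  }
  sp <- path_spacing(config, geometry)
  lin <- path[, 1] + d[1] * (path[, 2] - 1L) + d[1] * d[2] * (path[, 3] - 1L)
  density_term <- sum((1 - den[lin]) * config$f_s)
  length_term <- if (n > 1) {
    sum(sqrt(rowSums(sweep(diff(path), 2, sp, "*")^2)))
  } else 0
  density_term + length_term
}

path_spacing <- function(config, geometry) {
  if (identical(config$distance_units, "voxel")) c(1, 1, 1)
  else geometry$voxel_size
}

#' A* connection path between components
#'
#' Finds the cost-optimal path (under the reconnection objective) from
#' any voxel of `source` to any voxel of `target`, never entering
#' `forbidden` voxels (other anatomical structures). The heuristic is
#' the Euclidean distance to the target set, a lower bound on the
#' remaining cost because every density term is non-negative, so the
#' search is admissible and returns the same cost as an uninformed
#' Dijkstra search.
#'
#' @param den normalized density array in `[0, 1]`.
#' @param source,target logical arrays (non-empty, disjoint).
#' @param forbidden logical array or `NULL`.
#' @param config the `reconnect` section of [default_config()].
#' @param geometry a [voxel_geometry()].
#' @return list with `path` (n x 3 matrix of 1-based indices) and
#'   `cost`; raises a `spineflow_no_path` error when no admissible path
#'   exists.
#' @export
astar_connect <- function(den, source, target, forbidden = NULL,
                          config = default_config()$reconnect,
                          geometry = voxel_geometry()) {
  d <- dim(den)
  if (is.null(forbidden)) forbidden <- array(FALSE, dim = d)
  if (!any(source & !forbidden)) stop("source is empty or fully forbidden")
  if (!any(target)) stop("no target component")
  sp <- path_spacing(config, geometry)
  h <- cpp_edt(as.logical(target), as.integer(d), as.numeric(sp))
  res <- cpp_astar(as.numeric(den), as.integer(d), as.logical(source),
                   as.logical(target), as.logical(forbidden),
                   as.numeric(config$f_s), as.numeric(sp),
                   as.integer(config$connectivity), as.numeric(h))
  if (!isTRUE(res$found)) {
    stop(errorCondition("no admissible path between the components",
                        class = c("spineflow_no_path", "error", "condition")))
  }
  list(path = arrayInd(res$path, d), cost = res$cost)
}

#' Median denoising
#'
#' Box median filter; even window sizes are anchored with the extra
#' extent toward the +axis, and borders are handled by reflection.
#'
#' @param intensity an [intensity_volume()] or numeric array.
#' @param mask integer length-3 window in voxels (default 8 x 8 x 2).
#' @return same type as the input.
#' @export
median_denoise <- function(intensity, mask = c(8L, 8L, 2L)) {
  x <- as_array3d(intensity)
  if (any(mask < 1)) stop("median mask must be positive")
  out <- cpp_median_filter(as.numeric(x), as.integer(dim(x)),
                           as.integer(mask))
  out <- array(out, dim = dim(x))
  if (inherits(intensity, "intensity_volume"))
    intensity_volume(out, intensity$geometry) else out
}

# integer offsets inside the axis-aligned ellipsoid with semi-axes
# `semi` (voxels); zero semi-axes mean no extent on that axis
ellipsoid_offsets <- function(semi) {
  r <- floor(semi)
  grid <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  term <- function(dv, s) if (s > 0) (dv / s)^2 else ifelse(dv == 0, 0, Inf)
  keep <- term(grid$dx, semi[1]) + term(grid$dy, semi[2]) +
    term(grid$dz, semi[3]) <= 1
  as.matrix(grid[keep, , drop = FALSE])
}

# paste ellipsoid neighborhoods centered on every path voxel into a mask
stamp_ellipsoids <- function(path, semi, dims) {
  off <- ellipsoid_offsets(semi)
  out <- array(FALSE, dim = dims)
  for (r in seq_len(nrow(off))) {
    p <- sweep(path, 2, as.numeric(off[r, ]), "+")
    ok <- p[, 1] >= 1 & p[, 1] <= dims[1] & p[, 2] >= 1 & p[, 2] <= dims[2] &
      p[, 3] >= 1 & p[, 3] <= dims[3]
    if (any(ok)) {
      q <- p[ok, , drop = FALSE]
      out[q[, 1] + dims[1] * (q[, 2] - 1L) +
            dims[1] * dims[2] * (q[, 3] - 1L)] <- TRUE
    }
  }
  out
}

#' Tolerance flood fill around a connection path
#'
#' Every voxel inside the minimum ellipsoid centered on a path voxel is
#' labeled unconditionally. Additionally, a flood fill grows from each
#' path voxel (seed) over voxels whose filtered intensity lies within
#' `plus/minus tolerance` of that seed's own intensity, constrained to
#' the union of maximum ellipsoids centered on the path. Voxels of a
#' different structure class are never claimed.
#'
#' @param path integer matrix (n x 3) of 1-based voxel indices.
#' @param filtered median-filtered intensity array.
#' @param labels label array (same shape).
#' @param target_class class being grown (1 or 2).
#' @param config the `reconnect` section of [default_config()];
#'   `max_ellipsoid` selects the class-appropriate maximum mask when
#'   `NULL`.
#' @param max_ellipsoid optional length-3 semi-axes overriding the
#'   config choice.
#' @return logical array of voxels to relabel to `target_class`.
#' @export
flood_from_path <- function(path, filtered, labels, target_class,
                            config = default_config()$reconnect,
                            max_ellipsoid = NULL) {
  path <- rbind_index(path)
  img <- as_array3d(filtered)
  arr <- as_array3d(labels)
  d <- dim(img)
  if (is.null(max_ellipsoid)) {
    max_ellipsoid <- if (target_class == 1L) config$max_ellipsoid_shaft
                     else config$max_ellipsoid_spine
  }
  other <- arr > 0L & arr != target_class
  min_region <- stamp_ellipsoids(path, config$min_ellipsoid, d)
  allowed <- stamp_ellipsoids(path, max_ellipsoid, d)
  grow <- min_region & !other
  lin <- path[, 1] + d[1] * (path[, 2] - 1L) + d[1] * d[2] * (path[, 3] - 1L)
  seed_int <- img[lin]
  tol <- config$tolerance
  for (i in seq_len(nrow(path))) {
    band <- allowed & !other &
      abs(img - seed_int[i]) <= tol * abs(seed_int[i])
    if (!band[lin[i]]) next
    comp <- cpp_label_components(as.logical(band), as.integer(d),
                                 as.integer(config$connectivity))
    grow <- grow | (array(comp, d) == comp[lin[i]])
  }
  grow
}

#' Reconnect the detached parts of one structure
#'
#' Iterates over the structure's connected components largest-first
#' (the largest acting as anchor): an A* path joins the component to the
#' rest of the structure, the clipped image is median-denoised, and a
#' tolerance flood fill around the path is relabeled to the structure's
#' class. Stops when a single component remains or no component can be
#' connected. Voxels are only ever added, never removed.
#'
#' @param labels a [label_volume()] or array.
#' @param intensity an [intensity_volume()] or array.
#' @param structure_class 1 (shaft) or 2 (spine).
#' @param config the `reconnect` section of [default_config()].
#' @param geometry a [voxel_geometry()]; taken from `labels` if absent.
#' @param scope optional logical mask restricting the structure to a
#'   subset of its class voxels (same-class voxels outside the scope are
#'   treated as other structures).
#' @param max_ellipsoid optional semi-axes override.
#' @return labels of the input type, with attribute `report` (a
#'   data.frame of per-connection records) and attribute `warnings`
#'   (components left unconnected).
#' @export
reconnect_structure <- function(labels, intensity, structure_class,
                                config = default_config()$reconnect,
                                geometry = NULL, scope = NULL,
                                max_ellipsoid = NULL) {
  arr <- as_array3d(labels)
  img <- as_array3d(intensity)
  if (is.null(geometry)) geometry <- vol_geometry(labels)
  if (is.null(max_ellipsoid)) {
    max_ellipsoid <- if (structure_class == 1L) config$max_ellipsoid_shaft
                     else config$max_ellipsoid_spine
  }
  pad <- ceiling(max_ellipsoid) + 1
  report <- list()
  skipped <- integer(0)
  prev_n <- Inf
  repeat {
    struct_mask <- arr == structure_class
    if (!is.null(scope)) struct_mask <- struct_mask & scope
    if (!any(struct_mask)) break
    comps <- find_components(struct_mask * structure_class, structure_class,
                             config$connectivity, geometry)
    if (comps$n <= 1) break
    if (comps$n >= prev_n) {
      warning("reconnection made no progress; structure left partially connected")
      break
    }
    prev_n <- comps$n
    ord <- order(comps$sizes, decreasing = TRUE)
    progress <- FALSE
    for (ci in ord[-1]) {
      if (ci %in% skipped) next
      clip <- clip_bounding_box(arr, img, struct_mask, pad)
      sub <- function(a) a[clip$ranges[[1]], clip$ranges[[2]],
                           clip$ranges[[3]], drop = FALSE]
      ids_clip <- sub(comps$ids)
      source <- ids_clip == ci
      target <- ids_clip > 0L & ids_clip != ci
      forbidden <- clip$labels > 0L & clip$labels != structure_class
      if (!is.null(scope))
        forbidden <- forbidden |
          (clip$labels == structure_class & !sub(scope))
      den <- normalized_density(clip$intensity)
      res <- tryCatch(
        astar_connect(den, source, target, forbidden, config, geometry),
        spineflow_no_path = function(e) NULL)
      if (is.null(res)) {
        warning(sprintf(
          "structure class %d: component of %d voxels could not be connected",
          structure_class, comps$sizes[ci]))
        skipped <- c(skipped, ci)
        next
      }
      filtered <- median_denoise(clip$intensity, config$median_mask)
      grow <- flood_from_path(res$path, filtered, clip$labels,
                              structure_class, config, max_ellipsoid)
      added <- grow & clip$labels != structure_class
      patch <- clip$labels
      patch[grow] <- structure_class
      arr[clip$ranges[[1]], clip$ranges[[2]], clip$ranges[[3]]] <- patch
      if (!is.null(scope)) {
        sc <- sub(scope) | grow
        scope[clip$ranges[[1]], clip$ranges[[2]], clip$ranges[[3]]] <- sc
      }
      report[[length(report) + 1]] <- data.frame(
        class = structure_class, component_voxels = comps$sizes[ci],
        path_length = nrow(res$path), path_cost = res$cost,
        voxels_added = sum(added))
      skipped <- integer(0)  # component ids change after a merge
      progress <- TRUE
      break
    }
    if (!progress) break
  }
  out <- if (inherits(labels, "label_volume")) {
    label_volume(arr, geometry)
  } else arr
  attr(out, "report") <- if (length(report)) do.call(rbind, report) else
    data.frame(class = integer(0), component_voxels = integer(0),
               path_length = integer(0), path_cost = numeric(0),
               voxels_added = integer(0))
  attr(out, "unconnected") <- length(skipped)
  out
}

#' Automatic ground-truth preprocessing
#'
#' Repairs weakly annotated label volumes in three passes: (i) the
#' dendritic shaft's detached parts are reconnected (maximum ellipsoid
#' 3 x 3 x 2 voxels); (ii) when per-spine instance provenance is
#' available, each spine's own fragments are reconnected independently
#' (maximum ellipsoid 6 x 6 x 2); (iii) every spine component not
#' adjacent to the shaft is connected to it, shaft voxels (and already
#' attached spine voxels) acting as A* targets, with connector voxels
#' taking the spine class. Running the procedure on an already connected
#' volume returns it unchanged, and running it twice equals running it
#' once.
#'
#' @param labels a [label_volume()] or array.
#' @param intensity an [intensity_volume()] or array.
#' @param config a full [default_config()] list (its `reconnect` section
#'   is used).
#' @param geometry a [voxel_geometry()]; taken from `labels` if absent.
#' @param instances optional [instance_volume()] carrying per-spine
#'   identity for pass (ii).
#' @return labels of the input type with attribute `report` binding all
#'   per-connection records.
#' @export
preprocess_ground_truth <- function(labels, intensity,
                                    config = default_config(),
                                    geometry = NULL, instances = NULL) {
  rc <- config$reconnect
  if (is.null(geometry)) geometry <- vol_geometry(labels)
  reports <- list()
  grab <- function(x) {
    reports[[length(reports) + 1]] <<- attr(x, "report")
    x
  }

  # (i) shaft
  out <- grab(reconnect_structure(labels, intensity, 1L, rc, geometry,
                                  max_ellipsoid = rc$max_ellipsoid_shaft))
  arr <- as_array3d(out)

  # (ii) per-spine fragments, when instance provenance is known
  if (!is.null(instances)) {
    ids <- as_array3d(instances)
    spine_ids <- names(instances$class_of)[instances$class_of == 2L]
    for (sid in spine_ids) {
      scope <- ids == as.integer(sid)
      if (!any(scope & arr == 2L)) next
      arr <- as_array3d(grab(reconnect_structure(
        arr, intensity, 2L, rc, geometry, scope = scope,
        max_ellipsoid = rc$max_ellipsoid_spine)))
    }
  }

  # (iii) attach unconnected spine components to the shaft
  d <- dim(arr)
  img <- as_array3d(intensity)
  prev_loose <- Inf
  repeat {
    shaft <- arr == 1L
    if (!any(shaft) || !any(arr == 2L)) break
    comps <- find_components(arr, 2L, rc$connectivity, geometry)
    touch <- cpp_adjacent_mask(as.logical(comps$ids > 0L), as.logical(shaft),
                               as.integer(d), as.integer(rc$connectivity))
    attached <- unique(comps$ids[array(touch, d)])
    loose <- setdiff(seq_len(comps$n), attached)
    if (length(loose) == 0) break
    if (length(loose) >= prev_loose) {
      warning("spine attachment made no progress; left partially connected")
      break
    }
    prev_loose <- length(loose)
    loose <- loose[order(comps$sizes[loose], decreasing = TRUE)]
    progress <- FALSE
    for (ci in loose) {
      struct_mask <- comps$ids == ci | shaft
      clip <- clip_bounding_box(arr, img, struct_mask,
                                ceiling(rc$max_ellipsoid_spine) + 1)
      ids_clip <- comps$ids[clip$ranges[[1]], clip$ranges[[2]],
                            clip$ranges[[3]], drop = FALSE]
      source <- ids_clip == ci
      target <- clip$labels == 1L |
        (ids_clip > 0L & array(ids_clip %in% attached, dim(ids_clip)))
      forbidden <- ids_clip > 0L & ids_clip != ci &
        !array(ids_clip %in% attached, dim(ids_clip))
      den <- normalized_density(clip$intensity)
      res <- tryCatch(
        astar_connect(den, source, target, forbidden, rc, geometry),
        spineflow_no_path = function(e) NULL)
      if (is.null(res)) {
        warning(sprintf(
          "spine component of %d voxels could not be attached to the shaft",
          comps$sizes[ci]))
        next
      }
      filtered <- median_denoise(clip$intensity, rc$median_mask)
      grow <- flood_from_path(res$path, filtered, clip$labels, 2L, rc,
                              rc$max_ellipsoid_spine)
      added <- grow & clip$labels == 0L
      patch <- clip$labels
      patch[grow & clip$labels != 1L] <- 2L
      arr[clip$ranges[[1]], clip$ranges[[2]], clip$ranges[[3]]] <- patch
      reports[[length(reports) + 1]] <- data.frame(
        class = 2L, component_voxels = comps$sizes[ci],
        path_length = nrow(res$path), path_cost = res$cost,
        voxels_added = sum(added))
      progress <- TRUE
      break
    }
    if (!progress) break
  }

  out <- if (inherits(labels, "label_volume")) label_volume(arr, geometry)
         else arr
  reports <- Filter(function(r) !is.null(r) && nrow(r) > 0, reports)
  attr(out, "report") <- if (length(reports)) do.call(rbind, reports) else
    data.frame(class = integer(0), component_voxels = integer(0),
               path_length = integer(0), path_cost = numeric(0),
               voxels_added = integer(0))
  out
}
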