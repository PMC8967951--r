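#' Remove disconnected noise components
#'
#' Deletes a connected component `s` (of the classes in
#' `cfg$apply_to`) when BOTH conditions hold: the distance from `s` to
#' the nearest dendritic-shaft component larger than `V_d` exceeds `D`,
#' AND the volume of `s` is smaller than `V_s`. Distances are minimal
#' voxel-center distances in um; volumes in um^3. When no shaft
#' component exceeds `V_d`, every candidate is treated as "far".
#'
#' @param labels a [label_volume()] or array.
#' @param cfg the `postprocess` section of [default_config()]
#'   (`D`, `V_d`, `V_s`, `apply_to`).
#' @param geometry a [voxel_geometry()].
#' @param connectivity 6 or 26.
#' @return labels of the input type with attribute `removed`, a
#'   data.frame describing each deleted component.
#' @export
remove_noise <- function(labels, cfg = default_config()$postprocess,
                         geometry = NULL, connectivity = 26L) {
  arr <- as_array3d(labels)
  if (is.null(geometry)) geometry <- vol_geometry(labels)
  d <- dim(arr)
  shaft_comps <- find_components(arr, 1L, connectivity, geometry)
  anchors <- which(shaft_comps$sizes_um3 > cfg$V_d)
  anchor_mask <- array(shaft_comps$ids %in% anchors & shaft_comps$ids > 0L,
                       dim = d)
  dist_to_anchor <- if (any(anchor_mask)) {
    array(cpp_edt(as.logical(anchor_mask), as.integer(d),
                  as.numeric(geometry$voxel_size)), dim = d)
  } else {
    array(Inf, dim = d)  # no big shaft: every component is far
  }
  classes <- c(shaft = 1L, spine = 2L)[cfg$apply_to]
  removed <- list()
  for (k in classes) {
    comps <- find_components(arr, k, connectivity, geometry)
    for (ci in seq_len(comps$n)) {
      if (k == 1L && ci %in% anchors) next
      vol_um3 <- comps$sizes_um3[ci]
      dist <- min(dist_to_anchor[comps$voxels[[ci]]])
      if (dist > cfg$D && vol_um3 < cfg$V_s) {
        arr[comps$voxels[[ci]]] <- 0L
        removed[[length(removed) + 1]] <- data.frame(
          class = k, voxels = comps$sizes[ci], volume_um3 = vol_um3,
          distance_um = dist)
      }
    }
  }
  out <- if (inherits(labels, "label_volume")) label_volume(arr, geometry)
         else arr
  attr(out, "removed") <- if (length(removed)) do.call(rbind, removed) else
    data.frame(class = integer(0), voxels = integer(0),
               volume_um3 = numeric(0), distance_um = numeric(0))
  out
}

#' Relabel a voxel selection
#'
#' Changes exactly the selected voxels to `new_code`.
#'
#' @param labels a [label_volume()] or array.
#' @param voxels integer matrix (n x 3) of 1-based voxel indices, or a
#'   vector of linear indices.
#' @param new_code target class code in `{0, 1, 2}`.
#' @return labels of the input type.
#' @export
relabel_selection <- function(labels, voxels, new_code) {
  arr <- as_array3d(labels)
  d <- dim(arr)
  if (!new_code %in% 0:2) stop("new_code must be in {0, 1, 2}")
  if (!is.null(dim(voxels)) || length(voxels) == 3) {
    voxels <- rbind_index(voxels)
    if (any(voxels < 1) || any(sweep(voxels, 2, d, ">") != 0))
      stop("selection outside the volume")
    lin <- voxels[, 1] + d[1] * (voxels[, 2] - 1L) +
      d[1] * d[2] * (voxels[, 3] - 1L)
  } else {
    lin <- as.integer(voxels)
    if (length(lin) > 0 && (min(lin) < 1 || max(lin) > length(arr)))
      stop("selection outside the volume")
  }
  arr[lin] <- as.integer(new_code)
  if (inherits(labels, "label_volume")) label_volume(arr, labels$geometry)
  else arr
}

#' Extract structure instances from a label volume
#'
#' Connected components of the spine class become spine instances and
#' shaft components shaft instances, each with its own id in a separate
#' grid.
#'
#' @param labels a [label_volume()] or array.
#' @param connectivity 6 or 26.
#' @return An [instance_volume()].
#' @export
extract_instances <- function(labels, connectivity = 26L) {
  arr <- as_array3d(labels)
  geometry <- vol_geometry(labels)
  d <- dim(arr)
  ids <- array(0L, dim = d)
  class_of <- integer(0)
  nid <- 0L
  for (k in c(1L, 2L)) {
    comp <- find_components(arr, k, connectivity, geometry)
    for (ci in seq_len(comp$n)) {
      nid <- nid + 1L
      ids[comp$voxels[[ci]]] <- nid
      class_of[as.character(nid)] <- k
    }
  }
  instance_volume(ids, class_of, geometry)
}

#' Supervised reconnection of a chosen component pair
#'
#' One iteration of the automatic reconnection restricted to a
#' user-selected source/target pair, with user overrides of the
#' ellipsoid masks, median mask, and flood tolerance.
#'
#' @param labels a [label_volume()] or array.
#' @param intensity an [intensity_volume()] or array.
#' @param class structure class of the components (1 or 2).
#' @param source_id,target_id component ids as numbered by
#'   [find_components()] for that class (target may also be `"shaft"`
#'   to attach a spine component to the dendritic shaft).
#' @param config the `reconnect` section of [default_config()];
#'   overrides may be supplied via `...` (e.g. `tolerance = 0.2`).
#' @param geometry a [voxel_geometry()].
#' @param ... named overrides of `config` fields.
#' @return labels of the input type with attribute `report`.
#' @export
connect_components_supervised <- function(labels, intensity, class,
                                          source_id, target_id,
                                          config = default_config()$reconnect,
                                          geometry = NULL, ...) {
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(config)) stop("unknown reconnect option '", nm, "'")
    config[[nm]] <- overrides[[nm]]
  }
  arr <- as_array3d(labels)
  img <- as_array3d(intensity)
  if (is.null(geometry)) geometry <- vol_geometry(labels)
  if (identical(source_id, target_id))
    stop("source and target components are identical")
  comps <- find_components(arr, class, config$connectivity, geometry)
  if (source_id > comps$n) stop("source component id out of range")
  max_ell <- if (class == 1L) config$max_ellipsoid_shaft
             else config$max_ellipsoid_spine
  source_mask <- comps$ids == source_id
  target_mask <- if (identical(target_id, "shaft")) arr == 1L
                 else comps$ids == target_id
  if (!any(target_mask)) stop("target component is empty")
  clip <- clip_bounding_box(arr, img, source_mask | target_mask,
                            ceiling(max_ell) + 1)
  sub <- function(a) a[clip$ranges[[1]], clip$ranges[[2]], clip$ranges[[3]],
                       drop = FALSE]
  forbidden <- clip$labels > 0L & !sub(source_mask) & !sub(target_mask) &
    clip$labels != class
  den <- normalized_density(clip$intensity)
  res <- astar_connect(den, sub(source_mask), sub(target_mask), forbidden,
                       config, geometry)
  filtered <- median_denoise(clip$intensity, config$median_mask)
  grow <- flood_from_path(res$path, filtered, clip$labels, class, config,
                          max_ell)
  patch <- clip$labels
  patch[grow] <- class
  arr[clip$ranges[[1]], clip$ranges[[2]], clip$ranges[[3]]] <- patch
  out <- if (inherits(labels, "label_volume")) label_volume(arr, geometry)
         else arr
  attr(out, "report") <- data.frame(path_length = nrow(res$path),
                                    path_cost = res$cost,
                                    voxels_added = sum(grow & clip$labels != class))
  out
}

#' Marker-based watershed split of one instance
#'
#' Splits a connected instance into one instance per seed by flooding a
#' relief from the seeds. The default relief is the negated Euclidean
#' distance transform of the instance mask (geometry-aware), which
#' splits at neck constrictions; `relief = "intensity"` floods the
#' negated image instead. The union of the outputs equals the input
#' mask exactly and each output contains its seed.
#'
#' @param mask logical 3-D array (one instance), or an
#'   [instance_volume()] plus `id`.
#' @param seeds integer matrix (n x 3) of 1-based seed voxels.
#' @param geometry a [voxel_geometry()].
#' @param relief `"distance"` (default) or `"intensity"`.
#' @param intensity required when `relief = "intensity"`.
#' @param id instance id when `mask` is an [instance_volume()].
#' @param connectivity 6 or 26.
#' @return An [instance_volume()] with one instance per seed.
#' @export
watershed_split <- function(mask, seeds, geometry = NULL,
                            relief = c("distance", "intensity"),
                            intensity = NULL, id = NULL,
                            connectivity = 26L) {
  relief <- match.arg(relief)
  cls <- 2L
  if (inherits(mask, "instance_volume")) {
    if (is.null(id)) stop("an instance id is required")
    cls <- mask$class_of[[as.character(id)]]
    if (is.null(geometry)) geometry <- mask$geometry
    mask <- mask$ids == id
  }
  if (is.null(geometry)) geometry <- voxel_geometry()
  d <- dim(mask)
  seeds <- rbind_index(seeds)
  lin <- seeds[, 1] + d[1] * (seeds[, 2] - 1L) + d[1] * d[2] * (seeds[, 3] - 1L)
  if (any(!mask[lin])) stop("all seeds must lie inside the instance mask")
  rel <- if (relief == "distance") {
    edt_in <- cpp_edt(as.logical(!mask), as.integer(d),
                      as.numeric(geometry$voxel_size))
    -array(edt_in, dim = d)
  } else {
    if (is.null(intensity)) stop("intensity relief requires the image")
    -as_array3d(intensity)
  }
  markers <- array(0L, dim = d)
  markers[lin] <- seq_len(nrow(seeds))
  out <- cpp_marker_watershed(as.numeric(rel), as.integer(d),
                              as.integer(markers), as.logical(mask),
                              as.integer(connectivity))
  instance_volume(array(out, dim = d),
                  stats::setNames(rep(cls, nrow(seeds)),
                                  as.character(seq_len(nrow(seeds)))),
                  geometry)
}

#' Extract boundary surfaces from an instance volume
#'
#' Per-instance iso-surface of the binary mask at level 0.5, with
#' vertices in um (anisotropic voxel size applied) and consistent
#' outward orientation. Instances are padded by one background voxel
#' so instances away from the volume border yield watertight meshes.
#'
#' @param instances an [instance_volume()], or a [label_volume()]
#'   (instances extracted at 26-connectivity first).
#' @param geometry a [voxel_geometry()].
#' @return named list of [triangle_mesh()] objects, one per non-empty
#'   instance id.
#' @export
mesh_from_labels <- function(instances, geometry = NULL) {
  if (inherits(instances, "label_volume"))
    instances <- extract_instances(instances)
  if (is.null(geometry)) geometry <- instances$geometry
  ids <- instances$ids
  d <- dim(ids)
  out <- list()
  for (id in setdiff(sort(unique(as.vector(ids))), 0L)) {
    mask <- array(0, dim = d + 2L)
    mask[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (ids == id) * 1
    surf <- cpp_isosurface(as.numeric(mask), as.integer(dim(mask)), 0.5,
                           as.numeric(geometry$voxel_size),
                           as.numeric(geometry$origin - geometry$voxel_size))
    if (nrow(surf$faces) == 0) next
    out[[as.character(id)]] <- triangle_mesh(
      surf$vertices, surf$faces,
      structure_class = instances$class_of[[as.character(id)]],
      check = FALSE)
  }
  out
}

#' Count unconnected predicted spine parts
#'
#' Among the predicted spine components that share at least one voxel
#' with ground-truth spine voxels, counts those with no voxel adjacent
#' to a predicted shaft voxel. Calling it with `pred = gt` measures the
#' ground truth's own unconnected spine parts.
#'
#' @param pred predicted [label_volume()] or array.
#' @param gt ground-truth [label_volume()] or array.
#' @param connectivity adjacency used both for components and for the
#'   spine-shaft contact test (default 26).
#' @return list with `unconnected`, `considered` (components matching
#'   GT), and `total` (all predicted spine components).
#' @export
count_unconnected_spine_parts <- function(pred, gt, connectivity = 26L) {
  p <- as_array3d(pred)
  g <- as_array3d(gt)
  if (!identical(dim(p), dim(g))) stop("shape mismatch")
  d <- dim(p)
  comps <- find_components(p, 2L, connectivity)
  if (comps$n == 0)
    return(list(unconnected = 0L, considered = 0L, total = 0L))
  touch <- cpp_adjacent_mask(as.logical(comps$ids > 0L), as.logical(p == 1L),
                             as.integer(d), as.integer(connectivity))
  touch <- array(touch, dim = d)
  gt_spine <- g == 2L
  unconnected <- 0L
  considered <- 0L
  for (ci in seq_len(comps$n)) {
    vox <- comps$voxels[[ci]]
    if (!any(gt_spine[vox])) next
    considered <- considered + 1L
    if (!any(touch[vox])) unconnected <- unconnected + 1L
  }
  list(unconnected = unconnected, considered = considered, total = comps$n)
}

#' Improvement ratio between two unconnected-part counts
#'
#' `100 * (before - after) / before`, reported to two decimals.
#'
#' @param before count before the intervention (> 0).
#' @param after count after.
#' @return numeric percentage (2 decimals).
#' @export
improvement_ratio <- function(before, after) {
  if (before <= 0) stop("'before' must be positive")
  round(100 * (before - after) / before, 2)
}
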