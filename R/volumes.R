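#' Intensity volume
#'
#' A 3-D grid of raw fluorescence values (16-bit range semantics) plus
#' its voxel geometry. Arrays are stored with dim `c(nx, ny, nz)`; the
#' first index is x, matching the (x, y, z) convention of all APIs.
#'
#' @param values numeric 3-D array of non-negative, finite intensities.
#' @param geometry a [voxel_geometry()].
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(values, geometry = voxel_geometry()) {
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  if (any(dim(values) < 1)) stop("all axes must have positive extent")
  if (!all(is.finite(values))) stop("intensity values must be finite")
  if (min(values) < 0) stop("intensity values must be non-negative")
  storage.mode(values) <- "double"
  structure(list(values = values, geometry = geometry),
            class = "intensity_volume")
}

#' Label volume
#'
#' A 3-D grid of class codes over the same domain as an intensity
#' volume: background = 0, dendritic shaft = 1, spine = 2.
#'
#' @param labels integer 3-D array with codes in `{0, 1, 2}`.
#' @param geometry a [voxel_geometry()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, geometry = voxel_geometry()) {
  if (length(dim(labels)) != 3) stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  bad <- which(!(labels %in% c(0L, 1L, 2L)))
  if (length(bad) > 0) {
    ijk <- arrayInd(bad[1], dim(labels))
    stop(sprintf(
      "label codes must be in {0, 1, 2}; first offending voxel (%d, %d, %d) has code %d",
      ijk[1], ijk[2], ijk[3], labels[bad[1]]))
  }
  structure(list(labels = labels, geometry = geometry),
            class = "label_volume")
}

#' Instance volume
#'
#' Per-voxel instance identifiers (0 = none) with a map from instance id
#' to structure class (1 = shaft, 2 = spine). Instance ids live in a
#' separate grid so the three-class label codes stay untouched.
#'
#' @param ids integer 3-D array of instance ids (0 = none).
#' @param class_of named integer vector mapping id (as name) to class.
#' @param geometry a [voxel_geometry()].
#' @return An object of class `instance_volume`.
#' @export
instance_volume <- function(ids, class_of, geometry = voxel_geometry()) {
  if (length(dim(ids)) != 3) stop("ids must be a 3-D array")
  storage.mode(ids) <- "integer"
  if (min(ids) < 0) stop("instance ids must be non-negative")
  class_of <- stats::setNames(as.integer(class_of), names(class_of))
  present <- setdiff(sort(unique(as.vector(ids))), 0L)
  if (is.null(names(class_of))) names(class_of) <- as.character(present)
  if (!all(as.character(present) %in% names(class_of)))
    stop("class_of must cover every instance id present")
  if (!all(class_of %in% c(1L, 2L)))
    stop("instance classes must be 1 (shaft) or 2 (spine)")
  structure(list(ids = ids, class_of = class_of, geometry = geometry),
            class = "instance_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<intensity_volume> %d x %d x %d, range [%g, %g]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d | background %d, shaft %d, spine %d\n",
              d[1], d[2], d[3], sum(x$labels == 0L), sum(x$labels == 1L),
              sum(x$labels == 2L)))
  invisible(x)
}

#' @export
print.instance_volume <- function(x, ...) {
  d <- dim(x$ids)
  cat(sprintf("<instance_volume> %d x %d x %d, %d instances\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(x$ids)), 0L))))
  invisible(x)
}

# internal: pull the bare array out of a volume object or pass through
as_array3d <- function(x) {
  if (inherits(x, "intensity_volume")) return(x$values)
  if (inherits(x, "label_volume")) return(x$labels)
  if (inherits(x, "instance_volume")) return(x$ids)
  if (length(dim(x)) != 3) stop("expected a 3-D array or volume object")
  x
}

vol_geometry <- function(x, default = voxel_geometry()) {
  if (is.list(x) && !is.null(x$geometry)) x$geometry else default
}
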