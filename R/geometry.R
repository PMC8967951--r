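#' Voxel geometry
#'
#' Describes how a voxel grid is embedded in physical space. The voxel
#' with R index `(i, j, k)` (1-based) occupies the half-open box
#' `origin + [i-1, i) * voxel_size` per axis and has its center at
#' `origin + (i - 0.5) * voxel_size`. All lengths are in micrometers.
#'
#' @param voxel_size numeric length-3, voxel edge lengths (x, y, z) in um.
#'   The default is the confocal acquisition spacing used throughout the
#'   package examples.
#' @param origin numeric length-3, position of the grid corner in um.
#' @return An object of class `voxel_geometry`.
#' @export
voxel_geometry <- function(voxel_size = c(0.0751562, 0.0751562, 0.279911),
                           origin = c(0, 0, 0)) {
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  stopifnot(length(voxel_size) == 3, length(origin) == 3,
            all(is.finite(voxel_size)), all(is.finite(origin)))
  if (any(voxel_size <= 0)) stop("voxel_size must be positive on all axes")
  structure(list(voxel_size = voxel_size, origin = origin),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> size %g x %g x %g um, origin (%g, %g, %g)\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel index to physical coordinates
#'
#' @param geometry a [voxel_geometry()].
#' @param ijk integer matrix (n x 3) of 1-based voxel indices (x, y, z).
#' @return numeric matrix (n x 3) of voxel-center coordinates in um.
#' @export
voxel_center <- function(geometry, ijk) {
  ijk <- rbind_index(ijk)
  sweep(sweep(ijk - 0.5, 2, geometry$voxel_size, "*"), 2, geometry$origin, "+")
}

#' Physical coordinates to voxel index
#'
#' Inverse of [voxel_center()] under the half-open box convention.
#'
#' @param geometry a [voxel_geometry()].
#' @param pts numeric matrix (n x 3) of points in um.
#' @return integer matrix (n x 3) of 1-based voxel indices.
#' @export
point_to_voxel <- function(geometry, pts) {
  pts <- rbind_index(pts)
  idx <- sweep(sweep(pts, 2, geometry$origin, "-"), 2, geometry$voxel_size, "/")
  storage.mode(idx) <- "double"
  matrix(as.integer(floor(idx)) + 1L, ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

# accept a length-3 vector or an n x 3 matrix
rbind_index <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    x <- matrix(as.numeric(x), ncol = 3)
  }
  x
}
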