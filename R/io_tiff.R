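#' Read a multi-page grayscale TIFF as an intensity volume
#'
#' Page order maps to increasing z. Values are read without rescaling
#' (16-bit integers stay 16-bit integers) and widened to double.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param geometry a [voxel_geometry()] to attach (TIFF carries no
#'   trustworthy voxel-size metadata in this pipeline; the geometry must
#'   travel through the run configuration).
#' @return An [intensity_volume()].
#' @export
read_intensity_stack <- function(path, geometry = voxel_geometry()) {
  vol <- read_stack_array(path)
  intensity_volume(vol, geometry)
}

#' Write an intensity volume as a 16-bit multi-page TIFF
#'
#' @param volume an [intensity_volume()]; values must fit in `[0, 65535]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity_stack <- function(volume, path) {
  v <- as_array3d(volume)
  if (max(v) > 65535) stop("intensity values exceed the 16-bit range")
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF of class codes as a label volume
#'
#' @param path path to an integer-valued TIFF with codes in `{0, 1, 2}`.
#' @param geometry a [voxel_geometry()].
#' @return A [label_volume()]. Out-of-range codes raise a validation
#'   error naming the first offending voxel index.
#' @export
read_label_stack <- function(path, geometry = voxel_geometry()) {
  vol <- read_stack_array(path)
  label_volume(vol, geometry)
}

#' Write a label volume as an 8-bit multi-page TIFF
#'
#' @param volume a [label_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_stack <- function(volume, path) {
  v <- as_array3d(volume)
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

# shared page reader: list of (y, x) matrices -> (x, y, z) array
read_stack_array <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  if (length(d1) == 3 && d1[3] > 1)
    stop("unsupported format: multi-channel/RGB TIFF; a single grayscale channel is required")
  if (length(d1) == 3) pages <- lapply(pages, function(p) p[, , 1])
  nz <- length(pages)
  vol <- array(0, dim = c(d1[2], d1[1], nz))
  for (k in seq_len(nz)) vol[, , k] <- t(pages[[k]])
  vol
}
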