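#' Smoothed class weights
#'
#' For each class k with `#k` voxels out of `#Omega` total:
#' `w'_k = max(log(2 * #Omega / #k), 1)` (natural log), normalized to
#' `w_k = w'_k / sum(w')`. An absent class takes the single-voxel limit
#' `w'_k = log(2 * #Omega)`, keeping weights finite so patches without
#' spines still train.
#'
#' @param labels a [label_volume()], integer array, or a length-3
#'   count vector (background, shaft, spine).
#' @return numeric length-3 normalized weights (summing to 1) with
#'   attribute `w_prime` (the unnormalized values).
#' @export
class_weights_smoothed <- function(labels) {
  counts <- label_counts(labels)
  n_omega <- sum(counts)
  if (n_omega < 1) stop("at least one voxel is required")
  w_prime <- vapply(counts, function(nk) {
    if (nk == 0) log(2 * n_omega) else max(log(2 * n_omega / nk), 1)
  }, numeric(1))
  w <- w_prime / sum(w_prime)
  attr(w, "w_prime") <- w_prime
  w
}

#' Generalized-Dice class weights
#'
#' `w_k = 1 / (sum_x r_k(x))^2` from the one-hot ground truth. An
#' absent class receives weight 0, which removes it from both Dice sums
#' (the usual epsilon-guard policy).
#'
#' @param labels a [label_volume()], integer array, or count vector.
#' @return numeric length-3 weights (not normalized).
#' @export
class_weights_gdl <- function(labels) {
  counts <- label_counts(labels)
  ifelse(counts > 0, 1 / counts^2, 0)
}

label_counts <- function(labels) {
  if (is.numeric(labels) && is.null(dim(labels)) && length(labels) == 3)
    return(as.numeric(labels))
  arr <- as_array3d(labels)
  c(sum(arr == 0L), sum(arr == 1L), sum(arr == 2L))
}

#' Distance field to the labeled structures
#'
#' Exact Euclidean distance transform in physical um (anisotropic voxel
#' size honored); zero on every shaft or spine voxel.
#'
#' @param labels a [label_volume()] or array.
#' @param geometry a [voxel_geometry()]; taken from `labels` if absent.
#' @return numeric 3-D array of distances in um.
#' @export
distance_field <- function(labels, geometry = NULL) {
  arr <- as_array3d(labels)
  if (is.null(geometry)) geometry <- vol_geometry(labels)
  if (!any(arr > 0L)) stop("at least one labeled voxel is required")
  array(cpp_edt(as.logical(arr > 0L), as.integer(dim(arr)),
                as.numeric(geometry$voxel_size)), dim = dim(arr))
}

#' Exponential pixel weight
#'
#' `w(x) = (1 - r_decay)^d(x)` with d in um: 1 on the structures,
#' decaying with distance.
#'
#' @param d distance field in um (array).
#' @param r_decay decay ratio in `[0, 1]`.
#' @return numeric array of weights.
#' @export
pixel_weight_exp <- function(d, r_decay = 0.5) {
  stopifnot(r_decay >= 0, r_decay <= 1)
  (1 - r_decay)^d
}

#' Window pixel weight
#'
#' `w(x) = (1 - (d/d_max)^2)^2` for `d < d_max`, 0 beyond: a compact
#' window that reaches exactly 0 (continuously) at the maximum
#' influence distance.
#'
#' @param d distance field in um (array).
#' @param d_max maximum influence distance in um.
#' @return numeric array of weights.
#' @export
pixel_weight_window <- function(d, d_max = 5) {
  stopifnot(d_max > 0)
  w <- (1 - (d / d_max)^2)^2
  w[d >= d_max] <- 0
  w
}

# one-hot view r_k of a label array -> 4-D array (x, y, z, class)
one_hot_labels <- function(labels) {
  arr <- as_array3d(labels)
  d <- dim(arr)
  r <- array(0, dim = c(d, 3))
  for (k in 0:2) r[, , , k + 1][arr == k] <- 1
  r
}

#' Weighted cross-entropy loss
#'
#' `WCEL = -sum_x w(x) sum_k r_k(x) log(p_k(x))` over all voxels, with
#' the natural logarithm clamped at `p = 1e-12`. Zero exactly when the
#' prediction is one-hot correct on the support of `w`.
#'
#' @param pred 4-D probability array (x, y, z, class) with per-voxel
#'   class sums equal to 1.
#' @param gt a [label_volume()], label array, or one-hot 4-D array.
#' @param weight per-voxel weight array, or a scalar (default 1).
#' @return numeric scalar loss (a sum, not a mean).
#' @export
wcel <- function(pred, gt, weight = 1) {
  r <- if (length(dim(gt)) == 4) gt else one_hot_labels(gt)
  if (!identical(dim(pred), dim(r))) stop("prediction/ground-truth shape mismatch")
  if (!identical(length(weight), 1L) &&
      !identical(dim(weight), dim(pred)[1:3]))
    stop("weight map shape mismatch")
  p <- pmax(pred, 1e-12)
  ce <- -rowSums(matrix(r * log(p), ncol = 3))  # per-voxel cross entropy
  sum(as.vector(weight) * ce)
}

#' Generalized Dice loss
#'
#' `GDL = 1 - 2 * sum_k w_k sum_x r_k p_k / sum_k w_k sum_x (r_k + p_k)`
#' with inverse-squared-volume class weights ([class_weights_gdl()]).
#' Lies in `[0, 1]`; 0 for a perfect prediction; invariant to jointly
#' permuting the class indices of prediction and ground truth.
#'
#' @param pred 4-D probability array (x, y, z, class).
#' @param gt a [label_volume()], label array, or one-hot 4-D array.
#' @return numeric scalar loss.
#' @export
gdl <- function(pred, gt) {
  r <- if (length(dim(gt)) == 4) gt else one_hot_labels(gt)
  if (!identical(dim(pred), dim(r))) stop("prediction/ground-truth shape mismatch")
  counts <- apply(r, 4, sum)
  w <- ifelse(counts > 0, 1 / counts^2, 0)
  num <- sum(vapply(1:3, function(k) w[k] * sum(r[, , , k] * pred[, , , k]),
                    numeric(1)))
  den <- sum(vapply(1:3, function(k) w[k] * sum(r[, , , k] + pred[, , , k]),
                    numeric(1)))
  if (den == 0) return(0)
  1 - 2 * num / den
}

#' Build the per-voxel weight map for training
#'
#' `w(x) = w_class(x) * w_pixel(x)`: the class weight of the voxel's
#' ground-truth class (smoothed scheme, computed per patch or from
#' dataset-wide counts) times a distance-based pixel weight (`none`,
#' `exp`, or `window` mode).
#'
#' @param labels a [label_volume()] or array (the patch ground truth).
#' @param class_scope `"patch"` (counts from this volume) or
#'   `"dataset"` (counts supplied via `dataset_counts`).
#' @param pixel_cfg the `weighting` section of [default_config()].
#' @param dataset_counts length-3 counts for dataset scope.
#' @param geometry a [voxel_geometry()] for the distance field.
#' @return numeric 3-D weight array.
#' @export
build_weight_volume <- function(labels, class_scope = "patch",
                                pixel_cfg = default_config()$weighting,
                                dataset_counts = NULL, geometry = NULL) {
  arr <- as_array3d(labels)
  if (is.null(geometry)) geometry <- vol_geometry(labels)
  wk <- if (identical(class_scope, "dataset")) {
    if (is.null(dataset_counts)) stop("dataset scope requires dataset_counts")
    class_weights_smoothed(dataset_counts)
  } else {
    class_weights_smoothed(arr)
  }
  w_class <- array(wk[arr + 1L], dim = dim(arr))
  w_pixel <- switch(pixel_cfg$mode,
    none = 1,
    exp = {
      if (!any(arr > 0L)) 1
      else pixel_weight_exp(distance_field(arr, geometry), pixel_cfg$r_decay)
    },
    window = {
      if (!any(arr > 0L)) 1
      else pixel_weight_window(distance_field(arr, geometry), pixel_cfg$d_max)
    },
    stop("unknown pixel weight mode '", pixel_cfg$mode, "'"))
  w_class * w_pixel
}
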