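reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  # symmetric reflection with edge duplication, consistent with the C++ side
  vapply(i, function(j) {
    while (j < 1 || j > n) {
      if (j < 1) j <- 1 - j
      if (j > n) j <- 2 * n - j + 1
    }
    as.integer(j)
  }, integer(1))
}

# extract a window [start, start+size) allowing out-of-range indices,
# filled by reflection or zeros
padded_window <- function(arr, start, size, mode = "reflective") {
  d <- dim(arr)
  idx <- lapply(1:3, function(a) start[a] + seq_len(size[a]) - 1L)
  if (mode == "reflective") {
    ridx <- lapply(1:3, function(a) reflect_index(idx[[a]], d[a]))
    arr[ridx[[1]], ridx[[2]], ridx[[3]], drop = FALSE]
  } else {
    out <- array(0, dim = size)
    ok <- lapply(1:3, function(a) idx[[a]] >= 1 & idx[[a]] <= d[a])
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      arr[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]], drop = FALSE]
    out
  }
}

# for a same-convolution model any pooling-divisible window size works;
# predicting a volume in one tile avoids redundant context computation
prediction_config <- function(cfg, d) {
  if (cfg$conv_mode != "same") return(cfg)
  sizes <- d
  for (p in cfg$pool) {
    if (any(sizes %% p != 0)) return(cfg)
    sizes <- sizes %/% p
  }
  cfg$input_patch <- cfg$output_patch <- as.integer(d)
  cfg
}

tile_starts <- function(extent, size) {
  if (extent <= size) return(1L)
  s <- seq(1L, extent - size + 1L, by = size)
  if (s[length(s)] + size - 1L < extent) s <- c(s, extent - size + 1L)
  s
}

#' Extract training patches from a volume pair
#'
#' Tiles the volume with stride equal to the output patch (clamping the
#' final tile to the border, so coverage is complete), expands each
#' output window by the receptive-field margin with reflective (or
#' zero) padding, drops patches failing the labeled-content filter, and
#' attaches per-voxel weight maps.
#'
#' @param image an [intensity_volume()] or array.
#' @param labels a [label_volume()] or array (same shape).
#' @param cfg a [unet_config()].
#' @param train_cfg the `train` section of [default_config()]
#'   (`patch_filter`, `min_label_fraction`).
#' @param weighting_cfg the `weighting` section of [default_config()].
#' @param dataset_counts optional length-3 class counts for
#'   dataset-scope class weights.
#' @param geometry a [voxel_geometry()].
#' @return list of patches: each has `input` (input_patch array),
#'   `labels` and `weight` (output_patch arrays), and `start`.
#' @export
extract_patches <- function(image, labels, cfg,
                            train_cfg = default_config()$train,
                            weighting_cfg = default_config()$weighting,
                            dataset_counts = NULL, geometry = NULL) {
  img <- as_array3d(image) / 65535  # fixed 16-bit scaling, same at predict
  lab <- as_array3d(labels)
  if (!identical(dim(img), dim(lab))) stop("image/label shape mismatch")
  if (is.null(geometry)) geometry <- vol_geometry(labels, vol_geometry(image))
  d <- dim(img)
  out_sz <- cfg$output_patch
  in_sz <- cfg$input_patch
  margin <- cfg$margins
  starts <- expand.grid(x = tile_starts(d[1], out_sz[1]),
                        y = tile_starts(d[2], out_sz[2]),
                        z = tile_starts(d[3], out_sz[3]))
  patches <- list()
  for (r in seq_len(nrow(starts))) {
    s <- as.integer(starts[r, ])
    lab_win <- padded_window(lab, s, out_sz, "zero")  # labels never reflect
    frac <- mean(lab_win > 0)
    keep <- switch(train_cfg$patch_filter,
      any_labeled = frac > 0,
      min_fraction = frac > train_cfg$min_label_fraction,
      stop("unknown patch_filter '", train_cfg$patch_filter, "'"))
    if (!keep) next
    input <- padded_window(img, s - margin, in_sz, cfg$padding_mode)
    w <- build_weight_volume(lab_win, weighting_cfg$class_scope,
                             weighting_cfg, dataset_counts, geometry)
    patches[[length(patches) + 1]] <-
      list(input = input, labels = lab_win, weight = w, start = s)
  }
  patches
}

#' Random isometric augmentation of a patch
#'
#' Draws a transform from the isometry group that keeps voxel-to-voxel
#' correspondence -- axis flips, in-plane 90/180/270-degree rotations
#' (square x/y patches only), and small integer-voxel translations --
#' and applies the identical transform to image, labels, and weights.
#'
#' @param patch a patch from [extract_patches()].
#' @param transform optional explicit transform
#'   (`list(flip, rot, shift)`); drawn from the RNG when `NULL`.
#' @param max_shift largest voxel translation per axis.
#' @return the transformed patch (with the transform attached as
#'   attribute `transform`).
#' @export
augment_isometric <- function(patch, transform = NULL, max_shift = 2L) {
  sq <- dim(patch$input)[1] == dim(patch$input)[2] &&
    dim(patch$labels)[1] == dim(patch$labels)[2]
  if (is.null(transform)) {
    transform <- list(flip = stats::runif(3) < 0.5,
                      rot = if (sq) sample(0:3, 1) else 0L,
                      shift = sample(seq(-max_shift, max_shift), 3,
                                     replace = TRUE))
  }
  ap <- function(a, label_like = FALSE) {
    apply_isometry(a, transform, label_like)
  }
  out <- list(input = ap(patch$input), labels = ap(patch$labels, TRUE),
              weight = ap(patch$weight), start = patch$start)
  attr(out, "transform") <- transform
  out
}

apply_isometry <- function(a, tr, label_like = FALSE) {
  d <- dim(a)
  if (!is.null(tr$shift) && any(tr$shift != 0)) {
    idx <- lapply(1:3, function(ax)
      reflect_index(seq_len(d[ax]) + tr$shift[ax], d[ax]))
    a <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  if (tr$flip[1]) a <- a[d[1]:1, , , drop = FALSE]
  if (tr$flip[2]) a <- a[, d[2]:1, , drop = FALSE]
  if (tr$flip[3]) a <- a[, , d[3]:1, drop = FALSE]
  r <- tr$rot %% 4
  if (r > 0) {
    for (i in seq_len(r)) a <- rotate90_xy(a)
  }
  if (label_like) storage.mode(a) <- "integer"
  a
}

rotate90_xy <- function(a) {
  d <- dim(a)
  out <- aperm(a, c(2, 1, 3))
  out[d[2]:1, , , drop = FALSE]
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

loss_and_grad <- function(model, patch, loss_kind) {
  fwd <- unet_forward(model, patch$input, cache = TRUE)
  p <- fwd$probs
  r <- one_hot_labels(patch$labels)
  n_vox <- prod(dim(p)[1:3])
  w <- switch(loss_kind,
    wcel = patch$weight,
    cel = array(1, dim = dim(p)[1:3]),
    gdl = NULL,
    stop("unknown loss '", loss_kind, "'"))
  if (loss_kind %in% c("wcel", "cel")) {
    loss <- wcel(p, r, w) / n_vox
    dlogits <- as.vector(w) * (p - r) / n_vox
    dim(dlogits) <- dim(p)
  } else {
    loss <- gdl(p, r)
    counts <- apply(r, 4, sum)
    wk <- ifelse(counts > 0, 1 / counts^2, 0)
    num <- sum(vapply(1:3, function(k) wk[k] * sum(r[, , , k] * p[, , , k]),
                      numeric(1)))
    den <- sum(vapply(1:3, function(k) wk[k] * sum(r[, , , k] + p[, , , k]),
                      numeric(1)))
    gp <- array(0, dim = dim(p))
    for (k in 1:3)
      gp[, , , k] <- -2 * (wk[k] * r[, , , k] * den - num * wk[k]) / den^2
    inner <- array(0, dim = dim(p)[1:3])
    for (k in 1:3) inner <- inner + gp[, , , k] * p[, , , k]
    dlogits <- p * (gp - as.vector(inner))
    dim(dlogits) <- dim(p)
  }
  list(loss = loss, grads = unet_backward(model, fwd$cache, dlogits))
}

#' Train a U-Net on patches
#'
#' Minimizes the configured loss (per-voxel mean) with Adam, logging
#' per-epoch training loss and, when validation volumes are supplied,
#' validation loss proxy (1 - masked mean F1). The parameters with the
#' smallest validation error are retained.
#'
#' @param model a [build_model()] result.
#' @param patches list from [extract_patches()] (possibly several
#'   volumes' worth concatenated).
#' @param train_cfg the `train` section of [default_config()].
#' @param weighting_cfg the `weighting` section of [default_config()].
#' @param validation optional list of `list(image =, labels =)` volumes
#'   evaluated with [predict_volume()] + [evaluate()] each epoch.
#' @param mask_radius evaluation mask radius in um.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-validation parameters, or final when
#'   no validation), `final`, and `history` (data.frame).
#' @export
train_unet <- function(model, patches, train_cfg = default_config()$train,
                       weighting_cfg = default_config()$weighting,
                       validation = NULL, mask_radius = 7.58,
                       verbose = FALSE) {
  if (length(patches) == 0) stop("no training patches")
  state <- adam_init(model$params)
  best <- list(err = Inf, params = model$params)
  history <- list()
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample(length(patches))
    epoch_loss <- 0
    nb <- 0
    for (b0 in seq(1, length(ord), by = train_cfg$batch_size)) {
      batch <- ord[b0:min(b0 + train_cfg$batch_size - 1, length(ord))]
      acc <- NULL
      bloss <- 0
      for (pi in batch) {
        patch <- patches[[pi]]
        if (isTRUE(train_cfg$augment)) patch <- augment_isometric(patch)
        lg <- loss_and_grad(model, patch, weighting_cfg$loss)
        bloss <- bloss + lg$loss
        acc <- if (is.null(acc)) lg$grads else
          mapply(`+`, acc, lg$grads, SIMPLIFY = FALSE)
      }
      acc <- lapply(acc, `/`, length(batch))
      upd <- adam_step(model$params, acc, state, train_cfg$learning_rate,
                       train_cfg$beta1, train_cfg$beta2, train_cfg$epsilon)
      model$params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + bloss / length(batch)
      nb <- nb + 1
    }
    epoch_loss <- epoch_loss / nb
    val_f1 <- NA_real_
    if (!is.null(validation)) {
      f1s <- vapply(validation, function(v) {
        pcfg <- prediction_config(model$config, dim(as_array3d(v$image)))
        pred <- predict_volume(model, v$image, pcfg)
        evaluate(pred$labels, v$labels, mask_radius,
                 geometry = vol_geometry(v$labels))$f1_mean
      }, numeric(1))
      val_f1 <- mean(f1s)
      if (1 - val_f1 < best$err) {
        best$err <- 1 - val_f1
        best$params <- model$params
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = epoch_loss,
                                   val_f1 = val_f1)
    if (verbose)
      message(sprintf("epoch %d: loss %.5f, val F1 %.3f", epoch, epoch_loss,
                      val_f1))
  }
  final <- model
  if (!is.null(validation)) model$params <- best$params
  list(model = model, final = final, history = do.call(rbind, history))
}

#' Tiled full-volume prediction
#'
#' Tiles the volume with stride equal to the output patch, surrounding
#' each tile with the receptive-field margin of reflectively padded
#' context, and stitches the per-tile probabilities (disjoint writes,
#' so the result does not depend on tile order). The label map is the
#' per-voxel argmax, ties broken toward the lower class code.
#'
#' @param model a trained [build_model()] object.
#' @param image an [intensity_volume()] or array.
#' @param cfg a [unet_config()] (defaults to the model's).
#' @return list with `probs` (4-D array) and `labels` (a
#'   [label_volume()]).
#' @export
predict_volume <- function(model, image, cfg = model$config) {
  img <- as_array3d(image) / 65535  # fixed 16-bit scaling, as in training
  d <- dim(img)
  out_sz <- cfg$output_patch
  # valid mode consumes its margin by construction; same mode gets an
  # explicit receptive-field context margin so tiles agree with an
  # untiled run (pooling-aligned overlap-tile strategy)
  margin <- if (cfg$conv_mode == "valid") cfg$margins else rf_radius(cfg)
  in_sz <- out_sz + 2L * margin
  crop0 <- if (cfg$conv_mode == "valid") c(0L, 0L, 0L) else margin
  probs <- array(0, dim = c(d, cfg$n_classes))
  for (sx in tile_starts(d[1], out_sz[1]))
    for (sy in tile_starts(d[2], out_sz[2]))
      for (sz in tile_starts(d[3], out_sz[3])) {
        s <- c(sx, sy, sz)
        input <- padded_window(img, s - margin, in_sz, cfg$padding_mode)
        fwd <- unet_forward(model, input)
        keep <- pmin(out_sz, d - s + 1L)
        probs[s[1]:(s[1] + keep[1] - 1L), s[2]:(s[2] + keep[2] - 1L),
              s[3]:(s[3] + keep[3] - 1L), ] <-
          fwd$probs[crop0[1] + seq_len(keep[1]), crop0[2] + seq_len(keep[2]),
                    crop0[3] + seq_len(keep[3]), , drop = FALSE]
      }
  lab <- array(max.col(matrix(probs, ncol = cfg$n_classes),
                       ties.method = "first") - 1L, dim = d)
  list(probs = probs,
       labels = label_volume(lab, vol_geometry(image)))
}

#' Masked segmentation metrics
#'
#' Restricts evaluation to voxels within `mask_radius` um of the
#' ground-truth dendritic shaft (the region where spines can occur),
#' then reports one-vs-rest TP/FP/FN, precision, recall, and F1 per
#' foreground class plus their mean. A zero denominator yields a 0
#' metric and raises the `degenerate` flag.
#'
#' @param pred predicted [label_volume()] or array.
#' @param gt ground-truth [label_volume()] or array.
#' @param mask_radius mask radius in um (default 7.58; `Inf` disables
#'   masking).
#' @param geometry a [voxel_geometry()].
#' @return object of class `metrics_report`.
#' @export
evaluate <- function(pred, gt, mask_radius = 7.58, geometry = NULL) {
  p <- as_array3d(pred)
  g <- as_array3d(gt)
  if (!identical(dim(p), dim(g))) stop("prediction/ground-truth shape mismatch")
  if (is.null(geometry)) geometry <- vol_geometry(gt, vol_geometry(pred))
  mask <- if (is.finite(mask_radius) && any(g == 1L)) {
    array(cpp_edt(as.logical(g == 1L), as.integer(dim(g)),
                  as.numeric(geometry$voxel_size)), dim = dim(g)) <= mask_radius
  } else {
    array(TRUE, dim = dim(g))
  }
  degenerate <- FALSE
  rows <- lapply(c(shaft = 1L, spine = 2L), function(k) {
    tp <- sum(p == k & g == k & mask)
    fp <- sum(p == k & g != k & mask)
    fn <- sum(p != k & g == k & mask)
    prec <- if (tp + fp > 0) tp / (tp + fp) else {
      degenerate <<- TRUE; 0
    }
    rec <- if (tp + fn > 0) tp / (tp + fn) else {
      degenerate <<- TRUE; 0
    }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
      degenerate <<- TRUE; 0
    }
    data.frame(TP = tp, FP = fp, FN = fn, precision = prec, recall = rec,
               f1 = f1)
  })
  tab <- cbind(class = c("shaft", "spine"), do.call(rbind, rows))
  rownames(tab) <- NULL
  structure(list(metrics = tab, f1_mean = mean(tab$f1),
                 mask_radius = mask_radius, degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Masked segmentation metrics (mask radius %g um)\n",
              x$mask_radius))
  cat(sprintf("%-12s %-16s %-10s\n", "Metric", "Dendritic shaft", "Spine"))
  cat(sprintf("%-12s %-16s %-10s\n", "Precision",
              sprintf("%.1f %%", 100 * m$precision[1]),
              sprintf("%.1f %%", 100 * m$precision[2])))
  cat(sprintf("%-12s %-16s %-10s\n", "Recall",
              sprintf("%.1f %%", 100 * m$recall[1]),
              sprintf("%.1f %%", 100 * m$recall[2])))
  cat(sprintf("%-12s %-16s %-10s\n", "F1-score",
              sprintf("%.1f %%", 100 * m$f1[1]),
              sprintf("%.1f %%", 100 * m$f1[2])))
  cat(sprintf("F1-score mean: %.1f %%\n", 100 * x$f1_mean))
  if (x$degenerate) cat("(some metrics had zero denominators; reported as 0)\n")
  invisible(x)
}
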