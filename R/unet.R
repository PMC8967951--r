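#' 3D U-Net configuration
#'
#' Describes a volumetric encoder-decoder: `stages` resolution levels
#' with channel doubling, two 3x3x3 convolutions per level, max-pool
#' downsampling, transposed-convolution upsampling with skip
#' connections, and a final 3-class softmax. In `valid` convolution
#' mode the spatial contract `input_patch -> output_patch` must be
#' realizable by the shape arithmetic; the per-axis pooling schedule is
#' solved automatically (axes are independent), and an impossible
#' contract raises a config error listing the achievable output sizes.
#' In `same` mode output equals input and any patch size divisible by
#' the pooling applies.
#'
#' @param stages number of resolution levels (>= 2).
#' @param base_channels feature channels of the first level.
#' @param input_patch,output_patch integer length-3 patch shapes.
#' @param conv_mode `"valid"` (shrinking convolutions, the published
#'   contract) or `"same"` (padded convolutions, for desk-scale work).
#' @param padding_mode `"reflective"` or `"zero"`: border handling both
#'   inside same-mode convolutions and when patch windows are extracted
#'   near volume borders.
#' @param pool optional list of length `stages - 1` of per-axis pool
#'   factors; solved automatically when `NULL`.
#' @param n_classes number of output classes.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(stages = 5L, base_channels = 16L,
                        input_patch = c(300L, 300L, 66L),
                        output_patch = NULL,
                        conv_mode = c("valid", "same"),
                        padding_mode = c("reflective", "zero"),
                        pool = NULL, n_classes = 3L) {
  conv_mode <- match.arg(conv_mode)
  padding_mode <- match.arg(padding_mode)
  stages <- as.integer(stages)
  input_patch <- as.integer(input_patch)
  if (stages < 2) stop("stages must be >= 2")
  if (conv_mode == "same") {
    if (!is.null(output_patch) && !all(output_patch == input_patch))
      stop("same-convolution mode requires output_patch == input_patch")
    output_patch <- input_patch
    if (is.null(pool)) pool <- rep(list(c(2L, 2L, 2L)), stages - 1L)
    sizes <- input_patch
    for (l in seq_len(stages - 1L)) {
      if (any(sizes %% pool[[l]] != 0))
        stop(sprintf(
          "input_patch not divisible by the pooling at level %d (size %s, pool %s)",
          l, paste(sizes, collapse = "x"), paste(pool[[l]], collapse = "x")))
      sizes <- sizes %/% pool[[l]]
    }
  } else {
    if (is.null(pool) && is.null(output_patch)) {
      pool <- rep(list(c(2L, 2L, 2L)), stages - 1L)
    }
    if (is.null(pool)) {
      pool <- lapply(1:3, function(a) {
        sched <- solve_pool_schedule(input_patch[a], output_patch[a],
                                     stages)
        if (is.null(sched)) {
          achievable <- achievable_valid_outputs(input_patch[a], stages)
          stop(sprintf(
            "no valid-convolution schedule maps input %d to output %d on axis %d with %d stages; achievable outputs: %s (required margins: input minus these, halved)",
            input_patch[a], output_patch[a], a, stages,
            paste(sort(unique(achievable)), collapse = ", ")))
        }
        sched
      })
      pool <- lapply(seq_len(stages - 1L), function(l)
        vapply(pool, function(ax) ax[l], integer(1)))
    }
    out <- valid_output_shape(input_patch, pool, stages)
    if (any(is.na(out)))
      stop("input_patch is too small for this depth/pooling in valid mode")
    if (is.null(output_patch)) output_patch <- out
    if (!all(out == output_patch))
      stop(sprintf(
        "valid-mode shape contract violated: input %s yields output %s, not %s (required margin per axis: %s)",
        paste(input_patch, collapse = "x"), paste(out, collapse = "x"),
        paste(output_patch, collapse = "x"),
        paste((input_patch - out) %/% 2L, collapse = "x")))
  }
  margins <- (input_patch - output_patch) %/% 2L
  if (any((input_patch - output_patch) %% 2L != 0))
    stop("input/output patch margins must be integral")
  structure(list(stages = stages, base_channels = as.integer(base_channels),
                 input_patch = input_patch,
                 output_patch = as.integer(output_patch),
                 conv_mode = conv_mode, padding_mode = padding_mode,
                 pool = lapply(pool, as.integer),
                 n_classes = as.integer(n_classes), margins = margins),
            class = "unet_config")
}

# output extent of one axis in valid mode for a pooling schedule
valid_axis_output <- function(n, sched) {
  d <- n
  for (p in sched) {
    d <- d - 4L
    if (d < 1L || d %% p != 0L) return(NA_integer_)
    d <- d %/% p
  }
  d <- d - 4L  # bottleneck
  if (d < 1L) return(NA_integer_)
  for (p in rev(sched)) {
    d <- d * p - 4L
    if (d < 1L) return(NA_integer_)
  }
  d
}

solve_pool_schedule <- function(n_in, n_out, stages) {
  n_pool <- stages - 1L
  for (code in 0:(2^n_pool - 1)) {
    sched <- ifelse(bitwAnd(code, 2^(seq_len(n_pool) - 1)) > 0, 2L, 1L)
    if (identical(valid_axis_output(n_in, sched), as.integer(n_out)))
      return(sched)
  }
  NULL
}

achievable_valid_outputs <- function(n_in, stages) {
  n_pool <- stages - 1L
  outs <- integer(0)
  for (code in 0:(2^n_pool - 1)) {
    sched <- ifelse(bitwAnd(code, 2^(seq_len(n_pool) - 1)) > 0, 2L, 1L)
    o <- valid_axis_output(n_in, sched)
    if (!is.na(o)) outs <- c(outs, o)
  }
  outs
}

valid_output_shape <- function(input, pool, stages) {
  vapply(1:3, function(a)
    valid_axis_output(input[a], vapply(pool, `[`, integer(1), a)),
    integer(1))
}

# receptive-field radius of one output voxel, in input voxels per axis,
# rounded up to a multiple of the total pooling factor so that tiled
# prediction windows stay pooling-aligned
rf_radius <- function(cfg) {
  r <- c(0, 0, 0)
  scale <- c(1, 1, 1)
  for (l in seq_len(cfg$stages - 1L)) {
    r <- r + 4 * scale          # two 3x3x3 convolutions
    scale <- scale * cfg$pool[[l]]
  }
  r <- r + 4 * scale            # bottleneck
  for (l in rev(seq_len(cfg$stages - 1L))) {
    scale <- scale / cfg$pool[[l]]
    r <- r + 4 * scale          # decoder convolutions
  }
  total_pool <- Reduce(`*`, cfg$pool, accumulate = FALSE)
  as.integer(ceiling(r / total_pool) * total_pool)
}

#' Receptive-field margins of a patch contract
#'
#' `(input_patch - output_patch) / 2` per axis; the context a valid
#' U-Net consumes around its output window.
#'
#' @param cfg a [unet_config()].
#' @return integer length-3 margins in voxels.
#' @export
unet_margins <- function(cfg) cfg$margins

#' Build a 3D U-Net model
#'
#' He-initialized weights for the configured encoder-decoder. Note that
#' `seed` reseeds R's RNG.
#'
#' @param cfg a [unet_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return An object of class `unet_model` (config + flat parameter
#'   list).
#' @export
build_model <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- cfg$base_channels * 2L^(seq_len(cfg$stages) - 1L)
  params <- list()
  he <- function(kdim) {
    fan_in <- prod(kdim[1:4])
    array(stats::rnorm(prod(kdim), sd = sqrt(2 / fan_in)), dim = kdim)
  }
  for (l in seq_len(cfg$stages)) {
    cin <- if (l == 1) 1L else ch[l - 1]
    params[[sprintf("enc%d.wa", l)]] <- he(c(3, 3, 3, cin, ch[l]))
    params[[sprintf("enc%d.ba", l)]] <- numeric(ch[l])
    params[[sprintf("enc%d.wb", l)]] <- he(c(3, 3, 3, ch[l], ch[l]))
    params[[sprintf("enc%d.bb", l)]] <- numeric(ch[l])
  }
  for (l in seq_len(cfg$stages - 1L)) {
    f <- cfg$pool[[l]]
    params[[sprintf("dec%d.wu", l)]] <- he(c(f[1], f[2], f[3], ch[l + 1], ch[l]))
    params[[sprintf("dec%d.bu", l)]] <- numeric(ch[l])
    params[[sprintf("dec%d.wa", l)]] <- he(c(3, 3, 3, 2L * ch[l], ch[l]))
    params[[sprintf("dec%d.ba", l)]] <- numeric(ch[l])
    params[[sprintf("dec%d.wb", l)]] <- he(c(3, 3, 3, ch[l], ch[l]))
    params[[sprintf("dec%d.bb", l)]] <- numeric(ch[l])
  }
  params[["fin.w"]] <- he(c(1, 1, 1, ch[1], cfg$n_classes))
  params[["fin.b"]] <- numeric(cfg$n_classes)
  structure(list(config = cfg, params = params), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<unet_model> %d stages, %d base channels, %s conv, %s -> %s\n",
    cfg$stages, cfg$base_channels, cfg$conv_mode,
    paste(cfg$input_patch, collapse = "x"),
    paste(cfg$output_patch, collapse = "x")))
  cat(sprintf("  %d parameters\n",
              sum(vapply(x$params, length, numeric(1)))))
  invisible(x)
}

conv_pad <- function(cfg) if (cfg$conv_mode == "same") c(1L, 1L, 1L) else c(0L, 0L, 0L)

# pad borders of same-mode convolutions by reflection (the padding the
# workflow standardizes on) or zeros
conv_reflect <- function(cfg) {
  as.integer(cfg$conv_mode == "same" && cfg$padding_mode == "reflective")
}

conv_apply <- function(x, w, b, pad, reflect = 0L) {
  cpp_conv3d_fwd(as.numeric(x), as.integer(dim(x)), as.numeric(w),
                 as.integer(dim(w)), as.numeric(b), as.integer(pad),
                 as.integer(reflect))
}

crop_center4 <- function(x, target) {
  d <- dim(x)[1:3]
  off <- (d - target) %/% 2L
  x[off[1] + seq_len(target[1]), off[2] + seq_len(target[2]),
    off[3] + seq_len(target[3]), , drop = FALSE]
}

#' Forward pass of the U-Net
#'
#' @param model a [build_model()] result.
#' @param x 3-D input array of shape `input_patch` (or any compatible
#'   shape in same-convolution mode).
#' @param cache keep intermediate activations for [unet_backward()].
#' @return list with `probs` (4-D softmax output over
#'   `output_patch`), `logits`, and (optionally) `cache`.
#' @export
unet_forward <- function(model, x, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  pad <- conv_pad(cfg)
  refl <- conv_reflect(cfg)
  st <- list()
  h <- array(as.numeric(x), dim = c(dim(x), 1L))
  skips <- list()
  pools <- list()
  for (l in seq_len(cfg$stages)) {
    xin <- h
    h <- conv_apply(h, p[[sprintf("enc%d.wa", l)]], p[[sprintf("enc%d.ba", l)]], pad, refl)
    ha <- pmax(h, 0)
    dim(ha) <- dim(h)
    h2in <- ha
    h <- conv_apply(ha, p[[sprintf("enc%d.wb", l)]], p[[sprintf("enc%d.bb", l)]], pad, refl)
    hb <- pmax(h, 0)
    dim(hb) <- dim(h)
    if (cache) st[[sprintf("enc%d", l)]] <- list(xin = xin, ha = ha, h2in = h2in, hb = hb)
    if (l < cfg$stages) {
      skips[[l]] <- hb
      mp <- cpp_maxpool_fwd(as.numeric(hb), as.integer(dim(hb)),
                            as.integer(cfg$pool[[l]]))
      pools[[l]] <- mp$argmax
      if (cache) st[[sprintf("pool%d", l)]] <- list(indim = dim(hb), argmax = mp$argmax)
      h <- mp$out
    } else {
      h <- hb
    }
  }
  for (l in rev(seq_len(cfg$stages - 1L))) {
    upin <- h
    h <- cpp_upconv_fwd(as.numeric(h), as.integer(dim(h)),
                        as.numeric(p[[sprintf("dec%d.wu", l)]]),
                        as.integer(dim(p[[sprintf("dec%d.wu", l)]])),
                        as.numeric(p[[sprintf("dec%d.bu", l)]]))
    skip <- crop_center4(skips[[l]], dim(h)[1:3])
    hcat <- array(0, dim = c(dim(h)[1:3], dim(skip)[4] + dim(h)[4]))
    hcat[, , , seq_len(dim(skip)[4])] <- skip
    hcat[, , , dim(skip)[4] + seq_len(dim(h)[4])] <- h
    xin <- hcat
    h <- conv_apply(hcat, p[[sprintf("dec%d.wa", l)]], p[[sprintf("dec%d.ba", l)]], pad, refl)
    ha <- pmax(h, 0)
    dim(ha) <- dim(h)
    h2in <- ha
    h <- conv_apply(ha, p[[sprintf("dec%d.wb", l)]], p[[sprintf("dec%d.bb", l)]], pad, refl)
    hb <- pmax(h, 0)
    dim(hb) <- dim(h)
    if (cache) st[[sprintf("dec%d", l)]] <- list(upin = upin, xin = xin,
                                                 ha = ha, h2in = h2in, hb = hb,
                                                 n_skip = dim(skip)[4])
    h <- hb
  }
  fin_in <- h
  logits <- conv_apply(h, p[["fin.w"]], p[["fin.b"]], c(0L, 0L, 0L))
  if (cache) st[["fin"]] <- list(xin = fin_in)
  probs <- softmax4(logits)
  out <- list(probs = probs, logits = logits)
  if (cache) out$cache <- st
  out
}

softmax4 <- function(logits) {
  d <- dim(logits)
  m <- array(logits[, , , 1], dim = d[1:3])
  for (k in seq_len(d[4])[-1]) m <- pmax(m, logits[, , , k])
  e <- exp(logits - as.vector(m))
  s <- array(0, dim = d[1:3])
  for (k in seq_len(d[4])) s <- s + e[, , , k]
  out <- e / as.vector(s)
  dim(out) <- d
  out
}

#' Backward pass of the U-Net
#'
#' @param model a [build_model()] result.
#' @param cache the cache from `unet_forward(..., cache = TRUE)`.
#' @param dlogits gradient of the loss with respect to the logits.
#' @return named list of parameter gradients (same shapes as
#'   `model$params`).
#' @export
unet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  pad <- conv_pad(cfg)
  refl <- conv_reflect(cfg)
  g <- list()
  conv_back <- function(xin, w, dy, padc, reflect = refl) {
    cpp_conv3d_bwd(as.numeric(xin), as.integer(dim(xin)), as.numeric(w),
                   as.integer(dim(w)), as.numeric(dy),
                   as.integer(dim(dy)[1:3]), as.integer(padc),
                   as.integer(reflect))
  }
  fin <- cache[["fin"]]
  bw <- conv_back(fin$xin, p[["fin.w"]], dlogits, c(0L, 0L, 0L), 0L)
  g[["fin.w"]] <- bw$dw
  g[["fin.b"]] <- bw$db
  dh <- bw$dx
  dskips <- list()
  for (l in seq_len(cfg$stages - 1L)) {
    stg <- cache[[sprintf("dec%d", l)]]
    dh <- dh * (stg$hb > 0)
    bw <- conv_back(stg$h2in, p[[sprintf("dec%d.wb", l)]], dh, pad)
    g[[sprintf("dec%d.wb", l)]] <- bw$dw
    g[[sprintf("dec%d.bb", l)]] <- bw$db
    dh <- bw$dx * (stg$ha > 0)
    dim(dh) <- dim(bw$dx)
    bw <- conv_back(stg$xin, p[[sprintf("dec%d.wa", l)]], dh, pad)
    g[[sprintf("dec%d.wa", l)]] <- bw$dw
    g[[sprintf("dec%d.ba", l)]] <- bw$db
    dcat <- bw$dx
    ns <- stg$n_skip
    dskips[[l]] <- dcat[, , , seq_len(ns), drop = FALSE]
    dup <- dcat[, , , ns + seq_len(dim(dcat)[4] - ns), drop = FALSE]
    bw <- cpp_upconv_bwd(as.numeric(stg$upin), as.integer(dim(stg$upin)),
                         as.numeric(p[[sprintf("dec%d.wu", l)]]),
                         as.integer(dim(p[[sprintf("dec%d.wu", l)]])),
                         as.numeric(dup))
    g[[sprintf("dec%d.wu", l)]] <- bw$dw
    g[[sprintf("dec%d.bu", l)]] <- bw$db
    dh <- bw$dx
  }
  # dh now flows into the bottleneck (deepest encoder level)
  for (l in rev(seq_len(cfg$stages))) {
    stg <- cache[[sprintf("enc%d", l)]]
    if (l < cfg$stages) {
      pl <- cache[[sprintf("pool%d", l)]]
      dpool <- cpp_maxpool_bwd(as.numeric(dh), as.integer(pl$argmax),
                               as.integer(pl$indim))
      # add the skip-connection gradient (cropped center region)
      dsk <- dskips[[l]]
      tgt <- dim(dsk)[1:3]
      d <- pl$indim[1:3]
      off <- (d - tgt) %/% 2L
      dfull <- array(dpool, dim = pl$indim)
      dfull[off[1] + seq_len(tgt[1]), off[2] + seq_len(tgt[2]),
            off[3] + seq_len(tgt[3]), ] <-
        dfull[off[1] + seq_len(tgt[1]), off[2] + seq_len(tgt[2]),
              off[3] + seq_len(tgt[3]), , drop = FALSE] + dsk
      dh <- dfull
    }
    dh <- dh * (stg$hb > 0)
    bw <- conv_back(stg$h2in, p[[sprintf("enc%d.wb", l)]], dh, pad)
    g[[sprintf("enc%d.wb", l)]] <- bw$dw
    g[[sprintf("enc%d.bb", l)]] <- bw$db
    dh <- bw$dx * (stg$ha > 0)
    dim(dh) <- dim(bw$dx)
    bw <- conv_back(stg$xin, p[[sprintf("enc%d.wa", l)]], dh, pad)
    g[[sprintf("enc%d.wa", l)]] <- bw$dw
    g[[sprintf("enc%d.ba", l)]] <- bw$db
    dh <- bw$dx
  }
  g
}
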