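test_that("the published valid-convolution patch contract is realizable", {
  cfg <- unet_config(5L, 16L, c(300L, 300L, 66L), c(116L, 116L, 10L), "valid")
  expect_identical(unet_margins(cfg), c(92L, 92L, 28L))
  # x/y pool at every level; z pooling schedule solved per axis
  expect_true(all(vapply(cfg$pool, function(p) all(p[1:2] == 2L), logical(1))))
  # an impossible contract names the achievable margins
  expect_error(unet_config(5L, 16L, c(300L, 300L, 66L), c(100L, 100L, 10L),
                           "valid"),
               "no valid-convolution schedule")
})

test_that("tiny same-convolution model honors the shape contract", {
  cfg <- unet_config(2L, 4L, c(32L, 32L, 16L), conv_mode = "same")
  expect_identical(cfg$output_patch, cfg$input_patch)
  m <- build_model(cfg, seed = 1)
  x <- array(rnorm(prod(cfg$input_patch)), cfg$input_patch)
  out <- unet_forward(m, x)
  expect_identical(dim(out$probs), c(32L, 32L, 16L, 3L))
  sums <- out$probs[, , , 1] + out$probs[, , , 2] + out$probs[, , , 3]
  expect_equal(unname(sums), array(1, cfg$input_patch), tolerance = 1e-12)
  # constant input: probabilities sum to 1 and are finite
  outc <- unet_forward(m, array(0.5, cfg$input_patch))
  expect_true(all(is.finite(outc$probs)))
})

test_that("valid-convolution forward realizes its computed output shape", {
  cfg <- unet_config(2L, 4L, c(32L, 32L, 20L), conv_mode = "valid")
  m <- build_model(cfg, seed = 2)
  out <- unet_forward(m, array(rnorm(prod(cfg$input_patch)), cfg$input_patch))
  expect_identical(dim(out$probs)[1:3], cfg$output_patch)
})

test_that("backpropagation matches central-difference gradients", {
  cfg <- unet_config(2L, 3L, c(12L, 12L, 8L), conv_mode = "same")
  m <- build_model(cfg, seed = 3)
  set.seed(3)
  patch <- list(input = array(rnorm(prod(cfg$input_patch)), cfg$input_patch),
                labels = array(sample(0:2, prod(cfg$output_patch), TRUE),
                               cfg$output_patch),
                weight = array(runif(prod(cfg$output_patch)),
                               cfg$output_patch))
  ns <- asNamespace("spineflow")
  for (loss in c("wcel", "gdl")) {
    lg <- ns$loss_and_grad(m, patch, loss)
    eps <- 1e-6
    for (nm in c("enc1.wa", "dec1.wu", "fin.w")) {
      i <- 2L
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
      num <- (ns$loss_and_grad(mp, patch, loss)$loss -
                ns$loss_and_grad(mm, patch, loss)$loss) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("patch extraction filters and tiles as specified", {
  cfg <- unet_config(2L, 4L, c(16L, 16L, 8L), conv_mode = "same")
  d <- c(32L, 32L, 16L)
  img <- array(runif(prod(d)), d)
  tr <- default_config()$train
  wcfg <- default_config()$weighting
  # all-background labels with the any-labeled filter: empty stream
  tr$patch_filter <- "any_labeled"
  expect_length(extract_patches(img, array(0L, d), cfg, tr, wcfg), 0)
  # fraction filter: 9% labeled dropped, 11% kept (strictly more than 10%)
  tr$patch_filter <- "min_fraction"
  n_patch <- prod(cfg$output_patch)
  mk <- function(frac) {
    block <- array(0L, cfg$output_patch)
    block[seq_len(round(frac * n_patch))] <- 1L
    lab <- array(0L, d)
    lab[1:16, 1:16, 1:8] <- block  # labeled content in the first tile only
    lab
  }
  lab9 <- mk(0.09)
  lab11 <- mk(0.11)
  expect_length(extract_patches(img, lab9, cfg, tr, wcfg), 0)
  kept <- extract_patches(img, lab11, cfg, tr, wcfg)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$start, c(1L, 1L, 1L))
  # tiling covers the volume with stride = output_patch, no gaps/overlaps
  tr$patch_filter <- "any_labeled"
  laball <- array(1L, d)
  all_p <- extract_patches(img, laball, cfg, tr, wcfg)
  starts <- do.call(rbind, lapply(all_p, `[[`, "start"))
  cover <- array(0L, d)
  for (r in seq_len(nrow(starts))) {
    s <- starts[r, ]
    cover[s[1]:(s[1] + 15), s[2]:(s[2] + 15), s[3]:(s[3] + 7)] <-
      cover[s[1]:(s[1] + 15), s[2]:(s[2] + 15), s[3]:(s[3] + 7)] + 1L
  }
  expect_true(all(cover == 1L))
})

test_that("isometric augmentation is a group action preserving content", {
  cfg <- unet_config(2L, 4L, c(16L, 16L, 8L), conv_mode = "same")
  set.seed(6)
  patch <- list(input = array(rnorm(16 * 16 * 8), c(16, 16, 8)),
                labels = array(sample(0:2, 16 * 16 * 8, TRUE), c(16, 16, 8)),
                weight = array(runif(16 * 16 * 8), c(16, 16, 8)),
                start = c(1L, 1L, 1L))
  idt <- list(flip = c(FALSE, FALSE, FALSE), rot = 0L, shift = c(0L, 0L, 0L))
  same <- augment_isometric(patch, idt)
  expect_equal(same$input, patch$input)
  expect_equal(same$labels, patch$labels)
  # two 90-degree rotations equal one 180-degree rotation
  r90 <- list(flip = c(FALSE, FALSE, FALSE), rot = 1L, shift = c(0L, 0L, 0L))
  r180 <- list(flip = c(FALSE, FALSE, FALSE), rot = 2L, shift = c(0L, 0L, 0L))
  twice <- augment_isometric(augment_isometric(patch, r90), r90)
  once <- augment_isometric(patch, r180)
  expect_equal(twice$input, once$input)
  expect_identical(twice$labels, once$labels)
  # label histogram is invariant under any flip/rotation
  tr <- list(flip = c(TRUE, FALSE, TRUE), rot = 3L, shift = c(0L, 0L, 0L))
  expect_identical(table(augment_isometric(patch, tr)$labels),
                   table(patch$labels))
})

test_that("training on one repeated patch drives the loss down sharply", {
  cfg <- unet_config(2L, 4L, c(16L, 16L, 8L), conv_mode = "same")
  m <- build_model(cfg, seed = 11)
  ph <- generate_phantom(phantom_cfg(shape = c(16L, 16L, 8L), spine_count = 2L,
                                     neck_break_probability = 0), seed = 11)
  tr <- default_config()$train
  tr$patch_filter <- "any_labeled"
  patches <- extract_patches(ph$intensity, ph$labels, cfg, tr,
                             default_config()$weighting)[1]
  expect_length(patches, 1)
  ns <- asNamespace("spineflow")
  init_loss <- ns$loss_and_grad(m, patches[[1]], "wcel")$loss
  tr$learning_rate <- 1e-3
  tr$batch_size <- 1L
  tr$max_epochs <- 200L
  tr$augment <- FALSE
  set.seed(11)
  fit <- train_unet(m, patches, tr, default_config()$weighting)
  expect_lt(min(fit$history$train_loss), 0.1 * init_loss)
  # fixed seed: bit-identical history across runs
  set.seed(11)
  fit2 <- train_unet(build_model(cfg, seed = 11), patches, tr,
                     default_config()$weighting)
  expect_identical(fit$history$train_loss, fit2$history$train_loss)
})

test_that("tiled prediction equals untiled for a same-convolution model", {
  cfg <- unet_config(2L, 4L, c(16L, 16L, 8L), conv_mode = "same")
  m <- build_model(cfg, seed = 13)
  d <- c(32L, 32L, 16L)
  set.seed(13)
  img <- array(runif(prod(d)) * 65535, d)
  tiled <- predict_volume(m, img, cfg)
  whole_cfg <- unet_config(2L, 4L, d, conv_mode = "same")
  untiled <- predict_volume(m, img, whole_cfg)
  expect_equal(tiled$probs, untiled$probs, tolerance = 1e-12)
  expect_identical(tiled$labels$labels, untiled$labels$labels)
})

test_that("masked metrics reproduce precision/recall/F1 identities", {
  # pred == gt: perfect metrics for present classes
  g <- array(sample(0:2, 6 * 6 * 4, TRUE), c(6, 6, 4))
  r <- evaluate(g, g, Inf)
  expect_equal(r$metrics$precision, c(1, 1))
  expect_equal(r$metrics$recall, c(1, 1))
  expect_equal(r$f1_mean, 1)
  # constructed confusion: TP = 3, FP = 1, FN = 1 for the spine class
  gt <- array(0L, c(8, 1, 1))
  pr <- array(0L, c(8, 1, 1))
  gt[1:4] <- 2L
  pr[1:3] <- 2L  # 3 TP, 1 FN
  pr[5] <- 2L    # 1 FP
  rep2 <- evaluate(pr, gt, Inf)
  sp <- rep2$metrics[rep2$metrics$class == "spine", ]
  expect_equal(c(sp$TP, sp$FP, sp$FN), c(3, 1, 1))
  expect_equal(c(sp$precision, sp$recall, sp$f1), c(0.75, 0.75, 0.75))
  # infinite radius equals unmasked; a finite mask restricts the domain
  ph <- generate_phantom(phantom_cfg(shape = c(32L, 32L, 16L),
                                     neck_break_probability = 0), seed = 17)
  noisy <- ph$clean_labels$labels
  set.seed(17)
  flip <- sample(length(noisy), 200)
  noisy[flip] <- (noisy[flip] + 1L) %% 3L
  full <- evaluate(noisy, ph$clean_labels, Inf)
  wide <- evaluate(noisy, ph$clean_labels, 1e6)
  expect_equal(full$metrics, wide$metrics)
  # report prints the per-class table with an F1 mean line
  out <- capture.output(print(full))
  expect_true(any(grepl("F1-score mean", out)))
  expect_true(any(grepl("Dendritic shaft", out)))
})
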