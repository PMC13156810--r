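test_that("encoder stage bookkeeping halves the spatial size per stage", {
  cfg <- unet2d_config()  # 8 encoder / 7 decoder stages
  expect_equal(cfg$decoder_stages, cfg$encoder_stages - 1L)
  sh <- unet_shapes(cfg, c(512L, 512L))
  expect_equal(unname(sh[8, ]), c(512L, 512L) / 2L^7L)
  # deepest feature map of a desk-sized net
  cfg4 <- unet2d_config(4L, 4L, 32L)
  expect_equal(unname(unet_shapes(cfg4, c(96L, 96L))[4, ]), c(12L, 12L))
})

test_that("model builds are seeded and predictions are input-shaped", {
  cfg <- unet2d_config(3L, 2L, 8L)
  a <- build_locnet(cfg, seed = 4L)
  b <- build_locnet(cfg, seed = 4L)
  expect_identical(a$params, b$params)
  expect_gt(n_params(a), 0)
  x <- matrix(stats::rnorm(40 * 52), 40, 52)  # not divisible by 4: padded
  p <- unet_predict(a, x)
  expect_equal(dim(p), dim(x))
  expect_true(all(p > 0 & p < 1))
})

test_that("zero-epoch training leaves the model untouched", {
  cfg <- unet2d_config(3L, 2L, 8L)
  m <- build_locnet(cfg, seed = 1L)
  sl <- list(list(x = matrix(stats::rnorm(64), 8, 8), y = matrix(0L, 8, 8)))
  fit <- train_locnet(m, sl, train_schedule(batch_size = 2L, total_epochs = 0L))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history), 0)
  expect_error(train_locnet(m, list(), train_schedule(total_epochs = 1L)),
               "empty dataset")
})

test_that("fifty optimizer steps on one slice cut the training loss by half", {
  ph <- desk_phantom(seed = 11L)
  zn <- znorm(ph$image)
  infl <- inflate_labels(ph$label, inflation_spec(0.5))
  k <- which(apply(ph$label$mask, 1, sum) > 0)[10]
  x <- array(zn$values[k, , ], c(96, 96, 1, 1))
  t <- array(infl$mask[k, , ], c(96, 96, 1, 1))
  ug <- getFromNamespace("unet_loss_grads", "carotidseg")
  sg <- getFromNamespace("sgd_nesterov_step", "carotidseg")
  sched <- train_schedule(total_epochs = 1000L)  # standard decay, early phase
  m <- build_locnet(unet2d_config(4L, 4L, 32L), seed = 2L)
  l0 <- ug(m, x, t)$loss
  state <- NULL
  for (i in 1:50) {
    lg <- ug(m, x, t)
    st <- sg(m$params, lg$grads, state, lr_schedule(i - 1L, sched), 0.99)
    m$params <- st$params; state <- st$state
  }
  expect_lte(ug(m, x, t)$loss, 0.5 * l0)
})

test_that("brief training localizes phantom slices (Dice >= 0.8 vs inflated target)", {
  ph <- desk_phantom(seed = 3L)
  zn <- znorm(ph$image)
  infl <- inflate_labels(ph$label, inflation_spec(0.5))
  labeled <- which(apply(infl$mask, 1, sum) > 0)
  ks <- labeled[round(seq(2, length(labeled) - 1, length.out = 8))]
  slices <- lapply(ks, function(k) list(x = zn$values[k, , ], y = infl$mask[k, , ]))
  cfg <- unet2d_config(4L, 4L, 32L)
  fit <- train_locnet(build_locnet(cfg, seed = 2L), slices,
                      train_schedule(batch_size = 8L, total_epochs = 20L, seed = 5L),
                      steps_per_epoch = 5L)
  dvals <- vapply(slices, function(s)
    dice_of(unet_predict(fit$model, s$x) >= 0.5, s$y == 1L), numeric(1))
  expect_gte(mean(dvals), 0.8)
})

test_that("ROI prediction yields containing crop boxes and flags empty output", {
  ph <- desk_phantom(seed = 8L)
  pl <- roi_from_label(ph$label, margin = 8L)
  idx <- which(ph$label$mask == 1L, arr.ind = TRUE)
  expect_true(all(sweep(idx, 2, pl$lo, ">=") & sweep(idx, 2, pl$hi, "<=")))
  # degenerate single-voxel ROI with zero margin
  m <- array(0L, c(12L, 12L, 12L)); m[5, 7, 9] <- 1L
  pl0 <- roi_from_label(lumen_label(m, c(1, 1, 1)), margin = 0L)
  expect_equal(pl0$lo, c(5L, 7L, 9L))
  expect_equal(pl0$hi, c(5L, 7L, 9L))
  empty <- lumen_label(array(0L, c(8L, 8L, 8L)), c(1, 1, 1))
  expect_error(roi_from_label(empty), class = "carotidseg_no_roi")
  # an untrained wide-bias model predicting nothing raises the same signal
  cfg <- unet2d_config(3L, 2L, 8L)
  mdl <- build_locnet(cfg, seed = 1L)
  vol <- volume_image(array(0, c(4L, 16L, 16L)), c(1, 1, 1))
  expect_error(predict_roi(mdl, vol, threshold = 1.01),
               class = "carotidseg_no_roi")
})

test_that("crop and embed are exact inverses on the box", {
  ph <- desk_phantom(seed = 2L, grid = c(40L, 56L, 56L), segment_length = 8)
  vol <- ph$image; lab <- ph$label
  pl <- roi_from_label(lab, margin = 4L)
  cr <- crop_to_roi(vol, lab, pl)
  emb <- embed_from_roi(cr$label, pl)
  expect_identical(emb$mask[pl$lo[1]:pl$hi[1], pl$lo[2]:pl$hi[2], pl$lo[3]:pl$hi[3]],
                   cr$label$mask)
  outside <- emb$mask
  outside[pl$lo[1]:pl$hi[1], pl$lo[2]:pl$hi[2], pl$lo[3]:pl$hi[3]] <- 0L
  expect_equal(sum(outside), 0)
  # full-volume box is the identity
  full <- roi_placement(c(1, 1, 1), dim(lab$mask), dim(lab$mask))
  expect_identical(crop_to_roi(vol, lab, full)$label$mask, lab$mask)
  # random boxes match direct slicing (oracle)
  set.seed(31)
  for (i in 1:20) {
    d <- dim(lab$mask)
    lo <- vapply(d, function(n) sample.int(n - 2L, 1L), integer(1))
    hi <- pmin(lo + vapply(d, function(n) sample.int(6L, 1L), integer(1)), d)
    pl2 <- roi_placement(lo, hi, d)
    cr2 <- crop_to_roi(vol, lab, pl2)
    expect_identical(cr2$label$mask,
                     lab$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
  }
  expect_error(roi_placement(c(0, 1, 1), c(4, 4, 4), c(8, 8, 8)), "bounds")
})
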