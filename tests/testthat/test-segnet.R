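test_that("polynomial decay matches its closed form and boundary values", {
  sched <- train_schedule(total_epochs = 1000L, initial_lr = 0.01,
                          poly_exponent = 0.9)
  expect_identical(lr_schedule(0, sched), 0.01)
  expect_identical(lr_schedule(1000, sched), 0)
  expect_equal(lr_schedule(500, sched), 0.0053589, tolerance = 1e-5)
  # oracle: direct formula at 100 random epochs; strictly decreasing
  set.seed(1)
  eps <- sort(sample(0:1000, 100))
  vals <- vapply(eps, lr_schedule, numeric(1), sched = sched)
  expect_equal(vals, 0.01 * (1 - eps / 1000)^0.9, tolerance = 1e-14)
  expect_true(all(diff(vapply(0:1000, lr_schedule, numeric(1), sched = sched)) < 0))
  expect_error(lr_schedule(1001, sched), "range")
  expect_error(lr_schedule(-1, sched), "range")
})

test_that("patch cropping is exhaustive at exact fit and seeded otherwise", {
  v <- volume_image(array(stats::rnorm(16 * 24 * 24), c(16, 24, 24)), c(1, 1, 1))
  l <- lumen_label(array(as.integer(stats::runif(16 * 24 * 24) < 0.1),
                         c(16, 24, 24)), c(1, 1, 1))
  sp <- patch_spec(4L, c(16L, 24L, 24L), seed = 3L)
  ps <- crop_patches(v, l, sp)
  expect_length(ps, 4L)
  for (p in ps) {
    expect_identical(p$x, v$values)
    expect_identical(p$y, l$mask)
  }
  sp2 <- patch_spec(4L, c(8L, 8L, 8L), seed = 3L)
  a <- crop_patches(v, l, sp2)
  b <- crop_patches(v, l, sp2)
  expect_identical(a, b)
  c_ <- crop_patches(v, l, patch_spec(4L, c(8L, 8L, 8L), seed = 4L))
  expect_false(identical(a, c_))
  for (p in a) expect_equal(dim(p$x), c(8L, 8L, 8L))
})

test_that("combined loss matches a hand-coded scalar evaluation", {
  # perfect prediction (clamped binary probabilities)
  t <- array(c(1, 0, 1, 0), c(2, 2, 1, 1))
  p_perfect <- array(pmin(pmax(t, 1e-7), 1 - 1e-7), dim(t))
  expect_lte(combined_loss(p_perfect, t), 1e-5)
  # total miss on a half-foreground patch drives the Dice term to ~1
  p_miss <- array(1 - t, dim(t))
  eps <- 1e-7
  bce_miss <- -mean(t * log(eps) + (1 - t) * log(eps))
  dice_term <- 1 - (2 * sum(pmin(pmax(1 - t, eps), 1 - eps) * t) + 1e-5) /
    (sum(1 - t) + sum(t) + 1e-5)
  expect_equal(combined_loss(p_miss, t), bce_miss + dice_term, tolerance = 1e-6)
  expect_gt(dice_term, 0.99)
  # 2x2 hand-evaluated case
  p <- array(c(0.9, 0.1, 0.8, 0.2), c(2, 2, 1, 1))
  bce <- -mean(c(log(0.9), log(0.9), log(0.8), log(0.8)))
  sdice <- (2 * (0.9 + 0.8) + 1e-5) / ((0.9 + 0.1 + 0.8 + 0.2) + 2 + 1e-5)
  expect_equal(combined_loss(p, t), bce + (1 - sdice), tolerance = 1e-10)
  expect_error(combined_loss(p, array(0, c(3, 1, 1, 1))), "shape")
  expect_error(combined_loss(p, t, weights = c(bce = 0, dice = 1)), "positive")
})

test_that("loss gradients descend on a fixed batch", {
  cfg <- unet3d_config(3L, 2L, 8L, 1L)
  m <- build_unet(cfg, seed = 6L)
  set.seed(7)
  x <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  t <- array(as.integer(stats::runif(512) < 0.2), c(8, 8, 8, 1))
  ug <- getFromNamespace("unet_loss_grads", "carotidseg")
  sg <- getFromNamespace("sgd_nesterov_step", "carotidseg")
  l0 <- ug(m, x, t)$loss
  state <- NULL
  for (i in 1:15) {
    lg <- ug(m, x, t)
    stp <- sg(m$params, lg$grads, state, lr = 0.01, momentum = 0.9)
    m$params <- stp$params; state <- stp$state
  }
  expect_lt(ug(m, x, t)$loss, l0)
})

test_that("stratified folds partition lesions with balanced validation sets", {
  man <- as_manifest(data.frame(
    lesion_id = sprintf("l%02d", 1:10),
    grade = rep(c("severe", "moderate"), each = 5),
    stringsAsFactors = FALSE))
  fs <- make_folds(man, k = 5L, seed = 2L, stratify_scanner = FALSE)
  expect_equal(fs$k, 5L)
  # each validation fold holds 2 lesions, one of each grade
  for (f in 1:5) {
    val <- fs$folds[[f]]$val
    expect_length(val, 2L)
    expect_setequal(man$grade[match(val, man$lesion_id)], c("severe", "moderate"))
    expect_setequal(c(fs$folds[[f]]$train, val), man$lesion_id)
  }
  # validation sets are disjoint and cover everything
  allval <- unlist(lapply(fs$folds, `[[`, "val"))
  expect_setequal(allval, man$lesion_id)
  expect_equal(anyDuplicated(allval), 0L)
  expect_warning(make_folds(man[1:6, ], k = 5L, seed = 1L), "fewer than k")
  expect_error(make_folds(man[1:3, ], k = 5L), "at least k")
})

test_that("segnet training is skippable, seeded, and overfits one phantom", {
  ph <- desk_phantom(seed = 13L, grid = c(48L, 72L, 72L), segment_length = 11)
  zn <- znorm(ph$image)
  cr <- crop_to_roi(zn, ph$label, roi_from_label(ph$label, margin = 6L))
  cfg <- unet3d_config(4L, 4L, 32L, 1L)
  m0 <- build_segnet(cfg, seed = 3L)
  fit0 <- train_segnet(m0, list(list(vol = cr$vol, label = cr$label)),
                       train_schedule(batch_size = 2L, total_epochs = 0L))
  expect_identical(fit0$model$params, m0$params)
  fit <- train_segnet(m0, list(list(vol = cr$vol, label = cr$label)),
                      train_schedule(batch_size = 2L, total_epochs = 25L, seed = 9L),
                      patch_spec(2L, c(32L, 32L, 32L)))
  pred <- ensemble_predict(fit$model, cr$vol)
  expect_gte(dice_of(pred$mask == 1L, cr$label$mask == 1L), 0.8)
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_error(train_segnet(m0, list(), train_schedule(total_epochs = 1L)),
               "empty fold")
})

test_that("fold ensembling averages probabilities before thresholding", {
  # constant-output models: all conv weights zero, head bias fixes the logit
  cfg <- unet3d_config(2L, 2L, 4L, 1L)
  mk_const <- function(p_out) {
    m <- build_unet(cfg, seed = 1L)
    m$params <- rapply(m$params, function(x) x * 0, how = "replace")
    nh <- length(m$params$dec)
    m$params$dec[[nh]]$head$b <- stats::qlogis(p_out)
    m
  }
  vol <- volume_image(array(0, c(8L, 8L, 8L)), c(1, 1, 1))
  m8 <- mk_const(0.8); m4 <- mk_const(0.4)
  # single model equals its thresholded output
  expect_true(all(ensemble_predict(m8, vol)$mask == 1L))
  expect_true(all(ensemble_predict(m4, vol)$mask == 0L))
  # five copies of one model equal the single model
  expect_identical(ensemble_predict(rep(list(m4), 5), vol)$mask,
                   ensemble_predict(m4, vol)$mask)
  # mean(0.8, 0.4) = 0.6 -> foreground
  expect_true(all(ensemble_predict(list(m8, m4), vol)$mask == 1L))
  expect_error(ensemble_predict(list(), vol), "at least one")
})

test_that("model checkpoints round-trip through disk", {
  cfg <- unet3d_config(2L, 2L, 4L, 1L)
  m <- build_unet(cfg, seed = 5L)
  p <- file.path(tempdir(), "ckpt.rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(m2$params, m$params)
  expect_identical(m2$cfg, m$cfg)
  unlink(p)
})
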