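test_that("resample computes the rounded output shape and preserves extent", {
  v <- volume_image(array(stats::rnorm(1000), c(10, 10, 10)), c(1, 1, 1))
  out <- resample(v, c(0.59, 0.46, 0.46))
  expect_equal(dim(out$values), c(17L, 22L, 22L))
  # identity when target equals input spacing
  same <- resample(v, c(1, 1, 1))
  expect_identical(same$values, v$values)
  # labels go nearest and stay binary
  lab <- lumen_label(array(as.integer(stats::runif(1000) < 0.3), c(10, 10, 10)),
                     c(1, 1, 1))
  lr <- resample(lab, c(0.59, 0.46, 0.46))
  expect_true(all(lr$mask %in% c(0L, 1L)))
  expect_error(resample(v, c(0, 1, 1)), "positive")
})

test_that("resample round trip preserves labeled volume for lumen-sized objects", {
  tub <- straight_tube(radius = 3, length = 30, grid = c(90L, 40L, 40L),
                       spacing = c(0.5, 0.5, 0.5))
  down <- resample(tub, c(0.59, 0.46, 0.46))
  back <- resample(down, c(0.5, 0.5, 0.5))
  vol_mm <- function(l) sum(l$mask) * prod(l$spacing)
  expect_lt(abs(vol_mm(back) - vol_mm(tub)) / vol_mm(tub), 0.05)
})

test_that("znorm yields zero mean, unit population sd, and zero on constants", {
  v <- volume_image(array(c(1, 2, 3), c(3, 1, 1)), c(1, 1, 1))
  z <- znorm(v)
  expect_equal(as.numeric(z$values), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  cv <- volume_image(array(5, c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(znorm(cv)$values == 0))
  r <- znorm(volume_image(array(stats::rnorm(4096, 7, 3), c(16, 16, 16)), c(1, 1, 1)))
  expect_lt(abs(mean(r$values)), 1e-6)
  expect_lt(abs(sqrt(mean(r$values^2)) - 1), 1e-6)
})

test_that("slice_center is the coordinate mean and translation-equivariant", {
  expect_equal(slice_center(matrix(c(5, 7), 1)), c(5, 7))
  corners <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  expect_equal(slice_center(corners), c(1, 1))
  shift <- sweep(corners, 2, c(3, -4), "+")
  expect_equal(slice_center(shift), c(1, 1) + c(3, -4))
  expect_error(slice_center(matrix(numeric(0), 0, 2)), "empty")
})

test_that("inflation radius follows the equivalent-circle formula", {
  spec <- inflation_spec(epsilon = 0, pixel_length = 0.46, pixel_width = 0.46)
  expect_equal(inflation_radius(100, spec), 0.46 * sqrt(100 / pi), tolerance = 1e-12)
  expect_equal(inflation_radius(100, spec), 2.5953, tolerance = 1e-4)
  expect_equal(inflation_radius(0, spec), 0)
  # epsilon = 1 doubles the epsilon = 0 radius exactly
  s1 <- inflation_spec(1, 0.46, 0.46)
  for (n in c(1, 17, 100, 4096))
    expect_identical(inflation_radius(n, s1), 2 * inflation_radius(n, spec))
  # conformance against an independent area-based computation, 100 random slices
  set.seed(42)
  for (i in 1:100) {
    n <- sample.int(5000, 1)
    eps <- stats::runif(1)
    l <- stats::runif(1, 0.2, 1); w <- stats::runif(1, 0.2, 1)
    area_mm2 <- n * l * w
    oracle <- sqrt((1 + eps)^2 * area_mm2 / pi)
    got <- inflation_radius(n, inflation_spec(eps, l, w))
    expect_lt(abs(got - oracle) / oracle, 1e-12)
  }
})

test_that("inflate_labels unions a centered disk over the slice labels", {
  # synthetic filled disk on one slice
  n <- 64
  m <- array(0L, c(3, n, n))
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n)
    if ((i - ctr)^2 + (j - ctr)^2 <= 8^2) m[2, i, j] <- 1L
  lab <- lumen_label(m, c(1, 0.5, 0.5))
  out0 <- inflate_labels(lab, inflation_spec(0))
  # superset rule and slice preservation
  expect_true(all(out0$mask[m == 1L] == 1L))
  expect_equal(sum(out0$mask[1, , ]), 0)
  expect_equal(sum(out0$mask[3, , ]), 0)
  # a disk about the centroid of a disk roughly re-covers it
  expect_lte(sum(out0$mask[2, , ]) / sum(m[2, , ]), 1.6)
  # quadrupled disk area when epsilon goes 0 -> 1 (up to rasterization)
  out1 <- inflate_labels(lab, inflation_spec(1))
  expect_equal(sum(out1$mask[2, , ]) / sum(out0$mask[2, , ]), 4, tolerance = 0.1)
  # inflation never removes a labeled pixel on a phantom either
  ph <- desk_phantom(noise_sd = 0)
  infl <- inflate_labels(ph$label, inflation_spec(0.5))
  expect_true(all(infl$mask[ph$label$mask == 1L] == 1L))
})

test_that("augmentation honors probabilities, involution and seeding", {
  ph <- desk_phantom(grid = c(40L, 56L, 56L), segment_length = 8, noise_sd = 4)
  zn <- znorm(ph$image)
  off <- augment_spec(p_rotate = 0, p_scale = 0, p_flip = 0, p_noise = 0,
                      p_smooth = 0, p_intensity = 0, p_gamma = 0)
  id <- augment(zn, ph$label, off, seed = 1L)
  expect_identical(id$vol$values, zn$values)
  expect_identical(id$label$mask, ph$label$mask)
  # same seed, same transform draw
  spec <- augment_spec()
  a <- augment(zn, ph$label, spec, seed = 9L)
  b <- augment(zn, ph$label, spec, seed = 9L)
  expect_identical(a$vol$values, b$vol$values)
  expect_identical(a$label$mask, b$label$mask)
  # flip twice along the same axis is the identity
  flipped <- zn$values[dim(zn$values)[1]:1, , , drop = FALSE]
  flipped2 <- flipped[dim(flipped)[1]:1, , , drop = FALSE]
  expect_identical(flipped2, zn$values)
  expect_error(augment_spec(p_flip = 2), "probabilities")
})
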