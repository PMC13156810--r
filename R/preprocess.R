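#' Resample a volume or label to a target voxel spacing
#'
#' The output grid has shape \code{round(shape * spacing / target)} (at least
#' 1 per axis) and shares the input origin, so the world extent is preserved
#' to within a voxel. Images are interpolated trilinearly, labels with
#' nearest-neighbor; the default target spacing of
#' \code{c(0.59, 0.46, 0.46)} mm harmonizes scans from different scanners
#' before the networks see them.
#'
#' @param vol a [volume_image()] or [lumen_label()].
#' @param target_spacing positive mm triple.
#' @param mode \code{"linear"} or \code{"nearest"}; labels always use nearest.
#' @return resampled object of the same class.
#' @export
resample <- function(vol, target_spacing = c(0.59, 0.46, 0.46),
                     mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  target_spacing <- as.numeric(target_spacing)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be strictly positive")
  is_label <- inherits(vol, "lumen_label")
  if (is_label) mode <- "nearest"
  arr <- if (is_label) vol$mask else vol$values
  in_shape <- dim(arr); in_sp <- vol$spacing
  out_shape <- pmax(1L, as.integer(round(in_shape * in_sp / target_spacing)))
  if (identical(out_shape, in_shape) &&
      max(abs(in_sp - target_spacing)) < 1e-12) return(vol)
  # input (0-based) index coordinates of the output voxel centers
  ix <- lapply(1:3, function(k) (0:(out_shape[k] - 1)) * target_spacing[k] / in_sp[k])
  out <- array(if (is_label) 0L else 0, out_shape)
  if (mode == "nearest") {
    ii <- lapply(1:3, function(k) pmin(pmax(round(ix[[k]]), 0), in_shape[k] - 1) + 1L)
    out <- arr[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
    dim(out) <- out_shape
  } else {
    f0 <- lapply(1:3, function(k) pmin(pmax(floor(ix[[k]]), 0), in_shape[k] - 1))
    f1 <- lapply(1:3, function(k) pmin(f0[[k]] + 1, in_shape[k] - 1))
    w1 <- lapply(1:3, function(k) pmin(pmax(ix[[k]] - f0[[k]], 0), 1))
    # slice-wise trilinear gather keeps peak memory at one output slice
    i2_0 <- f0[[2]] + 1L; i2_1 <- f1[[2]] + 1L
    i3_0 <- f0[[3]] + 1L; i3_1 <- f1[[3]] + 1L
    w2 <- matrix(w1[[2]], out_shape[2], out_shape[3])
    w3 <- matrix(rep(w1[[3]], each = out_shape[2]), out_shape[2], out_shape[3])
    for (o1 in seq_len(out_shape[1])) {
      a <- f0[[1]][o1] + 1L; b <- f1[[1]][o1] + 1L; wa <- w1[[1]][o1]
      plane <- function(i1) {
        s <- arr[i1, , , drop = TRUE]
        (s[i2_0, i3_0] * (1 - w2) + s[i2_1, i3_0] * w2) * (1 - w3) +
        (s[i2_0, i3_1] * (1 - w2) + s[i2_1, i3_1] * w2) * w3
      }
      out[o1, , ] <- plane(a) * (1 - wa) + if (wa > 0) plane(b) * wa else 0
    }
  }
  if (is_label) lumen_label(out, target_spacing, vol$origin)
  else volume_image(out, target_spacing, vol$origin)
}

#' Z-score normalize a volume
#'
#' Subtracts the mean and divides by the population standard deviation, so
#' the output has mean 0 and sd 1. A constant input maps to all zeros.
#'
#' @param vol a [volume_image()].
#' @return normalized [volume_image()].
#' @export
znorm <- function(vol) {
  v <- vol$values
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  out <- if (sd_pop == 0) array(0, dim(v)) else (v - mu) / sd_pop
  volume_image(out, vol$spacing, vol$origin)
}

#' Inflation specification for building the localization target
#'
#' Controls how far each slice's labeled area is inflated into a disk:
#' the disk radius is \code{(1 + epsilon)} times the equivalent-circle radius
#' of the labeled area, \code{r = (1 + epsilon) * sqrt(l * w * N / pi)},
#' where \code{l}, \code{w} are the in-plane pixel dimensions (mm) and
#' \code{N} the labeled-pixel count.
#'
#' @param epsilon inflation factor in \code{[0, 1]}.
#' @param pixel_length,pixel_width in-plane pixel dimensions, mm.
#' @return list of class \code{inflation_spec}.
#' @export
inflation_spec <- function(epsilon = 0.5, pixel_length = 0.46,
                           pixel_width = 0.46) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (pixel_length <= 0 || pixel_width <= 0) stop("pixel dims must be > 0")
  structure(list(epsilon = epsilon, pixel_length = pixel_length,
                 pixel_width = pixel_width), class = "inflation_spec")
}

#' Center of the labeled pixels of one slice
#'
#' The ROI center of a slice is the arithmetic mean of its labeled pixel
#' coordinates (real-valued, not rounded).
#'
#' @param coords N x 2 matrix of labeled pixel coordinates (rows: pixels).
#' @return length-2 numeric center.
#' @export
slice_center <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) == 0) stop("empty slice: no center defined")
  colMeans(coords)
}

#' Inflation radius of one slice
#'
#' \code{r = (1 + epsilon) * sqrt(l * w * N / pi)} mm: the equivalent-circle
#' radius of the slice's labeled area, scaled by the inflation factor.
#' \code{N = 0} gives \code{r = 0}.
#'
#' @param n_labeled labeled-pixel count N of the slice.
#' @param spec an [inflation_spec()].
#' @return radius in mm.
#' @export
inflation_radius <- function(n_labeled, spec) {
  stopifnot(n_labeled >= 0)
  (1 + spec$epsilon) * sqrt(spec$pixel_length * spec$pixel_width * n_labeled / pi)
}

#' Inflate a lumen label into a localization target
#'
#' Per slice, the output is the union of the original labeled pixels and the
#' rasterized disk of [inflation_radius()] about the slice's [slice_center()]
#' (pixel-center-in-circle rule, distances in mm). Empty slices stay empty.
#' The inflated label is the training target of the localization network: it
#' marks the region of interest around the artery rather than the lumen
#' itself, guaranteeing coverage.
#'
#' @param label a [lumen_label()].
#' @param spec an [inflation_spec()]; its pixel dimensions are overridden by
#'   the label's in-plane spacing.
#' @return inflated [lumen_label()].
#' @export
inflate_labels <- function(label, spec = inflation_spec()) {
  sp <- label$spacing
  spec <- inflation_spec(spec$epsilon, sp[2], sp[3])
  m <- label$mask
  dims <- dim(m)
  out <- m
  for (i in seq_len(dims[1])) {
    sl <- m[i, , ]
    n <- sum(sl)
    if (n == 0) next
    coords <- which(sl == 1L, arr.ind = TRUE)
    ctr <- slice_center(coords)
    r <- inflation_radius(n, spec)
    # bounding box of the disk, then exact mm-distance test
    r_row <- ceiling(r / sp[2]); r_col <- ceiling(r / sp[3])
    rows <- max(1, floor(ctr[1] - r_row)):min(dims[2], ceiling(ctr[1] + r_row))
    cols <- max(1, floor(ctr[2] - r_col)):min(dims[3], ceiling(ctr[2] + r_col))
    d2 <- outer(((rows - ctr[1]) * sp[2])^2, ((cols - ctr[2]) * sp[3])^2, "+")
    disk <- d2 <= r^2
    out[i, rows, cols] <- as.integer(out[i, rows, cols] | disk)
  }
  lumen_label(out, label$spacing, label$origin)
}

#' Augmentation specification
#'
#' The augmentation families applied during training: in-plane rotation,
#' isotropic scaling, per-axis flips, additive Gaussian noise, Gaussian
#' smoothing, intensity scaling and gamma contrast adjustment. Each transform
#' fires independently with its own probability; ranges follow common
#' volumetric-segmentation practice and are all configurable.
#'
#' @param p_rotate,p_scale,p_flip,p_noise,p_smooth,p_intensity,p_gamma
#'   per-transform probabilities in \code{[0, 1]}.
#' @param rotate_deg max in-plane rotation magnitude, degrees.
#' @param scale_range isotropic scale factor range.
#' @param noise_sd_range additive noise sd range (in normalized units).
#' @param smooth_sigma_range Gaussian smoothing sigma range, voxels.
#' @param intensity_range multiplicative intensity factor range.
#' @param gamma_range gamma contrast exponent range.
#' @return list of class \code{augment_spec}.
#' @export
augment_spec <- function(p_rotate = 0.2, p_scale = 0.2, p_flip = 0.5,
                         p_noise = 0.15, p_smooth = 0.15,
                         p_intensity = 0.15, p_gamma = 0.15,
                         rotate_deg = 30, scale_range = c(0.7, 1.4),
                         noise_sd_range = c(0, 0.1),
                         smooth_sigma_range = c(0.5, 1.0),
                         intensity_range = c(0.75, 1.25),
                         gamma_range = c(0.7, 1.5)) {
  ps <- c(p_rotate, p_scale, p_flip, p_noise, p_smooth, p_intensity, p_gamma)
  if (any(ps < 0 | ps > 1)) stop("probabilities must be in [0, 1]")
  if (scale_range[1] <= 0 || gamma_range[1] <= 0) stop("invalid range")
  structure(list(p_rotate = p_rotate, p_scale = p_scale, p_flip = p_flip,
                 p_noise = p_noise, p_smooth = p_smooth,
                 p_intensity = p_intensity, p_gamma = p_gamma,
                 rotate_deg = rotate_deg, scale_range = scale_range,
                 noise_sd_range = noise_sd_range,
                 smooth_sigma_range = smooth_sigma_range,
                 intensity_range = intensity_range,
                 gamma_range = gamma_range), class = "augment_spec")
}

default_augment_spec <- function() unclass(augment_spec())

# in-plane (axes 2,3) rotation about the slice-plane center; bilinear for
# images, nearest for labels
rotate_inplane <- function(arr, angle_deg, mode = "linear") {
  d <- dim(arr)
  th <- angle_deg * pi / 180
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  gy <- matrix(seq_len(d[2]) - cy, d[2], d[3])
  gx <- matrix(rep(seq_len(d[3]) - cx, each = d[2]), d[2], d[3])
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  out <- array(0, d)
  if (mode == "nearest") {
    iy <- pmin(pmax(round(sy), 1), d[2]); ix <- pmin(pmax(round(sx), 1), d[3])
    idx <- cbind(as.vector(iy), as.vector(ix))
    for (i in seq_len(d[1])) {
      sl <- arr[i, , ]
      out[i, , ] <- matrix(sl[idx], d[2], d[3])
    }
  } else {
    y0 <- pmin(pmax(floor(sy), 1), d[2]); y1 <- pmin(y0 + 1, d[2])
    x0 <- pmin(pmax(floor(sx), 1), d[3]); x1 <- pmin(x0 + 1, d[3])
    wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
    i00 <- cbind(as.vector(y0), as.vector(x0)); i10 <- cbind(as.vector(y1), as.vector(x0))
    i01 <- cbind(as.vector(y0), as.vector(x1)); i11 <- cbind(as.vector(y1), as.vector(x1))
    for (i in seq_len(d[1])) {
      sl <- arr[i, , ]
      v <- (sl[i00] * (1 - wy) + sl[i10] * wy) * (1 - wx) +
           (sl[i01] * (1 - wy) + sl[i11] * wy) * wx
      out[i, , ] <- matrix(v, d[2], d[3])
    }
  }
  out
}

# separable Gaussian smoothing along all three axes, sigma in voxels
gaussian_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2)); k <- k / sum(k)
  sm_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - rad - 1L
      src <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
      out <- out + k[j] * switch(axis,
        a[src, , , drop = FALSE], a[, src, , drop = FALSE], a[, , src, drop = FALSE])
    }
    out
  }
  sm_axis(sm_axis(sm_axis(arr, 1L), 2L), 3L)
}

#' Apply seeded augmentation to an image/label pair
#'
#' Spatial transforms (rotation, scaling, flips) are applied identically to
#' image and label, with nearest-neighbor resampling for the label; intensity
#' transforms (noise, smoothing, scaling, gamma) touch the image only. The
#' same seed reproduces the same transform draw bit-identically.
#'
#' @param vol a [volume_image()] (typically already z-normalized).
#' @param label the aligned [lumen_label()].
#' @param spec an [augment_spec()].
#' @param seed integer seed.
#' @return list with transformed \code{vol} and \code{label}.
#' @export
augment <- function(vol, label, spec = augment_spec(), seed = 1L) {
  check_aligned(vol, label)
  v <- vol$values; m <- label$mask
  draws <- with_seed(seed, list(
    u = stats::runif(9),
    angle = stats::runif(1, -spec$rotate_deg, spec$rotate_deg),
    scale = stats::runif(1, spec$scale_range[1], spec$scale_range[2]),
    flips = stats::runif(3) < 0.5,
    noise_sd = stats::runif(1, spec$noise_sd_range[1], spec$noise_sd_range[2]),
    sigma = stats::runif(1, spec$smooth_sigma_range[1], spec$smooth_sigma_range[2]),
    ifac = stats::runif(1, spec$intensity_range[1], spec$intensity_range[2]),
    gam = stats::runif(1, spec$gamma_range[1], spec$gamma_range[2]),
    noise_seed = sample.int(1e6, 1)))
  u <- draws$u
  if (u[1] < spec$p_rotate) {
    v <- rotate_inplane(v, draws$angle, "linear")
    m <- rotate_inplane(m, draws$angle, "nearest")
  }
  if (u[2] < spec$p_scale) {
    # zoom about the volume center, output on the same grid
    sc <- draws$scale
    d <- dim(v)
    src <- lapply(d, function(n) {
      ctr <- (n + 1) / 2
      pmin(pmax(round(ctr + (seq_len(n) - ctr) / sc), 1L), n)
    })
    v <- v[src[[1]], src[[2]], src[[3]], drop = FALSE]
    m <- m[src[[1]], src[[2]], src[[3]], drop = FALSE]
    dim(v) <- d; dim(m) <- d
  }
  if (u[3] < spec$p_flip && draws$flips[1]) { v <- v[dim(v)[1]:1, , , drop = FALSE]; m <- m[dim(m)[1]:1, , , drop = FALSE] }
  if (u[4] < spec$p_flip && draws$flips[2]) { v <- v[, dim(v)[2]:1, , drop = FALSE]; m <- m[, dim(m)[2]:1, , drop = FALSE] }
  if (u[5] < spec$p_flip && draws$flips[3]) { v <- v[, , dim(v)[3]:1, drop = FALSE] ; m <- m[, , dim(m)[3]:1, drop = FALSE] }
  if (u[6] < spec$p_noise && draws$noise_sd > 0)
    v <- v + with_seed(draws$noise_seed,
                       array(stats::rnorm(length(v), 0, draws$noise_sd), dim(v)))
  if (u[7] < spec$p_smooth) v <- gaussian_smooth3(v, draws$sigma)
  if (u[8] < spec$p_intensity) v <- v * draws$ifac
  if (u[9] < spec$p_gamma) {
    rng <- range(v)
    if (diff(rng) > 0) {
      vn <- (v - rng[1]) / diff(rng)
      v <- vn^draws$gam * diff(rng) + rng[1]
    }
  }
  storage.mode(m) <- "integer"
  list(vol = volume_image(v, vol$spacing, vol$origin),
       label = lumen_label(m, label$spacing, label$origin))
}
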