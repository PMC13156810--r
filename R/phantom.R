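#' Specify a focal stenosis on one phantom branch
#'
#' A stenosis narrows the branch radius with a smooth cosine taper: over an
#' arc-length window of \code{length} mm centered at \code{center_arclength},
#' the radius falls from the branch radius to
#' \code{(1 - target_percent/100)} times it at the throat and recovers.
#'
#' @param branch one of \code{"CCA"}, \code{"ICA"}, \code{"ECA"}.
#' @param center_arclength throat position along the branch, mm from its
#'   proximal end.
#' @param length taper window length, mm.
#' @param target_percent NASCET percent diameter reduction at the throat,
#'   in \code{[0, 100)}.
#' @return list of class \code{stenosis_spec}.
#' @export
stenosis_spec <- function(branch, center_arclength, length, target_percent) {
  branch <- match.arg(branch, c("CCA", "ICA", "ECA"))
  if (!is.finite(length) || length <= 0) stop("stenosis length must be > 0")
  if (!is.finite(target_percent) || target_percent < 0 || target_percent >= 100)
    stop("target_percent must be in [0, 100)")
  structure(list(branch = branch, center_arclength = center_arclength,
                 length = length, target_percent = target_percent),
            class = "stenosis_spec")
}

#' Specify a synthetic bifurcating carotid phantom
#'
#' Defines a Y-shaped CCA -> ICA/ECA lumen voxelized on an anisotropic grid,
#' emulating the data regime of neck black-blood MRI: a dark lumen inside a
#' brighter wall ring on a mid-intensity background, with the artery occupying
#' under 0.1 percent of the grid at the default geometry.
#'
#' @param grid_shape integer triple of voxels (slice, row, col).
#' @param spacing mm triple (slice, row, col).
#' @param cca_radius,ica_radius,eca_radius branch radii, mm.
#' @param segment_length branch length, mm (each branch).
#' @param bifurcation_angle full ICA-ECA opening angle, degrees.
#' @param stenosis_list list of [stenosis_spec()] entries.
#' @param lumen_intensity,wall_intensity,background_intensity intensities
#'   (a.u.); the default dark-lumen polarity matches black-blood contrast.
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param wall_thickness bright wall ring thickness, mm.
#' @param margin distance from the CCA origin to the grid face, mm.
#' @param seed integer seed for the noise field.
#' @return list of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(192L, 352L, 352L),
                         spacing = c(0.59, 0.46, 0.46),
                         cca_radius = 3.0, ica_radius = 2.4, eca_radius = 1.8,
                         segment_length = 50, bifurcation_angle = 50,
                         stenosis_list = list(),
                         lumen_intensity = 20, wall_intensity = 120,
                         background_intensity = 60,
                         noise_sd = 8, wall_thickness = 1.0,
                         margin = 3, seed = 7L) {
  if (any(c(cca_radius, ica_radius, eca_radius) <= 0)) stop("radii must be > 0")
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (segment_length <= 0) stop("segment_length must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (inherits(stenosis_list, "stenosis_spec")) stenosis_list <- list(stenosis_list)
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    cca_radius = cca_radius, ica_radius = ica_radius, eca_radius = eca_radius,
    segment_length = segment_length, bifurcation_angle = bifurcation_angle,
    stenosis_list = stenosis_list,
    lumen_intensity = lumen_intensity, wall_intensity = wall_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, wall_thickness = wall_thickness,
    margin = margin, seed = as.integer(seed)), class = "phantom_spec")
  for (st in stenosis_list) {
    if (!inherits(st, "stenosis_spec")) stop("stenosis_list entries must be stenosis_spec")
    lo <- st$center_arclength - st$length / 2
    hi <- st$center_arclength + st$length / 2
    if (lo <= 0 || hi >= segment_length)
      stop("stenosis outside branch arc-length range (0, ", segment_length, ")")
  }
  spec
}

# branch centerline endpoints (world mm) for a phantom spec
phantom_branches <- function(spec) {
  ext <- (spec$grid_shape - 1) * spec$spacing
  cy <- ext[2] / 2; cx <- ext[3] / 2
  a <- spec$bifurcation_angle / 2 * pi / 180
  L <- spec$segment_length
  p0 <- c(spec$margin, cy, cx)
  pb <- p0 + c(L, 0, 0)
  d_ica <- c(cos(a), sin(a), 0)
  d_eca <- c(cos(a), -sin(a), 0)
  list(
    CCA = list(p = rbind(p0, pb), radius = spec$cca_radius),
    ICA = list(p = rbind(pb, pb + L * d_ica), radius = spec$ica_radius),
    ECA = list(p = rbind(pb, pb + L * d_eca), radius = spec$eca_radius)
  )
}

# radius profile along a branch: base radius times the cosine-taper factors
# of the stenoses sitting on it
branch_radius_fn <- function(base_radius, stenoses) {
  force(base_radius); force(stenoses)
  function(s) {
    r <- rep(base_radius, length(s))
    for (st in stenoses) {
      f <- 1 - st$target_percent / 100
      inwin <- abs(s - st$center_arclength) <= st$length / 2
      if (any(inwin)) {
        u <- (s[inwin] - st$center_arclength) / st$length  # in [-1/2, 1/2]
        fac <- 1 - (1 - f) / 2 * (1 + cos(2 * pi * u))
        r[inwin] <- pmin(r[inwin], base_radius * fac)
      }
    }
    r
  }
}

# Rasterize a tube around a polyline with an arc-length-dependent radius.
# A voxel belongs to the lumen iff its center lies within radius_fn(s) of the
# path (s = arc length of the nearest point); the wall ring extends a further
# wall_thickness. Updates `lumen` and `wall` logical arrays in the caller.
voxelize_tube <- function(points, radius_fn, max_radius, grid_shape, spacing,
                          origin = c(0, 0, 0), wall_thickness = 0) {
  points <- rbind(points)
  nseg <- nrow(points) - 1
  seglen <- sqrt(rowSums((points[-1, , drop = FALSE] -
                          points[-nrow(points), , drop = FALSE])^2))
  s0 <- c(0, cumsum(seglen))
  reach <- max_radius + wall_thickness + max(spacing)
  lo <- pmin(apply(points, 2, min), Inf) - reach
  hi <- apply(points, 2, max) + reach
  i_lo <- pmax(0L, floor((lo - origin) / spacing))
  i_hi <- pmin(grid_shape - 1L, ceiling((hi - origin) / spacing))
  if (any(i_hi < i_lo)) stop("grid too small to contain the tree")
  ax <- lapply(1:3, function(k) i_lo[k]:i_hi[k])
  nx <- lengths(ax)
  # voxel-center world coordinates of the candidate box
  g1 <- origin[1] + ax[[1]] * spacing[1]
  g2 <- origin[2] + ax[[2]] * spacing[2]
  g3 <- origin[3] + ax[[3]] * spacing[3]
  n <- prod(nx)
  c1 <- rep(g1, times = nx[2] * nx[3])
  c2 <- rep(rep(g2, each = nx[1]), times = nx[3])
  c3 <- rep(g3, each = nx[1] * nx[2])
  best_d2 <- rep(Inf, n); best_s <- numeric(n)
  # flat caps at the global tube ends; interior joints clamp the projection
  # (capsule behavior) so curved polylines leave no wedge gaps at the joints
  for (k in seq_len(nseg)) {
    p <- points[k, ]; q <- points[k + 1, ]
    u <- (q - p) / seglen[k]
    t <- (c1 - p[1]) * u[1] + (c2 - p[2]) * u[2] + (c3 - p[3]) * u[3]
    ok <- rep(TRUE, length(t))
    if (k == 1) ok <- ok & t >= 0
    if (k == nseg) ok <- ok & t <= seglen[k]
    if (!any(ok)) next
    tk <- pmin(pmax(t[ok], 0), seglen[k])
    d2 <- (c1[ok] - (p[1] + tk * u[1]))^2 + (c2[ok] - (p[2] + tk * u[2]))^2 +
          (c3[ok] - (p[3] + tk * u[3]))^2
    upd <- which(ok)[d2 < best_d2[ok]]
    keep <- d2 < best_d2[ok]
    best_d2[upd] <- d2[keep]
    best_s[upd] <- s0[k] + tk[keep]
  }
  r <- radius_fn(best_s)
  d <- sqrt(best_d2)
  list(index = list(ax[[1]] + 1L, ax[[2]] + 1L, ax[[3]] + 1L),
       lumen = array(d <= r, nx),
       wall = if (wall_thickness > 0) array(d > r & d <= r + wall_thickness, nx)
              else NULL)
}

#' Generate a synthetic carotid phantom
#'
#' Builds the analytic Y-tree of [phantom_spec()], voxelizes it with the
#' center-in-tube membership rule, renders the intensity model (lumen, wall
#' ring, background) and adds seeded Gaussian noise. Identical specs produce
#' bit-identical outputs.
#'
#' @param spec a [phantom_spec()].
#' @return list with \code{image} ([volume_image()]), \code{label}
#'   ([lumen_label()]) and \code{truth}, a ground-truth record holding, per
#'   branch, the true NASCET percent, MLD and RVD (mm), throat arc length,
#'   and the analytic centerline points.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  branches <- phantom_branches(spec)
  gs <- spec$grid_shape
  # containment check: every tube endpoint plus radius must fit the grid
  ext <- (gs - 1) * spec$spacing
  for (nm in names(branches)) {
    b <- branches[[nm]]
    pad <- b$radius + spec$wall_thickness
    if (any(b$p < -1e-9) || any(t(b$p) + pad > ext + 1e-9))
      stop("grid too small to contain the tree (branch ", nm, ")")
  }
  lumen <- array(FALSE, gs)
  wall <- array(FALSE, gs)
  truth <- list(branches = list())
  for (nm in names(branches)) {
    b <- branches[[nm]]
    sten <- Filter(function(s) s$branch == nm, spec$stenosis_list)
    rfun <- branch_radius_fn(b$radius, sten)
    vx <- voxelize_tube(b$p, rfun, b$radius, gs, spec$spacing,
                        wall_thickness = spec$wall_thickness)
    idx <- vx$index
    lumen[idx[[1]], idx[[2]], idx[[3]]] <-
      lumen[idx[[1]], idx[[2]], idx[[3]]] | vx$lumen
    wall[idx[[1]], idx[[2]], idx[[3]]] <-
      wall[idx[[1]], idx[[2]], idx[[3]]] | vx$wall
    pct <- if (length(sten)) max(vapply(sten, `[[`, 0, "target_percent")) else 0
    throat <- if (length(sten))
      sten[[which.max(vapply(sten, `[[`, 0, "target_percent"))]]$center_arclength
      else NA_real_
    ssamp <- seq(0, spec$segment_length, by = 0.5)
    dirv <- (b$p[2, ] - b$p[1, ]) / spec$segment_length
    cl <- t(b$p[1, ] + outer(dirv, ssamp))
    truth$branches[[nm]] <- list(
      true_percent = pct,
      true_rvd = 2 * b$radius,
      true_mld = (1 - pct / 100) * 2 * b$radius,
      throat_arclength = throat,
      centerline_points = cl)
  }
  wall <- wall & !lumen
  img <- array(spec$background_intensity, gs)
  img[wall] <- spec$wall_intensity
  img[lumen] <- spec$lumen_intensity
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           array(stats::rnorm(length(img), 0, spec$noise_sd), gs))
  }
  mask <- array(0L, gs); mask[lumen] <- 1L
  truth$spec <- spec
  class(truth) <- "phantom_truth"
  list(image = volume_image(img, spec$spacing),
       label = lumen_label(mask, spec$spacing),
       truth = truth)
}

#' Voxelize a free-form tube (testing helper)
#'
#' Rasterizes a tube of given radius around an arbitrary polyline on a grid,
#' using the same center-in-tube membership rule as [generate_phantom()].
#' Useful for building curved (e.g. torus-arc) test vessels.
#'
#' @param points n x 3 matrix of world-mm centerline points.
#' @param radius constant radius (mm) or a function of arc length.
#' @param grid_shape,spacing grid geometry.
#' @return A [lumen_label()].
#' @export
tube_label <- function(points, radius, grid_shape, spacing) {
  rfun <- if (is.function(radius)) radius else function(s) rep(radius, length(s))
  rmax <- if (is.function(radius)) max(radius(seq(0, 1e4, by = 5))) else radius
  vx <- voxelize_tube(points, rfun, rmax, as.integer(grid_shape), spacing)
  mask <- array(0L, grid_shape)
  mask[vx$index[[1]], vx$index[[2]], vx$index[[3]]] <-
    as.integer(vx$lumen)
  lumen_label(mask, spacing)
}

#' Generate a seeded phantom cohort on disk
#'
#' Writes \code{n_lesions} phantom image/label NIfTI pairs plus a manifest
#' CSV. Grades are allocated to match \code{grade_mix} by largest-remainder
#' rounding; each lesion gets one ICA stenosis whose target percent is drawn
#' within its grade band, plus small seeded jitter of the bifurcation angle
#' and radii so lesions differ geometrically. The default mix follows the
#' grade proportions of a training-validation cohort of 545 lesions
#' (3 mild, 206 moderate, 336 severe).
#'
#' @param n_lesions number of phantoms.
#' @param grade_mix named proportions over mild/moderate/severe; must sum to 1.
#' @param seed integer seed; lesions derive per-lesion seeds from it.
#' @param out_dir output directory.
#' @param base_spec [phantom_spec()] template for geometry/intensities.
#' @return the written manifest (invisibly readable via [read_manifest()]).
#' @export
generate_cohort <- function(n_lesions,
                            grade_mix = c(mild = 3, moderate = 206, severe = 336) / 545,
                            seed = 7L, out_dir,
                            base_spec = phantom_spec()) {
  stopifnot(n_lesions >= 1)
  if (abs(sum(grade_mix) - 1) > 1e-8) stop("grade_mix must sum to 1")
  grade_mix <- grade_mix[c("mild", "moderate", "severe")]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("unwritable directory: ", out_dir)
  # largest-remainder rounding of the requested mix
  raw <- grade_mix * n_lesions
  cnt <- floor(raw)
  rem <- n_lesions - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  grades <- rep(names(cnt), times = cnt)
  bands <- list(mild = c(15, 30), moderate = c(35, 70), severe = c(72, 92))
  tags <- c("ScI", "ScII", "ScIII")
  rows <- vector("list", n_lesions)
  for (i in seq_len(n_lesions)) {
    lseed <- as.integer((as.integer(seed) + 7919L * i) %% .Machine$integer.max)
    g <- grades[i]
    L <- base_spec$segment_length
    par <- with_seed(lseed, list(
      pct = stats::runif(1, bands[[g]][1], bands[[g]][2]),
      center_frac = stats::runif(1, 0.30, 0.45),
      len = min(stats::runif(1, 8, 12), 0.4 * L),
      angle = base_spec$bifurcation_angle + stats::runif(1, -5, 5),
      rscale = stats::runif(1, 0.9, 1.1),
      tag = sample(tags, 1)))
    spec_i <- phantom_spec(
      grid_shape = base_spec$grid_shape, spacing = base_spec$spacing,
      cca_radius = base_spec$cca_radius * par$rscale,
      ica_radius = base_spec$ica_radius * par$rscale,
      eca_radius = base_spec$eca_radius * par$rscale,
      segment_length = L, bifurcation_angle = par$angle,
      stenosis_list = list(stenosis_spec("ICA", par$center_frac * L,
                                         par$len, par$pct)),
      lumen_intensity = base_spec$lumen_intensity,
      wall_intensity = base_spec$wall_intensity,
      background_intensity = base_spec$background_intensity,
      noise_sd = base_spec$noise_sd,
      wall_thickness = base_spec$wall_thickness,
      margin = base_spec$margin, seed = lseed)
    ph <- generate_phantom(spec_i)
    lid <- sprintf("lesion_%03d", i)
    ipath <- file.path(out_dir, paste0(lid, "_image.nii.gz"))
    lpath <- file.path(out_dir, paste0(lid, "_label.nii.gz"))
    write_volume(ph$image, ipath)
    write_volume(ph$label, lpath)
    rows[[i]] <- data.frame(
      lesion_id = lid, image_path = ipath, label_path = lpath,
      grade = g, true_percent = par$pct, scanner_tag = par$tag,
      seed = lseed, stringsAsFactors = FALSE)
  }
  manifest <- as_manifest(do.call(rbind, rows))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
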