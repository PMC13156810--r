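# Geometric stenosis quantification: centerline extraction, vessel
# straightening, lumen-area profiling, MLD/RVD measurement and NASCET
# grading.

# boundary voxels: foreground with at least one of the 6 face neighbors
# background (volume border counts as background)
boundary_mask <- function(mask) {
  m <- mask == 1L
  d <- dim(m)
  shift_bg <- function(ax, dir) {
    # out[v] = is the (ax, dir) face neighbor foreground? outside the volume
    # counts as background, so border voxels are exposed
    out <- array(FALSE, d)
    if (ax == 1) { if (dir > 0) out[-d[1], , ] <- m[-1, , ] else out[-1, , ] <- m[-d[1], , ] }
    if (ax == 2) { if (dir > 0) out[, -d[2], ] <- m[, -1, ] else out[, -1, ] <- m[, -d[2], ] }
    if (ax == 3) { if (dir > 0) out[, , -d[3]] <- m[, , -1] else out[, , -1] <- m[, , -d[3]] }
    !out
  }
  exposed <- shift_bg(1, 1) | shift_bg(1, -1) | shift_bg(2, 1) |
             shift_bg(2, -1) | shift_bg(3, 1) | shift_bg(3, -1)
  m & exposed
}

# linear index -> 0-based (i, j, k) voxel coordinates
lin_to_ijk <- function(lin, d) {
  lin0 <- lin - 1L
  cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
}

# backtrack a Dijkstra parent chain from `from` (1-based linear index)
backtrack <- function(parent, from) {
  path <- integer(0)
  cur <- from
  while (cur > 0) {
    path <- c(path, cur)
    p <- parent[cur]
    cur <- if (p < 0) 0L else p + 1L
  }
  path
}

# moving-average smoothing of an n x 3 point path (window in points)
smooth_path <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (n <= 2 || window <= 1) return(pts)
  half <- window %/% 2
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}

# resample a polyline at a uniform arc-length step; returns points and s
resample_path <- function(pts, step) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  if (L == 0) return(list(pts = pts[1, , drop = FALSE], s = 0))
  ss <- seq(0, L, by = step)
  if (ss[length(ss)] < L) ss <- c(ss, L)
  out <- vapply(1:3, function(k) stats::approx(cs, pts[, k], xout = ss)$y,
                numeric(length(ss)))
  list(pts = matrix(out, ncol = 3), s = ss)
}

#' Extract the geometric centerline of a lumen mask
#'
#' Distance-transform-penalized geodesics over the foreground voxel graph:
#' path endpoints are found by geodesic eccentricity, the main path is the
#' minimal path between them under an edge cost that divides by the squared
#' medial depth (pulling the path onto the medial axis), and the third branch
#' is grown from the voxel geodesically farthest from the main path. The
#' common trunk (CCA) is the branch descending below the bifurcation along
#' the slice axis; of the two distal branches the internal carotid (ICA) is
#' the one with the larger mean medial radius. When no branch longer than
#' \code{min_branch} exists the tree degenerates to a single branch, which is
#' labeled ICA so downstream diameter measurement still applies.
#'
#' @param label a [lumen_label()]; must be non-empty and connected.
#' @param step resampling arc-length step, mm.
#' @param min_branch minimum side-branch length to accept a bifurcation, mm.
#' @param smooth_window moving-average window (points) for path smoothing.
#' @return object of class \code{centerline}: data.frame \code{points}
#'   (world mm, branch label, arc length \code{s} from the proximal end of
#'   each branch), \code{bifurcation} (world point or NULL), branch lengths.
#' @export
extract_centerline <- function(label, step = 0.5, min_branch = 5,
                               smooth_window = 5L) {
  mask <- label$mask
  sp <- label$spacing
  if (sum(mask) == 0) stop("empty mask: no centerline")
  d <- dim(mask)
  # medial depth: distance to the nearest background voxel
  bg <- array(1L - mask, d)
  depth <- sqrt(.edt_sq(bg, sp))
  fg1 <- which(mask == 1L)[1]
  plain <- function(src) .voxel_dijkstra(mask, sp, as.integer(src - 1L),
                                         numeric(0), 0.5, 2)
  penal <- function(src) .voxel_dijkstra(mask, sp, as.integer(src - 1L),
                                         as.numeric(depth), 0.5, 2)
  r0 <- plain(fg1)
  if (any(is.infinite(r0$dist[mask == 1L])))
    stop("mask has more than one connected component")
  e1 <- which.max(ifelse(mask == 1L, r0$dist, -Inf))
  r1 <- plain(e1)
  e2 <- which.max(ifelse(mask == 1L, r1$dist, -Inf))
  p1 <- penal(e1)
  main_path <- rev(backtrack(p1$parent, e2))      # e1 -> e2
  # third branch: farthest voxel from the main path
  rp <- plain(main_path)
  e3 <- which.max(ifelse(mask == 1L, rp$dist, -Inf))
  d3 <- rp$dist[e3]
  single <- !is.finite(d3) || d3 < min_branch
  to_world <- function(lin) {
    ijk <- lin_to_ijk(lin, d)
    sweep(ijk * rep(sp, each = nrow(ijk)), 2, label$origin, "+")
  }
  # drop path points closer to a free end than the local radius: at a vessel
  # end the medial path funnels from the end face to the axis, and the
  # centerline is not meaningful within one radius of the cap
  trim_free_end <- function(lin_path, at_end = TRUE) {
    if (length(lin_path) < 4) return(lin_path)
    path <- if (at_end) rev(lin_path) else lin_path
    pts <- to_world(path)
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    L <- c(0, cumsum(seg))
    target <- max(depth[path])  # full branch caliber
    keep_from <- 1
    lim <- max(2, length(path) - 3)
    for (i in seq_len(lim)) {
      if (depth[path[i]] < 0.9 * target && L[i] < 2 * target) keep_from <- i + 1
      else break
    }
    path <- path[keep_from:length(path)]
    if (at_end) rev(path) else path
  }
  finish_branch <- function(lin_path, trim_start = FALSE, trim_end = TRUE) {
    if (trim_end) lin_path <- trim_free_end(lin_path, at_end = TRUE)
    if (trim_start) lin_path <- trim_free_end(lin_path, at_end = FALSE)
    pts <- to_world(lin_path)
    pts <- smooth_path(pts, smooth_window)
    resample_path(pts, step)
  }
  if (single) {
    br <- finish_branch(main_path, trim_start = TRUE, trim_end = TRUE)
    pts <- data.frame(x = br$pts[, 1], y = br$pts[, 2], z = br$pts[, 3],
                      s = br$s, branch = "ICA", stringsAsFactors = FALSE)
    return(structure(list(points = pts, bifurcation = NULL,
                          branch_lengths = c(ICA = max(br$s)),
                          step = step), class = "centerline"))
  }
  pp <- .voxel_dijkstra(mask, sp, as.integer(main_path - 1L),
                        as.numeric(depth), 0.5, 2)
  b3 <- backtrack(pp$parent, e3)                   # e3 -> junction (on main path)
  junction <- b3[length(b3)]
  jpos <- which(main_path == junction)[1]
  if (is.na(jpos)) { # numerical corner: snap to nearest main-path voxel
    jw <- to_world(junction)
    mw <- to_world(main_path)
    jpos <- which.min(rowSums(sweep(mw, 2, as.numeric(jw), "-")^2))
  }
  # arms from the junction outward
  armA <- main_path[jpos:1]                        # junction -> e1
  armB <- main_path[jpos:length(main_path)]        # junction -> e2
  armC <- rev(b3)                                  # junction -> e3
  arms <- list(armA, armB, armC)
  arm_ok <- vapply(arms, length, integer(1)) >= 2
  if (!all(arm_ok)) stop("degenerate bifurcation geometry")
  tipz <- vapply(arms, function(a) to_world(a[length(a)])[1, 1], numeric(1))
  jz <- to_world(junction)[1, 1]
  # branch caliber judged on the distal 40% of each arm (minus a tip guard):
  # a focal stenosis near the bifurcation must not demote the ICA below the
  # ECA, and the distal segment is the normal reference caliber
  mean_depth <- vapply(arms, function(a) {
    n <- length(a)
    tip_guard <- min(ceiling(2 / min(sp)), max(n %/% 4, 1))
    lo <- max(1, ceiling(0.6 * n)); hi <- max(lo, n - tip_guard)
    mean(depth[a[lo:hi]])
  }, numeric(1))
  below <- which(tipz < jz)
  cca_i <- if (length(below) == 1) below
           else if (length(below) == 0) which.max(mean_depth)
           else below[which.max(mean_depth[below])]
  rest <- setdiff(1:3, cca_i)
  ica_i <- rest[which.max(mean_depth[rest])]
  eca_i <- setdiff(rest, ica_i)
  labels <- character(3)
  labels[c(cca_i, ica_i, eca_i)] <- c("CCA", "ICA", "ECA")
  rows <- list(); lens <- c(CCA = 0, ICA = 0, ECA = 0)
  for (i in c(cca_i, ica_i, eca_i)) {
    br <- finish_branch(arms[[i]])
    npts <- nrow(br$pts)
    if (labels[i] == "CCA") {
      # CCA ordered proximal -> bifurcation; arc length from the proximal tip
      ord <- npts:1
      svals <- max(br$s) - br$s[ord]
    } else {
      ord <- seq_len(npts)
      svals <- br$s
    }
    rows[[labels[i]]] <- data.frame(x = br$pts[ord, 1], y = br$pts[ord, 2],
                                    z = br$pts[ord, 3], s = svals,
                                    branch = labels[i], stringsAsFactors = FALSE)
    lens[labels[i]] <- max(br$s)
  }
  pts <- rbind(rows$CCA, rows$ICA, rows$ECA)
  structure(list(points = pts,
                 bifurcation = as.numeric(to_world(junction)),
                 branch_lengths = lens, step = step),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("<centerline> ", nrow(x$points), " points; branches: ",
      paste(names(x$branch_lengths),
            paste0(signif(x$branch_lengths, 3), " mm"),
            sep = " = ", collapse = ", "),
      if (is.null(x$bifurcation)) " (single-branch mode)" else "", "\n", sep = "")
  invisible(x)
}

# orthonormal frames along a point path by parallel transport
transport_frames <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  if (n == 1) { tg[1, ] <- c(1, 0, 0) } else {
    tg[1, ] <- pts[2, ] - pts[1, ]
    tg[n, ] <- pts[n, ] - pts[n - 1, ]
    if (n > 2) tg[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
    tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-12)
  }
  nrm <- matrix(0, n, 3); bnm <- matrix(0, n, 3)
  ref <- if (abs(tg[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * tg[1, ]) * tg[1, ]
  nrm[1, ] <- v / sqrt(sum(v^2))
  bnm[1, ] <- c(tg[1, 2] * nrm[1, 3] - tg[1, 3] * nrm[1, 2],
                tg[1, 3] * nrm[1, 1] - tg[1, 1] * nrm[1, 3],
                tg[1, 1] * nrm[1, 2] - tg[1, 2] * nrm[1, 1])
  for (i in seq_len(n - 1) + 1) {
    v <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tg[i, ]) * tg[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) v <- bnm[i - 1, ] - sum(bnm[i - 1, ] * tg[i, ]) * tg[i, ]
    nrm[i, ] <- v / sqrt(sum(v^2))
    bnm[i, ] <- c(tg[i, 2] * nrm[i, 3] - tg[i, 3] * nrm[i, 2],
                  tg[i, 3] * nrm[i, 1] - tg[i, 1] * nrm[i, 3],
                  tg[i, 1] * nrm[i, 2] - tg[i, 2] * nrm[i, 1])
  }
  list(t = tg, n = nrm, b = bnm)
}

# restrict a binary plane to the 4-connected component at its center: an
# orthogonal plane near a bifurcation also slices the sibling branch, which
# must not count toward this branch's lumen area. The seed is the foreground
# pixel nearest the plane center (within `reach` mm); no seed = empty plane.
plane_center_component <- function(vals, plane_spacing, reach = 1.5) {
  if (!any(vals == 1L)) return(vals)
  n <- nrow(vals)
  ctr <- (n + 1) / 2
  fg <- which(vals == 1L, arr.ind = TRUE)
  d2 <- (fg[, 1] - ctr)^2 + (fg[, 2] - ctr)^2
  if (min(d2) * plane_spacing^2 > reach^2) return(array(0L, dim(vals)))
  seed <- fg[which.min(d2), ]
  keep <- matrix(FALSE, n, n)
  queue <- matrix(seed, ncol = 2)
  keep[seed[1], seed[2]] <- TRUE
  # 8-connectivity: oblique cuts of a voxelized tube alias into diagonal
  # pixel chains that 4-connectivity would sever
  while (nrow(queue)) {
    cur <- queue
    queue <- matrix(0L, 0, 2)
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                    c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      nb <- cbind(cur[, 1] + dd[1], cur[, 2] + dd[2])
      ok <- nb[, 1] >= 1 & nb[, 1] <= n & nb[, 2] >= 1 & nb[, 2] <= n
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      new <- vals[nb] == 1L & !keep[nb]
      nb <- nb[new, , drop = FALSE]
      if (nrow(nb)) { keep[nb] <- TRUE; queue <- rbind(queue, nb) }
    }
  }
  out <- array(0L, dim(vals)); out[keep] <- 1L
  out
}

#' Straighten a vessel along its centerline
#'
#' Curved planar reformation: at every centerline sample the binary mask is
#' resampled (nearest neighbor) on a square plane orthogonal to the local
#' tangent, centered on the centerline point, then restricted to the
#' in-plane connected component at the center so planes near the bifurcation
#' do not count the sibling branch. Plane orientation is carried
#' along the path by parallel transport, so consecutive planes do not twist.
#' If any plane's lumen touches the plane border, the plane grid is enlarged
#' once (doubled) with a warning.
#'
#' @param label the [lumen_label()] being straightened.
#' @param cl a [extract_centerline()] result.
#' @param step arc-length step between planes, mm (defaults to the
#'   centerline step).
#' @param plane_n plane grid size (pixels per side).
#' @param plane_spacing plane grid spacing, mm.
#' @return object of class \code{straightened_vessel}: \code{planes}
#'   (n x plane_n x plane_n binary array), \code{branch}, \code{s} per plane,
#'   grid metadata.
#' @export
straighten <- function(label, cl, step = NULL, plane_n = 64L,
                       plane_spacing = 0.3) {
  stopifnot(inherits(cl, "centerline"))
  if (!is.null(step) && step <= 0) stop("step must be > 0")
  build <- function(plane_n) {
    pts_all <- cl$points
    n_total <- nrow(pts_all)
    half <- (plane_n - 1) / 2
    u <- (seq_len(plane_n) - 1 - half) * plane_spacing
    gu <- matrix(u, plane_n, plane_n); gv <- t(gu)
    planes <- array(0L, c(n_total, plane_n, plane_n))
    d <- dim(label$mask)
    for (br in unique(pts_all$branch)) {
      rows <- which(pts_all$branch == br)
      pts <- as.matrix(pts_all[rows, c("x", "y", "z")])
      fr <- transport_frames(pts)
      for (k in seq_along(rows)) {
        ctr <- pts[k, ]
        px <- ctr[1] + as.vector(gu) * fr$n[k, 1] + as.vector(gv) * fr$b[k, 1]
        py <- ctr[2] + as.vector(gu) * fr$n[k, 2] + as.vector(gv) * fr$b[k, 2]
        pz <- ctr[3] + as.vector(gu) * fr$n[k, 3] + as.vector(gv) * fr$b[k, 3]
        i1 <- round((px - label$origin[1]) / label$spacing[1]) + 1
        i2 <- round((py - label$origin[2]) / label$spacing[2]) + 1
        i3 <- round((pz - label$origin[3]) / label$spacing[3]) + 1
        ok <- i1 >= 1 & i1 <= d[1] & i2 >= 1 & i2 <= d[2] & i3 >= 1 & i3 <= d[3]
        vals <- integer(plane_n * plane_n)
        if (any(ok))
          vals[ok] <- label$mask[cbind(i1[ok], i2[ok], i3[ok])]
        dim(vals) <- c(plane_n, plane_n)
        planes[rows[k], , ] <- plane_center_component(vals, plane_spacing)
      }
    }
    planes
  }
  planes <- build(plane_n)
  # planes near the junction legitimately carry long in-plane components;
  # only a mid-branch plane running off the grid means the plane is too small
  near_junction <- if (is.null(cl$bifurcation)) rep(FALSE, nrow(cl$points)) else {
    pts <- as.matrix(cl$points[, c("x", "y", "z")])
    sqrt(colSums((t(pts) - cl$bifurcation)^2)) < 6
  }
  mid <- which(!near_junction)
  border_hit <- any(planes[mid, 1, ] == 1L) || any(planes[mid, plane_n, ] == 1L) ||
                any(planes[mid, , 1] == 1L) || any(planes[mid, , plane_n] == 1L)
  if (border_hit) {
    warning("lumen touches the straightening plane border; enlarging plane once")
    plane_n <- 2L * plane_n
    planes <- build(plane_n)
  }
  structure(list(planes = planes, branch = cl$points$branch, s = cl$points$s,
                 step = cl$step, plane_spacing = plane_spacing,
                 plane_n = plane_n), class = "straightened_vessel")
}

#' Lumen area profile of a straightened vessel
#'
#' Per plane, area = foreground-pixel count times the in-plane pixel area;
#' optionally smoothed with a centered moving average within each branch.
#'
#' @param sv a [straighten()] result.
#' @param smooth_window moving-average window in planes (1 = no smoothing).
#' @return data.frame of class \code{area_profile}: \code{index},
#'   \code{branch}, \code{s} (mm), \code{area} and \code{area_smooth} (mm^2).
#' @export
area_profile <- function(sv, smooth_window = 3L) {
  stopifnot(inherits(sv, "straightened_vessel"))
  counts <- apply(sv$planes, 1, sum)
  area <- counts * sv$plane_spacing^2
  smooth <- area
  if (smooth_window > 1) {
    half <- smooth_window %/% 2
    for (br in unique(sv$branch)) {
      idx <- which(sv$branch == br)
      a <- area[idx]
      sm <- vapply(seq_along(a), function(i)
        mean(a[max(1, i - half):min(length(a), i + half)]), numeric(1))
      smooth[idx] <- sm
    }
  }
  structure(data.frame(index = seq_along(area), branch = sv$branch, s = sv$s,
                       area = area, area_smooth = smooth,
                       stringsAsFactors = FALSE),
            class = c("area_profile", "data.frame"))
}

#' @export
plot.area_profile <- function(x, ...) {
  cols <- c(CCA = "#1b6ca8", ICA = "#c0392b", ECA = "#7f8c8d")
  graphics::plot(x$index, x$area, type = "h", col = cols[x$branch],
                 xlab = "slice number", ylab = expression(lumen ~ area ~ (mm^2)),
                 main = "Straightened lumen area profile", ...)
  graphics::lines(x$index, x$area_smooth, lwd = 2)
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Equivalent circular diameter of a cross-sectional area
#'
#' \code{d = 2 * sqrt(area / pi)}: the diameter of the circle with the same
#' area. Rotation-invariant stand-in for the luminal internal diameter.
#'
#' @param area area(s) in mm^2, \code{>= 0}.
#' @return diameter(s) in mm.
#' @export
equivalent_diameter <- function(area) {
  stopifnot(all(area >= 0))
  2 * sqrt(area / pi)
}

ica_window <- function(profile, guard, end_guard) {
  rows <- which(profile$branch == "ICA")
  if (!length(rows)) stop("ICA branch absent from profile")
  s <- profile$s[rows]
  keep <- s >= guard & s <= max(s) - end_guard
  if (!any(keep)) keep <- rep(TRUE, length(rows))
  rows[keep]
}

#' Minimum lumen diameter (MLD) on the ICA
#'
#' The equivalent diameter at the minimum of the smoothed ICA area profile,
#' excluding a guard zone distal to the bifurcation (flow-divider artifact)
#' and at the branch end. Ties resolve to the most proximal plane.
#'
#' @param profile an [area_profile()].
#' @param guard guard distance beyond the bifurcation, mm.
#' @param end_guard guard distance at the distal end, mm.
#' @return list with \code{slice} (profile index) and \code{mld} (mm).
#' @export
find_mld <- function(profile, guard = 2, end_guard = 2) {
  rows <- ica_window(profile, guard, end_guard)
  a <- profile$area_smooth[rows]
  k <- which(a == min(a))[1]           # ties -> smallest index (most proximal)
  list(slice = profile$index[rows[k]], mld = equivalent_diameter(a[k]))
}

#' Reference vessel diameter (RVD)
#'
#' Two strategies: \code{"distal_ica"} (default) takes the median equivalent
#' diameter over the distal ICA window, the normal segment beyond the
#' stenosis that the NASCET denominator prescribes; \code{"bulb_max"} takes
#' the maximum diameter near the bifurcation (the dilated carotid bulb).
#'
#' @param profile an [area_profile()].
#' @param strategy \code{"distal_ica"} or \code{"bulb_max"}.
#' @param distal_start start of the distal window as a fraction of ICA length.
#' @param end_guard distal end guard, mm.
#' @param bulb_reach how far from the bifurcation the bulb search extends, mm.
#' @return list with \code{slice} and \code{rvd} (mm).
#' @export
find_rvd <- function(profile, strategy = c("distal_ica", "bulb_max"),
                     distal_start = 0.55, end_guard = 2, bulb_reach = 10) {
  strategy <- match.arg(strategy)
  rows_ica <- which(profile$branch == "ICA")
  if (!length(rows_ica)) stop("ICA branch absent from profile")
  s <- profile$s[rows_ica]
  L <- max(s)
  if (strategy == "distal_ica") {
    keep <- s >= distal_start * L & s <= L - end_guard
    if (!any(keep)) keep <- s >= distal_start * L
    rows <- rows_ica[keep]
    dvec <- equivalent_diameter(profile$area_smooth[rows])
    med <- stats::median(dvec)
    k <- which.min(abs(dvec - med))
    list(slice = profile$index[rows[k]], rvd = med)
  } else {
    near_ica <- rows_ica[s <= bulb_reach]
    rows_cca <- which(profile$branch == "CCA")
    near_cca <- if (length(rows_cca)) {
      sc <- profile$s[rows_cca]
      rows_cca[sc >= max(sc) - bulb_reach]
    } else integer(0)
    rows <- c(near_cca, near_ica)
    dvec <- equivalent_diameter(profile$area_smooth[rows])
    k <- which.max(dvec)
    list(slice = profile$index[rows[k]], rvd = dvec[k])
  }
}

#' NASCET percent diameter stenosis
#'
#' \code{percent = (1 - MLD / RVD) * 100}, the North American Symptomatic
#' Carotid Endarterectomy Trial criterion.
#'
#' @param mld minimum lumen diameter, mm.
#' @param rvd reference vessel diameter, mm; must be positive.
#' @return percent in \code{[0, 100]}.
#' @export
nascet_percent <- function(mld, rvd) {
  if (rvd <= 0) stop("rvd must be > 0")
  if (mld < 0) stop("mld must be >= 0")
  if (mld > rvd)
    stop("measurement inconsistency: mld exceeds rvd")
  # (rvd - mld)/rvd keeps round ratios exact (e.g. 7/10 -> exactly 30)
  (rvd - mld) / rvd * 100
}

#' Three-class stenosis grade
#'
#' Mild for percent in (0, 30], moderate in (30, 70], severe in (70, 100);
#' the upper boundaries are closed. Complete occlusion (100 percent) is out
#' of scope, mirroring the exclusion of occluded arteries from the study
#' population.
#'
#' @param percent NASCET percent in \code{[0, 100)}.
#' @return \code{"mild"}, \code{"moderate"} or \code{"severe"}.
#' @export
grade_stenosis <- function(percent) {
  if (!is.finite(percent) || percent < 0 || percent >= 100)
    stop("percent must be in [0, 100); occlusion is out of scope")
  if (percent <= 30) "mild" else if (percent <= 70) "moderate" else "severe"
}

#' Merge grades to the two-class task
#'
#' Mild and moderate lesions are combined into \code{"non-severe"}; severe
#' stays \code{"severe"}. Reflects the clinical contrast that matters for
#' endarterectomy decisions (and the scarcity of mild lesions).
#'
#' @param grade a grade from [grade_stenosis()].
#' @return \code{"non-severe"} or \code{"severe"}.
#' @export
binarize_grade <- function(grade) {
  grade <- match.arg(grade, c("mild", "moderate", "severe"))
  if (grade == "severe") "severe" else "non-severe"
}

#' Quantify stenosis from a lumen mask
#'
#' The full geometric chain: centerline extraction, straightening, area
#' profiling, MLD/RVD measurement, NASCET percent and grading. Should the
#' median-based RVD fall below the measured MLD (possible on near-constant
#' vessels at voxel resolution), the RVD is raised to the MLD so the report
#' invariant \code{mld <= rvd} always holds and the percent reads 0.
#'
#' @param label a [lumen_label()] of the vessel.
#' @param config stenosis config block (see [default_config()]).
#' @return list of class \code{stenosis_report} with \code{mld}, \code{rvd}
#'   (mm), their profile indices, \code{percent}, \code{grade3},
#'   \code{grade2}, plus the \code{profile} ([area_profile()]) and
#'   \code{centerline}.
#' @export
quantify <- function(label, config = default_config()$stenosis) {
  cl <- extract_centerline(label, step = config$step)
  sv <- straighten(label, cl, plane_n = config$plane_n,
                   plane_spacing = config$plane_spacing)
  prof <- area_profile(sv, smooth_window = config$smooth_window)
  mld <- find_mld(prof, guard = config$guard, end_guard = config$end_guard)
  rvd <- find_rvd(prof, strategy = config$rvd_strategy,
                  end_guard = config$end_guard)
  r <- rvd$rvd
  if (mld$mld > r) r <- mld$mld
  pct <- nascet_percent(mld$mld, r)
  pct <- min(pct, 99.999)  # voxel dropout cannot certify occlusion
  g3 <- grade_stenosis(pct)
  structure(list(mld = mld$mld, rvd = r, mld_slice = mld$slice,
                 rvd_slice = rvd$slice, percent = pct, grade3 = g3,
                 grade2 = binarize_grade(g3), profile = prof,
                 centerline = cl), class = "stenosis_report")
}

#' @export
print.stenosis_report <- function(x, ...) {
  cat("Stenosis report (NASCET)\n")
  cat(sprintf("  MLD  %.2f mm (slice %d)\n", x$mld, x$mld_slice))
  cat(sprintf("  RVD  %.2f mm (slice %d)\n", x$rvd, x$rvd_slice))
  cat(sprintf("  stenosis %.1f%%  ->  %s (%s)\n", x$percent, x$grade3, x$grade2))
  invisible(x)
}

#' Write a stenosis report as JSON (plus optional profile CSV)
#'
#' @param report a [quantify()] result.
#' @param path JSON output path.
#' @param profile_csv optional CSV path for the area profile.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, profile_csv = NULL) {
  out <- report[c("mld", "rvd", "mld_slice", "rvd_slice", "percent",
                  "grade3", "grade2")]
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(profile_csv))
    utils::write.csv(as.data.frame(report$profile), profile_csv, row.names = FALSE)
  invisible(path)
}
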