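# Shared fixtures: small phantoms and brute-force oracles.

# small Y-phantom for fast module tests
desk_phantom <- function(stenosis = list(), seed = 11L, noise_sd = 8,
                         grid = c(64L, 96L, 96L), segment_length = 15) {
  generate_phantom(phantom_spec(grid_shape = grid, segment_length = segment_length,
                                margin = 2, stenosis_list = stenosis,
                                noise_sd = noise_sd, seed = seed))
}

# straight z-aligned tube label (first axis), radius mm
straight_tube <- function(radius = 3, length = 40, grid = c(110L, 48L, 48L),
                          spacing = c(0.4, 0.4, 0.4)) {
  ctr <- (grid[2:3] - 1) * spacing[2:3] / 2
  tube_label(rbind(c(2, ctr[1], ctr[2]), c(2 + length, ctr[1], ctr[2])),
             radius, grid, spacing)
}

# quarter-torus tube: bend radius R in the (z, y) plane, tube radius r
torus_tube <- function(r = 3, R = 18, spacing = c(0.4, 0.4, 0.4)) {
  th <- seq(0, pi / 2, length.out = 80)
  ctr_x <- 10
  pts <- cbind(4 + R * sin(th), 4 + R * (1 - cos(th)), rep(ctr_x, length(th)))
  grid <- c(ceiling((4 + R + r + 2) / spacing[1]),
            ceiling((4 + R + r + 2) / spacing[2]),
            ceiling(2 * ctr_x / spacing[3]))
  tube_label(pts, r, grid, spacing)
}

# brute-force all-pairs symmetric surface distances (oracle for ASSD/HD95)
brute_surface_distances <- function(pred, truth) {
  bmask <- function(mask) {
    d <- dim(mask)
    out <- NULL
    idx <- which(mask == 1L, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      exposed <- FALSE
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        n <- v; n[ax] <- n[ax] + dd
        if (n[ax] < 1 || n[ax] > d[ax] || mask[n[1], n[2], n[3]] == 0L) exposed <- TRUE
      }
      if (exposed) out <- rbind(out, v)
    }
    out
  }
  bp <- bmask(pred$mask); bt <- bmask(truth$mask)
  sp <- pred$spacing
  pw <- sweep((bp - 1), 2, sp, "*")
  tw <- sweep((bt - 1), 2, sp, "*")
  d2 <- outer(pw[, 1], tw[, 1], "-")^2 + outer(pw[, 2], tw[, 2], "-")^2 +
        outer(pw[, 3], tw[, 3], "-")^2
  dmat <- sqrt(d2)
  d_pt <- apply(dmat, 1, min)
  d_tp <- apply(dmat, 2, min)
  c(d_pt, d_tp)
}

# random small binary mask pair with guaranteed non-empty masks
random_mask_pair <- function(n = 8L, p = 0.2) {
  repeat {
    a <- array(as.integer(stats::runif(n^3) < p), c(n, n, n))
    b <- array(as.integer(stats::runif(n^3) < p), c(n, n, n))
    if (sum(a) > 0 && sum(b) > 0)
      return(list(pred = lumen_label(a, c(1, 1, 1)),
                  truth = lumen_label(b, c(1, 1, 1))))
  }
}

dice_of <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
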