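test_that("stenosis and phantom specs enforce their invariants", {
  expect_error(stenosis_spec("ICA", 10, 8, 100), "target_percent")
  expect_error(stenosis_spec("ICA", 10, -1, 50), "length")
  expect_error(stenosis_spec("XYZ", 10, 8, 50))
  # stenosis must lie strictly inside the branch arc-length range
  expect_error(phantom_spec(segment_length = 20,
                            stenosis_list = stenosis_spec("ICA", 19, 4, 50)),
               "outside branch")
  expect_error(phantom_spec(cca_radius = -1), "radii")
  expect_error(phantom_spec(spacing = c(0.5, 0, 0.5)), "spacing")
  # grid far too small for the tree
  expect_error(generate_phantom(phantom_spec(grid_shape = c(16L, 16L, 16L))),
               "grid too small")
})

test_that("phantom without stenosis has constant radius and zero true percent", {
  ph <- desk_phantom(noise_sd = 0)
  expect_equal(ph$truth$branches$ICA$true_percent, 0)
  expect_equal(ph$truth$branches$CCA$true_percent, 0)
  expect_equal(ph$truth$branches$ICA$true_mld, ph$truth$branches$ICA$true_rvd)
  # per-slice equivalent diameter of the z-aligned CCA recovers its radius
  # within one in-plane voxel (brute-force voxel counting)
  m <- ph$label$mask
  sp <- ph$label$spacing
  zs <- round((2 + c(4, 7, 10)) / sp[1])  # slices inside the CCA trunk
  for (z in zs + 1) {
    n_pix <- sum(m[z, , ])
    r_est <- sqrt(n_pix * sp[2] * sp[3] / pi)
    expect_lt(abs(r_est - 3.0), sp[2])
  }
})

test_that("a 70 percent ICA stenosis voxelizes to a 0.30 diameter ratio", {
  ph <- desk_phantom(stenosis = list(stenosis_spec("ICA", 6, 5, 70)),
                     noise_sd = 0)
  # brute-force per-slab voxel counting along the analytic ICA axis
  spec <- ph$truth$spec
  sp <- spec$spacing
  idx <- which(ph$label$mask == 1L, arr.ind = TRUE)
  w <- (idx - 1) * rep(sp, each = nrow(idx))
  ext <- (spec$grid_shape - 1) * sp
  a <- spec$bifurcation_angle / 2 * pi / 180
  pb <- c(spec$margin + spec$segment_length, ext[2] / 2, ext[3] / 2)
  dirv <- c(cos(a), sin(a), 0)
  rel <- sweep(w, 2, pb, "-")
  t <- as.numeric(rel %*% dirv)
  dist <- sqrt(rowSums((rel - outer(t, dirv))^2))
  slab_area <- function(t0) {
    sel <- t >= t0 - 0.5 & t < t0 + 0.5 & dist < spec$ica_radius + 1
    sum(sel) * prod(sp) / 1.0  # volume / slab thickness = mean area
  }
  d_throat <- 2 * sqrt(slab_area(6) / pi)
  d_ref <- 2 * sqrt(slab_area(12) / pi)
  expect_lt(abs(d_throat / d_ref - 0.30), 0.07)
})

test_that("labeled fraction is monotone non-increasing in target percent", {
  fr <- vapply(c(0, 40, 80), function(p) {
    st <- if (p > 0) list(stenosis_spec("ICA", 6, 6, p)) else list()
    label_fraction(desk_phantom(stenosis = st, noise_sd = 0)$label)
  }, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("noise-free image equals lumen intensity exactly on the lumen", {
  ph <- desk_phantom(noise_sd = 0)
  expect_true(all(ph$image$values[ph$label$mask == 1L] ==
                  ph$truth$spec$lumen_intensity))
})

test_that("identical seeds give bit-identical phantoms", {
  a <- desk_phantom(seed = 5L); b <- desk_phantom(seed = 5L)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$label$mask, b$label$mask)
  c_ <- desk_phantom(seed = 6L)
  expect_false(identical(a$image$values, c_$image$values))
})

test_that("ground truth is mld/rvd-consistent for stenosed branches", {
  ph <- desk_phantom(stenosis = list(stenosis_spec("ICA", 6, 5, 55)))
  br <- ph$truth$branches$ICA
  expect_equal(br$true_mld / br$true_rvd, 1 - br$true_percent / 100,
               tolerance = 1e-12)
})

test_that("generate_cohort writes a reproducible, correctly mixed cohort", {
  base <- phantom_spec(grid_shape = c(48L, 72L, 72L), segment_length = 11,
                       margin = 2)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  m1 <- generate_cohort(10, grade_mix = c(mild = 0.1, moderate = 0.4, severe = 0.5),
                        seed = 7L, out_dir = d1, base_spec = base)
  expect_equal(as.vector(table(factor(m1$grade, c("mild", "moderate", "severe")))),
               c(1L, 4L, 5L))
  m2 <- generate_cohort(10, grade_mix = c(mild = 0.1, moderate = 0.4, severe = 0.5),
                        seed = 7L, out_dir = d2, base_spec = base)
  expect_equal(m1$grade, m2$grade)
  expect_equal(m1$true_percent, m2$true_percent)
  # identical file contents under the same seed
  f1 <- file.path(d1, "lesion_003_label.nii.gz")
  f2 <- file.path(d2, "lesion_003_label.nii.gz")
  expect_identical(read_label(f1)$mask, read_label(f2)$mask)
  # manifest round trip
  mr <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(mr$lesion_id, m1$lesion_id)
  expect_true(all(mr$grade %in% c("mild", "moderate", "severe")))
  unlink(c(d1, d2), recursive = TRUE)
})
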