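test_that("centerline of a straight cylinder tracks the analytic axis", {
  tub <- straight_tube(radius = 3, length = 30, grid = c(90L, 40L, 40L),
                       spacing = c(0.4, 0.4, 0.4))
  cl <- extract_centerline(tub)
  expect_null(cl$bifurcation)           # single-branch mode
  expect_setequal(unique(cl$points$branch), "ICA")
  ctr <- (c(40, 40) - 1) * 0.4 / 2
  # off-axis deviation within one voxel at all sampled points
  dev <- sqrt((cl$points$y - ctr[1])^2 + (cl$points$z - ctr[2])^2)
  expect_lt(max(dev), 0.4 + 1e-9)
  expect_true(all(diff(cl$points$s) > 0))
})

test_that("Y-phantom centerlines carry three branches and one bifurcation", {
  ph <- desk_phantom(noise_sd = 0, seed = 4L)
  cl <- extract_centerline(ph$label)
  expect_setequal(unique(cl$points$branch), c("CCA", "ICA", "ECA"))
  expect_length(cl$bifurcation, 3L)
  # ICA is the wider distal branch: compare measured mean diameters distally
  prof <- area_profile(straighten(ph$label, cl))
  d_ica <- median(equivalent_diameter(prof$area[prof$branch == "ICA" & prof$s > 7]))
  d_eca <- median(equivalent_diameter(prof$area[prof$branch == "ECA" & prof$s > 7]))
  expect_gt(d_ica, d_eca)
  empty <- lumen_label(array(0L, c(8L, 8L, 8L)), c(1, 1, 1))
  expect_error(extract_centerline(empty), "empty")
  two <- array(0L, c(12L, 12L, 12L)); two[2:3, 2:3, 2:3] <- 1L; two[9:10, 9:10, 9:10] <- 1L
  expect_error(extract_centerline(lumen_label(two, c(1, 1, 1))), "connected")
})

test_that("straightened planes of a cylinder have the analytic area", {
  tub <- straight_tube(radius = 3, length = 30, grid = c(90L, 40L, 40L),
                       spacing = c(0.4, 0.4, 0.4))
  cl <- extract_centerline(tub)
  sv <- straighten(tub, cl)
  prof <- area_profile(sv, smooth_window = 1L)
  mid <- prof$area[prof$s > 4 & prof$s < max(prof$s) - 4]
  expect_true(all(abs(mid - pi * 9) / (pi * 9) < 0.10))
  expect_error(straighten(tub, cl, step = -1), "step")
})

test_that("straightening removes obliquity on a curved constant-radius tube", {
  tor <- torus_tube(r = 3, R = 18)
  cl <- extract_centerline(tor)
  sv <- straighten(tor, cl)
  prof <- area_profile(sv, smooth_window = 1L)
  mid <- prof$area[prof$s > 4 & prof$s < max(prof$s) - 4]
  expect_true(all(abs(mid - pi * 9) / (pi * 9) < 0.10))
})

test_that("a step longer than the vessel still yields at least one plane", {
  tub <- straight_tube(radius = 2, length = 6, grid = c(30L, 24L, 24L),
                       spacing = c(0.4, 0.4, 0.4))
  cl <- extract_centerline(tub, step = 50)
  sv <- straighten(tub, cl)
  expect_gte(nrow(cl$points), 1L)
  expect_gte(dim(sv$planes)[1], 1L)
})

test_that("area profile arithmetic and smoothing behave", {
  sv <- structure(list(planes = array(0L, c(3, 12, 12)),
                       branch = rep("ICA", 3), s = c(0, 0.5, 1),
                       step = 0.5, plane_spacing = 0.3, plane_n = 12L),
                  class = "straightened_vessel")
  sv$planes[2, 1:10, 1:10] <- 1L   # 100 pixels at 0.3 mm
  prof <- area_profile(sv, smooth_window = 1L)
  expect_equal(prof$area, c(0, 9, 0))
  expect_identical(prof$area, prof$area_smooth)  # window 1 = identity
  prof3 <- area_profile(sv, smooth_window = 3L)
  expect_equal(prof3$area_smooth[2], mean(c(0, 9, 0)))
})

test_that("equivalent diameter inverts the circle area", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(78.5398), 10, tolerance = 1e-5)
  expect_equal(equivalent_diameter(0), 0)
  expect_error(equivalent_diameter(-1))
})

test_that("MLD/RVD search respects guards, ties and strategies", {
  mk_prof <- function(areas, s = seq_along(areas) * 0.5 - 0.5,
                      branch = rep("ICA", length(areas))) {
    structure(data.frame(index = seq_along(areas), branch = branch, s = s,
                         area = areas, area_smooth = areas,
                         stringsAsFactors = FALSE),
              class = c("area_profile", "data.frame"))
  }
  # two equal minima: the more proximal one is reported
  a <- rep(20, 30); a[10] <- 5; a[20] <- 5
  pr <- mk_prof(a)
  expect_equal(find_mld(pr)$slice, 10)
  # guard excludes the first 2 mm beyond the bifurcation
  a2 <- rep(20, 30); a2[2] <- 1   # s = 0.5 mm, inside the guard
  expect_gt(find_mld(mk_prof(a2))$mld, equivalent_diameter(1))
  expect_error(find_mld(mk_prof(a, branch = rep("CCA", 30))), "ICA")
  # strategies disagree on a bulb + stenosis profile
  s <- seq(0, 19.5, by = 0.5)
  areas <- 18 + 14 * exp(-(s - 1)^2 / 4) - 12 * exp(-(s - 6)^2 / 2)
  pr2 <- mk_prof(areas, s = s)
  rvd_d <- find_rvd(pr2, "distal_ica")$rvd
  rvd_b <- find_rvd(pr2, "bulb_max")$rvd
  expect_gt(rvd_b, rvd_d)  # bulb maximum exceeds the distal median
})

test_that("NASCET percent hits the printed grade boundaries", {
  expect_equal(nascet_percent(3.0, 10.0), 70)
  expect_equal(nascet_percent(7.0, 10.0), 30)
  expect_equal(nascet_percent(4.8, 4.8), 0)
  expect_error(nascet_percent(1, 0), "rvd")
  expect_error(nascet_percent(5, 4), "inconsist")
})

test_that("grading uses closed upper boundaries and the two-class merge", {
  expect_equal(grade_stenosis(30), "mild")
  expect_equal(grade_stenosis(70), "moderate")
  expect_equal(grade_stenosis(85), "severe")
  expect_equal(grade_stenosis(30.0001), "moderate")
  expect_error(grade_stenosis(100), "occlusion")
  expect_error(grade_stenosis(-2))
  expect_equal(binarize_grade("mild"), "non-severe")
  expect_equal(binarize_grade("moderate"), "non-severe")
  expect_equal(binarize_grade("severe"), "severe")
  # boundary consistency through the composition
  expect_equal(grade_stenosis(nascet_percent(7, 10)), "mild")
  expect_equal(grade_stenosis(nascet_percent(3, 10)), "moderate")
})

test_that("quantify recovers the phantom stenosis and keeps mld <= rvd", {
  ph <- desk_phantom(stenosis = list(stenosis_spec("ICA", 10, 8, 70)),
                     noise_sd = 0, seed = 9L, grid = c(96L, 160L, 160L),
                     segment_length = 24)
  rep <- quantify(ph$label)
  expect_lt(abs(rep$percent - 70), 5)
  expect_lte(rep$mld, rep$rvd)
  expect_equal(rep$grade2, "non-severe")  # 70 is the closed moderate boundary
  # unstenosed phantom reads as (near-)zero
  ph0 <- desk_phantom(noise_sd = 0, seed = 9L)
  rep0 <- quantify(ph0$label)
  expect_lt(rep0$percent, 5)
  expect_equal(rep0$grade3, "mild")
  expect_lte(rep0$mld, rep0$rvd)
})

test_that("quantification is invariant to vessel curvature", {
  straight <- straight_tube(radius = 2.4, length = 28, grid = c(80L, 40L, 40L),
                            spacing = c(0.4, 0.3, 0.3))
  tor <- torus_tube(r = 2.4, R = 18, spacing = c(0.4, 0.3, 0.3))
  rs <- quantify(straight)
  rt <- quantify(tor)
  expect_lt(abs(rs$percent - rt$percent), 2)
})
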