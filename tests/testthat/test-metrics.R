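test_that("overlap metrics satisfy their defining identities", {
  p <- random_mask_pair(8L)
  # identity pair
  sm <- seg_metrics(p$truth, p$truth)
  expect_equal(sm$dsc, 1); expect_equal(sm$iou, 1); expect_equal(sm$rve, 0)
  expect_equal(sm$assd, 0); expect_equal(sm$hd95, 0); expect_equal(sm$sens, 1)
  # disjoint masks
  a <- array(0L, c(6, 6, 6)); a[1:2, 1:2, 1:2] <- 1L
  b <- array(0L, c(6, 6, 6)); b[5:6, 5:6, 5:6] <- 1L
  sm2 <- seg_metrics(lumen_label(a, c(1, 1, 1)), lumen_label(b, c(1, 1, 1)))
  expect_equal(sm2$dsc, 0); expect_equal(sm2$iou, 0)
  # hand-counted case: |P| = 4, |T| = 6, |P n T| = 3
  pa <- array(0L, c(4, 4, 4)); pa[1:4, 1, 1] <- 1L
  ta <- array(0L, c(4, 4, 4)); ta[2:4, 1, 1] <- 1L; ta[1:3, 2, 1] <- 1L
  sm3 <- seg_metrics(lumen_label(pa, c(1, 1, 1)), lumen_label(ta, c(1, 1, 1)))
  expect_equal(sm3$dsc, 2 * 3 / (4 + 6))
  expect_equal(sm3$iou, 3 / 7)
  expect_equal(sm3$sens, 0.5)
  expect_equal(sm3$rve, abs(4 - 6) / 6)
  # error signals
  e <- lumen_label(array(0L, c(8, 8, 8)), c(1, 1, 1))
  expect_error(seg_metrics(e, e), class = "carotidseg_undefined_metric")
  expect_error(seg_metrics(p$pred, e), class = "carotidseg_undefined_metric")
})

test_that("surface distances equal the brute-force all-pairs oracle", {
  # unit cube shifted by one voxel along one axis
  a <- array(0L, c(8, 8, 8)); a[2:4, 2:4, 2:4] <- 1L
  b <- array(0L, c(8, 8, 8)); b[3:5, 2:4, 2:4] <- 1L
  pl <- lumen_label(a, c(1, 1, 1)); tl <- lumen_label(b, c(1, 1, 1))
  sm <- seg_metrics(pl, tl)
  pooled <- brute_surface_distances(pl, tl)
  expect_equal(sm$assd, mean(pooled), tolerance = 1e-12)
  expect_equal(sm$hd95, as.numeric(quantile(pooled, 0.95, type = 7)),
               tolerance = 1e-12)
  # property: random pairs, including anisotropic spacing
  set.seed(5)
  for (i in 1:15) {
    pr <- random_mask_pair(7L)
    sp <- c(0.7, 0.5, 0.5)
    pl <- lumen_label(pr$pred$mask, sp); tl <- lumen_label(pr$truth$mask, sp)
    sm <- seg_metrics(pl, tl)
    pooled <- brute_surface_distances(pl, tl)
    expect_equal(sm$assd, mean(pooled), tolerance = 1e-10)
    expect_equal(sm$hd95, as.numeric(quantile(pooled, 0.95, type = 7)),
                 tolerance = 1e-10)
    # dsc = 2 iou / (1 + iou) identity
    expect_equal(sm$dsc, 2 * sm$iou / (1 + sm$iou), tolerance = 1e-12)
  }
})

test_that("diagnostic metrics match the 2x2 definitions and rank AUC", {
  d <- diag_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), scores = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unlist(d[c("acc", "f1", "sens", "precision", "spec", "auc")]),
               c(acc = 1, f1 = 1, sens = 1, precision = 1, spec = 1, auc = 1))
  # all-positive predictions on balanced truth
  d2 <- diag_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(d2$sens, 1); expect_equal(d2$spec, 0); expect_equal(d2$acc, 0.5)
  # Mann-Whitney enumeration: truth (1,1,0,0), scores (0.9, 0.4, 0.6, 0.1)
  d3 <- diag_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0), scores = c(0.9, 0.4, 0.6, 0.1))
  expect_equal(d3$auc, 0.75)
  expect_equal(sum(d3$confusion), 4)
  # cross-check AUC against pROC on a larger draw
  skip_if_not_installed("pROC")
  set.seed(8)
  tr <- rbinom(60, 1, 0.5); sc <- runif(60) + 0.4 * tr
  d4 <- diag_metrics(tr, as.integer(sc > 0.6), scores = sc)
  expect_equal(d4$auc,
               as.numeric(suppressMessages(pROC::auc(tr, sc, direction = "<"))),
               tolerance = 1e-12)
  # permutation invariance
  perm <- sample(60)
  d5 <- diag_metrics(tr[perm], as.integer(sc > 0.6)[perm], scores = sc[perm])
  expect_equal(d5[c("acc", "f1", "sens", "precision", "spec", "auc")],
               d4[c("acc", "f1", "sens", "precision", "spec", "auc")])
  expect_error(diag_metrics(c(1, 1), c(1, 0), scores = c(0.2, 0.3)),
               class = "carotidseg_undefined_metric")
})

test_that("concordance correlation matches hand algebra and bounds", {
  x <- c(1, 2, 3)
  expect_equal(ccc(x, x)$est, 1)
  expect_equal(ccc(c(-1, 0, 1), c(1, 0, -1))$est, -1)
  # shifted line: 2*(2/3) / ((2/3) + (2/3) + 1) = 4/7
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4))$est, 4 / 7, tolerance = 1e-12)
  # |ccc| <= |pearson| on random pairs; CI brackets the estimate
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30, sd = 0.5) + runif(1, -1, 1)
    cc <- ccc(a, b)
    expect_lte(abs(cc$est), abs(cor(a, b)) + 1e-12)
    expect_lte(cc$lwr, cc$est); expect_gte(cc$upr, cc$est)
  }
  expect_error(ccc(rep(1, 5), rep(2, 5)), class = "carotidseg_undefined_metric")
  expect_error(ccc(1:2, 1:2), "n >= 3")
})

test_that("ICC(A,1) reproduces ANOVA mean-squares arithmetic", {
  # identical raters
  r <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), 4, 2)
  expect_equal(icc_agreement(r)$est, 1)
  # hand-computed 4x2 table
  tab <- matrix(c(9, 6, 8, 7, 2, 1, 4, 3), 4, 2)
  n <- 4; k <- 2; gm <- mean(tab)
  msr <- k * sum((rowMeans(tab) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(tab) - gm)^2) / (k - 1)
  mse <- (sum((tab - gm)^2) - k * sum((rowMeans(tab) - gm)^2) -
          n * sum((colMeans(tab) - gm)^2)) / ((n - 1) * (k - 1))
  manual <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  got <- icc_agreement(tab)
  expect_equal(got$est, manual, tolerance = 1e-12)
  expect_lte(got$lwr, got$est); expect_gte(got$upr, got$est)
  # independent noise raters agree at ~0
  set.seed(3)
  noise <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc_agreement(noise)$est), 0.15)
  expect_error(icc_agreement(matrix(1, 2, 2)), "subjects")
})

test_that("signed-rank test matches exhaustive enumeration and base R", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5),
               class = "carotidseg_undefined_metric")
  set.seed(21)
  x <- rnorm(5); y <- x + rnorm(5)
  got <- wilcoxon_signed_rank(x, y)
  # oracle: enumerate all 2^5 sign assignments of the rank sums
  d <- x - y; r <- rank(abs(d)); V <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  Vs <- as.matrix(signs) %*% r
  p_exact <- 2 * min(mean(Vs <= V), mean(Vs >= V))
  expect_equal(got$p, min(1, p_exact), tolerance = 1e-12)
  expect_equal(got$statistic, V)
  # agreement with stats::wilcox.test in the exact, tie-free regime
  bt <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(got$p, bt$p.value, tolerance = 1e-12)
  # large-n normal approximation is close to base R's
  x2 <- rnorm(40); y2 <- x2 + rnorm(40, 0.3)
  gotn <- wilcoxon_signed_rank(x2, y2)
  btn <- wilcox.test(x2, y2, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(gotn$p, btn$p.value, tolerance = 1e-6)
  expect_identical(gotn$significant, gotn$p < 0.05)
})

test_that("subgroup summaries equal direct per-group computation", {
  res <- data.frame(
    lesion_id = sprintf("l%d", 1:8),
    grade = rep(c("severe", "moderate"), each = 4),
    scanner_tag = rep(c("ScI", "ScII"), 4),
    dsc = c(0.9, 0.92, 0.88, 0.95, 0.8, 0.82, 0.85, 0.83),
    true_percent = c(80, 85, 75, 90, 40, 45, 50, 55),
    est_percent = c(78, 86, 74, 88, 42, 44, 52, 56),
    stringsAsFactors = FALSE)
  # single subgroup equals the global summary
  one <- subgroup_report(cbind(res, all = "a"), keys = "all")
  expect_equal(one$dsc_mean, mean(res$dsc))
  expect_equal(one$dsc_sd, sd(res$dsc))
  expect_equal(one$ccc, ccc(res$true_percent, res$est_percent)$est)
  # two disjoint subgroups partition the lesions
  two <- subgroup_report(res, keys = "grade")
  expect_equal(sum(two$n), nrow(res))
  for (g in c("severe", "moderate")) {
    sub <- res[res$grade == g, ]
    row <- two[two$grade == g, ]
    expect_equal(row$dsc_mean, mean(sub$dsc))
    expect_equal(row$ccc, ccc(sub$true_percent, sub$est_percent)$est)
  }
  expect_error(subgroup_report(res, keys = "missing_col"), "missing key")
})
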