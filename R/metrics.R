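# Segmentation, diagnostic and agreement statistics.

undefined_metric <- function(msg) {
  stop(structure(class = c("carotidseg_undefined_metric", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Segmentation overlap and surface metrics
#'
#' Voxel-overlap metrics (Dice, IoU, relative volume error, sensitivity,
#' specificity) plus surface distances in mm: the average symmetric surface
#' distance (ASSD) and the 95th percentile of the pooled symmetric surface
#' distances (HD95). Surfaces are boundary voxels by 6-connectivity face
#' exposure; nearest distances come from an exact Euclidean distance
#' transform honoring the anisotropic spacing. Specificity is computed on
#' the union bounding box plus margin rather than the full grid, where the
#' background dominance of neck volumes would pin it at 1.
#'
#' @param pred,truth aligned [lumen_label()]s.
#' @param spec_margin margin (voxels) around the union bounding box for the
#'   specificity crop.
#' @return list of class \code{seg_metrics}: \code{dsc}, \code{iou},
#'   \code{rve}, \code{sens}, \code{spec}, \code{assd}, \code{hd95}.
#' @export
seg_metrics <- function(pred, truth, spec_margin = 8L) {
  check_aligned(volume_image(array(0, dim(pred$mask)), pred$spacing), truth)
  if (!identical(dim(pred$mask), dim(truth$mask))) stop("shape mismatch")
  P <- sum(pred$mask); T_ <- sum(truth$mask)
  if (P == 0 && T_ == 0) undefined_metric("both masks empty: metrics undefined")
  I <- sum(pred$mask & truth$mask)
  dsc <- 2 * I / (P + T_)
  iou <- I / (P + T_ - I)
  rve <- if (T_ == 0) undefined_metric("truth empty: rve undefined") else abs(P - T_) / T_
  sens <- if (T_ == 0) NA_real_ else I / T_
  # specificity on the union-bbox crop
  idx <- which((pred$mask | truth$mask) == 1L, arr.ind = TRUE)
  d <- dim(pred$mask)
  lo <- pmax(apply(idx, 2, min) - spec_margin, 1L)
  hi <- pmin(apply(idx, 2, max) + spec_margin, d)
  pm <- pred$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  tm <- truth$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  tn <- sum(pm == 0L & tm == 0L); fp <- sum(pm == 1L & tm == 0L)
  spc <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  if (P > 0 && T_ > 0) {
    bp <- boundary_mask(pred$mask); bt <- boundary_mask(truth$mask)
    dt_t <- sqrt(.edt_sq(array(as.integer(bt), d), truth$spacing))
    dt_p <- sqrt(.edt_sq(array(as.integer(bp), d), pred$spacing))
    d_pt <- dt_t[bp]   # pred surface -> truth surface
    d_tp <- dt_p[bt]
    pooled <- c(d_pt, d_tp)
    assd <- mean(pooled)
    hd95 <- as.numeric(stats::quantile(pooled, 0.95, type = 7))
  } else {
    assd <- NA_real_; hd95 <- NA_real_
  }
  structure(list(dsc = dsc, iou = iou, rve = rve, sens = sens, spec = spc,
                 assd = assd, hd95 = hd95), class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("DSC %.4f | IoU %.4f | RVE %.4f | Sens %s | Spec %s | ASSD %s mm | HD95 %s mm\n",
              x$dsc, x$iou, x$rve,
              ifelse(is.na(x$sens), "NA", sprintf("%.4f", x$sens)),
              ifelse(is.na(x$spec), "NA", sprintf("%.4f", x$spec)),
              ifelse(is.na(x$assd), "NA", sprintf("%.3f", x$assd)),
              ifelse(is.na(x$hd95), "NA", sprintf("%.3f", x$hd95))))
  invisible(x)
}

#' Per-artery diagnostic metrics
#'
#' Standard 2x2 diagnostic statistics for the severe / non-severe decision,
#' with AUC as the Mann-Whitney rank statistic over a continuous score
#' (typically the measured NASCET percent).
#'
#' @param truth binary vector (1 = severe).
#' @param pred binary vector of predicted classes.
#' @param scores optional continuous scores for AUC.
#' @return list of class \code{diag_metrics}: \code{acc}, \code{f1},
#'   \code{sens}, \code{precision}, \code{spec}, \code{auc} (NA without
#'   scores) and the 2x2 \code{confusion} matrix.
#' @export
diag_metrics <- function(truth, pred, scores = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("length mismatch")
  tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  acc <- (tp + tn) / length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  spc <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(truth)) < 2)
      undefined_metric("auc undefined: single-class truth")
    s1 <- scores[truth == 1]; s0 <- scores[truth == 0]
    cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
    auc <- mean(cmp)
  }
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(pred = c("severe", "non-severe"),
                                      truth = c("severe", "non-severe")))
  structure(list(acc = acc, f1 = f1, sens = sens, precision = prec,
                 spec = spc, auc = auc, confusion = confusion),
            class = "diag_metrics")
}

#' @export
print.diag_metrics <- function(x, ...) {
  cat(sprintf("Acc %.3f | F1 %.3f | Sens %.3f | Precision %.3f | Spec %.3f | AUC %s\n",
              x$acc, x$f1, x$sens, x$precision, x$spec,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  print(x$confusion)
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired continuous measurements around the identity line:
#' \code{ccc = 2 cov(x, y) / (var x + var y + (mean x - mean y)^2)} with
#' population (1/n) moments. The confidence interval uses Lin's
#' z-transformation with the asymptotic variance of the transformed
#' estimate.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param conf confidence level.
#' @return list of class \code{ccc}: \code{est}, \code{lwr}, \code{upr}.
#' @export
ccc <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 3) stop("need n >= 3")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0)
    undefined_metric("ccc undefined: zero variance in both vectors")
  sxy <- mean((x - mx) * (y - my))
  est <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  if (abs(est) >= 1 - 1e-12) {
    lwr <- upr <- est
  } else {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^0.25
    C <- est
    z <- atanh(C)
    sz2 <- ((1 - r^2) * C^2 / ((1 - C^2) * r^2) +
            4 * C^3 * (1 - C) * u^2 / (r * (1 - C^2)^2) -
            2 * C^4 * u^4 / (r^2 * (1 - C^2)^2)) / (n - 2)
    q <- stats::qnorm(1 - (1 - conf) / 2)
    lwr <- tanh(z - q * sqrt(max(sz2, 0)))
    upr <- tanh(z + q * sqrt(max(sz2, 0)))
  }
  structure(list(est = est, lwr = lwr, upr = upr, conf = conf), class = "ccc")
}

#' @export
print.ccc <- function(x, ...) {
  cat(sprintf("CCC %.4f (%d%% CI %.4f-%.4f)\n", x$est, round(100 * x$conf),
              x$lwr, x$upr))
  invisible(x)
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' ICC(A,1) from the two-way ANOVA decomposition of an n x k ratings table
#' (subjects x raters), with the F-distribution confidence interval of
#' McGraw and Wong.
#'
#' @param ratings numeric matrix, n subjects (rows) x k raters (columns).
#' @param conf confidence level.
#' @return list of class \code{icc}: \code{est}, \code{lwr}, \code{upr}.
#' @export
icc_agreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must be finite")
  gm <- mean(ratings)
  rm <- rowMeans(ratings); cm <- colMeans(ratings)
  ssr <- k * sum((rm - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0) undefined_metric("icc undefined: degenerate variance")
  est <- (msr - mse) / denom
  alpha <- 1 - conf
  if (mse == 0 && msc == 0) {
    lwr <- upr <- est
  } else {
    a <- k * est / (n * (1 - est)); b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
         ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lwr <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upr <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  structure(list(est = est, lwr = lwr, upr = upr, conf = conf), class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) %.4f (%d%% CI %.4f-%.4f)\n", x$est,
              round(100 * x$conf), x$lwr, x$upr))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ties get average ranks. The null
#' distribution is enumerated exactly (over all sign assignments, via the
#' rank-sum convolution) for n <= 25 and approximated normally with tie
#' correction and continuity correction otherwise. Significance is flagged
#' at the 0.05 level.
#'
#' @param x,y paired numeric vectors.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return list of class \code{wilcoxon_sr}: \code{statistic} (V, the
#'   positive-rank sum), \code{p}, \code{n} (non-zero pairs),
#'   \code{method}, \code{significant}.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d))
    undefined_metric("all differences zero: test undefined")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    # exact enumeration via convolution over doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    cnt <- numeric(maxs + 1); cnt[1] <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), cnt[seq_len(maxs + 1 - rr)])
      cnt <- cnt + shifted
    }
    probs <- cnt / sum(cnt)
    v2 <- round(2 * V)
    p_le <- sum(probs[seq_len(v2 + 1)])
    p_ge <- sum(probs[(v2 + 1):(maxs + 1)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z <- switch(alternative,
                two.sided = (V - mu - sign(V - mu) * cc) / sqrt(sig2),
                greater = (V - mu - cc) / sqrt(sig2),
                less = (V - mu + cc) / sqrt(sig2))
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(statistic = V, p = p, n = n, method = method,
                 significant = p < 0.05, alternative = alternative),
            class = "wilcoxon_sr")
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %g, n = %d, p = %.4g (%s)%s\n",
              x$statistic, x$n, x$p, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Subgroup summaries of per-lesion results
#'
#' Groups a per-lesion results table by the given keys (e.g. grade and
#' scanner tag) and reports mean and sd of every numeric metric column per
#' subgroup, plus the concordance correlation between true and estimated
#' percent when both columns are present.
#'
#' @param results data.frame with one row per lesion.
#' @param keys character vector of grouping columns present in
#'   \code{results}.
#' @param metrics numeric columns to summarize (default: all numeric except
#'   the CCC inputs).
#' @return data.frame with one row per subgroup.
#' @export
subgroup_report <- function(results, keys,
                            metrics = NULL) {
  if (!all(keys %in% names(results)))
    stop("missing key columns: ", paste(setdiff(keys, names(results)), collapse = ", "))
  ccc_cols <- c("true_percent", "est_percent")
  if (is.null(metrics)) {
    num <- vapply(results, is.numeric, logical(1))
    metrics <- setdiff(names(results)[num], ccc_cols)
  }
  key <- interaction(results[keys], drop = TRUE, sep = "/")
  rows <- lapply(levels(key), function(lv) {
    sub <- results[key == lv, , drop = FALSE]
    if (!nrow(sub)) { warning("empty subgroup ", lv, " omitted"); return(NULL) }
    out <- sub[1, keys, drop = FALSE]
    out$n <- nrow(sub)
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(sub[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(sub[[m]])
    }
    if (all(ccc_cols %in% names(sub)) && nrow(sub) >= 3) {
      cc <- tryCatch(ccc(sub$true_percent, sub$est_percent), error = function(e) NULL)
      out$ccc <- if (is.null(cc)) NA_real_ else cc$est
      out$ccc_lwr <- if (is.null(cc)) NA_real_ else cc$lwr
      out$ccc_upr <- if (is.null(cc)) NA_real_ else cc$upr
    }
    out
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
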