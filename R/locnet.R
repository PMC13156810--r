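#' Build the 2D localization network
#'
#' @param cfg a [unet2d_config()].
#' @param seed integer seed for weight initialization.
#' @return a \code{unet_model}.
#' @export
build_locnet <- function(cfg = unet2d_config(), seed = 1L) {
  stopifnot(cfg$dim == 2L)
  build_unet(cfg, seed)
}

# mean-pool a 2D slice by an integer factor (truncating ragged edges)
pool_slice <- function(sl, f) {
  f <- as.integer(f)
  n1 <- (nrow(sl) %/% f) * f; n2 <- (ncol(sl) %/% f) * f
  sl <- sl[seq_len(n1), seq_len(n2)]
  out <- matrix(0, n1 %/% f, n2 %/% f)
  for (a in seq_len(f)) for (b in seq_len(f))
    out <- out + sl[seq(a, n1, by = f), seq(b, n2, by = f)]
  out / f^2
}

# pad a (H, W, 1, 1)/(X, Y, Z, 1) pair so spatial dims divide `divs`
pad_pair <- function(x4, t4, divs) {
  pad <- (divs - dim(x4)[1:3] %% divs) %% divs
  if (all(pad == 0)) return(list(x = x4, t = t4))
  nd <- dim(x4)[1:3] + pad
  xp <- array(0, c(nd, 1L)); tp <- array(0, c(nd, 1L))
  xp[seq_len(dim(x4)[1]), seq_len(dim(x4)[2]), seq_len(dim(x4)[3]), ] <- x4
  tp[seq_len(dim(t4)[1]), seq_len(dim(t4)[2]), seq_len(dim(t4)[3]), ] <- t4
  list(x = xp, t = tp)
}

#' Pad an array so each spatial axis is divisible by a factor
#'
#' Zero-pads at the high end. Use \code{attr(out, "orig_shape")} to un-pad.
#'
#' @param arr 2D or 3D numeric array.
#' @param div integer divisibility factor (per spatial axis).
#' @return padded array with the original shape recorded as an attribute.
#' @export
pad_to_divisible <- function(arr, div) {
  d <- dim(arr)
  pad <- (div - d %% div) %% div
  if (all(pad == 0)) { attr(arr, "orig_shape") <- d; return(arr) }
  out <- array(0, d + pad)
  idx <- lapply(d, seq_len)
  out[idx[[1]], idx[[2]], if (length(d) > 2) idx[[3]] else 1] <- arr
  attr(out, "orig_shape") <- d
  out
}

#' Train the localization network on (slice, ROI-target) pairs
#'
#' Minimizes the combined BCE + Dice loss with SGD-Nesterov under the
#' polynomial learning-rate decay of [lr_schedule()]. Targets are the
#' inflated ROI labels from [inflate_labels()], not the raw lumen: the
#' network learns the region around the artery. With
#' \code{schedule$total_epochs = 0} the model is returned unchanged.
#'
#' @param model a model from [build_locnet()].
#' @param slices list of training samples, each \code{list(x =, y =)} with a
#'   numeric slice matrix and a binary target matrix of the same shape.
#' @param schedule a [train_schedule()]; \code{batch_size} defaults to the
#'   2D batch size of 12.
#' @param steps_per_epoch batches per epoch (batches are drawn with
#'   replacement when the dataset is smaller than a batch).
#' @return list with \code{model} (trained) and \code{history} (data.frame of
#'   epoch, lr, loss).
#' @export
train_locnet <- function(model, slices, schedule = train_schedule(batch_size = 12L),
                         steps_per_epoch = NULL) {
  stopifnot(model$cfg$dim == 2L)
  if (length(slices) == 0) stop("empty dataset")
  div <- 2L^(model$cfg$encoder_stages - 1L)
  divs <- c(div, div, 1L)
  bs <- schedule$batch_size
  if (is.null(steps_per_epoch))
    steps_per_epoch <- max(1L, length(slices) %/% bs)
  hist <- vector("list", schedule$total_epochs)
  if (schedule$total_epochs == 0)
    return(list(model = model, history = data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0))))
  state <- NULL
  with_seed(schedule$seed, {
    for (ep in seq_len(schedule$total_epochs)) {
      lr <- lr_schedule(ep - 1L, schedule)
      losses <- numeric(steps_per_epoch)
      for (st in seq_len(steps_per_epoch)) {
        take <- sample.int(length(slices), bs, replace = length(slices) < bs)
        acc <- NULL; lsum <- 0
        for (i in take) {
          s <- slices[[i]]
          pp <- pad_pair(array(s$x, c(dim(s$x), 1L, 1L)),
                         array(s$y, c(dim(s$y), 1L, 1L)), divs)
          lg <- unet_loss_grads(model, pp$x, pp$t, schedule$loss_weights)
          lsum <- lsum + lg$loss
          acc <- if (is.null(acc)) lg$grads
                 else map2_params(acc, lg$grads, `+`)
        }
        acc <- rapply(acc, function(g) g / bs, how = "replace")
        stp <- sgd_nesterov_step(model$params, acc, state, lr, schedule$momentum)
        model$params <- stp$params; state <- stp$state
        losses[st] <- lsum / bs
      }
      hist[[ep]] <- data.frame(epoch = ep, lr = lr, loss = mean(losses))
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' ROI placement record
#'
#' Book-keeping that lets a crop be re-embedded exactly: the global crop box
#' (1-based inclusive voxel index ranges) and the original volume shape.
#'
#' @param lo,hi integer triples, crop box corners (inclusive).
#' @param original_shape shape of the volume the box lives in.
#' @param slice_boxes optional per-slice bounding boxes (matrix with columns
#'   slice, r0, r1, c0, c1).
#' @return list of class \code{roi_placement}.
#' @export
roi_placement <- function(lo, hi, original_shape, slice_boxes = NULL) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  original_shape <- as.integer(original_shape)
  if (any(lo < 1L) || any(hi > original_shape) || any(hi < lo))
    stop("placement out of bounds")
  structure(list(lo = lo, hi = hi, original_shape = original_shape,
                 slice_boxes = slice_boxes), class = "roi_placement")
}

#' Predict the carotid ROI on a preprocessed volume
#'
#' Runs the 2D network slice by slice, thresholds the probabilities, and
#' returns per-slice masks plus the global crop box: the union bounding box
#' over slices, expanded by \code{margin} voxels per axis and clipped to the
#' volume. Signals a condition of class \code{carotidseg_no_roi} when no
#' voxel exceeds the threshold.
#'
#' @param model trained 2D model.
#' @param vol a (preprocessed) [volume_image()].
#' @param threshold probability threshold (default 0.5).
#' @param margin crop-box expansion, voxels per axis.
#' @param largest_component restrict the thresholded prediction to its
#'   largest 3D connected component before the box is computed. The carotid
#'   ROI is one connected tube, and a union bounding box is hopelessly
#'   sensitive to a single stray false-positive pixel, so this is on by
#'   default.
#' @param downsample integer in-plane pooling factor: slices are mean-pooled
#'   by this factor before the network sees them and the predicted masks are
#'   re-expanded. Localization only has to place a generous box, so a coarse
#'   factor (2 in the desk profile) trades no practical accuracy for a large
#'   speedup; the model must have been trained on equally pooled slices.
#' @return list with \code{masks} (binary array like the volume) and
#'   \code{placement} (a [roi_placement()]).
#' @export
predict_roi <- function(model, vol, threshold = 0.5, margin = 8L,
                        largest_component = TRUE, downsample = 1L) {
  v <- vol$values
  d <- dim(v)
  masks <- array(0L, d)
  for (i in seq_len(d[1])) {
    sl <- if (downsample > 1L) pool_slice(v[i, , ], downsample) else v[i, , ]
    p <- unet_predict(model, sl)
    m <- p >= threshold
    if (downsample > 1L)
      m <- m[rep(seq_len(nrow(m)), each = downsample),
             rep(seq_len(ncol(m)), each = downsample)][seq_len(d[2]),
                                                       seq_len(d[3])]
    if (any(m)) masks[i, , ][m] <- 1L
  }
  if (!any(masks == 1L))
    stop(structure(class = c("carotidseg_no_roi", "error", "condition"),
                   list(message = "no ROI found: no slice exceeds the threshold",
                        call = sys.call())))
  if (largest_component) {
    lc <- label_components(masks)
    if (lc$n > 1L) {
      sizes <- tabulate(lc$comp[lc$comp > 0L], nbins = lc$n)
      masks <- array(as.integer(lc$comp == which.max(sizes)), d)
    }
  }
  boxes <- NULL
  for (i in seq_len(d[1])) {
    m <- masks[i, , ] == 1L
    if (any(m)) {
      rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
      boxes <- rbind(boxes, c(i, rr[1], rr[2], cc[1], cc[2]))
    }
  }
  colnames(boxes) <- c("slice", "r0", "r1", "c0", "c1")
  lo <- c(min(boxes[, "slice"]), min(boxes[, "r0"]), min(boxes[, "c0"])) - margin
  hi <- c(max(boxes[, "slice"]), max(boxes[, "r1"]), max(boxes[, "c1"])) + margin
  lo <- pmax(lo, 1L); hi <- pmin(hi, d)
  list(masks = masks,
       placement = roi_placement(lo, hi, d, slice_boxes = boxes))
}

#' Oracle ROI placement from a ground-truth label
#'
#' Bounding box of the labeled voxels plus a margin; used to exercise the
#' cascade independently of localization quality.
#'
#' @param label a [lumen_label()].
#' @param margin expansion in voxels per axis.
#' @return a [roi_placement()].
#' @export
roi_from_label <- function(label, margin = 8L) {
  idx <- which(label$mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop(structure(class = c("carotidseg_no_roi", "error", "condition"),
                   list(message = "no ROI found: label is empty", call = sys.call())))
  d <- dim(label$mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  roi_placement(lo, hi, d)
}

#' Crop a volume (and optionally its label) to an ROI
#'
#' @param vol a [volume_image()].
#' @param label optional aligned [lumen_label()].
#' @param placement a [roi_placement()].
#' @return list with cropped \code{vol}, \code{label} (or NULL) and the
#'   \code{placement}.
#' @export
crop_to_roi <- function(vol, label = NULL, placement) {
  stopifnot(inherits(placement, "roi_placement"))
  d <- if (inherits(vol, "volume_image")) dim(vol$values) else dim(vol$mask)
  if (!identical(as.integer(d), placement$original_shape))
    stop("placement does not match volume shape")
  ix <- lapply(1:3, function(k) placement$lo[k]:placement$hi[k])
  sub <- function(a) a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  out_vol <- if (inherits(vol, "volume_image"))
    volume_image(sub(vol$values), vol$spacing,
                 vol$origin + (placement$lo - 1L) * vol$spacing)
  else lumen_label(sub(vol$mask), vol$spacing,
                   vol$origin + (placement$lo - 1L) * vol$spacing)
  out_lab <- if (!is.null(label))
    lumen_label(sub(label$mask), label$spacing,
                label$origin + (placement$lo - 1L) * label$spacing)
  list(vol = out_vol, label = out_lab, placement = placement)
}

#' Embed an ROI-sized mask back into the full volume
#'
#' Inverse of [crop_to_roi()]: inside the crop box the embedded mask equals
#' the input, outside it is zero.
#'
#' @param submask binary array (or [lumen_label()]) of the crop-box shape.
#' @param placement the [roi_placement()] used for cropping.
#' @param spacing,origin geometry of the full volume (taken from the submask
#'   when it is a label).
#' @return full-size [lumen_label()].
#' @export
embed_from_roi <- function(submask, placement, spacing = NULL, origin = c(0, 0, 0)) {
  stopifnot(inherits(placement, "roi_placement"))
  if (inherits(submask, "lumen_label")) {
    spacing <- submask$spacing
    origin <- submask$origin - (placement$lo - 1L) * spacing
    submask <- submask$mask
  }
  want <- placement$hi - placement$lo + 1L
  if (!identical(as.integer(dim(submask)), want))
    stop("submask shape does not match placement box")
  full <- array(0L, placement$original_shape)
  full[placement$lo[1]:placement$hi[1], placement$lo[2]:placement$hi[2],
       placement$lo[3]:placement$hi[3]] <- as.integer(submask)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  lumen_label(full, spacing, origin)
}
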