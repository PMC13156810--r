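#' Training schedule
#'
#' The optimization recipe shared by both networks: SGD with Nesterov
#' momentum 0.99, initial learning rate 0.01 decayed polynomially
#' (exponent 0.9) to zero over \code{total_epochs} (default 1000), combined
#' BCE + Dice loss with 1:1 weights, deep supervision on. Default batch
#' sizes are 12 for the 2D network and 4 for the 3D one.
#'
#' @param batch_size samples per optimization step.
#' @param total_epochs training length (epochs).
#' @param initial_lr initial learning rate.
#' @param poly_exponent polynomial decay exponent.
#' @param momentum Nesterov momentum.
#' @param deep_supervision enable auxiliary decoder losses.
#' @param loss_weights named \code{c(bce =, dice =)} weights, positive.
#' @param seed seed governing batch order and patch draws.
#' @return list of class \code{train_schedule}.
#' @export
train_schedule <- function(batch_size = 4L, total_epochs = 1000L,
                           initial_lr = 0.01, poly_exponent = 0.9,
                           momentum = 0.99, deep_supervision = TRUE,
                           loss_weights = c(bce = 1, dice = 1), seed = 1L) {
  if (any(loss_weights <= 0)) stop("loss weights must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 total_epochs = as.integer(total_epochs),
                 initial_lr = initial_lr, poly_exponent = poly_exponent,
                 momentum = momentum, deep_supervision = isTRUE(deep_supervision),
                 loss_weights = loss_weights, seed = as.integer(seed)),
            class = "train_schedule")
}

#' Polynomial learning-rate decay
#'
#' \code{lr(epoch) = initial_lr * (1 - epoch / total_epochs)^poly_exponent}:
#' the initial rate at epoch 0, strictly decreasing, exactly 0 at the final
#' epoch.
#'
#' @param epoch current epoch, in \code{[0, total_epochs]}.
#' @param sched a [train_schedule()].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, sched = train_schedule()) {
  if (epoch < 0 || epoch > sched$total_epochs)
    stop("epoch out of range [0, ", sched$total_epochs, "]")
  sched$initial_lr * (1 - epoch / sched$total_epochs)^sched$poly_exponent
}

#' Patch sampling specification
#'
#' Random crops fed to the 3D network: \code{n_patches} uniformly random
#' corner positions of fixed \code{patch_size} per ROI (default 4 patches of
#' 128 x 192 x 192).
#'
#' @param n_patches patches per volume.
#' @param patch_size integer triple.
#' @param seed integer seed.
#' @return list of class \code{patch_spec}.
#' @export
patch_spec <- function(n_patches = 4L, patch_size = c(128L, 192L, 192L),
                       seed = 1L) {
  structure(list(n_patches = as.integer(n_patches),
                 patch_size = as.integer(patch_size), seed = as.integer(seed)),
            class = "patch_spec")
}

# zero-pad a 3D array at the high end to at least `size`
pad_to_size <- function(arr, size, fill = 0) {
  d <- dim(arr)
  if (all(d >= size)) return(arr)
  nd <- pmax(d, size)
  out <- array(fill, nd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out
}

#' Randomly crop patches from an aligned image/label pair
#'
#' Inputs smaller than the patch are zero-padded first, so a patch always
#' fits; corners are drawn uniformly and reproducibly from \code{spec$seed}.
#'
#' @param vol a [volume_image()] (typically an ROI crop, z-normalized).
#' @param label the aligned [lumen_label()].
#' @param spec a [patch_spec()].
#' @return list of \code{spec$n_patches} elements, each
#'   \code{list(x =, y =)} of arrays of \code{patch_size}.
#' @export
crop_patches <- function(vol, label, spec = patch_spec()) {
  check_aligned(vol, label)
  ps <- spec$patch_size
  v <- pad_to_size(vol$values, ps)
  m <- pad_to_size(label$mask, ps, fill = 0L)
  d <- dim(v)
  corners <- with_seed(spec$seed, {
    t(vapply(seq_len(spec$n_patches), function(i)
      vapply(1:3, function(k) sample.int(d[k] - ps[k] + 1L, 1L), integer(1)),
      integer(3)))
  })
  lapply(seq_len(spec$n_patches), function(i) {
    c0 <- corners[i, ]
    list(x = v[c0[1]:(c0[1] + ps[1] - 1L), c0[2]:(c0[2] + ps[2] - 1L),
               c0[3]:(c0[3] + ps[3] - 1L), drop = FALSE],
         y = m[c0[1]:(c0[1] + ps[1] - 1L), c0[2]:(c0[2] + ps[2] - 1L),
               c0[3]:(c0[3] + ps[3] - 1L), drop = FALSE])
  })
}

#' Stratified k-fold split of a cohort
#'
#' Lesions are partitioned into \code{k} folds stratified by grade (and by
#' scanner tag when present): within each stratum, shuffled lesions are
#' dealt round-robin, so every fold's validation set mirrors the stratum
#' proportions as closely as integer counts allow. Warns when a stratum has
#' fewer members than folds.
#'
#' @param manifest a cohort manifest (data.frame with \code{lesion_id},
#'   \code{grade}, optionally \code{scanner_tag}).
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @param stratify_scanner also stratify by scanner tag if available.
#' @return list of class \code{fold_split}: \code{k}, \code{assignment}
#'   (named integer vector: validation fold per lesion), and \code{folds},
#'   a list of \code{list(train =, val =)} lesion-id vectors.
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L, stratify_scanner = TRUE) {
  if (nrow(manifest) < k) stop("need at least k lesions")
  strata <- manifest$grade
  if (stratify_scanner && "scanner_tag" %in% names(manifest))
    strata <- paste(strata, manifest$scanner_tag)
  tab <- table(strata)
  if (any(tab < k))
    warning("strata with fewer than k members: ",
            paste(names(tab)[tab < k], collapse = ", "),
            " (stratification degraded)")
  assignment <- integer(nrow(manifest))
  with_seed(seed, {
    # offset the deal per stratum so small strata do not pile into fold 1
    start <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  names(assignment) <- manifest$lesion_id
  folds <- lapply(seq_len(k), function(f)
    list(train = manifest$lesion_id[assignment != f],
         val = manifest$lesion_id[assignment == f]))
  structure(list(k = as.integer(k), assignment = assignment, folds = folds),
            class = "fold_split")
}

#' Build the 3D segmentation network
#'
#' @param cfg a [unet3d_config()].
#' @param seed weight-initialization seed.
#' @return a \code{unet_model}.
#' @export
build_segnet <- function(cfg = unet3d_config(), seed = 1L) {
  stopifnot(cfg$dim == 3L)
  build_unet(cfg, seed)
}

#' Train one 3D segmentation model
#'
#' Each epoch draws fresh random patches from every training pair and
#' optimizes the combined loss with SGD-Nesterov under the polynomial decay.
#' With \code{schedule$total_epochs = 0} the model is returned unchanged.
#'
#' @param model a model from [build_segnet()].
#' @param pairs list of training samples, each
#'   \code{list(vol = volume_image, label = lumen_label)} (usually ROI crops,
#'   z-normalized).
#' @param schedule a [train_schedule()]; batch size defaults to 4.
#' @param pspec a [patch_spec()].
#' @return list with \code{model} and \code{history}.
#' @export
train_segnet <- function(model, pairs, schedule = train_schedule(batch_size = 4L),
                         pspec = patch_spec()) {
  stopifnot(model$cfg$dim == 3L)
  if (length(pairs) == 0) stop("empty fold: no training pairs")
  if (schedule$total_epochs == 0)
    return(list(model = model, history = data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0))))
  div <- 2L^(model$cfg$encoder_stages - 1L)
  divs <- rep(div, 3L)
  bs <- schedule$batch_size
  hist <- vector("list", schedule$total_epochs)
  state <- NULL
  with_seed(schedule$seed, {
    for (ep in seq_len(schedule$total_epochs)) {
      lr <- lr_schedule(ep - 1L, schedule)
      # fresh patch draw per epoch, seeded by the loop's RNG stream
      patches <- list()
      for (pr in pairs) {
        pe <- patch_spec(pspec$n_patches, pspec$patch_size,
                         seed = sample.int(.Machine$integer.max, 1L))
        patches <- c(patches, crop_patches(pr$vol, pr$label, pe))
      }
      ord <- sample.int(length(patches))
      nb <- max(1L, length(patches) %/% bs)
      losses <- numeric(nb)
      for (st in seq_len(nb)) {
        take <- ord[((st - 1L) * bs + 1L):min(st * bs, length(patches))]
        acc <- NULL; lsum <- 0
        for (i in take) {
          p <- patches[[i]]
          pp <- pad_pair(array(p$x, c(dim(p$x), 1L)),
                         array(p$y, c(dim(p$y), 1L)), divs)
          lg <- unet_loss_grads(model, pp$x, pp$t, schedule$loss_weights)
          lsum <- lsum + lg$loss
          acc <- if (is.null(acc)) lg$grads else map2_params(acc, lg$grads, `+`)
        }
        acc <- rapply(acc, function(g) g / length(take), how = "replace")
        stp <- sgd_nesterov_step(model$params, acc, state, lr, schedule$momentum)
        model$params <- stp$params; state <- stp$state
        losses[st] <- lsum / length(take)
      }
      hist[[ep]] <- data.frame(epoch = ep, lr = lr, loss = mean(losses))
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' Five-fold cross-validated training of the 3D network
#'
#' Trains one model per fold on that fold's training lesions. Per-fold seeds
#' derive from \code{schedule$seed} so folds are independent but
#' reproducible.
#'
#' @param pairs named list of samples (names = lesion ids), each
#'   \code{list(vol =, label =)}.
#' @param folds a [make_folds()] split whose lesion ids match \code{names(pairs)}.
#' @param cfg a [unet3d_config()].
#' @param schedule a [train_schedule()].
#' @param pspec a [patch_spec()].
#' @return list of per-fold results (\code{model}, \code{history}, \code{val}).
#' @export
train_segnet_cv <- function(pairs, folds, cfg = unet3d_config(),
                            schedule = train_schedule(batch_size = 4L),
                            pspec = patch_spec()) {
  stopifnot(inherits(folds, "fold_split"))
  lapply(seq_len(folds$k), function(f) {
    ids <- folds$folds[[f]]$train
    if (!length(ids)) stop("empty fold ", f)
    sched_f <- schedule
    sched_f$seed <- as.integer((schedule$seed + 1009L * f) %% .Machine$integer.max)
    fit <- train_segnet(build_unet(cfg, seed = sched_f$seed),
                        pairs[ids], sched_f, pspec)
    list(model = fit$model, history = fit$history, val = folds$folds[[f]]$val)
  })
}

# connected components of a binary mask (26-connectivity); returns sizes and
# an integer component-label array
label_components <- function(mask) {
  m <- mask
  storage.mode(m) <- "integer"
  comp <- array(0L, dim(m))
  cid <- 0L
  remaining <- which(m == 1L & comp == 0L)
  while (length(remaining)) {
    cid <- cid + 1L
    src <- remaining[1]
    res <- .voxel_dijkstra(m, c(1, 1, 1), as.integer(src - 1L), numeric(0), 0.5, 2)
    reach <- is.finite(res$dist) & as.vector(m == 1L)
    comp[reach] <- cid
    m[reach] <- 0L
    remaining <- which(m == 1L & comp == 0L)
  }
  list(n = cid, comp = comp)
}

#' Ensemble prediction over cross-validation folds
#'
#' Averages the voxelwise foreground probabilities of the fold models,
#' thresholds at 0.5, optionally keeps only the largest connected component,
#' and (when a placement is given) embeds the result into the full volume.
#'
#' @param models list of trained 3D models (or a single model).
#' @param vol [volume_image()] the models should see (ROI crop, normalized).
#' @param placement optional [roi_placement()] for re-embedding.
#' @param threshold probability threshold.
#' @param largest_component drop all but the largest connected component.
#' @return a [lumen_label()] (full-size when \code{placement} is given).
#' @export
ensemble_predict <- function(models, vol, placement = NULL, threshold = 0.5,
                             largest_component = FALSE) {
  if (inherits(models, "unet_model")) models <- list(models)
  if (!length(models)) stop("need at least one model")
  v <- vol$values
  prob <- array(0, dim(v))
  for (m in models) prob <- prob + unet_predict(m, v)
  prob <- prob / length(models)
  mask <- array(as.integer(prob >= threshold), dim(v))
  if (largest_component && any(mask == 1L)) {
    lc <- label_components(mask)
    if (lc$n > 1L) {
      sizes <- tabulate(lc$comp[lc$comp > 0L], nbins = lc$n)
      mask <- array(as.integer(lc$comp == which.max(sizes)), dim(mask))
    }
  }
  lab <- lumen_label(mask, vol$spacing, vol$origin)
  if (!is.null(placement)) embed_from_roi(lab, placement) else lab
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the config, weights and the seed it was built with.
#'
#' @param model a \code{unet_model}.
#' @param path file path (\code{.rds}).
#' @return \code{path} / the restored model.
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "unet_model"))
  m
}
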