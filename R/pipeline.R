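#' Run the full cascade experiment on an in-memory cohort
#'
#' Trains the two-stage cascade with k-fold cross-validation on a list of
#' image/label pairs and evaluates fold-ensembled segmentation quality
#' against the ground truth. With \code{use_localization = TRUE} (the
#' cascade proper) a 2D localization network is trained per fold on the
#' inflated ROI targets, each volume is cropped to its predicted ROI, and
#' the 3D network trains and predicts on the crops; with
#' \code{use_localization = FALSE} (the ablation) the 3D network sees the
#' whole volume. Everything else — folds, schedules, patch budget, seeds —
#' is identical between the two arms, so the comparison isolates the value
#' of the localization stage.
#'
#' @param pairs named list of \code{list(vol =, label =)} pairs (raw
#'   intensities; z-normalization is applied internally).
#' @param manifest manifest data.frame for stratified folds (lesion ids must
#'   match \code{names(pairs)}).
#' @param cfg a [default_config()]-style configuration (use the desk profile
#'   for CPU-scale runs).
#' @param use_localization train/crop with the 2D stage (\code{TRUE}) or run
#'   the no-localization ablation (\code{FALSE}).
#' @param seed experiment seed.
#' @param loc_steps_per_epoch 2D batches per epoch.
#' @return list with \code{fold_dice} (per-fold validation Dice of each fold
#'   model), \code{ensemble_dice} (per-phantom Dice of the fold ensemble),
#'   \code{mean_ensemble_dice}, \code{folds}, and the per-fold models.
#' @export
cascade_experiment <- function(pairs, manifest, cfg = default_config("desk"),
                               use_localization = TRUE, seed = 1L,
                               loc_steps_per_epoch = 6L) {
  stopifnot(length(pairs) >= cfg$train$k_folds)
  ids <- names(pairs)
  stopifnot(!is.null(ids), all(manifest$lesion_id %in% ids))
  folds <- make_folds(manifest, k = cfg$train$k_folds, seed = seed)
  norm <- lapply(pairs, function(p) list(vol = znorm(p$vol), label = p$label))
  dice <- function(a, b) {
    s <- sum(a) + sum(b)
    if (s == 0) return(NA_real_)
    2 * sum(a & b) / s
  }
  lcfg <- unet2d_config(cfg$locnet$encoder_stages, cfg$locnet$base_channels,
                        cfg$locnet$max_channels)
  scfg <- unet3d_config(cfg$segnet$encoder_stages, cfg$segnet$base_channels,
                        cfg$segnet$max_channels, cfg$segnet$blocks_per_stage,
                        cfg$segnet$avgpool_stages)
  ps <- patch_spec(cfg$segnet$n_patches, cfg$segnet$patch_size)
  fold_models <- vector("list", folds$k)
  fold_dice <- numeric(folds$k)
  # full-size accumulated ensemble probabilities per phantom
  acc_prob <- lapply(norm, function(p) array(0, dim(p$vol$values)))
  for (f in seq_len(folds$k)) {
    fseed <- as.integer((seed + 7717L * f) %% .Machine$integer.max)
    train_ids <- folds$folds[[f]]$train
    val_ids <- folds$folds[[f]]$val
    placements <- NULL
    if (use_localization) {
      # 2D training set: all labeled slices plus as many empty ones
      slices <- list()
      with_seed(fseed, for (id in train_ids) {
        p <- norm[[id]]
        infl <- inflate_labels(p$label, inflation_spec(cfg$preprocess$epsilon))
        labeled <- which(apply(infl$mask, 1, sum) > 0)
        empties <- setdiff(seq_len(dim(infl$mask)[1]), labeled)
        empties <- empties[sample.int(length(empties),
                                      min(length(empties), length(labeled)))]
        ds <- cfg$locnet$downsample %||% 1L
        for (k in c(labeled, empties)) {
          xs <- p$vol$values[k, , ]; ys <- infl$mask[k, , ]
          if (ds > 1L) {
            xs <- pool_slice(xs, ds)
            ys <- (pool_slice(ys, ds) >= 0.5) * 1L
          }
          slices[[length(slices) + 1]] <- list(x = xs, y = ys)
        }
      })
      sched2 <- train_schedule(batch_size = cfg$train$batch_size_2d,
                               total_epochs = cfg$train$total_epochs,
                               initial_lr = cfg$train$initial_lr,
                               poly_exponent = cfg$train$poly_exponent,
                               momentum = cfg$train$momentum,
                               loss_weights = cfg$train$loss_weights,
                               seed = fseed)
      loc <- train_locnet(build_locnet(lcfg, seed = fseed), slices, sched2,
                          steps_per_epoch = loc_steps_per_epoch)
      placements <- lapply(norm, function(p)
        tryCatch(predict_roi(loc$model, p$vol, threshold = cfg$locnet$threshold,
                             margin = cfg$locnet$margin,
                             downsample = cfg$locnet$downsample %||% 1L)$placement,
                 carotidseg_no_roi = function(e) NULL))
      # a failed localization falls back to the uncropped volume
      placements <- lapply(seq_along(placements), function(i) {
        if (!is.null(placements[[i]])) placements[[i]]
        else roi_placement(c(1, 1, 1), dim(norm[[i]]$vol$values),
                           dim(norm[[i]]$vol$values))
      })
      names(placements) <- ids
    }
    crop_of <- function(id) {
      p <- norm[[id]]
      if (!use_localization) return(p)
      cr <- crop_to_roi(p$vol, p$label, placements[[id]])
      list(vol = cr$vol, label = cr$label)
    }
    train_pairs <- lapply(train_ids, crop_of)
    sched3 <- train_schedule(batch_size = cfg$train$batch_size_3d,
                             total_epochs = cfg$train$total_epochs,
                             initial_lr = cfg$train$initial_lr,
                             poly_exponent = cfg$train$poly_exponent,
                             momentum = cfg$train$momentum,
                             loss_weights = cfg$train$loss_weights,
                             seed = fseed)
    fit <- train_segnet(build_segnet(scfg, seed = fseed), train_pairs, sched3, ps)
    fold_models[[f]] <- fit$model
    # fold validation Dice + ensemble accumulation (full volume space)
    dvals <- numeric(0)
    for (id in ids) {
      p <- crop_of(id)
      prob <- unet_predict(fit$model, p$vol$values)
      if (use_localization) {
        full <- array(0, dim(norm[[id]]$vol$values))
        pl <- placements[[id]]
        full[pl$lo[1]:pl$hi[1], pl$lo[2]:pl$hi[2], pl$lo[3]:pl$hi[3]] <- prob
        prob <- full
      }
      acc_prob[[id]] <- acc_prob[[id]] + prob
      if (id %in% val_ids)
        dvals <- c(dvals, dice(prob >= 0.5, norm[[id]]$label$mask == 1L))
    }
    fold_dice[f] <- mean(dvals)
  }
  ens <- vapply(ids, function(id)
    dice(acc_prob[[id]] / folds$k >= 0.5, norm[[id]]$label$mask == 1L),
    numeric(1))
  list(fold_dice = fold_dice, ensemble_dice = ens,
       mean_ensemble_dice = mean(ens), folds = folds, models = fold_models)
}

#' Generate a small in-memory phantom cohort
#'
#' Desk-scale counterpart of [generate_cohort()]: returns the phantoms as
#' in-memory pairs plus a manifest, without touching disk. Grade mix,
#' per-lesion jitter and seeding follow [generate_cohort()].
#'
#' @param n_lesions number of phantoms.
#' @param grade_mix named proportions over mild/moderate/severe.
#' @param seed cohort seed.
#' @param base_spec template [phantom_spec()].
#' @return list with \code{pairs} (named list of vol/label/truth) and
#'   \code{manifest}.
#' @export
memory_cohort <- function(n_lesions,
                          grade_mix = c(mild = 3, moderate = 206, severe = 336) / 545,
                          seed = 7L,
                          base_spec = phantom_spec(grid_shape = c(64L, 96L, 96L),
                                                   segment_length = 15,
                                                   margin = 2)) {
  stopifnot(abs(sum(grade_mix) - 1) < 1e-8)
  grade_mix <- grade_mix[c("mild", "moderate", "severe")]
  raw <- grade_mix * n_lesions
  cnt <- floor(raw); rem <- n_lesions - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  grades <- rep(names(cnt), times = cnt)
  bands <- list(mild = c(15, 30), moderate = c(35, 70), severe = c(72, 92))
  pairs <- list(); rows <- list()
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
      tag = sample(c("ScI", "ScII", "ScIII"), 1)))
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
    pairs[[lid]] <- list(vol = ph$image, label = ph$label, truth = ph$truth)
    rows[[i]] <- data.frame(lesion_id = lid, grade = g, true_percent = par$pct,
                            scanner_tag = par$tag, seed = lseed,
                            stringsAsFactors = FALSE)
  }
  list(pairs = pairs, manifest = as_manifest(do.call(rbind, rows)))
}
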