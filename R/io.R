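#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI image and recovers voxel spacing and origin from its
#' affine. Only axis-aligned (non-oblique) affines are supported: the pipeline
#' assumes the first array axis is the slice axis.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3)
    stop("expected a 3D image, got ", length(dim(img)), "D: ", path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  # oblique check: off-axis components of each column must vanish
  aligned <- abs(rot) / rep(pmax(sp, 1e-12), each = 3)
  if (any(aligned > 1e-4 & aligned < 1 - 1e-4))
    stop("oblique affine not supported: ", path)
  origin <- xf[1:3, 4]
  vals <- array(as.numeric(img), dim = dim(img))
  volume_image(vals, spacing = abs(sp), origin = as.numeric(origin))
}

#' Read a NIfTI-1 binary label
#' @param path path to the label file.
#' @return A [lumen_label()].
#' @export
read_label <- function(path) {
  v <- read_volume(path)
  m <- array(as.integer(v$values != 0), dim(v$values))
  lumen_label(m, v$spacing, v$origin)
}

nifti_from_array <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  RNifti::`pixdim<-`(img, spacing)
  aff <- diag(4)
  aff[1, 1] <- spacing[1]; aff[2, 2] <- spacing[2]; aff[3, 3] <- spacing[3]
  aff[1:3, 4] <- origin
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

#' Write a volume or label as NIfTI-1
#'
#' The affine is diagonal (spacing on the diagonal, origin in the last
#' column), so a write/read round trip preserves values, spacing and origin.
#'
#' @param x a [volume_image()] or [lumen_label()].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "lumen_label")) {
    img <- nifti_from_array(x$mask, x$spacing, x$origin)
  } else if (inherits(x, "volume_image")) {
    img <- nifti_from_array(x$values, x$spacing, x$origin)
  } else stop("x must be a volume_image or lumen_label")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- cohort manifests ------------------------------------------------------

manifest_columns <- c("lesion_id", "image_path", "label_path", "grade",
                      "true_percent", "scanner_tag", "seed")

#' Read a cohort manifest CSV
#'
#' A manifest has one row per lesion with columns \code{lesion_id},
#' \code{image_path}, \code{label_path}, \code{grade} (mild/moderate/severe),
#' \code{true_percent}, \code{scanner_tag} and \code{seed}. Extra columns
#' (e.g. \code{patient_id}, \code{cohort}) are carried through.
#'
#' @param path CSV path.
#' @param check_paths verify that referenced image/label files exist.
#' @return data.frame of class \code{cohort_manifest}.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_manifest(df, check_paths = check_paths, dir = dirname(path))
}

#' Validate a data.frame as a cohort manifest
#' @param df data.frame with the manifest columns.
#' @param check_paths verify referenced files exist.
#' @param dir base directory for relative paths.
#' @return data.frame of class \code{cohort_manifest}.
#' @export
as_manifest <- function(df, check_paths = FALSE, dir = ".") {
  missing_cols <- setdiff(c("lesion_id", "grade"), names(df))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$lesion_id)) stop("duplicate lesion_id in manifest")
  bad <- setdiff(unique(df$grade), c("mild", "moderate", "severe"))
  if (length(bad)) stop("invalid grades: ", paste(bad, collapse = ", "))
  if (check_paths && all(c("image_path", "label_path") %in% names(df))) {
    paths <- c(df$image_path, df$label_path)
    paths <- ifelse(file.exists(paths), paths, file.path(dir, paths))
    if (!all(file.exists(paths)))
      stop("manifest references missing files, e.g. ",
           paths[!file.exists(paths)][1])
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest CSV
#' @param manifest a manifest data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Summarize one or more cohort manifests
#'
#' Aggregates patient-wise and lesion-wise counts per cohort and per stenosis
#' grade, with grand totals, mirroring the bookkeeping of a multicenter study
#' cohort table.
#'
#' @param manifests a single manifest or a (optionally named) list of them.
#' @return list of class \code{cohort_summary}: \code{per_cohort} (data.frame
#'   with lesion/patient counts and per-grade lesion counts), \code{totals}
#'   (named vector with \code{lesions}, \code{patients} when available, and
#'   per-grade totals).
#' @export
summarize_cohort <- function(manifests) {
  if (inherits(manifests, "data.frame")) manifests <- list(manifests)
  if (is.null(names(manifests)) || any(names(manifests) == ""))
    names(manifests) <- paste0("cohort", seq_along(manifests))
  ids <- unlist(lapply(manifests, function(m) m$lesion_id), use.names = FALSE)
  if (anyDuplicated(ids)) stop("duplicate lesion_id across manifests")
  grades <- c("mild", "moderate", "severe")
  rows <- lapply(names(manifests), function(nm) {
    m <- manifests[[nm]]
    gc <- vapply(grades, function(g) sum(m$grade == g), integer(1))
    data.frame(cohort = nm, lesions = nrow(m),
               patients = if ("patient_id" %in% names(m))
                 length(unique(m$patient_id)) else NA_integer_,
               mild = gc[1], moderate = gc[2], severe = gc[3],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  totals <- c(lesions = sum(per$lesions),
              patients = if (all(!is.na(per$patients))) sum(per$patients) else NA_integer_,
              mild = sum(per$mild), moderate = sum(per$moderate),
              severe = sum(per$severe))
  structure(list(per_cohort = per, totals = totals), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  print(x$per_cohort, row.names = FALSE)
  cat("Totals: ", paste(names(x$totals), x$totals, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---- configuration ---------------------------------------------------------

#' Default pipeline configuration
#'
#' Nested configuration for all stages. \code{profile = "paper"} uses the
#' full-scale settings (1000 epochs, 4 patches of 128 x 192 x 192, 8/7-stage
#' 2D and 6/5-stage 3D networks); \code{profile = "desk"} is a reduced profile
#' sized so the whole pipeline trains on one CPU in minutes (small phantoms,
#' 15 epochs, shallow narrow networks).
#'
#' @param profile \code{"paper"} or \code{"desk"}.
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#' @return nested named list of class \code{pipeline_config}.
#' @export
default_config <- function(profile = c("paper", "desk"), seed = 7L) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    preprocess = list(
      target_spacing = c(0.59, 0.46, 0.46),
      epsilon = 0.5,
      augment = default_augment_spec()
    ),
    locnet = list(
      encoder_stages = 8L, base_channels = 32L, max_channels = 320L,
      threshold = 0.5, margin = 8L, downsample = 1L
    ),
    segnet = list(
      encoder_stages = 6L, base_channels = 32L, max_channels = 320L,
      blocks_per_stage = 2L, avgpool_stages = c(2L, 3L),
      n_patches = 4L, patch_size = c(128L, 192L, 192L)
    ),
    train = list(
      batch_size_2d = 12L, batch_size_3d = 4L, total_epochs = 1000L,
      initial_lr = 0.01, poly_exponent = 0.9, momentum = 0.99,
      deep_supervision = TRUE, loss_weights = c(bce = 1, dice = 1),
      k_folds = 5L
    ),
    stenosis = list(
      step = 0.5, plane_n = 64L, plane_spacing = 0.3,
      smooth_window = 3L, guard = 2.0, end_guard = 2.0,
      rvd_strategy = "distal_ica"
    )
  )
  if (profile == "desk") {
    cfg$locnet$encoder_stages <- 4L
    cfg$locnet$base_channels <- 4L
    cfg$locnet$max_channels <- 32L
    cfg$segnet$encoder_stages <- 4L
    cfg$segnet$base_channels <- 4L
    cfg$segnet$max_channels <- 32L
    cfg$segnet$blocks_per_stage <- 1L
    cfg$segnet$n_patches <- 2L
    cfg$segnet$patch_size <- c(24L, 24L, 24L)
    cfg$locnet$downsample <- 2L
    cfg$train$total_epochs <- 15L
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @param profile base profile the file overrides.
#' @return \code{pipeline_config}.
#' @export
load_config <- function(path, profile = "paper") {
  user <- yaml::read_yaml(path)
  base <- default_config(profile = user$profile %||% profile,
                         seed = user$seed %||% 7L)
  merge_strict <- function(base, user, path = "") {
    for (k in names(user)) {
      if (!k %in% names(base))
        stop("unknown config key: ", paste0(path, k))
      if (is.list(base[[k]]) && is.list(user[[k]])) {
        base[[k]] <- merge_strict(base[[k]], user[[k]], paste0(path, k, "."))
      } else {
        v <- user[[k]]
        if (is.numeric(base[[k]]) && is.numeric(v)) storage.mode(v) <- storage.mode(base[[k]])
        base[[k]] <- v
      }
    }
    base
  }
  out <- merge_strict(unclass(base), user[setdiff(names(user), c("profile", "seed"))])
  class(out) <- c("pipeline_config", "list")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from the global seed
#'
#' Fixed offsets let individual stages be re-run independently while staying
#' reproducible from one global seed.
#'
#' @param seed global integer seed.
#' @param stage one of the pipeline stage names.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage = c("phantom", "preprocess", "locnet",
                                       "segnet", "stenosis", "metrics")) {
  stage <- match.arg(stage)
  offs <- c(phantom = 101L, preprocess = 211L, locnet = 307L,
            segnet = 401L, stenosis = 503L, metrics = 601L)
  as.integer((as.integer(seed) + offs[[stage]]) %% .Machine$integer.max)
}

# evaluate expr with a local, restored RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
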