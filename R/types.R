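#' Construct a 3D scalar volume with voxel geometry
#'
#' The common image container of the pipeline: a numeric 3D array plus the
#' voxel spacing and world origin. The first array axis is the slice axis;
#' world coordinates follow \code{world = origin + index * spacing} with
#' 0-based voxel indices.
#'
#' @param values numeric 3D array of intensities.
#' @param spacing positive numeric triple, voxel spacing in mm
#'   (slice, row, column).
#' @param origin numeric triple, world position of voxel (0, 0, 0) in mm.
#' @return An object of class \code{volume_image}.
#' @export
volume_image <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be a strictly positive mm triple")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be a finite mm triple")
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' Construct a binary lumen label aligned to a volume
#'
#' @param mask integer/logical 3D array with values in \{0, 1\}.
#' @param spacing,origin voxel geometry, as in [volume_image()].
#' @return An object of class \code{lumen_label}.
#' @export
lumen_label <- function(mask, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L))) stop("label mask must be binary")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(mask = mask, spacing = spacing, origin = origin),
            class = "lumen_label")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 3), collapse = "/"), " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.lumen_label <- function(x, ...) {
  n <- sum(x$mask)
  cat("<lumen_label> ", paste(dim(x$mask), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 3), collapse = "/"), " mm; ",
      n, " foreground (", signif(100 * n / length(x$mask), 3), "%)\n", sep = "")
  invisible(x)
}

# check that an image/label pair shares grid and geometry
check_aligned <- function(vol, label) {
  if (!identical(dim(vol$values), dim(label$mask)))
    stop("volume and label shapes differ")
  if (max(abs(vol$spacing - label$spacing)) > 1e-9)
    stop("volume and label spacings differ")
  invisible(TRUE)
}

#' Fraction of voxels labeled as lumen
#'
#' Diagnostic for the class-imbalance regime the pipeline is built for: in
#' neck MRI the carotid lumen occupies well under 0.1\% of the image grid.
#'
#' @param label a [lumen_label()].
#' @return proportion of foreground voxels (not percent).
#' @export
label_fraction <- function(label) {
  sum(label$mask) / length(label$mask)
}
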