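# Accuracy and trait measurements: multi-label Dice overlap and the two
# volumetric traits (total volume, percentage calcite).

#' Multi-label Dice score between two segmentations
#'
#' For segmentations `X` and `X'` over `n` labels,
#' `Dice = 2 * sum_i |X_i ∩ X'_i| / (|X| + |X'|)`, where `X_i` is the
#' voxel subset of `X` with label `i` and `|X|`, `|X'|` count the voxels
#' carrying an in-scope label. The score lies in `[0, 1]`: 0 means no
#' overlap for any label, 1 a perfect match.
#'
#' By default only the two foreground labels (external, internal) are in
#' scope: counting the dominant background class would push every score
#' towards 1 and mask real segmentation differences. Set
#' `labels_in_scope = foram_labels()` for the strict all-labels reading,
#' under which the denominator is twice the voxel count.
#'
#' @param x,x_prime Integer 3D label arrays of identical shape (or
#'   [volume_pair()]s, whose `labels` are used).
#' @param labels_in_scope Integer vector of label codes entering the
#'   sums. Default `c(1, 2)` (external, internal).
#' @return Scalar in `[0, 1]`. When neither segmentation contains any
#'   in-scope voxel the score is 1 by convention (two empty
#'   segmentations agree perfectly).
#' @export
#' @examples
#' a <- array(0L, c(2, 2, 2)); b <- a
#' a[1, 1, 1] <- 1L; b[1, 1, 1] <- 1L
#' dice(a, b)  # 1: identical
dice <- function(x, x_prime,
                 labels_in_scope = c(LABEL_EXTERNAL, LABEL_INTERNAL)) {
  if (inherits(x, "volume_pair")) x <- x$labels
  if (inherits(x_prime, "volume_pair")) x_prime <- x_prime$labels
  if (!identical(dim(x), dim(x_prime)))
    stop(sprintf("dimension mismatch: %s vs %s",
                 paste(dim(x), collapse = "x"),
                 paste(dim(x_prime), collapse = "x")))
  if (length(labels_in_scope) == 0L)
    stop("labels_in_scope must be non-empty")
  num <- 0
  for (lab in labels_in_scope)
    num <- num + sum(x == lab & x_prime == lab)
  denom <- sum(x %in% labels_in_scope) + sum(x_prime %in% labels_in_scope)
  if (denom == 0) return(1)
  2 * num / denom
}

#' Volumetric traits of a segmentation
#'
#' Total volume is the physical volume (voxel count times voxel volume)
#' of external plus internal structure; percentage calcite is the ratio
#' of external to internal volume times 100, a ratio convention kept
#' deliberately literal. A conventional fraction-of-total percentage,
#' `external / (external + internal) * 100`, is available via
#' `calcite_convention = "fraction_of_total"`.
#'
#' @param labels Integer 3D label array (or a [volume_pair()], whose
#'   labels and voxel size are used).
#' @param voxel_size_um Isotropic voxel size in micrometres (ignored
#'   when `labels` is a `volume_pair`).
#' @param calcite_convention `"ratio"` (default, the literal
#'   external/internal formula) or `"fraction_of_total"`.
#' @return Object of class `volumetric_traits`: list with
#'   `external_volume_um3`, `internal_volume_um3`, `total_volume_um3`,
#'   `percentage_calcite` (NA when undefined) and
#'   `percentage_calcite_defined`.
#' @export
volumetric_traits <- function(labels, voxel_size_um = NULL,
                              calcite_convention = c("ratio",
                                                     "fraction_of_total")) {
  calcite_convention <- match.arg(calcite_convention)
  if (inherits(labels, "volume_pair")) {
    voxel_size_um <- labels$voxel_size_um
    labels <- labels$labels
  }
  stopifnot(is.numeric(voxel_size_um), voxel_size_um > 0)
  vox3 <- voxel_size_um^3
  n_ext <- sum(labels == LABEL_EXTERNAL)
  n_int <- sum(labels == LABEL_INTERNAL)
  ext <- n_ext * vox3
  int <- n_int * vox3
  denom <- switch(calcite_convention, ratio = int,
                  fraction_of_total = ext + int)
  defined <- denom > 0
  pc <- if (!defined) NA_real_ else switch(
    calcite_convention,
    ratio = ext / int * 100,
    fraction_of_total = ext / (ext + int) * 100)
  structure(list(external_volume_um3 = ext, internal_volume_um3 = int,
                 total_volume_um3 = ext + int, percentage_calcite = pc,
                 percentage_calcite_defined = defined),
            class = "volumetric_traits")
}

#' @export
print.volumetric_traits <- function(x, ...) {
  cat(sprintf(
    "<volumetric_traits> external %.4g um^3 | internal %.4g um^3 | total %.4g um^3\n",
    x$external_volume_um3, x$internal_volume_um3, x$total_volume_um3))
  if (x$percentage_calcite_defined)
    cat(sprintf("  percentage calcite: %.4g\n", x$percentage_calcite))
  else cat("  percentage calcite: undefined (no internal volume)\n")
  invisible(x)
}
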