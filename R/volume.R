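#' Construct a grayscale volume
#'
#' A volume is a 3D array of non-negative intensities indexed `[z, y, x]`
#' with an isometric voxel edge length in micrometers and a bit-depth hint
#' (8 or 16) bounding the intensity range.
#'
#' @param data 3D numeric array of finite, non-negative intensities.
#' @param voxel_size_um Positive scalar, isometric voxel edge length (um).
#' @param bit_depth 8 or 16. If `NULL`, inferred from the data maximum
#'   (8 when all intensities fit in 0..255, else 16).
#' @return An object of class `mia_volume`: a list with elements `data`,
#'   `voxel_size_um` and `bit_depth`.
#' @export
#' @examples
#' v <- mia_volume(array(0, c(4, 4, 4)), voxel_size_um = 7.86)
#' dim(v)
mia_volume <- function(data, voxel_size_um, bit_depth = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L))
    stop("all three dimensions must be >= 1")
  if (anyNA(data) || !all(is.finite(data)))
    stop("intensities must be finite")
  if (min(data) < 0)
    stop("intensities must be non-negative")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  if (is.null(bit_depth))
    bit_depth <- if (max(data) <= 255) 8L else 16L
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16")
  if (max(data) > 2^bit_depth - 1)
    stop("intensities exceed 2^bit_depth - 1")
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         bit_depth = bit_depth),
    class = "mia_volume"
  )
}

#' Construct a label volume
#'
#' Integer class labels per voxel. Label 0 is reserved for
#' background/masked/sub-threshold voxels; labels `1..n_classes` denote
#' classes ordered by ascending class-center intensity.
#'
#' @param labels 3D integer array with values in `0..n_classes`.
#' @param n_classes Number of classes C >= 2.
#' @param voxel_size_um Positive scalar voxel edge length (um).
#' @return An object of class `mia_labels`.
#' @export
mia_labels <- function(labels, n_classes, voxel_size_um) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 1L)
    stop("`n_classes` must be a positive integer")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 0L || max(labels) > n_classes)
    stop("labels must lie in 0..n_classes")
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  structure(
    list(labels = labels, n_classes = n_classes,
         voxel_size_um = as.numeric(voxel_size_um)),
    class = "mia_labels"
  )
}

#' @export
dim.mia_volume <- function(x) dim(x$data)

#' @export
dim.mia_labels <- function(x) dim(x$labels)

#' @export
as.array.mia_volume <- function(x, ...) x$data

#' @export
as.array.mia_labels <- function(x, ...) x$labels

#' @export
print.mia_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mia_volume> %d x %d x %d voxels (z,y,x), %.4g um/voxel, %d-bit\n",
              d[1], d[2], d[3], x$voxel_size_um, x$bit_depth))
  cat(sprintf("  intensity range [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.mia_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<mia_labels> %d x %d x %d voxels (z,y,x), %d classes + background, %.4g um/voxel\n",
              d[1], d[2], d[3], x$n_classes, x$voxel_size_um))
  tab <- tabulate(x$labels + 1L, x$n_classes + 1L)
  cat("  voxels per label 0..C:", paste(tab, collapse = ", "), "\n")
  invisible(x)
}

# coerce any accepted mask representation to a logical 3D array
as_mask <- function(mask, shape = NULL) {
  if (inherits(mask, "mia_volume")) mask <- mask$data > 0
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    mask <- array(as.logical(mask), dim(mask))
  }
  if (!is.null(shape) && !identical(dim(mask), as.integer(shape)))
    stop("mask shape does not match volume shape")
  mask
}
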