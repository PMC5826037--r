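#' Pre-processing parameters
#'
#' The two pre-processing steps applied before clustering: a noise-reducing
#' cubic median filter and a background intensity threshold. Either may be
#' skipped.
#'
#' @param median_kernel Odd integer >= 3, edge length of the cubic median
#'   window; 0 (default) skips the filter.
#' @param background_threshold Non-negative intensity; voxels with
#'   intensity below it are excluded from clustering and labeled 0.
#'   `NULL` (default) skips thresholding.
#' @return An object of class `mia_pp`.
#' @export
pp_params <- function(median_kernel = 0L, background_threshold = NULL) {
  median_kernel <- as.integer(median_kernel)
  if (is.na(median_kernel) || median_kernel < 0L)
    stop("`median_kernel` must be a non-negative integer")
  if (median_kernel > 0L && (median_kernel %% 2L == 0L || median_kernel < 3L))
    stop("`median_kernel` must be an odd integer >= 3")
  if (!is.null(background_threshold)) {
    if (!is.numeric(background_threshold) || length(background_threshold) != 1L ||
        background_threshold < 0)
      stop("`background_threshold` must be a non-negative scalar")
    background_threshold <- as.numeric(background_threshold)
  }
  structure(list(median_kernel = median_kernel,
                 background_threshold = background_threshold),
            class = "mia_pp")
}

#' Cubic median filter
#'
#' Replaces each voxel by the median of its `kernel`^3 cubic neighborhood.
#' Volume borders are handled by edge replication, which avoids introducing
#' artificial dark borders that would bias the clustering of edge cubes.
#'
#' @param volume A [mia_volume()].
#' @param kernel Odd integer, >= 3 and <= the smallest volume dimension.
#' @return A filtered [mia_volume()] with unchanged metadata.
#' @export
median_filter <- function(volume, kernel) {
  stopifnot(inherits(volume, "mia_volume"))
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel %% 2L == 0L)
    stop("`kernel` must be an odd integer")
  if (kernel < 3L) stop("`kernel` must be >= 3")
  if (kernel > min(dim(volume$data)))
    stop("`kernel` exceeds the smallest volume dimension")
  out <- median3d_cpp(as.numeric(volume$data), dim(volume$data), kernel)
  mia_volume(array(out, dim(volume$data)), volume$voxel_size_um,
             volume$bit_depth)
}

#' Background mask
#'
#' Logical mask of voxels that take part in clustering: `TRUE` where
#' intensity meets or exceeds the threshold (the comparison is inclusive,
#' so the stated threshold value itself stays in phase). Masked-out voxels
#' keep their original intensities but are excluded from all
#' center/membership computations and receive label 0 downstream.
#'
#' @param volume A [mia_volume()].
#' @param threshold Non-negative intensity.
#' @return Logical 3D array.
#' @export
background_mask <- function(volume, threshold) {
  stopifnot(inherits(volume, "mia_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("`threshold` must be a non-negative scalar")
  volume$data >= threshold
}

#' Invert foreground intensities
#'
#' Within the mask, maps intensity `v` to `(2^bit_depth - 1) - v`; voxels
#' outside the mask are unchanged. Utility for workflows that require the
#' phase of interest to be the brightest in the image.
#'
#' @param volume A [mia_volume()].
#' @param mask Logical 3D array of the same shape (default: everywhere).
#' @return A [mia_volume()].
#' @export
invert_foreground <- function(volume, mask = NULL) {
  stopifnot(inherits(volume, "mia_volume"))
  if (is.null(mask)) mask <- array(TRUE, dim(volume$data))
  mask <- as_mask(mask, dim(volume$data))
  out <- volume$data
  top <- 2^volume$bit_depth - 1
  out[mask] <- top - out[mask]
  mia_volume(out, volume$voxel_size_um, volume$bit_depth)
}
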