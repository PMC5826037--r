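#' Build the overlapping-cube grid
#'
#' Cube origins are placed at multiples of `stride` along each axis, with
#' the final origin clamped so the last cube ends exactly at the volume
#' boundary. Every voxel is covered by at least one cube and cubes never
#' extend outside the volume. With the default stride `ceiling(g/2)` (50%
#' overlap) an interior voxel is covered by at most 2 cubes per axis, i.e.
#' at most 8 in 3D. A grid size larger than an axis extent is clamped to
#' that extent (a single cube covers the axis).
#'
#' @param shape Integer vector of 3 volume extents (z, y, x).
#' @param grid_size Cube edge length g >= 3 (voxels).
#' @param stride Origin spacing in `[1, g]`; default `ceiling(g/2)`.
#' @return An object of class `mia_grid`: list with `origins` (matrix of
#'   1-based cube origins, one row per cube), `edge` (per-axis cube edge
#'   after clamping), `grid_size`, `stride`, `shape`.
#' @export
build_grid <- function(shape, grid_size, stride = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be 3 positive extents")
  g <- as.integer(grid_size)
  if (is.na(g) || g < 3L) stop("`grid_size` must be an integer >= 3")
  if (is.null(stride)) stride <- as.integer(ceiling(g / 2))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L || stride > g)
    stop("`stride` must lie in [1, grid_size]")
  edge <- pmin(g, shape)
  ax <- lapply(1:3, function(a) {
    last <- shape[a] - edge[a]           # 0-based final origin
    o <- seq.int(0L, last, by = stride)
    k <- length(o)
    if (o[k] != last) {
      # clamp the final cube to the boundary: move the last origin when the
      # previous cube still bridges the widened spacing (always true at the
      # default 50% overlap, keeping per-axis coverage <= 2), else add one
      if (k >= 2L && last - o[k - 1L] <= edge[a]) o[k] <- last
      else o <- c(o, last)
    }
    o
  })
  origins <- as.matrix(expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]],
                                   KEEP.OUT.ATTRS = FALSE)) + 1L
  dimnames(origins) <- list(NULL, c("z", "y", "x"))
  structure(list(origins = origins, edge = edge, grid_size = g,
                 stride = stride, shape = shape),
            class = "mia_grid")
}

#' @export
print.mia_grid <- function(x, ...) {
  cat(sprintf("<mia_grid> %d cubes of %s voxels (edge %d, stride %d) over %s\n",
              nrow(x$origins), paste(x$edge, collapse = "x"),
              x$grid_size, x$stride, paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Per-voxel cube coverage counts
#'
#' Number of grid cubes covering each voxel; used to check the coverage
#' invariants (>= 1 everywhere, <= 8 at 50% overlap).
#'
#' @param grid A [build_grid()] result.
#' @return Integer 3D array of counts.
#' @export
grid_coverage <- function(grid) {
  stopifnot(inherits(grid, "mia_grid"))
  cov <- array(0L, grid$shape)
  e <- grid$edge
  for (q in seq_len(nrow(grid$origins))) {
    o <- grid$origins[q, ]
    cov[o[1]:(o[1] + e[1] - 1L), o[2]:(o[2] + e[2] - 1L),
        o[3]:(o[3] + e[3] - 1L)] <-
      cov[o[1]:(o[1] + e[1] - 1L), o[2]:(o[2] + e[2] - 1L),
          o[3]:(o[3] + e[3] - 1L)] + 1L
  }
  cov
}

#' Suggest a grid size from the structure width
#'
#' The grid size should be slightly larger than the largest dimension of
#' the phase of interest, so that the local clustering does not look for
#' features inside the structure itself. Given the structure width (in um
#' or voxels), returns `round(width_in_voxels) + margin`, floored at 3.
#'
#' @param width Structure width (> 0), in um when `voxel_size_um` is
#'   given, else in voxels.
#' @param voxel_size_um Voxel edge length (um); required for um widths.
#' @param margin Safety margin in voxels (default 2).
#' @return Integer grid size.
#' @export
#' @examples
#' suggest_grid_size(40, voxel_size_um = 7.86)  # 40 um wire at 7.86 um -> 7
#' suggest_grid_size(15, margin = 5)            # 15-voxel trabeculae -> 20
suggest_grid_size <- function(width, voxel_size_um = NULL, margin = 2L) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("`width` must be a positive scalar")
  margin <- as.integer(margin)
  if (is.na(margin) || margin < 1L) stop("`margin` must be an integer >= 1")
  w_vox <- if (is.null(voxel_size_um)) width else {
    if (voxel_size_um <= 0) stop("`voxel_size_um` must be positive")
    width / voxel_size_um
  }
  max(3L, as.integer(round(w_vox)) + margin)
}
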