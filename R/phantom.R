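#' Specify a synthetic phantom
#'
#' Deterministic, seeded ground-truth volumes emulating the validation
#' objects used for micro-CT segmentation testing: a coiled plate of known
#' uniform thickness in air (`plate_coil`, the machined-wire analog), a
#' connected rod lattice (`trabecular_lattice`), and a fossil-like volume
#' (`fossil_like`) with a bone-level lattice embedded in brighter invasive
#' matrix, background-level cracks, a center-bright radial intensity
#' gradient, small near-saturation inclusions, and background noise.
#'
#' @param kind `"plate_coil"`, `"trabecular_lattice"` or `"fossil_like"`.
#' @param shape 3 integer extents (z, y, x).
#' @param thickness_vox Structure thickness in voxels (>= 2).
#' @param foreground_level Structure (wire/bone) intensity.
#' @param background_level Air intensity.
#' @param matrix_level Invasive-matrix intensity; required for
#'   `fossil_like` and must exceed `foreground_level` (matrix attenuates
#'   more strongly than fossil bone).
#' @param gradient_amplitude Center-bright multiplicative radial ramp
#'   amplitude `a`: non-background voxels are scaled by
#'   `1 + a * (1 - r/r_max)` with `r` the distance from the volume center
#'   and `r_max` the largest such distance over the structure.
#' @param noise_sd Additive Gaussian intensity noise sd.
#' @param inclusion_density Fraction of structure+matrix voxels replaced
#'   by near-saturation bright specks.
#' @param bit_depth 8 or 16 (default 16); output is clipped and rounded
#'   to this range, like reconstructed CT data.
#' @param seed Integer RNG seed; identical specs give bit-identical
#'   phantoms.
#' @param voxel_size_um Voxel edge length (um), default 7.86.
#' @param coil_pitch Radial distance between successive coil walls
#'   (default `4 * thickness_vox`).
#' @param coil_r0 Innermost wall radius (default `3 * thickness_vox`).
#' @param lattice_spacing Rod-lattice period (default
#'   `4 * thickness_vox`).
#' @param n_cracks Number of planar background-level slits cut through a
#'   `fossil_like` body (default 2).
#' @return An object of class `mia_phantom_spec`.
#' @export
phantom_spec <- function(kind = c("plate_coil", "trabecular_lattice", "fossil_like"),
                         shape, thickness_vox = 5, foreground_level = 30000,
                         background_level = 0, matrix_level = NULL,
                         gradient_amplitude = 0, noise_sd = 0,
                         inclusion_density = 0, bit_depth = 16L, seed = 1L,
                         voxel_size_um = 7.86, coil_pitch = NULL,
                         coil_r0 = NULL, lattice_spacing = NULL,
                         n_cracks = 2L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("`shape` must be 3 extents, each >= 4")
  if (thickness_vox < 2) stop("`thickness_vox` must be >= 2")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  top <- 2^bit_depth - 1
  lv <- c(foreground_level, background_level, matrix_level)
  if (any(lv < 0) || any(lv > top))
    stop("intensity levels must lie within the bit-depth range [0, ", top, "]")
  if (foreground_level <= background_level)
    stop("`foreground_level` must exceed `background_level`")
  if (kind == "fossil_like") {
    if (is.null(matrix_level)) stop("`fossil_like` requires `matrix_level`")
    if (matrix_level <= foreground_level)
      stop("`matrix_level` must exceed `foreground_level`")
  }
  if (gradient_amplitude < 0) stop("`gradient_amplitude` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (inclusion_density < 0 || inclusion_density >= 1)
    stop("`inclusion_density` must lie in [0, 1)")
  structure(list(kind = kind, shape = shape,
                 thickness_vox = as.numeric(thickness_vox),
                 foreground_level = as.numeric(foreground_level),
                 background_level = as.numeric(background_level),
                 matrix_level = if (is.null(matrix_level)) NULL else as.numeric(matrix_level),
                 gradient_amplitude = as.numeric(gradient_amplitude),
                 noise_sd = as.numeric(noise_sd),
                 inclusion_density = as.numeric(inclusion_density),
                 bit_depth = bit_depth, seed = as.integer(seed),
                 voxel_size_um = as.numeric(voxel_size_um),
                 coil_pitch = coil_pitch %||% 4 * thickness_vox,
                 coil_r0 = coil_r0 %||% 3 * thickness_vox,
                 lattice_spacing = lattice_spacing %||% as.integer(round(4 * thickness_vox)),
                 n_cracks = as.integer(n_cracks)),
            class = "mia_phantom_spec")
}

#' Generate a phantom volume with ground truth
#'
#' Builds the geometry for the requested [phantom_spec()], then applies
#' artifacts in a fixed, documented order: radial center-bright gradient,
#' bright inclusions, additive Gaussian noise, clipping and rounding to
#' the bit-depth range. The RNG state is drawn from `spec$seed` in an
#' isolated stream (the caller's RNG state is untouched), so identical
#' specs produce bit-identical phantoms.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `mia_phantom`: `volume` ([mia_volume()]),
#'   `true_mask` (structure mask), `true_labels` ([mia_labels()]; for
#'   `fossil_like`: 1 = background/cracks, 2 = bone, 3 = matrix),
#'   `inclusion_mask`, and the `spec` echo.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "mia_phantom_spec"))
  geo <- switch(spec$kind,
                plate_coil = geom_plate_coil(spec),
                trabecular_lattice = geom_lattice(spec),
                fossil_like = geom_fossil(spec))
  vol <- geo$base                     # intensities before artifacts
  support <- geo$support              # non-background voxels
  top <- 2^spec$bit_depth - 1

  # 1) multiplicative center-bright radial ramp over the structure
  if (spec$gradient_amplitude > 0 && any(support)) {
    d <- spec$shape
    ctr <- (d + 1) / 2
    rz <- (seq_len(d[1]) - ctr[1])^2
    ry <- (seq_len(d[2]) - ctr[2])^2
    rx <- (seq_len(d[3]) - ctr[3])^2
    r <- sqrt(outer(outer(rz, ry, `+`), rx, `+`))
    rmax <- max(r[support])
    fac <- 1 + spec$gradient_amplitude * (1 - r / rmax)
    vol[support] <- vol[support] * fac[support]
  }

  # seeded, isolated RNG stream for the stochastic artifacts
  inc_mask <- array(FALSE, spec$shape)
  with_phantom_rng(spec$seed, {
    # 2) near-saturation bright specks
    if (spec$inclusion_density > 0 && any(support)) {
      cand <- which(support)
      n_inc <- round(spec$inclusion_density * length(cand))
      if (n_inc > 0) {
        pick <- sample(cand, n_inc)
        vol[pick] <- 0.98 * top
        inc_mask[pick] <- TRUE
      }
    }
    # 3) additive Gaussian noise, everywhere (background noise included)
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim(vol))
  })

  # 4) clip and round to the bit-depth range
  vol <- round(pmin(pmax(vol, 0), top))

  list2 <- list(volume = mia_volume(vol, spec$voxel_size_um, spec$bit_depth),
                true_mask = geo$true_mask,
                true_labels = mia_labels(geo$true_labels,
                                         n_classes = geo$n_classes,
                                         voxel_size_um = spec$voxel_size_um),
                inclusion_mask = inc_mask, spec = spec)
  structure(list2, class = "mia_phantom")
}

#' @export
print.mia_phantom <- function(x, ...) {
  cat(sprintf("<mia_phantom> kind %s, %s voxels, thickness %.3g vox, seed %d\n",
              x$spec$kind, paste(x$spec$shape, collapse = "x"),
              x$spec$thickness_vox, x$spec$seed))
  cat(sprintf("  structure voxels: %d (%.2f%%)\n", sum(x$true_mask),
              100 * mean(x$true_mask)))
  invisible(x)
}

# evaluate expr with a private RNG stream seeded from `seed`
with_phantom_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Square-wound coiled plate spanning all z, emulating a machined coil of
# rectangular cross-section.  The spiral path is traced on the voxel grid
# and dilated in-plane by a t x t square, so every wall is axis-aligned and
# spans exactly t voxels: the digitized wall thickness equals the nominal
# one, which is what makes the phantom usable as a metrology reference.
geom_plate_coil <- function(spec) {
  d <- spec$shape
  t <- as.integer(round(spec$thickness_vox))
  pitch <- as.integer(round(spec$coil_pitch))
  if (pitch < t + 2)
    stop("geometry error: coil pitch ", pitch,
         " leaves no air gap between walls of thickness ", t)
  margin <- t + 2L
  lo_y <- margin; hi_y <- d[2] - margin + 1L
  lo_x <- margin; hi_x <- d[3] - margin + 1L
  if (hi_y - lo_y < 2L * pitch || hi_x - lo_x < 2L * pitch)
    stop("geometry error: thickness/pitch too large for shape ",
         paste(d, collapse = "x"))
  # expanding square spiral: arm lengths pitch, pitch, 2*pitch, 2*pitch, ...
  py <- as.integer(round((d[2] + 1) / 2))
  px <- as.integer(round((d[3] + 1) / 2))
  path <- matrix(FALSE, d[2], d[3])
  path[py, px] <- TRUE
  dirs <- matrix(c(0L, 1L, 1L, 0L, 0L, -1L, -1L, 0L), 4, 2, byrow = TRUE)
  arm <- 0L
  repeat {
    len <- pitch * (arm %/% 2L + 1L)
    dy <- dirs[arm %% 4L + 1L, 1L]
    dx <- dirs[arm %% 4L + 1L, 2L]
    stopped <- FALSE
    for (s in seq_len(len)) {
      ny <- py + dy; nx <- px + dx
      if (ny < lo_y || ny > hi_y || nx < lo_x || nx > hi_x) {
        stopped <- TRUE
        break
      }
      py <- ny; px <- nx
      path[py, px] <- TRUE
    }
    if (stopped) break
    arm <- arm + 1L
  }
  # dilate the path by a t x t square (centered; one voxel further on the
  # positive side when t is even)
  hlo <- (t - 1L) %/% 2L
  hhi <- t %/% 2L
  inside <- matrix(FALSE, d[2], d[3])
  for (oy in (-hlo):hhi)
    for (ox in (-hlo):hhi) {
      ys <- pmin(pmax(seq_len(d[2]) - oy, 1L), d[2])
      xs <- pmin(pmax(seq_len(d[3]) - ox, 1L), d[3])
      inside <- inside | path[ys, xs]
    }
  mask <- array(rep(inside, each = d[1]), d)
  base <- array(spec$background_level, d)
  base[mask] <- spec$foreground_level
  labels <- array(1L, d)
  labels[mask] <- 2L
  list(base = base, support = mask, true_mask = mask, true_labels = labels,
       n_classes = 2L)
}

# periodic axis profile: slabs of width t every s voxels, centered in cell
axis_profile <- function(n, s, t) ((seq_len(n) - 1) %% s) < t

# connected rod-and-plate lattice: union of axis-aligned rods of square
# cross-section t x t on a cubic grid of period `lattice_spacing`
lattice_mask <- function(d, s, t) {
  pz <- axis_profile(d[1], s, t)
  py <- axis_profile(d[2], s, t)
  px <- axis_profile(d[3], s, t)
  mzy <- outer(pz, py)                       # rods along x
  mzx <- outer(pz, px)                       # rods along y
  myx <- outer(py, px)                       # rods along z
  m <- array(FALSE, d)
  m <- m | array(rep(mzy, times = d[3]), d)
  m <- m | aperm(array(rep(mzx, times = d[2]), c(d[1], d[3], d[2])), c(1, 3, 2))
  m <- m | aperm(array(rep(myx, times = d[1]), c(d[2], d[3], d[1])), c(3, 1, 2))
  m
}

geom_lattice <- function(spec) {
  d <- spec$shape
  t <- round(spec$thickness_vox)
  s <- spec$lattice_spacing
  if (s <= t)
    stop("geometry error: lattice spacing ", s,
         " must exceed rod thickness ", t)
  mask <- lattice_mask(d, s, t)
  base <- array(spec$background_level, d)
  base[mask] <- spec$foreground_level
  labels <- array(1L, d)
  labels[mask] <- 2L
  list(base = base, support = mask, true_mask = mask, true_labels = labels,
       n_classes = 2L)
}

# bone-level lattice inside an ellipsoidal body filled with brighter
# invasive matrix, cut by planar background-level cracks
geom_fossil <- function(spec) {
  d <- spec$shape
  t <- round(spec$thickness_vox)
  s <- spec$lattice_spacing
  if (s <= t)
    stop("geometry error: lattice spacing ", s,
         " must exceed rod thickness ", t)
  ctr <- (d + 1) / 2
  semi <- 0.42 * d
  ez <- ((seq_len(d[1]) - ctr[1]) / semi[1])^2
  ey <- ((seq_len(d[2]) - ctr[2]) / semi[2])^2
  ex <- ((seq_len(d[3]) - ctr[3]) / semi[3])^2
  body <- outer(outer(ez, ey, `+`), ex, `+`) <= 1
  lat <- lattice_mask(d, s, t)
  crack <- array(FALSE, d)
  if (spec$n_cracks > 0) {
    # evenly placed y-normal slits of 1-voxel width through the body
    ys <- round(ctr[2] + (seq_len(spec$n_cracks) - (spec$n_cracks + 1) / 2) *
                  d[2] / (spec$n_cracks + 2))
    ys <- ys[ys >= 1 & ys <= d[2]]
    crack[, ys, ] <- TRUE
    crack <- crack & body
  }
  bone <- body & lat & !crack
  matrix_ <- body & !lat & !crack
  base <- array(spec$background_level, d)
  base[matrix_] <- spec$matrix_level
  base[bone] <- spec$foreground_level
  labels <- array(1L, d)
  labels[bone] <- 2L
  labels[matrix_] <- 3L
  list(base = base, support = bone | matrix_, true_mask = bone,
       true_labels = labels, n_classes = 3L)
}

#' Score a segmentation against phantom ground truth
#'
#' Voxelwise sensitivity, specificity and Dice overlap of
#' `binarize(labels, class_id)` against the phantom's true structure mask,
#' restricted to non-inclusion voxels (bright specks belong to neither
#' phase).
#'
#' @param truth A [make_phantom()] result.
#' @param labels A [mia_labels()] of the same shape.
#' @param class_id Class to score (id or `"brightest"` /
#'   `"second-brightest"`).
#' @return A one-row tibble with `class_id`, `sensitivity`, `specificity`,
#'   `dice`.
#' @export
phantom_report <- function(truth, labels, class_id) {
  stopifnot(inherits(truth, "mia_phantom"), inherits(labels, "mia_labels"))
  if (!identical(dim(labels$labels), truth$spec$shape))
    stop("label volume shape does not match the phantom")
  pred <- binarize(labels, class_id)
  keep <- !truth$inclusion_mask
  p <- pred[keep]
  g <- truth$true_mask[keep]
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  tibble::tibble(class_id = if (is.character(class_id)) class_id else as.integer(class_id),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}
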