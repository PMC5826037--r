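#' Read a 3D grayscale volume
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`; gzip handled transparently) or
#' multi-page TIFF stacks (one page per z-slice) into a [mia_volume()].
#' Intensities are returned exactly as stored, never rescaled.
#'
#' Voxel size is taken from the NIfTI `pixdim` header when available; a
#' `voxel_size_um` override always wins (with a warning when it disagrees
#' with the header). TIFF files carry no reliable voxel-size metadata, so
#' the override is required there. Anisotropic spacing beyond 0.1% relative
#' tolerance is an error: the clustering and thickness modules assume
#' isometric voxels. A 4D image with a trailing singleton dimension (a
#' common exporter quirk) is accepted and squeezed.
#'
#' @param path Path to the image file.
#' @param format `"auto"` (by extension), `"nifti"` or `"tiff"`.
#' @param voxel_size_um Optional voxel-size override (um).
#' @param bit_depth Optional bit-depth hint (8 or 16); inferred otherwise.
#' @return A [mia_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff"),
                        voxel_size_um = NULL, bit_depth = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("cannot read NIfTI file '", path,
                                             "': ", conditionMessage(e)))
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) {
      img_d <- array(as.numeric(img), d)[, , , 1, drop = TRUE]
      dim(img_d) <- d[1:3]
    } else if (length(d) == 3L) {
      img_d <- array(as.numeric(img), d)
    } else {
      stop("image has ", length(d), " dimensions; a 3D volume is required")
    }
    px <- RNifti::pixdim(img)[1:3]
    header_vox <- NULL
    if (all(is.finite(px)) && all(px > 0)) {
      if (diff(range(px)) > 0.001 * mean(px))
        stop("anisotropic voxel spacing (", paste(signif(px, 6), collapse = " x "),
             "); isometric voxels are required")
      header_vox <- px[1]
    }
    if (!is.null(voxel_size_um)) {
      if (!is.null(header_vox) &&
          abs(header_vox - voxel_size_um) > 1e-6 * voxel_size_um)
        warning("voxel-size override ", voxel_size_um,
                " um differs from header pixdim ", signif(header_vox, 6),
                "; using the override")
      vox <- voxel_size_um
    } else if (!is.null(header_vox)) {
      vox <- header_vox
    } else {
      stop("no voxel size in header and no `voxel_size_um` override supplied")
    }
    return(mia_volume(img_d, voxel_size_um = vox, bit_depth = bit_depth))
  }
  # TIFF stack; readTIFF returns intensities normalized to [0, 1] for
  # integer samples and raw values for float samples, so integer pages are
  # rescaled back to their stored range using the recorded bit depth
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("cannot read TIFF file '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L || !is.matrix(pages[[1]]))
    stop("TIFF file does not contain 2D grayscale pages")
  if (is.null(voxel_size_um))
    stop("TIFF stacks carry no voxel size; supply `voxel_size_um`")
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  fmt <- attr(pages[[1]], "sample.format") %||% "uint"
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) {
    if (!identical(dim(pages[[z]])[1:2], c(ny, nx)))
      stop("TIFF pages have inconsistent dimensions")
    arr[z, , ] <- pages[[z]]
  }
  if (!identical(fmt, "float") && bits <= 16L)
    arr <- round(arr * (2^bits - 1))
  mia_volume(arr, voxel_size_um = voxel_size_um, bit_depth = bit_depth)
}

#' Write a volume, label volume or membership channel
#'
#' Writes NIfTI-1 or multi-page TIFF such that [read_volume()] returns the
#' identical data. Grayscale volumes are stored as unsigned integers at
#' their bit depth, label volumes as unsigned 8-bit integers, and
#' membership channels (numeric 3D arrays with values in `[0, 1]`) as
#' 32-bit floating point.
#'
#' @param x A [mia_volume()], [mia_labels()], or a 3D numeric array with
#'   values in `[0, 1]` (a membership channel).
#' @param path Output path.
#' @param format `"auto"` (by extension), `"nifti"` or `"tiff"`.
#' @param voxel_size_um Voxel size recorded in the NIfTI header; defaults
#'   to the object's own. Required for bare membership arrays written to
#'   NIfTI.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path, format = c("auto", "nifti", "tiff"),
                         voxel_size_um = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (inherits(x, "mia_volume")) {
    data <- x$data
    datatype <- if (x$bit_depth == 8L) "uint8" else "uint16"
    vox <- voxel_size_um %||% x$voxel_size_um
    tiff_bits <- x$bit_depth
    tiff_scale <- 2^x$bit_depth - 1
  } else if (inherits(x, "mia_labels")) {
    data <- x$labels
    if (x$n_classes > 255L) stop("more than 255 classes cannot be stored as uint8")
    datatype <- "uint8"
    vox <- voxel_size_um %||% x$voxel_size_um
    tiff_bits <- 8L
    tiff_scale <- 255
  } else if (is.array(x) && length(dim(x)) == 3L && is.numeric(x)) {
    if (min(x) < 0 || max(x) > 1)
      stop("membership channels must have values in [0, 1]")
    data <- x
    datatype <- "float"
    vox <- voxel_size_um %||% 1
    tiff_bits <- 32L
    tiff_scale <- 1
  } else {
    stop("`x` must be a mia_volume, mia_labels, or 3D numeric array in [0,1]")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (format == "nifti") {
    img <- RNifti::asNifti(array(as.numeric(data), dim(data)))
    RNifti::pixdim(img) <- rep(vox, 3)
    RNifti::writeNifti(img, path, datatype = datatype)
  } else {
    d <- dim(data)
    pages <- lapply(seq_len(d[1]), function(z) {
      m <- matrix(data[z, , ], d[2], d[3])
      m / tiff_scale
    })
    tiff::writeTIFF(pages, path, bits.per.sample = tiff_bits)
  }
  invisible(path)
}

#' Read a label volume
#'
#' Convenience wrapper around [read_volume()] returning a [mia_labels()].
#'
#' @inheritParams read_volume
#' @param n_classes Number of classes; defaults to the data maximum.
#' @return A [mia_labels()].
#' @export
read_labels <- function(path, format = c("auto", "nifti", "tiff"),
                        voxel_size_um = NULL, n_classes = NULL) {
  v <- read_volume(path, format, voxel_size_um = voxel_size_um)
  lab <- v$data
  if (max(abs(lab - round(lab))) > 1e-6)
    stop("file does not contain integer labels")
  lab <- array(as.integer(round(lab)), dim(lab))
  mia_labels(lab, n_classes = n_classes %||% max(lab, 1L),
             voxel_size_um = v$voxel_size_um)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.tiff?$", low)) return("tiff")
  stop("cannot infer format from extension of '", path,
       "'; pass format = \"nifti\" or \"tiff\"")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
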