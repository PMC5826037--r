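#' Segmentation configuration
#'
#' All user parameters of the clustering pipeline.
#'
#' @param n_classes Number of intensity classes C >= 2.
#' @param grid_size Edge length g >= 3 (voxels) of the overlapping cubes
#'   used by the local refinement; see [suggest_grid_size()].
#' @param class_presence_threshold Fraction in (0, 1), default 0.02: a
#'   class whose summed global membership inside a cube is below this
#'   fraction of the cube's in-mask voxel count is dropped from that
#'   cube's local clustering.
#' @param prob_threshold Optional probability threshold on a voxel's
#'   highest membership, as an integer percent in 51..100 or the
#'   equivalent fraction. 50 (or 0.5) is accepted as an alias for "no
#'   threshold". See [prob_threshold_menu()].
#' @param fuzziness Fuzzy c-means exponent m > 1, default 2.
#' @param tol Convergence tolerance on the relative center change,
#'   default 1e-5.
#' @param max_iter Iteration cap per c-means run, default 100.
#' @param stride Cube origin spacing; default `ceiling(grid_size/2)`.
#' @param emit_global Also return the global-only membership field and
#'   labels for comparison with the refined result.
#' @return An object of class `mia_config`.
#' @export
seg_config <- function(n_classes, grid_size, class_presence_threshold = 0.02,
                       prob_threshold = NULL, fuzziness = 2, tol = 1e-5,
                       max_iter = 100L, stride = NULL, emit_global = FALSE) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) stop("`n_classes` must be >= 2")
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 3L) stop("`grid_size` must be >= 3")
  if (!is.numeric(class_presence_threshold) ||
      class_presence_threshold <= 0 || class_presence_threshold >= 1)
    stop("`class_presence_threshold` must lie in (0, 1)")
  prob_threshold <- normalize_prob_threshold(prob_threshold)
  if (fuzziness <= 1) stop("`fuzziness` must be > 1")
  if (tol <= 0) stop("`tol` must be positive")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("`max_iter` must be >= 1")
  if (is.null(stride)) stride <- as.integer(ceiling(grid_size / 2))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L || stride > grid_size)
    stop("`stride` must lie in [1, grid_size]")
  structure(list(n_classes = n_classes, grid_size = grid_size,
                 class_presence_threshold = as.numeric(class_presence_threshold),
                 prob_threshold = prob_threshold,
                 fuzziness = as.numeric(fuzziness), tol = as.numeric(tol),
                 max_iter = max_iter, stride = stride,
                 emit_global = isTRUE(emit_global)),
            class = "mia_config")
}

#' The admissible probability-threshold menu
#'
#' The optional threshold on a voxel's highest membership probability takes
#' one of exactly 50 active integer-percent values, 51..100. 50% is
#' accepted on input as an alias for "no threshold" (for a two-class field
#' the highest of two probabilities summing to one is always >= 0.5).
#'
#' @return Integer vector `51:100` of active threshold percents.
#' @export
prob_threshold_menu <- function() 51:100

# Accepts NULL, integer percent 50..100, or fraction 0.50..1.00 on the
# percent grid; returns a fraction, or NULL for the 50% no-op alias.
normalize_prob_threshold <- function(t) {
  if (is.null(t)) return(NULL)
  if (!is.numeric(t) || length(t) != 1L || is.na(t))
    stop("`prob_threshold` must be a single number")
  pct <- if (t > 1) t else t * 100
  if (abs(pct - round(pct)) > 1e-9 || round(pct) < 50 || round(pct) > 100)
    stop("`prob_threshold` must be an integer percent in 50..100 ",
         "(50 = no threshold); got ", t)
  pct <- round(pct)
  if (pct == 50) return(NULL)
  pct / 100
}

#' Construct a membership field
#'
#' Per-voxel class membership probability vectors. In-mask voxels carry a
#' vector summing to 1; voxels outside the analysis mask are identically 0.
#'
#' @param u Either a 4D array `[z, y, x, class]` or an `n x C` matrix in
#'   voxel-linear order.
#' @param mask Logical 3D analysis mask.
#' @param voxel_size_um Voxel edge length (um).
#' @return An object of class `mia_membership` with elements `u` (4D
#'   array), `mask`, `n_classes`, `voxel_size_um`.
#' @export
membership_field <- function(u, mask, voxel_size_um) {
  mask <- as_mask(mask)
  shape <- dim(mask)
  if (is.matrix(u)) {
    if (nrow(u) != prod(shape)) stop("membership rows must match voxel count")
    C <- ncol(u)
    u <- array(u, c(shape, C))
  }
  if (length(dim(u)) != 4L || !identical(dim(u)[1:3], shape))
    stop("`u` must be [z, y, x, class] matching the mask shape")
  C <- dim(u)[4]
  if (min(u) < -1e-9 || max(u) > 1 + 1e-9)
    stop("memberships must lie in [0, 1]")
  structure(list(u = u, mask = mask, n_classes = C,
                 voxel_size_um = as.numeric(voxel_size_um)),
            class = "mia_membership")
}

#' @export
print.mia_membership <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("<mia_membership> %d x %d x %d voxels, %d classes, %d in mask\n",
              d[1], d[2], d[3], x$n_classes, sum(x$mask)))
  invisible(x)
}

# n x C matrix view of a membership field (shares the array's layout)
memb_matrix <- function(mf) {
  d <- dim(mf$u)
  matrix(mf$u, prod(d[1:3]), d[4])
}

#' Hard class assignment with optional probability threshold
#'
#' Each in-mask voxel is assigned to its highest-membership class (ties go
#' to the lowest class index), using 1-based class labels ordered by
#' ascending class-center intensity. When a probability threshold is set,
#' a voxel whose highest membership does not meet or exceed it is labeled
#' 0 instead; out-of-mask voxels are always 0.
#'
#' @param mf A [membership_field()].
#' @param prob_threshold Optional threshold; see [prob_threshold_menu()].
#' @return A [mia_labels()].
#' @export
assign_labels <- function(mf, prob_threshold = NULL) {
  stopifnot(inherits(mf, "mia_membership"))
  t <- normalize_prob_threshold(prob_threshold)
  u <- memb_matrix(mf)
  lab <- max.col(u, ties.method = "first")
  if (!is.null(t)) {
    umax <- u[cbind(seq_len(nrow(u)), lab)]
    lab[umax < t] <- 0L
  }
  lab[!mf$mask] <- 0L
  mia_labels(array(as.integer(lab), dim(mf$mask)), n_classes = mf$n_classes,
             voxel_size_um = mf$voxel_size_um)
}

#' Extract one class as a binary mask
#'
#' @param labels A [mia_labels()].
#' @param class Integer class id in `1..n_classes`, or `"brightest"` /
#'   `"second-brightest"`, resolved against the ascending class-center
#'   order (so `brightest` is class C, `second-brightest` is C - 1).
#' @return Logical 3D array, `TRUE` where `labels == class`.
#' @export
binarize <- function(labels, class) {
  stopifnot(inherits(labels, "mia_labels"))
  C <- labels$n_classes
  if (is.character(class)) {
    class <- switch(match.arg(class, c("brightest", "second-brightest")),
                    "brightest" = C, "second-brightest" = C - 1L)
  }
  class <- as.integer(class)
  if (is.na(class) || class < 1L || class > C)
    stop("`class` must lie in 1..", C)
  labels$labels == class
}

#' Local fuzzy c-means refinement in overlapping cubes
#'
#' The locally adaptive stage. For each cube of the grid: (i) classes whose
#' summed global membership over the cube's in-mask voxels falls below
#' `class_presence_threshold` times that voxel count are dropped; (ii) if
#' two or more classes survive, fuzzy c-means is re-run on the cube's
#' intensities, seeded with the surviving global centers and memberships
#' (renormalized over the survivors); a single surviving class gets
#' membership 1 throughout the cube; (iii) per-cube membership vectors are
#' averaged (unweighted) over all cubes covering each voxel and
#' renormalized to sum 1. Constant cubes, and cubes where the local
#' centers collapse, keep the global field.
#'
#' @param volume A [mia_volume()] (already pre-processed).
#' @param mask Logical analysis mask.
#' @param global_mf Global [membership_field()].
#' @param global_centers Ascending global class centers.
#' @param config A [seg_config()].
#' @return The merged, refined [membership_field()], with attribute
#'   `"refine_log"` carrying cube counts and total iterations.
#' @export
local_refine <- function(volume, mask, global_mf, global_centers, config) {
  stopifnot(inherits(volume, "mia_volume"),
            inherits(global_mf, "mia_membership"),
            inherits(config, "mia_config"))
  mask <- as_mask(mask, dim(volume$data))
  grid <- build_grid(dim(volume$data), config$grid_size, config$stride)
  res <- local_refine_cpp(as.numeric(volume$data), dim(volume$data), mask,
                          memb_matrix(global_mf), as.numeric(global_centers),
                          grid$origins - 1L, grid$edge,
                          config$class_presence_threshold, config$fuzziness,
                          config$tol, config$max_iter)
  out <- membership_field(res$memberships, mask, volume$voxel_size_um)
  attr(out, "refine_log") <- res[c("cubes_used", "cubes_dropping",
                                   "cubes_single", "cubes_degenerate",
                                   "iterations")]
  out
}

#' Segment a volume
#'
#' Full pipeline: optional median filter and background threshold, K-means
#' initialization on the in-mask intensities, global fuzzy c-means, local
#' refinement in overlapping cubes, and hard assignment with the optional
#' probability threshold.
#'
#' @param volume A [mia_volume()].
#' @param config A [seg_config()].
#' @param preprocess A [pp_params()] (default: no pre-processing).
#' @return An object of class `mia_segmentation`: list with `labels`
#'   ([mia_labels()]), `memberships` (refined [membership_field()]),
#'   `centers` (ascending global class centers), `mask`, `config`,
#'   `preprocess`, `log` (tibble of per-stage iteration counts),
#'   `objective` (global c-means objective trace) and, when
#'   `config$emit_global` is set, `global` (list of `memberships` and
#'   `labels` from the global stage alone).
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("plate_coil", shape = c(16, 48, 48),
#'                                 thickness_vox = 3, seed = 1))
#' seg <- segment(ph$volume, seg_config(n_classes = 2, grid_size = 5))
#' table(seg$labels$labels)
segment <- function(volume, config, preprocess = pp_params()) {
  stopifnot(inherits(volume, "mia_volume"), inherits(config, "mia_config"),
            inherits(preprocess, "mia_pp"))
  vol <- volume
  if (preprocess$median_kernel > 0L)
    vol <- with_stage("median_filter",
                      median_filter(vol, preprocess$median_kernel))
  mask <- if (!is.null(preprocess$background_threshold)) {
    with_stage("background_mask",
               background_mask(vol, preprocess$background_threshold))
  } else {
    array(TRUE, dim(vol$data))
  }
  x <- vol$data[mask]
  if (length(x) == 0L)
    stop("segment [background_mask]: no voxels remain above the threshold")

  centers0 <- with_stage("kmeans_init", kmeans_init(x, config$n_classes))

  # global c-means, run on the compressed intensity histogram when the
  # volume has few distinct values (always true for integer CT data)
  ux <- sort(unique(x))
  glob <- if (length(ux) <= length(x) / 4) {
    w <- tabulate(match(x, ux), length(ux))
    fit <- with_stage("global_fcm",
                      fcm(ux, centers0, m = config$fuzziness, tol = config$tol,
                          max_iter = config$max_iter, weights = w))
    list(fit = fit, u_x = fit$memberships[match(x, ux), , drop = FALSE])
  } else {
    fit <- with_stage("global_fcm",
                      fcm(x, centers0, m = config$fuzziness, tol = config$tol,
                          max_iter = config$max_iter))
    list(fit = fit, u_x = fit$memberships)
  }
  centers <- glob$fit$centers
  n <- prod(dim(vol$data))
  ug <- matrix(0, n, config$n_classes)
  ug[which(mask), ] <- glob$u_x
  global_mf <- membership_field(ug, mask, vol$voxel_size_um)

  refined <- with_stage("local_refine",
                        local_refine(vol, mask, global_mf, centers, config))
  rlog <- attr(refined, "refine_log")
  labels <- assign_labels(refined, config$prob_threshold)

  log <- tibble::tibble(
    stage = c("kmeans_init", "global_fcm", "local_refine"),
    iterations = c(NA_real_, glob$fit$iterations, rlog$iterations),
    detail = c(sprintf("%d classes", config$n_classes),
               sprintf("objective %.6g -> %.6g",
                       glob$fit$objective[1],
                       glob$fit$objective[length(glob$fit$objective)]),
               sprintf("%d cubes (%d dropped a class, %d single-class, %d kept global)",
                       rlog$cubes_used, rlog$cubes_dropping, rlog$cubes_single,
                       rlog$cubes_degenerate)))

  out <- list(labels = labels, memberships = refined, centers = centers,
              mask = mask, config = config, preprocess = preprocess,
              log = log, objective = glob$fit$objective)
  if (config$emit_global) {
    out$global <- list(memberships = global_mf,
                       labels = assign_labels(global_mf, config$prob_threshold))
  }
  class(out) <- "mia_segmentation"
  out
}

# wrap a pipeline stage so errors carry the stage name
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("segment [", stage, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.mia_segmentation <- function(x, ...) {
  cat("<mia_segmentation>\n")
  cat("  centers:", paste(signif(x$centers, 6), collapse = ", "), "\n")
  cat(sprintf("  labels: %d classes + background over %s voxels\n",
              x$labels$n_classes, paste(dim(x$labels), collapse = "x")))
  print(x$log)
  invisible(x)
}
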