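#' Sphere-fitting 3D local thickness
#'
#' Local thickness at a point is the diameter of the largest sphere that
#' contains the point and fits entirely inside the structure (the
#' definition used by standard bone-morphometry software). Computed via an
#' exact Euclidean distance transform, a distance ridge (medial spheres not
#' contained in a neighbor's sphere), and sphere painting taking the
#' maximum diameter over covering spheres. Distances are measured to the
#' nearest background voxel center, half a voxel beyond the physical
#' interface, so diameters are reported as `2*r - 1`; space outside the
#' volume is treated as structure (no artificial boundary).
#'
#' @param mask Logical 3D structure mask (non-empty), or a [mia_volume()]
#'   whose positive voxels form the structure.
#' @param voxel_size_um Voxel edge length (um) used for the um-scaled
#'   summary statistics.
#' @return An object of class `mia_thickness`: `thickness_map` (3D array,
#'   0 outside the structure), per-foreground-voxel summaries `mean_vox`,
#'   `sd_vox`, `mean_um`, `sd_um`, plus `n_foreground` and
#'   `voxel_size_um`.
#' @export
#' @examples
#' slab <- array(FALSE, c(20, 20, 11))
#' slab[, , 4:8] <- TRUE               # 5-voxel slab
#' local_thickness(slab, voxel_size_um = 10)$mean_vox
local_thickness <- function(mask, voxel_size_um = 1) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("empty structure: the mask has no foreground voxels")
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar")
  th <- local_thickness_cpp(mask, dim(mask))
  th <- array(th, dim(mask))
  vals <- th[mask]
  structure(list(thickness_map = th,
                 mean_vox = mean(vals), sd_vox = sd(vals),
                 mean_um = mean(vals) * voxel_size_um,
                 sd_um = sd(vals) * voxel_size_um,
                 n_foreground = sum(mask),
                 voxel_size_um = as.numeric(voxel_size_um)),
            class = "mia_thickness")
}

#' @export
print.mia_thickness <- function(x, ...) {
  cat(sprintf("<mia_thickness> %d structure voxels\n", x$n_foreground))
  cat(sprintf("  mean %.4f vox (sd %.4f) = %.4f um (sd %.4f) at %.4g um/voxel\n",
              x$mean_vox, x$sd_vox, x$mean_um, x$sd_um, x$voxel_size_um))
  invisible(x)
}

#' Parameter sweep with thickness read-out
#'
#' Re-runs the segmentation over a range of one parameter
#' (`prob_threshold` or `grid_size`), extracts the selected class, and
#' measures its mean 3D local thickness — the experiment used to assess
#' parameter robustness. The pipeline is deterministic, so for the
#' `prob_threshold` sweep the (threshold-independent) membership field is
#' computed once and only the hard assignment is repeated; each row still
#' equals a full run at that value.
#'
#' @param volume A [mia_volume()].
#' @param config Base [seg_config()]; the swept parameter overrides its
#'   value row by row.
#' @param values Vector of parameter values to sweep.
#' @param parameter `"prob_threshold"` or `"grid_size"`.
#' @param class Class to measure (id or `"brightest"` /
#'   `"second-brightest"`), default `"brightest"`.
#' @param preprocess A [pp_params()].
#' @return A tibble of class `mia_sweep` with columns `parameter`,
#'   `value`, `mean_vox`, `sd_vox`, `mean_um`, `sd_um`, `n_foreground`.
#' @export
thickness_sweep <- function(volume, config, values,
                            parameter = c("prob_threshold", "grid_size"),
                            class = "brightest", preprocess = pp_params()) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(volume, "mia_volume"), inherits(config, "mia_config"))
  if (length(values) < 1L) stop("`values` must be non-empty")
  rows <- vector("list", length(values))
  if (parameter == "prob_threshold") {
    for (v in values) normalize_prob_threshold(v)  # validate up front
    base <- segment(volume, config, preprocess)
    for (i in seq_along(values)) {
      lab <- assign_labels(base$memberships, values[i])
      rows[[i]] <- sweep_row(parameter, values[i], lab, class,
                             volume$voxel_size_um)
    }
  } else {
    for (i in seq_along(values)) {
      g <- as.integer(values[i])
      cfg_i <- seg_config(config$n_classes, g,
                          class_presence_threshold = config$class_presence_threshold,
                          prob_threshold = config$prob_threshold,
                          fuzziness = config$fuzziness, tol = config$tol,
                          max_iter = config$max_iter,
                          emit_global = FALSE)
      seg <- segment(volume, cfg_i, preprocess)
      rows[[i]] <- sweep_row(parameter, values[i], seg$labels, class,
                             volume$voxel_size_um)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mia_sweep", class(out))
  out
}

sweep_row <- function(parameter, value, labels, class, voxel_size_um) {
  m <- binarize(labels, class)
  if (!any(m)) {
    return(tibble::tibble(parameter = parameter, value = as.numeric(value),
                          mean_vox = NA_real_, sd_vox = NA_real_,
                          mean_um = NA_real_, sd_um = NA_real_,
                          n_foreground = 0L))
  }
  th <- local_thickness(m, voxel_size_um)
  tibble::tibble(parameter = parameter, value = as.numeric(value),
                 mean_vox = th$mean_vox, sd_vox = th$sd_vox,
                 mean_um = th$mean_um, sd_um = th$sd_um,
                 n_foreground = th$n_foreground)
}

#' Plot a thickness sweep
#'
#' Mean structure thickness (um) against the swept parameter, with a
#' +/- 1 sd ribbon.
#'
#' @param object A [thickness_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mia_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$mean_um)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_um - .data$sd_um,
                                      ymax = .data$mean_um + .data$sd_um),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$parameter[1], y = "mean thickness (um)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @noRd
NULL

#' @export
plot.mia_sweep <- function(x, ...) print(autoplot(x, ...))
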