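#' Deterministic 1D K-means initialization
#'
#' Solves the K-means problem on the intensity distribution exactly: since
#' the feature is one-dimensional, the optimal clusters are contiguous runs
#' of the sorted values, and the minimal within-cluster sum of squares is
#' found by dynamic programming over the (weight-compressed) intensity
#' histogram with divide-and-conquer split-point optimization. The result
#' is fully deterministic — no random initialization, no local optima.
#'
#' Intensity distributions with more than 65536 distinct values are
#' compressed to a 65536-bin histogram first; micro-CT data (8- or 16-bit
#' integers) are never binned.
#'
#' @param x Numeric vector of in-mask intensities.
#' @param n_classes Number of classes C (>= 1).
#' @return Numeric vector of C strictly ascending class centers.
#' @export
#' @examples
#' kmeans_init(c(0, 0, 0, 10, 10, 10), 2)
kmeans_init <- function(x, n_classes) {
  C <- as.integer(n_classes)
  if (is.na(C) || C < 1L) stop("`n_classes` must be a positive integer")
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) stop("`x` must be non-empty and free of NA")
  ux <- sort(unique(x))
  if (length(ux) < C)
    stop("degenerate input: ", length(ux), " distinct values < ", C, " classes")
  if (length(ux) > 65536L) {
    br <- seq(min(x), max(x), length.out = 65537L)
    bin <- findInterval(x, br, rightmost.closed = TRUE)
    w <- tabulate(bin, 65536L)
    keep <- w > 0
    mids <- (br[-1] + br[-length(br)]) / 2
    ux <- mids[keep]
    w <- w[keep]
  } else {
    w <- tabulate(match(x, ux), length(ux))
  }
  if (C == 1L) return(sum(w * ux) / sum(w))
  fit <- kmeans_dp_cpp(ux, as.numeric(w), C)
  centers <- fit$centers
  if (any(diff(centers) <= 0))
    stop("degenerate input: K-means centers are not strictly ascending")
  centers
}

#' Fuzzy c-means membership update
#'
#' Evaluates the standard fuzzy c-means membership formula for 1D features:
#' `u_c = [sum_j (|x - v_c| / |x - v_j|)^(2/(m-1))]^-1`. A point that
#' coincides exactly with one or more centers has membership 1 split
#' equally among the coinciding centers and 0 elsewhere.
#'
#' @param x Numeric vector of intensities.
#' @param centers Numeric vector of class centers.
#' @param m Fuzziness exponent (> 1, default 2).
#' @return Matrix of memberships (`length(x)` rows, one column per class);
#'   rows sum to 1.
#' @export
#' @examples
#' fcm_memberships(5, c(0, 10))         # symmetric point -> (0.5, 0.5)
#' fcm_memberships(2.5, c(0, 10))       # -> (0.9, 0.1)
fcm_memberships <- function(x, centers, m = 2) {
  if (m <= 1) stop("`m` must be > 1")
  fcm_memberships_cpp(as.numeric(x), as.numeric(centers), m)
}

#' Fuzzy c-means clustering of 1D intensities
#'
#' Alternates the membership update (see [fcm_memberships()]) with the
#' weighted center update `v_c = sum_k u_ck^m x_k / sum_k u_ck^m` until the
#' maximum center change, relative to the intensity spread, falls below
#' `tol` or `max_iter` is reached. The fuzzy objective
#' `J = sum u^m (x - v)^2` is recorded per iteration and is non-increasing.
#' Returned centers are sorted ascending with membership columns permuted
#' accordingly. Two centers collapsing within 1e-9 (relative to the spread)
#' is an error naming the classes.
#'
#' @param x Numeric vector of in-mask intensities.
#' @param centers Initial class centers (length C >= 2).
#' @param m Fuzziness exponent (> 1, default 2).
#' @param tol Convergence tolerance on the relative center change
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 100).
#' @param memberships Optional initial membership matrix (rows = points);
#'   when given, the first center update starts from it instead of
#'   `centers`.
#' @param weights Optional non-negative point weights (multiplicities),
#'   used to cluster a compressed intensity histogram.
#' @return A list of class `mia_fcm` with `memberships`, `centers`,
#'   `objective` (per-iteration trace) and `iterations`.
#' @export
fcm <- function(x, centers, m = 2, tol = 1e-5, max_iter = 100L,
                memberships = NULL, weights = NULL) {
  x <- as.numeric(x)
  centers <- as.numeric(centers)
  C <- length(centers)
  if (C < 2L) stop("at least 2 classes are required")
  if (m <= 1) stop("`m` must be > 1")
  if (tol <= 0) stop("`tol` must be positive")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || any(weights < 0))
    stop("`weights` must be non-negative and match `x`")
  u0 <- NULL
  if (!is.null(memberships)) {
    memberships <- as.matrix(memberships)
    if (nrow(memberships) != length(x) || ncol(memberships) != C)
      stop("`memberships` must be a length(x) x C matrix")
    u0 <- memberships
  }
  res <- fcm_fit_cpp(x, weights, centers, m, tol, as.integer(max_iter), u0)
  structure(res, class = "mia_fcm")
}
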