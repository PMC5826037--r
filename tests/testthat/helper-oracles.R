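# Independent oracles and small fixture builders used across the suite.

# Exact 1D clustering by dynamic programming over sorted values: minimal
# within-cluster sum of squares over all partitions into C contiguous runs.
dp_kmeans_wss <- function(x, C) {
  xs <- sort(x)
  n <- length(xs)
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  # cost of the run (i+1)..j as one cluster
  run_cost <- function(i, j) {
    s <- cs[j + 1] - cs[i + 1]
    s2 <- cs2[j + 1] - cs2[i + 1]
    s2 - s^2 / (j - i)
  }
  # D[k, j] = optimal WSS of first j points in k clusters
  D <- matrix(Inf, C, n)
  for (j in 1:n) D[1, j] <- run_cost(0, j)
  if (C > 1) {
    for (k in 2:C) {
      for (j in k:n) {
        best <- Inf
        for (i in (k - 1):(j - 1)) {
          v <- D[k - 1, i] + run_cost(i, j)
          if (v < best) best <- v
        }
        D[k, j] <- best
      }
    }
  }
  D[C, n]
}

# WSS of a set of centers on data x (hard nearest-center assignment)
centers_wss <- function(x, centers) {
  d2 <- outer(x, centers, function(a, b) (a - b)^2)
  sum(apply(d2, 1, min))
}

# Brute-force sphere-fitting local thickness on a small mask: every
# foreground voxel is a candidate sphere center with radius equal to its
# distance to the nearest background voxel center (space outside the
# volume is structure); a voxel's thickness is the largest 2*r - 1 over
# spheres strictly containing it.
brute_thickness <- function(mask) {
  d <- dim(mask)
  co <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                              x = seq_len(d[3])))
  fg <- co[as.vector(mask), , drop = FALSE]
  bg <- co[!as.vector(mask), , drop = FALSE]
  th <- array(0, d)
  if (nrow(fg) == 0) return(th)
  if (nrow(bg) == 0) stop("oracle needs at least one background voxel")
  # squared distance from each fg voxel to nearest bg voxel center
  dmin2 <- vapply(seq_len(nrow(fg)), function(i) {
    min(colSums((t(bg) - fg[i, ])^2))
  }, numeric(1))
  for (q in seq_len(nrow(fg))) {
    r2 <- dmin2[q]
    tq <- 2 * sqrt(r2) - 1
    covered <- colSums((t(fg) - fg[q, ])^2) < r2
    idx <- fg[covered, , drop = FALSE]
    cur <- th[idx]
    th[idx] <- pmax(cur, tq)
  }
  th
}

# random connected-ish blob: union of random balls inside a small volume
random_blob_mask <- function(d, n_balls = 3, rmax = 3, seed = 1) {
  set.seed(seed)
  m <- array(FALSE, d)
  co <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                              x = seq_len(d[3])))
  for (b in seq_len(n_balls)) {
    ctr <- sapply(d, function(n) runif(1, 2, n - 1))
    r <- runif(1, 1, rmax)
    inside <- colSums((t(co) - ctr)^2) <= r^2
    m[co[inside, , drop = FALSE]] <- TRUE
  }
  m
}

# 6-connected morphological erosion of a mask (volume border erodes)
erode_mask <- function(m) {
  d <- dim(m)
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    src[[ax]] <- src[[ax]] + by
    keep <- src[[ax]] >= 1 & src[[ax]] <= d[ax]
    dst[[ax]] <- dst[[ax]][keep]
    src[[ax]] <- src[[ax]][keep]
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  out <- m
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(m, ax, by)
  out
}

# brute-force cubic median filter with edge replication
brute_median3d <- function(a, k) {
  d <- dim(a)
  h <- k %/% 2
  out <- array(0, d)
  for (i3 in seq_len(d[3])) for (i2 in seq_len(d[2])) for (i1 in seq_len(d[1])) {
    zz <- pmin(pmax((i1 - h):(i1 + h), 1), d[1])
    yy <- pmin(pmax((i2 - h):(i2 + h), 1), d[2])
    xx <- pmin(pmax((i3 - h):(i3 + h), 1), d[3])
    out[i1, i2, i3] <- median(a[zz, yy, xx])
  }
  out
}

# small noisy two-phase volume for clustering tests
two_phase_volume <- function(d = c(8, 12, 12), lo = 100, hi = 30000,
                             noise = 0, seed = 1, voxel = 7.86) {
  set.seed(seed)
  a <- array(lo, d)
  a[, seq_len(d[2] / 2), ] <- hi
  if (noise > 0) a <- pmax(a + array(rnorm(prod(d), 0, noise), d), 0)
  mia_volume(round(a), voxel_size_um = voxel, bit_depth = 16)
}

# digital ball mask of the given radius
ball_mask <- function(d, radius, center = (d + 1) / 2) {
  co <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                              x = seq_len(d[3])))
  array(colSums((t(co) - center)^2) <= radius^2, d)
}

cli_path <- function() {
  p <- system.file("exec", "miaclust", package = "miaclust")
  if (!nzchar(p)) p <- file.path(dirname(system.file(package = "miaclust")),
                                 "miaclust", "exec", "miaclust")
  p
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

run_cli <- function(args) {
  out <- tempfile(); err <- tempfile()
  status <- suppressWarnings(
    system2(rscript_bin(), c(cli_path(), args), stdout = out, stderr = err))
  list(status = status,
       stdout = if (file.exists(out)) readLines(out, warn = FALSE) else character(),
       stderr = if (file.exists(err)) readLines(err, warn = FALSE) else character())
}

# run segment with the global field also emitted and report the largest
# membership discrepancy between the merged local field and the global one
local_fixed_point_check <- function(v, cfg) {
  cfg$emit_global <- TRUE
  seg <- segment(v, cfg)
  list(max_diff = max(abs(seg$memberships$u - seg$global$memberships$u)),
       seg = seg)
}
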