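#' Coarse-grain a series to time scale tau
#'
#' Non-overlapping means of `tau` consecutive samples; the trailing
#' remainder is dropped. Scale 1 is the identity; on a 30-s grid, scale 10
#' yields one sample every 5 minutes.
#'
#' @param x numeric vector
#' @param tau integer scale >= 1
#' @return numeric vector of length `floor(length(x) / tau)`
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1 || tau > length(x)) stop("tau must be in 1..length(x)")
  if (tau == 1) return(as.numeric(x))
  m <- length(x) %/% tau
  colMeans(matrix(x[seq_len(m * tau)], nrow = tau))
}

# Integer ranks 1..n per column. Duplicate values get seeded random rank
# jitter: index-based tie-breaking would turn heavy ties (e.g. constant
# signals) into a spurious perfect diagonal dependence.
rank_columns <- function(points, seed = 177L) {
  out <- matrix(0L, nrow(points), ncol(points))
  for (j in seq_len(ncol(points))) {
    col <- points[, j]
    out[, j] <- if (anyDuplicated(col)) {
      with_seed(seed + j, as.integer(rank(col, ties.method = "random")))
    } else {
      as.integer(rank(col, ties.method = "first"))
    }
  }
  out
}

#' Darbellay-Vajda adaptive partition of a point set
#'
#' Rank-normalises each coordinate (ties broken by original index), then
#' recursively splits each cell into `2^d` subcells at the midpoints of its
#' rank intervals. A split is accepted when the cell holds at least
#' `min_cell * 2^d` points and the chi-square uniformity statistic across
#' the subcells exceeds the `chi^2(2^d - 1)` critical value at `alpha`.
#'
#' @param points numeric matrix, n rows x d columns (d = 2 or 3)
#' @param min_cell minimum points per subcell scale factor (default 8)
#' @param alpha significance level of the uniformity test (default 0.05)
#' @return a `dv_partition`: list with `lo`, `hi` (leaf rank-interval
#'   bounds, half-open), `count` (leaf occupancy), `assign` (leaf index per
#'   point), `n`, `dim`
#' @export
dv_partition <- function(points, min_cell = 8L, alpha = 0.05) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (!d %in% c(2L, 3L)) stop("dimension must be 2 or 3")
  n <- nrow(points)
  if (n < min_cell) stop("need at least min_cell points")
  ranks <- rank_columns(points)
  crit <- qchisq(1 - alpha, df = 2^d - 1)
  res <- cpp_dv_partition(ranks, as.integer(min_cell), crit)
  structure(list(lo = res$lo, hi = res$hi, count = as.integer(res$count),
                 assign = as.integer(res$assign), n = n, dim = d),
            class = "dv_partition")
}

#' @export
print.dv_partition <- function(x, ...) {
  cat(sprintf("<dv_partition> %d-D, %d points, %d leaves\n",
              x$dim, x$n, length(x$count)))
  invisible(x)
}

#' Transfer entropy via adaptive partitioning
#'
#' Estimates the directed information flow from `x` to `y` with block
#' lengths and lags all equal to 1: embeds triples
#' `(y_i, y_{i-1}, x_{i-1})`, rank-normalises, partitions with the 3-D
#' Darbellay-Vajda scheme, and sums the plug-in conditional mutual
#' information over leaves, with marginal counts over each leaf's projected
#' rank ranges. Natural log: result in nats. Small negative values are an
#' accepted artefact of the projected-marginal estimator.
#'
#' @param x,y numeric vectors of equal length >= 50 (`x` drives, `y`
#'   responds)
#' @inheritParams dv_partition
#' @return transfer entropy in nats
#' @export
transfer_entropy <- function(x, y, min_cell = 8L, alpha = 0.05) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 50) stop("need at least 50 samples")
  emb <- cbind(y[2:n], y[1:(n - 1)], x[1:(n - 1)])
  ranks <- rank_columns(emb)
  crit <- qchisq(1 - alpha, df = 7)
  cpp_te_from_ranks(ranks, as.integer(min_cell), crit)
}

#' The six directed signal pairs of the coupling analysis
#'
#' @return data.frame with `src` and `dst` columns in the pinned order
#'   HR->DC, HR->Act, DC->Act, DC->HR, Act->HR, Act->DC
#' @export
mste_pairs <- function() {
  data.frame(src = c("HR", "HR", "DC", "DC", "Act", "Act"),
             dst = c("DC", "Act", "Act", "HR", "HR", "DC"))
}

#' Aligned trivariate 30-s grid
#'
#' @param t common timestamps (s)
#' @param hr heart rate (bpm)
#' @param dc deceleration capacity (ms)
#' @param act activity counts
#' @return a `trivariate_grid`
#' @export
trivariate_grid <- function(t, hr, dc, act) {
  n <- length(t)
  if (length(hr) != n || length(dc) != n || length(act) != n) {
    stop("all four components must have equal length")
  }
  if (anyNA(hr) || anyNA(dc) || anyNA(act)) {
    stop("grid must be gap-free (impute first)")
  }
  structure(list(t = t, hr = hr, dc = dc, act = act, n = n),
            class = "trivariate_grid")
}

#' Directed transfer entropies of one grid across scales
#'
#' @param grid a [trivariate_grid]
#' @param scales integer scales (default 1:10)
#' @inheritParams dv_partition
#' @return matrix, rows = 6 directed pairs (named `srctodst`), columns =
#'   scales
#' @export
te_profile <- function(grid, scales = 1:10, min_cell = 8L, alpha = 0.05) {
  stopifnot(inherits(grid, "trivariate_grid"))
  pairs <- mste_pairs()
  sig <- list(HR = grid$hr, DC = grid$dc, Act = grid$act)
  out <- matrix(NA_real_, nrow(pairs), length(scales),
                dimnames = list(paste0(pairs$src, "to", pairs$dst),
                                paste0("s", scales)))
  for (j in seq_along(scales)) {
    cg <- lapply(sig, coarse_grain, tau = scales[j])
    for (i in seq_len(nrow(pairs))) {
      out[i, j] <- transfer_entropy(cg[[pairs$src[i]]], cg[[pairs$dst[i]]],
                                    min_cell, alpha)
    }
  }
  out
}

#' Multiscale transfer entropy feature block over a surrogate ensemble
#'
#' Per ensemble member: 6 directed transfer entropies at each scale.
#' Features are the ensemble sample mean and sample variance per
#' (pair, scale): 120 features for 6 pairs x 10 scales.
#'
#' @param grids list of gap-free [trivariate_grid] ensemble members
#' @inheritParams te_profile
#' @return named numeric vector `mste_<src>to<dst>_s<scale>_<mean|var>`,
#'   all means first, then all variances
#' @export
mste_block <- function(grids, scales = 1:10, min_cell = 8L, alpha = 0.05) {
  if (!length(grids)) stop("ensemble must be non-empty")
  vals <- vapply(grids, function(g) {
    as.vector(te_profile(g, scales, min_cell, alpha))
  }, numeric(6 * length(scales)))
  vals <- matrix(vals, nrow = 6 * length(scales))
  pairs <- mste_pairs()
  base <- as.vector(outer(paste0("mste_", pairs$src, "to", pairs$dst),
                          paste0("_s", scales), paste0))
  mu <- rowMeans(vals)
  va <- if (ncol(vals) > 1) apply(vals, 1, var) else rep(0, nrow(vals))
  out <- c(mu, va)
  names(out) <- c(paste0(base, "_mean"), paste0(base, "_var"))
  out
}
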