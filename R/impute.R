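#' Fuse multi-channel ECG-derived windows by signal quality
#'
#' Per time window, the channel with the highest SQI is kept if and only if
#' its SQI is strictly greater than `threshold`; otherwise the window is
#' discarded (it becomes a gap). Equal top SQIs are broken by lowest channel
#' id, for determinism.
#'
#' @param windows data.frame with columns `window_start` (s), `channel_id`
#'   (1..4) and `sqi` (in `[0, 1]`), plus a list column `samples` where each
#'   element is a data.frame with columns `t` and `v` for that window
#' @param threshold strict SQI acceptance threshold (default 0.75)
#' @return list with `series` (a [ts_series] concatenating the kept
#'   windows) and `provenance` (data.frame `window_start`, `channel_id`
#'   chosen with NA for discarded windows, `sqi`)
#' @export
fuse_channels_by_sqi <- function(windows, threshold = 0.75) {
  stopifnot(is.data.frame(windows),
            all(c("window_start", "channel_id", "sqi", "samples") %in%
                  names(windows)))
  if (any(windows$sqi < 0 | windows$sqi > 1)) stop("sqi must lie in [0, 1]")
  if (any(table(windows$window_start, windows$channel_id) > 1)) {
    stop("inconsistent window grid: duplicated (window_start, channel) pairs")
  }
  starts <- sort(unique(windows$window_start))
  prov <- data.frame(window_start = starts, channel_id = NA_integer_,
                     sqi = NA_real_)
  t_out <- list()
  v_out <- list()
  for (i in seq_along(starts)) {
    w <- windows[windows$window_start == starts[i], , drop = FALSE]
    w <- w[order(w$channel_id), , drop = FALSE]
    best <- which.max(w$sqi)  # first max = lowest channel id on ties
    prov$sqi[i] <- w$sqi[best]
    if (w$sqi[best] > threshold) {
      prov$channel_id[i] <- w$channel_id[best]
      smp <- w$samples[[best]]
      t_out[[i]] <- smp$t
      v_out[[i]] <- smp$v
    }
  }
  tt <- unlist(t_out)
  vv <- unlist(v_out)
  if (is.null(tt)) tt <- numeric(0)
  if (is.null(vv)) vv <- numeric(0)
  list(series = ts_series(tt, vv), provenance = prov)
}

# Local-maximum peak picking above a threshold with a refractory period.
pick_peaks <- function(x, fs, thresh, refractory = 0.25) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] > thresh) + 1
  if (!length(cand)) return(integer(0))
  keep <- cand[1]
  for (i in cand[-1]) {
    if ((i - keep[length(keep)]) / fs >= refractory) keep <- c(keep, i)
  }
  keep
}

#' Simplified beat-agreement signal quality index
#'
#' Runs two dissimilar beat detectors on one ECG window — an
#' amplitude-threshold detector on the band-passed (5-15 Hz) signal, and a
#' slope-energy detector on the smoothed squared derivative — and returns
#' the fraction of beats on which they agree within ±150 ms
#' (matched pairs / max(n1, n2)). Returns 0 when either detector finds
#' fewer than 3 beats.
#'
#' @param ecg numeric ECG samples for one window (>= 10 s)
#' @param fs sampling rate in Hz
#' @return SQI fraction in `[0, 1]`
#' @export
simple_bsqi <- function(ecg, fs) {
  if (length(ecg) < 10 * fs) stop("window must be at least 10 s long")
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, ecg - mean(ecg)))
  # detector 1 is conservative (high amplitude threshold), detector 2 is
  # sensitive (low energy threshold): dissimilar noise responses are what
  # make the agreement fraction collapse on corrupted windows
  th1 <- 0.9 * quantile(abs(xf), 0.98)
  p1 <- pick_peaks(abs(xf), fs, th1)

  d <- c(0, diff(xf)) * fs
  e <- d^2
  k <- max(1L, round(0.05 * fs))
  e <- as.numeric(stats::filter(e, rep(1 / k, k), sides = 2))
  e[is.na(e)] <- 0
  th2 <- 0.1 * quantile(e, 0.98)
  p2 <- pick_peaks(e, fs, th2)

  if (length(p1) < 3 || length(p2) < 3) return(0)
  t1 <- p1 / fs
  t2 <- p2 / fs
  matched <- sum(vapply(t1, function(tb) any(abs(t2 - tb) <= 0.15), TRUE))
  matched / max(length(t1), length(t2))
}

# Longest admissible donor segment check: the candidate interval must lie
# within the data span and contain no internal spacing > th_g, and its ends
# must be covered within th_g.
donor_ok <- function(t, lo, hi, th_g) {
  if (lo < t[1] || hi > t[length(t)]) return(FALSE)
  idx <- which(t >= lo & t <= hi)
  if (length(idx) < 2) return(FALSE)
  tt <- t[idx]
  if (tt[1] - lo > th_g || hi - tt[length(tt)] > th_g) return(FALSE)
  all(diff(tt) <= th_g)
}

#' Stochastic surrogate gap imputation
#'
#' Fills every gap longer than `th_g` by copying a same-length donor
#' segment from the gap's neighbourhood. Gaps are processed in increasing
#' length order. Per gap: a fair coin picks the left or right side; a
#' folded-normal draw `|x_r|` (x_r ~ N(0,1)) sets the donor offset
#' `|x_r| * g_l` seconds beyond the admissible boundary — on the left the
#' donor ends at `t_b - g_l - offset` (so it lies wholly in `t < t_b -
#' g_l`), on the right it starts at `t_e + offset` (wholly in `t > t_e`).
#' The draw is repeated (up to `max_tries`) until the donor window is fully
#' covered by data; if the chosen side never yields a donor the other side
#' is tried. Donor values are copied into the gap with additive noise
#' `noise_frac * z`, `z ~ N(mu_S, sigma_S^2)` per sample, where `mu_S` and
#' `sigma_S^2` are the mean and variance of the pre-imputation series. The
#' series and timestamps are updated before the next gap, so small gaps
#' already imputed can donate to larger ones.
#'
#' @param s a [ts_series]
#' @param th_g gap threshold in seconds
#' @param noise_frac noise fraction (default 0.05)
#' @param seed RNG seed
#' @param max_tries folded-normal redraws per side before giving up
#' @return a [ts_series] with no remaining gap longer than `th_g`; all
#'   original samples preserved verbatim
#' @export
surrogate_impute <- function(s, th_g, noise_frac = 0.05, seed = 1L,
                             max_tries = 50L) {
  stopifnot(inherits(s, "ts_series"))
  mu_s <- mean(s$v)
  sd_s <- sd(s$v)
  if (is.na(sd_s)) sd_s <- 0
  t <- s$t
  v <- s$v
  with_seed(seed, {
    repeat {
      gaps <- detect_gaps(ts_series(t, v, s$unit), th_g)
      if (nrow(gaps) == 0) break
      g <- gaps[1, ]  # shortest first
      t_b <- g$t_b; t_e <- g$t_e; g_l <- g$g_l
      first_side <- if (runif(1) < 0.5) "left" else "right"
      placed <- FALSE
      for (side in unique(c(first_side, setdiff(c("left", "right"),
                                                first_side)))) {
        for (try in seq_len(max_tries)) {
          off <- abs(rnorm(1)) * g_l
          if (side == "left") {
            hi <- t_b - g_l - off
            lo <- hi - g_l
          } else {
            lo <- t_e + off
            hi <- lo + g_l
          }
          if (!donor_ok(t, lo, hi, th_g)) next
          idx <- which(t > lo & t < hi)
          if (!length(idx)) next
          new_t <- t[idx] - lo + t_b
          inside <- new_t > t_b & new_t < t_e
          if (!any(inside)) next
          new_t <- new_t[inside]
          new_v <- v[idx][inside] +
            noise_frac * rnorm(length(new_t), mu_s, sd_s)
          ord <- order(c(t, new_t))
          t <- c(t, new_t)[ord]
          v <- c(v, new_v)[ord]
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed) {
        stop(sprintf(
          "no contiguous donor of length %.1f s for gap [%.1f, %.1f]",
          g_l, t_b, t_e))
      }
    }
    ts_series(t, v, s$unit)
  })
}

#' Generate an ensemble of surrogate imputations
#'
#' Member `i` is seeded `base_seed + i`, so the ensemble is reproducible
#' and members differ unless the input was gap-free.
#'
#' @inheritParams surrogate_impute
#' @param m ensemble size (default 100)
#' @param base_seed base seed; member seeds are `base_seed + 1..m`
#' @return a `surrogate_ensemble`: list with `members` (list of
#'   [ts_series]), `member_seeds`, `th_g`, `noise_frac`
#' @export
generate_surrogate_ensemble <- function(s, th_g, m = 100L,
                                        noise_frac = 0.05, base_seed = 1L) {
  seeds <- base_seed + seq_len(m)
  members <- lapply(seeds, function(sd_i)
    surrogate_impute(s, th_g, noise_frac, seed = sd_i))
  structure(list(members = members, member_seeds = seeds, th_g = th_g,
                 noise_frac = noise_frac),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("<surrogate_ensemble> %d members, th_g = %g s\n",
              length(x$members), x$th_g))
  invisible(x)
}

#' Hourly aggregation with PCHIP imputation of empty hours
#'
#' Sums counts per clock hour over the series span; interior hours with no
#' data are filled by shape-preserving piecewise-cubic (PCHIP)
#' interpolation over the hour index. Leading/trailing empty hours are
#' filled by the nearest non-empty hour's value and flagged.
#'
#' @param counts a [ts_series] of activity counts
#' @return a [ts_series] with one value per hour (timestamps at hour
#'   starts), with attributes `imputed` (logical per hour) and `edge_filled`
#' @export
pchip_impute_hourly <- function(counts) {
  stopifnot(inherits(counts, "ts_series"))
  h0 <- floor(counts$t[1] / 3600)
  h1 <- floor(counts$t[length(counts$t)] / 3600)
  hours <- h0:h1
  idx <- floor(counts$t / 3600)
  sums <- vapply(hours, function(h) sum(counts$v[idx == h]), 0)
  nonempty <- hours %in% unique(idx)
  if (sum(nonempty) < 2) stop("need at least 2 non-empty hours")
  x <- as.numeric(seq_along(hours))
  vals <- sums
  edge <- logical(length(hours))
  first_ne <- which(nonempty)[1]
  last_ne <- which(nonempty)[sum(nonempty)]
  if (first_ne > 1) {
    vals[1:(first_ne - 1)] <- sums[first_ne]
    edge[1:(first_ne - 1)] <- TRUE
  }
  if (last_ne < length(hours)) {
    vals[(last_ne + 1):length(hours)] <- sums[last_ne]
    edge[(last_ne + 1):length(hours)] <- TRUE
  }
  interior <- !nonempty & !edge
  if (any(interior)) {
    vals[interior] <- if (sum(nonempty) >= 3) {
      pracma::pchip(x[nonempty], sums[nonempty], x[interior])
    } else {
      # cubic interpolation needs three anchors; with two it is linear
      approx(x[nonempty], sums[nonempty], xout = x[interior])$y
    }
  }
  out <- ts_series(hours * 3600, vals, counts$unit)
  attr(out, "imputed") <- !nonempty
  attr(out, "edge_filled") <- edge
  out
}
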