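#' Names of the 24 windowed HRV metrics
#'
#' Eleven time-domain metrics (NNmean, NNmedian, NNmode, NNvariance,
#' NNskew, NNkurt, NNiqr, SDNN, RMSSD, PNN50, meanHR), six frequency-domain
#' Lomb-Scargle band powers (ULF, VLF, LF, HF, LFHF, TOTPOW), two entropy
#' measures (SampEn, ApEn), two phase-rectified signal averaging capacities
#' (PRSA_AC, PRSA_DC) and three other non-linear metrics (DFA_alpha1,
#' DFA_alpha2, SD1SD2).
#'
#' @return character vector of length 24
#' @export
hrv_metric_names <- function() {
  c("NNmean", "NNmedian", "NNmode", "NNvariance", "NNskew", "NNkurt",
    "NNiqr", "SDNN", "RMSSD", "PNN50", "meanHR",
    "ULF", "VLF", "LF", "HF", "LFHF", "TOTPOW",
    "SampEn", "ApEn", "PRSA_AC", "PRSA_DC",
    "DFA_alpha1", "DFA_alpha2", "SD1SD2")
}

#' Remove RR artefacts before windowing
#'
#' Excludes intervals outside `[300, 2000]` ms or changing more than 20%
#' from the previous accepted beat (toolbox-style preprocessing).
#'
#' @param rr an [rr_series]
#' @return a cleaned [rr_series]
#' @export
clean_rr <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  keep <- cpp_rr_artifact_keep(rr$rr, 300, 2000, 0.2)
  rr_series(rr$beat_t[keep], rr$rr[keep])
}

#' Slice an RR series into overlapping analysis windows
#'
#' Windows are `[k * shift, k * shift + win)` seconds. A window is valid
#' when its beats cover at least `min_coverage` of the window duration
#' (sum of RR intervals / window length) and it holds at least `min_beats`
#' beats; invalid windows yield no metrics.
#'
#' @param rr an [rr_series]
#' @param win window length in seconds (default 300)
#' @param shift window shift in seconds (default 30)
#' @param min_coverage minimum beat-time coverage fraction (default 0.8)
#' @param min_beats minimum beats per valid window (default 30)
#' @return data.frame with `window_start` and index columns `i0`, `i1`
#'   (beat range) for each valid window
#' @export
window_rr <- function(rr, win = 300, shift = 30, min_coverage = 0.8,
                      min_beats = 30L) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$beat_t)
  if (n == 0) {
    return(data.frame(window_start = numeric(0), i0 = integer(0),
                      i1 = integer(0)))
  }
  span <- rr$beat_t[n]
  if (span < win) {
    return(data.frame(window_start = numeric(0), i0 = integer(0),
                      i1 = integer(0)))
  }
  starts <- seq(0, span - win, by = shift)
  i0 <- findInterval(starts, rr$beat_t, left.open = TRUE) + 1L
  i1 <- findInterval(starts + win, rr$beat_t)
  csum <- c(0, cumsum(rr$rr))
  nb <- i1 - i0 + 1L
  cov <- ifelse(nb > 0, (csum[pmax(i1, 1) + 1] - csum[pmax(i0 - 1, 0) + 1]) /
                  (win * 1000), 0)
  ok <- nb >= min_beats & cov >= min_coverage
  data.frame(window_start = starts[ok], i0 = i0[ok], i1 = i1[ok])
}

#' Compute the 24 HRV metrics for one window of beats
#'
#' @param beat_t beat times (s) within the window
#' @param rr RR intervals (ms)
#' @param prsa_L PRSA wavelet half-window in beats (default 30; reduced
#'   automatically when the window holds too few beats)
#' @param prsa_filter PRSA anchor artefact filter (default 5% change)
#' @param metrics metric subset to compute; families not requested are
#'   skipped (their slots return 0), which keeps reduced-metric runs cheap
#' @return named numeric vector of length 24 (see [hrv_metric_names()])
#' @export
compute_window_metrics <- function(beat_t, rr, prsa_L = 30L,
                                   prsa_filter = 0.05,
                                   metrics = hrv_metric_names()) {
  L <- min(prsa_L, max(1L, (length(rr) - 2L) %/% 2L))
  m <- cpp_rr_window_metrics(
    beat_t, rr, L, prsa_filter,
    any(c("ULF", "VLF", "LF", "HF", "LFHF", "TOTPOW") %in% metrics),
    any(c("SampEn", "ApEn") %in% metrics),
    any(c("DFA_alpha1", "DFA_alpha2") %in% metrics))
  names(m) <- hrv_metric_names()
  m
}

#' Windowed HRV metric table for a visit
#'
#' @inheritParams window_rr
#' @param metrics subset of [hrv_metric_names()] to compute (all by
#'   default); expensive metric families outside the subset are skipped
#' @return data.frame: `window_start` plus one column per metric
#' @export
hrv_windows <- function(rr, win = 300, shift = 30, min_coverage = 0.8,
                        min_beats = 30L, metrics = hrv_metric_names()) {
  w <- window_rr(rr, win, shift, min_coverage, min_beats)
  if (nrow(w) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(metrics) + 1))
    names(out) <- c("window_start", metrics)
    return(out)
  }
  vals <- t(vapply(seq_len(nrow(w)), function(k) {
    idx <- w$i0[k]:w$i1[k]
    compute_window_metrics(rr$beat_t[idx], rr$rr[idx], metrics = metrics)
  }, numeric(24)))
  colnames(vals) <- hrv_metric_names()
  cbind(data.frame(window_start = w$window_start),
        as.data.frame(vals)[, metrics, drop = FALSE])
}

#' Phase-rectified signal averaging capacities
#'
#' Anchors are beats where RR lengthens (deceleration capacity, DC) or
#' shortens (acceleration capacity, AC) versus the previous beat; relative
#' changes above `anchor_filter` are excluded as artefacts. Phase-aligned
#' windows of ±L beats are averaged into X(k) and
#' `DC = (X(0) + X(1) - X(-1) - X(-2)) / 4`.
#'
#' @param rr an [rr_series] or numeric RR vector (ms)
#' @param L half-window in beats (default 30)
#' @param anchor_filter maximum relative RR change for a valid anchor
#' @return list with `DC`, `AC` (ms; NA when no anchors) and anchor counts
#' @export
prsa_dc <- function(rr, L = 30L, anchor_filter = 0.05) {
  x <- if (inherits(rr, "rr_series")) rr$rr else as.numeric(rr)
  if (length(x) < 2 * L + 2) {
    return(list(DC = NA_real_, AC = NA_real_, n_dec = 0L, n_acc = 0L))
  }
  r <- cpp_prsa(x, L, anchor_filter)
  list(DC = unname(r["DC"]), AC = unname(r["AC"]),
       n_dec = as.integer(r["n_dec"]), n_acc = as.integer(r["n_acc"]))
}

#' Aggregate windowed metrics over the nocturnal interval
#'
#' Keeps windows whose start time falls in the half-open nocturnal
#' interval `[22:00, 10:00)` of either night (clock time = window start
#' modulo 24 h) and returns the sample mean and sample variance of each
#' metric: 2 features per metric, 48 for the full 24-metric set.
#'
#' @param win_df output of [hrv_windows()]
#' @param night `c(start_hour, end_hour)` of the nocturnal interval
#' @param min_windows minimum valid nocturnal windows (default 2); fewer
#'   returns NULL (visit flagged missing)
#' @return named numeric vector `mu_<metric>`, `var_<metric>`, or NULL
#' @export
nocturnal_aggregate <- function(win_df, night = c(22, 10), min_windows = 2L) {
  metrics <- setdiff(names(win_df), "window_start")
  clock_h <- (win_df$window_start %% 86400) / 3600
  noct <- clock_h >= night[1] | clock_h < night[2]
  sub <- win_df[noct, metrics, drop = FALSE]
  sub <- sub[complete.cases(sub), , drop = FALSE]
  if (nrow(sub) < min_windows) return(NULL)
  mu <- vapply(sub, mean, 0)
  va <- vapply(sub, var, 0)
  out <- c(mu, va)
  names(out) <- c(paste0("mu_", metrics), paste0("var_", metrics))
  out
}

#' Nocturnal HRV feature block for one visit
#'
#' Convenience wrapper: artefact filtering, 300-s/30-s windowing, 24
#' metrics per window, and nocturnal mean/variance aggregation into the
#' 48-dimensional HRV block.
#'
#' @inheritParams hrv_windows
#' @inheritParams nocturnal_aggregate
#' @param clean apply the RR artefact filter first (default TRUE)
#' @return named numeric vector (length `2 * length(metrics)`), or NULL if
#'   too few nocturnal windows
#' @export
hrv_block <- function(rr, win = 300, shift = 30, night = c(22, 10),
                      metrics = hrv_metric_names(), clean = TRUE) {
  if (clean) rr <- clean_rr(rr)
  nocturnal_aggregate(hrv_windows(rr, win, shift, metrics = metrics), night)
}

#' Heart-rate and deceleration-capacity grids at 30-s resolution
#'
#' `hr_grid` is the mean instantaneous HR (bpm) per 30-s bin; `dc_grid` is
#' the PRSA deceleration capacity over a 300-s window centred on each grid
#' point. Bins without data (or without anchors, for DC) are gaps, to be
#' surrogate-imputed downstream.
#'
#' @param rr an [rr_series]
#' @param duration_s visit span in seconds (default: last beat time)
#' @param dt grid step (default 30 s)
#' @param dc_win DC window length (default 300 s)
#' @param prsa_L,prsa_filter PRSA settings, see [prsa_dc()]
#' @return list with `hr_grid` and `dc_grid`, both [ts_series]
#' @export
hr_dc_grids <- function(rr, duration_s = NULL, dt = 30, dc_win = 300,
                        prsa_L = 30L, prsa_filter = 0.05) {
  stopifnot(inherits(rr, "rr_series"))
  n <- length(rr$beat_t)
  if (is.null(duration_s)) duration_s <- rr$beat_t[n]
  starts <- seq(0, duration_s - dt, by = dt)

  bin <- floor(rr$beat_t / dt) + 1L
  hr <- 60000 / rr$rr
  hr_by_bin <- vapply(split(hr, bin), mean, 0)
  bin_id <- as.integer(names(hr_by_bin))
  keep <- bin_id >= 1 & bin_id <= length(starts)
  hr_grid <- ts_series(starts[bin_id[keep]], hr_by_bin[keep], "bpm")

  centers <- starts + dt / 2
  lo <- findInterval(centers - dc_win / 2, rr$beat_t, left.open = TRUE) + 1L
  hi <- findInterval(centers + dc_win / 2, rr$beat_t)
  dc_t <- numeric(0)
  dc_v <- numeric(0)
  for (k in seq_along(starts)) {
    if (hi[k] - lo[k] + 1 < 2 * 2 + 2) next
    idx <- lo[k]:hi[k]
    L <- min(prsa_L, max(1L, (length(idx) - 2L) %/% 2L))
    r <- cpp_prsa(rr$rr[idx], L, prsa_filter)
    if (!is.na(r[["DC"]])) {
      dc_t <- c(dc_t, starts[k])
      dc_v <- c(dc_v, r[["DC"]])
    }
  }
  list(hr_grid = hr_grid, dc_grid = ts_series(dc_t, dc_v, "ms"))
}
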