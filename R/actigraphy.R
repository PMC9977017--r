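#' Convert an acceleration axis to Oakley activity counts
#'
#' High-pass filters the axis at 0.25 Hz (4th-order Butterworth, zero
#' phase) to remove gravity, takes the maximum absolute deviation per
#' second, zeroes values below the 0.05 g deadband, and sums the surviving
#' per-second maxima within each epoch.
#'
#' @param accel_z a [ts_series] of one acceleration axis in g, sampled at
#'   >= 20 Hz (uniform)
#' @param epoch epoch length in seconds (default 30)
#' @param deadband threshold in g (default 0.05)
#' @return a [ts_series] of counts per epoch (epoch starts as timestamps)
#' @export
oakley_counts <- function(accel_z, epoch = 30, deadband = 0.05) {
  stopifnot(inherits(accel_z, "ts_series"))
  n <- length(accel_z$t)
  if (n < 3) stop("acceleration series too short")
  fs <- 1 / median(diff(accel_z$t))
  if (fs < 20) stop(sprintf("sampling rate %.1f Hz below required 20 Hz", fs))
  hp <- signal::butter(4, 0.25 / (fs / 2), type = "high")
  # centring first keeps filter edge transients at zero for a pure
  # gravity offset; the high-pass removes any remaining slow drift
  xf <- as.numeric(signal::filtfilt(hp, accel_z$v - median(accel_z$v)))
  sec <- floor(accel_z$t - accel_z$t[1])
  per_sec <- vapply(split(abs(xf), sec), max, 0)
  per_sec[per_sec < deadband] <- 0
  sec_id <- as.numeric(names(per_sec))
  ep <- floor(sec_id / epoch)
  counts <- vapply(split(per_sec, ep), sum, 0)
  ts_series(as.numeric(names(counts)) * epoch + accel_z$t[1], counts,
            "counts")
}

# Hours (0-based) of a day that contain at least one sample.
covered_hours_by_day <- function(t) {
  hrs <- unique(floor(t / 3600))
  data.frame(day = floor(hrs / 24), hour = hrs %% 24)
}

#' Select the best two consecutive midnight-to-midnight days
#'
#' Among all consecutive day pairs, chooses the pair with the most
#' non-missing hours (ties go to the earliest pair). If either chosen day
#' has fewer than 12 h of data, the visit is rejected.
#'
#' @param counts a [ts_series] of activity counts
#' @return list with `accept` (logical), `days` (0-based indices of the
#'   two days, or NULL), `coverage_h` (hours with data per day), `reason`
#' @export
select_best_two_days <- function(counts) {
  stopifnot(inherits(counts, "ts_series"))
  cov <- covered_hours_by_day(counts$t)
  n_days <- floor(max(counts$t) / 86400) + 1
  if (n_days < 2) {
    return(list(accept = FALSE, days = NULL, coverage_h = NULL,
                reason = "span shorter than 2 days"))
  }
  per_day <- vapply(0:(n_days - 1), function(d) sum(cov$day == d), 0)
  pair_tot <- per_day[-n_days] + per_day[-1]
  best <- which.max(pair_tot)  # earliest on ties
  days <- c(best - 1, best)
  if (per_day[best] < 12 || per_day[best + 1] < 12) {
    return(list(accept = FALSE, days = days, coverage_h = per_day,
                reason = "chosen days have < 12 h of data"))
  }
  list(accept = TRUE, days = days, coverage_h = per_day, reason = NULL)
}

#' Non-parametric rest-activity rhythm metrics
#'
#' Interdaily stability (IS), intradaily variability (IV), least-active
#' 5-h mean (L5), most-active 10-h mean (M10) and relative rest-activity
#' amplitude `RA = (M10 - L5) / (M10 + L5)`, computed on 48 hourly values
#' (two full days, no missing hours).
#'
#' @param hourly numeric vector of exactly 48 hourly counts, or a
#'   [ts_series] with 48 hourly samples
#' @return named list; IS, IV and RA are NA for a constant series
#' @export
rest_activity_metrics <- function(hourly) {
  x <- if (inherits(hourly, "ts_series")) hourly$v else as.numeric(hourly)
  if (length(x) != 48) stop("need exactly 48 hourly values (two full days)")
  n <- length(x)
  xbar <- mean(x)
  ss_tot <- sum((x - xbar)^2)
  hod <- rep(0:23, 2)
  hmeans <- vapply(split(x, hod), mean, 0)
  is_v <- if (ss_tot > 0) (sum((hmeans - xbar)^2) / 24) / (ss_tot / n) else NA_real_
  iv_v <- if (ss_tot > 0) {
    (n * sum(diff(x)^2)) / ((n - 1) * ss_tot)
  } else NA_real_
  roll <- function(k) {
    cs <- c(0, cumsum(x))
    (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k
  }
  l5 <- min(roll(5))
  m10 <- max(roll(10))
  ra <- if (m10 + l5 > 0) (m10 - l5) / (m10 + l5) else NA_real_
  list(IS = is_v, IV = iv_v, L5 = l5, M10 = m10, RA = ra)
}

#' Cosinor rhythmometry fit
#'
#' Least-squares fit of `x(t) = M + A cos(2 pi (t - phi) / 24)` via the
#' linear cos/sin parameterisation. Amplitude is non-negative; acrophase
#' is reported in hours past midnight in `[0, 24)`.
#'
#' @param hourly a [ts_series] of hourly counts, or a numeric vector (then
#'   assumed to start at hour 0)
#' @param period period in hours (default 24)
#' @return list with `mesor`, `amplitude`, `acrophase` and `flat` (TRUE
#'   when amplitude is indistinguishable from 0, acrophase then pinned 0)
#' @export
cosinor_fit <- function(hourly, period = 24) {
  if (inherits(hourly, "ts_series")) {
    t_h <- hourly$t / 3600
    x <- hourly$v
  } else {
    x <- as.numeric(hourly)
    t_h <- seq_along(x) - 1
  }
  if (length(x) < 24) stop("need at least 24 hourly values")
  w <- 2 * pi * t_h / period
  X <- cbind(1, cos(w), sin(w))
  if (qr(X)$rank < 3) stop("singular cosinor design")
  b <- qr.solve(X, x)
  amp <- sqrt(b[2]^2 + b[3]^2)
  flat <- amp < 1e-9 * max(1, abs(b[1]))
  acro <- if (flat) 0 else (atan2(b[3], b[2]) * period / (2 * pi)) %% period
  list(mesor = unname(b[1]), amplitude = unname(amp),
       acrophase = unname(acro), flat = flat)
}

#' The 8-feature actigraphy block for one visit
#'
#' Applies best-two-day selection (midnight-to-midnight, >= 12 h data per
#' day), hourly aggregation with PCHIP imputation of empty hours, then the
#' non-parametric rhythm metrics and cosinor fit.
#'
#' @param counts a [ts_series] of activity counts spanning >= 48 h
#' @return named numeric vector of length 8 (IS, IV, L5, M10, RA, mesor,
#'   amplitude, acrophase), or NULL when the visit is rejected (reason in
#'   attribute `reason`)
#' @export
actigraphy_block <- function(counts) {
  sel <- select_best_two_days(counts)
  if (!sel$accept) {
    return(pm_excluded(sel$reason))
  }
  lo <- sel$days[1] * 86400
  hi <- (sel$days[2] + 1) * 86400
  keep <- counts$t >= lo & counts$t < hi
  sub <- ts_series(counts$t[keep], counts$v[keep], counts$unit)
  hourly <- pchip_impute_hourly(sub)
  # pad to the exact 48-hour grid of the chosen days
  grid <- seq(lo, hi - 3600, by = 3600)
  v <- approx(hourly$t, hourly$v, xout = grid, rule = 2)$y
  ram <- rest_activity_metrics(v)
  cf <- cosinor_fit(ts_series(grid, v, counts$unit))
  c(IS = ram$IS, IV = ram$IV, L5 = ram$L5, M10 = ram$M10, RA = ram$RA,
    mesor = cf$mesor, amplitude = cf$amplitude, acrophase = cf$acrophase)
}
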