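#' Timestamped scalar series
#'
#' The universal signal carrier: strictly increasing timestamps in seconds
#' (local clock, t = 0 at midnight of day 1 of the visit) and one value per
#' timestamp. Missingness is represented by time gaps, never by NA values.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing
#' @param v numeric vector of values, same length as `t`
#' @param unit value unit label (e.g. "ms", "bpm", "counts")
#' @return an object of class `ts_series`
#' @export
ts_series <- function(t, v, unit = "") {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v)) {
    stop("`t` and `v` must have the same length")
  }
  if (anyNA(t) || anyNA(v)) {
    stop("ts_series stores no NA values; represent missingness by time gaps")
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  structure(list(t = t, v = v, unit = unit), class = "ts_series")
}

#' @export
print.ts_series <- function(x, ...) {
  n <- length(x$t)
  span <- if (n > 1) sprintf("%.1f..%.1f s", x$t[1], x$t[n]) else "empty"
  cat(sprintf("<ts_series> %d samples [%s] %s\n", n, x$unit, span))
  invisible(x)
}

#' @export
length.ts_series <- function(x) length(x$t)

#' Beat-annotated RR-interval series
#'
#' Beat times in seconds and the RR interval (ms) ending at each beat.
#' `rr[i]` must be consistent with `beat_t[i] - beat_t[i-1]` up to the
#' beat-level jitter tolerance.
#'
#' @param beat_t beat timestamps (s), strictly increasing
#' @param rr RR intervals (ms), positive
#' @return an object of class `rr_series`
#' @export
rr_series <- function(beat_t, rr) {
  beat_t <- as.numeric(beat_t)
  rr <- as.numeric(rr)
  if (length(beat_t) != length(rr)) stop("`beat_t` and `rr` lengths differ")
  if (any(rr <= 0)) stop("RR intervals must be positive")
  if (length(beat_t) > 1 && any(diff(beat_t) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  structure(list(beat_t = beat_t, rr = rr), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, span %.1f s, mean RR %.1f ms\n",
              length(x$beat_t), diff(range(x$beat_t)), mean(x$rr)))
  invisible(x)
}

#' Detect gaps longer than a threshold
#'
#' A gap is an inter-sample spacing exceeding `th_g` seconds. Gaps are
#' returned sorted by increasing length (ties broken by start time), the
#' order in which the surrogate imputer processes them.
#'
#' @param s a [ts_series]
#' @param th_g gap threshold in seconds
#' @return data.frame with columns `t_b` (last sample before the gap),
#'   `t_e` (first sample after), `g_l` (length `t_e - t_b`)
#' @export
detect_gaps <- function(s, th_g) {
  stopifnot(inherits(s, "ts_series"), th_g > 0)
  empty <- data.frame(t_b = numeric(0), t_e = numeric(0), g_l = numeric(0))
  if (length(s$t) < 2) return(empty)
  d <- diff(s$t)
  idx <- which(d > th_g)
  if (!length(idx)) return(empty)
  g <- data.frame(t_b = s$t[idx], t_e = s$t[idx + 1], g_l = d[idx])
  g[order(g$g_l, g$t_b), , drop = FALSE]
}

#' Read a signal CSV into a typed series
#'
#' CSV dialect: comma-separated, UTF-8, header required, time column `t_sec`
#' in float seconds from local midnight of day 1 of the visit.
#'
#' @param path file path
#' @param kind one of "series" (`t_sec,value`), "rr" (`t_sec,rr_ms`),
#'   "acc" (`t_sec,ax,ay,az`)
#' @param unit unit label for `kind = "series"`
#' @return a [ts_series], [rr_series], or list of three axis [ts_series]
#' @export
read_signal_csv <- function(path, kind = c("series", "rr", "acc"), unit = "") {
  kind <- match.arg(kind)
  df <- read.csv(path)
  if (nrow(df) == 0) stop(sprintf("no samples in '%s'", path))
  if (!"t_sec" %in% names(df)) stop(sprintf("missing column 't_sec' in '%s'", path))
  bad <- which(diff(df$t_sec) <= 0)
  if (length(bad)) {
    stop(sprintf("non-increasing time at line %d of '%s'", bad[1] + 2, path))
  }
  need <- switch(kind, series = "value", rr = "rr_ms", acc = c("ax", "ay", "az"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing column(s) %s in '%s'", paste(miss, collapse = ", "), path))
  }
  switch(kind,
    series = ts_series(df$t_sec, df$value, unit = unit),
    rr = rr_series(df$t_sec, df$rr_ms),
    acc = list(x = ts_series(df$t_sec, df$ax, "g"),
               y = ts_series(df$t_sec, df$ay, "g"),
               z = ts_series(df$t_sec, df$az, "g"))
  )
}

#' @rdname read_signal_csv
#' @param s series to write
#' @export
write_signal_csv <- function(s, path, kind = c("series", "rr")) {
  kind <- match.arg(kind)
  df <- if (kind == "rr") {
    data.frame(t_sec = s$beat_t, rr_ms = s$rr)
  } else {
    data.frame(t_sec = s$t, value = s$v)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
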