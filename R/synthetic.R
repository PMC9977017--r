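#' Parameters for one synthetic patient-visit
#'
#' Defines the latent structure of a simulated 48-h wearable recording:
#' circadian modulation of activity and heart rate, directional
#' activity-to-HR coupling on a 30-s latent grid, severity-linked
#' deceleration-capacity level, and a wear-gap model (daily charging gaps
#' plus Poisson dropouts).
#'
#' @param patient_id,visit_id identifier strings
#' @param cgis CGI-S integer score 1..7
#' @param dc_mean deceleration-capacity level (ms); amplitude of injected
#'   deceleration episodes, lower in high-severity visits
#' @param coupling_gamma activity-to-HR coupling coefficient (dimensionless)
#' @param circadian_amp list with `act` (counts) and `hr` (bpm) 24-h cosine
#'   amplitudes
#' @param noise_sd list with `act`, `hr` innovation SDs and `jitter`
#'   (multiplicative beat-level RR jitter SD, default 3%)
#' @param gap_model list with `charging_gap_hours` (length of the daily
#'   charging gap), `dropout_rate` (expected dropouts per hour) and
#'   `dropout_mean_s` (mean dropout length, exponential)
#' @param duration_h recording length in hours (>= 48 for a valid visit)
#' @param n_channels number of simulated ECG channels (2..4)
#' @return a `visit_params` list
#' @export
visit_params <- function(patient_id = "P01", visit_id = "V1", cgis = 3L,
                         dc_mean = 8, coupling_gamma = 0.3,
                         circadian_amp = list(act = 20, hr = 8),
                         noise_sd = list(act = 6, hr = 2, jitter = 0.03),
                         gap_model = list(charging_gap_hours = 2,
                                          dropout_rate = 0.5,
                                          dropout_mean_s = 120),
                         duration_h = 48, n_channels = 2L) {
  cgis <- as.integer(cgis)
  if (!cgis %in% 1:7) stop("cgis must be an integer in 1..7")
  if (duration_h < 48) stop("a valid visit requires duration_h >= 48")
  if (gap_model$dropout_rate < 0) stop("dropout_rate must be >= 0")
  structure(list(patient_id = patient_id, visit_id = visit_id, cgis = cgis,
                 dc_mean = dc_mean, coupling_gamma = coupling_gamma,
                 circadian_amp = circadian_amp, noise_sd = noise_sd,
                 gap_model = gap_model, duration_h = duration_h,
                 n_channels = as.integer(n_channels)),
            class = "visit_params")
}

#' Cohort-level simulation configuration
#'
#' @param n_patients number of patients (>= 2)
#' @param visit_prob probabilities of 1 or 2 visits per patient; the default
#'   gives 32 expected visits from 20 patients
#' @param severity_split fraction of patients in the high-severity class
#' @param dc_low low-severity deceleration-capacity level (ms)
#' @param dc_effect group gap: high-severity level is `dc_low - dc_effect`
#' @param coupling_mean mean activity-to-HR coupling in both groups
#' @param coupling_sd per-group SD of the coupling coefficient,
#'   `c(low, high)`; unequal values give the groups different coupling
#'   variance
#' @param dc_within_sd within-group SD of the per-visit dc level (ms)
#' @param master_seed master seed; all visit streams derive from it
#' @param ... forwarded to [visit_params()] (e.g. `gap_model`, `duration_h`)
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_patients = 20, visit_prob = c(0.4, 0.6),
                          severity_split = 0.5, dc_low = 8, dc_effect = 4,
                          coupling_mean = 0.3, coupling_sd = c(0.05, 0.15),
                          dc_within_sd = 0.5, master_seed = 1L, ...) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  n_high <- round(n_patients * severity_split)
  if (n_high < 1 || n_high > n_patients - 1) {
    stop("severity_split would leave a class empty")
  }
  structure(list(n_patients = as.integer(n_patients), visit_prob = visit_prob,
                 severity_split = severity_split, n_high = n_high,
                 dc_low = dc_low, dc_effect = dc_effect,
                 coupling_mean = coupling_mean, coupling_sd = coupling_sd,
                 dc_within_sd = dc_within_sd,
                 master_seed = as.integer(master_seed),
                 visit_args = list(...)),
            class = "cohort_config")
}

#' Stationary VAR(1) parameters for the coupling oracle
#'
#' @param a HR autoregression coefficient, `|a| < 1`
#' @param gamma activity-to-HR coupling
#' @param b activity autoregression coefficient, `|b| < 1`
#' @param sigma_hr,sigma_act innovation SDs
#' @return a `var1_params` list
#' @export
var1_params <- function(a = 0.5, gamma = 0.5, b = 0.5,
                        sigma_hr = 1, sigma_act = 1) {
  if (abs(a) >= 1 || abs(b) >= 1) stop("non-stationary: need |a| < 1 and |b| < 1")
  structure(list(a = a, gamma = gamma, b = b,
                 sigma_hr = sigma_hr, sigma_act = sigma_act),
            class = "var1_params")
}

#' Exact Gaussian transfer entropy of the VAR(1) coupling model
#'
#' For `hr_t = a hr_{t-1} + gamma act_{t-1} + eps` and
#' `act_t = b act_{t-1} + eta`, returns the activity-to-HR transfer entropy
#' `0.5 * log(Var[hr_t | hr_{t-1}] / Var[hr_t | hr_{t-1}, act_{t-1}])`
#' in nats, computed from the stationary covariance (Lyapunov solve). This
#' is the closed-form oracle against which the partition-based estimator is
#' validated.
#'
#' @param p a [var1_params] object
#' @return transfer entropy in nats
#' @export
analytic_te_var1 <- function(p) {
  stopifnot(inherits(p, "var1_params"))
  A <- matrix(c(p$a, 0, p$gamma, p$b), 2, 2)  # state (hr, act)
  Q <- diag(c(p$sigma_hr^2, p$sigma_act^2))
  # vec(Sigma) = (I - A (x) A)^{-1} vec(Q)
  S <- matrix(solve(diag(4) - kronecker(A, A), as.vector(Q)), 2, 2)
  var_full <- p$sigma_hr^2
  cov_lag <- p$a * S[1, 1] + p$gamma * S[2, 1]  # Cov(hr_t, hr_{t-1})
  var_red <- S[1, 1] - cov_lag^2 / S[1, 1]
  0.5 * log(var_red / var_full)
}

#' Simulate the VAR(1) coupling model
#'
#' @inheritParams analytic_te_var1
#' @param n series length
#' @param seed RNG seed
#' @param burn burn-in samples discarded
#' @return list with `act` (x, the driver) and `hr` (y, the response)
#' @export
simulate_var1 <- function(p, n, seed, burn = 200) {
  stopifnot(inherits(p, "var1_params"))
  with_seed(seed, {
    m <- n + burn
    eh <- rnorm(m, 0, p$sigma_hr)
    ea <- rnorm(m, 0, p$sigma_act)
    act <- as.numeric(stats::filter(ea, p$b, method = "recursive"))
    hr <- numeric(m)
    hr[1] <- eh[1]
    for (i in 2:m) hr[i] <- p$a * hr[i - 1] + p$gamma * act[i - 1] + eh[i]
    list(act = act[(burn + 1):m], hr = hr[(burn + 1):m])
  })
}

# AR(1) noise with innovation sd chosen so the marginal sd equals `sd`.
ar1_noise <- function(n, phi, sd) {
  as.numeric(stats::filter(rnorm(n, 0, sd * sqrt(1 - phi^2)),
                           phi, method = "recursive"))
}

#' Generate the latent trivariate signals for one visit
#'
#' Produces a beat-level RR series, a 30-s activity-count series, and
#' per-window per-channel SQI traces for one visit, before any gaps are
#' injected. Activity has 24-h cosinor structure; the latent HR follows
#' `hr_t = a hr_{t-1} + gamma act_dev_{t-1} + circadian + noise` on a 30-s
#' grid and is upsampled to beats by rate inversion with multiplicative
#' jitter. Deceleration episodes (transient RR lengthenings of amplitude
#' `dc_mean` ms over four beats) are injected at a fixed Poisson rate, so
#' the phase-rectified deceleration capacity tracks `dc_mean`.
#'
#' @param p a [visit_params] object
#' @param seed RNG seed for this visit
#' @param ar_hr,ar_act latent autoregression coefficients (|.| < 1)
#' @param acrophase circadian peak time, hours past midnight
#' @param dec_amp deceleration episode amplitude in ms. Episodes are kept
#'   small and frequent: phase-rectified DC responds to the per-beat step
#'   size linearly while RMSSD/PNN50 respond quadratically, so this regime
#'   makes deceleration capacity the severity-specific metric, as observed
#'   in the target population
#' @param dec_rate_scale episodes per minute per ms of `dc_mean`
#' @return list with `rr` ([rr_series]), `counts` ([ts_series], 30-s epochs),
#'   `sqi` (data.frame `t_start_sec`, `channel`, `sqi`), and the latent
#'   `hr_latent` grid ([ts_series])
#' @export
generate_trivariate_signals <- function(p, seed = 1L, ar_hr = 0.6,
                                        ar_act = 0.7, acrophase = 15,
                                        dec_amp = 25, dec_rate_scale = 0.7) {
  stopifnot(inherits(p, "visit_params"))
  if (abs(ar_hr) >= 1 || abs(ar_act) >= 1) stop("non-stationary latent AR")
  with_seed(seed, {
    dt <- 30
    n <- as.integer(p$duration_h * 3600 / dt)
    tt <- (seq_len(n) - 1) * dt
    hrs <- tt / 3600
    circ <- cos(2 * pi * (hrs - acrophase) / 24)

    act_dev <- ar1_noise(n, ar_act, p$noise_sd$act)
    counts <- pmax(0, 30 + p$circadian_amp$act * circ + act_dev)

    hr_dev <- numeric(n)
    eh <- rnorm(n, 0, p$noise_sd$hr * sqrt(1 - ar_hr^2))
    for (i in 2:n) {
      hr_dev[i] <- ar_hr * hr_dev[i - 1] + p$coupling_gamma * act_dev[i - 1] + eh[i]
    }
    hr <- pmin(180, pmax(50, 90 + p$circadian_amp$hr * circ + hr_dev))

    # rate inversion: cumulative beat count at grid edges, beats at integers
    cum <- c(0, cumsum(hr / 60 * dt))
    n_beats <- floor(cum[n + 1])
    beat_t <- approx(cum, c(tt, p$duration_h * 3600), xout = seq_len(n_beats))$y
    rr0 <- diff(c(0, beat_t)) * 1000
    jit <- ar1_noise(n_beats, 0.5, p$noise_sd$jitter)
    rr <- rr0 * (1 + jit)

    # deceleration episodes at a Poisson rate proportional to dc_mean, so
    # PRSA-DC tracks dc_mean. The profile is asymmetric - a sharp
    # two-beat lengthening followed by a gradual recovery - as vagal
    # decelerations are, so acceleration capacity responds far less than
    # deceleration capacity; the modest steps keep PNN50/RMSSD driven
    # mainly by the jitter
    n_ev <- rpois(1, dec_rate_scale * p$dc_mean * p$duration_h * 60)
    prof <- dec_amp * c(0.5, 1, 1, 0.8, 0.6, 0.4, 0.2)
    np <- length(prof)
    if (n_ev > 0 && n_beats > 2 * np) {
      ev <- sample.int(n_beats - np, n_ev, replace = TRUE)
      for (j in ev) rr[j:(j + np - 1)] <- rr[j:(j + np - 1)] + prof
    }
    rr <- pmax(rr, 250)
    beat_t <- cumsum(rr) / 1000

    # per-60-s per-channel SQI, degrading with activity level
    w_start <- seq(0, p$duration_h * 3600 - 60, by = 60)
    act_w <- counts[pmin(n, floor(w_start / dt) + 1)]
    act_norm <- act_w / max(act_w, 1)
    sqi <- do.call(rbind, lapply(seq_len(p$n_channels), function(ch) {
      m <- pmin(0.98, pmax(0.05, 0.95 - 0.18 * act_norm +
                             rnorm(length(w_start), 0, 0.03)))
      data.frame(t_start_sec = w_start, channel = ch,
                 sqi = rbeta(length(w_start), m * 60, (1 - m) * 60))
    }))
    list(rr = rr_series(beat_t, rr),
         counts = ts_series((seq_len(n) - 1) * dt, counts, "counts"),
         sqi = sqi,
         hr_latent = ts_series(tt, hr, "bpm"))
  })
}

#' Sample wear-gap intervals from a gap model
#'
#' One charging gap per 24-h day (uniform start within the day) plus
#' Poisson dropouts with exponential lengths.
#'
#' @param gap_model list as in [visit_params()]
#' @param duration_s recording span in seconds
#' @param seed RNG seed
#' @return data.frame with `start`, `end` (seconds)
#' @export
sample_gap_intervals <- function(gap_model, duration_s, seed = 1L) {
  with_seed(seed, {
    iv <- data.frame(start = numeric(0), end = numeric(0))
    cg <- gap_model$charging_gap_hours * 3600
    if (cg > 0) {
      n_days <- ceiling(duration_s / 86400)
      for (d in seq_len(n_days)) {
        day_start <- (d - 1) * 86400
        day_end <- min(d * 86400, duration_s)
        if (day_end - day_start <= cg) next
        s <- day_start + runif(1, 0, day_end - day_start - cg)
        iv <- rbind(iv, data.frame(start = s, end = s + cg))
      }
    }
    n_drop <- rpois(1, gap_model$dropout_rate * duration_s / 3600)
    if (n_drop > 0) {
      s <- runif(n_drop, 0, duration_s)
      len <- rexp(n_drop, 1 / gap_model$dropout_mean_s)
      iv <- rbind(iv, data.frame(start = s, end = pmin(s + len, duration_s)))
    }
    iv[order(iv$start), , drop = FALSE]
  })
}

# Drop samples of a timestamp vector falling strictly inside any interval.
in_gap <- function(t, intervals) {
  keep <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals))) {
    keep <- keep | (t > intervals$start[i] & t < intervals$end[i])
  }
  keep
}

#' Inject wear gaps into a series
#'
#' Surviving samples are identical to the input at their timestamps.
#' Warns (and proceeds) if the gap model removes more than 90% of samples.
#'
#' @param s a [ts_series]
#' @param gap_model list as in [visit_params()]
#' @param seed RNG seed
#' @return a [ts_series] with samples inside gaps removed
#' @export
inject_gaps <- function(s, gap_model, seed = 1L) {
  stopifnot(inherits(s, "ts_series"), length(s$t) > 0)
  iv <- sample_gap_intervals(gap_model, max(s$t), seed)
  if (nrow(iv) == 0) return(s)
  drop <- in_gap(s$t, iv)
  if (mean(drop) > 0.9) {
    warning("gap model removes more than 90% of samples")
  }
  ts_series(s$t[!drop], s$v[!drop], s$unit)
}

#' Generate a labelled synthetic cohort
#'
#' Patients are assigned to severity groups by `severity_split`; visits get
#' CGI-S scores 2..4 (low) or 5..7 (high), a severity-linked
#' deceleration-capacity level, and a coupling coefficient whose variance
#' differs between groups per the config. Every visit carries an RR series,
#' a 30-s activity-count series and per-window SQI traces, with wear gaps
#' applied jointly to RR and counts (the device is off for both). The whole
#' cohort is a pure function of `master_seed`.
#'
#' @param config a [cohort_config]
#' @param signals generate the signal content (default). With
#'   `signals = FALSE` only the per-visit parameters and labels are drawn
#'   (identical to the full run), which is cheap enough for
#'   distribution-level checks on hundreds of visits
#' @return a `pm_cohort`: list of visits, each with `patient_id`,
#'   `visit_id`, `cgis`, `params`, `rr`, `counts`, `sqi`, plus the intact
#'   (pre-gap) signals under `full`
#' @export
generate_cohort <- function(config, signals = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(c("low", "high"),
                c(config$n_patients - config$n_high, config$n_high))
  visits <- list()
  for (pi in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", pi)
    grp <- groups[pi]
    nv <- with_seed(seed_stream(config$master_seed, pi, 0),
                    sample(seq_along(config$visit_prob), 1,
                           prob = config$visit_prob))
    for (vi in seq_len(nv)) {
      vseed <- seed_stream(config$master_seed, pi, vi)
      par <- with_seed(vseed, {
        cgis <- if (grp == "low") sample(2:4, 1) else sample(5:7, 1)
        dc <- max(0.5, (if (grp == "low") config$dc_low
                        else config$dc_low - config$dc_effect) +
                    rnorm(1, 0, config$dc_within_sd))
        gsd <- if (grp == "low") config$coupling_sd[1] else config$coupling_sd[2]
        gam <- rnorm(1, config$coupling_mean, gsd)
        do.call(visit_params,
                c(list(patient_id = pid, visit_id = sprintf("V%d", vi),
                       cgis = cgis, dc_mean = dc, coupling_gamma = gam),
                  config$visit_args))
      })
      entry <- list(patient_id = pid, visit_id = par$visit_id,
                    cgis = par$cgis, group = grp, params = par,
                    seed = vseed)
      if (signals) {
        sig <- generate_trivariate_signals(par, seed_stream(vseed, 1))
        iv <- sample_gap_intervals(par$gap_model, par$duration_h * 3600,
                                   seed_stream(vseed, 2))
        keep_b <- !in_gap(sig$rr$beat_t, iv)
        keep_c <- !in_gap(sig$counts$t, iv)
        entry$rr <- rr_series(sig$rr$beat_t[keep_b], sig$rr$rr[keep_b])
        entry$counts <- ts_series(sig$counts$t[keep_c],
                                  sig$counts$v[keep_c], "counts")
        entry$sqi <- sig$sqi
        entry$full <- sig
      }
      visits[[length(visits) + 1]] <- entry
    }
  }
  lab <- vapply(visits, function(v) v$group, "")
  if (length(unique(lab)) < 2) stop("generated cohort has an empty class")
  structure(list(visits = visits, config = config), class = "pm_cohort")
}

#' @export
print.pm_cohort <- function(x, ...) {
  lab <- vapply(x$visits, function(v) v$group, "")
  cat(sprintf("<pm_cohort> %d visits from %d patients (%d low / %d high)\n",
              length(x$visits),
              length(unique(vapply(x$visits, function(v) v$patient_id, ""))),
              sum(lab == "low"), sum(lab == "high")))
  invisible(x)
}

#' Write a cohort to per-visit directories
#'
#' Each visit directory gets `rr.csv` (t_sec, rr_ms), `counts_30s.csv`
#' (t_sec, value), `sqi.csv` (t_start_sec, channel, sqi) and `meta.json`.
#'
#' @param cohort a `pm_cohort`
#' @param dir output directory
#' @return invisibly, the visit directory paths
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort$visits, function(v) {
    vd <- file.path(dir, paste0(v$patient_id, "_", v$visit_id))
    dir.create(vd, showWarnings = FALSE)
    write_signal_csv(v$rr, file.path(vd, "rr.csv"), "rr")
    write_signal_csv(v$counts, file.path(vd, "counts_30s.csv"), "series")
    write.csv(v$sqi, file.path(vd, "sqi.csv"), row.names = FALSE)
    jsonlite::write_json(list(patient_id = v$patient_id,
                              visit_id = v$visit_id, cgis = v$cgis,
                              seed = v$seed,
                              dc_mean = v$params$dc_mean,
                              coupling_gamma = v$params$coupling_gamma),
                         file.path(vd, "meta.json"), auto_unbox = TRUE)
    vd
  }, "")
  invisible(paths)
}
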