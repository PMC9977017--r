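# Independent oracles and small fixture builders used across test files.

# Exhaustive k-cycle (subgraph) count by vertex-set enumeration.
brute_cycles <- function(adj, k) {
  n <- nrow(adj)
  if (n < k) return(0L)
  cnt <- 0L
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    v <- sets[, j]
    if (k == 3) {
      if (adj[v[1], v[2]] && adj[v[2], v[3]] && adj[v[1], v[3]]) {
        cnt <- cnt + 1L
      }
    } else {
      for (p in list(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4))) {
        w <- v[p]
        if (adj[w[1], w[2]] && adj[w[2], w[3]] && adj[w[3], w[4]] &&
              adj[w[4], w[1]]) {
          cnt <- cnt + 1L
        }
      }
    }
  }
  cnt
}

# AUC by explicit pair counting (ties get half credit).
brute_auc <- function(probs, labels) {
  hi <- probs[labels == "high"]
  lo <- probs[labels == "low"]
  s <- 0
  for (a in hi) for (b in lo) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(hi) * length(lo))
}

# Exhaustive L5/M10 window search over hourly values.
brute_l5_m10 <- function(x) {
  n <- length(x)
  m5 <- sapply(1:(n - 4), function(i) mean(x[i:(i + 4)]))
  m10 <- sapply(1:(n - 9), function(i) mean(x[i:(i + 9)]))
  list(L5 = min(m5), M10 = max(m10))
}

# Random symmetric 0/1 adjacency with zero diagonal.
rand_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, p)
  a + t(a)
}

# Transition-network object from an adjacency matrix (for metric tests).
net_from_adj <- function(adj, self_loops = integer(0)) {
  As <- adj
  diag(As) <- 0L
  idx <- which(As == 1 & upper.tri(As), arr.ind = TRUE)
  A <- As
  if (length(self_loops)) diag(A)[self_loops] <- 1L
  structure(list(n_nodes = nrow(adj), edges = idx, self_loops = self_loops,
                 adjacency = A),
            class = "transition_network")
}

# Synthetic single-channel ECG: Gaussian pulse train plus white noise.
mk_pulse_ecg <- function(fs = 125, dur = 15, bpm = 60, noise = 0) {
  t <- seq(0, dur, by = 1 / fs)
  beats <- seq(0.5, dur, by = 60 / bpm)
  x <- rowSums(sapply(beats, function(b) exp(-((t - b)^2) / (2 * 0.01^2))))
  x + rnorm(length(t), 0, noise)
}

# Reduced HRV metric set used for cohort-scale classification checks
# (deceleration/acceleration capacity plus core time-domain metrics).
fast_hrv_metrics <- c("NNmean", "SDNN", "RMSSD", "PNN50", "PRSA_AC",
                      "PRSA_DC")

# Cohort -> reduced nocturnal HRV feature table, the downstream input for
# the parameter-recovery and null-behaviour classification checks.
cohort_hrv_table <- function(seed, dc_effect, coupling_sd,
                             n_patients = 20) {
  cc <- cohort_config(n_patients = n_patients, dc_effect = dc_effect,
                      coupling_sd = coupling_sd, master_seed = seed)
  coh <- generate_cohort(cc)
  fb <- lapply(coh$visits, function(v)
    hrv_block(clean_rr(v$rr), metrics = fast_hrv_metrics, clean = FALSE))
  ok <- !vapply(fb, is.null, TRUE)
  X <- do.call(rbind, fb[ok])
  feature_table(X,
                vapply(coh$visits[ok], function(v) v$patient_id, ""),
                vapply(coh$visits[ok], function(v) v$cgis, 0L),
                family = rep("HRV", ncol(X)))
}

# Random labelled feature table: n patients, each with `visits` visits.
random_feature_table <- function(n_pat, n_feat = 8, seed = 1,
                                 effect = 0, visits = 1) {
  set.seed(seed)
  pid <- rep(sprintf("P%02d", 1:n_pat), each = visits)
  lab <- factor(rep(rep(c("low", "high"), each = n_pat / 2), each = visits),
                levels = c("low", "high"))
  X <- matrix(rnorm(length(pid) * n_feat), length(pid), n_feat,
              dimnames = list(NULL, paste0("f", seq_len(n_feat))))
  X[, 1] <- X[, 1] + ifelse(lab == "high", effect, 0)
  fam <- rep_len(c("HRV", "ACT", "MSTE", "MSNR"), n_feat)
  feature_table(X, pid, lab, family = fam)
}
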