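mk_windows <- function(starts, chans, sqis) {
  rows <- list()
  k <- 0
  for (i in seq_along(starts)) {
    for (j in seq_along(chans[[i]])) {
      k <- k + 1
      rows[[k]] <- data.frame(window_start = starts[i],
                              channel_id = chans[[i]][j],
                              sqi = sqis[[i]][j])
    }
  }
  df <- do.call(rbind, rows)
  df$samples <- lapply(seq_len(nrow(df)), function(r)
    data.frame(t = df$window_start[r] + c(10, 20),
               v = df$channel_id[r] * 100 + c(1, 2)))
  df
}

test_that("SQI fusion keeps the best channel only above the strict threshold", {
  w <- mk_windows(c(0, 60), list(1:2, 1:2),
                  list(c(0.80, 0.60), c(0.75, 0.70)))
  f <- fuse_channels_by_sqi(w)
  # window 0: channel 1 kept (0.80 > 0.75)
  expect_equal(f$provenance$channel_id[1], 1)
  # window 60: best SQI is exactly 0.75 -> discarded (strictly greater)
  expect_true(is.na(f$provenance$channel_id[2]))
  expect_equal(f$series$t, c(10, 20))
  expect_equal(f$series$v, c(101, 102))
})

test_that("SQI fusion breaks ties by lowest channel id", {
  w <- mk_windows(0, list(c(2, 1, 3)), list(c(1.0, 1.0, 1.0)))
  f <- fuse_channels_by_sqi(w)
  expect_equal(f$provenance$channel_id[1], 1)
})

test_that("SQI fusion never emits a window at or below the threshold", {
  set.seed(8)
  starts <- seq(0, 60 * 39, by = 60)
  w <- mk_windows(starts, rep(list(1:3), 40),
                  lapply(1:40, function(i) runif(3)))
  f <- fuse_channels_by_sqi(w)
  kept <- !is.na(f$provenance$channel_id)
  expect_true(all(f$provenance$sqi[kept] > 0.75))
  expect_true(all(f$provenance$sqi[!kept] <= 0.75))
})

test_that("fusion rejects inconsistent window grids", {
  w <- mk_windows(c(0, 0), list(1, 1), list(0.9, 0.8))
  expect_error(fuse_channels_by_sqi(w), "inconsistent")
})

test_that("beat-agreement SQI is 1 on clean trains and low on noise", {
  set.seed(1)
  expect_equal(simple_bsqi(mk_pulse_ecg(), 125), 1.0)
  noise_sqi <- sapply(1:100, function(s) {
    set.seed(s)
    simple_bsqi(rnorm(15 * 125), 125)
  })
  expect_lt(median(noise_sqi), 0.5)
  expect_error(simple_bsqi(rnorm(100), 125), "10 s")
})

test_that("beat-agreement SQI degrades as noise grows", {
  med <- sapply(c(0, 0.1, 0.3, 1), function(nz)
    median(sapply(1:10, function(s) {
      set.seed(s)
      simple_bsqi(mk_pulse_ecg(noise = nz), 125)
    })))
  expect_true(all(diff(med[1:3]) <= 0.08))  # non-increasing up to tolerance
  expect_lt(med[4], 0.5)
})

test_that("surrogate imputation fills gaps and preserves originals", {
  # no gaps above threshold: identity
  s <- ts_series(seq(0, 100), rnorm(101))
  expect_identical(surrogate_impute(s, th_g = 5, seed = 1), s)

  # constant series, degenerate noise: gap filled with exactly the constant
  t <- c(seq(0, 100), seq(161, 260))
  cs <- ts_series(t, rep(4.2, length(t)))
  out <- surrogate_impute(cs, th_g = 5, noise_frac = 0, seed = 2)
  expect_equal(nrow(detect_gaps(out, 5)), 0)
  expect_true(all(out$v == 4.2))

  # fixed seed reproducible; different seeds give different donor choices
  set.seed(33)
  tt <- sort(c(seq(0, 500), seq(560, 700), seq(790, 1000)))
  gs <- ts_series(tt, sin(tt / 20) + rnorm(length(tt), 0, 0.1))
  o1 <- surrogate_impute(gs, th_g = 10, seed = 9)
  o2 <- surrogate_impute(gs, th_g = 10, seed = 9)
  expect_identical(o1, o2)
  outs <- lapply(1:10, function(sd) surrogate_impute(gs, th_g = 10, seed = sd))
  expect_gt(length(unique(sapply(outs, function(o) paste(round(o$v, 6),
                                                         collapse = ",")))), 1)

  # original samples preserved verbatim, timestamps strictly increasing
  expect_true(all(diff(o1$t) > 0))
  expect_true(all(gs$v == o1$v[o1$t %in% gs$t]))

  # an unservable gap is reported with its location
  tiny <- ts_series(c(0, 1, 2, 300, 301), rnorm(5))
  expect_error(surrogate_impute(tiny, th_g = 10, seed = 1), "donor")
})

test_that("imputed values match the donor distribution on stationary signals", {
  ks_p <- sapply(1:50, function(s) {
    set.seed(s)
    x <- as.numeric(stats::filter(rnorm(1200), 0.7, method = "recursive"))
    t <- seq_along(x)
    gap <- 500:579
    sr <- ts_series(t[-gap], x[-gap])
    out <- surrogate_impute(sr, th_g = 5, seed = s + 1000)
    imput <- out$v[out$t > t[gap[1] - 1] & out$t < t[gap[length(gap)] + 1]]
    donor_pool <- x[c(300:499, 581:780)]
    suppressWarnings(ks.test(imput, donor_pool)$p.value)
  })
  expect_gt(median(ks_p), 0.01)
})

test_that("ensembles are seeded per member and sized as configured", {
  # gap-free input: all members identical
  s <- ts_series(seq(0, 200), rnorm(201))
  ens <- generate_surrogate_ensemble(s, th_g = 5, m = 10, base_seed = 3)
  expect_length(ens$members, 10)
  expect_true(all(sapply(ens$members, identical, s)))
  expect_equal(ens$member_seeds, 3 + 1:10)

  # gappy input: members differ, ensemble mean of the imputed region is
  # consistent with the donor neighbourhood
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(1000), 0.6, method = "recursive")) + 10
  t <- seq_along(x)
  gap <- 430:489
  sr <- ts_series(t[-gap], x[-gap])
  e2 <- generate_surrogate_ensemble(sr, th_g = 5, m = 100, base_seed = 7)
  imp_means <- sapply(e2$members, function(m)
    mean(m$v[m$t > t[429] & m$t < t[490]]))
  neigh <- x[c(230:429, 491:690)]
  se <- sd(neigh) / sqrt(30)  # conservative effective n for an AR signal
  expect_lt(abs(mean(imp_means) - mean(neigh)), 2 * sd(neigh))
  expect_gt(sd(imp_means), 0)  # members genuinely differ
})

test_that("hourly PCHIP imputation preserves sums and fills interior hours", {
  # no empty hours: output equals hourly sums exactly
  t <- seq(0, 3 * 3600 - 60, by = 60)
  s <- ts_series(t, rep(2, length(t)), "counts")
  h <- pchip_impute_hourly(s)
  expect_equal(h$v, rep(120, 3))

  # middle hour empty: shape-preserving interpolation stays in [10, 30]
  t2 <- c(0, 2 * 3600)
  s2 <- ts_series(t2, c(10, 30), "counts")
  h2 <- pchip_impute_hourly(s2)
  expect_length(h2$v, 3)
  expect_gte(h2$v[2], 10)
  expect_lte(h2$v[2], 30)
  expect_true(attr(h2, "imputed")[2])

  # linear ramp with one missing hour is recovered exactly
  hours <- c(0, 1, 2, 4, 5)
  s3 <- ts_series(hours * 3600, c(10, 20, 30, 50, 60), "counts")
  h3 <- pchip_impute_hourly(s3)
  expect_equal(h3$v[4], 40, tolerance = 1e-10)
})
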