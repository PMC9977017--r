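const_rr <- function(n, rr_ms = 800) {
  rr_series(cumsum(rep(rr_ms / 1000, n)), rep(rr_ms, n))
}

test_that("window slicing follows the 300 s / 30 s scheme", {
  rr <- const_rr(750)  # 600 s at 800 ms
  w <- window_rr(rr)
  expect_equal(nrow(w), 11)
  expect_equal(w$window_start, seq(0, 300, by = 30))

  # shorter than one window: nothing
  expect_equal(nrow(window_rr(const_rr(100))), 0)

  # a window fully inside a gap is absent
  bt <- c(cumsum(rep(0.8, 375)), 900 + cumsum(rep(0.8, 400)))
  rr2 <- rr_series(bt, rep(800, length(bt)))
  w2 <- window_rr(rr2)
  expect_false(any(w2$window_start >= 300 & w2$window_start < 600))
})

test_that("window metrics match hand-computed values", {
  m <- compute_window_metrics(cumsum(rep(0.8, 100)), rep(800, 100))
  expect_equal(unname(m["SDNN"]), 0)
  expect_equal(unname(m["RMSSD"]), 0)
  expect_equal(unname(m["PNN50"]), 0)
  expect_equal(unname(m["NNmean"]), 800)
  expect_equal(unname(m["meanHR"]), 75)

  # one of three successive differences exceeds 50 ms
  rr <- c(800, 860, 900, 940)
  m2 <- compute_window_metrics(cumsum(rr) / 1000, rr)
  expect_equal(unname(m2["PNN50"]), 100 / 3, tolerance = 1e-10)

  # alternating 800/900: all successive diffs are 100 ms
  rr3 <- rep(c(800, 900), 50)
  m3 <- compute_window_metrics(cumsum(rr3) / 1000, rr3)
  expect_equal(unname(m3["RMSSD"]), 100)
  expect_equal(unname(m3["PNN50"]), 100)
})

test_that("time/frequency metrics agree with brute-force recomputation", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(50:400, 1)
    rr <- 800 + cumsum(rnorm(n, 0, 8))
    m <- compute_window_metrics(cumsum(rr) / 1000, rr)
    d <- diff(rr)
    expect_equal(unname(m["SDNN"]), sd(rr), tolerance = 1e-10)
    expect_equal(unname(m["RMSSD"]), sqrt(mean(d^2)), tolerance = 1e-10)
    expect_equal(unname(m["PNN50"]), 100 * mean(abs(d) > 50),
                 tolerance = 1e-10)
    expect_equal(unname(m["NNvariance"]), var(rr), tolerance = 1e-8)
    expect_equal(unname(m["NNmedian"]), median(rr), tolerance = 1e-8)
    expect_equal(unname(m["NNiqr"]), unname(diff(quantile(rr, c(.25, .75)))),
                 tolerance = 1e-8)
  }
})

test_that("all 24 metrics are finite on a realistic window", {
  set.seed(9)
  rr <- 800 + cumsum(rnorm(400, 0, 6))
  m <- compute_window_metrics(cumsum(rr) / 1000, rr)
  expect_length(m, 24)
  expect_named(m, hrv_metric_names())
  expect_true(all(is.finite(m)))
})

test_that("a modulated RR series puts its power in the right band", {
  t <- cumsum(rep(0.8, 600))
  rr <- 800 + 40 * sin(2 * pi * 0.1 * t)  # 0.1 Hz -> LF
  m <- compute_window_metrics(t, rr)
  expect_gt(m[["LF"]], 10 * m[["HF"]])
  expect_gt(m[["LF"]], 10 * m[["VLF"]])
})

test_that("PRSA follows its defining algebra", {
  # constant series: no anchors
  expect_true(is.na(prsa_dc(rep(800, 200))$DC))

  # linear ramp with slope delta: DC equals delta exactly
  rr <- 800 + 2 * (1:100)
  expect_equal(prsa_dc(rr, L = 5)$DC, 2, tolerance = 1e-10)

  # time reversal swaps deceleration and acceleration capacity
  set.seed(2)
  rr2 <- 800 + cumsum(rnorm(300, 0, 3))
  a <- prsa_dc(rr2, L = 10)
  b <- prsa_dc(rev(rr2), L = 10)
  expect_equal(a$DC, -b$AC, tolerance = 0.01)
  expect_equal(a$AC, -b$DC, tolerance = 0.01)
})

test_that("RR artefact filtering removes out-of-range and jumping beats", {
  rr <- c(800, 810, 5000, 820, 100, 815, 1200, 805)
  cl <- clean_rr(rr_series(cumsum(rr) / 1000, rr))
  expect_false(any(cl$rr > 2000 | cl$rr < 300))
  expect_false(any(abs(diff(cl$rr)) / head(cl$rr, -1) > 0.2))
})

test_that("nocturnal aggregation yields mean and variance per metric", {
  # all windows of a metric equal to c: mu = c, var = 0
  wd <- data.frame(window_start = c(0, 30, 60), SDNN = c(5, 5, 5),
                   RMSSD = c(2, 3, 4))
  agg <- nocturnal_aggregate(wd)
  expect_equal(unname(agg["mu_SDNN"]), 5)
  expect_equal(unname(agg["var_SDNN"]), 0)
  expect_equal(unname(agg["var_RMSSD"]), var(c(2, 3, 4)))

  # half-open boundary: a 09:45 window is nocturnal, a 10:15 window is not
  wd2 <- data.frame(window_start = c(9.75 * 3600, 10.25 * 3600,
                                     33.75 * 3600),
                    SDNN = c(1, 100, 3))
  agg2 <- nocturnal_aggregate(wd2)
  expect_equal(unname(agg2["mu_SDNN"]), 2)  # 09:45 windows of both days only

  # permutation of window order changes nothing
  set.seed(5)
  wd3 <- data.frame(window_start = seq(0, 290 * 30, by = 30),
                    SDNN = rnorm(291), RMSSD = rnorm(291))
  p <- sample(nrow(wd3))
  expect_equal(nocturnal_aggregate(wd3), nocturnal_aggregate(wd3[p, ]))

  # fewer than two nocturnal windows: flagged missing
  wd4 <- data.frame(window_start = 12 * 3600, SDNN = 1)
  expect_null(nocturnal_aggregate(wd4))
})

test_that("a two-night visit yields the full 48-feature block", {
  # beats only within two nocturnal stretches, full 24-metric computation
  set.seed(6)
  seg <- function(t0, dur) {
    rr <- 800 + cumsum(rnorm(ceiling(dur / 0.7), 0, 5))
    rr <- pmin(pmax(rr, 600), 1100)
    bt <- t0 + cumsum(rr) / 1000
    list(bt = bt[bt < t0 + dur], rr = rr[bt < t0 + dur])
  }
  s1 <- seg(22.2 * 3600, 2400)
  s2 <- seg(26.5 * 3600, 2400)   # 02:30 of night two
  rr <- rr_series(c(s1$bt, s2$bt), c(s1$rr, s2$rr))
  block <- hrv_block(rr, clean = FALSE)
  expect_length(block, 48)
  expect_named(block, c(paste0("mu_", hrv_metric_names()),
                        paste0("var_", hrv_metric_names())))
  expect_true(all(is.finite(block)))
  expect_true(all(block[paste0("var_", hrv_metric_names())] >= 0))
})

test_that("HR and DC grids are built on the 30-s lattice", {
  rr <- const_rr(200, 1000)
  g <- hr_dc_grids(rr)
  expect_true(all(g$hr_grid$v == 60))
  # constant RR has no anchors anywhere: DC grid is empty
  expect_length(g$dc_grid$t, 0)

  # a 48-h gap-free visit yields a 5760-point HR grid
  sig <- generate_trivariate_signals(visit_params(), seed = 21)
  g2 <- hr_dc_grids(clean_rr(sig$rr), duration_s = 48 * 3600)
  expect_equal(length(g2$hr_grid$t), 5760)
  expect_gt(length(g2$dc_grid$t), 5000)
  expect_true(all(g2$hr_grid$t %% 30 == 0))
})
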