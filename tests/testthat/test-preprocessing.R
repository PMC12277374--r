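# Spike extraction: filter response, robust threshold formula, negative-peak
# detection with the refractory rule, and artifact-window exclusion.

fs <- 20000

test_that("bandpass keeps the signal band and rejects out-of-band components", {
  t <- seq_len(2 * fs) / fs
  mid <- sin(2 * pi * 1000 * t)
  f_mid <- bandpass_filter(mid, fs)
  core <- seq(fs / 2, 3 * fs / 2)  # away from edges
  expect_equal(max(abs(f_mid[core])), 1, tolerance = 0.05)

  low <- sin(2 * pi * 10 * t)
  f_low <- bandpass_filter(low, fs)
  expect_lt(max(abs(f_low[core])), 0.1)  # >= 90% attenuation

  hi <- sin(2 * pi * 6000 * t)
  f_hi <- bandpass_filter(hi, fs)
  expect_lt(max(abs(f_hi[core])), 10^(-20 / 20))  # >= 20 dB down

  dc <- rep(42, fs)
  f_dc <- bandpass_filter(dc, fs)
  expect_lt(max(abs(f_dc[2000:18000])), 1e-6)

  expect_error(bandpass_filter(rnorm(100), fs),
               class = "meaburst_invalid_argument")
})

test_that("filtering is zero-phase: spike peak times are not shifted", {
  set.seed(1)
  shape <- -exp(-((-20:20) / 4)^2)
  x <- rnorm(fs, 0, 1)
  centers <- c(4000, 9000, 14000)
  for (cc in centers) x[cc + (-20:20)] <- x[cc + (-20:20)] + 40 * shape
  f <- bandpass_filter(x, fs)
  for (cc in centers) {
    w <- f[(cc - 40):(cc + 40)]
    expect_lte(abs(which.min(w) - 41), 1)  # within one sample
  }
})

test_that("threshold follows the MAD/0.6745 robust estimate exactly", {
  p <- detection_params()
  # constant trace: degenerate MAD
  thr_c <- estimate_threshold(rep(3.5, 1000), p)
  expect_equal(thr_c$noise_sd_estimate, 0)
  expect_equal(thr_c$threshold, 3.5)
  expect_true(thr_c$degenerate)

  # sparse spike on zeros: MAD still 0
  thr_d <- estimate_threshold(c(0, 0, 0, 0, -10), p)
  expect_equal(thr_d$noise_sd_estimate, 0)
  expect_true(thr_d$degenerate)

  # exact formula on arbitrary vectors
  set.seed(2)
  for (x in list(rnorm(501, 2, 3), rexp(200) - 5, c(rnorm(999), -80))) {
    thr <- estimate_threshold(x, p)
    expect_identical(thr$noise_sd_estimate,
                     median(abs(x - median(x))) / 0.6745)
    expect_identical(thr$threshold, mean(x) - 5 * thr$noise_sd_estimate)
  }

  # consistency: long Gaussian noise recovers the true SD within 2%
  set.seed(3)
  thr_g <- estimate_threshold(rnorm(2e5), p)
  expect_equal(thr_g$noise_sd_estimate, 1, tolerance = 0.02)

  expect_error(estimate_threshold(numeric(0)), class = "meaburst_invalid_argument")
})

test_that("detector finds injected spikes and ignores sub-threshold dips", {
  p <- detection_params()
  set.seed(4)
  x <- rnorm(fs)
  thr0 <- estimate_threshold(x, p)
  inj <- 10000
  x[inj + (-4:4)] <- x[inj + (-4:4)] - 8 * c(1, 2, 4, 7, 8.5, 7, 4, 2, 1) / 8.5
  thr <- estimate_threshold(x, p)
  sp <- detect_spikes(x, fs, thr, p)
  near <- abs(sp$spike_times - (inj - 1) / fs) < 0.0005
  expect_equal(sum(near), 1L)
  # no other detections expected at 5 sigma in 1 s of noise... allow chance FP
  expect_lte(length(sp$spike_times) - 1L, 1L)

  y <- rnorm(fs)
  thr_y <- estimate_threshold(y, p)
  y2 <- y
  y2[c(5000, 9000) + rep(0, 2)] <- thr_y$mean - 3 * thr_y$noise_sd_estimate
  sp2 <- detect_spikes(y2, fs, estimate_threshold(y2, p), p)
  expect_lte(length(sp2$spike_times), 1L)  # the -3 sd dips never qualify
})

test_that("refractory rule keeps the first spike of each 2 ms run", {
  p <- detection_params()
  x <- numeric(fs)
  # supra-threshold dips at 10.0, 11.5 and 13.0 ms on a flat trace with
  # added jitter so the MAD is non-degenerate
  set.seed(5)
  x <- rnorm(fs, 0, 1)
  for (ms in c(10, 11.5, 13)) {
    i <- round(ms / 1000 * fs) + 1
    x[i + (-2:2)] <- c(-3, -6, -9, -6, -3)
  }
  sp <- detect_spikes(x, fs, estimate_threshold(x, p), p)
  got_ms <- sp$spike_times[sp$spike_times < 0.02] * 1000
  expect_equal(got_ms, c(10, 13), tolerance = 1e-6)
})

test_that("detector equals the exhaustive local-minimum + refractory oracle", {
  p <- detection_params()
  set.seed(6)
  for (rep in 1:25) {
    n <- 5000
    x <- rnorm(n)
    # sprinkle spikes of random depth, some closer than the refractory gap
    k <- sample(5:25, 1)
    at <- sort(sample(50:(n - 50), k))
    for (i in at) x[i + (-3:3)] <- x[i + (-3:3)] - runif(1, 4, 12) * c(.2, .5, .8, 1, .8, .5, .2)
    thr <- estimate_threshold(x, p)
    got <- detect_spikes(x, fs, thr, p)$spike_samples
    want <- oracle_detect(x, thr$threshold, p$refractory * fs)
    expect_identical(got, want)
  }
})

test_that("raising the threshold multiplier never increases spike count", {
  set.seed(7)
  x <- rnorm(2e4)
  at <- seq(500, 19500, by = 700)
  for (i in at) x[i + (-2:2)] <- x[i + (-2:2)] - runif(1, 2, 10) * c(.4, .8, 1, .8, .4)
  last <- Inf
  for (m in c(3, 4, 5, 6, 8)) {
    p <- detection_params(threshold_multiplier = m)
    n <- length(detect_spikes(x, fs, estimate_threshold(x, p), p)$spike_times)
    expect_lte(n, last)
    last <- n
  }
})

test_that("artifact exclusion removes spikes in closed +-1 ms padded windows", {
  p <- detection_params()
  stim <- data.frame(onset = 1.000, offset = 1.005)
  spikes <- c(0.9985, 1.002, 1.0055, 1.0062)
  kept <- exclude_artifact_spikes(spikes, stim, p)
  # window is [0.999, 1.006]: 1.002 and 1.0055 fall inside, the others out
  expect_equal(kept, c(0.9985, 1.0062))

  # closed boundaries
  expect_length(exclude_artifact_spikes(c(1.000 - 0.001), stim, p), 0)
  expect_length(exclude_artifact_spikes(c(1.005 + 0.001), stim, p), 0)
  expect_equal(exclude_artifact_spikes(c(1.005 + 0.001 + 1e-9), stim, p),
               1.005 + 0.001 + 1e-9)

  # identity on empty logs, idempotence, order preservation
  expect_equal(exclude_artifact_spikes(spikes, stim[0, ], p), spikes)
  set.seed(8)
  tt <- sort(runif(500, 0, 60))
  st <- data.frame(onset = seq(5, 55, by = 5), offset = seq(5, 55, by = 5) + 0.005)
  once <- exclude_artifact_spikes(tt, st, p)
  expect_identical(exclude_artifact_spikes(once, st, p), once)
  expect_false(is.unsorted(once))

  expect_error(exclude_artifact_spikes(tt, data.frame(onset = c(2, 1),
                                                      offset = c(2.1, 1.1)), p),
               class = "meaburst_invalid_argument")
})

test_that("degenerate-MAD electrodes are skipped rather than flooded", {
  p <- detection_params()
  x <- rep(0, 5000); x[2500] <- -10
  thr <- estimate_threshold(x, p)
  expect_true(thr$degenerate)
  sp <- detect_spikes(x, fs, thr, p)
  expect_length(sp$spike_times, 0)
})
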