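# Synthetic session generator: layout geometry, ground-truth spike trains,
# trace synthesis, determinism, and the statistical structure the
# downstream analysis assumes.

test_that("layout groups electrodes into 3x3 recording units", {
  lay1 <- generate_layout(1)
  expect_equal(nrow(lay1), 9L)
  expect_true(all(lay1$unit_id == 0L))

  lay <- generate_layout(110)
  expect_equal(nrow(lay), 990L)
  expect_equal(length(unique(lay$unit_id)), 110L)
  counts <- table(lay$unit_id)
  expect_true(all(counts == 9L))
  # positions within a unit mutually distinct
  for (u in c(0, 57, 109)) {
    p <- lay[lay$unit_id == u, c("x", "y")]
    expect_equal(nrow(unique(p)), 9L)
  }
  expect_identical(generate_layout(4, seed = 3), generate_layout(4, seed = 3))
  expect_error(generate_layout(0), class = "meaburst_invalid_argument")
  expect_error(generate_layout(2, pitch = -1), class = "meaburst_invalid_argument")
})

test_that("zero-rate population produces empty spike trains", {
  lay <- generate_layout(4)
  spec <- activity_spec(baseline_rate = 0, burst_rate_pre = 0,
                        burst_rate_in = 0, burst_rate_post = 0,
                        stim_response_prob = 0, inactive_frac = 0)
  pop <- generate_population(lay, spec = spec, periods_min = c(1, 1, 1), seed = 1)
  expect_true(all(lengths(pop$truth$spike_times) == 0L))
})

test_that("stimulation log covers the stimulation period at the pulse rate", {
  lay <- generate_layout(2)
  pop <- generate_population(lay, periods_min = c(2, 30, 2), seed = 4)
  expect_equal(nrow(pop$stim), 360L)  # 0.2 Hz x 1800 s
  expect_true(all(diff(pop$stim$onset) > 0))
  expect_equal(pop$stim$offset - pop$stim$onset, rep(0.005, 360))
  expect_true(all(pop$stim$onset >= pop$periods[2] &
                    pop$stim$offset <= pop$periods[3]))
})

test_that("burst leaders precede all other members by the propagation delay", {
  lay <- generate_layout(8)
  spec <- activity_spec(baseline_rate = 0, stim_response_prob = 0,
                        burst_rate_pre = 12, burst_rate_in = 12,
                        burst_rate_post = 12, inactive_frac = 0,
                        leader_ids = 3L, propagation_delay = 0.005,
                        participation_pre = 1, participation_in = 1,
                        participation_post = 1)
  pop <- generate_population(lay, spec = spec, periods_min = c(1, 1, 1), seed = 9)
  be <- pop$truth$burst_events
  expect_gt(length(be$onset), 5L)
  for (k in seq_along(be$onset)) {
    expect_identical(be$leader[k], 3L)
    first_by <- vapply(be$members[[k]], function(m) {
      tt <- pop$truth$spike_times[[m]]
      min(c(tt[tt >= be$onset[k]], Inf))  # Inf if truncated at session end
    }, 0)
    lead_first <- first_by[match(3L, be$members[[k]])]
    others <- first_by[be$members[[k]] != 3L]
    expect_true(all(others >= lead_first + 0.005 - 1e-12))
    # designated leader is the argmin of member first-spike times
    expect_equal(be$members[[k]][which.min(first_by)], 3L)
  }
})

test_that("initially inactive neurons are silent before stimulation onset", {
  lay <- generate_layout(10)
  pop <- generate_population(lay, periods_min = c(2, 2, 2), seed = 11)
  t_in <- pop$periods[2]
  for (i in pop$truth$inactive_ids)
    expect_true(all(pop$truth$spike_times[[i]] >= t_in))
  # and generated trains respect the refractory floor
  for (tt in pop$truth$spike_times)
    if (length(tt) > 1L) expect_true(all(diff(tt) >= 0.0025 - 1e-12))
})

test_that("trace synthesis superposes templates, noise and artifact", {
  lay <- generate_layout(2)
  spec0 <- activity_spec(baseline_rate = 0, burst_rate_pre = 0,
                         burst_rate_in = 0, burst_rate_post = 0,
                         stim_response_prob = 0, inactive_frac = 0)
  pop <- generate_population(lay, spec = spec0, periods_min = c(0.1, 0.1, 0.1),
                             seed = 2)
  # no spikes, no noise, no artifact -> all-zero traces
  rec0 <- synthesize_recording(pop$templates, pop$truth, pop$stim[0, ],
                               pop$periods, lay, noise_sd = 0,
                               artifact_amp = 0, seed = 2)
  expect_true(all(collect_traces(rec0) == 0))

  # one spike: minimum of the peak electrode lands within 1 ms of the spike
  truth1 <- pop$truth
  truth1$spike_times[[1]] <- 3.0
  rec1 <- synthesize_recording(pop$templates, truth1, pop$stim[0, ],
                               pop$periods, lay, noise_sd = 0,
                               artifact_amp = 0, seed = 2)
  tr <- get_trace(rec1, pop$templates[[1]]$peak_electrode)
  expect_lt(abs((which.min(tr) - 1) / 20000 - 3.0), 0.001)
  expect_equal(min(tr), -pop$templates[[1]]$amplitude, tolerance = 1e-6)

  # artifact alone: per-pulse extreme equals artifact_amp at the pulse end
  rec2 <- synthesize_recording(pop$templates, pop$truth, pop$stim,
                               pop$periods, lay, noise_sd = 0,
                               artifact_amp = 200, seed = 2)
  tr2 <- get_trace(rec2, 0)
  fs <- 20000
  for (k in seq_len(nrow(pop$stim))) {
    i0 <- round(pop$stim$onset[k] * fs) + 1
    i1 <- round(pop$stim$offset[k] * fs) + 1
    seg <- tr2[i0:i1]
    expect_equal(max(abs(seg)), 200)
    expect_equal(which.max(abs(seg)), length(seg))  # at the boundary
  }
})

test_that("lazy and materialised recordings agree and are seed-deterministic", {
  s1 <- small_session(seed = 21, n_units = 2, periods_min = c(2, 3, 2) / 60)
  s2 <- small_session(seed = 21, n_units = 2, periods_min = c(2, 3, 2) / 60)
  expect_identical(collect_traces(s1$recording), collect_traces(s2$recording))
  expect_identical(s1$truth, s2$truth)
  rec_lazy <- synthesize_recording(s1$templates, s1$truth, s1$stim,
                                   s1$periods, s1$layout, seed = 21,
                                   materialize = FALSE)
  expect_null(rec_lazy$traces)
  for (e in c(0, 8, 17))
    expect_identical(get_trace(rec_lazy, e), get_trace(s1$recording, e))
})

test_that("template insertions conserve the ground-truth spike count", {
  lay <- generate_layout(1)
  spec <- activity_spec(baseline_rate = 2, burst_rate_pre = 0,
                        burst_rate_in = 0, burst_rate_post = 0,
                        stim_response_prob = 0, inactive_frac = 0)
  pop <- generate_population(lay, spec = spec, periods_min = c(0.5, 0.5, 0.5),
                             seed = 31)
  rec <- synthesize_recording(pop$templates, pop$truth, pop$stim[0, ],
                              pop$periods, lay, noise_sd = 0, artifact_amp = 0,
                              seed = 31)
  tr <- get_trace(rec, pop$templates[[1]]$peak_electrode)
  amp <- pop$templates[[1]]$amplitude
  # noise-free, well-separated spikes: one deep minimum per insertion
  n_min <- sum(tr < -amp / 2 & tr <= c(Inf, head(tr, -1)) &
                 tr < c(tail(tr, -1), Inf))
  expect_equal(n_min, length(pop$truth$spike_times[[1]]))
})

test_that("baseline spike counts behave like a Poisson process", {
  lay <- generate_layout(1)
  rate <- 2; t_tot <- 180
  ok <- 0L; n_tot <- 0L
  for (seed in 1:3) {
    spec <- activity_spec(baseline_rate = rate, burst_rate_pre = 0,
                          burst_rate_in = 0, burst_rate_post = 0,
                          stim_response_prob = 0, inactive_frac = 0,
                          refractory = 1e-6)
    pop <- generate_population(lay, n_neurons = 40, spec = spec,
                               periods_min = c(1, 1, 1), seed = seed)
    counts <- lengths(pop$truth$spike_times)
    lam <- rate * t_tot
    ok <- ok + sum(abs(counts - lam) <= 4 * sqrt(lam))
    n_tot <- n_tot + length(counts)
  }
  expect_gte(ok / n_tot, 0.99)
})

test_that("colocalization point generator honours its contract", {
  g0 <- generate_colocalization_points(10, 0, 0, seed = 1)
  expect_equal(nrow(g0$marker), 0L)
  expect_equal(nrow(g0$nuclei), 10L)

  g1 <- generate_colocalization_points(50, 50, 1, jitter_sd = 0, seed = 2)
  d <- vapply(seq_len(50), function(i)
    min(sqrt((g1$nuclei$x[i] - g1$marker$x)^2 +
               (g1$nuclei$y[i] - g1$marker$y)^2)), 0)
  expect_true(all(d < 1e-9))

  expect_error(generate_colocalization_points(10, 2, 0.5),
               class = "meaburst_invalid_argument")
  g2 <- generate_colocalization_points(100, 100, 0.5, seed = 3)
  g3 <- generate_colocalization_points(100, 100, 0.5, seed = 3)
  expect_identical(g2, g3)
})
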