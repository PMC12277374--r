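# Network burst detection on the pooled raster, initiator attribution,
# propagation order, and the initiation-point map.

test_that("burst criterion is strict and merges overlapping windows", {
  p <- burst_params(window = 0.100, min_spikes = 50)
  # 60 spikes uniformly inside 50 ms -> one burst holding all 60
  t1 <- seq(2.000, 2.050, length.out = 60)
  b1 <- detect_bursts(list(t1), p)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$spike_count, 60L)
  expect_equal(b1$onset, 2.000)
  expect_equal(b1$offset, 2.050)

  # exactly 50 spikes in 100 ms: not a burst (strict >)
  t2 <- seq(1, 1.1, length.out = 50)
  expect_equal(nrow(detect_bursts(list(t2), p)), 0L)

  # two packets 1 s apart -> two bursts
  t3 <- c(seq(0.5, 0.55, length.out = 60), seq(1.5, 1.55, length.out = 60))
  b3 <- detect_bursts(list(t3), p)
  expect_equal(nrow(b3), 2L)
  expect_equal(b3$spike_count, c(60L, 60L))
})

test_that("burst detection equals the exhaustive windowed-count oracle", {
  p <- burst_params(window = 0.100, min_spikes = 20)
  set.seed(31)
  for (rep in 1:40) {
    # random rasters mixing background with dense packets
    n_bg <- sample(50:300, 1)
    tt <- runif(n_bg, 0, 30)
    for (k in seq_len(sample(0:4, 1))) {
      c0 <- runif(1, 1, 29)
      tt <- c(tt, c0 + sort(runif(sample(15:60, 1), 0, 0.08)))
    }
    tt <- sort(tt)
    got <- as.data.frame(detect_bursts(list(tt), p))
    want <- oracle_bursts(tt, p$window, p$min_spikes)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$onset, want$onset)
      expect_equal(got$offset, want$offset)
      expect_equal(got$spike_count, want$spike_count)
    }
  }
})

test_that("per-cluster mode applies the criterion to single trains", {
  p <- burst_params(min_spikes = 10, mode = "per-cluster")
  quiet <- seq(0, 29, by = 1)
  busy <- c(seq(5, 5.05, length.out = 30), seq(0, 29, by = 2))
  b <- detect_bursts(list(quiet, sort(busy)), p)
  expect_true(all(b$cluster_id == 2L))
  expect_equal(nrow(b), 1L)
})

test_that("initiator is the cluster with the earliest post-onset spike", {
  p <- burst_params(min_spikes = 10)
  # cluster A leads at the onset, B follows 4 ms later
  a <- c(10.000, 10.010 + (0:10) * 0.002)
  b <- c(10.004, 10.011 + (0:10) * 0.002)
  bursts <- data.frame(onset = 10.000, offset = 10.05, spike_count = 24L)
  class(bursts) <- c("mea_bursts", "data.frame")
  at <- attribute_initiators(bursts, list(a, b), p)
  expect_equal(at$bursts$initiator, 1L)
  expect_equal(at$bursts$initiator_first_spike, 10.000)
  expect_equal(at$bursts$n_participants, 2L)

  # tie at the onset resolves to the lowest cluster id
  at2 <- attribute_initiators(bursts, list(b, a, a), p)
  expect_equal(at2$bursts$initiator, 2L)

  # a burst window holding no spikes is impossible input: guarded
  empty_burst <- data.frame(onset = 50, offset = 50.1, spike_count = 60L)
  expect_error(attribute_initiators(empty_burst, list(a, b), p),
               class = "meaburst_attribution_impossible")
})

test_that("initiator table needs three or more bursts and conserves counts", {
  p <- burst_params(min_spikes = 5)
  mk_packet <- function(t0, lead_first = TRUE)
    if (lead_first) t0 + (0:8) * 0.005 else t0 + 0.002 + (0:8) * 0.005
  # cluster 1 initiates 3 bursts, cluster 2 initiates 2
  t_a <- c(mk_packet(1), mk_packet(5), mk_packet(9), mk_packet(13, FALSE),
           mk_packet(17, FALSE))
  t_b <- c(mk_packet(1, FALSE), mk_packet(5, FALSE), mk_packet(9, FALSE),
           mk_packet(13), mk_packet(17))
  bursts <- detect_bursts(list(t_a, t_b), p)
  expect_equal(nrow(bursts), 5L)
  at <- attribute_initiators(bursts, list(sort(t_a), sort(t_b)), p)
  expect_equal(at$initiator_table$cluster_id, 1L)
  expect_equal(at$initiator_table$n_initiated, 3L)
  expect_equal(sum(at$initiation_counts$n_initiated), nrow(bursts))
  expect_equal(at$bursts$below_threshold, c(F, F, F, T, T))
})

test_that("propagation order sorts participants by first post-onset spike", {
  burst <- data.frame(onset = 1.0, offset = 1.1)
  cl <- list(1.0 + (0:5) * 0.02, 1.005 + (0:5) * 0.02, 1.010 + (0:5) * 0.02)
  po <- propagation_order(burst, cl)
  expect_equal(po$cluster_id, c(1L, 2L, 3L))
  expect_true(!is.unsorted(po$first_spike))

  # identical orders correlate at 1, reversed orders at -1
  b2 <- data.frame(onset = 5.0, offset = 5.1)
  cl5 <- lapply(0:4, function(k) c(1.0 + k * 0.005, 5.0 + (4 - k) * 0.005))
  po_a <- propagation_order(data.frame(onset = 1.0, offset = 1.1), cl5)
  po_b <- propagation_order(b2, cl5)
  po_a2 <- propagation_order(data.frame(onset = 1.0, offset = 1.1), cl5)
  expect_equal(propagation_similarity(po_a, po_a2), 1.0)
  expect_equal(propagation_similarity(po_a, po_b), -1.0)
})

test_that("initiation map counts bursts per unit and period", {
  lay <- generate_layout(4)
  cl <- lapply(1:3, function(i)
    structure(list(cluster_id = i, unit_id = i - 1L, spike_times = numeric(0)),
              class = "waveform_cluster"))
  bursts <- data.frame(onset = c(10, 50, 70, 130, 200, 210),
                       offset = c(10, 50, 70, 130, 200, 210) + 0.1,
                       spike_count = 60L,
                       initiator = c(1L, 1L, 2L, 1L, 3L, 3L))
  periods <- c(0, 60, 180, 240)
  m <- initiation_point_map(bursts, cl, lay, periods)
  expect_equal(m$n_initiated[m$unit_id == 0 & m$period == "pre"], 2L)
  expect_equal(m$n_initiated[m$unit_id == 1 & m$period == "in"], 1L)
  expect_equal(m$n_initiated[m$unit_id == 0 & m$period == "in"], 1L)
  expect_equal(m$n_initiated[m$unit_id == 2 & m$period == "post"], 2L)
  # no spurious rows for empty combinations
  expect_false(any(m$period == "in" & m$unit_id == 2))
  expect_false(any(m$period == "pre" & m$unit_id == 1))
  # distinct initiation points per period: 1 before, 2 during stimulation
  expect_equal(length(unique(m$unit_id[m$period == "pre"])), 1L)
  expect_equal(length(unique(m$unit_id[m$period == "in"])), 2L)
})

test_that("more leaders during stimulation raise the initiation-point count", {
  lay <- generate_layout(6)
  spec <- activity_spec(baseline_rate = 0, stim_response_prob = 0,
                        burst_rate_pre = 4, burst_rate_in = 4,
                        burst_rate_post = 0,
                        inactive_ids = 2L, leader_ids = c(1L, 2L),
                        participation_pre = 1, participation_in = 1,
                        within_burst_spikes = 10L)
  pop <- generate_population(lay, spec = spec, periods_min = c(2, 2, 0.5),
                             seed = 41)
  bursts <- detect_bursts(pop$truth$spike_times,
                          burst_params(min_spikes = 20))
  at <- attribute_initiators(bursts, pop$truth$spike_times,
                             burst_params(min_spikes = 20,
                                          min_bursts_for_initiator = 1))
  cl <- lapply(seq_along(pop$truth$spike_times), function(i)
    structure(list(cluster_id = i, unit_id = pop$templates[[i]]$home_unit,
                   spike_times = pop$truth$spike_times[[i]]),
              class = "waveform_cluster"))
  m <- initiation_point_map(at$bursts, cl, lay, pop$periods)
  n_pre <- length(unique(m$unit_id[m$period == "pre"]))
  n_in <- length(unique(m$unit_id[m$period == "in"]))
  expect_equal(n_pre, 1L)  # only leader 1 is active before stimulation
  expect_equal(n_in, 2L)   # leader 2 joins once stimulation recruits it
})
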