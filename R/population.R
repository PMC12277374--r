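# Neuron templates, ground-truth spike trains, and the stimulation log.

# biphasic (negative-then-positive) difference-of-Gaussians spike shape,
# 41 samples at 20 kHz, peak-normalised to -1 at the centre sample
spike_shape <- function(neg_width_ms = 0.20, pos_width_ms = 0.35,
                        pos_frac = 0.55, sampling_rate = 20000) {
  t <- ((-20):20) / sampling_rate * 1000
  w <- -exp(-((t + 0.05) / neg_width_ms)^2) +
    pos_frac * exp(-((t - 0.45) / pos_width_ms)^2)
  w / abs(min(w))  # length 41, min exactly -1 near the centre sample
}

make_template <- function(neuron_id, layout, home_unit, amplitude,
                          peak_electrode = NULL) {
  el <- layout[layout$unit_id == home_unit, , drop = FALSE]
  el <- el[order(el$electrode_id), , drop = FALSE]
  if (is.null(peak_electrode)) peak_electrode <- el$electrode_id[5]  # centre
  p <- el[el$electrode_id == peak_electrode, ]
  d <- sqrt((el$x - p$x)^2 + (el$y - p$y)^2)
  amap <- exp(-d / attr(layout, "pitch"))
  amap <- amap / max(amap)
  # mild per-neuron shape variation so distinct neurons are separable
  shp <- spike_shape(neg_width_ms = 0.20 * (1 + 0.15 * ((neuron_id * 7) %% 5 - 2) / 2),
                     pos_frac = 0.45 + 0.05 * ((neuron_id * 3) %% 4))
  wf <- outer(amap * amplitude, shp)  # 9 x 41, uV
  list(neuron_id = neuron_id, home_unit = home_unit,
       electrode_ids = el$electrode_id, amplitude_map = amap,
       peak_electrode = peak_electrode, amplitude = amplitude, waveform = wf)
}

# Poisson event times on [t0, t1), optionally with a minimum separation
poisson_times <- function(rate, t0, t1, min_gap = 0) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- rpois(1L, rate * (t1 - t0))
  if (n == 0L) return(numeric(0))
  tt <- sort(runif(n, t0, t1))
  if (min_gap > 0 && length(tt) > 1L) {
    keep <- rep(TRUE, length(tt)); last <- tt[1L]
    for (i in seq_along(tt)[-1L]) {
      if (tt[i] - last < min_gap) keep[i] <- FALSE else last <- tt[i]
    }
    tt <- tt[keep]
  }
  tt
}

# greedy keep-first minimum-ISI rule
enforce_refractory <- function(times, refractory) {
  if (length(times) < 2L) return(times)
  keep <- rep(TRUE, length(times)); last <- times[1L]
  for (i in seq_along(times)[-1L]) {
    if (times[i] - last < refractory) keep[i] <- FALSE else last <- times[i]
  }
  times[keep]
}

#' Generate a synthetic neuronal population with ground-truth spike trains
#'
#' Builds per-neuron multi-electrode spike templates, draws baseline Poisson
#' spike trains, inserts network bursts led by designated initiator neurons,
#' adds stimulation-locked responses during the stimulation period, and
#' returns the stimulation log. Neurons in the inactive set emit no spikes
#' before stimulation onset and fire at the baseline rate from then on, so
#' stimulation both recruits silent neurons and raises network burst rates.
#'
#' @param layout an `mea_layout` from [generate_layout()].
#' @param n_neurons number of neurons; by default one per recording unit
#'   (neuron i lives on unit `(i - 1) %% n_units`).
#' @param spec an [activity_spec()].
#' @param periods_min session period durations (pre, stimulation, post) in
#'   minutes; default the full 20/30/20-min session.
#' @param stim_rate_hz,pulse_width_s optical pulse rate and width; defaults
#'   0.2 Hz and 5 ms.
#' @param amplitude_range per-neuron spike peak amplitude range, uV.
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with `templates` (list of per-neuron templates), `truth`
#'   (class `mea_ground_truth`: `spike_times` list, `burst_events`,
#'   `artifact_windows`, `leader_ids`, `inactive_ids`), `stim` (class
#'   `mea_stim_log`), and `periods` (boundaries in s, length 4).
#' @export
generate_population <- function(layout, n_neurons = NULL,
                                spec = activity_spec(),
                                periods_min = c(20, 30, 20),
                                stim_rate_hz = 0.2, pulse_width_s = 0.005,
                                amplitude_range = c(50, 120), seed = 1L) {
  if (!inherits(layout, "mea_layout")) stop_invalid("layout must be an mea_layout")
  if (!inherits(spec, "activity_spec")) stop_invalid("spec must be an activity_spec")
  if (spec$propagation_delay < 0) stop_invalid("propagation_delay must be >= 0")
  if (length(periods_min) != 3L || any(periods_min <= 0))
    stop_invalid("periods_min must be three positive durations")
  n_units <- length(unique(layout$unit_id))
  if (is.null(n_neurons)) n_neurons <- n_units
  check_scalar(n_neurons, "n_neurons", positive = TRUE, integerish = TRUE)
  n_neurons <- as.integer(n_neurons)

  periods <- c(0, cumsum(periods_min * 60))
  t_in <- periods[2]; t_post <- periods[3]; t_end <- periods[4]
  set.seed(sub_seed(seed, 1))

  ids <- seq_len(n_neurons)
  home <- (ids - 1L) %% n_units
  amp <- runif(n_neurons, amplitude_range[1], amplitude_range[2])
  templates <- lapply(ids, function(i) make_template(i, layout, home[i], amp[i]))

  # inactive + leader assignment
  inactive <- spec$inactive_ids
  if (is.null(inactive)) {
    k <- round(spec$inactive_frac * n_neurons)
    inactive <- if (k > 0) sort(sample(ids, k)) else integer(0)
  }
  inactive <- as.integer(inactive)
  if (length(setdiff(inactive, ids)))
    stop_invalid("inactive_ids must be a subset of neuron ids")
  leaders <- spec$leader_ids
  if (is.null(leaders)) {
    active <- setdiff(ids, inactive)
    n_lead <- min(spec$n_leaders, n_neurons)
    n_pre <- min(1L, length(active))
    lead_pre <- if (n_pre) sample(active, n_pre) else integer(0)
    pool <- if (length(inactive)) inactive else setdiff(active, lead_pre)
    lead_new <- if (n_lead > n_pre && length(pool))
      sample(pool, min(n_lead - n_pre, length(pool))) else integer(0)
    leaders <- sort(c(lead_pre, lead_new))
  }
  leaders <- as.integer(leaders)
  if (length(setdiff(leaders, ids)))
    stop_invalid("leader_ids must be a subset of neuron ids")

  active_at <- function(id, t) !(id %in% inactive) || t >= t_in

  # stimulation log: pulses at stim_rate_hz throughout the "in" period
  n_pulse <- floor((t_post - t_in) * stim_rate_hz)
  onsets <- if (n_pulse > 0) t_in + (seq_len(n_pulse) - 1L) / stim_rate_hz else numeric(0)
  stim <- data.frame(onset = onsets, offset = onsets + pulse_width_s,
                     target = if (n_pulse > 0) ids[(seq_len(n_pulse) - 1L) %% n_neurons + 1L]
                              else integer(0))
  attr(stim, "pulse_width") <- pulse_width_s
  attr(stim, "rate") <- stim_rate_hz
  class(stim) <- c("mea_stim_log", "data.frame")

  # network bursts: Poisson onsets per period, round-robin leaders among
  # those active at onset, fixed per-leader propagation order by distance
  upos <- unique(layout[, c("unit_id", "unit_x", "unit_y")])
  ux <- upos$unit_x[match(home, upos$unit_id)]
  uy <- upos$unit_y[match(home, upos$unit_id)]
  prop_order <- lapply(ids, function(l)
    ids[order((ux - ux[l])^2 + (uy - uy[l])^2, ids)])
  burst_rates <- c(spec$burst_rate_pre, spec$burst_rate_in, spec$burst_rate_post) / 60
  particip <- c(spec$participation_pre, spec$participation_in, spec$participation_post)

  burst_spikes <- vector("list", n_neurons)
  burst_onset <- numeric(0); burst_leader <- integer(0); burst_members <- list()
  for (p in 1:3) {
    onset_p <- poisson_times(burst_rates[p], periods[p], periods[p + 1], min_gap = 2)
    for (o in onset_p) {
      lead_ok <- leaders[vapply(leaders, active_at, logical(1), t = o)]
      if (!length(lead_ok)) next
      l <- lead_ok[(length(burst_onset) %% length(lead_ok)) + 1L]
      others <- setdiff(ids[vapply(ids, active_at, logical(1), t = o)], l)
      # recruit a fixed fraction of the whole population (capped by the
      # neurons active at onset) so per-burst participation percentages
      # track the participation parameters directly
      k <- min(length(others), round(particip[p] * (n_neurons - 1L)))
      mem <- if (k > 0) sample(others, k) else integer(0)
      mem_ord <- prop_order[[l]][prop_order[[l]] %in% c(l, mem)]
      for (r in seq_along(mem_ord)) {
        m <- mem_ord[r]
        tt <- o + (r - 1L) * spec$propagation_delay +
          (seq_len(spec$within_burst_spikes) - 1L) * spec$within_burst_isi
        burst_spikes[[m]] <- c(burst_spikes[[m]], tt[tt < t_end])
      }
      burst_onset <- c(burst_onset, o)
      burst_leader <- c(burst_leader, l)
      burst_members <- c(burst_members, list(mem_ord))
    }
  }

  # evoked responses to pulses
  evoked <- vector("list", n_neurons)
  if (n_pulse > 0) {
    hit <- runif(n_pulse) < spec$stim_response_prob
    lat <- spec$response_latency + abs(rnorm(n_pulse, 0, spec$response_jitter))
    for (k in which(hit)) {
      tg <- stim$target[k]
      evoked[[tg]] <- c(evoked[[tg]], stim$onset[k] + lat[k])
    }
  }

  spike_times <- vector("list", n_neurons)
  for (i in ids) {
    t0 <- if (i %in% inactive) t_in else 0
    base <- poisson_times(spec$baseline_rate, t0, t_end)
    tt <- sort(c(base, burst_spikes[[i]], evoked[[i]]))
    tt <- tt[tt >= t0 & tt < t_end]
    spike_times[[i]] <- enforce_refractory(tt, spec$refractory)
  }

  truth <- structure(list(
    spike_times = spike_times,
    burst_events = list(onset = burst_onset, leader = burst_leader,
                        members = burst_members),
    artifact_windows = stim[, c("onset", "offset")],
    leader_ids = leaders, inactive_ids = inactive
  ), class = "mea_ground_truth")

  list(templates = templates, truth = truth, stim = stim, periods = periods)
}
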