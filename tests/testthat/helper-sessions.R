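# Shared session fixtures, built in code. The full-scale acceptance session
# (2/3/2 min, 20 units) is expensive, so it is computed once per test run
# and cached in this environment for reuse across test blocks.

.session_cache <- new.env(parent = emptyenv())

# a 2/3/2-min, 20-unit session at the generator's default study conditions,
# analysed end to end; returns list(session, analysis)
acceptance_session <- function() {
  if (!is.null(.session_cache$big)) return(.session_cache$big)
  s <- simulate_session(n_units = 20, periods_min = c(2, 3, 2), seed = 101,
                        materialize = FALSE)
  a <- analyze_session(s$recording, seed = 101)
  .session_cache$big <- list(session = s, analysis = a)
  .session_cache$big
}

# small, fast session for smoke tests (materialised traces)
small_session <- function(seed = 7, n_units = 3, periods_min = c(20, 30, 20) / 60,
                          spec = activity_spec()) {
  simulate_session(n_units = n_units, periods_min = periods_min, spec = spec,
                   seed = seed, materialize = TRUE)
}

# per-neuron ground-truth spike times with artifact-window spikes removed,
# the reference the detector is scored against
truth_after_exclusion <- function(session) {
  lapply(session$truth$spike_times, function(tt)
    exclude_artifact_spikes(tt, session$stim))
}

# flattened multi-electrode waveform fixtures for two synthetic neurons on
# one unit, with additive Gaussian noise (in the filtered-trace scale)
two_template_waveforms <- function(n_each = 300, noise_sd = 3, seed = 5,
                                   amp = c(60, 130)) {
  lay <- generate_layout(1)
  spec <- activity_spec()
  pop <- generate_population(lay, n_neurons = 2, spec = spec,
                             periods_min = c(1, 1, 1), seed = seed,
                             amplitude_range = c(60, 60))
  w1 <- as.vector(t(pop$templates[[1]]$waveform / 60 * amp[1]))
  w2 <- as.vector(t(pop$templates[[2]]$waveform / 60 * amp[2]))
  set.seed(seed)
  wf <- rbind(
    matrix(rep(w1, each = n_each), n_each) + rnorm(n_each * length(w1), 0, noise_sd),
    matrix(rep(w2, each = n_each), n_each) + rnorm(n_each * length(w2), 0, noise_sd))
  list(waveforms = wf, truth = rep(1:2, each = n_each))
}
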