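#' Activity specification for the synthetic session generator
#'
#' Bundles the firing-regime parameters the simulator uses: low spontaneous
#' (baseline) firing, stimulation-locked responses, network bursts led by
#' designated initiator neurons, and a subset of neurons that are silent
#' before stimulation and become (and stay) active once stimulation starts.
#'
#' Defaults encode the study conditions the pipeline is meant to emulate:
#' spinal cultures with low baseline rates (0.5 Hz), burst rates of
#' 0.5/6/4 per minute in the pre/stimulation/post periods (programmed fold
#' changes of 12 and 8), 38% of neurons inactive before stimulation, and
#' per-burst recruitment fractions of 0.45/0.30/0.35.
#'
#' @param baseline_rate spontaneous rate, Hz, per active neuron.
#' @param stim_response_prob probability that a stimulation pulse evokes a
#'   spike in its target neuron.
#' @param burst_rate_pre,burst_rate_in,burst_rate_post network burst rates,
#'   bursts per minute, per session period.
#' @param leader_ids integer ids of designated burst initiators, or `NULL` to
#'   let [generate_population()] choose (one pre-active leader plus leaders
#'   drawn from the initially inactive set, so initiation points increase
#'   during stimulation).
#' @param n_leaders number of leaders chosen when `leader_ids` is `NULL`.
#' @param propagation_delay s between successive members' first spikes within
#'   a burst.
#' @param within_burst_spikes spikes each participating neuron fires per burst.
#' @param within_burst_isi s between a member's successive burst spikes.
#' @param inactive_ids ids of neurons with zero pre-stimulation rate, or
#'   `NULL` to sample `round(inactive_frac * n)` of them.
#' @param inactive_frac fraction of neurons initially inactive when
#'   `inactive_ids` is `NULL`.
#' @param participation_pre,participation_in,participation_post fraction of
#'   active non-leader neurons recruited into each burst, per period.
#' @param response_latency,response_jitter s; evoked spikes follow pulse onset
#'   by `response_latency + |N(0, response_jitter)|`.
#' @param refractory minimum inter-spike interval enforced in generated
#'   trains, s.
#' @return a list of class `activity_spec`.
#' @export
activity_spec <- function(baseline_rate = 0.5,
                          stim_response_prob = 0.6,
                          burst_rate_pre = 0.5,
                          burst_rate_in = 6,
                          burst_rate_post = 4,
                          leader_ids = NULL,
                          n_leaders = 6L,
                          propagation_delay = 0.005,
                          within_burst_spikes = 6L,
                          within_burst_isi = 0.003,
                          inactive_ids = NULL,
                          inactive_frac = 0.38,
                          participation_pre = 0.45,
                          participation_in = 0.30,
                          participation_post = 0.35,
                          response_latency = 0.004,
                          response_jitter = 0.001,
                          refractory = 0.0025) {
  check_scalar(baseline_rate, "baseline_rate", nonneg = TRUE)
  check_scalar(stim_response_prob, "stim_response_prob", nonneg = TRUE)
  if (stim_response_prob > 1) stop_invalid("stim_response_prob must be <= 1")
  for (nm in c("burst_rate_pre", "burst_rate_in", "burst_rate_post"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  check_scalar(propagation_delay, "propagation_delay", nonneg = TRUE)
  check_scalar(within_burst_spikes, "within_burst_spikes", positive = TRUE,
               integerish = TRUE)
  check_scalar(within_burst_isi, "within_burst_isi", positive = TRUE)
  check_scalar(inactive_frac, "inactive_frac", nonneg = TRUE)
  if (inactive_frac > 1) stop_invalid("inactive_frac must be <= 1")
  check_scalar(refractory, "refractory", positive = TRUE)

  structure(list(
    baseline_rate = baseline_rate,
    stim_response_prob = stim_response_prob,
    burst_rate_pre = burst_rate_pre,
    burst_rate_in = burst_rate_in,
    burst_rate_post = burst_rate_post,
    leader_ids = leader_ids,
    n_leaders = as.integer(n_leaders),
    propagation_delay = propagation_delay,
    within_burst_spikes = as.integer(within_burst_spikes),
    within_burst_isi = within_burst_isi,
    inactive_ids = inactive_ids,
    inactive_frac = inactive_frac,
    participation_pre = participation_pre,
    participation_in = participation_in,
    participation_post = participation_post,
    response_latency = response_latency,
    response_jitter = response_jitter,
    refractory = refractory
  ), class = "activity_spec")
}
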