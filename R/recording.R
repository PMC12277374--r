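# Trace synthesis and recording container.
#
# A recording can hold its traces in memory (small sessions) or synthesise
# them per electrode on demand (large sessions), so a full 20/30/20-min,
# 110-unit session never has to exist as one matrix. Both paths produce
# bit-identical traces for a given seed: each electrode's noise stream is
# seeded from (seed, electrode_id) alone.

#' Synthesize an extracellular recording from templates and ground truth
#'
#' The trace of each electrode is the additive superposition of (a) every
#' neuron's template inserted at each of its spike times on the electrodes of
#' its home unit, (b) white Gaussian noise of standard deviation `noise_sd`,
#' and (c) for every stimulation pulse, a linear ramp of peak amplitude
#' `artifact_amp` spanning the pulse with step discontinuities at onset and
#' offset, applied to all electrodes with alternating polarity — the
#' monotonic reference-potential drift that optical stimulation imposes on
#' the amplifier, whose switching edges are what the artifact-exclusion
#' window must remove.
#'
#' @param templates,truth,stim,periods as returned by [generate_population()].
#' @param layout the `mea_layout` the templates were built on.
#' @param noise_sd noise standard deviation, uV (>= 0).
#' @param artifact_amp stimulation artifact peak amplitude, uV. The default
#'   30 uV keeps the bandpass ringing of the idealized step edges inside the
#'   +-1 ms exclusion window (see the package vignette).
#' @param sampling_rate Hz; fixed-format recordings use 20 kHz.
#' @param seed integer seed for the noise streams.
#' @param materialize force (`TRUE`)/suppress (`FALSE`) holding the full
#'   trace matrix in memory; default (`NULL`) materialises recordings up to
#'   3e7 total samples.
#' @return an object of class `mea_recording`; use [get_trace()] to access
#'   per-electrode traces and [collect_traces()] for the full matrix.
#' @export
synthesize_recording <- function(templates, truth, stim, periods, layout,
                                 noise_sd = 6, artifact_amp = 30,
                                 sampling_rate = 20000, seed = 1L,
                                 materialize = NULL) {
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(artifact_amp, "artifact_amp", nonneg = TRUE)
  if (!inherits(layout, "mea_layout")) stop_invalid("layout must be an mea_layout")
  for (tp in templates) {
    el <- layout$electrode_id[layout$unit_id == tp$home_unit]
    if (!setequal(tp$electrode_ids, el))
      stop(errorCondition(
        sprintf("template for neuron %d does not match unit %d electrodes",
                tp$neuron_id, tp$home_unit),
        class = c("meaburst_inconsistent_input", "error")))
  }
  n_samples <- as.integer(round(periods[length(periods)] * sampling_rate))
  rec <- structure(list(
    sampling_rate = sampling_rate, layout = layout, periods = periods,
    n_samples = n_samples, n_electrodes = nrow(layout),
    templates = templates, truth = truth, stim = stim,
    noise_sd = noise_sd, artifact_amp = artifact_amp, seed = seed,
    traces = NULL
  ), class = "mea_recording")
  if (is.null(materialize))
    materialize <- as.double(n_samples) * nrow(layout) <= 3e7
  if (materialize) {
    tr <- matrix(0, nrow(layout), n_samples)
    for (e in layout$electrode_id)
      tr[match(e, layout$electrode_id), ] <- synth_trace(rec, e)
    rec$traces <- tr
  }
  rec
}

# raw trace synthesis for one electrode (always available)
synth_trace <- function(rec, electrode_id) {
  n <- rec$n_samples; fs <- rec$sampling_rate
  tr <- if (rec$noise_sd > 0) {
    set.seed(sub_seed(rec$seed, 7L + electrode_id))
    rnorm(n, 0, rec$noise_sd)
  } else numeric(n)
  for (tp in rec$templates) {
    row <- match(electrode_id, tp$electrode_ids)
    if (is.na(row)) next
    w <- tp$waveform[row, ]
    centers <- round(rec$truth$spike_times[[tp$neuron_id]] * fs) + 1L
    for (cc in centers) {
      lo <- max(1L, cc - 20L); hi <- min(n, cc + 20L)
      if (lo > hi) next
      tr[lo:hi] <- tr[lo:hi] + w[(lo - cc + 21L):(hi - cc + 21L)]
    }
  }
  if (rec$artifact_amp > 0 && nrow(rec$stim) > 0) {
    sgn <- rep_len(c(1, -1), nrow(rec$stim))
    for (k in seq_len(nrow(rec$stim))) {
      i0 <- round(rec$stim$onset[k] * fs) + 1L
      i1 <- round(rec$stim$offset[k] * fs) + 1L
      if (i0 > n) next
      i1 <- min(i1, n)
      ramp <- seq(rec$artifact_amp / 2, rec$artifact_amp,
                  length.out = i1 - i0 + 1L)
      tr[i0:i1] <- tr[i0:i1] + sgn[k] * ramp
    }
  }
  tr
}

#' Extract one electrode's trace from a recording
#'
#' @param rec an `mea_recording`.
#' @param electrode_id electrode id (0-based, as in the layout).
#' @return numeric vector of length `rec$n_samples` (uV).
#' @export
get_trace <- function(rec, electrode_id) {
  row <- match(electrode_id, rec$layout$electrode_id)
  if (is.na(row)) stop_invalid("unknown electrode_id ", electrode_id)
  if (!is.null(rec$traces)) rec$traces[row, ] else synth_trace(rec, electrode_id)
}

#' Collect the full electrode-by-sample trace matrix
#'
#' @inheritParams get_trace
#' @export
collect_traces <- function(rec) {
  if (!is.null(rec$traces)) return(rec$traces)
  tr <- matrix(0, rec$n_electrodes, rec$n_samples)
  for (e in rec$layout$electrode_id)
    tr[match(e, rec$layout$electrode_id), ] <- synth_trace(rec, e)
  tr
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d electrodes (%d units), %.1f s at %g kHz%s\n",
              x$n_electrodes, length(unique(x$layout$unit_id)),
              x$n_samples / x$sampling_rate, x$sampling_rate / 1000,
              if (is.null(x$traces)) " [lazy traces]" else ""))
  cat(sprintf("  periods (s): %s; %d stimulation pulses\n",
              paste(x$periods, collapse = " / "), nrow(x$stim)))
  invisible(x)
}

# file IO ----------------------------------------------------------------

#' Write / read a recording as HDF5
#'
#' Datasets: `traces` (electrodes x samples, uV), `sampling_rate`, `periods`,
#' and the electrode table under `layout/`. Lazy recordings are materialised
#' electrode by electrode while writing.
#'
#' @param rec an `mea_recording`.
#' @param path output `.h5` path (overwritten).
#' @return `path`, invisibly; `read_recording_h5()` returns an
#'   `mea_recording` with in-memory traces.
#' @export
write_recording_h5 <- function(rec, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "traces", dims = c(rec$n_electrodes, rec$n_samples),
                         storage.mode = "double", chunk = c(1, min(rec$n_samples, 2^20)),
                         level = 0)
  for (e in rec$layout$electrode_id) {
    row <- match(e, rec$layout$electrode_id)
    rhdf5::h5write(matrix(get_trace(rec, e), 1), path, "traces",
                   index = list(row, NULL))
  }
  rhdf5::h5write(rec$sampling_rate, path, "sampling_rate")
  rhdf5::h5write(rec$periods, path, "periods")
  rhdf5::h5createGroup(path, "layout")
  for (cl in c("electrode_id", "x", "y", "unit_id", "unit_x", "unit_y"))
    rhdf5::h5write(rec$layout[[cl]], path, paste0("layout/", cl))
  rhdf5::h5write(attr(rec$layout, "pitch"), path, "layout/pitch")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_recording_h5
#' @export
read_recording_h5 <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  tr <- rhdf5::h5read(path, "traces")
  lay <- data.frame(
    electrode_id = as.integer(rhdf5::h5read(path, "layout/electrode_id")),
    x = as.numeric(rhdf5::h5read(path, "layout/x")),
    y = as.numeric(rhdf5::h5read(path, "layout/y")),
    unit_id = as.integer(rhdf5::h5read(path, "layout/unit_id")),
    unit_x = as.numeric(rhdf5::h5read(path, "layout/unit_x")),
    unit_y = as.numeric(rhdf5::h5read(path, "layout/unit_y")))
  attr(lay, "pitch") <- as.numeric(rhdf5::h5read(path, "layout/pitch"))
  class(lay) <- c("mea_layout", "data.frame")
  periods <- as.numeric(rhdf5::h5read(path, "periods"))
  rhdf5::h5closeAll()
  structure(list(
    sampling_rate = as.numeric(rhdf5::h5read(path, "sampling_rate")),
    layout = lay, periods = periods, n_samples = ncol(tr),
    n_electrodes = nrow(tr), templates = NULL, truth = NULL,
    stim = NULL, noise_sd = NA_real_, artifact_amp = NA_real_,
    seed = NA_integer_, traces = tr), class = "mea_recording")
}

#' Write / read a stimulation log as CSV
#'
#' Columns `onset`, `offset` (s) and `target` (neuron id, `NA` if unknown).
#' @param stim an `mea_stim_log` data.frame.
#' @param path CSV path.
#' @export
write_stim_csv <- function(stim, path) {
  write.csv(as.data.frame(stim)[, c("onset", "offset", "target")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_stim_csv
#' @export
read_stim_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  stim <- read.csv(path)
  if (!all(c("onset", "offset") %in% names(stim)))
    stop_invalid("stim CSV must have onset and offset columns")
  stim$onset <- as.numeric(stim$onset)
  stim$offset <- as.numeric(stim$offset)
  if (is.null(stim$target)) stim$target <- NA_integer_
  class(stim) <- c("mea_stim_log", "data.frame")
  stim
}

#' Write ground truth to CSV files
#'
#' `spikes.csv` holds (neuron_id, time_s); `bursts.csv` holds one row per
#' burst event with members joined by `;`.
#' @param truth an `mea_ground_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth_csv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- data.frame(
    neuron_id = rep(seq_along(truth$spike_times),
                    lengths(truth$spike_times)),
    time_s = unlist(truth$spike_times, use.names = FALSE))
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  be <- truth$burst_events
  bd <- data.frame(onset = be$onset, leader = be$leader,
                   members = vapply(be$members, paste, "", collapse = ";"))
  write.csv(bd, file.path(dir, "bursts.csv"), row.names = FALSE)
  invisible(dir)
}
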