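# End-to-end orchestration: in-memory analysis of a session, and the
# file-based `run` with config, logging and a reproducibility manifest.

#' Simulate a complete synthetic HD-MEA session
#'
#' Convenience wrapper chaining [generate_layout()],
#' [generate_population()] and [synthesize_recording()].
#'
#' @param n_units recording units (default 110, a full array session).
#' @param periods_min pre/stimulation/post durations, minutes.
#' @param spec an [activity_spec()].
#' @param n_neurons neurons (default one per unit).
#' @param noise_sd,artifact_amp see [synthesize_recording()].
#' @param pitch electrode pitch, um.
#' @param seed integer seed.
#' @param materialize see [synthesize_recording()].
#' @return list of class `mea_session`: `recording`, `stim`, `truth`,
#'   `templates`, `layout`, `periods`.
#' @export
simulate_session <- function(n_units = 110L, periods_min = c(20, 30, 20),
                             spec = activity_spec(), n_neurons = NULL,
                             noise_sd = 6, artifact_amp = 30, pitch = 17.5,
                             seed = 1L, materialize = NULL) {
  layout <- generate_layout(n_units, pitch = pitch, seed = seed)
  pop <- generate_population(layout, n_neurons = n_neurons, spec = spec,
                             periods_min = periods_min, seed = seed)
  rec <- synthesize_recording(pop$templates, pop$truth, pop$stim, pop$periods,
                              layout, noise_sd = noise_sd,
                              artifact_amp = artifact_amp, seed = seed,
                              materialize = materialize)
  structure(list(recording = rec, stim = pop$stim, truth = pop$truth,
                 templates = pop$templates, layout = layout,
                 periods = pop$periods), class = "mea_session")
}

#' @export
print.mea_session <- function(x, ...) {
  cat("<mea_session>\n")
  print(x$recording)
  cat(sprintf("  %d neurons, %d ground-truth bursts, %d initially inactive\n",
              length(x$truth$spike_times), length(x$truth$burst_events$onset),
              length(x$truth$inactive_ids)))
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("meaburst_stage_error", "error")))
  })
}

#' Analyze a session: detection, sorting, bursts, metrics
#'
#' Runs the full analysis chain on a recording: per-electrode spike
#' extraction (bandpass, MAD threshold, refractory rule, artifact
#' exclusion), per-unit waveform clustering, pooled network-burst detection
#' with initiator attribution, and the per-period activity metrics.
#'
#' @param rec an `mea_recording`.
#' @param stim stimulation log (defaults to the one stored in `rec`; pass a
#'   zero-row data.frame for unstimulated sessions).
#' @param detection,sorting,burst parameter objects.
#' @param bin_width synchrony bin width, s.
#' @param seed integer seed (UMAP embeddings).
#' @param verbose print per-stage progress to stderr.
#' @return object of class `mea_analysis`; see [print.mea_analysis()],
#'   [summary.mea_analysis()], [plot.mea_analysis()].
#' @export
analyze_session <- function(rec, stim = NULL,
                            detection = detection_params(),
                            sorting = sorting_params(),
                            burst = burst_params(),
                            bin_width = 0.100, seed = 1L, verbose = FALSE) {
  if (!inherits(rec, "mea_recording")) stop_invalid("rec must be an mea_recording")
  if (is.null(stim)) stim <- rec$stim
  if (is.null(stim)) stim <- data.frame(onset = numeric(0), offset = numeric(0))
  say <- function(...) if (verbose) message(sprintf(...))

  units <- sort(unique(rec$layout$unit_id))
  electrode_rows <- list(); clusters <- list()
  spikes_by_electrode <- list()
  for (u in units) {
    els <- sort(unit_electrodes(rec$layout, u))
    filtered <- matrix(0, length(els), rec$n_samples)
    unit_spikes <- vector("list", length(els))
    with_stage("preprocessing", for (k in seq_along(els)) {
      pe <- process_electrode(get_trace(rec, els[k]), rec$sampling_rate,
                              stim, detection, electrode_id = els[k])
      filtered[k, ] <- pe$filtered
      unit_spikes[[k]] <- pe$spikes
      spikes_by_electrode[[as.character(els[k])]] <- pe$spikes$spike_times
      electrode_rows[[length(electrode_rows) + 1L]] <- data.frame(
        electrode_id = els[k], unit_id = u, mean = pe$spikes$trace_mean,
        sd_est = pe$spikes$noise_sd_estimate, threshold = pe$spikes$threshold,
        n_spikes = length(pe$spikes$spike_times))
    })
    ucl <- with_stage("sorting",
      sort_unit(filtered, unit_spikes, rec$sampling_rate, sorting,
                unit_id = u, seed = seed))
    clusters <- c(clusters, ucl)
    say("unit %d: %d electrodes, %d cluster(s)", u, length(els), length(ucl))
  }
  for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- i
  electrode_table <- do.call(rbind, electrode_rows)

  out <- structure(list(
    clusters = clusters, electrode_table = electrode_table,
    spikes_by_electrode = spikes_by_electrode,
    periods = rec$periods, stim = stim, seed = seed,
    params = list(detection = detection, sorting = sorting, burst = burst,
                  bin_width = bin_width),
    bursts = NULL, initiator_table = NULL, initiation_map = NULL,
    rates = NULL, changes = NULL, presence = NULL, burst_change = NULL,
    strength = NULL, synchrony = NULL), class = "mea_analysis")
  if (!length(clusters)) return(out)

  ba <- with_stage("burst-analysis", {
    b <- detect_bursts(clusters, burst)
    if (nrow(b)) {
      at <- attribute_initiators(b, clusters, burst)
      at$map <- initiation_point_map(at$bursts, clusters, rec$layout, rec$periods)
      at
    } else list(bursts = b, initiator_table = NULL, map = NULL)
  })
  out$bursts <- ba$bursts
  out$initiator_table <- ba$initiator_table
  out$initiation_map <- ba$map

  with_stage("activity-metrics", {
    out$rates <- rates_by_period(clusters, rec$periods)
    out$changes <- data.frame(
      cluster_id = out$rates$cluster_id,
      delta_in = normalized_change(out$rates$rate_pre, out$rates$rate_in),
      delta_post = normalized_change(out$rates$rate_pre, out$rates$rate_post))
    out$presence <- presence_distribution(clusters, rec$periods)
    if (nrow(out$bursts)) {
      out$burst_change <- burst_frequency_change(out$bursts, rec$periods)
      out$strength <- collective_activity_strength(out$bursts,
                                                   length(clusters), rec$periods)
    }
    if (length(clusters) >= 2L)
      out$synchrony <- pairwise_synchrony(clusters, rec$periods, bin_width)
  })
  out
}

#' @export
print.mea_analysis <- function(x, ...) {
  cat(sprintf("<mea_analysis> %d waveform cluster(s) on %d unit(s); %d burst(s)\n",
              length(x$clusters),
              length(unique(x$electrode_table$unit_id)),
              if (is.null(x$bursts)) 0L else nrow(x$bursts)))
  invisible(x)
}

#' Summary of an analyzed session
#'
#' @param object an `mea_analysis`.
#' @param ... unused.
#' @export
summary.mea_analysis <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$presence))
    cat(sprintf("  presence: %.1f%% in all periods, %.1f%% absent before stimulation\n",
                100 * x$presence$all_periods, 100 * x$presence$not_present_before))
  if (!is.null(x$burst_change))
    cat(sprintf("  burst rate (/min) pre/in/post: %.2f / %.2f / %.2f (fold in %.1f, post %.1f)\n",
                x$burst_change$rate_per_min[1], x$burst_change$rate_per_min[2],
                x$burst_change$rate_per_min[3], x$burst_change$fold_in,
                x$burst_change$fold_post))
  if (!is.null(x$strength))
    cat(sprintf("  collective activity strength (%%) pre/in/post: %.1f / %.1f / %.1f\n",
                x$strength[1], x$strength[2], x$strength[3]))
  if (!is.null(x$synchrony))
    cat(sprintf("  mean pairwise r pre/in/post: %.3f / %.3f / %.3f (in/pre %.0f%%, post/pre %.0f%%)\n",
                x$synchrony$mean_r[1], x$synchrony$mean_r[2], x$synchrony$mean_r[3],
                x$synchrony$relative_pct[1], x$synchrony$relative_pct[2]))
  if (!is.null(x$initiator_table))
    cat(sprintf("  %d initiator cluster(s) with >= %d bursts\n",
                nrow(x$initiator_table), x$params$burst$min_bursts_for_initiator))
  invisible(x)
}

#' Raster plot of an analyzed session
#'
#' Spike raster of the retained waveform clusters with period boundaries
#' (dashed) and detected burst onsets (red ticks).
#'
#' @param x an `mea_analysis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mea_analysis <- function(x, ...) {
  if (!length(x$clusters)) {
    warning("nothing to plot: no retained clusters")
    return(invisible(x))
  }
  n <- length(x$clusters)
  graphics::plot(NULL, xlim = range(x$periods), ylim = c(0.5, n + 0.5),
                 xlab = "time (s)", ylab = "waveform cluster",
                 main = "session raster", ...)
  for (i in seq_len(n)) {
    tt <- x$clusters[[i]]$spike_times
    if (length(tt))
      graphics::segments(tt, i - 0.4, tt, i + 0.4, col = "grey25", lwd = 0.4)
  }
  graphics::abline(v = x$periods[2:3], lty = 2, col = "blue")
  if (!is.null(x$bursts) && nrow(x$bursts))
    graphics::segments(x$bursts$onset, 0.5, x$bursts$onset, n + 0.5,
                       col = grDevices::adjustcolor("red", 0.5))
  invisible(x)
}

# file-based run ---------------------------------------------------------

resolve_params <- function(lst, ctor) {
  if (is.null(lst)) return(ctor())
  do.call(ctor, lst)
}

#' Run the full session analysis from a config, writing all outputs
#'
#' The `run` entry point: reads the recording (HDF5) and stimulation log
#' (CSV) named in the config, executes preprocessing, sorting, burst
#' analysis and activity metrics, and writes the stage tables
#' (`thresholds.csv`, `clusters.csv`, `spike_assignments.csv`,
#' `bursts.csv`, `initiator_map.csv`), a `metrics.json` summary and a
#' `manifest.json` with package version, parameters, seed and MD5
#' checksums of every input and output. Rerunning with an identical config
#' reproduces byte-identical outputs. Any stage failure aborts with the
#' stage name and cause.
#'
#' @param config a list, or path to a JSON file, with fields `recording`
#'   (h5 path), `stim` (CSV path, optional), `out_dir`, `seed`, optional
#'   `condition` (one of control / DRG-stim / SC-stim), `bin_width`, and
#'   optional `detection` / `sorting` / `burst` parameter lists.
#' @return the `mea_analysis`, invisibly; outputs are written to
#'   `config$out_dir`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (f in c("recording", "out_dir", "seed"))
    if (is.null(config[[f]])) stop_invalid("config is missing '", f, "'")
  if (!is.null(config$condition) &&
      !config$condition %in% c("control", "DRG-stim", "SC-stim"))
    stop_invalid("condition must be control, DRG-stim or SC-stim")

  rec <- with_stage("load-recording", read_recording_h5(config$recording))
  stim <- with_stage("artifact-exclusion", {
    if (is.null(config$stim)) data.frame(onset = numeric(0), offset = numeric(0))
    else read_stim_csv(config$stim)
  })
  detection <- resolve_params(config$detection, detection_params)
  sorting <- resolve_params(config$sorting, sorting_params)
  burst <- resolve_params(config$burst, burst_params)
  bin_width <- config$bin_width %||% 0.100

  an <- analyze_session(rec, stim, detection, sorting, burst,
                        bin_width = bin_width, seed = config$seed)

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_stage("outputs", {
    write.csv(an$electrode_table, file.path(out_dir, "thresholds.csv"),
              row.names = FALSE)
    cl_tab <- if (length(an$clusters)) data.frame(
      cluster_id = vapply(an$clusters, `[[`, 0L, "cluster_id"),
      unit_id = vapply(an$clusters, function(c) as.integer(c$unit_id), 0L),
      representative_electrode = vapply(an$clusters, function(c)
        as.integer(c$representative_electrode), 0L),
      n_spikes = vapply(an$clusters, `[[`, 0L, "n_spikes"))
    else data.frame(cluster_id = integer(0), unit_id = integer(0),
                    representative_electrode = integer(0), n_spikes = integer(0))
    write.csv(cl_tab, file.path(out_dir, "clusters.csv"), row.names = FALSE)
    asg <- if (length(an$clusters)) data.frame(
      cluster_id = rep(cl_tab$cluster_id,
                       vapply(an$clusters, function(c) length(c$spike_times), 0L)),
      time_s = unlist(lapply(an$clusters, `[[`, "spike_times")))
    else data.frame(cluster_id = integer(0), time_s = numeric(0))
    write.csv(asg, file.path(out_dir, "spike_assignments.csv"), row.names = FALSE)
    bt <- if (!is.null(an$bursts) && nrow(an$bursts)) {
      b <- as.data.frame(an$bursts)
      b$period <- as.character(cut(b$onset, an$periods,
                                   labels = c("pre", "in", "post"),
                                   right = FALSE, include.lowest = TRUE))
      b
    } else data.frame(onset = numeric(0), offset = numeric(0),
                      spike_count = integer(0))
    write.csv(bt, file.path(out_dir, "bursts.csv"), row.names = FALSE)
    write.csv(if (!is.null(an$initiation_map)) an$initiation_map else
                data.frame(unit_id = integer(0), unit_x = numeric(0),
                           unit_y = numeric(0), period = character(0),
                           n_initiated = integer(0)),
              file.path(out_dir, "initiator_map.csv"), row.names = FALSE)
    metrics <- list(
      n_clusters = length(an$clusters),
      presence = an$presence,
      burst_change = an$burst_change,
      collective_strength = as.list(an$strength),
      synchrony = if (!is.null(an$synchrony))
        list(bin_width = an$synchrony$bin_width,
             mean_r = as.list(an$synchrony$mean_r),
             relative_pct = as.list(an$synchrony$relative_pct)))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    out_files <- c("thresholds.csv", "clusters.csv", "spike_assignments.csv",
                   "bursts.csv", "initiator_map.csv", "metrics.json")
    inputs <- c(config$recording, config$stim)
    manifest <- list(
      package = "meaburst",
      version = as.character(utils::packageVersion("meaburst")),
      seed = config$seed,
      condition = config$condition %||% "control",
      bin_width = bin_width,
      parameters = list(detection = unclass(detection),
                        sorting = unclass(sorting), burst = unclass(burst)),
      input_md5 = as.list(stats::setNames(tools::md5sum(inputs),
                                          basename(inputs))),
      output_md5 = as.list(stats::setNames(
        tools::md5sum(file.path(out_dir, out_files)), out_files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(an)
}
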