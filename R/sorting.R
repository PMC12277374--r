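# Waveform clustering ("spike sorting") within 9-electrode recording units:
# representative-electrode alignment, multi-electrode waveform extraction,
# 2-D UMAP embedding, density clustering, cluster-size filtering.

#' Spike-sorting parameters
#'
#' @param n_neighbors,min_dist UMAP graph size and minimum embedding
#'   distance (defaults 20 and 0.2).
#' @param min_samples DBSCAN core-point neighbourhood size (default 5).
#' @param eps DBSCAN radius, or `"auto"` to select it at the knee of the
#'   sorted k-nearest-neighbour distance curve ([auto_eps()]).
#' @param min_cluster_spikes clusters with this many spikes *or fewer* are
#'   discarded (default 50, i.e. a cluster must exceed 50 spikes).
#' @return a list of class `sorting_params`.
#' @export
sorting_params <- function(n_neighbors = 20L, min_dist = 0.2,
                           min_samples = 5L, eps = "auto",
                           min_cluster_spikes = 50L) {
  check_scalar(n_neighbors, "n_neighbors", positive = TRUE, integerish = TRUE)
  if (n_neighbors < 2L) stop_invalid("n_neighbors must be >= 2")
  check_scalar(min_dist, "min_dist", nonneg = TRUE)
  check_scalar(min_samples, "min_samples", positive = TRUE, integerish = TRUE)
  if (!identical(eps, "auto")) check_scalar(eps, "eps", positive = TRUE)
  check_scalar(min_cluster_spikes, "min_cluster_spikes", nonneg = TRUE,
               integerish = TRUE)
  structure(list(n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
                 min_samples = as.integer(min_samples), eps = eps,
                 min_cluster_spikes = as.integer(min_cluster_spikes)),
            class = "sorting_params")
}

#' Select the representative electrode of a recording unit
#'
#' The electrode that detected the greatest number of spikes represents the
#' unit; its spike times anchor the multi-electrode waveform windows. Ties
#' are broken by the lowest electrode id; a unit where no electrode
#' detected anything has no representative and is skipped.
#'
#' @param unit_spikes list of `electrode_spikes`, one per electrode of the
#'   unit.
#' @return the chosen `electrode_id`, or `NA` (with a warning) when every
#'   electrode is empty.
#' @export
select_representative <- function(unit_spikes) {
  counts <- vapply(unit_spikes, function(s) length(s$spike_times), 0L)
  ids <- vapply(unit_spikes, function(s) as.integer(s$electrode_id), 0L)
  if (all(counts == 0L)) {
    warning("no spikes on any electrode of the unit; no representative")
    return(NA_integer_)
  }
  ids[order(-counts, ids)][1L]
}

#' Extract multi-electrode spike waveforms around representative spikes
#'
#' For every spike on the representative electrode, a 41-sample (2 ms at
#' 20 kHz) window centred on the spike sample is cut from each of the
#' unit's filtered traces. Spikes whose window would overrun a session edge
#' are dropped and counted.
#'
#' When `align_row` is given, the fractional peak position on that trace is
#' estimated by parabolic interpolation through the detected minimum and
#' its neighbours, and every electrode's window is resampled (linearly) at
#' that sub-sample offset. Without this, sampling jitter flips the detected
#' minimum between two near-equal samples and splits one neuron's
#' waveforms into two alignment families.
#'
#' @param filtered matrix (9 x samples) of the unit's filtered traces, rows
#'   ordered by electrode id.
#' @param spike_samples 1-based centre samples of the representative spikes.
#' @param half_width samples on each side of the centre (default 20, giving
#'   41 columns).
#' @param align_row row index of the representative electrode used for
#'   sub-sample alignment, or `NULL` for plain integer-sample windows.
#' @return list with `waveforms` (n_spikes x (9*41) matrix, each row a
#'   flattened 9 x 41 waveform, electrode-major), `spike_samples` (kept),
#'   `n_dropped` (edge drops), `n_electrodes`, `n_samples_wf`.
#' @export
extract_waveforms <- function(filtered, spike_samples, half_width = 20L,
                              align_row = NULL) {
  ns <- ncol(filtered)
  margin <- half_width + if (is.null(align_row)) 0L else 2L
  keep <- spike_samples > margin & spike_samples <= ns - margin
  kept <- spike_samples[keep]
  offs <- (-half_width):half_width
  wf <- matrix(0, length(kept), nrow(filtered) * length(offs))
  for (i in seq_along(kept)) {
    cc <- kept[i]
    if (is.null(align_row)) {
      win <- filtered[, cc + offs, drop = FALSE]
    } else {
      y0 <- filtered[align_row, cc + (-1:1)]
      den <- y0[1] - 2 * y0[2] + y0[3]
      delta <- if (abs(den) > 1e-12) 0.5 * (y0[1] - y0[3]) / den else 0
      delta <- max(-1, min(1, delta))
      lo <- floor(delta); frac <- delta - lo
      win <- (1 - frac) * filtered[, cc + lo + offs, drop = FALSE] +
        frac * filtered[, cc + lo + 1L + offs, drop = FALSE]
    }
    wf[i, ] <- as.vector(t(win))  # electrode-major: e1 s1..s41, e2 s1..s41, ...
  }
  list(waveforms = wf, spike_samples = kept, n_dropped = sum(!keep),
       n_electrodes = nrow(filtered), n_samples_wf = length(offs))
}

#' Embed waveforms in 2-D and density-cluster them
#'
#' Flattened multi-electrode waveforms are mapped to two dimensions with
#' UMAP (nearest-neighbour graph of size `n_neighbors`, minimum distance
#' `min_dist`) and the embedding is clustered with DBSCAN (`min_samples`,
#' radius `eps` or its knee-based automatic choice). UMAP is stochastic but
#' reproducible: the seed fixes the embedding, and the single-threaded
#' optimiser is used.
#'
#' @param waveforms n x p matrix of flattened waveforms.
#' @param params a [sorting_params()].
#' @param seed integer seed.
#' @return list with `labels` (integer per waveform, -1 = noise),
#'   `embedding` (n x 2), `eps` (radius used).
#' @export
embed_and_cluster <- function(waveforms, params = sorting_params(), seed = 1L) {
  n <- nrow(waveforms)
  if (n < params$n_neighbors + 1L)
    stop(errorCondition(
      sprintf("unit unsortable: %d waveforms < n_neighbors + 1 = %d",
              n, params$n_neighbors + 1L),
      class = c("meaburst_unsortable", "error")))
  set.seed(sub_seed(seed, 11L))
  emb <- uwot::umap(waveforms, n_neighbors = params$n_neighbors,
                    min_dist = params$min_dist, n_components = 2L,
                    n_threads = 1L, n_sgd_threads = 0L)
  eps <- if (identical(params$eps, "auto"))
    auto_eps(emb, params$min_samples) else params$eps
  labels <- dbscan_cluster(emb, eps, params$min_samples)
  list(labels = labels, embedding = emb, eps = eps)
}

#' Build waveform clusters from labels, dropping small clusters
#'
#' One cluster is kept per non-noise label with strictly more than
#' `min_cluster_spikes` member spikes (default: clusters of 50 or fewer
#' spikes are excluded). The mean waveform is the pointwise mean over
#' members.
#'
#' @param labels integer labels from [embed_and_cluster()].
#' @param waveforms the matrix given to [embed_and_cluster()].
#' @param spike_times representative spike times (s) matching the rows.
#' @param params a [sorting_params()].
#' @param unit_id,representative_electrode identifiers stored per cluster.
#' @return list of `waveform_cluster` objects (fields: `cluster_id` set by
#'   the caller or `NA`, `unit_id`, `representative_electrode`,
#'   `spike_times`, `mean_waveform`, `n_spikes`, `label`).
#' @export
filter_clusters <- function(labels, waveforms, spike_times,
                            params = sorting_params(),
                            unit_id = NA_integer_,
                            representative_electrode = NA_integer_) {
  out <- list()
  for (lb in sort(unique(labels[labels != -1L]))) {
    member <- which(labels == lb)
    if (length(member) <= params$min_cluster_spikes) next
    mw <- colMeans(waveforms[member, , drop = FALSE])
    out[[length(out) + 1L]] <- structure(list(
      cluster_id = NA_integer_, unit_id = unit_id,
      representative_electrode = representative_electrode,
      spike_times = sort(spike_times[member]),
      mean_waveform = mw, n_spikes = length(member), label = lb),
      class = "waveform_cluster")
  }
  out
}

#' Sort one recording unit end to end
#'
#' Chains [select_representative()], [extract_waveforms()],
#' [embed_and_cluster()] and [filter_clusters()] for a single 9-electrode
#' unit. Units with no spikes or with fewer waveforms than the UMAP
#' neighbourhood are reported unsortable (empty cluster list).
#'
#' @param filtered 9 x samples matrix of filtered traces, rows ordered by
#'   electrode id.
#' @param unit_spikes list of `electrode_spikes` matching the rows.
#' @param sampling_rate Hz.
#' @param params a [sorting_params()].
#' @param unit_id unit identifier.
#' @param seed integer seed.
#' @return list of `waveform_cluster`s (possibly empty).
#' @export
sort_unit <- function(filtered, unit_spikes, sampling_rate,
                      params = sorting_params(), unit_id = NA_integer_,
                      seed = 1L) {
  rep_el <- suppressWarnings(select_representative(unit_spikes))
  if (is.na(rep_el)) return(list())
  rep_row <- which(vapply(unit_spikes, function(s)
    as.integer(s$electrode_id), 0L) == rep_el)
  rep_sp <- unit_spikes[[rep_row]]
  ex <- extract_waveforms(filtered, rep_sp$spike_samples,
                          align_row = rep_row)
  if (nrow(ex$waveforms) < params$n_neighbors + 1L) return(list())
  ec <- embed_and_cluster(ex$waveforms, params, seed = sub_seed(seed, unit_id + 23L))
  filter_clusters(ec$labels, ex$waveforms,
                  (ex$spike_samples - 1L) / sampling_rate, params,
                  unit_id = unit_id, representative_electrode = rep_el)
}
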