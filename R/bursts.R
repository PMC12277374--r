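# Network burst detection on the pooled spike raster, burst-initiator
# attribution, propagation order, and the initiation-point map.

#' Burst-detection parameters
#'
#' @param window sliding-window length, s (default 100 ms).
#' @param min_spikes a window qualifies when it holds strictly more than
#'   this many spikes (default 50).
#' @param min_bursts_for_initiator clusters must initiate at least this many
#'   bursts (default 3) to enter the initiator table.
#' @param mode `"pooled"` applies the criterion to the pooled raster of all
#'   retained clusters (default; a network burst is the simultaneous
#'   activation of many neurons); `"per-cluster"` applies it to each
#'   cluster's own train.
#' @return a list of class `burst_params`.
#' @export
burst_params <- function(window = 0.100, min_spikes = 50L,
                         min_bursts_for_initiator = 3L,
                         mode = c("pooled", "per-cluster")) {
  check_scalar(window, "window", positive = TRUE)
  check_scalar(min_spikes, "min_spikes", positive = TRUE, integerish = TRUE)
  check_scalar(min_bursts_for_initiator, "min_bursts_for_initiator",
               nonneg = TRUE, integerish = TRUE)
  structure(list(window = window, min_spikes = as.integer(min_spikes),
                 min_bursts_for_initiator = as.integer(min_bursts_for_initiator),
                 mode = match.arg(mode)),
            class = "burst_params")
}

# burst detection on one sorted spike vector; event-driven: window anchors
# advance spike by spike, which is exhaustive for count-in-window criteria
# (any window holding a spike set can be slid left until it starts on its
# first spike without losing a member)
detect_bursts_train <- function(times, params) {
  n <- length(times)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      spike_count = integer(0))
  if (n <= params$min_spikes) return(empty)
  # count spikes in the closed window [t_i, t_i + window]
  hi <- findInterval(times + params$window, times)
  count <- hi - seq_len(n) + 1L
  q <- which(count > params$min_spikes)
  if (!length(q)) return(empty)
  # merge overlapping qualifying windows into maximal regions
  starts <- times[q]; ends <- times[q] + params$window
  reg_s <- starts[1L]; reg_e <- ends[1L]
  os <- numeric(0); oe <- numeric(0)
  if (length(q) > 1L) for (k in 2:length(q)) {
    if (starts[k] <= reg_e) {
      reg_e <- ends[k]
    } else {
      os <- c(os, reg_s); oe <- c(oe, reg_e)
      reg_s <- starts[k]; reg_e <- ends[k]
    }
  }
  os <- c(os, reg_s); oe <- c(oe, reg_e)
  onset <- offset <- numeric(length(os)); cnt <- integer(length(os))
  for (k in seq_along(os)) {
    inside <- times >= os[k] & times <= oe[k]
    onset[k] <- min(times[inside]); offset[k] <- max(times[inside])
    cnt[k] <- sum(inside)
  }
  data.frame(onset = onset, offset = offset, spike_count = cnt)
}

#' Detect network bursts from cluster spike trains
#'
#' A burst exists wherever some `window` (100 ms) interval contains strictly
#' more than `min_spikes` (50) spikes of the pooled raster; overlapping
#' qualifying windows are merged, the burst onset is the first spike of the
#' merged region and the offset its last spike. In `"per-cluster"` mode the
#' same rule is applied to each cluster separately and the results pooled.
#'
#' @param clusters list of `waveform_cluster`s (or a list of numeric spike
#'   time vectors).
#' @param params a [burst_params()].
#' @return data.frame of class `mea_bursts` with `onset`, `offset`,
#'   `spike_count` (and `cluster_id` in per-cluster mode), sorted by onset.
#' @export
detect_bursts <- function(clusters, params = burst_params()) {
  trains <- lapply(clusters, function(cl)
    if (inherits(cl, "waveform_cluster")) cl$spike_times else cl)
  if (params$mode == "pooled") {
    pooled <- sort(unlist(trains, use.names = FALSE))
    out <- detect_bursts_train(pooled, params)
  } else {
    pieces <- lapply(seq_along(trains), function(i) {
      b <- detect_bursts_train(sort(trains[[i]]), params)
      if (nrow(b)) b$cluster_id <- i
      b
    })
    out <- do.call(rbind, pieces[vapply(pieces, nrow, 0L) > 0])
    if (is.null(out)) out <- data.frame(onset = numeric(0), offset = numeric(0),
                                        spike_count = integer(0),
                                        cluster_id = integer(0))
    out <- out[order(out$onset), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mea_bursts", "data.frame")
  out
}

# first spike of each cluster inside [onset, offset]; NA when none
first_spikes_in_burst <- function(onset, offset, trains) {
  vapply(trains, function(tt) {
    i <- findInterval(onset, tt, left.open = TRUE) + 1L  # first tt >= onset
    if (i <= length(tt) && tt[i] <= offset) tt[i] else NA_real_
  }, 0)
}

#' Attribute each burst to its initiating waveform cluster
#'
#' The burst-triggering spike is the first spike at or after the burst
#' onset; the cluster owning it is the burst's initiation point (ties broken
#' by the lowest cluster id). The summary table counts bursts initiated per
#' cluster; clusters initiating fewer than `min_bursts_for_initiator`
#' (default 3) bursts are dropped from the table, and their bursts are
#' flagged `below_threshold`.
#'
#' @param bursts an `mea_bursts` data.frame.
#' @param clusters list of `waveform_cluster`s or spike-time vectors,
#'   indexed by cluster id.
#' @param params a [burst_params()].
#' @return list with `bursts` (input plus `initiator`, `initiator_first_spike`,
#'   `n_participants`, `below_threshold`), `initiator_table` (cluster_id,
#'   n_initiated; only clusters meeting the minimum), and
#'   `initiation_counts` (all clusters, before the minimum filter).
#' @export
attribute_initiators <- function(bursts, clusters, params = burst_params()) {
  trains <- lapply(clusters, function(cl)
    if (inherits(cl, "waveform_cluster")) cl$spike_times else sort(cl))
  nb <- nrow(bursts)
  init <- integer(nb); fs <- numeric(nb); np <- integer(nb)
  for (k in seq_len(nb)) {
    f <- first_spikes_in_burst(bursts$onset[k], bursts$offset[k], trains)
    if (all(is.na(f)))
      stop(errorCondition("burst with no post-onset spikes: attribution impossible",
                          class = c("meaburst_attribution_impossible", "error")))
    init[k] <- which(f == min(f, na.rm = TRUE))[1L]  # ties: lowest id
    fs[k] <- f[init[k]]
    np[k] <- sum(!is.na(f))
  }
  bursts$initiator <- init
  bursts$initiator_first_spike <- fs
  bursts$n_participants <- np
  counts <- table(factor(init, levels = seq_along(trains)))
  all_counts <- data.frame(cluster_id = seq_along(trains),
                           n_initiated = as.integer(counts))
  keep <- all_counts$n_initiated >= params$min_bursts_for_initiator &
    all_counts$n_initiated > 0L
  bursts$below_threshold <- !(init %in% all_counts$cluster_id[keep])
  list(bursts = bursts,
       initiator_table = all_counts[keep, , drop = FALSE],
       initiation_counts = all_counts[all_counts$n_initiated > 0L, , drop = FALSE])
}

#' Propagation order of one burst
#'
#' Participants sorted by their first spike at or after the burst onset.
#'
#' @param burst one row of an attributed `mea_bursts` data.frame.
#' @param clusters list of `waveform_cluster`s or spike-time vectors.
#' @return data.frame (`cluster_id`, `first_spike`) of class
#'   `propagation_order`, times non-decreasing, first row the initiator.
#' @export
propagation_order <- function(burst, clusters) {
  trains <- lapply(clusters, function(cl)
    if (inherits(cl, "waveform_cluster")) cl$spike_times else sort(cl))
  f <- first_spikes_in_burst(burst$onset, burst$offset, trains)
  ids <- which(!is.na(f))
  ord <- ids[order(f[ids], ids)]
  structure(data.frame(cluster_id = ord, first_spike = f[ord]),
            class = c("propagation_order", "data.frame"))
}

#' Similarity of two propagation orders
#'
#' Spearman rank correlation of the activation ranks of the clusters shared
#' by the two bursts; `NA` when fewer than 3 clusters are shared.
#'
#' @param a,b `propagation_order` data.frames.
#' @return rank correlation in [-1, 1], or `NA`.
#' @export
propagation_similarity <- function(a, b) {
  shared <- intersect(a$cluster_id, b$cluster_id)
  if (length(shared) < 3L) return(NA_real_)
  ra <- match(shared, a$cluster_id)
  rb <- match(shared, b$cluster_id)
  cor(ra, rb, method = "spearman")
}

#' Map burst-initiation points onto electrode units, per session period
#'
#' Counts, for each period and each recording unit, how many bursts were
#' initiated by a cluster of that unit (bursts assigned to periods by
#' onset). Supports the initiation-point heat map and the count difference
#' between periods.
#'
#' @param bursts attributed `mea_bursts` (with `initiator`).
#' @param clusters list of `waveform_cluster`s (to map cluster -> unit).
#' @param layout an `mea_layout`.
#' @param periods boundaries (length 4, s).
#' @return data.frame `unit_id`, `unit_x`, `unit_y`, `period` (pre/in/post),
#'   `n_initiated`; zero-count rows omitted.
#' @export
initiation_point_map <- function(bursts, clusters, layout, periods) {
  per <- cut(bursts$onset, periods, labels = c("pre", "in", "post"),
             right = FALSE, include.lowest = TRUE)
  units <- vapply(clusters, function(cl) as.integer(cl$unit_id), 0L)
  iu <- units[bursts$initiator]
  upos <- unique(as.data.frame(layout)[, c("unit_id", "unit_x", "unit_y")])
  out <- as.data.frame(table(unit_id = iu, period = per),
                       responseName = "n_initiated")
  out <- out[out$n_initiated > 0L, , drop = FALSE]
  out$unit_id <- as.integer(as.character(out$unit_id))
  m <- match(out$unit_id, upos$unit_id)
  out$unit_x <- upos$unit_x[m]; out$unit_y <- upos$unit_y[m]
  rownames(out) <- NULL
  out[, c("unit_id", "unit_x", "unit_y", "period", "n_initiated")]
}
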