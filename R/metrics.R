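# Per-period firing-rate, presence, burst and synchrony statistics.

period_labels <- c("pre", "in", "post")

cluster_trains <- function(clusters) {
  lapply(clusters, function(cl)
    if (inherits(cl, "waveform_cluster")) cl$spike_times else sort(cl))
}

#' Per-period firing rates of waveform clusters
#'
#' Rate = spike count / period duration, for the pre-stimulation,
#' stimulation and post-stimulation periods.
#'
#' @param clusters list of `waveform_cluster`s or spike-time vectors.
#' @param periods boundaries (length 4, s), strictly increasing.
#' @return data.frame: `cluster_id`, `n_pre`, `n_in`, `n_post`, `rate_pre`,
#'   `rate_in`, `rate_post` (Hz).
#' @export
rates_by_period <- function(clusters, periods) {
  if (length(periods) != 4L || any(diff(periods) <= 0))
    stop_invalid("periods must be 4 increasing boundaries")
  trains <- cluster_trains(clusters)
  cnt <- t(vapply(trains, function(tt)
    c(sum(tt >= periods[1] & tt < periods[2]),
      sum(tt >= periods[2] & tt < periods[3]),
      sum(tt >= periods[3] & tt <= periods[4])), numeric(3)))
  dur <- diff(periods)
  out <- data.frame(cluster_id = seq_along(trains),
                    n_pre = as.integer(cnt[, 1]), n_in = as.integer(cnt[, 2]),
                    n_post = as.integer(cnt[, 3]))
  out$rate_pre <- out$n_pre / dur[1]
  out$rate_in <- out$n_in / dur[2]
  out$rate_post <- out$n_post / dur[3]
  out
}

#' Normalized firing-rate change
#'
#' `(b - a) / (b + a)`: bounded in [-1, 1], equal to 1 for clusters newly
#' active in condition b (a = 0), 0 for unchanged rates, and -1 for
#' clusters that fell silent. Undefined (NA) when both rates are zero.
#'
#' @param rate_a reference (pre-stimulation) rate, Hz.
#' @param rate_b comparison rate, Hz. Both vectorised.
#' @return numeric score(s) in [-1, 1], NA where both rates are 0.
#' @export
normalized_change <- function(rate_a, rate_b) {
  if (any(rate_a < 0 | rate_b < 0, na.rm = TRUE))
    stop_invalid("rates must be >= 0")
  out <- (rate_b - rate_a) / (rate_b + rate_a)
  out[rate_a == 0 & rate_b == 0] <- NA_real_
  out
}

#' Distribution of cluster presence patterns across session periods
#'
#' A cluster is "present" in a period when it has at least one spike there.
#' Returns the fraction of clusters per nonempty presence pattern
#' (pre/in/post as a binary triplet, e.g. `"111"` = present throughout,
#' `"011"` = absent before stimulation, active during and after).
#'
#' @inheritParams rates_by_period
#' @return list with `pattern` (named fractions summing to 1), `n_clusters`,
#'   and the convenience fractions `all_periods` (pattern 111) and
#'   `not_present_before` (patterns with a leading 0).
#' @export
presence_distribution <- function(clusters, periods) {
  r <- rates_by_period(clusters, periods)
  pat <- paste0((r$n_pre > 0) + 0L, (r$n_in > 0) + 0L, (r$n_post > 0) + 0L)
  keep <- pat != "000"
  pat <- pat[keep]
  lv <- c("100", "010", "001", "110", "101", "011", "111")
  frac <- table(factor(pat, levels = lv)) / length(pat)
  list(pattern = c(frac), n_clusters = length(pat),
       all_periods = unname(frac["111"]),
       not_present_before = sum(frac[c("010", "001", "011")]))
}

#' Burst-frequency fold change between periods
#'
#' Fold = (bursts per minute in period) / (bursts per minute before
#' stimulation). A zero pre-stimulation burst rate gives an infinite fold,
#' returned as `Inf` with `pre_rate_zero = TRUE` rather than dropped, since
#' sessions can genuinely lack baseline bursts.
#'
#' @param bursts an `mea_bursts` data.frame (assigned to periods by onset).
#' @param periods boundaries (length 4, s).
#' @return list: per-period `rate_per_min`, `fold_in`, `fold_post`,
#'   `pre_rate_zero`.
#' @export
burst_frequency_change <- function(bursts, periods) {
  per <- cut(bursts$onset, periods, labels = period_labels,
             right = FALSE, include.lowest = TRUE)
  n <- table(per)
  rate <- as.numeric(n) / (diff(periods) / 60)
  names(rate) <- period_labels
  list(rate_per_min = rate,
       fold_in = rate[["in"]] / rate[["pre"]],
       fold_post = rate[["post"]] / rate[["pre"]],
       pre_rate_zero = rate[["pre"]] == 0)
}

#' Collective activity strength per period
#'
#' For each burst, the percentage of retained clusters that participate
#' (have at least one spike inside the burst); per period, the mean over
#' its bursts. Periods without bursts are undefined (NA).
#'
#' @param bursts attributed `mea_bursts` (with `n_participants`).
#' @param n_clusters total number of retained clusters.
#' @param periods boundaries (length 4, s).
#' @return named numeric (pre, in, post), percent.
#' @export
collective_activity_strength <- function(bursts, n_clusters, periods) {
  per <- cut(bursts$onset, periods, labels = period_labels,
             right = FALSE, include.lowest = TRUE)
  strength <- 100 * bursts$n_participants / n_clusters
  out <- tapply(strength, per, mean)
  stats::setNames(as.numeric(out), period_labels)
}

#' Pairwise Pearson synchrony of cluster spike trains
#'
#' Spike trains are binned per period (default 100 ms bins); the Pearson
#' correlation is computed for every pair of clusters with nonzero count
#' variance in that period, and the per-period mean correlation is
#' reported, with the stimulation and post periods also expressed relative
#' to the pre-stimulation mean (in percent).
#'
#' @inheritParams rates_by_period
#' @param bin_width bin width, s.
#' @return list of class `synchrony_report`: `bin_width`, `mean_r` (named,
#'   per period), `n_pairs` (pairs used), `relative_pct` (in/pre and
#'   post/pre as %).
#' @export
pairwise_synchrony <- function(clusters, periods, bin_width = 0.100) {
  check_scalar(bin_width, "bin_width", positive = TRUE)
  trains <- cluster_trains(clusters)
  if (length(trains) < 2L)
    stop_invalid("need >= 2 clusters for pairwise synchrony")
  mean_r <- stats::setNames(rep(NA_real_, 3), period_labels)
  n_pairs <- stats::setNames(rep(0L, 3), period_labels)
  for (p in 1:3) {
    brk <- seq(periods[p], periods[p + 1], by = bin_width)
    if (brk[length(brk)] < periods[p + 1]) brk <- c(brk, periods[p + 1])
    counts <- vapply(trains, function(tt)
      hist(tt[tt >= periods[p] & tt <= periods[p + 1]], breaks = brk,
           plot = FALSE)$counts, numeric(length(brk) - 1L))
    keep <- apply(counts, 2, stats::var) > 0
    if (sum(keep) < 2L) next
    cm <- cor(counts[, keep, drop = FALSE])
    rs <- cm[upper.tri(cm)]
    mean_r[p] <- mean(rs)
    n_pairs[p] <- length(rs)
  }
  structure(list(bin_width = bin_width, mean_r = mean_r, n_pairs = n_pairs,
                 relative_pct = c(
                   in_vs_pre = 100 * mean_r[["in"]] / mean_r[["pre"]],
                   post_vs_pre = 100 * mean_r[["post"]] / mean_r[["pre"]])),
            class = "synchrony_report")
}

#' Mean, sample standard deviation and n of a sample
#'
#' The SD uses the N - 1 (sample) denominator,
#' `sqrt(sum((x - mean(x))^2) / (N - 1))`; undefined (NA) for N < 2.
#'
#' @param x numeric vector.
#' @return list `mean`, `sd`, `n`, `values`.
#' @export
summary_stat <- function(x) {
  x <- x[is.finite(x)]
  list(mean = mean(x), sd = if (length(x) >= 2L) sd(x) else NA_real_,
       n = length(x), values = x)
}
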