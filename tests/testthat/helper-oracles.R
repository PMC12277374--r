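# Independent brute-force oracles used to cross-check the vectorised
# implementations. Deliberately written as explicit loops over the
# definitions, never sharing code with the package internals.

# exhaustive scan: sub-threshold local minima, then the greedy keep-first
# refractory rule
oracle_detect <- function(x, level, ref_samp) {
  cand <- integer(0)
  for (i in 2:(length(x) - 1L)) {
    if (x[i] < level && x[i] <= x[i - 1L] && x[i] < x[i + 1L])
      cand <- c(cand, i)
  }
  kept <- integer(0); last <- -Inf
  for (i in cand) {
    if (i - last >= ref_samp) { kept <- c(kept, i); last <- i }
  }
  kept
}

# O(n^2) windowed count: every window anchored at a spike is tested, then
# overlapping qualifying windows are unioned into regions
oracle_bursts <- function(times, window, min_spikes) {
  times <- sort(times); n <- length(times)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      spike_count = integer(0))
  if (n == 0L) return(empty)
  qual <- logical(n)
  for (i in seq_len(n))
    qual[i] <- sum(times >= times[i] & times <= times[i] + window) > min_spikes
  q <- which(qual)
  if (!length(q)) return(empty)
  regions <- list(); s <- times[q[1]]; e <- times[q[1]] + window
  for (k in q[-1]) {
    if (times[k] <= e) e <- times[k] + window
    else { regions <- c(regions, list(c(s, e))); s <- times[k]; e <- times[k] + window }
  }
  regions <- c(regions, list(c(s, e)))
  do.call(rbind, lapply(regions, function(r) {
    inside <- times[times >= r[1] & times <= r[2]]
    data.frame(onset = min(inside), offset = max(inside),
               spike_count = length(inside))
  }))
}

# all-pairs distances: each marker claims its nearest nucleus within the
# radius (first on ties); claimed nuclei are de-duplicated
oracle_coloc <- function(nuclei, marker, radius) {
  claimed <- integer(0)
  for (j in seq_len(nrow(marker))) {
    best <- 0L; bestd <- Inf
    for (i in seq_len(nrow(nuclei))) {
      d <- sqrt((nuclei$x[i] - marker$x[j])^2 + (nuclei$y[i] - marker$y[j])^2)
      if (d < bestd) { bestd <- d; best <- i }
    }
    if (best > 0L && bestd <= radius) claimed <- union(claimed, best)
  }
  length(claimed) / nrow(nuclei)
}

# exhaustive sign-flip enumeration of the signed-rank null (2^n outcomes)
oracle_wilcoxon <- function(x, y) {
  d <- x - y; d <- d[d != 0]; n <- length(d)
  if (n == 0L) return(NA_real_)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(flips, 1, function(s) sum(r[s]))
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# direct evaluation of the N-1 standard-deviation formula
oracle_sd <- function(x) {
  xb <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - xb)^2
  sqrt(acc / (length(x) - 1))
}
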