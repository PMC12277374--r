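# Density-based clustering (DBSCAN) on a low-dimensional embedding.
#
# Classic flood-fill formulation on closed eps-balls: a point is a core
# point when at least min_samples points (itself included) lie within eps;
# clusters are the connected components of core points, border points join
# the first cluster that reaches them, everything else is noise (-1).

#' DBSCAN density clustering
#'
#' @param x numeric matrix, observations in rows (here: 2-D embeddings).
#' @param eps neighbourhood radius.
#' @param min_samples minimum neighbourhood size (self included) for a core
#'   point.
#' @return integer labels, one per row: 1, 2, ... for clusters in order of
#'   discovery, -1 for noise.
#' @export
dbscan_cluster <- function(x, eps, min_samples = 5L) {
  x <- as.matrix(x)
  n <- nrow(x)
  check_scalar(eps, "eps", positive = TRUE)
  check_scalar(min_samples, "min_samples", positive = TRUE, integerish = TRUE)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == -1L])
      }
    }
  }
  labels
}

#' Knee-based neighbourhood radius for DBSCAN
#'
#' Sorts each point's distance to its `min_samples`-th nearest neighbour
#' (self excluded) in ascending order and returns the value at the knee of
#' that curve — where the nearest-neighbour distance starts to increase
#' rapidly. The knee is located as the point of maximum deviation below the
#' chord joining the curve's endpoints (the "kneedle" construction), which
#' finds the curve's global bend and is not distracted by a single tight
#' clump or gap early in the curve.
#'
#' @param x numeric matrix of observations.
#' @param min_samples neighbour rank to use.
#' @return the selected eps (> 0).
#' @export
auto_eps <- function(x, min_samples = 5L) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- min(min_samples, n - 1L)
  d <- as.matrix(stats::dist(x))
  kdist <- sort(vapply(seq_len(n), function(i) sort(d[i, -i])[k], 0))
  if (n < 3L || kdist[n] == kdist[1L])
    return(max(kdist[n], .Machine$double.eps))
  chord <- kdist[1L] + (seq_len(n) - 1) / (n - 1) * (kdist[n] - kdist[1L])
  dev_below <- chord - kdist
  knee <- if (any(dev_below > 0)) which.max(dev_below)
          else as.integer(stats::quantile(seq_len(n), 0.9))
  max(kdist[knee], .Machine$double.eps)
}
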