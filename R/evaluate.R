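# Ground-truth evaluation helpers for synthetic sessions.

#' Match a detected spike train against ground truth
#'
#' Greedy one-to-one matching in time order: each ground-truth spike is
#' paired with the nearest unused detected spike within `tol`. Recall is
#' matched / truth, precision is matched / detected.
#'
#' @param detected,truth sorted spike time vectors (s).
#' @param tol matching tolerance, s (default 1 ms).
#' @return list `n_matched`, `n_detected`, `n_truth`, `recall`, `precision`.
#' @export
match_spike_trains <- function(detected, truth, tol = 1e-3) {
  nd <- length(detected); nt <- length(truth)
  used <- logical(nd)
  matched <- 0L
  j <- 1L
  for (i in seq_len(nt)) {
    while (j <= nd && detected[j] < truth[i] - tol) j <- j + 1L
    k <- j
    best <- 0L; bestd <- Inf
    while (k <= nd && detected[k] <= truth[i] + tol) {
      if (!used[k] && abs(detected[k] - truth[i]) < bestd) {
        best <- k; bestd <- abs(detected[k] - truth[i])
      }
      k <- k + 1L
    }
    if (best > 0L) { used[best] <- TRUE; matched <- matched + 1L }
  }
  list(n_matched = matched, n_detected = nd, n_truth = nt,
       recall = if (nt) matched / nt else NA_real_,
       precision = if (nd) matched / nd else NA_real_)
}

#' Best label agreement between cluster labels and ground-truth identities
#'
#' Maximises agreement over label permutations greedily (labels are matched
#' to their modal truth identity, largest clusters first); adequate for the
#' small numbers of clusters per recording unit.
#'
#' @param labels integer cluster labels (-1 = noise, never matched).
#' @param truth_ids ground-truth identities, same length.
#' @return fraction of non-noise points whose mapped label equals the truth.
#' @export
label_agreement <- function(labels, truth_ids) {
  keep <- labels != -1L
  labels <- labels[keep]; truth_ids <- truth_ids[keep]
  if (!length(labels)) return(0)
  tab <- table(labels, truth_ids)
  agree <- 0L
  for (lb in names(sort(table(labels), decreasing = TRUE))) {
    row <- tab[lb, ]
    if (all(row == 0)) next
    pick <- names(row)[which.max(row)]
    agree <- agree + tab[lb, pick]
    tab[, pick] <- 0L
  }
  as.numeric(agree) / length(labels)
}
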