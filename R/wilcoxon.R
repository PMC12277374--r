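# Paired nonparametric comparisons: Wilcoxon signed-rank with an exact
# small-sample null (shift algorithm over doubled midranks, valid with
# ties) and Bonferroni correction.

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are discarded; the remaining absolute differences are
#' midranked. For fewer than `exact_limit` nonzero pairs the exact null
#' distribution of the positive-rank sum is computed by the shift
#' (convolution) algorithm, which stays correct in the presence of tied
#' ranks; the two-sided p-value is `2 * min(P(W <= w), P(W >= w))`, capped
#' at 1. For larger samples the tie-corrected normal approximation of
#' [stats::wilcox.test()] is used.
#'
#' @param x,y paired numeric vectors.
#' @param exact_limit switch point between exact and approximate null.
#' @return list: `statistic` (positive-rank sum W), `p_value`, `n_nonzero`,
#'   `method` ("exact" or "normal-approximation"); `p_value` is NA (flagged
#'   by `degenerate = TRUE`) when every difference is zero.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 20L) {
  if (length(x) != length(y)) stop_invalid("x and y must be paired")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_, n_nonzero = 0L,
                method = "exact", degenerate = TRUE))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n < exact_limit) {
    # exact null over doubled midranks (integers even with .5 midranks)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dens <- c(1, rep(0, total))      # dens[s + 1] = #assignments with sum s
    for (rk in r2) {
      shifted <- c(rep(0, rk), dens[seq_len(total + 1 - rk)])
      dens <- dens + shifted
    }
    dens <- dens / 2^n
    w2 <- round(2 * w)
    p_le <- sum(dens[seq_len(w2 + 1)])
    p_ge <- sum(dens[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = w, p_value = p, n_nonzero = n, method = "exact",
         degenerate = FALSE)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                       correct = TRUE))
    list(statistic = w, p_value = ht$p.value, n_nonzero = n,
         method = "normal-approximation", degenerate = FALSE)
  }
}

#' Compare paired condition samples with optional Bonferroni correction
#'
#' Runs a two-sided Wilcoxon signed-rank test for each comparison in a
#' named list of `(a, b)` pairs and, when requested, multiplies each
#' p-value by the number of comparisons (capped at 1).
#'
#' @param comparisons named list; each element a list/pair of two paired
#'   numeric vectors.
#' @param correction `"none"` or `"bonferroni"`.
#' @param min_n minimum number of pairs required per comparison.
#' @return data.frame: `comparison`, `n`, `statistic`, `p_value`, `p_adj`,
#'   `method`, `degenerate`.
#' @export
compare_conditions <- function(comparisons, correction = c("none", "bonferroni"),
                               min_n = 5L) {
  correction <- match.arg(correction)
  if (!length(comparisons)) stop_invalid("no comparisons given")
  rows <- lapply(seq_along(comparisons), function(i) {
    ab <- comparisons[[i]]
    a <- ab[[1]]; b <- ab[[2]]
    if (length(a) < min_n)
      stop_invalid("comparison ", i, " has fewer than ", min_n, " pairs")
    res <- wilcoxon_signed_rank(a, b)
    data.frame(comparison = names(comparisons)[i] %||% as.character(i),
               n = length(a), statistic = res$statistic,
               p_value = res$p_value, method = res$method,
               degenerate = res$degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "bonferroni")
    p.adjust(out$p_value, method = "bonferroni") else out$p_value
  out[, c("comparison", "n", "statistic", "p_value", "p_adj", "method",
          "degenerate")]
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || a == "") b else a
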