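# Point-based marker colocalization: fraction of nuclei within a radius of
# a marker point, with overlap de-duplication.

#' Marker-positive fraction of nuclei with overlap de-duplication
#'
#' Each marker point claims at most one nucleus — its nearest nucleus
#' within `radius` (ties broken by input order) — and a nucleus claimed by
#' several markers is counted once, so multiple nuclei crowding one marker
#' collapse to a single overlapping point. The fraction is the number of
#' distinct claimed nuclei over the total nucleus count. Distances are
#' Euclidean in the image plane.
#'
#' @param nuclei,marker data.frames with `x`, `y` (um), e.g. from
#'   [generate_colocalization_points()] or read from CSV.
#' @param radius colocalization radius, um (> 0; default 10).
#' @return list of class `colocalization_result`: `n_nuclei`, `n_marker`,
#'   `n_colocalized`, `fraction`, `radius`.
#' @export
marker_positive_fraction <- function(nuclei, marker, radius = 10) {
  check_scalar(radius, "radius", positive = TRUE)
  n_n <- nrow(nuclei); n_m <- nrow(marker)
  if (n_n == 0L)
    stop(errorCondition("empty nuclei set: fraction undefined",
                        class = c("meaburst_undefined", "error")))
  claimed <- logical(n_n)
  if (n_m > 0L) {
    for (j in seq_len(n_m)) {
      d2 <- (nuclei$x - marker$x[j])^2 + (nuclei$y - marker$y[j])^2
      i <- which.min(d2)  # first index on ties = input order
      if (d2[i] <= radius^2) claimed[i] <- TRUE
    }
  }
  structure(list(n_nuclei = n_n, n_marker = n_m,
                 n_colocalized = sum(claimed),
                 fraction = sum(claimed) / n_n, radius = radius),
            class = "colocalization_result")
}

#' @export
print.colocalization_result <- function(x, ...) {
  cat(sprintf("<colocalization> %d/%d nuclei within %g um of a marker (%.1f%%)\n",
              x$n_colocalized, x$n_nuclei, x$radius, 100 * x$fraction))
  invisible(x)
}

#' Read a point set from CSV
#'
#' Expects columns `x_um`, `y_um` (or `x`, `y`).
#' @param path CSV path.
#' @return data.frame with `x`, `y`.
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  p <- read.csv(path)
  if (all(c("x_um", "y_um") %in% names(p)))
    p <- data.frame(x = p$x_um, y = p$y_um)
  if (!all(c("x", "y") %in% names(p)))
    stop_invalid("point CSV needs x_um/y_um or x/y columns")
  if (!all(is.finite(p$x)) || !all(is.finite(p$y)))
    stop_invalid("point coordinates must be finite")
  p[, c("x", "y")]
}
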