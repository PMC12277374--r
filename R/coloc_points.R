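#' Generate synthetic nucleus / marker point sets for colocalization tests
#'
#' Emulates the point statistics of marker-based cell counting: `n_nuclei`
#' nucleus detections are scattered uniformly over the imaging field; a
#' fraction `marker_fraction` of them carry the marker, so a marker peak is
#' placed at each such nucleus displaced by isotropic Gaussian jitter
#' (`jitter_sd`, the registration error between the two channels); any
#' remaining marker points are uniform background detections.
#'
#' @param n_nuclei,n_marker point counts (`n_marker` must be at least the
#'   number of jittered matches, `round(marker_fraction * n_nuclei)`).
#' @param marker_fraction proportion of nuclei that are marker-positive.
#' @param jitter_sd channel registration jitter, um.
#' @param field field of view, um (width, height).
#' @param seed integer seed.
#' @return list with `nuclei` and `marker`, each a data.frame (`x`, `y` in
#'   um) of class `mea_points` with a `label` attribute.
#' @export
generate_colocalization_points <- function(n_nuclei, n_marker,
                                           marker_fraction, jitter_sd = 1,
                                           field = c(1000, 1000), seed = 1L) {
  check_scalar(n_nuclei, "n_nuclei", nonneg = TRUE, integerish = TRUE)
  check_scalar(n_marker, "n_marker", nonneg = TRUE, integerish = TRUE)
  check_scalar(marker_fraction, "marker_fraction", nonneg = TRUE)
  if (marker_fraction > 1) stop_invalid("marker_fraction must be <= 1")
  check_scalar(jitter_sd, "jitter_sd", nonneg = TRUE)
  set.seed(sub_seed(seed, 3L))

  nuclei <- data.frame(x = runif(n_nuclei, 0, field[1]),
                       y = runif(n_nuclei, 0, field[2]))
  k <- round(marker_fraction * n_nuclei)
  if (n_marker < k)
    stop_invalid("n_marker must be >= round(marker_fraction * n_nuclei)")
  matched <- if (k > 0) {
    idx <- sample(n_nuclei, k)
    data.frame(x = nuclei$x[idx] + rnorm(k, 0, jitter_sd),
               y = nuclei$y[idx] + rnorm(k, 0, jitter_sd))
  } else data.frame(x = numeric(0), y = numeric(0))
  extra <- n_marker - k
  background <- data.frame(x = runif(extra, 0, field[1]),
                           y = runif(extra, 0, field[2]))
  marker <- rbind(matched, background)

  attr(nuclei, "label") <- "nuclei"
  attr(marker, "label") <- "marker"
  class(nuclei) <- c("mea_points", "data.frame")
  class(marker) <- c("mea_points", "data.frame")
  list(nuclei = nuclei, marker = marker)
}
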