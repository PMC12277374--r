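#' Generate an HD-MEA electrode layout grouped into 9-electrode recording units
#'
#' Electrodes are laid out as 3x3 patches ("recording units") on a square grid,
#' mirroring the unit-based electrode selection used on high-density arrays
#' where nine electrodes are grouped to capture one neuron's footprint while
#' the units tile the network. Patches are placed on a near-square grid of
#' units with a gap of one pitch between adjacent patches.
#'
#' @param n_units number of recording units (>= 1).
#' @param pitch electrode pitch in micrometres (> 0). Default 17.5, the
#'   centre-to-centre spacing of the MaxOne-class arrays the pipeline targets.
#' @param seed integer seed (the layout is deterministic; the seed is accepted
#'   for interface uniformity and reserved for future jittered geometries).
#' @return a data.frame of class `mea_layout` with columns `electrode_id`
#'   (0-based), `x`, `y` (um), `unit_id` (0-based), `unit_x`, `unit_y`
#'   (centre of the unit's 3x3 patch).
#' @examples
#' lay <- generate_layout(n_units = 4)
#' table(lay$unit_id)
#' @export
generate_layout <- function(n_units, pitch = 17.5, seed = 1L) {
  check_scalar(n_units, "n_units", positive = TRUE, integerish = TRUE)
  check_scalar(pitch, "pitch", positive = TRUE)
  n_units <- as.integer(n_units)

  n_cols <- ceiling(sqrt(n_units))
  unit_id <- seq_len(n_units) - 1L
  ucol <- unit_id %% n_cols
  urow <- unit_id %/% n_cols
  # each 3x3 patch spans 2*pitch; one pitch of gap between patches
  ux0 <- ucol * 4 * pitch
  uy0 <- urow * 4 * pitch

  off <- expand.grid(dx = 0:2, dy = 0:2)
  lay <- data.frame(
    electrode_id = seq_len(9L * n_units) - 1L,
    x = rep(ux0, each = 9L) + rep(off$dx, n_units) * pitch,
    y = rep(uy0, each = 9L) + rep(off$dy, n_units) * pitch,
    unit_id = rep(unit_id, each = 9L)
  )
  lay$unit_x <- rep(ux0 + pitch, each = 9L)
  lay$unit_y <- rep(uy0 + pitch, each = 9L)
  attr(lay, "pitch") <- pitch
  class(lay) <- c("mea_layout", "data.frame")
  lay
}

unit_electrodes <- function(layout, unit) {
  layout$electrode_id[layout$unit_id == unit]
}
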