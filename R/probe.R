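#' Default 12-tile probe layout
#'
#' Builds a toy scalp patch version of a 12-tile high-density cap: each tile
#' carries 3 sources and 4 detectors, and every source-detector pairing is a
#' logical channel, giving `36 x 48 = 1728` channels per wavelength. Tiles
#' are placed on a regular grid in the scalp plane (z = 0, mm units); the
#' exact commercial geometry is not reproduced.
#'
#' @param n_tiles Number of tiles (default 12, arranged on a 4 x 3 grid).
#' @param tile_spacing_mm Center-to-center tile distance in mm (default 35).
#' @param wavelengths_nm Two operating wavelengths in nm (default 735, 850).
#' @return An object of class `probe_layout`: list with `sources` and
#'   `detectors` (n x 3 position matrices, mm), `tiles` (per-optode tile
#'   index), and `channels` (data frame: `channel`, `source_id`,
#'   `detector_id`, `wavelength_nm`, `sd_distance_mm`).
#' @examples
#' p <- default_probe()
#' sum(p$channels$wavelength_nm == 735) # 1728
#' @export
default_probe <- function(n_tiles = 12, tile_spacing_mm = 35,
                          wavelengths_nm = c(735, 850)) {
  if (n_tiles < 1) stop_arg("n_tiles must be >= 1")
  if (length(wavelengths_nm) < 1) stop_arg("at least one wavelength required")
  ncol_grid <- ceiling(sqrt(n_tiles * 4 / 3))
  nrow_grid <- ceiling(n_tiles / ncol_grid)
  centers <- cbind(
    x = (((seq_len(n_tiles) - 1L) %% ncol_grid) - (ncol_grid - 1) / 2) * tile_spacing_mm,
    y = (((seq_len(n_tiles) - 1L) %/% ncol_grid) - (nrow_grid - 1) / 2) * tile_spacing_mm
  )
  # within-tile optode offsets (mm): sources on a triangle, detectors at the
  # center and an interleaved triangle
  src_off <- rbind(c(0, 9), c(-7.8, -4.5), c(7.8, -4.5))
  det_off <- rbind(c(0, 0), c(0, -8.5), c(7.4, 4.25), c(-7.4, 4.25))
  sources <- do.call(rbind, lapply(seq_len(n_tiles), function(i)
    cbind(src_off[, 1] + centers[i, 1], src_off[, 2] + centers[i, 2], 0)))
  detectors <- do.call(rbind, lapply(seq_len(n_tiles), function(i)
    cbind(det_off[, 1] + centers[i, 1], det_off[, 2] + centers[i, 2], 0)))
  colnames(sources) <- colnames(detectors) <- c("x", "y", "z")
  ns <- nrow(sources); nd <- nrow(detectors)
  pairs <- expand.grid(source_id = seq_len(ns), detector_id = seq_len(nd),
                       KEEP.OUT.ATTRS = FALSE)
  dist_mm <- sqrt(rowSums((sources[pairs$source_id, , drop = FALSE] -
                             detectors[pairs$detector_id, , drop = FALSE])^2))
  channels <- do.call(rbind, lapply(wavelengths_nm, function(wl)
    data.frame(source_id = pairs$source_id, detector_id = pairs$detector_id,
               wavelength_nm = wl, sd_distance_mm = dist_mm)))
  channels$channel <- seq_len(nrow(channels))
  structure(list(
    sources = sources, detectors = detectors,
    source_tile = rep(seq_len(n_tiles), each = 3L),
    detector_tile = rep(seq_len(n_tiles), each = 4L),
    n_tiles = n_tiles,
    channels = channels[, c("channel", "source_id", "detector_id",
                            "wavelength_nm", "sd_distance_mm")]
  ), class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %d tiles, %d sources, %d detectors, %d channels (%s nm)\n",
              x$n_tiles, nrow(x$sources), nrow(x$detectors), nrow(x$channels),
              paste(unique(x$channels$wavelength_nm), collapse = "/")))
  invisible(x)
}
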