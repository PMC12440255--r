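#' Canonical infant hemodynamic response function
#'
#' Single-gamma kernel `h(t) = (t/peak_s)^k * exp(k * (1 - t/peak_s))`,
#' normalized so that `h(peak_s) = 1`. The default 4-s time-to-peak reflects
#' the faster hemodynamics reported for infants relative to the adult
#' canonical response.
#'
#' @param t Time grid in seconds (non-negative values; negative entries
#'   return 0).
#' @param peak_s Time-to-peak in seconds (default 4).
#' @param shape Dimensionless shape parameter `k` controlling kernel width
#'   (default 6).
#' @return Numeric vector of response values, peak value 1 at `t = peak_s`.
#' @examples
#' tt <- seq(0, 15, by = 0.25)
#' h <- canonical_hrf(tt)
#' tt[which.max(h)] # 4
#' @export
canonical_hrf <- function(t, peak_s = 4, shape = 6) {
  if (peak_s <= 0) stop_arg("peak_s must be positive")
  h <- ifelse(t <= 0, 0, (t / peak_s)^shape * exp(shape * (1 - t / peak_s)))
  h
}

# Convolve unit impulses (sample index + height) with the canonical HRF on a
# regular grid of n samples at rate_hz. Used by the generator and the design
# builder.
convolve_events <- function(n, rate_hz, onset_idx, heights, peak_s = 4, shape = 6) {
  out <- numeric(n)
  kern_len <- ceiling(6 * peak_s * rate_hz)  # kernel support ~6x peak
  kern <- canonical_hrf(seq_len(kern_len) / rate_hz - 1 / rate_hz,
                        peak_s = peak_s, shape = shape)
  for (i in seq_along(onset_idx)) {
    j0 <- onset_idx[i]
    if (j0 > n) next
    j1 <- min(n, j0 + kern_len - 1L)
    out[j0:j1] <- out[j0:j1] + heights[i] * kern[seq_len(j1 - j0 + 1L)]
  }
  out
}
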