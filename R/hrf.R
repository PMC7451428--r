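#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical HRF — a difference of two gamma densities, one for
#' the positive response peak and one for the late undershoot — on an
#' arbitrary time grid. With the default parameters (response delay 6 s,
#' undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6) the
#' kernel peaks near 5 s after stimulus onset and shows a shallow negative
#' undershoot between roughly 10 and 24 s, the shape conventionally used to
#' convolve block-design task regressors.
#'
#' @param t_grid Numeric vector of time points in seconds; must be
#'   non-negative and strictly increasing.
#' @param peak_delay Delay of the response gamma in seconds (shape =
#'   `peak_delay / peak_dispersion`).
#' @param undershoot_delay Delay of the undershoot gamma in seconds.
#' @param peak_dispersion,undershoot_dispersion Dispersion (scale) of the two
#'   gamma densities in seconds; must be positive.
#' @param ratio Peak-to-undershoot amplitude ratio.
#'
#' @return Numeric vector of kernel values on `t_grid`, normalised so the
#'   maximum equals 1. The value at `t = 0` is exactly 0.
#'
#' @examples
#' h <- canonical_hrf(seq(0, 32, by = 0.5))
#' plot(seq(0, 32, by = 0.5), h, type = "l")
#' @export
canonical_hrf <- function(t_grid,
                          peak_delay = 6,
                          undershoot_delay = 16,
                          peak_dispersion = 1,
                          undershoot_dispersion = 1,
                          ratio = 6) {
  stopifnot(is.numeric(t_grid), length(t_grid) >= 1)
  if (any(t_grid < 0)) stop("t_grid must be non-negative")
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be strictly increasing")
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0) {
    stop("dispersion parameters must be positive")
  }
  if (peak_delay <= 0 || undershoot_delay <= 0) stop("delay parameters must be positive")
  if (ratio <= 0) stop("ratio must be positive")

  h <- stats::dgamma(t_grid, shape = peak_delay / peak_dispersion,
                     scale = peak_dispersion) -
    stats::dgamma(t_grid, shape = undershoot_delay / undershoot_dispersion,
                  scale = undershoot_dispersion) / ratio
  m <- max(h)
  if (m <= 0) stop("HRF kernel has no positive peak on the supplied grid")
  h / m
}
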