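#' Canonical double-gamma hemodynamic response parameters
#'
#' The conventional parameterization: response peak at 6 s, undershoot at
#' 16 s, unit dispersions, peak-to-undershoot ratio 6.
#'
#' @param peak_delay,undershoot_delay gamma means in seconds.
#' @param peak_dispersion,undershoot_dispersion gamma scales in seconds.
#' @param peak_undershoot_ratio positive scalar dividing the undershoot.
#' @param sampling_dt microtime resolution in seconds at which regressors are
#'   built before resampling at the TR.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, sampling_dt = 0.1) {
  ok <- all(c(peak_delay, undershoot_delay, peak_dispersion,
              undershoot_dispersion, peak_undershoot_ratio, sampling_dt) > 0)
  if (!ok) vl_error("all HRF parameters must be positive",
                    "voicelight_parameter_error")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 sampling_dt = sampling_dt),
            class = "hrf_params")
}

#' Sample the canonical HRF kernel
#'
#' Difference of two gamma densities (peak minus scaled undershoot),
#' normalized to unit peak so fitted beta amplitudes are in signal units.
#' The kernel is zero at t = 0.
#'
#' @param params an [hrf_params()].
#' @param duration kernel support in seconds.
#' @return Numeric vector sampled at `params$sampling_dt`, with attribute
#'   `"times"`.
#' @export
canonical_hrf <- function(params = hrf_params(), duration = 32) {
  stopifnot(inherits(params, "hrf_params"))
  vl_assert(duration > 0, "duration must be positive")
  t <- seq(0, duration, by = params$sampling_dt)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay /
                    params$undershoot_dispersion,
                  scale = params$undershoot_dispersion) /
      params$peak_undershoot_ratio
  h <- h / max(h)
  attr(h, "times") <- t
  h
}
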