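#' Canonical haemodynamic response parameters
#'
#' Defaults are the conventional double-gamma shape: response gamma peaking
#' near 5-6 s, undershoot gamma near 16 s, unit dispersions, undershoot
#' ratio 1/6, 32 s of support, sampled on a 0.1 s microtime grid.
#'
#' @param peak_delay,undershoot_delay gamma delays (s).
#' @param peak_dispersion,undershoot_dispersion gamma dispersions (s).
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @param duration kernel support (s).
#' @param dt microtime step (s).
#' @return An `hrf_params` object.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, duration = 32, dt = 0.1) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_dispersion > 0,
            undershoot_dispersion > 0, undershoot_ratio >= 0, dt > 0,
            duration >= undershoot_delay)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, duration = duration,
                 dt = dt),
            class = "hrf_params")
}

#' Sample the canonical double-gamma haemodynamic response
#'
#' The kernel is the difference of two gamma densities (response minus
#' scaled undershoot) evaluated on the microtime grid and normalised to a
#' peak of 1.
#'
#' @param params an [hrf_params()].
#' @return Numeric vector of kernel samples at `0, dt, 2 dt, ...`, with
#'   attribute `t` holding the sample times.
#' @export
canonical_hrf <- function(params = hrf_params()) {
  p <- params
  t <- seq(0, p$duration, by = p$dt)
  h <- stats::dgamma(t, shape = p$peak_delay / p$peak_dispersion,
                     scale = p$peak_dispersion) -
    p$undershoot_ratio *
      stats::dgamma(t, shape = p$undershoot_delay / p$undershoot_dispersion,
                    scale = p$undershoot_dispersion)
  h <- h / max(h)
  attr(h, "t") <- t
  h
}
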