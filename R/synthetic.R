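#' Synthetic oscillatory test series
#'
#' Generates a damped or sustained cosine with optional Gaussian noise and
#' constant offset, sampled on a uniform grid — a controlled stand-in for
#' rhythmic count data, used to exercise the spectral and rhythm-statistics
#' machinery independently of the simulator.
#'
#' @param t_end length of the record, hours.
#' @param dt sampling interval, hours.
#' @param period oscillation period, hours.
#' @param amplitude cosine amplitude.
#' @param damping exponential decay rate of the amplitude, per hour
#'   (0 = sustained).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param offset constant baseline added to the series.
#' @param phase phase shift, radians.
#' @param seed optional seed for the noise.
#' @return List with `times` and `values`.
#' @examples
#' s <- synthetic_oscillation(200, 0.5, period = 24, noise_sd = 0.1, seed = 1)
#' @export
synthetic_oscillation <- function(t_end, dt, period = 24, amplitude = 1,
                                  damping = 0, noise_sd = 0, offset = 0,
                                  phase = 0, seed = NULL) {
  stopifnot(t_end > 0, dt > 0, period > 0)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, t_end, by = dt)
  values <- offset +
    amplitude * exp(-damping * times) * cos(2 * pi * times / period + phase)
  if (noise_sd > 0) values <- values + rnorm(length(times), sd = noise_sd)
  list(times = times, values = values)
}

#' Synthetic event log
#'
#' Builds an event-log `data.frame` in the format produced by [run_ssa()],
#' for testing tallying code against hand-computable inputs.
#'
#' @param time event times, hours.
#' @param channel channel names (recycled), from the set used by
#'   [run_ssa()].
#' @param compartment compartment indices (recycled).
#' @return `data.frame` with `time`, `channel` (factor), `compartment`.
#' @export
synthetic_event_log <- function(time, channel = "transcription",
                                compartment = 1L) {
  stopifnot(all(channel %in% CHANNELS))
  data.frame(time = as.numeric(time),
             channel = factor(rep_len(channel, length(time)),
                              levels = CHANNELS),
             compartment = as.integer(rep_len(compartment, length(time))))
}
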