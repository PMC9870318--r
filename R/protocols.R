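#' Step-protocol specifications
#'
#' A protocol describes one family of stimulus episodes ("sweeps"): a square
#' step of varying amplitude delivered from a holding level, with a pre-step
#' baseline and a post-step window. Three canonical protocols are provided,
#' matching common practice for intrinsic-property characterization of
#' forebrain projection neurons:
#'
#' * `protocol_excitability()`: current clamp, steps -80 to +60 pA in 10 pA
#'   increments, 500 ms, from a -60 mV holding potential. Used for evoked
#'   spike counts, voltage sag, rebound spikes, first-spike latency and ISIs.
#' * `protocol_ih()`: voltage clamp, steps -150 to -60 mV in 10 mV increments,
#'   800 ms, from -60 mV. Used to measure the hyperpolarization-activated
#'   current (Ih).
#' * `protocol_mfr()`: current clamp, steps +50 to +750 pA in 50 pA
#'   increments, 1000 ms. Used for the maximum firing rate before
#'   depolarization block.
#'
#' All times are in ms; step windows are half-open `[onset, onset + duration)`.
#' Current-clamp sweeps have command in pA and response in mV; voltage-clamp
#' sweeps have command in mV and response in pA.
#'
#' @param name Protocol label.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param holding Holding level (mV) maintained outside the step.
#' @param step_onset,step_duration,post_window Timing of the step (ms).
#' @param amplitudes Ordered vector of step amplitudes (pA or mV by mode).
#' @param increment Spacing between amplitudes (pA or mV).
#' @return A `protocol_spec` object (a named list).
#' @examples
#' protocol_excitability()
#' @export
protocol_spec <- function(name, mode, holding, step_onset, step_duration,
                          post_window, amplitudes, increment) {
  mode <- match.arg(mode, c("current_clamp", "voltage_clamp"))
  if (step_duration <= 0) abort("`step_duration` must be positive")
  if (any(diff(amplitudes) <= 0)) abort("`amplitudes` must be strictly increasing")
  structure(
    list(name = name, mode = mode, holding = holding,
         step_onset = step_onset, step_duration = step_duration,
         post_window = post_window, amplitudes = amplitudes,
         increment = increment),
    class = "protocol_spec")
}

#' @rdname protocol_spec
#' @export
protocol_excitability <- function() {
  protocol_spec("excitability", "current_clamp", holding = -60,
                step_onset = 100, step_duration = 500, post_window = 600,
                amplitudes = seq(-80, 60, by = 10), increment = 10)
}

#' @rdname protocol_spec
#' @export
protocol_ih <- function() {
  protocol_spec("ih", "voltage_clamp", holding = -60,
                step_onset = 100, step_duration = 800, post_window = 100,
                amplitudes = seq(-150, -60, by = 10), increment = 10)
}

#' @rdname protocol_spec
#' @export
protocol_mfr <- function() {
  protocol_spec("mfr", "current_clamp", holding = -60,
                step_onset = 100, step_duration = 1000, post_window = 100,
                amplitudes = seq(50, 750, by = 50), increment = 50)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("<protocol_spec> %s (%s)\n", x$name, x$mode))
  cat(sprintf("  holding %g mV; step [%g, %g) ms; post %g ms\n",
              x$holding, x$step_onset, x$step_onset + x$step_duration,
              x$post_window))
  cat(sprintf("  %d steps: %g to %g by %g %s\n", length(x$amplitudes),
              min(x$amplitudes), max(x$amplitudes), x$increment,
              if (x$mode == "current_clamp") "pA" else "mV"))
  invisible(x)
}

#' The canonical protocol set
#'
#' @return Named list of the three standard protocols keyed by name.
#' @export
default_protocols <- function() {
  list(excitability = protocol_excitability(),
       ih = protocol_ih(),
       mfr = protocol_mfr())
}

# total sweep length in ms
protocol_total_ms <- function(protocol) {
  protocol$step_onset + protocol$step_duration + protocol$post_window
}

# command waveform sampled on the output grid
protocol_command <- function(protocol, step, dt_out) {
  t <- seq(0, protocol_total_ms(protocol), by = dt_out)
  base <- if (protocol$mode == "current_clamp") 0 else protocol$holding
  cmd <- rep(base, length(t))
  on <- t >= protocol$step_onset &
    t < protocol$step_onset + protocol$step_duration
  cmd[on] <- if (protocol$mode == "current_clamp") step else step
  cmd
}

expected_units <- function(mode) {
  if (mode == "current_clamp") {
    list(command = "pA", response = "mV")
  } else {
    list(command = "mV", response = "pA")
  }
}
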