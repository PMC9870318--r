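#' Simulation configuration
#'
#' @param dt Integration step (ms); fixed-step scheme, must be <= 0.05 ms.
#' @param dt_out Sampling interval of the recorded traces (ms); 0.1 ms
#'   corresponds to a 10 kHz acquisition rate. Must be an integer multiple
#'   of `dt`.
#' @param noise_sd Standard deviation (pA) of white current noise injected in
#'   current clamp. Default 0: sweeps are then exactly reproducible and
#'   feature tests are exact.
#' @param holding Holding potential (mV) maintained by a bias current in
#'   current clamp and by the command in voltage clamp.
#' @param seed Seed used for the noise stream (only consumed when
#'   `noise_sd > 0`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.05, dt_out = 0.1, noise_sd = 0,
                       holding = -60, seed = 1) {
  if (dt <= 0 || dt > 0.05) abort("`dt` must be in (0, 0.05] ms")
  ratio <- dt_out / dt
  if (abs(ratio - round(ratio)) > 1e-9)
    abort("`dt_out` must be an integer multiple of `dt`")
  structure(list(dt = dt, dt_out = dt_out, noise_sd = noise_sd,
                 holding = holding, seed = as.integer(seed)),
            class = "sim_config")
}

# bias current holding the membrane at `holding` (what the amplifier applies):
# equals the total steady-state ionic current at that voltage
holding_bias <- function(params, holding) {
  total_ionic_steady_cpp(params, holding)
}

sweep_noise <- function(config, n_steps) {
  if (config$noise_sd <= 0) return(numeric(0))
  rnorm(n_steps, 0, config$noise_sd)
}

#' Simulate current-clamp step responses
#'
#' Integrates the single-compartment model for every amplitude of a
#' current-clamp protocol. Sweeps start at the holding potential (maintained
#' by a pre-computed bias current, as an amplifier would) with all gates at
#' their steady state. Spike peaks are painted into the sampled trace at the
#' spike amplitude so that threshold-based event detection sees overshooting
#' action potentials.
#'
#' @param params Named parameter vector (one row of [make_cohort()] via its
#'   parameter columns, or a [phenotype_template()]).
#' @param protocol A current-clamp [protocol_spec()].
#' @param config A [sim_config()].
#' @return Tibble with columns `step`, `time_ms`, `command` (pA),
#'   `response` (mV).
#' @export
simulate_current_clamp <- function(params, protocol = protocol_excitability(),
                                   config = sim_config()) {
  if (protocol$mode != "current_clamp")
    abort("`protocol` must be a current-clamp protocol")
  bias <- holding_bias(params, config$holding)
  total <- protocol_total_ms(protocol)
  n_int <- round(total / config$dt)
  if (config$noise_sd > 0) set.seed(config$seed)
  purrr::map(protocol$amplitudes, function(a) {
    lab <- sprintf("%s %+g pA", protocol$name, a)
    sim <- sim_cc_cpp(params, a, bias, total,
                      protocol$step_onset, protocol$step_duration,
                      config$dt, config$dt_out, config$holding,
                      sweep_noise(config, n_int), lab)
    tibble(step = a,
           time_ms = seq(0, total, by = config$dt_out),
           command = protocol_command(protocol, a, config$dt_out),
           response = sim$response)
  }) |>
    purrr::list_rbind()
}

#' Simulate voltage-clamp step responses
#'
#' Ideal clamp: the membrane follows the command exactly and the recorded
#' signal is the total ionic current (outward positive, pA). The Ih gate
#' relaxes toward its voltage-dependent steady state, so hyperpolarizing
#' steps show a slowly developing inward current.
#'
#' @inheritParams simulate_current_clamp
#' @param protocol A voltage-clamp [protocol_spec()].
#' @return Tibble with columns `step`, `time_ms`, `command` (mV),
#'   `response` (pA).
#' @export
simulate_voltage_clamp <- function(params, protocol = protocol_ih(),
                                   config = sim_config()) {
  if (protocol$mode != "voltage_clamp")
    abort("`protocol` must be a voltage-clamp protocol")
  total <- protocol_total_ms(protocol)
  purrr::map(protocol$amplitudes, function(a) {
    lab <- sprintf("%s %g mV", protocol$name, a)
    sim <- sim_vc_cpp(params, config$holding, a, total,
                      protocol$step_onset, protocol$step_duration,
                      config$dt, config$dt_out, lab)
    tibble(step = a,
           time_ms = seq(0, total, by = config$dt_out),
           command = protocol_command(protocol, a, config$dt_out),
           response = sim$response)
  }) |>
    purrr::list_rbind()
}

#' Simulate the zero-current resting trace
#'
#' Records the membrane with no bias and no injected current (amplifier at
#' I = 0), starting from the leak reversal; the mean of the settled trace is
#' the resting membrane potential.
#'
#' @inheritParams simulate_current_clamp
#' @param duration Trace length (ms).
#' @return Tibble with `step` (0), `time_ms`, `command`, `response`.
#' @export
simulate_rmp <- function(params, config = sim_config(), duration = 500) {
  sim <- sim_cc_cpp(params, 0, 0, duration, 0, 0,
                    config$dt, config$dt_out, params[["e_l"]],
                    numeric(0), "rmp")
  tibble(step = 0,
         time_ms = seq(0, duration, by = config$dt_out),
         command = 0,
         response = sim$response)
}

#' Simulate all protocols for one neuron
#'
#' Runs the excitability, Ih and maximum-firing-rate protocols plus the
#' zero-current resting trace, returning one long tibble.
#'
#' @inheritParams simulate_current_clamp
#' @param protocols Named list of protocols as from [default_protocols()].
#' @return Tibble with columns `protocol`, `step`, `time_ms`, `command`,
#'   `response`.
#' @export
simulate_neuron <- function(params, config = sim_config(),
                            protocols = default_protocols()) {
  sims <- purrr::imap(protocols, function(pr, nm) {
    out <- if (pr$mode == "current_clamp") {
      simulate_current_clamp(params, pr, config)
    } else {
      simulate_voltage_clamp(params, pr, config)
    }
    mutate(out, protocol = nm, .before = 1)
  })
  rest <- mutate(simulate_rmp(params, config), protocol = "rmp", .before = 1)
  bind_rows(purrr::list_rbind(sims), rest)
}

#' Resting potential of the model at steady state
#'
#' Solves the zero-current fixed point of the model (all gates at steady
#' state) by root finding; useful as ground truth against the measured
#' resting membrane potential.
#'
#' @param params Named parameter vector.
#' @return Resting potential (mV).
#' @export
resting_potential <- function(params) {
  uniroot(function(v) total_ionic_steady_cpp(params, v),
          lower = -120, upper = -20, tol = 1e-9)$root
}
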