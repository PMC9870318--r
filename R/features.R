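#' Spike detection by threshold crossing
#'
#' An event is the peak of a maximal run of samples at or above `threshold`;
#' events closer than `min_interval` are merged, keeping the larger peak.
#' This mirrors amplitude-threshold event detection as used for overshooting
#' somatic action potentials; 0 mV is a robust criterion for such spikes.
#'
#' @param sweep Data frame with `time_ms` and `response` columns (one sweep).
#' @param threshold Detection threshold (mV).
#' @param min_interval Minimum inter-event interval (ms).
#' @param mode Sweep mode; voltage-clamp sweeps are rejected.
#' @return Numeric vector of spike peak times (ms), sorted ascending.
#' @export
detect_spikes <- function(sweep, threshold = 0, min_interval = 2,
                          mode = "current_clamp") {
  if (mode != "current_clamp")
    abort("spike detection requires a current-clamp sweep")
  spike_times(sweep$time_ms, sweep$response, threshold, min_interval)
}

# vector worker shared by all spike-based features
spike_times <- function(time_ms, v, threshold = 0, min_interval = 2) {
  above <- v >= threshold
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  peaks <- purrr::map_dbl(which(keep), function(k) {
    i <- starts[k]:ends[k]
    time_ms[i[which.max(v[i])]]
  })
  peaks <- sort(peaks)
  # merge events closer than min_interval, keeping the larger peak
  if (length(peaks) > 1) {
    vals <- v[match(peaks, time_ms)]
    repeat {
      gaps <- diff(peaks)
      j <- which(gaps < min_interval)
      if (length(j) == 0) break
      j <- j[1]
      drop <- if (vals[j] >= vals[j + 1]) j + 1 else j
      peaks <- peaks[-drop]
      vals <- vals[-drop]
    }
  }
  peaks
}

# exponential low-pass with time constant tau (ms)
lowpass <- function(x, dt, tau) {
  a <- 1 - exp(-dt / tau)
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive", init = x[1]))
}

sweep_dt <- function(sweep) {
  d <- diff(sweep$time_ms[1:2])
  if (!is.finite(d) || d <= 0) abort("sweep has no valid time base")
  d
}

# split a sweep set into one tibble per step; sweeps are stored as
# contiguous per-step blocks, so run-length boundaries avoid an expensive
# factor() over the full trace table (falls back to split() otherwise)
split_steps <- function(sweeps) {
  s <- sweeps$step
  r <- rle(s)
  if (anyDuplicated(r$values)) return(split(sweeps, s))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- purrr::map(seq_along(ends),
                    function(k) dplyr::slice(sweeps, starts[k]:ends[k]))
  setNames(out, as.character(r$values))
}

#' Evoked spike counts per step
#'
#' Counts spikes whose peaks fall in the half-open step window
#' `[onset, onset + duration)`.
#'
#' @param sweeps Sweep-set tibble (`step`, `time_ms`, `response`).
#' @param protocol The current-clamp [protocol_spec()] the sweeps follow.
#' @inheritParams detect_spikes
#' @return Tibble with `step` and `n_spikes`.
#' @export
count_evoked_spikes <- function(sweeps, protocol = protocol_excitability(),
                                threshold = 0, min_interval = 2) {
  if (nrow(sweeps) == 0)
    return(tibble(step = numeric(), n_spikes = integer()))
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  purrr::map(split_steps(sweeps), function(sw) {
    st <- spike_times(sw$time_ms, sw$response, threshold, min_interval)
    tibble(step = sw$step[1], n_spikes = sum(st >= on & st < off))
  }) |>
    purrr::list_rbind() |>
    arrange(.data$step)
}

#' Voltage sag per hyperpolarizing step
#'
#' Sag is the steady-state voltage minus the early negative peak
#' (`V_steady - V_peak`), clipped at zero: the peak is the minimum of the
#' response within `peak_window` ms after step onset, the steady state the
#' mean over the final `steady_window` ms of the step.
#'
#' @inheritParams count_evoked_spikes
#' @param peak_window Early search window for the sag trough (ms).
#' @param steady_window Length of the steady-state window before offset (ms).
#' @return Tibble with `step` and `sag_mv` (>= 0) for steps < 0.
#' @export
voltage_sag <- function(sweeps, protocol = protocol_excitability(),
                        peak_window = 150, steady_window = 100) {
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  hyper <- filter(sweeps, .data$step < 0)
  if (nrow(hyper) == 0) return(tibble(step = numeric(), sag_mv = numeric()))
  purrr::map(split_steps(hyper), function(sw) {
    early <- sw$response[sw$time_ms >= on & sw$time_ms <= on + peak_window]
    steady <- sw$response[sw$time_ms >= off - steady_window & sw$time_ms < off]
    tibble(step = sw$step[1],
           sag_mv = max(0, mean(steady) - min(early)))
  }) |>
    purrr::list_rbind() |>
    arrange(.data$step)
}

#' Rebound spikes per step
#'
#' Counts spikes in the window `(offset, offset + window]` after the end of a
#' hyperpolarizing current step — the rebound-depolarization signature of
#' de-inactivated low-threshold currents.
#'
#' @inheritParams count_evoked_spikes
#' @param window Rebound window after step offset (ms); truncated at the end
#'   of the sweep.
#' @return Tibble with `step` and `n_rebound` for steps <= 0.
#' @export
rebound_spikes <- function(sweeps, protocol = protocol_excitability(),
                           window = 500, threshold = 0, min_interval = 2) {
  off <- protocol$step_onset + protocol$step_duration
  hyper <- filter(sweeps, .data$step <= 0)
  if (nrow(hyper) == 0)
    return(tibble(step = numeric(), n_rebound = integer()))
  purrr::map(split_steps(hyper), function(sw) {
    st <- spike_times(sw$time_ms, sw$response, threshold, min_interval)
    tibble(step = sw$step[1],
           n_rebound = sum(st > off & st <= off + window))
  }) |>
    purrr::list_rbind() |>
    arrange(.data$step)
}

#' Depolarization-block onset within a sweep
#'
#' Block is declared at the first time the low-pass-filtered (time constant
#' `filter_tau` ms) voltage stays above `v_block` for at least `min_quiet` ms
#' with no spike in that stretch. Returns `Inf` when no block occurs.
#'
#' @param time_ms,v Time base and voltage of one sweep.
#' @param spikes Spike peak times of the sweep (ms).
#' @param v_block Block voltage criterion (mV).
#' @param filter_tau Low-pass time constant (ms).
#' @param min_quiet Minimum spike-free duration above `v_block` (ms).
#' @return Block onset time (ms) or `Inf`.
#' @export
detect_depolarization_block <- function(time_ms, v, spikes,
                                        v_block = -20, filter_tau = 5,
                                        min_quiet = 50) {
  dt <- time_ms[2] - time_ms[1]
  vf <- lowpass(v, dt, filter_tau)
  above <- vf > v_block
  if (!any(above)) return(Inf)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    t0 <- time_ms[starts[k]]
    t1 <- time_ms[ends[k]]
    bounds <- c(t0, sort(spikes[spikes > t0 & spikes < t1]), t1)
    quiet <- diff(bounds)
    hit <- which(quiet >= min_quiet)
    if (length(hit) > 0) return(bounds[hit[1]])
  }
  Inf
}

#' Maximum firing rate and the step producing it
#'
#' Within each sweep, spikes are counted only up to the first detected
#' depolarization block; the maximum firing rate (MFR) is the maximum such
#' count over sweeps, and `mfr_step` the lowest step amplitude attaining it.
#'
#' @inheritParams count_evoked_spikes
#' @inheritParams detect_depolarization_block
#' @return One-row tibble with `mfr` and `mfr_step`; `mfr = 0` and
#'   `mfr_step = NA` when no sweep has any spike.
#' @export
max_firing_rate <- function(sweeps, protocol = protocol_mfr(),
                            threshold = 0, min_interval = 2,
                            v_block = -20, filter_tau = 5, min_quiet = 50) {
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  counts <- purrr::map(split_steps(sweeps), function(sw) {
    st <- spike_times(sw$time_ms, sw$response, threshold, min_interval)
    st <- st[st >= on & st < off]
    blk <- detect_depolarization_block(sw$time_ms, sw$response, st,
                                       v_block, filter_tau, min_quiet)
    tibble(step = sw$step[1], n = sum(st < blk))
  }) |>
    purrr::list_rbind() |>
    arrange(.data$step)
  if (nrow(counts) == 0 || max(counts$n) == 0)
    return(tibble(mfr = 0L, mfr_step = NA_real_))
  best <- counts$step[counts$n == max(counts$n)]
  tibble(mfr = as.integer(max(counts$n)), mfr_step = min(best))
}

#' Ih amplitude per voltage step
#'
#' The hyperpolarization-activated current amplitude is
#' `|I_steady - I_instant|`: the instantaneous current is the mean over
#' `instant_window` ms after step onset (past the capacitive transient), the
#' steady-state current the mean over the final `steady_window` ms of the
#' step. Both means use the same windows on every step, so any constant
#' offset (holding current) cancels.
#'
#' @param sweeps Voltage-clamp sweep-set tibble (`step`, `time_ms`,
#'   `response` in pA).
#' @param protocol The voltage-clamp [protocol_spec()].
#' @param instant_window Two numbers: window after onset for the
#'   instantaneous current (ms).
#' @param steady_window Length of the steady-state window before offset (ms).
#' @return Tibble with `step` and `ih_pa`.
#' @export
ih_amplitude <- function(sweeps, protocol = protocol_ih(),
                         instant_window = c(10, 30), steady_window = 50) {
  if (nrow(sweeps) == 0) return(tibble(step = numeric(), ih_pa = numeric()))
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  purrr::map(split_steps(sweeps), function(sw) {
    inst <- sw$response[sw$time_ms >= on + instant_window[1] &
                          sw$time_ms <= on + instant_window[2]]
    steady <- sw$response[sw$time_ms >= off - steady_window & sw$time_ms < off]
    tibble(step = sw$step[1], ih_pa = abs(mean(steady) - mean(inst)))
  }) |>
    purrr::list_rbind() |>
    arrange(.data$step)
}

#' Ih current density
#'
#' @param ih Tibble from [ih_amplitude()].
#' @param capacitance Cell capacitance (pF); when missing the density is an
#'   explicit missing value.
#' @return The input with an added `ih_density` column (pA/pF).
#' @export
ih_density <- function(ih, capacitance) {
  if (is.null(capacitance) || length(capacitance) == 0 || is.na(capacitance))
    return(mutate(ih, ih_density = NA_real_))
  mutate(ih, ih_density = .data$ih_pa / capacitance)
}

#' Inter-spike intervals, first ISI and first-spike latency
#'
#' ISIs are successive spike-peak time differences within the step window.
#' The first ISI of a step is its earliest interval; it is missing with fewer
#' than two spikes. First-spike latency (FSL) is the time from step onset to
#' the first spike peak; missing with no spike.
#'
#' @inheritParams count_evoked_spikes
#' @return `isi_list()`: tibble `step`, `isi_ms` (one row per interval);
#'   `first_isi()` / `first_spike_latency()`: tibble `step`, `value` (ms,
#'   `NA` when undefined) over depolarizing steps.
#' @export
isi_list <- function(sweeps, protocol = protocol_excitability(),
                     threshold = 0, min_interval = 2) {
  dep <- filter(sweeps, .data$step > 0)
  if (nrow(dep) == 0) return(tibble(step = numeric(), isi_ms = numeric()))
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  purrr::map(split_steps(dep), function(sw) {
    st <- spike_times(sw$time_ms, sw$response, threshold, min_interval)
    st <- st[st >= on & st < off]
    if (length(st) < 2) return(NULL)
    tibble(step = sw$step[1], isi_ms = diff(st))
  }) |>
    purrr::list_rbind()
}

#' @rdname isi_list
#' @export
first_isi <- function(sweeps, protocol = protocol_excitability(),
                      threshold = 0, min_interval = 2) {
  isis <- isi_list(sweeps, protocol, threshold, min_interval)
  steps <- protocol$amplitudes[protocol$amplitudes > 0]
  purrr::map(steps, function(s) {
    v <- isis$isi_ms[isis$step == s]
    tibble(step = s, value = if (length(v)) v[1] else NA_real_)
  }) |>
    purrr::list_rbind()
}

#' @rdname isi_list
#' @export
first_spike_latency <- function(sweeps, protocol = protocol_excitability(),
                                threshold = 0, min_interval = 2) {
  on <- protocol$step_onset
  off <- on + protocol$step_duration
  steps <- protocol$amplitudes[protocol$amplitudes > 0]
  by_step <- split_steps(filter(sweeps, .data$step > 0))
  purrr::map(steps, function(s) {
    sw <- by_step[[as.character(s)]]
    if (is.null(sw)) return(tibble(step = s, value = NA_real_))
    st <- spike_times(sw$time_ms, sw$response, threshold, min_interval)
    st <- st[st >= on & st < off]
    tibble(step = s, value = if (length(st)) st[1] - on else NA_real_)
  }) |>
    purrr::list_rbind()
}

#' Normalized ISI histogram per neuron type
#'
#' Bins are half-open `[k * bin_ms, (k + 1) * bin_ms)`; each bin count is
#' divided by the number of neurons of that type.
#'
#' @param isis Tibble with columns `type` and `isi_ms` (pooled intervals).
#' @param type_sizes Named vector: number of neurons per type.
#' @param bin_ms Bin width (ms).
#' @return Tibble with `type`, `bin_lo`, `bin_hi`, `count`, `norm_count`.
#' @export
isi_histogram <- function(isis, type_sizes, bin_ms = 5) {
  isis |>
    mutate(bin_lo = floor(.data$isi_ms / bin_ms) * bin_ms) |>
    count(.data$type, .data$bin_lo, name = "count") |>
    mutate(bin_hi = .data$bin_lo + bin_ms,
           norm_count = .data$count / unname(type_sizes[.data$type])) |>
    select("type", "bin_lo", "bin_hi", "count", "norm_count")
}

#' Passive membrane properties from step responses
#'
#' Resting membrane potential (RMP) is the mean of the settled zero-current
#' trace. Input resistance is the through-origin slope of steady-state
#' voltage deflection versus injected current over small hyperpolarizing
#' steps (-30 to -10 pA). The membrane time constant comes from a
#' mono-exponential fit to the onset of the -20 pA step, and capacitance is
#' `tau / R_in`.
#'
#' @param excitability Sweep-set tibble of the excitability protocol.
#' @param rmp_sweep Tibble of the zero-current resting trace
#'   ([simulate_rmp()]), or `NULL` to skip RMP.
#' @param protocol The excitability [protocol_spec()].
#' @param rin_steps Step amplitudes (pA) used for the resistance fit.
#' @param tau_step Step amplitude (pA) used for the time-constant fit.
#' @param fit_window Fit window after onset (ms).
#' @param settle_ms RMP is averaged over the final `settle_ms` of the resting
#'   trace.
#' @return One-row tibble: `rmp` (mV), `input_resistance` (MOhm),
#'   `capacitance` (pF), `tau_m` (ms).
#' @export
passive_properties <- function(excitability, rmp_sweep = NULL,
                               protocol = protocol_excitability(),
                               rin_steps = c(-30, -20, -10), tau_step = -20,
                               fit_window = 150, settle_ms = 200) {
  on <- protocol$step_onset
  off <- on + protocol$step_duration

  rmp <- NA_real_
  if (!is.null(rmp_sweep) && nrow(rmp_sweep) > 0) {
    tmax <- max(rmp_sweep$time_ms)
    rmp <- mean(rmp_sweep$response[rmp_sweep$time_ms >= tmax - settle_ms])
  }

  by_step <- split_steps(excitability)
  dv <- purrr::map(rin_steps, function(s) {
    sw <- by_step[[as.character(s)]]
    if (is.null(sw)) return(NULL)
    base <- mean(sw$response[sw$time_ms >= on - 50 & sw$time_ms < on])
    steady <- mean(sw$response[sw$time_ms >= off - 100 & sw$time_ms < off])
    tibble(i_pa = s, dv_mv = steady - base)
  }) |>
    purrr::list_rbind()
  if (is.null(dv) || nrow(dv) == 0)
    return(tibble(rmp = rmp, input_resistance = NA_real_,
                  capacitance = NA_real_, tau_m = NA_real_))
  # through-origin least squares; mV/pA = GOhm -> MOhm
  rin <- 1000 * sum(dv$dv_mv * dv$i_pa) / sum(dv$i_pa^2)

  tau <- NA_real_
  sw <- by_step[[as.character(tau_step)]]
  if (!is.null(sw)) {
    seg <- filter(sw, .data$time_ms >= on, .data$time_ms <= on + fit_window)
    d <- tibble(t = seg$time_ms - on, v = seg$response)
    fit <- tryCatch(
      nls(v ~ vinf + (v0 - vinf) * exp(-t / tau),
          data = d,
          start = list(vinf = tail(d$v, 1), v0 = d$v[1], tau = 30)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tau <- coef(fit)[["tau"]]
    } else {
      # nls cannot fit zero-residual data; use the exact log-linear form
      vinf <- mean(sw$response[sw$time_ms >= off - 100 & sw$time_ms < off])
      y <- vinf - d$v
      ok <- abs(y) > max(abs(y)) * 1e-6
      if (sum(ok) > 2) {
        sl <- lm(log(abs(y[ok])) ~ d$t[ok])
        tau <- -1 / coef(sl)[[2]]
      }
    }
  }
  tibble(rmp = rmp, input_resistance = rin,
         capacitance = 1000 * tau / rin, tau_m = tau)
}

#' Extract the full per-neuron feature vector
#'
#' Runs every feature extractor over the sweep sets of one or more neurons
#' and assembles the wide per-neuron feature table used by classification,
#' clustering and statistics. Features that require spikes are missing (not
#' zero) when no spikes occur.
#'
#' @param sims Long sweep tibble as from [simulate_neuron()] (columns
#'   `protocol`, `step`, `time_ms`, `command`, `response`), optionally with a
#'   `neuron_id` column for multiple neurons.
#' @param protocols Named protocol list matching the `protocol` column.
#' @param sag_step,rebound_step,ih_step,fsl_step,isi_step Steps at which the
#'   headline parameters are read out (pA / mV).
#' @param ... Passed to the individual extractors (thresholds, windows).
#' @return Tibble with one row per neuron: passives, `sag_80`, `rebound_80`,
#'   `ih_amp_140`, `ih_140` (density, pA/pF), `mfr`, `mfr_step`, `fsl_10`,
#'   `first_isi_40`, `evoked_60`, `max_evoked`, `min_firing_step`.
#' @export
extract_features <- function(sims, protocols = default_protocols(),
                             sag_step = -80, rebound_step = -80,
                             ih_step = -140, fsl_step = 10, isi_step = 40,
                             ...) {
  purrr::list_rbind(purrr::map(
    split_neurons(sims),
    function(d) extract_one(d, protocols, sag_step, rebound_step, ih_step,
                            fsl_step, isi_step, ...)$wide))
}

#' Long per-step feature table
#'
#' One row per neuron, protocol, step and feature; the long companion of
#' [extract_features()] used for step-resolved statistics and plots.
#'
#' @inheritParams extract_features
#' @return Tibble `neuron_id`, `protocol`, `step`, `feature`, `value`.
#' @export
extract_step_features <- function(sims, protocols = default_protocols(),
                                  ...) {
  purrr::list_rbind(purrr::map(
    split_neurons(sims),
    function(d) extract_one(d, protocols, ...)$long))
}

split_neurons <- function(sims) {
  if (!"neuron_id" %in% names(sims)) sims$neuron_id <- "neuron"
  ids <- unique(sims$neuron_id)
  if (length(ids) == 1) return(list(sims))
  split(sims, sims$neuron_id)
}

# one pass over one neuron's sweeps computing every feature once;
# returns both the wide row and the long per-step table
extract_one <- function(d, protocols = default_protocols(),
                        sag_step = -80, rebound_step = -80, ih_step = -140,
                        fsl_step = 10, isi_step = 40, ...) {
  id <- d$neuron_id[1]
  exc <- filter(d, .data$protocol == "excitability")
  vc <- filter(d, .data$protocol == "ih")
  mfr_sw <- filter(d, .data$protocol == "mfr")
  rest <- filter(d, .data$protocol == "rmp")

  pas <- passive_properties(exc, if (nrow(rest)) rest else NULL,
                            protocols$excitability)
  sag <- voltage_sag(exc, protocols$excitability)
  reb <- rebound_spikes(exc, protocols$excitability, ...)
  ev <- count_evoked_spikes(exc, protocols$excitability, ...)
  fsl <- first_spike_latency(exc, protocols$excitability, ...)
  fi <- first_isi(exc, protocols$excitability, ...)
  ih <- if (nrow(vc)) {
    ih_density(ih_amplitude(vc, protocols$ih), pas$capacitance)
  } else {
    tibble(step = numeric(), ih_pa = numeric(), ih_density = numeric())
  }
  counts <- if (nrow(mfr_sw)) {
    pr <- protocols$mfr
    purrr::list_rbind(purrr::map(split_steps(mfr_sw), function(sw) {
      st <- spike_times(sw$time_ms, sw$response)
      st <- st[st >= pr$step_onset & st < pr$step_onset + pr$step_duration]
      blk <- detect_depolarization_block(sw$time_ms, sw$response, st)
      tibble(step = sw$step[1], n = sum(st < blk))
    })) |> arrange(.data$step)
  } else {
    tibble(step = numeric(), n = integer())
  }
  mfr_tb <- if (nrow(counts) && max(counts$n) > 0) {
    tibble(mfr = as.integer(max(counts$n)),
           mfr_step = min(counts$step[counts$n == max(counts$n)]))
  } else if (nrow(counts)) {
    tibble(mfr = 0L, mfr_step = NA_real_)
  } else {
    tibble(mfr = NA_integer_, mfr_step = NA_real_)
  }

  dep <- filter(ev, .data$step > 0)
  fired <- dep$step[dep$n_spikes > 0]
  pick <- function(tb, col, s) {
    v <- tb[[col]][tb$step == s]
    if (length(v)) v[1] else NA_real_
  }
  wide <- tibble(
    neuron_id = id,
    rmp = pas$rmp, input_resistance = pas$input_resistance,
    capacitance = pas$capacitance, tau_m = pas$tau_m,
    sag_80 = pick(sag, "sag_mv", sag_step),
    rebound_80 = pick(reb, "n_rebound", rebound_step),
    ih_amp_140 = pick(ih, "ih_pa", ih_step),
    ih_140 = pick(ih, "ih_density", ih_step),
    mfr = mfr_tb$mfr, mfr_step = mfr_tb$mfr_step,
    fsl_10 = pick(fsl, "value", fsl_step),
    first_isi_40 = pick(fi, "value", isi_step),
    evoked_60 = pick(ev, "n_spikes", 60),
    max_evoked = if (nrow(dep)) max(dep$n_spikes) else NA_real_,
    min_firing_step = if (length(fired)) min(fired) else NA_real_)

  long_tb <- function(tb, proto, feature, col) {
    if (nrow(tb) == 0) return(NULL)
    tibble(neuron_id = id, protocol = proto, step = tb$step,
           feature = feature, value = as.numeric(tb[[col]]))
  }
  long <- purrr::list_rbind(purrr::compact(list(
    long_tb(ev, "excitability", "evoked_spikes", "n_spikes"),
    long_tb(sag, "excitability", "sag", "sag_mv"),
    long_tb(reb, "excitability", "rebound_spikes", "n_rebound"),
    long_tb(fsl, "excitability", "fsl", "value"),
    long_tb(fi, "excitability", "first_isi", "value"),
    long_tb(ih, "ih", "ih_amp", "ih_pa"),
    long_tb(ih, "ih", "ih_density", "ih_density"),
    long_tb(counts, "mfr", "spikes_before_block", "n"))))
  list(wide = wide, long = long)
}
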