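# Independent oracles used across the suite. These deliberately re-derive
# results with naive, loop-based algorithms so they share no code with the
# package implementations they check.

# brute-force spike scan: walk the trace sample by sample, track runs at or
# above threshold, emit the run maximum, then merge events < min_interval
# apart keeping the taller peak
oracle_spike_scan <- function(time_ms, v, threshold = 0, min_interval = 2) {
  peaks_t <- numeric(0)
  peaks_v <- numeric(0)
  in_run <- FALSE
  best_i <- NA_integer_
  for (i in seq_along(v)) {
    if (v[i] >= threshold) {
      if (!in_run || v[i] > v[best_i]) best_i <- i
      in_run <- TRUE
    } else if (in_run) {
      peaks_t <- c(peaks_t, time_ms[best_i])
      peaks_v <- c(peaks_v, v[best_i])
      in_run <- FALSE
    }
  }
  if (in_run) {
    peaks_t <- c(peaks_t, time_ms[best_i])
    peaks_v <- c(peaks_v, v[best_i])
  }
  i <- 1
  while (i < length(peaks_t)) {
    if (peaks_t[i + 1] - peaks_t[i] < min_interval) {
      drop <- if (peaks_v[i] >= peaks_v[i + 1]) i + 1 else i
      peaks_t <- peaks_t[-drop]
      peaks_v <- peaks_v[-drop]
    } else {
      i <- i + 1
    }
  }
  peaks_t
}

# random band-limited trace: sum of a few low-frequency sinusoids plus a
# baseline, mimicking a smooth voltage recording
random_trace <- function(n = 1500, dt = 0.5) {
  t <- seq(0, by = dt, length.out = n)
  nf <- sample(1:4, 1)
  v <- rnorm(1, -55, 10) +
    rowSums(sapply(seq_len(nf), function(j) {
      runif(1, 5, 35) * sin(2 * pi * runif(1, 0.001, 0.02) * t + runif(1, 0, 2 * pi))
    }))
  list(time_ms = t, v = as.numeric(v))
}

# exhaustive Ward agglomeration: at every step recompute, from the raw
# points, the increase in total within-cluster sum of squares for every
# candidate merge, and take the cheapest (lowest creation-order indices on
# ties). Heights are sqrt(2 * delta_SS), the ward.D2 convention.
oracle_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  members <- as.list(seq_len(n))
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  ss <- function(rows) {
    if (length(rows) == 1) return(0)
    xc <- x[rows, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }
  for (s in seq_len(n - 1)) {
    m <- length(members)
    best <- Inf; bi <- NA; bj <- NA
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        cost <- ss(c(members[[i]], members[[j]])) -
          ss(members[[i]]) - ss(members[[j]])
        if (cost < best - 1e-12) {
          best <- cost; bi <- i; bj <- j
        }
      }
    }
    merge[s, ] <- sort(c(id[bi], id[bj]))
    height[s] <- sqrt(2 * best)
    members[[bi]] <- c(members[[bi]], members[[bj]])
    id[bi] <- s
    members[[bj]] <- NULL
    id <- id[-bj]
  }
  list(merge = merge, height = height)
}

# quasi-static ionic steady state: every gate at its voltage steady state
# except the slow K inactivation (time constant far beyond the step), which
# stays frozen at its holding value — the ground truth for what a 500 ms
# step protocol can measure
oracle_steady_iv <- function(p, v, v_hold = -60) {
  sig <- function(v, half, slope) 1 / (1 + exp((v - half) / slope))
  bD <- sig(v_hold, p[["db_half"]], p[["db_slope"]])
  p[["g_l"]] * (v - p[["e_l"]]) +
    p[["g_h"]] * sig(v, p[["h_half"]], p[["h_slope"]]) * (v - p[["e_h"]]) +
    p[["g_t"]] * sig(v, p[["tm_half"]], -p[["tm_slope"]]) *
      sig(v, p[["th_half"]], p[["th_slope"]]) * (v - p[["e_t"]]) +
    p[["g_d"]] * sig(v, p[["da_half"]], -p[["da_slope"]]) * bD *
      (v - p[["e_k"]])
}

# model input resistance (MOhm) over the same -30/-20/-10 pA steps the
# measurement uses, from the quasi-static I-V curve
oracle_input_resistance <- function(p, steps = c(-30, -20, -10)) {
  bias <- oracle_steady_iv(p, -60)
  v_at <- function(i) {
    uniroot(function(v) oracle_steady_iv(p, v) - (bias + i),
            c(-140, -50), tol = 1e-10)$root
  }
  v0 <- v_at(0)
  dv <- vapply(steps, function(i) v_at(i) - v0, numeric(1))
  1000 * sum(dv * steps) / sum(steps^2)
}

# a synthetic current-clamp sweep tibble from an arbitrary voltage function
synthetic_sweep <- function(f, total = 1200, dt = 0.5, step = -80) {
  t <- seq(0, total, by = dt)
  tibble::tibble(step = step, time_ms = t, command = 0, response = f(t))
}
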