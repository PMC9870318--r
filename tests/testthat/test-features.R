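test_that("spike detection handles flat, periodic and merged events", {
  t <- seq(0, 500, by = 0.5)
  flat <- tibble::tibble(time_ms = t, response = rep(-60, length(t)))
  expect_equal(detect_spikes(flat), numeric(0))

  sine <- tibble::tibble(time_ms = t,
                         response = 40 * sin(2 * pi * 10 * t / 1000))
  st <- detect_spikes(sine, threshold = 0)
  expect_equal(st, c(25, 125, 225, 325, 425))

  # two nearby peaks within min_interval merge to the taller one
  v <- rep(-60, length(t))
  v[t == 100] <- 10; v[t == 101] <- 20
  two <- tibble::tibble(time_ms = t, response = v)
  expect_equal(detect_spikes(two, min_interval = 2), 101)
  expect_equal(detect_spikes(two, min_interval = 0.25), c(100, 101))

  expect_error(detect_spikes(flat, mode = "voltage_clamp"), "current-clamp")
})

test_that("spike detector equals the brute-force scan on random traces", {
  set.seed(11)
  for (i in 1:50) {
    tr <- random_trace()
    sw <- tibble::tibble(time_ms = tr$time_ms, response = tr$v)
    expect_equal(detect_spikes(sw, threshold = -40),
                 oracle_spike_scan(tr$time_ms, tr$v, threshold = -40))
  }
})

test_that("evoked spike counting is restricted to the step window", {
  pr <- protocol_excitability()  # step [100, 600)
  t <- seq(0, 1200, by = 0.5)
  v <- rep(-60, length(t))
  v[t %in% c(50, 200, 620)] <- 30
  sw <- tibble::tibble(step = 10, time_ms = t, command = 0, response = v)
  expect_equal(count_evoked_spikes(sw, pr)$n_spikes, 1L)
  v0 <- rep(-60, length(t))
  sw0 <- tibble::tibble(step = 10, time_ms = t, command = 0, response = v0)
  expect_equal(count_evoked_spikes(sw0, pr)$n_spikes, 0L)
})

test_that("voltage sag matches constructed traces and is offset-invariant", {
  pr <- protocol_excitability()
  drop_relax <- function(t) {
    ifelse(t < 100, -60,
           ifelse(t < 600, -75 - 10 * exp(-(t - 100) / 20), -60))
  }
  sw <- synthetic_sweep(drop_relax)
  expect_equal(voltage_sag(sw, pr)$sag_mv, 10, tolerance = 1e-3)
  # constant level during the step: zero sag
  flat <- synthetic_sweep(function(t) ifelse(t >= 100 & t < 600, -70, -60))
  expect_equal(voltage_sag(flat, pr)$sag_mv, 0)
  # monotone relaxation without undershoot: zero sag
  mono <- synthetic_sweep(function(t)
    ifelse(t < 100, -60, ifelse(t < 600, -80 + 5 * exp(-(t - 100) / 50), -60)))
  expect_equal(voltage_sag(mono, pr)$sag_mv, 0)
  # adding a constant offset leaves sag unchanged
  off <- sw
  off$response <- off$response + 12.3
  expect_equal(voltage_sag(off, pr)$sag_mv, voltage_sag(sw, pr)$sag_mv)
})

test_that("rebound spikes count only the post-offset window", {
  pr <- protocol_excitability()  # offset 600
  t <- seq(0, 1200, by = 0.5)
  mk <- function(spike_times) {
    v <- rep(-60, length(t)); v[t %in% spike_times] <- 30
    tibble::tibble(step = -80, time_ms = t, command = 0, response = v)
  }
  expect_equal(rebound_spikes(mk(c(650, 700)), pr)$n_rebound, 2L)
  expect_equal(rebound_spikes(mk(c(200, 400)), pr)$n_rebound, 0L)
  expect_equal(rebound_spikes(mk(1150), pr)$n_rebound, 0L)  # past the window
})

test_that("MFR takes the argmax with lowest-step tie-break", {
  pr <- protocol_mfr()
  t <- seq(0, 1200, by = 0.5)
  mk <- function(step, n) {
    v <- rep(-60, length(t))
    if (n > 0) v[t %in% (150 + 20 * seq_len(n))] <- 30
    tibble::tibble(step = step, time_ms = t, command = 0, response = v)
  }
  sw <- dplyr::bind_rows(mk(50, 2), mk(100, 5), mk(150, 9), mk(200, 4))
  expect_equal(max_firing_rate(sw, pr), tibble::tibble(mfr = 9L, mfr_step = 150))
  tie <- dplyr::bind_rows(mk(100, 7), mk(150, 7))
  expect_equal(max_firing_rate(tie, pr), tibble::tibble(mfr = 7L, mfr_step = 100))
  silent <- mk(100, 0)
  expect_equal(max_firing_rate(silent, pr)$mfr, 0L)
})

test_that("depolarization block truncates within-sweep spike counts", {
  pr <- protocol_mfr()
  t <- seq(0, 1200, by = 0.5)
  # three spikes, then a sustained plateau at -10 mV with no spikes
  v <- rep(-60, length(t))
  v[t %in% c(150, 200, 250)] <- 30
  v[t > 300 & t < 1100] <- -10
  sw <- tibble::tibble(step = 300, time_ms = t, command = 0, response = v)
  st <- detect_spikes(sw)
  blk <- detect_depolarization_block(t, v, st)
  expect_true(is.finite(blk) && blk > 250 && blk < 400)
  expect_equal(max_firing_rate(sw, pr)$mfr, 3L)
  # no plateau, no block
  v2 <- rep(-60, length(t)); v2[t %in% c(150, 200, 250)] <- 30
  expect_equal(detect_depolarization_block(t, v2, detect_spikes(
    tibble::tibble(time_ms = t, response = v2))), Inf)
})

test_that("Ih amplitude follows the analytic clamp fixture and density rules", {
  pr <- protocol_ih()
  t <- seq(0, 1000, by = 0.5)
  resp <- ifelse(t < 100 | t >= 900, -20,
                 -100 - 50 * (1 - exp(-(t - 100) / 100)))
  sw <- tibble::tibble(step = -140, time_ms = t, command = -140,
                       response = resp)
  got <- ih_amplitude(sw, pr)$ih_pa
  # closed form averaged over the same measurement windows
  w_inst <- t >= 110 & t <= 130
  w_steady <- t >= 850 & t < 900
  expected <- abs(mean(resp[w_steady]) - mean(resp[w_inst]))
  expect_equal(got, expected)
  expect_gt(got, 40)  # most of the 50 pA relaxation develops

  expect_equal(ih_density(tibble::tibble(step = -140, ih_pa = 50), 50)$ih_density, 1)
  expect_true(is.na(ih_density(tibble::tibble(step = -140, ih_pa = 50),
                               NA_real_)$ih_density))
  # offset invariance
  sw2 <- sw; sw2$response <- sw2$response + 200
  expect_equal(ih_amplitude(sw2, pr)$ih_pa, got)
})

test_that("ISI, first ISI and FSL follow spike-peak arithmetic", {
  pr <- protocol_excitability()
  t <- seq(0, 1200, by = 0.5)
  v <- rep(-60, length(t)); v[t %in% c(200, 212, 224)] <- 30
  sw <- tibble::tibble(step = 40, time_ms = t, command = 0, response = v)
  isis <- isi_list(sw, pr)
  expect_equal(isis$isi_ms, c(12, 12))
  expect_equal(first_isi(sw, pr)$value[first_isi(sw, pr)$step == 40], 12)
  expect_equal(first_spike_latency(sw, pr)$value[
    first_spike_latency(sw, pr)$step == 40], 100)
  # < 2 spikes: first ISI missing; no spikes: FSL missing
  v1 <- rep(-60, length(t)); v1[t == 250] <- 30
  sw1 <- tibble::tibble(step = 20, time_ms = t, command = 0, response = v1)
  expect_true(is.na(first_isi(sw1, pr)$value[first_isi(sw1, pr)$step == 20]))
  expect_equal(first_spike_latency(sw1, pr)$value[
    first_spike_latency(sw1, pr)$step == 20], 150)
  expect_true(all(is.na(first_spike_latency(sw1, pr)$value[
    first_spike_latency(sw1, pr)$step != 20])))
})

test_that("ISI histogram bins and normalization are consistent", {
  isis <- tibble::tibble(type = c("I", "I", "I", "II"),
                         isi_ms = c(12, 12, 14.9, 30))
  h <- isi_histogram(isis, c(I = 2, II = 4), bin_ms = 5)
  r1 <- dplyr::filter(h, type == "I", bin_lo == 10)
  expect_equal(r1$count, 3L)
  expect_equal(r1$norm_count, 1.5)
  expect_equal(r1$bin_hi, 15)
  # total counts recovered from normalized values times sample size
  tot <- h |>
    dplyr::mutate(back = norm_count * c(I = 2, II = 4)[type]) |>
    dplyr::summarise(s = sum(back))
  expect_equal(tot$s, nrow(isis))
})

test_that("passive properties follow ohmic and exponential arithmetic", {
  pr <- protocol_excitability()
  t <- seq(0, 1200, by = 0.5)
  # ideal RC response: R = 100 MOhm, tau = 10 ms from every step
  rc <- function(step) {
    v <- ifelse(t < 100, -60,
                ifelse(t < 600, -60 + step * 0.1 * (1 - exp(-(t - 100) / 10)),
                       -60))
    tibble::tibble(step = step, time_ms = t, command = 0, response = v)
  }
  sw <- dplyr::bind_rows(lapply(c(-30, -20, -10), rc))
  rest <- tibble::tibble(step = 0, time_ms = seq(0, 500, 0.5),
                         command = 0, response = -65)
  pas <- passive_properties(sw, rest, pr)
  expect_equal(pas$rmp, -65)
  expect_equal(pas$input_resistance, 100, tolerance = 1e-6)
  expect_equal(pas$tau_m, 10, tolerance = 1e-3)
  expect_equal(pas$capacitance, 100, tolerance = 1e-2)  # C = tau / R
})
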