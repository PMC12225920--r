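# Light-evoked EPSP detection, quantification, threshold-intensity and
# responsiveness calls.

test_that("baseline statistics are the pre-stimulus sample mean and SD", {
  flat <- voltage_trace(rep(-70, 4000), rate_hz = 20000, onset_ms = 100, dur_ms = 1)
  bs <- baseline_stats(flat)
  expect_equal(bs$mean_mv, -70)
  expect_equal(bs$sd_mv, 0)
  alt <- voltage_trace(alt_baseline(4000, -71, 1), rate_hz = 20000,
                       onset_ms = 100, dur_ms = 1)
  bsa <- baseline_stats(alt, window_ms = 50)
  expect_equal(bsa$mean_mv, -71)
  expect_equal(bsa$sd_mv, 1.0, tolerance = 1e-3)
  set.seed(42)
  g <- voltage_trace(c(rnorm(1000, -70, 0.1), rep(-70, 100)),
                     rate_hz = 20000, onset_ms = 50, dur_ms = 1)
  expect_equal(baseline_stats(g, 50)$sd_mv, 0.1, tolerance = 0.1)
  expect_error(baseline_stats(flat, window_ms = 200), "exceeds")
})

test_that("event detection implements the 3-SD crossing with debounce", {
  flat <- voltage_trace(rep(-70, 6000), rate_hz = 20000, onset_ms = 100, dur_ms = 1)
  expect_null(detect_event(flat))
  # deflection peaking at 2.5 SD stays undetected
  small <- square_epsp_trace(5, 0.25, base_sd = 0.1)
  expect_null(detect_event(small))
  # clear square event: latency recovered at the pulse onset
  big <- square_epsp_trace(5, 2, base_sd = 0.1)
  ev <- detect_event(big)
  expect_false(is.null(ev))
  expect_equal(ev$latency_ms, 5, tolerance = 0.06 / 5)
  expect_false(ev$truncated)
  # degenerate baseline (SD = 0) is flagged and the noise floor used
  clean <- square_epsp_trace(5, 2, base_sd = 0)
  evc <- detect_event(clean)
  expect_true(evc$degenerate_baseline)
  expect_equal(evc$latency_ms, 5, tolerance = 0.06 / 5)
})

test_that("biexponential EPSP latency is recovered within one sample period", {
  cell <- mc_cell(0)
  syn <- synapse_params(latency_ms = 5, jitter_sd_ms = 0,
                        midpoint_mw = 0.1, slope_per_mw = 100)
  cp <- protocol_spec("cracm", levels = 2, reps = 3, sweep_ms = 400)
  ss <- simulate_cracm_sweeps(cell, syn, cp, seed = 1)
  ev <- detect_event(ss$sweeps[[1]][[1]])
  expect_equal(ev$latency_ms, 5, tolerance = 0.11 / 5)
})

test_that("quantification: amplitude, integral and rise time", {
  # ideal 2 mV square pulse, 10 ms long, 5 ms after the flash
  tr <- square_epsp_trace(5, 2, dur_pulse_ms = 10, base_sd = 0)
  ev <- quantify_event(tr, detect_event(tr))
  expect_equal(ev$amplitude_mv, 2, tolerance = 1e-6)
  expect_equal(ev$integral_mvs, 0.020, tolerance = 0.01)
  expect_lt(ev$risetime_ms, 0.5)
  # alpha-shaped event: peak A at t = tau after onset, rise time ~ tau
  rate <- 20000; A <- 3; tau <- 6
  t <- (seq_len(round(0.4 * rate)) - 1) * 1000 / rate
  v <- rep(-70, length(t))
  post <- t >= 105
  ta <- t[post] - 105
  v[post] <- -70 + A * (ta / tau) * exp(1 - ta / tau)
  atr <- voltage_trace(v, rate_hz = rate, onset_ms = 100, dur_ms = 1)
  aev <- quantify_event(atr, detect_event(atr))
  expect_equal(aev$amplitude_mv, A, tolerance = 1e-3)
  expect_equal(aev$peak_t_ms, 105 + tau, tolerance = 0.01)
  expect_equal(aev$risetime_ms, tau, tolerance = 0.05)
})

test_that("noiseless biexponential events round-trip amplitude and integral", {
  cell <- mc_cell(0)
  syn <- synapse_params(latency_ms = 4, jitter_sd_ms = 0, amp_max_mv = 2,
                        midpoint_mw = 0.1, slope_per_mw = 100)
  cp <- protocol_spec("cracm", levels = 2, reps = 3, sweep_ms = 500)
  ss <- simulate_cracm_sweeps(cell, syn, cp, seed = 1)
  tr <- ss$sweeps[[1]][[1]]
  ev <- quantify_event(tr, detect_event(tr))
  truth <- biexp_truth(2, syn$tau_rise_ms, syn$tau_decay_ms)
  expect_equal(ev$amplitude_mv, 2, tolerance = 0.05)
  expect_equal(ev$integral_mvs, truth$integral_mvs, tolerance = 0.10)
  expect_equal(ev$risetime_ms, truth$peak_time_ms, tolerance = 0.15)
})

test_that("10-trial mean amplitude at noise SD 0.1 stays within 5%", {
  cell <- mc_cell(0.1)
  syn <- synapse_params(latency_ms = 4, jitter_sd_ms = 0.2, amp_max_mv = 2,
                        midpoint_mw = 0.05, slope_per_mw = 200)
  cp <- protocol_spec("cracm", levels = 2, reps = 10, sweep_ms = 400)
  ss <- simulate_cracm_sweeps(cell, syn, cp, seed = 3)
  amps <- vapply(ss$sweeps[[1]], function(tr) {
    quantify_event(tr, detect_event(tr))$amplitude_mv
  }, 0)
  expect_equal(mean(amps), 2, tolerance = 0.05)
})

test_that("threshold intensity applies the all-trials + 1.5 ms latency rule", {
  # events tight only from 0.4 mW upward
  ss <- square_epsp_set(c(0.1, 0.2, 0.4),
                        list(c(NA, 5, NA), c(5, NA, 5), c(5.0, 5.3, 5.5)))
  thr <- threshold_intensity(ss)
  expect_equal(thr$threshold_mw, 0.4)
  expect_true(thr$responsive)
  # all levels respond but latencies spread 2 ms -> no threshold
  wide <- square_epsp_set(c(0.1, 0.2), list(c(4, 5, 6), c(4, 5, 6)))
  expect_false(threshold_intensity(wide)$responsive)
  expect_true(is.na(threshold_intensity(wide)$threshold_mw))
  # appending higher intensities above a qualifying level changes nothing
  ss2 <- square_epsp_set(c(0.1, 0.2, 0.4, 0.8),
                         list(c(NA, 5, NA), c(5, NA, 5), c(5.0, 5.3, 5.5),
                              c(5, 5, 5)))
  expect_equal(threshold_intensity(ss2)$threshold_mw, 0.4)
  expect_error(threshold_intensity(square_epsp_set(0.1, list(c(5, 5)))), "3 trials")
})

test_that("adding depolarization never raises latency nor lowers amplitude", {
  base <- square_epsp_trace(6, 1.5, base_sd = 0.1)
  ev0 <- quantify_event(base, detect_event(base))
  for (extra in c(0.5, 1, 2)) {
    tr <- base
    i_on <- which(trace_time(tr) >= tr$onset_ms + 6)[1]
    tr$v[i_on:length(tr$v)] <- tr$v[i_on:length(tr$v)] + extra
    ev <- quantify_event(tr, detect_event(tr))
    expect_lte(ev$latency_ms, ev0$latency_ms + 1e-9)
    expect_gte(ev$amplitude_mv, ev0$amplitude_mv - 1e-9)
  }
})

test_that("false-positive rate on pure noise stays below 5%", {
  cell <- mc_cell(0.1)
  syn <- synapse_params(midpoint_mw = 10, fail_below = 1)
  cp <- protocol_spec("cracm", levels = 0.01, reps = 500, sweep_ms = 200)
  ss <- simulate_cracm_sweeps(cell, syn, cp, seed = 7)
  fp <- mean(!vapply(ss$sweeps[[1]], function(tr) is.null(detect_event(tr)), TRUE))
  expect_lt(fp, 0.05)
})

test_that("responsiveness calls propagate through a generated cohort", {
  des <- data.frame(type = "VIP", nucleus = "VPM", solution = "K",
                    n = 12L, n_responsive = 9L)
  prot <- protocol_spec("cracm", levels = cracm_ramp(max_mw = 1.5),
                        sweep_ms = 300, rate_hz = 10000)
  g <- generate_cohort(des, seed = 21, sweeps = "cracm", protocol = prot)
  called <- vapply(g$cohort$cell_id, function(id)
    classify_responsive(g$recordings[[id]]), TRUE)
  expect_identical(unname(called), g$cohort$responsive)
  expect_identical(sum(called), 9L)
})
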