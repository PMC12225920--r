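# Intrinsic-property extractors: resting potential, input resistance, time
# constant, sag, AP detection/metrics and the F-I protocol.

ref_step_set <- function(cell, current = -50, reps = 10, seed = 1,
                         sweep_ms = 1200, dur_ms = 1000) {
  prot <- protocol_spec("current-step", levels = current, reps = reps,
                        sweep_ms = sweep_ms, dur_ms = dur_ms)
  simulate_step_protocol(cell, prot, seed = seed)
}

test_that("resting potential averages the pre-stimulus baseline", {
  flat <- voltage_trace(rep(-70, 4000), rate_hz = 20000, onset_ms = 100,
                        dur_ms = 50)
  ss <- sweep_set(list(`-10` = list(flat)))
  expect_equal(resting_potential(ss), -70)
  # two sweeps with baselines -70 / -72 average to -71
  s1 <- flat; s2 <- flat; s2$v <- rep(-72, 4000)
  ss2 <- sweep_set(list(`-10` = list(s1, s2)))
  expect_equal(resting_potential(ss2), -71)
  # pooled over 10 noisy iterations: within +/- 0.05 mV of truth
  cell <- mc_cell(noise_sd = 0.1)
  ssn <- ref_step_set(cell, sweep_ms = 400, dur_ms = 250)
  expect_equal(resting_potential(ssn), cell$v_rest, tolerance = 0.05 / abs(cell$v_rest))
  short <- voltage_trace(rep(-70, 100), rate_hz = 2000, onset_ms = 10, dur_ms = 20)
  expect_error(resting_potential(sweep_set(list(`-10` = list(short)))), "baseline")
})

test_that("input resistance follows Ohm's law and the generator round-trips", {
  cell <- mc_cell()
  cell$r_in <- 100; cell$sag_fraction <- 0
  for (I in c(-50, -10)) {
    ss <- ref_step_set(cell, current = I, reps = 1)
    expect_equal(input_resistance(ss, I), 100, tolerance = 1e-3)
  }
  ss232 <- ref_step_set(mc_cell(0), reps = 1)
  expect_equal(input_resistance(ss232, -50), 232.0, tolerance = 0.01)
  expect_error(input_resistance(ss232, 0), "nonzero")
})

test_that("R_in is invariant to step magnitude for a linear cell", {
  cell <- make_cell_params("VIP", seed = 5, spread = 0, noise_sd = 0)
  cell$sag_fraction <- 0
  r10 <- input_resistance(ref_step_set(cell, -10, reps = 1), -10)
  r50 <- input_resistance(ref_step_set(cell, -50, reps = 1), -50)
  expect_equal(r10, r50, tolerance = 1e-6)
})

test_that("membrane time constant is read from the exponential fit", {
  # pure exponential with tau = 10 ms
  rate <- 20000
  t <- seq(0, 500, by = 1000 / rate)
  v <- c(rep(-70, 2000), -70 - 8 * (1 - exp(-t / 10)))
  tr <- voltage_trace(v, rate_hz = rate, onset_ms = 100, dur_ms = 400)
  fit <- membrane_time_constant(tr)
  expect_true(fit$valid)
  expect_gt(fit$r_squared, 0.999)
  expect_equal(fit$tau_ms, 10, tolerance = 0.02)
  # white noise: R^2 gate rejects
  set.seed(1)
  wn <- voltage_trace(rnorm(10000, -70, 1), rate_hz = rate, onset_ms = 100,
                      dur_ms = 300)
  expect_false(membrane_time_constant(wn)$valid)
  # generator round trip at tau = 30.51 ms with noise
  cell <- mc_cell(noise_sd = 0.1)
  avg <- average_sweep(ref_step_set(cell), -50)
  fit2 <- membrane_time_constant(avg)
  expect_true(fit2$valid)
  expect_equal(fit2$tau_ms, 30.51, tolerance = 0.05)
})

test_that("tau validity fraction rises to 1 as noise vanishes", {
  valid_frac <- function(noise) {
    mean(vapply(1:5, function(s) {
      cell <- make_cell_params("SST-nMC", seed = s, spread = 0.2, noise_sd = noise)
      avg <- average_sweep(ref_step_set(cell, reps = 3, seed = s,
                                        sweep_ms = 600, dur_ms = 450), -50)
      membrane_time_constant(avg)$valid
    }, TRUE))
  }
  expect_equal(valid_frac(0), 1)
  expect_equal(valid_frac(0.05), 1)
})

test_that("sag index implements (peak - steady)/peak", {
  # constructed two-level deflection: peak -10 mV then steady -8 mV
  rate <- 2000
  n_base <- 200; n_peak <- 300; n_ss <- 1500
  v <- c(rep(-70, n_base), seq(-70, -80, length.out = 100),
         rep(-80, n_peak), rep(-78, n_ss))
  tr <- voltage_trace(v, rate_hz = rate, onset_ms = 100,
                      dur_ms = (length(v) - n_base) * 1000 / rate)
  expect_equal(sag_index(tr), 0.2, tolerance = 0.01)
  # no sag: index 0
  cell <- mc_cell(); cell$sag_fraction <- 0
  avg <- average_sweep(ref_step_set(cell, reps = 1), -50)
  expect_equal(sag_index(avg), 0, tolerance = 1e-6)
  # generator round trip at 0.2
  cell$sag_fraction <- 0.2
  avg2 <- average_sweep(ref_step_set(cell, reps = 1), -50)
  expect_equal(sag_index(avg2), 0.2, tolerance = 0.01)
})

test_that("AP detection counts template spikes and finds the 10%-slope threshold", {
  sub <- simulate_step_sweep(mc_cell(), 20, protocol_spec("fi", levels = 20), seed = 1)
  expect_length(detect_aps(sub), 0L)
  cell <- mc_cell()
  for (I in c(cell$rheobase, cell$rheobase + 50)) {
    tr <- simulate_step_sweep(cell, I, protocol_spec("fi", levels = I), seed = 1)
    evs <- detect_aps(tr)
    expect_identical(length(evs), as.integer(attr(tr, "n_spikes")))
    # threshold voltage = template threshold (10% of max slope reached there)
    expect_equal(evs[[1]]$threshold_v, cell$ap_threshold, tolerance = 0.02)
  }
  # detection works down to spikes riding on noise
  noisy <- simulate_step_sweep(mc_cell(0.1), 90,
                               protocol_spec("fi", levels = 90), seed = 2)
  expect_identical(length(detect_aps(noisy)), as.integer(attr(noisy, "n_spikes")))
})

test_that("AP width and AHP follow their geometric definitions", {
  # symmetric triangular spike: threshold -40, peak +20, 1 ms rise and fall
  rate <- 20000
  tr <- triangle_train_trace(50, rise_ms = 1, thr = -40, peak = 20,
                             trough = -75, plateau = -50, rate_hz = rate)
  ev <- detect_aps(tr)
  expect_length(ev, 1L)
  m <- ap_metrics(ev[[1]], tr)
  expect_equal(m$width_ms, 1.0, tolerance = 0.05)       # half of each limb
  expect_equal(m$ahp_mv, ev[[1]]$threshold_v - (-75), tolerance = 0.2)
  # generator template: half-width recovered within one sample period
  cell <- mc_cell()
  tr2 <- simulate_step_sweep(cell, cell$rheobase,
                             protocol_spec("fi", levels = cell$rheobase), seed = 1)
  ev2 <- detect_aps(tr2)
  m2 <- ap_metrics(ev2[[1]], tr2)
  expect_equal(m2$width_ms, cell$ap_halfwidth, tolerance = 0.05 / cell$ap_halfwidth)
  expect_equal(m2$ahp_mv, cell$ahp_depth, tolerance = 0.03)
})

test_that("F-I protocol finds rheobase on the grid and the adaptation ratio", {
  cell <- mc_cell()
  cell$rheobase <- 60
  prot <- protocol_spec("fi", levels = seq(10, 150, 10), reps = 1)
  fi <- fi_protocol(simulate_step_protocol(cell, prot, seed = 1))
  expect_true(fi$rheobase_defined)
  expect_identical(fi$rheobase_pa, 60)
  # regular train (equal tenth counts) -> ratio 0
  reg <- train_set(list(`100` = list(seq(25, 975, by = 50))))
  fi_reg <- fi_protocol(reg)
  expect_equal(fi_reg$adaptation_ratio, 0)
  # firing ceases in the last tenth -> ratio 1
  ceasing <- train_set(list(`100` = list(c(10, 30, 50, 70, 150, 250, 400))))
  expect_equal(fi_protocol(ceasing)$adaptation_ratio, 1)
  # partial adaptation: 4 spikes in first tenth, 2 in last -> 0.5
  part <- train_set(list(`100` = list(c(10, 30, 50, 70, 300, 500, 910, 960))))
  expect_equal(fi_protocol(part)$adaptation_ratio, 0.5)
  # no level spikes: rheobase undefined, flagged
  silent <- ref_step_set(mc_cell(), current = -10, reps = 1)
  fi_s <- fi_protocol(silent)
  expect_false(fi_s$rheobase_defined)
  expect_true(is.na(fi_s$rheobase_pa))
})

test_that("intrinsic_profile assembles the per-cell vector", {
  cell <- mc_cell(noise_sd = 0.1)
  step <- ref_step_set(cell, reps = 5)
  prot <- protocol_spec("fi", levels = seq(20, 120, 10), reps = 1)
  fi <- simulate_step_protocol(cell, prot, seed = 3)
  prof <- intrinsic_profile(step, fi)
  expect_s3_class(prof, "intrinsic_profile")
  expect_equal(prof$rin_mohm, 232, tolerance = 0.05)
  expect_equal(prof$tau_ms, 30.51, tolerance = 0.05)
  expect_equal(prof$rheobase_pa, 40)
  expect_true(prof$tau_valid)
})
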