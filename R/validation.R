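# Validation harnesses: seeded parameter-recovery batteries that run the
# full generator -> extractor loop and report estimate-vs-truth errors.
# These back the package's accuracy claims and the reproduction script.

#' Intrinsic-property recovery battery
#'
#' Generates `n_cells` synthetic cells spanning the VIP / Martinotti /
#' non-Martinotti parameter ranges (log-normal spread, baseline noise
#' 0.1 mV), simulates the hyperpolarizing step protocol (10 iterations of
#' -50 pA) and an ascending F-I series bracketing each cell's rheobase, runs
#' every intrinsic extractor, and tabulates estimates against the generating
#' parameters.
#'
#' @param n_cells Number of cells (default 100).
#' @param seed Integer seed.
#' @param reps Step repetitions per cell (default 10).
#' @return Data frame with one row per cell: subtype, true and estimated
#'   R_in, tau, sag, rheobase (plus the 10-pA grid ceiling of the true
#'   value), AP half-width, and the adaptation ratio estimate together with
#'   the ground-truth ratio counted from the generator's spike times.
#' @export
recovery_battery <- function(n_cells = 100L, seed = 1L, reps = 10L) {
  subtypes <- rep(c("VIP", "SST-MC", "SST-nMC"), length.out = n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell <- make_cell_params(subtypes[i], seed = seed + i, spread = 0.25,
                             noise_sd = 0.1)
    step <- simulate_step_protocol(
      cell, protocol_spec("current-step", levels = -50, reps = reps),
      seed = seed + 1000L + i)
    rin_hat <- input_resistance(step, -50)
    avg <- average_sweep(step, -50)
    tau_hat <- membrane_time_constant(avg)
    sag_hat <- sag_index(avg)
    # ascending 10-pA grid bracketing the rheobase, as the lab ramp would
    lo <- max(10, 10 * floor((cell$rheobase - 30) / 10))
    fi_prot <- protocol_spec("fi", levels = seq(lo, lo + 90, by = 10), reps = 1L)
    fi_sweeps <- simulate_step_protocol(cell, fi_prot, seed = seed + 2000L + i)
    fi <- fi_protocol(fi_sweeps)
    # AP width from a clearly suprathreshold level
    wlev <- fi_prot$levels[which(fi_prot$levels >= cell$rheobase + 40)[1L]]
    width_hat <- NA_real_
    if (!is.na(wlev)) {
      tr <- sweeps_at(fi_sweeps, wlev)[[1L]]
      evs <- detect_aps(tr)
      if (length(evs))
        width_hat <- ap_metrics(evs[[1L]], tr)$width_ms
    }
    # ground-truth adaptation ratio from the generator's spike times at the
    # saturation level used by the estimator
    adapt_true <- NA_real_
    if (fi$rheobase_defined) {
      tr_sat <- sweeps_at(fi_sweeps, fi$saturation_pa)[[1L]]
      st <- attr(tr_sat, "spike_times_ms") - tr_sat$onset_ms
      f10 <- sum(st < tr_sat$dur_ms / 10)
      l10 <- sum(st >= 0.9 * tr_sat$dur_ms)
      if (f10 > 0) adapt_true <- 1 - l10 / f10
    }
    rows[[i]] <- data.frame(
      subtype = subtypes[i],
      rin_true = cell$r_in, rin_hat = rin_hat,
      tau_true = cell$tau_m, tau_hat = tau_hat$tau_ms,
      tau_valid = tau_hat$valid,
      sag_true = cell$sag_fraction, sag_hat = sag_hat,
      rheo_true = cell$rheobase, rheo_grid = 10 * ceiling(cell$rheobase / 10),
      rheo_hat = fi$rheobase_pa,
      width_true = cell$ap_halfwidth, width_hat = width_hat,
      adapt_true = adapt_true, adapt_hat = fi$adaptation_ratio)
  }
  do.call(rbind, rows)
}

#' Threshold-intensity recovery Monte Carlo
#'
#' Replicates the laser-ramp experiment for a synapse with known recruitment
#' midpoint and asks how often the threshold-intensity call lands within one
#' ramp step of the level closest to the midpoint.
#'
#' @param n_seeds Number of replicate experiments (default 200).
#' @param seed Base integer seed.
#' @param midpoint_mw Generating recruitment midpoint (default 0.23 mW).
#' @param jitter_sd_ms Latency jitter SD (default 0.2 ms).
#' @param levels Laser ramp (default [cracm_ramp()]).
#' @param sweep_ms Sweep length per trial (default 300 ms).
#' @return List with `hit_rate` (fraction of seeds within one ramp step),
#'   `thresholds` (per-seed calls, NA when unresponsive) and `target_level`.
#' @export
threshold_recovery_mc <- function(n_seeds = 200L, seed = 1L, midpoint_mw = 0.23,
                                  jitter_sd_ms = 0.2, levels = cracm_ramp(),
                                  sweep_ms = 300) {
  prot <- protocol_spec("cracm", levels = levels, sweep_ms = sweep_ms)
  target_i <- which.min(abs(levels - midpoint_mw))
  cell <- make_cell_params("VIP", seed = seed, spread = 0, noise_sd = 0.1)
  syn <- synapse_params(midpoint_mw = midpoint_mw, jitter_sd_ms = jitter_sd_ms)
  calls <- vapply(seq_len(n_seeds), function(s) {
    ss <- simulate_cracm_sweeps(cell, syn, prot, seed = seed + 7L * s)
    threshold_intensity(ss)$threshold_mw
  }, 0)
  idx <- vapply(calls, function(cv)
    if (is.na(cv)) NA_integer_ else which.min(abs(levels - cv)), 1L)
  hit <- !is.na(idx) & abs(idx - target_i) <= 1L
  list(hit_rate = mean(hit), thresholds = calls,
       target_level = levels[target_i])
}
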