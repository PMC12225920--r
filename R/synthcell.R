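# Synthetic patch-clamp generator: seeded cells, protocols and voltage sweeps
# with the statistical structure the extractors assume. Passive responses are
# RC with an Ih-like sag; spikes are a stereotyped template with geometric
# inter-spike-interval adaptation; light-evoked EPSPs are difference-of-
# exponentials kernels recruited along a sigmoid of laser intensity.

.subtypes <- c("VIP", "SST-MC", "SST-nMC")

# per-subtype parameter centres. R_in / tau_m centres for the SST subtypes are
# the observed Martinotti / non-Martinotti medians (232.0 MOhm, 30.51 ms vs
# 121.5 MOhm, 9.94 ms); the remaining values are plausible interneuron
# waveform/excitability settings, documented in the methods vignette.
.subtype_centers <- list(
  "VIP" = list(v_rest = -62, r_in = 250, tau_m = 15, sag_fraction = 0.10,
               ap_threshold = -40, ap_peak = 25, ap_halfwidth = 0.45,
               ahp_depth = 15, rheobase = 50, adaptation = 0.10),
  "SST-MC" = list(v_rest = -60, r_in = 232.0, tau_m = 30.51, sag_fraction = 0.15,
                  ap_threshold = -42, ap_peak = 22, ap_halfwidth = 0.50,
                  ahp_depth = 12, rheobase = 40, adaptation = 0.15),
  "SST-nMC" = list(v_rest = -64, r_in = 121.5, tau_m = 9.94, sag_fraction = 0.05,
                   ap_threshold = -41, ap_peak = 28, ap_halfwidth = 0.30,
                   ahp_depth = 18, rheobase = 110, adaptation = 0.03)
)

#' Draw parameters for one synthetic cell
#'
#' Deterministic for a given `(subtype, seed)`. With `spread = 0` the cell sits
#' exactly at its subtype centre; otherwise input resistance, time constant and
#' rheobase receive independent log-normal spread (`sdlog = spread`) and the
#' voltage-scale parameters small Gaussian spread, so a seeded battery of cells
#' spans a realistic within-type range.
#'
#' @param subtype One of `"VIP"`, `"SST-MC"`, `"SST-nMC"`.
#' @param seed Integer seed; all randomness of the draw flows from it.
#' @param spread Log-normal sdlog applied to R_in, tau_m and rheobase
#'   (default 0.25); 0 returns the centre values exactly.
#' @param noise_sd Baseline noise SD in mV (default 0.1).
#' @return An object of class `cell_params`.
#' @export
make_cell_params <- function(subtype, seed, spread = 0.25, noise_sd = 0.1) {
  subtype <- match.arg(subtype, .subtypes)
  ctr <- .subtype_centers[[subtype]]
  p <- ctr
  if (spread > 0) {
    rng <- .local_rng(seed)
    p$r_in <- ctr$r_in * exp(rng$norm(1, 0, spread))
    p$tau_m <- ctr$tau_m * exp(rng$norm(1, 0, spread))
    p$rheobase <- ctr$rheobase * exp(rng$norm(1, 0, spread))
    p$sag_fraction <- min(0.6, max(0, ctr$sag_fraction + rng$norm(1, 0, 0.03)))
    p$v_rest <- ctr$v_rest + rng$norm(1, 0, 2)
    p$ap_threshold <- ctr$ap_threshold + rng$norm(1, 0, 1.5)
    p$ahp_depth <- max(5, ctr$ahp_depth + rng$norm(1, 0, 2))
    p$ap_halfwidth <- max(0.2, ctr$ap_halfwidth * exp(rng$norm(1, 0, 0.1)))
  }
  stopifnot(p$r_in > 0, p$tau_m > 0, p$sag_fraction >= 0, p$sag_fraction < 1,
            p$ap_peak > p$ap_threshold, p$ap_threshold > p$v_rest, noise_sd >= 0)
  structure(c(p, list(subtype = subtype, noise_sd = noise_sd, seed = seed)),
            class = "cell_params")
}

#' Synaptic parameters for a transduced-fibre input
#'
#' Describes the light-evoked monosynaptic EPSP of one cell: biexponential
#' kinetics, latency with trial-to-trial jitter, and a sigmoidal recruitment
#' curve over laser intensity that governs both event probability and
#' amplitude scaling.
#'
#' @param latency_ms True synaptic latency after flash onset (ms).
#' @param jitter_sd_ms Trial-to-trial latency jitter SD (ms).
#' @param tau_rise_ms,tau_decay_ms EPSP kinetics; decay must exceed rise.
#' @param amp_max_mv Peak amplitude at recruitment saturation (mV).
#' @param midpoint_mw Laser intensity at half recruitment (mW).
#' @param slope_per_mw Logistic recruitment slope (per mW).
#' @param fail_below Extra failure probability applied below the midpoint
#'   (default 0; 1 makes every sub-midpoint trial a failure).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(latency_ms = 3.7, jitter_sd_ms = 0.2,
                           tau_rise_ms = 2, tau_decay_ms = 15,
                           amp_max_mv = 2, midpoint_mw = 0.23,
                           slope_per_mw = 40, fail_below = 0) {
  stopifnot(latency_ms > 0, jitter_sd_ms >= 0, tau_decay_ms > tau_rise_ms,
            tau_rise_ms > 0, midpoint_mw > 0, fail_below >= 0, fail_below <= 1)
  structure(list(latency_ms = latency_ms, jitter_sd_ms = jitter_sd_ms,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 amp_max_mv = amp_max_mv, midpoint_mw = midpoint_mw,
                 slope_per_mw = slope_per_mw, fail_below = fail_below),
            class = "synapse_params")
}

#' Protocol specification
#'
#' @param kind `"current-step"`, `"fi"` (1-s steps in 10-pA increments) or
#'   `"cracm"` (1-ms flashes over an ascending laser ramp).
#' @param levels Stimulus levels: pA for current protocols, mW for CRACM.
#' @param reps Repetitions per level (CRACM requires at least 3).
#' @param sweep_ms,onset_ms,dur_ms Sweep length, stimulus onset and duration.
#' @param rate_hz Sampling rate; 20 kHz by default.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("current-step", "fi", "cracm"),
                          levels, reps = if (kind == "cracm") 3L else 10L,
                          sweep_ms = if (kind == "cracm") 1000 else 1200,
                          onset_ms = 100,
                          dur_ms = if (kind == "cracm") 1 else 1000,
                          rate_hz = 20000) {
  kind <- match.arg(kind)
  if (length(levels) == 0L) stop("empty level list")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  if (kind == "cracm" && reps < 3L) stop("CRACM protocols need >= 3 repetitions per level")
  if (onset_ms + dur_ms >= sweep_ms) stop("stimulus must end before the sweep does")
  if (sweep_ms <= 0) stop("nonpositive sweep duration")
  structure(list(kind = kind, levels = as.numeric(levels), reps = as.integer(reps),
                 sweep_ms = sweep_ms, onset_ms = onset_ms, dur_ms = dur_ms,
                 rate_hz = rate_hz),
            class = "protocol_spec")
}

#' Default geometric laser ramp
#'
#' Intensities ascending by a constant factor, emulating step-wise laser
#' "titration" from sub-threshold tens of microwatts upward.
#'
#' @param min_mw,max_mw Ramp endpoints (mW).
#' @param factor Geometric step between consecutive intensities.
#' @return Numeric vector of intensities (mW).
#' @export
cracm_ramp <- function(min_mw = 0.03, max_mw = 2.5, factor = 1.5) {
  n <- ceiling(log(max_mw / min_mw) / log(factor))
  min_mw * factor^(0:n)
}

# Self-contained RNG: every generator call draws from its own stream so no
# global seed state leaks between calls.
.local_rng <- function(seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(norm = with_state(stats::rnorm), unif = with_state(stats::runif))
}

# logistic recruitment probability/scale at intensity L
.recruitment <- function(syn, intensity_mw) {
  p <- stats::plogis(syn$slope_per_mw * (intensity_mw - syn$midpoint_mw))
  if (syn$fail_below > 0)
    p <- p * ifelse(intensity_mw < syn$midpoint_mw, 1 - syn$fail_below, 1)
  p
}

# peak-normalised biexponential kernel sampled at dt_ms, long enough to decay
.biexp_kernel <- function(tau_rise, tau_decay, dt_ms, len_ms) {
  t <- seq(0, len_ms, by = dt_ms)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

# closed-form peak time of the biexponential (used by tests and docs)
.biexp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# --- stereotyped action-potential template -----------------------------------
# Piecewise: slow foot (plateau -> threshold), linear upstroke of duration w
# (half-amplitude crossed at w/2), linear downstroke to the AHP trough timed so
# the half-width equals w exactly, then exponential recovery to the plateau.
.ap_template <- function(cell, plateau, dt_ms, foot_ms = 1.5, tau_rec_ms = 3) {
  thr <- cell$ap_threshold
  pk <- cell$ap_peak
  trough <- thr - cell$ahp_depth
  w <- cell$ap_halfwidth
  vhalf <- (thr + pk) / 2
  t_rise <- w                                   # upstroke: half-amp at w/2
  t_fall <- (w / 2) * (pk - trough) / (pk - vhalf) # downstroke: half-amp at w/2 after peak
  t_foot <- foot_ms
  t_rec <- 5 * tau_rec_ms
  tt <- seq(0, t_foot + t_rise + t_fall + t_rec, by = dt_ms)
  v <- numeric(length(tt))
  seg_foot <- tt < t_foot
  v[seg_foot] <- plateau + (thr - plateau) * tt[seg_foot] / t_foot
  seg_rise <- tt >= t_foot & tt < t_foot + t_rise
  v[seg_rise] <- thr + (pk - thr) * (tt[seg_rise] - t_foot) / t_rise
  seg_fall <- tt >= t_foot + t_rise & tt < t_foot + t_rise + t_fall
  v[seg_fall] <- pk - (pk - trough) * (tt[seg_fall] - t_foot - t_rise) / t_fall
  seg_rec <- tt >= t_foot + t_rise + t_fall
  v[seg_rec] <- plateau + (trough - plateau) *
    exp(-(tt[seg_rec] - t_foot - t_rise - t_fall) / tau_rec_ms)
  list(v = v, onset_idx = as.integer(round(t_foot / dt_ms)) + 1L)
}

# spike times (ms, relative to step onset) for a train of n spikes whose
# inter-spike intervals grow geometrically with adaptation strength
.spike_times <- function(n, dur_ms, adaptation, t_first = 5) {
  if (n <= 0L) return(numeric(0))
  if (n == 1L) return(t_first)
  g <- 1 + adaptation
  span <- 0.92 * dur_ms - t_first
  isi1 <- if (abs(g - 1) < 1e-12) span / (n - 1) else span * (g - 1) / (g^(n - 1) - 1)
  t_first + c(0, cumsum(isi1 * g^(0:(n - 2))))
}

# target spike count for a current step: 1 at rheobase, + fi_gain per 10 pA,
# capped at n_max (the saturation plateau)
.spike_count <- function(cell, current_pA, fi_gain = 2, n_max = 30) {
  if (current_pA < cell$rheobase) return(0L)
  as.integer(min(n_max, 1 + round(fi_gain * (current_pA - cell$rheobase) / 10)))
}

#' Simulate one current-step sweep
#'
#' Subthreshold responses follow the RC form
#' `V(t) = V_rest + I * R_in * (1 - exp(-t/tau))`; with a nonzero
#' `sag_fraction` the deflection rises to its peak and then relaxes with time
#' constant `3 * tau_m` toward a steady state of `(1 - sag_fraction)` times the
#' peak. Currents at or above the cell's rheobase evoke a stereotyped spike
#' train whose inter-spike intervals grow geometrically with the adaptation
#' strength. Gaussian baseline noise with the cell's noise SD is added last.
#'
#' @param cell A [make_cell_params()] object.
#' @param current_pA Step current in pA (negative = hyperpolarizing).
#' @param protocol A [protocol_spec()] of kind `"current-step"` or `"fi"`.
#' @param seed Integer seed for the sweep's noise.
#' @return A [voltage_trace()].
#' @export
simulate_step_sweep <- function(cell, current_pA, protocol = NULL, seed = 1) {
  if (is.null(protocol))
    protocol <- protocol_spec("current-step", levels = current_pA)
  if (protocol$kind == "cracm") stop("use simulate_cracm_sweeps for light protocols")
  dt <- 1000 / protocol$rate_hz
  n <- as.integer(round(protocol$sweep_ms / dt))
  t_ms <- (seq_len(n) - 1) * dt
  v <- rep(cell$v_rest, n)
  on_i <- which(t_ms >= protocol$onset_ms)[1L]
  off_i <- which(t_ms >= protocol$onset_ms + protocol$dur_ms)[1L]
  if (is.na(off_i)) off_i <- n + 1L
  step_idx <- on_i:(off_i - 1L)
  ts <- t_ms[step_idx] - protocol$onset_ms
  D <- current_pA * cell$r_in / 1000   # pA * MOhm -> mV
  spiking <- current_pA > 0 && current_pA >= cell$rheobase

  if (!spiking) {
    if (cell$sag_fraction > 0 && current_pA != 0) {
      tp <- -log(1e-3) * cell$tau_m          # rise reaches 99.9% of D
      tau_sag <- 3 * cell$tau_m
      Dss <- (1 - cell$sag_fraction) * D
      Dpk <- 0.999 * D
      defl <- ifelse(ts <= tp,
                     D * (1 - exp(-ts / cell$tau_m)),
                     Dss + (Dpk - Dss) * exp(-(ts - tp) / tau_sag))
    } else {
      defl <- D * (1 - exp(-ts / cell$tau_m))
    }
    if (current_pA > 0)  # subthreshold depolarization is capped near threshold
      defl <- pmin(defl, cell$ap_threshold - 1 - cell$v_rest)
    v[step_idx] <- cell$v_rest + defl
    v_end <- v[off_i - 1L]
    if (off_i <= n)
      v[off_i:n] <- cell$v_rest + (v_end - cell$v_rest) *
        exp(-(t_ms[off_i:n] - t_ms[off_i]) / cell$tau_m)
  } else {
    plateau <- cell$ap_threshold - 2
    rise <- cell$v_rest + (plateau - cell$v_rest) * (1 - exp(-ts / cell$tau_m))
    v[step_idx] <- pmin(rise, plateau)
    n_sp <- .spike_count(cell, current_pA)
    st <- .spike_times(n_sp, protocol$dur_ms, cell$adaptation)
    tmpl <- .ap_template(cell, plateau, dt)
    for (s_ms in st) {
      i0 <- on_i + as.integer(round(s_ms / dt)) - (tmpl$onset_idx - 1L)
      idx <- i0:(i0 + length(tmpl$v) - 1L)
      keep <- idx >= on_i & idx < off_i
      v[idx[keep]] <- tmpl$v[keep]
    }
    if (off_i <= n)
      v[off_i:n] <- cell$v_rest + (v[off_i - 1L] - cell$v_rest) *
        exp(-(t_ms[off_i:n] - t_ms[off_i]) / cell$tau_m)
    attr(v, "spike_times_ms") <- protocol$onset_ms + st
  }

  if (cell$noise_sd > 0) {
    rng <- .local_rng(seed)
    v <- v + rng$norm(n, 0, cell$noise_sd)
  }
  tr <- voltage_trace(as.numeric(v), rate_hz = protocol$rate_hz,
                      onset_ms = protocol$onset_ms, dur_ms = protocol$dur_ms,
                      kind = protocol$kind, level = current_pA,
                      cell_id = as.character(cell$seed))
  attr(tr, "spike_times_ms") <- attr(v, "spike_times_ms")
  attr(tr, "n_spikes") <- if (spiking) .spike_count(cell, current_pA) else 0L
  tr
}

#' Simulate a full current-step protocol into a sweep set
#'
#' @inheritParams simulate_step_sweep
#' @param protocol A [protocol_spec()]; one sweep per repetition per level.
#' @param seed Integer seed; repetition seeds are derived from it.
#' @return A [sweep_set()].
#' @export
simulate_step_protocol <- function(cell, protocol, seed = 1) {
  by_level <- list()
  for (i in seq_along(protocol$levels)) {
    lv <- protocol$levels[i]
    by_level[[as.character(lv)]] <- lapply(seq_len(protocol$reps), function(r)
      simulate_step_sweep(cell, lv, protocol, seed = seed + 1000L * i + r))
  }
  sweep_set(by_level, kind = protocol$kind)
}

#' Simulate a CRACM laser-ramp protocol
#'
#' Per trial, with probability given by the sigmoidal recruitment curve at
#' that intensity, a peak-normalised difference-of-exponentials EPSP (amplitude
#' scaled by the same curve) is injected at `latency + jitter` after flash
#' onset; otherwise the trial is a failure (baseline only). All trials carry
#' Gaussian baseline noise. Cells are represented at a holding potential of
#' -70 mV.
#'
#' @param cell A [make_cell_params()] object (supplies the noise SD).
#' @param syn A [synapse_params()] object.
#' @param protocol A [protocol_spec()] of kind `"cracm"` (1-ms flash).
#' @param seed Integer seed; all trial randomness derives from it.
#' @param hold_mv Holding potential (mV), default -70.
#' @return A [sweep_set()] over the laser ramp. Each trace carries attributes
#'   `event` (logical: was an EPSP injected) and `true_onset_ms`.
#' @export
simulate_cracm_sweeps <- function(cell, syn, protocol, seed = 1, hold_mv = -70) {
  if (protocol$kind != "cracm") stop("protocol kind must be 'cracm'")
  dt <- 1000 / protocol$rate_hz
  n <- as.integer(round(protocol$sweep_ms / dt))
  rng <- .local_rng(seed)
  kern <- .biexp_kernel(syn$tau_rise_ms, syn$tau_decay_ms, dt,
                        len_ms = 8 * syn$tau_decay_ms)
  by_level <- list()
  for (i in seq_along(protocol$levels)) {
    lv <- protocol$levels[i]
    p <- .recruitment(syn, lv)
    trials <- vector("list", protocol$reps)
    for (r in seq_len(protocol$reps)) {
      v <- rep(hold_mv, n)
      has_event <- rng$unif(1) < p
      onset <- NA_real_
      if (has_event) {
        onset <- protocol$onset_ms + syn$latency_ms +
          (if (syn$jitter_sd_ms > 0) rng$norm(1, 0, syn$jitter_sd_ms) else 0)
        amp <- syn$amp_max_mv * p
        i0 <- as.integer(round(onset / dt)) + 1L
        idx <- i0:min(n, i0 + length(kern) - 1L)
        v[idx] <- v[idx] + amp * kern[seq_along(idx)]
      }
      if (cell$noise_sd > 0) v <- v + rng$norm(n, 0, cell$noise_sd)
      tr <- voltage_trace(v, rate_hz = protocol$rate_hz,
                          onset_ms = protocol$onset_ms, dur_ms = protocol$dur_ms,
                          kind = "cracm", level = lv,
                          cell_id = as.character(cell$seed))
      attr(tr, "event") <- has_event
      attr(tr, "true_onset_ms") <- onset
      trials[[r]] <- tr
    }
    by_level[[as.character(lv)]] <- trials
  }
  sweep_set(by_level, kind = "cracm")
}

#' Default cohort design mirroring the study composition
#'
#' One row per (type, nucleus) group with the recorded and responsive cell
#' counts of the mapped cohorts: VPM 53/56 VIP and 52/54 SST responsive,
#' POm 51/54 VIP and 36/41 SST.
#'
#' @return Data frame with columns `type, nucleus, solution, n, n_responsive`.
#' @export
cohort_design_default <- function() {
  data.frame(
    type = c("VIP", "SST", "VIP", "SST"),
    nucleus = c("VPM", "VPM", "POm", "POm"),
    solution = c("K", "K", "Cs", "Cs"),
    n = c(56L, 54L, 54L, 41L),
    n_responsive = c(53L, 52L, 51L, 36L),
    stringsAsFactors = FALSE
  )
}

.layers <- c("LI", "LII/III", "LIV", "LVa", "LVb", "LVI")

#' Generate a synthetic cohort
#'
#' Emits one per-cell record per requested cell and (optionally) a CRACM sweep
#' set per cell. Counts match the design exactly: each (type, nucleus,
#' solution) group gets `n` cells of which exactly `n_responsive` carry a
#' recruitable synapse; the rest are generated with failure probability 1 at
#' every intensity. Layers and normalized depths are drawn from the default
#' laminar proportions; SST cells are split between Martinotti and
#' non-Martinotti subtypes.
#'
#' @param design Data frame with columns `type, nucleus, solution, n,
#'   n_responsive` (default [cohort_design_default()]). An optional `layer`
#'   column pins a group to one layer.
#' @param seed Integer seed.
#' @param sweeps Generate per-cell recordings: `"none"` (records only) or
#'   `"cracm"`.
#' @param protocol CRACM [protocol_spec()] used when `sweeps = "cracm"`;
#'   defaults to a [cracm_ramp()] protocol.
#' @param prob_mc Probability that an SST cell is a Martinotti cell.
#' @return List with `cohort` (per-cell data frame, cohort CSV columns plus
#'   `subtype` ground truth) and `recordings` (named list of CRACM
#'   [sweep_set()]s, empty when `sweeps = "none"`).
#' @export
generate_cohort <- function(design = cohort_design_default(), seed = 1,
                            sweeps = c("none", "cracm"), protocol = NULL,
                            prob_mc = 0.65) {
  sweeps <- match.arg(sweeps)
  if (any(design$n < 0) || any(design$n_responsive < 0))
    stop("negative counts in design")
  if (any(design$n_responsive > design$n))
    stop("n_responsive exceeds n")
  if (nrow(design) == 0L || sum(design$n) == 0L)
    return(list(cohort = data.frame(cell_id = character(), type = character(),
                                    layer = character(), depth_norm = numeric(),
                                    solution = character(), nucleus = character(),
                                    responsive = logical(), subtype = character(),
                                    stringsAsFactors = FALSE),
                recordings = list()))
  if (is.null(protocol) && sweeps == "cracm")
    protocol <- protocol_spec("cracm", levels = cracm_ramp())
  rng <- .local_rng(seed)
  lb <- layer_boundaries()
  layer_w <- lb$to - lb$from   # sample cells proportionally to layer thickness
  rows <- list()
  recordings <- list()
  cid <- 0L
  for (g in seq_len(nrow(design))) {
    ng <- design$n[g]
    if (ng == 0L) next
    resp <- rep(c(TRUE, FALSE), c(design$n_responsive[g], ng - design$n_responsive[g]))
    for (j in seq_len(ng)) {
      cid <- cid + 1L
      id <- sprintf("c%04d", cid)
      if (!is.null(design$layer) && !is.na(design$layer[g])) {
        layer <- design$layer[g]
      } else {
        k <- findInterval(rng$unif(1), cumsum(layer_w) / sum(layer_w)) + 1L
        layer <- lb$layer[min(k, length(lb$layer))]
      }
      li <- match(layer, lb$layer)
      depth <- lb$from[li] + rng$unif(1) * (lb$to[li] - lb$from[li])
      subtype <- if (design$type[g] == "VIP") "VIP" else
        if (rng$unif(1) < prob_mc) "SST-MC" else "SST-nMC"
      rows[[cid]] <- data.frame(
        cell_id = id, type = design$type[g], layer = layer,
        depth_norm = depth, solution = design$solution[g],
        nucleus = design$nucleus[g], responsive = resp[j], subtype = subtype,
        stringsAsFactors = FALSE)
      if (sweeps == "cracm") {
        cell <- make_cell_params(subtype, seed = seed + 17L * cid)
        mid_ctr <- if (design$nucleus[g] == "POm" && design$type[g] == "SST") 0.44 else 0.23
        syn <- synapse_params(
          latency_ms = 3.7 * exp(rng$norm(1, 0, 0.15)),
          midpoint_mw = mid_ctr * exp(rng$norm(1, 0, 0.3)),
          amp_max_mv = 2 * exp(rng$norm(1, 0, 0.3)))
        if (!resp[j]) syn$fail_below <- 1
        ss <- simulate_cracm_sweeps(cell, syn, protocol, seed = seed + 31L * cid)
        if (!resp[j]) {
          # unresponsive cells: strip any supra-midpoint event, pure noise only
          ss$sweeps <- lapply(ss$sweeps, function(trials) lapply(trials, function(tr) {
            if (isTRUE(attr(tr, "event"))) {
              tr$v <- rep(-70, length(tr$v)) +
                rng$norm(length(tr$v), 0, max(cell$noise_sd, 1e-6))
              attr(tr, "event") <- FALSE
              attr(tr, "true_onset_ms") <- NA_real_
            }
            tr
          }))
        }
        recordings[[id]] <- ss
      }
    }
  }
  list(cohort = do.call(rbind, rows), recordings = recordings)
}
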