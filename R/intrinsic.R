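# Intrinsic electrophysiological properties from current-step sweep sets:
# resting potential, input resistance (Ohm's law on the largest deflection),
# membrane time constant (exponential fit, R^2-gated), sag index, AP detection
# with the 10%-of-maximum-slope threshold criterion, AP width/AHP, and the
# F-I protocol (rheobase, saturation, 10:01 adaptation ratio).

#' Resting membrane potential
#'
#' Mean pre-stimulus membrane voltage pooled across all repetitions of the
#' hyperpolarizing step protocol.
#'
#' @param sweeps A [sweep_set()] (typically the -10 or -50 pA iterations).
#' @param baseline_ms Pre-stimulus window to average over, counted back from
#'   stimulus onset; `NULL` (default) uses the whole pre-stimulus segment.
#'   At least 50 ms of baseline must be available.
#' @return Resting potential in mV.
#' @export
resting_potential <- function(sweeps, baseline_ms = NULL) {
  tr <- unlist(sweeps$sweeps, recursive = FALSE)
  t0 <- tr[[1L]]
  if (t0$onset_ms < 50) stop("need >= 50 ms of pre-stimulus baseline")
  win <- if (is.null(baseline_ms)) t0$onset_ms else min(baseline_ms, t0$onset_ms)
  i1 <- .time_index(t0, t0$onset_ms - win)
  i2 <- .time_index(t0, t0$onset_ms) - 1L
  if (i2 < i1) stop("no pre-stimulus window")
  mean(vapply(tr, function(s) mean(s$v[i1:i2]), 0))
}

# average sweep at a level together with its baseline mean and step indices
.step_segments <- function(ss, level) {
  avg <- average_sweep(ss, level)
  i_on <- .time_index(avg, avg$onset_ms)
  i_off <- min(length(avg$v), .time_index(avg, avg$onset_ms + avg$dur_ms))
  base <- mean(avg$v[1:(i_on - 1L)])
  list(avg = avg, i_on = i_on, i_off = i_off, base = base)
}

#' Input resistance by Ohm's law
#'
#' Potential change measured from rest to the highest (largest-magnitude)
#' deflection on the average sweep, divided by the step current.
#'
#' @param sweeps A [sweep_set()] of current steps.
#' @param current_pA Step current in pA (nonzero; hyperpolarizing in practice).
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sweeps, current_pA = min(sweeps$levels)) {
  if (current_pA == 0) stop("step current must be nonzero")
  sg <- .step_segments(sweeps, current_pA)
  defl <- sg$avg$v[sg$i_on:sg$i_off] - sg$base
  peak <- defl[which.max(abs(defl))]
  1000 * peak / current_pA   # mV / pA -> MOhm
}

#' Membrane time constant from an exponential fit
#'
#' Fits `V(t) = V0 + dV * (1 - exp(-t/tau))` from stimulus onset to the highest
#' deflection of the average sweep (Levenberg-Marquardt least squares) and
#' returns the time at which 63% of the peak voltage change is reached,
#' read from the fitted curve. The fit is flagged invalid when its R-squared
#' is at or below 0.9.
#'
#' @param avg_sweep Average [voltage_trace()] of the hyperpolarizing steps
#'   used for the input resistance.
#' @return List with `tau_ms` (time to 63% of peak change), `tau_fit_ms`
#'   (the fitted exponential constant), `r_squared` and `valid`.
#' @export
membrane_time_constant <- function(avg_sweep) {
  i_on <- .time_index(avg_sweep, avg_sweep$onset_ms)
  i_off <- min(length(avg_sweep$v), .time_index(avg_sweep, avg_sweep$onset_ms + avg_sweep$dur_ms))
  base <- mean(avg_sweep$v[1:(i_on - 1L)])
  seg <- avg_sweep$v[i_on:i_off]
  i_pk <- which.max(abs(seg - base))
  if (i_pk < 5L) stop("fewer than 5 samples between onset and peak")
  t <- (seq_len(i_pk) - 1) * 1000 / avg_sweep$rate_hz
  y <- seg[seq_len(i_pk)]
  dv0 <- y[i_pk] - base
  tau0 <- max(t[i_pk] / 5, t[min(which(abs(y - base) >= 0.63 * abs(dv0)))], 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ v0 + dv * (1 - exp(-t / tau)),
                      start = list(v0 = base, dv = dv0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau_ms = NA_real_, tau_fit_ms = NA_real_,
                r_squared = 0, valid = FALSE))
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  # 63% of the fitted change at the highest deflection
  frac_pk <- 1 - exp(-t[i_pk] / cf[["tau"]])
  t63 <- -cf[["tau"]] * log(1 - 0.63 * frac_pk)
  list(tau_ms = unname(t63), tau_fit_ms = unname(cf[["tau"]]),
       r_squared = r2, valid = is.finite(r2) && r2 > 0.9 && cf[["tau"]] > 0)
}

#' Sag index
#'
#' Fractional relaxation of a hyperpolarizing response: voltage change at the
#' highest deflection minus change at steady state, divided by the former.
#' Steady state is measured over the final fraction of the step (default the
#' last 20%).
#'
#' @param avg_sweep Average [voltage_trace()] of a hyperpolarizing step.
#' @param ss_fraction Fraction of the step, counted from its end, over which
#'   the steady-state voltage is averaged (default 0.2).
#' @return Sag index (dimensionless; 0 for a pure RC response).
#' @export
sag_index <- function(avg_sweep, ss_fraction = 0.2) {
  i_on <- .time_index(avg_sweep, avg_sweep$onset_ms)
  i_off <- min(length(avg_sweep$v), .time_index(avg_sweep, avg_sweep$onset_ms + avg_sweep$dur_ms))
  base <- mean(avg_sweep$v[1:(i_on - 1L)])
  seg <- avg_sweep$v[i_on:i_off]
  dpk <- seg[which.max(abs(seg - base))] - base
  if (dpk == 0) stop("zero peak deflection")
  i_ss <- max(1L, floor(length(seg) * (1 - ss_fraction)))
  dss <- mean(seg[i_ss:length(seg)]) - base
  (dpk - dss) / dpk
}

#' Detect action potentials
#'
#' Events are seeded as voltage excursions above a coarse peak criterion
#' (default -20 mV, peaks separated by at least 1 ms); per event, the AP
#' threshold is the first sample, searching backward from the peak, at which
#' the upstroke slope still reaches 10% of that AP's maximum rising slope.
#'
#' @param trace A [voltage_trace()].
#' @param peak_criterion_mv Coarse seeding criterion (default -20 mV).
#' @param min_separation_ms Minimum peak separation (default 1 ms).
#' @return List of `ap_event` objects (possibly empty), ordered in time. Each
#'   has `peak_idx`, `peak_t_ms`, `peak_v`, `threshold_idx`, `threshold_t_ms`,
#'   `threshold_v` and `max_slope_mv_ms`.
#' @export
detect_aps <- function(trace, peak_criterion_mv = -20, min_separation_ms = 1) {
  v <- trace$v
  dt <- 1000 / trace$rate_hz
  above <- v > peak_criterion_mv
  if (!any(above)) return(list())
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peak_idx <- integer(0)
  for (r in which(runs$values)) {
    seg <- starts[r]:ends[r]
    peak_idx <- c(peak_idx, seg[which.max(v[seg])])
  }
  # merge peaks closer than the separation criterion, keep the higher one
  if (length(peak_idx) > 1L) {
    keep <- peak_idx[1L]
    for (p in peak_idx[-1L]) {
      if ((p - keep[length(keep)]) * dt < min_separation_ms) {
        if (v[p] > v[keep[length(keep)]]) keep[length(keep)] <- p
      } else keep <- c(keep, p)
    }
    peak_idx <- keep
  }
  slopes <- c(diff(v) / dt, 0)   # forward-difference slope at each sample
  prev_pk <- 0L
  events <- vector("list", length(peak_idx))
  for (e in seq_along(peak_idx)) {
    pk <- peak_idx[e]
    lo <- max(prev_pk + 1L, pk - as.integer(round(10 / dt)), 1L)
    rise <- lo:max(lo, pk - 1L)
    smax <- max(slopes[rise])
    thr_i <- pk
    i <- pk - 1L
    while (i >= lo && slopes[i] >= 0.1 * smax) {
      thr_i <- i
      i <- i - 1L
    }
    events[[e]] <- structure(
      list(peak_idx = pk, peak_t_ms = (pk - 1) * dt, peak_v = v[pk],
           threshold_idx = thr_i, threshold_t_ms = (thr_i - 1) * dt,
           threshold_v = v[thr_i], max_slope_mv_ms = smax),
      class = "ap_event")
    prev_pk <- pk
  }
  events
}

#' AP width and afterhyperpolarization
#'
#' Width is the time between the upstroke and downstroke crossings of the
#' half-amplitude voltage `(threshold + peak) / 2` (sub-sample linear
#' interpolation); the AHP amplitude is the difference between the threshold
#' voltage and the post-AP hyperpolarization trough.
#'
#' @param event An `ap_event` from [detect_aps()].
#' @param trace The [voltage_trace()] the event was detected in.
#' @param next_event_idx Sample index bounding the search for the AHP trough
#'   (default: 25 ms after the peak or the end of the trace).
#' @return List with `width_ms`, `ahp_mv`, `trough_v` and `truncated` (TRUE if
#'   the downstroke never returned to half-amplitude inside the trace).
#' @export
ap_metrics <- function(event, trace, next_event_idx = NULL) {
  v <- trace$v
  dt <- 1000 / trace$rate_hz
  half <- (event$threshold_v + event$peak_v) / 2
  # upstroke crossing (between threshold and peak)
  up <- event$threshold_idx:event$peak_idx
  iu <- up[which(v[up] >= half)[1L]]
  t_up <- (iu - 1) * dt
  if (iu > 1L && v[iu] > half && v[iu - 1L] < half)
    t_up <- t_up - dt * (v[iu] - half) / (v[iu] - v[iu - 1L])
  # downstroke crossing
  lim <- if (is.null(next_event_idx))
    min(length(v), event$peak_idx + as.integer(round(25 / dt))) else next_event_idx
  down <- event$peak_idx:lim
  below <- which(v[down] <= half)
  if (length(below) == 0L)
    return(list(width_ms = NA_real_, ahp_mv = NA_real_,
                trough_v = NA_real_, truncated = TRUE))
  id <- down[below[1L]]
  t_dn <- (id - 1) * dt
  if (id > 1L && v[id] < half && v[id - 1L] > half)
    t_dn <- t_dn - dt * (half - v[id]) / (v[id - 1L] - v[id])
  trough <- min(v[id:lim])
  list(width_ms = t_dn - t_up, ahp_mv = event$threshold_v - trough,
       trough_v = trough, truncated = FALSE)
}

# spike count within [t1, t2) ms of the stimulus window of a trace
.count_spikes_in <- function(events, trace, t1, t2) {
  if (length(events) == 0L) return(0L)
  pt <- vapply(events, function(e) e$peak_t_ms, 0) - trace$onset_ms
  sum(pt >= t1 & pt < t2)
}

#' F-I protocol: rheobase, saturation and adaptation
#'
#' Scans an ascending series of 1-s current steps. Rheobase is the lowest
#' level evoking at least one AP. The cell is considered saturated at the
#' first level whose AP count does not exceed the previous level's, or whose
#' AP-amplitude coefficient of variation exceeds `cv_limit`; the 10:01
#' adaptation ratio, `1 - (count in last tenth)/(count in first tenth)` of the
#' stimulus window, is computed at the saturation level and averaged over
#' repetitions.
#'
#' @param sweeps A [sweep_set()] over ascending current steps.
#' @param cv_limit AP-amplitude coefficient-of-variation bound used as a
#'   secondary saturation criterion (default 0.2).
#' @return List with `rheobase_pa` (NA with `rheobase_defined = FALSE` when no
#'   level spikes), `fi_curve` (data frame level/mean AP count),
#'   `saturation_pa`, `adaptation_ratio` and per-tenth counts.
#' @export
fi_protocol <- function(sweeps, cv_limit = 0.2) {
  lv <- sweeps$levels
  counts <- numeric(length(lv))
  spiked <- logical(length(lv))
  ev_by_level <- vector("list", length(lv))
  for (i in seq_along(lv)) {
    evs <- lapply(sweeps$sweeps[[i]], detect_aps)
    ev_by_level[[i]] <- evs
    counts[i] <- mean(vapply(evs, length, 0L))
    spiked[i] <- any(vapply(evs, length, 0L) > 0L)
  }
  fi <- data.frame(level_pa = lv, ap_count = counts)
  if (!any(spiked))
    return(list(rheobase_pa = NA_real_, rheobase_defined = FALSE,
                fi_curve = fi, saturation_pa = NA_real_,
                adaptation_ratio = NA_real_))
  rheo <- lv[which(spiked)[1L]]
  sat_i <- length(lv)
  for (i in seq_along(lv)[-1L]) {
    amp_cv <- {
      amps <- unlist(lapply(ev_by_level[[i]], function(evs)
        vapply(evs, function(e) e$peak_v, 0)))
      if (length(amps) > 1L && mean(amps) != 0) stats::sd(amps) / abs(mean(amps)) else 0
    }
    if (counts[i] <= counts[i - 1L] && counts[i] > 0 || amp_cv > cv_limit) {
      sat_i <- i
      break
    }
  }
  tr_sat <- sweeps$sweeps[[sat_i]]
  dur <- tr_sat[[1L]]$dur_ms
  first10 <- vapply(seq_along(tr_sat), function(r)
    .count_spikes_in(ev_by_level[[sat_i]][[r]], tr_sat[[r]], 0, dur / 10), 0)
  last10 <- vapply(seq_along(tr_sat), function(r)
    .count_spikes_in(ev_by_level[[sat_i]][[r]], tr_sat[[r]], dur * 0.9, dur), 0)
  adapt <- if (mean(first10) > 0) 1 - mean(last10) / mean(first10) else NA_real_
  list(rheobase_pa = rheo, rheobase_defined = TRUE, fi_curve = fi,
       saturation_pa = lv[sat_i], adaptation_ratio = adapt,
       first_tenth_count = mean(first10), last_tenth_count = mean(last10))
}

#' Extract the full intrinsic profile of one cell
#'
#' Convenience wrapper running every intrinsic extractor on a hyperpolarizing
#' step sweep set and an F-I sweep set.
#'
#' @param step_sweeps [sweep_set()] with the -10/-50 pA iterations.
#' @param fi_sweeps Optional [sweep_set()] over the F-I ramp.
#' @param step_pa Which hyperpolarizing level to use (default the most
#'   negative).
#' @return A one-row data frame (`intrinsic_profile`): `vm_mv, rin_mohm,
#'   tau_ms, tau_r2, tau_valid, sag, rheobase_pa, ap_threshold_mv, ap_width_ms,
#'   ahp_mv, adaptation_ratio`.
#' @export
intrinsic_profile <- function(step_sweeps, fi_sweeps = NULL,
                              step_pa = min(step_sweeps$levels)) {
  vm <- resting_potential(step_sweeps)
  rin <- input_resistance(step_sweeps, step_pa)
  avg <- average_sweep(step_sweeps, step_pa)
  tau <- membrane_time_constant(avg)
  sag <- sag_index(avg)
  out <- data.frame(vm_mv = vm, rin_mohm = rin, tau_ms = tau$tau_ms,
                    tau_r2 = tau$r_squared, tau_valid = tau$valid, sag = sag,
                    rheobase_pa = NA_real_, ap_threshold_mv = NA_real_,
                    ap_width_ms = NA_real_, ahp_mv = NA_real_,
                    adaptation_ratio = NA_real_)
  if (!is.null(fi_sweeps)) {
    fi <- fi_protocol(fi_sweeps)
    out$rheobase_pa <- fi$rheobase_pa
    out$adaptation_ratio <- fi$adaptation_ratio
    if (fi$rheobase_defined) {
      tr <- sweeps_at(fi_sweeps, fi$rheobase_pa)[[1L]]
      evs <- detect_aps(tr)
      if (length(evs)) {
        m <- ap_metrics(evs[[1L]], tr)
        out$ap_threshold_mv <- evs[[1L]]$threshold_v
        out$ap_width_ms <- m$width_ms
        out$ahp_mv <- m$ahp_mv
      }
    }
  }
  class(out) <- c("intrinsic_profile", class(out))
  out
}
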