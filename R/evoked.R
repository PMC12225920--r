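# Detection and quantification of light-evoked monosynaptic EPSPs and the
# threshold-intensity / responsiveness calls. Detection criterion: membrane
# voltage passes 3x the SD of the pre-stimulus baseline and stays above it for
# a debounce period; the response ends when the voltage returns below that
# level. The amplitude is the maximum deviation within the first 50 ms of the
# flash, the integral is the area between trace and baseline over the
# response, and the rise time runs from threshold crossing to the peak.

#' Baseline mean and SD before the stimulus
#'
#' @param trace A [voltage_trace()].
#' @param window_ms Pre-stimulus window length (default 50 ms), counted back
#'   from the stimulus onset. Must fit before the onset.
#' @return List with `mean_mv` and `sd_mv` (sample SD, n-1 denominator).
#' @export
baseline_stats <- function(trace, window_ms = 50) {
  if (window_ms > trace$onset_ms) stop("window exceeds available baseline")
  i2 <- .time_index(trace, trace$onset_ms) - 1L
  i1 <- .time_index(trace, trace$onset_ms - window_ms)
  seg <- trace$v[i1:i2]
  list(mean_mv = mean(seg), sd_mv = stats::sd(seg))
}

#' Detect a light-evoked event in one sweep
#'
#' Scans a post-flash search window (default 1-50 ms after onset; the 1-ms
#' lower bound excludes the stimulus artifact) for the first depolarization
#' exceeding `baseline mean + 3 * SD` that persists for at least the debounce
#' period. The event ends at the first later return below that level (or the
#' sweep end, flagged truncated). Hyperpolarizing deflections are ignored.
#'
#' @param trace A [voltage_trace()] held near -70 mV.
#' @param window_ms Search window after flash onset, `c(lower, upper)` in ms.
#' @param baseline_ms Baseline window passed to [baseline_stats()].
#' @param debounce_ms Minimum time the crossing must persist (default 0.5 ms).
#' @param k_sd Criterion multiple of the baseline SD (default 3).
#' @param noise_floor_mv SD floor substituted when the baseline SD is
#'   degenerate (0); such events carry `degenerate_baseline = TRUE`.
#' @return An `evoked_event` list (`latency_ms`, `crossing_t_ms`, `end_t_ms`,
#'   `threshold_level_mv`, `truncated`, `degenerate_baseline`) or `NULL` when
#'   no qualifying crossing exists.
#' @export
detect_event <- function(trace, window_ms = c(1, 50), baseline_ms = 50,
                         debounce_ms = 0.5, k_sd = 3, noise_floor_mv = 0.01) {
  bs <- baseline_stats(trace, baseline_ms)
  degenerate <- bs$sd_mv <= .Machine$double.eps
  sdv <- if (degenerate) noise_floor_mv else bs$sd_mv
  level <- bs$mean_mv + k_sd * sdv
  dt <- 1000 / trace$rate_hz
  i1 <- .time_index(trace, trace$onset_ms + window_ms[1L])
  i2 <- min(length(trace$v), .time_index(trace, trace$onset_ms + window_ms[2L]))
  if (i2 <= i1) stop("empty search window")
  nb <- max(1L, as.integer(round(debounce_ms / dt)))
  above <- trace$v >= level
  cross <- NA_integer_
  i <- i1
  while (i <= i2) {
    if (above[i]) {
      j <- min(length(above), i + nb - 1L)
      if (all(above[i:j])) {
        cross <- i
        break
      }
      i <- i + which(!above[i:j])[1L]  # skip past the failed run
    } else i <- i + 1L
  }
  if (is.na(cross)) return(NULL)
  after <- which(!above[cross:length(above)])
  truncated <- length(after) == 0L
  end_i <- if (truncated) length(above) else cross + after[1L] - 1L
  structure(list(
    latency_ms = (cross - 1) * dt - trace$onset_ms,
    crossing_idx = cross, end_idx = end_i,
    crossing_t_ms = (cross - 1) * dt, end_t_ms = (end_i - 1) * dt,
    threshold_level_mv = level, baseline_mv = bs$mean_mv,
    baseline_sd_mv = bs$sd_mv, truncated = truncated,
    degenerate_baseline = degenerate), class = "evoked_event")
}

#' Quantify a detected event
#'
#' Completes an `evoked_event` with amplitude (maximum deviation from baseline
#' within the first 50 ms of the flash), integral (trapezoidal area between
#' trace and baseline from the threshold crossing to the response end, in
#' mV*s) and rise time (threshold crossing to peak).
#'
#' @param trace The [voltage_trace()] the event was detected in.
#' @param event An `evoked_event` from [detect_event()].
#' @param amp_window_ms Amplitude window after flash onset (default 50 ms).
#' @param amp_smooth_ms Centered moving-average window applied to the trace
#'   before reading off the peak (default 0.5 ms). EPSP peaks are smooth on
#'   the millisecond scale, so this suppresses the upward bias that taking a
#'   pointwise maximum over wideband noise would add; 0 disables.
#' @return The completed `evoked_event` with `amplitude_mv`, `integral_mvs`,
#'   `risetime_ms`, `peak_t_ms` and `peak_outside_window` flag.
#' @export
quantify_event <- function(trace, event, amp_window_ms = 50,
                           amp_smooth_ms = 0.5) {
  dt <- 1000 / trace$rate_hz
  i_on <- .time_index(trace, trace$onset_ms)
  i_w <- min(length(trace$v), .time_index(trace, trace$onset_ms + amp_window_ms))
  v_amp <- trace$v
  k <- as.integer(round(amp_smooth_ms / dt))
  if (k > 1L) {
    if (k %% 2L == 0L) k <- k + 1L
    sm <- as.numeric(stats::filter(v_amp, rep(1 / k, k), sides = 2L))
    v_amp[!is.na(sm)] <- sm[!is.na(sm)]
  }
  wseg <- v_amp[i_on:i_w] - event$baseline_mv
  amp <- max(wseg)
  pk_i <- i_on + which.max(wseg) - 1L
  # integral over the whole response (crossing to end), baseline-referenced
  rseg <- trace$v[event$crossing_idx:event$end_idx] - event$baseline_mv
  integ <- sum((rseg[-1L] + rseg[-length(rseg)]) / 2) * dt / 1000  # mV*s
  event$amplitude_mv <- amp
  event$peak_t_ms <- (pk_i - 1) * dt
  event$risetime_ms <- event$peak_t_ms - event$crossing_t_ms
  event$integral_mvs <- integ
  event$peak_outside_window <- pk_i >= i_w
  event
}

#' Threshold-intensity call over a laser ramp
#'
#' Scanning the ramp in ascending order, the threshold intensity is the lowest
#' level at which every trial yields a detected event and the latency spread
#' (max - min) across the level's trials stays within `latency_range_ms`
#' (1.5 ms). Event metrics at the threshold level are averaged into the
#' cell's threshold-response record.
#'
#' @param sweeps A [sweep_set()] over an ascending laser ramp with >= 3
#'   trials per level.
#' @param latency_range_ms Consistency window for "reliably following" events.
#' @param ... Passed to [detect_event()].
#' @return A `threshold_result` list: `threshold_mw` (NA when no level
#'   qualifies), `responsive`, per-trial events at threshold and mean
#'   `latency_ms`, `amplitude_mv`, `integral_mvs`, `risetime_ms`.
#' @export
threshold_intensity <- function(sweeps, latency_range_ms = 1.5, ...) {
  if (any(vapply(sweeps$sweeps, length, 0L) < 3L))
    stop("need >= 3 trials per level")
  for (i in seq_along(sweeps$levels)) {
    trials <- sweeps$sweeps[[i]]
    events <- lapply(trials, detect_event, ...)
    if (any(vapply(events, is.null, TRUE))) next
    lat <- vapply(events, function(e) e$latency_ms, 0)
    if (diff(range(lat)) > latency_range_ms) next
    events <- Map(quantify_event, trials, events)
    return(structure(list(
      threshold_mw = sweeps$levels[i], responsive = TRUE, events = events,
      latency_ms = mean(lat),
      amplitude_mv = mean(vapply(events, function(e) e$amplitude_mv, 0)),
      integral_mvs = mean(vapply(events, function(e) e$integral_mvs, 0)),
      risetime_ms = mean(vapply(events, function(e) e$risetime_ms, 0))),
      class = "threshold_result"))
  }
  structure(list(threshold_mw = NA_real_, responsive = FALSE, events = list(),
                 latency_ms = NA_real_, amplitude_mv = NA_real_,
                 integral_mvs = NA_real_, risetime_ms = NA_real_),
            class = "threshold_result")
}

#' Responsiveness call
#'
#' A cell is responsive iff some intensity on the tested ramp qualifies as a
#' threshold level (see [threshold_intensity()]).
#'
#' @inheritParams threshold_intensity
#' @return Logical.
#' @export
classify_responsive <- function(sweeps, ...) {
  if (length(sweeps$levels) == 0L) stop("empty ramp")
  threshold_intensity(sweeps, ...)$responsive
}
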