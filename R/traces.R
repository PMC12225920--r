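# Sweep containers: a voltage_trace is the atomic unit every extractor consumes,
# a sweep_set groups repetitions by protocol level (current step in pA or laser
# intensity in mW).

#' Construct a voltage trace
#'
#' A single current-clamp sweep: a sampled membrane-voltage vector plus the
#' stimulus annotation needed to interpret it.
#'
#' @param v Numeric vector of membrane voltage samples (mV). Must be finite.
#' @param rate_hz Sampling rate in Hz (default 20000, i.e. 20 kHz digitisation).
#' @param onset_ms Stimulus onset, ms from the first sample.
#' @param dur_ms Stimulus duration in ms.
#' @param kind Stimulus kind: `"current-step"`, `"fi"` or `"cracm"`.
#' @param level Stimulus level: current in pA or laser intensity in mW.
#' @param cell_id Optional cell identifier.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(v, rate_hz = 20000, onset_ms = 100, dur_ms = 1000,
                          kind = "current-step", level = NA_real_,
                          cell_id = NA_character_) {
  v <- as.numeric(v)
  if (length(v) < 2L) stop("trace must contain at least 2 samples")
  if (!all(is.finite(v))) stop("trace samples must be finite")
  if (rate_hz <= 0) stop("sampling rate must be positive")
  if (onset_ms < 0 || onset_ms > 1000 * length(v) / rate_hz)
    stop("stimulus onset lies outside the trace")
  structure(
    list(v = v, rate_hz = rate_hz, onset_ms = onset_ms, dur_ms = dur_ms,
         kind = kind, level = level, cell_id = cell_id),
    class = "voltage_trace"
  )
}

#' Time axis of a trace, in ms from the first sample
#' @param trace A [voltage_trace()].
#' @return Numeric vector of sample times (ms).
#' @export
trace_time <- function(trace) {
  (seq_along(trace$v) - 1) * 1000 / trace$rate_hz
}

# index of the first sample at or after time t_ms (1-based)
.time_index <- function(trace, t_ms) {
  max(1L, min(length(trace$v), 1L + as.integer(ceiling(t_ms * trace$rate_hz / 1000 - 1e-9))))
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g kHz, %s level %g, onset %g ms\n",
              length(x$v), x$rate_hz / 1000, x$kind, x$level, x$onset_ms))
  invisible(x)
}

#' Construct a sweep set
#'
#' Repetitions grouped by protocol level. Levels are kept strictly increasing;
#' all sweeps must share sampling rate and duration.
#'
#' @param sweeps_by_level Named list: one entry per stimulus level, each a list
#'   of [voltage_trace()] repetitions. Names are the numeric levels.
#' @param kind Protocol kind, taken from the sweeps if missing.
#' @return An object of class `sweep_set` with fields `levels` (numeric,
#'   increasing) and `sweeps` (list of lists of traces, parallel to `levels`).
#' @export
sweep_set <- function(sweeps_by_level, kind = NULL) {
  if (length(sweeps_by_level) == 0L) stop("empty level list")
  lv <- as.numeric(names(sweeps_by_level))
  if (anyNA(lv)) stop("level names must be numeric")
  o <- order(lv)
  lv <- lv[o]
  sweeps_by_level <- sweeps_by_level[o]
  if (any(diff(lv) <= 0)) stop("levels must be strictly increasing")
  all_tr <- unlist(sweeps_by_level, recursive = FALSE)
  rates <- vapply(all_tr, function(s) s$rate_hz, 0)
  lens <- vapply(all_tr, function(s) length(s$v), 0L)
  if (length(unique(rates)) > 1L || length(unique(lens)) > 1L)
    stop("all sweeps must share sampling rate and duration")
  if (is.null(kind)) kind <- all_tr[[1L]]$kind
  structure(list(levels = lv, sweeps = unname(sweeps_by_level), kind = kind),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s, %d levels (%g..%g), %s reps/level\n",
              x$kind, length(x$levels), min(x$levels), max(x$levels),
              paste(range(vapply(x$sweeps, length, 0L)), collapse = "-")))
  invisible(x)
}

#' Sweeps at one level
#' @param ss A [sweep_set()].
#' @param level Stimulus level (must be a member of `ss$levels`).
#' @return List of [voltage_trace()] repetitions at that level.
#' @export
sweeps_at <- function(ss, level) {
  i <- match(level, ss$levels)
  if (is.na(i)) stop("level ", level, " not in sweep set")
  ss$sweeps[[i]]
}

#' Average the repetitions at one level into a single trace
#' @inheritParams sweeps_at
#' @return A [voltage_trace()] holding the pointwise mean.
#' @export
average_sweep <- function(ss, level) {
  tr <- sweeps_at(ss, level)
  m <- rowMeans(vapply(tr, function(s) s$v, numeric(length(tr[[1L]]$v))))
  out <- tr[[1L]]
  out$v <- m
  out
}
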