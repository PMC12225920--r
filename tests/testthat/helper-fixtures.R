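# Programmatic fixtures shared across test files.

# a noiseless reference cell at the Martinotti parameter centre
mc_cell <- function(noise_sd = 0) {
  make_cell_params("SST-MC", seed = 1, spread = 0, noise_sd = noise_sd)
}

# deterministic baseline "noise": alternating +/- sd around mean
alt_baseline <- function(n, mean = -70, sd = 0.1) {
  mean + sd * rep_len(c(1, -1), n)
}

# a trace with a square EPSP: deterministic baseline of known SD, square pulse
# of given amplitude starting latency_ms after flash onset
square_epsp_trace <- function(latency_ms, amp_mv, dur_pulse_ms = 10,
                              rate_hz = 20000, sweep_ms = 300, onset_ms = 100,
                              base_sd = 0.1) {
  n <- round(sweep_ms * rate_hz / 1000)
  t <- (seq_len(n) - 1) * 1000 / rate_hz
  v <- alt_baseline(n, -70, base_sd)
  on <- t >= onset_ms + latency_ms & t < onset_ms + latency_ms + dur_pulse_ms
  v[on] <- -70 + amp_mv
  voltage_trace(v, rate_hz = rate_hz, onset_ms = onset_ms, dur_ms = 1,
                kind = "cracm", level = 1)
}

# sweep set of square-EPSP trials: latencies is a list (one numeric vector of
# per-trial latencies per level, NA = failure trial)
square_epsp_set <- function(levels, latencies, amp_mv = 2, ...) {
  by_level <- list()
  for (i in seq_along(levels)) {
    by_level[[as.character(levels[i])]] <- lapply(latencies[[i]], function(l) {
      if (is.na(l)) {
        tr <- square_epsp_trace(5, 0, ...)
      } else tr <- square_epsp_trace(l, amp_mv, ...)
      tr$level <- levels[i]
      tr
    })
  }
  sweep_set(by_level, kind = "cracm")
}

# hand-built spike train: symmetric triangular spikes (thr -> peak -> thr over
# rise_ms each way, so the half-amplitude width equals rise_ms exactly), with
# a slow 2-ms foot from the plateau so the 10%-slope criterion lands at thr,
# then a dip to the AHP trough and linear recovery
triangle_train_trace <- function(times_ms, rate_hz = 20000, sweep_ms = 1200,
                                 onset_ms = 100, dur_ms = 1000, plateau = -50,
                                 thr = -40, peak = 20, trough = -55,
                                 rise_ms = 0.5) {
  n <- round(sweep_ms * rate_hz / 1000)
  dt <- 1000 / rate_hz
  v <- rep(plateau, n)
  n_foot <- round(2 / dt)
  n_rise <- round(rise_ms / dt)
  for (s in times_ms) {
    t0 <- onset_ms + s    # time of the threshold sample
    i_thr <- round(t0 / dt) + 1
    foot <- seq(plateau, thr, length.out = n_foot + 1)[-(n_foot + 1)]
    up <- seq(thr, peak, length.out = n_rise + 1)
    down <- seq(peak, thr, length.out = n_rise + 1)[-1]
    dip <- seq(thr, trough, length.out = round(1 / dt) + 1)[-1]
    rec <- seq(trough, plateau, length.out = round(3 / dt))[-1]
    wav <- c(foot, up, down, dip, rec)
    idx <- (i_thr - n_foot):(i_thr - n_foot + length(wav) - 1)
    ok <- idx <= n & idx >= 1
    v[idx[ok]] <- wav[ok]
  }
  voltage_trace(v, rate_hz = rate_hz, onset_ms = onset_ms, dur_ms = dur_ms,
                kind = "fi", level = 100)
}

# sweep-set wrapper for hand-built trains at one or more levels
train_set <- function(trains_by_level, ...) {
  by_level <- list()
  for (lv in names(trains_by_level)) {
    by_level[[lv]] <- lapply(trains_by_level[[lv]], function(times) {
      tr <- triangle_train_trace(times, ...)
      tr$level <- as.numeric(lv)
      tr
    })
  }
  sweep_set(by_level, kind = "fi")
}

# two-band laminar test image: rows x cols, bright bands at fractional depths
band_image <- function(nrow = 220, ncol = 40, pia_row = 10, wm_row = 210,
                       band_depths, band_halfwidth = 0.02, intensity = 100) {
  img <- matrix(1, nrow, ncol)
  depth_of_row <- (seq_len(nrow) - pia_row) / (wm_row - pia_row)
  for (d in band_depths) {
    rows <- abs(depth_of_row - d) <= band_halfwidth
    img[rows, ] <- intensity
  }
  list(img = img, pia_row = pia_row, wm_row = wm_row)
}
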