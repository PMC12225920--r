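# Injection-specificity QC from vertical fluorescence depth profiles and
# normalized soma depth. Lemniscal (VPM) injections must peak in LIV and at
# the LVb/LVI border; paralemniscal (POm) injections in LI and LVa. A peak in
# any other lamina flags the slice for exclusion.

#' Default fractional layer boundaries
#'
#' Fractional cortical depths (0 = pia, 1 = white matter) of layers LI-LVI,
#' following standard mouse barrel-cortex proportions. Configurable because
#' QC decisions depend on them.
#'
#' @param from,to Optional replacement boundary vectors (length 6, contiguous,
#'   covering `[0, 1]`).
#' @return Data frame with `layer`, `from`, `to`.
#' @export
layer_boundaries <- function(from = c(0, 0.08, 0.35, 0.50, 0.60, 0.75),
                             to = c(0.08, 0.35, 0.50, 0.60, 0.75, 1.0)) {
  if (length(from) != 6L || length(to) != 6L) stop("six layers required")
  if (from[1L] != 0 || to[6L] != 1 || any(abs(to[-6L] - from[-1L]) > 1e-9))
    stop("intervals must be contiguous and cover [0, 1]")
  if (any(to <= from)) stop("degenerate layer interval")
  data.frame(layer = .layers, from = from, to = to, stringsAsFactors = FALSE)
}

#' Vertical fluorescence depth profile
#'
#' Column-sums a 2-D intensity matrix (rows = image rows from pia downward)
#' between the pia and white-matter lines, resamples onto a fixed
#' normalized-depth grid, applies a moving-average smooth and min-max
#' normalizes to `[0, 1]`.
#'
#' @param img Numeric matrix of intensities (sum projection), rows running
#'   from above the pia to below the white matter, or a path to a TIFF file.
#' @param pia_row,wm_row Row indices of the pia and the white-matter border
#'   (pia above white matter).
#' @param bins Number of normalized-depth bins (default 100).
#' @param smooth_bins Moving-average window in bins (default 5; 1 disables).
#' @return A `depth_profile` list: `depth` (bin centers in `[0, 1]`),
#'   `intensity` (normalized), `flat` flag (degenerate min-max range).
#' @export
depth_profile <- function(img, pia_row, wm_row, bins = 100L, smooth_bins = 5L) {
  if (is.character(img)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF files requires the 'tiff' package")
    img <- tiff::readTIFF(img)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
  }
  if (pia_row >= wm_row) stop("pia line must lie above the white-matter line")
  prof_raw <- rowSums(img[pia_row:wm_row, , drop = FALSE])
  depth_raw <- seq(0, 1, length.out = length(prof_raw))
  grid <- (seq_len(bins) - 0.5) / bins
  prof <- stats::approx(depth_raw, prof_raw, xout = grid, rule = 2)$y
  if (smooth_bins > 1L) {
    k <- rep(1 / smooth_bins, smooth_bins)
    pad <- (smooth_bins - 1L) %/% 2L
    padded <- c(rep(prof[1L], pad), prof, rep(prof[length(prof)], smooth_bins - 1L - pad))
    prof <- as.numeric(stats::filter(padded, k, sides = 1L))[(smooth_bins - 1L + 1L):(smooth_bins - 1L + bins)]
  }
  rng <- range(prof)
  flat <- diff(rng) <= .Machine$double.eps * max(1, abs(rng[2L]))
  intensity <- if (flat) rep(1, bins) else (prof - rng[1L]) / diff(rng)
  structure(list(depth = grid, intensity = intensity, flat = flat,
                 bins = bins, smooth_bins = smooth_bins),
            class = "depth_profile")
}

# topographic prominence of the local maximum at index p: height above the
# lowest saddle separating it from higher ground on either side
.peak_prominence <- function(y, p) {
  h <- y[p]
  side_min <- function(idx_seq) {
    m <- h
    for (i in idx_seq) {
      if (y[i] > h) return(m)
      if (y[i] < m) m <- y[i]
    }
    m
  }
  ml <- if (p > 1L) side_min((p - 1L):1L) else h
  mr <- if (p < length(y)) side_min((p + 1L):length(y)) else h
  h - max(ml, mr)
}

# allowed fractional-depth zones per nucleus; the VPM border zone is
# LVb plus the first quarter of LVI
.allowed_zones <- function(nucleus, layers) {
  z <- function(l) {
    i <- match(l, layers$layer)
    c(layers$from[i], layers$to[i])
  }
  if (nucleus == "VPM") {
    lvi <- z("LVI")
    list(LIV = z("LIV"),
         `LVb/LVI` = c(z("LVb")[1L], lvi[1L] + 0.25 * diff(lvi)))
  } else if (nucleus == "POm") {
    list(LI = z("LI"), LVa = z("LVa"))
  } else stop("unknown nucleus: ", nucleus)
}

#' Injection-specificity QC of a depth profile
#'
#' Detects local maxima with prominence of at least `prominence` times the
#' profile range and passes the slice iff every detected peak lies inside the
#' nucleus's allowed laminar zones (VPM: LIV and the LVb/LVI border zone;
#' POm: LI and LVa) and each required zone contains at least one peak.
#'
#' @param profile A [depth_profile()].
#' @param nucleus `"VPM"` or `"POm"`.
#' @param layers Layer boundaries, default [layer_boundaries()].
#' @param prominence Minimum peak prominence as a fraction of the profile
#'   range (default 0.1).
#' @return List with `pass`, `peaks` (data frame of depth/height per detected
#'   peak, with the zone it falls in or NA), and `reasons` (character; empty
#'   when passing).
#' @export
qc_injection <- function(profile, nucleus, layers = layer_boundaries(),
                         prominence = 0.1) {
  zones <- .allowed_zones(nucleus, layers)
  y <- profile$intensity
  rng <- diff(range(y))
  reasons <- character()
  if (profile$flat || rng == 0) {
    return(list(pass = FALSE,
                peaks = data.frame(depth = numeric(), height = numeric(),
                                   zone = character()),
                reasons = "no peaks detected (flat profile)"))
  }
  pad <- min(y)  # pad so maxima at the profile ends are detectable
  yy <- c(pad, y, pad)
  pk <- pracma::findpeaks(yy, peakpat = "[+]{1,}[0]{0,}[-]{1,}")
  if (!is.null(pk)) {
    prom <- vapply(pk[, 2L], function(p) .peak_prominence(yy, p), 0)
    pk <- pk[prom >= prominence * rng, , drop = FALSE]
  }
  if (is.null(pk) || nrow(pk) == 0L) {
    return(list(pass = FALSE,
                peaks = data.frame(depth = numeric(), height = numeric(),
                                   zone = character()),
                reasons = "no peaks detected"))
  }
  idx <- pk[, 2L] - 1L                     # undo padding offset
  depth <- profile$depth[idx]
  zone_of <- vapply(depth, function(d) {
    hit <- names(zones)[vapply(zones, function(zz) d >= zz[1L] & d <= zz[2L], TRUE)]
    if (length(hit)) hit[1L] else NA_character_
  }, "")
  peaks <- data.frame(depth = depth, height = y[idx], zone = zone_of,
                      stringsAsFactors = FALSE)
  if (anyNA(zone_of)) {
    bad <- signif(depth[is.na(zone_of)], 3)
    reasons <- c(reasons, paste0("peak outside allowed laminae at depth ",
                                 paste(bad, collapse = ", ")))
  }
  missing_zone <- setdiff(names(zones), zone_of[!is.na(zone_of)])
  if (length(missing_zone))
    reasons <- c(reasons, paste0("no peak in required zone ",
                                 paste(missing_zone, collapse = ", ")))
  list(pass = length(reasons) == 0L, peaks = peaks, reasons = reasons)
}

#' Normalized soma depth
#'
#' Soma position rescaled so that the pia is 0 and the white matter 1.
#'
#' @param soma_y,pia_y,wm_y Image-coordinate positions (same axis, any affine
#'   scale); `pia_y` must differ from `wm_y`.
#' @return Fraction in `[0, 1]`; error when the soma falls outside the cortex.
#' @export
normalized_depth <- function(soma_y, pia_y, wm_y) {
  if (pia_y == wm_y) stop("pia and white-matter lines coincide")
  d <- (soma_y - pia_y) / (wm_y - pia_y)
  if (any(d < 0 | d > 1)) stop("soma outside cortex (normalized depth not in [0, 1])")
  d
}
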