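# Respiratory-rate extraction from chest motion:
# sliding 4-frame temporal filter -> dense optical flow on the chest crop ->
# spatial averaging -> Butterworth bandpass -> autocorrelation -> peak pick.

#' Respiration pipeline configuration
#'
#' @param fs sampling rate in Hz (thermal ICU recordings run at 4 fps).
#' @param band_low,band_high bandpass edges in Hz; the defaults 0.15 and
#'   0.44 Hz bracket the physiological respiratory band (9 to 26.4 bpm).
#' @param filter_order Butterworth prototype order (default 2).
#' @param window_frames analysis window length in frames (default 960,
#'   i.e. 240 s at 4 fps).
#' @param flow_params a [flow_params()] object.
#' @param motion_axis `"x"`, `"y"` or `"auto"` (the axis of larger variance
#'   over the window; breathing motion direction depends on camera pose).
#' @param peak_floor minimum normalized autocorrelation at the picked peak
#'   for a valid estimate.  The default 0.5 is the SNR = 1 point for a
#'   sinusoid in noise; narrow-band-filtered sensor noise alone reaches
#'   in-band ACF peaks of about 0.3, while real respiration at the lowest
#'   usable amplitudes scores above 0.9, so 0.5 separates the two regimes
#'   with wide margins on both sides.
#' @param overlap_cap maximum tolerated fraction of samples with a clinician
#'   box overlapping the chest before the window is excluded (default 0.5).
#' @param gap_cap maximum tolerated fraction of invalid (detection-gap)
#'   samples (default 0.1).
#' @param bridge_max detection gaps up to this many frames are bridged with
#'   the last seen chest box (default 2); longer gaps invalidate samples.
#' @return An object of class `respiration_config`.
#' @export
respiration_config <- function(fs = 4,
                               band_low = 0.15,
                               band_high = 0.44,
                               filter_order = 2L,
                               window_frames = 960L,
                               flow_params = thermovitals::flow_params(),
                               motion_axis = c("auto", "x", "y"),
                               peak_floor = 0.5,
                               overlap_cap = 0.5,
                               gap_cap = 0.1,
                               bridge_max = 2L) {
  motion_axis <- match.arg(motion_axis)
  stopifnot(band_low > 0, band_low < band_high, band_high < fs / 2,
            window_frames >= 4)
  structure(list(fs = fs, band_low = band_low, band_high = band_high,
                 filter_order = as.integer(filter_order),
                 window_frames = as.integer(window_frames),
                 flow_params = flow_params, motion_axis = motion_axis,
                 peak_floor = peak_floor, overlap_cap = overlap_cap,
                 gap_cap = gap_cap, bridge_max = as.integer(bridge_max)),
            class = "respiration_config")
}

#' Temporal filter of a 4-frame chest buffer
#'
#' Averages overlapping triples of four consecutive cropped chest frames:
#' the first three (t-2, t-1, t) form the "previous" input and the last
#' three (t-1, t, t+1) the "next" input of the optical-flow step.  The
#' pixel-wise mean suppresses sensor noise (variance / 3 for i.i.d. noise)
#' while the one-frame centre offset preserves the inter-frame motion.
#'
#' @param frames list of 4 numeric matrices of identical shape.
#' @return List with `prev_avg` and `next_avg` matrices.
#' @export
temporal_filter <- function(frames) {
  if (length(frames) != 4L) stop("temporal_filter needs exactly 4 frames")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("shape mismatch across the 4-frame buffer")
  list(prev_avg = (frames[[1]] + frames[[2]] + frames[[3]]) / 3,
       next_avg = (frames[[2]] + frames[[3]] + frames[[4]]) / 3)
}

boxes_overlap <- function(a, b) {
  min(a$x_max, b$x_max) > max(a$x_min, b$x_min) &&
    min(a$y_max, b$y_max) > max(a$y_min, b$y_min)
}

# integer-snapped crop window for a chest box, clamped to the frame
snap_box <- function(box, H, W) {
  x0 <- max(floor(box$x_min), 0); y0 <- max(floor(box$y_min), 0)
  x1 <- min(ceiling(box$x_max), W); y1 <- min(ceiling(box$y_max), H)
  clipped <- x0 > box$x_min + 1e-9 || y0 > box$y_min + 1e-9 ||
    x1 < box$x_max - 1e-9 || y1 < box$y_max - 1e-9
  list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, clipped = clipped)
}

#' Spatially averaged chest motion signal
#'
#' For every sliding 4-frame buffer the chest crop (chest box of the buffer
#' centre frame, snapped to whole pixels and held fixed across the buffer)
#' is temporally filtered, dense flow is computed between the two averaged
#' crops on a jointly min-max normalized intensity scale, and the
#' displacement field is averaged over all crop pixels.  One sample is
#' emitted per buffer (stride 1 frame).
#'
#' Missing chest boxes are bridged with the last seen box for up to
#' `cfg$bridge_max` frames (flag `detection_gap`); longer gaps invalidate
#' the sample.  Samples whose chest box intersects a clinician box carry the
#' `clinician_overlap` flag; crops clamped at the frame border carry
#' `clipped_roi`.
#'
#' @param seq a [thermal_sequence()].
#' @param track a [roi_track()] with chest (and optionally clinician) boxes.
#' @param cfg a [respiration_config()].
#' @return An object of class `motion_signal`: data.frame with `time`, `dx`,
#'   `dy`, `value` (selected axis), `valid` and the three flag columns, plus
#'   attributes `axis` and `fs`.
#' @export
chest_motion_signal <- function(seq, track, cfg = respiration_config()) {
  n <- length(seq)
  if (n < 4L) stop("need at least 4 frames")
  d <- dim(seq)
  ts <- seq_timestamps(seq)
  ns <- n - 3L
  dx <- dy <- rep(NA_real_, ns)
  gap <- overlap <- clipped <- rep(FALSE, ns)
  valid <- rep(TRUE, ns)

  last_box <- NULL; last_seen <- -Inf
  for (i in seq_len(ns)) {
    centre <- i + 2L                     # frame t of the (t-2 .. t+1) buffer
    cb <- track_boxes(track, centre, "chest")
    if (nrow(cb)) {
      box <- cb[1, , drop = FALSE]
      last_box <- box; last_seen <- centre
    } else if (!is.null(last_box) && centre - last_seen <= cfg$bridge_max) {
      box <- last_box
      gap[i] <- TRUE
    } else {
      gap[i] <- TRUE; valid[i] <- FALSE
      next
    }
    cl <- track_boxes(track, centre, "clinician")
    if (nrow(cl))
      overlap[i] <- any(vapply(seq_len(nrow(cl)), function(k)
        boxes_overlap(box, cl[k, , drop = FALSE]), logical(1)))

    sb <- snap_box(box, d[1], d[2])
    clipped[i] <- sb$clipped
    rows <- (sb$y0 + 1):sb$y1; cols <- (sb$x0 + 1):sb$x1
    buf <- lapply(0:3, function(k) seq$frames[[i + k]]$values[rows, cols,
                                                              drop = FALSE])
    tf <- temporal_filter(buf)
    # joint normalization: a shared affine map keeps the two inputs on one
    # intensity scale (independent per-image scaling would fake motion)
    rng <- range(tf$prev_avg, tf$next_avg)
    if (rng[2] > rng[1]) {
      p <- (tf$prev_avg - rng[1]) / (rng[2] - rng[1])
      q <- (tf$next_avg - rng[1]) / (rng[2] - rng[1])
    } else {
      p <- array(0, dim(tf$prev_avg)); q <- p
    }
    fl <- dense_flow(p, q, cfg$flow_params)
    dx[i] <- mean(fl$dx); dy[i] <- mean(fl$dy)
  }

  axis <- cfg$motion_axis
  if (axis == "auto") {
    vx <- stats::var(dx[valid]); vy <- stats::var(dy[valid])
    axis <- if (isTRUE(vx > vy)) "x" else "y"
  }
  out <- data.frame(time = ts[3:(n - 1L)],
                    dx = dx, dy = dy,
                    value = if (axis == "x") dx else dy,
                    valid = valid, detection_gap = gap,
                    clinician_overlap = overlap, clipped_roi = clipped)
  structure(out, axis = axis, fs = cfg$fs,
            class = c("motion_signal", "data.frame"))
}

#' Bandpass-filter a motion signal
#'
#' Zero-phase 2nd-order Butterworth bandpass over the respiratory band;
#' the mean is removed and short invalid runs are linearly interpolated
#' before filtering (flags are preserved).
#'
#' @param signal a [chest_motion_signal()] result (or numeric vector).
#' @param cfg a [respiration_config()].
#' @return Same shape as the input with `value` replaced by the filtered
#'   signal.
#' @export
bandpass <- function(signal, cfg = respiration_config()) {
  x <- if (is.data.frame(signal)) signal$value else signal
  if (anyNA(x)) {
    ok <- which(!is.na(x))
    if (length(ok) < 2) stop("no usable samples to filter")
    x <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
  }
  filt <- butter_bandpass(cfg$band_low, cfg$band_high, cfg$fs,
                          cfg$filter_order)
  y <- filtfilt(filt, x - mean(x))
  if (is.data.frame(signal)) {
    signal$value <- y
    signal
  } else y
}

#' Biased normalized autocorrelation
#'
#' Sample autocorrelation with the biased (divide-by-n) estimator,
#' normalized so that `r[lag 0] = 1`.  The bias tapers long-lag noise
#' peaks, which is what peak picking wants.
#'
#' @param signal numeric vector or a `motion_signal` (its `value` column).
#' @param max_lag largest lag in samples (default `length - 1`).
#' @return An object of class `acf_series`: list with `lag` (samples 0..L)
#'   and `r`; `undefined = TRUE` for a zero-variance signal.
#' @export
autocorrelation <- function(signal, max_lag = NULL) {
  x <- if (is.data.frame(signal)) signal$value else signal
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("signal too short")
  if (stats::var(x) == 0)
    return(structure(list(lag = 0L, r = NA_real_, undefined = TRUE),
                     class = "acf_series"))
  if (is.null(max_lag)) max_lag <- n - 1L
  r <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  structure(list(lag = 0:max_lag, r = r, undefined = FALSE),
            class = "acf_series")
}

#' Respiratory rate from an autocorrelation peak
#'
#' Searches local maxima of the autocorrelation whose lag corresponds to a
#' period inside the respiratory band, picks the maximum-valued one, and
#' refines the lag by three-point parabolic interpolation (at 4 fps the
#' integer-lag grid alone is too coarse for sub-bpm resolution).
#'
#' @param acf an [autocorrelation()] result.
#' @param cfg a [respiration_config()].
#' @return An object of class `rr_estimate`: list with `rr_bpm`, `peak_lag`
#'   (s), `peak_value`, `valid`, `exclusion_reason`.
#' @export
estimate_rr <- function(acf, cfg = respiration_config()) {
  invalid <- function(reason)
    structure(list(rr_bpm = NA_real_, peak_lag = NA_real_,
                   peak_value = NA_real_, valid = FALSE,
                   exclusion_reason = reason),
              class = "rr_estimate")
  if (isTRUE(acf$undefined)) return(invalid("zero_variance"))
  fs <- cfg$fs
  lo <- 1 / cfg$band_high * fs            # shortest period, in samples
  hi <- 1 / cfg$band_low * fs
  r <- acf$r
  ks <- which(acf$lag >= lo & acf$lag <= hi)
  ks <- ks[ks > 1 & ks < length(r)]
  if (!length(ks)) return(invalid("no_peak_in_band"))
  is_peak <- r[ks] > r[ks - 1] & r[ks] >= r[ks + 1]
  ks <- ks[is_peak]
  if (!length(ks)) return(invalid("no_peak_in_band"))
  # parabolic refinement of each candidate's lag and height: the integer lag
  # grid is coarse at 4 fps and can sample a subharmonic peak closer to its
  # continuum maximum than the fundamental
  refine <- function(k) {
    denom <- r[k - 1] - 2 * r[k] + r[k + 1]
    delta <- if (denom < 0) 0.5 * (r[k - 1] - r[k + 1]) / denom else 0
    delta <- min(max(delta, -0.5), 0.5)
    c(lag = acf$lag[k] + delta,
      value = r[k] - 0.25 * (r[k - 1] - r[k + 1]) * delta,
      raw = r[k])
  }
  cand <- vapply(ks, refine, numeric(3))
  best <- which.max(cand["value", ])
  # harmonic disambiguation: a peak near half the chosen lag with comparable
  # height is the true fundamental (the chosen one was its subharmonic)
  repeat {
    half <- cand["lag", best] / 2
    at_half <- which(abs(cand["lag", ] - half) <= 0.75 &
                     cand["value", ] >= 0.8 * cand["value", best])
    if (!length(at_half) || at_half[1] == best) break
    best <- at_half[1]
  }
  if (cand["raw", best] < cfg$peak_floor) return(invalid("below_peak_floor"))
  lag_s <- unname(cand["lag", best]) / fs
  freq <- 1 / lag_s
  if (freq < cfg$band_low || freq > cfg$band_high)
    return(invalid("peak_outside_band"))
  structure(list(rr_bpm = 60 / lag_s, peak_lag = lag_s,
                 peak_value = unname(cand["raw", best]),
                 valid = TRUE, exclusion_reason = NA_character_),
            class = "rr_estimate")
}

#' @export
print.rr_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<rr_estimate: %.2f bpm (peak %.2f at lag %.2f s)>\n",
                x$rr_bpm, x$peak_value, x$peak_lag))
  else
    cat(sprintf("<rr_estimate: invalid (%s)>\n", x$exclusion_reason))
  invisible(x)
}

#' End-to-end respiratory-rate extraction
#'
#' Composition of [chest_motion_signal()], [bandpass()],
#' [autocorrelation()] and [estimate_rr()] over the configured analysis
#' window (the first `window_frames` frames).  Windows dominated by
#' clinician overlap or detection gaps are excluded rather than estimated:
#' a crop containing non-patient movement carries no usable respiration
#' signal.
#'
#' @inheritParams chest_motion_signal
#' @return An [estimate_rr()] result with additional fields
#'   `overlap_fraction` and `gap_fraction`.
#' @export
extract_rr <- function(seq, track, cfg = respiration_config()) {
  nw <- min(length(seq), cfg$window_frames)
  sub <- thermal_sequence(seq$frames[seq_len(nw)], fps = seq$fps,
                          meta = seq$meta)
  sig <- chest_motion_signal(sub, track, cfg)
  ofrac <- mean(sig$clinician_overlap)
  gfrac <- mean(!sig$valid)
  finish <- function(est) {
    est$overlap_fraction <- ofrac
    est$gap_fraction <- gfrac
    est
  }
  invalid <- function(reason)
    finish(structure(list(rr_bpm = NA_real_, peak_lag = NA_real_,
                          peak_value = NA_real_, valid = FALSE,
                          exclusion_reason = reason),
                     class = "rr_estimate"))
  if (ofrac > cfg$overlap_cap) return(invalid("clinician_overlap"))
  if (gfrac > cfg$gap_cap) return(invalid("detection_gap"))
  filtered <- bandpass(sig, cfg)
  ac <- autocorrelation(filtered)
  finish(estimate_rr(ac, cfg))
}
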