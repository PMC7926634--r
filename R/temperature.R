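# Body-surface temperature trend from the head ROI with ambient correction.
#
# Absolute radiometric accuracy of low-cost thermal cameras (about +/-2 degC)
# is far worse than their sensitivity (40 mK), so only *relative* deviations
# from the first measurement point are reported, with the ambient estimate
# (mean of a corner ROI) subtracted to cancel camera and room drift.

#' Temperature trend configuration
#'
#' @param ambient_roi box (list with `x_min`, `y_min`, `x_max`, `y_max`)
#'   used for the room-temperature estimate; default the 5 x 5 px upper-left
#'   corner, which sees wall/background rather than the patient.
#' @param aggregation_frames frames averaged per measurement point
#'   (default 240, i.e. 60 s at 4 fps).
#' @return An object of class `temperature_config`.
#' @export
temperature_config <- function(ambient_roi = list(x_min = 0, y_min = 0,
                                                  x_max = 5, y_max = 5),
                               aggregation_frames = 240L) {
  stopifnot(aggregation_frames >= 1)
  structure(list(ambient_roi = ambient_roi,
                 aggregation_frames = as.integer(aggregation_frames)),
            class = "temperature_config")
}

#' Head-surface temperature of one frame
#'
#' Maximum temperature inside the head bounding box.  The maximum (rather
#' than mean) statistic tracks the warmest exposed skin and is insensitive
#' to how much cooler background the box includes.
#'
#' @param frame a [thermal_frame()] or matrix.
#' @param head_box one-row box data.frame.
#' @return Temperature in degC.
#' @export
head_temperature <- function(frame, head_box) {
  max(crop(frame, head_box))
}

#' Ambient (room) temperature estimate of one frame
#'
#' Mean over the configured corner ROI.
#'
#' @param frame a [thermal_frame()] or matrix.
#' @param cfg a [temperature_config()].
#' @return Temperature in degC.
#' @export
ambient_estimate <- function(frame, cfg = temperature_config()) {
  roi <- cfg$ambient_roi
  v <- if (inherits(frame, "thermal_frame")) frame$values else frame
  mean(v[(roi$y_min + 1):roi$y_max, (roi$x_min + 1):roi$x_max])
}

#' Head-temperature trend series with ambient correction
#'
#' Frames are grouped into consecutive measurement points of
#' `aggregation_frames` frames.  Per point, the per-frame head maxima
#' (frames with a head box) and ambient estimates are averaged;
#' `deviation_raw` is the difference from the first point and
#' `deviation_corrected` subtracts the ambient estimate before differencing,
#' so a drift common to head and corner cancels exactly.  Points without
#' any head detection are reported as missing, never interpolated.
#'
#' @param seq a [thermal_sequence()].
#' @param track a [roi_track()] with head boxes.
#' @param cfg a [temperature_config()].
#' @return An object of class `trend_series`: data.frame with `time` (point
#'   centre, s), `head_max`, `ambient` (degC), `deviation_raw`,
#'   `deviation_corrected` (K), `n_frames` and `missing`.
#' @export
trend <- function(seq, track, cfg = temperature_config()) {
  n <- length(seq)
  ts <- seq_timestamps(seq)
  starts <- seq(1L, n, by = cfg$aggregation_frames)
  pts <- lapply(starts, function(s) {
    idx <- s:min(s + cfg$aggregation_frames - 1L, n)
    hm <- vapply(idx, function(i) {
      hb <- track_boxes(track, i, "head")
      if (nrow(hb)) head_temperature(seq$frames[[i]], hb[1, , drop = FALSE])
      else NA_real_
    }, numeric(1))
    amb <- vapply(idx, function(i)
      ambient_estimate(seq$frames[[i]], cfg), numeric(1))
    data.frame(time = mean(ts[idx]),
               head_max = if (all(is.na(hm))) NA_real_ else mean(hm, na.rm = TRUE),
               ambient = mean(amb),
               n_frames = sum(!is.na(hm)),
               missing = all(is.na(hm)))
  })
  out <- do.call(rbind, pts)
  first <- which(!out$missing)[1]
  if (is.na(first)) stop("no measurement point has a head detection")
  ref_raw <- out$head_max[first]
  ref_cor <- out$head_max[first] - out$ambient[first]
  out$deviation_raw <- out$head_max - ref_raw
  out$deviation_corrected <- (out$head_max - out$ambient) - ref_cor
  structure(out[, c("time", "head_max", "ambient", "deviation_raw",
                    "deviation_corrected", "n_frames", "missing")],
            class = c("trend_series", "data.frame"))
}

#' Regression diagnostics of estimated against reference temperatures
#'
#' Ordinary least squares of the reference on the estimate, with residual
#' MSE, coefficient of determination and Pearson correlation.
#'
#' @param estimates,reference equal-length numeric series (degC or K).
#' @return List with `slope`, `intercept`, `mse`, `r_squared`, `r`.
#' @export
trend_regression <- function(estimates, reference) {
  stopifnot(length(estimates) == length(reference), length(estimates) >= 3)
  if (stats::var(estimates) == 0) stop("zero-variance estimates")
  fit <- stats::lm(reference ~ estimates)
  res <- stats::residuals(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       mse = mean(res^2),
       r_squared = summary(fit)$r.squared,
       r = stats::cor(estimates, reference))
}

#' Export a trend series as CSV
#'
#' @param tr a [trend()] result.
#' @param path output file.
#' @export
write_trend_csv <- function(tr, path) {
  utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
  invisible(path)
}
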