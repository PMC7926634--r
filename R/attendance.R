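# Clinician attendance: binary per-frame presence and the pooled
# time-of-day profile ("how often is staff at the bed at 3 am?").

#' Binary clinician-presence series
#'
#' @param track a [roi_track()].
#' @param timestamps absolute date-times (POSIXct), one per frame.
#' @return An object of class `attendance_series`: data.frame with
#'   `timestamp` and `present` (0/1).
#' @export
presence_series <- function(track, timestamps) {
  if (length(track) != length(timestamps))
    stop("timestamps must align with frames")
  present <- vapply(seq_along(track), function(i)
    as.integer(any(track[[i]]$label == "clinician")), integer(1))
  structure(data.frame(timestamp = timestamps, present = present),
            class = c("attendance_series", "data.frame"))
}

#' Time-of-day attendance profile
#'
#' Pools presence samples from all days (and, if concatenated, all patients)
#' into time-of-day bins and reports the percentage of samples with a
#' clinician present per bin; 100 means continuous presence throughout that
#' time of day.  Empty bins are filled by linear interpolation between their
#' nearest non-empty neighbours, circularly across midnight.
#'
#' @param series an [presence_series()] result (or several, row-bound).
#' @param bin_minutes bin width in minutes (default 60; must divide 1440).
#' @return Data.frame with `bin_start_min` (minutes after midnight),
#'   `percent`, `n` (samples pooled; 0 marks interpolated bins).
#' @export
daily_profile <- function(series, bin_minutes = 60) {
  stopifnot(nrow(series) >= 1, 1440 %% bin_minutes == 0)
  lt <- as.POSIXlt(series$timestamp)
  mins <- lt$hour * 60 + lt$min + lt$sec / 60
  bin <- floor(mins / bin_minutes)
  nbin <- as.integer(1440 / bin_minutes)
  pct <- n <- numeric(nbin)
  for (b in seq_len(nbin) - 1L) {
    idx <- bin == b
    n[b + 1L] <- sum(idx)
    pct[b + 1L] <- if (any(idx)) 100 * mean(series$present[idx]) else NA_real_
  }
  if (anyNA(pct)) {
    if (all(is.na(pct))) stop("no samples in any bin")
    pct <- interp_circular(pct)
  }
  data.frame(bin_start_min = (seq_len(nbin) - 1L) * bin_minutes,
             percent = pct, n = n)
}

# linear interpolation of NA runs on a circular axis
interp_circular <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  for (i in which(is.na(x))) {
    # distances on the circle to previous/next known bins
    dprev <- (i - ok) %% n
    dnext <- (ok - i) %% n
    ip <- ok[which.min(replace(dprev, dprev == 0, n))]
    inx <- ok[which.min(replace(dnext, dnext == 0, n))]
    dp <- (i - ip) %% n
    dn <- (inx - i) %% n
    x[i] <- (x[ip] * dn + x[inx] * dp) / (dp + dn)
  }
  x
}

#' Export a daily profile as CSV
#'
#' @param profile a [daily_profile()] result.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
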