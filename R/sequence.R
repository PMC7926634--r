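#' Radiometric thermal frame
#'
#' A single calibrated frame: a matrix of temperatures in degrees Celsius
#' plus its acquisition time relative to the start of the sequence.
#'
#' @param values numeric matrix of temperatures (degC), rows = image rows
#'   (y, top-left origin, growing downward), columns = image columns (x).
#' @param timestamp seconds since sequence start.
#' @param index 1-based frame ordinal.
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(values, timestamp = 0, index = 1L) {
  if (!is.matrix(values) || !all(is.finite(values)))
    stop("frame values must be a finite numeric matrix")
  structure(list(values = values, timestamp = as.numeric(timestamp),
                 index = as.integer(index)),
            class = "thermal_frame")
}

#' Radiometric thermal sequence
#'
#' An ordered collection of [thermal_frame()]s sharing one grid geometry and
#' a nominal sampling rate.
#'
#' @param frames list of `thermal_frame` objects (or plain matrices, which
#'   are wrapped with timestamps `(i - 1) / fps`).
#' @param fps sampling rate in Hz (> 0).
#' @param meta free-form provenance list.
#' @return An object of class `thermal_sequence`.
#' @export
thermal_sequence <- function(frames, fps, meta = list()) {
  if (length(frames) < 1L) stop("a sequence needs at least one frame")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (is.matrix(f)) f <- thermal_frame(f, timestamp = (i - 1) / fps, index = i)
    f
  })
  d <- dim(frames[[1L]]$values)
  ok <- vapply(frames, function(f) identical(dim(f$values), d), logical(1))
  if (!all(ok)) stop("inconsistent frame shapes in sequence")
  ts <- vapply(frames, `[[`, numeric(1), "timestamp")
  if (is.unsorted(ts)) stop("timestamps must be non-decreasing")
  structure(list(frames = frames, fps = fps, meta = meta),
            class = "thermal_sequence")
}

#' @export
length.thermal_sequence <- function(x) length(x$frames)

#' @export
dim.thermal_sequence <- function(x) dim(x$frames[[1L]]$values)

#' @export
print.thermal_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<thermal_sequence: %d frames of %d x %d px at %g fps, %.1f s>\n",
              length(x), d[1], d[2], x$fps, (length(x) - 1) / x$fps))
  invisible(x)
}

seq_timestamps <- function(seq) {
  vapply(seq$frames, `[[`, numeric(1), "timestamp")
}

#' Min-max normalization of a thermal frame
#'
#' Linearly maps a frame onto \[0, 1\] using its own minimum and maximum
#' temperature.  Normalization is per frame (not per sequence): scenes whose
#' temperature range changes over time then yield different per-frame
#' contrasts, which is the behaviour the downstream consumers assume.
#' A constant frame maps to all zeros (a flat frame carries no contrast).
#'
#' @param frame a [thermal_frame()] or a plain numeric matrix.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
normalize_frame <- function(frame) {
  v <- if (inherits(frame, "thermal_frame")) frame$values else frame
  if (!all(is.finite(v))) stop("frame must be finite")
  rng <- range(v)
  if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else array(0, dim(v))
}
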