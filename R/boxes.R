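#' @keywords internal
#' @useDynLib thermovitals, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
"_PACKAGE"

# The four-class vocabulary; the integer class ids of darknet label files map
# onto it by position (0 -> patient, 1 -> chest, 2 -> head, 3 -> clinician).
#' @export
BOX_LABELS <- c("patient", "chest", "head", "clinician")

#' Bounding box
#'
#' Boxes use one convention everywhere: 0-based pixel coordinates, top-left
#' origin with y growing downward, half-open intervals `[x_min, x_max) x
#' [y_min, y_max)`.  Coordinates may be fractional (continuous geometry).
#'
#' @param label one of `"patient"`, `"chest"`, `"head"`, `"clinician"`.
#' @param x_min,y_min,x_max,y_max corner coordinates with
#'   `x_min < x_max`, `y_min < y_max`.
#' @param confidence detector confidence in \[0, 1\], or `NA` for ground truth.
#' @return A one-row data.frame; multiple boxes are row-bound data.frames of
#'   the same columns.
#' @export
bounding_box <- function(label, x_min, y_min, x_max, y_max, confidence = NA_real_) {
  label <- match.arg(label, BOX_LABELS)
  if (!(x_min < x_max && y_min < y_max))
    stop("degenerate box: require x_min < x_max and y_min < y_max")
  if (!is.na(confidence) && (confidence < 0 || confidence > 1))
    stop("confidence must be in [0, 1]")
  data.frame(label = label, x_min = x_min, y_min = y_min,
             x_max = x_max, y_max = y_max, confidence = confidence,
             stringsAsFactors = FALSE)
}

empty_boxes <- function() {
  data.frame(label = character(), x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(), confidence = numeric(),
             stringsAsFactors = FALSE)
}

#' Per-frame box track
#'
#' A track holds, for every frame of a sequence, the labeled boxes observed
#' in that frame (possibly none: a detection gap).
#'
#' @param entries list with one box data.frame per frame (see
#'   [bounding_box()]); `NULL` entries are treated as empty.
#' @param n_frames number of frames; defaults to `length(entries)`.
#' @return An object of class `roi_track` (list of box data.frames).
#' @export
roi_track <- function(entries, n_frames = length(entries)) {
  if (length(entries) < n_frames)
    entries <- c(entries, vector("list", n_frames - length(entries)))
  entries <- lapply(entries, function(e) if (is.null(e)) empty_boxes() else e)
  structure(entries, class = "roi_track")
}

#' @export
print.roi_track <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat(sprintf("<roi_track: %d frames, %d boxes (%d frames empty)>\n",
              length(x), sum(n), sum(n == 0L)))
  invisible(x)
}

track_boxes <- function(track, frame, label = NULL) {
  b <- track[[frame]]
  if (!is.null(label) && nrow(b)) b <- b[b$label == label, , drop = FALSE]
  b
}

#' Parse a darknet-format label file
#'
#' Each line is `class_id x_center y_center w h` with all geometry normalized
#' to \[0, 1\] by the image size, and `class_id` in `0:3` mapping to
#' patient/chest/head/clinician.  An optional sixth field is read as a
#' detector confidence.
#'
#' @param path label file (one file per frame); may be empty.
#' @param width,height frame size in px used to de-normalize.
#' @return Box data.frame (see [bounding_box()]) in continuous half-open
#'   pixel coordinates.
#' @export
parse_labels <- function(path, width, height) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  out <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) < 5L || anyNA(f[1:5]))
      stop(sprintf("line %d: expected 'class_id x_center y_center w h'", i))
    cls <- f[1]
    if (cls != round(cls) || cls < 0 || cls > 3)
      stop(sprintf("line %d: class id %g outside 0..3", i, cls))
    cx <- f[2]; cy <- f[3]; w <- f[4]; h <- f[5]
    # centre and size must be normalized; the derived corners may reach
    # slightly past the frame (annotation tools allow it; crop() clamps)
    if (any(c(cx, cy, w, h) < 0) || any(c(cx, cy, w, h) > 1))
      stop(sprintf("line %d: coordinates out of [0, 1]", i))
    bounding_box(BOX_LABELS[cls + 1L],
                 x_min = (cx - w / 2) * width, y_min = (cy - h / 2) * height,
                 x_max = (cx + w / 2) * width, y_max = (cy + h / 2) * height,
                 confidence = if (length(f) >= 6L) f[6] else NA_real_)
  })
  do.call(rbind, out)
}

#' Serialize boxes to a darknet-format label file
#'
#' Inverse of [parse_labels()]; coordinates are written with 6 decimals.
#'
#' @param boxes box data.frame.
#' @param path output file.
#' @param width,height frame size in px used to normalize.
#' @param confidence if `TRUE`, append the confidence as a sixth field.
#' @export
serialize_labels <- function(boxes, path, width, height, confidence = FALSE) {
  lines <- character(0)
  if (nrow(boxes)) {
    cls <- match(boxes$label, BOX_LABELS) - 1L
    cx <- (boxes$x_min + boxes$x_max) / 2 / width
    cy <- (boxes$y_min + boxes$y_max) / 2 / height
    w <- (boxes$x_max - boxes$x_min) / width
    h <- (boxes$y_max - boxes$y_min) / height
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", cls, cx, cy, w, h)
    if (confidence)
      lines <- paste(lines, sprintf("%.6f", boxes$confidence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Crop a frame to a bounding box
#'
#' Returns the half-open sub-grid `[y_min, y_max) x [x_min, x_max)` of the
#' frame.  Fractional box edges are snapped outward (floor/ceiling) so the
#' crop covers the box.  Boxes reaching outside the frame are clamped to it
#' and the result carries attribute `clipped = TRUE` instead of failing
#' (detector jitter at frame borders is expected).
#'
#' @param frame a [thermal_frame()] or numeric matrix.
#' @param box one-row box data.frame.
#' @return Numeric matrix with attribute `clipped` (logical).
#' @export
crop <- function(frame, box) {
  v <- if (inherits(frame, "thermal_frame")) frame$values else frame
  H <- nrow(v); W <- ncol(v)
  x0 <- floor(box$x_min); x1 <- ceiling(box$x_max)
  y0 <- floor(box$y_min); y1 <- ceiling(box$y_max)
  clipped <- x0 < 0 || y0 < 0 || x1 > W || y1 > H
  x0 <- max(x0, 0); y0 <- max(y0, 0)
  x1 <- min(x1, W); y1 <- min(y1, H)
  if (x1 <= x0 || y1 <= y0) stop("box does not intersect the frame")
  out <- v[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  attr(out, "clipped") <- clipped
  out
}
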