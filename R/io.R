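# Portable radiometric sequence IO.
#
# Two dialects:
#  * "tiff16"   - one multi-page baseline TIFF (little-endian, uncompressed,
#                 16-bit grey, one strip per page).  Temperatures are stored
#                 as counts with a linear map degC = count * scale + offset;
#                 scale/offset (and fps / per-frame timestamps on page 1) live
#                 as JSON in the ImageDescription tag.  scale is chosen per
#                 file as (max - min) / 65535, so the quantization step stays
#                 below the 40 mK sensor sensitivity for any range <= 2.6 K
#                 ... 26 K typical of a ward scene (20 K range -> 0.3 mK).
#  * "csv_stack" - a directory of frame_NNNNNN.csv matrices plus a meta.json
#                 sidecar holding fps and timestamps; lossless, human-readable.
#
# Only the dialect written here is read back; this is an exchange format of
# the package, not a general TIFF implementation.

TIFF_MAGIC_JSON <- "thermovitals-tiff16"

write_u <- function(con, x, size) {
  x <- as.numeric(x)
  if (size == 2L) x <- ifelse(x > 32767, x - 65536, x)
  if (size == 4L) x <- ifelse(x > 2147483647, x - 4294967296, x)
  writeBin(as.integer(x), con, size = size, endian = "little")
}

tiff_ifd_entry <- function(con, tag, type, count, value) {
  write_u(con, tag, 2L)
  write_u(con, type, 2L)   # 2 = ASCII, 3 = SHORT, 4 = LONG
  write_u(con, count, 4L)
  if (type == 3L && count == 1L) {       # SHORT packed left-justified
    write_u(con, value, 2L)
    write_u(con, 0L, 2L)
  } else {
    write_u(con, value, 4L)
  }
}

#' Write a thermal sequence to disk
#'
#' @param seq a [thermal_sequence()].
#' @param path output file (`tiff16`) or directory (`csv_stack`).
#' @param dialect `"tiff16"` or `"csv_stack"`.
#' @return `path`, invisibly.
#' @seealso [read_sequence()] for the inverse; the round trip is exact for
#'   `csv_stack` and exact up to the 16-bit quantization step for `tiff16`.
#' @export
write_sequence <- function(seq, path, dialect = c("tiff16", "csv_stack")) {
  dialect <- match.arg(dialect)
  if (!inherits(seq, "thermal_sequence") || length(seq) < 1L)
    stop("seq must be a non-empty thermal_sequence")
  if (dialect == "csv_stack") return(write_csv_stack(seq, path))

  d <- dim(seq)
  H <- d[1]; W <- d[2]; n <- length(seq)
  all_rng <- range(vapply(seq$frames, function(f) range(f$values),
                          numeric(2)))
  offset <- all_rng[1]
  scale <- if (all_rng[2] > all_rng[1]) (all_rng[2] - all_rng[1]) / 65535 else 1
  ts <- seq_timestamps(seq)

  descs <- lapply(seq_len(n), function(i) {
    meta <- list(dialect = TIFF_MAGIC_JSON, scale = scale, offset = offset,
                 timestamp = ts[i])
    if (i == 1L) {
      meta$fps <- seq$fps
      meta$timestamps <- ts
      meta$meta <- seq$meta
    }
    r <- c(charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
           as.raw(0))                    # ASCII tags are NUL-terminated
    if (length(r) %% 2L == 1L) r <- c(r, as.raw(0))
    r
  })
  dlen <- lengths(descs)

  strip_bytes <- H * W * 2L
  ifd_size <- 2L + 11L * 12L + 4L
  data_off <- desc_off <- ifd_off <- integer(n)
  cur <- 8L
  for (i in seq_len(n)) {
    data_off[i] <- cur; cur <- cur + strip_bytes
    desc_off[i] <- cur; cur <- cur + dlen[i]
    ifd_off[i] <- cur; cur <- cur + ifd_size
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_u(con, 42L, 2L)
  write_u(con, ifd_off[1], 4L)
  for (i in seq_len(n)) {
    counts <- round((t(seq$frames[[i]]$values) - offset) / scale)  # row-major
    write_u(con, pmin(pmax(counts, 0), 65535), 2L)
    writeBin(descs[[i]], con)
    write_u(con, 11L, 2L)
    tiff_ifd_entry(con, 256L, 3L, 1L, W)            # ImageWidth
    tiff_ifd_entry(con, 257L, 3L, 1L, H)            # ImageLength
    tiff_ifd_entry(con, 258L, 3L, 1L, 16L)          # BitsPerSample
    tiff_ifd_entry(con, 259L, 3L, 1L, 1L)           # Compression: none
    tiff_ifd_entry(con, 262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    tiff_ifd_entry(con, 270L, 2L, dlen[i], desc_off[i])  # ImageDescription
    tiff_ifd_entry(con, 273L, 4L, 1L, data_off[i])  # StripOffsets
    tiff_ifd_entry(con, 277L, 3L, 1L, 1L)           # SamplesPerPixel
    tiff_ifd_entry(con, 278L, 3L, 1L, H)            # RowsPerStrip
    tiff_ifd_entry(con, 279L, 4L, 1L, strip_bytes)  # StripByteCounts
    tiff_ifd_entry(con, 339L, 3L, 1L, 1L)           # SampleFormat: unsigned
    write_u(con, if (i < n) ifd_off[i + 1] else 0L, 4L)
  }
  invisible(path)
}

read_u <- function(con, size, n = 1L) {
  x <- readBin(con, "integer", n = n, size = size, endian = "little",
               signed = size >= 4L)
  if (size == 4L) x <- ifelse(x < 0, x + 4294967296, x)
  x
}

#' Read a thermal sequence from disk
#'
#' @param path file (`tiff16`) or directory (`csv_stack`) written by
#'   [write_sequence()].
#' @param dialect `"tiff16"` or `"csv_stack"`.
#' @return A [thermal_sequence()] with values in degC.
#' @export
read_sequence <- function(path, dialect = c("tiff16", "csv_stack")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such path: ", path)
  if (dialect == "csv_stack") return(read_csv_stack(path))

  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 2L)) != "II" || read_u(con, 2L) != 42L)
    stop("not a little-endian TIFF file")
  ifd_off <- read_u(con, 4L)
  frames <- list(); fps <- NULL; ts_all <- NULL; meta <- list(); i <- 0L
  while (ifd_off != 0L) {
    i <- i + 1L
    seek(con, ifd_off)
    n_ent <- read_u(con, 2L)
    tags <- vector("list", 0L)
    for (k in seq_len(n_ent)) {
      tag <- read_u(con, 2L); type <- read_u(con, 2L); count <- read_u(con, 4L)
      if (type == 3L && count == 1L) {
        val <- read_u(con, 2L); read_u(con, 2L)
      } else {
        val <- read_u(con, 4L)
      }
      tags[[as.character(tag)]] <- c(type = type, count = count, value = val)
    }
    ifd_off <- read_u(con, 4L)
    need <- c("256", "257", "258", "259", "273", "279")
    if (!all(need %in% names(tags))) stop("format error: missing TIFF tags")
    W <- tags[["256"]]["value"]; H <- tags[["257"]]["value"]
    if (tags[["258"]]["value"] != 16L || tags[["259"]]["value"] != 1L)
      stop("format error: only uncompressed 16-bit pages are supported")
    if (is.null(tags[["270"]]))
      stop("dialect error: page lacks scale/offset metadata (ImageDescription)")
    seek(con, tags[["270"]]["value"])
    desc <- readBin(con, "raw", tags[["270"]]["count"])
    desc <- rawToChar(desc[desc != as.raw(0)])
    info <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    if (is.null(info) || !identical(info$dialect, TIFF_MAGIC_JSON) ||
        is.null(info$scale) || is.null(info$offset))
      stop("dialect error: page lacks scale/offset metadata")
    if (i == 1L) {
      if (is.null(info$fps)) stop("dialect error: first page lacks fps")
      fps <- info$fps
      ts_all <- info$timestamps
      meta <- if (is.null(info$meta)) list() else as.list(info$meta)
    }
    seek(con, tags[["273"]]["value"])
    counts <- readBin(con, "integer", n = H * W, size = 2L,
                      endian = "little", signed = FALSE)
    vals <- matrix(as.numeric(counts) * info$scale + info$offset,
                   nrow = H, ncol = W, byrow = TRUE)
    if (length(frames) && !identical(dim(vals), dim(frames[[1]]$values)))
      stop("format error: inconsistent frame shapes")
    frames[[i]] <- thermal_frame(vals, timestamp = info$timestamp, index = i)
  }
  if (!is.null(ts_all) && length(ts_all) == length(frames))
    for (k in seq_along(frames)) frames[[k]]$timestamp <- ts_all[k]
  thermal_sequence(frames, fps = fps, meta = meta)
}

write_csv_stack <- function(seq, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$frames)) {
    v <- seq$frames[[i]]$values
    txt <- apply(v, 1L, function(r)
      paste(formatC(r, digits = 17, format = "g"), collapse = ","))
    writeLines(txt, file.path(path, sprintf("frame_%06d.csv", i)))
  }
  jsonlite::write_json(
    list(fps = seq$fps, timestamps = seq_timestamps(seq), meta = seq$meta),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_csv_stack <- function(path) {
  mpath <- file.path(path, "meta.json")
  if (!file.exists(mpath)) stop("dialect error: meta.json sidecar missing")
  info <- jsonlite::fromJSON(mpath)
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("format error: no frame files in ", path)
  frames <- lapply(seq_along(files), function(i) {
    rows <- strsplit(readLines(files[i]), ",", fixed = TRUE)
    v <- do.call(rbind, lapply(rows, as.numeric))
    thermal_frame(v, timestamp = info$timestamps[i], index = i)
  })
  thermal_sequence(frames, fps = info$fps,
                   meta = if (is.null(info$meta)) list() else as.list(info$meta))
}

#' Read a per-frame label directory into a track
#'
#' Reads `frame_NNNNNN.txt` darknet label files (missing files mean no boxes
#' in that frame) into a [roi_track()].
#'
#' @param dir directory of label files.
#' @param n_frames number of frames in the sequence.
#' @param width,height frame size in px.
#' @export
read_label_track <- function(dir, n_frames, width, height) {
  entries <- lapply(seq_len(n_frames), function(i) {
    p <- file.path(dir, sprintf("frame_%06d.txt", i))
    if (file.exists(p)) parse_labels(p, width, height) else empty_boxes()
  })
  roi_track(entries, n_frames)
}

#' Write a track as a per-frame label directory
#'
#' @param track a [roi_track()].
#' @param dir output directory.
#' @param width,height frame size in px.
#' @param confidence write confidences as a sixth field.
#' @export
write_label_track <- function(track, dir, width, height, confidence = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(track))
    serialize_labels(track[[i]], file.path(dir, sprintf("frame_%06d.txt", i)),
                     width, height, confidence = confidence)
  invisible(dir)
}
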