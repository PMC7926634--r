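# Seeded synthetic radiometric scenes with exact ground truth.
#
# The generator emulates the measurement model of a ceiling-mounted thermal
# camera over an ICU bed: a cool background following the room temperature
# (with optional drift), a warm patient body, a head ellipse whose core
# temperature may trend over time, a textured chest patch displaced
# vertically by the breathing waveform, transient clinician blobs, and
# additive i.i.d. Gaussian sensor noise (40 mK class).  Chest motion is
# rendered by evaluating a smooth analytic temperature profile at
# sub-pixel-shifted coordinates, which is exact sub-pixel resampling, so
# sub-pixel optical flow on the rendered frames is physically meaningful.

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Synthetic scene configuration
#'
#' Geometry defaults scale with the frame size; temperatures are degC.
#' All randomness (texture phases, sensor noise) derives from `seed` with
#' R's Mersenne-Twister / Inversion generators, so identical configurations
#' render bit-identical scenes.
#'
#' @param width,height frame size in px (default the 382 x 288 sensor grid).
#' @param fps sampling rate in Hz (default 4).
#' @param duration scene length in s (default 240, one analysis window).
#' @param background_temp room temperature (default 21).
#' @param ambient_drift camera/room drift in K/h (default 0), applied
#'   additively to the whole frame (sensor-drift model); the recorded
#'   `head_series` truth stays drift-free, so the drift is exactly what the
#'   ambient correction must remove.
#' @param head list: `cx`, `cy`, `ax`, `ay` (ellipse centre/half-axes, px),
#'   `core_temp` (default 36.8), `trend` (K/h).
#' @param chest list: `x0`, `y0`, `x1`, `y1` (base rectangle, px),
#'   `temp` (default 33), `rr_bpm` (default 15), `amplitude` (px, default 1),
#'   `waveform` ("sine" or "sine+harmonic").
#' @param body list: `cx`, `cy`, `ax`, `ay`, `temp` for the torso ellipse.
#' @param noise_sigma sensor noise SD in K (default 0.04).
#' @param clinician_events list of [clinician_event()]s.
#' @param seed integer RNG seed.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 382L, height = 288L, fps = 4, duration = 240,
                         background_temp = 21, ambient_drift = 0,
                         head = list(), chest = list(), body = list(),
                         noise_sigma = 0.04, clinician_events = list(),
                         seed = 1L) {
  W <- as.integer(width); H <- as.integer(height)
  head <- utils::modifyList(list(
    cx = 0.50 * W, cy = 0.20 * H, ax = 0.09 * W, ay = 0.10 * H,
    core_temp = 36.8, trend = 0), head)
  chest <- utils::modifyList(list(
    x0 = 0.37 * W, y0 = 0.40 * H, x1 = 0.63 * W, y1 = 0.60 * H,
    temp = 33, rr_bpm = 15, amplitude = 1, waveform = "sine"), chest)
  body <- utils::modifyList(list(
    cx = 0.50 * W, cy = 0.52 * H, ax = 0.23 * W, ay = 0.40 * H,
    temp = 31), body)
  stopifnot(noise_sigma >= 0, fps > 0, duration > 0,
            chest$x0 < chest$x1, chest$y0 < chest$y1)
  amp <- chest$amplitude
  if (chest$x0 < 0 || chest$y0 - amp < 0 || chest$x1 > W ||
      chest$y1 + amp > H || head$cx + head$ax > W || head$cy + head$ay > H ||
      head$cx - head$ax < 0 || head$cy - head$ay < 0)
    stop("scene geometry outside the frame")
  structure(list(width = W, height = H, fps = fps, duration = duration,
                 background_temp = background_temp,
                 ambient_drift = ambient_drift,
                 head = head, chest = chest, body = body,
                 noise_sigma = noise_sigma,
                 clinician_events = clinician_events,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Clinician presence event for a synthetic scene
#'
#' @param start,end event interval in s.
#' @param cx,cy,ax,ay blob ellipse centre and half axes in px.
#' @param temp blob temperature in degC (clothed person, default 34).
#' @export
clinician_event <- function(start, end, cx, cy, ax, ay, temp = 34) {
  stopifnot(start < end, ax > 0, ay > 0)
  list(start = start, end = end, cx = cx, cy = cy, ax = ax, ay = ay,
       temp = temp)
}

ellipse_mask <- function(X, Y, cx, cy, ax, ay, edge = 0.25) {
  r <- sqrt(((X - cx) / ax)^2 + ((Y - cy) / ay)^2)
  smoothstep((1 - r) / edge)
}

#' Render a synthetic thermal scene with ground truth
#'
#' @param cfg a [scene_config()].
#' @return List with `sequence` (a [thermal_sequence()]) and `truth`: a list
#'   with `boxes` (exact [roi_track()]), `rr_bpm`, `displacement` (chest
#'   shift per frame, px), `head_series`, `ambient_series` (degC per frame)
#'   and `presence` (0/1 clinician per frame).
#' @export
generate_scene <- function(cfg = scene_config()) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  W <- cfg$width; H <- cfg$height
  n <- max(2L, as.integer(round(cfg$duration * cfg$fps)))
  tt <- (seq_len(n) - 1) / cfg$fps
  X <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)   # pixel centres
  Y <- matrix(rep(seq_len(H) - 0.5, W), H, W)

  hd <- cfg$head; ch <- cfg$chest; bd <- cfg$body
  m_body <- ellipse_mask(X, Y, bd$cx, bd$cy, bd$ax, bd$ay, edge = 0.15)
  m_head <- ellipse_mask(X, Y, hd$cx, hd$cy, hd$ax, hd$ay, edge = 0.25)

  amb0 <- cfg$background_temp
  base <- amb0 * (1 - m_body) + bd$temp * m_body
  static <- base * (1 - m_head) + hd$core_temp * m_head

  # chest texture: band-limited sum of sinusoids, seeded once per scene
  K <- 5L
  tex_f <- runif(K, 0.02, 0.08)           # cycles/px
  tex_th <- runif(K, 0, pi)
  tex_ph <- runif(K, 0, 2 * pi)
  tex_a <- runif(K, 0.25, 0.5)            # K (temperature units)

  # local chest window large enough for the motion envelope + soft edge
  edge_px <- 2.5
  pad <- ceiling(ch$amplitude + 4 * edge_px)
  rows <- max(1, floor(ch$y0) - pad):min(H, ceiling(ch$y1) + pad)
  cols <- max(1, floor(ch$x0) - pad):min(W, ceiling(ch$x1) + pad)
  xl <- cols - 0.5; yl <- rows - 0.5
  mx <- smoothstep((xl - ch$x0) / edge_px) * smoothstep((ch$x1 - xl) / edge_px)
  texS <- texC <- vector("list", K)
  for (k in seq_len(K)) {
    # phase grid: 2*pi*f*(cos(th)*x + sin(th)*y) + ph
    P <- 2 * pi * tex_f[k] *
      (cos(tex_th[k]) * matrix(rep(xl, each = length(yl)), length(yl)) +
       sin(tex_th[k]) * matrix(rep(yl, length(xl)), length(yl))) + tex_ph[k]
    texS[[k]] <- sin(P); texC[[k]] <- cos(P)
  }

  disp <- ch$amplitude * sin(2 * pi * ch$rr_bpm / 60 * tt)
  if (identical(ch$waveform, "sine+harmonic"))
    disp <- disp + 0.3 * ch$amplitude * sin(4 * pi * ch$rr_bpm / 60 * tt + 0.7)

  ev <- cfg$clinician_events
  ev_masks <- lapply(ev, function(e) {
    er <- max(1, floor(e$cy - e$ay)):min(H, ceiling(e$cy + e$ay))
    ec <- max(1, floor(e$cx - e$ax)):min(W, ceiling(e$cx + e$ax))
    list(rows = er, cols = ec,
         m = ellipse_mask(matrix(rep(ec - 0.5, each = length(er)), length(er)),
                          matrix(rep(er - 0.5, length(ec)), length(er)),
                          e$cx, e$cy, e$ax, e$ay, edge = 0.3))
  })

  amb_series <- amb0 + cfg$ambient_drift * tt / 3600
  head_series <- hd$core_temp + hd$trend * tt / 3600
  presence <- integer(n)
  frames <- vector("list", n)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    t <- tt[i]
    # ambient/camera drift is a global additive term: sensor calibration
    # drift shifts every pixel, which is exactly what the corner-ROI
    # correction is designed to cancel
    fr <- static + (amb_series[i] - amb0) +
      (head_series[i] - hd$core_temp) * m_head

    # chest patch, evaluated at y - disp (exact sub-pixel shift)
    s <- disp[i]
    ys <- yl - s
    my <- smoothstep((ys - ch$y0) / edge_px) * smoothstep((ch$y1 - ys) / edge_px)
    mc <- outer(my, mx)
    sb <- sin(2 * pi * tex_f * sin(tex_th) * s)
    cb <- cos(2 * pi * tex_f * sin(tex_th) * s)
    tex <- 0
    for (k in seq_len(K))
      tex <- tex + tex_a[k] * (texS[[k]] * cb[k] - texC[[k]] * sb[k])
    loc <- fr[rows, cols]
    fr[rows, cols] <- loc * (1 - mc) + (ch$temp + tex) * mc

    boxes <- rbind(
      bounding_box("patient", bd$cx - bd$ax, bd$cy - bd$ay,
                   bd$cx + bd$ax, min(bd$cy + bd$ay, H)),
      bounding_box("head", hd$cx - hd$ax, hd$cy - hd$ay,
                   hd$cx + hd$ax, hd$cy + hd$ay),
      bounding_box("chest", ch$x0, ch$y0 + s, ch$x1, ch$y1 + s))

    for (j in seq_along(ev)) {
      e <- ev[[j]]
      if (t >= e$start && t < e$end) {
        em <- ev_masks[[j]]
        fr[em$rows, em$cols] <- fr[em$rows, em$cols] * (1 - em$m) +
          e$temp * em$m
        presence[i] <- 1L
        boxes <- rbind(boxes,
                       bounding_box("clinician", e$cx - e$ax, e$cy - e$ay,
                                    e$cx + e$ax, e$cy + e$ay))
      }
    }
    if (cfg$noise_sigma > 0)
      fr <- fr + matrix(rnorm(H * W, 0, cfg$noise_sigma), H, W)
    frames[[i]] <- thermal_frame(fr, timestamp = t, index = i)
    entries[[i]] <- boxes
  }

  list(sequence = thermal_sequence(frames, fps = cfg$fps,
                                   meta = list(synthetic = TRUE,
                                               seed = cfg$seed)),
       truth = list(boxes = roi_track(entries, n),
                    rr_bpm = ch$rr_bpm,
                    displacement = disp,
                    head_series = head_series,
                    ambient_series = amb_series,
                    presence = presence))
}

#' Perturb a ground-truth track into a synthetic detector output
#'
#' Stands in for a trained object detector: boxes are dropped independently
#' with probability `drop_rate` (emulating detection gaps), corners are
#' jittered with Gaussian noise of SD `jitter_px`, and confidences are drawn
#' from a clipped Gaussian.
#'
#' @param truth_track a [roi_track()] (e.g. `truth$boxes` of
#'   [generate_scene()]).
#' @param jitter_px corner jitter SD in px (default 0).
#' @param drop_rate per-box drop probability (default 0).
#' @param conf_mean,conf_sd confidence model (default 0.85 +/- 0.08).
#' @param seed RNG seed.
#' @return A [roi_track()] with confidences.
#' @export
generate_detection_fixture <- function(truth_track, jitter_px = 0,
                                       drop_rate = 0, conf_mean = 0.85,
                                       conf_sd = 0.08, seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  entries <- lapply(seq_along(truth_track), function(i) {
    b <- truth_track[[i]]
    if (!nrow(b)) return(empty_boxes())
    keep <- runif(nrow(b)) >= drop_rate
    b <- b[keep, , drop = FALSE]
    if (!nrow(b)) return(empty_boxes())
    if (jitter_px > 0) {
      b$x_min <- b$x_min + rnorm(nrow(b), 0, jitter_px)
      b$x_max <- b$x_max + rnorm(nrow(b), 0, jitter_px)
      b$y_min <- b$y_min + rnorm(nrow(b), 0, jitter_px)
      b$y_max <- b$y_max + rnorm(nrow(b), 0, jitter_px)
      bad <- b$x_min >= b$x_max | b$y_min >= b$y_max
      b <- b[!bad, , drop = FALSE]
    }
    if (nrow(b))
      b$confidence <- pmin(pmax(rnorm(nrow(b), conf_mean, conf_sd), 0.01), 1)
    b
  })
  roi_track(entries, length(truth_track))
}
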