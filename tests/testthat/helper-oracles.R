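# Shared fixtures and independent oracles, built in code at test time.

# Band-limited texture (sum of seeded sinusoids) with exact analytic
# sub-pixel shifts; shared intensity scale across shifts.
make_texture_fun <- function(seed = 42, K = 8, fmin = 0.03, fmax = 0.12) {
  set.seed(seed)
  fr <- runif(K, fmin, fmax)
  th <- runif(K, 0, pi)
  ph <- runif(K, 0, 2 * pi)
  amp <- runif(K, 0.5, 1)
  S <- sum(amp)
  function(W, H, sx = 0, sy = 0) {
    outer(seq_len(H), seq_len(W), function(r, c) {
      z <- 0
      for (i in seq_len(K))
        z <- z + amp[i] * sin(2 * pi * fr[i] *
                                (cos(th[i]) * (c - sx) +
                                 sin(th[i]) * (r - sy)) + ph[i])
      (z + S) / (2 * S)
    })
  }
}

# Brute-force polynomial expansion: per-pixel Gaussian-weighted least
# squares over the replicated-border window, solved with lm-style normal
# equations.  Independent of the separable-moment implementation.
oracle_poly_exp <- function(img, window, sigma) {
  n <- window %/% 2
  H <- nrow(img); W <- ncol(img)
  g1 <- exp(-0.5 * (-n:n)^2 / sigma^2)
  g1 <- g1 / sum(g1)
  offs <- expand.grid(y = -n:n, x = -n:n)
  wts <- g1[offs$y + n + 1] * g1[offs$x + n + 1]
  X <- cbind(1, offs$x, offs$y, offs$x^2, offs$y^2, offs$x * offs$y)
  out <- array(NA_real_, c(H, W, 6))
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rr <- pmin(pmax(r + offs$y, 1), H)
    cc <- pmin(pmax(c + offs$x, 1), W)
    f <- img[cbind(rr, cc)]
    beta <- solve(t(X) %*% (wts * X), t(X) %*% (wts * f))
    out[r, c, ] <- beta
  }
  list(c = out[, , 1], bx = out[, , 2], by = out[, , 3],
       axx = out[, , 4], ayy = out[, , 5], axy = out[, , 6])
}

# Exhaustive integer block matching (SSD over the shared valid region).
oracle_block_match <- function(a, b, max_shift = 4) {
  best <- c(0, 0); best_ssd <- Inf
  H <- nrow(a); W <- ncol(a)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    r1 <- max(1, 1 - dy):min(H, H - dy)
    c1 <- max(1, 1 - dx):min(W, W - dx)
    ssd <- mean((a[r1, c1] - b[r1 + dy, c1 + dx])^2)
    if (ssd < best_ssd) { best_ssd <- ssd; best <- c(dx, dy) }
  }
  best  # displacement of a's content inside b (dx, dy)
}

# Rasterization IoU oracle: count sub-pixel grid cells (step px) inside
# each box and both boxes over the joint bounding region; counting is
# separable per axis, so a very fine grid stays cheap.  Worst-case error
# ~ step * perimeter / union, i.e. < 1e-3 for boxes of >= 2 px sides.
oracle_iou_raster <- function(a, b, step = 5e-4) {
  x0 <- min(a$x_min, b$x_min); x1 <- max(a$x_max, b$x_max)
  y0 <- min(a$y_min, b$y_min); y1 <- max(a$y_max, b$y_max)
  xs <- seq(x0 + step / 2, x1, by = step)
  ys <- seq(y0 + step / 2, y1, by = step)
  inx_a <- xs >= a$x_min & xs < a$x_max
  iny_a <- ys >= a$y_min & ys < a$y_max
  inx_b <- xs >= b$x_min & xs < b$x_max
  iny_b <- ys >= b$y_min & ys < b$y_max
  na <- sum(inx_a) * sum(iny_a)
  nb <- sum(inx_b) * sum(iny_b)
  ni <- sum(inx_a & inx_b) * sum(iny_a & iny_b)
  ni / (na + nb - ni)
}

# AP by explicit PR-point enumeration over every confidence cutoff.
oracle_ap <- function(is_tp, n_truth) {
  pts <- t(vapply(seq_along(is_tp), function(k) {
    tp <- sum(is_tp[1:k]); fp <- k - tp
    c(recall = tp / n_truth, precision = tp / (tp + fp))
  }, numeric(2)))
  ap <- 0; prev_r <- 0
  for (i in seq_len(nrow(pts))) {
    pmax_right <- max(pts[i:nrow(pts), "precision"])
    ap <- ap + (pts[i, "recall"] - prev_r) * pmax_right
    prev_r <- pts[i, "recall"]
  }
  unname(ap)
}

# random box with sides >= 2 px inside [0, lim]^2
random_box <- function(lim = 20, min_side = 2, label = "chest") {
  repeat {
    p <- sort(runif(2, 0, lim)); q <- sort(runif(2, 0, lim))
    if (diff(p) >= min_side && diff(q) >= min_side) break
  }
  bounding_box(label, p[1], q[1], p[2], q[2])
}

# small default scene used by several module tests (fast to render)
tiny_scene <- function(seed = 1, duration = 30, rr_bpm = 15, amplitude = 1,
                       noise_sigma = 0.04, ...) {
  generate_scene(scene_config(width = 140, height = 110, fps = 4,
                              duration = duration, noise_sigma = noise_sigma,
                              chest = list(rr_bpm = rr_bpm,
                                           amplitude = amplitude),
                              seed = seed, ...))
}

# scene dimensions used by the acceptance RR criteria
accept_scene <- function(seed, rr_bpm, amplitude) {
  generate_scene(scene_config(width = 200, height = 150, fps = 4,
                              duration = 240, noise_sigma = 0.04,
                              chest = list(rr_bpm = rr_bpm,
                                           amplitude = amplitude),
                              seed = seed))
}
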