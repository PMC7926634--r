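# IIR utilities: Butterworth bandpass design via the bilinear transform and
# zero-phase (forward-backward) filtering with steady-state initialisation,
# mirroring the scipy.signal butter/filtfilt behaviour the field relies on.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0) - x * c(0, p)
  p
}

#' Design a digital Butterworth bandpass filter
#'
#' Analog Butterworth prototype of the given order, lowpass-to-bandpass
#' transformed and discretized by the bilinear transform with frequency
#' prewarping.  An order-`n` design yields a digital filter with `2n` poles
#' (the usual scipy/Matlab convention for "n-th order bandpass").
#'
#' @param low,high band edges in Hz (0 < low < high < fs / 2); the -3 dB
#'   points of the single-pass magnitude response.
#' @param fs sampling rate in Hz.
#' @param order prototype order (default 2).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low, high, fs, order = 2L) {
  stopifnot(low > 0, low < high, high < fs / 2, order >= 1)
  # prewarped analog edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog prototype poles on the unit circle's left half
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # lowpass -> bandpass: each pole maps to a conjugate-free pair
  pb <- p_proto * bw / 2
  disc <- sqrt(pb^2 - w0^2)
  p_a <- c(pb + disc, pb - disc)
  z_a <- rep(0 + 0i, order)
  k_a <- bw^order
  # bilinear transform (fs2 = 2 * fs)
  fs2 <- 2 * fs
  p_d <- (fs2 + p_a) / (fs2 - p_a)
  z_d <- c((fs2 + z_a) / (fs2 - z_a), rep(-1 + 0i, length(p_a) - length(z_a)))
  k_d <- k_a * Re(prod(fs2 - z_a) / prod(fs2 - p_a))
  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a)
}

#' Magnitude response of a digital filter
#'
#' @param filt list with `b`, `a` (see [butter_bandpass()]).
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param passes 1 for single-pass, 2 for the forward-backward (filtfilt)
#'   response `|H|^2`.
#' @return Magnitude (linear) at each frequency.
#' @export
filter_response <- function(filt, f, fs, passes = 1L) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1)),
                complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1)),
                complex(1))
  Mod(num / den)^passes
}

# direct-form II transposed IIR with initial conditions
iir_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  z <- if (is.null(zi)) rep(0, nfilt - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nfilt > 2)
      for (j in seq_len(nfilt - 2))
        z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nfilt - 1] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial conditions for a unit-step input (scipy lfilter_zi)
iir_filter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  companion <- rbind(-a[-1], cbind(diag(n - 2), 0))
  IminusA <- diag(n - 1) - t(companion)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forward and backward with odd-reflection padding and
#' steady-state initial conditions, so the net response has zero phase and
#' the squared magnitude of the single-pass design.
#'
#' @param filt list with `b`, `a`.
#' @param x numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(filt, x) {
  b <- filt$b; a <- filt$a
  padlen <- 3L * (max(length(a), length(b)) - 1L)
  if (length(x) <= padlen)
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 padlen))
  n <- length(x)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- iir_filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}
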