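#' Optical-flow parameters
#'
#' Parameters of the polynomial-expansion (Farneback) dense flow estimator.
#' The displacement field is obtained by fitting Gaussian-weighted quadratic
#' polynomials to each pixel neighbourhood of both frames and solving for the
#' displacement that maps one set of coefficients onto the other, refined
#' iteratively over a coarse-to-fine image pyramid.
#'
#' @param window_size odd neighbourhood size (px) of the quadratic fit.
#' @param gaussian_sigma width (px) of the Gaussian applicability weighting;
#'   defaults to `1.5 * window_size / 5`.
#' @param pyramid_levels maximum number of pyramid levels; levels smaller than
#'   twice the window are not built.
#' @param pyramid_scale downsampling factor between levels, in (0, 1).
#' @param iterations displacement refinement iterations per level.
#' @param smoothing_size box-averaging window (px) applied to the local
#'   normal equations before solving for the displacement.
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(window_size = 15L,
                        gaussian_sigma = NULL,
                        pyramid_levels = 3L,
                        pyramid_scale = 0.5,
                        iterations = 3L,
                        smoothing_size = 5L) {
  window_size <- as.integer(window_size)
  if (window_size < 3L || window_size %% 2L == 0L)
    stop("window_size must be an odd integer >= 3")
  if (is.null(gaussian_sigma)) gaussian_sigma <- 1.5 * window_size / 5
  if (pyramid_scale <= 0 || pyramid_scale >= 1)
    stop("pyramid_scale must be in (0, 1)")
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(window_size = window_size,
                 gaussian_sigma = gaussian_sigma,
                 pyramid_levels = as.integer(pyramid_levels),
                 pyramid_scale = pyramid_scale,
                 iterations = as.integer(iterations),
                 smoothing_size = as.integer(smoothing_size)),
            class = "flow_params")
}

#' Local quadratic (polynomial) expansion of an image
#'
#' Fits `f(x, y) ~ c + bx*x + by*y + axx*x^2 + ayy*y^2 + axy*x*y` in every
#' pixel neighbourhood by Gaussian-weighted least squares (x = column offset,
#' y = row offset, y grows downward; borders replicated).
#'
#' @param image numeric matrix, typically normalized to \[0, 1\].
#' @param params a [flow_params()] object.
#' @return List of coefficient matrices `c`, `bx`, `by`, `axx`, `ayy`, `axy`,
#'   each the shape of `image`.
#' @export
polynomial_expansion <- function(image, params = flow_params()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  .fb_poly_exp(image, params$window_size, params$gaussian_sigma)
}

#' Dense two-frame optical flow (polynomial expansion)
#'
#' @param prev,nxt numeric matrices of equal shape, normalized to \[0, 1\].
#' @param params a [flow_params()] object.
#' @return An object of class `flow_field`: list with displacement matrices
#'   `dx` (columns, positive rightward) and `dy` (rows, positive downward),
#'   in px per frame pair.
#' @export
dense_flow <- function(prev, nxt, params = flow_params()) {
  if (!is.matrix(prev) || !is.matrix(nxt) || !all(dim(prev) == dim(nxt)))
    stop("prev and nxt must be matrices of identical shape")
  fl <- .fb_dense_flow(prev, nxt,
                       params$window_size, params$gaussian_sigma,
                       params$pyramid_levels, params$pyramid_scale,
                       params$iterations, params$smoothing_size)
  structure(fl, class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field %d x %d px, mean |d| = %.3f px>\n",
              nrow(x$dx), ncol(x$dx),
              mean(sqrt(x$dx^2 + x$dy^2))))
  invisible(x)
}
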