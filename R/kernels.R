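#' Gaussian derivative kernels
#'
#' Analytic sampled kernels of mixed partial derivatives of the 2-D isotropic
#' unit-integral Gaussian. The closed form uses (physicists') Hermite
#' polynomials: d^n/dx^n g(x; sigma) = (-1)^n (sigma*sqrt(2))^{-n}
#' H_n(x / (sigma*sqrt(2))) g(x; sigma), so a mixed derivative factorizes into
#' an outer product of two 1-D profiles.
#'
#' @name gaussian-derivative-kernels
NULL

## Physicists' Hermite polynomial H_n evaluated by the three-term recurrence.
hermite_poly <- function(n, u) {
  if (n == 0L) return(rep(1, length(u)))
  if (n == 1L) return(2 * u)
  hm2 <- rep(1, length(u))
  hm1 <- 2 * u
  for (k in 2:n) {
    h <- 2 * u * hm1 - 2 * (k - 1) * hm2
    hm2 <- hm1
    hm1 <- h
  }
  hm1
}

#' Evaluate a 1-D Gaussian derivative profile at arbitrary positions
#'
#' @param x numeric positions (pixels).
#' @param order non-negative integer derivative order.
#' @param sigma positive Gaussian scale in pixels.
#' @return numeric vector d^order/dx^order g(x; sigma).
#' @keywords internal
gauss_deriv_1d <- function(x, order, sigma) {
  stopifnot(order >= 0, sigma > 0)
  g <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  if (order == 0L) return(g)
  u <- x / (sigma * sqrt(2))
  (-1)^order * (sigma * sqrt(2))^(-order) * hermite_poly(order, u) * g
}

#' Kernel half-width for a given scale
#'
#' @param sigma positive scale (pixels).
#' @param truncation kernel support in units of sigma (default 4).
#' @return integer half-width; full extent is \code{2*half+1}.
#' @export
kernel_half_width <- function(sigma, truncation = 4) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (truncation < 3) stop("truncation must be >= 3")
  as.integer(ceiling(truncation * sigma))
}

#' Sampled mixed Gaussian-derivative kernel
#'
#' Evaluates the analytic mixed partial derivative
#' \eqn{\partial_x^{i}\partial_y^{j} G_\sigma(x,y)} of the unit-integral 2-D
#' Gaussian on the integer pixel grid. Rows index y, columns index x, both
#' relative to the geometric center.
#'
#' @param dx_order,dy_order non-negative integer derivative orders along x
#'   (columns) and y (rows).
#' @param sigma positive Gaussian scale in pixels.
#' @param truncation support half-width in units of sigma (>= 3; half-width is
#'   \code{ceiling(truncation*sigma)}).
#' @return an object of class \code{"gdf_kernel"}: list with \code{values}
#'   (odd-extent numeric matrix), \code{center} (row, col of the center),
#'   \code{sigma}, \code{dx_order}, \code{dy_order}.
#' @examples
#' k <- gaussian_derivative_kernel(1, 0, sigma = 1)
#' sum(k$values)   # ~0: odd derivative
#' @export
gaussian_derivative_kernel <- function(dx_order, dy_order, sigma, truncation = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("invalid parameter: sigma must be a positive finite number")
  if (dx_order < 0 || dy_order < 0) stop("derivative orders must be >= 0")
  h <- kernel_half_width(sigma, truncation)
  g <- seq.int(-h, h)
  vals <- outer(gauss_deriv_1d(g, dy_order, sigma),
                gauss_deriv_1d(g, dx_order, sigma))
  structure(list(values = vals,
                 center = c(row = h + 1L, col = h + 1L),
                 sigma = sigma,
                 dx_order = as.integer(dx_order),
                 dy_order = as.integer(dy_order)),
            class = "gdf_kernel")
}

#' Evaluate an analytic Gaussian-derivative kernel at arbitrary coordinates
#'
#' Continuous-coordinate evaluation (used e.g. to sample rotated kernels).
#'
#' @param x,y numeric coordinate vectors (same length), x along columns, y
#'   along rows.
#' @inheritParams gaussian_derivative_kernel
#' @return numeric vector of kernel values.
#' @keywords internal
gauss_deriv_eval <- function(x, y, dx_order, dy_order, sigma) {
  gauss_deriv_1d(x, dx_order, sigma) * gauss_deriv_1d(y, dy_order, sigma)
}

## Mirror (symmetric, edge-repeating) padding of a matrix by h pixels.
mirror_pad <- function(m, h) {
  if (h == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (h > nr || h > nc) stop("image smaller than kernel support")
  ri <- c(h:1, 1:nr, nr:(nr - h + 1L))
  ci <- c(h:1, 1:nc, nc:(nc - h + 1L))
  m[ri, ci, drop = FALSE]
}

## Valid 1-D convolution of the rows/columns of a padded matrix with a tap
## vector, implemented as a sum of shifted slabs (true convolution: taps are
## applied flipped). `along` = 1 convolves down columns (y), 2 along rows (x).
conv_axis_valid <- function(padded, taps, along) {
  L <- length(taps)
  h <- (L - 1L) %/% 2L
  nr <- nrow(padded); nc <- ncol(padded)
  if (along == 1L) {
    out <- matrix(0, nr - L + 1L, nc)
    for (t in seq_len(L)) {
      w <- taps[L - t + 1L]           # flip for convolution
      if (w != 0)
        out <- out + w * padded[t:(t + nr - L), , drop = FALSE]
    }
  } else {
    out <- matrix(0, nr, nc - L + 1L)
    for (t in seq_len(L)) {
      w <- taps[L - t + 1L]
      if (w != 0)
        out <- out + w * padded[, t:(t + nc - L), drop = FALSE]
    }
  }
  out
}

#' Convolve an image with a separable Gaussian-derivative kernel
#'
#' True 2-D convolution with mirror (reflect) boundary handling, computed as
#' two 1-D passes; equal to dense 2-D convolution of the mirror-padded image
#' to ~1e-10.
#'
#' @param image numeric matrix.
#' @inheritParams gaussian_derivative_kernel
#' @return numeric matrix of the same shape as \code{image}.
#' @export
convolve_gauss_deriv <- function(image, dx_order, dy_order, sigma, truncation = 4) {
  h <- kernel_half_width(sigma, truncation)
  if (nrow(image) < 2L * h + 1L || ncol(image) < 2L * h + 1L)
    stop(sprintf("image (%d x %d) smaller than kernel support (%d x %d)",
                 nrow(image), ncol(image), 2L * h + 1L, 2L * h + 1L))
  g <- seq.int(-h, h)
  padded <- mirror_pad(image, h)
  tmp <- conv_axis_valid(padded, gauss_deriv_1d(g, dy_order, sigma), along = 1L)
  conv_axis_valid(tmp, gauss_deriv_1d(g, dx_order, sigma), along = 2L)
}

#' Dense 2-D convolution with an arbitrary odd-extent kernel
#'
#' Direct (non-separable) spatial convolution with mirror boundary handling.
#' Used for rotated sampled kernels, where separability does not hold.
#'
#' @param image numeric matrix.
#' @param kernel numeric matrix with odd extent in both axes.
#' @return numeric matrix of the same shape as \code{image}.
#' @export
convolve_dense <- function(image, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2L == 0L || kc %% 2L == 0L) stop("kernel extent must be odd")
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  if (nrow(image) < kr || ncol(image) < kc)
    stop("image smaller than kernel support")
  h <- max(hr, hc)
  padded <- mirror_pad(image, h)
  nr <- nrow(padded); nc <- ncol(padded)
  out <- matrix(0, nrow(image), ncol(image))
  ro <- h - hr; co <- h - hc   # offset when padding exceeds kernel half-width
  for (u in seq_len(kr)) {
    for (v in seq_len(kc)) {
      w <- kernel[kr - u + 1L, kc - v + 1L]   # flipped: convolution
      if (w != 0)
        out <- out + w * padded[(ro + u):(ro + u + nrow(image) - 1L),
                                (co + v):(co + v + ncol(image) - 1L)]
    }
  }
  out
}
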