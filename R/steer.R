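#' Steerable filtering: base responses, steering coefficients, oriented response
#'
#' @name steerable-filtering
NULL

#' Base filter responses needed to steer a template
#'
#' Convolves the image with every mixed Gaussian-derivative kernel of each
#' total order present in the template (all order-m pairs, not only the pairs
#' named in the template -- steering mixes all same-order derivatives).
#'
#' @param image numeric matrix (intensities; 8-bit inputs should be divided by
#'   255 before filtering).
#' @param template a \code{\link{steerable_template}} or built-in name.
#' @param sigma positive Gaussian scale in pixels.
#' @param truncation kernel support half-width in units of sigma.
#' @return object of class \code{"base_response_set"}: list with
#'   \code{responses} (named list \code{"i.j"} -> matrix for dx order i, dy
#'   order j), \code{sigma}, \code{truncation}, \code{image_shape},
#'   \code{orders}.
#' @export
base_responses <- function(image, template, sigma, truncation = 4) {
  template <- resolve_template(template)
  orders <- template_orders(template)
  responses <- list()
  for (m in orders) {
    for (i in 0:m) {
      key <- paste0(i, ".", m - i)
      responses[[key]] <- convolve_gauss_deriv(image, i, m - i, sigma, truncation)
    }
  }
  structure(list(responses = responses, sigma = sigma, truncation = truncation,
                 image_shape = dim(image), orders = orders),
            class = "base_response_set")
}

#' Steering coefficients of a template at an orientation
#'
#' Rotating a derivative operator by theta substitutes
#' \eqn{\partial_{x'} = \cos\theta\,\partial_x + \sin\theta\,\partial_y} and
#' \eqn{\partial_{y'} = -\sin\theta\,\partial_x + \cos\theta\,\partial_y};
#' expanding each rotated term of the template and collecting same-order
#' monomials yields the weights alpha such that the rotated-template response
#' equals \eqn{\sum \alpha_{m,i} I_{m,i}}. Term weights are sigma-folded
#' (weight * sigma^sigma_exponent) before collection. Theta is measured
#' counter-clockwise from the +x axis.
#'
#' @inheritParams base_responses
#' @param theta orientation in radians.
#' @return named numeric vector, names \code{"i.j"} for the (dx=i, dy=j) base
#'   kernels.
#' @export
steering_coefficients <- function(template, theta, sigma) {
  template <- resolve_template(template)
  if (!is.finite(theta)) stop("theta must be finite")
  ct <- cos(theta); st <- sin(theta)
  w <- folded_weights(template, sigma)
  alpha <- numeric(0)
  for (t in seq_along(template$terms)) {
    tm <- template$terms[[t]]
    i <- tm$dx_order; j <- tm$dy_order
    m <- i + j
    ## coefficients of dx^a dy^(m-a) in (ct*dx + st*dy)^i  (index a = 0..i)
    px <- vapply(0:i, function(a) choose(i, a) * ct^a * st^(i - a), 1.0)
    ## coefficients in (-st*dx + ct*dy)^j
    py <- vapply(0:j, function(a) choose(j, a) * (-st)^a * ct^(j - a), 1.0)
    prod_coef <- if (length(py) == 1L) px * py else convolve(px, rev(py), type = "open")
    for (a in 0:m) {
      key <- paste0(a, ".", m - a)
      cur <- if (key %in% names(alpha)) alpha[[key]] else 0
      alpha[[key]] <- cur + w[t] * prod_coef[a + 1L]
    }
  }
  alpha
}

#' Oriented filter response by steering
#'
#' Computes the response of the image to the template rotated by theta as a
#' weighted sum of base responses. Responses at theta and theta+pi differ only
#' by the parity sign of the derivative orders, so orientation sampling is
#' restricted to [0, pi).
#'
#' @inheritParams base_responses
#' @param theta orientation in radians.
#' @param base optional precomputed \code{\link{base_responses}} result (must
#'   match template orders, sigma).
#' @return object of class \code{"oriented_response"}: list with \code{values}
#'   (matrix), \code{theta}, \code{sigma}, \code{template_name},
#'   \code{margin} (interior margin = kernel half-width).
#' @export
oriented_response <- function(image, template, sigma, theta,
                              base = NULL, truncation = 4) {
  template <- resolve_template(template)
  if (is.null(base)) base <- base_responses(image, template, sigma, truncation)
  alpha <- steering_coefficients(template, theta, sigma)
  vals <- 0
  for (key in names(alpha)) {
    if (alpha[[key]] == 0) next
    r <- base$responses[[key]]
    if (is.null(r)) stop("base response set lacks kernel ", key)
    vals <- vals + alpha[[key]] * r
  }
  if (is.null(dim(vals))) vals <- matrix(vals, base$image_shape[1], base$image_shape[2])
  structure(list(values = vals, theta = theta, sigma = sigma,
                 template_name = template$name,
                 margin = kernel_half_width(sigma, base$truncation)),
            class = "oriented_response")
}

#' Interior pixels of an oriented response
#'
#' Drops a margin of one kernel half-width on every side, so that
#' mirror-padding boundary artifacts do not enter response statistics.
#'
#' @param x an \code{oriented_response} or a plain matrix.
#' @param margin margin in pixels (defaults to the stored kernel half-width).
#' @return numeric matrix of interior values.
#' @export
interior_values <- function(x, margin = NULL) {
  if (inherits(x, "oriented_response")) {
    if (is.null(margin)) margin <- x$margin
    x <- x$values
  }
  if (is.null(margin)) stop("margin required for plain matrices")
  nr <- nrow(x); nc <- ncol(x)
  if (2L * margin >= nr || 2L * margin >= nc) stop("margin leaves no interior")
  x[(margin + 1L):(nr - margin), (margin + 1L):(nc - margin), drop = FALSE]
}

#' Sample a rotated template kernel on the pixel grid
#'
#' Evaluates the analytic template kernel at coordinates rotated by theta
#' (the reference oracle for the steering identity; this path does a dense
#' convolution per angle and is used for validation, not production).
#'
#' @inheritParams base_responses
#' @param theta orientation in radians.
#' @return numeric matrix of the sampled rotated kernel.
#' @export
rotated_template_kernel <- function(template, sigma, theta, truncation = 4) {
  template <- resolve_template(template)
  h <- kernel_half_width(sigma, truncation)
  g <- seq.int(-h, h)
  X <- matrix(rep(g, each = length(g)), length(g))   # x along columns
  Y <- matrix(rep(g, times = length(g)), length(g))  # y along rows
  ct <- cos(theta); st <- sin(theta)
  U <- ct * X + st * Y
  V <- -st * X + ct * Y
  w <- folded_weights(template, sigma)
  vals <- matrix(0, length(g), length(g))
  for (t in seq_along(template$terms)) {
    tm <- template$terms[[t]]
    vals <- vals + w[t] * gauss_deriv_eval(U, V, tm$dx_order, tm$dy_order, sigma)
  }
  vals
}
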