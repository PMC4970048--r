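#' Steerable Gaussian-derivative filter templates
#'
#' A steerable template is a weighted sum of mixed Gaussian-derivative terms
#' \eqn{\sum_t w_t \sigma^{e_t} \, \partial_x^{i_t}\partial_y^{j_t} G_\sigma}.
#' Because each term is a derivative of an isotropic Gaussian, the response of
#' the rotated template at any angle is an exact linear combination of the
#' responses to all same-order derivative kernels (the steering property), so
#' orientation sweeps cost one weighted sum per angle instead of one
#' convolution per angle.
#'
#' @name steerable-templates
NULL

#' Construct a steerable template
#'
#' @param name identifier for the template.
#' @param terms a list of terms; each term is a list/vector with fields
#'   \code{weight} (real), \code{sigma_exponent} (non-negative integer power of
#'   sigma multiplying the weight), \code{dx_order} and \code{dy_order}
#'   (non-negative integer derivative orders; the total order of every term
#'   must be >= 1 -- templates contain no pure smoothing term).
#' @param extra_params named list of auxiliary reals (e.g. the wedge angle
#'   \code{phi} of the wedge detector).
#' @return object of class \code{"steerable_template"}.
#' @export
steerable_template <- function(name, terms, extra_params = list()) {
  if (length(terms) < 1L) stop("template needs at least one term")
  terms <- lapply(terms, function(tm) {
    tm <- as.list(tm)
    stopifnot(all(c("weight", "sigma_exponent", "dx_order", "dy_order") %in% names(tm)))
    tm$dx_order <- as.integer(tm$dx_order)
    tm$dy_order <- as.integer(tm$dy_order)
    tm$sigma_exponent <- as.integer(tm$sigma_exponent)
    if (tm$dx_order < 0 || tm$dy_order < 0) stop("derivative orders must be >= 0")
    if (tm$dx_order + tm$dy_order < 1L)
      stop("every term must have total derivative order >= 1")
    if (tm$sigma_exponent < 0L) stop("sigma_exponent must be >= 0")
    tm
  })
  structure(list(name = name, terms = terms, extra_params = extra_params),
            class = "steerable_template")
}

#' @export
print.steerable_template <- function(x, ...) {
  cat("Steerable template", x$name, "with", length(x$terms), "term(s):\n")
  for (tm in x$terms)
    cat(sprintf("  %+ .6g * sigma^%d * d^%d/dx^%d d^%d/dy^%d G\n",
                tm$weight, tm$sigma_exponent, tm$dx_order, tm$dx_order,
                tm$dy_order, tm$dy_order))
  invisible(x)
}

template_orders <- function(template) {
  sort(unique(vapply(template$terms, function(tm) tm$dx_order + tm$dy_order, 1L)))
}

## sigma-folded weights: weight * sigma^sigma_exponent per term
folded_weights <- function(template, sigma) {
  vapply(template$terms, function(tm) tm$weight * sigma^tm$sigma_exponent, 1.0)
}

#' Built-in steerable detector templates
#'
#' The six classical edge/ridge/wedge detector templates used for
#' granulated-product texture analysis: T1-T3 are Canny-like optimal edge
#' detectors of increasing derivative order, T4 and T5 are ridge detectors,
#' and T6 is a wedge detector with opening angle \code{phi}. Two printed
#' constants in the literature are typographically ambiguous; the
#' \code{radical_constants} switch replaces \code{-2/pi} (T1) by
#' \code{-sqrt(2/pi)}, \code{-3/(4*pi)} (T4) by \code{-sqrt(3/(4*pi))} and the
#' wedge normalizer by its square-root variant. A global template rescaling
#' only rescales the fitted location and scale parameters and leaves the shape
#' parameter untouched, so downstream features are robust to this choice.
#'
#' @param name one of \code{"T1"} ... \code{"T6"}.
#' @param phi wedge angle in radians for T6 (default \code{pi/2}).
#' @param radical_constants logical; use the square-root variants of the
#'   ambiguous printed constants (default \code{FALSE}: literal constants).
#' @return a \code{\link{steerable_template}}.
#' @export
gdf_template <- function(name, phi = pi / 2, radical_constants = FALSE) {
  trm <- function(w, e, dx, dy)
    list(weight = w, sigma_exponent = e, dx_order = dx, dy_order = dy)
  c1 <- if (radical_constants) -sqrt(2 / pi) else -2 / pi
  c4 <- if (radical_constants) -sqrt(3 / (4 * pi)) else -3 / (4 * pi)
  c6 <- if (radical_constants) -sqrt(2 / (2 + pi + 2 * cos(phi)))
        else -2 / (2 + pi + 2 * cos(phi))
  switch(name,
    T1 = steerable_template("T1", list(trm(c1, 0L, 0L, 1L))),
    T2 = steerable_template("T2", list(
      trm(-0.966, 0L, 0L, 1L),
      trm(-0.256, 2L, 2L, 1L))),
    T3 = steerable_template("T3", list(
      trm(-1.0655, 0L, 0L, 1L),
      trm(-0.2,    2L, 2L, 1L),
      trm(-0.042,  2L, 0L, 3L))),
    T4 = steerable_template("T4", list(
      trm(c4,      1L, 0L, 2L),
      trm(-c4 / 3, 1L, 2L, 0L))),
    T5 = steerable_template("T5", list(
      trm(-0.204, 0L, 0L, 2L),
      trm( 0.059, 1L, 2L, 0L),
      trm( 0.063, 2L, 0L, 4L),
      trm(-0.194, 3L, 2L, 2L),
      trm( 0.024, 3L, 4L, 0L))),
    T6 = steerable_template("T6", list(
      trm(c6, 0L, 1L, 0L),
      trm( c6 * cos(phi / 2) / pi, 1L, 2L, 0L),
      trm(-c6 * cos(phi / 2) / pi, 1L, 0L, 2L)),
      extra_params = list(phi = phi)),
    stop("unknown template: ", name)
  )
}

#' List the built-in template names
#' @return character vector \code{c("T1", ..., "T6")}.
#' @export
gdf_template_names <- function() paste0("T", 1:6)

#' Build a template from a plain list (e.g. parsed from YAML)
#'
#' Expects \code{list(name =, terms = list(list(weight=, sigma_exponent=,
#' dx_order=, dy_order=), ...), extra_params = list(...))}.
#'
#' @param x plain list description.
#' @return a \code{\link{steerable_template}}.
#' @export
template_from_list <- function(x) {
  steerable_template(x$name, x$terms,
                     if (is.null(x$extra_params)) list() else x$extra_params)
}

## Resolve either a template object or a built-in name.
resolve_template <- function(template, phi = pi / 2) {
  if (inherits(template, "steerable_template")) return(template)
  if (is.character(template) && length(template) == 1L)
    return(gdf_template(template, phi = phi))
  stop("template must be a steerable_template or a built-in name")
}
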