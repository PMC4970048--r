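#' Multi-scale omnidirectional Weibull texture features
#'
#' One image is turned into a feature vector by fitting the integral-form
#' Weibull distribution to steered filter responses over a sweep of
#' orientations and Gaussian scales, on the whole image (global block) and on
#' a grid of non-overlapping subimages (local blocks). Per direction the
#' (mu, beta, lambda) triple is emitted; directions are fastest within a
#' scale, scales within a region, the global block precedes the subimage
#' blocks, and templates are concatenated outermost.
#'
#' @name texture-features
NULL

#' Feature extraction configuration
#'
#' Defaults follow the standard operating point: 60 uniformly spaced
#' directions in [0, pi), the geometric scale ladder
#' \code{c(0.5, sqrt(2)/2, 1, sqrt(2), 2)} (ratio sqrt(2)), and a 2x2
#' subimage grid (N = 4 local blocks).
#'
#' @param template_names character vector of built-in template names or a
#'   list of \code{\link{steerable_template}} objects.
#' @param n_directions number of orientations sampled uniformly in [0, pi).
#' @param scales positive Gaussian scales (pixels).
#' @param subimage_grid integer (rows, cols) of the non-overlapping grid.
#' @param truncation kernel support half-width in units of sigma.
#' @param warm_start logical; reuse the previous direction's fitted parameters
#'   as the Nelder-Mead start after the first direction of each sweep.
#' @param fit_reltol,fit_maxit Nelder-Mead controls for the per-direction fits.
#' @return object of class \code{"feature_config"}.
#' @export
feature_config <- function(template_names = "T1",
                           n_directions = 60L,
                           scales = c(0.5, sqrt(2) / 2, 1, sqrt(2), 2),
                           subimage_grid = c(2L, 2L),
                           truncation = 4,
                           warm_start = TRUE,
                           fit_reltol = 1e-8,
                           fit_maxit = 2000L) {
  if (n_directions < 1L) stop("n_directions must be >= 1")
  if (any(scales <= 0)) stop("scales must be strictly positive")
  if (any(subimage_grid < 1L)) stop("subimage_grid dims must be >= 1")
  structure(list(template_names = template_names,
                 n_directions = as.integer(n_directions),
                 scales = scales,
                 subimage_grid = as.integer(subimage_grid),
                 truncation = truncation,
                 warm_start = isTRUE(warm_start),
                 fit_reltol = fit_reltol,
                 fit_maxit = as.integer(fit_maxit)),
            class = "feature_config")
}

#' Total feature length implied by a configuration
#'
#' Per template: |scales| * n_directions * 3 * (grid cells + 1).
#'
#' @param config a \code{\link{feature_config}}.
#' @return integer feature-vector length.
#' @export
feature_length <- function(config) {
  n_tpl <- length(config$template_names)
  n_regions <- prod(config$subimage_grid) + 1L
  as.integer(n_tpl * length(config$scales) * config$n_directions * 3L * n_regions)
}

#' Column layout of a feature vector
#'
#' @param config a \code{\link{feature_config}}.
#' @return data.frame with columns template, region, scale_index, scale,
#'   direction_index, param, and the encoded column \code{name}
#'   (\code{template.region.sXX.dXX.param}).
#' @export
feature_layout <- function(config) {
  tpl_names <- unname(vapply(config$template_names, function(t)
    if (inherits(t, "steerable_template")) t$name else t, ""))
  n_sub <- prod(config$subimage_grid)
  regions <- c("global", paste0("sub", seq_len(n_sub)))
  rows <- expand.grid(param = c("mu", "beta", "lambda"),
                      direction_index = seq_len(config$n_directions),
                      scale_index = seq_along(config$scales),
                      region = regions,
                      template = tpl_names,
                      stringsAsFactors = FALSE)
  rows <- rows[, c("template", "region", "scale_index", "direction_index", "param")]
  rows$scale <- config$scales[rows$scale_index]
  rows$name <- sprintf("%s.%s.s%02d.d%02d.%s", rows$template, rows$region,
                       rows$scale_index, rows$direction_index, rows$param)
  rows
}

## Fit the WD to the pixels of one steered response, with optional warm start.
fit_response <- function(values, config, start = NULL, what = "") {
  v <- as.numeric(values)
  if (length(v) < 50L)
    stop("subimage too small for distribution fitting", what)
  if (stats::sd(v) == 0)
    stop("degenerate input: constant filter response", what)
  fit <- fit_wd_mle(v, start = start, reltol = config$fit_reltol,
                    maxit = config$fit_maxit, gof = FALSE)
  fit$params
}

## Region masks: list of row/col index pairs for global + grid blocks,
## intersected with the interior margin. Remainder pixels go to the last
## block in each axis.
region_indices <- function(image_dim, margin, grid) {
  nr <- image_dim[1]; nc <- image_dim[2]
  int_r <- (margin + 1L):(nr - margin)
  int_c <- (margin + 1L):(nc - margin)
  if (length(int_r) < 1L || length(int_c) < 1L)
    stop("image smaller than kernel support at this scale")
  regions <- list(global = list(rows = int_r, cols = int_c))
  rb <- floor(seq(0L, nr, length.out = grid[1] + 1L))
  cb <- floor(seq(0L, nc, length.out = grid[2] + 1L))
  k <- 0L
  for (i in seq_len(grid[1])) {
    for (j in seq_len(grid[2])) {
      k <- k + 1L
      rows <- intersect((rb[i] + 1L):rb[i + 1L], int_r)
      cols <- intersect((cb[j] + 1L):cb[j + 1L], int_c)
      if (length(rows) * length(cols) < 50L)
        stop(sprintf("subimage %d (block %d,%d) too small at margin %d",
                     k, i, j, margin))
      regions[[paste0("sub", k)]] <- list(rows = rows, cols = cols)
    }
  }
  regions
}

## Core sweep: for one template and one scale, fit (mu, beta, lambda) at each
## direction for each requested region. Base responses are computed once per
## (image, scale) and reused across all directions (the steerability payoff).
## Returns a list region -> numeric vector length 3 * n_directions.
sweep_directions <- function(image, template, sigma, config, regions) {
  base <- base_responses(image, template, sigma, config$truncation)
  thetas <- (seq_len(config$n_directions) - 1L) * pi / config$n_directions
  out <- lapply(regions, function(r) numeric(3L * config$n_directions))
  starts <- vector("list", length(regions))
  names(starts) <- names(regions)
  for (j in seq_along(thetas)) {
    resp <- oriented_response(image, template, sigma, thetas[j], base = base,
                              truncation = config$truncation)
    for (rn in names(regions)) {
      reg <- regions[[rn]]
      vals <- resp$values[reg$rows, reg$cols]
      pars <- tryCatch(
        fit_response(vals, config,
                     start = if (config$warm_start) starts[[rn]] else NULL,
                     what = sprintf(" (region %s, theta = %.4f)", rn, thetas[j])),
        error = function(e) stop(conditionMessage(e), call. = FALSE))
      starts[[rn]] <- pars
      out[[rn]][(3L * (j - 1L) + 1L):(3L * j)] <- c(pars$mu, pars$beta, pars$lam)
    }
  }
  out
}

#' Omnidirectional features at one scale
#'
#' Fits the Weibull model to the interior pixels of the steered response at
#' each direction \eqn{\theta_j = (j-1)\pi/n} and emits the (mu, beta,
#' lambda) triple per direction.
#'
#' @param image numeric matrix in [0, 1].
#' @param template a \code{\link{steerable_template}} or built-in name.
#' @param sigma positive Gaussian scale.
#' @param n_directions number of directions.
#' @param config optional \code{\link{feature_config}} carrying fit options.
#' @return numeric vector of length \code{3 * n_directions}.
#' @export
directional_features <- function(image, template, sigma, n_directions = 60L,
                                 config = NULL) {
  if (is.null(config)) config <- feature_config(n_directions = n_directions)
  config$n_directions <- as.integer(n_directions)
  template <- resolve_template(template)
  margin <- kernel_half_width(sigma, config$truncation)
  regions <- list(global = region_indices(dim(image), margin, c(1L, 1L))$global)
  sweep_directions(image, template, sigma, config, regions)$global
}

#' Multi-scale omnidirectional features
#'
#' Concatenation of \code{\link{directional_features}} over the configured
#' scales, in order.
#'
#' @inheritParams directional_features
#' @param config a \code{\link{feature_config}}.
#' @return numeric vector of length \code{|scales| * 3 * n_directions}.
#' @export
multiscale_features <- function(image, template, config = feature_config()) {
  unlist(lapply(config$scales, function(s)
    directional_features(image, template, s, config$n_directions, config)),
    use.names = FALSE)
}

#' Extended (global + local) feature vector
#'
#' The full texture descriptor: for every template, the global multi-scale
#' omnidirectional block followed by one block per subimage of the
#' non-overlapping grid. The image is filtered once per (scale, direction)
#' and the response is split into grid blocks (intersected with the interior
#' margin), so local blocks share the global filtering work.
#'
#' @param image numeric matrix in [0, 1].
#' @param config a \code{\link{feature_config}}.
#' @param source_id identifier stored with the vector.
#' @return object of class \code{"feature_vector"}: list with \code{values}
#'   (named numeric vector), \code{layout} (see \code{\link{feature_layout}}),
#'   \code{source_id}.
#' @export
extended_features <- function(image, config = feature_config(),
                              source_id = "image") {
  layout <- feature_layout(config)
  templates <- lapply(config$template_names, resolve_template)
  n_dir3 <- 3L * config$n_directions
  values <- numeric(0)
  for (tpl in templates) {
    per_region <- vector("list", prod(config$subimage_grid) + 1L)
    names(per_region) <- c("global", paste0("sub", seq_len(prod(config$subimage_grid))))
    for (rn in names(per_region)) per_region[[rn]] <- numeric(0)
    for (s in config$scales) {
      margin <- kernel_half_width(s, config$truncation)
      regions <- region_indices(dim(image), margin, config$subimage_grid)
      blocks <- sweep_directions(image, tpl, s, config, regions)
      for (rn in names(per_region))
        per_region[[rn]] <- c(per_region[[rn]], blocks[[rn]])
    }
    values <- c(values, unlist(per_region, use.names = FALSE))
  }
  stopifnot(length(values) == feature_length(config))
  names(values) <- layout$name
  structure(list(values = values, layout = layout, source_id = source_id),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("Feature vector '%s': %d values (%d templates x %d scales x %d directions x 3 params x %d regions)\n",
              x$source_id, length(x$values),
              length(unique(x$layout$template)), length(unique(x$layout$scale_index)),
              max(x$layout$direction_index), length(unique(x$layout$region))))
  invisible(x)
}

#' Write / read feature tables as CSV with a JSON sidecar
#'
#' One row per image; the header encodes (template, region, scale index,
#' direction index, parameter). A sidecar \code{<path>.json} stores the exact
#' configuration; the reader validates the header against it.
#'
#' @param features a \code{feature_vector}, a list of them, or a data.frame
#'   whose first column is \code{source_id}.
#' @param path CSV output path.
#' @param config the \code{\link{feature_config}} used.
#' @return the path, invisibly.
#' @export
write_features_csv <- function(features, path, config) {
  if (inherits(features, "feature_vector")) features <- list(features)
  if (is.data.frame(features)) {
    df <- features
  } else {
    df <- do.call(rbind, lapply(features, function(fv)
      data.frame(source_id = fv$source_id, t(fv$values), check.names = FALSE)))
    colnames(df) <- c("source_id", feature_layout(config)$name)
  }
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- config
  cfg$template_names <- vapply(cfg$template_names, function(t)
    if (inherits(t, "steerable_template")) t$name else t, "")
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path, config = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(config)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      cfg <- jsonlite::fromJSON(readLines(sidecar))
      config <- feature_config(template_names = cfg$template_names,
                               n_directions = cfg$n_directions,
                               scales = cfg$scales,
                               subimage_grid = cfg$subimage_grid,
                               truncation = cfg$truncation,
                               warm_start = cfg$warm_start,
                               fit_reltol = cfg$fit_reltol,
                               fit_maxit = cfg$fit_maxit)
    }
  }
  if (!is.null(config)) {
    expected <- c("source_id", feature_layout(config)$name)
    if (!identical(colnames(df), expected))
      stop("feature table header does not match the configuration layout")
  }
  df
}
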