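#' Seeded synthetic fixtures
#'
#' Generators for (a) granular-product-like images -- many stochastically
#' packed, locally homogeneous bright particles on a darker background with
#' shading and sub-pixel edge structure -- and (b) two-class semi-supervised
#' feature datasets with a controllable label rate. Both are pure functions
#' of their spec (seed included).
#'
#' @name synthetic-fixtures
NULL

#' Specification of a synthetic granular image
#'
#' @param shape integer (rows, cols), both >= 64.
#' @param n_particles number of ellipses to render.
#' @param axis_mean mean (major, minor) semi-axes in pixels.
#' @param axis_spread multiplicative spread of the axes (lognormal sd).
#' @param orientation \code{"isotropic"} or a list
#'   \code{list(angle =, spread =)} for orientations concentrated at an angle
#'   (radians, sd of a wrapped normal).
#' @param fg_mean,bg_mean foreground / background intensity means in [0, 1].
#' @param fg_jitter per-particle intensity jitter (sd).
#' @param shading amplitude of the Lambertian-like linear shading across each
#'   particle (0 = flat).
#' @param noise_sd Gaussian pixel noise sd.
#' @param overlap logical; allow overlapping particles (painter's order). If
#'   FALSE, placement is rejection-sampled with bounded retries.
#' @param seed integer seed.
#' @return object of class \code{"granular_image_spec"}.
#' @export
granular_image_spec <- function(shape = c(128L, 128L),
                                n_particles = 120L,
                                axis_mean = c(7, 3.2),
                                axis_spread = 0.25,
                                orientation = "isotropic",
                                fg_mean = 0.72, bg_mean = 0.22,
                                fg_jitter = 0.05,
                                shading = 0.35,
                                noise_sd = 0.02,
                                overlap = TRUE,
                                seed = 1L) {
  if (any(shape < 64L)) stop("image dimensions must be >= 64")
  if (fg_mean < 0 || fg_mean > 1 || bg_mean < 0 || bg_mean > 1)
    stop("intensity means must lie in [0, 1]")
  structure(list(shape = as.integer(shape), n_particles = as.integer(n_particles),
                 axis_mean = axis_mean, axis_spread = axis_spread,
                 orientation = orientation, fg_mean = fg_mean, bg_mean = bg_mean,
                 fg_jitter = fg_jitter, shading = shading, noise_sd = noise_sd,
                 overlap = isTRUE(overlap), seed = as.integer(seed)),
            class = "granular_image_spec")
}

#' Render a synthetic granular image
#'
#' Renders shaded ellipses at random positions and orientations with
#' anti-aliased (soft, ~1 pixel) edges, so derivative filters see sub-pixel
#' gradients rather than pathological hard steps. Intensities are clipped to
#' [0, 1]; output is reproducible given the spec's seed.
#'
#' @param spec a \code{\link{granular_image_spec}}.
#' @return numeric matrix in [0, 1].
#' @export
generate_granular_image <- function(spec) {
  stopifnot(inherits(spec, "granular_image_spec"))
  with_seed(spec$seed, render_granular(spec))
}

render_granular <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  img <- matrix(spec$bg_mean, nr, nc)
  placed <- matrix(numeric(0), 0, 3)  # cx, cy, radius (for overlap rejection)
  max_retries <- 40L
  for (p in seq_len(spec$n_particles)) {
    a <- spec$axis_mean[1] * exp(stats::rnorm(1, 0, spec$axis_spread))
    b <- spec$axis_mean[2] * exp(stats::rnorm(1, 0, spec$axis_spread))
    ang <- if (identical(spec$orientation, "isotropic")) stats::runif(1, 0, pi)
           else stats::rnorm(1, spec$orientation$angle, spec$orientation$spread) %% pi
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
      if (spec$overlap || nrow(placed) == 0L) { ok <- TRUE; break }
      d <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
      if (all(d > placed[, 3] + max(a, b))) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible packing: could not place particle without overlap")
    placed <- rbind(placed, c(cx, cy, max(a, b)))
    ## local bounding box
    r <- ceiling(max(a, b)) + 2L
    rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
    cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
    X <- outer(rep(1, length(rows)), cols) - cx
    Y <- outer(rows, rep(1, length(cols))) - cy
    ca <- cos(ang); sa <- sin(ang)
    U <- (ca * X + sa * Y) / a
    V <- (-sa * X + ca * Y) / b
    q <- sqrt(U^2 + V^2)
    ## anti-aliased coverage: soft edge about one pixel wide
    edge <- 1 / max(1, min(a, b))
    alpha <- pmin(1, pmax(0, (1 - q) / edge + 0.5))
    base <- spec$fg_mean + stats::rnorm(1, 0, spec$fg_jitter)
    shade <- 1 + spec$shading * U   # linear shading along the major axis
    tile <- base * shade
    blk <- img[rows, cols]
    img[rows, cols] <- alpha * tile + (1 - alpha) * blk
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  img[] <- pmin(1, pmax(0, img))
  img
}

#' Specification of a two-class semi-supervised feature dataset
#'
#' Two Gaussian classes with means at -m and +m on every coordinate
#' (class -1 at -m) and isotropic covariance.
#'
#' @param n_per_class samples per class.
#' @param k feature dimension.
#' @param separation distance between the two class means per coordinate
#'   (class means are at \code{-separation/2} and \code{+separation/2} times
#'   the all-ones vector).
#' @param cov_scale standard deviation of each coordinate within a class.
#' @param label_rate fraction in (0, 1] of each class carrying labels;
#'   requires \code{round(label_rate * n_per_class) >= k + 2} per class so the
#'   thin-plate classifier is solvable.
#' @param groups optional integer vector of group sizes summing to
#'   \code{2 * n_per_class} (for per-group error metrics).
#' @param seed integer seed.
#' @return object of class \code{"ss_dataset_spec"}.
#' @export
ss_dataset_spec <- function(n_per_class = 200L, k = 4L, separation = 2,
                            cov_scale = 1, label_rate = 0.45,
                            groups = NULL, seed = 1L) {
  if (label_rate <= 0 || label_rate > 1) stop("label_rate must be in (0, 1]")
  n_lab <- round(label_rate * n_per_class)
  if (n_lab < k + 2L)
    stop("label_rate * n_per_class must be >= k + 2 per class")
  if (!is.null(groups) && sum(groups) != 2L * n_per_class)
    stop("group sizes must sum to the total sample count")
  structure(list(n_per_class = as.integer(n_per_class), k = as.integer(k),
                 separation = separation, cov_scale = cov_scale,
                 label_rate = label_rate, groups = groups, seed = as.integer(seed)),
            class = "ss_dataset_spec")
}

#' Generate a two-class semi-supervised dataset
#'
#' @param spec an \code{\link{ss_dataset_spec}}.
#' @return list with \code{labeled} (a \code{\link{labeled_set}}),
#'   \code{unlabeled} (features matrix), \code{truth} (hidden true labels of
#'   the unlabeled rows), \code{groups} (group ids of the unlabeled rows, if
#'   requested).
#' @export
generate_ss_dataset <- function(spec) {
  stopifnot(inherits(spec, "ss_dataset_spec"))
  with_seed(spec$seed, {
    n <- spec$n_per_class; k <- spec$k
    m <- spec$separation / 2
    Xneg <- matrix(stats::rnorm(n * k, -m, spec$cov_scale), n, k)
    Xpos <- matrix(stats::rnorm(n * k, +m, spec$cov_scale), n, k)
    X <- rbind(Xneg, Xpos)
    y <- c(rep(-1, n), rep(1, n))
    grp <- if (is.null(spec$groups)) rep(1L, 2L * n)
           else rep(seq_along(spec$groups), spec$groups)
    n_lab <- round(spec$label_rate * n)
    lab_idx <- c(sample(seq_len(n), n_lab), n + sample(seq_len(n), n_lab))
    lab_idx <- sort(lab_idx)
    unl_idx <- setdiff(seq_len(2L * n), lab_idx)
    list(labeled = labeled_set(X[lab_idx, , drop = FALSE], y[lab_idx]),
         unlabeled = X[unl_idx, , drop = FALSE],
         truth = y[unl_idx],
         groups = grp[unl_idx])
  })
}
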