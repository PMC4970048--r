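# Shared fixtures, all generated in code.

# seeded random test image
random_image <- function(n = 64, seed = 42) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# noisy sinusoidal stripes varying along columns (x); the gradient points
# along x, so a first-derivative (edge) template steered to pi/2 responds most
stripe_image <- function(n = 80, period = 9, noise_sd = 0.03, seed = 2) {
  set.seed(seed)
  img <- outer(rep(1, n), seq_len(n))
  img <- 0.5 + 0.35 * sin(2 * pi * img / period) +
    matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  img[] <- pmin(1, pmax(0, img))
  img
}

# small granular image for feature tests
small_grain_image <- function(seed = 5, shape = c(96, 96), n_particles = 70)
  generate_granular_image(granular_image_spec(shape = shape,
                                              n_particles = n_particles,
                                              seed = seed))

# reduced-tier feature configuration used throughout the feature tests
small_feature_config <- function(...)
  feature_config(template_names = "T2", n_directions = 12L,
                 scales = c(0.5, 1), subimage_grid = c(2L, 2L), ...)

# select parameter columns out of a feature vector by name
feat_param <- function(fv, param)
  fv$values[grepl(paste0("\\.", param, "$"), names(fv$values))]

# two seeded Gaussian clouds as a labeled set
gaussian_clouds <- function(n = 100, k = 4, shift = 1, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n / 2 * k, -shift), n / 2, k),
             matrix(stats::rnorm(n / 2 * k, +shift), n / 2, k))
  labeled_set(X, rep(c(-1, 1), each = n / 2))
}
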