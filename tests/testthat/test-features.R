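# Feature extraction: layout contracts, directional behavior, determinism.

test_that("feature lengths follow the |scales| x n_dir x 3 x (N+1) contract", {
  cfg_full <- feature_config()   # 5 scales, 60 directions, 2x2 grid
  expect_identical(feature_length(cfg_full), 4500L)
  expect_identical(nrow(feature_layout(cfg_full)), 4500L)
  cfg2 <- feature_config(template_names = c("T1", "T5"), n_directions = 10,
                         scales = c(1, 2), subimage_grid = c(1, 3))
  expect_identical(feature_length(cfg2), 2L * 2L * 10L * 3L * 4L)
  lay <- feature_layout(cfg2)
  # layout order: template, region (global first), scale, direction, (mu, beta, lambda)
  expect_identical(lay$param[1:6], rep(c("mu", "beta", "lambda"), 2))
  expect_identical(lay$template[1], "T1")
  expect_identical(unique(lay$region)[1], "global")
})

test_that("directional features have the right length and stripe anisotropy", {
  img <- stripe_image()
  # stripes are "regular" texture: lambda >> 2 fits are expected and warned
  df <- suppressWarnings(
    directional_features(img, "T1", sigma = 1, n_directions = 12))
  expect_length(df, 36L)
  beta <- df[seq(2, 36, by = 3)]
  # gradient along x: the steered edge response peaks at theta = pi/2 (j = 7)
  expect_lte(abs(which.max(beta) - 7L), 1L)
})

test_that("isotropic particle images give near-flat lambda profiles", {
  img <- small_grain_image()
  df <- directional_features(img, "T1", sigma = 1, n_directions = 12)
  lam <- df[seq(3, 36, by = 3)]
  expect_lt((max(lam) - min(lam)) / mean(lam), 0.15)
})

test_that("multiscale features concatenate per-scale blocks in order", {
  img <- small_grain_image()
  cfg <- feature_config(template_names = "T1", n_directions = 6,
                        scales = c(0.5, 1))
  ms <- multiscale_features(img, "T1", cfg)
  expect_length(ms, 2L * 3L * 6L)
  one <- directional_features(img, "T1", 0.5, 6, cfg)
  expect_identical(ms[1:18], one)
  # permuting the scale list permutes the blocks
  cfg_rev <- feature_config(template_names = "T1", n_directions = 6,
                            scales = c(1, 0.5))
  ms_rev <- multiscale_features(img, "T1", cfg_rev)
  expect_identical(ms_rev[19:36], ms[1:18])
  expect_identical(ms_rev[1:18], ms[19:36])
})

test_that("extended features are deterministic with the documented layout", {
  img <- small_grain_image()
  cfg <- small_feature_config()
  fv <- extended_features(img, cfg, source_id = "fix")
  expect_s3_class(fv, "feature_vector")
  expect_length(fv$values, feature_length(cfg))
  expect_identical(names(fv$values), feature_layout(cfg)$name)
  expect_identical(fv$values, extended_features(img, cfg)$values)
  # distinct seeded images give widely different vectors
  fv2 <- extended_features(small_grain_image(seed = 6), cfg)
  expect_gt(mean(fv$values != fv2$values), 0.5)
})

test_that("intensity rescaling scales mu/beta and leaves lambda fixed", {
  img <- small_grain_image()
  cfg <- small_feature_config()
  f1 <- extended_features(img, cfg)
  f2 <- extended_features(img * 0.5, cfg)
  expect_equal(unname(feat_param(f2, "beta") / feat_param(f1, "beta")),
               rep(0.5, length(feat_param(f1, "beta"))), tolerance = 0.05)
  lam1 <- feat_param(f1, "lambda"); lam2 <- feat_param(f2, "lambda")
  expect_lt(max(abs(lam2 - lam1) / abs(lam1)), 0.05)
})

test_that("warm-started direction sweeps agree with cold-started fits", {
  img <- small_grain_image()
  cfg_w <- feature_config(template_names = "T1", n_directions = 8, scales = 1,
                          subimage_grid = c(1, 1), warm_start = TRUE)
  cfg_c <- feature_config(template_names = "T1", n_directions = 8, scales = 1,
                          subimage_grid = c(1, 1), warm_start = FALSE)
  fw <- extended_features(img, cfg_w)$values
  fc <- extended_features(img, cfg_c)$values
  expect_equal(unname(fw), unname(fc), tolerance = 0.02)
})

test_that("degenerate and undersized inputs raise informative errors", {
  expect_error(directional_features(matrix(0.5, 70, 70), "T1", 1, 4),
               "constant filter response")
  cfg_big <- feature_config(template_names = "T1", n_directions = 2,
                            scales = 8, subimage_grid = c(2, 2))
  expect_error(extended_features(matrix(runif(64^2), 64, 64), cfg_big))
  # a 1x1 grid's local block equals the global block (same pixels)
  img <- small_grain_image(shape = c(96, 96))
  cfg1 <- feature_config(template_names = "T1", n_directions = 4, scales = 1,
                         subimage_grid = c(1, 1))
  fv <- extended_features(img, cfg1)
  n <- length(fv$values)
  expect_equal(unname(fv$values[1:(n / 2)]), unname(fv$values[(n / 2 + 1):n]),
               tolerance = 1e-6)
})

test_that("feature tables round-trip through CSV with header validation", {
  img <- small_grain_image()
  cfg <- feature_config(template_names = "T1", n_directions = 4, scales = 1,
                        subimage_grid = c(1, 1))
  fv <- extended_features(img, cfg, source_id = "img1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fv, path, cfg)
  expect_true(file.exists(paste0(path, ".json")))
  df <- read_features_csv(path)            # config restored from sidecar
  expect_identical(nrow(df), 1L)
  expect_equal(unname(unlist(df[1, -1])), unname(fv$values))
  bad_cfg <- feature_config(template_names = "T2", n_directions = 4, scales = 1)
  expect_error(read_features_csv(path, bad_cfg), "header")
})
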