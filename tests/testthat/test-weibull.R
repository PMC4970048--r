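# Integral-form Weibull distribution: closed forms, sampling, MLE, fit scores.

test_that("normalization constant matches closed forms and scales as 1/beta", {
  expect_equal(wd_normalization_constant(1, 1), 0.5, tolerance = 1e-12)
  expect_equal(wd_normalization_constant(2, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  for (lam in c(0.7, 1.3, 4)) {
    expect_equal(wd_normalization_constant(lam, 2),
                 wd_normalization_constant(lam, 1) / 2, tolerance = 1e-12)
  }
  expect_error(wd_normalization_constant(-1, 1), "positive")
  expect_error(wd_params(0, 1, -2), "beta")
})

test_that("pdf peaks at mu, integrates to one, and is symmetric about mu", {
  p <- wd_params(0.7, 1.4, 2.3)
  expect_equal(wd_pdf(p$mu, p), wd_normalization_constant(p$lam, p$beta))
  v <- stats::integrate(function(x) wd_pdf(x, p), p$mu - 40 * p$beta,
                        p$mu + 40 * p$beta, rel.tol = 1e-9)$value
  expect_equal(v, 1, tolerance = 1e-6)
  t <- c(0.1, 0.5, 2, 7)
  expect_equal(wd_pdf(p$mu + t, p), wd_pdf(p$mu - t, p))
})

test_that("lambda = 2 reduces to the normal density, lambda = 1 to Laplace", {
  x <- seq(-4, 4, length.out = 20)
  expect_equal(wd_pdf(x, wd_params(0.3, 2, 1.2)),
               stats::dnorm(x, 0.3, 1.2), tolerance = 1e-12)
  expect_equal(wd_pdf(x, wd_params(0, 1, 1)),
               0.5 * exp(-abs(x)), tolerance = 1e-12)
})

test_that("sampler moments match the gamma transform and draws are seeded", {
  p <- wd_params(1.5, 1.5, 2)
  n <- 1e5
  x <- wd_sample(p, n, seed = 7)
  # E|X - mu|^lambda = beta^lambda; 3 standard errors of the MC estimate
  m <- mean(abs(x - p$mu)^p$lam)
  se <- stats::sd(abs(x - p$mu)^p$lam) / sqrt(n)
  expect_lt(abs(m - p$beta^p$lam), 3 * se)
  expect_lt(abs(mean(x) - p$mu), 3 * stats::sd(x) / sqrt(n))
  expect_identical(x, wd_sample(p, n, seed = 7))
})

test_that("MLE recovers parameters on self-generated and special-case data", {
  x <- wd_sample(wd_params(0, 1.5, 2), 1e4, seed = 7)
  f <- fit_wd_mle(x)
  expect_true(f$converged)
  expect_lt(abs(f$params$lam - 1.5) / 1.5, 0.05)
  expect_lt(abs(f$params$beta - 2) / 2, 0.05)
  expect_lt(abs(f$params$mu), 0.1)

  set.seed(11)
  g <- fit_wd_mle(stats::rnorm(1e4))
  expect_gt(g$params$lam, 1.85); expect_lt(g$params$lam, 2.15)
  expect_gt(g$params$beta, 0.95); expect_lt(g$params$beta, 1.05)

  set.seed(12)
  l <- fit_wd_mle(stats::rexp(1e4) * sample(c(-1, 1), 1e4, replace = TRUE))
  expect_gt(l$params$lam, 0.9); expect_lt(l$params$lam, 1.1)

  expect_error(fit_wd_mle(rep(3, 100)), "degenerate")
  expect_error(fit_wd_mle(stats::rnorm(10)), "at least")
})

test_that("fits are location-scale equivariant with lambda invariant", {
  x <- wd_sample(wd_params(0, 1.3, 1), 5e3, seed = 21)
  f0 <- fit_wd_mle(x, gof = FALSE)
  f1 <- fit_wd_mle(3 * x + 5, gof = FALSE)
  expect_equal(f1$params$mu, 3 * f0$params$mu + 5, tolerance = 0.05)
  expect_equal(f1$params$beta, 3 * f0$params$beta, tolerance = 0.02)
  expect_equal(f1$params$lam, f0$params$lam, tolerance = 0.02)
})

test_that("estimation error shrinks as the sample grows", {
  err <- sapply(c(1e3, 1e4), function(n) {
    e <- sapply(1:10, function(s) {
      f <- fit_wd_mle(wd_sample(wd_params(0, 1.5, 2), n, seed = 100 + s),
                      gof = FALSE)
      c(abs(f$params$lam - 1.5), abs(f$params$beta - 2))
    })
    apply(e, 1, median)
  })
  expect_lt(err[1, 2], err[1, 1])
  expect_lt(err[2, 2], err[2, 1])
})

test_that("goodness of fit is zero on identical distributions and ranks models", {
  x <- wd_sample(wd_params(0, 1.5, 2), 4e3, seed = 3)
  p <- fit_wd_mle(x)$params
  b <- wd_bin(x, p)
  expect_equal(sum(b$empirical_probs), 1, tolerance = 1e-9)
  self <- wd_goodness_of_fit(list(empirical_probs = b$model_probs,
                                  model_probs = b$model_probs))
  expect_lt(self$chi2, 1e-12)
  expect_lt(abs(self$kld), 1e-12)

  # true parameters beat a wrong shape on both scores (seeded Monte-Carlo)
  wins <- sapply(1:20, function(s) {
    xs <- wd_sample(wd_params(0, 1.5, 2), 2000, seed = 300 + s)
    gt <- wd_goodness_of_fit(wd_bin(xs, wd_params(0, 1.5, 2)))
    gw <- wd_goodness_of_fit(wd_bin(xs, wd_params(0, 3.2, 2)))
    c(gt$chi2 < gw$chi2, gt$kld < gw$kld)
  })
  expect_gte(mean(wins), 0.95)

  # Gibbs inequality on normalized vectors
  h <- c(0.2, 0.3, 0.5); f <- c(0.25, 0.35, 0.4)
  expect_gte(wd_goodness_of_fit(list(empirical_probs = h, model_probs = f))$kld, 0)
})

test_that("KL direction flag and fractal-dimension mapping behave", {
  b <- list(empirical_probs = c(0.5, 0.5, 0), model_probs = c(0.4, 0.4, 0.2))
  g1 <- wd_goodness_of_fit(b)                                # merges empty bin
  expect_true(is.finite(g1$kld))
  g2 <- wd_goodness_of_fit(b, direction = "empirical_to_model")
  expect_true(is.finite(g2$kld))
  expect_false(isTRUE(all.equal(g1$kld, g2$kld)))
  expect_equal(wd_fractal_dimension(1.5), -4.5)
  f <- fit_wd_mle(wd_sample(wd_params(0, 1, 1), 500, seed = 5), gof = FALSE)
  expect_equal(wd_fractal_dimension(f), -3 * f$params$lam)
})

test_that("fit results serialize to JSON and back", {
  f <- fit_wd_mle(wd_sample(wd_params(0.5, 1.2, 1.7), 500, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  wd_fit_to_json(f, path)
  f2 <- wd_fit_from_json(path)
  expect_equal(f2$params, f$params)
  expect_equal(f2$nll, f$nll)
  expect_equal(f2$chi2, f$chi2)
  expect_equal(f2$converged, f$converged)
})
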