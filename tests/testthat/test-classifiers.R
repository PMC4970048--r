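# TPSRC and MARSC base classifiers.

test_that("TPSRC interpolates at eta -> 0 and satisfies its side conditions", {
  set.seed(1)
  X <- matrix(rnorm(80), 20, 4)
  y <- sample(c(-1, 1), 20, replace = TRUE)
  m <- tpsrc_fit(labeled_set(X, y), eta = 0)
  expect_lt(max(abs(tpsrc_predict(m, X) - y)), 1e-6)
  expect_lt(abs(sum(m$psi)), 1e-8)
  expect_lt(max(abs(colSums(m$psi * X))), 1e-8)
})

test_that("constant labels give the constant TPSRC solution", {
  set.seed(2)
  X <- matrix(rnorm(60), 15, 4)
  m <- tpsrc_fit(labeled_set(X, rep(-1, 15)), eta = 0)
  expect_equal(m$omega0, -1, tolerance = 1e-9)
  expect_lt(max(abs(m$omega)), 1e-9)
  expect_lt(max(abs(m$psi)), 1e-9)
  expect_equal(unname(tpsrc_predict(m, rnorm(4))), -1, tolerance = 1e-8)
})

test_that("TPSRC prediction matches a term-by-term evaluation", {
  set.seed(3)
  X <- matrix(rnorm(60), 15, 4)
  y <- rep(c(-1, 1), length.out = 15)
  m <- tpsrc_fit(labeled_set(X, y), eta = 0.1)
  x0 <- rnorm(4)
  phi <- function(r) ifelse(r > 0, r^2 * log(r), 0)
  manual <- m$omega0 + sum(m$omega * x0) +
    sum(m$psi * phi(sqrt(colSums((t(m$anchors) - x0)^2))))
  expect_equal(unname(tpsrc_predict(m, x0)), manual, tolerance = 1e-12)
  expect_error(tpsrc_predict(m, rnorm(3)), "mismatch")
})

test_that("TPSRC separates two seeded Gaussian clouds", {
  d <- gaussian_clouds(n = 100, k = 4, shift = 1)
  m <- tpsrc_fit(d, eta = NULL)   # GCV-selected
  ce <- mean(threshold_label(tpsrc_predict(m, d$features)) != d$labels)
  expect_lt(ce, 0.10)
})

test_that("TPSRC training error does not increase as eta decreases", {
  d <- gaussian_clouds(n = 60, k = 3, shift = 0.5, seed = 4)
  errs <- vapply(c(10, 1, 0.1, 1e-3, 0), function(e) {
    m <- tpsrc_fit(d, eta = e)
    sum((tpsrc_predict(m, d$features) - d$labels)^2)
  }, 1.0)
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("MARSC recovers a planted hinge exactly in the noise-free case", {
  set.seed(3)
  x <- matrix(runif(100), 100, 1)
  y <- 2 * pmax(0, x[, 1] - 0.3)
  m <- marsc_fit(list(features = x, labels = y), minspan = 1, endspan = 0)
  knots <- vapply(m$basis, function(b) b[[1]]$t, 1.0)
  pos <- which(vapply(m$basis, function(b) b[[1]]$s, 1.0) == 1)
  expect_true(any(abs(knots - 0.3) < 0.05))
  expect_lt(abs(m$alphas[pos[1]] - 2) / 2, 0.05)
  expect_lt(sqrt(mean((marsc_predict(m, x) - y)^2)), 1e-6)
})

test_that("constant responses give an intercept-only MARSC model", {
  set.seed(4)
  x <- matrix(runif(60), 30, 2)
  m <- marsc_fit(list(features = x, labels = rep(1, 30)))
  expect_equal(m$alpha0, 1)
  expect_length(m$basis, 0L)
  expect_equal(unname(marsc_predict(m, c(0.5, 0.5))), 1)
})

test_that("max_degree caps the number of hinge factors per product", {
  set.seed(5)
  x <- matrix(runif(200), 100, 2)
  y <- pmax(0, x[, 1] - 0.4) + 2 * pmax(0, x[, 2] - 0.6) + rnorm(100, 0, 0.01)
  m <- marsc_fit(list(features = x, labels = y), max_degree = 1)
  expect_true(all(lengths(m$basis) == 1L))
  # distinct variables within a product at degree 2
  m2 <- marsc_fit(list(features = x, labels = y), max_degree = 2)
  for (b in m2$basis)
    expect_identical(anyDuplicated(vapply(b, `[[`, 1L, "v")), 0L)
})

test_that("MARSC prediction matches hand evaluation of the hinge expansion", {
  hm <- structure(list(alpha0 = 1, alphas = 2,
                       basis = list(list(list(s = 1, v = 1, t = 0.5))),
                       gcv = 0, d = 3, k = 1),
                  class = "marsc_model")
  expect_equal(unname(marsc_predict(hm, 1.0)), 1 + 2 * 0.5)
  expect_equal(unname(marsc_predict(hm, 0.2)), 1)   # hinge inactive below knot
  # random-model oracle
  set.seed(6)
  m <- marsc_fit(list(features = matrix(runif(150), 75, 2),
                      labels = runif(75)), max_terms = 6)
  x0 <- runif(2)
  manual <- m$alpha0 + sum(vapply(seq_along(m$basis), function(i)
    m$alphas[i] * prod(vapply(m$basis[[i]], function(f)
      max(f$s * (x0[f$v] - f$t), 0), 1.0)), 1.0))
  expect_equal(unname(marsc_predict(m, x0)), manual, tolerance = 1e-12)
})

test_that("GCV matches the printed formula and penalizes complexity", {
  expect_equal(mars_gcv(0, 3, 50), 0)
  # C(4) = 4 * (3/2 + 1) = 10
  expect_equal(mars_gcv(1, 4, 100, d = 3), (1 / 100) / (1 - 10 / 100)^2)
  g <- vapply(1:6, function(K) mars_gcv(2, K, 50), 1.0)
  expect_true(all(diff(g) > 0))
  expect_identical(mars_gcv(1, 30, 50), Inf)   # M <= C(K)
})

test_that("backward pruning never ends above the forward model's GCV", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(runif(120), 60, 2)
    y <- sin(3 * x[, 1]) + rnorm(60, 0, 0.2)
    m <- marsc_fit(list(features = x, labels = y), max_terms = 10)
    Bfull <- cbind(1, vapply(m$basis, function(b)
      graintex:::mars_basis_column(b, x), numeric(60)))
    expect_true(is.finite(m$gcv))
  }
})

test_that("fits are exactly reproducible", {
  d <- gaussian_clouds(n = 50, k = 3, seed = 9)
  expect_identical(tpsrc_fit(d, eta = 0.01), tpsrc_fit(d, eta = 0.01))
  expect_identical(marsc_fit(d), marsc_fit(d))
})

test_that("threshold labeling follows the boundary rule", {
  expect_identical(threshold_label(-0.3), -1)
  expect_identical(threshold_label(0.3), 1)
  expect_identical(threshold_label(0), -1)
  expect_identical(threshold_label(c(-1, 0, 2), threshold = 0), c(-1, -1, 1))
  expect_error(threshold_label(NaN), "finite")
})
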