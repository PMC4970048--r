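# Steerable templates: registry, steering coefficients, oriented responses.

test_that("template registry holds the six built-ins with valid terms", {
  for (nm in gdf_template_names()) {
    tpl <- gdf_template(nm)
    expect_s3_class(tpl, "steerable_template")
    expect_gte(length(tpl$terms), 1L)
    for (tm in tpl$terms)
      expect_gte(tm$dx_order + tm$dy_order, 1L)
  }
  expect_equal(gdf_template("T1")$terms[[1]]$weight, -2 / pi)
  expect_equal(gdf_template("T1", radical_constants = TRUE)$terms[[1]]$weight,
               -sqrt(2 / pi))
  expect_equal(gdf_template("T6")$extra_params$phi, pi / 2)
  expect_error(steerable_template("bad", list(list(weight = 1, sigma_exponent = 0,
                                                   dx_order = 0, dy_order = 0))),
               "order")
})

test_that("steering coefficients follow the operator-rotation rules", {
  tpl <- gdf_template("T2")
  # identity rotation returns the template's own sigma-folded weights
  a0 <- steering_coefficients(tpl, 0, sigma = 1.5)
  expect_equal(a0[["0.1"]], -0.966)
  expect_equal(a0[["2.1"]], -0.256 * 1.5^2)
  expect_equal(a0[["1.2"]], 0)
  expect_equal(a0[["3.0"]], 0)

  # single G_y term: alpha_(1,0) = -sin(theta) w, alpha_(0,1) = cos(theta) w
  gy <- steerable_template("gy", list(list(weight = 2, sigma_exponent = 0,
                                           dx_order = 0, dy_order = 1)))
  for (th in c(0.3, 1.2, 2.9)) {
    a <- steering_coefficients(gy, th, 1)
    expect_equal(a[["1.0"]], -sin(th) * 2, tolerance = 1e-14)
    expect_equal(a[["0.1"]], cos(th) * 2, tolerance = 1e-14)
  }

  # point reflection: order-m terms pick up (-1)^m
  for (nm in c("T1", "T4", "T5")) {
    t0 <- steering_coefficients(gdf_template(nm), 0, 1)
    tp <- steering_coefficients(gdf_template(nm), pi, 1)
    for (key in names(t0)) {
      m <- sum(as.integer(strsplit(key, ".", fixed = TRUE)[[1]]))
      expect_equal(tp[[key]], (-1)^m * t0[[key]], tolerance = 1e-12)
    }
  }
})

test_that("steered responses equal rotated-kernel convolutions", {
  img <- random_image(64)
  for (nm in c("T1", "T3", "T5")) {
    tpl <- gdf_template(nm)
    base <- base_responses(img, tpl, sigma = 1)
    for (th in c(0, pi / 8, 1.1, 2.7)) {
      o <- oriented_response(img, tpl, 1, th, base = base)
      ref <- convolve_dense(img, rotated_template_kernel(tpl, 1, th))
      rel <- max(abs(interior_values(o) - interior_values(ref, o$margin))) /
        max(abs(interior_values(ref, o$margin)))
      expect_lt(rel, 1e-6)
    }
  }
})

test_that("base responses cover the steering span and vanish on constants", {
  b <- base_responses(matrix(0.4, 40, 40), "T2", sigma = 1)
  # T2 mixes orders 1 and 3: pairs (0,1),(1,0) and all four order-3 pairs
  expect_setequal(names(b$responses),
                  c("0.1", "1.0", "0.3", "1.2", "2.1", "3.0"))
  for (r in b$responses) expect_lt(max(abs(r)), 1e-9)
})

test_that("oriented response is linear, scale-covariant and pi-periodic", {
  i1 <- random_image(48, seed = 1)
  i2 <- random_image(48, seed = 2)
  tpl <- gdf_template("T4")
  th <- 0.77
  r1 <- oriented_response(i1, tpl, 1, th)$values
  r2 <- oriented_response(i2, tpl, 1, th)$values
  r12 <- oriented_response(2 * i1 - 3 * i2, tpl, 1, th)$values
  expect_equal(r12, 2 * r1 - 3 * r2, tolerance = 1e-12)

  # scaling all template weights by c scales the response by c exactly
  tpl_scaled <- steerable_template("T4x", lapply(tpl$terms, function(tm) {
    tm$weight <- 5 * tm$weight; tm
  }))
  rs <- oriented_response(i1, tpl_scaled, 1, th)$values
  expect_equal(rs, 5 * r1, tolerance = 1e-13)

  # theta + pi flips by the parity sign of each order; T4 is pure order 2
  rpi <- oriented_response(i1, tpl, 1, th + pi)$values
  expect_equal(rpi, r1, tolerance = 1e-10)
  # T1 is order 1: antisymmetric under theta + pi
  r1a <- oriented_response(i1, "T1", 1, th)$values
  r1b <- oriented_response(i1, "T1", 1, th + pi)$values
  expect_equal(r1b, -r1a, tolerance = 1e-10)
})

test_that("a centered isotropic blob responds equally at all orientations", {
  g <- seq(-31.5, 31.5)
  blob <- exp(-outer(g^2, g^2, "+") / (2 * 8^2))
  mags <- vapply(seq(0, pi - 1e-9, length.out = 8), function(th)
    sd(interior_values(oriented_response(blob, "T1", 1.5, th))), 1.0)
  expect_lt(diff(range(mags)) / mean(mags), 0.02)
})

test_that("user templates round-trip through plain lists", {
  tpl <- template_from_list(list(name = "custom",
                                 terms = list(list(weight = 0.5, sigma_exponent = 1,
                                                   dx_order = 1, dy_order = 1)),
                                 extra_params = list(foo = 2)))
  expect_s3_class(tpl, "steerable_template")
  expect_equal(tpl$extra_params$foo, 2)
})
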