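make_data <- function(n = 20, rho = 0.8, seed = 1) {
  generate_model_data(n, rho, seed = seed)
}

test_that("NW estimator: global-mean limit, constancy, near-interpolation", {
  d <- make_data(30, 0.7, seed = 2)
  md <- mean_direction(d$y)
  fit_inf <- nw_fit(d, h = 1e6, x_eval = c(d$x, 0, 10))
  expect_true(all(circ_distance(fit_inf, md) < 1e-6))
  dc <- circ_data(d$x, rep(2.2, length(d$x)))
  for (h in c(0.05, 0.5, 5)) {
    expect_true(all(circ_distance(nw_fit(dc, h), 2.2) < 1e-12))
  }
  # near-interpolation: at h = 0.05 the neighbours at distance >= 1 carry
  # weight exp(-200) and the fit reproduces the local point
  d2 <- circ_data(c(0, 1, 2), c(0.1, 0.2, 0.3))
  expect_equal(circ_distance(nw_fit(d2, h = 0.05, x_eval = 0), 0.1), 0,
               tolerance = 1e-6)
})

test_that("LL estimator equals the explicit weighted-least-squares oracle", {
  set.seed(3)
  d <- make_data(20, 0.8, seed = 3)
  x_eval <- c(d$x, seq(min(d$x), max(d$x), length.out = 7))
  for (h in c(0.2, 0.6)) {
    expect_equal(ll_fit(d, h, x_eval),
                 wls_ll_oracle(d$x, d$y, h, x_eval),
                 tolerance = 1e-10)
  }
  # h -> Inf reproduces the global linear fit on sine/cosine components
  h_big <- 1e5
  yl <- atan2(lm(sin(d$y) ~ d$x)$fitted.values,
              lm(cos(d$y) ~ d$x)$fitted.values) %% (2 * pi)
  expect_true(all(circ_distance(ll_fit(d, h_big), yl) < 1e-5))
  # constant response stays constant
  dc <- circ_data(d$x, rep(0.4, length(d$x)))
  expect_true(all(circ_distance(ll_fit(dc, 0.5), 0.4) < 1e-10))
})

test_that("both estimators are rotation-equivariant and permutation-invariant", {
  d <- make_data(25, 0.6, seed = 4)
  set.seed(4)
  for (method in c("NW", "LL")) {
    fitter <- if (method == "NW") nw_fit else ll_fit
    base <- fitter(d, h = 0.4)
    for (cshift in runif(5, 0, 2 * pi)) {
      rot <- fitter(circ_data(d$x, d$y + cshift), h = 0.4)
      expect_true(all(circ_distance(rot, base + cshift) < 1e-8))
    }
    perm <- sample(length(d$x))
    fp <- fitter(circ_data(d$x[perm], d$y[perm]), h = 0.4, x_eval = d$x)
    expect_true(all(circ_distance(fp, base) < 1e-10))
  }
})

test_that("CV bandwidth selection honors the leave-one-out contract", {
  d <- make_data(25, 0.9, seed = 5)
  # single-element grid returned as-is; scores bounded by the cosine range
  cv1 <- cv_bandwidth(d, "NW", grid = 0.37)
  expect_equal(cv1$h_opt, 0.37)
  cv <- cv_bandwidth(d, "NW")
  n <- length(d$x)
  expect_true(all(cv$cv_scores >= -n & cv$cv_scores <= n))
  # the selected bandwidth beats gross over- and under-smoothing
  sc <- function(h) cv_bandwidth(d, "NW", grid = h)$cv_scores
  expect_lte(min(cv$cv_scores), sc(cv$h_opt * 10))
  expect_lte(min(cv$cv_scores), sc(cv$h_opt / 10))
  # f_{-i}(x_i) does not depend on (x_i, y_i)
  loo <- circout:::loo_fitted(d$x, d$y, 0.4, "NW")
  y2 <- d$y; y2[7] <- as_angles(y2[7] + 2)
  loo2 <- circout:::loo_fitted(d$x, y2, 0.4, "NW")
  expect_equal(loo[7], loo2[7])
  expect_error(cv_bandwidth(d, "NW", grid = numeric(0)), "grid")
})

test_that("circular residuals and mean circular error follow their formulas", {
  set.seed(6)
  y <- as_angles(runif(40, 0, 2 * pi))
  expect_equal(circular_residuals(y, y), rep(0, 40))
  expect_equal(circular_residuals(y, y + pi), rep(pi, 40))
  yh <- as_angles(runif(40, 0, 2 * pi))
  expect_equal(circular_residuals(y, yh), circ_distance(y, yh))
  expect_error(circular_residuals(y, yh[-1]), "length")
  expect_equal(mce(y, y), 0)
  expect_equal(mce(y, y + pi), 2)
  expect_equal(mce(y, yh), sum(1 - cos(y - yh)) / 40)
})

test_that("circ_fit returns coherent in-sample and deleted residuals", {
  d <- make_data(30, 0.9, seed = 8)
  f <- circ_fit(d, "NW")
  expect_s3_class(f, "circ_fit")
  expect_gt(f$h, 0)
  expect_true(all(f$residuals >= 0 & f$residuals <= pi))
  expect_true(all(f$deleted_residuals >= 0 & f$deleted_residuals <= pi))
  # deleted residuals cannot be systematically smaller than in-sample ones
  expect_gte(mean(f$deleted_residuals), mean(f$residuals))
  expect_equal(f$deleted_residuals,
               circ_distance(d$y, circout:::loo_fitted(d$x, d$y, f$h, "NW")))
})
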