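test_that("reference model generator: determinism, moments, concentration limit", {
  d1 <- generate_model_data(50, 0.3, seed = 10)
  d2 <- generate_model_data(50, 0.3, seed = 10)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$y, d2$y)
  big <- generate_model_data(1e5, 0.5, seed = 11)
  expect_equal(mean(big$x), 3, tolerance = 0.01)
  expect_equal(var(big$x), 0.25, tolerance = 0.01)
  # rho -> 1: response collapses onto the mean curve
  dcc <- generate_model_data(500, 0.999, seed = 12)
  close <- circ_distance(dcc$y, attr(dcc, "mean_values")) < 0.05
  expect_gte(mean(close), 0.95)
  expect_error(generate_model_data(2, 0.5), "n")
  expect_error(generate_model_data(10, 1.0), "rho")
})

test_that("single-replicate quantiles: degenerate case, monotonicity, order-statistic oracle", {
  # all residuals equal => all distances zero => all quantiles zero
  e <- rep(0.7, 12)
  md <- median_distances(e)
  expect_equal(md$distances, rep(0, 12))
  expect_equal(md$median, 0.7)
  qs <- single_rep_quantiles(30, 0.5, "NW", q = c(0.5, 0.9, 0.95, 0.99),
                             seed = 13)
  expect_true(all(diff(qs) >= 0))
  expect_true(all(qs >= 0 & qs <= pi))
  # type-7 convention against a direct order-statistic interpolation
  set.seed(14)
  v <- runif(20, 0, pi)
  sv <- sort(v)
  for (q in c(0.90, 0.95, 0.99)) {
    hrank <- (20 - 1) * q + 1
    lo <- floor(hrank)
    oracle <- sv[lo] + (hrank - lo) * (sv[lo + 1] - sv[lo])
    expect_equal(quantile(v, q, type = 7, names = FALSE), oracle)
  }
})

test_that("Monte-Carlo cut-offs: single-rep identity, quantile ordering, SE shrinkage", {
  # reps = 1 equals the single replicate run at the spawned substream seed
  co1 <- generate_cutoffs(20, 0.5, "NW", q = c(0.9, 0.99), reps = 1,
                          seed = 77)
  set.seed(77)
  sub <- sample.int(.Machine$integer.max, 1)
  expect_equal(co1$cutoff,
               single_rep_quantiles(20, 0.5, "NW", q = c(0.9, 0.99),
                                    seed = sub))
  co <- generate_cutoffs(20, 0.5, "NW", reps = 40, seed = 78)
  expect_true(all(diff(co$cutoff) >= 0))  # q99 >= q95 >= q90
  expect_true(all(co$cutoff > 0 & co$cutoff < pi))
  co_big <- generate_cutoffs(20, 0.5, "NW", reps = 160, seed = 78)
  expect_lt(mean(co_big$se), mean(co$se))
})

test_that("packaged cut-off tables load and order correctly", {
  tab <- load_cutoff_table()
  expect_s3_class(tab, "cutoff_table")
  expect_equal(nrow(tab), 432)
  expect_true(all(tab$cutoff > 0 & tab$cutoff < pi))
  # for every (method, n, rho): value nondecreasing in q
  key <- interaction(tab$method, tab$n, tab$rho)
  for (k in unique(key)) {
    sub <- tab[key == k, ]
    expect_true(all(diff(sub$cutoff[order(sub$q)]) >= 0))
  }
  # concentrated residuals give far smaller cut-offs than diffuse ones
  for (m in c("NW", "LL")) for (q in c(0.90, 0.95, 0.99)) {
    hi <- tab$cutoff[tab$method == m & tab$q == q & tab$rho == 0.99]
    lo <- tab$cutoff[tab$method == m & tab$q == q & tab$rho == 0.50]
    expect_true(all(hi < lo))
  }
})

test_that("cut-off lookup: exact cells, knot identity, bilinear midpoints, clamping", {
  tab <- load_cutoff_table()
  expect_equal(lookup_cutoff(tab, 20, 0.10, 0.90, "NW"), 1.4027)
  expect_equal(lookup_cutoff(tab, 200, 0.95, 0.99, "LL"), 1.6882)
  # interpolation reduces to the cell at the knots
  expect_equal(lookup_cutoff(tab, 50, 0.40, 0.95, "NW"), 1.8227)
  # one active axis: midpoint equals the arithmetic mean of the two cells
  expect_equal(lookup_cutoff(tab, 20, 0.15, 0.90, "NW"),
               (1.4027 + 1.4011) / 2)
  expect_equal(lookup_cutoff(tab, 25, 0.10, 0.90, "NW"),
               (1.4027 + 1.4362) / 2)
  # both axes active
  expect_equal(lookup_cutoff(tab, 25, 0.15, 0.90, "NW"),
               mean(c(1.4027, 1.4011, 1.4362, 1.4463)))
  expect_warning(v <- lookup_cutoff(tab, 20, 0.05, 0.90, "NW"), "rho")
  expect_equal(v, 1.4027)
  expect_warning(lookup_cutoff(tab, 500, 0.10, 0.90, "NW"), "clamped")
  expect_error(lookup_cutoff(tab, 10, 0.10, 0.90, "NW"), "extrapolate")
  expect_warning(lookup_cutoff(tab, 10, 0.10, 0.90, "NW",
                               extrapolate = TRUE), "clamped")
  expect_error(lookup_cutoff(tab, 20, 0.10, 0.93, "NW"), "not tabulated")
})
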