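test_that("relative depth normalises by OPD and flags the anoxic side", {
  expect_equal(as.numeric(relative_depth(0, 0.15)), 0)
  expect_equal(as.numeric(relative_depth(0.15, 0.15)), 1)
  expect_equal(as.numeric(relative_depth(0.075, 0.15)), 0.5)
  x <- relative_depth(c(0.1, 0.2), 0.15)
  expect_identical(attr(x, "out_of_oxic_zone"), c(FALSE, TRUE))
  expect_error(relative_depth(0.1, 0), "OPD")
  expect_error(relative_depth(-0.1, 1), ">= 0")
})

test_that("noiseless exponential data are recovered exactly", {
  x <- seq(0, 1, length.out = 20)
  f <- fit_exponential_decay(x, 10 * exp(-x))
  expect_equal(f$a, 10, tolerance = 1e-6)
  expect_equal(f$b, -1, tolerance = 1e-6)
  expect_equal(f$R2, 1, tolerance = 1e-9)
  # zero-noise fit: confidence band collapses
  pr <- predict(f, c(0.2, 0.8))
  expect_lt(max(pr$ci_high - pr$ci_low), 1e-5)
})

test_that("degenerate inputs are handled or refused", {
  x <- seq(0, 1, length.out = 10)
  f <- fit_exponential_decay(x, rep(7, 10))   # constant fractions
  expect_equal(f$a, 7, tolerance = 1e-6)
  expect_equal(f$b, 0, tolerance = 1e-6)
  expect_equal(f$R2, 0)
  expect_error(fit_exponential_decay(rep(0.3, 10), runif(10)),
               "no depth contrast")
  expect_error(fit_exponential_decay(c(0, 0.5), c(1, 2)), "at least 3")
  expect_error(fit_exponential_decay(x, -abs(rnorm(10))), ">= 0")
  expect_error(fit_exponential_decay(x * 2, rep(1, 10)), "\\[0, 1\\]")
})

test_that("a noisy n=40 simulation lands in the observed-fit regime", {
  pp <- make_site_preset("AMOR-like")
  obs <- generate_community_observations(pp, opd = 0.9, n_samples = 40,
                                         seed = 7)
  f <- fit_exponential_decay(obs$x, obs$aoa_fraction_pct)
  expect_gt(f$a, 22.3 / 2)
  expect_lt(f$a, 22.3 * 2)
  expect_lt(abs(f$b - (-2)), 0.7)
  expect_gt(f$R2, 0.3)
  expect_lt(f$R2, 0.9)
})

test_that("predictions evaluate the printed decay constants", {
  x <- seq(0, 1, length.out = 40)
  f <- fit_exponential_decay(x, 22.3 * exp(-2 * x))
  expect_equal(predict(f, 0)$fraction, 22.3, tolerance = 1e-4)
  expect_equal(predict(f, 1)$fraction, 22.3 * exp(-2), tolerance = 1e-4)
  expect_equal(predict(f, 1)$fraction, 3.0177, tolerance = 1e-3)
  expect_error(predict(f, 1.2), "extrapolate")
  # monotone decline for a negative decay constant
  pr <- predict(f, seq(0, 1, 0.05))
  expect_true(all(diff(pr$fraction) < 0))
})

test_that("scaling the fractions scales the intercept and nothing else", {
  set.seed(11)
  x <- runif(30)
  y <- 20 * exp(-1.5 * x) * exp(rnorm(30, 0, 0.3))
  f1 <- fit_exponential_decay(x, y)
  f2 <- fit_exponential_decay(x, 3 * y)
  expect_equal(f2$a, 3 * f1$a, tolerance = 1e-5)
  expect_equal(f2$b, f1$b, tolerance = 1e-5)
  expect_equal(f2$R2, f1$R2, tolerance = 1e-8)
})

test_that("absolute abundance multiplies totals by fraction with CI", {
  ab <- estimate_aoa_absolute(1e8, 22.3)
  expect_equal(ab$abundance, 2.23e7)
  expect_equal(estimate_aoa_absolute(0, 50)$abundance, 0)
  ab2 <- estimate_aoa_absolute(1e6, 10, ci_low = 5, ci_high = 20)
  expect_equal(ab2$ci_low, 5e4)
  expect_equal(ab2$ci_high, 2e5)
  expect_error(estimate_aoa_absolute(1e6, 120), "exceeds 100")
})

test_that("surface abundance of the high-flux preset sits in the expected band", {
  pp <- make_site_preset("SAST-like")
  totals <- pp$community$N0 * 0.01^(-pp$community$m)
  ab <- estimate_aoa_absolute(totals, 22.3)
  expect_gt(ab$abundance, 1.5e7)
  expect_lt(ab$abundance, 1.7e8)
})

test_that("qPCR comparison reports fold differences and excludes zeros", {
  est <- data.frame(depth = c(0.1, 0.2, 0.3), abundance = c(1e5, 2e5, 3e5))
  q <- data.frame(depth = c(0.1, 0.2, 0.3), copies = c(1e5, 5e4, 0))
  expect_warning(cmp <- compare_with_qpcr(est, q), "excluded")
  expect_equal(cmp$per_depth$fold, c(1, 4))
  expect_equal(cmp$max_fold, 4)
  same <- compare_with_qpcr(est, data.frame(depth = est$depth,
                                            copies = est$abundance))
  expect_true(all(same$per_depth$fold == 1))
})

test_that("qPCR scatter of 0.3 log10 units keeps most depths within 10-fold", {
  pp <- make_site_preset("AMOR-like")
  obs <- generate_community_observations(pp, opd = 0.9, n_samples = 200,
                                         seed = 5)
  est <- data.frame(depth = obs$depth,
                    abundance = obs$aoa_fraction_pct / 100 *
                      obs$total_cells_per_cm3)
  q <- data.frame(depth = obs$depth, copies = obs$amoa_copies_per_cm3)
  cmp <- compare_with_qpcr(est, q)
  expect_gte(mean(cmp$per_depth$fold < 10), 0.95)
})
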