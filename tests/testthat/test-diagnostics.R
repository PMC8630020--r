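test_that("oxygen penetration depth interpolates linearly and reports beyond-domain", {
  expect_identical(oxygen_penetration_depth(seq(0, 1, 0.1), rep(0.1, 11)),
                   Inf)
  # 10 uM at the surface falling linearly to 0 at 0.1 m: 1 uM at 0.09 m
  z <- seq(0, 0.1, length.out = 11)
  o2 <- seq(0.01, 0, length.out = 11)
  expect_equal(oxygen_penetration_depth(z, o2), 0.09, tolerance = 1e-12)
})

test_that("the high-flux preset oxic zone ends near 0.15 m, the gyre preset stays oxic", {
  opd <- oxygen_penetration_depth(preset_solution("SAST-like")$solution)
  expect_gt(opd, 0.1)
  expect_lt(opd, 0.2)
  expect_identical(oxygen_penetration_depth(preset_solution("SPG-like")$solution),
                   Inf)
})

test_that("rmse follows the mean-square form and drops unusable records", {
  sol <- preset_solution("AMOR-like")$solution
  depths <- c(0.2, 0.6, 1.2, 2.5)
  model <- vapply(depths, function(d)
    sedpower:::.interp_model(sol, "DIC", d), numeric(1))
  exact <- data.frame(depth = depths, species = "DIC", value = model)
  expect_equal(unname(rmse(sol, exact)["DIC"]), 0)
  # alternating residuals +-1 give RMSE exactly 1
  off <- exact; off$value <- model + c(1, -1, 1, -1)
  expect_equal(unname(rmse(sol, off)["DIC"]), 1)
  # a single residual of 3 gives RMSE 3
  one <- data.frame(depth = 0.5, species = "O2",
                    value = sedpower:::.interp_model(sol, "O2", 0.5) + 3)
  expect_equal(unname(rmse(sol, one)["O2"]), 3)
  # records outside the domain are excluded with a warning
  out <- data.frame(depth = 99, species = "NO3", value = 0.01)
  expect_warning(r <- rmse(sol, out), "no overlap")
  expect_false("NO3" %in% names(r))
})

test_that("nitrate against consumed oxygen recovers the imposed slope", {
  o2 <- seq(0.2, 0.05, length.out = 20)
  dat <- data.frame(O2 = o2, NO3 = 0.094 * (0.2 - o2))
  expect_equal(nitrate_oxygen_slope(dat), 0.094, tolerance = 1e-12)
  flat <- data.frame(O2 = o2, NO3 = rep(0.02, 20))
  expect_equal(nitrate_oxygen_slope(flat), 0, tolerance = 1e-12)
  expect_error(nitrate_oxygen_slope(data.frame(O2 = 1:2, NO3 = 1:2)),
               "at least 3")
})

test_that("a Redfield-coupled solve returns a slope near the stoichiometric value", {
  sol <- preset_solution("NP-like")$solution
  # NO3 gained per O2 consumed: (1/rCN) / (1 + 2/rCN) when denitrification
  # is minor
  rcn <- 106 / 16
  expected <- (1 / rcn) / (1 + 2 / rcn)
  sl <- nitrate_oxygen_slope(sol, c(0, 10))
  expect_equal(sl, expected, tolerance = 0.15)
})

test_that("sensitivity scan at factor 1 reproduces the base solve", {
  pre <- preset_solution("NPG-like")
  sc <- sensitivity_scan(pre$preset$site, pre$preset$kinetics, "k_nit",
                         factors = 1, grid = pre$preset$grid)
  expect_equal(sc$entries[[1]]$no3_divergence, 0, tolerance = 1e-12)
  expect_equal(sc$entries[[1]]$solution$profiles$solutes$O2,
               sc$base$profiles$solutes$O2, tolerance = 1e-9)
})

test_that("nitrate-profile divergence grows as oxygen inhibition weakens", {
  pre <- preset_solution("AMOR-like")
  sc <- sensitivity_scan(pre$preset$site, pre$preset$kinetics, "k_O2_inhib",
                         factors = c(1, 0.1, 0.01), grid = pre$preset$grid)
  div <- vapply(sc$entries, function(e) e$no3_divergence, numeric(1))
  expect_true(all(diff(div) > 0))
  expect_error(sensitivity_scan(pre$preset$site, pre$preset$kinetics,
                                "nope", 1), "unknown parameter")
})
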