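test_that("presets encode the published site metadata", {
  sast <- make_site_preset("SAST-like")
  expect_equal(sast$site$organic_flux, 0.24)
  expect_equal(sast$site$water_depth, 4424)
  expect_equal(sast$site$sedimentation_rate, 1.2e-5)

  spg <- make_site_preset("SPG-like")
  expect_equal(spg$site$organic_flux, 1.4e-4)
  expect_equal(spg$site$domain_length, 67)
  expect_true(spg$site$fully_oxic)

  amor <- make_site_preset("AMOR-like")
  expect_equal(amor$site$water_depth, 2476)
  expect_equal(amor$site$sedimentation_rate, 2.0e-5)

  expect_error(make_site_preset("Atlantis"), "SAST-like")
  # fluxes span more than three orders of magnitude
  fl <- vapply(preset_names(),
               function(n) make_site_preset(n)$site$organic_flux, numeric(1))
  expect_gt(log10(max(fl) / min(fl)), 3)
})

test_that("observation generation is deterministic and honest at zero noise", {
  sol <- preset_solution("NPG-like")$solution
  a <- generate_observations(sol, n_depths = 15, noise_cv = 0.1, seed = 9)
  b <- generate_observations(sol, n_depths = 15, noise_cv = 0.1, seed = 9)
  expect_identical(a, b)
  c2 <- generate_observations(sol, n_depths = 15, noise_cv = 0.1, seed = 10)
  expect_false(identical(a$value, c2$value))

  clean <- generate_observations(sol, n_depths = 12, noise_cv = 0, seed = 3)
  o2 <- clean[clean$species == "O2", ]
  expect_equal(o2$value,
               vapply(o2$depth, function(d)
                 sedpower:::.interp_model(sol, "O2", d), numeric(1)))
  expect_error(generate_observations(sol, n_depths = 3), ">= 4")
})

test_that("nitrogen species below 0.1 uM become left-censored records", {
  sol <- preset_solution("NPG-like")$solution  # NH4 stays in the nM range
  obs <- generate_observations(sol, n_depths = 20, noise_cv = 0.1, seed = 2)
  nh4 <- obs[obs$species == "NH4", ]
  expect_true(all(nh4$censored))
  expect_true(all(nh4$value == 1e-4))
  expect_false(any(obs$censored[obs$species == "O2"]))
})

test_that("community observations reproduce their ground truth at zero noise", {
  pp <- make_site_preset("AMOR-like")
  pp$community$sigma_frac <- 0
  pp$community$sigma_log10 <- 0
  obs <- generate_community_observations(pp, opd = 0.9, n_samples = 30,
                                         seed = 4)
  f <- fit_exponential_decay(obs$x, obs$aoa_fraction_pct)
  expect_equal(f$a, 22.3, tolerance = 1e-5)
  expect_equal(f$b, -2, tolerance = 1e-5)
  cmp <- compare_with_qpcr(
    data.frame(depth = obs$depth,
               abundance = obs$aoa_fraction_pct / 100 *
                 obs$total_cells_per_cm3),
    data.frame(depth = obs$depth, copies = obs$amoa_copies_per_cm3))
  expect_equal(cmp$max_fold, 1, tolerance = 1e-12)
  expect_error(generate_community_observations(pp, opd = 0.9, n_samples = 4),
               ">= 5")
  expect_error(generate_community_observations(pp, opd = Inf), "positive")
})

test_that("total cells decline as a power law of depth", {
  pp <- make_site_preset("NP-like")
  obs <- generate_community_observations(pp, opd = 5, n_samples = 40,
                                         seed = 6)
  keep <- obs$depth > 0.01
  fit <- lm(log10(total_cells_per_cm3) ~ log10(depth),
            data = obs[keep, ])
  expect_equal(unname(coef(fit)[2]), -pp$community$m, tolerance = 1e-6)
})
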