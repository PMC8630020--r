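test_that("with no organic flux and no reactions every solute stays at its top value", {
  site <- site_config("inert", water_depth = 100, organic_flux = 0,
                      sedimentation_rate = 1e-5, domain_length = 1,
                      porosity_surface = 0.8, porosity_deep = 0.8,
                      top_concentrations = c(O2 = 0.2, NO3 = 0.03))
  p <- kinetic_params(k1 = 0, k2 = 0, k_nit = 0, k_mnox = 0, k_amx = 0)
  sol <- solve_steady_state(site, p, build_grid(1, 50))
  expect_equal(sol$profiles$solutes$O2, rep(0.2, 49), tolerance = 1e-9)
  expect_equal(sol$profiles$solutes$NO3, rep(0.03, 49), tolerance = 1e-9)
  for (k in paste0("R", 1:6)) expect_true(all(sol$rates[[k]] == 0))
})

test_that("solved oxygen matches the cosh closed form, converging at second order", {
  prob <- cosh_oracle_problem()
  errs <- vapply(c(201, 2001), function(n) {
    g <- build_grid(prob$L, n, 1)
    sol <- solve_steady_state(prob$site, prob$kinetics, g,
                              control = list(tol = 1e-13))
    exact <- cosh_oracle_exact(prob, g$z_mid)
    max(abs(sol$profiles$solutes$O2 - exact)) / max(exact)
  }, numeric(1))
  expect_lt(errs[1], 0.01)     # < 1% at 200 nodes
  expect_lt(errs[2], 0.001)    # < 0.1% at 2000 nodes
  expect_gte(log10(errs[1] / errs[2]), 1.8)  # convergence order
})

test_that("oxygen is monotone non-increasing when it is only consumed", {
  sol <- preset_solution("AMOR-like")$solution
  o2 <- sol$profiles$solutes$O2
  top <- sol$profiles$top_concentrations[["O2"]]
  expect_true(all(diff(c(top, o2)) <= 1e-9 * top))
})

test_that("steady-state concentrations are non-negative on every preset", {
  for (nm in preset_names()) {
    sol <- preset_solution(nm)$solution
    for (v in c(sol$profiles$solutes, sol$profiles$solids))
      expect_true(all(v >= 0))
  }
})

test_that("element flux budgets close on every preset", {
  for (nm in preset_names()) {
    b <- flux_budget(preset_solution(nm)$solution)
    expect_true(all(b$closure_error < 1e-3),
                info = paste(nm, "max closure",
                             signif(max(b$closure_error), 2)))
  }
})

test_that("weaker oxygen inhibition lets more denitrification into the oxic zone", {
  pre <- preset_solution("AMOR-like")
  pp <- pre$preset
  opd <- oxygen_penetration_depth(pre$solution)
  oxic <- pp$grid$z_mid < opd
  ir2 <- vapply(c(0.5, 1, 2), function(f) {
    p <- pp$kinetics
    p$k_O2_inhib <- p$k_O2_inhib * f
    s <- solve_steady_state(pp$site, p, pp$grid,
                            control = list(init = pre$solution$state))
    sum(s$rates$R2[oxic] * pp$grid$cell_widths[oxic])
  }, numeric(1))
  expect_true(all(diff(ir2) > 0))
})

test_that("depth-integrated nitrification is set by ammonium supply when transport-limited", {
  pp <- make_site_preset("SPG-like")
  site <- pp$site
  site$top_concentrations[["NH4"]] <- 1e-8  # suppress the interface source
  ir4 <- vapply(c(0.1, 1, 10), function(f) {
    p <- pp$kinetics; p$k_nit <- p$k_nit * f
    s <- solve_steady_state(site, p, pp$grid)
    sum(s$rates$R4 * pp$grid$cell_widths)
  }, numeric(1))
  expect_lt((max(ir4) - min(ir4)) / ir4[2], 0.10)
})

test_that("non-convergence raises a diagnostic error", {
  prob <- cosh_oracle_problem()
  expect_error(
    solve_steady_state(prob$site, prob$kinetics, build_grid(prob$L, 50),
                       control = list(maxit = 1)),
    "did not converge")
})
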