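test_that("ammonia follows the pH/pKa power-of-ten scaling", {
  expect_equal(nh3_from_nh4(1, 9.3), 1)
  expect_equal(nh3_from_nh4(0, 7), 0)
  expect_equal(nh3_from_nh4(1, 7.79), 0.030902954, tolerance = 1e-7)
  expect_error(nh3_from_nh4(-1, 7), ">= 0")
})

test_that("extended Debye-Hueckel coefficients behave at the limits", {
  expect_equal(activity_coefficient(0, 0.7, 277, 3), 1)
  expect_equal(activity_coefficient(1, 0, 277, 3), 1)
  expect_equal(activity_coefficient(-2, 0, 300, 4), 1)
  # regression-locked hand evaluation: z=1, I=0.7 mol/kg, T=277 K, 3 Angstrom
  expect_equal(activity_coefficient(1, 0.7, 277, 3), 0.5919158,
               tolerance = 1e-6)
  # gamma -> 1 as I -> 0, monotonically
  g <- activity_coefficient(1, c(0.5, 0.1, 0.01, 1e-4), 277, 3)
  expect_true(all(diff(g) > 0))
  expect_lt(abs(g[4] - 1), 0.02)
  expect_error(activity_coefficient(1, -0.1, 277, 3), ">= 0")
})

test_that("standard Gibbs energy of nitrification matches the formation sums", {
  tab <- thermo_table()
  rx <- nitrification_reaction()
  # 25 C, 1 bar reference: plain sum of formation energies, ~ -355 kJ/mol
  expect_equal(standard_gibbs(rx, tab, 298.15, 1), -354.86, tolerance = 1e-6)
  # dV = 0 makes the result pressure-independent
  expect_equal(standard_gibbs(rx, tab, 277, 500),
               standard_gibbs(rx, tab, 277, 1))
  # a nonzero reaction volume shifts it by dV (P - 1) (1 cm3 bar = 1e-4 kJ)
  expect_equal(standard_gibbs(rx, tab, 277, 401, dV_cm3 = -30) -
                 standard_gibbs(rx, tab, 277, 1, dV_cm3 = -30),
               -30 * 400 * 1e-4)
  expect_error(standard_gibbs(c(XYZ = 1), tab), "missing species")
})

test_that("the Gibbs energy profile is internally consistent and oxic-masked", {
  sol <- preset_solution("AMOR-like")$solution
  th <- gibbs_energy_profile(sol)
  opd <- oxygen_penetration_depth(sol)
  expect_true(all(th$depth < opd))
  expect_gt(length(attr(th, "excluded_depths")), 0)
  # dG = dG0 + RT ln Q at every depth
  expect_equal(th$dG_kJ_mol,
               th$dG0_kJ_mol + 8.314e-3 * th$T_K * log(th$Q),
               tolerance = 1e-12)
  expect_true(all(th$Q > 0))
  expect_true(all(th$dG_per_e_kJ < 0))  # nitrification stays favourable
  expect_true(all(th$gamma_NO3 > 0 & th$gamma_NO3 <= 1.2))
})

test_that("per-electron energy responds to activities with RT nu / n_e slopes", {
  pre <- preset_solution("AMOR-like")
  sol <- pre$solution
  th0 <- gibbs_energy_profile(sol)
  RT <- 8.314e-3 * th0$T_K[1]
  nu <- c(NH4 = -1, O2 = -2, NO3 = 1)
  for (sp in names(nu)) {
    sol2 <- sol
    sol2$profiles$solutes[[sp]] <- sol$profiles$solutes[[sp]] * 10
    th2 <- gibbs_energy_profile(sol2, site = sol$site)
    common <- intersect(th0$depth, th2$depth)
    d0 <- th0$dG_per_e_kJ[match(common, th0$depth)]
    d2 <- th2$dG_per_e_kJ[match(common, th2$depth)]
    expected <- RT * log(10) * nu[[sp]] / 8
    expect_lt(max(abs((d2 - d0) - expected)), 1e-6)
  }
})

test_that("power supply converts rate and energy with the exact unit factor", {
  z <- c(0.1, 0.2)
  fake <- fake_rate_solution(z, R4 = c(1e-3, 0))
  th <- data.frame(depth = z, dG_per_e_kJ = c(-50, -50), n_e = 8)
  ps <- power_supply_profile(th, fake)
  expect_equal(ps$Ps_W_m3[1], 1.2683917e-05, tolerance = 1e-7)
  expect_identical(ps$Ps_W_m3[2], 0)          # no rate, no power
  # linear in the rate
  fake2 <- fake_rate_solution(z, R4 = c(2e-3, 0))
  expect_equal(power_supply_profile(th, fake2)$Ps_W_m3[1],
               2 * ps$Ps_W_m3[1])
  # independent of the per-electron normalisation
  th4 <- data.frame(depth = z, dG_per_e_kJ = c(-100, -100), n_e = 4)
  expect_equal(power_supply_profile(th4, fake)$Ps_W_m3[1], ps$Ps_W_m3[1])
  expect_error(power_supply_profile(data.frame(depth = 9, dG_per_e_kJ = -50,
                                               n_e = 8), fake),
               "do not align")
})
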