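# Shared fixtures. Everything is built in code; the heavier preset solves are
# cached per test session so multiple test files can reuse them.

# site/kinetics reducing the oxygen equation to first-order consumption with
# constant porosity and no burial: O2(z) = CB cosh(a(L-z))/cosh(aL),
# a = sqrt(k/Ds)
cosh_oracle_problem <- function(L = 0.1, CB = 0.01, k_lin = 20, phi = 0.8) {
  list(
    site = site_config("cosh-oracle", water_depth = 0, organic_flux = 0,
                       sedimentation_rate = 0, domain_length = L,
                       porosity_surface = phi, porosity_deep = phi,
                       top_concentrations = c(O2 = CB, NO3 = 0, NH4 = 0,
                                              Mn = 0, DIC = 0)),
    kinetics = kinetic_params(k1 = 0, k2 = 0, k_nit = 0, k_mnox = 0,
                              k_amx = 0, k_O2_linear = k_lin),
    CB = CB, L = L, k_lin = k_lin, phi = phi)
}

cosh_oracle_exact <- function(prob, z) {
  Ds <- effective_transport(
    solute_diffusivity("O2", prob$site$temperature), prob$phi)
  alpha <- sqrt(prob$k_lin / Ds)
  prob$CB * cosh(alpha * (prob$L - z)) / cosh(alpha * prob$L)
}

.solution_cache <- new.env(parent = emptyenv())

preset_solution <- function(name) {
  if (is.null(.solution_cache[[name]])) {
    pp <- make_site_preset(name)
    .solution_cache[[name]] <- list(
      preset = pp,
      solution = solve_steady_state(pp$site, pp$kinetics, pp$grid))
  }
  .solution_cache[[name]]
}

# minimal stand-in solution carrying just a grid and an R4 profile, for
# testing the power-supply arithmetic in isolation
fake_rate_solution <- function(z, R4) {
  structure(list(profiles = list(grid = list(z_mid = z)),
                 rates = list(R4 = R4)),
            class = "rtm_solution")
}
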