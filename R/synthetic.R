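# Synthetic sites with known ground truth.
#
# Presets emulate the five contrasting depositional regimes of the study
# sites: organic fluxes spanning 1.4e-4 to 0.24 mol C m-2 yr-1 and oxygen
# penetration from ~0.15 m to beyond a 67 m domain. Water depths and
# sedimentation rates follow the published site table; kinetic constants,
# G-pool partitioning and bottom-water chemistry are design choices fixed
# once so that each preset reproduces its site's qualitative behaviour
# (see the methods vignette).

.presets <- list(
  "SAST-like" = list(
    site = list(name = "SAST-like", water_depth = 4424, temperature = 1.5,
                sedimentation_rate = 1.2e-5, domain_length = 0.4,
                organic_flux = 0.24,
                top_concentrations = c(O2 = 0.16, NO3 = 0.037),
                G_fractions = c(0.10, 0.35, 0.55), mno2_flux = 1e-3,
                fully_oxic = FALSE),
    kinetics = list(k1 = 6e-4, k2 = 2e-5),
    grid = list(n_nodes = 200, refinement = 1.04),
    community = list(a = 22.3, b = -2, sigma_frac = 0.5,
                     N0 = 4e7, m = 0.6, sigma_log10 = 0.3)),
  "AMOR-like" = list(
    site = list(name = "AMOR-like", water_depth = 2476, temperature = 0.5,
                sedimentation_rate = 2.0e-5, domain_length = 4,
                organic_flux = 0.03,
                top_concentrations = c(O2 = 0.30, NO3 = 0.015),
                G_fractions = c(0.30, 0.30, 0.40), mno2_flux = 2e-3,
                fully_oxic = FALSE),
    kinetics = list(k1 = 2e-4, k2 = 1e-5, k_nit = 300),
    grid = list(n_nodes = 200, refinement = 1.04),
    community = list(a = 22.3, b = -2, sigma_frac = 0.5,
                     N0 = 6e6, m = 0.6, sigma_log10 = 0.3)),
  "GC09-like" = list(
    site = list(name = "GC09-like", water_depth = 1653, temperature = 0.5,
                sedimentation_rate = 5.0e-5, domain_length = 3,
                organic_flux = 0.05,
                top_concentrations = c(O2 = 0.28, NO3 = 0.012),
                G_fractions = c(0.30, 0.35, 0.35), mno2_flux = 3e-3,
                fully_oxic = FALSE),
    kinetics = list(k1 = 3e-4, k2 = 1.5e-5, k_nit = 300),
    grid = list(n_nodes = 200, refinement = 1.04),
    community = list(a = 22.3, b = -2, sigma_frac = 0.5,
                     N0 = 1e7, m = 0.6, sigma_log10 = 0.3)),
  "NP-like" = list(
    site = list(name = "NP-like", water_depth = 4476, temperature = 2.5,
                sedimentation_rate = 9.4e-6, domain_length = 10,
                organic_flux = 1e-3,
                top_concentrations = c(O2 = 0.25, NO3 = 0.021),
                G_fractions = c(0.20, 0.30, 0.50), mno2_flux = 0,
                fully_oxic = TRUE),
    kinetics = list(k1 = 1e-4, k2 = 2e-6, k_nit = 50),
    grid = list(n_nodes = 200, refinement = 1.03),
    community = list(a = 22.3, b = -2, sigma_frac = 0.5,
                     N0 = 2e6, m = 0.7, sigma_log10 = 0.3)),
  "NPG-like" = list(
    site = list(name = "NPG-like", water_depth = 6000, temperature = 1.5,
                sedimentation_rate = 1.0e-6, domain_length = 8,
                organic_flux = 4e-4,
                top_concentrations = c(O2 = 0.15, NO3 = 0.036),
                G_fractions = c(0.20, 0.30, 0.50), mno2_flux = 0,
                fully_oxic = TRUE),
    kinetics = list(k1 = 2e-5, k2 = 2e-7, k_nit = 50),
    grid = list(n_nodes = 200, refinement = 1.04),
    community = list(a = 22.3, b = -2, sigma_frac = 0.5,
                     N0 = 5e5, m = 0.8, sigma_log10 = 0.3)),
  "SPG-like" = list(
    site = list(name = "SPG-like", water_depth = 5075, temperature = 1.0,
                sedimentation_rate = 1.5e-6, domain_length = 67,
                organic_flux = 1.4e-4,
                top_concentrations = c(O2 = 0.21, NO3 = 0.033),
                G_fractions = c(0.25, 0.35, 0.40), mno2_flux = 0,
                fully_oxic = TRUE),
    kinetics = list(k1 = 1e-6, k2 = 3e-8, k_nit = 50),
    grid = list(n_nodes = 200, refinement = 1.04),
    community = list(a = 22.3, b = -2, sigma_frac = 0.5,
                     N0 = 2e4, m = 0.75, sigma_log10 = 0.3))
)

#' Synthetic site presets
#'
#' Returns the fully specified configuration of one of the five synthetic
#' site archetypes, spanning ~3-4 orders of magnitude in organic flux and
#' oxygen penetration depth.
#'
#' @param name One of \code{"SAST-like"}, \code{"AMOR-like"},
#'   \code{"NP-like"}, \code{"NPG-like"}, \code{"SPG-like"}.
#' @return List of class \code{site_preset}: \code{site}
#'   (\code{\link{site_config}}), \code{kinetics}
#'   (\code{\link{kinetic_params}}), \code{grid} (\code{\link{build_grid}}),
#'   \code{community} (ground-truth community parameters: surface fraction
#'   \code{a} percent, decay \code{b}, fraction noise \code{sigma_frac} on the
#'   log scale, total cells \code{N0} at the 0.01 m reference times
#'   depth^-m, qPCR scatter \code{sigma_log10}).
#' @export
make_site_preset <- function(name) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.presets), collapse = ", "))
  pp <- .presets[[name]]
  site <- do.call(site_config, pp$site)
  kin <- do.call(kinetic_params, pp$kinetics)
  grid <- build_grid(site$domain_length, pp$grid$n_nodes, pp$grid$refinement)
  structure(list(name = name, site = site, kinetics = kin, grid = grid,
                 community = pp$community),
            class = "site_preset")
}

#' Names of the available presets
#' @return Character vector.
#' @export
preset_names <- function() names(.presets)

# run expr with a fixed RNG state, restoring the caller's state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate noisy geochemical observations from a solved profile
#'
#' Subsamples a solved profile at stratified random depths and applies
#' multiplicative lognormal noise (mean-one, coefficient of variation
#' \code{noise_cv}). Depth strata are uniform in log10 depth between L/1000
#' and L, mimicking the dense near-surface and sparse deep sampling of real
#' coring campaigns. Nitrogen species below the 0.1 uM detection limit are
#' returned as left-censored records at the limit.
#'
#' @param solution An \code{rtm_solution} or \code{rtm_fit}.
#' @param n_depths Number of sampling depths (>= 4).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed RNG seed (reproducible: same seed, same output).
#' @param species Species to report.
#' @param detection_limit Censoring threshold for NO3/NH4 (mol m-3).
#' @return Measured-data frame: depth, species, value, sd, censored.
#' @export
generate_observations <- function(solution, n_depths = 30, noise_cv = 0.1,
                                  seed = 1,
                                  species = c("O2", "NO3", "NH4", "DIC",
                                              "TOC"),
                                  detection_limit = 1e-4) {
  if (inherits(solution, "rtm_fit")) solution <- solution$solution
  if (n_depths < 4) stop("n_depths must be >= 4")
  L <- max(solution$profiles$grid$node_depths)
  .with_seed(seed, {
    edges <- 10^seq(log10(L / 1000), log10(L), length.out = n_depths + 1)
    depths <- stats::runif(n_depths, edges[-(n_depths + 1)], edges[-1])
    sdlog <- sqrt(log(1 + noise_cv^2))
    out <- do.call(rbind, lapply(species, function(sp) {
      v <- .interp_model(solution, sp, depths)
      noise <- if (noise_cv > 0)
        exp(stats::rnorm(n_depths, -sdlog^2 / 2, sdlog)) else 1
      data.frame(depth = depths, species = sp, value = v * noise,
                 sd = noise_cv * v)
    }))
    out$censored <- out$species %in% c("NO3", "NH4") &
      out$value < detection_limit
    out$value[out$censored] <- detection_limit
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic community observations
#'
#' Emulates amplicon/counting data over the oxic zone: AOA fractions decay
#' exponentially with relative depth with lognormal scatter, total cells
#' decline with depth as a power law, and amoA qPCR copies scatter around
#' fraction x totals on the log10 scale.
#'
#' @param preset A \code{site_preset} (supplies the ground truth).
#' @param opd Oxygen penetration depth (m) delimiting the sampled zone.
#' @param n_samples Number of sampled horizons (>= 5).
#' @param seed RNG seed.
#' @return Data frame: core, depth, opd, x (relative depth),
#'   aoa_fraction_pct, total_cells_per_cm3, amoa_copies_per_cm3.
#' @export
generate_community_observations <- function(preset, opd, n_samples = 40,
                                            seed = 1) {
  if (n_samples < 5) stop("n_samples must be >= 5")
  if (!is.finite(opd) || opd <= 0) stop("opd must be a positive length")
  cm <- preset$community
  .with_seed(seed, {
    edges <- seq(0, 1, length.out = n_samples + 1)
    x <- stats::runif(n_samples, edges[-(n_samples + 1)], edges[-1])
    z <- x * opd
    frac <- cm$a * exp(cm$b * x)
    if (cm$sigma_frac > 0)
      frac <- frac * exp(stats::rnorm(n_samples, 0, cm$sigma_frac))
    frac <- pmin(pmax(frac, 0), 100)
    totals <- cm$N0 * pmax(z, 0.01)^(-cm$m)
    copies <- frac / 100 * totals
    if (cm$sigma_log10 > 0)
      copies <- copies * 10^stats::rnorm(n_samples, 0, cm$sigma_log10)
    data.frame(core = preset$name, depth = z, opd = opd, x = x,
               aoa_fraction_pct = frac,
               total_cells_per_cm3 = totals,
               amoa_copies_per_cm3 = copies)
  })
}
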