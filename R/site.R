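#' Site configuration for a sediment core
#'
#' Bundles the geometry, physics, boundary conditions and metadata of a single
#' sediment core. Depths are measured positive downward from the
#' sediment-water interface (z = 0). Porosity follows an exponential
#' compaction profile \eqn{\phi(z) = \phi_\infty + (\phi_0-\phi_\infty)
#' e^{-\beta z}}.
#'
#' @param name Site label.
#' @param water_depth Water depth (m); used for the hydrostatic pressure
#'   default \code{1 + water_depth/10} bar.
#' @param organic_flux Organic carbon flux at the sediment-water interface
#'   (mol C m-2 yr-1).
#' @param sedimentation_rate Burial velocity w (m yr-1); may be zero.
#' @param domain_length Modelled sediment column length L (m).
#' @param temperature In-situ temperature (degrees C).
#' @param pressure Pressure (bar); default hydrostatic.
#' @param pH Porewater pH; default 7.79, the average of the measured values
#'   at the ridge sites, used wherever a core lacks its own pH record.
#' @param porosity_surface,porosity_deep,porosity_attenuation Porosity at the
#'   interface, at depth, and its attenuation scale (m-1).
#' @param dry_density Dry solid density (g cm-3).
#' @param top_concentrations Named vector of fixed interface concentrations
#'   (mol m-3 porewater) for \code{O2}, \code{NO3}, \code{NH4}, \code{Mn},
#'   \code{DIC}. Missing entries take defaults (NH4 defaults to 1e-5 mol m-3,
#'   i.e. 0.01 uM).
#' @param G_fractions Length-3 vector partitioning the organic flux into the
#'   labile, less-labile and inert pools; must sum to 1.
#' @param CN_ratio Molar C:N ratio of degrading organic matter (default
#'   Redfield, 106/16).
#' @param mno2_flux Depositional MnO2 flux (mol Mn m-2 yr-1).
#' @param fully_oxic Logical; when TRUE the Mn-reduction, Mn-oxidation and
#'   anammox reactions are switched off (appropriate where the whole modelled
#'   column stays oxic).
#'
#' @return An object of class \code{sed_site}.
#' @export
site_config <- function(name,
                        water_depth,
                        organic_flux,
                        sedimentation_rate,
                        domain_length,
                        temperature = 2,
                        pressure = NULL,
                        pH = 7.79,
                        porosity_surface = 0.85,
                        porosity_deep = 0.75,
                        porosity_attenuation = 1,
                        dry_density = 2.65,
                        top_concentrations = c(),
                        G_fractions = c(0.5, 0.3, 0.2),
                        CN_ratio = 106 / 16,
                        mno2_flux = 0,
                        fully_oxic = FALSE) {
  top_default <- c(O2 = 0.2, NO3 = 0.02, NH4 = 1e-5, Mn = 0, DIC = 2.3)
  top <- top_default
  if (length(top_concentrations)) {
    bad <- setdiff(names(top_concentrations), names(top_default))
    if (length(bad)) stop("unknown top_concentrations species: ",
                          paste(bad, collapse = ", "))
    top[names(top_concentrations)] <- top_concentrations
  }
  if (is.null(pressure)) pressure <- 1 + water_depth / 10

  if (!is.numeric(domain_length) || domain_length <= 0)
    stop("domain_length must be > 0")
  if (!(porosity_deep > 0 && porosity_deep <= porosity_surface &&
        porosity_surface < 1))
    stop("need 0 < porosity_deep <= porosity_surface < 1")
  if (length(G_fractions) != 3 || abs(sum(G_fractions) - 1) > 1e-12)
    stop("G_fractions must have length 3 and sum to 1")
  if (any(top < 0)) stop("top concentrations must be >= 0")
  if (CN_ratio <= 0) stop("CN_ratio must be > 0")
  if (sedimentation_rate < 0) stop("sedimentation_rate must be >= 0")
  if (organic_flux < 0) stop("organic_flux must be >= 0")

  structure(list(
    name = name,
    water_depth = water_depth,
    temperature = temperature,
    pressure = pressure,
    pH = pH,
    sedimentation_rate = sedimentation_rate,
    domain_length = domain_length,
    porosity_surface = porosity_surface,
    porosity_deep = porosity_deep,
    porosity_attenuation = porosity_attenuation,
    dry_density = dry_density,
    top_concentrations = top,
    organic_flux = organic_flux,
    G_fractions = G_fractions,
    CN_ratio = CN_ratio,
    mno2_flux = mno2_flux,
    fully_oxic = fully_oxic
  ), class = "sed_site")
}

#' @export
print.sed_site <- function(x, ...) {
  cat("<sed_site>", x$name, "\n")
  cat(sprintf("  water depth %.0f m, T %.1f C, P %.0f bar, pH %.2f\n",
              x$water_depth, x$temperature, x$pressure, x$pH))
  cat(sprintf("  L = %g m, w = %.3g m/yr, F_org = %.3g mol C m-2 yr-1%s\n",
              x$domain_length, x$sedimentation_rate, x$organic_flux,
              if (x$fully_oxic) " [fully oxic]" else ""))
  cat("  top concentrations (mol m-3):",
      paste(sprintf("%s=%.3g", names(x$top_concentrations),
                    x$top_concentrations), collapse = " "), "\n")
  invisible(x)
}

#' Porosity profile of a site
#'
#' @param site A \code{sed_site}.
#' @param z Depths (m).
#' @return Porosity at \code{z}.
#' @export
porosity_profile <- function(site, z) {
  site$porosity_deep + (site$porosity_surface - site$porosity_deep) *
    exp(-site$porosity_attenuation * z)
}

#' Kinetic and transport parameters
#'
#' Rate constants for the multi-G degradation network and its secondary redox
#' reactions, plus molecular diffusivities. The organic matter is split into
#' three pools: G1 (labile, first-order reactivity \code{k1}), G2 (less
#' labile, \code{k2}) and G3 (inert). Degradation is distributed over the
#' terminal electron acceptors by Monod limitation and hyperbolic inhibition
#' terms; the secondary reactions (nitrification, Mn(II) oxidation, anammox)
#' are bimolecular.
#'
#' @param k1,k2 First-order reactivities of G1 and G2 (yr-1); \code{k1 >= k2}.
#' @param K_O2 Monod half-saturation of aerobic degradation (mol m-3).
#' @param K_NO3 Monod half-saturation of denitrification (mol m-3).
#' @param k_O2_inhib Oxygen inhibition constant on denitrification (mol m-3).
#'   Values of 4-30 uM (4e-3 to 3e-2 mol m-3) permit denitrification within
#'   the oxic zone.
#' @param k_NO3_inhib Nitrate inhibition constant on MnO2 reduction (mol m-3).
#' @param K_MnO2 Monod half-saturation of MnO2 reduction (mol m-3 bulk).
#' @param k_nit,k_mnox,k_amx Bimolecular rate constants (m3 mol-1 yr-1) of
#'   nitrification, aerobic Mn(II) oxidation and anammox.
#' @param D0 Optional named vector of free-solution diffusivities
#'   (m2 yr-1) for \code{O2,NO3,NH4,Mn,DIC}; when NULL, temperature-dependent
#'   defaults from \code{\link{solute_diffusivity}} are used.
#' @param Db Biodiffusion coefficient (m2 yr-1), default 0.
#' @param k_O2_linear Optional first-order O2 consumption rate (yr-1,
#'   porewater basis); a verification hook that reduces the oxygen equation
#'   to a closed-form solvable problem. Default 0.
#'
#' @return An object of class \code{sed_kinetics}.
#' @export
kinetic_params <- function(k1 = 1e-4,
                           k2 = 1e-5,
                           K_O2 = 8e-3,
                           K_NO3 = 5e-3,
                           k_O2_inhib = 1e-2,
                           k_NO3_inhib = 5e-3,
                           K_MnO2 = 10,
                           k_nit = 1e3,
                           k_mnox = 1e3,
                           k_amx = 1e2,
                           D0 = NULL,
                           Db = 0,
                           k_O2_linear = 0) {
  p <- list(k1 = k1, k2 = k2, K_O2 = K_O2, K_NO3 = K_NO3,
            k_O2_inhib = k_O2_inhib, k_NO3_inhib = k_NO3_inhib,
            K_MnO2 = K_MnO2, k_nit = k_nit, k_mnox = k_mnox, k_amx = k_amx,
            D0 = D0, Db = Db, k_O2_linear = k_O2_linear)
  num <- unlist(p[setdiff(names(p), "D0")])
  if (any(num < 0)) stop("kinetic parameters must be >= 0")
  if (k1 < k2) stop("k1 must be >= k2 (G1 is the more labile pool)")
  structure(p, class = "sed_kinetics")
}

#' @export
print.sed_kinetics <- function(x, ...) {
  cat("<sed_kinetics>\n")
  cat(sprintf("  k1 = %.3g, k2 = %.3g yr-1;  K_O2 = %.3g, K_NO3 = %.3g mol m-3\n",
              x$k1, x$k2, x$K_O2, x$K_NO3))
  cat(sprintf("  k_O2_inhib = %.3g mol m-3;  k_nit = %.3g, k_mnox = %.3g, k_amx = %.3g m3 mol-1 yr-1\n",
              x$k_O2_inhib, x$k_nit, x$k_mnox, x$k_amx))
  invisible(x)
}

# order in which species blocks are laid out in the solver state vector
.solutes <- c("O2", "NO3", "NH4", "Mn", "DIC")
.solids  <- c("G1", "G2", "G3", "MnO2")
.species <- c(.solutes, .solids)
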