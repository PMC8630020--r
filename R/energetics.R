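# Thermodynamics of nitrification along model profiles.
#
# The catabolic reaction is written with ammonia (the actual substrate of the
# ammonia monooxygenase) as
#     NH3 + 2 O2(aq) -> NO3- + H+ + H2O         (8 electrons transferred)
# and evaluated as dGr = dGr0(T,P) + RT ln Qr, Qr the activity quotient.
# dGr0 is corrected from the 25 C reference with the van 't Hoff relation
# (constant reaction enthalpy) plus a constant-volume pressure term, a
# deliberately simple desk-scale alternative to a full equation of state.

.R_GAS <- 8.314e-3      # kJ mol-1 K-1
.SEC_PER_YEAR <- 3.1536e7
.T_REF <- 298.15

#' Load a thermodynamic data table
#'
#' Reads a CSV of standard-state formation properties (25 C, 1 bar):
#' columns \code{species, dGf_kJ_mol, dHf_kJ_mol, charge, ion_size_A}.
#' The packaged default covers the nitrification reaction species.
#'
#' @param path Optional path to a user table; default is the packaged table.
#' @return Data frame with species as row names.
#' @export
thermo_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "thermo_nitrification.csv",
                        package = "sedpower")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "dGf_kJ_mol", "dHf_kJ_mol", "charge", "ion_size_A")
  if (!all(need %in% names(tab)))
    stop("thermo table must have columns: ", paste(need, collapse = ", "))
  rownames(tab) <- tab$species
  tab
}

#' Nitrification reaction stoichiometry
#'
#' Named stoichiometric coefficients (products positive) of
#' NH3 + 2 O2 -> NO3- + H+ + H2O.
#' @return Named numeric vector.
#' @export
nitrification_reaction <- function() {
  c(NH3 = -1, O2 = -2, NO3 = 1, H = 1, H2O = 1)
}

#' Ammonia from ammonium via the acid-base equilibrium
#'
#' \eqn{[NH_3] = [NH_4^+] \times 10^{pH - pKa}} with pKa 9.3.
#'
#' @param nh4 Ammonium concentration (any unit; >= 0).
#' @param pH Porewater pH.
#' @param pKa Acid dissociation constant exponent (default 9.3).
#' @return Ammonia concentration in the same unit.
#' @export
nh3_from_nh4 <- function(nh4, pH, pKa = 9.3) {
  if (any(nh4 < 0)) stop("nh4 must be >= 0")
  nh4 * 10^(pH - pKa)
}

#' Extended Debye-Hueckel activity coefficient
#'
#' \eqn{\log_{10}\gamma = -A z^2 \sqrt I / (1 + B \aa \sqrt I)} with
#' temperature-dependent Debye-Hueckel parameters A and B (linear fits to the
#' standard 0-50 C tabulation). Neutral species have \eqn{\gamma = 1}.
#'
#' @param charge Ionic charge z.
#' @param I Ionic strength (mol kg-1), >= 0.
#' @param T_K Temperature (K).
#' @param ion_size Ion-size parameter (Angstrom).
#' @return Activity coefficient.
#' @export
activity_coefficient <- function(charge, I, T_K, ion_size) {
  if (any(I < 0)) stop("ionic strength must be >= 0")
  if (charge == 0) return(rep(1, length(I)))
  tC <- T_K - 273.15
  A <- 0.4918 + 6.96e-4 * tC
  B <- 0.3248 + 1.4e-4 * tC
  10^(-A * charge^2 * sqrt(I) / (1 + B * ion_size * sqrt(I)))
}

#' Standard Gibbs energy of a reaction at temperature and pressure
#'
#' \eqn{\Delta G_r^0(T) = \Delta H_r^0 - T \Delta S_r^0} (van 't Hoff,
#' constant enthalpy, with \eqn{\Delta S_r^0} from the 25 C values) plus a
#' constant-volume pressure correction \eqn{\Delta V (P - 1)}.
#'
#' @param reaction Named stoichiometric vector (see
#'   \code{\link{nitrification_reaction}}).
#' @param table Thermo table from \code{\link{thermo_table}}.
#' @param T_K Temperature (K).
#' @param P_bar Pressure (bar).
#' @param dV_cm3 Reaction volume change (cm3 mol-1), default 0.
#' @return kJ per mol of reaction turnover.
#' @export
standard_gibbs <- function(reaction, table = thermo_table(), T_K = .T_REF,
                           P_bar = 1, dV_cm3 = 0) {
  miss <- setdiff(names(reaction), rownames(table))
  if (length(miss))
    stop("thermo table missing species: ", paste(miss, collapse = ", "))
  nu <- reaction
  dG25 <- sum(nu * table[names(nu), "dGf_kJ_mol"])
  dH25 <- sum(nu * table[names(nu), "dHf_kJ_mol"])
  dS <- (dH25 - dG25) / .T_REF
  dH25 - T_K * dS + dV_cm3 * (P_bar - 1) * 1e-4  # 1 cm3 bar = 1e-4 kJ
}

#' Gibbs energy of nitrification along a solved profile
#'
#' Computes, for every depth inside the oxic zone (O2 at or above the OPD
#' threshold), the activities, reaction quotient and Gibbs energy of
#' nitrification per mole of electrons. Depths with a vanishing substrate
#' activity are excluded (flagged, not extrapolated).
#'
#' @param solution An \code{rtm_solution} or \code{rtm_fit}.
#' @param site Site (defaults to the solution's site); supplies T, P, pH.
#' @param table Thermo table.
#' @param n_e Electrons transferred per reaction for the per-electron
#'   normalisation: 8 (stoichiometric default) or 4 ("paper-equivalent"
#'   electron-equivalents mode).
#' @param ionic_strength Porewater ionic strength (mol kg-1), default
#'   seawater 0.7.
#' @param opd_threshold Oxic-zone threshold (mol m-3).
#' @param dV_cm3 Reaction volume change for the pressure term.
#' @return Data frame of class \code{thermo_result}: depth, T_K, P_bar,
#'   ionic_strength, activities, gamma values, Q, dG0_kJ_mol, dG_kJ_mol,
#'   dG_per_e_kJ, n_e.
#' @export
gibbs_energy_profile <- function(solution, site = NULL, table = thermo_table(),
                                 n_e = 8, ionic_strength = 0.7,
                                 opd_threshold = 1e-3, dV_cm3 = 0) {
  if (inherits(solution, "rtm_fit")) solution <- solution$solution
  if (is.null(site)) site <- solution$site
  if (!n_e %in% c(4, 8))
    warning("n_e is normally 8 (stoichiometric) or 4 (electron-equivalents)")
  pr <- solution$profiles
  z <- pr$grid$z_mid
  oxic <- pr$solutes$O2 >= opd_threshold
  T_K <- site$temperature + 273.15
  P <- site$pressure
  # mol m-3 porewater -> mol/kg (approximated by molarity)
  nh4_M <- pr$solutes$NH4 / 1000
  o2_M <- pr$solutes$O2 / 1000
  no3_M <- pr$solutes$NO3 / 1000
  nh3_M <- nh3_from_nh4(nh4_M, site$pH)

  g_no3 <- activity_coefficient(table["NO3", "charge"], ionic_strength, T_K,
                                table["NO3", "ion_size_A"])
  a_nh3 <- nh3_M            # neutral, gamma = 1
  a_o2 <- o2_M              # neutral
  a_no3 <- g_no3 * no3_M
  a_h <- 10^(-site$pH)      # pH defines the H+ activity directly

  ok <- oxic & a_nh3 > 0 & a_o2 > 0 & a_no3 > 0
  Q <- a_no3[ok] * a_h / (a_nh3[ok] * a_o2[ok]^2)   # a(H2O) = 1
  dG0 <- standard_gibbs(nitrification_reaction(), table, T_K, P, dV_cm3)
  dG <- dG0 + .R_GAS * T_K * log(Q)
  out <- data.frame(depth = z[ok], T_K = T_K, P_bar = P,
                    ionic_strength = ionic_strength,
                    a_NH3 = a_nh3[ok], a_O2 = a_o2[ok], a_NO3 = a_no3[ok],
                    a_H = a_h, gamma_NO3 = g_no3, Q = Q,
                    dG0_kJ_mol = dG0, dG_kJ_mol = dG,
                    dG_per_e_kJ = dG / n_e, n_e = n_e)
  class(out) <- c("thermo_result", class(out))
  attr(out, "excluded_depths") <- z[!ok]
  out
}

#' Volumetric power supply of nitrification
#'
#' \eqn{P_s = |\Delta G_r| \cdot R_4}, converted from kJ m-3 yr-1 to W m-3.
#' The per-reaction energy is reconstructed as \code{|dG_per_e| * n_e}, so
#' the result does not depend on the per-electron normalisation. Supply is
#' reported as a positive magnitude and is zero wherever the rate is zero.
#'
#' @param thermo A \code{thermo_result}.
#' @param solution The \code{rtm_solution} (or \code{rtm_fit}) providing the
#'   nitrification rate R4 (mol N m-3 bulk yr-1) on its grid.
#' @return Data frame of class \code{power_profile}: depth,
#'   rate_molN_m3_yr, Ps_W_m3.
#' @export
power_supply_profile <- function(thermo, solution) {
  if (inherits(solution, "rtm_fit")) solution <- solution$solution
  z <- solution$profiles$grid$z_mid
  idx <- match(thermo$depth, z)
  if (anyNA(idx)) stop("thermo and rate grids do not align")
  R4 <- solution$rates$R4[idx]
  Ps <- abs(thermo$dG_per_e_kJ) * thermo$n_e * R4 * 1e3 / .SEC_PER_YEAR
  out <- data.frame(depth = thermo$depth, rate_molN_m3_yr = R4, Ps_W_m3 = Ps)
  class(out) <- c("power_profile", class(out))
  out
}
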