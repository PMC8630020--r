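# Reaction network of the diagenetic model.
#
# Primary reactions distribute multi-G organic matter degradation over the
# terminal electron acceptors in order of decreasing energy yield:
#   R1 aerobic degradation        (Monod in O2)
#   R2 heterotrophic denitrification (Monod in NO3, inhibited by O2)
#   R3 MnO2 reduction             (Monod in MnO2, inhibited by O2 and NO3)
# Secondary bimolecular reactions:
#   R4 nitrification   k_nit * [NH4] * [O2]
#   R5 Mn(II) oxidation k_mnox * [Mn] * [O2]
#   R6 anammox         k_amx * [NH4] * [NO3]
# plus an optional first-order O2 sink (verification hook).
# Solute rates are converted from a porewater to a bulk basis with porosity;
# primary rates are bulk already because the G pools are bulk quantities.

# Evaluate all reaction rates and (optionally) their partial derivatives with
# respect to the local concentrations. `C` is a named list of vectors, one per
# species in .species. Concentrations are clamped at zero inside the rate laws
# so that Newton iterates passing through negative values remain well defined.
.rate_terms <- function(C, p, site, phi, deriv = TRUE) {
  pos <- function(x) pmax(x, 0)
  gate <- function(x) as.numeric(x > 0)  # derivative of the clamp

  O2 <- pos(C$O2); NO3 <- pos(C$NO3); NH4 <- pos(C$NH4)
  Mn <- pos(C$Mn); G1 <- pos(C$G1); G2 <- pos(C$G2); MnO2 <- pos(C$MnO2)

  kdeg <- p$k1 * G1 + p$k2 * G2

  fO2 <- O2 / (O2 + p$K_O2)
  dfO2 <- p$K_O2 / (O2 + p$K_O2)^2 * gate(C$O2)
  fNO3 <- NO3 / (NO3 + p$K_NO3)
  dfNO3 <- p$K_NO3 / (NO3 + p$K_NO3)^2 * gate(C$NO3)
  iO2 <- p$k_O2_inhib / (p$k_O2_inhib + O2)
  diO2 <- -p$k_O2_inhib / (p$k_O2_inhib + O2)^2 * gate(C$O2)
  iNO3 <- p$k_NO3_inhib / (p$k_NO3_inhib + NO3)
  diNO3 <- -p$k_NO3_inhib / (p$k_NO3_inhib + NO3)^2 * gate(C$NO3)
  fMn <- MnO2 / (MnO2 + p$K_MnO2)
  dfMn <- p$K_MnO2 / (MnO2 + p$K_MnO2)^2 * gate(C$MnO2)

  ox <- site$fully_oxic

  rxn <- list()
  rxn$R1 <- list(val = kdeg * fO2,
                 d = list(O2 = kdeg * dfO2,
                          G1 = p$k1 * fO2 * gate(C$G1),
                          G2 = p$k2 * fO2 * gate(C$G2)))
  rxn$R2 <- list(val = kdeg * fNO3 * iO2,
                 d = list(NO3 = kdeg * dfNO3 * iO2,
                          O2 = kdeg * fNO3 * diO2,
                          G1 = p$k1 * fNO3 * iO2 * gate(C$G1),
                          G2 = p$k2 * fNO3 * iO2 * gate(C$G2)))
  if (!ox) {
    rxn$R3 <- list(val = kdeg * fMn * iO2 * iNO3,
                   d = list(MnO2 = kdeg * dfMn * iO2 * iNO3,
                            O2 = kdeg * fMn * diO2 * iNO3,
                            NO3 = kdeg * fMn * iO2 * diNO3,
                            G1 = p$k1 * fMn * iO2 * iNO3 * gate(C$G1),
                            G2 = p$k2 * fMn * iO2 * iNO3 * gate(C$G2)))
  } else {
    z <- numeric(length(O2))
    rxn$R3 <- list(val = z, d = list())
  }
  rxn$R4 <- list(val = phi * p$k_nit * NH4 * O2,
                 d = list(NH4 = phi * p$k_nit * O2 * gate(C$NH4),
                          O2 = phi * p$k_nit * NH4 * gate(C$O2)))
  if (!ox) {
    rxn$R5 <- list(val = phi * p$k_mnox * Mn * O2,
                   d = list(Mn = phi * p$k_mnox * O2 * gate(C$Mn),
                            O2 = phi * p$k_mnox * Mn * gate(C$O2)))
    rxn$R6 <- list(val = phi * p$k_amx * NH4 * NO3,
                   d = list(NH4 = phi * p$k_amx * NO3 * gate(C$NH4),
                            NO3 = phi * p$k_amx * NH4 * gate(C$NO3)))
  } else {
    z <- numeric(length(O2))
    rxn$R5 <- list(val = z, d = list())
    rxn$R6 <- list(val = z, d = list())
  }
  rxn$Rlin <- list(val = phi * p$k_O2_linear * O2,
                   d = list(O2 = phi * p$k_O2_linear * gate(C$O2)))

  # pool-resolved degradation (guarantees exact C balance with the DIC source)
  Sfac <- fO2 + fNO3 * iO2 + if (ox) 0 else fMn * iO2 * iNO3
  dSfac <- list(
    O2 = dfO2 + fNO3 * diO2 + if (ox) 0 else fMn * diO2 * iNO3,
    NO3 = dfNO3 * iO2 + if (ox) 0 else fMn * iO2 * diNO3,
    MnO2 = if (ox) numeric(length(O2)) else dfMn * iO2 * iNO3)
  rxn$Rg1 <- list(val = p$k1 * G1 * Sfac,
                  d = c(list(G1 = p$k1 * Sfac * gate(C$G1)),
                        lapply(dSfac, function(d) p$k1 * G1 * d)))
  rxn$Rg2 <- list(val = p$k2 * G2 * Sfac,
                  d = c(list(G2 = p$k2 * Sfac * gate(C$G2)),
                        lapply(dSfac, function(d) p$k2 * G2 * d)))
  rxn
}

# stoichiometric matrix: contribution of each reaction to each species source
.stoich <- list(
  O2   = c(R1 = -1, R4 = -2, R5 = -0.5, Rlin = -1),
  NO3  = c(R2 = -0.8, R4 = 1, R6 = -1),
  NH4  = c(Rg1 = NA, Rg2 = NA, R4 = -1, R6 = -1),  # NA -> 1/rCN, filled in
  DIC  = c(Rg1 = 1, Rg2 = 1),
  Mn   = c(R3 = 2, R5 = -1),
  G1   = c(Rg1 = -1),
  G2   = c(Rg2 = -1),
  G3   = c(),
  MnO2 = c(R3 = -2, R5 = 1)
)

.stoich_for <- function(site) {
  st <- .stoich
  st$NH4[c("Rg1", "Rg2")] <- 1 / site$CN_ratio
  st
}

# net volumetric source of every species (bulk basis), plus sparse Jacobian
# triplets (target species, source species, value vector) when deriv = TRUE
.source_terms <- function(C, p, site, phi, deriv = TRUE) {
  rxn <- .rate_terms(C, p, site, phi, deriv)
  st <- .stoich_for(site)
  n <- length(C$O2)
  src <- lapply(.species, function(s) {
    out <- numeric(n)
    nu <- st[[s]]
    for (r in names(nu)) out <- out + nu[[r]] * rxn[[r]]$val
    out
  })
  names(src) <- .species
  jac <- NULL
  if (deriv) {
    jac <- list()
    for (s in .species) {
      nu <- st[[s]]
      acc <- list()
      for (r in names(nu)) {
        for (q in names(rxn[[r]]$d)) {
          v <- nu[[r]] * rxn[[r]]$d[[q]]
          acc[[q]] <- if (is.null(acc[[q]])) v else acc[[q]] + v
        }
      }
      jac[[s]] <- acc
    }
  }
  list(rxn = rxn, src = src, jac = jac)
}

#' Volumetric reaction rates at a given state
#'
#' Evaluates the six reaction rates of the network on a solved (or candidate)
#' profile set. Rates are on a bulk-sediment basis: R1-R3 in mol C m-3 yr-1,
#' R4 and R6 in mol N m-3 yr-1, R5 in mol Mn m-3 yr-1.
#'
#' @param profiles A profile set as returned in \code{rtm_solution$profiles}
#'   (list with \code{solutes}, \code{solids}, \code{porosity}).
#' @param p A \code{\link{kinetic_params}} object.
#' @param site A \code{\link{site_config}} object.
#' @return List of class \code{rate_profiles} with elements \code{R1..R6}
#'   and a \code{basis} annotation.
#' @export
reaction_rates <- function(profiles, p, site) {
  C <- c(profiles$solutes, profiles$solids)
  if (any(unlist(C) < 0)) stop("negative concentrations in solver state")
  rx <- .rate_terms(C, p, site, profiles$porosity, deriv = FALSE)
  out <- lapply(rx[c("R1", "R2", "R3", "R4", "R5", "R6")],
                function(r) r$val)
  out$basis <- c(R1 = "mol C m-3 bulk yr-1", R2 = "mol C m-3 bulk yr-1",
                 R3 = "mol C m-3 bulk yr-1", R4 = "mol N m-3 bulk yr-1",
                 R5 = "mol Mn m-3 bulk yr-1", R6 = "mol N m-3 bulk yr-1")
  class(out) <- "rate_profiles"
  out
}
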