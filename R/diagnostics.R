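#' Oxygen penetration depth
#'
#' Depth at which porewater O2 first drops below a threshold (default 1 uM =
#' 1e-3 mol m-3), found by linear interpolation between grid points. Returns
#' \code{Inf} when oxygen persists through the whole domain ("beyond domain").
#'
#' @param x An \code{rtm_solution}/\code{rtm_fit}, or a numeric vector of
#'   depths (m) for the default method.
#' @param o2 For the default method, O2 concentrations (mol m-3) at \code{x}.
#' @param threshold Threshold concentration (mol m-3).
#' @param ... Unused.
#' @return OPD in m, or \code{Inf}.
#' @export
oxygen_penetration_depth <- function(x, ...) UseMethod("oxygen_penetration_depth")

#' @rdname oxygen_penetration_depth
#' @export
oxygen_penetration_depth.default <- function(x, o2, threshold = 1e-3, ...) {
  z <- x
  stopifnot(length(z) == length(o2), !is.unsorted(z))
  below <- which(o2 < threshold)
  if (!length(below)) return(Inf)
  i <- below[1]
  if (i == 1) return(z[1])
  # linear interpolation between the bracketing points
  z[i - 1] + (threshold - o2[i - 1]) * (z[i] - z[i - 1]) / (o2[i] - o2[i - 1])
}

#' @rdname oxygen_penetration_depth
#' @export
oxygen_penetration_depth.rtm_solution <- function(x, threshold = 1e-3, ...) {
  z <- c(0, x$profiles$grid$z_mid)
  o2 <- c(x$profiles$top_concentrations[["O2"]], x$profiles$solutes$O2)
  oxygen_penetration_depth.default(z, o2, threshold)
}

#' @rdname oxygen_penetration_depth
#' @export
oxygen_penetration_depth.rtm_fit <- function(x, threshold = 1e-3, ...) {
  oxygen_penetration_depth(x$solution, threshold = threshold)
}

# interpolate a modeled quantity to arbitrary depths; species is one of the
# solutes or "TOC" (% dry weight)
.interp_model <- function(sol, species, depths) {
  pr <- sol$profiles
  L <- max(pr$grid$node_depths)
  if (species == "TOC") {
    y <- stats::approx(pr$grid$z_mid, pr$toc_percent, xout = depths,
                       rule = 2)$y
  } else if (species %in% .solutes) {
    y <- stats::approx(c(0, pr$grid$z_mid),
                       c(pr$top_concentrations[[species]],
                         pr$solutes[[species]]),
                       xout = depths, rule = 2)$y
  } else {
    stop("unknown species for interpolation: ", species)
  }
  y[depths < 0 | depths > L] <- NA_real_  # outside the modelled domain
  y
}

#' Root mean square error of a model against measurements
#'
#' Per-species RMSE, \eqn{\sqrt{\mathrm{mean}((model - measured)^2)}}, with
#' modeled values interpolated to the measured depths. Left-censored records
#' (below detection) and depths outside the modelled domain are excluded;
#' a species with no usable overlap is dropped with a warning.
#'
#' @param modeled An \code{rtm_solution} or \code{rtm_fit}.
#' @param measured Data frame with columns \code{depth}, \code{species},
#'   \code{value} (mol m-3, or % dry weight for TOC) and optionally
#'   \code{censored} (logical).
#' @return Named numeric vector of RMSE per species.
#' @export
rmse <- function(modeled, measured) {
  if (inherits(modeled, "rtm_fit")) modeled <- modeled$solution
  stopifnot(all(c("depth", "species", "value") %in% names(measured)))
  if (!is.null(measured$censored))
    measured <- measured[!measured$censored, , drop = FALSE]
  out <- c()
  for (sp in unique(measured$species)) {
    d <- measured[measured$species == sp, , drop = FALSE]
    m <- .interp_model(modeled, sp, d$depth)
    keep <- !is.na(m)
    if (!any(keep)) {
      warning("species ", sp, " has no overlap with the modelled domain; excluded")
      next
    }
    out[sp] <- sqrt(mean((m[keep] - d$value[keep])^2))
  }
  out
}

#' Porewater nitrate-to-consumed-oxygen slope
#'
#' Ordinary least-squares slope of NO3- against consumed oxygen
#' (top-concentration minus O2) over a depth window: a porewater proxy of
#' the C/N ratio of degrading organic matter (Redfield value 16/106 ~ 0.094
#' once the nitrification/degradation stoichiometry is folded in).
#'
#' @param x An \code{rtm_solution}, or a data frame with columns
#'   \code{O2} and \code{NO3} (paired observations, mol m-3).
#' @param depth_window Length-2 numeric, depths (m) to include (solutions
#'   only).
#' @return Dimensionless slope.
#' @export
nitrate_oxygen_slope <- function(x, depth_window = c(0, Inf)) {
  if (inherits(x, "rtm_fit")) x <- x$solution
  if (inherits(x, "rtm_solution")) {
    z <- x$profiles$grid$z_mid
    keep <- z >= depth_window[1] & z <= depth_window[2]
    o2 <- x$profiles$solutes$O2[keep]
    no3 <- x$profiles$solutes$NO3[keep]
  } else {
    stopifnot(all(c("O2", "NO3") %in% names(x)))
    o2 <- x$O2
    no3 <- x$NO3
  }
  if (length(o2) < 3) stop("need at least 3 points for the NO3/-O2 slope")
  minus_o2 <- -o2
  unname(stats::coef(stats::lm(no3 ~ minus_o2))[2])
}

#' Element flux budget of a converged solution
#'
#' Steady-state conservation audit. For each element (C, N, O2, Mn) the
#' boundary influx, outflux and depth-integrated net production are
#' recomputed directly from the solved profiles and rate laws, and the
#' relative closure error |influx - outflux + net production| / max(influx)
#' is reported. A converged solve closes to well below 1e-3.
#'
#' @param solution An \code{rtm_solution}.
#' @param site,p Site and kinetics used for the solve (defaults taken from
#'   the solution).
#' @return Data frame (class \code{budget_report}) with one row per element.
#' @export
flux_budget <- function(solution, site = solution$site, p = solution$kinetics) {
  pr <- solution$profiles
  grid <- pr$grid
  n <- grid$n_cells
  w <- site$sedimentation_rate
  phi_f0 <- porosity_profile(site, 0)
  phi_fend <- porosity_profile(site, grid$node_depths[n + 1])
  cf <- .top_flux_coefs(grid$z_mid[1], grid$z_mid[2])

  jtop <- c(); jbot <- c()
  for (s in .solutes) {
    D0 <- if (!is.null(p$D0) && s %in% names(p$D0)) p$D0[[s]] else
      solute_diffusivity(s, site$temperature)
    phiD0 <- phi_f0 * (effective_transport(D0, phi_f0) + p$Db)
    ctop <- site$top_concentrations[[s]]
    # same one-sided quadratic flux stencil as the solver (discrete audit)
    dcdz <- cf[["c0"]] * ctop + cf[["c1"]] * pr$solutes[[s]][1] +
      cf[["c2"]] * pr$solutes[[s]][2]
    jtop[s] <- -phiD0 * dcdz + w * phi_f0 * ctop
    jbot[s] <- w * phi_fend * pr$solutes[[s]][n]
  }
  Ftop <- c(G1 = site$organic_flux * site$G_fractions[1],
            G2 = site$organic_flux * site$G_fractions[2],
            G3 = site$organic_flux * site$G_fractions[3],
            MnO2 = site$mno2_flux)
  for (s in .solids) {
    jtop[s] <- Ftop[[s]]
    jbot[s] <- w * pr$solids[[s]][n]
  }

  st <- .source_terms(c(pr$solutes, pr$solids), p, site, pr$porosity,
                      deriv = FALSE)
  h <- grid$cell_widths
  netsrc <- vapply(.species, function(s) sum(st$src[[s]] * h), numeric(1))

  wts <- list(
    C = c(DIC = 1, G1 = 1, G2 = 1, G3 = 1),
    N = c(NO3 = 1, NH4 = 1, G1 = 1 / site$CN_ratio, G2 = 1 / site$CN_ratio,
          G3 = 1 / site$CN_ratio),
    O2 = c(O2 = 1),
    Mn = c(Mn = 1, MnO2 = 1))

  rows <- lapply(names(wts), function(e) {
    wv <- wts[[e]]
    infl <- sum(wv * jtop[names(wv)])
    outf <- sum(wv * jbot[names(wv)])
    np <- sum(wv * netsrc[names(wv)])
    data.frame(element = e, influx = infl, outflux = outf,
               net_production = np,
               closure_error = abs(infl - outf + np) / max(abs(infl), 1e-30))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("budget_report", class(out))
  out
}

#' Sensitivity scan over one parameter
#'
#' Re-solves the model with a parameter scaled by each factor and summarises
#' the response (OPD, optional RMSE, nitrate profile divergence from the
#' base case). Solver failures for individual factors are caught and
#' reported without aborting the scan.
#'
#' @param site,p Site and kinetics.
#' @param param_name Name of a scalar kinetic parameter, or \code{"F_org"}.
#' @param factors Positive multiplicative factors to apply.
#' @param grid Grid (default from \code{\link{build_grid}} on the site).
#' @param measured Optional measured data for RMSE reporting.
#' @param control Solver control list.
#' @return List of class \code{sensitivity_scan}; one entry per factor with
#'   \code{factor, solution, opd, rmse, no3_divergence, error}.
#' @export
sensitivity_scan <- function(site, p, param_name, factors,
                             grid = NULL, measured = NULL, control = list()) {
  if (any(factors <= 0)) stop("factors must be > 0")
  if (is.null(grid)) grid <- build_grid(site$domain_length)
  is_site_param <- param_name == "F_org"
  if (!is_site_param && (!param_name %in% names(p) ||
                         !is.numeric(p[[param_name]])))
    stop("unknown parameter: ", param_name)

  base <- solve_steady_state(site, p, grid, control)
  no3_base <- base$profiles$solutes$NO3

  entries <- lapply(factors, function(f) {
    s2 <- site; p2 <- p
    if (is_site_param) s2$organic_flux <- site$organic_flux * f
    else p2[[param_name]] <- p[[param_name]] * f
    sol <- tryCatch(
      solve_steady_state(s2, p2, grid,
                         utils::modifyList(control, list(init = base$state))),
      error = function(e) e)
    if (inherits(sol, "error"))
      return(list(factor = f, solution = NULL, opd = NA_real_, rmse = NULL,
                  no3_divergence = NA_real_, error = conditionMessage(sol)))
    list(factor = f, solution = sol,
         opd = oxygen_penetration_depth(sol),
         rmse = if (!is.null(measured)) rmse(sol, measured) else NULL,
         no3_divergence = max(abs(sol$profiles$solutes$NO3 - no3_base)),
         error = NULL)
  })
  structure(list(param = param_name, factors = factors, base = base,
                 entries = entries),
            class = "sensitivity_scan")
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat("<sensitivity_scan>", x$param, "\n")
  for (e in x$entries) {
    if (!is.null(e$error)) {
      cat(sprintf("  x%-6g  FAILED: %s\n", e$factor, e$error))
    } else {
      cat(sprintf("  x%-6g  OPD %s  max|dNO3| %.3g mol m-3\n", e$factor,
                  if (is.finite(e$opd)) sprintf("%.3g m", e$opd) else ">L",
                  e$no3_divergence))
    }
  }
  invisible(x)
}
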