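# File interfaces and the end-to-end pipeline.

.profile_species <- c("O2", "NO3", "NH4", "Mn", "DIC", "TOC")
.profile_units <- c("uM", "mmol/L", "mol/m3", "percent_dw")

#' Read a porewater/solid-phase profile table
#'
#' CSV with header \code{site,depth_m,species,value,unit,sd}. Values like
#' \code{"<0.1"} are read as left-censored records at the stated bound.
#' Units are normalised to mol m-3 (\code{uM} x 1e-3, \code{mmol/L} x 1,
#' \code{mol/m3} x 1); TOC uses \code{percent_dw} and is kept in % dry
#' weight.
#'
#' @param path CSV path.
#' @return Data frame: site, depth, species, value (mol m-3 or % dw), sd,
#'   censored.
#' @export
read_profile_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("site", "depth_m", "species", "value", "unit")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("profile table is missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(raw)
  censored <- grepl("^\\s*<", raw$value)
  valnum <- as.numeric(sub("^\\s*<", "", raw$value))
  depth <- as.numeric(raw$depth_m)
  sdv <- if ("sd" %in% names(raw)) suppressWarnings(as.numeric(raw$sd)) else
    rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!raw$species[i] %in% .profile_species)
      stop(sprintf("row %d: unknown species '%s'", i, raw$species[i]))
    if (!raw$unit[i] %in% .profile_units)
      stop(sprintf("row %d: unknown unit '%s'", i, raw$unit[i]))
    if (is.na(valnum[i]) || is.na(depth[i]))
      stop(sprintf("row %d: non-numeric depth or value", i))
    if ((raw$unit[i] == "percent_dw") != (raw$species[i] == "TOC"))
      stop(sprintf("row %d: unit percent_dw is for TOC only", i))
  }
  fac <- c(uM = 1e-3, `mmol/L` = 1, `mol/m3` = 1, percent_dw = 1)[raw$unit]
  data.frame(site = raw$site, depth = depth, species = raw$species,
             value = valnum * unname(fac), sd = sdv * unname(fac),
             censored = censored)
}

#' Write a profile table
#'
#' Inverse of \code{\link{read_profile_table}}: writes mol m-3 values in
#' \code{mol/m3} (TOC in \code{percent_dw}), censored records as
#' \code{"<bound"}.
#'
#' @param data Data frame as returned by \code{read_profile_table} (or
#'   \code{\link{generate_observations}} plus a \code{site} column).
#' @param path Output CSV path.
#' @export
write_profile_table <- function(data, path) {
  if (is.null(data$site)) data$site <- "site"
  if (is.null(data$censored)) data$censored <- FALSE
  out <- data.frame(site = data$site,
                    depth_m = data$depth,
                    species = data$species,
                    value = ifelse(data$censored,
                                   paste0("<", format(data$value, digits = 15)),
                                   format(data$value, digits = 15)),
                    unit = ifelse(data$species == "TOC", "percent_dw",
                                  "mol/m3"),
                    sd = if (is.null(data$sd)) NA else
                      format(data$sd, digits = 15))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.run_defaults <- list(seed = 1, n_e = 8, electron_equivalents = 4,
                      n_samples = 40, opd_threshold = 1e-3,
                      noise_cv = 0.1, community_noise = TRUE,
                      ionic_strength = 0.7)

#' Read a run configuration
#'
#' YAML file with sections \code{preset} (a preset name) or \code{site} and
#' \code{kinetics} (arguments of \code{\link{site_config}} and
#' \code{\link{kinetic_params}}), plus optional \code{grid}
#' (\code{n_nodes}, \code{refinement}) and \code{run} (seed, n_e,
#' electron_equivalents, n_samples, opd_threshold, noise_cv,
#' community_noise, ionic_strength). Unknown keys are rejected.
#'
#' @param path YAML path.
#' @return List of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  top <- setdiff(names(cfg), c("preset", "site", "kinetics", "grid", "run"))
  if (length(top)) stop("unknown config section(s): ",
                        paste(top, collapse = ", "))
  if (!is.null(cfg$site)) {
    bad <- setdiff(names(cfg$site), names(formals(site_config)))
    if (length(bad)) stop("unknown site key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$kinetics)) {
    bad <- setdiff(names(cfg$kinetics), names(formals(kinetic_params)))
    if (length(bad)) stop("unknown kinetics key(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$grid)) {
    bad <- setdiff(names(cfg$grid), c("n_nodes", "refinement"))
    if (length(bad)) stop("unknown grid key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$run)) {
    bad <- setdiff(names(cfg$run), names(.run_defaults))
    if (length(bad)) stop("unknown run key(s): ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Run the full pipeline on a preset or configuration
#'
#' Solve -> oxygen penetration depth -> nitrification thermodynamics and
#' power supply -> synthetic community observations -> exponential-decay fit
#' of the AOA fraction -> absolute abundance -> cell-specific power, with
#' every intermediate kept in the returned bundle. When the domain is oxic
#' throughout, the domain length bounds the oxic zone for relative-depth
#' purposes.
#'
#' @param config A preset name (see \code{\link{preset_names}}), a
#'   \code{site_preset}, or a \code{run_config}.
#' @param seed RNG seed for the synthetic observation stages.
#' @param ... Overrides of the run options (see \code{\link{read_run_config}}).
#' @return List of class \code{sed_pipeline} with elements \code{fit}
#'   (\code{rtm_fit}), \code{opd}, \code{thermo}, \code{power},
#'   \code{community}, \code{aoa_fit}, \code{abundance},
#'   \code{cell_power} (data frame with depth, x, Ps_W_m3, abundance and
#'   p_cell_W columns), \code{summary}, and \code{resolved_config}.
#' @export
run_pipeline <- function(config, seed = NULL, ...) {
  if (is.character(config)) config <- make_site_preset(config)
  run <- .run_defaults
  if (inherits(config, "run_config")) {
    if (!is.null(config$run)) run <- utils::modifyList(run, config$run)
    if (!is.null(config$preset)) {
      preset <- make_site_preset(config$preset)
    } else {
      site <- do.call(site_config, config$site)
      kin <- do.call(kinetic_params,
                     if (is.null(config$kinetics)) list() else config$kinetics)
      g <- utils::modifyList(list(n_nodes = 200, refinement = 1.04),
                             if (is.null(config$grid)) list() else config$grid)
      grid <- build_grid(site$domain_length, g$n_nodes, g$refinement)
      preset <- structure(list(name = site$name, site = site, kinetics = kin,
                               grid = grid,
                               community = list(a = 22.3, b = -2,
                                                sigma_frac = 0.5, N0 = 1e6,
                                                m = 0.7, sigma_log10 = 0.3)),
                          class = "site_preset")
    }
  } else if (inherits(config, "site_preset")) {
    preset <- config
  } else {
    stop("config must be a preset name, site_preset or run_config")
  }
  run <- utils::modifyList(run, list(...))
  if (!is.null(seed)) run$seed <- seed

  fit <- rtm(preset$site, preset$kinetics, grid = preset$grid)
  opd <- oxygen_penetration_depth(fit, threshold = run$opd_threshold)
  oxic_extent <- if (is.finite(opd)) opd else preset$site$domain_length

  thermo <- gibbs_energy_profile(fit$solution, n_e = run$n_e,
                                 ionic_strength = run$ionic_strength,
                                 opd_threshold = run$opd_threshold)
  power <- power_supply_profile(thermo, fit$solution)

  cm <- preset$community
  if (!run$community_noise) {
    cm0 <- cm; cm0$sigma_frac <- 0; cm0$sigma_log10 <- 0
    preset_noiseless <- preset; preset_noiseless$community <- cm0
    community <- generate_community_observations(preset_noiseless,
                                                 opd = oxic_extent,
                                                 n_samples = run$n_samples,
                                                 seed = run$seed)
  } else {
    community <- generate_community_observations(preset, opd = oxic_extent,
                                                 n_samples = run$n_samples,
                                                 seed = run$seed)
  }
  afit <- fit_exponential_decay(community$x, community$aoa_fraction_pct)

  x <- power$depth / oxic_extent
  keep <- x <= 1
  pred <- predict_fraction(afit, x[keep])
  totals <- cm$N0 * pmax(power$depth[keep], 0.01)^(-cm$m)
  ab <- estimate_aoa_absolute(totals, pred$fraction, pred$ci_low,
                              pred$ci_high)
  cp <- cell_specific_power(power$Ps_W_m3[keep], ab$abundance,
                            ab$ci_low, ab$ci_high)
  cell_power <- data.frame(depth = power$depth[keep], x = x[keep],
                           Ps_W_m3 = power$Ps_W_m3[keep],
                           abundance = ab$abundance,
                           abundance_lo = ab$ci_low,
                           abundance_hi = ab$ci_high,
                           p_cell_W = cp$p_cell_W,
                           p_cell_lo = cp$ci_low, p_cell_hi = cp$ci_high)
  summ <- summarize_cell_power(cell_power)

  resolved <- list(preset = preset$name, run = run,
                   community_truth = preset$community)
  structure(list(fit = fit, opd = opd, oxic_extent = oxic_extent,
                 thermo = thermo, power = power, community = community,
                 aoa_fit = afit, cell_power = cell_power, summary = summ,
                 resolved_config = resolved),
            class = "sed_pipeline")
}

#' @export
print.sed_pipeline <- function(x, ...) {
  cat("<sed_pipeline>", x$resolved_config$preset, "\n")
  cat("  OPD:", if (is.finite(x$opd)) sprintf("%.3g m", x$opd) else
    sprintf("beyond domain (oxic through %g m)", x$oxic_extent), "\n")
  cat(sprintf("  dG: %.3g to %.3g kJ (mol e-)-1 over the oxic zone\n",
              min(x$thermo$dG_per_e_kJ), max(x$thermo$dG_per_e_kJ)))
  ps <- x$power$Ps_W_m3[x$power$Ps_W_m3 > 0]
  if (length(ps))
    cat(sprintf("  Ps: %.3g to %.3g W m-3\n", min(ps), max(ps)))
  pc <- x$cell_power$p_cell_W
  pc <- pc[!is.na(pc) & pc > 0]
  if (length(pc))
    cat(sprintf("  cell-specific power: %.3g to %.3g W cell-1\n",
                min(pc), max(pc)))
  cat(sprintf("  AOA fit: a = %.3g%%, b = %.3g, R2 = %.2f (n = %d)\n",
              x$aoa_fit$a, x$aoa_fit$b, x$aoa_fit$R2, x$aoa_fit$n))
  invisible(x)
}

#' Write a pipeline bundle to JSON
#'
#' Serialises the grid, profiles, rates, OPD, thermodynamics, power,
#' community fit and cell-power table, together with the resolved
#' configuration, to a single JSON document.
#'
#' @param bundle A \code{sed_pipeline}.
#' @param path Output path.
#' @export
write_bundle_json <- function(bundle, path) {
  pr <- bundle$fit$solution$profiles
  doc <- list(
    resolved_config = bundle$resolved_config,
    grid = list(node_depths = pr$grid$node_depths, z_mid = pr$grid$z_mid),
    profiles = c(pr$solutes, list(toc_percent = pr$toc_percent)),
    rates = bundle$fit$solution$rates[paste0("R", 1:6)],
    opd = if (is.finite(bundle$opd)) bundle$opd else "beyond domain",
    thermo = bundle$thermo,
    power = bundle$power,
    aoa_fit = list(a = bundle$aoa_fit$a, b = bundle$aoa_fit$b,
                   R2 = bundle$aoa_fit$R2, n = bundle$aoa_fit$n),
    cell_power = bundle$cell_power)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Packaged site-property table
#'
#' Metadata of the eight study cores (region, water depth, sedimentation
#' rate, coring method) as shipped in \code{inst/extdata}.
#' @return Data frame.
#' @export
site_properties <- function() {
  utils::read.csv(system.file("extdata", "site_properties.csv",
                              package = "sedpower"),
                  comment.char = "#", stringsAsFactors = FALSE)
}
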