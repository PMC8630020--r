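#' Fit a steady-state diagenetic reaction-transport model
#'
#' Central modelling interface: solves the steady-state model for a site and,
#' when measured data and free parameters are supplied, calibrates the free
#' parameters first. Returns a classed fit with the usual accessor methods
#' (\code{print}, \code{summary}, \code{coef}, \code{predict}, \code{plot},
#' \code{residuals}, \code{fitted}).
#'
#' @param site A \code{\link{site_config}}.
#' @param kinetics A \code{\link{kinetic_params}} (defaults apply).
#' @param data Optional measured data frame (columns \code{depth},
#'   \code{species}, \code{value}, optional \code{sd}, \code{censored}).
#' @param free Optional character vector of parameters to calibrate (requires
#'   \code{data}); see \code{\link{calibrate}}.
#' @param grid Optional \code{\link{build_grid}} grid; by default 200 faces
#'   with geometric refinement 1.04 toward the interface.
#' @param control Solver control list.
#' @param ... Passed to \code{\link{calibrate}} when calibrating.
#' @return Object of class \code{rtm_fit}.
#' @export
rtm <- function(site, kinetics = kinetic_params(), data = NULL,
                free = NULL, grid = NULL, control = list(), ...) {
  if (is.null(grid)) grid <- build_grid(site$domain_length, 200, 1.04)
  cal <- NULL
  if (!is.null(free) && length(free)) {
    if (is.null(data)) stop("calibration requires measured data")
    cal <- calibrate(site, kinetics, data, free = free, grid = grid,
                     control = control, ...)
    site <- cal$site
    kinetics <- cal$kinetics
  }
  sol <- solve_steady_state(site, kinetics, grid, control)
  structure(list(site = site, kinetics = kinetics, grid = grid,
                 solution = sol, data = data, calibration = cal),
            class = "rtm_fit")
}

#' @export
print.rtm_fit <- function(x, ...) {
  cat("<rtm_fit>", x$site$name, "\n")
  d <- x$solution$diagnostics
  cat(sprintf("  %d cells on [0, %g] m; converged in %d iterations (residual %.2e)\n",
              x$grid$n_cells, x$site$domain_length, d$iterations,
              d$relative_residual))
  opd <- oxygen_penetration_depth(x)
  cat("  OPD:", if (is.finite(opd)) sprintf("%.4g m", opd) else
    "beyond domain (fully oxic)", "\n")
  if (!is.null(x$calibration) && length(x$calibration$free))
    cat("  calibrated:", paste(sprintf("%s=%.4g", x$calibration$free,
                                       x$calibration$fitted_values),
                               collapse = ", "), "\n")
  if (!is.null(x$data)) {
    rm <- rmse(x, x$data)
    cat("  RMSE:", paste(sprintf("%s=%.3g", names(rm), rm), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
coef.rtm_fit <- function(object, ...) {
  p <- object$kinetics
  sc <- names(p)[vapply(p, function(x) is.numeric(x) && length(x) == 1,
                        logical(1))]
  c(unlist(p[sc]), F_org = object$site$organic_flux)
}

#' @export
summary.rtm_fit <- function(object, ...) {
  h <- object$grid$cell_widths
  r <- object$solution$rates
  intr <- vapply(paste0("R", 1:6), function(k) sum(r[[k]] * h), numeric(1))
  out <- list(site = object$site$name,
              opd = oxygen_penetration_depth(object),
              integrated_rates = intr,
              budget = flux_budget(object$solution),
              diagnostics = object$solution$diagnostics,
              rmse = if (!is.null(object$data)) rmse(object, object$data))
  class(out) <- "summary.rtm_fit"
  out
}

#' @export
print.summary.rtm_fit <- function(x, ...) {
  cat("Steady-state diagenetic model fit:", x$site, "\n")
  cat("  OPD:", if (is.finite(x$opd)) sprintf("%.4g m", x$opd) else
    "beyond domain", "\n")
  cat("  depth-integrated rates (mol m-2 yr-1):\n")
  print(signif(x$integrated_rates, 4))
  cat("  element budget closure:\n")
  print(data.frame(element = x$budget$element,
                   closure_error = signif(x$budget$closure_error, 3)))
  if (!is.null(x$rmse)) {
    cat("  RMSE per species:\n")
    print(signif(x$rmse, 4))
  }
  invisible(x)
}

#' Predict modeled quantities at arbitrary depths
#'
#' @param object An \code{rtm_fit}.
#' @param depths Depths (m).
#' @param species Character vector from \code{O2, NO3, NH4, Mn, DIC, TOC}.
#' @param ... Unused.
#' @return Data frame with \code{depth}, \code{species}, \code{value}.
#' @export
predict.rtm_fit <- function(object,
                            depths = object$grid$z_mid,
                            species = c("O2", "NO3", "NH4", "Mn", "DIC",
                                        "TOC"), ...) {
  out <- do.call(rbind, lapply(species, function(sp)
    data.frame(depth = depths, species = sp,
               value = .interp_model(object$solution, sp, depths))))
  rownames(out) <- NULL
  out
}

#' @export
fitted.rtm_fit <- function(object, ...) {
  if (is.null(object$data)) stop("no measured data attached to this fit")
  d <- object$data
  vapply(seq_len(nrow(d)), function(i)
    .interp_model(object$solution, d$species[i], d$depth[i]), numeric(1))
}

#' @export
residuals.rtm_fit <- function(object, ...) {
  if (is.null(object$data)) stop("no measured data attached to this fit")
  object$data$value - fitted(object)
}

#' Plot modeled depth profiles
#'
#' Base-graphics panel plot of modeled solute/TOC profiles (lines) with
#' measured data overlaid as points where available.
#'
#' @param x An \code{rtm_fit}.
#' @param species Panels to draw.
#' @param ... Passed to \code{plot}.
#' @export
plot.rtm_fit <- function(x, species = c("O2", "NO3", "NH4", "DIC", "TOC"),
                         ...) {
  old <- graphics::par(mfrow = c(1, length(species)), mar = c(4, 4, 2, 0.5))
  on.exit(graphics::par(old))
  z <- x$grid$z_mid
  for (sp in species) {
    v <- .interp_model(x$solution, sp, z)
    graphics::plot(v, z, type = "l", ylim = rev(range(z)),
                   xlab = if (sp == "TOC") "TOC (% dw)" else
                     paste0(sp, " (mol m-3)"),
                   ylab = "depth (m)", main = sp, ...)
    if (!is.null(x$data)) {
      d <- x$data[x$data$species == sp, , drop = FALSE]
      if (nrow(d)) graphics::points(d$value, d$depth, pch = 19, cex = 0.6)
    }
  }
  invisible(x)
}
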