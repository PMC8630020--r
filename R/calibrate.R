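#' Calibrate kinetic parameters against measured profiles
#'
#' Formal weighted-least-squares counterpart of visual profile fitting.
#' Each record contributes \eqn{((model - measured)/w_i)^2}: the weight is
#' the record's measurement sd where one is reported, and otherwise the
#' species scale (largest measured value of that species), so that species
#' of very different magnitudes contribute comparably. Censored records are
#' excluded. Free parameters are optimised on a log10 scale with box
#' constraints (L-BFGS-B).
#'
#' @param site Site configuration; \code{"F_org"} may be a free parameter.
#' @param p0 Starting \code{\link{kinetic_params}}.
#' @param measured Measured data frame (see \code{\link{rmse}}).
#' @param free Character vector of parameter names to optimise (subset of the
#'   scalar kinetic parameters plus \code{"F_org"}). Empty set returns
#'   \code{p0} with the objective evaluated.
#' @param bounds Named list of length-2 numeric bounds per free parameter;
#'   defaults to a factor of 100 either side of the start value.
#' @param grid Grid for the solves (default \code{build_grid} on the site).
#' @param control Solver control passed to \code{\link{solve_steady_state}}.
#' @param optim_control Control list for \code{\link[stats]{optim}}.
#' @return List of class \code{rtm_calibration}: fitted \code{kinetics} and
#'   \code{site}, the start \code{p0}, \code{objective}, objective
#'   \code{trace}, per-species \code{rmse}, \code{convergence} flag.
#' @export
calibrate <- function(site, p0, measured, free = character(),
                      bounds = NULL, grid = NULL, control = list(),
                      optim_control = list()) {
  if (is.null(grid)) grid <- build_grid(site$domain_length)
  scalar_kin <- names(p0)[vapply(p0, function(x)
    is.numeric(x) && length(x) == 1, logical(1))]
  allowed <- c(scalar_kin, "F_org")
  if (!all(free %in% allowed))
    stop("free parameters must be among: ", paste(allowed, collapse = ", "))

  meas <- measured
  cens <- if (!is.null(meas$censored)) meas$censored else
    rep(FALSE, nrow(meas))
  # left-censored records ("< bound") contribute one-sided: only a model
  # value exceeding the bound is penalised
  scales <- vapply(split(meas$value, meas$species),
                   function(v) max(v, na.rm = TRUE), numeric(1))
  wts <- if (!is.null(meas$sd)) meas$sd else rep(NA_real_, nrow(meas))
  bad_w <- !is.finite(wts) | wts <= 0
  wts[bad_w] <- scales[meas$species[bad_w]]
  # floor the weights at the analytical detection limit (0.1 uM for solutes,
  # 2% of scale for TOC) so near-zero records cannot dominate the objective
  wts <- pmax(wts, ifelse(meas$species == "TOC",
                          0.02 * max(meas$value[meas$species == "TOC"], 0,
                                     na.rm = TRUE), 1e-4))
  if (any(!is.finite(wts))) stop("could not derive calibration weights")

  apply_params <- function(theta) {
    s2 <- site; p2 <- p0
    for (k in seq_along(free)) {
      val <- unname(10^theta[k])
      if (free[k] == "F_org") s2$organic_flux <- val else p2[[free[k]]] <- val
    }
    list(site = s2, p = p2)
  }

  env <- new.env()
  env$warm <- NULL
  env$trace <- numeric(0)
  env$best <- NULL

  objective <- function(theta) {
    sp <- apply_params(theta)
    sol <- tryCatch(
      solve_steady_state(sp$site, sp$p, grid,
                         utils::modifyList(control, list(init = env$warm))),
      error = function(e) NULL)
    if (is.null(sol) && !is.null(env$warm))  # retry from a cold start
      sol <- tryCatch(solve_steady_state(sp$site, sp$p, grid, control),
                      error = function(e) NULL)
    if (is.null(sol)) return(1e8)
    env$warm <- sol$state
    m <- vapply(seq_len(nrow(meas)), function(i)
      .interp_model(sol, meas$species[i], meas$depth[i]), numeric(1))
    keep <- is.finite(m)
    dev <- m - meas$value
    dev[cens] <- pmax(dev[cens], 0)   # one-sided for "< bound" records
    obj <- mean((dev[keep] / wts[keep])^2)
    rm <- rmse(sol, measured)
    if (!is.finite(obj)) return(1e8)
    env$trace <- c(env$trace, obj)
    if (is.null(env$best) || obj < env$best$obj)
      env$best <- list(obj = obj, theta = theta, rmse = rm)
    obj
  }

  if (!length(free)) {
    obj <- objective(numeric(0))
    return(structure(list(kinetics = p0, site = site, p0 = p0,
                          objective = obj, trace = env$trace,
                          rmse = env$best$rmse, free = free,
                          convergence = TRUE),
                     class = "rtm_calibration"))
  }

  start <- vapply(free, function(f)
    if (f == "F_org") site$organic_flux else p0[[f]], numeric(1))
  if (any(start <= 0)) stop("free parameters must start > 0 for log scaling")
  theta0 <- log10(start)
  lo <- hi <- numeric(length(free))
  for (k in seq_along(free)) {
    b <- if (!is.null(bounds) && free[k] %in% names(bounds))
      bounds[[free[k]]] else start[k] * c(1e-2, 1e2)
    if (any(!is.finite(b)) || b[1] <= 0) stop("bounds must be finite and > 0")
    lo[k] <- log10(b[1]); hi[k] <- log10(b[2])
  }

  obj0 <- objective(theta0)
  # the weighted mean square is O(1) at a statistically consistent optimum;
  # when the whole landscape is much smaller (noise-free data) rescale so
  # the optimizer still sees O(1) gradients
  oc <- utils::modifyList(
    list(maxit = 200, factr = 1e9,
         fnscale = max(1e-12, min(obj0, 1))),
    optim_control)
  fit <- tryCatch(
    stats::optim(theta0, objective, method = "L-BFGS-B",
                 lower = lo, upper = hi, control = oc),
    error = function(e) NULL)

  converged <- !is.null(fit) && fit$convergence == 0
  theta_hat <- if (!is.null(env$best)) env$best$theta else fit$par
  if (is.null(theta_hat))
    stop("calibration failed: objective could never be evaluated")
  sp <- apply_params(theta_hat)

  structure(list(kinetics = sp$p, site = sp$site, p0 = p0,
                 objective = env$best$obj, trace = env$trace,
                 rmse = env$best$rmse, free = free,
                 fitted_values = stats::setNames(10^theta_hat, free),
                 convergence = converged),
            class = "rtm_calibration")
}

#' @export
print.rtm_calibration <- function(x, ...) {
  cat("<rtm_calibration>",
      if (x$convergence) "converged" else "NOT converged (best-so-far)", "\n")
  if (length(x$free)) {
    cat("  fitted:", paste(sprintf("%s=%.4g", x$free, x$fitted_values),
                           collapse = ", "), "\n")
  }
  cat(sprintf("  objective %.4g after %d evaluations\n",
              x$objective, length(x$trace)))
  invisible(x)
}
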