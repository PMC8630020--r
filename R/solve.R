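# Steady-state finite-volume solver.
#
# Unknowns are cell-centre concentrations, species-major: for species s
# (order .species) and cell i, index (s-1)*n + i. Solutes carry
# diffusion (harmonic-mean interface diffusivities), porewater burial
# advection (upwind) and bulk reaction sources; solids carry upwind burial
# advection with a prescribed depositional flux at the top face. The top
# boundary holds fixed solute concentrations; the bottom boundary is
# zero-gradient (advective outflow only). The nonlinear system is solved by
# damped Newton iteration with a pseudo-transient fallback.

.spidx <- function(species, n) (match(species, .species) - 1L) * n + seq_len(n)

# one-sided quadratic derivative weights at z = 0 through (0, C_top),
# (z1, C1), (z2, C2): dC/dz(0) ~ c0*C_top + c1*C1 + c2*C2 (second order)
.top_flux_coefs <- function(z1, z2) {
  c(c0 = -(z1 + z2) / (z1 * z2),
    c1 = z2 / (z1 * (z2 - z1)),
    c2 = -z1 / (z2 * (z2 - z1)))
}

# Precompute the linear transport operator T and constant vector b such that
# the residual of the discrete steady state is T %*% U + b + src * h.
.transport_operator <- function(site, p, grid) {
  n <- grid$n_cells
  z <- grid$z_mid
  h <- grid$cell_widths
  faces <- grid$node_depths
  w <- site$sedimentation_rate
  phi_mid <- porosity_profile(site, z)
  phi_face <- porosity_profile(site, faces)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  b <- numeric(9L * n)

  add <- function(i, j, v) {
    if (length(v) == 1L) v <- rep(v, length(i))
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }

  for (s in .solutes) {
    off <- (match(s, .species) - 1L) * n
    D0 <- if (!is.null(p$D0) && s %in% names(p$D0)) p$D0[[s]] else
      solute_diffusivity(s, site$temperature)
    Ds_mid <- effective_transport(D0, phi_mid) + p$Db
    phiD <- phi_mid * Ds_mid
    # interior faces: distance-weighted harmonic mean of phi*Ds
    j <- seq_len(n - 1)
    d1 <- faces[j + 1] - z[j]
    d2 <- z[j + 1] - faces[j + 1]
    phiD_f <- (d1 + d2) / (d1 / phiD[j] + d2 / phiD[j + 1])
    beta <- phiD_f / (d1 + d2)
    a <- w * phi_face[j + 1]
    add(off + j,     off + j + 1,  beta)
    add(off + j,     off + j,     -beta - a)
    add(off + j + 1, off + j + 1, -beta)
    add(off + j + 1, off + j,      beta + a)
    # top face: fixed concentration boundary, one-sided quadratic flux
    Ds_top <- effective_transport(D0, phi_face[1]) + p$Db
    phiD0 <- phi_face[1] * Ds_top
    cf <- .top_flux_coefs(z[1], z[2])
    a0 <- w * phi_face[1]
    add(off + 1L, off + 1L, -phiD0 * cf[["c1"]])
    add(off + 1L, off + 2L, -phiD0 * cf[["c2"]])
    b[off + 1L] <- (-phiD0 * cf[["c0"]] + a0) * site$top_concentrations[[s]]
    # bottom face: advective outflow
    add(off + n, off + n, -w * phi_face[n + 1])
  }

  Ftop <- c(G1 = site$organic_flux * site$G_fractions[1],
            G2 = site$organic_flux * site$G_fractions[2],
            G3 = site$organic_flux * site$G_fractions[3],
            MnO2 = site$mno2_flux)
  for (s in .solids) {
    off <- (match(s, .species) - 1L) * n
    if (w > 0) {
      j <- seq_len(n - 1)
      add(off + j,     off + j, -w)
      add(off + j + 1, off + j,  w)
      add(off + n,     off + n, -w)
    }
    b[off + 1L] <- Ftop[[s]]
  }

  Tm <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                             dims = c(9L * n, 9L * n))
  list(Tm = Tm, b = b, phi_mid = phi_mid, phi_face = phi_face,
       trip = list(i = ii, j = jj, x = vv))
}

.state_list <- function(U, n) {
  out <- lapply(seq_along(.species), function(k) U[((k - 1L) * n + 1L):(k * n)])
  names(out) <- .species
  out
}

# initial guess: solutes at their top values, solids from an upwind sweep
# assuming unthrottled degradation
.initial_state <- function(site, p, grid) {
  n <- grid$n_cells
  h <- grid$cell_widths
  w <- site$sedimentation_rate
  U <- numeric(9L * n)
  for (s in .solutes)
    U[.spidx(s, n)] <- site$top_concentrations[[s]]
  kpool <- c(G1 = p$k1, G2 = p$k2, G3 = 0, MnO2 = 0)
  Ftop <- c(G1 = site$organic_flux * site$G_fractions[1],
            G2 = site$organic_flux * site$G_fractions[2],
            G3 = site$organic_flux * site$G_fractions[3],
            MnO2 = site$mno2_flux)
  for (s in .solids) {
    S <- numeric(n)
    inflow <- Ftop[[s]]
    for (i in seq_len(n)) {
      den <- w + kpool[[s]] * h[i]
      S[i] <- if (den > 0) inflow / den else 0
      inflow <- w * S[i]
    }
    U[.spidx(s, n)] <- S
  }
  U
}

#' Solve the steady-state diagenetic model
#'
#' Finite-volume discretisation of the coupled solute/solid diagenetic
#' equations, driven to steady state by damped Newton iteration (line search
#' on the scaled residual norm) with pseudo-transient continuation as a
#' fallback when a Newton step is rejected.
#'
#' @param site A \code{\link{site_config}}.
#' @param p A \code{\link{kinetic_params}}.
#' @param grid A \code{\link{build_grid}} result.
#' @param control List of solver options: \code{tol} (relative residual
#'   tolerance, default 1e-10), \code{maxit} (default 200), \code{verbose},
#'   \code{init} (optional initial state vector from a previous solve).
#' @return Object of class \code{rtm_solution}: \code{profiles} (grid,
#'   porosity, solutes in mol m-3 porewater, solids in mol m-3 bulk,
#'   \code{toc_percent} in % dry weight), \code{rates} (R1-R6),
#'   \code{diagnostics} (iterations, scaled residual, convergence flag).
#' @export
solve_steady_state <- function(site, p, grid, control = list()) {
  ctl <- utils::modifyList(list(tol = 1e-10, maxit = 200L, verbose = FALSE,
                                init = NULL), control)
  n <- grid$n_cells
  op <- .transport_operator(site, p, grid)
  h <- grid$cell_widths
  hrep <- rep(h, times = 9L)
  phi <- op$phi_mid

  residual <- function(U) {
    st <- .source_terms(.state_list(U, n), p, site, phi, deriv = FALSE)
    srcvec <- unlist(st$src, use.names = FALSE)
    tu <- as.numeric(op$Tm %*% U)
    res <- tu + op$b + srcvec * hrep
    # per-species relative scaling against the largest flux-like term
    rel <- 0
    for (k in seq_along(.species)) {
      id <- ((k - 1L) * n + 1L):(k * n)
      sc <- max(1e-30, max(abs(op$b[id])), max(abs(tu[id])),
                max(abs(srcvec[id] * h)))
      rel <- max(rel, max(abs(res[id])) / sc)
    }
    list(res = res, rel = rel)
  }

  jacobian <- function(U, inv_dt = 0) {
    st <- .source_terms(.state_list(U, n), p, site, phi, deriv = TRUE)
    ii <- op$trip$i; jj <- op$trip$j; vv <- op$trip$x
    for (s in .species) {
      acc <- st$jac[[s]]
      if (!length(acc)) next
      ro <- (match(s, .species) - 1L) * n
      for (q in names(acc)) {
        co <- (match(q, .species) - 1L) * n
        ii <- c(ii, ro + seq_len(n))
        jj <- c(jj, co + seq_len(n))
        vv <- c(vv, acc[[q]] * h)
      }
    }
    if (inv_dt > 0) {
      mass <- rep(h, times = 9L)
      for (s in .solutes) mass[.spidx(s, n)] <- phi * h
      ii <- c(ii, seq_len(9L * n))
      jj <- c(jj, seq_len(9L * n))
      vv <- c(vv, -mass * inv_dt)
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(9L * n, 9L * n))
  }

  U <- if (!is.null(ctl$init) && length(ctl$init) == 9L * n) ctl$init else
    .initial_state(site, p, grid)
  r <- residual(U)
  dt <- Inf  # Inf = plain Newton; finite = pseudo-transient step length (yr)
  it <- 0L
  while (r$rel > ctl$tol && it < ctl$maxit) {
    it <- it + 1L
    J <- jacobian(U, inv_dt = if (is.finite(dt)) 1 / dt else 0)
    delta <- tryCatch(as.numeric(Matrix::solve(J, -r$res)),
                      error = function(e) NULL)
    if (is.null(delta) || anyNA(delta)) {
      dt <- if (is.finite(dt)) dt / 10 else 1
      if (dt < 1e-12)
        stop("solver failed: singular Jacobian; residual ", signif(r$rel, 3))
      next
    }
    if (is.finite(dt)) {
      # pseudo-transient: accept the implicit Euler step, adapt dt
      Unew <- U + delta
      rnew <- residual(Unew)
      if (is.finite(rnew$rel) && rnew$rel < 10 * r$rel) {
        U <- Unew; r <- rnew
        dt <- dt * 5
        if (dt > 1e14) dt <- Inf
      } else {
        dt <- dt / 10
        if (dt < 1e-12)
          stop("solver failed to converge; residual ", signif(r$rel, 3))
      }
    } else {
      lambda <- 1
      ok <- FALSE
      for (ls in 1:15) {
        Unew <- U + lambda * delta
        rnew <- residual(Unew)
        if (is.finite(rnew$rel) &&
            (rnew$rel < r$rel * (1 - 1e-4 * lambda) || rnew$rel < ctl$tol)) {
          ok <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (ok) {
        U <- Unew; r <- rnew
      } else {
        dt <- 1  # switch to pseudo-transient continuation
      }
    }
    if (ctl$verbose)
      message(sprintf("iter %3d  relres %.3e  dt %s", it, r$rel,
                      if (is.finite(dt)) format(dt) else "Newton"))
  }
  if (r$rel > ctl$tol)
    stop(sprintf(
      "steady-state solver did not converge in %d iterations (residual %.3e)",
      ctl$maxit, r$rel))

  # positivity audit, then clip
  st <- .state_list(U, n)
  for (s in .species) {
    ref <- max(abs(st[[s]]),
               if (s %in% .solutes) site$top_concentrations[[s]] else 0, 1e-30)
    if (min(st[[s]]) < -1e-9 * ref)
      stop("solver produced negative steady-state concentration for ", s)
    st[[s]] <- pmax(st[[s]], 0)
  }

  solutes <- st[.solutes]
  solids <- st[.solids]
  toc <- 100 * 12.011 * (solids$G1 + solids$G2 + solids$G3) /
    (site$dry_density * 1e6 * (1 - phi))
  profiles <- list(grid = grid, porosity = phi,
                   solutes = solutes, solids = solids,
                   toc_percent = toc,
                   top_concentrations = site$top_concentrations)
  rates <- reaction_rates(profiles, p, site)
  structure(list(profiles = profiles, rates = rates, site = site,
                 kinetics = p,
                 diagnostics = list(iterations = it, relative_residual = r$rel,
                                    converged = TRUE),
                 state = U),
            class = "rtm_solution")
}

#' @export
print.rtm_solution <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<rtm_solution> %s: %d cells, converged in %d iterations (residual %.2e)\n",
              x$site$name, x$profiles$grid$n_cells, d$iterations,
              d$relative_residual))
  opd <- oxygen_penetration_depth(x)
  cat("  OPD:", if (is.finite(opd)) sprintf("%.3g m", opd) else
    "beyond domain", "\n")
  invisible(x)
}
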