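#' Build a finite-volume grid
#'
#' Constructs a 1-D cell-centred finite-volume grid over \code{[0, L]}.
#' \code{node_depths} are the n cell faces (including 0 and L); the unknowns
#' live at the n-1 cell centres. With \code{refinement > 1} cell widths grow
#' geometrically with depth by that ratio per cell, concentrating resolution
#' at the sediment-water interface where gradients are steepest; the first
#' cell width is then \eqn{L (r-1) / (r^{n-1} - 1)}.
#'
#' @param L Domain length (m), > 0.
#' @param n_nodes Number of faces (>= 10).
#' @param refinement Geometric width ratio between successive cells (>= 1).
#' @return An object of class \code{sed_grid} with fields \code{node_depths}
#'   (faces), \code{z_mid} (cell centres), \code{cell_widths}, \code{n_cells}.
#' @export
#' @examples
#' g <- build_grid(1, 11)           # uniform 0.1 m cells
#' g2 <- build_grid(0.5, 10, refinement = 2)
build_grid <- function(L, n_nodes = 200, refinement = 1) {
  if (!is.numeric(L) || length(L) != 1 || L <= 0)
    stop("L must be a positive number")
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  if (refinement < 1) stop("refinement must be >= 1")
  nc <- n_nodes - 1
  if (refinement == 1) {
    faces <- seq(0, L, length.out = n_nodes)
  } else {
    r <- refinement
    # cumulative widths (r^j - 1)/(r^(nc) - 1), computed in log space so that
    # strongly refined deep domains stay monotone without overflow
    j <- 0:nc
    logr <- log(r)
    # (r^j - 1)/(r^nc - 1) = exp((j-nc) log r) * (1 - r^-j)/(1 - r^-nc)
    frac <- exp((j - nc) * logr) * (-expm1(-j * logr)) / (-expm1(-nc * logr))
    faces <- L * frac
    faces[1] <- 0
    faces[n_nodes] <- L
  }
  h <- diff(faces)
  if (any(h <= 0)) stop("degenerate grid: non-positive cell width")
  structure(list(node_depths = faces,
                 z_mid = (faces[-1] + faces[-n_nodes]) / 2,
                 cell_widths = h,
                 n_cells = nc),
            class = "sed_grid")
}

#' @export
print.sed_grid <- function(x, ...) {
  cat(sprintf("<sed_grid> %d cells on [0, %g] m; widths %.3g - %.3g m\n",
              x$n_cells, max(x$node_depths), min(x$cell_widths),
              max(x$cell_widths)))
  invisible(x)
}

#' Free-solution diffusivity of a porewater solute
#'
#' Linear-in-temperature free-solution diffusion coefficients, after the
#' standard seawater tabulations used in early-diagenesis modelling
#' (coefficients in 1e-6 cm2 s-1 per degree C, converted to m2 yr-1).
#'
#' @param species One of \code{O2, NO3, NH4, Mn, DIC}.
#' @param temperature Temperature (degrees C).
#' @return Diffusivity (m2 yr-1).
#' @export
solute_diffusivity <- function(species, temperature) {
  # m0 + m1 * t, units 1e-6 cm2/s (DIC uses the bicarbonate coefficients)
  tab <- list(O2  = c(11.70, 0.344),
              NO3 = c(9.72, 0.365),
              NH4 = c(9.76, 0.398),
              Mn  = c(3.04, 0.153),
              DIC = c(5.06, 0.275))
  if (!species %in% names(tab)) stop("unknown solute: ", species)
  co <- tab[[species]]
  (co[1] + co[2] * temperature) * 1e-6 * 1e-4 * 3.1536e7  # -> m2 yr-1
}

#' Effective sediment diffusivity
#'
#' Corrects a free-solution diffusivity for tortuosity,
#' \eqn{D_s = D_0/\theta^2} with \eqn{\theta^2 = 1 - 2\ln\phi}.
#'
#' @param D0 Free-solution diffusivity (m2 yr-1), > 0.
#' @param phi Porosity, in (0, 1]; may be a vector.
#' @return Effective diffusivity, same shape as \code{phi}.
#' @export
effective_transport <- function(D0, phi) {
  if (any(D0 <= 0)) stop("D0 must be > 0")
  if (any(phi <= 0 | phi > 1)) stop("porosity must lie in (0, 1]")
  D0 / (1 - 2 * log(phi))
}
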