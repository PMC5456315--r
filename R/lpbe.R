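## Linearized Poisson-Boltzmann on a regular grid.
##
##   div(eps(r) grad phi) - eps_out kappa^2 a(r) phi = -4 pi C rho
##
## phi in kT/e, lengths in Angstrom, charges in e.  C = e^2/(4 pi eps0
## kB T) in Angstrom (560.74 at 298.15 K), so a unit charge in a uniform
## dielectric eps gives phi = C/(eps r) kT/e.  The dielectric map is
## eps_in inside any (non-inflated) atom sphere and eps_out elsewhere;
## ions are excluded within atom radius + ion_probe.  Dirichlet boundary
## values are the sum of Debye-Hueckel monopoles.

coulomb_kt <- function(temperature = 298.15) COULOMB_KT * 298.15 / temperature

#' Inverse Debye length
#'
#' @param ionic_strength 1:1 salt concentration, mol/L.
#' @param eps_out solvent dielectric.
#' @param temperature Kelvin.
#' @return kappa in 1/Angstrom (0 for zero ionic strength).
#' @export
debye_kappa <- function(ionic_strength, eps_out = 78.4,
                        temperature = 298.15) {
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  n <- ionic_strength * 6.02214076e-4      # ions per A^3 per species
  lb <- coulomb_kt(temperature) / eps_out  # Bjerrum length, A
  sqrt(8 * pi * lb * n)
}

#' Solver parameters for the LPBE
#'
#' Defaults: protein dielectric 4, solvent dielectric 78.4, 0.15 M
#' 1:1 salt, 298.15 K, ion probe 2 A, relative-residual tolerance 1e-6.
#' None of these are prescribed by any single experimental setup; they
#' are explicit so runs are reproducible, and they are recorded in the
#' attributes of every solved grid.
#'
#' @param eps_in protein interior dielectric (> 0).
#' @param eps_out solvent dielectric (> 0).
#' @param ionic_strength mol/L (>= 0).
#' @param temperature Kelvin.
#' @param ion_probe ion-exclusion inflation added to atom radii, A.
#' @param tol convergence tolerance on the relative residual.
#' @param max_iter maximum SOR sweeps.
#' @param omega SOR relaxation factor; `NULL` chooses
#'   `2 / (1 + sin(pi / max(dims)))` automatically.
#' @return an object of class `"SolverParams"`.
#' @export
solver_params <- function(eps_in = 4.0, eps_out = 78.4,
                          ionic_strength = 0.150, temperature = 298.15,
                          ion_probe = 2.0, tol = 1e-6,
                          max_iter = 20000L, omega = NULL) {
  if (eps_in <= 0 || eps_out <= 0) stop("dielectrics must be positive")
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(eps_in = eps_in, eps_out = eps_out,
                 ionic_strength = ionic_strength,
                 temperature = temperature, ion_probe = ion_probe,
                 tol = tol, max_iter = as.integer(max_iter),
                 omega = omega),
            class = "SolverParams")
}

## Debye-Hueckel monopole superposition at arbitrary points (used for
## boundary conditions); charges: matrix [x y z q].  With nonzero
## ion-exclusion radii a_i the corrected monopole
## q e^{-kappa (d - a)} / (eps d (1 + kappa a)) is used, the exact
## solution outside an ion-excluded sphere centred on the charge.
dh_monopoles <- function(charges, points, eps, kappa,
                         temperature = 298.15, a = NULL) {
  ck <- coulomb_kt(temperature)
  if (is.null(a)) a <- rep(0, nrow(charges))
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(charges))) {
    q <- charges[i, 4]
    if (q == 0) next
    d <- sqrt((points[, 1] - charges[i, 1])^2 +
              (points[, 2] - charges[i, 2])^2 +
              (points[, 3] - charges[i, 3])^2)
    if (any(d < 1e-9)) stop("evaluation point coincides with a charge")
    out <- out + ck * q * exp(-kappa * (d - a[i])) /
      (eps * d * (1 + kappa * a[i]))
  }
  unname(out)
}

#' Analytic (screened) Coulomb reference potential
#'
#' Superposition of Debye-Hueckel monopoles
#' `phi = sum_i C q_i exp(-kappa r_i) / (eps r_i)` in kT/e: the closed-form
#' solution for point charges in a uniform dielectric, used as the
#' independent oracle for the finite-difference solver.
#'
#' @param charges matrix or data frame with columns `x`, `y`, `z`, `q`.
#' @param points n x 3 matrix of evaluation positions, Angstrom.
#' @param eps uniform dielectric (> 0).
#' @param kappa inverse Debye length, 1/Angstrom (default 0 = Coulomb).
#' @param temperature Kelvin (enters the kT/e scale).
#' @return numeric vector of potentials, kT/e.
#' @export
analytic_reference <- function(charges, points, eps, kappa = 0,
                               temperature = 298.15) {
  if (eps <= 0) stop("eps must be positive")
  charges <- as.matrix(as.data.frame(charges)[, c("x", "y", "z", "q")])
  points <- matrix(as.numeric(points), ncol = 3)
  dh_monopoles(charges, points, eps, kappa, temperature)
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Finite-difference 7-point discretization with SOR iteration; node
#' dielectric `eps_in` inside any atom sphere, `eps_out` elsewhere; ion
#' accessibility zero within atom radius + `ion_probe`; point charges
#' distributed trilinearly onto the 8 surrounding nodes; Dirichlet
#' boundary from Debye-Hueckel monopoles.  Iterates until the relative
#' residual drops below `p$tol`.
#'
#' @param s a `Structure` with charges and radii assigned.
#' @param g a [grid_spec()] enclosing `s` (>= 10 A padding recommended).
#' @param p a [solver_params()].
#' @return a `PotentialGrid` (kT/e) with attributes `iterations`,
#'   `residual` and `params`.
#' @export
solve_lpbe <- function(s, g = grid_from_structure(s), p = solver_params()) {
  a <- s$atoms
  if (nrow(a) == 0) stop("structure has no atoms")
  if (anyNA(a$radius)) stop("radii not assigned (run assign_charges first)")
  xyz <- coords(s)
  ax <- grid_axes(g)
  lo <- g$origin
  hi <- g$origin + g$spacing * (g$dims - 1)
  if (any(sweep(xyz, 2, lo) < 0) || any(sweep(xyz, 2, hi) > 0)) {
    stop("structure extends outside the grid")
  }
  pad <- min(c(apply(sweep(xyz, 2, lo), 2, min),
               apply(sweep(xyz, 2, hi, function(x, y) y - x), 2, min)))
  if (pad < 10) {
    warning(sprintf("grid padding %.1f A is below the recommended 10 A", pad))
  }
  h <- g$spacing
  n <- prod(g$dims)
  kappa <- debye_kappa(p$ionic_strength, p$eps_out, p$temperature)
  ck <- coulomb_kt(p$temperature)

  eps <- paint_spheres_cpp(rep(p$eps_out, n), g$origin, h, g$dims,
                           xyz, a$radius, p$eps_in)
  acc <- paint_spheres_cpp(rep(1, n), g$origin, h, g$dims,
                           xyz, a$radius + p$ion_probe, 0)
  kap2h2 <- (h^2 * p$eps_out * kappa^2) * acc

  ## trilinear charge spreading: h^2 * b = h^2 * 4 pi C Q_node / h^3
  src <- numeric(n)
  charged <- which(a$charge != 0)
  for (i in charged) {
    t <- (xyz[i, ] - g$origin) / h
    i0 <- pmin(pmax(floor(t), 0), g$dims - 2)
    f <- t - i0
    w <- outer(outer(c(1 - f[1], f[1]), c(1 - f[2], f[2])),
               c(1 - f[3], f[3]))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      idx <- (i0[1] + dx) + g$dims[1] * ((i0[2] + dy) +
               g$dims[2] * (i0[3] + dz)) + 1
      src[idx] <- src[idx] +
        4 * pi * ck * a$charge[i] * w[dx + 1, dy + 1, dz + 1] / h
    }
  }

  ## Dirichlet boundary: Debye-Hueckel monopoles on the 6 faces
  phi <- numeric(n)
  dims <- g$dims
  bidx <- which(slice.index(array(0, dims), 1) %in% c(1, dims[1]) |
                slice.index(array(0, dims), 2) %in% c(1, dims[2]) |
                slice.index(array(0, dims), 3) %in% c(1, dims[3]))
  if (length(charged) > 0) {
    karr <- arrayInd(bidx, dims)
    bpts <- cbind(ax[[1]][karr[, 1]], ax[[2]][karr[, 2]], ax[[3]][karr[, 3]])
    phi[bidx] <- dh_monopoles(cbind(xyz[charged, , drop = FALSE],
                                    a$charge[charged]),
                              bpts, p$eps_out, kappa, p$temperature,
                              a = a$radius[charged] + p$ion_probe)
  }

  omega <- if (is.null(p$omega)) 2 / (1 + sin(pi / max(dims))) else p$omega
  sol <- sor_lpbe_cpp(phi, eps, kap2h2, src, dims, p$tol, p$max_iter, omega)
  if (!sol$converged) {
    stop(sprintf("LPBE solver did not converge in %d iterations (relative residual %.3e)",
                 p$max_iter, sol$residual))
  }
  out <- potential_grid(g, array(sol$phi, dims))
  attr(out, "iterations") <- sol$iterations
  attr(out, "residual") <- sol$residual
  attr(out, "params") <- p
  out
}
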