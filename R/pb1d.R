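#' Debye screening length
#'
#' @param ionic_strength Symmetric monovalent ionic strength (M).
#' @param eps Relative dielectric of the solution.
#' @param temperature Temperature (K).
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(ionic_strength, eps = 80, temperature = 298.15) {
  pc <- phys_constants()
  n <- 2 * 1000 * pc$N_A * ionic_strength  # charges per m^3 (symmetric 1:1)
  sqrt(eps * pc$eps0 * pc$k_B * temperature / (n * pc$e^2)) * 1e10
}

#' Effective mobile charge density
#'
#' The reduced-potential-dependent net charge number density of a
#' symmetric monovalent electrolyte, n_eff = 2e-27 N_A I sinh(u) per
#' cubic Angstrom; this is the source term that propagates an applied
#' boundary potential through connected solvent cavities.
#'
#' @param ionic_strength Molar concentration of the symmetric monovalent
#'   mobile salt (M).
#' @param u Reduced potential (eV/kT), vectorised.
#' @return Charge number density in 1/A^3 (signed).
#' @export
n_eff <- function(ionic_strength, u) {
  2e-27 * phys_constants()$N_A * ionic_strength * sinh(u)
}

#' Planar membrane slab system for the 1D Poisson-Boltzmann equation
#'
#' Three regions along the membrane normal z: intracellular solution,
#' a low-dielectric hydrophobic slab (default 29.2 A thick, dielectric 2,
#' no mobile ions), and extracellular solution (dielectric 80). Reduced
#' boundary potentials are Dirichlet: `u_int` at the lower grid edge
#' (e.g. -1 for -25 mV at room temperature) and `u_ext = 0` at the upper
#' edge. `vestibule_top` optionally extends the intracellular boundary
#' potential up to a given z, the 1D analogue of treating a hydrated
#' cytoplasmic vestibule as a conductor.
#'
#' @param ionic_strength Symmetric monovalent ionic strength (M).
#' @param u_int,u_ext Reduced boundary potentials.
#' @param slab_thickness Hydrophobic core thickness (A).
#' @param slab_center z of the slab centre (A).
#' @param eps_solution,eps_slab Relative dielectrics.
#' @param z_range Grid range (A); must extend at least 5 Debye lengths
#'   into each bulk.
#' @param dz Grid spacing (A).
#' @param vestibule_top z up to which the region is held at `u_int`
#'   (`NULL` for none).
#' @param temperature Temperature (K).
#' @return Object of class `"slab_system"`.
#' @export
slab_system <- function(ionic_strength = 0.1, u_int = -1, u_ext = 0,
                        slab_thickness = 29.2, slab_center = 0,
                        eps_solution = 80, eps_slab = 2,
                        z_range = c(-100, 100), dz = 0.1,
                        vestibule_top = NULL, temperature = 298.15) {
  stopifnot(ionic_strength > 0, eps_solution > 0, eps_slab > 0,
            slab_thickness > 0, dz > 0)
  lam <- debye_length(ionic_strength, eps_solution, temperature)
  lo_gap <- (slab_center - slab_thickness / 2) - z_range[1]
  hi_gap <- z_range[2] - (slab_center + slab_thickness / 2)
  if (lo_gap < 5 * lam || hi_gap < 5 * lam) {
    stop(sprintf("grid must extend >= 5 Debye lengths (%.1f A) beyond the slab on each side", 5 * lam))
  }
  structure(list(ionic_strength = ionic_strength, u_int = u_int,
                 u_ext = u_ext, slab_thickness = slab_thickness,
                 slab_center = slab_center, eps_solution = eps_solution,
                 eps_slab = eps_slab, z_range = z_range, dz = dz,
                 vestibule_top = vestibule_top, temperature = temperature,
                 lambda_D = lam),
            class = "slab_system")
}

## tridiagonal solver (Thomas algorithm)
.thomas <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Solve the 1D nonlinear Poisson-Boltzmann equation
#'
#' Finite-difference solution of d/dz( eps(z) du/dz ) =
#' (eps_sol / lambda_D^2) sinh(u - u_bath) in the solution regions (no
#' source in the slab) with Dirichlet boundaries, by damped Newton
#' iteration (damping factor 0.5 with residual-based step acceptance).
#' The mobile-charge term is referenced to the local bath potential
#' (`u_int` below the slab, `u_ext` above): each electrolyte is in
#' equilibrium with its own electrode, so an applied membrane potential
#' propagates through the bulk and drops across the slab, rather than
#' being screened out at the grid boundary. Converged when the max-norm
#' residual of the discretised equation is below `tol`.
#'
#' @param system A [slab_system()].
#' @param tol Residual tolerance (default 1e-8).
#' @param max_iter Newton iteration cap.
#' @param linear If `TRUE`, solve the linearised (Debye-Huckel) equation
#'   instead (sinh(u) -> u).
#' @return Object of class `"potential_profile"`: list with `z`, `u`
#'   (reduced potential), `d` (field fraction, 0 intracellular to 1
#'   extracellular), `residual`, and the `system`.
#' @export
solve_pb_1d <- function(system, tol = 1e-8, max_iter = 200, linear = FALSE) {
  z <- seq(system$z_range[1], system$z_range[2], by = system$dz)
  n <- length(z)
  h <- system$dz
  z_half <- (z[-1] + z[-n]) / 2
  slab_lo <- system$slab_center - system$slab_thickness / 2
  slab_hi <- system$slab_center + system$slab_thickness / 2
  eps_half <- ifelse(z_half > slab_lo & z_half < slab_hi,
                     system$eps_slab, system$eps_solution)
  in_sol <- !(z > slab_lo & z < slab_hi)
  kap2 <- system$eps_solution / system$lambda_D^2
  fixed <- rep(FALSE, n)
  fixed[1] <- TRUE
  fixed[n] <- TRUE
  u <- system$u_int + (system$u_ext - system$u_int) * (z - z[1]) / (z[n] - z[1])
  u[1] <- system$u_int
  u[n] <- system$u_ext
  if (!is.null(system$vestibule_top)) {
    fixed[z <= system$vestibule_top] <- TRUE
    u[z <= system$vestibule_top] <- system$u_int
  }
  u_bath <- ifelse(z < system$slab_center, system$u_int, system$u_ext)
  src <- function(u) if (linear) (u - u_bath) else sinh(u - u_bath)
  dsrc <- function(u) if (linear) rep(1, length(u)) else cosh(u - u_bath)

  resid_fun <- function(u) {
    r <- numeric(n)
    i <- 2:(n - 1)
    r[i] <- (eps_half[i] * (u[i + 1] - u[i]) -
             eps_half[i - 1] * (u[i] - u[i - 1])) / h^2 -
      kap2 * ifelse(in_sol[i], src(u)[i], 0)
    r[fixed] <- 0
    r
  }

  r <- resid_fun(u)
  for (iter in seq_len(max_iter)) {
    rn <- max(abs(r))
    if (rn < tol) break
    ## tridiagonal Jacobian of the residual
    lower <- c(0, eps_half / h^2)
    upper <- c(eps_half / h^2, 0)
    dg <- numeric(n)
    i <- 2:(n - 1)
    dv <- dsrc(u)
    dg[i] <- -(eps_half[i] + eps_half[i - 1]) / h^2 -
      kap2 * ifelse(in_sol[i], dv[i], 0)
    lower[fixed] <- 0
    upper[fixed] <- 0
    dg[fixed] <- 1
    du <- .thomas(lower, dg, upper, -r)
    step <- 1
    repeat {
      u_try <- u + step * du
      r_try <- resid_fun(u_try)
      if (max(abs(r_try)) < rn || step < 1e-6) break
      step <- step * 0.5
    }
    u <- u + step * du
    r <- resid_fun(u)
  }
  if (max(abs(r)) >= tol) {
    stop(sprintf("PB iteration did not converge (residual %.3g)", max(abs(r))))
  }
  denom <- system$u_ext - system$u_int
  d <- if (abs(denom) > 0) (u - system$u_int) / denom else rep(NA_real_, n)
  structure(list(z = z, u = u, d = d, residual = max(abs(r)),
                 system = system),
            class = "potential_profile")
}

#' @export
print.potential_profile <- function(x, ...) {
  cat("potential_profile:", length(x$z), "nodes, residual",
      format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Field fraction (electrical distance) at a position
#'
#' d(z) = (u(z) - u_int)/(u_ext - u_int): 0 in the intracellular bulk,
#' 1 in the extracellular bulk, monotone across the slab for this planar
#' geometry.
#'
#' @param profile A [solve_pb_1d()] result.
#' @param z_site Position(s) along the membrane normal (A), inside the grid.
#' @return Field fraction(s) in [0, 1].
#' @export
field_fraction <- function(profile, z_site) {
  if (any(z_site < min(profile$z) | z_site > max(profile$z))) {
    stop("site outside the solved grid")
  }
  stats::approx(profile$z, profile$d, xout = z_site)$y
}

#' Screened-Coulomb Ca2+ perturbation of the Cl- energy profile
#'
#' Approximates the electrostatic contribution of bound Ca2+ ions to the
#' Cl- free-energy profile as a Debye-screened Coulomb interaction,
#' dG(s) = sum_Ca [z_Cl z_Ca e^2 / (4 pi eps0 eps_eff r)] exp(-r/lambda_D)
#' in kT, with r the distance from each path node to each Ca2+ position.
#' Subtracting this from a doubly bound profile gives approximate 1-Ca /
#' 0-Ca profiles. This is a deliberately simple stand-in for a full 3D
#' continuum calculation; see the methods vignette.
#'
#' @param path A path object ([straight_path()] / [pathway_spline()]).
#' @param ca_positions Matrix (n x 3) of Ca2+ coordinates (A).
#' @param lambda_D Debye length (A), > 0.
#' @param eps_eff Effective dielectric, > 0.
#' @param z_cl,z_ca Valences (defaults -1 and +2).
#' @param temperature Temperature (K).
#' @return A [profile_1d()] in kT per unit Cl- charge.
#' @export
ca_perturbation_profile <- function(path, ca_positions, lambda_D,
                                    eps_eff = 40, z_cl = -1, z_ca = 2,
                                    temperature = 298.15) {
  stopifnot(lambda_D > 0, eps_eff > 0)
  ca_positions <- matrix(ca_positions, ncol = 3)
  pc <- phys_constants()
  ## e^2/(4 pi eps0) in J.m -> kT.A
  coul_kT_A <- pc$e^2 / (4 * pi * pc$eps0) /
    (pc$k_B * temperature) * 1e10
  dg <- numeric(nrow(path$nodes))
  for (k in seq_len(nrow(ca_positions))) {
    r <- sqrt(rowSums(sweep(path$nodes, 2, ca_positions[k, ])^2))
    if (any(r < 1e-6)) stop("a Ca2+ position coincides with a path node")
    dg <- dg + z_cl * z_ca * coul_kT_A / (eps_eff * r) * exp(-r / lambda_D)
  }
  spacing <- if (nrow(path$nodes) > 1) path$s[2] - path$s[1] else 1
  profile_1d(s = path$s, value = dg, bin = spacing, unit = "kT")
}
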