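#' Brownian-dynamics configuration
#'
#' Parameters of the overdamped Langevin generator of ion/water motion in a
#' model cylindrical pore. Defaults describe a dilute chloride system:
#' bulk-like diffusion, an ion diameter of 3.6 A for the hard-sphere
#' exclusion, and a 90 A periodic box with a 4 A-radius cylinder.
#'
#' @param n_ions Number of ions.
#' @param n_waters Number of tracer waters (force-free).
#' @param z_charge Ion valence (-1 for Cl-).
#' @param D Diffusion coefficient (A^2/ns).
#' @param dt Timestep (ns).
#' @param n_steps Number of steps.
#' @param stride Save every `stride` steps.
#' @param pore_radius Cylinder radius (A). The cylinder has this radius
#'   over the whole box so that the 1D Boltzmann density oracle is exact
#'   (no cross-section correction between pore and bulk).
#' @param box_height Periodic box height (A).
#' @param voltage Transmembrane voltage V = phi_in - phi_out (mV), applied
#'   as a linear potential ramp across the pore region of the landscape;
#'   both bulk slabs are isopotential.
#' @param exclusion_radius Centre-to-centre hard-sphere distance between
#'   ions (A); 0 disables ion-ion interactions (independent tracers).
#' @param temperature Temperature (K), used to reduce the voltage.
#' @param seed Integer master seed; per-particle streams are derived from
#'   it by fixed offsets.
#' @return Object of class `"bd_config"` (a validated list).
#' @export
bd_config <- function(n_ions = 8, n_waters = 20, z_charge = -1,
                      D = 200, dt = 0.0025, n_steps = 1e6, stride = 5,
                      pore_radius = 4, box_height = 90, voltage = 0,
                      exclusion_radius = 3.6, temperature = 303.15,
                      seed = 1) {
  stopifnot(n_ions >= 0, n_waters >= 0, n_ions + n_waters >= 1,
            D > 0, dt > 0, n_steps >= 1, stride >= 1,
            pore_radius > 0, box_height > 0, exclusion_radius >= 0)
  structure(
    list(n_ions = as.integer(n_ions), n_waters = as.integer(n_waters),
         z_charge = z_charge, D = D, dt = dt,
         n_steps = as.integer(n_steps), stride = as.integer(stride),
         pore_radius = pore_radius, box_height = box_height,
         voltage = voltage, exclusion_radius = exclusion_radius,
         temperature = temperature, seed = as.integer(seed)),
    class = "bd_config"
  )
}

#' Simulate Brownian dynamics in a pore landscape
#'
#' Runs overdamped (position) Langevin dynamics of `n_ions` ions and
#' `n_waters` tracer waters in the cylindrical pore: per axis
#' x <- x - beta D grad(U) dt + sqrt(2 D dt) eta, with
#' U(s) = kT G(s) + z e phi_V(s), where phi_V is the linear voltage ramp
#' across the pore region. The z axis is periodic (ions recirculate, which
#' sustains a steady current under voltage); the cylinder wall reflects.
#' Construction fails if the per-step RMS displacement exceeds a quarter of
#' the narrowest barrier width (the smallest landscape knot spacing).
#'
#' @param landscape A [pore_landscape()].
#' @param cfg A [bd_config()].
#' @return A [trajectory()] whose ions are labelled `ion:Cl` (`z_charge`
#'   -1), `ion:K` (+1) or `ion:Ca` (+2) and waters `water`. Attributes:
#'   `unwrapped_z` (matrix frames x particles of unwrapped z, for drift
#'   diagnostics), `config`, `landscape`.
#' @export
simulate_pore <- function(landscape, cfg) {
  stopifnot(inherits(landscape, "pore_landscape"), inherits(cfg, "bd_config"))
  rms <- sqrt(2 * cfg$D * cfg$dt)
  min_width <- min(diff(landscape$s_knots))
  if (rms >= 0.25 * min_width) {
    stop(sprintf(paste0("per-step RMS displacement %.3f A exceeds 0.25 x ",
                        "minimum barrier width (%.3f A); reduce dt or D"),
                 rms, 0.25 * min_width))
  }
  u_volt <- cfg$voltage / thermal_voltage_mV(cfg$temperature)
  half <- cfg$box_height / 2
  grid_s <- seq(-half, half, by = 0.05)
  grid_force <- -landscape_energy(landscape, grid_s, deriv = 1)
  res <- bd_simulate_cpp(grid_force, -half, 0.05,
                         landscape$s_lo, landscape$s_hi, u_volt,
                         cfg$z_charge, cfg$n_ions, cfg$n_waters,
                         cfg$D, cfg$dt, cfg$n_steps, cfg$stride,
                         cfg$pore_radius, cfg$box_height,
                         cfg$exclusion_radius, cfg$seed)
  np <- cfg$n_ions + cfg$n_waters
  nf <- nrow(res$z)
  times <- (seq_len(nf) - 1) * cfg$dt * cfg$stride
  ion_species <- switch(as.character(cfg$z_charge),
                        "-1" = "ion:Cl", "1" = "ion:K", "2" = "ion:Ca",
                        "ion:Cl")
  species <- c(rep(ion_species, cfg$n_ions), rep("water", cfg$n_waters))
  parts <- data.frame(
    time_ns = rep(times, each = np),
    id = rep(seq_len(np), nf),
    species = rep(species, nf),
    x = as.vector(t(res$x)),
    y = as.vector(t(res$y)),
    z = as.vector(t(res$z)),
    stringsAsFactors = FALSE
  )
  traj <- trajectory(parts, box = c(2 * cfg$pore_radius, 2 * cfg$pore_radius,
                                    cfg$box_height))
  attr(traj, "unwrapped_z") <- res$z_unwrapped
  attr(traj, "config") <- cfg
  attr(traj, "landscape") <- landscape
  traj
}

#' Analytic equilibrium density along the pore
#'
#' Boltzmann density rho(s) proportional to exp(-G(s) - z u (1 - d(s)))
#' where d(s) is the fractional position of the voltage ramp (0 at the
#' intracellular boundary, 1 at the extracellular one), normalised to the
#' extracellular bulk value. At V = 0 this is the exact long-run density of
#' [simulate_pore()] in the non-interacting limit and serves as the oracle
#' for free-energy recovery.
#'
#' @param landscape A [pore_landscape()].
#' @param cfg A [bd_config()] (supplies voltage, valence, temperature and
#'   the box extent).
#' @param bin Bin width in A for the returned grid.
#' @return A [profile_1d()] with relative density values.
#' @export
equilibrium_density <- function(landscape, cfg, bin = 0.5) {
  half <- cfg$box_height / 2
  s <- seq(-half + bin / 2, half - bin / 2, by = bin)
  u_volt <- cfg$voltage / thermal_voltage_mV(cfg$temperature)
  d <- pmin(pmax((s - landscape$s_lo) / (landscape$s_hi - landscape$s_lo), 0), 1)
  U <- landscape_energy(landscape, s) + cfg$z_charge * u_volt * (1 - d)
  profile_1d(s = s, value = exp(-U), bin = bin,
             unit = "relative density")
}
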