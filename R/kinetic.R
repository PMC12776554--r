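#' The 7-state occupancy space of a 3-site pore
#'
#' All occupancies of sites {A, B, C} with at most two ions present.
#'
#' @return List of 7 character vectors (the occupied sites of each state),
#'   in the fixed order {}, A, B, C, AB, AC, BC.
#' @export
occupancy_states <- function() {
  list(character(0), "A", "B", "C", c("A", "B"), c("A", "C"), c("B", "C"))
}

.state_labels <- c("empty", "A", "B", "C", "AB", "AC", "BC")

#' Kinetic rate specification for the 3-site permeation model
#'
#' Sites C (inner), B (central), A (outer) with energies in kT, the four
#' barrier tops between them and the bulks, electrical distances d in [0,1]
#' (fraction of the membrane voltage dropped between the intracellular bulk
#' and the position; d = 0 intracellular, d = 1 extracellular), a shared
#' Eyring-like attempt prefactor k0, bulk concentrations, and the membrane
#' voltage. Transition rates are
#' k = k0 exp(-(G_barrier - G_origin + z u (d_origin - d_barrier))) with
#' u = eV/kT and V = phi_in - phi_out (so positive voltage pulls the anion
#' inward), entry rates additionally scaled by c_bulk/c_ref.
#'
#' @param site_energies Named numeric `C`, `B`, `A` (kT).
#' @param barrier_energies Named numeric over the edges `bulk_int-C`,
#'   `C-B`, `B-A`, `A-bulk_ext` (kT, barrier tops).
#' @param d_sites Named numeric `C`, `B`, `A` in (0,1), monotone.
#' @param d_barriers Named numeric over the four edges, interleaving the
#'   site electrical distances.
#' @param k0 Attempt prefactor (1/ns).
#' @param c_int,c_ext Bulk Cl- concentrations (mM).
#' @param c_ref Reference concentration (mM) at which entry rates equal
#'   k0 exp(-barrier).
#' @param voltage Membrane voltage (mV).
#' @param z_charge Permeant valence (-1 for Cl-).
#' @param G_int Pairwise ion-ion interaction energy added to
#'   doubly-occupied states (kT, default 0).
#' @param temperature Temperature (K).
#' @return Object of class `"rate_spec"`.
#' @export
rate_spec <- function(site_energies, barrier_energies, d_sites, d_barriers,
                      k0 = 1, c_int = 150, c_ext = 150, c_ref = 150,
                      voltage = 0, z_charge = -1, G_int = 0,
                      temperature = 303.15) {
  site_energies <- site_energies[c("C", "B", "A")]
  edge_names <- c("bulk_int-C", "C-B", "B-A", "A-bulk_ext")
  barrier_energies <- barrier_energies[edge_names]
  d_sites <- d_sites[c("C", "B", "A")]
  d_barriers <- d_barriers[edge_names]
  if (anyNA(c(site_energies, barrier_energies, d_sites, d_barriers))) {
    stop("incomplete site/barrier specification")
  }
  d_seq <- c(0, d_barriers[1], d_sites["C"], d_barriers[2], d_sites["B"],
             d_barriers[3], d_sites["A"], d_barriers[4], 1)
  if (any(diff(d_seq) < 0)) {
    stop("electrical distances must be monotone from intracellular (0) to ",
         "extracellular (1)")
  }
  stopifnot(k0 > 0, c_int > 0, c_ext > 0, c_ref > 0)
  structure(list(site_energies = site_energies,
                 barrier_energies = barrier_energies,
                 d_sites = d_sites, d_barriers = d_barriers, k0 = k0,
                 c_int = c_int, c_ext = c_ext, c_ref = c_ref,
                 voltage = voltage, z_charge = z_charge, G_int = G_int,
                 temperature = temperature),
            class = "rate_spec")
}

#' Build a rate spec from a pore landscape
#'
#' Site and barrier energies are read off the landscape; electrical
#' distances default to the geometric fractions
#' d(s) = (s - s_lo)/(s_hi - s_lo) (linear constant-field drop across the
#' pore region), or are supplied via `d_of_s` (e.g. a field-fraction
#' function derived from [solve_pb_1d()]).
#'
#' @param landscape A [pore_landscape()].
#' @param d_of_s Optional function mapping s (A) to electrical distance.
#' @param ... Passed to [rate_spec()] (k0, concentrations, voltage, ...).
#' @return A [rate_spec()].
#' @export
rate_spec_from_landscape <- function(landscape, d_of_s = NULL, ...) {
  if (is.null(d_of_s)) {
    d_of_s <- function(s) {
      pmin(pmax((s - landscape$s_lo) / (landscape$s_hi - landscape$s_lo),
                0), 1)
    }
  }
  rate_spec(
    site_energies = landscape$site_energies,
    barrier_energies = stats::setNames(landscape$barriers$G,
                                       landscape$barriers$name),
    d_sites = vapply(landscape$sites, d_of_s, numeric(1)),
    d_barriers = stats::setNames(vapply(landscape$barriers$s, d_of_s,
                                        numeric(1)),
                                 landscape$barriers$name),
    ...)
}

## enumerate the single-ion moves between the 7 states
.kinetic_edges <- function() {
  ## from, to (state index), moving ion goes site_from -> site_to over
  ## `barrier`; bulk endpoints are "bulk_int"/"bulk_ext"
  e <- rbind(
    data.frame(from = 1, to = 2, site_from = "bulk_ext", site_to = "A",
               barrier = "A-bulk_ext"),
    data.frame(from = 3, to = 5, site_from = "bulk_ext", site_to = "A",
               barrier = "A-bulk_ext"),
    data.frame(from = 4, to = 6, site_from = "bulk_ext", site_to = "A",
               barrier = "A-bulk_ext"),
    data.frame(from = 1, to = 4, site_from = "bulk_int", site_to = "C",
               barrier = "bulk_int-C"),
    data.frame(from = 2, to = 6, site_from = "bulk_int", site_to = "C",
               barrier = "bulk_int-C"),
    data.frame(from = 3, to = 7, site_from = "bulk_int", site_to = "C",
               barrier = "bulk_int-C"),
    data.frame(from = 2, to = 3, site_from = "A", site_to = "B",
               barrier = "B-A"),
    data.frame(from = 6, to = 7, site_from = "A", site_to = "B",
               barrier = "B-A"),
    data.frame(from = 3, to = 4, site_from = "B", site_to = "C",
               barrier = "C-B"),
    data.frame(from = 5, to = 6, site_from = "B", site_to = "C",
               barrier = "C-B")
  )
  e
}

.site_G <- function(spec, site) {
  switch(site,
         bulk_int = 0, bulk_ext = 0,
         spec$site_energies[[site]])
}

.site_volt <- function(spec, site, u) {
  d <- switch(site, bulk_int = 0, bulk_ext = 1, spec$d_sites[[site]])
  ## energy of the permeant charge: z u (1 - d); phi = V at the
  ## intracellular side, 0 extracellular
  spec$z_charge * u * (1 - d)
}

#' Build the 7-state generator matrix
#'
#' Returns the master-equation generator Q (columns sum to zero;
#' `Q[j, i]` is the rate from state i to state j). Rates obey detailed
#' balance with respect to the state energies, concentration terms for
#' entry/exit, and the voltage partitioned by electrical distance; an
#' internal assertion verifies detailed balance edge by edge at V = 0 with
#' equal concentrations.
#'
#' @param spec A [rate_spec()].
#' @return 7 x 7 matrix with attribute `"edges"` (the per-edge rate table
#'   used for flux readouts).
#' @export
build_rate_matrix <- function(spec) {
  u <- spec$voltage / thermal_voltage_mV(spec$temperature)
  states <- occupancy_states()
  edges <- .kinetic_edges()
  n_e <- nrow(edges)
  k_fwd <- numeric(n_e)
  k_rev <- numeric(n_e)
  for (i in seq_len(n_e)) {
    sf <- edges$site_from[i]
    st <- edges$site_to[i]
    spectators <- setdiff(states[[edges$to[i]]], st)
    n_total <- length(spectators) + 1
    gint_ts <- if (n_total >= 2) spec$G_int else 0
    gint_pore <- function(site, n_in_pore) {
      if (site %in% c("bulk_int", "bulk_ext")) 0
      else if (n_in_pore >= 2) spec$G_int else 0
    }
    e_barrier <- spec$barrier_energies[[edges$barrier[i]]] +
      spec$z_charge * u * (1 - spec$d_barriers[[edges$barrier[i]]]) + gint_ts
    e_from <- .site_G(spec, sf) + .site_volt(spec, sf, u) +
      gint_pore(sf, n_total)
    e_to <- .site_G(spec, st) + .site_volt(spec, st, u) +
      gint_pore(st, n_total)
    conc_f <- switch(sf, bulk_int = spec$c_int / spec$c_ref,
                     bulk_ext = spec$c_ext / spec$c_ref, 1)
    conc_r <- switch(st, bulk_int = spec$c_int / spec$c_ref,
                     bulk_ext = spec$c_ext / spec$c_ref, 1)
    k_fwd[i] <- spec$k0 * conc_f * exp(-(e_barrier - e_from))
    k_rev[i] <- spec$k0 * conc_r * exp(-(e_barrier - e_to))
  }
  Q <- matrix(0, 7, 7, dimnames = list(.state_labels, .state_labels))
  for (i in seq_len(n_e)) {
    Q[edges$to[i], edges$from[i]] <- Q[edges$to[i], edges$from[i]] + k_fwd[i]
    Q[edges$from[i], edges$to[i]] <- Q[edges$from[i], edges$to[i]] + k_rev[i]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  edges$k_fwd <- k_fwd
  edges$k_rev <- k_rev
  attr(Q, "edges") <- edges
  Q
}

#' Steady-state distribution of a generator
#'
#' @param Q Generator matrix (columns sum to zero) from
#'   [build_rate_matrix()].
#' @return Probability vector p with Q p = 0, nonnegative, summing to 1.
#' @export
steady_state <- function(Q) {
  n <- nrow(Q)
  A <- Q
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- tryCatch(solve(A, b),
                error = function(e) stop("reducible or singular generator"))
  if (any(p < -1e-9)) stop("negative steady-state probability; generator ",
                           "is not irreducible")
  p <- pmax(p, 0)
  p / sum(p)
  }

## net outward ion flux (1/ns) across the three cuts; they must agree
.cut_fluxes <- function(Q, p) {
  edges <- attr(Q, "edges")
  ## int cut: an entry bulk_int -> C crosses the cytoplasmic boundary
  ## moving towards the extracellular side, i.e. outward
  ent <- edges$site_from == "bulk_int"
  j_int <- sum(edges$k_fwd[ent] * p[edges$from[ent]]) -
    sum(edges$k_rev[ent] * p[edges$to[ent]])
  ## B-C cut: forward C-B hops are stored as B -> C (inward); negate
  hop_bc <- edges$barrier == "C-B"
  j_bc <- -(sum(edges$k_fwd[hop_bc] * p[edges$from[hop_bc]]) -
            sum(edges$k_rev[hop_bc] * p[edges$to[hop_bc]]))
  ## ext cut: entries bulk_ext -> A cross inward
  exte <- edges$site_from == "bulk_ext"
  j_ext <- -(sum(edges$k_fwd[exte] * p[edges$from[exte]]) -
             sum(edges$k_rev[exte] * p[edges$to[exte]]))
  c(int = j_int, BC = j_bc, ext = j_ext)
}

#' Single-channel current of the kinetic model
#'
#' Solves the steady state and reads the net probability flux across the
#' B-C bond (the int and ext bulk cuts are asserted to agree - flux
#' conservation makes the cut choice irrelevant). The current is
#' I = z e J_outward, so that I and V share sign for a passive pore.
#'
#' @param spec A [rate_spec()].
#' @param voltage Optional voltage (mV) overriding `spec$voltage`.
#' @return Current in pA.
#' @export
single_channel_current <- function(spec, voltage = NULL) {
  if (!is.null(voltage)) spec$voltage <- voltage
  Q <- build_rate_matrix(spec)
  p <- steady_state(Q)
  j <- .cut_fluxes(Q, p)
  scale <- max(abs(j), spec$k0 * 1e-6)
  if (max(abs(j - mean(j))) > 1e-8 * scale) {
    stop("flux not conserved across cuts (internal error)")
  }
  spec$z_charge * .e_charge_pA_ns * mean(j)
}

#' Model I-V curve over a voltage grid
#'
#' @param spec A [rate_spec()].
#' @param V Voltages (mV).
#' @return data.frame with `V` and `I` (pA).
#' @export
model_iv <- function(spec, V) {
  data.frame(V = V,
             I = vapply(V, function(v) single_channel_current(spec, v),
                        numeric(1)))
}

#' Calibrate the attempt prefactor to a target conductance
#'
#' The current is exactly linear in k0, so scaling k0 by
#' target/g(current k0) matches the small-voltage slope conductance
#' exactly.
#'
#' @param spec A [rate_spec()].
#' @param target_g_pS Target slope conductance at V -> 0 (pS), > 0.
#' @param dV Half-width of the finite-difference voltage (mV).
#' @return The calibrated k0 (1/ns).
#' @export
calibrate_prefactor <- function(spec, target_g_pS, dV = 1) {
  stopifnot(target_g_pS > 0)
  slope <- (single_channel_current(spec, dV) -
            single_channel_current(spec, -dV)) / (2 * dV) * 1000
  if (abs(slope) < .Machine$double.xmin * 1e10 || slope <= 0) {
    stop("zero or negative small-voltage slope; cannot calibrate")
  }
  spec$k0 * target_g_pS / slope
}

#' Voltage-dependent sequential Ca2+ gating specification
#'
#' Two sequential Ca2+ binding steps from the apo (closed) state: the
#' upper site binds first (energy E1, field fraction delta1), then the
#' lower site (E2, delta2). Each bound Ca2+ (valence +2), entering from
#' the intracellular side, gains -2 delta u kT at reduced voltage
#' u = eV/kT, making binding depolarization-favoured when
#' delta1 + delta2 > 0. Default E1/E2/delta values are calibrated so that
#' the doubly bound probability at 10 uM Ca2+ stays above 80% across
#' +/-150 mV while sub-uM Ca2+ leaves the channel shut at negative
#' voltages; they are representative, not experimentally fitted.
#'
#' @param E1,E2 Binding energies (kT) of the upper and lower sites at the
#'   reference concentration.
#' @param delta1,delta2 Field fractions experienced by the upper and lower
#'   Ca2+.
#' @param c_ref Reference Ca2+ concentration (M, default 1e-6).
#' @param temperature Temperature (K).
#' @return Object of class `"ca_gating_spec"`.
#' @export
ca_gating_spec <- function(E1 = 1.5, E2 = -2.5, delta1 = 0.15,
                           delta2 = 0.05, c_ref = 1e-6,
                           temperature = 303.15) {
  structure(list(E1 = E1, E2 = E2, delta1 = delta1, delta2 = delta2,
                 z_ca = 2, c_ref = c_ref, temperature = temperature),
            class = "ca_gating_spec")
}

#' Ca2+ occupancy probabilities (P0, P1, P2)
#'
#' Sequential-binding partition: w0 = 1,
#' w1 = (ca/c_ref) exp(-E1 + 2 delta1 u),
#' w2 = w1 (ca/c_ref) exp(-E2 + 2 delta2 u), Pi = wi / sum(w).
#'
#' @param gating A [ca_gating_spec()].
#' @param voltage Membrane voltage (mV); vectorised.
#' @param ca Intracellular Ca2+ concentration (M), >= 0.
#' @return data.frame with `V`, `P0`, `P1`, `P2` (rows sum to 1).
#' @export
ca_state_probabilities <- function(gating, voltage, ca) {
  stopifnot(ca >= 0)
  u <- voltage / thermal_voltage_mV(gating$temperature)
  r <- ca / gating$c_ref
  w0 <- rep(1, length(u))
  w1 <- r * exp(-gating$E1 + 2 * gating$delta1 * u)
  w2 <- w1 * r * exp(-gating$E2 + 2 * gating$delta2 * u)
  tot <- w0 + w1 + w2
  data.frame(V = voltage, P0 = w0 / tot, P1 = w1 / tot, P2 = w2 / tot)
}

#' Ensemble I-V curve under Ca2+ gating
#'
#' Mixes the conduction states by their Ca2+-occupancy probabilities:
#' I(V) = P1(V) I_1Ca(V) + P2(V) I_2Ca(V); the Ca2+-free state is
#' non-conductive.
#'
#' @param gating A [ca_gating_spec()].
#' @param spec_1ca,spec_2ca [rate_spec()] objects for the singly and doubly
#'   Ca2+-bound conduction landscapes.
#' @param V Voltage grid (mV).
#' @param ca Intracellular Ca2+ concentration (M).
#' @return data.frame with `V`, `I` (ensemble, pA), `I1`, `I2`, `P0`,
#'   `P1`, `P2`.
#' @export
ensemble_iv <- function(gating, spec_1ca, spec_2ca, V, ca) {
  pr <- ca_state_probabilities(gating, V, ca)
  I1 <- vapply(V, function(v) single_channel_current(spec_1ca, v), numeric(1))
  I2 <- vapply(V, function(v) single_channel_current(spec_2ca, v), numeric(1))
  data.frame(V = V, I = pr$P1 * I1 + pr$P2 * I2, I1 = I1, I2 = I2,
             P0 = pr$P0, P1 = pr$P1, P2 = pr$P2)
}

#' Kinetic-model presets
#'
#' `"paper2Ca"` / `"paper1Ca"` rate specs built from the corresponding
#' [landscape_preset()] with geometric electrical distances. By default the
#' shared prefactor k0 is calibrated so the doubly bound model has the
#' reference 4.4 pS small-voltage slope conductance (both conduction
#' states are assumed to share k0).
#'
#' @param name Preset name.
#' @param calibrate_to Target conductance (pS) for the 2-Ca model, or
#'   `NULL` to keep `k0 = 1`.
#' @param ... Further arguments to [rate_spec_from_landscape()].
#' @return A [rate_spec()].
#' @export
kinetic_preset <- function(name = c("paper2Ca", "paper1Ca"),
                           calibrate_to = 4.4, ...) {
  name <- match.arg(name)
  spec <- rate_spec_from_landscape(landscape_preset(name), ...)
  if (!is.null(calibrate_to)) {
    ref <- rate_spec_from_landscape(landscape_preset("paper2Ca"), ...)
    spec$k0 <- calibrate_prefactor(ref, calibrate_to)
  }
  spec
}
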