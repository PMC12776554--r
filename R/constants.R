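#' Physical constants (CODATA)
#'
#' Returns the fixed set of physical constants used throughout the package.
#' All energies elsewhere are expressed in thermal units (kT) unless a
#' function name or argument says otherwise; coordinates are in Angstrom,
#' time in ns, voltages in mV and currents in pA.
#'
#' @return A named list with elements `e` (elementary charge, C), `k_B`
#'   (Boltzmann constant, J/K), `N_A` (Avogadro number, 1/mol), `F`
#'   (Faraday constant, C/mol), `R` (molar gas constant, J/mol/K) and
#'   `eps0` (vacuum permittivity, F/m).
#' @examples
#' phys_constants()$e
#' @export
phys_constants <- function() {
  list(
    e    = 1.602176634e-19,
    k_B  = 1.380649e-23,
    N_A  = 6.02214076e23,
    F    = 96485.33212,
    R    = 8.31446261815324,
    eps0 = 8.8541878128e-12
  )
}

#' Thermal energy kT
#'
#' @param temperature Temperature in K (default 303.15, the simulation
#'   temperature used throughout).
#' @param unit `"J"` for Joule, `"kcal_mol"` for kcal/mol.
#' @return kT in the requested unit.
#' @examples
#' kt_energy(303.15, "kcal_mol")  # ~0.6024
#' @export
kt_energy <- function(temperature = 303.15, unit = c("J", "kcal_mol")) {
  unit <- match.arg(unit)
  pc <- phys_constants()
  kT <- pc$k_B * temperature
  switch(unit,
    J = kT,
    kcal_mol = kT * pc$N_A / 4184
  )
}

#' Convert an energy in kT to kcal/mol
#'
#' @param x Energy in thermal units (kT).
#' @param temperature Temperature in K.
#' @return Energy in kcal/mol.
#' @examples
#' kt_to_kcal(5.5)  # ~3.3 kcal/mol at 303.15 K
#' @export
kt_to_kcal <- function(x, temperature = 303.15) {
  x * kt_energy(temperature, "kcal_mol")
}

#' Convert kcal/mol to kT
#' @param x Energy in kcal/mol.
#' @param temperature Temperature in K.
#' @return Energy in kT.
#' @export
kcal_to_kt <- function(x, temperature = 303.15) {
  x / kt_energy(temperature, "kcal_mol")
}

#' Thermal voltage kT/e in mV
#'
#' The voltage for which an elementary charge gains one kT; used to reduce
#' membrane voltages to dimensionless form u = eV/kT.
#'
#' @param temperature Temperature in K.
#' @return kT/e in mV.
#' @export
thermal_voltage_mV <- function(temperature = 303.15) {
  pc <- phys_constants()
  1e3 * pc$k_B * temperature / pc$e
}

#' Aggregate simulated subunit time
#'
#' Bookkeeping helper for simulation campaigns of homodimeric channels:
#' total per-subunit sampling equals replicates x starting models x length
#' x subunits per assembly.
#'
#' @param n_replicates Independent replicates per model.
#' @param n_models Number of starting models.
#' @param t_us Length of each run in microseconds.
#' @param n_subunits Subunits per assembly (2 for a dimer).
#' @return Total subunit time in microseconds.
#' @examples
#' total_subunit_time(3, 4, 1, 2)  # 24 us
#' @export
total_subunit_time <- function(n_replicates, n_models, t_us, n_subunits = 2) {
  n_replicates * n_models * t_us * n_subunits
}
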