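---
title: "Methods: pore profiling, permeation counting, and the kinetic conduction model"
author: "porekinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore profiling, permeation counting, and the kinetic conduction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porekinetics)
```

`porekinetics` implements the quantitative workflow used to characterise
conductive states of anion channels such as TMEM16A, the Ca$^{2+}$-activated
chloride channel: profiling ion and water density along the pore, counting
complete permeation events and converting them to currents and conductances,
and a master-equation model of multi-ion conduction coupled to
voltage-dependent Ca$^{2+}$ gating that reproduces the switch between
outwardly rectifying and Ohmic current–voltage behaviour. Because raw
molecular-dynamics trajectories of a real channel are large and rarely
redistributable, the package includes a Brownian-dynamics (BD) generator
that emulates the statistical structure of such data in a model cylindrical
pore; every analysis function runs identically on real trajectories (PDB +
DCD, or the documented CSV dialect) and on the synthetic ones.

## Conventions

Coordinates are in Å and time in ns; energies are in thermal units (kT)
unless a name says otherwise; voltages are in mV and currents in pA. The
z axis is the membrane normal with positive z pointing extracellular, and
the membrane voltage is $V = \phi_{in} - \phi_{out}$, so a positive
(depolarising) voltage pulls anions inward and carries positive (outward)
current. The default temperature is 303.15 K, where
$kT = `r round(kt_energy(303.15, "kcal_mol"), 4)`$ kcal/mol; continuum
electrostatics defaults to 298.15 K, matching common practice for such
calculations.

## The model pore landscape

A `pore_landscape` is a one-dimensional free-energy profile $G(s)$ built
from three ion-binding sites — A (outer), B (central), C (inner) — and the
four barriers separating them from each other and from the bulks, with
$G \equiv 0$ outside the pore region. A natural cubic spline through the
site minima and barrier maxima gives a continuous, differentiable curve.

The preset `"paper2Ca"` encodes the doubly Ca$^{2+}$-bound conduction
landscape: sites A and B level with solution, site C stabilised at
$-2.5\,kT$, a $\sim 2\,kT$ barrier between A and B, and the two dominant
barriers flanking site C at $+3.5\,kT$, so the climb out of C is $6\,kT$
on both sides — the cytoplasmic entrance barrier is $3.5\,kT$ as seen
from bulk. The preset `"paper1Ca"` encodes the electrostatic consequence
of removing the lower (cytoplasmic) Ca$^{2+}$: site C destabilised by
$4\,kT$ (the middle of the reported 3–5 kT range) and both flanking
barriers raised by $2\,kT$, with A and B essentially unchanged. Sites sit
at $s = -10, 0, +10$ Å with barriers midway and bulk boundaries at
$\pm 20$ Å; these positions are geometric choices of the synthetic pore
(a real pathway would supply its own).

## The Brownian-dynamics generator

`simulate_pore()` evolves point ions and tracer waters by overdamped
(position) Langevin dynamics,
$$x \leftarrow x - \beta D\, \nabla U\, dt + \sqrt{2 D\, dt}\,\eta,$$
with $U(s) = kT\,G(s) + z e\,\phi_V(s)$ and $\phi_V$ a linear voltage ramp
across the pore region (the 1D analogue of the constant-field protocol;
the bulk slabs are isopotential, so electrical distances equal geometric
fractions and closed-form oracles exist). Design choices worth knowing:

* **Integrator.** The driven axis uses the Leimkuhler–Matthews update
  (averaging successive Gaussian variates), which has far smaller
  finite-step-size bias in the sampled configurational distribution than
  plain Euler–Maruyama; with the default $D = 200$ Å$^2$/ns (bulk-like
  chloride diffusion) and $dt = 0.0025$ ns, the long-run density of the
  `paper2Ca` preset matches the analytic Boltzmann profile to a
  Kolmogorov–Smirnov distance of $\sim 0.01$.
* **Geometry.** The cylinder has a single radius (default 4 Å) along the
  whole 90 Å periodic box — a "test-tube" rather than an hourglass. A
  wider bulk would add a $\ln(\text{area ratio})$ offset between pore and
  bulk in any density-derived energy profile; the uniform cross-section
  makes $\rho(s) \propto e^{-G(s)}$ exact in the dilute limit, which is
  what the recovery tests check. The z axis is periodic, so ions
  recirculate and sustain a steady current under voltage.
* **Stability guard.** Construction fails if the per-step RMS displacement
  exceeds a quarter of the narrowest barrier width, and the integrator
  aborts if the deterministic displacement of any step exceeds three times
  the step RMS.
* **Interactions.** Ions exclude each other as hard spheres (default
  3.6 Å, a chloride contact distance) by move rejection; waters are
  non-interacting tracers, because only their density and flux statistics
  are consumed downstream. Validation runs that are compared against the
  *single-ion* Boltzmann oracle use `exclusion_radius = 0` (independent
  tracers): Boltzmann inversion recovers the one-particle potential of
  mean force, and crowding would fold pair correlations into the estimate.
* **Seeding.** One master seed; each particle gets an independent stream
  derived by a fixed offset, so results do not depend on particle
  ordering.

What the generator does *not* emulate: atomic detail, hydrodynamic and
dielectric self-energy effects, flexible pore walls, lipids, and genuine
multi-ion single-file correlation structure. Passing tests on BD data
therefore demonstrate the correctness of the *analysis machinery*
(counting, binning, inversion, statistics), not fidelity to any particular
channel.

## Pathway and profiles

`water_density_grid()` accumulates occupancy counts on a 0.5 Å grid in a
25×35×150 Å box centred on a reference point (for TMEM16A-like analyses,
the Cα of the upper gate residue). `pathway_spline()` takes the
density-weighted centroid of each z slice, fits smoothing splines to the
centroid sequence — the smoothing degree is escalated only until the
residual per populated slice is at most one voxel (0.5 Å), so noise in
sparsely populated slices is not chased — and resamples the curve at
uniform arc length (0.5 Å nodes for density profiling, 2.5 Å for flux
binning). Empty slices inherit interpolated centroids and are logged.

`ion_density_profile()` assigns each ion observation to its nearest path
node and counts it if it lies within the radial cutoff (7 Å for density
maps, 5.7 Å for the free-energy profile). "Distance to the path" is the
true 3D distance to the nearest node rather than an in-plane distance at
fixed z: the former is well defined for curved paths and reduces to the
same thing for a straight axis. `free_energy_profile()` performs the
Boltzmann inversion $G(s) = -\ln(\rho(s)/\rho_{bulk})$ with the bulk
reference taken as the mean over the outer 15 Å of the profiled range on
each side. Zero-count bins are masked, never set to $+\infty$ — finite
sampling must not fabricate infinite barriers — and profile readout
interpolates across masked gaps of at most two bins, reporting `NA` for
anything wider. `radius_profile()` is a deliberately simple geometric
profiler (minimum over atoms of centre distance minus van der Waals
radius, capped at 20 Å), a stand-in for full sphere-inflation profilers,
adequate for constriction tracking on fixtures.

## Permeation statistics

`detect_permeation()` runs a three-zone state machine (below / inside /
above the pore bounds) per ion: an outward event is a below→inside→above
passage that never returns below while inside, and symmetrically for
inward. A periodic-boundary jump (above→below with no inside visit)
creates no event. The implementation is run-length based; the test suite
holds it to *exact* agreement with an independently written brute-force
scanner on a thousand random walks.

Block currents use $I = N e / t$ on fixed time blocks (default 200 ns),
with events credited to the block containing their exit time so blocks
stay independent. Whether $N$ is the unsigned total or the signed net
count is a flag: unsigned totals are used for conductance magnitudes at
finite voltage, signed nets for zero-voltage sanity checks. Conductance is
mean current over voltage (pS), with the spread reported as the standard
deviation over blocks.

Event-count uncertainty uses the Garwood (exact chi-square) Poisson
interval by default: $[\,\tfrac12\chi^2_{\alpha/2}(2n),\
\tfrac12\chi^2_{1-\alpha/2}(2n+2)\,]$. Exact intervals guarantee *at
least* nominal coverage but are conservative for discrete counts — at a
true rate of 5 the 95% interval covers about 98% of draws; `type =
"midp"` provides the mid-P variant whose average coverage is closer to
nominal. The conservative default is kept because guaranteed coverage is
the safer property for the very small event counts typical of simulated
single-channel data.

`contact_stats()`, `gate_metrics()` and `kink_angle()` use heavy atoms
only (hydrogens excluded), matching how gate separations are normally
reported. The kink angle is measured between least-squares axes of the
Cα runs one helical turn (±4 residues) either side of the kink residue —
the smallest window that gives a stable axis — with 180° meaning
straight.

## The 7-state kinetic conduction model

Three sites with at most two ions in the pore give seven occupancy states
({}, A, B, C, AB, AC, BC). Transitions add or remove one ion at the two
bulk interfaces or hop one ion between adjacent sites. Rates are
transition-state-like,
$$k = k_0 \exp\!\big[-(G_b - G_o + z u\,(d_o - d_b))\big],$$
with a single shared attempt prefactor $k_0$, $u = eV/kT$, and electrical
distances $d \in [0,1]$ (fraction of the voltage dropped between the
intracellular bulk and the position). Entry rates scale with
$c_{bulk}/c_{ref}$ ($c_{ref} = 150$ mM). Doubly occupied states add a
configurable pairwise interaction energy $G_{int}$ (default 0; the
seven-state scheme itself does not prescribe an interaction). Detailed
balance holds on every edge by construction and is asserted both
internally and in property tests over random landscapes. The supplementary
equations of the original study were not available, so this standard
construction — the simplest one consistent with the stated
detailed-balance constraint — is the package's own choice; every
parameter is exposed.

Electrical distances default to geometric fractions of the pore span
(consistent with the constant-field generator); `solve_pb_1d()` +
`field_fraction()` can supply profile-derived distances instead. The
steady state of the 7×7 generator is solved directly; the current is the
elementary charge times the net steady-state flux across the B–C bond,
with the intracellular and extracellular bulk cuts asserted equal (flux
conservation). $k_0$ is linear in the current, so
`calibrate_prefactor()` matches the small-voltage slope to a target
conductance exactly; the presets calibrate the doubly bound model to the
4.4 pS reference value and share $k_0$ with the singly bound model
(whether the two states share a prefactor is unknowable from the data;
sharing is the parsimonious choice).

Solved over ±350 mV, the doubly bound preset is near-Ohmic
(rectification ratio $\approx 1.03$ at ±150 mV) while the singly bound
preset rectifies outwardly and exceeds the doubly bound current above
about +125 mV — the profile asymmetry alone, however, is far too weak to
explain the strong rectification seen at sub-saturating Ca$^{2+}$.

## Voltage-dependent Ca$^{2+}$ gating

The conduction states are mixed by a sequential two-step binding model:
apo (non-conductive) → upper Ca$^{2+}$ bound (rectifying conduction
landscape) → both bound (Ohmic landscape), with equilibrium weights
$$w_1 = \frac{[\mathrm{Ca}]}{c_{ref}}\,e^{-E_1 + 2\delta_1 u},\qquad
  w_2 = w_1\,\frac{[\mathrm{Ca}]}{c_{ref}}\,e^{-E_2 + 2\delta_2 u},$$
where $\delta_i$ is the fraction of the membrane field the $i$-th bound
Ca$^{2+}$ (valence +2, entering from the intracellular side) experiences.
Depolarisation drives the cation into the field, so binding is favoured at
positive voltages when $\delta_1 + \delta_2 > 0$. The ensemble current is
$I(V) = P_1 I_{1Ca}(V) + P_2 I_{2Ca}(V)$.

The binding energetics are not experimentally determined quantities here:
$E_1 = 1.5\,kT$, $E_2 = -2.5\,kT$ (cooperative second step),
$\delta_1 = 0.15$, $\delta_2 = 0.05$, $c_{ref} = 1\ \mu$M are
representative defaults calibrated once so that (i) the doubly bound
probability at 10 µM Ca$^{2+}$ stays above 80% across ±150 mV, and (ii)
sub-µM Ca$^{2+}$ leaves the channel shut at hyperpolarised voltages. With
them, the ensemble curve at 400 nM Ca$^{2+}$ is strongly outwardly
rectifying ($|I(+150)/I(-150)| \approx 15$) while at 10 µM the slope
asymmetry is ~6% — the qualitative rectifying-to-Ohmic switch driven
purely by the voltage dependence of binding.

## 1D Poisson–Boltzmann electrostatics

`solve_pb_1d()` solves
$\frac{d}{dz}\varepsilon(z)\frac{du}{dz} =
\frac{\varepsilon_{sol}}{\lambda_D^2}\sinh(u - u_{bath})$
on a planar three-region system (solution / 29.2 Å hydrophobic slab with
$\varepsilon = 2$ / solution with $\varepsilon = 80$; headgroups are
treated as solvent) by damped Newton iteration on a second-order finite
difference scheme (tridiagonal Jacobian, damping 0.5 with residual-based
acceptance, converged residual $< 10^{-8}$). Two points deserve emphasis:

* The mobile-charge term is referenced to the **local bath potential** —
  $u_{int}$ below the slab, $u_{ext}$ above. Each electrolyte is in
  equilibrium with its own electrode; with a global reference the salt
  would screen the applied potential out within a Debye length of the
  boundary instead of propagating it to the membrane, and every field
  fraction would collapse towards one end. With the local reference the
  bulk stays flat at its boundary value, the drop concentrates across the
  slab, and the field fraction $d(z) = (u - u_{int})/(u_{ext} - u_{int})$
  rises monotonically from 0 to 1 with $d = 1/2$ at the slab midplane of
  a symmetric system. The effective charge density obeys
  $n_{e\!f\!f} = 2\times10^{-27} N_A I \sinh(u)$ per Å$^3$ in the local
  reduced potential.
* A hydrated intracellular vestibule that behaves as a conductor is
  modelled by extending the $u_{int}$ Dirichlet condition up to a
  configurable `vestibule_top` — the 1D analogue of flooding cytoplasmic
  cavities with the effective charge density. A fenestration-size
  criterion for deciding *which* cavities flood has no 1D analogue and is
  out of scope.

This planar solver is an acknowledged approximation to full 3D
focused-grid calculations on a molecular surface: it yields qualitatively
correct field fractions and potential profiles, not structure-specific
ones. In the same spirit, `ca_perturbation_profile()` approximates the
electrostatic contribution of a bound Ca$^{2+}$ to the Cl$^-$ profile as
a Debye-screened Coulomb term
$\Delta G(s) = \sum z_{Cl} z_{Ca}\,e^2 e^{-r/\lambda_D}/(4\pi\varepsilon_0
\varepsilon_{e\!f\!f}\, r)$; subtracting it from a doubly bound profile
gives approximate singly/un-bound profiles. It cannot reproduce the
nonlinearity of the full Poisson–Boltzmann response (which is exactly why
removing the *second* Ca$^{2+}$ changes little in the real system).

## Conductance–voltage analysis

`nernst()` gives reversal potentials; `gv_from_iv()` forms
$G = I/(V - E_{rev})$, masks points within 2 mV of the reversal potential
(vanishing driving force), and normalises at a reference voltage.
Published work uses both +140 and +150 mV as the normalisation point; the
default is +140 mV and the reference is configurable.
`boltzmann_fit()` fits the two-state activation curve
$G(V) = G_{max}/(1 + e^{-(V - V_{1/2})/k})$ by unweighted
Levenberg–Marquardt least squares (no weighting is applied because none
is standard for these recordings), with data-derived start values and a
monotonicity check that rejects degenerate inputs. `synth_gv()` generates
noisy synthetic curves for recovery tests: the fit is exact at zero noise
and the $V_{1/2}$ bias stays below 1 mV at noise σ = 0.02 over hundreds
of replicates.

## Problem sizes and determinism

The test suite and the acceptance script use: $10^6$ BD steps (eight
independent ions) for landscape recovery, recovering all site and barrier
energies to within 0.3 kT; 1000 random-walk traces for the event-counting
oracle; $10^4$ draws for interval coverage; 500 replicates for fit-bias
estimation; and a 2001-point PB grid. All stochastic steps consume
explicit seeds — identical configuration implies identical output — and
the whole suite completes in a few minutes on one CPU.

## Known limitations

* The BD pore is a statistical surrogate; none of its parameters are fit
  to a real channel, and analyses of real trajectories should treat its
  defaults only as sensible starting points.
* Ion coordinates are analysed as read; trajectories must be pre-imaged
  (whole-frame wrapping only is stored).
* The Ca$^{2+}$ gating energetics and field fractions are representative
  calibrated defaults, not measurements; fitting them to experimental
  G(V) data is deliberately out of scope.
* The planar PB solver and the screened-Coulomb Ca$^{2+}$ perturbation
  trade structural specificity for transparency; quantitative
  reproduction of 3D continuum calculations is not attempted.
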