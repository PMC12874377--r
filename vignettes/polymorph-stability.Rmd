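---
title: "Finite-temperature polymorph ranking: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-temperature polymorph ranking: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`polystab` ranks rigid-molecule crystal polymorphs at finite
temperature by chaining three models of increasing cost: static lattice
energies, harmonic lattice-dynamics (HA-LD) free energies, and
pseudosupercritical-path (PSCP) alchemical free energies estimated with
MBAR. This vignette is the package's own account of the science: what
each stage assumes, which knobs matter, what the synthetic fixtures do
and do not probe, and where the open design decisions were made.

## The energy model

The static lattice energy of a crystal is decomposed as

\[ U_\mathrm{latt} = \Delta U_\mathrm{intra} + U_\mathrm{elec} + U_\mathrm{rd}, \]

per mole of molecules. Molecules are rigid, so the intramolecular term
is identically zero: the reference internal geometry stored in each
`rigid_molecule` never deforms, and intramolecular nonbonded pairs are
fully excluded. This is appropriate for small, stiff molecules; for
flexible molecules the rigid-body model (and HA-LD generally) degrades.

`U_rd`, the repulsion–dispersion term, is a Buckingham (exp-6) pair
potential \(A e^{-rB} - C/r^6\) summed over intermolecular atom pairs
within a real-space cutoff (default 30 Å). The exponent is written as
\(-rB\), so `B` carries units of Å\(^{-1}\); force-field files using
the equivalent \(e^{-r/\rho}\) convention must supply \(B = 1/\rho\).
No long-range tail correction is applied for solids (the sum is
converged by the cutoff); an isotropic tail correction would matter
only for liquid-phase absolute energies, which the workflow never uses
in isolation.

`U_elec` treats electrostatics as fixed atomic point charges with full
Ewald summation (real + reciprocal + self + intramolecular-exclusion
corrections). Point charges are the global-search-grade model;
distributed multipoles, which improve directional interactions, are out
of scope and this is the main accuracy caveat of the energy model.
Periodic images are enumerated explicitly, so cutoffs may exceed the
cell dimensions and no minimum-image restriction applies to the static
model. Ewald parameters default to `"auto"`: the splitting parameter
and reciprocal cutoff are tuned from a target accuracy (`1e-8`
relative), which suits the small fixture cells better than any fixed
literature settings; fixed values can be supplied instead. The tests
verify invariance of `U_elec` to a factor-of-two change in the
splitting parameter at matched cutoffs.

Analytic gradients and Hessians are implemented for every term. The
Hessian is assembled from pairwise radial second derivatives plus the
reciprocal-space contribution; its translation invariance (acoustic sum
rule) holds to `1e-7` kJ/mol/Å\(^2\) and it matches finite differences
of the analytic gradient at two step sizes to better than `1e-5`
relative.

### Harmonic anchors and Gaussian restraints

Two auxiliary potentials are attached to structures or sampling
systems:

* **Harmonic anchors** (`with_anchors`) tether every atom to a site
  with spring constant `K` (kJ/mol/Å\(^2\)), optionally anisotropic
  and negative (to build saddle-point decoys). Anchors turn a crystal
  into an Einstein-style toy whose spectrum, classical free energy and
  PSCP stage values are known exactly — the backbone of the oracle
  tests.
* **Gaussian restraints** (`restraint_spec`) are the PSCP's attractive
  wells \(-\varepsilon e^{-|x-x_0|^2/2\sigma^2}\) applied to all atoms
  in weakened intermediates. Well depths of 20.92 and 41.84 kJ/mol are
  the protocol's convergence pair. The width \(\sigma\) is never
  printed in the protocol literature; `calibrate_restraint_sigma`
  chooses it so the Boltzmann positional variance of the well at the
  reference temperature matches a target (normally the crystal-phase
  variance from an NVT run), integrating the well region out to where
  the well has decayed to 1% of its depth — beyond that radius the
  crystal cage, not the restraint, confines the atom.

## Lattice dynamics

Force constants are built by computing the analytic Hessian of an
\(n_{sc}^3\) supercell and slicing it into image-resolved blocks
\(\Phi(L)\); the dynamical matrix is their mass-weighted Fourier
transform. This "literal supercell" construction handles the Ewald
part without a separate reciprocal-space phonon formalism, and the
commensurate uniform \(n_{sc}^3\) k-mesh (including \(\Gamma\)) is
exactly equivalent to diagonalising the supercell at \(\Gamma\) — an
equality the tests assert on an fcc fixture. The supercell factor
follows the cutoff rule: the smallest integer strictly exceeding
cutoff / shortest cell edge, with the \(\Gamma\)-only limit for a zero
cutoff.

Numerical tolerances, all exposed as arguments:

* `acoustic_tol = 1e-6` (mass-weighted kJ/mol/Å\(^2\)/amu): \(\Gamma\)
  eigenvalues inside `±acoustic_tol` are acoustic translations and are
  zeroed (at most three); any eigenvalue below `-acoustic_tol`
  anywhere flags the structure dynamically unstable. The margin
  separates genuine instability from roundoff.
* `grad_tol = 1e-6` kJ/mol/Å: structures whose gradient exceeds this
  are refused with a "minimize first" error, because loose minima
  produce spurious imaginary modes that masquerade as instability. A
  rigid-body quasi-Newton relaxation (`relax_structure`, BFGS over
  centroids and orientations with analytic forces and torques) is
  provided so fixtures reach tight minima.

The vibrational free energy uses the quantum harmonic expression;
zero-frequency modes contribute nothing, and at \(T = 0\) only the
zero-point term survives. Frequencies convert from mass-weighted
eigenvalues through a single explicit constant
(\(1000/(N_A\,m_u\,10^{-20})\) s\(^{-2}\) per kJ/mol/Å\(^2\)/amu), and
\(\hbar\omega/k_BT\) is always formed in one unit system. Free energies
are normalised per mole of molecules (matching the kJ/mol scale on
which polymorph gaps of a few kJ/mol are meaningful); curves are
isochoric single-point evaluations with geometry fixed across the
0–400 K grid (20 K steps by default). Screening at `T_select = 300 K`
advances the `top_k = 5` most stable survivors by default.

## The sampler

The PSCP estimators (ensemble averages and MBAR) are sampler-agnostic,
so sampling uses rigid-body Metropolis Monte Carlo rather than
thermostatted molecular dynamics: exactly ergodic at these system
sizes, dependency-free, and bit-exact reproducible under a fixed seed.
Translation and rotation step sizes adapt toward ~40% acceptance
during burn-in (default 40% of sweeps, mirroring the
discard-the-first-40% convention of the underlying protocol) and are
frozen afterwards so production sampling satisfies detailed balance.
NPT adds log-scale volume moves — anisotropic single-edge moves for
crystals, isotropic for liquid boxes — with the \((M+1)\ln(V'/V)\)
Jacobian for molecular scaling; the near-ideal-gas test pins this
exponent.

Sampler pair interactions use the minimum-image convention within a
cutoff capped at half the shortest box edge (an explicit error asks for
replication otherwise), and electrostatics in the *sampler* are plain
minimum-image Coulomb: the toy systems the sampler targets are neutral
and mostly charge-free, and the static lattice-energy model retains the
full Ewald treatment. This is a deliberate desk-scale simplification;
charged sampling systems beyond toy scale would need an Ewald (or
damped-sum) sampler backend.

## PSCP staging and MBAR

Melting is the three-step path solid → dense weak fluid (DWF) → weak
fluid (WF) → liquid; solid–solid transitions convert each polymorph
independently to a DWF and expand both into a common WF, so

\[ \Delta A_{S_1 \to S_j} = [\Delta A_{S_1 \to DWF_1} + \Delta A_{DWF_1 \to WF}]
 - [\Delta A_{S_j \to DWF_j} + \Delta A_{DWF_j \to WF}]. \]

Schedule defaults are the protocol's: 40 equally spaced \(\lambda\)
values plus extra points concentrated in \([0.8, 0.9]\) for the
solid→DWF leg (the extra count is not printed anywhere; 8 is this
package's default and it is configurable), 20 for WF→liquid, 20 volume
states for DWF→WF.

The \(\lambda\)-scaling functional form is not specified by the
protocol; the choices here are linear scaling for electrostatics,
soft-core (power-4 shifted separation) scaling for the Buckingham term
with a residual floor (`vdw_floor = 0.1`) so the weakened endpoint
remains a *weak* fluid rather than an ideal gas, and restraints ramped
complementarily (fully on in the DWF, absent at physical endpoints).
All three are config-exposed. Physical endpoints reproduce the
unscaled potential exactly (`1e-12`, tested). For anchored
Einstein-style toys the anchors *are* the interactions: they morph
linearly toward a common weak spring, and the static offset ramps off
with them so the weakened endpoints of different polymorphs coincide —
which makes the whole stage analytic and is how the estimator is
validated end to end. Volume stages map configurations between volumes
affinely through fractional centroids (rigid internal geometry
untouched) and carry the \(-M\ln V\) translational measure term in the
reduced potentials; for harmonic anchors this stage is exactly
free-energy neutral, a null the tests assert.

The MBAR solver minimises the convex MBAR objective by BFGS and
polishes with self-consistent iteration to `1e-10` in the gauge
\(f_1 = 0\); uncertainties come from the standard asymptotic
covariance (SVD-reduced, pseudo-inverted across the gauge null space)
and 95% intervals are \(1.96\sigma\). Adjacent-state overlap below
0.03 records a warning in the fit. Cross-checks: identical states,
the harmonic pair \(\Delta f = \tfrac12\ln(K_2/K_1)\), agreement with
an independent Bennett (BAR) solver to `1e-8`, cycle closure to
`1e-10`, and empirical interval coverage over repeated seeded
estimates.

Reduced free-energy differences over temperature, \(\Delta f(T)\), are
assembled by chaining two-state MBAR between adjacent temperatures
within each phase — the protocol does not state how its \(\Delta f\)
tables are built, and the adjacent-temperature chain is this package's
choice, documented rather than asserted. For anchored toys the chains
run in NVT: their anchor free energies are volume-independent, so
Helmholtz and Gibbs coincide and NPT boxes of anchored systems would
collapse. Temperature extrapolation then follows

\[ \Delta G(T) = k_BT[\Delta f(T) - \Delta f(T_\mathrm{ref})] +
  (T/T_\mathrm{ref})\,\Delta G(T_\mathrm{ref}), \]

with the quadrature error propagation
\((\delta\Delta G/k_BT)^2 = (\delta\Delta f)^2 +
(\delta\Delta f_\mathrm{ref})^2 +
(\delta\Delta G_\mathrm{ref}/k_BT_\mathrm{ref})^2\). Transition
temperatures are piecewise-linear roots of the central curve; their
uncertainty is half the spread of the band-edge crossings; multiple
sign changes return all roots with a warning rather than failing. The
pressure–volume correction \(P\Delta V\) is carried but is below 0.011
kJ/mol for any \(|\Delta V| \le 100\) cm\(^3\)/mol at 1 atm.

The van der Waals / electrostatic / volumetric decomposition
re-expresses a solid–solid \(\Delta A\) through component-resolved
sub-stages (electrostatics scaled off first, then van der Waals), with
the volumetric term \(\Delta A_{DWF_1\to WF} - \Delta A_{DWF_j\to WF}\).
Components must close on the total within 0.02 kJ/mol — the rounding
scale of component tables printed to 2–3 decimals.

## Packing similarity

`packing_shell_rmsd` is a COMPACK-like score, not COMPACK (which is
proprietary): around a central molecule the N nearest molecules by
centroid distance form a cluster (N = 15 by default, threshold 0.50 Å);
clusters are superposed by Kabsch rotation with molecule
correspondence found by iterative closest point over the 24 octahedral
starting rotations. Declared simplifications: the central molecule
iterates over all molecules of both structures taking the minimum;
atoms within paired molecules match by identical ordering (guaranteed
by the fixture generators); boundary-shell ties are handled by
extending the candidate pool to all tied distances; and the score is
symmetrised by evaluating both directions. Formula mismatches return a
no-match result rather than an error.

## What the fixtures emulate — and what they do not

`generate_toy_polymorph_set` builds deterministic sets with engineered
ground truth:

* `einstein`: single-atom molecules on cubic lattices held by
  independent harmonic anchors. The stiff polymorph (`K = 2.2`
  kJ/mol/Å\(^2\)) wins at low temperature; the soft one
  (`K = 2.2/e`) carries the static penalty
  \(\Delta U = \tfrac32 k_B T_\times \ln(K_1/K_2)\) that puts the
  classical crossing exactly at \(T_\times = 300\) K. Springs are soft
  enough (\(\hbar\omega/k_B \approx 30\) K) that the quantum LD
  crossing sits within a fraction of a kelvin of the classical one, so
  the LD stage and the classical Monte Carlo stage share one ground
  truth. The decoy has a negative anchor curvature along z — a genuine
  saddle with imaginary modes. The melting point of the stiff
  polymorph against the weakly anchored "liquid" is engineered 80 K
  above the crossing.
* `rigid-dimer`: the same construction with two-atom rigid dimers,
  both atoms anchored, exercising rotational moves.
* `buckingham-lattice`: argon-like exp-6 fcc and hcp packings (both
  mechanically stable, nearly degenerate — a realistic hard pair) and
  a simple-cubic decoy, which really is shear-unstable for pair
  potentials; no crossing is engineered here.

These fixtures reproduce the *statistical structure* the workflow
assumes — competing minima, entropy-driven reranking, dynamical
instability, a liquid reference — with exactly known answers. They do
not probe force-field realism: anharmonic wells, multipolar
electrostatics, molecular flexibility, finite-size effects of real
cells, or the slow nucleation physics that separates thermodynamic
from kinetic stability. A green test suite therefore certifies the
estimators and the plumbing, not the accuracy of any particular force
field on real crystals.

## Problem sizes and reproducibility

Sampling lengths in the tests and the acceptance script are chosen so
estimator bias is negligible against the reported standard errors:
PSCP stages run 2 500 sweeps per state thinned to every 25th sweep
(shorter, less-thinned runs leave visible equilibration bias and
correlation-deflated error bars — the repeat-coverage check is the
guard), free-energy chains 1 200–1 500 sweeps, the end-to-end toy
pipeline 10–16 \(\lambda\) states on a 250–400 K grid. Every stochastic
path is seeded; single-threaded runs are bit-exact reproducible, and
the pipeline caches completed stages by config hash so re-runs are
no-ops. The empirical 95%-interval coverage of the Einstein PSCP
recovery, measured over independent seeded repeats, is the package's
own calibration check on its uncertainty estimates.

## Known limitations

* Point charges only; no distributed multipoles or polarisation.
* Harmonic LD only: no quasi-harmonic volume dependence and no
  anharmonic corrections, so LD rankings degrade with temperature —
  which is exactly why the workflow treats LD as a prescreen and PSCP
  as the final ranking.
* The sampler's electrostatics are minimum-image Coulomb, adequate
  only for the neutral toy systems it targets.
* The minimum-image convention in the sampler is exact for
  orthorhombic boxes and approximate for strongly sheared cells; the
  fixture cells are orthogonal.
* `Z'` (asymmetric-unit bookkeeping) is stored as metadata only and
  never used in computation.
* Space-group symmetry is not exploited: fixtures provide explicit
  full cells, and all sums run over all atoms.
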