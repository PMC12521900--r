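---
title: "Bottom-up coarse-graining of polymer melts: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up coarse-graining of polymer melts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cgmelt implements a systematic bottom-up coarse-graining workflow for linear
polymer melts at one bead per monomer, together with the structural and
dynamical observables used to judge whether the coarse model reproduces the
fine one. This vignette explains the model, the numerical choices, and the
places where a design decision was genuinely open — and why it was made the
way it was.

## The coarse-graining model

A melt of `n_chains` identical chains of `N` monomers is reduced to one
spherical interaction site ("bead") per monomer, placed at the monomer's
center of mass. For poly(ε-caprolactone)-like chains, `build_pcl_topology()`
provides the atom bookkeeping: internal monomers carry the 18 atoms of the
C6H10O2 repeat unit, the two chain ends carry 19 and 20 atoms for their
end groups, and 7 atoms per monomer (six carbons and the ester oxygen) are
flagged as backbone, so backbone separations run up to `7N - 1`. Chain molar
mass follows the capping-hydrogen convention `N * 114.144 + 2 * 1.008` g/mol,
which reproduces the catalogue values 1143, 3426, 5709, 11416 and
14270 g/mol for N = 10 to 125. The terminal *atom counts* and the
capping-hydrogen *mass rule* are two different bookkeeping conventions for
the chain ends; the topology honors both by carrying one zero-mass virtual
site on the 20-atom end. Center-of-mass mapping is mass-weighted, computed
on unwrapped molecules (a center of mass across a periodic seam is otherwise
ill-defined), and preserves total mass and the system's mass-weighted center
exactly.

The coarse interactions are four tabulated potentials: bond length `r`
between consecutive beads, bending angle `θ` between consecutive bead
triples, torsion `φ` between consecutive quadruples, and a nonbonded pair
potential acting between all bead pairs except intramolecular pairs three or
fewer bonds apart — the same exclusion used when measuring the monomeric
radial distribution function, because those short-range correlations are the
job of the bonded terms.

## Target distributions

`measure_distributions()` builds the four targets: normalized histograms of
bond lengths (default bin 0.002 nm), angles (1°), signed dihedrals (2°,
cis = 0, trans = ±180°), and `g(r)` (0.01 nm bins, ideal-gas shell
normalization at the system's bead density, `r_max = min(2 nm, half box)`).
The source data do not fix bin widths; the defaults resolve the structure of
melt-state monomer distributions without being noise-dominated at the sample
sizes the package's fixtures produce, and every width is a parameter.
Distributions are frame-averaged with equal weights, and the IBI loop always
re-measures on the target's own bin grid so norms compare like with like.

## Inversion and iterative refinement

Direct Boltzmann inversion provides the starting potentials:
`U_bond = -kT ln[P(r)/r²]`, `U_angle = -kT ln[P(θ)/sin θ]`,
`U_dihedral = -kT ln P(φ)` (no Jacobian: the torsion is flat-measured),
`U_nonbonded = -kT ln g(r)`. Bonded potentials are shifted to zero minimum;
the nonbonded one is shifted to zero at the cutoff so the plain-cutoff
convention is exact. Bins below a density floor (1e-8) are excluded before
the logarithm.

Two numerical safeguards matter in practice and are worth stating plainly:

* **Support walls.** A finite-sample histogram ends in noisy bins whose
  local slope can even point *outward*; a simulation run on the naively
  extrapolated potential then drifts into configurations the targets never
  sampled and heats up catastrophically. Inverted bond, angle and inner
  nonbonded tables are therefore continued beyond their sampled support with
  a rising quadratic wall before they ever reach the engine.
* **Update masking and capping.** The IBI update
  `U' = U + α kT ln(P_current/P_target)` is applied only where both
  densities exceed 1% of the target's peak; outside that well-sampled region
  the correction is continued as a constant (which adds no force). Each
  iteration's correction is capped at `±kT` and smoothed with a cubic
  smoothing spline. Undamped, unmasked updates are unstable on finite-sample
  histograms; the damping default is α = 0.2–0.3.

The refinement is staged as the method prescribes: per-contribution cycles
in the order bond → angle → dihedral → nonbonded (at most 20 iterations per
contribution by default), then simultaneous tuning of all contributions,
then optional pressure-correction iterations. The convergence norm scales
both distributions by the factor that unit-normalizes the target and
integrates their absolute difference; the overall norm is the mean over the
four contributions, and the loop stops when it falls below the tolerance
(default 0.02) or the relative improvement drops below 1% — the two stopping
rules are part of the method, the numbers are this package's defaults. In
the package's own recovery experiments the coupled angle–torsion–packing
contributions respond far better to the *simultaneous* stage than to long
sequential cycles, so the desk-scale schedule runs one short sequential
cycle and lets the simultaneous stage finish the job.

The pressure correction adds a linear tail `ΔU = A (1 - r/r_cut)` with
`|A| = strength·kT` and the sign of the measured-minus-target pressure; the
functional form is the standard linear-tail correction, since the source
method states only that a correction stage exists. The desk-scale recovery
experiment runs at fixed volume and defaults to zero pressure iterations;
the stage itself is exercised by its unit tests.

## The embedded engine

`run_md()` integrates bead dynamics with a velocity-Verlet core (BAOAB
splitting), a Langevin thermostat and an isotropic weak-coupling barostat,
under periodic boundary conditions with minimum-image convention, cell-list
neighbor search (0.3 nm skin, displacement-triggered rebuilds) and a plain
nonbonded cutoff (default 1.5 nm; tables are built energy-shifted to zero
there). The reference conditions are 500 K, 1 bar and a 5 fs time step. The
thermostat/barostat pair is deliberately simpler than extended-Lagrangian
couplings: the observables this package computes depend on the sampled
ensemble, not on the coupling mechanism, and the stochastic pair is
unconditionally stable. Positions are kept unwrapped throughout, so centers
of mass and displacement statistics need no unwrapping step. A dedicated
xorshift/Box–Muller RNG stream seeded from the `seed` argument makes
trajectories bit-reproducible independent of R's RNG state.

Three engine conventions deserve emphasis:

* Energies and forces come from one natural cubic spline per table; the
  force is the exact derivative of the interpolated energy, so the field is
  conservative by construction and NVE drift tests are meaningful.
* The bending potential is interpolated in `cos θ`. A table interpolated in
  `θ` needs the factor `1/sin θ` in its force, which diverges for collinear
  triples; in `cos θ` the force is regular everywhere.
* Torsions are applied in the combined bending-torsion form
  `U = T(φ) sin³θ₁ sin³θ₂`, the established remedy for the collinear-triple
  singularity of plain torsion forces in coarse-grained chains with soft
  bending potentials. Because the sin³ factors attenuate the applied torsion
  by roughly `⟨sin³θ⟩²`, the direct inversion divides its raw dihedral
  estimate by that factor (measured from the angle target, bounded to
  at most 8), and IBI dihedral updates carry the same gain. Bonds are
  governed by the tabulated bond potential and never constrained —
  constraining them would contradict matching the bond-length distribution.

The dihedral table is padded periodically before splining so the force is
continuous across ±180°.

## Synthetic fixtures and what they do (not) show

`generate_ideal_chains()` builds freely jointed or freely rotating
ensembles — the closed-form baselines for `⟨R_e²⟩`, `C_n`, `R_e/R_g → √6`
and the Debye form factor — without excluded-volume relaxation, because
those identities hold for ideal chains and need no packing.
`generate_reference_melt()` equilibrates 70 chains of 10 beads at 500 K and
930 kg/m³ under known potentials (harmonic bond k = 20000 kJ/mol/nm² at
0.66 nm, matching the CG monomer spacing; cosine-harmonic angle k = 50 at
135°; single-cosine torsion barrier 4 kJ/mol; Lennard-Jones σ = 0.55 nm,
ε = 2.5 kJ/mol with a quintic switch to zero at the 1.5 nm cutoff), and
measures its own distributions. Those distributions are the ground truth for
the recovery experiments: the IBI loop must reproduce them, although the
potentials themselves are only determined up to additive constants. The melt
density, bond length and temperature mirror the melt conditions of the
workflow's origin; the bonded constants were chosen once to give
liquid-like packing, broad but structured angle/dihedral distributions and
a stable 5 fs time step, and are not tuned thereafter.

Passing these tests shows the machinery is self-consistent at desk scale; it
does not show that a 10-bead Lennard-Jones fixture reproduces the chemistry
of a real atomistic melt. Conversely the published-value checks (chain
masses, entanglement arithmetic, shift-factor ratios) validate the analysis
formulas on their printed inputs, independent of any simulation.

## Observables

* Internal distances `⟨R_n²⟩/n` at monomer or backbone-atom level;
  `C_n = ⟨R_n²⟩/(n b²)` with `b` the root-mean-square consecutive backbone
  distance (so `C_1 = 1` identically), and `C_∞` estimated as the mean of
  `C_n` over the top decile of `n` — a reproducible surrogate for reading a
  plateau off a plot.
* Gyration tensor in the unweighted double-sum form (algebraically the
  centered second-moment tensor; the identity is tested to 1e-12),
  eigenvalue-based asphericity (0 = sphere, 1 = rod), `R_g²` from the trace,
  `R_e` between first and last particle.
* Single-chain form factor by the isotropic Debye sum
  `W(q)/N_p`, with the fractal exponent ν fitted as `-1/slope` of
  `log W` vs `log q` on `1/R_g ≤ q ≤ 1/b`. The sinc kernel is exact for
  isotropic ensembles and deterministic, which is why explicit q-vector
  averaging is not used. For chains of order a hundred beads this window is
  barely one decade, and the Guinier shoulder biases a plain log–log slope
  away from the asymptotic exponent even for the exact ideal-chain
  scattering function; the fit therefore carries a `1/q²`
  correction-to-scaling regressor, which restores the asymptotic exponent
  (0.52 on the exact Debye curve of a 125-bead chain, against 0.71 for the
  naive slope).
* End-to-end orientational ACF: the per-sample cosine between `R_e(t₀+t)`
  and `R_e(t₀)` averaged over chains and log-spaced origins. The averaging
  order (average of the ratio) is a recorded convention; the alternative
  (ratio of averages) differs only in heteroscedastic weighting and the
  choice is switchable in principle by post-processing the stored vectors.
* Stretched-exponential fits `A exp(-(t/τ)^β)` by bounded
  Levenberg–Marquardt with `A ≤ 1`, `β ∈ (0, 1.5]`, τ started from the 1/e
  crossing; the default window keeps lags with `C(t) > 0.05` and at least 10
  origins, because long-lag estimates from few origins are noise. The
  terminal time is `τ_end = (τ/β)Γ(1/β)`, the exact integral of the KWW
  curve.
* Center-of-mass MSD `g₁(t)` with wrapped-input detection, and the two
  time-scaling routes: `t_CG = τ_A/τ_CG` and `t_CG^MSD = t₁,A/t₁,CG` with
  `g₁(t₁) = R_g²` located by log–log interpolation and never extrapolated.
* Packing length `p = M_w/(⟨R_e²⟩ρN_A)` with `M_w` read as the *chain*
  molar mass — the reading that is numerically consistent with the melt's
  stiffness plateau and density — and the entanglement chain
  `M_e = n_t²ρN_A p³` (`n_t ≈ 21`), `N_e = round(M_e/M_monomer)`,
  `M_c = 2M_e`, and the onset chain length `2N_e`.

## Problem sizes

The recovery experiment runs 70 chains × 10 beads with 20 000-step
iterations (100 ps each at 5 fs), 2 500-step re-equilibration between
iterations and 400 sampled frames per iteration; ideal-chain checks use
ensembles of 1 500–5 000 chains. These sizes put every distribution's
statistical noise floor comfortably below the 0.05 recovery tolerance while
keeping a full test run on one core in the minutes range; all of them are
configuration, not constants.

## Known limitations

* The engine targets orthorhombic (cubic in practice) boxes, single-bead
  monomers and linear chains; no electrostatics, no anisotropic coupling,
  no parallel decomposition.
* IBI matches local structure; like any structure-matching coarse model,
  long-range chain dimensions and dynamics are reproduced only up to the
  usual representability limits, which is exactly why the validation suite
  (internal distances, form factor, time-scaling factors) exists.
* The combined bending-torsion convention means a recovered torsion table
  equals the generating one only up to the `sin³` weighting and additive
  constants; recovery is judged on distributions, which is the method's own
  criterion.
* The weak-coupling barostat samples an approximate isobaric ensemble; the
  desk-scale workflow therefore runs structure matching at fixed volume and
  treats the pressure stage as a correction, not a sampler.
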