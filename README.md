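# cgmelt

Bottom-up coarse-graining of linear polymer melts in R.

Molecular simulations of polymer melts at atomistic resolution cannot reach
the time and length scales where chain-level physics (Rouse relaxation,
entanglement onset, terminal rheology) lives. The standard remedy is
systematic coarse-graining: group each monomer into a single bead at its
center of mass, measure the monomer-level structural distributions from the
fine-grained melt, and derive effective bead–bead potentials whose
simulations reproduce those distributions. cgmelt implements that entire
workflow for linear melts such as poly(ε-caprolactone) (PCL), for
simulation practitioners who want a self-contained, scriptable, fully
testable version of it:

* **Mapping** — GRO-format configuration/trajectory I/O, PCL chain
  topologies (18-atom repeat units, 19/20-atom chain ends, 7 backbone atoms
  per monomer), periodic unwrapping, and mass-weighted mapping to one bead
  per monomer.
* **Targets** — bond-length, bending-angle, dihedral and monomeric
  radial-distribution histograms, the latter excluding intramolecular pairs
  within 3 bonds.
* **Potentials** — direct Boltzmann inversion
  (`U = -k_B T ln[P/J]` with the appropriate Jacobian `J`), Iterative
  Boltzmann Inversion with the convergence norm
  `∫|P_current - P_target| dx` (both scaled so the target integrates to 1),
  staged tuning (sequential per contribution, then simultaneous), and a
  linear-tail pressure correction.
* **Engine** — an embedded tabulated-potential MD engine (Rcpp): cubic
  splines with analytically consistent forces, Langevin thermostat,
  weak-coupling barostat, cell lists, bit-reproducible seeding.
* **Validation** — internal distances and the characteristic ratio
  `C_n = ⟨R_n²⟩/(n b²)`, gyration-tensor shape analysis
  (`R_g²`, asphericity), single-chain form factor `W(q)/N_p` with fractal
  exponent ν, end-to-end orientational relaxation with stretched-exponential
  fits `A·exp(-(t/τ)^β)` and terminal time `τ_end = (τ/β)Γ(1/β)`,
  center-of-mass MSD `g₁(t)`, atomistic↔CG time-scaling factors
  `t_CG = τ_A/τ_CG`, packing length `p = M_w/(⟨R_e²⟩ρN_A)` and the
  entanglement estimates `M_e = n_t² ρ N_A p³`, `N_e`, `M_c = 2M_e`.

Results come back as tibbles with `ggplot2::autoplot()` methods; fitted
relaxation objects support `tidy()`/`glance()`.

## Worked example

Generate a reference CG melt with known potentials, rederive potentials
from its own distributions, and check the recovery — the package's central
self-consistency experiment:

```r
library(cgmelt)

melt <- generate_reference_melt(seed = 11)        # 70 chains x 10 beads, 500 K
res <- run_ibi(melt$distributions, melt$topology,
               ibi_engine_config(seed = 31, sample_stride = 50,
                                 equil_steps = 2500),
               ibi_schedule(max_cycles = 1, max_iter = 1, tolerance = 0.05,
                            damping = 0.3, simultaneous_iters = 12),
               initial_state = melt$final_state)
res$state
#> ibi_state: 10 evaluations, 9 refinements, mean norm 0.0358 (converged)
```

The mean norm is the average total-variation-style distance between the
four measured distributions and their targets; 0.036 means the rederived
potentials reproduce the reference melt's structure to within a few percent
of probability mass per observable.

Entanglement arithmetic from measured melt properties (packing length
0.27 nm, density 928 kg/m³, packing number 21):

```r
entanglement_estimates(p = 0.27, rho = 928, n_t = 21, monomer_mass = 114.14)
#> entanglement_estimate: p = 0.270 nm, M_e = 4851 g/mol, N_e = 43, M_c = 9702 g/mol, onset N = 86
```

Ideal-chain checks of the analysis stack:

```r
chains <- generate_ideal_chains(N = 125, n_chains = 2000, bond_length = 0.66,
                                kind = "fjc", seed = 1)
sh <- chain_shapes(chains)
sqrt(mean(sh$Re^2) / mean(sh$Rg2))   # -> 2.433, the ideal-chain sqrt(6)
attr(form_factor(chains), "nu")      # -> 0.509, the Gaussian-chain exponent
```

See `vignettes/coarse-graining-methods.Rmd` for the model, parameter and
numerics documentation.

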