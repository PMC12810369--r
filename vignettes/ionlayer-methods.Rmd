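---
title: "ionlayer: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ionlayer: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionlayer)
```

`ionlayer` studies divalent-cation binding at a deprotonated
carboxylate-terminated monolayer with a deliberately reduced model. This
vignette records the science behind each component, the tunable parameters
that matter, and the design decisions taken where more than one defensible
choice existed. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The reduced physical model

### Geometry

The monolayer is the (√3×√3)R30° triangular adlattice that thiols form on
Au(111). We build only what the binding analysis observes: one rigid
carboxylate headgroup per lattice site (a carbon at the site, two oxygens
0.22 nm apart at a random in-plane azimuth), with a net charge of −1 e per
deprotonated ligand, by default −0.5 e on each oxygen.

- `spacing` (nm, default **0.497**): the nearest-neighbour S–S distance.
  The primary literature on the monolayer system does not state the value
  used; 0.497 nm is √3 times the Au(111) lattice constant, the standard
  figure for this adlattice, and is flagged as an assumption — it is a
  single multiplicative knob on all in-plane distances.
- `nx = 14, ny = 11`: the reference array (154 ligands).
- `oo_distance` (nm, default **0.22**): the intramolecular carboxylate O–O
  distance.
- The alkyl chains and the gold substrate are not represented. Chain
  observables (`tilt_angles()`) operate on externally supplied full-chain
  coordinates only.

### Dynamics

`simulate_langevin()` integrates overdamped (inertialess) Langevin dynamics
with the Euler–Maruyama scheme,

$$x_{t+\Delta t} = x_t + \frac{F\,\Delta t}{m\gamma}
  + \sqrt{\frac{2 k_B T \Delta t}{m\gamma}}\,\xi,$$

in GROMACS-consistent units (nm, ps, kJ/mol, u), where
$D = k_BT/(m\gamma)$ emerges directly in nm²/ps. Design choices:

- **Overdamped rather than full MD.** The analysis pipeline, not the
  dynamics, is the package's core; Brownian dynamics reaches the same
  stationary (Boltzmann) distribution with far less machinery. Energy
  conservation is therefore meaningless here and is not asserted; instead
  the tests check stationary statistics (equipartition variance, a χ² test
  against the analytic Gaussian in a harmonic well, the Einstein relation
  for free diffusion).
- **Implicit solvent.** A relative dielectric `eps_r` (default **78.5**)
  divides the Coulomb constant. This screens the *medium*; ECC charge
  scaling (below) models *electronic* polarizability. Enabling both is not
  double counting and the code keeps them independent, but note that ECC
  parameter sets were calibrated for explicit-solvent MD — here ECC is
  exposed mainly so its algebra (an exact f² scaling of the Coulomb term)
  can be exercised.
- **Boundaries.** Periodic in x,y with minimum image; reflecting walls at
  z = 0 and z = lz replace the vacuum-slab-plus-Ewald construction of
  cluster-scale MD. Nonbonded interactions use a plain cutoff (default
  **1.2 nm**, mirroring a 12 Å cutoff) — no Ewald summation, consistent
  with the simulator's role as a test harness.
- **Stability.** The explicit scheme needs
  $\Delta t \ll m\gamma/k$ for the stiffest harmonic restraint $k$; a
  warning fires at $\Delta t > 0.1\,m\gamma/k$ for bias springs. The
  first-order scheme's stationary variance carries a relative bias of
  $\approx a/2$ with $a = k\Delta t/(m\gamma)$, so quantitative tests use
  $a \le 0.02$.
- **Headgroups are static.** The reference simulations restrain the sulfur
  atoms with a stiff spring (50,000 kJ/mol·nm²); with no alkyl chain in
  the model we take the rigid-tether limit and hold headgroups fixed,
  which also keeps the integrator's stiffness budget in the ion springs.
- **RNG.** One seeded generator per run, recorded in the trajectory's
  provenance; the global RNG state of the session is saved and restored.

### Force field

Pair interactions combine per-species parameters by Lorentz–Berthelot
(geometric ε, arithmetic R_min) — the convention of the CHARMM lineage the
monolayer force field belongs to. The primary text does not state the
combining rule; it is recorded per `forcefield_set` and overridable. ECC is
applied to ion charges only by default (`ecc_headgroups = FALSE`); whether
the original work scaled the carboxylate charges as well is unstated, so
the choice is a documented flag rather than a hard-coded behaviour.

The shipped numeric tables (`ff_li_tip3p`, `ff_mamatkulov`, `ff_mendes`
under `inst/extdata/`) are transcriptions from the cited primary
literature, carried with provenance notes; the package performs no
re-fitting, and every quantitative test is independent of the specific
values (identities, derivatives, scaling laws, recovery of generated
truth). Users supply their own YAML table for production parameter sets.

## The synthetic-data generator

`generate_labeled_trajectory()` is the ground-truth engine for
parameter-recovery tests. Each ion independently carries a motif state in
{B, M, I, unbound}; at rate `exchange_rate` (per ps) it resamples its state
from `target_fractions`, making that distribution exactly stationary. The
ion is then placed inside the distance band of its state around a private
anchor ligand, with a small Gaussian jitter (`jitter_sd`, default 0.002 nm)
that produces the rare band-edge misclassifications (≥ 99 % per-frame
agreement is the contract, and what the tests assert).

Anchors are laid out at ≥ 2.2 × `total_max` spacing so an ion can only ever
be in contact with its own ligand — geometric feasibility is checked and
violated configurations are rejected. What this generator deliberately does
*not* emulate: multi-ligand contacts (composite motifs like "B+M"), spatial
correlations between ions, realistic exchange pathways (a bound ion may
"teleport" within its band between frames), and any energetics. Passing
recovery tests therefore demonstrates that the classifier and the
downstream statistics are correct bookkeeping, not that the physics of a
real trajectory is reproduced; motif *frequencies* in real data come from
the energetics, which only the Langevin simulator (qualitatively) and
full MD (quantitatively) provide.

Default study conditions mirror the reference system: a
6.06 × 5.20 × 7.00 nm box, compositions of 100 divalent cations + 54 Na⁺ +
100 (or 60) Cl⁻ (`scenario_composition()`), 300 K. Tests and the acceptance
script run 10–20 ions and 10³–10⁴ frames so the whole suite stays fast;
those sizes are stated with each analysis.

## Binding-motif analysis

The observable is the **carboxylate-carbon–ion distance** — the quantity
whose RDF separates bidentate direct (first peak), monodentate direct
(second peak) and solvent-shared/indirect binding (the region ending near
0.59 nm, with an internal dip near 0.45 nm for strongly hydrated ions such
as Mg²⁺ that distinguishes two- from one-hydrogen-bond solvent-shared
pairs). An oxygen-coordination-count criterion would be an alternative
bidentate definition; the carbon-distance bands are chosen because they are
what the RDF analysis actually measures, and the O-based view can be built
from the same frames if needed.

- `compute_rdf()` normalizes g(r) for slab geometry: each reference
  particle's spherical shell is clipped to the box in z (zone area
  2πr·h), integrated over the bin by Simpson's rule, so an ideal gas gives
  g ≈ 1 even near the walls. Coordination n(r) is the running B-count per
  A particle.
- `derive_cutoffs()` smooths with a centred moving average (default window
  **5 bins**) and places each cutoff at the *first* local minimum after
  each peak (ties broken first). With fewer than three resolvable peaks
  there is no identifiable indirect region and the function refuses,
  directing the user to `cutoff_scheme()` — the cutoffs are then labelled
  `source = "manual"`, and all downstream results carry the scheme used.
- Per ion and frame the counts satisfy bidentate ≤ direct ≤ total by
  construction; the category string is the sorted union of contact types
  ("B+M+I" etc.).
- `bound_count_series()` operationalizes convergence as: the two
  half-window means of the final `window` frames differ by < `tol` ions,
  default **1 ion** — the observed run-to-run standard deviation of the
  bound count in the reference simulations.

## The three binding-strength estimators

**Adhesion forces.** Pull records hold the force the ion exerts on its
moving restraint, so a bound ion produces a negative dip returning to ≈ 0
after detachment (whether published pull forces are spring or constraint
forces is not always stated; we record the spring force and say so).
`extract_adhesion()` uses non-overlapping bins of **500 points** and takes
the plateau as the final **20 %** of bins (configurable, logged); the
adhesion force is |most-attractive bin mean − plateau|, reported positive.
Binning flattens a dip by ≈ w²/(24σ²) for bin width w and dip width σ, so
synthetic-recovery tests use dips wide against the bin. `tip_average()`
means over the pulled ions whose start positions fall in a centred
**2.4 nm × 2.4 nm** square — the footprint matching a 3–6 nm² AFM tip
contact area.

**WHAM PMF.** Standard self-consistent iteration on the window free
energies to max|Δf| < **10⁻⁸ kJ/mol** (default bin width **0.02 nm**);
uncertainty by Bayesian bootstrap — flat Dirichlet weights over windows,
**200** replicates, seeded. Bins with fewer than `min_count = 5` pooled
samples are reported `NA` rather than as wild free energies; the PMF is
anchored so the final 10 % of well-sampled bins average zero, and
`pmf_binding_dg()` reads ΔG as the interior minimum's depth below that
plateau (no interior minimum ⇒ unbound, ΔG = 0, flagged). The per-ligand
view divides by the mean ligands-per-bound-ion (≈ 4.7 for Mg²⁺, 4.4 for
the larger ions in the reference system).

**Langmuir isotherm.** `K₀ = q_e/(q_m−q_e)·C₀/C_e`, `ΔG° = −RT ln K₀` at
C₀ = 1 mol/L. Three readings had to be fixed:

- *q_m*: taken as the **total divalent-ion count** — the source's "assuming
  all divalent metal ions are bound… because there are fewer divalent metal
  ions than binding sites" sentence conflates q_e and q_m, and this reading
  makes q_m the attainable capacity. The lattice-site alternative is one
  argument away (`n_divalent_total`).
- *Units*: the isotherm is dimensionless in q, so ion counts are used
  directly; `ions_to_mg_per_g()` provides the mg/g reporting view with
  standard atomic weights.
- *Solution volume for C_e*: box cross-section × slab height above the
  headgroup plane, both configurable — no volume convention is stated in
  the source. "Bound" means any contact within `total_max` (whether the
  indirect band counts is unstated; the inclusive reading is the default
  and the cutoff scheme travels with the result).

**AFM conversions.** The work picture is ΔG_bind = N_A·F_AD·L per mole —
the printed form of the conversion shows F·L and k_BT together ambiguously,
and the source's own worked number (78.4 pN × 3.32 Å → 15.7 kJ/mol) fixes
the per-mole convention adopted here; k_BT survives only as the optional
dimensionless `dG_over_kT` column. L defaults to the 0.22 nm O–O distance
(the length a carboxylate traverses leaving an ion bridge); the hydrated-
or ionic-radius alternatives rescale ΔG without reordering ions. The
Friddle equilibrium limit is ΔG = N_A·F_eq²/(2k); the two agree exactly
when L = F_eq/(2k), an identity the tests assert numerically.

## Structural observables

Chain tilt uses the **principal axis** of the chain atoms (robust to kinks;
the endpoint vector is available via `method = "endpoints"`), folded to
[0°, 90°] so it is reversal-invariant. Density profiles are per-species z
histograms normalized to integrate back to particle counts. The
electrostatic potential solves the planar Poisson problem by two
trapezoidal cumulative integrations of ρ(z) with ψ(0) = 0, E(0) = 0;
`eps_r` defaults to 78.5 with 1.0 for vacuum-referenced profiles (which
convention the reference supplementary profiles used is unstated — both
are supported). A sign change of ψ in the interior flags charge inversion.

## Problem sizes and limitations

The test suite and `scripts/acceptance.R` use: 10–20 ions over 10³–10⁴
generated frames; 16 independent Brownian walkers for 10⁵ steps; 21
analytic umbrella windows × 4000 samples with 200 bootstrap replicates;
10⁴-point force traces; 50-particle RDF frames. These sizes make every
recovery criterion sharp (agreement ≥ 99 %, fractions within ±0.02,
variance within 5 %, PMF within 0.5 kJ/mol) while the whole pipeline runs
in about a minute.

Known limitations, by construction:

- No explicit water: hydrogen-bond-based motif subtyping is impossible;
  the indirect split is available only as an RDF-dip criterion.
- The toy simulator will not reproduce absolute binding statistics or PMF
  magnitudes of cluster-scale explicit-solvent MD (tens to hundreds of
  kJ/mol); it exists to generate controlled test data and qualitative
  behaviour (a divalent ion does bind to the charged lattice).
- Binary trajectory formats (XTC/TRR/DCD) are out of scope; GRO/XYZ/XVG
  text formats are supported.
- The 12-6-4 potential and force-field reparametrization are out of scope.
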