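---
title: "Methods behind halokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind halokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halokin)
```

halokin bundles the desk-side computations of a halophilic dehydrogenase
characterization: steady-state kinetics, coupled-assay design, surface-shell
statistics, molecular-dynamics observables and motif scanning. This vignette
explains the models, their assumptions, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Michaelis–Menten kinetics

Initial velocities are fitted to `v = Vmax [S]/(KM + [S])` by unweighted
nonlinear least squares (Levenberg–Marquardt via minpack.lm). The model
assumes a single saturable site and true initial-rate conditions; it is
appropriate for enzymes that show hyperbolic saturation for both substrates,
and the package deliberately offers no Hill, substrate-inhibition or
bi-substrate models.

Two choices matter for reproducibility:

* **Initialisation.** `Vmax0 = 1.2 × max(v)` and `KM0` equal to the
  substrate concentration whose velocity is closest to `Vmax0/2`. This is
  deterministic — no random restarts — and lands inside the attraction basin
  for any data with visible curvature. Degenerate designs (all-zero
  velocities, or no curvature so `KM` is unbounded) raise a diagnostic error
  rather than returning a silent estimate.
* **Weighting.** Unweighted least squares. Whether published fits of this
  kind weight by variance is rarely stated; with constant-CV noise a
  weighted fit would down-weight the saturated plateau slightly, but on the
  designs used here (7 concentrations spanning ~0.2–13 × KM) the difference
  is well inside the parameter standard errors, so the simpler estimator is
  the default.

Standard errors come from the linearised covariance at the optimum; when a
`replicate` column is present each replicate is also fitted separately and
the SD of the per-replicate estimates is reported, mirroring the
"mean ± SD of three independent measurements" convention of kinetics tables.

Units are mM and minutes internally. `catalytic_efficiency()` is the only
place concentrations are converted to molar, and rounding (2 significant
figures, the table convention) happens only at reporting; full precision is
kept everywhere else.

## Coupled-assay design

A coupled assay observes an enzyme of interest (velocity `v1`, here a
glucokinase producing G6P) through an auxiliary enzyme that consumes the
intermediate B with Michaelis–Menten kinetics. The intermediate balance

$$\frac{d[B]}{dt} = v_1 - \frac{V_2 [B]}{K_{M2} + [B]}, \qquad [B](0) = 0$$

is integrated with fixed-step classical RK4, halving the step until the
maximum change in `[B]` between successive halvings is below 1 nM
(`tol = 1e-9` mM). The full ODE is used rather than the tabulated
transient-time approximations, because it is correct in all regimes —
including auxiliary activities barely above `v1`, where the linearised
theory fails. The first-order closed form
`v2/v1 = 1 − exp(−V2 t/KM2)` (valid when the steady intermediate
`[B]ss = v1 KM2/(V2 − v1)` is far below `KM2`) serves only as an independent
oracle in the tests.

`lag_time()` returns the first time `v2/v1 ≥ ρ`, refined by bisection to
1e-4 min; a configuration whose limiting ratio `min(1, V2/v1)` never
exceeds ρ is reported infeasible. `minimal_auxiliary_activity()` bisects on
`V2` (relative tolerance 1e-6, upper bracket doubled until feasible, hard
cap 10⁶ U/ml) for the smallest auxiliary activity whose lag is within
`t_max`. Defaults fix ρ = 0.99 and `t_max` = 5 min with one-significant-
figure reporting — the strict end of the usual 0.95–0.99 / 1–5 min design
window; under this setting the sizing for `v1 = 0.01` mM/min and
`KM2 = 2.34` mM comes out at 2 U/ml (one significant figure), the
recommendation quoted for this assay. The unit identity 1 U/ml ≡ 1 µmol·min⁻¹·ml⁻¹ ≡ 1 mM/min of
Vmax in the cuvette makes `V2` directly comparable to dispensed units.

Assumptions stated loudly: `v1` is constant (no upstream substrate
depletion), the co-substrate is saturating, and the auxiliary enzyme's
promiscuous background (`promiscuous_rate()`, first-order in enzyme and
substrate, valid for `[S] ≪ KM`) is additive and subtractable
(`background_corrected_rate()`, which warns when background exceeds half the
total signal).

## Solvent-accessible surface area and shells

SASA is computed by the Shrake–Rupley construction: each atom's sphere is
inflated by the probe radius (1.4 Å, water), covered with a deterministic
golden-spiral point set (default 960 points), and the accessible area is the
fraction of points outside every neighbour's inflated sphere times
`4π(r + probe)²`. Two implementation details:

* **Covariant point frames.** Each atom's point set is expressed in a local
  frame built from the directions to its nearest neighbours (ties broken by
  atom index). Distances and indices are unchanged by a global rotation, so
  the frame — and therefore the discretized SASA — rotates exactly with the
  structure: rigid-motion invariance holds to machine precision rather than
  to the ~2% of a fixed laboratory-frame point set. Isolated atoms take the
  identity frame (every point is exposed anyway) and collinear structures an
  arbitrary azimuth (occlusion is then axially symmetric, so the choice
  cannot matter).
* **Determinism.** No randomness anywhere; doubling `n_points` changes the
  exposed/core labels of the test fixtures in under 1% of residues, the
  convergence check shipped in the suite.

Residues with SASA ≥ 20 Å² are classified exposed (external shell), the
boundary inclusive; the rest form the core (internal shell). Whether such a
criterion should use the whole residue or only its side chain is genuinely
ambiguous in the literature, so `residue_sasa(sidechain_only = TRUE)`
provides both; the default sums all atoms. Hydrogens are excluded by
default since homology models are heavy-atom.

`shell_composition()` reports per-shell residue percentages, the acidic
(Asp+Glu) fraction, per-type exposure counts (e.g. exposed tryptophans),
and the core fraction both by residue count and by summed standard residue
volume (a Zamyatnin-style table via `residue_volumes()`): "fraction of the
protein in the core" is quoted both ways in the literature, so both are
given, clearly labelled. The hydrophobic-core set defaults to
{A,V,L,I,M,F,W,C,G} and is configurable.

Van der Waals radii default to C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
H 1.20 Å (others 1.70) and can be overridden from a TSV.

## Trajectory observables

`kabsch_superpose()` computes the optimal rigid superposition by SVD of the
weighted covariance, correcting reflections through the sign of the smallest
singular value; collinear geometries are refused with a rank message. RMSD
series superpose every frame onto a reference over a selection (Cα-only is
the conventional protein choice). RMSF uses an iterated mean reference —
align to the first frame, average, re-align to the average, twice — because
fluctuations should be measured about the mean structure in the molecule
frame; per-atom values are averaged per residue. The radius of gyration is
mass-weighted by default. `replicate_stats()` pools replicate series
pointwise and summarises windows, with a trailing-fraction shorthand
(`window = 0.1` = "last 10%", the usual "last 10 ns of 100 ns" convention).

Selection-pair energies are direct sums: Coulomb
`k q_i q_j / r_ij` with `k = 332.0636` kcal·Å·mol⁻¹·e⁻², and 12-6
Lennard-Jones with Lorentz–Berthelot combination (arithmetic σ, geometric
ε), optionally cut off by distance. An `(A, B)` coefficient reader converts
via `σ = (A/B)^{1/6}`, `ε = B²/4A`. These are *analysis* energies between
two selections (e.g. a substrate against a binding loop, where the sign
separates repulsive from attractive electrostatics), not total-system
energies: there is no periodic imaging, Ewald summation, thermostat or
minimizer here, and input trajectories are assumed already imaged. Energies
are reported in kcal/mol.

## Motif scanning

Exact-pattern scanning with `X` as a wildcard, case-insensitive, 1-based,
overlapping hits reported — biological motifs can overlap, and 1-based
coordinates match residue numbering in structure papers. There is no PWM or
alignment-based inference; conserved-motif discovery from an MSA is a
different workflow. The shipped convention covers loop signatures such as
`NLTXXH` (placed so N and H fall at 181/186 in the reference numbering) and
`YERG`.

## Synthetic data: what it emulates and what it does not

The generators replace the study inputs that cannot be shipped — plate-
reader saturation data, a homology model, and Amber trajectories:

* `gen_mm_dataset()` applies multiplicative Gaussian noise of fixed CV
  (default designs use cv = 0.05, three replicates, seven concentrations
  from 0.5 to 30 mM), the error structure of absorbance-slope assays where
  error scales with signal.
* `gen_toy_structure()` builds burial fixtures with analytic expectations:
  isolated atoms (full sphere area), pairs (two-sphere cap geometry), and
  an icosahedrally caged atom (fully buried centre).
* `gen_trajectory()` adds isotropic per-coordinate Gaussian noise of SD σ
  (expected RMSF `σ√3`), optionally under random per-frame rigid motion;
  noise is additive, the instrument-like choice for positional scatter.
* `gen_progress_curve()` adds Gaussian detector noise to the deterministic
  assay curve.

Each generator is a pure function of its parameters and a single seed, with
the seed recorded on the output and the RNG state scoped locally.

Passing tests on these fixtures show that the estimators and observables are
correct *as computations*: they do not show that real trajectories are
converged, that real assay noise is Gaussian, or that a homology model's
surface is accurate. In particular, synthetic trajectories contain no
force-field physics — no correlated motions, no solvent shielding — so
trajectory-observable values from real simulations (RMSD plateaus, energy
magnitudes) are not reproduced here, only the machinery that measures them.

## Problem sizes and runtimes

The shipped suite uses sizes chosen to exercise every code path at
desk scale: 1000 × 1000 brute-force grids for the fit oracle, 200 seeded
datasets for the recovery study, 2000-frame / 60-atom trajectories for the
RMSF expectation, 960–1920 point SASA on fixtures up to 200 atoms, and an
Euler-grid rotation search refined far below 0.1°. The full suite runs in
well under a minute on a laptop-class core.

## Known limitations

* No weighting, cooperativity or bi-substrate kinetics; no pH modelling.
* The coupled-assay model treats `v1` as constant and single-substrate.
* SASA has no analytic derivatives and the 20 Å² criterion, while standard,
  is a convention; side-chain-only mode exists because the criterion's
  reference area is ambiguous.
* Energies are direct-sum selection-pair terms only; magnitudes from
  periodic simulations with Ewald electrostatics will differ.
* Motif scanning is exact-pattern only.
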