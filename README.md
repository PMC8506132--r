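# halokin

Tools for the computational characterization of halophilic NAD(P)-dependent
dehydrogenases — enzymes such as the short-chain glucose-6-phosphate
dehydrogenase (G6PDH) of *Haloferax volcanii*, which require molar KCl/NaCl
for activity and show the canonical haloadaptation signature (acidic surface,
depleted hydrophobic core). The package is aimed at enzymologists and
structural bioinformaticians who want the full desk-side analysis chain for
such a study in one place, with every input replaceable by a seeded synthetic
generator.

## What it computes

**Enzyme kinetics.** Initial velocities from A340 slopes via Beer–Lambert
(ε = 6.22 mM⁻¹cm⁻¹ for NADH), unweighted Levenberg–Marquardt fits of the
Michaelis–Menten equation

    v = Vmax [S] / (KM + [S])

per salt condition, turnover numbers `kcat = Vmax/[E]`, catalytic
efficiencies `kcat/KM` (M⁻¹s⁻¹), and salt-activity profiles normalized to a
reference condition.

**Coupled-assay design** (Storer–Cornish-Bowden). The intermediate balance
of a two-enzyme assay,

    d[B]/dt = v1 − V2 [B]/(KM2 + [B]),

is integrated with converged fixed-step RK4; the lag time is the first time
the indicator velocity reaches a fraction ρ of the target velocity, and
`minimal_auxiliary_activity()` bisects on V2 for the smallest auxiliary
activity (U/ml) that keeps the lag under a bound. Promiscuous background
activity of the auxiliary enzyme (e.g. glucose oxidation by a G6PDH) is
modelled first-order and subtracted with a dominance warning.

**Surface shells.** Shrake–Rupley solvent-accessible surface area (probe
1.4 Å, deterministic golden-spiral point sets, exactly rigid-motion
invariant), residues classified as exposed when SASA ≥ 20 Å² (inclusive),
and haloadaptation composition statistics: per-shell residue percentages,
core fraction by count and by standard residue volume, acidic (Asp+Glu)
fractions, tryptophan exposure counts, and paired comparisons between a
halophilic protein and a non-halophilic homolog.

**Trajectory observables.** Kabsch superposition, RMSD series, per-residue
RMSF, radius of gyration, replicate mean ± SD with window summaries, and
direct-sum selection-pair nonbonded energies (Coulomb with k = 332.0636
kcal·Å·mol⁻¹·e⁻², 12-6 Lennard-Jones with Lorentz–Berthelot combination) —
the standard CPPTRAJ-style analyses, re-implemented on multi-model PDB or
XYZ trajectories.

**Motifs.** Wildcard scanning (X matches anything) for conserved loop
signatures such as `NLTXXH` (the β6-α10 loop motif, N181…H186) and `YERG`.

**Synthetic data.** Seeded generators for saturation datasets, toy
structures with known burial, Gaussian-fluctuation trajectories with known
RMSF, and noisy progress curves; all are pure functions of their parameters
and seed.

## Worked example

A saturation curve at 2.0 M KCl (synthetic, generated at the fitted scale of
the real assay: 5 nM enzyme, 5% assay noise), fitted and summarised:

```r
library(halokin)

d <- gen_mm_dataset(Vmax = 0.01473, KM = 2.34,
                    s_values = c(0.5, 1, 2, 4, 8, 16, 30),
                    cv = 0.05, replicates = 3, seed = 1,
                    condition = "KCl 2.0 M")
fit <- fit_michaelis_menten(d, enzyme_M = 5e-9)
glance(fit)
#> # A tibble: 1 × 7
#>     Vmax  se_Vmax KM_mM se_KM kcat_s    sigma n_points
#>    <dbl>    <dbl> <dbl> <dbl>  <dbl>    <dbl>    <int>
#> 1 0.0146 0.000262  2.18 0.143   48.7 0.000497       21

catalytic_efficiency(fit$kcat, fit$KM, sig_figs = 2)
#> [1] 22000
```

`Vmax` is in mM/min, `KM` in mM; `kcat` (s⁻¹) divides Vmax by the enzyme
molar concentration, and the efficiency of 2.2 × 10⁴ M⁻¹s⁻¹ is the apparent
second-order constant at sub-saturating G6P. Sizing the auxiliary enzyme for
a glucokinase-coupled assay (target velocity 0.01 mM/min, auxiliary KM
2.34 mM, ratio 0.99 within 5 min):

```r
minimal_auxiliary_activity(v1 = 0.01, KM2 = 2.34, rho = 0.99, t_max = 5)
#> # A tibble: 1 × 7
#>   v1_mM_min KM2_mM   rho t_max_min V2_U_ml V2_reported lag_min
#>       <dbl>  <dbl> <dbl>     <dbl>   <dbl>       <dbl>   <dbl>
#> 1      0.01   2.34  0.99         5    2.17           2    5.00
```

i.e. 2 U/ml of auxiliary enzyme suffices.

## Documentation

The methods vignette (`vignettes/halokin-methods.Rmd`) describes the models,
the numerical choices (integrator convergence, SASA point sets and local
frames, fit initialisation), what the synthetic generators do and do not
emulate, and known limitations.
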