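# ifacetools

Tidy R toolkit for the structural-ensemble and biophysical analyses that sit
downstream of protein–protein docking and molecular-dynamics runs, built
around a concrete biological question: how a homodimeric PAPS-synthase-like
enzyme presents a binding site for a sulfotransferase partner. It is aimed at
structural bioinformaticians who have a pile of docked poses, trajectory
frames, alignments and titration curves and want reproducible, testable
statistics out of them — without re-running the docking or MD engines
themselves.

## What it computes

**Interface contact prevalence.** For an ensemble of docked poses, a residue
is *in contact* in a pose when its minimum heavy-atom distance to the partner
protein is ≤ 3 Å. The prevalence of residue *i* is

&nbsp;&nbsp;&nbsp;&nbsp;*f(i)* = (# poses in which *i* makes ≥ 1 contact) / *n*<sub>poses</sub>,

computed per docking ensemble and then averaged across ensembles with equal
weight (mean ± SD per residue). For a C2-symmetric homodimeric receptor the
two equivalent binding sites are pooled by a union rule:
*f*<sub>folded</sub>(*i*) counts poses in which residue *i* **or** its
symmetry mate contacts the ligand. Domain localization of the top-*k* most
frequent interface residues and the fraction of poses with a *composite*
(two-subunit) binding site are summarised on top.

**Geometry.** Kabsch least-squares superposition (SVD, det = +1 enforced);
the "average complex" of an ensemble (coordinate mean after receptor-Cα
superposition, with the medoid pose reported alongside); interface RMSD of a
pose against that reference (interface = reference residues with heavy atoms
within 10 Å of the partner; fit on receptor Cα, measured on interface Cα
without re-fitting); funnel diagnostics for (score, iRMSD) clouds (Spearman
ρ ≥ 0.4 and best-decile median iRMSD below the global median); trajectory
RMSD traces, earliest-stable-window equilibration detection, and per-residue
RMSF = √⟨|xᵢ − x̄ᵢ|²⟩ with proximal-vs-distant subunit deltas.

**Interface evolution.** Structure-residue ↔ alignment-column maps,
lineage-specific interface residue calls (a column is called when all
in-clade rows share one non-gap residue absent from every out-clade row),
global percent identity (affine-gap dynamic programming, BLOSUM62, 10/0.5)
and Henderson–Hasselbalch isoelectric points (Bjellqvist pKa set, bisection).

**Binding kinetics.** Equilibrium titration fits where the probe is *not*
assumed negligible: the single-site ligand-depletion solution

&nbsp;&nbsp;&nbsp;&nbsp;f<sub>b</sub> = ((P + L + K<sub>D</sub>) − √((P + L + K<sub>D</sub>)² − 4PL)) / 2L,

the Hill equation y ∝ Pⁿ/(K<sup>n</sup> + Pⁿ), an exact competitive
displacement model (coupled mass balances solved numerically per point, EC50
by bisection on the fitted model), and coupled-assay specific-activity
conversion from A340 slopes (ε = 6220 M⁻¹cm⁻¹).

**Synthetic data.** Every input class has a seeded generator with planted
ground truth (exact contact counts, known σ fluctuation profiles, known
clade-specific columns, exact forward-model titrations), so the entire
pipeline is testable end to end with no structure downloads.

## Worked example

```r
library(ifacetools)

base <- make_dimer_complex(site_residues = c(5, 9, 13, 21), seed = 1)
ens  <- make_pose_ensemble(base, n_poses = 30,
                           target_freqs = c(1, 0.8, 0.5, 0.1), seed = 1)
prof <- prevalence_profile(ens, receptor_chains = c("A", "B"),
                           ligand_chains = "L")
dplyr::filter(prof, freq > 0, side == "receptor")
#> # A tibble: 4 × 8
#>   side     chain resno icode resid count n_poses  freq
#> 1 receptor A         5 ""    ALA      30      30   1
#> 2 receptor A         9 ""    ALA      24      30   0.8
#> 3 receptor A        13 ""    ALA      15      30   0.5
#> 4 receptor A        21 ""    ALA       3      30   0.1
```

The planted contact frequencies come back exactly: residue 5 touches the
ligand in all 30 poses, residue 21 in 3 of 30. `fold_dimer_symmetry()` then
pools the two dimer sites, and `autoplot(prof)` draws the profile.

```r
cur <- make_titration("single_site", params = list(KD = 13.2, L = 1),
                      x_grid = c(0.5, 1, 2, 5, 10, 20, 35, 50, 75, 100, 125, 150),
                      noise_sigma = 0)
fit_single_site(cur)
#> <iface_binding_fit> model = single_site, n = 12, RSS = 2.775e-18
#>   KD             13.2 +/- 3.6e-08
#>   F_min     1.241e-09 +/- 1.94e-10
#>   F_max             1 +/- 5.18e-10
```

A 1 µM fluorescent probe titrated with 0–150 µM protein sits squarely in the
ligand-depletion regime; the quadratic fit recovers the generating
K<sub>D</sub> = 13.2 µM to machine precision. `tidy()`, `glance()`,
`augment()` and `autoplot()` work on all fit objects.

```r
funnel_analysis(make_funnel_points(n = 200, seed = 1))
#> # A tibble: 1 × 7
#>     rho low_score_median_irmsd global_median_irmsd is_funnel     n ...
#> 1 0.955                   1.67                6.31 TRUE        200
```

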