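---
title: "Interface ensemble analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface ensemble analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifacetools)
library(dplyr)
```

This vignette is the package's own account of the science it implements: the
statistical models behind each stage, the conventions adopted where several
are defensible, what the synthetic generators do and do not emulate, and the
numerical choices that make results deterministic.

## The setting

The package targets a recurring analysis pattern in structural biology:
a homodimeric enzyme (here, a PAPS-synthase-like receptor with an APS kinase
and an ATP sulfurylase domain per subunit) is docked against a monomeric
partner (a sulfotransferase-like ligand), producing tens of plausible poses
per docking run rather than one answer. The scientific questions are then
statistical: *which receptor residues are repeatedly at the interface?* *do
they cluster in one domain?* *do better-scoring poses agree geometrically
(a funnel)?* *does the partner rigidify the subunit it touches?* *which
interface residues are lineage-specific?* and, on the wet side, *what are
the binding constants of the nucleotide that modulates the receptor?*

## Contact prevalence

A residue pair (receptor residue $r$, ligand residue $l$) is a **contact**
when the minimum distance between any heavy atom of $r$ and any heavy atom
of $l$ is at most the cutoff (default 3 Å). Two conventions are deliberate:

* **Heavy atoms only.** Docked and modelled structures frequently lack
  hydrogens, and a residue-level 3 Å criterion is conventionally read as
  heavy-atom distance; hydrogens are parsed but excluded by default
  (`atoms = "all"` restores them).
* **Per-pose, binary counting.** The prevalence of residue $i$ is the
  fraction of poses in which $i$ makes *at least one* contact. A residue
  touching the ligand through four atoms in one pose counts once: the unit
  of observation is the docking experiment, not the atom pair.

The search is cell-list accelerated (cubic cells with edge = cutoff; only the
27 neighbouring cells are compared), which is exact for this geometry; the
test suite verifies exact agreement with an all-pairs brute-force scan on
1,000 random complexes.

**Symmetry folding.** A C2-symmetric homodimer presents two equivalent
binding sites. Treating them separately halves every frequency and hides the
signal, so the two sites are pooled with a **union rule**: the folded count
of position $i$ is the number of poses in which $i$ *or* its symmetry mate
contacts the ligand. The union satisfies
$\max(f_A, f_B) \le f_{folded} \le \min(f_A + f_B, 1)$, which the tests
assert on random ensembles. Folding requires the per-pose contact records,
which `prevalence_profile()` keeps on the profile object; a frequency table
alone cannot be folded correctly.

**Averaging across ensembles** is unweighted per ensemble (mean and sample
SD per residue) even if pose counts differ, because each docking set is one
independent experiment of equal standing.

**Domain localization.** The top-$k$ residues by mean frequency (default
$k = 20$, ties broken by ascending residue number for determinism) are
assigned to user-supplied domain intervals; the localization index is the
largest single-domain share and the profile is flagged "localized" at
index ≥ 0.8. Both the $k$ and the threshold are artifact defaults: they
operationalise a qualitative "clustered vs scattered" contrast and are
exposed in the run configuration precisely because they are judgement calls.

**Composite sites.** A pose is *composite* when at least 3 contacting
receptor residues (configurable) come from each subunit — the signature of a
binding site built jointly by both copies of the dimer, including the
swapped N-terminal peptide geometry seen in this enzyme family.

## Geometry

**Superposition** is the classical Kabsch solution via SVD of the 3×3
cross-covariance, with the smallest singular direction sign-flipped when
needed so the rotation always has determinant +1 (reflections excluded).
The tests cross-check the minimal RMSD against an independent quaternion
(Horn) implementation on 1,000 random instances.

**Average complex and iRMSD.** Docking clouds are summarised against an
"average complex": all poses are superposed on the first pose's receptor
C$\alpha$ atoms and averaged per atom. Coordinate means can be
stereochemically unphysical, so the **medoid** pose (minimum mean RMSD to
the others in the common frame, ties to the lowest index) is reported
alongside as the robust fallback. The interface RMSD convention — one of
several defensible ones, so it is stated explicitly and configurable — is:

1. interface residues are defined **on the reference only**: any residue
   with a heavy atom within 10 Å of the partner;
2. the pose is fitted to the reference on **receptor C$\alpha$** atoms;
3. iRMSD is the C$\alpha$ RMSD over the union of receptor- and ligand-side
   interface residues, **without re-fitting** on the interface set.

**Funnel analysis.** "Better scores coincide with smaller deviations" is
made operational as: Spearman rank correlation $\rho(\text{score},
\text{iRMSD}) \ge 0.4$ *and* the median iRMSD of the best-scoring decile
below the global median. Both thresholds are reported with every result and
never applied silently; on the synthetic funnel generator
(score = iRMSD + $\mathcal N(0,1)$, 200 points) versus its score-shuffled
null, this classifier is correct in ≥ 95% of seeded replicates.

**Trajectories.** RMSD traces superpose each frame onto the reference on the
selected atoms (time = frame index × dt, first frame at 0 ps).
Equilibration is the earliest start frame from which *every* subsequent
sliding window (default 10 frames) has range ≤ 0.5 Å — defaults chosen to
express a "reaches a plateau within a nanosecond" criterion at a 2 ps frame
spacing, and both exposed. RMSF uses a 2-pass alignment (to the topology,
then to the resulting mean structure); aligning to the topology rather than
to frame 1 makes the estimate independent of frame order, which the tests
assert. For iid isotropic per-atom displacements of standard deviation
$\sigma$ per axis, $\mathbb E[\text{RMSF}] = \sigma\sqrt 3$; the rigid-body
fit absorbs 6 degrees of freedom, i.e. a fraction $6/(3N)$ of the
fluctuation variance for $N$ fitted atoms, so recovery tests use structures
large enough ($N \gtrsim 150$) that this bias stays below ~1%.

The proximal/distant comparison maps each interface residue of the subunit
touching the partner onto its copy in the distant subunit and reports
$\Delta_i = \text{RMSF}_\text{prox}(i) - \text{RMSF}_\text{dist}(i)$; a
predominance of negative deltas is the rigidification signature of a bound
partner.

## Interface evolution

**Residue–column maps** pair the $k$-th non-gap character of an alignment
row with the $k$-th structure residue; the degapped row may be a substring
or superstring of the structure sequence (constructs and crystals rarely
cover identical ranges), with unmatched tails reported. Columns are 1-based
throughout, the R convention.

**Lineage-specific calls** are strict by default: all in-clade rows share
one non-gap residue and that residue occurs in *no* out-clade row; a gap in
any in-clade row disqualifies the column. A relaxed mode
(`max_out_freq > 0`) tolerates low-frequency leakage but is off by default
because "specific to a clade" is an absolute claim.

**Percent identity** uses an in-package Gotoh global alignment (affine gaps:
a gap of length $L$ costs $10 + 0.5L$; BLOSUM62). Identity = identical
aligned pairs / alignment columns, excluding terminal-gap columns and any
column containing `X` from both numerator and denominator. Identity values
are sensitive to these conventions (and to which co-optimal alignment the
traceback picks), so they are declared rather than implied; alignment
*scores* are verified against an independent implementation in the tests.

**Isoelectric points** solve $Z(\text{pH}) = 0$ by bisection, where $Z$ is
the Henderson–Hasselbalch sum over the termini and the D, E, C, Y
(negative) and H, K, R (positive) side chains with the Bjellqvist pKa set
(Cys ionizable, disulfides ignored; `X` carries no charge). The result
depends only on composition plus the N-terminal residue class.

## Binding kinetics

Fluorescent-probe titrations here use ~1 µM probe against affinities of
10–25 µM, so the textbook assumption "free ≈ total titrant" fails at the low
end. The default single-site model is therefore the **exact
ligand-depletion quadratic**
$$f_b = \frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4PL}}{2L},$$
which reduces to the hyperbola $P/(K_D + P)$ as $L \to 0$ (relative
deviation < 0.1% at $L = K_D/1000$, asserted). The Hill model
$y \propto P^n/(K^n + P^n)$ quantifies apparent cooperativity, with $n$
bounded to $[0.2, 5]$ and a warning when pinned.

All fits use Levenberg–Marquardt least squares from **three deterministic
starts** ($K_D$ initialised at the curve midpoint and ×0.1 / ×10 of it),
keeping the best-RSS solution — multi-start removes basin sensitivity
without introducing seed-dependent behaviour. Standard errors come from the
local curvature of the objective at the optimum. Grid-search oracles
(linear parameters profiled out in closed form) confirm the optimizer finds
the global basin on noisy instances.

**Displacement titrations** (fixed protein + probe, rising competitor) are
fitted with the exact competitive equilibrium: the free-protein mass balance
$p + L_t p/(K_{D,probe} + p) + C_t p/(K_{D,comp} + p) = P_t$ is solved
numerically per point (bisection to $10^{-9}$ µM), with the probe $K_D$
fixed from the prior direct titration and the competitor $K_D$ fitted. EC50
is derived by bisection on the fitted model as the competitor concentration
halving the bound probe. A descending-logistic fallback exists for data the
equilibrium model cannot describe. The displacement fitter is validated on
synthetic truth only: no reference EC50 values are assumed.

**Coupled-assay rates** convert an A340 slope to a molar rate with the NADH
extinction coefficient ε = 6220 M⁻¹cm⁻¹ (the standard constant) and the
cuvette volume, then normalise by enzyme mass. The linear window is
user-selected, not auto-detected — automatic window selection hides
judgement that belongs to the analyst.

## The synthetic-data generators

The generators exist so every stage can be tested by *recovery of planted
truth*; their defaults encode the study conditions the analyses are meant
for (30 poses per docking ensemble, 3 Å contacts, a 1 µM probe titrated to
150 µM protein, 2 ps frame spacing). Key design points:

* **Exact counts, not sampling.** Contact planting realises
  `round(f · n_poses)` contacts exactly, so prevalence recovery is an exact
  equality test; a Bernoulli mode exists for stochastic tests.
* **Margins.** Planted contacts sit at ≤ 2.7 Å and everything else at
  ≥ 3.3 Å, so floating-point noise cannot flip a contact at the 3 Å cutoff.
* **Adversarial-noise-free MSAs.** One out-clade "keeper" row per background
  column always retains the consensus and is never gapped, so substitution
  noise and gaps can never fabricate a clade-specific column; planted
  columns satisfy the strict call definition by construction.
* **Purity.** Every generator is a pure function of its arguments, seed
  included; regeneration is byte-identical, and all randomness is local to
  the call (no global RNG state leaks).

What the generators do **not** emulate: docking energetics, force-field
physics, realistic side-chain packing or sequence covariation. Geometry is
minimal (pseudo-atoms with correct heavy-atom contact semantics). Passing
recovery tests therefore demonstrates that the *statistics* are computed
correctly, not that any particular docking or MD result is right — real
pose ensembles bring correlated errors, missing density and renumbering
that the generators deliberately avoid.

## Problem sizes and determinism

The shipped tests run at desk scale by choice: 1,000 random complexes of up
to ~500 atoms for the contact oracle, 1,000 instances for the superposition
oracle, 2,000 frames for the RMSF closed-form recovery, 200 seeded
replicates each for funnel discrimination, noisy-fit recovery and MSA
calling. Tie-breaks are deterministic everywhere (top-$k$ by ascending
residue number, medoid by lowest index, multi-start by best RSS with fixed
start order), and `run_pipeline()` records the configuration hash and seed
in its run log so identical inputs yield identical outputs.

## Known limitations

* PDB only; mmCIF and compressed trajectory formats are out of scope, as are
  bond perception and protonation.
* Prevalence denominators count all supplied poses; if an upstream filter
  discarded poses, the caller must pass the filtered ensemble.
* Identity percentages depend on the stated alignment conventions; compare
  across methods only at the integer level.
* The ligand-depletion model assumes one class of independent sites; it is
  not a multi-site cooperative binding model (the Hill fit is the
  phenomenological check that $n \approx 1$ justifies the single-site
  reading).
* The mean structure used as the RMSF reference can be unphysical for large
  conformational changes; the medoid is reported for exactly that reason.
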