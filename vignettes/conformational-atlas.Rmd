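---
title: "Conformational ensemble atlases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensemble atlases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confatlas)
```

## The problem

Small GTPases such as Ras switch between GTP- and GDP-bound conformations
that differ mainly in two loops, switch 1 (residues 25–40) and switch 2
(57–75). Individual crystal structures show these states frozen; a
*crystallographic ensemble* — dozens of deposited structures of the same
domain — samples the accessible conformational space. This package builds a
principal-component "atlas" of such an ensemble and uses it as a fixed
reference frame: new conformers (crystal structures or trajectory frames)
are projected into the atlas, where hierarchical clustering separates
nucleotide-dependent states, and per-trajectory analytics (RMSF, DCCMs,
catalytic distances, pseudo-torsions) quantify dynamics.

## The model, step by step

**Common residue frame.** Structures of near-identical isoforms (H-Ras vs
K-Ras: >90% identity) are mapped onto a reference by global sequence
alignment (match +1, mismatch 0, linear gap −1; at this identity the
alignment is insensitive to scoring details). `build_ensemble()` restricts
the frame to a residue window — by default 1–166, the catalytic G domain —
and keeps the intersection of positions present in every member, so each
conformer contributes exactly one Cα coordinate per frame position.

**Invariant core.** Superposing on all residues lets mobile loops bias the
reference orientation. `find_core()` instead iterates: superpose all
conformers onto the ensemble mean over the currently retained positions
(one pass per round), score each retained position by the trace of its 3×3
coordinate covariance across conformers, and remove the highest-variance
batch. Ties remove the higher residue index first, making the search fully
deterministic. The stop rule — retain `stop_fraction` (default 0.5) of the
positions, never fewer than `min_positions` (default 3) — is a free
parameter of this family of methods; because the per-round removal history
is recorded, any other cut can be revisited after the fact without
re-running. The variance score is monotone-equivalent, for these purposes,
to the ellipsoid-volume scores used elsewhere, and simpler to reason about.

**PCA atlas.** `fit_pca()` superposes every conformer onto the ensemble
mean over the *core* positions, then diagonalizes the covariance matrix of
all 3M Cartesian coordinates (divisor N−1). The covariance deliberately
spans the full frame, not just the core: the core defines the orientation,
while the mobile switch regions dominate the leading eigenvectors — which
is exactly what separates GTP-like from GDP-like states on PC1. The
internal fit-to-mean cycle is iterated to convergence (mean change below
1e−12), so that re-fitting any member onto the stored mean is the identity
transform; this makes two algebraic identities hold exactly, and both are
tested: projecting the fitting ensemble returns per-component score
variances equal to the eigenvalues, and keeping all components
reconstructs every fitting conformer. Eigenvector signs are fixed (largest
coordinate positive), since a covariance eigenvector's sign is arbitrary
but reproducible projections are not negotiable.

**Projection and state clustering.** `project()` superposes a conformer
onto the atlas mean over the core and scores it against the leading
eigenvectors; a rigidly transformed copy therefore projects identically.
`cluster_projections()` applies agglomerative clustering with complete
linkage and Euclidean distance in the projected subspace — chosen for the
compact, ball-like clusters that nucleotide states form — and renumbers
labels by descending cluster size. Linkage and metric are configurable;
the cluster count is a user decision, not estimated.

**Trajectory metrics.** All fluctuation statistics use the same
convention: frames are superposed onto their mean over a fit set (initial
fit to frame 1, one mean recomputation — the standard two-pass choice that
makes RMSF minimal without over-fitting each frame), then

* `rmsf()` is the root mean square of the per-residue displacement about
  the mean (divisor N);
* `dccm()` is the normalized displacement-vector covariance
  C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩), symmetric, unit diagonal,
  in [−1, 1]. Residues with zero fluctuation get flagged zeros rather than
  an exception. The conventional display cutoff (|C| > 0.25) is stored as
  a view option and never applied to the data;
* `rmsd_series()` superposes each frame onto a reference over the fit set
  and evaluates RMSD over a selection (named presets: P-loop 10–17,
  switch 1 25–40, switch 2 57–75, switch 3 {47–49, 161–165});
* `pseudo_torsions()` computes the Cα(i−1, i, i+1, i+2) virtual dihedral,
  undefined across chain breaks (consecutive Cα–Cα distance > 4.5 Å
  against a ~3.8 Å virtual bond); `torsion_delta()` wraps differences onto
  [0, 180] degrees;
* `compare_rmsf()` pairs the replicate-mean RMSF of the two systems by
  residue and applies the classic two-sided paired t-test with M−1 degrees
  of freedom. If the differences have zero variance the statistic is
  undefined; the result is flagged and reported as the limiting p-value
  (1 for identical profiles, 0 for a constant offset) instead of raising.

## What the synthetic data emulates — and what it does not

`sample_ensemble()` plants low-rank structure (orthogonal modes with
chosen variances, cluster offsets with mixing weights) on an ideal
reference chain, plus isotropic noise and optional rigid-body jitter;
`sample_trajectory()` draws per-frame displacements whose residue-level
correlation equals a target matrix (the same correlation applied
independently per Cartesian axis, the simplest construction whose DCCM
equals the target analytically); `plant_flexible_appendage()` turns chosen
positions into a rigidly jittering appendage with the complementary rigid
core as ground truth. Generation is deterministic: one substream per
conformer index, so enlarging N never reshuffles earlier members.

Two design points deserve emphasis, because they encode what superposition
can and cannot see:

* **Planted modes are internal motions.** Random mode directions (and the
  two-state fixture's cluster offset) are orthogonalized against the
  six-dimensional rigid-body subspace of the reference. Superposition
  removes rigid components by construction, so a "mode" with rigid content
  is simply not observable; planting one would bias eigenvalue recovery by
  about 6/(3M) and shrink planted cluster separations.
* **Correlated trajectories carry quasi-rigid anchors.** If every residue
  fluctuates with the planted correlation, fitting frames on all residues
  absorbs the rigid-like component of the correlated field — a two-block
  anticorrelated pattern on an elongated chain looks like a rotation, and
  recovery fails badly (errors up to ~0.7 in correlation units). Giving a
  subset of residues a much smaller displacement amplitude
  (`displacement_sigma` as a per-residue vector) and fitting on them
  mirrors actual practice — superpose on the invariant core, measure
  correlations everywhere — and makes the planted matrix recoverable to
  within sampling error.

The generator emulates the *statistical* structure the analysis assumes:
Gaussian modes, well-separated states, stationary correlations, exact
rigid contamination. Real ensembles violate all of these gracefully —
anharmonic loops, partially occupied states, missing residues, crystal
contacts — so passing tests demonstrate correctness of the machinery, not
that any particular biological conclusion transfers.

## Numerical choices and edge cases

* Kabsch superposition via SVD with reflection correction (det +1
  enforced); fit sets must contain ≥3 non-collinear points, checked via
  the second singular value (< 1e−8 is degenerate).
* Altloc resolution keeps the highest-occupancy copy, first-in-file on
  ties; waters are dropped; HETATM nucleotide records (GTP, GDP, and the
  non-hydrolyzable analogs GNP/GCP) are retained and flagged, with the
  γ-phosphate named PG.
* An ensemble of identical conformers ties every position at zero
  variance; the core search then retains the lowest-index positions — a
  stated tie-break, not an accident.
* Torsions are reported in (−180, 180] and differences wrapped to
  [0, 180], so 170° vs −170° is a 20° change.
* Projection requires exact residue-frame agreement with the atlas and
  names the offending residues otherwise.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to separate signal from sampling error by a comfortable
margin while completing in seconds: 500-conformer ensembles for
eigenvalue/mode recovery (sampling sd of an eigenvalue estimate at N = 500
is ~6%, against planted variances 9/4/1 Å² and 0.01 Å noise), 100 seeds of
50-position ensembles for core recovery, 5000-frame trajectories for DCCM
recovery (entrywise sampling error ~1/√(3N) ≈ 0.008 against a 0.05 band),
40-conformer two-state ensembles (10 Å separation, 0.5 Å noise) for
clustering, 50 random 6-point instances for the Kabsch-vs-brute-force
equivalence, and 100 replicates of 166-residue profiles for the paired-t
power check (0.3 Å offset against 0.2 Å residue noise).

## Known limitations

* Only the PDB dialect is read (no mmCIF); chains are selected by id, not
  by biological assembly.
* The core search's stop rule is a convention; the history log is the
  mechanism for exploring alternatives, and no attempt is made to infer an
  "optimal" core size.
* The paired t-test treats residues as paired observations; spatial
  correlation along the chain makes its p-values optimistic, which is the
  field's standard usage of this test, not a claim of independence.
* Fig-level quantities that depend on long explicit-solvent trajectories
  (absolute RMSF magnitudes, specific catalytic distance averages) cannot
  be reproduced without those trajectories and are out of scope for the
  checks; the machinery that would compute them is exercised on synthetic
  trajectories instead.
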