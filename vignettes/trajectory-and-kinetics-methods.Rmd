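---
title: "Methods: ensemble post-processing and cleavage/religation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble post-processing and cleavage/religation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topotraj)
```

## Scope and motivation

Human topoisomerase IB (hTop1) relaxes DNA supercoils through a transient
covalent 3'-phosphotyrosine intermediate; camptothecin (CPT) kills cells by
slowing the religation step of that cycle. Resistance mutations in the linker
domain (residues 636-712) are repeatedly explained by the same two
observations: a faster religation rate in vitro, and a loss of correlated
motion between the linker and the C-terminal domain in simulation. This
package implements the quantitative layer of that explanation — everything
after the trajectory or the gel:

* multi-model PDB ensemble I/O with a validated atom roster;
* Kabsch superposition, per-frame RMSD, per-residue RMSF;
* the C-alpha dynamic cross-correlation map (DCCM), summarised over a domain
  decomposition, and wild-type/mutant map comparison;
* salt-bridge occupancy and nearest-partner switching;
* normalisation and first-order rate fitting of densitometry time courses,
  with a bootstrap rate-ratio comparison;
* synthetic generators for all of the above with known ground truth.

Running molecular dynamics itself, building solvated systems, and gel image
processing are out of scope: the package consumes coordinate ensembles and
quantified band intensities.

## Data model

A `ConformationalEnsemble` is a fixed atom roster (serial, atom name, residue
name and number, chain, element) plus an `n_atoms x 3 x n_frames` coordinate
array in Angstrom. Atom identity is `(chain, residue number, atom name)`;
when reading multi-model PDB files every model is mapped onto the first
model's roster by identity, so renumbered serials are tolerated and a missing
or extra atom is an error naming the offending atom. Residue numbering is
1-based author numbering and intervals are inclusive on both ends, matching
the conventional "residues 1-214" style of domain definitions. Insertion
codes are rejected (interval arithmetic over author numbering would be
ambiguous); alternate locations keep altloc "A" or blank. Frame times default
to the 0-based frame index. Frame slicing (`slice_frames`) is exposed for
stride/equilibration handling, but no analysis discards frames silently —
which frames enter an analysis is always the caller's decision.

## Superposition, RMSD, RMSF

`kabsch_align` is the closed-form SVD solution of weighted least-squares
rigid superposition, with the reflection case resolved by flipping the
smallest singular vector so a proper rotation (det = +1) is always returned.
Collinear point sets leave the rotation underdetermined and are rejected.
Weights default to uniform: the analyses here are C-alpha-based and no mass
weighting is implied. The test suite checks the implementation against an
independently coded closed-form quaternion (Horn) superposition.

`rmsf_profile` reports, per residue, the root-mean-square deviation of its
single selected atom (default C-alpha) from its ensemble-mean position after
superposition. Three fit modes are provided:

* `"iterative-mean"` (default): superpose all frames on the first frame,
  recompute the mean structure, re-superpose on it, and repeat (two
  refinement passes). This is the standard convention when no external
  reference is preferred, and it is shared with the DCCM computation so
  fluctuations and covariances use one alignment.
* `"frame0"`: superpose on a reference frame, the RMSD-style convention.
* `"none"`: no superposition, for ensembles known to contain no global
  motion (e.g. synthetic ones).

Units are Angstrom by default with an `"nm"` toggle. For isotropic Gaussian
jitter with per-coordinate standard deviation sigma, RMSF equals
sigma * sqrt(3); the suite verifies this closed form to 2% at sigma in
{0.2, 0.5, 1.0} Angstrom with 20,000 frames and 60 residues, using
`fit = "none"` because the generator adds no global motion — with fitting
enabled, removing the 6 rigid-body degrees of freedom deflates RMSF by a
factor of about sqrt(1 - 2/N), which is a property of the convention, not an
error. Superposition removal is validated separately: ensembles corrupted
with per-frame random rigid motions (rotations uniform on SO(3), translations
in a 10 Angstrom cube) recover the fluctuation statistics of their
uncorrupted twins.

## Dynamic cross-correlation maps

The DCCM entry for residues i and j is the normalised scalar covariance of
their displacement vectors,

C_ij = <dr_i . dr_j> / sqrt(<dr_i^2> <dr_j^2>),

with dr the displacement from the mean structure after superposition. This
is the standard C-alpha DCCM with values in [-1, 1]; +1 is fully correlated,
-1 fully anticorrelated motion. One map is computed from the full trajectory:
no windowing or striding is applied by default (windowed averaging is left to
the caller via `slice_frames`). Zero-variance residues make the normalisation
undefined and are reported by residue number.

`block_summary` turns the visual reading of a map into numbers: the mean (and
signed extreme) of C_ij over every pair of domains of a `DomainMap`, with the
diagonal excluded from within-domain blocks. `compose_triangle_map` builds
the conventional two-system rendering (one map in the upper triangle, the
other in the lower), and `correlation_loss` reports per-block mean
differences plus each map's global mean |C| — the scalar that drops when a
mutation decouples domain motions.

The implementation is vectorised (per-axis cross-products); the suite pins it
to a naive per-pair double loop at 1e-12 and to an independent reference
implementation (bio3d) at 1e-6.

## Salt bridges and partner switching

A salt bridge is scored per frame by the minimum distance over all cross
pairs of the two residues' selector atoms; the default selectors are the
charged side-chain heavy atoms (ARG: NH1/NH2/NE, LYS: NZ, ASP: OD1/OD2,
GLU: OE1/OE2, HIS: ND1/NE2) and the default criterion is 4.0 Angstrom.
No angular term is used: the binary formed/broken reading keeps occupancy
monotone in the cutoff, and the cutoff is a per-pair parameter. Occupancy
("existence") is the percent of frames formed. A glycine has no charged side
chain, so requesting selectors for it is an error — which is exactly what a
Glu-to-Gly resistance mutation does to its salt bridge.

`partner_switch_profile` finds, per frame, the nearest of several candidate
residues to a probe residue (minimum cross-atom distance, ties to the lower
residue number for determinism) and reports the fraction of frames each
partner wins — the statistic behind "residue X contacts T605 in the wild
type but L606 in the mutant".

## Synthetic ensembles with known ground truth

`ensemble_spec`/`sample_ensemble` generate Gaussian C-alpha ensembles around
a helix-like mean chain (3.8 Angstrom spacing): per-residue, per-coordinate
standard deviations sigma_i, and scalar correlations prescribed per residue
pair as isotropic couplings (the same rho on x, y, z). Isotropy makes the
expected DCCM entry exactly rho, the cleanest ground truth for recovery
tests. The full correlation model is validated to be positive semidefinite
at build time; an infeasible request (e.g. the triangle 0.9/0.9/-0.9) is an
error, and a cross-block anticorrelation is only feasible together with
within-block correlation (a shared-mode structure such as +0.49 within each
block and -0.49 across is used throughout the tests). Optional rigid-body
noise composites each frame with a uniform random rotation and a translation
in a 10 Angstrom cube — large enough that unremoved global motion visibly
corrupts naive statistics, which is what the negative controls check.

`telegraph_spec`/`sample_telegraph` generate a two-state Markov chain with
stationary formed probability exactly p (exit probabilities (1-p)/dwell and
p/dwell; the initial state is drawn from the stationary law, so the
occupancy estimator is unbiased at any length). `dwell` is the chain's
relaxation time in frames: dwell = 1 gives i.i.d. states, for which the
binomial confidence interval is the exact sampling law used in the
occupancy-recovery tests (at p in {0.09, 0.85, 0.96}, the persistences
reported for the wild-type and mutant bridges); for correlated chains the
tests use the exact two-state Markov variance p(1-p)(1+lambda)/((1-lambda)n)
instead, since a binomial interval would be the wrong oracle there.

`kinetics_spec`/`sample_timecourse` generate first-order cleavage
accumulation (plateau * (1 - exp(-kt))) or religation decay
(plateau * exp(-kt)) observed with multiplicative noise y(1 + cv * eps) and
packaged as band/lane-total signals. Default time grids are 9 points from
0.25 to 30 minutes for cleavage and the same grid anchored at t = 0 for
religation (the assay takes a pre-reaction aliquot as its time-0 point).
Negative noisy observations are clipped at zero with a recorded count.

What the generators deliberately do not emulate: anharmonic and
non-stationary dynamics, solvent and DNA, realistic side-chain geometry, or
multiphasic kinetics. Passing the recovery tests therefore demonstrates that
the estimators are correct under their stated models, not that any particular
experimental trajectory or gel would reproduce the published persistences or
rates — those depend on trajectories that are not deposited and on
densitometry of specific gels.

## Kinetics quantification

The normalisation chain mirrors the assays: `lane_fraction` divides the band
of interest by its lane total (percent), `normalize_to_reference_max`
expresses two conditions on the wild-type maximum, and `normalize_to_t0`
converts a decay course to percent remaining with the first point pinned at
100.

`fit_first_order` fits a single exponential — the minimal model consistent
with first-order cleavage/religation language; the assays this emulates plot
normalised percentages without fitting a model, so rates produced here are
this package's quantification, not published values. The rise model is
plateau * (1 - exp(-kt)). The decay model is offset + A * exp(-kt) with the
offset (a non-religatable fraction) bounded in [0, 50] and a free amplitude
A. The amplitude is free rather than pinned at 100 - offset deliberately:
percent-remaining series are divided by a noisy t = 0 observation, which
injects a common scale error into the whole series; a pinned amplitude
transmits that error directly into the rate, and in simulation the pinned
model's bootstrap intervals covered the true rate in barely half the
replicates, whereas the free-amplitude model restores nominal coverage. Free
amplitude also makes both fits scale-equivariant (multiplying the signal by a
constant cannot change a rate).

Because the noise is multiplicative (constant CV), plain least squares is
inefficient; fitting is therefore weighted with w = 1/max(fitted, 1)^2, one
reweighted Levenberg-Marquardt pass after an unweighted pass (the floor at 1
percentage point keeps near-zero tails from receiving unbounded weight).
Non-convergence is retried from a grid of initial rates (0.02 to 3 per
minute) before erroring.

The rate confidence interval is a seeded residual-resampling bootstrap
(default 1,000 draws) on relative residuals: resampled series are
fitted * (1 + r*), matching the multiplicative error model; refits start
from the base fit's coefficients. `rate_ratio` compares two fits of the same
model by pairing their bootstrap draws index by index and taking percentile
bounds of k_a/k_b. In a simulation at the assay's own scale (5% CV, 9 time
points), a true two-fold religation-rate difference yields a 95% ratio
interval excluding 1 in well over 90% of replicates. An `initial_rate`
estimator (slope of the first few points) is reported alongside for data
where early-slope and full-curve readings could disagree; the two agree for
clean single-exponential courses.

## Numerical choices and degenerate inputs

* PSD validation of correlation models uses a relative eigenvalue tolerance
  of 1e-8; sampling uses the symmetric eigendecomposition square root with
  negative eigenvalues clamped at zero, so rank-deficient (rho = 1) models
  are accepted.
* Kabsch rejects configurations whose second singular value is below 1e-9 of
  the first (collinearity), and always returns det = +1.
* DCCM entries are clamped to [-1, 1] after normalisation to absorb
  last-digit rounding; symmetry is enforced by averaging with the transpose.
* Nearest-partner ties break to the lower residue number; occupancy uses a
  closed criterion (distance <= cutoff).
* `write_multimodel_pdb` emits fixed-width 3-decimal coordinates, so a PDB
  round trip is exact to 1e-3 Angstrom and the roster round-trips exactly.
* Validation problem sizes: 20,000 frames for closed-form and
  correlation-recovery checks, 10,000 frames for occupancy recovery, 100
  seeds for the rate-ratio power study — sizes at which Monte Carlo error is
  comfortably inside each stated tolerance.

## Known limitations

Occupancy percentages depend on the distance criterion; 4.0 Angstrom between
charged heavy atoms is conventional but not universal, and published
persistences computed with other criteria (or angular terms) will differ.
The DCCM here is the scalar-product form: it cannot see correlated motions
at right angles, and no mutual-information or normal-mode alternatives are
provided. The single-exponential kinetics model is intentionally minimal;
multiphasic religation or dose-dependent CPT effects need richer models than
this package fits.
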