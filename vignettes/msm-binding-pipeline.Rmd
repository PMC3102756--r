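---
title: "Markov state model analysis of protein-ligand binding with msmbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state model analysis of protein-ligand binding with msmbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two-lobed periplasmic binding proteins (PBPs) such as the lysine-,
arginine-, ornithine-binding (LAO) protein close around their ligand like a
Venus flytrap: in the bound crystal structure the binding site is fully
occluded, so the ligand cannot enter after the protein has closed. How the
system reaches the closed, bound state — by the ligand selecting a
pre-existing minor conformation (conformational selection), by
ligand-induced closure (induced fit), or by a mixture — is a kinetic
question. A Markov state model (MSM) built from many short molecular
dynamics trajectories answers it by discretizing the conformational space
into metastable states and estimating the transition probabilities between
them, from which equilibrium populations, mean first passage times (MFPTs),
binding free energies, and transition-path fluxes all follow.

`msmbind` implements the complete post-simulation half of such a study as a
reusable, tested pipeline: featurization, two-regime geometric clustering,
transition-matrix estimation with a recrossing filter, super-level-set
hierarchical (SHC) lumping into macrostates, and the kinetic and
thermodynamic readouts. Because MD datasets of this kind are rarely
deposited, the package also contains a first-class synthetic generator with
planted ground truth, so that every stage can be validated quantitatively.

## Reaction coordinates

Protein conformations are described by two hinge dihedrals computed from
Calpha-group centroids:

* the **opening angle**, between the planes spanned by the lobe-I centroid
  (residues 6–88 and 195–227), the two opening-hinge centroids (residues
  162–168 and 121–127), and the lobe-II centroid (residues 92–185);
* the **twisting angle**, defined with the same lobe centroids but its own
  hinge groups (83–88 with 194–199, and 92–97 with 156–161).

Both angles are signed dihedrals about the axis from the first to the
second hinge centroid, wrapped to (−180°, 180°]. Raw plane angles would not
vanish on any particular structure, so angles are *referenced*: the closed
holo crystal structure defines (0°, 0°), and the open apo form then scores
approximately (+38°, −26°). Centroids use unit masses (all Calpha masses
are equal), which keeps the computation bit-reproducible.

The ligand contributes its position: the distance between its heavy-atom
centre of mass and the binding-site Calpha centroid, the minimum
protein–ligand heavy-atom distance, and the centre-of-mass coordinates
themselves. Ligand positions are only comparable between frames in a
protein-fixed frame; `align_to_reference()` superposes each frame's
protein Calpha onto the reference structure (Kabsch) before ligand
coordinates are used. Whether and how the original workflow aligned frames
is not recorded anywhere we could consult; the protein-fixed convention is
the only one under which clustering ligand positions is geometrically
meaningful, so it is adopted here.

The toy-structure builder (`build_toy_structure()`) places a minimal
point-set protein whose group centroids realize any requested angle pair
exactly, in closed form. It is the round-trip oracle for the featurizer:
build at known angles, featurize, recover them to 1e-6 degrees. Because the
lobe-II group necessarily contains the hinge residues (the ranges overlap
by construction), a ballast residue keeps the lobe-II centroid on target.
The builder covers openings in (−150°, 150°) and twists in (−90°, 90°);
outside that range its closed-form solution degenerates, and real PBP hinge
motions lie far inside it.

## Two-regime discretization

Microstates are built by greedy farthest-point (k-centers) clustering,
which covers the sampled space with clusters of roughly equal radius and is
a 2-approximation to the optimal covering radius. The initial center is the
first frame (deterministic; the algorithm has no other free choice), and
all ties break to the lowest index.

Ligand dynamics fall into two regimes. While in contact with the protein
(minimum heavy-atom distance ≤ 5 Å) the ligand moves slowly and deserves
fine resolution: 50 protein-angle clusters × 5000 ligand-coordinate
clusters by default. While freely diffusing (> 5 Å) a fine model would
produce many states with poor statistics and no insight, so those frames
are re-clustered coarsely (10 × 100) on the ligand centre of mass. The two
product-state label spaces are disjoint; empty product states are dropped
and labels densified. Requested cluster counts are capped at the number of
distinct points, so the paper-scale defaults apply safely to small data.
The original workflow's re-clustering criterion (< 10 transitions) is kept
as a diagnostic (`poorly_sampled_states()`); the 5 Å rule alone defines
the regimes.

Angle space uses plain Euclidean distance without periodic wrapping:
observed hinge angles span far less than 360°, so wrapping would never
trigger and would only complicate the metric.

## Transition counting and the recrossing filter

Counts are collected with a sliding window at the lag time: every frame
pair (t, t + lag) contributes. Hard state boundaries let trajectories
oscillate rapidly at barrier tops, inflating transition counts; the
recrossing filter therefore accepts a cross-state pair only when the
destination is occupied for a minimum residence time (default 300 ps = 15
frames at 20 ps spacing) immediately after arrival. Self pairs are always
counted; residence windows cut off by the end of a trajectory reject the
count, because the residence cannot be verified. Only the destination's
residence is checked, and trajectories are never concatenated.

Rows of the count matrix are normalized to give the transition matrix;
all-zero rows become absorbing self-loops (a conservative convention for
unvisited states). Equilibrium populations are the stationary left
eigenvector of the transition matrix — consistent with treating the MSM as
the model of the equilibrium — with raw frame-count populations reported
alongside for comparison. No reversibility (detailed-balance) constraint
is imposed at any point, since none was used in the source workflow.

Markovianity is validated with implied timescales,
t_i = −tau / log(lambda_i): for a Markovian discretization they are
lag-independent. `choose_lag()` finds the first lag at which the slowest
timescale changes by less than 10% and steps one grid point beyond it,
mirroring the usual practice of building the model slightly past the
leveling-off point.

## Super-level-set hierarchical lumping

Microstates are lumped into macrostates density-first. Microstate density
is its fraction of all frames; a *super level set* at level L is the
smallest prefix of states, sorted by descending density, whose cumulative
density reaches L. The high-resolution (contact) regime uses the ladder
0.50, 0.55, …, 0.95, 0.99; the diffusing regime uses the coarse ladder
0.4, 0.95 — a detailed hierarchy of freely diffusing states would carry no
information. The two regimes are lumped separately (their state sizes are
not comparable, so neither are their densities) and combined with disjoint
macrostate label ranges.

At each level, the symmetrized count graph restricted to the level set is
decomposed into connected components, and every component is partitioned
by `spectral_split()`: the coupling matrix is degree-normalized
(D^−1/2 W D^−1/2) and the number of blocks is chosen by the largest gap in
its leading eigenvalues (capped at 5); memberships come from a
deterministic k-means on the leading-eigenvector embedding, seeded by
k-centers. A strongly mixing component has its spectral gap right after
the first eigenvalue and stays whole. Clusters containing no previously
assigned state seed new macrostates; in clusters that do contain assigned
states, each new state joins the macrostate it is most strongly coupled to
in total symmetrized counts. Two design points deserve emphasis:

* *Splitting runs on every component, not only on all-new ones.* Inter-basin
  transitions, however rare, connect basins in the count graph, so a new
  basin almost always enters the hierarchy inside the component of an
  already-seeded one; only the spectral split can see that it is a distinct
  block. Restricting the split to components without assigned states would
  let the first macrostate absorb everything connected to it.
* *Attachment compares total coupling to each candidate macrostate*, not
  the single strongest-coupled neighbour state. A microstate visited once
  has unit counts on all its edges; the per-neighbour maximum is then a
  many-way tie that an index-based tie-break resolves arbitrarily, while
  the aggregate count flux into each macrostate resolves it correctly.

After the final level, any remaining unassigned states join the macrostate
they are most strongly coupled to; a state with no coupling at all becomes
its own macrostate with a warning. Seeds created at denser levels are
never dissolved, only grown, so the hierarchy is nested. In the pipeline,
the coupling counts for lumping are estimated at lag 1 (the frame
interval), where every visited state has coupling by construction; the
kinetic model itself uses the validated lag.

The macrostate count of a given dataset (54 in the reference analysis) is
an *output* of this procedure, not a target: it depends on the data's
density profile and cannot be reproduced without the original
trajectories.

## Kinetics and thermodynamics

**MFPT.** With X_f = 0 on the target set and
X_i = lag + sum_j T_ij X_j elsewhere, the MFPT from a source set is the
stationary-population-weighted mean over its members (the reference
analysis reports single numbers "from all unbound states" without stating
weights; population weighting is the natural choice and is configurable).
Error bars come from bootstrapping whole trajectories: resampled datasets
redraw trajectories with replacement, the statistic is recomputed on each
(with the state definition held fixed, as is standard), and the bootstrap
mean and standard deviation are reported. The default draw equals the
number of trajectories.

**Binding free energy.** For a box with one protein and one ligand, the
population-ratio method gives
ΔG = −RT ln[(1 − α_free) / (α_free² c₀ / c°)], where α_free is the free
fraction, c₀ = 1/(N_A V_box) the overall ligand concentration, and
c° = 1 mol/L. The squared denominator reflects that dissociated protein
and ligand are at equal concentration α_free c₀. The functional form was
reconstructed from the population-ratio (double-decoupling) literature the
source cites, and is validated against all three printed values it must
reproduce: −8.46 kcal/mol at α_free = 1.75%, c₀ = 0.0049 mol/L, 318 K;
α_bound = 98.25%; and the experimental reference −9.95 kcal/mol from
K_d ≈ 14 nM at 277 K via ΔG = RT ln(K_d/c°). The gas constant is
1.987×10⁻³ kcal/(mol·K); energies are reported in kcal/mol and times in
microseconds unless stated.

**Association.** Under ligand excess the free-protein concentration decays
pseudo-first-order, giving the half-life τ½ = ln 2/(k_on c₀). The k_on
used for the published cross-protein comparison is not recoverable from
the source text, so τ½ is exposed as a formula, not validated against a
number.

**Transition-path fluxes.** The forward committor q+ solves the standard
boundary-value problem; the backward committor is computed as the forward
committor of the time-reversed chain rather than taken as 1 − q+, because
the latter only conserves flux exactly for reversible chains and no
reversibility is enforced anywhere in the pipeline (for reversible chains
the two coincide). Gross flux is f_ij = π_i q−_i T_ij q+_j, net flux
F_ij = max(0, f_ij − f_ji), and pathways are extracted by iterated widest
paths: find the source-to-sink path with the largest bottleneck flux,
subtract that flux along it, repeat. Each path is reported with its flux
and fraction of the total.

**Transition-event localization** finds label changes whose destination
persists for a minimum residence (the published figure uses 6 ns here,
versus 300 ps in counting — both are exposed as parameters, since the two
filters serve different analyses) and reports the feature vector at the
last frame in the origin state, i.e. the conformation from which the jump
was made.

**Free-energy surfaces** are Boltzmann inversions of 2-D histograms,
F = −kT ln(n/n_max), deepest bin at zero, empty bins undefined. **Medoid
conformations** are the members of a state with the smallest mean
superposed-RMSD to all others — exact up to 2000 conformations, and on a
fixed-seed subsample above that.

## The synthetic generator

The generator emulates the *architecture* of the study's data, not its
scale: a discrete Markov chain over four metastable basins — open unbound
(opening 40°, twist −25°, site distance 30 Å), partially closed encounter
complex (25°, −15°, 4 Å), closed bound (0°, 0°, 1 Å), and an off-pathway
mis-bound state (35°, −20°, 6 Å, in contact with the protein but away
from the site) — with diagonal-Gaussian emissions per state and 20 ps
frames. The basin centres follow the published state architecture; the
paper gives no quantitative basin geometry or rates for a generator, so
the remaining numbers are constructed realism: per-frame transition
probabilities of 0.0025–0.02 give dwell times of 1–8 ns, the encounter
complex is the obligatory gateway between unbound and bound, the mis-bound
basin exchanges only with the unbound one, and the stationary distribution
(0.098, 0.098, 0.780, 0.024) makes the bound state dominant, as in the
real system. Emission standard deviations (1.5–2° in angles, 0.15–2 Å in
distances) keep basins well separated — many standard deviations apart —
which is what makes exact planted-truth recovery a meaningful test.
Distances are truncated at zero; the state means sit several standard
deviations above zero, so the truncation is negligible.

What the generator deliberately does *not* emulate: intra-basin diffusive
correlation (frames are conditionally independent given the state), basin
anisotropy and curvature, partial overlap between states, atomistic detail
beyond what the featurizer round-trips require, and the microsecond
timescale separation of the real system (dwell times are scaled down by
roughly three orders of magnitude so that rare events are observable at
test problem sizes). Passing the recovery tests therefore demonstrates
correctness of the estimators on data satisfying the MSM assumptions; it
does not certify behaviour on data that violate them.

A Metropolis Monte Carlo walker on a Gaussian-mixture landscape
(`toy_landscape()`, `simulate_landscape()`) provides a second, continuous
data source whose Boltzmann statistics are known in closed form; it backs
the free-energy-surface and sampling tests.

## Validation strategy and problem sizes

Every operation is tested against an independent oracle: brute-force
window enumeration for counting, exhaustive center enumeration for
k-centers, Monte-Carlo first passage (10⁶ walkers) for the MFPT solver,
the gambler's-ruin profile for the committor, hand-built networks for the
pathway decomposition, and closed forms for the thermodynamics. Recovery
tests run the full pipeline on generated data and compare against the
planted truth computed analytically at run time: a 65-trajectory ×
8000-frame dataset (clustered at 40×200 and 8×40) recovers the planted
unbound→bound MFPT within 15% and the bound population within 0.02; a
20 × 5000 three-basin dataset is lumped back to exactly three macrostates
with adjusted Rand index 1.0. These sizes were chosen so that the slowest
planted process is sampled a few hundred times — enough that estimator
error, not sampling noise, dominates the comparison — while keeping the
full suite fast.

For the end-to-end runs the kinetic lag is 5 frames (0.1 ns), well below
the shortest planted dwell time, and the recrossing residence is 1 frame:
the filter exists to suppress discretization-induced boundary
oscillation, which well-separated Gaussian basins do not produce, and at
these scaled-down dwell times a 300 ps residence would reject genuine
exits. On real MD data, where dwell times exceed the residence window by
orders of magnitude, the 300 ps default applies.

Numerical conventions throughout: ties in clustering, attachment, and
path selection break to the lowest index; fixed seeds derive per-stream
from a master seed, so parallel trajectory generation is reproducible;
angles live in (−180°, 180°]; stationary vectors come from the single
closed communicating class (several closed classes is an error, since the
model then has no unique equilibrium).

## Known limitations

* The SHC variant here is fully specified and deterministic, but it is a
  reconstruction in the spirit of the published method; the original
  implementation's interior details were not available, so macrostate
  counts on real data may differ.
* The committor/flux machinery assumes the lumped chain is a faithful
  kinetic model; at coarse lags, multi-step journeys within one lag window
  appear as direct edges and shift a small fraction of path flux onto
  shortcut routes (visible even on synthetic data).
* Absolute binding free energies by alchemical methods, reversible
  maximum-likelihood estimators, Bayesian MSMs, and k_off estimation
  beyond MFPT readouts are out of scope.

## A worked example

```{r}
library(msmbind)

cfg <- pipeline_config(list(
  paths = list(output_dir = "lao_demo"),
  synth = list(n_traj = 20L, n_frames = 4000L, seed = 1L),
  discretize = list(k_protein_high = 20L, k_ligand_high = 100L,
                    k_protein_low = 6L, k_ligand_low = 20L),
  msm = list(lag_ns = 0.1, min_residence_ps = 20,
             lag_scan_ns = c(0.04, 0.1, 0.2)),
  kinetics = list(n_boot = 50L)))
report <- run_pipeline(cfg)

report$n_macrostates
report$mfpt$value_us          # unbound -> bound MFPT
report$flux$path_fraction     # flux decomposition over pathways
```
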