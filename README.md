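# msmbind

Markov state model (MSM) analysis of protein–ligand binding kinetics, for
computational biophysicists studying receptors that close around their
ligand — periplasmic binding proteins (PBPs) such as the lysine-,
arginine-, ornithine-binding (LAO) protein being the motivating case.
Given per-frame reaction coordinates from molecular dynamics
trajectories, the package discretizes conformational space into
microstates, estimates a transition matrix, lumps kinetically related
microstates into metastable macrostates, and derives the observables that
let the model be compared with experiment and interrogated for mechanism
(conformational selection vs induced fit).

## What it computes

- **Featurization** — hinge *opening* and *twisting* dihedrals between
  lobe planes defined by Cα-group centroids, referenced so that the
  closed holo structure scores (0°, 0°); ligand–binding-site distance;
  minimum protein–ligand heavy-atom distance; superposed Cα RMSD; ligand
  rotational autocorrelation. An analytic toy-structure builder provides
  exact round-trip oracles for the angle definitions.
- **Discretization** — deterministic greedy farthest-point (k-centers)
  clustering in two regimes: fine protein-angle × ligand-coordinate
  product states while the ligand is in contact (min distance ≤ 5 Å),
  coarse centre-of-mass states while it diffuses freely.
- **MSM estimation** — sliding-window transition counts at lag τ with a
  recrossing filter (cross-state counts require the destination to stay
  occupied for a minimum residence time), row-normalized transition
  matrix T, stationary populations π (πT = π), implied timescales
  t_i = −τ/ln λ_i(T) for Markovianity validation, and lag selection.
- **SHC lumping** — super-level-set hierarchical spectral clustering:
  macrostates are seeded in the densest regions first (density-level
  ladders 0.50…0.99 for the contact regime, 0.4/0.95 for the diffusing
  regime) and grown as sparser microstates enter; eigengap-limited
  spectral splits decide how many kinetic blocks each level holds.
- **Kinetics & thermodynamics** — MFPTs by linear solve
  (X_f = 0, X_i = τ + Σ_j T_ij X_j) with trajectory-bootstrap error bars;
  binding free energy from bound/free fractions,
  ΔG = −RT ln[(1−α_free)/(α_free² c₀/c°)]; reference ΔG = RT ln(K_d/c°);
  association half-life τ½ = ln2/(k_on c₀); forward/backward committors,
  transition-path net flux f⁺_ij = π_i q⁻_i T_ij q⁺_j, and highest-flux
  pathways by iterated widest paths; transition-event localization;
  Boltzmann-inversion free-energy surfaces; medoid conformations.
- **Synthetic data** — a planted Markov chain over four basins (open
  unbound, encounter complex, closed bound, mis-bound) with Gaussian
  emissions, plus a Metropolis walker on a Gaussian-mixture landscape,
  so every stage is testable against known ground truth.

## A worked example

The staged pipeline runs end-to-end on generated data with planted
kinetics:

```r
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
#> [1] 4
sum(unlist(report$macro_populations)[unlist(report$state_sets$bound)])
#> [1] 0.7518133
report$mfpt$value_us
#> [1] 0.004904464
unlist(report$flux$paths); round(unlist(report$flux$path_fraction), 3)
#> [1] "4-2-1" "4-1"
#> [1] 0.938 0.062
```

The four macrostates recover the four planted basins. The bound state
carries 75% of the equilibrium population (planted truth 78%, here
estimated from a deliberately small run), the unbound→bound MFPT is
0.0049 µs against a planted 0.00475 µs, and 94% of the binding flux runs
through the encounter-complex macrostate (path 4–2–1:
unbound → encounter → bound) — the planted gateway architecture. The
same thermodynamic formulas evaluated at study conditions give

```r
binding_free_energy(alpha_free = 0.0175, c0_molar = 0.0049, T_K = 318)
#> [1] -8.461933
dG_from_Kd(14e-9, 277)
#> [1] -9.95353
```

i.e. a −8.46 kcal/mol population-ratio binding free energy against a
−9.95 kcal/mol experimental reference.

A thin command-line driver is installed as `exec/msmbind`
(`msmbind all --config config.yaml`), and the methods vignette
(`vignettes/msm-binding-pipeline.Rmd`) documents the model, parameter
choices, and design decisions.

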