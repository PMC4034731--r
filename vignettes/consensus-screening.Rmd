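---
title: "Consensus virtual screening with cvscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus virtual screening with cvscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvscreen)
```

`cvscreen` implements the analysis layer of a consensus virtual-screening
campaign against FKBP52, plus the trajectory statistics used to vet the
selected candidates. This vignette is the package's account of the science:
what each stage computes, which conventions were chosen where several were
defensible, and what the tests do and do not establish.

## The screening pipeline

The pipeline consumes ligand structures, a descriptor–activity training
table, dock scores, and (downstream) MD trajectories. Docking and MD are
deliberately out of scope: their outputs are inputs here.

### Descriptors

`compute_descriptors()` returns the ten-descriptor panel used by the
screening equation.

* **E-state counts and sums.** Atom types follow Kier–Hall conventions
  (`aaCH`, `sOH`, `sssN`, ...; bond symbols ordered t, d, a, s). The
  E-state of heavy atom $i$ is
  $S_i = I_i + \sum_j (I_i - I_j)/d_{ij}^2$, $d_{ij}$ = graph distance + 1,
  with intrinsic state $I = ((2/N)^2 \delta^v + 1)/\delta$. Hydrogens are
  folded into attached-H counts; the graph is heavy-atom only. Since the
  perturbation terms cancel pairwise, $\sum_i S_i = \sum_i I_i$ — the suite
  asserts this to 1e-9 as a correctness invariant. An isolated heavy atom
  has $\delta$ clamped to 1 (so $S = I$).
* **Aromaticity.** Perceived via ChemmineR's ring perception on the parsed
  structure. Counts such as `ES_Count_aaCH` depend on this model; a
  different aromaticity model would shift borderline heteroaromatics.
* **`Molecular_PolarSurfaceArea`** is the 2D Ertl fragment-sum TPSA over
  N/O environments (S/P available behind `include_sp`), in Å². The fragment
  table was validated during development against an independent
  implementation of the same published scheme on a ten-molecule panel;
  those values are frozen in the tests.
* **`Jurs_TPSA`** is deliberately different: the Jurs descriptor family is
  surface-based, so it is computed as 3D polar SASA — Shrake–Rupley over
  the whole molecule, summed over N, O and their attached hydrogens
  (probe 1.4 Å). It requires coordinates; without them the value is `NA`
  (or an error with `need_3d = TRUE`).
* **`Shadow_Ylength`** is the extent of the molecule along the *second*
  principal axis of the coordinate covariance (axes ordered by descending
  variance), inflated by van der Waals radii. The "Y = second axis"
  convention is the standard shadow-descriptor one; the invariance of the
  value under rigid motion of the input is asserted to 1e-6 Å.
* **`Minimized_Energy`** is injectable: the original value came from a
  proprietary forcefield, so the pipeline treats it as a numeric feature
  the caller supplies from any minimizer (kcal/mol), never computed
  internally.

### GFA descriptor selection

`gfa()` evolves descriptor subsets of fixed size. Each subset is fitted by
least squares and scored by the Friedman lack-of-fit
$\mathrm{LOF} = \mathrm{SSE} / \big(n(1 - (c + dp)/n)^2\big)$ with
$c = p + 1$ and smoothing $d = 1$ (`lof_d`); fitness is its negation, and
collinear subsets receive $-\infty$ rather than crashing the search.
Genetic operators are deliberately the canonical defaults — tournament
selection of size 2, one-point subset crossover, swap mutation at rate 0.1,
elitism of 1 — all exposed as arguments, because the original study names
the method but none of its settings. Runs are deterministic given `seed`.

The published ten-term equation ships as `eq1_model()` (intercept 14.911,
training R² 0.9402 as reported). Its 37-ligand training set is not
publicly deposited, so retraining cannot reproduce it; the bundled model is
the supported way to score new descriptor vectors, and parity of a fresh
GFA run with the printed R² is *not* claimed. Recovery is instead
demonstrated on planted synthetic tables (exact at zero noise; the correct
3-of-10 subset in ≥ 9/10 seeds at noise σ = 0.1).

### The three predictors

* **MLR** (`fit_mlr()`): ordinary least squares; rank deficiency is an
  error naming the collinear columns. Residual–design orthogonality is a
  tested invariant.
* **SVR** (`fit_svr()`): ε-insensitive radial-basis regression through
  libsvm (e1071) — the same engine family the original models used.
  Defaults C = 10, ε = 0.1, γ = 1/p; descriptors are z-scored on training
  statistics internally. Constant columns are dropped with a warning; a
  single-row fit degenerates to a constant predictor.
* **Bayesian network** (`fit_bn()`): variables (ten descriptors + pIC50)
  are discretized into at most five equal-frequency categories (duplicate
  quantile edges merged, so realized bins may be fewer); structure is
  learned by greedy hill climbing with add/delete/reverse moves and random
  restarts, maximizing the BDeu score (equivalent sample size 1, parent cap
  3); CPTs use add-one smoothing so unseen bin combinations never yield a
  zero posterior. Prediction discretizes the query (values outside all bins
  clamp to the nearest), computes the exact posterior over pIC50 categories
  — every descriptor is observed, so enumeration over the single latent
  node is exact and removes any sampling stochasticity — and evaluates the
  MAP category's per-category linear regression (ties break to the lower
  category; a posterior-weighted mean is available via
  `combine = "posterior"`). Per-category regressions use all ten
  descriptors when the category is large enough; small or degenerate
  categories fall back to a lightly ridge-regularized fit so prediction
  never fails, at the cost of exact-recovery guarantees in those
  categories.

### Consensus voting and selection

`consensus_vote()` awards, per metric, the vote to the top three
candidates by descending score: weight 1 for dock, SVM and MLR, weight 2
for the Bayesian network. Ties spanning rank 3 are resolved *inclusively*
(all tied candidates receive the vote) — the only order-independent rule;
absent such ties exactly 15 vote points are distributed, which the suite
checks as a conservation law. The dock gate keeps candidates with scores
`>=` the control (elimination is of strictly lower scores) and is exposed
as an optional stage, since whether it ran before or after the published
table's assembly is ambiguous. Final selection sorts by vote sum, then
dock score, then name — the published table needs no tie-break, but the
package must be deterministic on tables that do.

### Interaction profiling

Contact tables are residue-labelled cell matrices with kinds H (hydrogen
bond), Hb (hydrophobic) and Pi (π–π). Two counting conventions coexist in
the source material: the per-ligand totals count *interactions* (a `Pi/Hb`
cell contributes two), while the per-residue percentages count *ligands
with any contact* (the same cell counts once). `ligand_totals()` defaults
to the interaction convention because that is the one the bundled table's
printed totals follow; `count = "residues"` gives the other. The
percentage denominator is all ligands in the table, control included.

## Trajectory statistics

All metrics operate on a plain `trajectory` container (topology +
time-ordered coordinate frames, Å, times in ns) read from multi-model PDB
or DCD via bio3d. XTC is not supported (no installed reader); DCD or
multi-model PDB cover the tested workflows.

* **Superposition** is Kabsch via SVD with a proper-rotation guarantee;
  RMSD is unweighted over the fitted selection (the common convention for
  ligand RMSD; mass-weighting would change protein numbers only
  marginally). Correctness is established against an independent
  quaternion-eigenvalue formulation to 1e-6 Å.
* **RMSD series** use frame 0 as reference; ligand RMSD fits on the
  protein and measures on the ligand.
* **RMSF** superposes frames to the evolving average structure (two
  refinement passes) before measuring per-atom fluctuation; `fit = FALSE`
  serves pre-aligned input.
* **Rg** is mass-weighted and reported in nm.
* **SASA** is Shrake–Rupley with golden-spiral test points (default 960;
  the suite checks < 2 % drift against 4000 points) and probe 1.4 Å.
  Totals are reported in nm² (the source material's surface unit is taken
  as nm²; values are Å² internally).
* **H-bond occupancy** counts frames whose donor–acceptor distance lies in
  the 2.3–3.2 Å optimum-H-bond window (both edges inclusive). Distances
  are donor–acceptor by default — whether the original figures used
  hydrogen–acceptor is unstated, so `use_hydrogen = TRUE` is provided.
  The common d ≤ 3.5 Å alternative is `lo = 0, hi = 3.5`.
* **Torsions** report the raw dihedral X ∈ (−180°, 180°], the unwrapped
  Y = X + 360 when X < 0, and the increment Z = ΔY. A collinear middle
  bond yields `NA` for the frame rather than an error.
* **Secondary structure** is a Kabsch–Sander reduction to five classes:
  H-bond energy $E = 0.084(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})
  \times 332$ kcal/mol, bond when $E < -0.5$; two consecutive n→n+4 turns
  give H, bridge patterns give E, n→n+3/5 turns give T, Cα curvature
  > 70° over i±2 gives S, else C (priority H > E > T > S). Missing amide
  hydrogens are imputed 1 Å from N along the previous residue's C=O
  direction; turns never span chain breaks. The ideal-geometry fixtures
  below were cross-checked once against an established DSSP implementation
  during development and the expectations frozen.
* **Clustering** is the GROMOS algorithm (iterated most-neighbours centre
  removal) on the pairwise superposed-RMSD matrix; cutoff default 1.0 Å
  (the source is silent; 1 Å is conventional for backbone clustering), and
  ties for both centre and largest cluster resolve to the earliest frame
  so representatives are deterministic.

## The synthetic-data generators

The package's validation strategy substitutes property-based checks on
generated data for the undeposited originals; the generators therefore
*are* the study conditions, not tuning knobs.

* `gen_qsar_table()` emulates the 37-ligand table: default 37 rows split
  30/7 train/test, descriptors uniform over plausible physical ranges
  (counts 0–10, E-state sums 0–20, areas 0–200 Å², CHI₂ 0–10, energies
  −100–0 kcal/mol, lengths 0–20 Å), and pIC50 linear in three active
  descriptors plus Gaussian noise. These ranges are invented (documented
  here once) and configurable.
* `gen_score_table()` produces structurally valid random score tables; the
  published table itself ships verbatim as `published_scores()`.
* `gen_trajectory()` plants exact observables in a jittered rigid layout:
  a designated pair distance is placed in/out of the H-bond window to
  realize a target occupancy to one-frame quantization, and a designated
  torsion follows a prescribed schedule; jitter never touches the planted
  atoms.
* `gen_ss_fixtures()` builds ideal backbones from internal coordinates
  (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å, trans peptide):
  a 12-residue α-helix (φ = −57°, ψ = −47°), an antiparallel two-strand
  sheet (φ = −139°, ψ = 135°; the second strand is placed by a
  deterministic grid search over 180° flips and offsets maximizing
  inter-strand H-bonds), and an extended chain.

What passing on such data does *not* show: robustness to force-field
artefacts, solvent, periodic-boundary imaging, correlated (non-isotropic)
fluctuations, or chemically realistic descriptor correlations. The
generators make the *algorithms* falsifiable, not the upstream physics.

## Problem sizes and numerical choices

The test suite runs at deliberately modest sizes — tables of 37 rows,
trajectories of ≤ 800 frames and ≤ 25 atoms, clustering on ≤ 20 frames,
50 seeds for the coefficient-bias check — chosen so the whole suite
completes in well under a minute while still exercising every contract.
Key tolerances: E-state conservation 1e-9; Kabsch vs quaternion 1e-6 Å;
SASA vs analytic sphere formulas 2 % (point-sampling limited); RMSF vs the
σ√3 closed form 5 % at 800 frames (sampling limited); occupancy to
one-frame quantization. Degenerate inputs (collinear superposition,
single-frame RMSF, constant descriptor columns, empty dock-gate survivor
sets, unseen discretization bins) warn or error informatively rather than
propagating NaNs.

## Known limitations

* Numeric parity with the original descriptor software is not attempted:
  its exact E-state, shadow and aromaticity conventions are undocumented,
  and no parity claim appears anywhere in the source material. The
  conventions used here are the standard published ones.
* The published per-ligand SVM/MLR/BN predictions cannot be re-derived
  (training structures absent); they are consumed as inputs, and the
  consensus stage is validated by reproducing the published votes from
  them.
* Formal charges are read from V2000 atom-block charge codes; exotic
  charged species beyond the Ertl table's patterns contribute 0 to TPSA.
* The published trajectory-derived numbers (Rg table, SASA averages,
  occupancy percentages) require the original trajectories; the metrics
  are validated against closed forms and independent oracles instead.
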