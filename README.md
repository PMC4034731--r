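# cvscreen

Consensus virtual screening and molecular-dynamics summary statistics for
small-molecule ligand discovery, built around an FKBP52 (FK506-binding
protein 52) ligand-screening study in which natural-product candidates were
ranked against the immunosuppressant Tacrolimus (FK506).

`cvscreen` is aimed at computational chemists who want the *analysis* layer
of such a campaign as tested, reusable R code: the docking engine, the MD
engine and ligand parametrization stay upstream (their scores, poses and
trajectories are inputs), while everything downstream — descriptors, model
fitting, consensus ranking, interaction profiling and trajectory
statistics — is reproducible here.

## What the package computes

**Descriptors** (`compute_descriptors()`): the ten-descriptor panel used by
the screening model — Kier–Hall electrotopological-state (E-state) counts
and sums (`ES_Count_aaCH`, `ES_Count_sOH`, `ES_Sum_aaCH`, `ES_Sum_sssN`,
where the E-state of atom *i* is
S_i = I_i + Σ_j (I_i − I_j)/d_ij² with intrinsic state
I = ((2/N)²·δᵛ + 1)/δ), six-membered-ring count, Ertl fragment TPSA,
second-order connectivity index ²χ = Σ (δ_i δ_j δ_k)^(−1/2), 3D polar
solvent-accessible surface area, a caller-supplied minimized energy, and
the molecular extent along the second principal axis. SMILES/SDF input is
parsed with ChemmineR/OpenBabel.

**Model selection and pIC50 predictors**: Genetic Function Approximation
(`gfa()`) evolves fixed-size descriptor subsets scored by the Friedman
lack-of-fit LOF = SSE / (n(1 − (c + dp)/n)²); the three predictors of the
consensus are ordinary least squares (`fit_mlr()`), radial-basis
ε-support-vector regression via libsvm (`fit_svr()`), and a discretized
Bayesian-network predictor (`fit_bn()`) that bins variables into at most
five equal-frequency categories, learns a network by BDeu hill climbing,
and maps a query to the MAP category's linear regression. The published
ten-term screening equation (intercept 14.911) ships as `eq1_model()`
because its 37-ligand training set is not publicly deposited.

**Consensus screening** (`screen_candidates()`): candidates with dock
scores below the control are eliminated; the top-3 per dock, SVM and MLR
score earn 1 vote each and the top-3 Bayesian-network scores earn 2; the
three highest vote sums are selected.

**Interaction profiling** (`read_interactions()`, `ligand_totals()`,
`residue_percentages()`, `compare_to_control()`): summaries of recorded
protein–ligand contact tables (hydrogen bond / hydrophobic / π–π).

**Trajectory statistics** (`read_trajectory()` + friends): Kabsch
superposition and RMSD series, RMSF, mass-weighted radius of gyration,
Shrake–Rupley SASA, hydrogen-bond distance series and occupancy in the
2.3–3.2 Å window, torsion unwrapping (Y = X + 360 for X < 0, Z = ΔY),
Kabsch–Sander secondary structure, and GROMOS conformational clustering.

**Synthetic data** (`gen_qsar_table()`, `gen_score_table()`,
`gen_trajectory()`, `gen_ss_fixtures()`): generators with planted ground
truth so every stage is testable without downloads.

## Worked example

```r
library(cvscreen)
out <- screen_candidates(published_scores(), k = 3)
out$voted[, c("name", "svm", "mlr", "bn", "dock", "vote_sum")]
#>                                  name  svm  mlr   bn  dock vote_sum
#>                    Lathyranoic acid A 4.81 5.12 5.45 86.20        1
#>                           Daphnetoxin 5.09 8.89 7.46 84.88        4
#>                          Aurantiamide 4.89 6.42 5.43 83.89        1
#>  ...                                                              ...
#>                        Lythrancine II 5.03 8.92 6.74 62.03        3
#>                            Tacrolimus 5.11 6.25 5.33 58.10       NA
out$selected$name
#> [1] "Daphnetoxin"  "Lythrancine II"  "20-O-(2'E4'E-Decadienoyl)ingenol"
```

Daphnetoxin tops the consensus with 4 votes (top-3 in MLR and dock score,
top-3 Bayesian network for 2); the control never votes. The interaction
profile of the docked poses:

```r
ligand_totals(published_interactions())
#>      Tacrolimus       Daphnetoxin  20-O-(...)ingenol  Lythrancine II
#>               4                 5                  7               7
compare_to_control(published_interactions(), "Tacrolimus")$Daphnetoxin$control_only
#> [1] "Glu85"
```

Every candidate reaches all Tacrolimus-contacting residues except Glu85.
The bundled screening equation evaluates exactly:

```r
evaluate_linear(eq1_model(), setNames(rep(0, 10), descriptor_names()))
#> [1] 14.911
```

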