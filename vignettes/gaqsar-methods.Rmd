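---
title: "GA-MLR QSAR modelling and trajectory post-analysis with gaqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GA-MLR QSAR modelling and trajectory post-analysis with gaqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaqsar)
```

## The problem

Acetylcholinesterase (AChE) inhibition remains the main symptomatic lever in
Alzheimer's disease, and the enzyme's ~20 Å active-site gorge — catalytic
site at the bottom, peripheral anionic site at the rim — rewards "dual-site"
ligands long enough to bridge both. `gaqsar` implements a complete
quantitative structure-activity relationship (QSAR) workflow of the kind
used to design such ligands: descriptor computation for quinoline-family
inhibitors, descriptor-pool pre-filtering, genetic-algorithm (GA) subset
selection over multiple linear regression (MLR), the OECD-style validation
statistics suite, and the molecular-dynamics post-statistics used to rank
lead candidates after simulation.

The centerpiece is the published five-descriptor activity model, bundled as
`published_model("paper2026_ache_gamlr")`:

$$pIC_{50} = 4.9509 + 0.0554\cdot max\_conj\_path + 5.3355\cdot MATS3s
          + 2.0399\cdot R8m + 1.186\cdot(C\!-\!N\!-\!C\!=\!O)
          + 1.5020\cdot MNA$$

where activity is $pIC_{50} = -\log_{10} IC_{50}\,[M]$ (`to_pic50()`).

## Descriptors

Five descriptor families feed the model. Each is computed from a
`molecular_graph` (SMILES or SDF input); only R8m needs 3D coordinates.

* **max_conj_path** — the number of bonds in the longest simple path through
  the conjugated-bond subgraph. A bond is conjugated when it is aromatic, a
  multiple bond, or a single bond flanked by multiple/aromatic bonds on both
  ends. Paths may not revisit atoms, so a closed aromatic ring of size $k$
  scores $k-1$ (benzene: 5). Commercial implementations do not publish their
  exact convention; this one is chosen because it is exactly testable by
  exhaustive path enumeration.
* **MATS3s** — Moran autocorrelation at topological lag 3, weighted by the
  Kier–Hall intrinsic state $I = ((2/L)^2\delta^v + 1)/\delta$. The centered
  Dragon-style form is used, with pairs counted once and normalized by the
  lag-3 pair count. Zero-variance weights or an empty lag return 0.
* **R8m** — GETAWAY R autocorrelation at lag 8,
  $R_8 = \sum_{i<j: d_{ij}=8} \sqrt{h_{ii}h_{jj}}/r_{ij}\cdot w_i w_j$ with
  molecular-influence-matrix leverages $h_{ii}$ on centroid-centered
  coordinates and masses scaled by the carbon mass. Exactly planar or linear
  geometries use the pseudo-inverse, so $\sum_i h_{ii}$ equals the
  coordinate rank rather than erroring. A molecule with no lag-8 pair
  scores 0; a molecule without coordinates reports R8m as missing, not 0.
* **C-N-C=O** — carbamoyl/urea fragment count. Quadruple matches that
  differ only by symmetry-equivalent first carbons on the same nitrogen are
  collapsed (tetramethylurea counts 2, not 4), using refinement-orbit atom
  ranks.
* **MNA** — the multilevel-neighborhood-of-atoms substructure
  `-H(-C(C-H-H-C))`: hydrogens attached to a carbon whose full neighbor
  multiset, with hydrogens expanded virtually, is {C, C, H, H}. Neighbor
  lists are sorted canonically so the notation is deterministic.

Native descriptor values are intended for de-novo work and synthetic tests.
The equation's original descriptor values came from commercial generators
whose aromaticity, protonation and centering conventions are not public, so
when reproducing published predictions the descriptor table should be
supplied by the user rather than recomputed. (One cosmetic note: the
equation as printed spells the Moran term "MAT53s" where its definition
says "MATS3s"; the package uses the defined symbol.)

Aromaticity for Kekulé input is perceived by a Hückel-style rule over 5- and
6-membered rings (in-ring double bonds count one π electron, lone-pair
heteroatoms two, rings with exocyclic double bonds are skipped), iterated so
fused bicyclics such as naphthalene and quinoline resolve fully. Lowercase
aromatic SMILES bypasses perception. Exotic aromatics (azulenes, fulvenes,
charged rings) are outside the supported scope and should be written in
aromatic SMILES form.

## Dataset handling

`prefilter()` applies the three-stage pool reduction in a fixed order:
near-constant columns (modal frequency > 0.80), then pairwise correlated
columns ($|r| > 0.95$, scanned in lexicographic name order, dropping the
member less correlated with the response, falling back to smaller variance
and then to the later name), then low-variance columns. The low-variance
floor is not standardized anywhere, so it is an explicit parameter
(`var_floor`, default $10^{-4}$ on raw values). The filter is deterministic,
stable (never reorders survivors) and idempotent.

`partition_compounds()` draws a seeded random training/test split (the
study-scale default is 81/34 out of 115). The original split membership is
not published, so a fixed documented default seed stands in; any analysis
that depends on the split should report the seed.

## Model building

`fit_mlr()` is ordinary least squares with an intercept; columns are scaled
to unit variance internally for conditioning and coefficients
back-transformed, so reported equations are in raw descriptor units.
Rank-deficient designs fail loudly with the dependent column names.

`ga_select()` searches k-subsets (default $k = 5$) of the filtered pool.
Chromosomes are descriptor index sets; generations apply tournament
selection (size 2), uniform set-crossover with duplicate repair, per-gene
mutation to a random non-member (rate 0.1), and single-chromosome elitism.
The fitness is $Q^2_{LOO}$ rather than training $R^2$, which removes the
incentive to overfit; a singular candidate scores $-\infty$. Ties resolve
to the lexicographically smaller index set, and the seed is mandatory, so a
run is a pure function of its inputs. Defaults (population 100, 200
generations) solve the packaged synthetic benchmark in roughly ten seconds
on one core.

## Validation statistics

`validate_all()` assembles the full bundle; each statistic is also exported
alone. Conventions, where the literature is ambiguous, are:

* RMSE uses denominator $n$ (not $n-p'-1$); MAE is the plain mean absolute
  residual.
* Lin's concordance correlation coefficient uses population ($1/n$)
  moments.
* $Q^2_{LOO}$ uses the hat-matrix shortcut $e_i/(1-h_{ii})$, verified in
  the tests against explicit refits to $10^{-10}$; leverages at 1 trigger an
  explicit refit with a warning.
* $Q^2_{LMO}$ defaults to leaving out 20% per round, 1000 seeded rounds,
  aggregating held-out squared errors over all rounds. With group size 1
  and $n$ rounds it reduces exactly to $Q^2_{LOO}$.
* $rm^2$ metrics evaluate the through-origin scaled determination
  coefficient in both regression directions and report the average and the
  absolute difference; radicands pushed below zero by rounding are clamped
  at zero with a warning.
* `external_regression()` regresses calculated on experimental activity and
  reports the squared Pearson correlation as $R^2_{ext}$.
* `y_randomize()` permutes the response (default 2000 iterations) and
  refits coefficients on the frozen descriptor subset — re-running the GA
  per scramble would test a different null and is intentionally not the
  default. Means and maxima of the scrambled $R^2$ and $Q^2$ are both
  reported, since summaries in the literature are sometimes one and
  sometimes the other. Under independence the scrambled $R^2$ mean sits at
  $p'/(n-1)$ — for $p'=5$, $n=81$ that is 0.0625, which is also a useful
  plausibility anchor for published scrambling summaries.
* `williams_ad()` computes leverages with the intercept column included,
  standardized residuals with the $n-p'-1$ residual standard deviation, and
  the warning threshold $h^* = 3(p'+1)/n$ — 0.222 for the published model's
  $p'=5$, $n=81$. Flags: leverage above $h^*$, residuals beyond $\pm3\sigma$.

No leverage-based outlier exclusion is performed during fitting; the
workflow reports influential points rather than silently dropping them.

## Synthetic data: what it emulates, and what it does not

`gen_qsar_dataset()` produces descriptor pools with the planted five-term
signal: the five planted columns use realistic marginals (conjugation-path
integers around 14 ± 11; Moran values around 0.05 ± 0.11; R8m around
0.9 ± 0.29; Bernoulli fragment indicators), scaled so each term contributes
about 0.6 activity-SD. At the default response noise of $\sigma = 0.75$ log
units the planted population $R^2$ is about 0.76, matching the regime of
the published training fit; across seeds the realized $R^2$ averages
0.70–0.82, with per-seed spread of roughly ±0.08 dominated by chance
correlations among the planted columns at $n \approx 115$. Decoys are
standard normal (optionally lognormal), with optional correlated decoys,
near-constant columns, and exact duplicates for exercising the pre-filter.
Generators are pure functions of (parameters, seed).

What the generator does **not** emulate: real descriptor pools are far
larger (thousands of columns), heavily blockwise-correlated, and the true
structure-activity relationship is not exactly linear in five columns.
Passing the packaged recovery tests therefore demonstrates that the search
and validation machinery is correct, not that a five-descriptor model is
recoverable from any real pool.

`gen_trajectory()` builds harmonic-style trajectories: a reference
structure plus optional exactly anti-correlated atom-pair modes, isotropic
Gaussian noise, and an optional two-state rigid jump with chosen occupancy
for free-energy closed forms. It does not emulate solvent, force-field
physics, or autocorrelated dynamics.

## MD post-statistics

All statistics are computed from coordinates alone. `superpose()` is the
Kabsch least-squares fit (mass-unweighted, determinant-corrected);
the default superposition reference is the first frame, with the mean
structure available by flag. RMSD/RMSF/Rg follow their textbook
definitions; RMSF assumes pre-superposed frames. `dccm()` normalizes
fluctuation covariances to $[-1, 1]$; zero-fluctuation atoms yield zero
off-diagonals (unit diagonal) with a warning rather than NaN. `pca_modes()`
eigendecomposes the $3N \times 3N$ fluctuation covariance; eigenvalues are
clamped at zero against rounding. `fel()` Boltzmann-inverts 2D bin
occupancies at $T = 300$ K by default ($k_B = 0.0083145$ kJ/mol/K), masks
empty bins as missing (not infinite), and anchors the global minimum at
exactly zero. Both PC1/PC2 and RMSD/Rg axis pairs are supported, since both
appear in practice; the axis choice is the caller's. Published landscapes
sometimes report nonzero global minima, which implies an undocumented
offset convention; no such offset is applied here.

## Problem sizes in the test suite

The packaged tests run the GA recovery benchmark at 120 compounds × 60
descriptors over 10 seeds (about two minutes on one core), Y-randomization
at 2000 iterations, DCCM noise-decay at 5000 frames × 20 atoms, and oracle
comparisons (explicit leave-one-out refits, double-loop autocorrelations,
breadth-first distances) on small seeded instances. These sizes were chosen
as the smallest at which the statistical claims are sharp.

## Interfaces

The package API, `run_pipeline()` (which chains descriptors → prefilter →
partition → GA selection → validation → applicability domain and
Y-randomization → prediction, with a manifest of seeds, parameters and
input hashes), and this vignette are the intended interfaces; pipeline
configuration is a YAML-serializable list, so runs are reproducible from a
single file. No shell wrapper is shipped: the functions compose better in R
scripts, and every artifact the pipeline writes is plain CSV/JSON.

## Known limitations

* The SMILES dialect covers the organic subset, bracket atoms, rings and
  branches; stereochemistry is parsed but ignored, and isotopes are
  ignored. Tautomer enumeration and 3D conformer generation are out of
  scope — R8m expects user-supplied coordinates (SDF).
* Native descriptor values can differ from commercial generators' values
  for the same molecule; the bundled equation should be applied to
  descriptor tables produced under the conventions it was trained with.
* Training-set statistics of the published model (its $R^2$, $Q^2$, and
  related table) cannot be recomputed here because the 81-compound
  descriptor table is not public; the package instead verifies every
  statistic against closed forms and independent oracles on seeded data.
* The 115-compound pool reduction (11,135 → 2,140 descriptors) is likewise
  not reproducible without the original pool; the pre-filter is verified on
  planted synthetic pools instead.
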