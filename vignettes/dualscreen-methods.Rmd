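---
title: "Methods behind dualscreen: curation, screening, QSAR and trajectory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind dualscreen: curation, screening, QSAR and trajectory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

`dualscreen` implements the statistical and cheminformatic machinery of a
dual-target inhibitor discovery campaign: starting from public bioactivity
records for two protein targets, it curates and classifies compounds,
compares the chemical space of the two inhibitor sets, screens docked poses
by protein–ligand interaction fingerprint (PLIF) similarity, trains weighted
decision-tree QSAR models, and summarises molecular-dynamics (MD)
trajectories of the final candidates. Every stage is paired with a seeded
synthetic-data generator that plants a known ground truth, so the entire
pipeline can be exercised and validated without external downloads or
commercial software.

This vignette describes the model behind each stage, the defaults and the
reasoning behind them, and the deliberate simplifications of the synthetic
generators.

## 1. Bioactivity curation

Public bioactivity tables (ChEMBL-style exports) mix units, censored values,
surrogate readouts and low-confidence assays. `curate_bioactivity()` applies
a fixed, auditable sequence:

1. **Row filters**, each counted separately in the curation report: empty
   activity values, values that do not parse as a non-negative number,
   censored relations (`>`, `>=`, `≥` — these are lower bounds, not
   measurements), excluded readout types (`FC`, `Ratio` — fold changes are
   not concentrations), empty units, units that cannot be converted to
   molar concentration (e.g. `%`, `mg/mL`, which need molecular weights or
   are not concentrations at all), and assay confidence below a threshold
   (default 8, the ChEMBL level for a direct single-protein assignment).
   Each row is attributed to the *first* rule it violates, so the per-rule
   counts sum to the number rejected.
2. **Unit normalisation** to nanomolar with exact factors
   (M = 1e9, mM = 1e6, µM = 1e3, nM = 1, pM = 1e-3).
3. **Structure normalisation**: each SMILES is canonicalised after keeping
   the largest connected component (salt stripping) and neutralising formal
   charges, so a parent acid, its sodium salt and its anion share one key.
4. **Deduplication**: the *minimum* activity per canonical structure is
   kept. Taking the minimum (the most potent measurement) is the common
   conservative choice when assays disagree; the group size is retained so
   downstream users can weight by evidence.
5. **Three-class binning** with strict thresholds: `active` below
   1000 nM, `inactive` above 10 000 nM, `moderate` in between, with both
   boundary values (1000, 10 000) falling in the moderate class.

```{r curation}
gb <- gen_bioactivity_table(seed = 1)
cur <- curate_bioactivity(gb$records)
str(cur$report$filter)
table(cur$compounds$activity_class)
```

`gen_bioactivity_table()` plants an exactly known number of violations of
each rule, duplicate groups with known minima (values expressed in mixed
units with full-precision strings, so conversion is exact), and clean
records with known classes. The test suite checks that curation recovers
every planted count exactly.

## 2. Chemical space

Two inhibitor sets are compared on three levels.

**Physicochemical profile** (`physchem_profile()`): TPSA, rotatable bonds,
logP, hydrogen-bond donor + acceptor count, molecular weight and ring
count. The continuous descriptors come from OpenBabel; ring counts are the
cyclomatic number of the molecular graph and rotatable bonds are acyclic
single bonds between two non-terminal atoms, both computed on the parsed
connection table so that single-atom molecules and other edge cases are
handled uniformly.

**Scaffolds** (`murcko_scaffold()`, `scaffold_overlap()`): the Bemis–Murcko
scaffold is obtained by iteratively pruning terminal heavy atoms, keeping
exocyclic atoms attached by double or triple bonds (a linker carbonyl
oxygen is part of the scaffold), and discarding acyclic fragments. Pruned
substituents are replaced by hydrogens on the hydrogen-explicit connection
table before re-canonicalisation; this keeps pyrrole-type nitrogens
aromatic, so N-methylindole and indole map to the same scaffold:

```{r scaffold}
murcko_scaffold("Cn1ccc2ccccc21")   # N-methylindole
murcko_scaffold("c1ccc2[nH]ccc2c1") # indole
```

**Similarity and embedding**: Morgan/ECFP4 fingerprints (OpenBabel ECFP4,
folded to 1024 bits by OR-ing bit index modulo width) feed Tanimoto
similarity, per-compound maximum cross-set similarity
(`cross_max_similarity()`), maximum-common-substructure search
(`mcs_size()`, exact connected-subgraph backtracking with a strict
element+aromaticity mode and a relaxed element-only mode, under a per-pair
time budget), and a 2-D embedding. The embedding uses classical metric
multidimensional scaling of the Tanimoto distance matrix rather than t-SNE:
MDS is deterministic, dependency-free and adequate for the set sizes
involved here; the `seed` argument is kept for interface stability but no
randomness is consumed.

## 3. PLIF screening

A docked pose is reduced to a binary vector over binding-site residues —
its protein–ligand interaction fingerprint. Given a reference profile (the
contacts of a co-crystallised ligand), compounds are scored by Tanimoto
similarity of their PLIF to the reference, optionally restricted to the
top-N most frequently contacted residues (`select_top_residues()`, ties
broken by ascending residue number for determinism).

Screening quality is summarised by an enrichment curve: at each similarity
threshold, the percentage of passing compounds that are true actives
(`enrichment_pct`) and how many compounds pass (`coverage`). At the loosest
threshold everybody passes, so enrichment equals the base active rate;
coverage can only shrink as the threshold tightens. `curve_diagnostics()`
reports the maximum and any non-monotone "drops", which flag unstable
threshold regions.

```{r plif}
gp <- gen_plif_matrix(seed = 1)
cm <- gp$matrix
top <- select_top_residues(contact_frequency(cm), 10)
sims <- plif_similarity_all(cm, gp$reference, subset = top)
ec <- enrichment_curve(sims, cm$labels)
as.data.frame(ec)[c(1, 9, 11), ]
```

`gen_plif_matrix()` draws contacts independently: actives hit each of the
`k` reference residues with probability `p_active` (default 0.9),
inactives with `p_inactive` (default 0.3), and everyone hits background
residues with `q` (default 0.05). Moderates use the midpoint of the two
rates — a deliberate one-parameter simplification rather than a separate
knob. Docking scores are drawn independently of class, so the generator
cannot leak label information through the score column. The generator also
returns the analytic expected Tanimoto similarity per class (an exact sum
over the binomial background), which the tests compare against simulated
means.

Dual-target hits are selected with `dual_criterion()`: similarity to
target A in the half-open window (0.8, 0.9] and similarity to target B at
least 0.9. The window on A is motivated by screening practice — compounds
almost identical to the reference inhibitor (similarity > 0.9) are
redundant, while the band just below keeps the binding mode but allows new
chemistry; target B only needs to be matched well. All three cutoffs and
their inclusivities are arguments.

## 4. Decision-tree QSAR

`fit_and_evaluate()` trains a CART classification tree (package `rpart`)
for the three activity classes, with class weights applied as per-case
weights. Class weighting matters because curated sets are usually
imbalanced; the `"balanced"` scheme uses inverse class frequency
(n / (k·n_c)), and fixed schemes (1:1:1 up to 1:5:10) allow deliberate
up-weighting of rare classes. Hyperparameters (maximum depth, minimum leaf
size) are tuned by stratified k-fold cross-validation maximising macro-F1
(`tune_tree()`); ties go to the shallower tree with larger leaves, i.e. the
simpler model. Splitting (`split_train_test()`) is stratified 80:20 and
deterministic per seed.

All metrics are computed from the confusion matrix with explicit formulas:
per-class precision TP/(TP+FP), recall TP/(TP+FN), F1 as their harmonic
mean, and overall accuracy as the trace over the total. A class that is
never predicted has *undefined* precision; it is reported as `NA` and
flagged rather than silently zeroed (during CV tuning, undefined F1 is
scored as 0 so such models lose).

`cross_apply()` applies a model trained on one target's compounds to
another's, flagging compounds whose maximum Tanimoto similarity to the
training set falls below 0.3 as outside the applicability domain — below
that level the model's training chemistry says little about the new
compound.

`gen_descriptor_table()` plants `n_informative` descriptors whose class
means are separated by `separation` standard deviations, among pure-noise
descriptors. At separation 5 the classes are nearly disjoint and a shallow
tree must reach ≥ 95 % test accuracy; at separation 0 the labels are
unlearnable, which the tests use as a negative control.

## 5. MD post-analysis

All statistics work on a plain `trajectory()` object (times, a
frames × atoms × 3 coordinate array, and an atom table with residue and
role annotations).

- `energy_drift()` fits a least-squares line to the energy series and
  compares the relative drift (slope × duration / mean) against a 1 %
  tolerance — the usual sanity check that an equilibrated run is not
  heating.
- `rmsf()` computes per-residue root-mean-square fluctuation about the
  time-mean position, optionally after Kabsch (SVD) superposition of every
  frame onto the first. For isotropic per-axis jitter of standard deviation
  σ the expected RMSF is σ√3. Note that superposition itself removes part
  of the apparent fluctuation (the fitted rigid body absorbs roughly 2/N of
  the variance); recovery tests against planted jitter therefore use
  `superpose = FALSE`, since the generator plants no rigid-body drift to
  remove. Use superposition on real trajectories, where global tumbling
  dominates.
- `min_distance_series()` and `fraction_within()` give the
  ligand-to-residue minimum distance per frame and the fraction of frames
  strictly below a cutoff (default 5 Å).
- `detect_hbonds()` applies the standard geometric criterion —
  donor–acceptor distance ≤ 3.5 Å and hydrogen–donor–acceptor angle ≤ 30° —
  to every protein/ligand donor–H/acceptor triple, producing an existence
  matrix. `occupancy_stats()` reduces it to per-residue occupancies and the
  fractions of frames with ≥ 1 and ≥ 2 simultaneously bonded residues;
  `binned_hbond_counts()` bins bond counts into the categories < 10,
  10–20 (inclusive) and > 20 frames per bin.

`gen_trajectory()` places residues 10 Å apart with independent Gaussian
jitter, and can plant a ligand at exactly 3 Å (contact) or 8 Å
(no contact) from the reference residue in a chosen fraction of frames, so
`fraction_within()` must recover that fraction *exactly*.
`gen_hbond_matrix()` in deterministic mode plants exact occupancies by
prefix placement, giving closed-form per-residue, ≥ 1 and ≥ 2 fractions.

```{r md}
gt <- gen_trajectory(seed = 1, n_frames = 2000, sigma = 0.5,
                     frac_within = 0.164)
mean(rmsf(gt$trajectory, superpose = FALSE)$rmsf)  # expect ~0.866
fraction_within(min_distance_series(gt$trajectory, "A:THR:1"))
```

## 6. Text formats

`load_xvg()`/`write_xvg()` read and write GROMACS XVG time series
(preserving `#` comments and `@` directives; numbers are written with 17
significant digits so round trips are lossless). `load_xpm()`/`write_xpm()`
handle GROMACS-style XPM pixmaps (one character per level, colour-map
labels in comments, pixel rows top-first). Contact matrices, H-bond
existence matrices and trajectories have tab-delimited writers and readers
with lossless round trips.

## Limitations

The synthetic generators are deliberately minimal: PLIF contacts are
independent Bernoulli draws (no residue correlation, no pose geometry),
descriptors are Gaussian (no descriptor correlation structure), trajectories
are i.i.d. jitter around fixed means (no kinetics, no solvent), and the toy
SMILES library covers 132 small drug-like structures rather than real
screening chemistry. They exist to *validate the statistics*, not to
emulate physics. Problem sizes and default parameters (200 residues, 200
compounds, 10 reference contacts, etc.) were chosen so the full validation
suite runs in well under a minute per stage on one CPU; all of them are
arguments.
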