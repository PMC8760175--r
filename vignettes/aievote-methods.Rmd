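---
title: "Predicting AIE versus ACQ with multi-modal ensemble voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting AIE versus ACQ with multi-modal ensemble voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aievote)
```

## The problem

Aggregation-induced emission (AIE) luminogens light up when they
aggregate; conventional fluorophores suffer aggregation-caused quenching
(ACQ). The dominant design heuristic is structural: propeller-shaped
molecules carrying several freely rotating aryl "rotors" (the
tetraphenylethylene motif) tend to be AIE-active, because aggregation
restricts intramolecular rotation and closes the non-radiative decay
channel, whereas large planar fused aromatics pack into tight π-stacks
and quench. `aievote` turns that heuristic into a supervised
classification pipeline: given only a SMILES string, predict AIE or ACQ.

The pipeline has five stages, each exposed as ordinary functions over
tibbles and matrices:

1. **dataio** — read and validate labeled SMILES tables, canonicalize
   structures (OpenBabel canonical SMILES), reject unparseable rows into
   an explicit report.
2. **featurize** — five feature modes per molecule: four hashed
   2048-bit fingerprints (Morgan circular, linear-path, atom-pair,
   topological torsion) and a 108-dimensional quantitative descriptor
   vector (20 composition-level "1D" + 88 graph-level "2D" descriptors).
3. **fuse** — optional multi-modal fusion: full-rank PCA on a
   fingerprint block concatenated with the z-scored quantitative block.
4. **models / ensemble** — five classifier families (logistic
   regression, KNN, gradient boosting, random forest, multilayer
   perceptron), each tuned by inner 5-fold grid search per feature mode;
   all (family, mode) combinations vote with hard labels and the
   majority wins (25 voters single-modal, 20 multi-modal).
5. **evaluate** — stratified outer 10-fold cross-validation with
   accuracy, precision/recall/F1, ROC/AUC and pooled confusion counts,
   reported as mean ± sd over folds.

## Feature modes

All four fingerprints are presence/absence bit vectors folded to a
common width (default 2048 bits) so the modes are directly comparable.
Substructure identifiers are hashed with 32-bit FNV-1a and taken modulo
the width; collisions are an accepted property of hashed fingerprints,
not an error.

* **Morgan (circular)** — iterative neighbourhood identifiers up to a
  radius (default 2, the ECFP4-equivalent diameter). The initial atom
  invariant combines element, heavy degree, implicit hydrogen count,
  π-electron count, aromaticity and ring membership. An atom stops
  emitting new identifiers when its covered neighbourhood no longer
  grows, so a single-atom molecule sets at most one bit.
* **Linear-path** — all simple paths of 1–7 bonds, encoded as the
  lexicographically smaller of the forward/reverse strings of atom
  symbols (aromatic atoms tagged) and bond symbols. This is the classic
  path-based (Daylight-style) construction; the original Daylight
  algorithm is proprietary, so a hashed linear-path generator of the
  same family is used.
* **Atom-pair** — for every atom pair, the sorted pair of atom types
  (element, heavy-neighbour count, π-electron count) plus their
  topological distance.
* **Topological torsion** — every linear sequence of four bonded heavy
  atoms, each typed by element, π-electron count and the number of
  branches outside the path.

Aromatic bonds carry their own bond symbol everywhere, so a molecule's
fingerprint cannot depend on which Kekulé structure the parser happened
to emit, and all generators are invariant to the atom order of the
input SMILES.

The quantitative block is a fixed, documented registry of 108
descriptors: 20 composition-level (element counts, molecular weight,
formal charge, ...) and 88 graph-level (bond and degree profiles,
Wiener/Balaban/Harary/Zagreb indices, Kier–Hall chi and kappa families,
ring-system statistics, path and distance-pair counts, and four
OpenBabel-backed physicochemical values: logP, molar refractivity,
TPSA, H-bond acceptor count). Any ordered subset of registered names
can be requested instead, so a user holding a different canonical
descriptor list can reproduce it exactly.

## Multi-modal fusion

Fingerprints are 2048-dimensional and binary; descriptors are 108
continuous values on wildly different scales. Fusion makes the two
modalities commensurate:

* PCA (centred, unscaled) on the fingerprint block with
  `k = min(n_samples, n_features)` components by default. At full rank
  the projection is an isometry of the training rows and conserves all
  variance — the explained-variance ratios sum to 1 (the package
  asserts this to 1e-9). On an n-molecule dataset with 2048-bit
  fingerprints and n < 2048 this yields exactly n components, e.g. 356
  components on a 356-molecule dataset, hence 356 + 108 = 464 fused
  dimensions.
* z-scoring of each quantitative column by its training mean and sd.
  Constant columns (sd = 0) map to 0 rather than NaN so the fused width
  never varies.

The binary fingerprint block is centred but deliberately not scaled:
per-bit scaling would blow up rare bits, and the z-scoring step is
defined for the quantitative block only.

**Fit scope.** By default the fusion (PCA axes and z-statistics) is
fitted once on the full dataset before cross-validation; that is the
only protocol under which the fused dimension equals
n_samples + 108 on the full data, and it mirrors common QSAR practice
of treating unsupervised feature construction as preprocessing. It
does, however, let test-fold feature geometry see training folds. The
`fold_safe = TRUE` switch refits the fusion inside every outer training
fold for a strictly leakage-free protocol; both scopes are recorded in
the run manifest. For prediction of new molecules the fitted model's
`k` is frozen: the fused dimension of any future batch is set at train
time, never by the batch size.

## Classifier families and tuning

Each family delegates to the standard R learner and is searched over
the published grid by inner 5-fold cross-validation (selection metric:
accuracy by default, F1 optionally; ties go to the first grid point in
declared order so runs are reproducible):

| family | backend | grid |
|---|---|---|
| logistic regression | glmnet (ridge) | C = 10^(-3..3), 7 points |
| KNN | class::knn | k ∈ {3,5,7,9,11,13,15,17,18}, Euclidean |
| gradient boosting | xgboost | leaf fraction {0.1..0.5} × depth {3,5,7} × subsample {0.5,0.75,0.95} |
| random forest | ranger | min split {2,4} × trees {10,50,100,200,500} |
| MLP | nnet | weight decay α ∈ {1e-5,1e-4,1e-3} |

Numerical choices that the grids do not cover are fixed and logged in
the run manifest: boosting uses 100 rounds at learning rate 0.1 with
`min_child_weight = 0.25 · leaf_fraction · n` (the hessian of the
logistic loss is at most 1/4, so this is the closest analogue of a
minimum-samples-per-leaf fraction; a separate minimum-samples-per-split
control does not exist in this tree learner and collapses into the leaf
constraint). The perceptron has one hidden layer of 4 units trained by
BFGS with at most 60 iterations; BFGS keeps a dense
n-weights × n-weights workspace, which rules out very wide hidden
layers on 464-dimensional inputs, and it has no learning-rate
hyperparameter, so weight decay is the tuned axis. The KNN grid's final
value 18 breaks the odd sequence but is used verbatim as published.
KNN distance ties are broken under a per-model seed so the family stays
deterministic; logistic regression and KNN are fully seed-invariant on
fixed folds, while boosting, forests and the perceptron are stochastic
families whose seeds derive from the global seed by a stage-name hash.

## The voting ensemble

Every (family, feature-mode) pair is one voter emitting a hard
AIE/ACQ label; the category with more votes is the final call. With all
five families this gives 25 voters over the five single-modal feature
sets and 20 over the four fused multi-modal sets. The fraction of AIE
votes serves as the ensemble's score for ROC/AUC — votes are hard
labels, so the vote fraction is the canonical soft surrogate, and this
interpretation is documented rather than hidden. Even panels can tie
(10 vs 10): the default policy predicts the training-majority class
(ACQ on the default class balance), flags the record, and is switchable
to a fixed class or to the mean voter score.

## Evaluation protocol

Outer stratified 10-fold cross-validation is shared across all voters,
so methods are compared on identical splits. Stratification allocates
each class as evenly as possible and places remainders on the currently
smallest folds; with 134/222 labels in 10 folds every fold holds 13–14
positives and 35–36 records. Hyperparameters are re-tuned inside every
outer training fold (nested CV), train accuracy is the tuned model's
accuracy on its own outer-training split, and the mean ± sd column uses
the sample (n−1) standard deviation over the K folds. Undefined ratios
(zero denominators) are reported as NA, never silently zeroed. AUC is
computed as the rank-based Mann–Whitney statistic — the probability
that a random positive outranks a random negative, ties counting one
half — which is identical to the trapezoidal area under the ROC curve
and invariant under monotone transforms of the scores. The false
positive rate is FP/(TN+FP), the only definition consistent with the
ROC construction.

## The synthetic testbed

Real AIE/ACQ labels come from photoluminescence titrations and live in
curated literature datasets; none ship with this package. For testing,
`generate_dataset()` assembles molecules from a fragment library and
labels them with a planted, deterministic rule:

> AIE iff the molecule carries at least `rotor_threshold` (default 3)
> aryl rotors — benzene or naphthalene units attached by exactly one
> acyclic single bond — and its largest fused ring system has fewer
> than `fused_ring_block` (default 3) rings.

The AIE side of the library assembles tetra-/tri-aryl ethylenes,
triarylamines and triarylmethanes from phenyl/naphthyl rotors; the ACQ
side decorates planar fused aromatics (naphthalene through pyrene,
triphenylene, chrysene) and includes deliberately boundary-adjacent
two-rotor molecules (biphenyls, stilbenes, benzophenones). Defaults
emulate the study conditions: 356 molecules, 134 AIE vs 222 ACQ, zero
label noise, seed-deterministic down to the output bytes. Candidates
are rejection-sampled: each assembly is canonicalized, deduplicated and
relabeled by the rule itself, so stored labels always agree with the
planted ground truth before noise, and `label_noise` then flips each
label independently with the given probability.

The rule is intentionally visible to every feature mode — rotor counts
and fused-ring fragments appear in all four fingerprints and in the 2D
descriptors — so an end-to-end accuracy test on noise-free data is a
meaningful check of the whole pipeline rather than a vacuous one. The
generator emulates the class structure and the structural logic of the
real problem, not its photophysics: passing on synthetic data shows the
pipeline machinery is sound, not that real-world accuracy will match.
Real datasets carry correlated scaffolds, label noise from differing
experimental conditions, and chemistry (charged dyes, heteroaromatic
cores, non-rotor AIEgens) the library does not emit.

## Problem sizes used in the shipped checks

The package's own test suite runs the full protocol at study scale for
the structural checks (356-molecule generation, 2048-bit blocks,
full-rank PCA, 464 fused dimensions) and evaluates the end-to-end
multi-modal ensemble with grids thinned to two points per
hyperparameter axis — endpoints kept — which preserves the protocol
shape while keeping a laptop-scale runtime. Unit tests use a
48-molecule dataset and a 3-fold/3-fold nested split for the same
reason. These sizes are the package's choices for routine verification;
nothing in the implementation caps the full grids or fold counts.

## Worked example

```{r example, eval = FALSE}
library(aievote)

data <- generate_dataset(n = 120, n_positive = 45, seed = 7)
config <- aie_config(grid_points_per_axis = 2)
cv <- run_cv(data, config, multimodal = TRUE, seed = 7)
cv_table(cv)        # Table-style mean ± sd report
glance(cv)          # one row per (family, mode)
autoplot(cv)        # mean ± sd bars per voter cell

panel <- train_full_panel(data, config, multimodal = TRUE, seed = 7)
newdata <- as_dataset(tibble::tibble(
  id = "tpe", smiles = "C(=C(c1ccccc1)c1ccccc1)(c1ccccc1)c1ccccc1"))
predict(panel, newdata)
```

## Known limitations

* OpenBabel is the single source of structural truth (parsing,
  canonical SMILES, aromaticity); molecules OpenBabel mis-parses are
  mis-featurized. Stereochemistry is ignored throughout — all
  descriptors are 1D/2D, as designed.
* Formal charges are read from bracket atoms of the SMILES text, not
  from a full valence model; exotic charged species may get descriptor
  values of limited meaning.
* The descriptor registry is a documented, reproducible set, not a
  reimplementation of any particular toolkit's list; absolute values of
  e.g. chi/kappa descriptors follow the standard definitions but a user
  comparing against another toolkit should swap in their own list via
  `aie_config(descriptors = ...)`.
* The ensemble's AUC rests on the vote-fraction score, which is a
  20–25-level discretisation; per-voter AUCs use continuous scores.
* Single-modal logistic regression on raw (unstandardised) descriptors
  is known to behave poorly; that is a property of the protocol, not a
  bug, and the multi-modal path z-scores the block.
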