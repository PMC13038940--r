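---
title: "Classifying phage virion proteins with stacked ensembles of PSSM-derived features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying phage virion proteins with stacked ensembles of PSSM-derived features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phage virion proteins (PVPs) are the structural proteins of the mature
bacteriophage particle — capsid, tail, baseplate, fibers. They mediate host
recognition and genome injection, which makes them primary candidates for
phage-therapy engineering and the first thing one wants annotated in a new
phage genome. Distinguishing PVPs from the phage's intracellular (non-virion)
proteins from sequence alone is hard: phage proteins are hyper-diverse and
poorly conserved at the residue level, so plain composition features carry a
weak signal.

`pvpstack` implements a two-layer stacked ensemble classifier over
*evolutionary* sequence representations. The premise is that although raw
sequences diverge quickly, the per-position substitution preferences captured
by a PSI-BLAST position-specific scoring matrix (PSSM) are far more stable,
so descriptors computed from the PSSM separate virion from non-virion
proteins better than descriptors computed from the sequence itself.

The package consumes FASTA sequences plus precomputed ASCII PSSM profiles
(the `-out_ascii_pssm` output of PSI-BLAST). It deliberately does **not** run
PSI-BLAST or download reference databases; profile generation (typically 3
iterations against UniRef50 at E-value 0.001) is an external preprocessing
step, as is redundancy removal with CD-HIT.

## Feature representations

A PSSM is an $L \times 20$ matrix $p(k, j)$ of log-odds scores: position $k$
of the protein, substituted by amino-acid type $j$. Internally all profiles
are stored with columns in alphabetical amino-acid order, remapped from the
PSI-BLAST file order at parse time, so encoders never depend on file layout.
Four descriptors are computed, concatenated to 860 features:

* **AAC-PSSM** (20): column means, $x_j = \frac{1}{L}\sum_{k=1}^{L} p(k,j)$ —
  the average evolutionary propensity toward each residue type.
* **DPC-PSSM** (400): adjacent-position column products,
  $y(i,j) = \frac{1}{L-1}\sum_{k=1}^{L-1} p(k,i)\,p(k+1,j)$ — local
  residue-pair dependency.
* **PSSM-COM** (400): the $20\times20$ matrix whose $i$-th row is the sum of
  PSSM rows at positions where the sequence carries amino acid $a_i$
  (indicator-weighted row sums), divided by $L$ by default. Length
  normalisation removes the strong dependence of raw sums on protein length;
  it can be disabled for strict raw sums.
* **Pse-PSSM** (40): 20 column means of the row-standardised profile plus 20
  lag-$\xi$ terms $\frac{1}{L-\xi}\sum_k (\tilde p(k,j) - \tilde
  p(k+\xi,j))^2$ with $\xi = 1$, capturing sequence-order information. Only
  the 40-dimensional form is consistent with the 860-feature total; the
  package implements exactly that form.

Normalisation is per-descriptor: raw log-odds for AAC-PSSM, DPC-PSSM and
PSSM-COM, row-standardisation (zero mean, unit variance across the 20 entries
of each row; zero-variance rows map to zeros) for Pse-PSSM. These match the
descriptors' original definitions; `normalize_pssm()` also exposes a sigmoid
mode for experimentation.

For comparison, seven classical descriptors (723 features) are available:
AAC (20), DPC (400), GAAC (5) and GDPC (25) over the five physicochemical
groups (aliphatic, aromatic, positively/negatively charged, uncharged), and
the CTD family — composition (39), transition (39) and distribution (195)
over 13 three-group physicochemical partitions of the alphabet (seven
hydrophobicity scales, van der Waals volume, polarity, polarizability,
charge, secondary structure, solvent accessibility). The partitions are
pinned as constants and tested to be exact partitions; distribution
percentiles use 1-based indexing with ceilings on fractional counts and
report five zeros for an absent group.

## Dataset hygiene

`filter_records()` applies the benchmark conventions: sequences are
upper-cased, terminal `*` stop characters are stripped (and logged), and a
record is rejected when shorter than 50 residues (`SHORT`) or containing any
character outside the 20 standard letters, including the ambiguity codes X,
U, Z, B (`NONSTANDARD`). Length is assessed on the raw sequence and takes
precedence when both rules fail. Both the cutoff and the forbidden set are
arguments.

## Feature selection

Three selectors reduce the 860-feature space; each returns a named,
re-playable `pvp_selection` fitted on training data only:

* **F-score** (`f_select`): per-feature one-way two-group ANOVA F statistic.
  Zero within-class variance with distinct class means yields a `+Inf`
  sentinel (ranked first); all-constant features score 0. Ties break by
  original column order. Default kept count: `min(400, d)` — the retained
  dimensionalities of the original experiments are unpublished, so the
  default is an explicit, recorded stand-in.
* **Variance** (`variance_select`): keeps features with population variance
  at or above a threshold; the default threshold is the 25th percentile of
  the observed feature variances, again an explicit stand-in recorded in the
  selection's provenance.
* **RFECV** (`rfecv_select`): recursive feature elimination — repeatedly fit
  an estimator, drop the `step` least-important features — with the retained
  count chosen to maximise mean stratified-CV accuracy (ties to the smaller
  count). The default importance source is a linear max-margin classifier
  (absolute hyperplane coefficients); a random-forest Gini alternative is
  selectable. With 860 features, `step = 1` is exact but slow; `step` of
  20-25 is the practical choice and what the command-line pipeline defaults
  to.

Selections serialise to delimited text so a train-time selection can be
replayed verbatim at prediction time; `apply_selection()` only subsets and
reorders columns by name and never recomputes statistics, which is the
leakage guard the tests assert.

## The stacked ensemble

The first layer is a panel of base classifiers; the canonical roster has 12
slots: DT, RF, EF (extremely randomised trees), GBDT, XGBoost, LightGBM,
AdaBoost, CatBoost, SVM, ANN, KNN, MLP. In this R implementation ten slots
have installed backends (rpart, randomForest, ranger, xgboost in two
configurations — classic exact-split boosting for GBDT and regularised
histogram boosting for XGBoost — a SAMME AdaBoost implemented in-package
over shallow rpart trees, e1071 SVM, two nnet single-hidden-layer networks
for ANN/MLP, and caret's k-nearest-neighbour model). LightGBM and CatBoost
have no R backend in the dependency set: they remain in the roster and in
the enumerated experiment grid, but requesting them at fit time is an
explicit error, never a silent substitution. `available_algorithms()` is the
default fitting panel.

For each selector-reduced dataset, `fit_base_layer()` builds **out-of-fold
(OOF) meta-features**: a single stratified 10-fold plan (one seed, shared by
all algorithms so rows align) partitions the training set; the fold-$f$
model of each algorithm is trained without fold $f$ and predicts the
positive-class probability of fold $f$'s rows. Every training row's
meta-feature vector therefore comes from models that never saw that row —
the construction that prevents the meta-learner from fitting base-model
overfit. A final refit on all rows is stored for inference. Meta-features
are probabilities, not hard labels: the merge of base outputs is ambiguous
in principle, and probabilities are the information-preserving standard
choice.

Blocks from multiple selectors concatenate in the fixed order F, Var, RFECV
(width $12 \times$ number of blocks with the full roster), and a
meta-classifier — logistic regression, random forest, or SVM — is trained on
the OOF matrix. The full experiment grid is $12 \times 3 = 36$ base models
and $(2^3 - 1) \times 3 = 21$ stacked configurations (`enumerate_grid()`,
`run_grid()`). The default `pvp_stack()` configuration is the
grid's best performer: F-score + RFECV blocks with a random-forest meta
model. Prediction threshold is 0.5 and a probability exactly at the
threshold counts positive; both the threshold and the tie rule are
documented and tested.

Base hyperparameters are nowhere published for this framework; the package
uses each backend's documented defaults with every seed pinned (a
deterministic per-algorithm, per-fold seed schedule derived from the spec
seed), all overridable via `base_layer_spec(params = ...)` and recorded in
the fitted object.

One degenerate input is handled explicitly: a meta-feature matrix in which
no column varies admits no classifier better than the class prior, and
tree backends cannot split on it at all (randomForest in fact loops
indefinitely on such input), so `fit_meta()` returns an explicit
constant-prior model in that case.

## Evaluation

`classification_metrics()` implements ACC, Sn, Sp, Precision,
F1 $= 2\,TP/(2\,TP+FP+FN)$ and
MCC $= (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}$.
Metrics with zero denominators are reported as `NA` with a warning — an
explicit undefined sentinel, never silently zero. Two AUC-like quantities
are kept deliberately distinct, because the literature this framework sits
in sometimes prints the closed form $\frac{1}{2}(Sn + Sp)$ under the name
"AUC" while reporting ROC-derived values: `roc_auc()` is the rank-based
(Mann-Whitney, ties at half weight) area under the ROC curve and is what
all reports use; `balanced_auc()` is the closed-form balanced accuracy of a
single confusion matrix. `cross_validate()` drives stratified 10-fold CV
with per-fold and pooled-OOF reports.

## The synthetic fixture generator

`synth_dataset()` exists so the whole pipeline is testable without UniRef50
or PSI-BLAST. It emulates random-coil profiles: integer log-odds drawn as
rounded $\mathcal{N}(0, 2^2)$ clamped to $[-10, 10]$ (the realistic
PSI-BLAST output range, which exercises the parser's negative and
double-digit alignment cases), residue strings drawn from a fixed
non-uniform background. The class signal is a $+\delta$ mean shift applied
to a configurable set of PSSM columns of positive-class profiles — planted
in the profile, not the sequence, mirroring the premise that evolutionary
features carry the discriminative signal; a sequence-composition mode
exists to exercise the 723-feature path. Generation is deterministic given
the master seed, with per-record derived seeds.

What the generator does *not* emulate: homology structure, protein
families, real amino-acid covariance, alignment-depth effects on profile
sharpness, or any biological difference between virion and non-virion
proteins. Passing the end-to-end tests therefore demonstrates that the
pipeline recovers a planted signal of known size without leaking
information — not that it attains any particular accuracy on real phage
data, which additionally depends on the quality of the PSSM profiles.

## Problem sizes and numerical choices

The shipped end-to-end checks use 200-sample synthetic datasets (100 per
class, lengths 60-100), a stratified 70/30 split, F-score selection to 50
features, a four-algorithm base panel (DT, RF, SVM, KNN) with 5 folds, and
an RF meta model; the signal-recovery checks ask for held-out ROC AUC at or
above 0.9 at $\delta = 4$ and a chance-level band of $[0.4, 0.6]$ for the
mean held-out AUC across seeds at $\delta = 0$, with mean AUC
non-decreasing over $\delta \in \{0, 1, 2, 4\}$ (tolerance 0.03, 5 seeds
per point). These sizes keep the default check suite fast while leaving the
effect sizes unambiguous; the full 10-algorithm, 10-fold configuration is
exercised on smaller problems elsewhere in the suite.

Other numerical choices: row standardisation uses the sample (n−1) standard
deviation and maps zero-variance rows to zeros; population (n) variance is
used by the variance selector, computed two-pass for stability; F-score
ties and RFECV count ties have deterministic break rules (original order /
smaller count); the PSSM writer emits only integer log-odds (the dialect's
native content) and refuses normalised profiles rather than rounding them
silently.

## Limitations

* PSSM quality bounds everything: orphan proteins with no detectable
  homologs yield flat profiles and uninformative evolutionary features.
* The descriptors see local conservation only; no long-range pairings or
  structural information.
* Published benchmark performance of this model family depends on specific
  benchmark sets and UniRef50-derived profiles; this package reproduces the
  machinery and its structural/metric claims exactly, but not those
  database-dependent numbers.
* The meta-learner inherits the base panel's biases; no probability
  calibration or hyperparameter search is attempted (out of scope by
  design).
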