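---
title: "Methods: fingerprint-based virtual screening with fpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint-based virtual screening with fpscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ligand-based virtual screening ranks large vendor libraries of purchasable
molecules by their predicted probability of inhibiting a protein target —
here, cyclin-dependent kinase 5 (Cdk5) — so that only a handful of
high-confidence candidates need to be purchased and assayed. `fpscreen`
implements the full classification workflow: curation of public bioactivity
data into labeled training/test sets, binary molecular fingerprints, four
classifier families with MCC-scored hyperparameter selection, consensus
scoring, precision-oriented threshold analysis, and library screening with
diversity clustering. A synthetic benchmark generator with a hidden
structure–activity rule makes the whole pipeline testable offline.

## Bioactivity curation

Raw input is one row per measurement: `compound_id`, `smiles`, `endpoint`
(Ki or IC50), `relation` (EQ/GT/LT), `value_nM`, `source_id`. The pipeline:

1. **Standardization.** Every structure is canonicalized with OpenBabel;
   salts are stripped by keeping the largest organic (carbon-containing)
   fragment; charges are neutralized where chemically possible. The
   canonical SMILES is the deduplication key. Stereochemistry is kept as
   written; no tautomer enumeration is attempted.
2. **Censored records** (`GT`/`LT`) are dropped before aggregation: a
   censored potency cannot enter an arithmetic mean.
3. **Replicate aggregation.** One value is used as is; two are averaged;
   with three or more, values deviating by more than 25% from the mean of
   all values are discarded and the mean of the survivors is recomputed
   once. The filter is deliberately single-pass (one recalculation);
   `iterate = TRUE` switches to a run-to-convergence variant. The deviation
   is linear and relative to the pre-discard mean; deviations of exactly
   25% are kept (an epsilon guards the boundary against floating-point
   noise in the mean). If every replicate is discarded the compound is
   dropped with a warning.
4. **Labeling.** Potency ≤ 1000 nM is ACTIVE, ≥ 5000 nM INACTIVE, the band
   in between EXCLUDED and removed. Both boundaries are inclusive.
5. **Split assembly.** Ki-measured compounds form the training pool; a
   seeded uniform random holdout (default 100 compounds) moves to the
   external test set, which additionally receives IC50-measured compounds
   not already used for training, plus any Ki compounds rejected by an
   optional `source_filter` (used in real-data mode to restrict training to
   one laboratory's assay series). Training and test sets never share a
   canonical SMILES.

Real ChEMBL-style exports enter through `read_bioactivity_csv()`; nothing
in the pipeline depends on the synthetic generator.

## Fingerprints

All six families produce fixed-length 0/1 vectors and are pure functions of
the molecular graph, so any SMILES spelling of a molecule gives the same
vector.

* **morgan** (default; radius 2, 2048 bits): circular ECFP-style
  environments. Each atom starts from an invariant hashing (element,
  degree, H count, charge, ring and aromatic flags); two rounds of
  neighborhood refinement append bond-order/neighbor-invariant pairs in
  sorted order; every (atom, radius) identifier is folded modulo 2048.
* **topological** (2048 bits): all simple linear paths of 1–7 bonds, atoms
  typed by element and aromaticity, canonicalized over traversal direction
  and hashed.
* **layered** (2048 bits): the same path enumeration hashed under three
  abstraction layers — bond orders only; elements plus bonds; elements plus
  aromaticity plus bonds — so substructures match at several specificity
  levels.
* **pattern** (2048 bits): generic substructure patterns, i.e. paths of 1–4
  bonds with atoms reduced to ring/aromatic classes plus single-atom
  element patterns.
* **maccs** (166 bits): the public 166 MACCS structural keys, computed by
  OpenBabel.
* **pharm2d** (2048 bits): 2- and 3-point pharmacophores over five feature
  types (H-bond acceptor, H-bond donor, positive ionizable, negative
  ionizable, aromatic ring), with topological distances binned at
  0–2 / 3–5 / 6–8 / >8 bonds; triangles are canonicalized over their six
  vertex orderings before hashing. Feature typing is rule-based on the
  neutralized graph (e.g. basic amine = non-aromatic N with no adjacent
  carbonyl). The folded length (2048) is recorded in `params`.

Hashing uses a fixed polynomial rolling hash over integer codes, exact in
double precision and identical across platforms. The Morgan, path and
pharmacophore algorithms are implemented in the package itself; their
definitions above are the reference.

Tanimoto similarity is `c / (|a| + |b| − c)` on bit counts. Two all-zero
vectors compare as identical (similarity 1), a convention that preserves
`T(x, x) = 1` universally; the degenerate case is reported with a message.
On binary vectors the similarity is a positive-semidefinite kernel, so
`tanimoto_kernel_matrix()` can be handed directly to an SVM.

## Models and model selection

Four families consume fingerprint matrices and expose a probability score
(PS) for the ACTIVE class; a compound is predicted active when PS ≥ 0.5
unless another threshold is requested.

| family | backend | declared grid |
|---|---|---|
| rf  | randomForest | n_estimators {100, 500} × max_features {log2, sqrt, none} |
| svm | kernlab C-SVC on a precomputed Gram matrix | C {0.01, 0.1, 1, 10, 100} × kernel {linear, tanimoto} |
| knn | in-package, Tanimoto distance | k 1..30 × weights {uniform, distance} |
| mlp | in-package feed-forward network | layers {[50,50,50], [50,100,50], [100]} × solver {lbfgs, adam, sgd} × activation {identity, logistic, tanh, relu} × learning_rate_init {1e-2..1e-5} |

Design choices where the design was genuinely open:

* **SVM probability scores** come from kernlab's Platt-type sigmoid
  calibration (`prob.model = TRUE`), fitted on internal cross-validated
  decision values with a recorded seed.
* **KNN metric.** Distance is 1 − Tanimoto, the field-standard choice for
  binary fingerprints (rather than a Euclidean/Minkowski metric). Under
  distance weighting, exact-duplicate neighbors (distance 0) dominate the
  vote.
* **MLP.** The network is implemented in the package (logistic output,
  binary cross-entropy, L2 penalty 1e-4, Glorot-uniform seeded
  initialization). `adam` and `sgd` run full batch for `max_iter`
  (default 200) iterations; `lbfgs` delegates to `stats::optim`. No early
  stopping.
* **Grid search** is exhaustive over the declared grid, scored by the mean
  MCC of stratified 5-fold cross-validation at the 0.5 threshold; ties go
  to the earlier grid point in the declared enumeration order.
* **Repeated cross-validation** implements the 10 × 70/30 protocol as
  Monte-Carlo resampling: ten independent seeded stratified splits, each
  holding out 30%, rather than disjoint folds. Splits are stratified
  because the datasets are imbalanced and MCC needs both classes present;
  a degenerate split would be resampled (up to ten derived seeds) with a
  warning, though stratification makes this unreachable in practice.

With a fixed master seed the entire tune/train/CV path is bit-reproducible;
child seeds are derived arithmetically from the master seed per fold,
repeat and model.

## Evaluation and consensus

`compute_metrics()` reports Precision = TP/(TP+FP), Recall = TP/(TP+FN) and
MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)). Any metric with a
zero denominator is reported as 0 and flagged `degenerate` — the standard
convention for an undefined MCC. The MCC denominator is accumulated in log
space and the result clamped to [−1, 1] against rounding noise.

`threshold_sweep()` re-evaluates predictions at thresholds 0.5–0.9 in steps
of 0.1 (the precision-maximization analysis). The predicted-positive count
and the recall are provably non-increasing in the threshold and are tested
as invariants; a precision *rise* is data-dependent and deliberately not
asserted.

Two consensus rules are implemented because both occur in practice:
**mean** (active iff the average PS of the member models is ≥ 0.5; the
default) and **unanimity** (active iff every member's PS is ≥ 0.5).
Unanimity-active is always a subset of mean-active; the quadruple
[0.9, 0.9, 0.9, 0.3] separates the two rules.

## Screening

`screen_library()` pushes a raw SMILES library through the same
standardizer used in curation, featurizes it with the model's stored
fingerprint settings, and scores it. `max_ps` retention keeps exactly the
argmax-PS set (ties compared at 1e-9, since reported PS values are often
rounded); `ps_at_least` keeps everything at or above a cutoff. Each library
is screened independently against its own maximum. `diversity_filter()`
then applies deterministic leader clustering on Morgan/Tanimoto similarity
(default cutoff 0.7): hits are visited in rank order and join the first
cluster whose leader is at least cutoff-similar, otherwise they found a new
cluster; the leaders are the representatives carried forward. Visual
inspection of representatives is, by nature, out of scope.

## The synthetic benchmark

`benchmark_spec()` fixes the study conditions of the test bed. Compounds
are scaffold × substituent decorations from ten two-point templates
(benzenes, pyridine, thiophene, furan, cyclohexane, piperazine, indole, an
acylated pyrrolidine) and ~30 substituents; the hidden rule is the literal
presence of a sulfonamide-bearing substituent, chosen so that circular
fingerprints can capture it within radius 2. Defaults, chosen once as
realistic for a kinase-inhibitor curation exercise:

* 600 compounds, 35% rule-matching;
* true Ki log-normal around 100 nM (rule matches) or 50 µM (others) with
  0.6 log10 spread — a bimodal distribution whose tails straddle the 1 µM
  and 5 µM labeling thresholds;
* 1–4 replicates per compound (probabilities 0.4/0.3/0.2/0.1) with 0.1
  log10 multiplicative noise and a 5% chance per replicate of a ×3–10
  outlier (what the 25% discard rule exists to catch);
* 15% of compounds reported as IC50 (routed to the external test set), 3%
  censored records, 10% salt/charged SMILES spellings;
* master seed 7.

The generator emulates replicate noise, outliers, salts, endpoint mixing
and a learnable substructure rule. It does **not** emulate real kinase
chemotypes, assay heterogeneity between laboratories, activity cliffs, or
any structure–activity relationship more subtle than one substructure —
so a passing recovery test shows the pipeline's plumbing and learning
machinery work, not that comparable accuracy would be reached on real
data.

Recovery is checked at two levels (tests and the acceptance script use the
same sizes): curated labels must agree with the truth table for ≥95% of
non-boundary compounds, where boundary means a true Ki within a factor 1.8
(≈2.5 standard deviations of aggregated replicate noise) of either
threshold; and a Morgan+RF model must reach held-out MCC ≥ 0.7 on the
external test set — in practice it lands near 0.99 because a single-rule
benchmark is almost perfectly learnable. The acceptance run grid-searches
the full RF grid, cross-validates the winner, and fits the three companion
families at fixed documented configurations for the consensus; screening
uses a fresh 500-compound library from the same chemical space.

## Known limitations

* Standardization follows OpenBabel's neutralization and canonicalization;
  molecules OpenBabel cannot neutralize (e.g. quaternary ammonium) keep
  their charge, and no tautomer canonicalization is applied.
* The in-package fingerprint families are defined by this document, not by
  any external toolkit's bit-for-bit layout; models and libraries must be
  featurized by the same package version.
* MACCS keys are delegated to OpenBabel's public-166 implementation,
  including its SMARTS interpretations.
* The MLP trains full-batch; very large training sets would warrant
  mini-batching that the current solver set does not provide.
* Real-data dataset-assembly counts depend on a user-supplied ChEMBL
  export and its document metadata; they cannot be reproduced offline.
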