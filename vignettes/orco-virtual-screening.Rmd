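---
title: "Virtual screening for Orco antagonists: models, validation, and assay analytics"
author: "orcoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual screening for Orco antagonists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcoscreen)
```

## The problem

Insect odorant receptors are heteromeric channels built from a variable
odorant-specificity subunit and the universal co-receptor Orco. An Orco
antagonist inhibits agonist activation of these channels allosterically and
therefore acts across receptors and species, which makes the chemotype
attractive for repellent/confusant development. The practical bottleneck is
that electrophysiological screening (two-electrode voltage clamp on
receptor-expressing oocytes) is low-throughput: a panel of order 10^2
compounds is feasible, a vendor catalog of order 10^3 is not. `orcoscreen`
implements the standard ligand-based answer: learn from the tested panel,
rank the catalog, and assay only a diverse, high-probability slice.

This vignette describes the models and the numerical choices; the README
shows the code path end to end.

## Features

Molecules are standardized before anything else: parse, strip to the
largest organic fragment, neutralize formal charges where chemically valid,
canonicalize. The sequence is idempotent, and both the fragment rule and
the neutralization go through OpenBabel, so canonical SMILES — not atom
order in the input file — defines identity. Stereochemistry is deliberately
ignored throughout: antagonist panels of this kind mix enantiomer pairs
whose activities differ only modestly, and circular fingerprints without
chiral flags keep enantiomers in one equivalence class.

Each molecule is then described by

* **hashed circular fingerprint environments** of bond radius 0..2
  (ECFP4-class; radius 3, ECFP6-class, for clustering), kept as sparse
  integer ids rather than folded bit strings. Unfolded ids avoid folding
  collisions and suit a frequentist classifier that counts per-feature
  occurrences. The initial atom invariant combines atomic number, heavy
  degree, total bond order, implicit hydrogens and formal charge; each
  iteration hashes the invariant with the sorted (bond order, neighbor
  invariant) list. An atom whose environment already covers its connected
  component emits no further ids, so a single-heavy-atom molecule has
  exactly one feature at any radius.
* **six physicochemical descriptors** — AlogP-type lipophilicity, molecular
  weight, H-bond donors and acceptors, rotatable bonds, and fractional
  polar surface area — discretized into B = 10 equal-frequency (quantile)
  bins learned on the training set, outer bins open-ended. Quantile bins
  are robust to the skewed descriptor distributions of fragrance-like
  chemistry. Descriptor-bin indicator ids live above 2^30 while fingerprint
  ids hash below it, so the two ranges cannot collide. The fractional PSA is
  approximated as TPSA divided by an additive full-sphere van der Waals
  surface estimate, clamped to [0, 1]; only its ranking through the
  quantile bins matters to the classifier.

## The classifier

For feature *i* seen in `t_i` training molecules, `a_i` of them active, with
base rate `P(good) = A/T`, the Laplacian-corrected weight is

$$w_i = \ln \frac{(a_i + P \cdot K)/(t_i + K)}{P}, \qquad K = 1/P .$$

With `K = 1/P(good)` a feature occurring at the base rate gets weight
exactly zero and a feature seen once moves the estimate minimally — the
correction that makes naive Bayes usable on thousands of rare
substructures. Raw scores are sums of weights over a molecule's features;
features unseen in training contribute zero. The **normalized score**
divides the raw score by the molecule's own feature count, removing the
molecule-size dependence so that score distributions are comparable across
molecules; the choice is recorded in the serialized model manifest so
alternatives can be swapped.

**EstPGood.** Leave-one-out scores of the training set (computed exactly,
by decrementing the held-out record's counts — the package tests this path
against a naive retrain-per-record loop to full precision) define one
Gaussian per class; a new molecule's probability of activity is the active
density over the sum of both, evaluated in log space so extreme scores
saturate at 0/1 instead of producing NaN. Class standard deviations are
floored at 10^-6 to keep degenerate training sets defined. The binary call
uses the normalized-score cut minimizing total LOO misclassifications, ties
resolved to the midpoint between adjacent scores and then to the lower cut.

## Validation

Three procedures, matching standard QSAR practice:

* **Leave-one-out ROC** — AUC of the LOO scores, Mann–Whitney convention
  (tied pairs credited 0.5).
* **Label-randomization null** (y-scrambling) — labels permuted with class
  sizes preserved, model retrained, LOO AUC recomputed; 100 repetitions by
  default. A sound model sits many null standard deviations above 0.5.
* **Repeated stratified k-fold CV** — each class shuffled and split into k
  equal bins by floor division, leftovers dropped *for that repetition*
  (every repetition reshuffles, so nothing is excluded systematically);
  test-fold AUCs averaged within a repetition and then across repetitions
  (1000 by default).

All three consume a pre-featurized dataset, so repeated retraining reduces
to integer count arithmetic; 1000 repetitions of 5-fold CV on an
83-compound panel run in under a minute.

## Screening, clustering, selection, novelty

Both models score the library; a compound is *predicted active* only when
EstPGood exceeds 0.9 under **both** (strict inequality), and *predicted
inactive* when below 0.1 under both. Gated compounds are partitioned into
`round_half_up(N/5)` clusters: the proprietary partitioning component this
emulates is described only as Tanimoto-based with average cluster size 5,
so the package uses a deterministic, reproducible equivalent — max-min
(farthest-point) centroid seeding from the highest-combined-EstPGood
compound, nearest-centroid assignment with distance 1 − Tanimoto on
radius-3 fingerprints, all ties broken by id. A fixed `n_clusters` override
exists because the round-half-up rule is a convention, not a law. From
every non-singleton cluster the non-training member with the highest mean
EstPGood (optionally inside a molecular-weight window) is shortlisted;
vendor availability, a manual criterion in real campaigns, is intentionally
not modeled so the shortlist stays reproducible. Novelty is each hit's
maximum Tanimoto similarity to the known actives on radius-2 fingerprints,
histogrammed in 0.1-wide bins.

## Assay analytics

Percent-of-control normalization follows the assay's order of operations:
response with candidate divided by the mean of the two preceding
agonist-alone responses, times 100; then divided by the sham (vehicle-only)
percent to correct rundown. Inhibition is 100 minus that; a compound is
inactive iff inhibition ≤ 20 % at the 3 mM screening concentration, and
the potent-active gate for model B is IC50 strictly below 500 µM.

Concentration-inhibition data are fit to `I = I_max/(1 + (X/IC50)^n)` by
nonlinear least squares with all three parameters free and kept positive by
log-parameterization (initials: `I_max = max(I)`, IC50 = geometric mean of
the tested concentrations, n = 1). Because percent-of-control responses
carry relative (constant-CV) error rather than constant-variance error,
points are weighted `1/I^2` by default — without weighting, the IC50
sampling error roughly doubles and the asymptotic standard errors
undercover. The weights are folded into the model rows, and fitting
cascades through Gauss–Newton with a convergence scale offset (plain
relative-offset convergence is undefined on zero-residual, i.e. noiseless,
data), then Levenberg–Marquardt, then the `port` algorithm; a fit that
still fails returns `converged = FALSE` rather than an exception, and an
IC50 outside the tested concentration range is flagged. Standard errors are
asymptotic (delta method from the log-scale covariance), matching the
default of mainstream curve-fitting software. Replicate oocytes are pooled
after per-oocyte normalization rather than fit per oocyte and averaged.

The larval two-choice Response Index is `(S − C)/(S + C)` over larvae on
the stimulus and control sides; larvae still in the starting circle or
touching the center line are excluded before counting, and a trial with
`S + C = 0` is undefined rather than zero.

## The synthetic-data generators

No public accession deposits the study's compound panel (the supplementary
material maps compounds to PubChem CIDs, and structure retrieval is out of
scope), so the package ships generators that emulate the study conditions
and make every stage testable offline:

* **Training panel** — 58 actives / 25 inactives by default. Actives are
  enumerated from motif-bearing scaffold grammars (substituted phenols and
  cinnamate-type esters, the dominant chemotypes of this antagonist class);
  inactives come from motif-free flavor/fragrance-like decoys (esters,
  ketones, ethers, alcohols, alkylbenzenes, lactones, pyrazines, ...).
  Ground truth is assigned by SMARTS matching on the generated structures,
  not by bookkeeping. Active potencies are log-normal with median 800 µM
  and sd 1.3 natural-log units, spanning roughly 10 µM–13 mM, so the
  strict < 500 µM gate selects a model-B-sized subset (~21 of 58).
* **Screening library** — 1280 compounds, 5 % motif-bearing by default,
  with an option to spike training records in under their own ids (16
  actives + 8 inactives by default, the composition a vendor catalog showed
  in the campaign this emulates). Truth labels are returned in a separate
  table so pipeline code cannot consume them accidentally.
* **Dose-response tables** — oocyte-like currents consistent with a Hill
  curve (default IC50 48 µM, n = 1, I_max = 100 %) at 8 log-spaced
  concentrations over 1 µM–10 mM under 5 % multiplicative noise truncated
  at zero, plus a sham percent near 95; the percent-response path recovers
  the noisy response exactly, so fit error reflects noise, not plumbing.
* **Behavior trials** — binomial exclusion (default 12 % of 50 larvae)
  followed by independent binomial side choice (default p = 0.88, expected
  RI 0.76, a strongly attractive odorant).

One knob, `label_noise`, swaps a fraction of active/inactive label pairs
after assignment; it exists to make ground-truth separability tunable, and
the test suite checks that LOO AUC degrades monotonically along a
0/0.2/0.4 grid.

**What passing tests do and do not show.** The generated actives share
discrete, perfectly informative substructure motifs, so classifiers reach
LOO AUCs near 1.0 — above the 0.89/0.95 a real mixed-potency panel yields.
Synthetic results therefore validate the machinery (exact count
bookkeeping, probability calibration plumbing, gate/cluster/selection
determinism, estimator behavior under known noise), not the attainable
accuracy on laboratory data; reproducing the published operating points
numerically requires resolving the published compound identifiers to
structures and running this same pipeline on them.

## Numerical and testing choices

* Feature hashing is a polynomial hash modulo a prime below 2^30 computed
  in exact double arithmetic, so fingerprints are bit-identical across
  platforms and sessions.
* All stochastic procedures take an explicit seed and are bit-reproducible;
  the acceptance script derives every sub-seed from one `--seed`.
* The classifier is tested for exact agreement (tolerance 10^-10) against
  an independent brute-force reference across 1000 randomized small
  datasets, and the AUC against exhaustive pair enumeration and pROC.
* Test problem sizes are the study-scale defaults (83-compound panel,
  1280-compound library) with repetition counts of 50–200 in tests and the
  full 100/1000 repetitions in the acceptance script.

## Known limitations

* Equivalence with the commercial standardizer, fingerprint and clustering
  implementations the emulated campaign used is structural, not numerical;
  fingerprint dialect differences shift scores by small amounts.
* Implicit-hydrogen assignment uses standard organic valence rules; exotic
  elements fall back to zero implicit hydrogens.
* Kekulized bond orders from canonical SMILES enter the atom invariants, so
  symmetric aromatic rings can split chemically equivalent atoms into
  distinct environments; this is deterministic and harmless for
  similarity/classification use but differs from aromatic-perception
  fingerprints.
* The Hill fit's asymptotic standard errors undercover slightly at 8
  points (about 87 % for nominal 95 % intervals in the package's own
  simulations); profile-likelihood intervals would be better calibrated but
  are not what mainstream assay software reports.
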