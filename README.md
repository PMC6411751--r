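# orcoscreen

Ligand-based virtual screening and assay analytics for the discovery of
insect **Orco antagonists** — and, more generally, for any small
active/inactive compound panel screened against a structurally diverse
chemical library.

All insect odorant receptors (ORs) are heteromers of a variable
odorant-specificity subunit and the conserved odorant receptor co-receptor
**Orco**. Compounds that antagonize Orco allosterically inhibit odorant
activation across receptors and species, which makes them candidate
repellents/confusants. Finding new, volatile Orco antagonists by brute-force
electrophysiology is slow; this package implements the machine-learning
prioritization route: train Bayesian classifiers on a modest panel of tested
compounds, rank a flavor/fragrance-scale library, and test only a diverse,
high-probability subset.

## The model

The core classifier is a **Laplacian-corrected Naïve Bayes** over sparse
binary chemical features: hashed circular (ECFP-style) fingerprint
environments of bond radius 2 ("ECFP4-class"), plus quantile-binned
physicochemical descriptors (AlogP, MW, HBD, HBA, rotatable bonds,
fractional PSA). For a feature seen in `t_i` training molecules of which
`a_i` are active, with base rate `P(good) = A/T`:

    w_i = ln[ ((a_i + P(good)·K) / (t_i + K)) / P(good) ],   K = 1/P(good)

so a feature occurring at the base rate carries weight exactly 0 and a
feature seen only once moves the estimate minimally. A molecule's raw score
is `Σ w_i` over its features; the **normalized score** divides by the
molecule's feature count. Class probabilities (**EstPGood**) come from
Gaussian densities fitted to the active and inactive classes' leave-one-out
score distributions:

    EstPGood(s) = φ(s; μ_A, σ_A) / (φ(s; μ_A, σ_A) + φ(s; μ_I, σ_I))

Two models are trained — A on all actives, B on the potent subset (IC50
< 500 µM) — and a library compound passes the gate when EstPGood > 0.9 under
*both*. Gated compounds are partitioned into diversity clusters (1 − Tanimoto
distance on radius-3 fingerprints, max-min centroid selection, average
cluster size 5) and one representative per non-singleton cluster is
shortlisted. Structural novelty is the maximum Tanimoto similarity of each
hit to the known actives.

The assay side implements sham-normalized percent-of-control inhibition,
the ≤ 20 %-inhibition-at-3-mM inactivity rule, weighted nonlinear
least-squares fitting of the Hill equation `I = I_max / (1 + (X/IC50)^n)`,
and the larval two-choice Response Index `RI = (S − C)/(S + C)`.

Everything is testable offline: seeded generators build training panels
with embedded structure–activity signal (substituted phenols and
cinnamate-type esters as activity motifs), decoy libraries with hidden
ground truth, noisy dose-response tables, and behavior-trial counts.

## Worked example

```r
library(orcoscreen)

spec     <- library_spec(seed = 1)            # 58 actives / 25 inactives / 1280 library
training <- generate_training_set(spec)
model_a  <- train_bayes(training)
model_b  <- train_bayes(training, actives_max_ic50 = 500)
model_a
#> Laplacian-corrected Naive Bayes model
#>   training: 83 molecules (58 active, 25 inactive), P(good) = 0.699
#>   features: 403 weighted (radius 2 fingerprints + binned descriptors)
#>   LOO score distributions: active N(0.105, 0.046), inactive N(-0.093, 0.091)
#>   decision threshold (normalized score): -0.0031

loo_roc(featurize_dataset(training))
#> ROC AUC = 0.9869 (58 active vs 25 inactive, 0 tied pair(s))

lib <- generate_library(spec, training = training, spike_training = TRUE)
scr <- gate_candidates(screen_library(model_a, model_b, lib$molecules))
table(scr$gate)
#>            neither   predicted_active predicted_inactive
#>                164                 57               1059

part <- cluster_partition(scr[scr$gate == "predicted_active", ], lib$molecules)
nrow(part$clusters)      # round(57 / 5) = 11 diversity clusters
sel <- select_representatives(part)
sum(sel$selected)        # one pick per non-singleton cluster
```

The LOO AUC near 0.99 says the classifier almost perfectly ranks held-out
panel members; the gate keeps 57 of 1280 library compounds (including the
spiked-in training actives), and the cluster representatives are the
compounds one would carry into the oocyte assay. On the assay side:

```r
tab <- generate_dose_response(dose_response_spec(true_ic50 = 48, seed = 1))
resp <- percent_response(tab$i_pre1, tab$i_pre2, tab$i_test, tab$sham_percent)
fit_concentration_inhibition(tab$concentration_um, resp$normalized_percent)
#> Hill fit (8 points): IC50 = 49.68 +/- 4 uM, n = 1 +/- 0.016, Imax = 98.57%
```

## Package layout

| Area | Functions |
|---|---|
| Molecule I/O & standardization | `read_molecules`, `standardize_molecules`, `write_molecule_table` |
| Featurization | `circular_fingerprint`, `physchem_descriptors`, `fit_binning_scheme`, `featurize`, `featurize_dataset`, `feature_dataset`, `tanimoto` |
| Classifier | `feature_weight`, `train_bayes`, `score_features`, `loo_scores`, `est_p_good`, `predict`, `select_model_b_set`, `write_bayes_model`, `read_bayes_model` |
| Validation | `roc_auc`, `loo_roc`, `randomization_null`, `kfold_cv` |
| Screening | `screen_library`, `gate_candidates`, `cluster_partition`, `select_representatives`, `max_pairwise_similarity` |
| Assay analytics | `percent_response`, `classify_antagonist`, `fit_concentration_inhibition`, `fit_dose_response_table`, `select_model_b_actives`, `response_index` |
| Synthetic data | `library_spec`, `generate_training_set`, `generate_library`, `dose_response_spec`, `generate_dose_response`, `generate_behavior_trial` |

See `vignettes/orco-virtual-screening.Rmd` for the methods account.
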