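# Model validation: leave-one-out ROC, label-randomization null models, and
# repeated stratified k-fold cross-validation.

#' ROC AUC by Mann-Whitney concordance
#'
#' `AUC = (#concordant + 0.5 * #tied) / (n_active * n_inactive)` over all
#' active x inactive score pairs; tied pairs get half credit, the standard
#' Mann-Whitney convention. Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param scores numeric scores (higher = more active-like).
#' @param labels `"active"`/`"inactive"` labels (or logical, `TRUE` = active).
#' @return a `RocResult` list: `auc`, `n_active`, `n_inactive`, `tie_count`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "active", "inactive")
  active <- labels == "active"
  n_a <- sum(active); n_i <- sum(!active)
  if (n_a == 0L || n_i == 0L) stop("need at least one record of each class")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[active]) - n_a * (n_a + 1) / 2) / (n_a * n_i)
  # tied active-inactive pairs
  tc <- 0
  for (v in unique(scores[active])) {
    tc <- tc + sum(scores[active] == v) * sum(scores[!active] == v)
  }
  structure(list(auc = auc, n_active = n_a, n_inactive = n_i,
                 tie_count = as.integer(tc)),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC AUC = %.4f (%d active vs %d inactive, %d tied pair(s))\n",
              x$auc, x$n_active, x$n_inactive, x$tie_count))
  invisible(x)
}

#' Leave-one-out ROC
#'
#' The AUC of the per-record leave-one-out normalized scores from
#' [loo_scores()] against the true labels; the estimate behind the headline
#' model-quality figures.
#'
#' @param x labeled `MoleculeSet` or `orco_features` dataset.
#' @param radius,bins featurization config when `x` is a `MoleculeSet`.
#' @return a `RocResult`.
#' @export
loo_roc <- function(x, radius = 2, bins = 10) {
  fd <- .as_features(x, radius, bins)
  roc_auc(loo_scores(fd), fd$labels)
}

#' Label-randomization (y-scrambling) null distribution
#'
#' For each repetition the activity labels are permuted uniformly at random
#' (class sizes preserved), the model is retrained, and the leave-one-out
#' AUC recomputed. A model carrying real signal should sit far above this
#' null, whose mean concentrates near 0.5.
#'
#' @param x labeled `MoleculeSet` or `orco_features` dataset.
#' @param n_reps number of label permutations (default 100).
#' @param seed RNG seed; the result is bit-identical for a fixed seed.
#' @param radius,bins featurization config when `x` is a `MoleculeSet`.
#' @param keep_reps keep the per-repetition AUC vector.
#' @return a `NullDistribution` list: `mean_auc`, `sd_auc`, `n_reps`, `seed`,
#'   and optionally `reps`.
#' @export
randomization_null <- function(x, n_reps = 100, seed = 1,
                               radius = 2, bins = 10, keep_reps = FALSE) {
  stopifnot(n_reps >= 1)
  fd <- .as_features(x, radius, bins)
  .check_labels(fd)
  set.seed(seed)
  aucs <- vapply(seq_len(n_reps), function(r) {
    perm <- fd
    perm$labels <- sample(fd$labels)
    roc_auc(loo_scores(perm), perm$labels)$auc
  }, 0)
  structure(list(mean_auc = mean(aucs),
                 sd_auc = if (n_reps > 1) stats::sd(aucs) else 0,
                 n_reps = as.integer(n_reps),
                 seed = as.integer(seed),
                 reps = if (keep_reps) aucs else NULL),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("Label-randomization null: mean AUC %.3f (sd %.3f, %d rep(s), seed %d)\n",
              x$mean_auc, x$sd_auc, x$n_reps, x$seed))
  invisible(x)
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repetition, actives and inactives are shuffled independently and each
#' class split into `k` equal bins (floor division); leftover records are
#' dropped for that repetition (each repetition reshuffles, so no record is
#' left out altogether across repetitions). Each bin serves once as the test
#' set for a model trained on the remaining bins; the k test-fold AUCs are
#' averaged, and the repetition means are summarized across `n_reps`.
#'
#' @param x labeled `MoleculeSet` or `orco_features` dataset.
#' @param k number of folds (>= 2; each class must have >= k members).
#' @param n_reps repetitions (default 1000).
#' @param seed RNG seed.
#' @param radius,bins featurization config when `x` is a `MoleculeSet`.
#' @param keep_reps keep the per-repetition mean AUCs.
#' @return a `KFoldResult` list: `k`, `n_reps`, `mean_auc`, `sd_auc`,
#'   `dropped_per_rep`, `seed`, optionally `reps`.
#' @export
kfold_cv <- function(x, k = 5, n_reps = 1000, seed = 1,
                     radius = 2, bins = 10, keep_reps = FALSE) {
  stopifnot(k >= 2, n_reps >= 1)
  fd <- .as_features(x, radius, bins)
  active <- .check_labels(fd)
  idx_a <- which(active); idx_i <- which(!active)
  if (length(idx_a) < k || length(idx_i) < k)
    stop("each class needs at least k members")
  size_a <- length(idx_a) %/% k
  size_i <- length(idx_i) %/% k
  dropped <- (length(idx_a) %% k) + (length(idx_i) %% k)
  n_univ <- length(fd$universe)
  set.seed(seed)
  rep_auc <- vapply(seq_len(n_reps), function(r) {
    sh_a <- sample(idx_a); sh_i <- sample(idx_i)
    fold_auc <- vapply(seq_len(k), function(fold) {
      test <- c(sh_a[((fold - 1) * size_a + 1):(fold * size_a)],
                sh_i[((fold - 1) * size_i + 1):(fold * size_i)])
      train <- setdiff(c(sh_a[seq_len(k * size_a)], sh_i[seq_len(k * size_i)]),
                       test)
      counts <- .nb_counts(fd$index[train], active[train], n_univ)
      wt <- .nb_weights(counts)
      sc <- .nb_score_idx(fd$index[test], fd$n_feat[test], wt$w)
      roc_auc(sc$s, active[test])$auc
    }, 0)
    mean(fold_auc)
  }, 0)
  structure(list(k = as.integer(k), n_reps = as.integer(n_reps),
                 mean_auc = mean(rep_auc),
                 sd_auc = if (n_reps > 1) stats::sd(rep_auc) else 0,
                 dropped_per_rep = as.integer(dropped),
                 seed = as.integer(seed),
                 reps = if (keep_reps) rep_auc else NULL),
            class = "KFoldResult")
}

#' @export
print.KFoldResult <- function(x, ...) {
  cat(sprintf(
    "%d-fold stratified CV: mean AUC %.3f (sd %.3f) over %d rep(s); %d record(s) dropped per rep\n",
    x$k, x$mean_auc, x$sd_auc, x$n_reps, x$dropped_per_rep))
  invisible(x)
}
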