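# Laplacian-corrected Naive Bayesian classifier on sparse chemical features,
# with the normalized score and EstPGood dual-Gaussian class probability.

.SIGMA_FLOOR <- 1e-6

#' Laplacian-corrected feature weight
#'
#' For a feature seen in `t_i` training molecules of which `a_i` are active,
#' with base active rate `p_good`, the weight is
#' \deqn{w = \ln\frac{(a_i + p_{good} K)/(t_i + K)}{p_{good}},\quad K = 1/p_{good},}
#' i.e. `log((a_i + 1) / ((t_i + 1/p_good) * p_good))`. A feature occurring
#' at exactly the base rate gets weight 0; with this smoothing a feature
#' seen only once moves the class estimate minimally.
#'
#' @param a_i active-count of the feature (0 <= a_i <= t_i).
#' @param t_i total training count of the feature (>= 1).
#' @param p_good base active rate in (0, 1).
#' @return weight in natural-log units (vectorized over `a_i`, `t_i`).
#' @export
feature_weight <- function(a_i, t_i, p_good) {
  stopifnot(p_good > 0, p_good < 1)
  if (any(t_i < 1)) stop("t_i must be >= 1 (absent features get weight 0 upstream)")
  if (any(a_i < 0 | a_i > t_i)) stop("need 0 <= a_i <= t_i")
  log((a_i + 1) / ((t_i + 1 / p_good) * p_good))
}

# dense count-based core used by train, LOO, and the CV procedures.
# idx: list of dense feature-index vectors; active: logical vector.
.nb_counts <- function(idx, active, n_universe) {
  all_idx <- unlist(idx, use.names = FALSE)
  t_cnt <- tabulate(all_idx, n_universe)
  a_cnt <- tabulate(unlist(idx[active], use.names = FALSE), n_universe)
  list(a = a_cnt, t = t_cnt, n_active = sum(active), n_total = length(idx))
}

.nb_weights <- function(counts) {
  p_good <- counts$n_active / counts$n_total
  w <- numeric(length(counts$t))
  seen <- counts$t > 0
  w[seen] <- feature_weight(counts$a[seen], counts$t[seen], p_good)
  list(w = w, p_good = p_good)
}

# raw and normalized scores for molecules given dense weights.
# n_feat: the molecule's own feature count (normalization denominator).
.nb_score_idx <- function(idx, n_feat, w) {
  raw <- vapply(idx, function(f) sum(w[f]), 0)
  list(raw = raw, s = raw / pmax(1, n_feat))
}

.as_features <- function(x, radius = 2, bins = 10) {
  if (inherits(x, "orco_features")) return(x)
  if (inherits(x, "MoleculeSet")) return(featurize_dataset(x, radius, bins))
  stop("expected a MoleculeSet or orco_features object")
}

.check_labels <- function(fd) {
  lab <- fd$labels
  if (any(is.na(lab))) stop("every record needs an 'active'/'inactive' label")
  if (length(unique(lab)) < 2L) stop("training set must contain both classes")
  if (sum(lab == "active") < 2L || sum(lab == "inactive") < 2L)
    stop("need at least 2 actives and 2 inactives")
  lab == "active"
}

#' Leave-one-out normalized scores
#'
#' Scores each training record under a model trained on all other records.
#' Implemented exactly, by decrementing the held-out record's feature counts
#' and class totals; no approximation is involved, so the result equals a
#' naive retrain-per-record loop to full precision.
#'
#' @param x labeled `MoleculeSet` or `orco_features` dataset.
#' @param radius,bins featurization config when `x` is a `MoleculeSet`.
#' @return numeric vector of normalized LOO scores, in input order.
#' @export
loo_scores <- function(x, radius = 2, bins = 10) {
  fd <- .as_features(x, radius, bins)
  active <- .check_labels(fd)
  counts <- .nb_counts(fd$index, active, length(fd$universe))
  n <- length(fd$index)
  vapply(seq_len(n), function(i) {
    f <- fd$index[[i]]
    t_i <- counts$t[f] - 1L
    a_i <- counts$a[f] - if (active[i]) 1L else 0L
    nA <- counts$n_active - if (active[i]) 1L else 0L
    nT <- counts$n_total - 1L
    if (nA == 0L || nA == nT) {
      # single-class fold: base rate degenerates, all weights 0 by convention
      return(0)
    }
    p_good <- nA / nT
    w <- numeric(length(f))
    seen <- t_i > 0
    w[seen] <- feature_weight(a_i[seen], t_i[seen], p_good)
    sum(w) / max(1, fd$n_feat[i])
  }, 0)
}

#' Train a Laplacian-corrected Naive Bayes model
#'
#' Computes a weight for every feature observed in training, the base active
#' rate, per-class Gaussian parameters of the leave-one-out normalized score
#' distributions (used by [est_p_good()]), and the binary decision threshold
#' (the normalized-score cut minimizing total LOO misclassifications; ties
#' resolved toward the lower cut). Features unseen in training contribute
#' weight 0 at prediction time.
#'
#' @param x labeled `MoleculeSet` or `orco_features` dataset.
#' @param radius fingerprint bond radius.
#' @param bins descriptor bins (`NULL`/0 for fingerprints only).
#' @param actives_max_ic50 optional potency gate in micromolar: records with
#'   `ic50_um` strictly below the gate stay active, other actives are
#'   dropped (the potent-subset "model B" construction). Requires a
#'   `MoleculeSet`.
#' @return an object of class `orco_nb`.
#' @export
train_bayes <- function(x, radius = 2, bins = 10, actives_max_ic50 = NULL) {
  if (!is.null(actives_max_ic50)) {
    stopifnot(inherits(x, "MoleculeSet"))
    x <- select_model_b_set(x, cutoff = actives_max_ic50)
  }
  fd <- .as_features(x, radius, bins)
  if (anyDuplicated(fd$ids)) stop("duplicate ids in training set")
  active <- .check_labels(fd)
  counts <- .nb_counts(fd$index, active, length(fd$universe))
  wt <- .nb_weights(counts)
  loo <- loo_scores(fd)
  mu_a <- mean(loo[active]); sd_a <- max(.SIGMA_FLOOR, stats::sd(loo[active]))
  mu_i <- mean(loo[!active]); sd_i <- max(.SIGMA_FLOOR, stats::sd(loo[!active]))
  structure(list(
    p_good = wt$p_good,
    feature_ids = fd$universe,
    weights = wt$w,
    a_counts = counts$a,
    t_counts = counts$t,
    n_active = counts$n_active,
    n_total = counts$n_total,
    mu_active = mu_a, sigma_active = sd_a,
    mu_inactive = mu_i, sigma_inactive = sd_i,
    threshold = .loo_threshold(loo, active),
    loo = loo,
    radius = fd$radius,
    scheme = fd$scheme,
    training_ids = fd$ids,
    training_labels = fd$labels
  ), class = "orco_nb")
}

# normalized-score cut minimizing LOO misclassification (call: active iff
# s > threshold); candidate cuts are midpoints between adjacent distinct
# scores plus one cut below all scores and one above; ties -> lowest cut.
.loo_threshold <- function(scores, active) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  errs <- vapply(cand, function(th)
    sum((scores > th) != active), 0L)
  cand[which.min(errs)]
}

#' @export
print.orco_nb <- function(x, ...) {
  cat(sprintf(paste0(
    "Laplacian-corrected Naive Bayes model\n",
    "  training: %d molecules (%d active, %d inactive), P(good) = %.3f\n",
    "  features: %d weighted (radius %d fingerprints%s)\n",
    "  LOO score distributions: active N(%.3f, %.3f), inactive N(%.3f, %.3f)\n",
    "  decision threshold (normalized score): %.4f\n"),
    x$n_total, x$n_active, x$n_total - x$n_active, x$p_good,
    length(x$feature_ids), x$radius,
    if (is.null(x$scheme)) "" else " + binned descriptors",
    x$mu_active, x$sigma_active, x$mu_inactive, x$sigma_inactive,
    x$threshold))
  invisible(x)
}

#' Score feature sets under a trained model
#'
#' The raw score is the sum of trained feature weights over the molecule's
#' features (unseen features contribute 0); the normalized score divides by
#' the molecule's own feature count, removing molecule-size dependence.
#'
#' @param model an `orco_nb` model.
#' @param features one integer feature-id vector, or a list of them.
#' @return data frame with columns `raw` and `s` (normalized score).
#' @export
score_features <- function(model, features) {
  stopifnot(inherits(model, "orco_nb"))
  if (!is.list(features)) features <- list(features)
  raw <- vapply(features, function(f) {
    hit <- match(f, model$feature_ids)
    sum(model$weights[hit[!is.na(hit)]])
  }, 0)
  data.frame(raw = raw, s = raw / pmax(1, lengths(features)))
}

#' EstPGood: dual-Gaussian probability of being active
#'
#' The normalized score is inserted into Gaussian densities parameterized by
#' the mean and standard deviation of the active and inactive training
#' classes' leave-one-out scores; EstPGood is the active density divided by
#' the sum of both. Computed in log space, so it never underflows to NaN.
#'
#' @param model an `orco_nb` model.
#' @param s normalized score(s).
#' @return probabilities in (0, 1).
#' @export
est_p_good <- function(model, s) {
  la <- stats::dnorm(s, model$mu_active, model$sigma_active, log = TRUE)
  li <- stats::dnorm(s, model$mu_inactive, model$sigma_inactive, log = TRUE)
  1 / (1 + exp(li - la))
}

#' Predict activity for new molecules
#'
#' @param object an `orco_nb` model.
#' @param newdata a standardized `MoleculeSet`, or a list of feature-id
#'   vectors already in the model's feature space.
#' @param ... unused.
#' @return data frame with one row per molecule: `id`, `raw`, `s`
#'   (normalized score), `est_p_good`, and the binary `call`
#'   (`active` iff `s > threshold`).
#' @export
predict.orco_nb <- function(object, newdata, ...) {
  if (inherits(newdata, "MoleculeSet")) {
    feats <- featurize(newdata, radius = object$radius, scheme = object$scheme)
  } else if (is.list(newdata)) {
    feats <- newdata
  } else {
    stop("newdata must be a MoleculeSet or a list of feature vectors")
  }
  sc <- score_features(object, feats)
  ids <- names(feats)
  if (is.null(ids)) ids <- paste0("mol", seq_along(feats))
  data.frame(id = ids, raw = sc$raw, s = sc$s,
             est_p_good = est_p_good(object, sc$s),
             call = ifelse(sc$s > object$threshold, "active", "inactive"),
             stringsAsFactors = FALSE)
}

#' Apply the potency gate that defines the model-B training set
#'
#' Keeps inactives unchanged and restricts actives to those with an IC50
#' strictly below `cutoff` micromolar.
#'
#' @param ms a labeled `MoleculeSet` with `ic50_um` for actives.
#' @param cutoff potency gate in micromolar (default 500).
#' @return the gated `MoleculeSet`.
#' @export
select_model_b_set <- function(ms, cutoff = 500) {
  stopifnot(inherits(ms, "MoleculeSet"))
  keep <- ms$label == "inactive" |
    (ms$label == "active" & !is.na(ms$ic50_um) & ms$ic50_um < cutoff)
  out <- ms[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MoleculeSet", "data.frame")
  out
}
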