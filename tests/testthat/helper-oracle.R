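# Independent brute-force reference implementation of the
# Laplacian-corrected NB, written as plain loops that recount everything
# from scratch. Used to cross-check train/score/LOO; deliberately shares no
# code with the package internals.

brute_weight <- function(a, t, p) {
  K <- 1 / p
  log(((a + p * K) / (t + K)) / p)
}

# score one molecule's feature set under a model trained on (features, labels)
brute_score <- function(train_features, train_labels, mol_features) {
  n_active <- sum(train_labels == "active")
  p <- n_active / length(train_labels)
  raw <- 0
  for (f in mol_features) {
    t_i <- 0; a_i <- 0
    for (j in seq_along(train_features)) {
      if (f %in% train_features[[j]]) {
        t_i <- t_i + 1
        if (train_labels[j] == "active") a_i <- a_i + 1
      }
    }
    if (t_i > 0) raw <- raw + brute_weight(a_i, t_i, p)
  }
  c(raw = raw, s = raw / max(1, length(mol_features)))
}

# naive leave-one-out: retrain on all-but-i for every record
brute_loo <- function(features, labels) {
  vapply(seq_along(features), function(i) {
    brute_score(features[-i], labels[-i], features[[i]])[["s"]]
  }, 0)
}

# AUC by exhaustive pair enumeration
brute_auc <- function(scores, labels) {
  act <- scores[labels == "active"]
  ina <- scores[labels == "inactive"]
  tot <- 0
  for (a in act) for (b in ina) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(act) * length(ina))
}

# random small feature dataset for property tests
random_feature_data <- function(n_mol = 8, n_feat = 8, seed = 1) {
  set.seed(seed)
  repeat {
    feats <- lapply(seq_len(n_mol), function(i) {
      k <- sample(1:n_feat, 1)
      sort(sample(seq_len(n_feat), k))
    })
    labels <- sample(c("active", "inactive"), n_mol, replace = TRUE)
    if (sum(labels == "active") >= 2 && sum(labels == "inactive") >= 2) {
      names(feats) <- paste0("m", seq_len(n_mol))
      return(list(features = feats, labels = labels))
    }
  }
}
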