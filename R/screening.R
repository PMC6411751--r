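# Dual-model virtual screening: EstPGood gating, diversity clustering,
# representative selection, and structural novelty scoring.

#' Screen a library with two trained models
#'
#' Scores every library compound under both models (which must share the
#' same featurization config), computes both EstPGood probabilities, flags
#' training-set members by id, and ranks deterministically by
#' `est_p_good_A + est_p_good_B` (ties broken by id).
#'
#' @param model_a,model_b trained `orco_nb` models.
#' @param library a standardized `MoleculeSet`.
#' @param training_ids ids to flag as training-set members; defaults to the
#'   union of both models' training ids.
#' @return a `ScreenRecords` data frame: `id`, `score_A`, `score_B`,
#'   `estpgood_A`, `estpgood_B`, `is_training`, plus `gate`, `cluster_id`,
#'   `selected` columns (filled by the downstream steps).
#' @export
screen_library <- function(model_a, model_b, library, training_ids = NULL) {
  stopifnot(inherits(model_a, "orco_nb"), inherits(model_b, "orco_nb"))
  if (model_a$radius != model_b$radius)
    stop("models were trained with different fingerprint radii")
  if (is.null(training_ids))
    training_ids <- union(model_a$training_ids, model_b$training_ids)
  if (nrow(library) == 0L) {
    warning("empty screening library")
    return(.empty_screen())
  }
  # chemistry is computed once and shared by both models (only the frozen
  # descriptor binning schemes differ between them)
  graphs <- build_mol_graphs(library$smiles, library$id)
  desc <- if (is.null(model_a$scheme) && is.null(model_b$scheme)) NULL
          else physchem_descriptors(library, graphs)
  fps <- lapply(graphs, .fp_from_graph, radius = model_a$radius)
  with_desc <- function(scheme) {
    if (is.null(scheme)) return(stats::setNames(fps, library$id))
    out <- lapply(seq_along(fps), function(i)
      sort(c(fps[[i]], .descriptor_feature_ids(desc[i, ], scheme))))
    stats::setNames(out, library$id)
  }
  pa <- predict(model_a, with_desc(model_a$scheme))
  pb <- predict(model_b, with_desc(model_b$scheme))
  rec <- data.frame(id = library$id,
                    score_A = pa$s, score_B = pb$s,
                    estpgood_A = pa$est_p_good, estpgood_B = pb$est_p_good,
                    gate = "neither",
                    is_training = library$id %in% training_ids,
                    cluster_id = NA_integer_,
                    selected = FALSE,
                    stringsAsFactors = FALSE)
  rec <- rec[order(-(rec$estpgood_A + rec$estpgood_B), rec$id), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("ScreenRecords", "data.frame")
  rec
}

.empty_screen <- function() {
  rec <- data.frame(id = character(0), score_A = numeric(0),
                    score_B = numeric(0), estpgood_A = numeric(0),
                    estpgood_B = numeric(0), gate = character(0),
                    is_training = logical(0), cluster_id = integer(0),
                    selected = logical(0), stringsAsFactors = FALSE)
  class(rec) <- c("ScreenRecords", "data.frame")
  rec
}

#' Gate screen records on dual-model EstPGood
#'
#' A compound is `predicted_active` iff EstPGood is strictly above `hi`
#' under both models, `predicted_inactive` iff strictly below `lo` under
#' both, otherwise `neither` (strict inequalities throughout).
#'
#' @param records `ScreenRecords` from [screen_library()].
#' @param hi,lo probability cutoffs, `0 <= lo < hi <= 1` (defaults 0.9/0.1).
#' @return the records with the `gate` column filled.
#' @export
gate_candidates <- function(records, hi = 0.9, lo = 0.1) {
  stopifnot(lo >= 0, hi <= 1, lo < hi)
  gate <- rep("neither", nrow(records))
  gate[records$estpgood_A > hi & records$estpgood_B > hi] <- "predicted_active"
  gate[records$estpgood_A < lo & records$estpgood_B < lo] <- "predicted_inactive"
  records$gate <- gate
  records
}

#' Partition gated compounds into diversity clusters
#'
#' Deterministic diversity partitioning with distance `1 - Tanimoto` on
#' circular fingerprints (radius 3 by default, the ECFP6-class space). The
#' number of clusters is `max(1, round_half_up(N / average_size))` unless
#' overridden. The first centroid is the compound with the highest combined
#' EstPGood (ties by id); each subsequent centroid maximizes its minimum
#' distance to the existing centroids (max-min); every compound is then
#' assigned to its nearest centroid (ties toward the lower cluster id).
#'
#' @param records gated `ScreenRecords` subset to cluster (e.g. the
#'   predicted actives).
#' @param library the standardized `MoleculeSet` holding the structures.
#' @param average_size target average cluster size (default 5).
#' @param radius fingerprint radius for the clustering space (default 3).
#' @param n_clusters optional override of the cluster count.
#' @return a list: `records` (with `cluster_id` filled) and `clusters`, a
#'   data frame of `cluster_id`, `centroid_id`, `size`.
#' @export
cluster_partition <- function(records, library, average_size = 5,
                              radius = 3, n_clusters = NULL) {
  stopifnot(nrow(records) > 0L)
  n <- nrow(records)
  if (is.null(n_clusters)) n_clusters <- max(1L, as.integer(floor(n / average_size + 0.5)))
  n_clusters <- min(n_clusters, n)
  lib <- library[match(records$id, library$id), , drop = FALSE]
  class(lib) <- c("MoleculeSet", "data.frame")
  fps <- featurize(lib, radius = radius)
  combined <- records$estpgood_A + records$estpgood_B
  ord <- order(-combined, records$id)
  centroids <- ord[1]
  # distance of every compound to its nearest chosen centroid
  mind <- vapply(seq_len(n), function(i) 1 - tanimoto(fps[[i]], fps[[centroids]]), 0)
  while (length(centroids) < n_clusters) {
    cand <- which(mind == max(mind))
    nxt <- cand[order(records$id[cand])][1]
    centroids <- c(centroids, nxt)
    dn <- vapply(seq_len(n), function(i) 1 - tanimoto(fps[[i]], fps[[nxt]]), 0)
    mind <- pmin(mind, dn)
  }
  assign <- vapply(seq_len(n), function(i) {
    d <- vapply(centroids, function(cc) 1 - tanimoto(fps[[i]], fps[[cc]]), 0)
    which.min(d)  # ties -> lower cluster id
  }, 0L)
  records$cluster_id <- assign
  clusters <- data.frame(cluster_id = seq_along(centroids),
                         centroid_id = records$id[centroids],
                         size = as.integer(tabulate(assign, length(centroids))),
                         stringsAsFactors = FALSE)
  list(records = records, clusters = clusters)
}

#' Select cluster representatives for experimental follow-up
#'
#' For every non-singleton cluster, selects the non-training member with the
#' highest mean EstPGood across the two models (ties by id), optionally
#' restricted to a molecular-weight window. Singleton clusters yield no
#' selection; clusters whose members are all training compounds yield a
#' warning and no selection. The manual "availability" judgment of a bench
#' campaign is intentionally not modeled, so the shortlist is reproducible.
#'
#' @param partition result of [cluster_partition()].
#' @param library the standardized `MoleculeSet` (needed when `mw_range` is
#'   given).
#' @param mw_range optional numeric length-2 molecular-weight window (Da).
#' @return the `ScreenRecords` with the `selected` flag set.
#' @export
select_representatives <- function(partition, library = NULL, mw_range = NULL) {
  records <- partition$records
  clusters <- partition$clusters
  mw <- NULL
  if (!is.null(mw_range)) {
    stopifnot(!is.null(library), length(mw_range) == 2)
    lib <- library[match(records$id, library$id), , drop = FALSE]
    class(lib) <- c("MoleculeSet", "data.frame")
    mw <- physchem_descriptors(lib)$mw
  }
  records$selected <- FALSE
  for (cl in clusters$cluster_id[clusters$size > 1L]) {
    members <- which(records$cluster_id == cl & !records$is_training)
    if (!is.null(mw))
      members <- members[mw[members] >= mw_range[1] & mw[members] <= mw_range[2]]
    if (length(members) == 0L) {
      warning("cluster ", cl, " has no selectable (non-training) member")
      next
    }
    mean_p <- (records$estpgood_A[members] + records$estpgood_B[members]) / 2
    pick <- members[order(-mean_p, records$id[members])][1]
    records$selected[pick] <- TRUE
  }
  records
}

#' Maximum pairwise Tanimoto similarity to the training actives
#'
#' For each novel compound, the maximum Tanimoto similarity over all
#' training actives on radius-2 (ECFP4-class) fingerprints - the structural
#' novelty score. Low values mean the hit is far from every previously known
#' active.
#'
#' @param novel standardized `MoleculeSet` of novel compounds.
#' @param training_actives standardized `MoleculeSet` of known actives.
#' @param radius fingerprint radius (default 2).
#' @return list with `max_sim` (named numeric, one per novel compound),
#'   `nearest_id` (the most similar training active), and `histogram`
#'   (counts over the bins `[0,0.1), ..., [0.9,1.0]`).
#' @export
max_pairwise_similarity <- function(novel, training_actives, radius = 2) {
  stopifnot(nrow(novel) > 0L, nrow(training_actives) > 0L)
  fn <- featurize(novel, radius = radius)
  ft <- featurize(training_actives, radius = radius)
  sims <- vapply(fn, function(f) {
    s <- vapply(ft, function(g) tanimoto(f, g), 0)
    c(max(s), which.max(s))
  }, c(0, 0))
  max_sim <- sims[1, ]
  nearest <- training_actives$id[sims[2, ]]
  names(max_sim) <- novel$id
  bin <- pmin(findInterval(max_sim, seq(0, 1, 0.1), rightmost.closed = TRUE), 10L)
  hist <- tabulate(bin, 10L)
  names(hist) <- sprintf("[%.1f,%.1f%s", seq(0, 0.9, 0.1), seq(0.1, 1, 0.1),
                         c(rep(")", 9), "]"))
  list(max_sim = max_sim, nearest_id = nearest, histogram = hist)
}
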