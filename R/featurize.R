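# Sparse circular fingerprints, physicochemical descriptors, descriptor
# binning, and the combined feature space shared by both classifiers.
#
# Fingerprint ids live in [0, 2^30); descriptor-bin indicator ids start at
# 2^30, so the two ranges can never collide.

.HASH_MOD <- 1073741789  # largest prime below 2^30
.DESC_ID_BASE <- 2^30
.DESC_NAMES <- c("alogp", "mw", "hbd", "hba", "rotb", "fpsa")

# deterministic polynomial hash of an integer vector onto [0, 2^30).
# double arithmetic stays exact: h < 2^30, h*33 + x < 2^36 << 2^53.
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 33 + (x + 16)) %% .HASH_MOD
  as.integer(h)
}

#' Circular (ECFP-style) fingerprint of one molecule
#'
#' Computes sparse hashed atom-environment identifiers for all environments
#' of bond radius 0 up to `radius`, in unfolded (sparse-id) form. Radius 2
#' corresponds to ECFP4-class fingerprints, radius 3 to ECFP6-class. The
#' initial atom invariant combines atomic number, heavy-atom degree, total
#' bond order, implicit hydrogen count, and formal charge; each iteration
#' hashes the invariant together with the sorted (bond order, neighbor
#' invariant) pairs. An atom whose environment stops growing (it already
#' covers its connected component) emits no further features, so methane
#' yields exactly one feature at any radius.
#'
#' @param smiles a standardized SMILES string (see [standardize_molecules()]).
#' @param radius integer bond radius, 1-3.
#' @param graph optional pre-built molecular graph (internal use).
#' @return sorted integer vector of distinct feature ids.
#' @export
circular_fingerprint <- function(smiles, radius = 2, graph = NULL) {
  stopifnot(radius %in% 1:3)
  if (is.null(graph)) graph <- build_mol_graphs(smiles)[[1]]
  .fp_from_graph(graph, radius)
}

.fp_from_graph <- function(graph, radius) {
  at <- graph$atoms
  bd <- graph$bonds
  natom <- nrow(at)
  inv <- vapply(seq_len(natom), function(i)
    .hash_ints(c(at$z[i], at$degree[i], at$bosum[i], at$nh[i], at$charge[i])),
    0L)
  feats <- inv
  if (natom > 1L && radius > 0L && nrow(bd) > 0L) {
    nbrs <- vector("list", natom)
    for (b in seq_len(nrow(bd))) {
      nbrs[[bd$a1[b]]] <- rbind(nbrs[[bd$a1[b]]], c(bd$order[b], bd$a2[b]))
      nbrs[[bd$a2[b]]] <- rbind(nbrs[[bd$a2[b]]], c(bd$order[b], bd$a1[b]))
    }
    env <- lapply(seq_len(natom), function(i) i)
    for (r in seq_len(radius)) {
      new_inv <- inv
      new_env <- env
      emit <- logical(natom)
      for (i in seq_len(natom)) {
        nb <- nbrs[[i]]
        if (is.null(nb)) next
        pairs <- cbind(nb[, 1], inv[nb[, 2]])
        o <- order(pairs[, 1], pairs[, 2])
        new_inv[i] <- .hash_ints(c(r, inv[i], t(pairs[o, , drop = FALSE])))
        grown <- sort(unique(c(env[[i]], unlist(env[nb[, 2]]))))
        if (!identical(grown, env[[i]])) {
          emit[i] <- TRUE
          new_env[[i]] <- grown
        }
      }
      if (!any(emit)) break
      feats <- c(feats, new_inv[emit])
      inv <- new_inv
      env <- new_env
    }
  }
  sort(unique(feats))
}

#' Physicochemical descriptors
#'
#' Computes the six modeling descriptors for every record of a standardized
#' `MoleculeSet`: AlogP-type lipophilicity (`alogp`), molecular weight `mw`
#' (Da), hydrogen-bond donor and acceptor counts (`hbd`, `hba`), rotatable
#' bond count `rotb` (acyclic single bonds between two non-terminal heavy
#' atoms), and fractional polar surface area `fpsa` (topological PSA divided
#' by an atomic-contribution estimate of total van der Waals surface area,
#' clamped to \[0, 1\]). Lipophilicity, weight, donor/acceptor counts and
#' TPSA come from OpenBabel.
#'
#' @param ms a standardized `MoleculeSet`.
#' @return data frame with one row per record (rownames = ids) and columns
#'   `alogp`, `mw`, `hbd`, `hba`, `rotb`, `fpsa`.
#' @export
physchem_descriptors <- function(ms, graphs = NULL) {
  stopifnot(inherits(ms, "MoleculeSet"))
  if (!all(ms$standardized)) stop("standardize the MoleculeSet first")
  if (is.null(graphs)) graphs <- build_mol_graphs(ms$smiles, ms$id)
  tags <- paste0("d", seq_len(nrow(ms)))
  src <- paste0(paste(ms$smiles, tags, sep = "\t"), collapse = "\n")
  out <- ChemmineOB::convertFormat(
    "SMI", "TXT", paste0(src, "\n"),
    options = data.frame(names = "append", args = "logP MW TPSA HBA1 HBD"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(trimws(lines), "[\t ]+")
  got_tag <- vapply(parts, `[`, "", 1)
  hit <- match(tags, got_tag)
  if (anyNA(hit)) stop("OpenBabel descriptor computation failed for: ",
                       paste(ms$id[is.na(hit)], collapse = ", "))
  val <- function(k) as.numeric(vapply(parts[hit], `[`, "", k))
  logp <- val(2); mw <- val(3); tpsa <- val(4)
  hba <- as.integer(val(5)); hbd <- as.integer(val(6))
  rotb <- vapply(graphs, .rotatable_bonds, 0L)
  fpsa <- vapply(seq_along(graphs), function(i) {
    sa <- .total_vdw_surface(graphs[[i]])
    if (sa <= 0) return(0)
    min(1, max(0, tpsa[i] / sa))
  }, 0)
  out <- data.frame(alogp = logp, mw = mw, hbd = hbd, hba = hba,
                    rotb = rotb, fpsa = fpsa)
  rownames(out) <- ms$id
  out
}

.rotatable_bonds <- function(graph) {
  bd <- graph$bonds
  if (nrow(bd) == 0L) return(0L)
  inring <- .bonds_in_ring(graph)
  deg <- graph$atoms$degree
  sum(bd$order == 1L & !inring & deg[bd$a1] >= 2L & deg[bd$a2] >= 2L)
}

# crude additive surface area: full vdW sphere per atom (heavy + implicit H)
.total_vdw_surface <- function(graph) {
  r <- .VDW_RADIUS[graph$atoms$element]
  r[is.na(r)] <- 1.7
  sum(4 * pi * r^2) + sum(graph$atoms$nh) * 4 * pi * .VDW_RADIUS[["H"]]^2
}

#' Learn a descriptor binning scheme
#'
#' Discretizes each continuous descriptor into `bins` equal-frequency
#' (quantile) bins learned from a training `MoleculeSet`. The outer bins are
#' open-ended, so any value seen at prediction time maps to exactly one bin.
#' The scheme is frozen after training and must be reused unchanged when
#' featurizing new molecules.
#'
#' @param ms a standardized training `MoleculeSet`.
#' @param bins bins per descriptor (default 10).
#' @param descriptors optional precomputed [physchem_descriptors()] table.
#' @return a `BinningScheme` object holding the per-descriptor cut points.
#' @export
fit_binning_scheme <- function(ms, bins = 10, descriptors = NULL) {
  stopifnot(bins >= 2)
  if (is.null(descriptors)) descriptors <- physchem_descriptors(ms)
  cuts <- lapply(.DESC_NAMES, function(d) {
    x <- descriptors[[d]]
    q <- stats::quantile(x, probs = seq_len(bins - 1) / bins,
                         na.rm = TRUE, names = FALSE, type = 7)
    sort(unique(q))
  })
  names(cuts) <- .DESC_NAMES
  structure(list(bins = as.integer(bins), cuts = cuts),
            class = "BinningScheme")
}

#' @export
print.BinningScheme <- function(x, ...) {
  cat(sprintf("BinningScheme: %d quantile bins per descriptor\n", x$bins))
  for (d in names(x$cuts))
    cat(sprintf("  %-5s cuts: %s\n", d,
                paste(signif(x$cuts[[d]], 4), collapse = ", ")))
  invisible(x)
}

# descriptor-bin indicator ids for one descriptor row
.descriptor_feature_ids <- function(desc_row, scheme) {
  ids <- integer(length(.DESC_NAMES))
  for (j in seq_along(.DESC_NAMES)) {
    d <- .DESC_NAMES[j]
    bin <- findInterval(desc_row[[d]], scheme$cuts[[d]])
    ids[j] <- as.integer(.DESC_ID_BASE + (j - 1L) * (scheme$bins + 1L) + bin)
  }
  ids
}

#' Featurize molecules into the combined feature space
#'
#' Builds, per molecule, the union of its sparse circular-fingerprint ids
#' and one indicator id per (descriptor, bin) pair under a frozen
#' [fit_binning_scheme()] scheme. Fingerprint and descriptor ids occupy
#' disjoint ranges.
#'
#' @param ms a standardized `MoleculeSet`.
#' @param radius fingerprint bond radius (default 2, the ECFP4-class space).
#' @param scheme a trained `BinningScheme`, or `NULL` for fingerprints only.
#' @return named list of sorted integer feature-id vectors, one per record.
#' @export
featurize <- function(ms, radius = 2, scheme = NULL, graphs = NULL,
                      descriptors = NULL) {
  stopifnot(inherits(ms, "MoleculeSet"))
  if (!all(ms$standardized)) stop("standardize the MoleculeSet first")
  if (is.null(graphs)) graphs <- build_mol_graphs(ms$smiles, ms$id)
  fps <- lapply(graphs, .fp_from_graph, radius = radius)
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "BinningScheme"))
    if (is.null(descriptors)) descriptors <- physchem_descriptors(ms, graphs)
    fps <- lapply(seq_along(fps), function(i)
      sort(c(fps[[i]], .descriptor_feature_ids(descriptors[i, ], scheme))))
  }
  names(fps) <- ms$id
  fps
}

#' Prepare a featurized dataset for modeling
#'
#' Featurizes a `MoleculeSet` once and packages feature sets, labels, and
#' feature-index bookkeeping so that training, leave-one-out scoring, and
#' the cross-validation procedures can run repeatedly without touching the
#' chemistry layer again.
#'
#' @param ms a standardized `MoleculeSet` (labels required for modeling).
#' @param radius fingerprint bond radius.
#' @param bins descriptor bins; `NULL` or 0 disables descriptor features.
#' @param scheme optional frozen `BinningScheme` to reuse (e.g. a model's
#'   training scheme when featurizing a screening library).
#' @return an `orco_features` object: ids, labels, per-molecule global
#'   feature ids and dense feature indices, and the feature universe.
#' @export
featurize_dataset <- function(ms, radius = 2, bins = 10, scheme = NULL) {
  stopifnot(inherits(ms, "MoleculeSet"))
  graphs <- build_mol_graphs(ms$smiles, ms$id)
  desc <- NULL
  if (is.null(scheme) && !is.null(bins) && bins >= 2) {
    desc <- physchem_descriptors(ms, graphs)
    scheme <- fit_binning_scheme(ms, bins = bins, descriptors = desc)
  } else if (!is.null(scheme)) {
    desc <- physchem_descriptors(ms, graphs)
  }
  feats <- featurize(ms, radius = radius, scheme = scheme, graphs = graphs,
                     descriptors = desc)
  universe <- sort(unique(unlist(feats)))
  idx <- lapply(feats, function(f) match(f, universe))
  structure(list(ids = ms$id,
                 labels = ms$label,
                 features = feats,
                 index = idx,
                 n_feat = lengths(feats),
                 universe = universe,
                 radius = radius,
                 scheme = scheme),
            class = "orco_features")
}

#' Assemble a feature dataset from precomputed feature sets
#'
#' Builds the modeling container used by [train_bayes()] and the validation
#' procedures directly from feature-id sets, bypassing the chemistry layer.
#' Useful for custom featurizations and for testing the classifier in
#' isolation.
#'
#' @param features named list of integer feature-id vectors (sets).
#' @param labels optional `"active"`/`"inactive"` labels, one per molecule.
#' @param radius bookkeeping only: the radius recorded on the dataset.
#' @return an `orco_features` object.
#' @export
feature_dataset <- function(features, labels = NULL, radius = 2) {
  stopifnot(is.list(features))
  ids <- names(features)
  if (is.null(ids)) ids <- paste0("mol", seq_along(features))
  if (is.null(labels)) labels <- rep(NA_character_, length(features))
  stopifnot(length(labels) == length(features))
  features <- lapply(features, function(f) sort(unique(as.integer(f))))
  universe <- sort(unique(unlist(features)))
  structure(list(ids = ids,
                 labels = as.character(labels),
                 features = features,
                 index = lapply(features, function(f) match(f, universe)),
                 n_feat = lengths(features),
                 universe = universe,
                 radius = as.integer(radius),
                 scheme = NULL),
            class = "orco_features")
}

#' @export
print.orco_features <- function(x, ...) {
  cat(sprintf("orco_features: %d molecule(s), %d distinct feature(s), radius %d\n",
              length(x$ids), length(x$universe), x$radius))
  invisible(x)
}

#' Tanimoto similarity of two feature sets
#'
#' `|a intersect b| / |a union b|` on sparse feature-id sets. Two empty sets
#' are defined as identical (similarity 1).
#'
#' @param a,b integer feature-id vectors (sets).
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
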