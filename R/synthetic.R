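# Seeded generators for every pipeline input: labeled training molecules
# with an embedded structure-activity signal, decoy screening libraries,
# noisy concentration-inhibition data, and two-choice behavior counts.
#
# Scaffold chemistry mirrors the chemotypes of the screening campaign the
# package models (substituted phenols and cinnamate-type esters as
# activity-conferring motifs; flavor/fragrance-like esters, ketones, ethers,
# alcohols and alkylbenzenes as decoys). Truth labels are assigned by SMARTS
# matching on the generated structures, never by bookkeeping alone.

# substituents written attach-first; only ever used after an atom or inside
# parentheses, so plain concatenation yields valid SMILES
.SUBS_R <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "C(C)C",
             "C(C)(C)C", "CC(C)C", "CCC(C)C", "CC(C)CC", "CCCCCCC",
             "C(C)CC", "CCCCCCCC")
.SUBS_Q <- c("C", "CC", "CCC", "C(C)C", "C(C)(C)C", "CC(C)C", "OC", "CCCC")

.fill <- function(template, R = NULL, Q = NULL) {
  out <- template
  if (!is.null(R)) out <- sub("{R}", R, out, fixed = TRUE)
  if (!is.null(Q)) out <- sub("{Q}", Q, out, fixed = TRUE)
  out
}

.expand_templates <- function(templates) {
  out <- character(0)
  for (tp in templates) {
    hasR <- grepl("{R}", tp, fixed = TRUE)
    hasQ <- grepl("{Q}", tp, fixed = TRUE)
    if (hasR && hasQ) {
      for (r in .SUBS_R) for (q in .SUBS_Q)
        out <- c(out, .fill(tp, R = r, Q = q))
    } else if (hasR) {
      for (r in .SUBS_R) out <- c(out, .fill(tp, R = r))
    } else if (hasQ) {
      for (q in .SUBS_Q) out <- c(out, .fill(tp, Q = q))
    } else {
      out <- c(out, tp)
    }
  }
  unique(out)
}

# motif-bearing (active-like) scaffolds: substituted phenols and
# cinnamate-type esters
.ACTIVE_TEMPLATES <- c(
  "Oc1ccccc1{R}",            # ortho-substituted phenols
  "Oc1ccc({R})cc1",          # para
  "Oc1cccc({R})c1",          # meta
  "Oc1cc({Q})ccc1{R}",       # 2,4-disubstituted
  "Oc1ccc({Q})cc1{R}",       # 2,5-disubstituted
  "Oc1c({Q})cccc1{R}",       # 2,6-disubstituted
  "Oc1ccc({R})cc1O",         # hydroquinone-type
  "Oc1cccc({R})c1O",         # catechol-type
  "O=C(O{R})C=Cc1ccccc1",    # cinnamate esters
  "O=C(O{R})C=Cc1ccc({Q})cc1"
)

# motif-free decoys (no free aromatic OH, no cinnamate-type conjugation)
.DECOY_TEMPLATES <- c(
  "O=C(O{R}){Q}",            # aliphatic esters
  "O=C(O{R})C{Q}",
  "O=C({R}){Q}",             # ketones
  "O({R}){Q}",               # ethers
  "OC({R}){Q}",              # secondary alcohols
  "OC{R}",                   # primary alcohols
  "O=C{R}",                  # aldehydes
  "N#C{R}",                  # nitriles
  "O=C(NC){R}",              # N-methyl amides
  "c1ccccc1{R}",             # alkylbenzenes
  "c1ccc({Q})cc1{R}",
  "COc1ccc({Q})cc1",         # anisoles
  "O=C(C)Oc1ccc({Q})cc1",    # aryl acetates
  "O=Cc1ccc({Q})cc1",        # benzaldehydes
  "c1ccncc1{R}",             # alkylpyridines
  "c1ccoc1{R}",              # alkylfurans
  "O=C(O{R})c1ccc({Q})cc1",  # benzoate esters
  "O=C({R})c1ccc({Q})cc1",   # aryl ketones
  "O=C(O{R})CCC(=O)O{Q}",    # succinate diesters
  "O=C(OC{R})C{Q}",          # homologated esters
  "O=C(O{R})C(C){Q}",        # branched-acid esters
  "O(c1ccc({Q})cc1){R}",     # aryl alkyl ethers
  "C(OC)(OC){R}",            # dimethyl acetals
  "O=CC({R}){Q}",            # branched aldehydes
  "O=C1CCC(O1){R}",          # gamma-lactones
  "c1cnc({R})cn1",           # alkylpyrazines
  "S({R})C"                  # methyl thioethers
)

.DEFAULT_MOTIFS <- c(phenol = "[OX2H]c1ccccc1",
                     cinnamate = "O=C(O[#6])C=Cc1ccccc1")

# SMARTS matches per molecule, any of several patterns
.matches_any_motif <- function(ms, motif_smarts) {
  heavy <- vapply(ms$smiles, smiles_heavy_atoms, 1L, USE.NAMES = FALSE)
  hit <- rep(FALSE, nrow(ms))
  multi <- which(heavy > 1L)
  if (length(multi) == 0L) return(hit)
  smi <- ms$smiles[multi]
  names(smi) <- paste0("q", seq_along(smi))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  for (pat in motif_smarts) {
    counts <- ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = TRUE)
    hit[multi] <- hit[multi] | counts > 0
  }
  hit
}

#' Specification for synthetic compound-set generation
#'
#' The defaults reproduce the study conditions the generators emulate: a
#' 58-active / 25-inactive training panel whose actives carry phenol or
#' cinnamate-type motifs with a wide log-normal potency range (median about
#' 800 micromolar, sd 1.3 natural-log units, spanning roughly 10 uM-13 mM),
#' and a 1280-compound flavor/fragrance-like screening library of which 5%
#' bear a motif.
#'
#' @param n_actives,n_inactives,n_library set sizes.
#' @param motif_smarts activity-conferring substructure patterns (SMARTS).
#' @param active_fraction_library proportion of motif-bearing library
#'   members.
#' @param potency_log_mu,potency_log_sigma natural-log mean/sd of the
#'   active IC50 distribution (micromolar).
#' @param label_noise fraction of active/inactive label pairs swapped after
#'   assignment (0 = clean labels); a knob for degrading ground-truth
#'   separability without touching the structures.
#' @param seed RNG seed; identical spec + seed gives byte-identical output.
#' @return a `LibrarySpec` list.
#' @export
library_spec <- function(n_actives = 58, n_inactives = 25, n_library = 1280,
                         motif_smarts = .DEFAULT_MOTIFS,
                         active_fraction_library = 0.05,
                         potency_log_mu = log(800), potency_log_sigma = 1.3,
                         label_noise = 0, seed = 1) {
  stopifnot(n_actives >= 0, n_inactives >= 0, n_library >= 0,
            active_fraction_library >= 0, active_fraction_library <= 1,
            label_noise >= 0, label_noise <= 0.5)
  structure(list(n_actives = as.integer(n_actives),
                 n_inactives = as.integer(n_inactives),
                 n_library = as.integer(n_library),
                 motif_smarts = motif_smarts,
                 active_fraction_library = active_fraction_library,
                 potency_log_mu = potency_log_mu,
                 potency_log_sigma = potency_log_sigma,
                 label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "LibrarySpec")
}

# standardized scaffold pools, split into motif-bearing and motif-free by
# SMARTS (the generated truth authority); cached per motif set
.scaffold_pools <- local({
  cache <- new.env(parent = emptyenv())
  function(motif_smarts) {
    key <- paste(motif_smarts, collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cand <- unique(c(.expand_templates(.ACTIVE_TEMPLATES),
                     .expand_templates(.DECOY_TEMPLATES)))
    ms <- molecule_set(paste0("pool_", seq_along(cand)), cand)
    ms <- standardize_molecules(ms)
    dup <- duplicated(ms$smiles)
    ms <- ms[!dup, , drop = FALSE]
    class(ms) <- c("MoleculeSet", "data.frame")
    hit <- .matches_any_motif(ms, motif_smarts)
    pools <- list(active = ms$smiles[hit], decoy = ms$smiles[!hit])
    cache[[key]] <- pools
    pools
  }
})

#' Generate a labeled synthetic training set
#'
#' Actives are drawn (without replacement) from an enumerated pool of
#' motif-bearing scaffolds, inactives from motif-free decoy scaffolds; each
#' active receives a log-normal IC50. All structures are standardized and
#' every active matches at least one motif pattern, verified by SMARTS.
#'
#' @param spec a [library_spec()].
#' @return a labeled, standardized `MoleculeSet` with `ic50_um` on actives.
#' @export
generate_training_set <- function(spec = library_spec()) {
  stopifnot(inherits(spec, "LibrarySpec"))
  pools <- .scaffold_pools(spec$motif_smarts)
  if (length(pools$active) == 0L)
    stop("no constructible scaffold matches the motif patterns")
  if (spec$n_actives > length(pools$active))
    stop("n_actives exceeds the constructible motif-bearing pool (",
         length(pools$active), ")")
  if (spec$n_inactives > length(pools$decoy))
    stop("n_inactives exceeds the constructible decoy pool")
  set.seed(spec$seed)
  act <- sample(pools$active, spec$n_actives)
  inact <- sample(pools$decoy, spec$n_inactives)
  ic50 <- exp(stats::rnorm(spec$n_actives, spec$potency_log_mu,
                           spec$potency_log_sigma))
  ms <- molecule_set(
    id = c(sprintf("act_%03d", seq_len(spec$n_actives)),
           sprintf("inact_%03d", seq_len(spec$n_inactives))),
    smiles = c(act, inact),
    source = "synthetic",
    label = rep(c("active", "inactive"), c(spec$n_actives, spec$n_inactives)),
    ic50_um = c(ic50, rep(NA_real_, spec$n_inactives)),
    standardized = TRUE)
  if (spec$label_noise > 0) {
    m <- floor(spec$label_noise * min(spec$n_actives, spec$n_inactives))
    if (m > 0) {
      swap_a <- sample(which(ms$label == "active"), m)
      swap_i <- sample(which(ms$label == "inactive"), m)
      ms$label[swap_a] <- "inactive"
      ms$label[swap_i] <- "active"
      ms$ic50_um[swap_a] <- NA_real_
    }
  }
  ms
}

#' Generate a synthetic screening library with hidden ground truth
#'
#' Builds `n_library` standardized molecules of which a fraction
#' `active_fraction_library` bear an activity motif; the ground truth is
#' returned as a separate table (id, `is_motif`, `is_training`) so pipeline
#' code cannot accidentally consume it. With `spike_training`, a subset of
#' training records (16 actives and 8 inactives by default, mirroring the
#' composition of a screened catalog that contains its own training
#' compounds) is inserted under its training ids.
#'
#' @param spec a [library_spec()].
#' @param training optional training `MoleculeSet` (required for spiking).
#' @param spike_training insert training records into the library.
#' @param n_spike_active,n_spike_inactive how many training records to spike.
#' @return list with `molecules` (standardized `MoleculeSet`) and `truth`
#'   (data frame).
#' @export
generate_library <- function(spec = library_spec(), training = NULL,
                             spike_training = FALSE,
                             n_spike_active = 16, n_spike_inactive = 8) {
  stopifnot(inherits(spec, "LibrarySpec"))
  pools <- .scaffold_pools(spec$motif_smarts)
  n_motif <- round(spec$n_library * spec$active_fraction_library)
  n_decoy <- spec$n_library - n_motif
  if (n_motif > length(pools$active))
    stop("motif-bearing library fraction exceeds the constructible pool")
  if (n_decoy > length(pools$decoy))
    stop("library size exceeds the constructible decoy pool (",
         length(pools$decoy), " decoys available)")
  set.seed(spec$seed + 1L)
  smi <- c(sample(pools$active, n_motif), sample(pools$decoy, n_decoy))
  is_motif <- rep(c(TRUE, FALSE), c(n_motif, n_decoy))
  ord <- sample(spec$n_library)
  smi <- smi[ord]; is_motif <- is_motif[ord]
  ids <- sprintf("lib_%04d", seq_len(spec$n_library))
  is_training <- rep(FALSE, spec$n_library)
  if (spike_training) {
    if (is.null(training)) stop("spike_training requires the training set")
    sp_a <- sample(which(training$label == "active"),
                   min(n_spike_active, sum(training$label == "active")))
    sp_i <- sample(which(training$label == "inactive"),
                   min(n_spike_inactive, sum(training$label == "inactive")))
    sp <- c(sp_a, sp_i)
    slots <- sample(spec$n_library, length(sp))
    smi[slots] <- training$smiles[sp]
    ids[slots] <- training$id[sp]
    is_training[slots] <- TRUE
    ms_tmp <- molecule_set(ids, smi, source = "synthetic", standardized = TRUE)
    is_motif[slots] <- .matches_any_motif(ms_tmp[slots, , drop = FALSE],
                                          spec$motif_smarts)
  }
  ms <- molecule_set(ids, smi, source = "synthetic", standardized = TRUE)
  list(molecules = ms,
       truth = data.frame(id = ids, is_motif = is_motif,
                          is_training = is_training,
                          stringsAsFactors = FALSE))
}

#' Specification for synthetic concentration-inhibition data
#'
#' Defaults emulate a potent antagonist measured over eight log-spaced
#' concentrations with 5% multiplicative noise: true IC50 48 uM, Hill
#' coefficient 1, Imax 100% of control.
#'
#' @param true_ic50,true_n,true_imax generating Hill parameters.
#' @param concentrations micromolar test concentrations.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed.
#' @return a `DoseResponseSpec` list.
#' @export
dose_response_spec <- function(true_ic50 = 48, true_n = 1, true_imax = 100,
                               concentrations = 10^seq(0, 4, length.out = 8),
                               noise_cv = 0.05, seed = 1) {
  stopifnot(true_ic50 > 0, true_n > 0, true_imax > 0,
            all(concentrations > 0), noise_cv >= 0)
  structure(list(true_ic50 = true_ic50, true_n = true_n,
                 true_imax = true_imax,
                 concentrations = concentrations,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "DoseResponseSpec")
}

#' Generate synthetic concentration-inhibition assay rows
#'
#' Draws per-concentration oocyte currents consistent with the Hill curve
#' `I = Imax / (1 + (X/IC50)^n)` under multiplicative noise
#' `(1 + eps), eps ~ N(0, noise_cv)`, truncated at 0, plus a sham
#' percent-of-control near 95%. The emitted table matches the assay input
#' schema (`compound_id`, `concentration_um`, `i_pre1`, `i_pre2`, `i_test`,
#' `sham_percent`), and [percent_response()] recovers the noisy response
#' exactly.
#'
#' @param spec a [dose_response_spec()].
#' @param compound_id id written on every row.
#' @return the assay data frame, with the realized `true_response` attached
#'   as column `response_percent` for reference.
#' @export
generate_dose_response <- function(spec = dose_response_spec(),
                                   compound_id = "cmpd_1") {
  stopifnot(inherits(spec, "DoseResponseSpec"))
  set.seed(spec$seed)
  x <- spec$concentrations
  hill <- spec$true_imax / (1 + (x / spec$true_ic50)^spec$true_n)
  resp <- pmax(0, hill * (1 + stats::rnorm(length(x), 0, spec$noise_cv)))
  i0 <- stats::rlnorm(length(x), log(800), 0.15)       # oocyte baseline, nA
  jit <- function(v) v * (1 + stats::rnorm(length(v), 0, 0.02))
  i_pre1 <- jit(i0); i_pre2 <- jit(i0)
  sham <- pmin(110, pmax(80, stats::rnorm(length(x), 95, 3)))
  pre_mean <- (i_pre1 + i_pre2) / 2
  i_test <- pre_mean * resp * sham / 1e4
  data.frame(compound_id = compound_id, concentration_um = x,
             i_pre1 = i_pre1, i_pre2 = i_pre2, i_test = i_test,
             sham_percent = sham, response_percent = resp,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-choice larval behavior trial
#'
#' `excluded ~ Binomial(n_larvae, p_excluded)` larvae stay in the starting
#' circle or touch the center line; the remainder choose the stimulus side
#' independently with probability `p_stim`. Defaults emulate a strongly
#' attractive odorant plated with 50 larvae (expected Response Index 0.76).
#'
#' @param n_larvae larvae plated (default 50).
#' @param p_stim per-larva probability of choosing the stimulus side.
#' @param p_excluded per-larva probability of exclusion.
#' @param seed RNG seed.
#' @return a `BehaviorTrial` list: `s_count`, `c_count`, `excluded`, `ri`.
#' @export
generate_behavior_trial <- function(n_larvae = 50, p_stim = 0.88,
                                    p_excluded = 0.12, seed = 1) {
  stopifnot(n_larvae >= 1, p_stim >= 0, p_stim <= 1,
            p_excluded >= 0, p_excluded <= 1)
  set.seed(seed)
  excluded <- stats::rbinom(1, n_larvae, p_excluded)
  scored <- n_larvae - excluded
  s <- stats::rbinom(1, scored, p_stim)
  c_ <- scored - s
  structure(list(s_count = s, c_count = c_, excluded = excluded,
                 ri = if (s + c_ >= 1) response_index(s, c_) else NA_real_),
            class = "BehaviorTrial")
}

#' @export
print.BehaviorTrial <- function(x, ...) {
  cat(sprintf("BehaviorTrial: S = %d, C = %d, excluded = %d, RI = %s\n",
              x$s_count, x$c_count, x$excluded,
              if (is.na(x$ri)) "undefined" else sprintf("%.3f", x$ri)))
  invisible(x)
}
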