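#' Construct a MoleculeSet
#'
#' A `MoleculeSet` is an ordered data frame of small-molecule records with
#' columns `id`, `name`, `smiles`, `source`, `standardized`, and the optional
#' activity annotations `label` (`"active"`/`"inactive"`) and `ic50_um`
#' (potency in micromolar, actives only). Identifiers must be unique.
#'
#' @param id character identifiers, unique within the set.
#' @param smiles line-notation structures.
#' @param name human-readable labels (defaults to `id`).
#' @param source free-text provenance tag.
#' @param label optional per-record activity, `"active"` or `"inactive"`.
#' @param ic50_um optional per-record IC50 in micromolar; only meaningful for
#'   actives.
#' @param standardized logical; whether `smiles` is already canonical output
#'   of [standardize_molecules()].
#' @return a `MoleculeSet` data frame.
#' @export
molecule_set <- function(id, smiles, name = id, source = "",
                         label = NA_character_, ic50_um = NA_real_,
                         standardized = FALSE) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate molecule ids: ", paste(dup, collapse = ", "))
  }
  label <- as.character(label)
  okl <- is.na(label) | label %in% c("active", "inactive")
  if (!all(okl)) stop("labels must be 'active', 'inactive' or NA")
  ms <- data.frame(id = id, name = as.character(name),
                   smiles = as.character(smiles),
                   source = as.character(source),
                   standardized = as.logical(standardized),
                   label = label,
                   ic50_um = as.numeric(ic50_um),
                   stringsAsFactors = FALSE)
  class(ms) <- c("MoleculeSet", "data.frame")
  ms
}

#' @export
print.MoleculeSet <- function(x, ...) {
  cat(sprintf("MoleculeSet with %d record(s)", nrow(x)))
  if (any(!is.na(x$label))) {
    cat(sprintf(" (%d active, %d inactive)",
                sum(x$label == "active", na.rm = TRUE),
                sum(x$label == "inactive", na.rm = TRUE)))
  }
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more record(s)\n")
  invisible(x)
}

#' Rejected records of a read or standardization step
#'
#' @param x a `MoleculeSet` returned by [read_molecules()] or
#'   [standardize_molecules()].
#' @return a data frame with columns `id` and `reason` (zero rows when
#'   nothing was rejected).
#' @export
rejections <- function(x) {
  r <- attr(x, "rejections")
  if (is.null(r)) data.frame(id = character(0), reason = character(0)) else r
}

#' Read molecules from SDF, SMILES-lines, or CSV
#'
#' SMILES line files carry one record per line as `SMILES<TAB>id` (a single
#' space also works); CSV files need columns `id` and `smiles` plus optional
#' `name`, `label` (`active`/`inactive`) and `ic50_um`. Unparseable records
#' are reported via [rejections()], never silently dropped; input order is
#' preserved.
#'
#' @param path file to read.
#' @param format one of `"sdf"`, `"smiles-lines"`, `"csv"`.
#' @param source provenance tag stored on every record.
#' @return a `MoleculeSet`; rejected records are attached as an attribute.
#' @export
read_molecules <- function(path, format = c("sdf", "smiles-lines", "csv"),
                           source = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  rej <- data.frame(id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (format == "sdf") {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    if (length(sdf) == 0L) stop("no records in SDF file: ", path)
    valid <- ChemmineR::validSDF(sdf)
    ids <- ChemmineR::sdfid(sdf)
    ids[is.na(ids) | !nzchar(ids)] <- paste0("sdf_", which(is.na(ids) | !nzchar(ids)))
    smi <- rep(NA_character_, length(sdf))
    if (any(valid)) {
      conv <- suppressWarnings(ChemmineR::sdf2smiles(sdf[valid]))
      smi[valid] <- as.character(conv)
    }
    keep <- valid & !is.na(smi) & nzchar(smi)
    if (any(!keep)) {
      rej <- data.frame(id = ids[!keep], reason = "invalid SDF record",
                        stringsAsFactors = FALSE)
    }
    if (!any(keep)) stop("zero valid records in ", path)
    ids_k <- ids[keep]
    if (anyDuplicated(ids_k))
      stop("duplicate molecule ids in ", path, ": ",
           paste(unique(ids_k[duplicated(ids_k)]), collapse = ", "))
    ms <- molecule_set(ids_k, smi[keep], source = source)
  } else if (format == "smiles-lines") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("zero records in ", path)
    parts <- strsplit(trimws(lines), "[\t ]+")
    smi <- vapply(parts, `[`, "", 1)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
    ids[is.na(ids)] <- paste0("smi_", which(is.na(ids)))
    ok <- vapply(smi, function(s) smiles_tokenize(s)$ok, logical(1))
    if (any(!ok)) {
      reasons <- vapply(smi[!ok], function(s) smiles_tokenize(s)$reason, "")
      rej <- data.frame(id = ids[!ok], reason = reasons,
                        stringsAsFactors = FALSE)
    }
    if (!any(ok)) stop("zero valid records in ", path)
    ids_k <- ids[ok]
    if (anyDuplicated(ids_k))
      stop("duplicate molecule ids in ", path, ": ",
           paste(unique(ids_k[duplicated(ids_k)]), collapse = ", "))
    ms <- molecule_set(ids_k, smi[ok], source = source)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "smiles")
    if (!all(need %in% names(tab)))
      stop("CSV must have columns id and smiles")
    if (nrow(tab) == 0L) stop("zero records in ", path)
    ok <- vapply(tab$smiles, function(s) smiles_tokenize(s)$ok, logical(1))
    if (any(!ok)) {
      reasons <- vapply(tab$smiles[!ok], function(s) smiles_tokenize(s)$reason, "")
      rej <- data.frame(id = as.character(tab$id[!ok]), reason = reasons,
                        stringsAsFactors = FALSE)
    }
    if (!any(ok)) stop("zero valid records in ", path)
    tab <- tab[ok, , drop = FALSE]
    if (anyDuplicated(tab$id))
      stop("duplicate molecule ids in ", path, ": ",
           paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
    ms <- molecule_set(
      tab$id, tab$smiles,
      name = if ("name" %in% names(tab)) tab$name else tab$id,
      source = source,
      label = if ("label" %in% names(tab)) tab$label else NA_character_,
      ic50_um = if ("ic50_um" %in% names(tab)) tab$ic50_um else NA_real_)
  }
  attr(ms, "rejections") <- rej
  ms
}

# canonical SMILES via OpenBabel, optionally neutralizing formal charges;
# returns NA for inputs OpenBabel cannot convert
.canonical_smiles <- function(smiles, neutralize = TRUE) {
  ids <- paste0("x", seq_along(smiles))
  src <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else NULL
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"), options = opts),
    error = function(e) "")
  res <- rep(NA_character_, length(smiles))
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_smi <- vapply(parts, `[`, "", 1)
    got_id <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""))
    hit <- match(ids, got_id)
    res <- got_smi[hit]
  }
  res
}

#' Standardize the structures of a MoleculeSet
#'
#' Applies a fixed sequence: parse, strip to the largest organic fragment
#' (salt/solvent removal), neutralize formal charges where chemically valid,
#' and emit canonical SMILES. The operation is idempotent: standardizing an
#' already standardized set leaves every structure unchanged. Records that
#' fail to parse, or that contain no organic (carbon-bearing) fragment, are
#' dropped and reported via [rejections()].
#'
#' @param ms a `MoleculeSet`.
#' @return the standardized `MoleculeSet` (possibly with fewer records),
#'   with `standardized = TRUE` and a `rejections` attribute.
#' @export
standardize_molecules <- function(ms) {
  stopifnot(inherits(ms, "MoleculeSet"))
  n <- nrow(ms)
  reason <- rep(NA_character_, n)
  frag <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tk <- smiles_tokenize(ms$smiles[i])
    if (!tk$ok) { reason[i] <- tk$reason; next }
    pieces <- strsplit(ms$smiles[i], ".", fixed = TRUE)[[1]]
    organic <- pieces[vapply(pieces, smiles_has_carbon, logical(1))]
    if (length(organic) == 0L) { reason[i] <- "no organic fragment"; next }
    heavy <- vapply(organic, smiles_heavy_atoms, 1L)
    frag[i] <- organic[which.max(heavy)]  # ties: first fragment wins
  }
  todo <- which(is.na(reason))
  if (length(todo) > 0L) {
    can <- .canonical_smiles(frag[todo], neutralize = TRUE)
    fail <- is.na(can) | !nzchar(can)
    reason[todo[fail]] <- "OpenBabel conversion failed"
    frag[todo] <- can
  }
  keep <- is.na(reason)
  rej <- data.frame(id = ms$id[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  out <- ms[keep, , drop = FALSE]
  out$smiles <- frag[keep]
  out$standardized <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("MoleculeSet", "data.frame")
  attr(out, "rejections") <- rej
  out
}

#' Standardize a single structure
#'
#' Convenience wrapper around [standardize_molecules()] for one SMILES
#' string.
#'
#' @param smiles a single line-notation structure.
#' @return the canonical standardized SMILES, or an error if the structure
#'   is rejected.
#' @export
standardize_smiles <- function(smiles) {
  ms <- molecule_set("x", smiles)
  out <- standardize_molecules(ms)
  if (nrow(out) == 0L) stop("structure rejected: ", rejections(out)$reason[1])
  out$smiles[1]
}

#' Write a standardized molecule table
#'
#' Writes `id`, `name`, canonical `smiles`, and `rejection_reason` (empty for
#' retained records, the reported reason for rejected ones) to CSV.
#'
#' @param ms a standardized `MoleculeSet`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_molecule_table <- function(ms, path) {
  rej <- rejections(ms)
  tab <- data.frame(id = c(ms$id, rej$id),
                    name = c(ms$name, rej$id),
                    smiles = c(ms$smiles, rep("", nrow(rej))),
                    rejection_reason = c(rep("", nrow(ms)), rej$reason),
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
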