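# Internal SMILES tokenization and molecular-graph extraction.
#
# Parsing proper is delegated to OpenBabel (via ChemmineR/ChemmineOB); the
# tokenizer here only does cheap structural validation (balanced brackets,
# paired ring closures, known atom symbols) and fragment bookkeeping, so
# malformed input is rejected with a reason instead of being silently
# "repaired" by the lenient OpenBabel reader.

.ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
                     "b", "c", "n", "o", "p", "s")

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                    S = 16, Cl = 17, Br = 35, I = 53, Se = 34, Na = 11,
                    K = 19, Li = 3, Mg = 12, Ca = 20, Zn = 30, Fe = 26)

# default valences used for implicit-hydrogen assignment on organic atoms
.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1, Se = 2)

# van der Waals radii (Angstrom) for the surface-area approximation
.VDW_RADIUS <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85,
                 I = 1.98, Se = 1.90)

#' @noRd
smiles_tokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(list(ok = FALSE, reason = "empty or non-character SMILES"))
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  tokens <- character(0)
  types <- character(0)
  depth <- 0L
  ring_open <- character(0)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) return(list(ok = FALSE, reason = "unclosed bracket atom"))
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      types <- c(types, "atom")
      i <- j + 1L
    } else if (ch %in% c("(", ")")) {
      depth <- depth + if (ch == "(") 1L else -1L
      if (depth < 0L) return(list(ok = FALSE, reason = "unbalanced parentheses"))
      tokens <- c(tokens, ch); types <- c(types, "paren")
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~")) {
      tokens <- c(tokens, ch); types <- c(types, "bond")
      i <- i + 1L
    } else if (ch == ".") {
      tokens <- c(tokens, ch); types <- c(types, "dot")
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[(i + 1):(i + 2)], collapse = "")))
        return(list(ok = FALSE, reason = "malformed %nn ring closure"))
      num <- paste(chars[i:(i + 2)], collapse = "")
      ring_open <- .toggle_ring(ring_open, num)
      tokens <- c(tokens, num); types <- c(types, "ring")
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      ring_open <- .toggle_ring(ring_open, ch)
      tokens <- c(tokens, ch); types <- c(types, "ring")
      i <- i + 1L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        tokens <- c(tokens, two); types <- c(types, "atom")
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        tokens <- c(tokens, ch); types <- c(types, "atom")
        i <- i + 1L
      } else {
        return(list(ok = FALSE, reason = sprintf("unknown symbol '%s'", ch)))
      }
    }
  }
  if (depth != 0L) return(list(ok = FALSE, reason = "unbalanced parentheses"))
  if (length(ring_open) > 0L)
    return(list(ok = FALSE, reason = "unpaired ring-closure digit"))
  if (!any(types == "atom"))
    return(list(ok = FALSE, reason = "no atoms"))
  list(ok = TRUE, tokens = tokens, types = types)
}

.toggle_ring <- function(open, num) {
  hit <- match(num, open)
  if (is.na(hit)) c(open, num) else open[-hit]
}

# element symbol of an atom token ("[NH3+]" -> "N", "c" -> "C")
.token_element <- function(tok) {
  if (startsWith(tok, "[")) {
    m <- regmatches(tok, regexpr("[A-Za-z][a-z]?", sub("^\\[[0-9]*", "", tok)))
    el <- m[1]
  } else {
    el <- tok
  }
  paste0(toupper(substr(el, 1, 1)), substring(el, 2))
}

# formal charge encoded in a bracket-atom token
.token_charge <- function(tok) {
  if (!startsWith(tok, "[")) return(0L)
  body <- gsub("^\\[|\\]$", "", tok)
  m <- regmatches(body, regexpr("[+-]+[0-9]*$|[+-][0-9]+$", body))
  if (length(m) == 0L || !nzchar(m)) return(0L)
  sign <- if (substr(m, 1, 1) == "+") 1L else -1L
  digits <- gsub("[+-]", "", m)
  if (nzchar(digits)) sign * as.integer(digits) else sign * nchar(m)
}

#' @noRd
smiles_heavy_atoms <- function(smiles) {
  tk <- smiles_tokenize(smiles)
  if (!tk$ok) return(NA_integer_)
  atoms <- tk$tokens[tk$types == "atom"]
  sum(vapply(atoms, .token_element, "") != "H")
}

#' @noRd
smiles_has_carbon <- function(smiles) {
  tk <- smiles_tokenize(smiles)
  if (!tk$ok) return(FALSE)
  atoms <- tk$tokens[tk$types == "atom"]
  any(vapply(atoms, .token_element, "") == "C")
}

# V2000 atom-block charge codes
.SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

.implicit_h <- function(element, charge, bond_order_sum) {
  val <- .DEFAULT_VALENCE[element]
  if (is.na(val)) return(0L)
  adj <- if (element %in% c("N", "P", "O", "S")) charge
         else if (element == "C") -abs(charge)
         else 0L
  # hypervalent S/P: step up to the next standard valence when bonds exceed it
  target <- val + adj
  if (element == "S" && bond_order_sum > target) target <- max(target, min(c(4, 6)[c(4, 6) >= bond_order_sum], 6))
  if (element == "P" && bond_order_sum > target) target <- 5
  if (element == "N" && charge == 0 && bond_order_sum > target) target <- bond_order_sum
  max(0L, as.integer(round(target - bond_order_sum)))
}

#' Build molecular graphs for a vector of SMILES
#'
#' Returns, per molecule, an atom table (element, atomic number, formal
#' charge, heavy-atom degree, bond-order sum, implicit hydrogens) and a bond
#' table (atom indices, integer bond order). Single-heavy-atom molecules are
#' handled directly from the token stream; everything else goes through the
#' OpenBabel SDF round trip.
#'
#' @param smiles character vector of (ideally standardized) SMILES.
#' @param ids optional identifiers used in error messages.
#' @return a list of graph objects, one per input, in input order.
#' @noRd
build_mol_graphs <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  n <- length(smiles)
  out <- vector("list", n)
  heavy <- vapply(smiles, smiles_heavy_atoms, 1L, USE.NAMES = FALSE)
  bad <- which(is.na(heavy) | heavy < 1L)
  if (length(bad) > 0L) {
    stop("unparseable SMILES for: ", paste(ids[bad], collapse = ", "))
  }
  single <- which(heavy == 1L)
  for (i in single) {
    tk <- smiles_tokenize(smiles[i])
    atok <- tk$tokens[tk$types == "atom"]
    atok <- atok[vapply(atok, .token_element, "") != "H"][1]
    el <- .token_element(atok)
    ch <- .token_charge(atok)
    nh <- .implicit_h(el, ch, 0)
    out[[i]] <- list(
      atoms = data.frame(element = el, z = unname(.ATOMIC_NUMBER[el]),
                         charge = ch, degree = 0L, bosum = 0L, nh = nh,
                         stringsAsFactors = FALSE),
      bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    )
  }
  multi <- which(heavy > 1L)
  if (length(multi) > 0L) {
    smi_multi <- smiles[multi]
    names(smi_multi) <- paste0("g", seq_along(multi))
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi_multi))
    valid <- ChemmineR::validSDF(sdf)
    if (!all(valid)) {
      stop("OpenBabel could not build a structure for: ",
           paste(ids[multi[!valid]], collapse = ", "))
    }
    for (j in seq_along(multi)) {
      i <- multi[j]
      mol <- sdf[[j]]
      ab <- ChemmineR::atomblock(mol)
      bb <- ChemmineR::bondblock(mol)
      el <- sub("_.*$", "", rownames(ab))
      ccode <- as.character(ab[, "C6"])
      charge <- unname(.SDF_CHARGE[ccode])
      charge[is.na(charge)] <- 0L
      a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
      ord <- as.integer(bb[, 3])
      ord[ord == 4L] <- 1L  # aromatic code, not expected from kekulized SMILES
      natom <- nrow(ab)
      degree <- tabulate(c(a1, a2), natom)
      bosum <- rep(0L, natom)
      for (b in seq_along(a1)) {
        bosum[a1[b]] <- bosum[a1[b]] + ord[b]
        bosum[a2[b]] <- bosum[a2[b]] + ord[b]
      }
      nh <- vapply(seq_len(natom), function(a)
        .implicit_h(el[a], charge[a], bosum[a]), 0L)
      z <- unname(.ATOMIC_NUMBER[el])
      z[is.na(z)] <- 0
      out[[i]] <- list(
        atoms = data.frame(element = el, z = z, charge = charge,
                           degree = degree, bosum = bosum, nh = nh,
                           stringsAsFactors = FALSE),
        bonds = data.frame(a1 = a1, a2 = a2, order = ord)
      )
    }
  }
  names(out) <- ids
  out
}

# is each bond part of a ring? ring bonds are exactly the non-bridge edges;
# bridges found by iterative Tarjan lowlink in O(V + E)
.bonds_in_ring <- function(graph) {
  nb <- graph$bonds
  natom <- nrow(graph$atoms)
  nbond <- nrow(nb)
  if (nbond == 0L) return(logical(0))
  adj <- vector("list", natom)
  for (b in seq_len(nbond)) {
    adj[[nb$a1[b]]] <- c(adj[[nb$a1[b]]], b)
    adj[[nb$a2[b]]] <- c(adj[[nb$a2[b]]], b)
  }
  disc <- rep(0L, natom)
  low <- rep(0L, natom)
  bridge <- rep(FALSE, nbond)
  timer <- 0L
  for (root in seq_len(natom)) {
    if (disc[root] > 0L) next
    # explicit stack of (vertex, incoming bond, next adjacency position)
    stack_v <- root; stack_b <- 0L; stack_i <- 1L
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack_v) > 0L) {
      top <- length(stack_v)
      v <- stack_v[top]
      if (stack_i[top] <= length(adj[[v]])) {
        b <- adj[[v]][stack_i[top]]
        stack_i[top] <- stack_i[top] + 1L
        if (b == stack_b[top]) next
        w <- if (nb$a1[b] == v) nb$a2[b] else nb$a1[b]
        if (disc[w] == 0L) {
          timer <- timer + 1L
          disc[w] <- low[w] <- timer
          stack_v <- c(stack_v, w)
          stack_b <- c(stack_b, b)
          stack_i <- c(stack_i, 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        # retreat: propagate lowlink to parent and test the tree edge
        stack_v <- stack_v[-top]
        bin <- stack_b[top]
        stack_b <- stack_b[-top]
        stack_i <- stack_i[-top]
        if (length(stack_v) > 0L) {
          p <- stack_v[length(stack_v)]
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) bridge[bin] <- TRUE
        }
      }
    }
  }
  !bridge
}
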