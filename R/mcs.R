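# ---------------------------------------------------------------------------
# Maximum common (connected) substructure search between two molecules, by
# branch-and-bound backtracking over atom mappings. Two mapping modes:
#   strict_aromatic - atoms match on element AND aromatic flag; bonds match
#                     on type (aromatic only to aromatic);
#   relaxed         - atoms match on element only; bond types are ignored,
#                     so aromatic atoms may map to equivalent aliphatic ones.
# Strict compatibility is a subset of relaxed compatibility, so the strict
# MCS size can never exceed the relaxed one.
# ---------------------------------------------------------------------------

.bond_key <- function(order) ifelse(order == "am", "1", order)

.mcs_adj <- function(mol) {
  n <- mol$n_atoms
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    o <- .bond_key(mol$bonds$order[k])
    adj[[a]] <- rbind(adj[[a]], data.frame(nbr = b, order = o))
    adj[[b]] <- rbind(adj[[b]], data.frame(nbr = a, order = o))
  }
  adj
}

#' Maximum common substructure size between two molecules
#'
#' Finds the largest connected common substructure (counted in atoms) under
#' the chosen mapping mode, with a per-pair wall-clock budget. When the
#' budget is exhausted the best size found so far is returned with
#' `timed_out = TRUE`.
#'
#' @param mol_a,mol_b `mol` objects from [parse_smiles()].
#' @param mode `"strict_aromatic"` or `"relaxed"`.
#' @param time_budget seconds of search time allowed (default 5).
#' @return list with `size` (atoms in the MCS) and `timed_out`.
#' @export
mcs_size <- function(mol_a, mol_b, mode = c("strict_aromatic", "relaxed"),
                     time_budget = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(mol_a, "mol"), inherits(mol_b, "mol"),
            mol_a$valid, mol_b$valid)
  strict <- mode == "strict_aromatic"
  elA <- mol_a$atoms$element; elB <- mol_b$atoms$element
  arA <- mol_a$atoms$aromatic; arB <- mol_b$atoms$aromatic
  nA <- mol_a$n_atoms; nB <- mol_b$n_atoms
  atom_ok <- outer(seq_len(nA), seq_len(nB), function(i, j) {
    ok <- elA[i] == elB[j]
    if (strict) ok <- ok & (arA[i] == arB[j])
    ok
  })
  adjA <- .mcs_adj(mol_a); adjB <- .mcs_adj(mol_b)
  bond_ok <- function(oa, ob) if (strict) oa == ob else TRUE

  env <- new.env()
  env$best <- 0L
  env$timed_out <- FALSE
  deadline <- proc.time()[["elapsed"]] + time_budget

  extend <- function(mapA, mapB, seed) {
    if (env$timed_out) return(invisible())
    if (proc.time()[["elapsed"]] > deadline) {
      env$timed_out <- TRUE
      return(invisible())
    }
    size <- length(mapA)
    if (size > env$best) env$best <- size
    # candidate pairs adjacent (through compatible bonds) to the mapping
    cand <- list()
    for (k in seq_along(mapA)) {
      u <- mapA[k]; v <- mapB[k]
      na_ <- adjA[[u]]; nb_ <- adjB[[v]]
      if (is.null(na_) || is.null(nb_)) next
      for (ia in seq_len(nrow(na_))) {
        x <- na_$nbr[ia]
        if (x <= seed || x %in% mapA) next
        for (ib in seq_len(nrow(nb_))) {
          y <- nb_$nbr[ib]
          if (y %in% mapB) next
          if (atom_ok[x, y] && bond_ok(na_$order[ia], nb_$order[ib])) {
            cand[[length(cand) + 1L]] <- c(x, y)
          }
        }
      }
    }
    if (!length(cand)) return(invisible())
    cand <- unique(do.call(rbind, cand))
    # upper bound: current size + distinct extendable atoms on each side
    ub <- size + min(length(unique(cand[, 1])) +
                       sum(!seq_len(nA) %in% c(mapA, cand[, 1]) &
                             seq_len(nA) > seed),
                     nB - size)
    if (ub <= env$best) return(invisible())
    tried_pairs <- character(0)
    for (r in seq_len(nrow(cand))) {
      x <- cand[r, 1]; y <- cand[r, 2]
      key <- paste(x, y)
      if (key %in% tried_pairs) next
      tried_pairs <- c(tried_pairs, key)
      extend(c(mapA, x), c(mapB, y), seed)
      if (env$timed_out) return(invisible())
    }
    invisible()
  }

  for (i in seq_len(nA)) {
    if (env$timed_out) break
    for (j in seq_len(nB)) {
      if (atom_ok[i, j]) {
        if (min(nA - i + 1L, nB) <= env$best) next
        extend(i, j, i)
        if (env$timed_out) break
      }
    }
  }
  list(size = env$best, timed_out = env$timed_out)
}

#' All cross-set compound pairs sharing a large substructure
#'
#' Compares every compound of one set against every compound of the other
#' and keeps the unique pairs whose maximum common substructure exceeds
#' `min_atoms` atoms under the given mapping mode. Pairs whose search
#' exhausts the per-pair time budget are skipped and reported.
#'
#' @param set_a,set_b character vectors of SMILES.
#' @param ids_a,ids_b compound identifiers.
#' @param min_atoms minimum shared-substructure size; a pair is kept when the
#'   MCS has strictly more atoms than this (default 15).
#' @param mode mapping mode, see [mcs_size()].
#' @param time_budget seconds allowed per pair (default 5).
#' @return data.frame with `id_a`, `id_b`, `n_matched_atoms`, `mode`;
#'   skipped (timed-out) pairs in `attr(, "skipped")`.
#' @export
shared_substructure_pairs <- function(set_a, set_b, ids_a = NULL,
                                      ids_b = NULL, min_atoms = 15,
                                      mode = c("strict_aromatic", "relaxed"),
                                      time_budget = 5) {
  mode <- match.arg(mode)
  if (is.null(ids_a)) ids_a <- as.character(set_a)
  if (is.null(ids_b)) ids_b <- as.character(set_b)
  mols_a <- parse_smiles(set_a, ids_a)
  mols_b <- parse_smiles(set_b, ids_b)
  rows <- list(); skipped <- list()
  for (i in seq_along(mols_a)) {
    if (!mols_a[[i]]$valid) next
    for (j in seq_along(mols_b)) {
      if (!mols_b[[j]]$valid) next
      res <- mcs_size(mols_a[[i]], mols_b[[j]], mode = mode,
                      time_budget = time_budget)
      if (res$timed_out) {
        skipped[[length(skipped) + 1L]] <- c(ids_a[i], ids_b[j])
        next
      }
      if (res$size > min_atoms) {
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = ids_a[i], id_b = ids_b[j],
          n_matched_atoms = res$size, mode = mode,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0),
               n_matched_atoms = integer(0), mode = character(0),
               stringsAsFactors = FALSE)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    matrix(character(0), ncol = 2)
  out
}
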