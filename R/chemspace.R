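# ---------------------------------------------------------------------------
# Chemical-space comparison of two inhibitor sets: physicochemical profiles,
# Bemis-Murcko scaffold content, cross-set similarity and a 2-D embedding.
# ---------------------------------------------------------------------------

#' Six-property physicochemical profile
#'
#' Computes, per compound: topological polar surface area (TPSA, A^2),
#' rotatable-bond count, lipophilicity (logP), total hydrogen-bond
#' donor + acceptor count, molecular weight (g/mol) and ring count.
#' Unparseable structures are flagged (`valid = FALSE`), never silently
#' dropped.
#'
#' @param smiles character vector of SMILES.
#' @param ids compound identifiers.
#' @return data.frame with columns `compound_id`, `valid`, `TPSA`,
#'   `rotatable_bonds`, `logP`, `hbond_atoms`, `MW`, `rings`.
#' @export
physchem_profile <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- as.character(smiles)
  mols <- parse_smiles(smiles, ids)
  out <- data.frame(compound_id = ids, valid = FALSE, TPSA = NA_real_,
                    rotatable_bonds = NA_integer_, logP = NA_real_,
                    hbond_atoms = NA_integer_, MW = NA_real_,
                    rings = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(smiles)) {
    if (!mols[[i]]$valid) next
    props <- tryCatch({
      m <- suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles[i],
                                                   identity))
      ChemmineOB::prop_OB(m)
    }, error = function(e) NULL)
    if (is.null(props)) next
    out$valid[i] <- TRUE
    out$TPSA[i] <- props$TPSA
    out$logP[i] <- props$logP
    out$MW[i] <- props$MW
    out$hbond_atoms[i] <- props$HBD + props$HBA2
    out$rotatable_bonds[i] <- .rotatable_bonds(mols[[i]])
    out$rings[i] <- .ring_count(mols[[i]])
  }
  out
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The ring systems plus the linkers that connect them: terminal atoms
#' attached through single bonds are pruned iteratively, then any remaining
#' acyclic fragments are discarded. Exocyclic atoms held by a double or
#' triple bond (e.g. a carbonyl oxygen on a linker) are retained, matching
#' the usual scaffold definition. The result is returned as canonical
#' SMILES; acyclic molecules yield the empty string.
#'
#' @param smiles a single SMILES string.
#' @return canonical scaffold SMILES, `""` for acyclic molecules, `NA` for
#'   unparseable input.
#' @export
murcko_scaffold <- function(smiles) {
  if (is.na(smiles) || !nzchar(trimws(smiles))) return(NA_character_)
  # work on the hydrogen-explicit connection table so pyrrole-type nitrogens
  # keep their hydrogen and the fragment re-perceives aromaticity correctly
  txt <- .ob_convert("SMI", "MOL2", smiles,
                     options = data.frame(names = "h", args = "",
                                          stringsAsFactors = FALSE))
  if (is.na(txt)) return(NA_character_)
  parsed <- .parse_mol2_block(txt)
  if (is.null(parsed) || nrow(parsed$atoms) == 0) return(NA_character_)
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  heavy <- atoms$idx[atoms$element != "H"]
  hb <- bonds[bonds$a1 %in% heavy & bonds$a2 %in% heavy, , drop = FALSE]
  # prune every terminal heavy atom iteratively: what survives is the ring
  # systems plus the linker paths between them
  keep <- heavy
  b <- hb
  repeat {
    deg <- table(factor(c(b$a1, b$a2), levels = keep))
    removable <- as.integer(names(deg)[deg <= 1])
    if (!length(removable)) break
    keep <- setdiff(keep, removable)
    b <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
    if (!length(keep)) return("")
  }
  # re-attach atoms held by a double/triple bond to a kept atom (e.g. the
  # carbonyl oxygen of a linker amide), which the scaffold retains
  multi <- hb[!hb$order %in% c("1", "am"), , drop = FALSE]
  add <- unique(c(multi$a1[multi$a2 %in% keep & !multi$a1 %in% keep],
                  multi$a2[multi$a1 %in% keep & !multi$a2 %in% keep]))
  keep <- c(keep, add)
  b <- hb[hb$a1 %in% keep & hb$a2 %in% keep, , drop = FALSE]
  # drop remaining fragments that contain no ring (e.g. a stranded C=O pair)
  g <- igraph::graph_from_data_frame(
    b[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = keep))
  comp <- igraph::components(g)
  cyclic <- which(vapply(seq_len(comp$no), function(k) {
    vids <- which(comp$membership == k)
    sub <- igraph::induced_subgraph(g, vids)
    igraph::ecount(sub) >= igraph::vcount(sub)
  }, logical(1)))
  if (!length(cyclic)) return("")
  keep <- as.integer(igraph::V(g)$name[comp$membership %in% cyclic])
  # carry over the original hydrogens of scaffold atoms, and cap each bond
  # to a pruned substituent with a new hydrogen
  h_atoms <- atoms$idx[atoms$element == "H"]
  h_kept <- unique(c(
    bonds$a1[bonds$a1 %in% h_atoms & bonds$a2 %in% keep],
    bonds$a2[bonds$a2 %in% h_atoms & bonds$a1 %in% keep]))
  single <- hb[hb$order %in% c("1", "am"), , drop = FALSE]
  cap_on <- c(single$a1[single$a1 %in% keep & !single$a2 %in% keep],
              single$a2[single$a2 %in% keep & !single$a1 %in% keep])
  frag <- .fragment_mol2(atoms, bonds, c(keep, h_kept), extra_h_on = cap_on)
  can <- .ob_convert("MOL2", "CAN", frag)
  if (is.na(can)) return(NA_character_)
  strsplit(trimws(can), "[ \t]")[[1]][1]
}

#' Scaffold content of two compound sets and their overlap
#'
#' @param set_a,set_b character vectors of SMILES (nonempty).
#' @return list with `summary_a`, `summary_b` (each: `scaffolds`,
#'   `n_compounds`, `ratio` = unique scaffolds per compound) and `shared`,
#'   the intersection of the two scaffold sets. Acyclic molecules contribute
#'   no scaffold but still count as compounds.
#' @export
scaffold_overlap <- function(set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stop("both sets must be nonempty")
  summarise <- function(smis) {
    sc <- vapply(smis, murcko_scaffold, character(1), USE.NAMES = FALSE)
    sc <- sc[!is.na(sc) & nzchar(sc)]
    scaffolds <- sort(unique(sc))
    list(scaffolds = scaffolds, n_compounds = length(smis),
         ratio = length(scaffolds) / length(smis))
  }
  a <- summarise(set_a)
  b <- summarise(set_b)
  list(summary_a = a, summary_b = b,
       shared = intersect(a$scaffolds, b$scaffolds))
}

#' 2-D embedding of chemical space
#'
#' Embeds compounds into the plane by classical metric multidimensional
#' scaling of the pairwise Tanimoto distance matrix (1 - similarity). The
#' embedding is fully deterministic; `seed` is accepted for interface
#' stability but no randomness is consumed.
#'
#' @param fps a `fingerprint_set` with at least 3 compounds.
#' @param seed integer, kept for a reproducibility-stable interface.
#' @return data.frame with `compound_id`, `x`, `y`.
#' @export
embed_chemical_space <- function(fps, seed = 1L) {
  stopifnot(inherits(fps, "fingerprint_set"))
  n <- nrow(fps$bits)
  if (n < 3) stop("need at least 3 compounds to embed")
  A <- fps$bits
  inter <- A %*% t(A)
  cnt <- rowSums(A)
  uni <- outer(cnt, cnt, `+`) - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  diag(sim) <- 1
  d <- as.dist(1 - sim)
  xy <- cmdscale(d, k = 2)
  if (ncol(xy) < 2) xy <- cbind(xy, 0)  # degenerate all-coincident case
  data.frame(compound_id = fps$compound_ids, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}
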