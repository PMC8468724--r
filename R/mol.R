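#' @importFrom stats aggregate coef cmdscale density lm predict quantile sd var
#' @importFrom utils head read.table write.table
NULL

# ---------------------------------------------------------------------------
# Light molecule layer on top of OpenBabel (via ChemmineOB).
#
# Molecules are parsed from OpenBabel MOL2 text rather than SDF because MOL2
# carries explicit aromatic atom types (C.ar, ...) and aromatic bond records
# ("ar"), which the strict/relaxed substructure mapping modes need, and it
# represents single-atom molecules without trouble.
# ---------------------------------------------------------------------------

.ob_opts_none <- function() data.frame(names = character(0), args = character(0))

.ob_convert <- function(from, to, src, options = .ob_opts_none()) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, src, options = options)),
    error = function(e) ""
  )
  if (is.null(out) || !nzchar(trimws(out))) return(NA_character_)
  out
}

#' Canonicalise a SMILES string
#'
#' Returns the OpenBabel canonical SMILES. Optionally keeps only the largest
#' connected component (salt stripping) and/or neutralises formal charges,
#' which together form the duplicate key used during curation.
#'
#' @param smiles character vector of SMILES.
#' @param strip_salt keep only the component with the most heavy atoms.
#' @param neutralize apply OpenBabel's charge neutralisation before writing.
#' @return character vector of canonical SMILES; `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles, strip_salt = FALSE, neutralize = FALSE) {
  opts <- if (neutralize) {
    data.frame(names = "neutralize", args = "")
  } else {
    .ob_opts_none()
  }
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    can <- .ob_convert("SMI", "CAN", s, options = opts)
    if (is.na(can)) return(NA_character_)
    can <- strsplit(trimws(can), "[ \t]")[[1]][1]
    if (strip_salt && grepl(".", can, fixed = TRUE)) {
      parts <- strsplit(can, ".", fixed = TRUE)[[1]]
      sizes <- vapply(parts, function(p) {
        m <- parse_smiles(p)[[1]]
        if (m$valid) m$n_atoms else -1L
      }, integer(1))
      can <- .ob_convert("SMI", "CAN", parts[which.max(sizes)], options = opts)
      if (is.na(can)) return(NA_character_)
      can <- strsplit(trimws(can), "[ \t]")[[1]][1]
    }
    can
  }, character(1), USE.NAMES = FALSE)
}

.parse_mol2_block <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  imol <- grep("^@<TRIPOS>MOLECULE", lines)
  iat <- grep("^@<TRIPOS>ATOM", lines)
  ibd <- grep("^@<TRIPOS>BOND", lines)
  if (length(imol) < 1 || length(iat) < 1) return(NULL)
  counts <- as.integer(strsplit(trimws(lines[imol[1] + 2]), "[ \t]+")[[1]])
  n_atoms <- counts[1]
  n_bonds <- if (length(counts) >= 2) counts[2] else 0L
  atoms <- data.frame(
    idx = integer(0), element = character(0), type = character(0),
    aromatic = logical(0), x = numeric(0), y = numeric(0), z = numeric(0),
    stringsAsFactors = FALSE
  )
  if (n_atoms > 0) {
    at_lines <- lines[(iat[1] + 1):(iat[1] + n_atoms)]
    f <- strsplit(trimws(at_lines), "[ \t]+")
    atoms <- data.frame(
      idx = as.integer(vapply(f, `[`, "", 1)),
      element = vapply(f, function(v) strsplit(v[6], ".", fixed = TRUE)[[1]][1], ""),
      type = vapply(f, `[`, "", 6),
      x = as.numeric(vapply(f, `[`, "", 3)),
      y = as.numeric(vapply(f, `[`, "", 4)),
      z = as.numeric(vapply(f, `[`, "", 5)),
      stringsAsFactors = FALSE
    )
    atoms$aromatic <- grepl("\\.ar$", atoms$type)
  }
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  if (n_bonds > 0 && length(ibd) >= 1) {
    bd_lines <- lines[(ibd[1] + 1):(ibd[1] + n_bonds)]
    f <- strsplit(trimws(bd_lines), "[ \t]+")
    bonds <- data.frame(
      a1 = as.integer(vapply(f, `[`, "", 2)),
      a2 = as.integer(vapply(f, `[`, "", 3)),
      order = vapply(f, `[`, "", 4),
      stringsAsFactors = FALSE
    )
  }
  # atoms bonded by an "ar" bond are aromatic even if typed otherwise (e.g. N.2)
  if (nrow(bonds) > 0) {
    ar <- bonds$order == "ar"
    atoms$aromatic[atoms$idx %in% c(bonds$a1[ar], bonds$a2[ar])] <- TRUE
  }
  list(atoms = atoms, bonds = bonds)
}

#' Parse SMILES into molecular graphs
#'
#' Each molecule is converted through OpenBabel to MOL2 and parsed into an
#' atom table (element, aromatic flag) and a bond table (endpoints, order,
#' with "ar" marking aromatic bonds). Unparseable SMILES yield an invalid
#' placeholder, never an error, so callers can flag rather than drop rows.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional compound identifiers (default: the SMILES themselves).
#' @return list of `mol` objects with fields `id`, `smiles`, `valid`,
#'   `atoms`, `bonds`, `n_atoms`.
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- as.character(smiles)
  stopifnot(length(ids) == length(smiles))
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    mol <- list(id = ids[i], smiles = s, valid = FALSE,
                atoms = NULL, bonds = NULL, n_atoms = 0L)
    if (!is.na(s) && nzchar(trimws(s))) {
      txt <- .ob_convert("SMI", "MOL2", s)
      if (!is.na(txt)) {
        parsed <- .parse_mol2_block(txt)
        if (!is.null(parsed) && nrow(parsed$atoms) > 0) {
          mol$valid <- TRUE
          mol$atoms <- parsed$atoms
          mol$bonds <- parsed$bonds
          mol$n_atoms <- nrow(parsed$atoms)
        }
      }
    }
    class(mol) <- "mol"
    out[[i]] <- mol
  }
  out
}

#' @export
print.mol <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<mol %s: %d heavy atoms, %d bonds>\n",
                x$id, x$n_atoms, nrow(x$bonds)))
  } else {
    cat(sprintf("<mol %s: INVALID (%s)>\n", x$id, x$smiles))
  }
  invisible(x)
}

.mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = mol$atoms$idx)
  )
}

# logical vector over bonds: TRUE iff the bond is part of a ring
.ring_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0) return(logical(0))
  g <- .mol_graph(mol)
  res <- rep(TRUE, igraph::ecount(g))
  res[igraph::bridges(g)] <- FALSE
  res
}

# smallest-set ring count = cyclomatic number (edges - vertices + components)
.ring_count <- function(mol) {
  if (!mol$valid || mol$n_atoms == 0) return(NA_integer_)
  g <- .mol_graph(mol)
  as.integer(igraph::ecount(g) - igraph::vcount(g) +
               igraph::count_components(g))
}

# rotatable bond: acyclic single bond whose two endpoints each carry at least
# one further heavy-atom connection
.rotatable_bonds <- function(mol) {
  if (!mol$valid) return(NA_integer_)
  if (nrow(mol$bonds) == 0) return(0L)
  g <- .mol_graph(mol)
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  inring <- .ring_bonds(mol)
  single <- mol$bonds$order %in% c("1", "am")
  ok <- single & !inring &
    deg[as.character(mol$bonds$a1)] >= 2 &
    deg[as.character(mol$bonds$a2)] >= 2
  sum(ok)
}

# serialize an induced subgraph of an atom/bond table back to MOL2 text;
# `extra_h_on` lists kept atom indices that each receive one new hydrogen
# (replacing a pruned substituent, so valence and aromaticity perception of
# the fragment match the parent molecule)
.fragment_mol2 <- function(all_atoms, all_bonds, keep_idx,
                           extra_h_on = integer(0)) {
  atoms <- all_atoms[all_atoms$idx %in% keep_idx, , drop = FALSE]
  bonds <- all_bonds[all_bonds$a1 %in% keep_idx &
                       all_bonds$a2 %in% keep_idx, , drop = FALSE]
  remap <- seq_len(nrow(atoms))
  names(remap) <- as.character(atoms$idx)
  n_extra <- length(extra_h_on)
  hdr <- c("@<TRIPOS>MOLECULE", "fragment",
           sprintf(" %d %d 0 0 0", nrow(atoms) + n_extra,
                   nrow(bonds) + n_extra),
           "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM")
  at <- sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %3d UNL1 0.0000",
                remap, atoms$element, atoms$x, atoms$y, atoms$z,
                atoms$type, 1L)
  if (n_extra) {
    at <- c(at, sprintf("%7d H    %9.4f %9.4f %9.4f H     %3d UNL1 0.0000",
                        nrow(atoms) + seq_len(n_extra), 0, 0, 0, 1L))
  }
  bd <- "@<TRIPOS>BOND"
  n_b <- nrow(bonds)
  if (n_b) {
    bd <- c(bd, sprintf("%6d %5d %5d %4s", seq_len(n_b),
                        remap[as.character(bonds$a1)],
                        remap[as.character(bonds$a2)], bonds$order))
  }
  if (n_extra) {
    bd <- c(bd, sprintf("%6d %5d %5d    1", n_b + seq_len(n_extra),
                        remap[as.character(extra_h_on)],
                        nrow(atoms) + seq_len(n_extra)))
  }
  paste(c(hdr, at, bd, ""), collapse = "\n")
}
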