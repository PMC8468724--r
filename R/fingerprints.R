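# ---------------------------------------------------------------------------
# Circular (Morgan / ECFP) fingerprints and Tanimoto similarity.
# OpenBabel computes the raw ECFP bits; they are folded down to the working
# width (default 1024 bits, radius 2 = ECFP4) by OR-ing bit index mod n_bits.
# ---------------------------------------------------------------------------

#' Morgan (circular) fingerprints for a set of compounds
#'
#' @param smiles character vector of SMILES.
#' @param ids compound identifiers (default: the SMILES).
#' @param n_bits folded fingerprint width (default 1024).
#' @param radius circular neighbourhood radius (default 2, i.e. ECFP4).
#' @return object of class `fingerprint_set`: list with `compound_ids`,
#'   binary `bits` matrix (compounds x n_bits), `radius`, `n_bits`.
#'   Unparseable molecules get an all-zero row and are listed in
#'   `attr(, "failed")`.
#' @export
morgan_fp <- function(smiles, ids = NULL, n_bits = 1024L, radius = 2L) {
  if (is.null(ids)) ids <- as.character(smiles)
  stopifnot(length(ids) == length(smiles), n_bits >= 8, radius %in% 0:5)
  fpname <- paste0("ECFP", 2L * radius)
  bits <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  failed <- character(0)
  for (i in seq_along(smiles)) {
    raw <- if (is.na(smiles[i]) || !nzchar(trimws(smiles[i]))) NULL else
      tryCatch({
        mols <- suppressWarnings(
          ChemmineOB::forEachMol("SMILES", smiles[i], identity))
        f <- ChemmineOB::fingerprint_OB(mols, fpname)
        if (is.matrix(f)) as.integer(f[1, ]) else as.integer(f)
      }, error = function(e) NULL)
    if (is.null(raw)) { failed <- c(failed, ids[i]); next }
    on_bits <- which(raw != 0L) - 1L
    folded <- unique(on_bits %% n_bits) + 1L
    bits[i, folded] <- 1L
  }
  rownames(bits) <- ids
  out <- list(compound_ids = ids, bits = bits,
              radius = as.integer(radius), n_bits = as.integer(n_bits))
  class(out) <- "fingerprint_set"
  attr(out, "failed") <- failed
  out
}

#' Construct a fingerprint set from a precomputed binary matrix
#'
#' @param bits binary matrix (compounds x bits).
#' @param ids compound identifiers.
#' @param radius,n_bits metadata describing how the bits were derived.
#' @export
fingerprint_set <- function(bits, ids = rownames(bits),
                            radius = NA_integer_, n_bits = ncol(bits)) {
  bits <- as.matrix(bits)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(bits)))
  stopifnot(length(ids) == nrow(bits), all(bits %in% c(0L, 1L)))
  storage.mode(bits) <- "integer"
  rownames(bits) <- ids
  out <- list(compound_ids = as.character(ids), bits = bits,
              radius = as.integer(radius), n_bits = as.integer(n_bits))
  class(out) <- "fingerprint_set"
  out
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("<fingerprint_set: %d compounds x %d bits (radius %s)>\n",
              nrow(x$bits), x$n_bits,
              ifelse(is.na(x$radius), "?", x$radius)))
  invisible(x)
}

#' Tanimoto coefficient of two binary vectors
#'
#' |intersection| / |union|; defined as 0 when both vectors are all-zero
#' (the undefined 0/0 case).
#'
#' @param a,b binary vectors of equal length.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Per-compound maximum Tanimoto similarity of one set against another
#'
#' For each compound in `fps_a`, the highest Tanimoto coefficient against all
#' compounds of `fps_b`. Calling with the arguments swapped gives the reverse
#' distribution.
#'
#' @param fps_a,fps_b `fingerprint_set` objects with equal bit width.
#' @return named numeric vector (one value in [0,1] per compound of `fps_a`).
#' @export
cross_max_similarity <- function(fps_a, fps_b) {
  stopifnot(inherits(fps_a, "fingerprint_set"),
            inherits(fps_b, "fingerprint_set"))
  if (ncol(fps_a$bits) != ncol(fps_b$bits))
    stop("fingerprint lengths differ")
  if (nrow(fps_b$bits) == 0) stop("comparison set is empty")
  A <- fps_a$bits; B <- fps_b$bits
  inter <- A %*% t(B)
  na <- rowSums(A); nb <- rowSums(B)
  uni <- outer(na, nb, `+`) - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  res <- apply(sim, 1, max)
  names(res) <- fps_a$compound_ids
  res
}
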