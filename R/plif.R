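# ---------------------------------------------------------------------------
# PLIF-similarity screening: residue contact matrices, Tanimoto similarity to
# an X-ray reference profile over an optimised residue subset, enrichment /
# coverage curves for ranking functions, and the dual-target hit criterion.
# ---------------------------------------------------------------------------

#' Construct a residue contact matrix
#'
#' @param contacts binary matrix, compounds x residues.
#' @param compound_ids row identifiers (default: rownames).
#' @param residues residue labels, e.g. `"K:THR:1"` (default: colnames).
#' @param docking_score optional numeric score per compound (lower = better).
#' @param n_heavy_atoms optional positive integer per compound.
#' @param labels optional activity class per compound
#'   (active/moderate/inactive).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(contacts, compound_ids = rownames(contacts),
                           residues = colnames(contacts),
                           docking_score = NULL, n_heavy_atoms = NULL,
                           labels = NULL) {
  contacts <- as.matrix(contacts)
  storage.mode(contacts) <- "integer"
  if (is.null(compound_ids))
    compound_ids <- as.character(seq_len(nrow(contacts)))
  if (is.null(residues))
    residues <- paste0("res", seq_len(ncol(contacts)))
  stopifnot(length(compound_ids) == nrow(contacts),
            length(residues) == ncol(contacts),
            all(contacts %in% c(0L, 1L)))
  if (!is.null(docking_score))
    stopifnot(length(docking_score) == nrow(contacts))
  if (!is.null(n_heavy_atoms))
    stopifnot(length(n_heavy_atoms) == nrow(contacts), all(n_heavy_atoms >= 1))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(contacts))
    labels <- factor(as.character(labels),
                     levels = c("active", "moderate", "inactive"))
  }
  dimnames(contacts) <- list(compound_ids, residues)
  out <- list(compound_ids = as.character(compound_ids),
              residues = as.character(residues), contacts = contacts,
              docking_score = docking_score, n_heavy_atoms = n_heavy_atoms,
              labels = labels)
  class(out) <- "contact_matrix"
  out
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix: %d compounds x %d residues%s>\n",
              nrow(x$contacts), ncol(x$contacts),
              if (!is.null(x$labels)) ", labelled" else ""))
  invisible(x)
}

#' Per-residue contact frequency
#'
#' @param cm a `contact_matrix`.
#' @return named numeric vector: fraction of compounds contacting each
#'   residue.
#' @export
contact_frequency <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"), nrow(cm$contacts) > 0)
  colMeans(cm$contacts)
}

#' Select the N most frequently contacted residues
#'
#' Ties are broken by ascending residue sequence number (the trailing integer
#' of the residue label), then by label order.
#'
#' @param frequencies named frequency vector from [contact_frequency()].
#' @param N subset size; must not exceed the number of residues.
#' @return character vector of N residue labels, ordered by decreasing
#'   frequency.
#' @export
select_top_residues <- function(frequencies, N) {
  if (N > length(frequencies)) stop("N exceeds the number of residues")
  seqnum <- suppressWarnings(
    as.integer(sub(".*?([0-9]+)$", "\\1", names(frequencies))))
  seqnum[is.na(seqnum)] <- seq_along(frequencies)[is.na(seqnum)]
  ord <- order(-frequencies, seqnum, names(frequencies))
  names(frequencies)[ord][seq_len(N)]
}

#' PLIF similarity between two contact profiles over a residue subset
#'
#' Tanimoto coefficient of the subset-restricted contact sets; defined as 0
#' when both restricted profiles are empty.
#'
#' @param profile_a,profile_b named binary vectors over residue labels.
#' @param subset residue labels to restrict to (default: all shared labels).
#' @return similarity in [0, 1].
#' @export
plif_similarity <- function(profile_a, profile_b,
                            subset = intersect(names(profile_a),
                                               names(profile_b))) {
  missing_a <- setdiff(subset, names(profile_a))
  missing_b <- setdiff(subset, names(profile_b))
  if (length(missing_a) || length(missing_b))
    stop("subset residues absent from a profile: ",
         paste(unique(c(missing_a, missing_b)), collapse = ", "))
  tanimoto(profile_a[subset], profile_b[subset])
}

#' PLIF similarity of every compound to a reference profile
#'
#' @param cm a `contact_matrix`.
#' @param reference named binary vector (the X-ray ligand's contacts) over at
#'   least the subset residues.
#' @param subset residue labels used for the similarity (default: all
#'   residues of `cm`).
#' @return named numeric vector, one similarity per compound.
#' @export
plif_similarity_all <- function(cm, reference, subset = cm$residues) {
  stopifnot(inherits(cm, "contact_matrix"))
  vapply(seq_len(nrow(cm$contacts)), function(i) {
    prof <- cm$contacts[i, ]
    plif_similarity(prof, reference, subset = subset)
  }, numeric(1)) -> sims
  names(sims) <- cm$compound_ids
  sims
}

#' Ligand efficiency
#'
#' Docking score divided by the number of heavy atoms.
#'
#' @param score docking score (lower = better).
#' @param n_heavy positive heavy-atom count.
#' @export
ligand_efficiency <- function(score, n_heavy) {
  if (any(n_heavy < 1)) stop("n_heavy must be >= 1")
  score / n_heavy
}

#' Enrichment / coverage curve of a ranking function
#'
#' At each threshold t the selected set is `value >= t` (higher_better) or
#' `value <= t` (lower_better); enrichment is the percentage of strict
#' actives among selected compounds (moderates count against enrichment) and
#' coverage the number selected. Thresholds selecting nothing are flagged
#' undefined.
#'
#' @param values numeric per compound (similarity or score).
#' @param labels activity classes aligned with `values`.
#' @param thresholds ascending threshold grid (default 0 to 1 by 0.1).
#' @param direction `"higher_better"` (similarity) or `"lower_better"`
#'   (docking score).
#' @return object of class `enrichment_curve`: data.frame with `threshold`,
#'   `enrichment_pct`, `coverage`, `defined`.
#' @export
enrichment_curve <- function(values, labels,
                             thresholds = seq(0, 1, by = 0.1),
                             direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(labels))
  active <- as.character(labels) == "active"
  if (!any(active)) warning("no active compounds in the dataset")
  rows <- lapply(thresholds, function(t) {
    sel <- if (direction == "higher_better") values >= t else values <= t
    cov <- sum(sel)
    enr <- if (cov > 0) 100 * sum(active & sel) / cov else NA_real_
    data.frame(threshold = t, enrichment_pct = enr, coverage = cov,
               defined = cov > 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_curve", "data.frame")
  attr(out, "direction") <- direction
  attr(out, "base_rate_pct") <- 100 * mean(active)
  out
}

#' Summary diagnostics of an enrichment curve
#'
#' Reports the maximum enrichment, the threshold at which it is attained
#' (first occurrence on ties), the coverage there, and the number and depth
#' of non-monotone drops along the defined part of the curve — the quantities
#' used to choose among candidate screening functions.
#'
#' @param curve an `enrichment_curve`.
#' @return list with `max_enrichment_pct`, `threshold_at_max`,
#'   `coverage_at_max`, `n_drops`, `max_drop_depth`, `drops` (data.frame).
#' @export
curve_diagnostics <- function(curve) {
  stopifnot(inherits(curve, "enrichment_curve"), nrow(curve) > 0)
  def <- curve[curve$defined, , drop = FALSE]
  if (!nrow(def)) {
    return(list(max_enrichment_pct = NA_real_, threshold_at_max = NA_real_,
                coverage_at_max = NA_integer_, n_drops = 0L,
                max_drop_depth = 0, drops = data.frame()))
  }
  i <- which.max(def$enrichment_pct)  # first occurrence wins ties
  e <- def$enrichment_pct
  d <- diff(e)
  drop_idx <- which(d < 0)
  drops <- data.frame(from_threshold = def$threshold[drop_idx],
                      to_threshold = def$threshold[drop_idx + 1],
                      depth = -d[drop_idx])
  list(max_enrichment_pct = def$enrichment_pct[i],
       threshold_at_max = def$threshold[i],
       coverage_at_max = def$coverage[i],
       n_drops = length(drop_idx),
       max_drop_depth = if (length(drop_idx)) max(-d[drop_idx]) else 0,
       drops = drops)
}

#' Dual-target interval criterion
#'
#' Encodes a rule of the form `lower_a < sim_a <= upper_a AND sim_b >=
#' lower_b` with explicit inclusivity flags. The default reproduces the
#' screening rule `0.8 < sim_A <= 0.9 and sim_B >= 0.9`.
#'
#' @param lower_a,upper_a interval bounds on target A's similarity.
#' @param lower_b lower bound on target B's similarity.
#' @param incl_lower_a,incl_upper_a,incl_lower_b inclusivity of each bound.
#' @export
dual_criterion <- function(lower_a = 0.8, upper_a = 0.9, lower_b = 0.9,
                           incl_lower_a = FALSE, incl_upper_a = TRUE,
                           incl_lower_b = TRUE) {
  stopifnot(lower_a < upper_a)
  out <- list(lower_a = lower_a, upper_a = upper_a, lower_b = lower_b,
              incl_lower_a = incl_lower_a, incl_upper_a = incl_upper_a,
              incl_lower_b = incl_lower_b)
  class(out) <- "dual_criterion"
  out
}

#' Select dual-target hits
#'
#' Applies the interval criterion to per-compound similarities against two
#' targets. Compounds present in only one map are excluded with a warning.
#'
#' @param sims_a,sims_b named similarity vectors (target A and B).
#' @param criterion a [dual_criterion()].
#' @return data.frame (Table-1 shape) with `compound_id`, `sim_a`, `sim_b`
#'   for every hit.
#' @export
select_dual_hits <- function(sims_a, sims_b, criterion = dual_criterion()) {
  stopifnot(inherits(criterion, "dual_criterion"))
  common <- intersect(names(sims_a), names(sims_b))
  missing <- union(setdiff(names(sims_a), common),
                   setdiff(names(sims_b), common))
  if (length(missing))
    warning("compounds missing from one similarity map: ",
            paste(missing, collapse = ", "))
  a <- sims_a[common]; b <- sims_b[common]
  ok_lo <- if (criterion$incl_lower_a) a >= criterion$lower_a else
    a > criterion$lower_a
  ok_hi <- if (criterion$incl_upper_a) a <= criterion$upper_a else
    a < criterion$upper_a
  ok_b <- if (criterion$incl_lower_b) b >= criterion$lower_b else
    b > criterion$lower_b
  hit <- ok_lo & ok_hi & ok_b
  data.frame(compound_id = common[hit], sim_a = unname(a[hit]),
             sim_b = unname(b[hit]), stringsAsFactors = FALSE)
}

#' Read / write a contact matrix as delimited text
#'
#' Format: tab-separated, first column `compound_id`, remaining columns one
#' per residue label; optional `docking_score`, `n_heavy_atoms` and `label`
#' columns are recognised on read and emitted on write when present.
#'
#' @param cm a `contact_matrix` (for writing).
#' @param path file path.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  df <- data.frame(compound_id = cm$compound_ids, cm$contacts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cm$docking_score)) df$docking_score <- cm$docking_score
  if (!is.null(cm$n_heavy_atoms)) df$n_heavy_atoms <- cm$n_heavy_atoms
  if (!is.null(cm$labels)) df$label <- as.character(cm$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  special <- c("compound_id", "docking_score", "n_heavy_atoms", "label")
  res_cols <- setdiff(names(df), special)
  contact_matrix(
    as.matrix(df[, res_cols, drop = FALSE]),
    compound_ids = df$compound_id, residues = res_cols,
    docking_score = if ("docking_score" %in% names(df)) df$docking_score,
    n_heavy_atoms = if ("n_heavy_atoms" %in% names(df)) df$n_heavy_atoms,
    labels = if ("label" %in% names(df)) df$label)
}
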