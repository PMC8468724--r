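# ---------------------------------------------------------------------------
# Bioactivity curation: record-level filters, unit normalisation to nM,
# structure-keyed deduplication (minimum activity kept) and three-class
# activity binning (active < 1 uM, inactive > 10 uM, moderate between).
# ---------------------------------------------------------------------------

.unit_factors <- c(m = 1e9, mm = 1e6, um = 1e3, nm = 1, pm = 1e-3)

.normalise_unit <- function(units) {
  u <- tolower(trimws(units))
  u <- gsub("µ|μ", "u", u)  # micro-sign dialects -> "u"
  u
}

#' Convert a concentration to nanomolar
#'
#' @param value positive numeric value(s).
#' @param units unit string(s); one of M, mM, uM (also written with a micro
#'   sign), nM, pM, case-insensitive.
#' @return value expressed in nM.
#' @export
convert_to_nM <- function(value, units) {
  u <- .normalise_unit(units)
  f <- .unit_factors[u]
  if (any(is.na(f))) {
    bad <- unique(units[is.na(f)])
    stop("cannot convert units to nM: ", paste(bad, collapse = ", "))
  }
  unname(value * f)
}

.is_convertible_unit <- function(units) {
  .normalise_unit(units) %in% names(.unit_factors)
}

.filter_rules <- c("empty_value", "unparseable", "relation_censored",
                   "type_excluded", "empty_units", "units_not_convertible",
                   "low_confidence")

#' Filter raw bioactivity records
#'
#' Applies, in a fixed documented order, the record-level exclusion rules:
#' empty standard value; unparseable value; censored relation (">" or ">=");
#' excluded standard types (FC, Ratio); empty units; units not convertible to
#' nM; confidence score below `min_confidence`. A record is charged to the
#' first rule it violates. Relations "<" and "<=" are retained as stated
#' values.
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `standard_type`, `standard_relation`, `standard_value`,
#'   `standard_units`, `confidence_score` (and optionally `target_id`).
#' @param min_confidence minimum ChEMBL-style confidence score (default 8).
#' @return list with `records` (surviving rows, with numeric
#'   `standard_value`) and `log` (named integer vector of per-rule rejection
#'   counts plus `kept`).
#' @export
filter_records <- function(records, min_confidence = 8) {
  need <- c("compound_id", "smiles", "standard_type", "standard_relation",
            "standard_value", "standard_units", "confidence_score")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  raw_val <- records$standard_value
  empty_val <- is.na(raw_val) | !nzchar(trimws(as.character(raw_val)))
  val <- suppressWarnings(as.numeric(as.character(raw_val)))
  unparseable <- !empty_val & (is.na(val) | !is.finite(val) | val < 0)

  rel <- trimws(as.character(records$standard_relation))
  censored <- rel %in% c(">", ">=", "≥")

  type <- toupper(trimws(as.character(records$standard_type)))
  type_bad <- type %in% c("FC", "RATIO")

  units <- as.character(records$standard_units)
  empty_units <- is.na(units) | !nzchar(trimws(units))
  not_conv <- !empty_units & !.is_convertible_unit(units)

  conf <- suppressWarnings(as.numeric(records$confidence_score))
  low_conf <- is.na(conf) | conf < min_confidence

  rules <- list(empty_value = empty_val, unparseable = unparseable,
                relation_censored = censored, type_excluded = type_bad,
                empty_units = empty_units, units_not_convertible = not_conv,
                low_confidence = low_conf)
  for (r in .filter_rules) {
    hit <- rules[[r]] & is.na(reason)
    reason[hit] <- r
  }
  kept <- records[is.na(reason), , drop = FALSE]
  kept$standard_value <- val[is.na(reason)]
  log <- vapply(.filter_rules, function(r) sum(reason == r, na.rm = TRUE),
                integer(1))
  log <- c(log, kept = nrow(kept))
  list(records = kept, log = log,
       rejected = data.frame(compound_id = records$compound_id[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE))
}

#' Assign the three-class activity label
#'
#' Active strictly below 1000 nM (1 uM), inactive strictly above 10000 nM
#' (10 uM), moderate otherwise (boundaries fall in the middle class).
#'
#' @param activity_nM positive activity value(s) in nM.
#' @return factor with levels active, moderate, inactive.
#' @export
assign_activity_class <- function(activity_nM) {
  if (any(is.na(activity_nM)) || any(activity_nM <= 0))
    stop("activity_nM must be positive")
  cls <- ifelse(activity_nM < 1000, "active",
                ifelse(activity_nM > 10000, "inactive", "moderate"))
  factor(cls, levels = c("active", "moderate", "inactive"))
}

#' Deduplicate curated activities by canonical structure, keeping the minimum
#'
#' When several measurements map to the same canonical structure the smallest
#' activity value is kept; the readout (e.g. IC50 or Ki) of the kept value
#' and the group size are recorded.
#'
#' @param df data.frame with columns `compound_id`, `canonical_structure`,
#'   `activity_nM` and optionally `readout`.
#' @return data.frame of unique compounds with columns `compound_id`,
#'   `canonical_structure`, `activity_nM`, `readout`, `n_measurements`.
#'   Groups without any valid activity are dropped; dropped keys are listed
#'   in `attr(, "dropped")`.
#' @export
deduplicate_min <- function(df) {
  stopifnot(all(c("compound_id", "canonical_structure", "activity_nM")
                %in% names(df)))
  if (!"readout" %in% names(df)) df$readout <- NA_character_
  keys <- unique(df$canonical_structure)
  rows <- vector("list", length(keys))
  dropped <- character(0)
  for (i in seq_along(keys)) {
    g <- df[df$canonical_structure == keys[i], , drop = FALSE]
    ok <- is.finite(g$activity_nM)
    if (!any(ok)) { dropped <- c(dropped, keys[i]); next }
    g <- g[ok, , drop = FALSE]
    j <- which.min(g$activity_nM)
    rows[[i]] <- data.frame(compound_id = g$compound_id[j],
                            canonical_structure = keys[i],
                            activity_nM = g$activity_nM[j],
                            readout = g$readout[j],
                            n_measurements = sum(ok),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(compound_id = character(0),
                      canonical_structure = character(0),
                      activity_nM = numeric(0), readout = character(0),
                      n_measurements = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Curate a raw bioactivity table end to end
#'
#' Filters records, converts activities to nM, canonicalises structures
#' (largest component, charges neutralised) as the duplicate key,
#' deduplicates keeping the minimum activity, and assigns the three-class
#' activity label.
#'
#' @param records raw record data.frame (see [filter_records()]).
#' @param min_confidence minimum confidence score (default 8).
#' @return list with `compounds` (curated table: `compound_id`,
#'   `canonical_structure`, `activity_nM`, `activity_class`, `readout`,
#'   `n_measurements`) and `report` (per-rule rejection counts, structure
#'   failures, duplicate statistics, class counts).
#' @export
curate_bioactivity <- function(records, min_confidence = 8) {
  flt <- filter_records(records, min_confidence = min_confidence)
  kept <- flt$records
  if (nrow(kept) == 0) {
    return(list(compounds = deduplicate_min(
      data.frame(compound_id = character(0),
                 canonical_structure = character(0),
                 activity_nM = numeric(0))),
      report = list(filter = as.list(flt$log), bad_structures = character(0),
                    n_duplicate_groups = 0L, class_counts = c(
                      active = 0L, moderate = 0L, inactive = 0L))))
  }
  kept$activity_nM <- convert_to_nM(kept$standard_value, kept$standard_units)
  key <- canonical_smiles(kept$smiles, strip_salt = TRUE, neutralize = TRUE)
  bad <- is.na(key)
  bad_ids <- kept$compound_id[bad]
  kept <- kept[!bad, , drop = FALSE]
  key <- key[!bad]
  dedup <- deduplicate_min(data.frame(
    compound_id = kept$compound_id, canonical_structure = key,
    activity_nM = kept$activity_nM, readout = kept$standard_type,
    stringsAsFactors = FALSE))
  dedup$activity_class <- assign_activity_class(dedup$activity_nM)
  cls <- table(dedup$activity_class)
  report <- list(
    filter = as.list(flt$log),
    bad_structures = bad_ids,
    n_input = nrow(records),
    n_curated = nrow(dedup),
    n_duplicate_groups = sum(dedup$n_measurements > 1),
    class_counts = as.list(cls)
  )
  list(compounds = dedup[, c("compound_id", "canonical_structure",
                             "activity_nM", "activity_class", "readout",
                             "n_measurements")],
       report = report)
}

#' Read a raw bioactivity table from delimited text
#'
#' Accepts comma- or tab-separated files with a header naming the ChEMBL
#' export fields.
#'
#' @param path file path.
#' @export
read_bioactivity <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, quote = "\"",
             stringsAsFactors = FALSE, comment.char = "")
}

#' Write a curated compound table and JSON curation report
#'
#' @param curated result of [curate_bioactivity()].
#' @param path output path for the delimited compound table.
#' @param report_path optional output path for the JSON report.
#' @export
write_curated <- function(curated, path, report_path = NULL) {
  write.table(curated$compounds, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(curated$report, report_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
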