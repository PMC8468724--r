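# Bioactivity curation: unit conversion, filtering, dedup, class binning.

make_record <- function(...) {
  base <- list(compound_id = "X1", smiles = "c1ccccc1",
               standard_value = "100", standard_units = "nM",
               standard_relation = "=", standard_type = "IC50",
               confidence_score = 9)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

test_that("unit conversion to nM is exact for all supported units", {
  expect_equal(convert_to_nM(1, "M"), 1e9)
  expect_equal(convert_to_nM(1, "mM"), 1e6)
  expect_equal(convert_to_nM(1, "uM"), 1e3)
  expect_equal(convert_to_nM(1, "µM"), 1e3)  # micro sign
  expect_equal(convert_to_nM(1, "nM"), 1)
  expect_equal(convert_to_nM(1, "pM"), 1e-3)
  expect_equal(convert_to_nM(2.5, "uM"), 2500)
})

test_that("unit conversion round-trips within 1e-9 relative error", {
  vals <- c(0.001, 0.5, 1, 123.456, 1e6)
  for (v in vals) {
    nm <- convert_to_nM(v, "uM")
    back <- nm / 1e3
    expect_lt(abs(back - v) / v, 1e-9)
  }
})

test_that("unknown units raise an error naming the unit", {
  expect_error(convert_to_nM(1, "mg/mL"), "mg/mL")
  expect_error(convert_to_nM(1, "%"), "%")
})

test_that("each filter rule rejects its violation and logs it once", {
  recs <- rbind(
    make_record(compound_id = "ok"),
    make_record(compound_id = "v1", standard_value = ""),
    make_record(compound_id = "v2", standard_value = "abc"),
    make_record(compound_id = "v3", standard_relation = ">"),
    make_record(compound_id = "v4", standard_type = "FC"),
    make_record(compound_id = "v5", standard_units = ""),
    make_record(compound_id = "v6", standard_units = "mg/mL"),
    make_record(compound_id = "v7", confidence_score = 7))
  res <- filter_records(recs)
  expect_equal(res$log[["empty_value"]], 1L)
  expect_equal(res$log[["unparseable"]], 1L)
  expect_equal(res$log[["relation_censored"]], 1L)
  expect_equal(res$log[["type_excluded"]], 1L)
  expect_equal(res$log[["empty_units"]], 1L)
  expect_equal(res$log[["units_not_convertible"]], 1L)
  expect_equal(res$log[["low_confidence"]], 1L)
  expect_equal(res$log[["kept"]], 1L)
  expect_equal(res$records$compound_id, "ok")
})

test_that("greater-or-equal relations are censored like strict greater", {
  recs <- rbind(make_record(standard_relation = ">"),
                make_record(standard_relation = ">="))
  res <- filter_records(recs)
  expect_equal(res$log[["relation_censored"]], 2L)
})

test_that("filtering is idempotent", {
  gb <- gen_bioactivity_table(33)
  once <- filter_records(gb$records)
  twice <- filter_records(once$records)
  expect_equal(nrow(once$records), nrow(twice$records))
  expect_equal(twice$log[["kept"]], once$log[["kept"]])
  expect_true(all(unlist(twice$log[setdiff(names(twice$log), "kept")]) == 0))
})

test_that("activity classes respect strict thresholds at the boundaries", {
  cls <- assign_activity_class(c(999, 1000, 10000, 10001))
  expect_equal(as.character(cls),
               c("active", "moderate", "moderate", "inactive"))
})

test_that("class assignment is monotone in activity value", {
  vals <- sort(10^runif(200, -1, 6))
  cls <- as.integer(assign_activity_class(vals))  # active < moderate < inactive
  expect_true(all(diff(cls) >= 0))
})

test_that("non-positive activities are rejected", {
  expect_error(assign_activity_class(c(100, 0)))
  expect_error(assign_activity_class(-5))
})

test_that("deduplication keeps the minimum activity per structure", {
  df <- data.frame(compound_id = paste0("c", 1:5),
                   canonical_structure = c("a", "a", "b", "a", "b"),
                   activity_nM = c(50, 10, 700, 30, 900),
                   stringsAsFactors = FALSE)
  out <- deduplicate_min(df)
  expect_equal(nrow(out), 2)
  expect_equal(out$activity_nM[out$canonical_structure == "a"], 10)
  expect_equal(out$activity_nM[out$canonical_structure == "b"], 700)
  expect_equal(out$n_measurements[out$canonical_structure == "a"], 3L)
})

test_that("salt forms and neutral parents deduplicate to one compound", {
  # benzoic acid, its sodium salt, and its carboxylate anion
  smis <- c("OC(=O)c1ccccc1", "[Na+].[O-]C(=O)c1ccccc1",
            "[O-]C(=O)c1ccccc1")
  keys <- vapply(smis, function(s)
    canonical_smiles(s, strip_salt = TRUE, neutralize = TRUE), character(1),
    USE.NAMES = FALSE)
  expect_equal(length(unique(keys)), 1L)
})

test_that("curation pipeline recovers the planted truth end to end", {
  for (seed in c(1, 77)) {
    gb <- gen_bioactivity_table(seed)
    cur <- curate_bioactivity(gb$records)
    for (rule in names(gb$truth$violations))
      expect_equal(cur$report$filter[[rule]],
                   unname(gb$truth$violations[rule]))
    expect_equal(cur$report$n_curated, gb$truth$n_surviving)
    cc <- table(cur$compounds$activity_class)
    expect_equal(unname(cc[["active"]]),
                 unname(gb$truth$class_counts[["active"]]))
    expect_equal(unname(cc[["moderate"]]),
                 unname(gb$truth$class_counts[["moderate"]]))
    expect_equal(unname(cc[["inactive"]]),
                 unname(gb$truth$class_counts[["inactive"]]))
  }
})

test_that("curated table round-trips through disk", {
  gb <- gen_bioactivity_table(4)
  cur <- curate_bioactivity(gb$records)
  f <- tempfile(fileext = ".tsv")
  write_curated(cur, f)
  back <- read_bioactivity(f)
  expect_equal(nrow(back), nrow(cur$compounds))
  expect_equal(back$activity_nM, cur$compounds$activity_nM)
})
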