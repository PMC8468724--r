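# Three-class decision-tree QSAR: splitting, weighting, tuning, metrics,
# cross-application with applicability domain.

test_that("confusion-matrix metrics match hand-computed values", {
  conf <- matrix(0, 3, 3,
                 dimnames = list(c("active", "moderate", "inactive"),
                                 c("active", "moderate", "inactive")))
  conf["active", "active"] <- 9       # TP
  conf["moderate", "active"] <- 1     # FP for active
  conf["active", "moderate"] <- 3     # FN for active
  m <- metrics_from_confusion(conf)
  a <- m$per_class[m$per_class$class == "active", ]
  expect_equal(a$precision, 0.9, tolerance = 1e-12)
  expect_equal(a$recall, 0.75, tolerance = 1e-12)
  expect_equal(a$F1, 2 * 0.9 * 0.75 / (0.9 + 0.75), tolerance = 1e-12)
  expect_equal(m$accuracy, 9 / 13)
})

test_that("a never-predicted class has NA precision and is flagged", {
  conf <- matrix(c(5, 0, 0,
                   2, 0, 0,
                   1, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("active", "moderate", "inactive"),
                                 c("active", "moderate", "inactive")))
  m <- metrics_from_confusion(conf)
  expect_true(all(c("moderate", "inactive") %in% m$undefined_precision))
  expect_true(is.na(m$per_class$precision[2]))
})

test_that("metrics are recomputable from the reported confusion matrix", {
  g <- gen_descriptor_table(19, separation = 3)
  sp <- split_train_test(g$data, seed = 19)
  rep <- fit_and_evaluate(sp$train, sp$test,
                          list(max_depth = 4, min_leaf = 10))
  again <- metrics_from_confusion(rep$confusion)
  expect_equal(again$accuracy, rep$accuracy)
  expect_equal(again$per_class$F1, rep$per_class$F1)
})

test_that("stratified split is disjoint, exhaustive and proportional", {
  g <- gen_descriptor_table(8)
  sp <- split_train_test(g$data, fraction = 0.8, seed = 8)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), seq_len(nrow(g$data)))
  expect_equal(length(intersect(sp$train_idx, sp$test_idx)), 0L)
  for (lv in levels(g$data$activity_class)) {
    frac <- sum(sp$train$activity_class == lv) /
      sum(g$data$activity_class == lv)
    expect_equal(frac, 0.8, tolerance = 0.02)
  }
})

test_that("splits are reproducible per seed and differ across seeds", {
  g <- gen_descriptor_table(8)
  s1 <- split_train_test(g$data, seed = 1)
  s2 <- split_train_test(g$data, seed = 1)
  s3 <- split_train_test(g$data, seed = 2)
  expect_equal(s1$train_idx, s2$train_idx)
  expect_false(identical(s1$train_idx, s3$train_idx))
})

test_that("balanced class weights are inverse to class frequency", {
  labels <- c(rep("active", 60), rep("moderate", 30), rep("inactive", 10))
  w <- class_weights("balanced", labels)$weights
  expect_equal(unname(w), 100 / (3 * c(60, 30, 10)))
  expect_lt(w[["active"]], w[["inactive"]])
})

test_that("well-separated classes are classified almost perfectly", {
  g <- gen_descriptor_table(42, separation = 5)
  sp <- split_train_test(g$data, seed = 42)
  rep <- fit_and_evaluate(sp$train, sp$test,
                          list(max_depth = 4, min_leaf = 10),
                          weights = class_weights("w111"))
  expect_gte(rep$accuracy, 0.95)
})

test_that("upweighting a class does not reduce its recall (majority of seeds)", {
  better <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    g <- gen_descriptor_table(seed, separation = 1,
                              n_active = 200, n_moderate = 100,
                              n_inactive = 60)
    sp <- split_train_test(g$data, seed = seed)
    params <- list(max_depth = 4, min_leaf = 10)
    r_flat <- fit_and_evaluate(sp$train, sp$test, params,
                               weights = class_weights("w111"))
    r_up <- fit_and_evaluate(sp$train, sp$test, params,
                             weights = class_weights("w1510"))
    rec <- function(r, cls)
      r$per_class$recall[r$per_class$class == cls]
    if (isTRUE(rec(r_up, "inactive") >= rec(r_flat, "inactive")))
      better <- better + 1L
  }
  expect_gt(better, n_seeds / 2)
})

test_that("tuning prefers the simpler model on ties", {
  g <- gen_descriptor_table(3, separation = 5)
  sp <- split_train_test(g$data, seed = 3)
  grid <- data.frame(max_depth = c(2, 10), min_leaf = c(20, 20))
  tuned <- tune_tree(sp$train, grid, k = 3, seed = 3)
  # both depths separate these classes; the shallower must win the tie
  if (abs(diff(tuned$grid_results$cv_macro_f1)) < 1e-12)
    expect_equal(tuned$max_depth, 2)
  expect_true(tuned$max_depth %in% grid$max_depth)
})

test_that("cross-application flags chemically dissimilar compounds", {
  g <- gen_descriptor_table(13, separation = 5, n_active = 40,
                            n_moderate = 40, n_inactive = 40)
  sp <- split_train_test(g$data, seed = 13)
  rep <- fit_and_evaluate(sp$train, sp$test,
                          list(max_depth = 3, min_leaf = 5))
  fps_train <- morgan_fp(toy_smiles_library(10, seed = 1))
  # identical library: in domain; disjoint chemistry: out of domain
  fps_same <- morgan_fp(toy_smiles_library(5, seed = 1))
  desc_b <- sp$test[seq_len(5), setdiff(names(sp$test), "activity_class")]
  res_same <- cross_apply(rep, desc_b, fps_train, fps_same)
  expect_true(all(res_same$in_domain))
  expect_true(all(res_same$predicted_class %in%
                    c("active", "moderate", "inactive")))
})

test_that("cross-application rejects a mismatched descriptor schema", {
  g <- gen_descriptor_table(14, n_descriptors = 20)
  sp <- split_train_test(g$data, seed = 14)
  rep <- fit_and_evaluate(sp$train, sp$test,
                          list(max_depth = 3, min_leaf = 5))
  fps <- morgan_fp(toy_smiles_library(3, seed = 1))
  bad <- data.frame(Z1 = rnorm(3), Z2 = rnorm(3))
  expect_error(cross_apply(rep, bad, fps, fps), "schema")
})
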