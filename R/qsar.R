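# ---------------------------------------------------------------------------
# Three-class decision-tree QSAR harness: stratified splitting, k-fold
# hyperparameter tuning (max depth, min leaf size), class-weighted fitting,
# confusion-matrix metrics, and cross-application between datasets with
# applicability-domain flagging. The tree engine is rpart; class weights are
# applied as per-case weights, and the metric layer is computed here from
# first principles.
# ---------------------------------------------------------------------------

.activity_levels <- c("active", "moderate", "inactive")

# evaluate code under a temporary RNG seed, restoring global RNG state after
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Class-weight schemes for three-class models
#'
#' Named schemes: `"balanced"` (inverse class frequency, n / (k * n_c)),
#' `"w111"` (1:1:1), `"w122"` (1:2:2), `"w125"` (1:2:5), `"w1510"` (1:5:10),
#' in class order active : moderate : inactive.
#'
#' @param scheme scheme name.
#' @param labels class labels of the training set (required for
#'   `"balanced"`).
#' @return object of class `class_weights`: list with `scheme` and `weights`
#'   (named positive numeric over the three classes).
#' @export
class_weights <- function(scheme = c("balanced", "w111", "w122", "w125",
                                     "w1510"),
                          labels = NULL) {
  scheme <- match.arg(scheme)
  fixed <- list(w111 = c(1, 1, 1), w122 = c(1, 2, 2), w125 = c(1, 2, 5),
                w1510 = c(1, 5, 10))
  if (scheme == "balanced") {
    if (is.null(labels)) stop("'balanced' weights need the training labels")
    cnt <- table(factor(as.character(labels), levels = .activity_levels))
    if (any(cnt == 0)) stop("'balanced' weights need all three classes")
    w <- sum(cnt) / (length(cnt) * as.numeric(cnt))
  } else {
    w <- fixed[[scheme]]
  }
  names(w) <- .activity_levels
  out <- list(scheme = scheme, weights = w)
  class(out) <- "class_weights"
  out
}

#' Stratified train/test split
#'
#' Disjoint and exhaustive; stratified by activity class by default so class
#' proportions are preserved within rounding; deterministic per seed.
#'
#' @param dataset data.frame with an `activity_class` column.
#' @param fraction training fraction (default 0.8).
#' @param seed integer RNG seed (mandatory).
#' @param stratified stratify by class (default TRUE).
#' @return list with `train` and `test` data.frames and the corresponding
#'   row indices `train_idx`, `test_idx`.
#' @export
split_train_test <- function(dataset, fraction = 0.8, seed, stratified = TRUE) {
  stopifnot("activity_class" %in% names(dataset), fraction > 0, fraction < 1)
  cls <- as.character(dataset$activity_class)
  train_idx <- .with_seed(seed, {
    if (stratified) {
      idx <- integer(0)
      for (lv in unique(cls)) {
        rows <- which(cls == lv)
        if (length(rows) < 2)
          stop("class '", lv, "' has fewer than 2 members; cannot stratify")
        n_tr <- max(1L, round(fraction * length(rows)))
        if (n_tr == length(rows)) n_tr <- length(rows) - 1L
        idx <- c(idx, sample(rows, n_tr))
      }
      sort(idx)
    } else {
      sort(sample(nrow(dataset), round(fraction * nrow(dataset))))
    }
  })
  test_idx <- setdiff(seq_len(nrow(dataset)), train_idx)
  list(train = dataset[train_idx, , drop = FALSE],
       test = dataset[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

.fit_tree <- function(train, max_depth, min_leaf, weights = NULL) {
  y <- factor(as.character(train$activity_class), levels = .activity_levels)
  x <- train[, setdiff(names(train), "activity_class"), drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(train)) else
    unname(weights$weights[as.character(y)])
  df <- data.frame(activity_class = y, x, check.names = FALSE)
  rpart::rpart(activity_class ~ ., data = df, weights = w, method = "class",
               control = rpart::rpart.control(maxdepth = max_depth,
                                              minbucket = min_leaf,
                                              minsplit = max(2L, min_leaf),
                                              cp = 0, xval = 0))
}

.predict_tree <- function(fit, newdata) {
  x <- newdata[, setdiff(names(newdata), "activity_class"), drop = FALSE]
  factor(as.character(predict(fit, newdata = x, type = "class")),
         levels = .activity_levels)
}

#' Metrics derived from a 3x3 confusion matrix
#'
#' Rows are true classes, columns predicted classes. Per class c:
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean,
#' one-vs-rest accuracy = (TP+TN)/total. Overall accuracy is
#' trace / total. A class never predicted has undefined (NA) precision,
#' flagged rather than forced to 0.
#'
#' @param confusion square integer matrix with identical row/col names.
#' @return list with `per_class` data.frame (`class`, `n`, `precision`,
#'   `recall`, `F1`, `accuracy_ovr`), `accuracy`, and
#'   `undefined_precision` (classes with no predictions).
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  total <- sum(confusion)
  classes <- rownames(confusion)
  per <- lapply(seq_along(classes), function(i) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(class = classes[i], n = tp + fn, precision = prec,
               recall = rec, F1 = f1,
               accuracy_ovr = (tp + tn) / total,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_class = per,
       accuracy = sum(diag(confusion)) / total,
       undefined_precision = per$class[is.na(per$precision)])
}

.macro_f1 <- function(truth, pred) {
  cm <- table(truth, pred)
  m <- metrics_from_confusion(cm)
  f1 <- m$per_class$F1
  f1[is.na(f1)] <- 0  # undefined F1 scored as 0 during tuning
  mean(f1)
}

#' Tune decision-tree hyperparameters by stratified k-fold cross-validation
#'
#' Selects the (max_depth, min_leaf) pair maximising mean CV macro-F1; ties
#' are broken toward the simpler model (smaller depth, then larger leaf). If
#' k exceeds the smallest class count, k is reduced with a warning.
#'
#' @param train training data.frame (`activity_class` + numeric features).
#' @param grid data.frame with columns `max_depth`, `min_leaf`.
#' @param k number of folds (default 10).
#' @param seed integer RNG seed for the fold assignment.
#' @param weights optional [class_weights()] used during CV fits.
#' @return list with `max_depth`, `min_leaf`, `cv_macro_f1`, and the full
#'   `grid_results` table.
#' @export
tune_tree <- function(train, grid, k = 10, seed, weights = NULL) {
  stopifnot(nrow(train) > 0, nrow(grid) > 0,
            all(c("max_depth", "min_leaf") %in% names(grid)))
  y <- factor(as.character(train$activity_class), levels = .activity_levels)
  min_cls <- min(table(droplevels(y)))
  if (k > min_cls) {
    warning("k reduced from ", k, " to ", min_cls,
            " (smallest class count)")
    k <- max(2L, min_cls)
  }
  folds <- .with_seed(seed, {
    f <- integer(length(y))
    for (lv in levels(droplevels(y))) {
      rows <- which(y == lv)
      f[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    f
  })
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    per_fold <- vapply(seq_len(k), function(fold) {
      tr <- train[folds != fold, , drop = FALSE]
      te <- train[folds == fold, , drop = FALSE]
      if (!nrow(te)) return(NA_real_)
      fit <- .fit_tree(tr, grid$max_depth[g], grid$min_leaf[g], weights)
      .macro_f1(factor(as.character(te$activity_class),
                       levels = .activity_levels),
                .predict_tree(fit, te))
    }, numeric(1))
    mean(per_fold, na.rm = TRUE)
  }, numeric(1))
  res <- cbind(grid, cv_macro_f1 = scores)
  ord <- order(-res$cv_macro_f1, res$max_depth, -res$min_leaf)
  best <- res[ord[1], ]
  list(max_depth = best$max_depth, min_leaf = best$min_leaf,
       cv_macro_f1 = best$cv_macro_f1, grid_results = res)
}

#' Fit a weighted decision tree and evaluate it on a test set
#'
#' @param train,test data.frames with identical feature columns and an
#'   `activity_class` column.
#' @param params list with `max_depth` and `min_leaf` (e.g. from
#'   [tune_tree()]).
#' @param weights a [class_weights()] object (default 1:1:1).
#' @param seed optional seed recorded in the report (fitting itself is
#'   deterministic).
#' @return object of class `model_report`: confusion matrix (rows = truth),
#'   per-class metrics, overall accuracy, chosen hyperparameters, weight
#'   scheme, the fitted model (`fit`), and `undefined_precision` flags.
#' @export
fit_and_evaluate <- function(train, test, params,
                             weights = class_weights("w111"), seed = NA) {
  f_tr <- setdiff(names(train), "activity_class")
  f_te <- setdiff(names(test), "activity_class")
  if (!identical(sort(f_tr), sort(f_te)))
    stop("feature columns differ between train and test: ",
         paste(union(setdiff(f_tr, f_te), setdiff(f_te, f_tr)),
               collapse = ", "))
  fit <- .fit_tree(train, params$max_depth, params$min_leaf, weights)
  truth <- factor(as.character(test$activity_class),
                  levels = .activity_levels)
  pred <- .predict_tree(fit, test)
  confusion <- table(truth = truth, predicted = pred)
  m <- metrics_from_confusion(confusion)
  out <- list(confusion = unclass(confusion), per_class = m$per_class,
              accuracy = m$accuracy,
              undefined_precision = m$undefined_precision,
              max_depth = params$max_depth, min_leaf = params$min_leaf,
              weight_scheme = weights$scheme, weights = weights$weights,
              seed = seed, fit = fit)
  class(out) <- "model_report"
  out
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("Decision-tree model report (depth %d, min leaf %d, weights %s)\n",
              x$max_depth, x$min_leaf, x$weight_scheme))
  tab <- x$per_class
  tab$precision <- round(tab$precision, 2)
  tab$recall <- round(tab$recall, 2)
  tab$F1 <- round(tab$F1, 2)
  tab$accuracy_ovr <- NULL
  print(tab, row.names = FALSE)
  cat(sprintf("Overall accuracy: %.2f\n", x$accuracy))
  invisible(x)
}

#' Serialise a fitted tree as a portable rule list
#'
#' @param report a `model_report` (or an rpart fit).
#' @return character vector, one line per node rule.
#' @export
tree_rules <- function(report) {
  fit <- if (inherits(report, "model_report")) report$fit else report
  utils::capture.output(print(fit))
}

#' Apply a model trained on one dataset to another, with domain flagging
#'
#' Predicts the class of every compound of dataset B with a model trained on
#' dataset A and flags compounds as outside the applicability domain when
#' their maximum Tanimoto similarity to A's training compounds falls below
#' `ad_threshold` (default 0.3, the similarity level below which two
#' inhibitor sets are considered chemically disjoint).
#'
#' @param report `model_report` trained on dataset A.
#' @param descriptors_b data.frame of B's descriptors (same schema as A's).
#' @param fps_train `fingerprint_set` of A's training compounds.
#' @param fps_b `fingerprint_set` of B's compounds (aligned with
#'   `descriptors_b` rows).
#' @param ad_threshold applicability-domain similarity threshold.
#' @return data.frame with `compound_id`, `predicted_class`,
#'   `max_similarity`, `in_domain`.
#' @export
cross_apply <- function(report, descriptors_b, fps_train, fps_b,
                        ad_threshold = 0.3) {
  stopifnot(inherits(report, "model_report"))
  needed <- setdiff(attr(report$fit$terms, "term.labels"),
                    names(descriptors_b))
  if (length(needed))
    stop("descriptor schema mismatch; missing: ",
         paste(needed, collapse = ", "))
  stopifnot(nrow(descriptors_b) == nrow(fps_b$bits))
  pred <- .predict_tree(report$fit, descriptors_b)
  maxsim <- cross_max_similarity(fps_b, fps_train)
  data.frame(compound_id = fps_b$compound_ids,
             predicted_class = as.character(pred),
             max_similarity = unname(maxsim),
             in_domain = unname(maxsim >= ad_threshold),
             stringsAsFactors = FALSE)
}
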