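# Random-forest pair classifier: balanced train/test splits, probability
# forests, threshold metrics, stratified k-fold cross-validation, and the
# control experiments (split resampling, class-label shuffling, tree-count
# sweep).

.label_col <- "label"

.feature_cols <- function(dataset) {
  grep("^z_", names(dataset), value = TRUE)
}

#' Draw a balanced, disjoint train/test split
#'
#' Randomly selects `n_train_per_class` and `n_test_per_class` pairs of each
#' class, without overlap; seeded and deterministic.
#'
#' @param dataset data.frame with a 0/1 `label` column and `z_*` feature
#'   columns (one row per labeled pair).
#' @param n_train_per_class,n_test_per_class Pairs per class in each split.
#' @param seed Integer seed.
#' @return List of class `dataset_split`: `train`, `test`, `seed`.
#' @export
sample_balanced_split <- function(dataset, n_train_per_class,
                                  n_test_per_class, seed = 1) {
  pos <- which(dataset[[.label_col]] == 1)
  neg <- which(dataset[[.label_col]] == 0)
  need <- n_train_per_class + n_test_per_class
  if (length(pos) < need || length(neg) < need) {
    stop("not enough labeled pairs for the requested split: need ", need,
         " per class, have ", length(pos), " positive and ", length(neg),
         " negative")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pos <- sample(pos)
  neg <- sample(neg)
  train_idx <- c(pos[seq_len(n_train_per_class)],
                 neg[seq_len(n_train_per_class)])
  test_idx <- c(pos[n_train_per_class + seq_len(n_test_per_class)],
                neg[n_train_per_class + seq_len(n_test_per_class)])
  structure(list(train = dataset[train_idx, , drop = FALSE],
                 test = dataset[test_idx, , drop = FALSE],
                 seed = seed),
            class = "dataset_split")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Train a probability random forest on pair features
#'
#' @param train data.frame with `label` and `z_*` columns.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @param drop_features Optional feature names to exclude (used by the
#'   leave-one-tissue-out ensemble).
#' @return Object of class `pair_forest` with elements `fit` (ranger),
#'   `features`, `n_trees`, `seed`, `importance` (Gini importances
#'   normalized to sum 1).
#' @export
train_forest <- function(train, n_trees = 100, seed = 1,
                         drop_features = character(0)) {
  features <- setdiff(.feature_cols(train), drop_features)
  if (length(features) == 0) stop("no features left to train on")
  y <- train[[.label_col]]
  if (length(unique(y)) < 2) {
    stop("training data contains a single class")
  }
  x <- train[, features, drop = FALSE]
  if (any(!is.finite(as.matrix(x)))) stop("non-finite feature values")
  df <- cbind(x, .pair_class = factor(y, levels = c(0, 1)))
  fit <- ranger::ranger(dependent.variable.name = ".pair_class", data = df,
                        num.trees = n_trees, probability = TRUE,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  imp <- fit$variable.importance
  imp <- imp / sum(imp)
  structure(list(fit = fit, features = features, n_trees = n_trees,
                 seed = seed, importance = imp),
            class = "pair_forest")
}

#' @export
print.pair_forest <- function(x, ...) {
  cat("<pair_forest> ", x$n_trees, " trees, ", length(x$features),
      " features\n", sep = "")
  invisible(x)
}

#' Predict functional probabilities for pair feature rows
#'
#' @param object A [train_forest()] model.
#' @param data data.frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1] (probability of the
#'   functional class).
#' @export
predict.pair_forest <- function(object, data, ...) {
  p <- stats::predict(object$fit, data = data[, object$features,
                                              drop = FALSE],
                      num.threads = 1)$predictions
  unname(p[, "1"])
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation with midrank tie handling.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration of precision over recall increments
#' (average-precision form), scanning thresholds from the highest score
#' down; tied scores are processed as one block.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # block ends for tied scores
  tp <- tp[keep]
  fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Threshold and curve metrics for pair predictions
#'
#' Accuracy, AUROC, AUPRC, precision, recall, F1 and Matthews correlation
#' coefficient from the 2x2 confusion matrix at the stated threshold.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels; both classes must be present.
#' @param threshold Classification threshold (default 0.5; a score at or
#'   above it predicts functional).
#' @return List of class `evaluation_report` with the scalar metrics and
#'   the confusion counts.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("evaluation requires both classes in the labels")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else
    (tp * tn - fp * fn) / mcc_den
  structure(list(accuracy = (tp + tn) / length(labels),
                 auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 precision = precision, recall = recall, f1 = f1,
                 mcc = mcc, threshold = threshold,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> accuracy %.3f auroc %.3f auprc ",
                     "%.3f precision %.3f recall %.3f f1 %.3f mcc %.3f\n"),
              x$accuracy, x$auroc, x$auprc, x$precision, x$recall, x$f1,
              x$mcc))
  invisible(x)
}

#' Train on a split and evaluate on its held-out test set
#'
#' @param split A [sample_balanced_split()].
#' @param n_trees,seed Forest parameters.
#' @return List: `model`, `report`.
#' @export
train_and_evaluate <- function(split, n_trees = 100, seed = 1) {
  model <- train_forest(split$train, n_trees = n_trees, seed = seed)
  scores <- predict(model, split$test)
  list(model = model,
       report = evaluate(scores, split$test[[.label_col]]))
}

#' Stratified k-fold cross-validation
#'
#' Folds partition the data with per-fold class frequencies within one
#' example of the global frequency; each fold is held out once.
#'
#' @param dataset Labeled pair feature frame.
#' @param k Number of folds (default 10).
#' @param n_trees,seed Forest parameters.
#' @return List of k [evaluate()] reports; fold assignment in
#'   `attr(, "folds")`.
#' @export
stratified_kfold <- function(dataset, k = 10, n_trees = 100, seed = 1) {
  y <- dataset[[.label_col]]
  if (min(table(y)) < k) stop("fewer examples than folds in a class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(nrow(dataset))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  reports <- lapply(seq_len(k), function(f) {
    model <- train_forest(dataset[fold != f, , drop = FALSE],
                          n_trees = n_trees, seed = seed + f)
    scores <- predict(model, dataset[fold == f, , drop = FALSE])
    evaluate(scores, y[fold == f])
  })
  attr(reports, "folds") <- fold
  reports
}

#' Control experiments: split resampling and class-label shuffling
#'
#' `mode = "resample"` re-draws the balanced train/test split each
#' repetition and measures the spread of the metrics. `mode =
#' "shuffle_labels"` randomly permutes the class labels (exactly
#' preserving the class distribution) before splitting, destroying the
#' feature-class relationship: the expected AUROC is 0.5.
#'
#' @param dataset Labeled pair feature frame.
#' @param n_reps Number of repetitions.
#' @param mode `"resample"` or `"shuffle_labels"`.
#' @param n_train_per_class,n_test_per_class Split sizes.
#' @param n_trees,seed Forest parameters; repetition r uses `seed + r`.
#' @return data.frame of per-repetition metrics.
#' @export
randomization_suite <- function(dataset, n_reps,
                                mode = c("resample", "shuffle_labels"),
                                n_train_per_class, n_test_per_class,
                                n_trees = 100, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_reps >= 1)
  rows <- lapply(seq_len(n_reps), function(r) {
    rep_seed <- seed + r
    ds <- dataset
    if (mode == "shuffle_labels") {
      old <- .Random.seed_save()
      set.seed(rep_seed)
      ds[[.label_col]] <- sample(ds[[.label_col]])
      .Random.seed_restore(old)
    }
    split <- sample_balanced_split(ds, n_train_per_class, n_test_per_class,
                                   seed = rep_seed)
    rep <- train_and_evaluate(split, n_trees = n_trees,
                              seed = rep_seed)$report
    data.frame(rep = r, accuracy = rep$accuracy, auroc = rep$auroc,
               auprc = rep$auprc, precision = rep$precision,
               recall = rep$recall, f1 = rep$f1, mcc = rep$mcc)
  })
  do.call(rbind, rows)
}

#' Sweep the number of trees
#'
#' Trains one seeded model per tree count on the same split and evaluates
#' each on the held-out test set; performance is expected to plateau
#' around 100 trees.
#'
#' @param split A [sample_balanced_split()].
#' @param tree_counts Tree counts (default the 9-point grid
#'   10, 20, 50, 100, 200, 500, 1000, 2000, 5000).
#' @param seed Forest seed (shared across counts).
#' @return data.frame with one row per tree count and the test metrics.
#' @export
tree_sweep <- function(split,
                       tree_counts = c(10, 20, 50, 100, 200, 500, 1000,
                                       2000, 5000),
                       seed = 1) {
  rows <- lapply(tree_counts, function(nt) {
    rep <- train_and_evaluate(split, n_trees = nt, seed = seed)$report
    data.frame(n_trees = nt, accuracy = rep$accuracy, auroc = rep$auroc,
               auprc = rep$auprc, mcc = rep$mcc)
  })
  do.call(rbind, rows)
}
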