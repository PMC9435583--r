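# Cross-validation schemes, RBF-SVM training, overlap-rate stability
# selection, strong-edge flagging, and held-out evaluation.

#' Pair subjects into balanced subsets and assign roles
#'
#' Pairs each positive-class (CPS) subject with the negative-class (SPS)
#' subject of matching segment-count rank, so every subset holds one
#' subject per group with roughly equal sample counts. Two subsets are
#' reserved for testing (seeded random draw, or pinned via
#' `test_subsets`); the rest train.
#'
#' @param subjects Data frame with columns `subject_id`, `group_label`
#'   (exactly two groups, equal sizes), and `n_segments`.
#' @param seed Integer seed for the test-subset draw (required unless
#'   `test_subsets` is given).
#' @param n_test Number of test subsets (default 2).
#' @param test_subsets Optional integer vector of subset ids to pin as the
#'   test set, overriding the random draw.
#' @return A `subset_partition`: data frame with one row per subject and
#'   columns `subset`, `subject_id`, `group_label`, `n_segments`, `role`
#'   (`"training"` or `"testing"`). Subsets are numbered by ascending
#'   segment-count rank.
#' @export
build_subset_partition <- function(subjects, seed = NULL, n_test = 2,
                                   test_subsets = NULL) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "group_label", "n_segments") %in%
                  names(subjects)))
  groups <- sort(unique(as.character(subjects$group_label)))
  if (length(groups) != 2L) stop("exactly two groups are required")
  a <- subjects[subjects$group_label == groups[1], ]
  b <- subjects[subjects$group_label == groups[2], ]
  if (nrow(a) != nrow(b)) stop("groups must have equal subject counts")
  n_sub <- nrow(a)
  if (is.null(test_subsets) && n_sub - n_test < 2L)
    stop("cannot reserve ", n_test, " test subsets and still leave >= 2 ",
         "training subsets; pin `test_subsets` to override")
  a <- a[order(a$n_segments, a$subject_id), ]
  b <- b[order(b$n_segments, b$subject_id), ]
  part <- rbind(
    data.frame(subset = seq_len(n_sub), subject_id = a$subject_id,
               group_label = a$group_label, n_segments = a$n_segments),
    data.frame(subset = seq_len(n_sub), subject_id = b$subject_id,
               group_label = b$group_label, n_segments = b$n_segments))
  if (is.null(test_subsets)) {
    if (is.null(seed)) stop("`seed` is required for the random test draw")
    test_subsets <- with_seed(seed, sort(sample.int(n_sub, n_test)))
  } else {
    test_subsets <- as.integer(test_subsets)
    if (any(test_subsets < 1L) || any(test_subsets > n_sub))
      stop("`test_subsets` out of range")
  }
  part$role <- ifelse(part$subset %in% test_subsets, "testing", "training")
  part <- part[order(part$subset, part$group_label), ]
  rownames(part) <- NULL
  class(part) <- c("subset_partition", class(part))
  part
}

#' Train an RBF-kernel SVM
#'
#' Thin wrapper around [e1071::svm()] with the radial-basis kernel
#' `k(u, v) = exp(-gamma * ||u - v||^2)`, no feature scaling (FC values
#' already lie in `[0, 1]`), and fixed hyperparameters. The fit is
#' deterministic given the data.
#'
#' @param x Samples x features numeric matrix (already restricted to the
#'   selected features).
#' @param y Factor of class labels; both classes must be present.
#' @param cost SVM margin parameter C (default 1.2).
#' @param gamma RBF kernel width (default 5).
#' @return A fitted `e1071::svm` model.
#' @export
train_rbf_svm <- function(x, y, cost = 1.2, gamma = 5) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  e1071::svm(as.matrix(x), y, kernel = "radial", cost = cost, gamma = gamma,
             scale = FALSE)
}

new_fold_result <- function(fold_id, selected, fscores, accuracy, n_val) {
  list(fold_id = fold_id, selected_features = selected,
       fscores = fscores, validation_accuracy = accuracy,
       n_validation = n_val)
}

run_fold <- function(train_ft, val_ft, fold_id, k_fraction, cost, gamma) {
  if (nlevels(droplevels(train_ft$labels)) < 2L)
    stop("a sub-training fold lost one class entirely")
  sc <- f_score(train_ft)
  sel <- select_top_fraction(sc, k_fraction)
  fit <- train_rbf_svm(train_ft$x[, sel, drop = FALSE], train_ft$labels,
                       cost, gamma)
  pred <- predict(fit, val_ft$x[, sel, drop = FALSE])
  acc <- mean(as.character(pred) == as.character(val_ft$labels))
  new_fold_result(fold_id, sel, sc[sel], acc, nrow(val_ft$x))
}

#' Leave-one-subset-out stability run
#'
#' For each training subset in turn: hold it out for validation, compute
#' F-scores on the remaining subsets' segments only, keep the top
#' `k_fraction` features, train the RBF-SVM on those features, and score
#' the held-out subset's segments. Feature scoring never sees the held-out
#' or testing subjects, so fold selections are leakage-free by
#' construction.
#'
#' @param features A `fc_feature_table` (all subjects).
#' @param partition A `subset_partition`; only its `"training"` subsets
#'   enter the folds.
#' @param k_fraction Fraction of features kept per fold (default 0.01).
#' @param cost,gamma SVM hyperparameters (defaults 1.2 and 5).
#' @return A `fold_results` list (one element per training subset) with
#'   attribute `scheme = "subject_subsets"`; each element holds the fold
#'   id, selected feature indices (descending score), their F-scores, the
#'   validation accuracy, and the validation sample count.
#' @export
loo_stability_run <- function(features, partition, k_fraction = 0.01,
                              cost = 1.2, gamma = 5) {
  stopifnot(inherits(features, "fc_feature_table"),
            inherits(partition, "subset_partition"))
  train_part <- partition[partition$role == "training", ]
  subsets <- sort(unique(train_part$subset))
  if (length(subsets) < 3L) stop("at least 3 training subsets are required")
  subj_subset <- stats::setNames(train_part$subset, train_part$subject_id)
  in_training <- features$subject_ids %in% train_part$subject_id
  folds <- vector("list", length(subsets))
  for (k in seq_along(subsets)) {
    held <- subsets[k]
    val_rows <- in_training &
      subj_subset[features$subject_ids] == held
    sub_rows <- in_training & !val_rows
    folds[[k]] <- run_fold(ft_subset(features, which(sub_rows)),
                           ft_subset(features, which(val_rows)),
                           fold_id = held, k_fraction, cost, gamma)
  }
  structure(folds, scheme = "subject_subsets", class = "fold_results")
}

#' Random-split stability run
#'
#' Pools all training samples (ignoring subject identity), and for each
#' repetition draws a seeded uniform `train_frac` / `1 - train_frac` split
#' at the sample level; feature scoring, selection, SVM training and
#' validation proceed as in [loo_stability_run()]. A split that leaves a
#' class empty on either side is redrawn with the next derived seed (with
#' a message).
#'
#' @param features A `fc_feature_table` of the pooled training samples.
#' @param train_frac Fraction of samples used for training per repetition
#'   (default 0.9).
#' @param n_reps Number of repetitions (default 14).
#' @param k_fraction,cost,gamma As in [loo_stability_run()].
#' @param seed Integer seed; all splits derive from it.
#' @return A `fold_results` list with attribute `scheme = "random_split"`.
#' @export
random_split_run <- function(features, train_frac = 0.9, n_reps = 14,
                             k_fraction = 0.01, cost = 1.2, gamma = 5,
                             seed) {
  stopifnot(inherits(features, "fc_feature_table"))
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must lie in (0, 1)")
  if (missing(seed)) stop("`seed` is required")
  n <- nrow(features$x)
  n_train <- as.integer(round(train_frac * n))
  if (n_train < 2L || n - n_train < 1L) stop("too few samples to split")
  rep_seeds <- derive_seeds(seed, 2L * n_reps)   # spares for redraws
  folds <- vector("list", n_reps)
  next_seed <- 1L
  for (r in seq_len(n_reps)) {
    repeat {
      if (next_seed > length(rep_seeds))
        rep_seeds <- c(rep_seeds, derive_seeds(rep_seeds[length(rep_seeds)],
                                               n_reps))
      idx <- with_seed(rep_seeds[next_seed], sample.int(n, n_train))
      next_seed <- next_seed + 1L
      train_ft <- ft_subset(features, idx)
      val_ft <- ft_subset(features, setdiff(seq_len(n), idx))
      ok <- nlevels(droplevels(train_ft$labels)) == 2L &&
        length(val_ft$labels) > 0L
      if (ok) break
      message("random split left a class empty; redrawing with next seed")
    }
    folds[[r]] <- run_fold(train_ft, val_ft, fold_id = r, k_fraction,
                           cost, gamma)
  }
  structure(folds, scheme = "random_split", class = "fold_results")
}

#' Overlap-rate stability selection
#'
#' Counts, for every feature that appeared in any fold's selection, the
#' number of folds that selected it, and keeps the features selected in at
#' least `threshold` folds as the stable set. Each stable feature's mean
#' F-score is averaged over the folds in which it was selected.
#'
#' @param fold_results A `fold_results` list.
#' @param threshold Minimum number of folds a stable feature must appear
#'   in (default 12, i.e. the ">= 12 of 14" rule).
#' @return A `stability_result`: list with `n_folds`, `threshold`,
#'   `scheme`, `occurrence` (named counts over all appearing features), and
#'   `stable` (data frame `feature`, `count`, `mean_fscore`, descending by
#'   mean F-score).
#' @export
overlap_select <- function(fold_results, threshold = 12) {
  stopifnot(inherits(fold_results, "fold_results"), length(fold_results) >= 1L)
  n_folds <- length(fold_results)
  if (threshold > n_folds)
    stop("`threshold` cannot exceed the number of folds")
  all_sel <- unlist(lapply(fold_results, `[[`, "selected_features"))
  all_fs <- unlist(lapply(fold_results, `[[`, "fscores"))
  occ <- table(all_sel)
  feats <- as.integer(names(occ))
  counts <- as.integer(occ)
  mean_fs <- vapply(feats, function(f) mean(all_fs[all_sel == f]),
                    numeric(1))
  keep <- counts >= threshold
  stable <- data.frame(feature = feats[keep], count = counts[keep],
                       mean_fscore = mean_fs[keep])
  stable <- stable[order(-stable$mean_fscore, stable$feature), ]
  rownames(stable) <- NULL
  structure(list(n_folds = n_folds, threshold = as.integer(threshold),
                 scheme = attr(fold_results, "scheme"),
                 occurrence = stats::setNames(counts, feats),
                 stable = stable),
            class = "stability_result")
}

#' Flag strong edges within a stable set
#'
#' Marks the stable features whose mean F-score exceeds `frac` of the
#' largest mean F-score in the stable set (the "red line" convention for
#' highlighting the strongest discriminative edges).
#'
#' @param stability A `stability_result` with a non-empty stable set.
#' @param frac Fraction of the maximum mean F-score (default 0.75).
#' @return The `stability_result` with a logical `strong` column added to
#'   `$stable`.
#' @export
flag_strong_edges <- function(stability, frac = 0.75) {
  stopifnot(inherits(stability, "stability_result"))
  if (nrow(stability$stable) == 0L)
    stop("the stable set is empty; nothing to flag")
  mx <- max(stability$stable$mean_fscore)
  stability$stable$strong <- stability$stable$mean_fscore > frac * mx
  stability
}

#' Retrain on the full training pool and evaluate on held-out subjects
#'
#' Trains the RBF-SVM on all training samples restricted to the stable
#' feature set and scores the held-out test segments. CPS is the positive
#' class: sensitivity is the CPS recall, specificity the SPS recall.
#'
#' @param train_features,test_features `fc_feature_table`s with disjoint
#'   subjects.
#' @param stable_set Integer vector of stable feature indices, or a
#'   `stability_result`.
#' @param cost,gamma SVM hyperparameters (defaults 1.2 and 5).
#' @param positive Positive-class label (default `"CPS"`).
#' @return A `fc_eval`: list with `confusion` (TP, FN, TN, FP),
#'   `accuracy`, `sensitivity`, `specificity`, `n_test`, and
#'   `stable_set`.
#' @export
finalize_and_evaluate <- function(train_features, test_features, stable_set,
                                  cost = 1.2, gamma = 5, positive = "CPS") {
  if (inherits(stable_set, "stability_result"))
    stable_set <- stable_set$stable$feature
  stable_set <- as.integer(stable_set)
  if (length(stable_set) == 0L)
    stop("no reliable features: the stable set is empty at this threshold")
  if (length(intersect(unique(train_features$subject_ids),
                       unique(test_features$subject_ids))) > 0L)
    stop("training and testing subjects overlap")
  fit <- train_rbf_svm(train_features$x[, stable_set, drop = FALSE],
                       train_features$labels, cost, gamma)
  pred <- as.character(predict(fit,
                               test_features$x[, stable_set, drop = FALSE]))
  ev <- confusion_metrics(pred, as.character(test_features$labels), positive)
  ev$stable_set <- stable_set
  ev
}

# Confusion counts and derived rates with the given positive class.
confusion_metrics <- function(pred, truth, positive = "CPS") {
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  structure(list(
    confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_test = length(truth), positive = positive
  ), class = "fc_eval")
}

#' @export
print.fc_eval <- function(x, ...) {
  cat(sprintf(
    "test accuracy %.2f%% (sensitivity %.2f%%, specificity %.2f%%) on %d segments\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity, x$n_test))
  invisible(x)
}
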