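# Synthetic labelled feature tables with a controllable class separation on
# one feature; segment counts vary per subject so rank pairing is exercised.
make_cohort_ft <- function(n_per_group = 5, m = 10, sep_feature = 3, sep = 0,
                           seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("CPS_%02d", seq_len(n_per_group)),
           sprintf("SPS_%02d", seq_len(n_per_group)))
  groups <- rep(c("CPS", "SPS"), each = n_per_group)
  counts <- sample(5:9, 2 * n_per_group, replace = TRUE)
  X <- matrix(rnorm(sum(counts) * m, sd = 0.3), sum(counts), m)
  lab <- rep(groups, counts)
  X[, sep_feature] <- X[, sep_feature] + sep * (lab == "CPS")
  list(features = feature_table(X, lab, rep(ids, counts)),
       subjects = data.frame(subject_id = ids, group_label = groups,
                             n_segments = counts))
}

test_that("subset partition pairs by segment-count rank and assigns roles", {
  subj <- data.frame(subject_id = c("a", "b", "c", "d"),
                     group_label = c("CPS", "CPS", "SPS", "SPS"),
                     n_segments = c(10, 100, 12, 95))
  part <- build_subset_partition(subj, test_subsets = 1)
  expect_equal(sort(part$n_segments[part$subset == 1]), c(10, 12))
  expect_equal(sort(part$n_segments[part$subset == 2]), c(95, 100))
  # 16 + 16 subjects: 16 subsets, 14 training + 2 testing
  big <- make_cohort_ft(16)$subjects
  p16 <- build_subset_partition(big, seed = 5)
  expect_equal(max(p16$subset), 16L)
  expect_equal(sum(p16$role == "testing"), 4L)     # 2 subsets x 2 subjects
  expect_equal(length(unique(p16$subset[p16$role == "training"])), 14L)
  expect_true(all(table(p16$subject_id) == 1))
  # degenerate guard: 2 + 2 subjects cannot reserve 2 test + >= 2 train
  expect_error(build_subset_partition(subj, seed = 1), "training subsets")
  expect_error(
    build_subset_partition(subj[c(1, 2, 3), ], seed = 1), "equal")
})

test_that("RBF-SVM separates separable data and is deterministic", {
  set.seed(20)
  X <- rbind(matrix(rnorm(40, mean = 0), 20, 2),
             matrix(rnorm(40, mean = 4), 20, 2))
  y <- factor(rep(c("CPS", "SPS"), each = 20))
  fit <- train_rbf_svm(X, y)
  expect_equal(mean(predict(fit, X) == y), 1)
  # duplicated dataset rows give the identical decision function
  fit2 <- train_rbf_svm(rbind(X, X), factor(c(as.character(y),
                                              as.character(y))))
  grid <- matrix(rnorm(40), 20, 2)
  expect_equal(as.character(predict(fit, grid)),
               as.character(predict(fit2, grid)))
  expect_error(train_rbf_svm(X, factor(rep("CPS", 40))), "single class")
})

test_that("labels independent of features classify at chance", {
  set.seed(21)
  accs <- replicate(30, {
    X <- matrix(rnorm(200 * 5), 200, 5)
    y <- factor(sample(rep(c("CPS", "SPS"), 100)))
    idx <- sample(200, 160)
    fit <- train_rbf_svm(X[idx, ], y[idx])
    mean(predict(fit, X[-idx, ]) == y[-idx])
  })
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("leave-one-subset-out folds select on sub-training data only", {
  sep <- make_cohort_ft(5, sep = 5, seed = 3)
  part <- build_subset_partition(sep$subjects, test_subsets = c(4, 5))
  folds <- loo_stability_run(sep$features, part)
  expect_length(folds, 3L)                 # 3 training subsets
  # a separable cohort validates perfectly and always picks the true feature
  for (f in folds) {
    expect_equal(f$validation_accuracy, 1)
    expect_equal(f$selected_features, 3L)  # k = ceil(0.01 * 10) = 1
  }
  # fold selections are recomputable from the sub-training subjects alone
  # (held-out and testing subjects excluded): no test-set leakage
  held <- folds[[1]]$fold_id
  sub_ids <- part$subject_id[part$role == "training" & part$subset != held]
  rows <- sep$features$subject_ids %in% sub_ids
  sc <- oracle_fscore(sep$features$x[rows, ],
                      as.character(sep$features$labels)[rows])
  expect_equal(folds[[1]]$selected_features, which.max(sc))
  expect_error(loo_stability_run(sep$features,
                                 build_subset_partition(sep$subjects,
                                                        test_subsets = 3:5)),
               "at least 3")
})

test_that("random splits are seeded, sized, and reproducible", {
  sep <- make_cohort_ft(5, sep = 5, seed = 4)
  n <- nrow(sep$features$x)
  r1 <- random_split_run(sep$features, n_reps = 4, seed = 77)
  r2 <- random_split_run(sep$features, n_reps = 4, seed = 77)
  expect_length(r1, 4L)
  expect_identical(lapply(r1, `[[`, "selected_features"),
                   lapply(r2, `[[`, "selected_features"))
  expect_identical(vapply(r1, `[[`, numeric(1), "validation_accuracy"),
                   vapply(r2, `[[`, numeric(1), "validation_accuracy"))
  expect_equal(r1[[1]]$n_validation, n - round(0.9 * n))
  expect_error(random_split_run(sep$features, train_frac = 1, seed = 1),
               "train_frac")
})

test_that("overlap selection counts folds and applies the threshold", {
  mk <- function(sel, fs) structure(
    list(list(fold_id = 1, selected_features = sel[[1]], fscores = fs[[1]],
              validation_accuracy = 1, n_validation = 10),
         list(fold_id = 2, selected_features = sel[[2]], fscores = fs[[2]],
              validation_accuracy = 1, n_validation = 10),
         list(fold_id = 3, selected_features = sel[[3]], fscores = fs[[3]],
              validation_accuracy = 1, n_validation = 10)),
    scheme = "subject_subsets", class = "fold_results")
  fr <- mk(list(c(1L, 2L), c(2L, 3L), c(2L, 1L)),
           list(c(4, 3), c(5, 1), c(7, 2)))
  st <- overlap_select(fr, threshold = 2)
  expect_equal(st$stable$feature, c(2L, 1L))        # by descending mean F
  expect_equal(st$stable$count, c(3L, 2L))
  expect_equal(st$stable$mean_fscore, c(5, 3))      # folds where selected
  expect_equal(unname(st$occurrence[c("1", "2", "3")]), c(2L, 3L, 1L))
  # threshold 1: union of all fold selections
  expect_setequal(overlap_select(fr, 1)$stable$feature, 1:3)
  # threshold n_folds: containment in every fold's selection
  st3 <- overlap_select(fr, 3)
  for (f in fr)
    expect_true(all(st3$stable$feature %in% f$selected_features))
  expect_error(overlap_select(fr, 4), "exceed")
})

test_that("strong-edge flagging uses the 75%-of-maximum rule", {
  st <- structure(list(n_folds = 14, threshold = 12, scheme = "s",
                       occurrence = c(`1` = 14L),
                       stable = data.frame(feature = 1:3, count = c(14, 13, 12),
                                           mean_fscore = c(1.0, 0.8, 0.5))),
                  class = "stability_result")
  out <- flag_strong_edges(st)
  expect_equal(out$stable$strong, c(TRUE, TRUE, FALSE))
  st$stable <- st$stable[1, ]
  expect_true(flag_strong_edges(st)$stable$strong)   # 1 > 0.75 of itself
  st$stable <- data.frame(feature = 1:3, count = 14,
                          mean_fscore = c(2, 2, 2))
  expect_true(all(flag_strong_edges(st)$stable$strong))
  st$stable <- st$stable[0, ]
  expect_error(flag_strong_edges(st), "empty")
})

test_that("confusion arithmetic gives accuracy, sensitivity, specificity", {
  pred <- c(rep("CPS", 90), rep("SPS", 10), rep("SPS", 80), rep("CPS", 20))
  truth <- c(rep("CPS", 100), rep("SPS", 100))
  ev <- seizfc:::confusion_metrics(pred, truth)
  expect_equal(unname(ev$confusion), c(90, 10, 80, 20))
  expect_equal(ev$accuracy, 0.85)
  expect_equal(ev$sensitivity, 0.90)
  expect_equal(ev$specificity, 0.80)
  # complement under flipped predictions
  flip <- ifelse(pred == "CPS", "SPS", "CPS")
  expect_equal(seizfc:::confusion_metrics(flip, truth)$accuracy,
               1 - ev$accuracy)
})

test_that("final evaluation retrains on the pool and guards leakage", {
  sep <- make_cohort_ft(5, sep = 5, seed = 6)
  part <- build_subset_partition(sep$subjects, test_subsets = c(4, 5))
  train_ids <- part$subject_id[part$role == "training"]
  ft <- sep$features
  tr <- seizfc:::ft_subset(ft, which(ft$subject_ids %in% train_ids))
  te <- seizfc:::ft_subset(ft, which(!ft$subject_ids %in% train_ids))
  ev <- finalize_and_evaluate(tr, te, stable_set = 3L)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_error(finalize_and_evaluate(tr, te, integer()), "empty")
  expect_error(finalize_and_evaluate(tr, tr, 3L), "overlap")
})
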