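# Atlas handling, reference bookkeeping tables, edge reports, run
# configuration, and the end-to-end pipeline driver.

#' Load a parcel atlas table
#'
#' Reads a two-column TSV (`index`, `label`) mapping parcel indices to
#' anatomical labels.
#'
#' @param path Path to the TSV file.
#' @return Data frame with integer `index` and unique character `label`.
#' @export
load_atlas <- function(path) {
  at <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("index", "label") %in% names(at)))
    stop("atlas file needs `index` and `label` columns")
  if (anyDuplicated(at$label)) stop("atlas labels must be unique")
  if (!identical(as.integer(at$index), seq_len(nrow(at))))
    stop("atlas indices must run 1..n_parcels")
  at
}

#' The 74-parcel cortical atlas shipped with the package
#'
#' Gyral/sulcal parcellation labels (Destrieux-style names such as
#' `G_front_middle` or `S_intrapariet_and_P_trans`), one row per parcel.
#'
#' @return Data frame with `index` and `label` for 74 parcels.
#' @export
default_atlas <- function() {
  load_atlas(system.file("extdata", "destrieux_74.tsv", package = "seizfc",
                         mustWork = TRUE))
}

#' Reference clinical cohort bookkeeping
#'
#' Per-subject clean-segment counts of the reference clinical cohort this
#' pipeline mirrors: 16 CPS and 16 SPS subjects paired into 16 subsets,
#' with two subsets held out for testing. Used for bookkeeping checks
#' (group totals, test-set sizes) and as a realistic template of how
#' unbalanced per-subject segment counts can be.
#'
#' @return Data frame with columns `group`, `subset`, `role`,
#'   `subject_id`, `n_segments`.
#' @export
reference_cohort <- function() {
  utils::read.delim(system.file("extdata", "reference_cohort.tsv",
                                package = "seizfc", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Reference per-fold validation accuracies
#'
#' The reference analysis's reported validation accuracy (percent) for each
#' of the 14 cross-validation folds, under both sample-selection schemes.
#'
#' @param scheme `"subject_subsets"` (leave-one-subset-out) or
#'   `"random_split"` (pooled 90/10 splits).
#' @return Data frame with columns `scheme`, `fold`, `accuracy_pct`.
#' @export
reference_fold_accuracies <- function(scheme = c("subject_subsets",
                                                 "random_split")) {
  scheme <- match.arg(scheme)
  df <- utils::read.delim(system.file("extdata",
                                      "reference_validation_accuracy.tsv",
                                      package = "seizfc", mustWork = TRUE),
                          stringsAsFactors = FALSE)
  df[df$scheme == scheme, ]
}

#' Aggregate fold accuracies
#'
#' @param acc Numeric vector of per-fold accuracies, or a data frame with
#'   an `accuracy_pct` column, or a `fold_results` list.
#' @return List with `mean`, `min`, `max`.
#' @export
summarize_fold_accuracies <- function(acc) {
  if (inherits(acc, "fold_results"))
    acc <- vapply(acc, `[[`, numeric(1), "validation_accuracy")
  if (is.data.frame(acc)) acc <- acc$accuracy_pct
  list(mean = mean(acc), min = min(acc), max = max(acc))
}

#' Tabulate stable edges with anatomical labels
#'
#' Maps each stable feature back to its parcel pair and reports the edge
#' with atlas labels, fold-occurrence count, mean F-score, and (when
#' present) the strong-edge flag. `ROI1` is the row (larger-index) parcel
#' of the canonical lower-triangle indexing. Rows are ordered by
#' descending mean F-score.
#'
#' @param stability A `stability_result`.
#' @param atlas Atlas data frame (default [default_atlas()]).
#' @return Data frame with columns `feature`, `roi1`, `roi2`, `count`,
#'   `mean_fscore`, and optionally `strong`.
#' @export
edge_report <- function(stability, atlas = default_atlas()) {
  stopifnot(inherits(stability, "stability_result"))
  p <- nrow(atlas)
  map <- fc_index_map(p)
  st <- stability$stable
  if (nrow(st) == 0L) {
    out <- data.frame(feature = integer(), roi1 = character(),
                      roi2 = character(), count = integer(),
                      mean_fscore = numeric())
    return(out)
  }
  if (any(st$feature > nrow(map)))
    stop("stable feature index exceeds the atlas feature space")
  out <- data.frame(feature = st$feature,
                    roi1 = atlas$label[map$parcel_i[st$feature]],
                    roi2 = atlas$label[map$parcel_j[st$feature]],
                    count = st$count,
                    mean_fscore = st$mean_fscore)
  if (!is.null(st$strong)) out$strong <- st$strong
  out[order(-out$mean_fscore, out$feature), , drop = FALSE]
}

#' Mark edges found by both sample-selection schemes
#'
#' @param report Edge report (from [edge_report()]).
#' @param other Edge report from the other scheme.
#' @return `report` with a logical `coincident` column.
#' @export
mark_coincident <- function(report, other) {
  report$coincident <- report$feature %in% other$feature
  report
}

#' Assemble and validate a pipeline configuration
#'
#' Bundles all stage parameters of an end-to-end run. Validation happens
#' here, before any computation: in particular the stability threshold
#' must not exceed the number of folds of the chosen scheme.
#'
#' @param cohort A [cohort_config()] (its `seed` is overridden by the
#'   run's root seed).
#' @param coupling A [coupling_spec()].
#' @param scheme `"subsets"`, `"random"`, or `"both"`.
#' @param window_s,overlap,band_hz,absolute FC estimator settings.
#' @param k_fraction,cost,gamma Selection and SVM settings.
#' @param threshold Overlap-rate stability threshold (folds).
#' @param strong_frac Strong-edge fraction of the maximum mean F-score.
#' @param train_frac,n_reps Random-split scheme settings.
#' @param n_test,test_subsets Test-subset reservation (see
#'   [build_subset_partition()]).
#' @param seed Root seed; every stage seed derives from it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(cohort, coupling = coupling_spec(),
                       scheme = c("subsets", "random", "both"),
                       window_s = 1, overlap = 0.5, band_hz = c(1, 40),
                       absolute = TRUE, k_fraction = 0.01, cost = 1.2,
                       gamma = 5, threshold = 12, strong_frac = 0.75,
                       train_frac = 0.9, n_reps = 14, n_test = 2,
                       test_subsets = NULL, seed) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(coupling, "coupling_spec"))
  if (missing(seed)) stop("`seed` is mandatory")
  n_loo_folds <- cohort$n_subjects_per_group - n_test
  if (scheme %in% c("subsets", "both") && threshold > n_loo_folds)
    stop(sprintf("threshold %d exceeds the %d leave-one-out folds",
                 threshold, n_loo_folds))
  if (scheme %in% c("random", "both") && threshold > n_reps)
    stop(sprintf("threshold %d exceeds the %d random-split repetitions",
                 threshold, n_reps))
  stopifnot_scalar_number(k_fraction, "k_fraction", min = 1e-12, max = 1)
  stopifnot_scalar_number(cost, "cost", min = 1e-12)
  stopifnot_scalar_number(gamma, "gamma", min = 1e-12)
  structure(list(cohort = cohort, coupling = coupling, scheme = scheme,
                 window_s = window_s, overlap = overlap, band_hz = band_hz,
                 absolute = absolute, k_fraction = k_fraction, cost = cost,
                 gamma = gamma, threshold = as.integer(threshold),
                 strong_frac = strong_frac, train_frac = train_frac,
                 n_reps = as.integer(n_reps), n_test = as.integer(n_test),
                 test_subsets = test_subsets, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Convenience wrapper building a [run_config()] from a YAML document with
#' optional `cohort:` and `coupling:` blocks plus top-level stage
#' parameters. Requires the `yaml` package.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the `yaml` package")
  doc <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, doc$cohort %||% list())
  coupling <- if (is.null(doc$coupling)) coupling_spec() else
    coupling_spec(edges = do.call(rbind, doc$coupling$edges),
                  lag_ms = doc$coupling$lag_ms %||% 20,
                  strength = doc$coupling$strength %||% 0.6,
                  group = doc$coupling$group %||% "both")
  rest <- doc[setdiff(names(doc), c("cohort", "coupling"))]
  do.call(run_config, c(list(cohort = cohort, coupling = coupling), rest))
}

config_hash <- function(config) {
  strip <- function(x) {
    x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(strip(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> per-segment FC -> subset partition -> stability
#' scheme(s) -> overlap selection -> strong-edge flagging -> held-out test
#' evaluation, and writes `folds.csv`, `stable_edges.csv`, `edges.csv`
#' (plain `i,j,weight` rows for external brain-plot tools), and
#' `metrics.json` into `out_dir`. Every output carries the configuration
#' hash and root seed; reruns with the same configuration are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param features Optional precomputed cohort, as returned by
#'   [simulate_fc_cohort()]; bypasses simulation (the entry point for
#'   users bringing their own source-reconstructed segments).
#' @param atlas Atlas for edge labelling; defaults to the shipped 74-parcel
#'   atlas when the cohort has 74 parcels, else plain numbered parcels.
#' @return (Invisibly) a list with the partition, per-scheme results
#'   (`folds`, `stability`, `evaluation`, `report`), and `metrics`.
#' @export
run_pipeline <- function(config, out_dir = NULL, features = NULL,
                         atlas = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 3L)
  if (is.null(features)) {
    cc <- config$cohort
    cc$seed <- seeds[1]
    message("simulating cohort: ", 2L * cc$n_subjects_per_group,
            " subjects, ", cc$n_parcels, " parcels")
    sim <- simulate_fc_cohort(cc, config$coupling, config$window_s,
                              config$overlap, config$band_hz,
                              config$absolute)
  } else {
    sim <- features
  }
  ft <- sim$features
  message("cohort yielded ", nrow(ft$x), " segments")
  if (is.null(atlas)) {
    p <- sim$config$n_parcels
    atlas <- if (p == 74L) default_atlas() else
      data.frame(index = seq_len(p), label = sprintf("parcel_%02d", seq_len(p)))
  }
  partition <- build_subset_partition(sim$subjects, seed = seeds[2],
                                      n_test = config$n_test,
                                      test_subsets = config$test_subsets)
  train_ids <- partition$subject_id[partition$role == "training"]
  test_ids <- partition$subject_id[partition$role == "testing"]
  train_ft <- ft_subset(ft, which(ft$subject_ids %in% train_ids))
  test_ft <- ft_subset(ft, which(ft$subject_ids %in% test_ids))

  schemes <- switch(config$scheme, subsets = "subsets", random = "random",
                    both = c("subsets", "random"))
  results <- list()
  for (sc in schemes) {
    message("running scheme: ", sc)
    folds <- if (sc == "subsets") {
      loo_stability_run(ft, partition, config$k_fraction, config$cost,
                        config$gamma)
    } else {
      random_split_run(train_ft, config$train_frac, config$n_reps,
                       config$k_fraction, config$cost, config$gamma,
                       seed = seeds[3])
    }
    stab <- overlap_select(folds, config$threshold)
    ev <- NULL
    if (nrow(stab$stable) > 0L) {
      stab <- flag_strong_edges(stab, config$strong_frac)
      ev <- finalize_and_evaluate(train_ft, test_ft, stab, config$cost,
                                  config$gamma)
    } else {
      message("scheme ", sc, ": stable set empty at threshold ",
              config$threshold, "/", stab$n_folds)
    }
    results[[sc]] <- list(folds = folds, stability = stab, evaluation = ev,
                          report = edge_report(stab, atlas))
  }
  if (length(results) == 2L) {
    results[[1]]$report <- mark_coincident(results[[1]]$report,
                                           results[[2]]$report)
    results[[2]]$report <- mark_coincident(results[[2]]$report,
                                           results[[1]]$report)
  }

  hash <- config_hash(config)
  gt <- sim$ground_truth
  metrics <- list(
    config_hash = hash, seed = config$seed, scheme = config$scheme,
    n_subjects = nrow(sim$subjects), n_segments = nrow(ft$x),
    n_features = ncol(ft$x),
    planted_edges = if (nrow(gt)) gt$feature else integer(),
    schemes = lapply(results, function(r) {
      list(n_folds = r$stability$n_folds,
           threshold = r$stability$threshold,
           stable_set_size = nrow(r$stability$stable),
           planted_recovered = if (nrow(gt))
             sum(gt$feature %in% r$stability$stable$feature) else 0L,
           test_accuracy = if (!is.null(r$evaluation))
             r$evaluation$accuracy else NULL,
           sensitivity = if (!is.null(r$evaluation))
             r$evaluation$sensitivity else NULL,
           specificity = if (!is.null(r$evaluation))
             r$evaluation$specificity else NULL)
    }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    folds_df <- do.call(rbind, lapply(names(results), function(sc) {
      fr <- results[[sc]]$folds
      data.frame(scheme = sc,
                 fold = vapply(fr, `[[`, numeric(1), "fold_id"),
                 validation_accuracy = vapply(fr, `[[`, numeric(1),
                                              "validation_accuracy"),
                 n_validation = vapply(fr, `[[`, numeric(1), "n_validation"),
                 n_selected = vapply(fr, function(f)
                   length(f$selected_features), numeric(1)),
                 config_hash = hash)
    }))
    utils::write.csv(folds_df, file.path(out_dir, "folds.csv"),
                     row.names = FALSE)
    edges_df <- do.call(rbind, lapply(names(results), function(sc) {
      rp <- results[[sc]]$report
      if (nrow(rp) == 0L) return(NULL)
      cbind(scheme = sc, rp, config_hash = hash)
    }))
    if (is.null(edges_df))
      edges_df <- data.frame(scheme = character(), feature = integer(),
                             roi1 = character(), roi2 = character(),
                             count = integer(), mean_fscore = numeric(),
                             config_hash = character())
    utils::write.csv(edges_df, file.path(out_dir, "stable_edges.csv"),
                     row.names = FALSE)
    map <- fc_index_map(nrow(atlas))
    plain <- do.call(rbind, lapply(results, function(r) {
      st <- r$stability$stable
      if (nrow(st) == 0L) return(NULL)
      data.frame(i = map$parcel_i[st$feature], j = map$parcel_j[st$feature],
                 weight = st$mean_fscore)
    }))
    if (is.null(plain)) plain <- data.frame(i = integer(), j = integer(),
                                            weight = numeric())
    utils::write.csv(plain, file.path(out_dir, "edges.csv"),
                     row.names = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
  }
  invisible(list(partition = partition, results = results,
                 metrics = metrics))
}
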