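#' Confusion matrix over the four nucleolar classes
#'
#' @param truth,predicted Vectors (character or factor) of true and
#'   predicted class labels, same length.
#' @return 4x4 integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as_nucleolar_class(truth)
  predicted <- as_nucleolar_class(predicted)
  stopifnot(length(truth) == length(predicted))
  m <- table(truth = truth, predicted = predicted)
  matrix(as.integer(m), nrow = 4,
         dimnames = list(truth = nucleolar_classes(),
                         predicted = nucleolar_classes()))
}

#' Per-class sensitivity, PPV and overall accuracy
#'
#' Sensitivity is TP / (TP + FN) and positive predictive value TP /
#' (TP + FP), computed one-vs-rest per class; overall accuracy is the
#' diagonal fraction of the confusion matrix. A metric with a zero
#' denominator is reported as `NA`, never as 0.
#'
#' @param confusion 4x4 confusion matrix from [confusion_matrix()].
#' @param coverage Fraction of the original predictions retained (1 for a
#'   plain evaluation; reliability sweeps pass the retained fraction).
#' @return Object of class `nucleo_eval`: list with `metrics` (tibble of
#'   class, n_true, n_predicted, tp, sensitivity, ppv), `accuracy`, `n`,
#'   `coverage` and zeroed `accuracy_sd` / per-metric SD placeholders
#'   (filled by [multirun_evaluate()]).
#' @export
class_metrics <- function(confusion, coverage = 1) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == c(4, 4)))
  if (sum(confusion) < 1) abort("Confusion matrix is empty.")
  tp <- diag(confusion)
  n_true <- rowSums(confusion)
  n_pred <- colSums(confusion)
  metrics <- tibble(
    class = nucleolar_classes(),
    n_true = unname(as.integer(n_true)),
    n_predicted = unname(as.integer(n_pred)),
    tp = unname(as.integer(tp)),
    sensitivity = unname(ifelse(n_true > 0, tp / n_true, NA_real_)),
    ppv = unname(ifelse(n_pred > 0, tp / n_pred, NA_real_))
  )
  structure(
    list(
      metrics = metrics,
      accuracy = sum(tp) / sum(confusion),
      n = sum(confusion),
      coverage = coverage,
      confusion = confusion,
      accuracy_sd = 0,
      metric_sd = NULL
    ),
    class = "nucleo_eval"
  )
}

#' @export
print.nucleo_eval <- function(x, ...) {
  cat("<nucleo_eval> n = ", x$n, ", accuracy = ", round(x$accuracy, 4),
      if (x$accuracy_sd > 0) paste0(" (sd ", signif(x$accuracy_sd, 3), ")"),
      ", coverage = ", round(x$coverage, 3), "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.nucleo_eval <- function(x, ...) x$metrics

#' @export
glance.nucleo_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, accuracy_sd = x$accuracy_sd,
         n = x$n, coverage = x$coverage)
}

#' Leave-one-out cross-validation
#'
#' Each labelled protein is held out in turn: the reference structures are
#' rebuilt without it (the held-out protein is removed from every training
#' protein's interactor set, from the GO class counts and from the
#' co-expression reference group), the model is retrained on the remaining
#' proteins, and the held-out protein is scored.
#'
#' @param cohort A `nucleo_cohort`.
#' @param labels Labelled corpus (tibble `id`, `class`); defaults to the
#'   cohort's own labels. Needs >= 2 proteins spanning >= 2 classes.
#' @param config Binning configuration; `NULL` (default) calibrates
#'   equal-frequency thresholds on the cohort via [calibrate_binning()].
#' @param priors,alpha Passed to [train_model()].
#' @return List with `predictions` (prediction tibble plus a `truth`
#'   column) and `report` (a `nucleo_eval`).
#' @export
loocv <- function(cohort, labels = NULL, config = NULL,
                  priors = default_priors(), alpha = 0.1) {
  stopifnot(inherits(cohort, "nucleo_cohort"))
  labels <- labels %||% cohort$labels
  if (is.null(labels)) abort("No labels available for cross-validation.")
  labels <- mutate(labels, class = as_nucleolar_class(.data$class))
  if (nrow(labels) < 2 || dplyr::n_distinct(labels$class) < 2) {
    abort("LOOCV needs >= 2 proteins spanning >= 2 classes.")
  }
  missing_ids <- setdiff(labels$id, cohort$proteins$id)
  if (length(missing_ids) > 0) {
    abort(paste0("Labelled protein(s) not in cohort: ",
                 paste(missing_ids, collapse = ", ")))
  }
  if (is.null(config)) {
    config <- calibrate_binning(new_cohort_labels(cohort, labels))
  }
  state <- feature_state(cohort)

  one_fold <- function(i) {
    held <- labels$id[i]
    train_labels <- labels[-i, , drop = FALSE]
    groups <- training_groups(train_labels)
    feats <- features_from_state(state, groups, config, exclude = held)
    model <- train_model(
      feats[feats$id %in% train_labels$id, , drop = FALSE],
      train_labels, priors = priors, alpha = alpha, config = config
    )
    classify(model, feats[feats$id == held, , drop = FALSE])
  }
  predictions <- bind_rows(lapply(seq_len(nrow(labels)), one_fold))
  predictions <- left_join(predictions, rename(labels, truth = "class"), by = "id")
  report <- class_metrics(confusion_matrix(predictions$truth, predictions$label))
  list(predictions = predictions, report = report)
}

# swap the labels table of a cohort (no copy of the heavy tables)
new_cohort_labels <- function(cohort, labels) {
  cohort$labels <- labels
  cohort
}

#' Evaluate a trained model on an independent test set
#'
#' Scores test proteins with a fitted model, using the model's own training
#' groups as reference structures. Any overlap between the test ids and the
#' model's training manifest is an error (leakage guard), as is an empty
#' test set.
#'
#' @param model A `nucleo_model`.
#' @param cohort Cohort holding the test proteins' sequences/annotations
#'   (and the training proteins', which anchor the reference structures).
#' @param test_labels Tibble `id`, `class` of test proteins.
#' @return List with `predictions` and `report`, as [loocv()].
#' @export
evaluate_independent <- function(model, cohort, test_labels) {
  stopifnot(inherits(model, "nucleo_model"), inherits(cohort, "nucleo_cohort"))
  if (is.null(test_labels) || nrow(test_labels) == 0) {
    abort("Independent test set is empty.")
  }
  test_labels <- mutate(test_labels, class = as_nucleolar_class(.data$class))
  overlap <- intersect(test_labels$id, model$manifest$id)
  if (length(overlap) > 0) {
    abort(paste0("Test set overlaps the training manifest: ",
                 paste(overlap, collapse = ", ")))
  }
  groups <- training_groups(model$manifest)
  feats <- extract_features(cohort, groups = groups, config = model$binning)
  missing_ids <- setdiff(test_labels$id, feats$id)
  if (length(missing_ids) > 0) {
    abort(paste0("Test protein(s) not in cohort: ",
                 paste(missing_ids, collapse = ", ")))
  }
  predictions <- classify(model, feats[match(test_labels$id, feats$id), , drop = FALSE])
  predictions <- left_join(predictions, rename(test_labels, truth = "class"), by = "id")
  report <- class_metrics(confusion_matrix(predictions$truth, predictions$label))
  list(predictions = predictions, report = report)
}

#' Average accuracy over runs with resampled negative sets
#'
#' All runs share the three nucleolar training groups but differ in their
#' non-nucleolar sets, each drawn reproducibly from the negative pool with
#' its own seed. Reported metrics are means with run-to-run standard
#' deviations (n - 1 denominator; 0 for a single run).
#'
#' @param cohort A `nucleo_cohort`.
#' @param nucleolar_labels Tibble `id`, `class` for the three nucleolar
#'   groups; defaults to the non-`NON_NUCLEOLAR` rows of the cohort labels.
#' @param n_negative Negatives drawn per run (default 200).
#' @param n_runs Number of runs (default 10).
#' @param mode `"loocv"` or `"independent"` (which requires `test_labels`).
#' @param seeds Integer vector of per-run seeds, default `1:n_runs`.
#' @param negative_pool Candidate negative ids; defaults to all cohort
#'   proteins not in `nucleolar_labels`.
#' @param test_labels Independent test set for `mode = "independent"`.
#' @param config,priors,alpha As in [loocv()].
#' @return A `nucleo_eval` whose metrics are run means, with `accuracy_sd`
#'   and a `metric_sd` tibble of per-class SDs; individual run reports in
#'   `$runs`.
#' @export
multirun_evaluate <- function(cohort, nucleolar_labels = NULL, n_negative = 200,
                              n_runs = 10, mode = c("loocv", "independent"),
                              seeds = NULL, negative_pool = NULL,
                              test_labels = NULL, config = NULL,
                              priors = default_priors(), alpha = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "nucleo_cohort"))
  if (is.null(nucleolar_labels)) {
    if (is.null(cohort$labels)) abort("No labels available.")
    nucleolar_labels <- filter(cohort$labels, .data$class != "NON_NUCLEOLAR")
  }
  nucleolar_labels <- mutate(nucleolar_labels, class = as_nucleolar_class(.data$class))
  seeds <- seeds %||% seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  pool_ids <- negative_pool %||% setdiff(cohort$proteins$id, nucleolar_labels$id)
  pool <- tibble(id = pool_ids)
  if (is.null(config)) {
    full_labels <- bind_rows(
      nucleolar_labels,
      tibble(id = pool_ids,
             class = as_nucleolar_class(rep("NON_NUCLEOLAR", length(pool_ids))))
    )
    config <- calibrate_binning(new_cohort_labels(cohort, full_labels))
  }

  run_once <- function(seed) {
    negs <- sample_non_nucleolar(pool, nucleolar_labels$id, n_negative, seed)
    run_labels <- bind_rows(nucleolar_labels, negs)
    if (mode == "loocv") {
      loocv(cohort, labels = run_labels, config = config,
            priors = priors, alpha = alpha)$report
    } else {
      if (is.null(test_labels)) abort("`test_labels` required for independent mode.")
      feats <- extract_features(cohort, groups = training_groups(run_labels),
                                config = config)
      model <- train_model(feats[feats$id %in% run_labels$id, , drop = FALSE],
                           run_labels, priors = priors, alpha = alpha,
                           config = config)
      evaluate_independent(model, cohort, test_labels)$report
    }
  }
  runs <- lapply(seeds, run_once)

  acc <- vapply(runs, function(r) r$accuracy, numeric(1))
  sens <- vapply(runs, function(r) r$metrics$sensitivity, numeric(4))
  ppv <- vapply(runs, function(r) r$metrics$ppv, numeric(4))
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  row_mean_na <- function(m) apply(m, 1, function(x) mean(x[!is.na(x)]))
  row_sd_na <- function(m) apply(m, 1, function(x) sd0(x[!is.na(x)]))
  out <- runs[[1]]
  out$accuracy <- mean(acc)
  out$accuracy_sd <- sd0(acc)
  out$n <- mean(vapply(runs, function(r) r$n, numeric(1)))
  sens_mean <- row_mean_na(sens); sens_sd <- row_sd_na(sens)
  ppv_mean <- row_mean_na(ppv); ppv_sd <- row_sd_na(ppv)
  out$metrics <- tibble(
    class = nucleolar_classes(),
    sensitivity = sens_mean,
    ppv = ppv_mean,
    sensitivity_sd = sens_sd,
    ppv_sd = ppv_sd
  )
  out$metric_sd <- select(out$metrics, "class", "sensitivity_sd", "ppv_sd")
  out$confusion <- NULL
  out$runs <- runs
  out
}

#' Accuracy as a function of the minimum reliability index
#'
#' At each threshold `t`, only predictions with reliability index >= `t`
#' are scored; coverage is the retained fraction and is non-increasing in
#' `t`.
#'
#' @param predictions Prediction tibble (needs `id`, `label`,
#'   `reliability_index`).
#' @param truths Tibble `id`, `class` (or a `truth` column already in
#'   `predictions`); every prediction must have a truth.
#' @param thresholds Ascending numeric thresholds, default
#'   `c(1, 2, 5, 10, 25, 50, 100, 150)`.
#' @return Tibble of class `nucleo_sweep`: `threshold`, `n_retained`,
#'   `coverage`, `accuracy`, plus a `metrics` list-column of per-class
#'   tibbles.
#' @export
reliability_sweep <- function(predictions, truths = NULL,
                              thresholds = c(1, 2, 5, 10, 25, 50, 100, 150)) {
  if (!is.null(truths)) {
    predictions <- left_join(select(predictions, -dplyr::any_of("truth")),
                             rename(truths, truth = "class"), by = "id")
  }
  if (!"truth" %in% names(predictions) || anyNA(predictions$truth)) {
    abort("Every prediction needs a true class (missing `truth`).")
  }
  total <- nrow(predictions)
  rows <- lapply(thresholds, function(t) {
    keep <- predictions$reliability_index >= t
    n_keep <- sum(keep)
    if (n_keep == 0) {
      return(tibble(threshold = t, n_retained = 0L, coverage = 0,
                    accuracy = NA_real_, metrics = list(NULL)))
    }
    rep_t <- class_metrics(
      confusion_matrix(predictions$truth[keep], predictions$label[keep]),
      coverage = n_keep / total
    )
    tibble(threshold = t, n_retained = n_keep, coverage = n_keep / total,
           accuracy = rep_t$accuracy, metrics = list(rep_t$metrics))
  })
  out <- bind_rows(rows)
  class(out) <- c("nucleo_sweep", class(out))
  out
}
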