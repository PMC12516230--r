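#' Recipe: refit a fixed-variable logistic model
#'
#' Returns a model-building function for [crossval_evaluate()]: given a
#' training table it fits an unpenalised logistic model on `variables` and
#' returns a prediction function.
#'
#' @param variables predictor column names.
#' @param outcome binary outcome column name.
#' @return `function(train) -> function(newdata) -> probabilities`.
#' @export
logistic_recipe <- function(variables, outcome = "he") {
  force(variables); force(outcome)
  function(train) {
    m <- fit_logistic(train, variables, outcome)
    function(newdata) predict_risk(m, newdata)
  }
}

#' Recipe: the full selection-plus-fit procedure
#'
#' Re-runs the entire Model-1 construction (encoding, LASSO path,
#' cross-validated lambda, top-k selection, logistic refit) inside each
#' training fold, so the cross-validated performance accounts for the
#' selection step.
#'
#' @inheritParams build_model_suite
#' @param inner_folds folds of the inner lambda cross-validation.
#' @export
selection_recipe <- function(candidates = NULL, outcome = "he", k_top = 7,
                             inner_folds = 5, seed = 1L) {
  force(candidates); force(outcome); force(k_top); force(inner_folds)
  force(seed)
  function(train) {
    cand <- candidates
    if (is.null(cand))
      cand <- setdiff(colnames(train),
                      c("id", outcome, "sri", "dcv", "baseline_ml",
                        "followup_ml", "volume_ml"))
    X <- encode_features(train, cand)
    y <- train[[outcome]]
    path <- select_lambda_cv(X, y, k = inner_folds, seed = seed)
    sel <- suppressWarnings(select_top_k(path, k = k_top))
    if (length(sel) == 0) {
      prev <- mean(y)
      return(function(newdata) rep(prev, nrow(newdata)))
    }
    m <- fit_logistic(train, sel, outcome)
    function(newdata) predict_risk(m, newdata)
  }
}

#' Stratified k-fold cross-validated evaluation
#'
#' Assigns records to `k` outcome-stratified folds (seed-deterministic),
#' re-runs the full model-building recipe on each training fold, pools the
#' out-of-fold predictions and reports pooled AUROC and calibration plus
#' per-fold AUROCs.
#'
#' @param table cohort data frame.
#' @param recipe a function `train -> (newdata -> probabilities)`, e.g.
#'   [logistic_recipe()] or [selection_recipe()].
#' @param k number of folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param outcome binary outcome column name.
#' @param bins calibration bins.
#' @return List with `pooled_auroc`, `fold_auroc`, `calibration`,
#'   `predictions` (out-of-fold, in row order), `foldid`.
#' @export
crossval_evaluate <- function(table, recipe, k = 5, seed = 1L,
                              outcome = "he", bins = 10) {
  stopifnot(is.data.frame(table), is.function(recipe))
  y <- check_labels(table[[outcome]])
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (min(n1, n0) < k)
    stop("too few events to give every fold at least one", call. = FALSE)
  foldid <- integer(length(y))
  foldid[y == 1L] <- with_stream(seed, "folds_event",
                                 sample(rep_len(seq_len(k), n1)))
  foldid[y == 0L] <- with_stream(seed, "folds_nonevent",
                                 sample(rep_len(seq_len(k), n0)))
  pred <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    train <- table[foldid != f, , drop = FALSE]
    test <- table[foldid == f, , drop = FALSE]
    predictor <- recipe(train)
    pred[foldid == f] <- predictor(test)
  }
  fold_auc <- vapply(seq_len(k), function(f)
    auroc(pred[foldid == f], y[foldid == f]), numeric(1))
  list(pooled_auroc = auroc(pred, y),
       fold_auroc = fold_auc,
       calibration = calibration_curve(pred, y, bins = bins),
       predictions = pred, foldid = foldid)
}

#' Pairwise comparison of the three models
#'
#' For each pair (Model 2 vs 1, Model 3 vs 1, Model 3 vs 2) on the given
#' cohort: DeLong p-value for the AUROC difference, continuous NRI and IDI
#' with percentile-bootstrap confidence intervals. Models are held fixed
#' across resamples by default (`refit = FALSE`); with `refit = TRUE` each
#' model is refitted (same variables) on every resample.
#'
#' @param suite a [build_model_suite()] result.
#' @param table evaluation cohort (derivation or external validation).
#' @param B bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param refit refit the models on each resample?
#' @return Data frame of class `comparison_report` with one row per pair:
#'   `comparison`, `auroc_new`, `auroc_old`, `delong_p`, `nri`, `nri_low`,
#'   `nri_high`, `idi`, `idi_low`, `idi_high`.
#' @export
compare_models <- function(suite, table, B = 5000, seed = 1L,
                           refit = FALSE) {
  stopifnot(inherits(suite, "model_suite"))
  y <- check_labels(table[[suite$outcome]])
  preds <- lapply(suite$models, predict_risk, newdata = table)
  pairs <- list(c(2, 1), c(3, 1), c(3, 2))
  rows <- lapply(seq_along(pairs), function(i) {
    new_i <- pairs[[i]][1]; old_i <- pairs[[i]][2]
    p_new <- preds[[new_i]]; p_old <- preds[[old_i]]
    dl <- delong_test(p_new, p_old, y)
    stat <- function(metric) {
      function(idx) {
        pn <- p_new[idx]; po <- p_old[idx]
        if (refit) {
          res <- table[idx, , drop = FALSE]
          mn <- fit_logistic(res, suite$models[[new_i]]$variables,
                             suite$outcome)
          mo <- fit_logistic(res, suite$models[[old_i]]$variables,
                             suite$outcome)
          pn <- predict_risk(mn, res); po <- predict_risk(mo, res)
        }
        metric(po, pn, y[idx])
      }
    }
    nri_ci <- bootstrap_ci(stat(continuous_nri), n = length(y), B = B,
                           seed = stream_seed(seed, paste0("nri", i)),
                           labels = y)
    idi_ci <- bootstrap_ci(stat(idi), n = length(y), B = B,
                           seed = stream_seed(seed, paste0("idi", i)),
                           labels = y)
    data.frame(comparison = sprintf("Model %d vs Model %d", new_i, old_i),
               auroc_new = dl$auroc_a, auroc_old = dl$auroc_b,
               delong_p = dl$p,
               nri = continuous_nri(p_old, p_new, y),
               nri_low = nri_ci$low, nri_high = nri_ci$high,
               idi = idi(p_old, p_new, y),
               idi_low = idi_ci$low, idi_high = idi_ci$high)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", "data.frame")
  out
}
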