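# Orchestration: cohort summary in the reporting style of a baseline
# characteristics table, and the end-to-end run (measure/generate ->
# models -> evaluation -> comparison) with deterministic, manifest-stamped
# outputs.

# round-half-up to `digits` decimals (R's round() is round-half-even, which
# would print 19.15 -> 19.1 rather than the conventional 19.2)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarise a cohort table
#'
#' One row per variable: binary columns as count (percentage, one decimal,
#' half-up), numeric columns as median (IQR). The outcome prevalence row
#' is listed first.
#'
#' @param table cohort data frame.
#' @param outcome binary outcome column (default `"he"`).
#' @return Data frame of class `cohort_summary` with columns `variable`,
#'   `type`, `summary`, `value`, and for binary rows `count` and
#'   `percent`.
#' @examples
#' tab <- data.frame(he = rep(c(1, 0), c(70, 294)),
#'                   male = rep(c(1, 0), c(265, 99)))
#' summarize_cohort(tab)  # 70 (19.2%), 265 (72.8%)
#' @export
summarize_cohort <- function(table, outcome = "he") {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("empty cohort table", call. = FALSE)
  vars <- setdiff(colnames(table), "id")
  if (outcome %in% vars) vars <- c(outcome, setdiff(vars, outcome))
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.logical(x)) x <- as.integer(x)
    if (is.numeric(x) && all(x %in% c(0, 1))) {
      cnt <- sum(x == 1)
      pct <- round_half_up(100 * cnt / length(x), 1)
      data.frame(variable = v, type = "binary",
                 summary = sprintf("%d (%.1f%%)", cnt, pct),
                 value = pct, count = cnt, percent = pct)
    } else if (is.numeric(x)) {
      med <- stats::median(x)
      iqr <- stats::IQR(x)
      data.frame(variable = v, type = "numeric",
                 summary = sprintf("%.1f (IQR: %.1f)", med, iqr),
                 value = med, count = NA_integer_, percent = NA_real_)
    } else {
      data.frame(variable = v, type = "other",
                 summary = paste(length(unique(x)), "distinct values"),
                 value = NA_real_, count = NA_integer_, percent = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

# FNV-1a hash of a character scalar, returned as 8 hex digits; used to
# stamp configs and outputs into the run manifest without binary deps
fnv1a <- function(text) {
  bytes <- utf8ToInt(enc2utf8(paste(text, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648) , b) +
      (if (h >= 2147483648) 2147483648 else 0)
    # multiply by the FNV prime 16777619 mod 2^32 without losing precision
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

serialize_model <- function(model) {
  list(model_id = model$model_id,
       variables = as.list(model$variables),
       coefficients = as.list(model$coefficients),
       n = model$fit_metadata$n, events = model$fit_metadata$events,
       converged = model$fit_metadata$converged)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, applies complete-case filtering, builds
#' the three nested models, evaluates discrimination, calibration and
#' decision curves for each, compares the model pairs, and writes every
#' artifact to `output_dir` as CSV/JSON plus a line-oriented log and a
#' manifest with config and results hashes. Outputs are a deterministic
#' function of `(config, seed)`.
#'
#' @param config a list (or path to a JSON file) with any of:
#'   `cohort_csv` (path; otherwise a synthetic cohort is generated),
#'   `n` (synthetic cohort size, default 364), `candidates`, `k_top`
#'   (default 7), `cv_folds` (default 5), `bootstrap_B` (default 5000),
#'   `thresholds` (DCA grid), `seed` (required), `output_dir` (required).
#' @return Invisibly, a list with `suite`, `summary`, `evaluations`,
#'   `comparisons`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  if (is.null(config$output_dir))
    stop("config$output_dir is required", call. = FALSE)
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logmsg <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # --- cohort -------------------------------------------------------------
  tab <- tryCatch({
    if (!is.null(config$cohort_csv)) {
      logmsg("cohort", "reading ", config$cohort_csv)
      if (!file.exists(config$cohort_csv))
        stop("cohort file not found: ", config$cohort_csv, call. = FALSE)
      utils::read.csv(config$cohort_csv)
    } else {
      n <- if (is.null(config$n)) 364L else as.integer(config$n)
      logmsg("cohort", "generating synthetic cohort, n = ", n)
      generate_cohort(cohort_spec(n = n, seed = seed))
    }
  }, error = function(e) fail("cohort", e))
  n0 <- nrow(tab)
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < n0)
    logmsg("cohort", "complete-case filter removed ", n0 - nrow(tab),
           " record(s)")
  utils::write.csv(tab, file.path(out_dir, "cohort.csv"), row.names = FALSE)

  # --- summary ------------------------------------------------------------
  summ <- tryCatch(summarize_cohort(tab),
                   error = function(e) fail("summary", e))
  utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  logmsg("summary", "HE prevalence ",
         summ$summary[summ$variable == "he"])

  # --- models -------------------------------------------------------------
  k_top <- if (is.null(config$k_top)) 7 else config$k_top
  cv_folds <- if (is.null(config$cv_folds)) 5 else config$cv_folds
  suite <- tryCatch(
    build_model_suite(tab, candidates = config$candidates, k_top = k_top,
                      cv_folds = cv_folds, seed = seed),
    error = function(e) fail("models", e))
  logmsg("models", "lambda_opt = ", format(suite$path$lambda_opt,
                                           digits = 4),
         "; Model 1: ", paste(suite$selection, collapse = ", "))
  for (m in suite$models)
    jsonlite::write_json(serialize_model(m),
                         file.path(out_dir,
                                   sprintf("model%d.json", m$model_id)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- evaluation ---------------------------------------------------------
  thresholds <- if (is.null(config$thresholds))
    seq(0.01, 0.99, by = 0.01) else config$thresholds
  y <- tab[[suite$outcome]]
  evals <- tryCatch(lapply(suite$models, function(m) {
    p <- predict_risk(m, tab)
    list(model_id = m$model_id, auroc = auroc(p, y),
         calibration = calibration_curve(p, y),
         dca = decision_curve(p, y, thresholds), predictions = p)
  }), error = function(e) fail("evaluation", e))
  roc_tab <- data.frame(model = vapply(evals, `[[`, 0, "model_id"),
                        auroc = vapply(evals, `[[`, 0, "auroc"))
  utils::write.csv(roc_tab, file.path(out_dir, "auroc.csv"),
                   row.names = FALSE)
  for (ev in evals) {
    utils::write.csv(ev$calibration,
                     file.path(out_dir,
                               sprintf("calibration_model%d.csv",
                                       ev$model_id)), row.names = FALSE)
    utils::write.csv(ev$dca,
                     file.path(out_dir,
                               sprintf("dca_model%d.csv", ev$model_id)),
                     row.names = FALSE)
  }
  logmsg("evaluation", "AUROC: ",
         paste(sprintf("Model %d %.3f", roc_tab$model, roc_tab$auroc),
               collapse = ", "))

  # --- comparison ---------------------------------------------------------
  B <- if (is.null(config$bootstrap_B)) 5000 else config$bootstrap_B
  comp <- tryCatch(
    suppressMessages(compare_models(suite, tab, B = B, seed = seed)),
    error = function(e) fail("comparison", e))
  utils::write.csv(comp, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  logmsg("comparison", "wrote ", nrow(comp), " pairwise rows (B = ", B, ")")

  # --- manifest -----------------------------------------------------------
  cfg <- config[setdiff(names(config), "output_dir")]  # location, not a parameter
  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))],
                               auto_unbox = TRUE, digits = NA)
  outputs <- sort(setdiff(list.files(out_dir),
                          c("manifest.json", "log.txt")))
  results_hash <- fnv1a(vapply(outputs, function(f)
    fnv1a(readChar(file.path(out_dir, f), 1e7, useBytes = TRUE)),
    character(1)))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("ichmorph")),
                   seed = seed, config_hash = fnv1a(cfg_json),
                   results_hash = results_hash, outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(suite = suite, summary = summ, evaluations = evals,
                 comparisons = comp, manifest = manifest))
}
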