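#' Unpenalised logistic regression fit
#'
#' Maximum-likelihood logistic fit on raw-scale variables, used for the
#' final (post-selection) models whose coefficients feed the nomograms.
#' Perfect or quasi-perfect separation is an error rather than a silently
#' regularised fit, because diverging coefficients would make the nomogram
#' point scales meaningless.
#'
#' @param table data frame containing `variables` and `outcome`.
#' @param variables character vector of predictor column names.
#' @param outcome name of the binary outcome column (default `"he"`).
#' @param model_id optional label (1, 2 or 3 in the model suite).
#' @return An object of class `fitted_model`: list with `model_id`,
#'   `variables`, `coefficients` (named, raw scale, including
#'   `(Intercept)`), `vcov`, `fit_metadata` (n, events, converged) and the
#'   underlying `glm` fit.
#' @export
fit_logistic <- function(table, variables, outcome = "he",
                         model_id = NULL) {
  stopifnot(is.data.frame(table))
  missing_vars <- setdiff(c(variables, outcome), colnames(table))
  if (length(missing_vars) > 0)
    stop("columns not present in table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  y <- table[[outcome]]
  if (length(unique(y)) < 2)
    stop("outcome has a single class", call. = FALSE)
  rhs <- if (length(variables) == 0) "1" else
    paste(variables, collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = table),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warning <<- TRUE
      invokeRestart("muffleWarning")
    })
  eta <- stats::predict(fit, type = "link")
  if (sep_warning && max(abs(eta)) > 15)
    stop("perfect (or quasi-perfect) separation detected: the logistic ",
         "MLE does not exist. Remove or merge the separating variable(s) ",
         "before fitting; do not rely on a silently regularised fit.",
         call. = FALSE)
  structure(list(model_id = model_id, variables = variables,
                 coefficients = stats::coef(fit),
                 vcov = stats::vcov(fit),
                 fit_metadata = list(n = nrow(table),
                                     events = sum(y == 1),
                                     converged = fit$converged),
                 glm = fit),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  id <- if (is.null(x$model_id)) "" else paste0(" (Model ", x$model_id, ")")
  cat("<fitted_model>", id, " ", x$fit_metadata$events, "/",
      x$fit_metadata$n, " events; variables: ",
      paste(x$variables, collapse = ", "), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted expansion risk
#'
#' Inverse-logit of the linear predictor: `p = plogis(a + sum(b * x))`.
#'
#' @param model a [fit_logistic()] result.
#' @param newdata data frame with the model's variables.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_risk <- function(model, newdata) {
  stopifnot(inherits(model, "fitted_model"))
  missing_vars <- setdiff(model$variables, colnames(newdata))
  if (length(missing_vars) > 0)
    stop("newdata lacks model variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  if (!is.null(model$glm))
    return(as.numeric(stats::predict(model$glm, newdata = newdata,
                                     type = "response")))
  b <- model$coefficients
  eta <- rep(b[["(Intercept)"]], nrow(newdata))
  for (v in model$variables) eta <- eta + b[[v]] * as.numeric(newdata[[v]])
  stats::plogis(eta)
}

#' Default radiological sign columns
#'
#' The eight qualitative signs used as candidate predictors: the CTA spot
#' sign and seven non-contrast CT signs.
#' @return Character vector of column names.
#' @export
sign_variables <- function() {
  c("cta_spot", "hypodensities", "blend", "black_hole", "island",
    "satellite", "heterogeneous", "irregular")
}

#' Build the three nested expansion models
#'
#' Model 1: LASSO-selected top-`k_top` variables from the candidate set of
#' clinical covariates and radiological signs (quantitative shape/density
#' markers excluded from selection). Model 2: Model 1's variables plus SRI
#' and DCV. Model 3: Model 1's clinical (non-sign) variables plus SRI and
#' DCV, i.e. the quantitative markers replace all imaging signs. Each model
#' is then fitted by unpenalised logistic regression on the raw scale.
#'
#' @param table cohort data frame (see [generate_cohort()] for the column
#'   conventions).
#' @param candidates candidate variables for selection; defaults to every
#'   column except `id`, the outcome, SRI/DCV and the volume pair.
#' @param quantitative the quantitative marker columns (default
#'   `c("sri", "dcv")`).
#' @param signs which candidate columns are imaging signs (dropped in
#'   Model 3); default [sign_variables()].
#' @param outcome binary outcome column name.
#' @param k_top number of variables selected into Model 1 (default 7).
#' @param cv_folds folds for the lambda cross-validation.
#' @param seed integer seed (fold assignment).
#' @return An object of class `model_suite`: list with `models` (list of
#'   three `fitted_model`s), `path` (the CV'd `lasso_path`), `selection`
#'   (ordered selected variables), `candidates`, `seed`.
#' @export
build_model_suite <- function(table, candidates = NULL,
                              quantitative = c("sri", "dcv"),
                              signs = sign_variables(), outcome = "he",
                              k_top = 7, cv_folds = 5, seed = 1L) {
  stopifnot(is.data.frame(table))
  if (is.null(candidates))
    candidates <- setdiff(colnames(table),
                          c("id", outcome, quantitative,
                            "baseline_ml", "followup_ml", "volume_ml"))
  missing_vars <- setdiff(c(candidates, quantitative, outcome),
                          colnames(table))
  if (length(missing_vars) > 0)
    stop("columns not present in table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  X <- encode_features(table, candidates)
  y <- table[[outcome]]
  path <- lasso_logistic_path(X, y)
  path <- select_lambda_cv(X, y, k = cv_folds, seed = seed, path = path)
  selection <- select_top_k(path, k = k_top)
  m1 <- fit_logistic(table, selection, outcome, model_id = 1)
  m2 <- fit_logistic(table, c(selection, quantitative), outcome,
                     model_id = 2)
  clinical <- setdiff(selection, signs)
  m3 <- fit_logistic(table, c(clinical, quantitative), outcome,
                     model_id = 3)
  structure(list(models = list(model1 = m1, model2 = m2, model3 = m3),
                 path = path, selection = selection,
                 candidates = candidates, quantitative = quantitative,
                 signs = signs, outcome = outcome, seed = seed),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("<model_suite> lambda_opt = ", format(x$path$lambda_opt, digits = 4),
      "; selection: ", paste(x$selection, collapse = ", "), "\n", sep = "")
  for (m in x$models)
    cat("  Model ", m$model_id, ": ",
        paste(m$variables, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Nomogram point tables for a fitted model
#'
#' Maps each variable's observed range onto a 0–100 point scale: the
#' variable with the largest `|coefficient| * range` spans exactly 0–100
#' points, every other variable spans proportionally fewer, and points are
#' affine in the variable's contribution to the linear predictor
#' (direction-aware, so more points always means higher risk). The total
#' points map back to predicted risk through the linear predictor, so
#' summing a record's points and reading the lookup reproduces
#' [predict_risk()] exactly.
#'
#' @param model a `fitted_model`.
#' @param data data frame used to set the variable ranges (training
#'   cohort), or `NULL` if `ranges` is given.
#' @param ranges optional named list `variable -> c(min, max)`.
#' @param grid_length points per variable table (numeric variables).
#' @return An object of class `nomogram`: list with `points` (per-variable
#'   data frames of value/points), `risk` (data frame total_points/risk),
#'   `unit` (linear-predictor change per point) and `base` (linear
#'   predictor at the zero-point reference).
#' @export
nomogram_table <- function(model, data = NULL, ranges = NULL,
                           grid_length = 11) {
  stopifnot(inherits(model, "fitted_model"))
  b <- model$coefficients
  vars <- model$variables
  if (is.null(ranges)) {
    if (is.null(data))
      stop("supply `data` or `ranges`", call. = FALSE)
    ranges <- lapply(vars, function(v) range(as.numeric(data[[v]])))
    names(ranges) <- vars
  }
  span <- vapply(vars, function(v)
    abs(b[[v]]) * diff(ranges[[v]]), numeric(1))
  if (all(span == 0))
    stop("all model variables have zero range or zero coefficient",
         call. = FALSE)
  maxspan <- max(span)
  unit <- maxspan / 100                      # linear predictor per point
  ref <- vapply(vars, function(v)
    if (b[[v]] >= 0) ranges[[v]][1] else ranges[[v]][2], numeric(1))
  base <- b[["(Intercept)"]] + sum(b[vars] * ref)
  points_of <- function(v, x) (b[[v]] * (x - ref[[v]])) / unit
  tables <- lapply(vars, function(v) {
    r <- ranges[[v]]
    x <- if (isTRUE(all.equal(r[1], 0)) && isTRUE(all.equal(r[2], 1)))
      c(0, 1) else seq(r[1], r[2], length.out = grid_length)
    data.frame(value = x, points = points_of(v, x))
  })
  names(tables) <- vars
  total_max <- sum(vapply(tables, function(t) max(t$points), numeric(1)))
  tp <- seq(0, max(total_max, 100), length.out = 101)
  risk <- data.frame(total_points = tp,
                     risk = stats::plogis(base + unit * tp))
  structure(list(points = tables, risk = risk, unit = unit, base = base,
                 ref = ref, ranges = ranges, coefficients = b,
                 model_id = model$model_id),
            class = "nomogram")
}

#' Total nomogram points for records
#'
#' @param nomogram a [nomogram_table()] result.
#' @param newdata data frame with the model variables.
#' @return Numeric vector of total points; converting through the
#'   nomogram's risk mapping reproduces the model's predicted risk.
#' @export
nomogram_points <- function(nomogram, newdata) {
  stopifnot(inherits(nomogram, "nomogram"))
  vars <- names(nomogram$points)
  b <- nomogram$coefficients
  total <- rep(0, nrow(newdata))
  for (v in vars)
    total <- total + (b[[v]] * (as.numeric(newdata[[v]]) -
                                nomogram$ref[[v]])) / nomogram$unit
  total
}

#' @export
print.nomogram <- function(x, ...) {
  cat("<nomogram>", if (!is.null(x$model_id))
    paste0(" Model ", x$model_id), " — points per variable:\n", sep = "")
  for (v in names(x$points))
    cat(sprintf("  %-14s %6.1f .. %6.1f points\n", v,
                min(x$points[[v]]$points), max(x$points[[v]]$points)))
  invisible(x)
}
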