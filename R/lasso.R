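# L1-penalised logistic regression for variable selection. The path itself
# is fitted by glmnet (coordinate descent with warm starts); the lambda
# grid, fold stratification, tuning criterion and top-k selection rule are
# defined here.

design_x <- function(x) {
  if (inherits(x, "design_matrix")) x$matrix else as.matrix(x)
}

#' L1-penalised logistic coefficient path
#'
#' Fits penalised logistic coefficients along a decreasing lambda grid. By
#' default the grid has 100 log-spaced values running four decades down
#' from `lambda_max = max_j |sum_i x_ij (y_i - ybar)| / n`, the smallest
#' penalty at which every non-intercept coefficient is zero. Columns are
#' used as supplied (standardise with [encode_features()] first); the
#' intercept is unpenalised.
#'
#' @param x a `design_matrix` or numeric matrix.
#' @param y binary outcome vector (0/1) with both classes present.
#' @param lambdas optional decreasing positive grid.
#' @param nlambda,lambda_min_ratio grid size and lower end relative to
#'   `lambda_max`.
#' @param thresh coordinate-descent convergence tolerance.
#' @return An object of class `lasso_path`: list with `lambdas`,
#'   `coefficients` (p x L matrix), `intercepts`, `lambda_max`, the
#'   underlying `glmnet` fit, and (after [select_lambda_cv()]) `cv` and
#'   `lambda_opt`.
#' @export
lasso_logistic_path <- function(x, y, lambdas = NULL, nlambda = 100,
                                lambda_min_ratio = 1e-4, thresh = 1e-7) {
  X <- design_x(x)
  y <- as.numeric(y)
  if (any(!is.finite(X))) stop("non-finite values in design matrix",
                               call. = FALSE)
  if (length(unique(y)) < 2)
    stop("outcome has a single class", call. = FALSE)
  n <- nrow(X)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (is.null(lambdas)) {
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = nlambda))
  } else {
    if (any(diff(lambdas) >= 0) || any(lambdas <= 0))
      stop("lambdas must be a decreasing positive sequence", call. = FALSE)
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = lambdas,
                        standardize = FALSE, thresh = thresh)
  beta <- as.matrix(fit$beta)
  structure(list(lambdas = fit$lambda, coefficients = beta,
                 intercepts = as.numeric(fit$a0), lambda_max = lambda_max,
                 glmnet_fit = fit,
                 encoding = if (inherits(x, "design_matrix")) x$encoding,
                 cv = NULL, lambda_opt = NULL),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("<lasso_path> ", nrow(x$coefficients), " coefficients, ",
      length(x$lambdas), " lambdas (max ", format(x$lambda_max, digits = 4),
      ")", sep = "")
  if (!is.null(x$lambda_opt))
    cat(", lambda_opt ", format(x$lambda_opt, digits = 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Select the penalty by stratified k-fold cross-validation
#'
#' Folds are stratified by outcome (events and non-events assigned to
#' folds separately, shuffled under `seed`), and the selected lambda
#' minimises the mean out-of-fold binomial deviance (the minimum-error
#' criterion; no one-standard-error rule).
#'
#' @inheritParams lasso_logistic_path
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param path optional [lasso_logistic_path()] result whose grid is reused.
#' @return The `lasso_path` with `cv` (per-lambda mean and SE of the
#'   out-of-fold deviance) and `lambda_opt` filled in.
#' @export
select_lambda_cv <- function(x, y, k = 5, seed = 1L, path = NULL,
                             thresh = 1e-7) {
  X <- design_x(x)
  y <- as.numeric(y)
  n_event <- sum(y == 1); n_non <- sum(y == 0)
  if (min(n_event, n_non) < k)
    stop("too few events (", min(n_event, n_non),
         ") to stratify into ", k, " folds", call. = FALSE)
  if (is.null(path)) path <- lasso_logistic_path(x, y, thresh = thresh)
  foldid <- integer(length(y))
  foldid[y == 1] <- with_stream(seed, "folds_event",
                                sample(rep_len(seq_len(k), n_event)))
  foldid[y == 0] <- with_stream(seed, "folds_nonevent",
                                sample(rep_len(seq_len(k), n_non)))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                          lambda = path$lambdas, standardize = FALSE,
                          type.measure = "deviance", thresh = thresh)
  path$cv <- data.frame(lambda = cv$lambda, mean_deviance = cv$cvm,
                        se_deviance = cv$cvsd)
  path$lambda_opt <- cv$lambda.min
  path$foldid <- foldid
  path
}

#' Top-k variables by absolute penalised coefficient
#'
#' Returns the `k` variables with the largest absolute standardised-scale
#' coefficients at the selected lambda, in descending order of
#' `|coefficient|`. One-hot level columns are aggregated to their source
#' variable (scored by the largest `|coefficient|` among the levels), so a
#' categorical variable counts once towards `k`. Exact ties are broken
#' lexicographically by variable name. If fewer than `k` variables have
#' non-zero coefficients, all non-zero ones are returned with a warning.
#'
#' @param path a `lasso_path` with `lambda_opt` set (see
#'   [select_lambda_cv()]), or `lambda` given explicitly.
#' @param k number of variables to keep (default 7, the 10
#'   events-per-variable budget of a 70-event cohort).
#' @param lambda optional penalty at which to read the coefficients.
#' @return Character vector of source-variable names, ordered by
#'   decreasing `|coefficient|`, with the scores as attribute `scores`.
#' @export
select_top_k <- function(path, k = 7, lambda = NULL) {
  stopifnot(inherits(path, "lasso_path"))
  if (is.null(lambda)) lambda <- path$lambda_opt
  if (is.null(lambda))
    stop("no lambda selected; run select_lambda_cv() or supply `lambda`",
         call. = FALSE)
  idx <- which.min(abs(path$lambdas - lambda))
  beta <- path$coefficients[, idx]
  source_of <- function(nm) {
    e <- path$encoding[[nm]]
    if (is.null(e)) nm else e$source
  }
  src <- vapply(names(beta), source_of, character(1))
  score <- tapply(abs(beta), src, max)
  score <- score[score > 0]
  if (length(score) == 0) {
    warning("no non-zero coefficients at the selected lambda")
    return(character(0))
  }
  ord <- order(-score, names(score))
  selected <- names(score)[ord]
  if (length(selected) < k)
    warning("only ", length(selected), " variables have non-zero ",
            "coefficients (requested ", k, ")")
  out <- utils::head(selected, k)
  attr(out, "scores") <- score[ord][seq_along(out)]
  out
}
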