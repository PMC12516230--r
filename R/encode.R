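#' Encode cohort variables into a numeric design matrix
#'
#' Categorical variables are one-hot encoded with the first (reference)
#' level dropped; binary 0/1 variables (including logicals and two-level
#' factors) become a single unstandardised indicator column; all other
#' numeric variables are standardised to `(x - mean) / sd` using the sample
#' SD (divisor n-1). When `training` is supplied (a `design_matrix` from a
#' previous call), its means, SDs and level sets are reused, so new data is
#' transformed exactly as the training data was; an unseen factor level is
#' an error naming the level. The encoding record allows exact
#' back-transformation of standardised-scale coefficients to the raw scale.
#'
#' @param table a data frame.
#' @param variables character vector of column names to encode.
#' @param training optional `design_matrix` whose encoding is reused.
#' @return An object of class `design_matrix`: list with `matrix` (n x p
#'   numeric), `encoding` (per-column records: source variable, type,
#'   level, center, scale) and `levels` (per-factor level sets).
#' @export
encode_features <- function(table, variables, training = NULL) {
  stopifnot(is.data.frame(table))
  missing_vars <- setdiff(variables, colnames(table))
  if (length(missing_vars) > 0)
    stop("variables not present in table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  for (v in variables)
    if (anyNA(table[[v]]))
      stop("missing values in variable '", v,
           "'; apply complete-case filtering first", call. = FALSE)

  if (!is.null(training)) {
    stopifnot(inherits(training, "design_matrix"))
    return(apply_encoding(table, training))
  }

  cols <- list(); enc <- list(); levs <- list()
  for (v in variables) {
    x <- table[[v]]
    if (is.logical(x)) x <- as.integer(x)
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      lv <- levels(droplevels(x))
      levs[[v]] <- lv
      if (length(lv) < 2)
        stop("variable '", v, "' has a single level", call. = FALSE)
      for (l in lv[-1]) {
        nm <- paste0(v, ".", l)
        cols[[nm]] <- as.numeric(x == l)
        enc[[nm]] <- list(source = v, type = "onehot", level = l,
                          center = 0, scale = 1)
      }
    } else if (is.numeric(x)) {
      if (all(x %in% c(0, 1))) {
        cols[[v]] <- as.numeric(x)
        enc[[v]] <- list(source = v, type = "binary", level = NA,
                         center = 0, scale = 1)
      } else {
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0)
          stop("variable '", v, "' has zero SD; cannot standardise",
               call. = FALSE)
        m <- mean(x)
        cols[[v]] <- (x - m) / s
        enc[[v]] <- list(source = v, type = "numeric", level = NA,
                         center = m, scale = s)
      }
    } else {
      stop("variable '", v, "' has unsupported type ", class(x)[1],
           call. = FALSE)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(matrix = X, encoding = enc, levels = levs,
                 variables = variables),
            class = "design_matrix")
}

apply_encoding <- function(table, training) {
  cols <- list()
  for (nm in names(training$encoding)) {
    e <- training$encoding[[nm]]
    x <- table[[e$source]]
    if (is.null(x))
      stop("variable '", e$source, "' not present in table", call. = FALSE)
    if (e$type == "onehot") {
      if (is.logical(x)) x <- as.integer(x)
      x <- as.character(x)
      unseen <- setdiff(unique(x), training$levels[[e$source]])
      if (length(unseen) > 0)
        stop("unseen level(s) in variable '", e$source, "': ",
             paste(unseen, collapse = ", "), call. = FALSE)
      cols[[nm]] <- as.numeric(x == e$level)
    } else if (e$type == "binary") {
      cols[[nm]] <- as.numeric(x)
    } else {
      cols[[nm]] <- (as.numeric(x) - e$center) / e$scale
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(matrix = X, encoding = training$encoding,
                 levels = training$levels, variables = training$variables),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " (", length(x$variables), " source variables)\n", sep = "")
  invisible(x)
}
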