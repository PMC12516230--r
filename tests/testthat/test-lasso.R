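sim_design <- function(n, p, beta, seed, intercept = -1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  eta <- intercept + X %*% beta
  y <- rbinom(n, 1, plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}

test_that("at lambda_max all coefficients vanish and the intercept is logit(ybar)", {
  d <- sim_design(300, 4, c(1, -0.5, 0, 0), seed = 1)
  path <- lasso_logistic_path(d$X, d$y)
  expect_true(all(path$coefficients[, 1] == 0))
  expect_equal(path$intercepts[1], qlogis(mean(d$y)), tolerance = 1e-6)
  # KKT: the gradient bound at the null model defines lambda_max
  expect_equal(path$lambda_max,
               max(abs(crossprod(d$X, d$y - mean(d$y)))) / nrow(d$X))
})

test_that("the path approaches the unpenalised MLE as lambda -> 0", {
  d <- sim_design(200, 3, c(0.8, -0.6, 0.3), seed = 2)
  lam <- max(abs(crossprod(d$X, d$y - mean(d$y)))) / 200
  grid <- exp(seq(log(lam), log(lam * 1e-7), length.out = 120))
  path <- lasso_logistic_path(d$X, d$y, lambdas = grid, thresh = 1e-12)
  mle <- glm(d$y ~ d$X, family = binomial())
  expect_equal(unname(path$coefficients[, 120]),
               unname(coef(mle)[-1]), tolerance = 1e-4)
  expect_equal(path$intercepts[120], unname(coef(mle)[1]),
               tolerance = 1e-4)
})

test_that("duplicating a column leaves predictions unchanged", {
  d <- sim_design(250, 3, c(1, -0.5, 0.2), seed = 3)
  Xd <- cbind(d$X, x1b = d$X[, 1])
  p1 <- lasso_logistic_path(d$X, d$y)
  p2 <- lasso_logistic_path(Xd, d$y, lambdas = p1$lambdas)
  k <- 50  # a mid-path penalty
  eta1 <- p1$intercepts[k] + d$X %*% p1$coefficients[, k]
  eta2 <- p2$intercepts[k] + Xd %*% p2$coefficients[, k]
  expect_equal(as.numeric(plogis(eta1)), as.numeric(plogis(eta2)),
               tolerance = 1e-4)
})

test_that("cross-validated lambda selection is stratified and reproducible", {
  d <- sim_design(300, 5, c(1.2, -0.8, 0, 0, 0), seed = 4)
  a <- select_lambda_cv(d$X, d$y, seed = 11)
  b <- select_lambda_cv(d$X, d$y, seed = 11)
  expect_identical(a$lambda_opt, b$lambda_opt)
  expect_identical(a$foldid, b$foldid)
  # every fold holds events and non-events
  for (f in 1:5) {
    expect_gt(sum(d$y[a$foldid == f] == 1), 0)
    expect_gt(sum(d$y[a$foldid == f] == 0), 0)
  }
  expect_error(select_lambda_cv(d$X, c(rep(0, 297), 1, 1, 1), k = 5),
               "stratify")
})

test_that("pure-noise covariates leave the null model competitive", {
  res <- vapply(1:50, function(s) {
    set.seed(10000 + s)
    X <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    y <- c(0, 1, rbinom(198, 1, 0.3))
    path <- select_lambda_cv(X, y, seed = s)
    idx <- which.min(abs(path$lambdas - path$lambda_opt))
    c(nonzero = sum(path$coefficients[, idx] != 0), idx = idx)
  }, numeric(2))
  # lambda_opt sits near the top of the grid (heaviest penalties) and the
  # selected models are essentially empty
  expect_gte(mean(res["idx", ] <= 25), 0.8)
  expect_lte(median(res["nonzero", ]), 1)
})

test_that("a strong predictor survives selection at lambda_opt", {
  hits <- vapply(1:20, function(s) {
    d <- sim_design(1000, 4, c(2, 0, 0, 0), seed = 100 + s)
    path <- select_lambda_cv(d$X, d$y, seed = s)
    sel <- suppressWarnings(select_top_k(path, k = 4))
    "x1" %in% sel
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("top-k ranking, grouping, ties and boundaries behave as documented", {
  fake_path <- structure(list(
    lambdas = 0.1,
    coefficients = matrix(c(0.5, -0.7, 0.1, 0), ncol = 1,
                          dimnames = list(c("a", "b", "c", "d"), NULL)),
    intercepts = 0, lambda_max = 1, encoding = NULL, lambda_opt = 0.1),
    class = "lasso_path")
  expect_identical(as.character(select_top_k(fake_path, k = 2)),
                   c("b", "a"))
  tied <- fake_path
  tied$coefficients[, 1] <- c(0.5, -0.5, 0.2, 0)
  expect_identical(as.character(select_top_k(tied, k = 1)), "a")

  onehot <- fake_path
  rownames(onehot$coefficients) <- c("loc.a", "loc.b", "x", "z")
  onehot$coefficients[, 1] <- c(0.2, -0.9, 0.5, 0)
  onehot$encoding <- list(
    `loc.a` = list(source = "loc", type = "onehot"),
    `loc.b` = list(source = "loc", type = "onehot"),
    x = list(source = "x", type = "numeric"),
    z = list(source = "z", type = "numeric"))
  sel <- select_top_k(onehot, k = 2)
  expect_identical(as.character(sel), c("loc", "x"))

  allzero <- fake_path
  allzero$coefficients[, 1] <- rep(0, 4)
  expect_warning(sel0 <- select_top_k(allzero, k = 2), "non-zero")
  expect_length(sel0, 0)
  expect_warning(select_top_k(fake_path, k = 5), "only 3")
})
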