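test_that("logistic fits recover generating coefficients and basic MLE facts", {
  tab <- generate_risk_cohort(5000, intercept = -0.9, beta_sri = -0.05,
                              beta_dcv = 0.25, seed = 21)
  m <- fit_logistic(tab, c("sri", "dcv"))
  truth <- attr(tab, "truth")
  se <- sqrt(diag(m$vcov))
  for (v in c("(Intercept)", "sri", "dcv"))
    expect_lt(abs(m$coefficients[[v]] - truth[[v]]), 3 * se[[v]])

  null <- fit_logistic(tab, character(0))
  expect_equal(unique(round(predict_risk(null, tab), 12)),
               round(mean(tab$he), 12))

  dup <- rbind(tab, tab)
  m2 <- fit_logistic(dup, c("sri", "dcv"))
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-8)
})

test_that("perfect separation raises instead of silently regularising", {
  tab <- data.frame(x = c(-(1:20) / 10, (1:20) / 10),
                    he = rep(c(0L, 1L), each = 20))
  expect_error(fit_logistic(tab, "x"), "separation")
})

test_that("predict_risk is the inverse-logit of the linear predictor", {
  m0 <- structure(list(model_id = NULL, variables = "x",
                       coefficients = c(`(Intercept)` = 0, x = 0),
                       glm = NULL),
                  class = "fitted_model")
  expect_equal(predict_risk(m0, data.frame(x = c(-5, 0, 5))),
               rep(0.5, 3))
  m1 <- m0; m1$coefficients[["(Intercept)"]] <- qlogis(0.192)
  expect_equal(predict_risk(m1, data.frame(x = 0)), 0.192)
  m2 <- m0; m2$coefficients[["x"]] <- 1.3
  p <- predict_risk(m2, data.frame(x = sort(rnorm(50))))
  expect_true(all(diff(p) >= 0))
  expect_error(predict_risk(m2, data.frame(y = 1)), "lacks")
})

test_that("the suite nests Models 1-3 as constructed", {
  tab <- generate_cohort(cohort_spec(n = 364, seed = 42))
  suite <- build_model_suite(tab, seed = 7)
  v1 <- suite$models$model1$variables
  v2 <- suite$models$model2$variables
  v3 <- suite$models$model3$variables
  expect_lte(length(v1), 7)
  expect_setequal(v2, c(v1, "sri", "dcv"))
  expect_true(all(c("sri", "dcv") %in% v3))
  expect_length(intersect(v3, sign_variables()), 0)
  expect_setequal(setdiff(v3, c("sri", "dcv")),
                  setdiff(v1, sign_variables()))
  # seeded rerun reproduces the suite exactly
  suite2 <- build_model_suite(tab, seed = 7)
  expect_identical(suite2$selection, suite$selection)
  expect_identical(suite2$models$model2$coefficients,
                   suite$models$model2$coefficients)
  expect_identical(suite2$path$lambda_opt, suite$path$lambda_opt)
})

test_that("nomogram points are affine, 0-100-scaled and risk-consistent", {
  tab <- generate_cohort(cohort_spec(n = 364, seed = 42))
  suite <- build_model_suite(tab, seed = 7)
  m <- suite$models$model2
  nom <- nomogram_table(m, data = tab)
  spans <- vapply(nom$points, function(t) max(t$points) - min(t$points),
                  numeric(1))
  expect_equal(max(spans), 100)
  expect_true(all(spans >= 0 & spans <= 100))
  expect_true(all(vapply(nom$points, function(t) min(t$points),
                         numeric(1)) == 0))
  tp <- nomogram_points(nom, tab)
  expect_equal(plogis(nom$base + nom$unit * tp), predict_risk(m, tab),
               tolerance = 1e-6)
  # a zero-coefficient variable maps to zero points everywhere
  mz <- structure(list(model_id = NULL, variables = c("a", "b"),
                       coefficients = c(`(Intercept)` = -1, a = 0.5, b = 0),
                       glm = NULL),
                  class = "fitted_model")
  nomz <- nomogram_table(mz, ranges = list(a = c(0, 2), b = c(0, 4)))
  expect_true(all(nomz$points$b$points == 0))
  expect_error(nomogram_table(mz, ranges = list(a = c(1, 1), b = c(0, 0))),
               "zero range")
})
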