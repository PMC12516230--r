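test_that("AUROC equals brute-force pair enumeration, with ties half", {
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  for (s in 1:30) {
    d <- random_scored_labels(sample(8:50, 1), seed = s)
    expect_identical(auroc(d$scores, d$labels),
                     auroc_brute(d$scores, d$labels))
    expect_equal(auroc(-d$scores, d$labels),
                 1 - auroc(d$scores, d$labels))
  }
})

test_that("AUROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  for (s in 1:5) {
    d <- random_scored_labels(40, seed = s)
    ref <- as.numeric(pROC::auc(pROC::roc(d$labels, d$scores,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(d$scores, d$labels), ref, tolerance = 1e-12)
  }
})

test_that("DeLong variance matches direct placement-value enumeration", {
  set.seed(99)
  sa <- round(runif(12), 1)
  sb <- round(runif(12), 1)
  labels <- c(rep(1, 5), rep(0, 7))
  dl <- delong_test(sa, sb, labels)
  expect_equal(dl$se^2, delong_var_brute(sa, sb, labels),
               tolerance = 1e-12)
  for (s in 1:8) {
    n <- sample(10:30, 1)
    d <- random_scored_labels(n, seed = 1000 + s)
    sb2 <- round(runif(n), 1)
    dl2 <- delong_test(d$scores, sb2, d$labels)
    expect_equal(dl2$se^2, delong_var_brute(d$scores, sb2, d$labels),
                 tolerance = 1e-12)
    swapped <- delong_test(sb2, d$scores, d$labels)
    expect_equal(swapped$z, -dl2$z)
    expect_equal(swapped$p, dl2$p)
  }
})

test_that("DeLong agrees with pROC and degrades gracefully", {
  skip_if_not_installed("pROC")
  d <- random_scored_labels(60, seed = 5)
  sb <- plogis(qlogis(pmin(pmax(d$scores, 0.02), 0.98)) +
                 rnorm(60, 0, 0.5))
  ref <- pROC::roc.test(pROC::roc(d$labels, d$scores, quiet = TRUE),
                        pROC::roc(d$labels, sb, quiet = TRUE),
                        method = "delong", paired = TRUE)
  mine <- delong_test(d$scores, sb, d$labels)
  expect_equal(mine$p, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_message(self <- delong_test(d$scores, d$scores, d$labels),
                 "convention")
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)
})

test_that("continuous NRI and IDI match hand-enumerated toys", {
  p_old <- c(0.2, 0.3, 0.5, 0.6)
  p_new <- c(0.4, 0.5, 0.4, 0.6)
  labels <- c(1, 1, 0, 0)
  expect_equal(continuous_nri(p_old, p_new, labels), 1.5)
  expect_equal(idi(p_old, p_new, labels), 0.25)
  expect_equal(continuous_nri(p_new, p_old, labels), -1.5)
  expect_equal(idi(p_new, p_old, labels), -0.25)
  expect_equal(continuous_nri(p_old, p_old, labels), 0)
  expect_equal(idi(p_old, p_old, labels), 0)
  set.seed(3)
  po <- runif(200); pn <- runif(200)
  lb <- c(0, 1, rbinom(198, 1, 0.3))
  expect_equal(continuous_nri(po, pn, lb), -continuous_nri(pn, po, lb))
  expect_lte(abs(idi(po, pn, lb)), 1)
  expect_lte(abs(continuous_nri(po, pn, lb)), 2)
})

test_that("bootstrap CIs are deterministic, degenerate-safe and calibrated", {
  ci <- bootstrap_ci(function(idx) 42, n = 50, B = 100, seed = 1)
  expect_equal(c(ci$low, ci$high), c(42, 42))
  x <- rnorm(80)
  s1 <- bootstrap_ci(function(idx) mean(x[idx]), n = 80, B = 200, seed = 9)
  s2 <- bootstrap_ci(function(idx) mean(x[idx]), n = 80, B = 200, seed = 9)
  expect_identical(s1$estimates, s2$estimates)
  # coverage of the percentile interval for a sample mean
  set.seed(17)
  hits <- vapply(1:200, function(r) {
    z <- rnorm(200, mean = 1)
    ci <- bootstrap_ci(function(idx) mean(z[idx]), n = 200, B = 2000,
                       seed = r)
    ci$low <= 1 && 1 <= ci$high
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("calibration bins track simulated truth", {
  set.seed(8)
  p <- runif(10000)
  y <- rbinom(10000, 1, p)
  cal <- calibration_curve(p, y)
  expect_equal(nrow(cal), 10)
  expect_equal(sum(cal$n), 10000)
  expect_lt(max(abs(cal$mean_predicted - cal$observed_fraction)), 0.05)
  expect_true(all(cal$observed_fraction >= 0 & cal$observed_fraction <= 1))
  # constant predictions collapse to a single effective bin
  expect_message(flat <- calibration_curve(rep(0.3, 100),
                                           rbinom(100, 1, 0.3)),
                 "collapsed")
  expect_equal(nrow(flat), 1)
})

test_that("net benefit closed forms and bounds hold", {
  set.seed(4)
  y <- c(rep(1, 20), rep(0, 80))
  p <- runif(100)
  dca <- decision_curve(p, y)
  expect_true(all(dca$net_benefit_none == 0))
  at25 <- decision_curve(p, y, thresholds = 0.25)
  expect_equal(at25$net_benefit_all, 0.2 - 0.8 * (0.25 / 0.75),
               tolerance = 1e-10)
  # a perfect predictor attains the prevalence bound below the event scores
  perfect <- ifelse(y == 1, 0.9, 0.1)
  dcp <- decision_curve(perfect, y, thresholds = c(0.2, 0.5, 0.8))
  expect_equal(dcp$net_benefit_model, rep(0.2, 3))
  expect_true(all(dca$net_benefit_model <= mean(y) + 1e-12))
  expect_error(decision_curve(p, y, thresholds = c(0.5, 1)), "inside")
})
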