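# Discrimination, reclassification, calibration and clinical-utility
# statistics, implemented from first principles (the established packages
# serve only as cross-checks in the test suite).

check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  labels
}

#' Area under the ROC curve (Mann–Whitney estimator)
#'
#' `AUROC = P(score_event > score_nonevent) + 0.5 P(equal)`: the
#' probability that a randomly chosen event outscores a randomly chosen
#' non-event, with ties counted one half. Computed via midranks in
#' O(n log n).
#'
#' @param scores numeric predictions (any monotone scale).
#' @param labels binary outcomes (0/1), both classes present.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels))
  r <- rank(scores)                       # midranks handle ties
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values: for each event, the fraction of non-events it beats
# (ties half), and vice versa. The building block of the DeLong variance.
placements <- function(scores, labels) {
  s1 <- scores[labels == 1L]; s0 <- scores[labels == 0L]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp),              # per-event
       v01 = 1 - colMeans(cmp))          # per-non-event, complement scale
}

#' DeLong test for two paired AUROCs
#'
#' Compares the AUROCs of two score vectors computed on the same subjects
#' using the DeLong placement-value (structural component) covariance with
#' midrank tie handling; the two-sided p-value is normal-based. If the two
#' score vectors are identical the variance of the difference is zero and
#' p = 1 by convention (with a message).
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary outcomes (0/1).
#' @return List with `auroc_a`, `auroc_b`, `delta`, `se`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_labels(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  # covariance matrices of the placement vectors (sample covariance)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(1 - pa$v01, 1 - pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- auc_a - auc_b
  if (var_delta <= .Machine$double.eps) {
    message("DeLong test: zero variance of the AUROC difference; ",
            "p = 1 by convention")
    return(list(auroc_a = auc_a, auroc_b = auc_b, delta = delta,
                se = 0, z = 0, p = 1))
  }
  se <- sqrt(var_delta)
  z <- delta / se
  list(auroc_a = auc_a, auroc_b = auc_b, delta = delta, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Continuous net reclassification improvement
#'
#' `NRI = [P(up | event) - P(down | event)] + [P(down | nonevent) -
#' P(up | nonevent)]`, where "up"/"down" are strict increases/decreases of
#' the predicted risk from the old to the new model; unchanged risks count
#' neither way. Range `[-2, 2]`; antisymmetric under swapping old and new.
#'
#' @param p_old,p_new paired predicted probabilities.
#' @param labels binary outcomes (0/1).
#' @return The continuous NRI.
#' @export
continuous_nri <- function(p_old, p_new, labels) {
  labels <- check_labels(labels)
  stopifnot(length(p_old) == length(labels),
            length(p_new) == length(labels))
  up <- p_new > p_old; down <- p_new < p_old
  e <- labels == 1L
  (mean(up[e]) - mean(down[e])) + (mean(down[!e]) - mean(up[!e]))
}

#' Integrated discrimination improvement
#'
#' `IDI = [mean(p_new | event) - mean(p_old | event)] -
#' [mean(p_new | nonevent) - mean(p_old | nonevent)]`: the change in the
#' mean risk separation between events and non-events.
#'
#' @inheritParams continuous_nri
#' @return The IDI, bounded in `[-1, 1]`.
#' @export
idi <- function(p_old, p_new, labels) {
  labels <- check_labels(labels)
  stopifnot(length(p_old) == length(labels),
            length(p_new) == length(labels))
  e <- labels == 1L
  (mean(p_new[e]) - mean(p_old[e])) - (mean(p_new[!e]) - mean(p_old[!e]))
}

#' Percentile bootstrap confidence interval
#'
#' Patient-level resampling with replacement; the interval is the
#' percentile interval of the statistic over `B` resamples. If `labels`
#' is supplied, resamples containing a single class are redrawn (counted
#' and reported via a message); resamples on which the statistic fails
#' contribute `NA`, and more than 10% failures is an error.
#'
#' @param statistic function of an index vector: `statistic(idx)` must
#'   return a scalar computed on the resampled rows.
#' @param n number of rows being resampled.
#' @param B number of resamples (the headline analyses use 5000).
#' @param seed integer seed.
#' @param labels optional binary labels used to reject single-class
#'   resamples.
#' @param conf confidence level (default 0.95).
#' @return List with `low`, `high`, `estimates` (the B statistics),
#'   `redraws`.
#' @export
bootstrap_ci <- function(statistic, n, B = 5000, seed = 1L, labels = NULL,
                         conf = 0.95) {
  stopifnot(is.function(statistic), n >= 1, B >= 1)
  est <- numeric(B)
  redraws <- 0L
  with_stream(seed, "bootstrap", {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (is.null(labels) || length(unique(labels[idx])) > 1) break
        redraws <- redraws + 1L
      }
      est[b] <- tryCatch(statistic(idx), error = function(e) NA_real_)
    }
  })
  fail <- mean(is.na(est))
  if (fail > 0.1)
    stop("statistic failed on ", round(100 * fail), "% of resamples",
         call. = FALSE)
  if (redraws > 0)
    message("bootstrap_ci: ", redraws, " single-class resample(s) redrawn")
  alpha <- (1 - conf) / 2
  q <- stats::quantile(est, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(low = q[1], high = q[2], estimates = est, redraws = redraws)
}

#' Calibration curve by risk deciles
#'
#' Groups predictions into equal-count bins (deciles by default) and
#' compares the mean predicted risk with the observed event fraction per
#' bin. If there are fewer distinct predicted values than requested bins,
#' bins are collapsed (with a message).
#'
#' @param p_hat predicted probabilities.
#' @param labels binary outcomes (0/1).
#' @param bins number of equal-count bins (default 10).
#' @return Data frame of class `calibration_curve` with columns `bin`,
#'   `n`, `mean_predicted`, `observed_fraction`.
#' @export
calibration_curve <- function(p_hat, labels, bins = 10) {
  labels <- check_labels(labels)
  stopifnot(length(p_hat) == length(labels))
  if (length(p_hat) < bins)
    stop("need at least as many observations as bins", call. = FALSE)
  brk <- unique(stats::quantile(p_hat, probs = seq(0, 1, length.out = bins + 1)))
  if (length(brk) < bins + 1)
    message("calibration_curve: fewer distinct predictions than bins; ",
            "collapsed to ", length(brk) - 1, " bin(s)")
  if (length(brk) == 1) brk <- c(brk - 1e-12, brk + 1e-12)
  g <- cut(p_hat, breaks = brk, include.lowest = TRUE)
  out <- data.frame(
    bin = seq_along(levels(g)),
    n = as.integer(table(g)),
    mean_predicted = as.numeric(tapply(p_hat, g, mean)),
    observed_fraction = as.numeric(tapply(labels, g, mean)))
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Decision-curve analysis (net benefit)
#'
#' `NB(pt) = TP/n - FP/n * pt/(1-pt)` where a subject is treated when
#' `p_hat >= pt`. The treat-all curve is `prev - (1-prev) * pt/(1-pt)`
#' and treat-none is identically zero.
#'
#' @param p_hat predicted probabilities.
#' @param labels binary outcomes (0/1).
#' @param thresholds decision thresholds in (0, 1); default a 0.01–0.99
#'   grid in steps of 0.01.
#' @return Data frame of class `dca_curve` with columns `threshold`,
#'   `net_benefit_model`, `net_benefit_all`, `net_benefit_none`.
#' @export
decision_curve <- function(p_hat, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- check_labels(labels)
  stopifnot(length(p_hat) == length(labels))
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  n <- length(labels)
  prev <- mean(labels)
  odds <- thresholds / (1 - thresholds)
  nb_model <- vapply(seq_along(thresholds), function(i) {
    treat <- p_hat >= thresholds[i]
    tp <- sum(treat & labels == 1L)
    fp <- sum(treat & labels == 0L)
    tp / n - fp / n * odds[i]
  }, numeric(1))
  out <- data.frame(threshold = thresholds,
                    net_benefit_model = nb_model,
                    net_benefit_all = prev - (1 - prev) * odds,
                    net_benefit_none = 0)
  class(out) <- c("dca_curve", "data.frame")
  out
}
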