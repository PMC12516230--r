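# Fixtures are generated in code; oracles below are deliberately naive,
# independent implementations (brute-force enumeration) of the statistics
# they check.

digital_sphere <- function(r_mm, h, margin = 6L) {
  n <- as.integer(ceiling(2 * r_mm / h)) + margin
  c0 <- (n - 1) / 2
  ax <- (seq_len(n) - 1 - c0) * h
  x <- array(rep(ax, times = n * n), c(n, n, n))
  y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  z <- array(rep(ax, each = n * n), c(n, n, n))
  hematoma_mask(array(as.integer(x^2 + y^2 + z^2 <= r_mm^2), c(n, n, n)),
                spacing = c(h, h, h))
}

digital_box <- function(nvox, h) {
  hematoma_mask(array(1L, nvox), spacing = rep(h, 3))
}

flat_volume <- function(mask, hu = 60) {
  voxel_volume(array(hu, dim(mask$data)), spacing = mask$spacing)
}

# AUROC by brute-force enumeration of all event/non-event pairs
auroc_brute <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(s1) * length(s0))
}

# DeLong variance of the AUROC difference by direct enumeration of the
# placement values and their sample covariances
delong_var_brute <- function(sa, sb, labels) {
  s1a <- sa[labels == 1]; s0a <- sa[labels == 0]
  s1b <- sb[labels == 1]; s0b <- sb[labels == 0]
  n1 <- length(s1a); n0 <- length(s0a)
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10a <- vapply(seq_len(n1), function(i)
    mean(vapply(seq_len(n0), function(j) psi(s1a[i], s0a[j]), 0)), 0)
  v01a <- vapply(seq_len(n0), function(j)
    mean(vapply(seq_len(n1), function(i) psi(s1a[i], s0a[j]), 0)), 0)
  v10b <- vapply(seq_len(n1), function(i)
    mean(vapply(seq_len(n0), function(j) psi(s1b[i], s0b[j]), 0)), 0)
  v01b <- vapply(seq_len(n0), function(j)
    mean(vapply(seq_len(n1), function(i) psi(s1b[i], s0b[j]), 0)), 0)
  cv <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
  (cv(v10a, v10a) + cv(v10b, v10b) - 2 * cv(v10a, v10b)) / n1 +
    (cv(v01a, v01a) + cv(v01b, v01b) - 2 * cv(v01a, v01b)) / n0
}

random_scored_labels <- function(n, seed, ties = TRUE) {
  set.seed(seed)
  labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes
  scores <- stats::runif(n)
  if (ties) scores <- round(scores, 1)
  list(scores = scores, labels = labels)
}
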