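# Synthetic patient cohorts. The default parameters reproduce the printed
# structure of the derivation cohort: HE prevalence ~19.2%, the
# label-conditional prevalences of the radiological signs, and the location
# shifts of SRI and DCV between expanders and non-expanders. Signs are
# conditionally independent given the outcome (no joint structure is
# published); clinical covariate distributions are plausible defaults, not
# published values. These are generator settings for testing the pipeline,
# not a claim of recovering the real joint distribution.

#' Specify a synthetic ICH cohort
#'
#' @param n cohort size.
#' @param he_prevalence probability of hematoma expansion (HE).
#' @param sign_prevalence named list; each element is `c(he = P(sign | HE),
#'   no = P(sign | no HE))`.
#' @param sri_location median SRI by outcome, `c(he = , no = )`; SRI is
#'   drawn log-normally, truncated to (0, 100], with the truncated median
#'   matched to these values.
#' @param sri_sdlog log-scale SD of the SRI draw.
#' @param dcv_location median DCV (%) by outcome; DCV is drawn normally,
#'   truncated at 0.
#' @param dcv_sd SD of the DCV draw.
#' @param leukocyte_mean,leukocyte_sd leukocyte count (10^9/L) by outcome.
#' @param protein_mean,protein_sd total protein (g/L) by outcome.
#' @param baseline_median_ml,baseline_sdlog baseline hematoma volume
#'   distribution (log-normal, mL).
#' @param male_prevalence,age_mean,age_sd demographics (outcome-independent).
#' @param seed integer seed. Every column is drawn from its own named
#'   random stream derived from this seed, so adding a column never
#'   perturbs existing columns.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 364,
                        he_prevalence = 0.192,
                        sign_prevalence = list(
                          cta_spot      = c(he = 0.200, no = 0.051),
                          hypodensities = c(he = 0.629, no = 0.425),
                          blend         = c(he = 0.150, no = 0.100),
                          black_hole    = c(he = 0.150, no = 0.100),
                          island        = c(he = 0.150, no = 0.100),
                          satellite     = c(he = 0.329, no = 0.211),
                          heterogeneous = c(he = 0.257, no = 0.112),
                          irregular     = c(he = 0.329, no = 0.194)),
                        sri_location = c(he = 56.9, no = 75.9),
                        sri_sdlog = 0.35,
                        dcv_location = c(he = 13.5, no = 11.9),
                        dcv_sd = 2.0,
                        leukocyte_mean = c(he = 10.5, no = 8.6),
                        leukocyte_sd = c(he = 3.0, no = 2.5),
                        protein_mean = c(he = 66.0, no = 69.5),
                        protein_sd = c(he = 6.0, no = 6.0),
                        baseline_median_ml = 23.8,
                        baseline_sdlog = 0.6,
                        male_prevalence = 0.728,
                        age_mean = 56, age_sd = 14,
                        seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(c(he_prevalence, unlist(sign_prevalence), male_prevalence) < 0 |
          c(he_prevalence, unlist(sign_prevalence), male_prevalence) > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  spec <- mget(names(formals()))
  structure(spec, class = "cohort_spec")
}

# meanlog of a log-normal truncated to (0, upper] whose truncated median
# equals `med`: solve Phi((log med - mu)/s) = 0.5 * Phi((log upper - mu)/s)
truncated_lnorm_meanlog <- function(med, sdlog, upper = 100) {
  f <- function(mu)
    stats::pnorm((log(med) - mu) / sdlog) -
      0.5 * stats::pnorm((log(upper) - mu) / sdlog)
  stats::uniroot(f, interval = log(med) + c(-5, 5))$root
}

rlnorm_trunc <- function(n, med, sdlog, upper = 100) {
  mu <- truncated_lnorm_meanlog(med, sdlog, upper)
  u <- stats::runif(n) * stats::plnorm(upper, mu, sdlog)
  stats::qlnorm(u, mu, sdlog)
}

rnorm_trunc0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

# follow-up volumes consistent with the HE label under the strict
# >6 mL / >33% rule
draw_followup <- function(baseline_ml, he) {
  n <- length(baseline_ml)
  followup <- numeric(n)
  mode_abs <- stats::runif(n) < 0.5
  extra_abs <- 6 + stats::rexp(n, rate = 1 / 8)
  extra_rel <- 0.33 + stats::rexp(n, rate = 1 / 0.4)
  frac <- stats::runif(n, min = -0.5, max = 0.999)
  exp_idx <- which(he == 1L)
  followup[exp_idx] <- ifelse(mode_abs[exp_idx],
                              baseline_ml[exp_idx] + extra_abs[exp_idx],
                              baseline_ml[exp_idx] * (1 + extra_rel[exp_idx]))
  stab_idx <- which(he == 0L)
  cap <- pmin(6, 0.33 * baseline_ml[stab_idx])
  followup[stab_idx] <- baseline_ml[stab_idx] + cap * frac[stab_idx]
  followup
}

#' Generate a synthetic ICH cohort table
#'
#' Draws the HE label first, then every other column conditionally on it:
#' binary radiological signs from their label-conditional prevalences, SRI
#' and DCV from label-conditional truncated distributions, clinical
#' covariates from label-conditional normals, and baseline/follow-up
#' volumes constructed so that [classify_expansion()] reproduces the label
#' for every record. Fully deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @return A data frame with columns `id`, `age`, `male`, `leukocyte`,
#'   `total_protein`, the eight binary signs, `sri`, `dcv`, `baseline_ml`,
#'   `followup_ml`, `he`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  he <- with_stream(spec$seed, "he",
                    as.integer(stats::runif(n) < spec$he_prevalence))
  is_he <- he == 1L
  pick <- function(par) ifelse(is_he, par[["he"]], par[["no"]])

  out <- data.frame(id = sprintf("P%04d", seq_len(n)))
  out$age <- with_stream(spec$seed, "age",
                         round(stats::rnorm(n, spec$age_mean, spec$age_sd)))
  out$male <- with_stream(spec$seed, "male",
                          as.integer(stats::runif(n) < spec$male_prevalence))
  out$leukocyte <- with_stream(spec$seed, "leukocyte", {
    z <- stats::rnorm(n)
    pmax(1, pick(spec$leukocyte_mean) + z * pick(spec$leukocyte_sd))
  })
  out$total_protein <- with_stream(spec$seed, "total_protein", {
    z <- stats::rnorm(n)
    pmax(30, pick(spec$protein_mean) + z * pick(spec$protein_sd))
  })
  for (sign in names(spec$sign_prevalence)) {
    p <- spec$sign_prevalence[[sign]]
    out[[sign]] <- with_stream(spec$seed, paste0("sign_", sign),
                               as.integer(stats::runif(n) < pick(p)))
  }
  out$sri <- with_stream(spec$seed, "sri", {
    x <- numeric(n)
    x[is_he] <- rlnorm_trunc(sum(is_he), spec$sri_location[["he"]],
                             spec$sri_sdlog)
    x[!is_he] <- rlnorm_trunc(sum(!is_he), spec$sri_location[["no"]],
                              spec$sri_sdlog)
    x
  })
  out$dcv <- with_stream(spec$seed, "dcv", {
    x <- numeric(n)
    x[is_he] <- rnorm_trunc0(sum(is_he), spec$dcv_location[["he"]],
                             spec$dcv_sd)
    x[!is_he] <- rnorm_trunc0(sum(!is_he), spec$dcv_location[["no"]],
                              spec$dcv_sd)
    x
  })
  out$baseline_ml <- with_stream(spec$seed, "baseline",
    rlnorm_trunc(n, spec$baseline_median_ml, spec$baseline_sdlog,
                 upper = 150))
  out$followup_ml <- with_stream(spec$seed, "followup",
                                 draw_followup(out$baseline_ml, he))
  out$he <- he
  attr(out, "cohort_spec") <- spec
  out
}

#' Generate a cohort from a known logistic risk model on (SRI, DCV)
#'
#' A lightweight generator for parameter-recovery and null-behaviour
#' studies: SRI and DCV are drawn from cohort-level marginals, optional
#' standard-normal noise covariates are appended, and the HE label is drawn
#' from `plogis(intercept + beta_sri * sri + beta_dcv * dcv)`. Volumes are
#' then constructed to agree with the label. The true coefficient vector is
#' attached as attribute `truth`.
#'
#' @param n cohort size.
#' @param intercept,beta_sri,beta_dcv generating coefficients (raw scale).
#' @param n_noise number of independent N(0,1) noise covariates
#'   (`noise1`, `noise2`, ...).
#' @param sri_median,sri_sdlog,dcv_mean,dcv_sd marginal parameters.
#' @param seed integer seed.
#' @return A data frame with columns `sri`, `dcv`, any noise columns,
#'   `baseline_ml`, `followup_ml`, `he`.
#' @export
generate_risk_cohort <- function(n, intercept = -0.9, beta_sri = -0.05,
                                 beta_dcv = 0.25, n_noise = 0L,
                                 sri_median = 69.8, sri_sdlog = 0.4,
                                 dcv_mean = 12.1, dcv_sd = 2.0,
                                 seed = 1L) {
  sri <- with_stream(seed, "sri", rlnorm_trunc(n, sri_median, sri_sdlog))
  dcv <- with_stream(seed, "dcv", rnorm_trunc0(n, dcv_mean, dcv_sd))
  p <- stats::plogis(intercept + beta_sri * sri + beta_dcv * dcv)
  he <- with_stream(seed, "he", as.integer(stats::runif(n) < p))
  out <- data.frame(sri = sri, dcv = dcv)
  if (n_noise > 0) {
    noise <- with_stream(seed, "noise",
                         matrix(stats::rnorm(n * n_noise), n, n_noise))
    colnames(noise) <- paste0("noise", seq_len(n_noise))
    out <- cbind(out, as.data.frame(noise))
  }
  out$baseline_ml <- with_stream(seed, "baseline",
                                 rlnorm_trunc(n, 23.8, 0.6, upper = 150))
  out$followup_ml <- with_stream(seed, "followup",
                                 draw_followup(out$baseline_ml, he))
  out$he <- he
  attr(out, "truth") <- c(`(Intercept)` = intercept, sri = beta_sri,
                          dcv = beta_dcv,
                          stats::setNames(rep(0, n_noise),
                                          if (n_noise > 0)
                                            paste0("noise", seq_len(n_noise))
                                          else character(0)))
  out
}

#' Generate a cohort of phantoms with measured morphometry
#'
#' End-to-end fixture: for each synthetic patient a phantom is generated
#' with per-patient shape and density parameters, its SRI and DCV are
#' *measured* through the morphometry pipeline (not copied from the
#' generating parameters), and the HE label is then drawn from a logistic
#' model on the measured values.
#'
#' @param n number of patients.
#' @param radius_range,amplitude_range,noise_sd_range,blob_count_range
#'   per-patient parameter ranges sampled uniformly.
#' @param spacing voxel spacing for the phantoms (coarser than clinical CT
#'   by default to keep the fixture light).
#' @param intercept,beta_sri,beta_dcv coefficients of the generating
#'   logistic model on measured (SRI, DCV).
#' @param seed integer seed.
#' @param keep_phantoms if `TRUE`, the phantom objects are returned too.
#' @return A list with `table` (data frame: `id`, `sri`, `dcv`,
#'   `volume_ml`, `baseline_ml`, `followup_ml`, `he`) and, optionally,
#'   `phantoms`.
#' @export
generate_phantom_cohort <- function(n, radius_range = c(8, 15),
                                    amplitude_range = c(0, 0.35),
                                    noise_sd_range = c(3, 9),
                                    blob_count_range = c(0L, 2L),
                                    spacing = c(1, 1, 1),
                                    intercept = 2.5, beta_sri = -0.06,
                                    beta_dcv = 0.15, seed = 1L,
                                    keep_phantoms = FALSE) {
  pars <- with_stream(seed, "phantom_params", data.frame(
    radius = stats::runif(n, radius_range[1], radius_range[2]),
    amplitude = stats::runif(n, amplitude_range[1], amplitude_range[2]),
    noise_sd = stats::runif(n, noise_sd_range[1], noise_sd_range[2]),
    blobs = {
      choices <- seq(blob_count_range[1], blob_count_range[2])
      choices[sample.int(length(choices), n, replace = TRUE)]
    }))
  phantoms <- vector("list", n)
  sri <- dcv <- vol_ml <- numeric(n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(base_radius = pars$radius[i],
                         perturbation_amplitude = pars$amplitude[i],
                         noise_sd = pars$noise_sd[i],
                         hypodense_blob_count = pars$blobs[i],
                         spacing = spacing,
                         seed = stream_seed(seed, paste0("phantom", i)))
    ph <- generate_phantom(spec)
    m <- measure_hematoma(ph$volume, ph$mask)
    sri[i] <- m$sri; dcv[i] <- m$dcv; vol_ml[i] <- m$volume_ml
    if (keep_phantoms) phantoms[[i]] <- ph
  }
  p <- stats::plogis(intercept + beta_sri * sri + beta_dcv * dcv)
  he <- with_stream(seed, "he", as.integer(stats::runif(n) < p))
  baseline <- vol_ml
  followup <- with_stream(seed, "followup", draw_followup(baseline, he))
  tab <- data.frame(id = sprintf("PH%04d", seq_len(n)), sri = sri,
                    dcv = dcv, volume_ml = vol_ml, baseline_ml = baseline,
                    followup_ml = followup, he = he)
  out <- list(table = tab)
  if (keep_phantoms) out$phantoms <- phantoms
  out
}
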