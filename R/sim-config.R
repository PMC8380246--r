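#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set that [simulate_cohort()] and its
#' component generators use.  Defaults emulate an 8-week escitalopram trial:
#' 153 patients sampled from four latent MADRS trajectory classes (early
#' responder, later responder, flat nonresponder, relapsing nonresponder) in
#' the proportions 22.9/32.0/30.1/15.0%, plus 104 healthy controls sampled at
#' baseline only.
#'
#' @param n_patients,n_controls Cohort sizes (positive integers).
#' @param class_proportions Four nonnegative fractions summing to one, in the
#'   order early responder, later responder, flat nonresponder, relapsing
#'   nonresponder.
#' @param madrs_class_means 4 x 5 matrix of mean MADRS at weeks 0, 2, 4, 6, 8
#'   (rows in the class order above).  All week-0 means must be at least 21,
#'   the trial's inclusion threshold.
#' @param madrs_noise_sd Standard deviation of the i.i.d. Gaussian noise added
#'   to each subject's class mean curve before rounding (MADRS points).
#' @param n_genes,n_marker_genes Total genes simulated and how many of them are
#'   treatment-emergent markers (`n_marker_genes <= n_genes`).
#' @param baseline_lfc_markers Absolute log2 case-vs-control shift applied to
#'   marker genes at every patient timepoint (so markers are baseline
#'   differentially expressed; sign alternates across markers).
#' @param slope_effect Absolute per-week log2 expression slope given to marker
#'   genes in the responder classes (zero at week 0, so markers carry no
#'   baseline association with outcome; sign alternates across markers).
#' @param dispersion_range Length-2 positive range; per-gene NB dispersions
#'   alpha (variance mu + alpha * mu^2) are drawn uniformly from it.
#' @param size_factor_log_sd SD of per-sample log-normal sequencing-depth
#'   factors (0 means equal depth).
#' @param covariate_effects Named list with elements `age`, `sex`, `rin`: SDs
#'   of the per-gene log2 coefficients for each (centred) covariate.
#' @param subject_intercept_sd,subject_slope_sd SDs of the per-subject,
#'   per-gene random intercept (log2 units) and random slope (log2 units per
#'   week) of expression — the biological between-subject heterogeneity that
#'   the latent growth model's variance components describe.  Setting both to
#'   0 gives counts independent across timepoints given class.
#' @param seed Integer seed driving a single RNG stream ordered
#'   phenotypes -> MADRS -> counts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 40, n_controls = 20, n_genes = 50)
#' cfg$class_proportions
sim_config <- function(n_patients = 153L,
                       n_controls = 104L,
                       class_proportions = c(early = 0.229, later = 0.320,
                                             nr_flat = 0.301, nr_relapse = 0.150),
                       madrs_class_means = default_madrs_means(),
                       madrs_noise_sd = 3,
                       n_genes = 2000L,
                       n_marker_genes = 4L,
                       baseline_lfc_markers = 0.5,
                       slope_effect = 0.1,
                       dispersion_range = c(0.05, 0.2),
                       size_factor_log_sd = 0.25,
                       covariate_effects = list(age = 0.005, sex = 0.05, rin = 0.05),
                       subject_intercept_sd = 0.5,
                       subject_slope_sd = 0.1,
                       seed = 1L) {
  stopifnot(n_patients >= 1, n_controls >= 1, n_genes >= 1)
  if (length(class_proportions) != 4L || any(class_proportions < 0)) {
    stop("`class_proportions` must be 4 nonnegative fractions", call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    stop("`class_proportions` must sum to 1 (within 1e-12)", call. = FALSE)
  }
  madrs_class_means <- as.matrix(madrs_class_means)
  if (!all(dim(madrs_class_means) == c(4L, 5L))) {
    stop("`madrs_class_means` must be a 4 x 5 matrix (classes x weeks 0,2,4,6,8)",
         call. = FALSE)
  }
  if (any(madrs_class_means[, 1L] < 21)) {
    stop("all week-0 class means must be >= 21 (MADRS inclusion criterion)",
         call. = FALSE)
  }
  stopifnot(madrs_noise_sd >= 0)
  if (n_marker_genes > n_genes) {
    stop("`n_marker_genes` cannot exceed `n_genes`", call. = FALSE)
  }
  if (length(dispersion_range) != 2L || dispersion_range[1L] <= 0 ||
      diff(dispersion_range) < 0) {
    stop("`dispersion_range` must be an increasing pair with lower bound > 0",
         call. = FALSE)
  }
  stopifnot(size_factor_log_sd >= 0, subject_intercept_sd >= 0,
            subject_slope_sd >= 0)
  if (!all(c("age", "sex", "rin") %in% names(covariate_effects))) {
    stop("`covariate_effects` needs elements age, sex, rin", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls),
         class_proportions = class_proportions,
         madrs_class_means = madrs_class_means,
         madrs_noise_sd = madrs_noise_sd,
         n_genes = as.integer(n_genes),
         n_marker_genes = as.integer(n_marker_genes),
         baseline_lfc_markers = baseline_lfc_markers,
         slope_effect = slope_effect,
         dispersion_range = dispersion_range,
         size_factor_log_sd = size_factor_log_sd,
         covariate_effects = covariate_effects,
         subject_intercept_sd = subject_intercept_sd,
         subject_slope_sd = subject_slope_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Default MADRS class mean curves
#'
#' Mean MADRS at weeks 0, 2, 4, 6, 8 for the four latent trajectory classes.
#' Early responders drop below half their baseline by week 2; later responders
#' only by week 8; flat nonresponders change by less than 15% of baseline at
#' every visit; relapsing nonresponders first fall like early responders, reach
#' a nadir mid-trial, then rise again.
#'
#' @return A 4 x 5 numeric matrix with row names
#'   `early`, `later`, `nr_flat`, `nr_relapse`.
#' @export
default_madrs_means <- function() {
  rbind(early      = c(30, 13, 10,  8,  6),
        later      = c(30, 22, 16, 12,  9),
        nr_flat    = c(30, 29, 28, 29, 28),
        nr_relapse = c(30, 15, 13, 18, 26))
}

madrs_weeks <- c(0L, 2L, 4L, 6L, 8L)
trajectory_classes <- c("early", "later", "nr_flat", "nr_relapse")
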