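#' Covariate-adjusted expression matrices by timepoint
#'
#' Normalizes a cohort's counts (median-of-ratios + log2) and residualizes
#' age, sex and RIN per timepoint, returning one gene x subject matrix per
#' patient timepoint with columns named by subject.
#'
#' @param cohort A `cohort_tables` list.
#' @param pseudocount Pseudocount for [normalize_log2()].
#' @return Named list of matrices `T0`, `T2`, `T8`.
#' @export
adjust_expression <- function(cohort, pseudocount = 1) {
  counts <- cohort$counts
  sf <- size_factors(counts)
  phen <- cohort$phenotypes
  tps <- split_counts_by_timepoint(counts)
  lapply(tps[c("T0", "T2", "T8")], function(m) {
    ids <- strip_sample_suffix(colnames(m))
    cov <- phen[match(ids, phen$subject_id), c("age", "sex", "rin")]
    r <- residualize(normalize_log2(m, sf[colnames(m)], pseudocount), cov)
    colnames(r) <- ids
    r
  })
}

#' Null operating characteristics of the screening and association steps
#'
#' Simulates marker-free cohorts and measures, per seed: the type-I error of
#' the baseline NB Wald test at nominal 0.05 (patients vs controls at T0,
#' where no gene is truly differential) and the fraction of RNAs advanced by
#' the step-1 slope-response logistic screen (which should sit near its
#' nominal 5% level).
#'
#' @param seeds Integer vector of simulation seeds.
#' @param n_patients,n_controls,n_genes Cohort dimensions.
#' @return A tibble: `seed`, `de_type1`, `step1_advance`, `n_degenerate`
#'   (RNAs whose slope factor collapsed and were excluded).
#' @export
study_null_funnel <- function(seeds = 1:3, n_patients = 150,
                              n_controls = 104, n_genes = 2000) {
  purrr::map_dfr(seeds, function(s) {
    cfg <- sim_config(n_patients = n_patients, n_controls = n_controls,
                      n_genes = n_genes, n_marker_genes = 0, seed = s)
    coh <- simulate_cohort(cfg)
    lab <- classify_response(coh$madrs)
    tps <- split_counts_by_timepoint(coh$counts)
    sf <- size_factors(coh$counts)
    base_counts <- cbind(tps$HC, tps$T0)
    grp <- factor(rep(c("control", "patient"),
                      c(ncol(tps$HC), ncol(tps$T0))),
                  levels = c("control", "patient"))
    de <- nb_wald_de(base_counts, grp, sf[colnames(base_counts)])
    adj <- adjust_expression(coh)
    gm <- fit_growth_models(adj)
    phen <- coh$phenotypes
    ass <- run_three_step(gm$scores, lab,
                          phen[phen$group == "patient",
                               c("subject_id", "age", "sex", "anxiety",
                                 "suicidality")])
    tibble::tibble(seed = s,
                   de_type1 = mean(de$p < 0.05, na.rm = TRUE),
                   step1_advance = mean(ass$step1$advance),
                   n_degenerate = sum(is.na(ass$step1$slope_p)))
  })
}

#' End-to-end power of the slope-response association
#'
#' Simulates cohorts with a marker-poor gene universe (as after genome-wide
#' normalization) in which exactly `n_markers` of `n_candidates` candidate
#' RNAs carry true responder-class slope effects, runs growth modelling and
#' the three-step association on the candidates, and counts true and false
#' discoveries at FDR < `fdr`.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param n_patients Patients per cohort.
#' @param n_universe Genes simulated (normalization universe).
#' @param n_candidates Candidate RNAs passed to the longitudinal analysis
#'   (the markers plus the first nulls).
#' @param n_markers True marker RNAs.
#' @param fdr Discovery threshold on the BH-adjusted slope p-values.
#' @return A tibble: `seed`, `true_positives`, `false_positives`,
#'   `n_advanced`.
#' @export
study_power <- function(seeds = 1:5, n_patients = 1000, n_universe = 500,
                        n_candidates = 32, n_markers = 4, fdr = 0.05) {
  purrr::map_dfr(seeds, function(s) {
    cfg <- sim_config(n_patients = n_patients, n_controls = 104,
                      n_genes = n_universe, n_marker_genes = n_markers,
                      seed = s)
    coh <- simulate_cohort(cfg)
    lab <- classify_response(coh$madrs)
    adj <- adjust_expression(coh)
    candidates <- rownames(coh$counts)[seq_len(n_candidates)]
    gm <- fit_growth_models(adj, genes = candidates)
    phen <- coh$phenotypes
    ass <- run_three_step(gm$scores, lab,
                          phen[phen$group == "patient",
                               c("subject_id", "age", "sex", "anxiety",
                                 "suicidality")])
    hits <- unique(ass$table$gene[ass$table$fdr < fdr])
    truth <- coh$truth$gene
    tibble::tibble(seed = s,
                   true_positives = sum(truth %in% hits),
                   false_positives = sum(!hits %in% truth),
                   n_advanced = sum(ass$step1$advance))
  })
}

#' Growth-model parameter recovery study
#'
#' Simulates three-timepoint data from a stated latent growth model and
#' refits it, returning per-parameter Monte-Carlo summaries: the bias of the
#' mean estimate in units of the Monte-Carlo standard error.
#'
#' @param seeds Integer vector of simulation seeds (one replicate each).
#' @param n Subjects per replicate.
#' @param mu,psi,theta True mean vector (intercept, slope), 2 x 2 latent
#'   covariance and residual variance (scalar, shared by timepoints).
#' @return A tibble with one row per parameter: `term`, `true`, `mean_est`,
#'   `mc_se`, `z` (= |mean - true| / mc_se).
#' @export
study_lgm_recovery <- function(seeds = 1:10, n = 5000, mu = c(5, 0.3),
                               psi = matrix(c(1, 0, 0, 0.04), 2),
                               theta = 0.25) {
  lam <- cbind(1, c(0, 2, 8))
  est <- purrr::map_dfr(seeds, function(s) {
    set.seed(s)
    ab <- MASS::mvrnorm(n, mu, psi)
    y <- ab %*% t(lam) + matrix(stats::rnorm(n * 3, 0, sqrt(theta)), n, 3)
    f <- fit_lgm(y)
    tibble::tibble(term = c("mu_i", "mu_s", "var_i", "var_s", "cov_is",
                            "theta_t0", "theta_t2", "theta_t8"),
                   est = c(f$mu_i, f$mu_s, f$psi[1, 1], f$psi[2, 2],
                           f$psi[1, 2], f$theta))
  })
  truth <- c(mu_i = mu[1], mu_s = mu[2], var_i = psi[1, 1], var_s = psi[2, 2],
             cov_is = psi[1, 2], theta_t0 = theta, theta_t2 = theta,
             theta_t8 = theta)
  out <- dplyr::summarise(dplyr::group_by(est, .data$term),
                          mean_est = mean(.data$est),
                          mc_se = stats::sd(.data$est) / sqrt(dplyr::n()),
                          .groups = "drop")
  out$true <- truth[out$term]
  out$z <- abs(out$mean_est - out$true) / out$mc_se
  out[, c("term", "true", "mean_est", "mc_se", "z")]
}
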