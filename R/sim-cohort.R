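#' Simulate patient phenotypes
#'
#' Draws demographic and clinical covariates for patients and controls: age
#' uniform over 18-61 years, sex Bernoulli(0.627 female), RIN uniform 6-10,
#' history of anxiety disorders Bernoulli(0.497) and of suicidality
#' Bernoulli(0.752) (patients only), and a latent trajectory class per patient
#' from `config$class_proportions`.
#'
#' Uses the current RNG state; seed it (or call via [simulate_cohort()], which
#' seeds a single stream) for reproducibility.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   ("patient"/"control"), `true_class`, `age`, `sex`, `rin`, `anxiety`,
#'   `suicidality`.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  np <- config$n_patients
  nc <- config$n_controls
  n <- np + nc
  ids <- c(sprintf("P%03d", seq_len(np)), sprintf("C%03d", seq_len(nc)))
  true_class <- sample(trajectory_classes, np, replace = TRUE,
                       prob = config$class_proportions)
  tibble::tibble(
    subject_id = ids,
    group = rep(c("patient", "control"), c(np, nc)),
    true_class = c(true_class, rep(NA_character_, nc)),
    age = stats::runif(n, 18, 61),
    sex = ifelse(stats::rbinom(n, 1L, 0.627) == 1L, "female", "male"),
    rin = stats::runif(n, 6, 10),
    anxiety = c(stats::rbinom(np, 1L, 0.497), rep(NA_integer_, nc)),
    suicidality = c(stats::rbinom(np, 1L, 0.752), rep(NA_integer_, nc)))
}

#' Simulate MADRS trajectories
#'
#' Each patient's 5-visit MADRS row (weeks 0, 2, 4, 6, 8) is their latent
#' class's mean curve plus i.i.d. Gaussian noise, rounded to integers and
#' truncated to the scale range [0, 60]; week-0 values are additionally
#' truncated from below at 21 so every draw respects the inclusion criterion.
#'
#' @param config A [sim_config()] object.
#' @param true_class Character vector of latent classes (from
#'   [simulate_phenotypes()]); one per patient.
#' @return A tibble with `subject_id` (taken as `P001`, ... if not supplied via
#'   names), `true_class` and integer columns `madrs_w0` ... `madrs_w8`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 5, madrs_noise_sd = 0)
#' set.seed(1)
#' simulate_madrs(cfg, rep("early", 5))
simulate_madrs <- function(config, true_class) {
  stopifnot(inherits(config, "sim_config"))
  cls <- match(true_class, trajectory_classes)
  if (anyNA(cls)) stop("unknown trajectory class in `true_class`", call. = FALSE)
  n <- length(cls)
  mu <- config$madrs_class_means[cls, , drop = FALSE]
  noise <- matrix(stats::rnorm(n * 5L, 0, config$madrs_noise_sd), n, 5L)
  m <- round(mu + noise)
  m <- pmin(pmax(m, 0), 60)
  m[, 1L] <- pmax(m[, 1L], 21)
  ids <- names(true_class)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- paste0("madrs_w", madrs_weeks)
  dplyr::bind_cols(tibble::tibble(subject_id = ids, true_class = true_class), out)
}

#' Simulate negative-binomial RNA-seq counts
#'
#' Counts for gene g in sample j are NB with mean `s_j * q_gj` and variance
#' `mu + alpha_g * mu^2`.  On the log2 scale, `q_gj` is a per-gene baseline
#' (uniform 3-9) plus: a case-vs-control shift for marker genes at every
#' patient timepoint; a class-specific linear slope in weeks for marker genes
#' (responder classes only, zero at week 0); small per-gene effects of
#' centred age, sex and RIN; and per-subject random intercepts and slopes
#' shared across that subject's timepoints (the biological heterogeneity the
#' latent growth model decomposes).  Size factors `s_j` are log-normal.
#' Marker signs alternate so roughly half the markers fall with response.
#'
#' @param config A [sim_config()] object.
#' @param phenotypes Tibble from [simulate_phenotypes()].
#' @return A list: `counts` (gene x sample integer matrix; patient columns
#'   `<id>_T0/_T2/_T8`, control columns `<id>_HC`), `size_factors` (true
#'   simulated factors), `covariate_coefs` (per-gene tibble), `truth` (tibble
#'   of gene, is_marker, baseline_lfc, slope per responder class).
#' @export
simulate_counts <- function(config, phenotypes) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_marker_genes > config$n_genes) {
    stop("`n_marker_genes` cannot exceed `n_genes`", call. = FALSE)
  }
  pat <- phenotypes[phenotypes$group == "patient", ]
  ctl <- phenotypes[phenotypes$group == "control", ]
  G <- config$n_genes
  genes <- sprintf("G%04d", seq_len(G))

  tp_weeks <- c(0L, 2L, 8L)
  sample_id <- c(as.vector(t(outer(pat$subject_id, paste0("_T", tp_weeks), paste0))),
                 paste0(ctl$subject_id, "_HC"))
  n_pat_samp <- nrow(pat) * 3L
  n_samp <- n_pat_samp + nrow(ctl)
  is_patient <- rep(c(TRUE, FALSE), c(n_pat_samp, nrow(ctl)))
  week <- c(rep(tp_weeks, nrow(pat)), rep(0L, nrow(ctl)))
  subj_row <- c(rep(seq_len(nrow(pat)), each = 3L),
                nrow(pat) + seq_len(nrow(ctl)))
  phen_all <- rbind(pat, ctl)

  base <- stats::runif(G, 3, 9)
  alpha <- stats::runif(G, config$dispersion_range[1L], config$dispersion_range[2L])
  b_age <- stats::rnorm(G, 0, config$covariate_effects$age)
  b_sex <- stats::rnorm(G, 0, config$covariate_effects$sex)
  b_rin <- stats::rnorm(G, 0, config$covariate_effects$rin)
  sf <- exp(stats::rnorm(n_samp, 0, config$size_factor_log_sd))

  marker <- seq_len(config$n_marker_genes)
  sign_g <- numeric(G)
  sign_g[marker] <- rep_len(c(1, -1), length(marker))
  lfc_g <- sign_g * config$baseline_lfc_markers
  slope_g <- sign_g * config$slope_effect

  age_c <- phen_all$age[subj_row] - 39.5
  sex_c <- as.numeric(phen_all$sex[subj_row] == "female") - 0.627
  rin_c <- phen_all$rin[subj_row] - 8
  responder <- !is.na(phen_all$true_class[subj_row]) &
    phen_all$true_class[subj_row] %in% c("early", "later")

  # subject-level biological heterogeneity: per-gene random intercept and
  # random slope shared across a subject's timepoints (what the growth
  # model's latent variance components estimate)
  n_subj <- nrow(phen_all)
  A <- matrix(stats::rnorm(G * n_subj, 0, config$subject_intercept_sd), G, n_subj)
  B <- matrix(stats::rnorm(G * n_subj, 0, config$subject_slope_sd), G, n_subj)

  # log2 mean matrix built in blocks to avoid G x n outer products in a loop
  log2q <- outer(base, rep(1, n_samp)) +
    outer(b_age, age_c) + outer(b_sex, sex_c) + outer(b_rin, rin_c) +
    outer(lfc_g, as.numeric(is_patient)) +
    outer(slope_g, ifelse(responder, week, 0)) +
    A[, subj_row, drop = FALSE] +
    sweep(B[, subj_row, drop = FALSE], 2L, week, "*")
  mu <- 2^log2q * rep(sf, each = G)
  counts <- matrix(stats::rnbinom(G * n_samp, mu = mu, size = rep(1 / alpha, n_samp)),
                   G, n_samp, dimnames = list(genes, sample_id))
  storage.mode(counts) <- "integer"

  truth <- tibble::tibble(
    gene = genes[marker],
    baseline_lfc = lfc_g[marker],
    slope_early = slope_g[marker],
    slope_later = slope_g[marker])
  list(counts = counts,
       size_factors = stats::setNames(sf, sample_id),
       covariate_coefs = tibble::tibble(gene = genes, b_age = b_age,
                                        b_sex = b_sex, b_rin = b_rin,
                                        dispersion = alpha),
       truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Seeds a single RNG stream from `config$seed` and draws, in order,
#' phenotypes, MADRS trajectories and counts, so identical configs give
#' byte-identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cohort_tables`: `phenotypes`, `madrs`, `counts`,
#'   `size_factors`, `truth`, `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 12, n_controls = 8,
#'                                   n_genes = 30, seed = 7))
#' dim(coh$counts)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  phen <- simulate_phenotypes(config)
  pat <- phen[phen$group == "patient", ]
  madrs <- simulate_madrs(config,
                          stats::setNames(pat$true_class, pat$subject_id))
  cts <- simulate_counts(config, phen)
  structure(list(phenotypes = phen, madrs = madrs, counts = cts$counts,
                 size_factors = cts$size_factors, truth = cts$truth,
                 config = config),
            class = "cohort_tables")
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes `counts.tsv` (gene rows; sample columns named
#' `<subject>_T0/_T2/_T8` or `<subject>_HC`), `phenotypes.csv` (including the
#' MADRS panel for patients) and `truth.tsv` into `dir`; `read_cohort()`
#' restores them.  The round trip is lossless for the tables the pipeline
#' consumes.
#'
#' @param cohort A `cohort_tables` list from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the paths invisibly; `read_cohort()` a list
#'   with `phenotypes`, `madrs`, `counts`, `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(cohort$counts, paths[["counts"]])
  phen <- dplyr::left_join(cohort$phenotypes, cohort$madrs,
                           by = c("subject_id", "true_class"))
  readr::write_csv(phen, paths[["phenotypes"]], na = "")
  readr::write_tsv(cohort$truth, paths[["truth"]], na = "")
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  phen <- readr::read_csv(file.path(dir, "phenotypes.csv"),
                          show_col_types = FALSE)
  madrs_cols <- grep("^madrs_w", names(phen), value = TRUE)
  madrs <- phen[phen$group == "patient",
                c("subject_id", "true_class", madrs_cols)]
  list(phenotypes = phen[, setdiff(names(phen), madrs_cols)],
       madrs = tibble::as_tibble(madrs),
       counts = read_counts(file.path(dir, "counts.tsv")),
       truth = readr::read_tsv(file.path(dir, "truth.tsv"),
                               show_col_types = FALSE))
}
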