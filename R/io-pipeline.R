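#' Read / write a gene x sample count matrix
#'
#' Tab-delimited text with gene ids in the first column and sample ids in the
#' header.  Cells must be nonnegative integers; duplicate gene ids and
#' non-integer cells are rejected with the offending location named.
#'
#' @param path File path.
#' @return `read_counts()`: an integer matrix with gene row names.
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  genes <- tab[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(tab[, -1L])
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(num) | num < 0 | num != floor(num))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(vals)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(vals)) + 1L
    stop(sprintf("non-integer count '%s' at gene %s, sample %s",
                 vals[bad[1L]], genes[i], colnames(vals)[j]), call. = FALSE)
  }
  m <- matrix(as.integer(num), nrow(vals), ncol(vals),
              dimnames = list(genes, colnames(vals)))
  m
}

#' @rdname read_counts
#' @param counts Integer matrix to write.
#' @export
write_counts <- function(counts, path) {
  df <- tibble::as_tibble(counts, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Thresholds and options for [run_pipeline()], with the discovery analysis's
#' defaults: baseline DE FDR 0.20, endpoint-correlation p 0.05, baseline-
#' correlation exclusion p 0.20, step-1 advancement p 0.05, final FDR 0.05.
#'
#' @param de_fdr,corr_p,baseline_p,step1_p,final_fdr Thresholds in (0, 1).
#' @param criterion2_variable Which expression variable enters the endpoint
#'   correlation: `"t8"` (level at week 8, default) or `"delta"` (T8 - T0
#'   change).
#' @param pseudocount Pseudocount for [normalize_log2()].
#' @param chisq_scale Growth-model chi-square convention (see [fit_lgm()]).
#' @param weeks Measurement weeks of the three expression timepoints.
#' @param seed Integer seed for any stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(de_fdr = 0.20, corr_p = 0.05, baseline_p = 0.20,
                            step1_p = 0.05, final_fdr = 0.05,
                            criterion2_variable = c("t8", "delta"),
                            pseudocount = 1, chisq_scale = c("n-1", "n"),
                            weeks = c(0, 2, 8), seed = 1L) {
  for (th in c(de_fdr, corr_p, baseline_p, step1_p, final_fdr)) {
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(list(de_fdr = de_fdr, corr_p = corr_p, baseline_p = baseline_p,
                 step1_p = step1_p, final_fdr = final_fdr,
                 criterion2_variable = match.arg(criterion2_variable),
                 pseudocount = pseudocount,
                 chisq_scale = match.arg(chisq_scale),
                 weeks = weeks, seed = as.integer(seed)),
            class = "pipeline_config")
}

split_counts_by_timepoint <- function(counts) {
  cn <- colnames(counts)
  list(T0 = counts[, grepl("_T0$", cn), drop = FALSE],
       T2 = counts[, grepl("_T2$", cn), drop = FALSE],
       T8 = counts[, grepl("_T8$", cn), drop = FALSE],
       HC = counts[, grepl("_HC$", cn), drop = FALSE])
}

strip_sample_suffix <- function(x) sub("_(T0|T2|T8|HC)$", "", x)

#' Run the full trajectory-biomarker pipeline
#'
#' Orchestrates the stages in the discovery order: response classification
#' from the MADRS panel; median-of-ratios normalization, log2 transform and
#' covariate adjustment (age, sex, RIN, per timepoint); baseline NB Wald
#' differential expression vs controls; the three-criterion selection funnel;
#' per-RNA latent growth models with factor scores; and the three-step
#' slope-response association.  Deterministic given the config seed.
#'
#' @param cohort A `cohort_tables` list ([simulate_cohort()] /
#'   [read_cohort()]): `phenotypes`, `madrs`, `counts`.
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `labels`, `de`, `funnel`,
#'   `growth` (NULL if nothing selected), `association` (NULL likewise) and
#'   `manifest` (tibble of stage, n_in, n_out, seconds; attribute
#'   `config_hash`).
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  manifest <- list()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, sec = proc.time()[["elapsed"]] - t0)
  }

  st <- clock(classify_response(cohort$madrs))
  labels <- st$val
  manifest$classify <- c(nrow(cohort$madrs), nrow(labels), st$sec)

  counts <- cohort$counts
  tps <- split_counts_by_timepoint(counts)
  phen <- cohort$phenotypes

  # normalization + covariate adjustment per timepoint (columns -> subjects)
  sf_all <- size_factors(counts)
  adj <- adjust_expression(cohort, pseudocount = config$pseudocount)

  # baseline DE: patients at T0 vs controls
  st <- clock({
    base_counts <- cbind(tps$HC, tps$T0)
    grp <- factor(rep(c("control", "patient"), c(ncol(tps$HC), ncol(tps$T0))),
                  levels = c("control", "patient"))
    nb_wald_de(base_counts, grp, sf_all[colnames(base_counts)])
  })
  de <- st$val
  manifest$baseline_de <- c(nrow(counts), sum(de$padj <= config$de_fdr, na.rm = TRUE),
                            st$sec)

  # correlation screens against the T8/T0 MADRS ratio
  st <- clock({
    dm <- labels$delta_madrs_t8[match(colnames(adj$T8), labels$subject_id)]
    expr2 <- if (config$criterion2_variable == "t8") adj$T8 else adj$T8 - adj$T0
    corr_t8 <- pearson_screen(expr2, dm)
    corr_t0 <- pearson_screen(adj$T0, dm)
    miss <- rownames(counts)[apply(is.na(cbind(tps$T0, tps$T8)), 1L, any)]
    select_candidates(de, corr_t8, corr_t0, de_fdr = config$de_fdr,
                      corr_p = config$corr_p, baseline_p = config$baseline_p,
                      missing_genes = miss)
  })
  funnel <- st$val
  manifest$funnel <- c(nrow(counts), length(funnel$selected), st$sec)

  growth <- NULL; assoc <- NULL
  if (length(funnel$selected)) {
    st <- clock(fit_growth_models(adj, genes = funnel$selected,
                                  weeks = config$weeks,
                                  chisq_scale = config$chisq_scale))
    growth <- st$val
    manifest$growth <- c(length(funnel$selected), nrow(growth$fits), st$sec)

    st <- clock(run_three_step(growth$scores, labels,
                               phen[phen$group == "patient",
                                    c("subject_id", "age", "sex", "anxiety",
                                      "suicidality")],
                               step1_p = config$step1_p))
    assoc <- st$val
    manifest$associate <- c(sum(assoc$step1$advance),
                            sum(assoc$table$fdr < config$final_fdr), st$sec)
  }

  man <- tibble::tibble(
    stage = names(manifest),
    n_in = vapply(manifest, `[`, 0, 1L),
    n_out = vapply(manifest, `[`, 0, 2L),
    seconds = vapply(manifest, `[`, 0, 3L))
  attr(man, "config_hash") <- rlang::hash(unclass(config))
  structure(list(labels = labels, de = de, funnel = funnel, growth = growth,
                 association = assoc, manifest = man, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Trajectory-biomarker pipeline run\n")
  print(x$manifest)
  if (!is.null(x$association) && nrow(x$association$table)) {
    hits <- unique(x$association$table$gene[x$association$table$fdr <
                                              x$config$final_fdr])
    cat("RNAs at FDR <", x$config$final_fdr, ":",
        if (length(hits)) paste(hits, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
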