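#' Per-gene Pearson correlation screen
#'
#' Correlates each gene's expression vector with a clinical change score
#' (the MADRS ratio), returning the Pearson r and the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.  Genes
#' with zero variance are flagged (`r` and `p` set to NA) rather than dropped.
#'
#' @param expr Gene x subject matrix of (adjusted) expression.
#' @param delta Numeric vector, one value per subject (e.g. the T8/T0 MADRS
#'   ratio); must be complete, n >= 3.
#' @return A tibble: `gene`, `n`, `r`, `p`, `flag` ("ok" or "zero_variance").
#' @export
pearson_screen <- function(expr, delta) {
  expr <- as.matrix(expr)
  n <- length(delta)
  stopifnot(ncol(expr) == n)
  if (n < 3L) stop("Pearson screen needs n >= 3 paired observations",
                   call. = FALSE)
  if (anyNA(delta) || anyNA(expr)) {
    stop("complete paired observations required", call. = FALSE)
  }
  xm <- sweep(expr, 1L, rowMeans(expr))
  dm <- delta - mean(delta)
  sx <- unname(sqrt(rowSums(xm^2)))
  sd_ <- sqrt(sum(dm^2))
  r <- as.vector(xm %*% dm) / (sx * sd_)
  zero <- sx == 0 | sd_ == 0
  r[zero] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
                 n = n, r = r, p = p,
                 flag = ifelse(zero, "zero_variance", "ok"))
}

#' Apply the three-criterion RNA selection funnel
#'
#' Orders the screening stages as in the discovery analysis:
#' \enumerate{
#'   \item baseline case-vs-control differential expression at
#'     `de_fdr` (BH-adjusted p <= 0.20 by default);
#'   \item exclusion of genes with missing data at T0 or T8;
#'   \item correlation of expression with the MADRS change ratio at T8
#'     (p < `corr_p`, default 0.05);
#'   \item exclusion of genes whose baseline expression correlates with the
#'     same change ratio (kept iff p >= `baseline_p`, default 0.2), so that
#'     selected genes track response without being baseline predictors.
#' }
#'
#' @param de A tibble from [nb_wald_de()] (needs `gene`, `padj`).
#' @param corr_t8 A tibble from [pearson_screen()] on T8 expression.
#' @param corr_t0 Same, on baseline (T0) expression.
#' @param de_fdr,corr_p,baseline_p Stage thresholds, each in (0, 1).
#' @param missing_genes Character vector of genes excluded for missing data
#'   at T0 or T8 (default none).
#' @return A list of class `screen_funnel`: `funnel` (per-gene tibble with the
#'   stage statistics, per-stage booleans and `final_selected`), `counts`
#'   (tibble of stage, n_remaining), `selected` (character vector).
#' @export
select_candidates <- function(de, corr_t8, corr_t0,
                              de_fdr = 0.20, corr_p = 0.05, baseline_p = 0.20,
                              missing_genes = character()) {
  for (th in c(de_fdr, corr_p, baseline_p)) {
    if (!is.numeric(th) || th <= 0 || th >= 1) {
      stop("funnel thresholds must lie strictly inside (0, 1)", call. = FALSE)
    }
  }
  genes <- de$gene
  if (!setequal(genes, corr_t8$gene) || !setequal(genes, corr_t0$gene)) {
    stop("the three tables must be indexed by the same gene universe",
         call. = FALSE)
  }
  tab <- dplyr::left_join(
    dplyr::select(de, gene, de_log2fc = "log2fc", de_p = "p", de_padj = "padj"),
    dplyr::select(corr_t8, gene, t8_r = "r", t8_p = "p"),
    by = "gene")
  tab <- dplyr::left_join(
    tab,
    dplyr::select(corr_t0, gene, t0_r = "r", t0_p = "p"),
    by = "gene")
  tab <- dplyr::mutate(
    tab,
    criterion1 = !is.na(.data$de_padj) & .data$de_padj <= de_fdr,
    not_missing = !(.data$gene %in% missing_genes),
    criterion2 = .data$criterion1 & .data$not_missing &
      !is.na(.data$t8_p) & .data$t8_p < corr_p,
    criterion3 = .data$criterion2 & !is.na(.data$t0_p) & .data$t0_p >= baseline_p,
    final_selected = .data$criterion3)
  counts <- tibble::tibble(
    stage = c("universe", "baseline_de", "complete_data",
              "t8_correlation", "no_baseline_correlation"),
    n_remaining = c(nrow(tab), sum(tab$criterion1),
                    sum(tab$criterion1 & tab$not_missing),
                    sum(tab$criterion2), sum(tab$criterion3)))
  structure(list(funnel = tab, counts = counts,
                 selected = tab$gene[tab$final_selected],
                 thresholds = c(de_fdr = de_fdr, corr_p = corr_p,
                                baseline_p = baseline_p)),
            class = "screen_funnel")
}

#' @export
print.screen_funnel <- function(x, ...) {
  cat("Three-criterion RNA selection funnel\n")
  print(x$counts)
  cat(length(x$selected), "gene(s) selected\n")
  invisible(x)
}
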