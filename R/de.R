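#' Negative-binomial Wald differential expression
#'
#' Per gene, fits the negative-binomial GLM
#' `log mu = b0 + b1 * group + log s_j` (log link, size-factor offset) with
#' per-gene dispersion estimated by maximum likelihood (alternating IRLS for
#' the coefficients and profile ML for the dispersion, via [MASS::glm.nb()]),
#' and tests `b1 = 0` with a two-sided Wald z test.  Fold changes are reported
#' on the log2 scale.  Genes for which the ML dispersion diverges towards zero
#' (underdispersed counts) are refit as Poisson, the NB limit.  All-zero genes
#' are flagged and given p = 1 rather than dropped.
#'
#' @param counts Nonnegative integer gene x sample matrix.
#' @param group Two-level factor (or coercible) of length `ncol(counts)`; the
#'   second level is the "case" whose fold change is reported.  Each level
#'   needs at least 2 samples.
#' @param sf Size factors (default: [size_factors()] of `counts`).
#' @return A tibble of class `nb_de` with one row per gene: `gene`,
#'   `base_mean` (mean normalized count), `log2fc`, `se` (log2 scale), `z`,
#'   `p`, `padj` (BH), `dispersion`, `flag` ("ok", "all_zero", "poisson_limit",
#'   "failed").
#' @export
nb_wald_de <- function(counts, group, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly two levels",
                                 call. = FALSE)
  if (any(table(group) < 2L)) stop("each group needs at least 2 samples",
                                   call. = FALSE)
  g01 <- as.numeric(group == levels(group)[2L])
  off <- log(sf)
  norm_counts <- sweep(counts, 2L, sf, "/")

  fit_one <- function(y) {
    if (all(y == 0)) {
      return(c(NA, NA, NA, 1, NA, 1))  # lfc, se, z, p, disp, flag-code
    }
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ g01 + offset(off))),
      error = function(e) NULL)
    flag <- 0
    if (is.null(fit) || !is.finite(fit$theta) || fit$theta > 1e7) {
      # Poisson limit: theta -> Inf, alpha -> 0
      fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ g01 + offset(off), family = stats::poisson())),
        error = function(e) NULL)
      if (is.null(fit)) return(c(NA, NA, NA, NA, NA, 3))
      disp <- 0
      flag <- 2
    } else {
      disp <- 1 / fit$theta
    }
    cf <- summary(fit)$coefficients
    b <- cf["g01", "Estimate"]; se <- cf["g01", "Std. Error"]
    z <- b / se
    c(b / log(2), se / log(2), z, 2 * stats::pnorm(-abs(z)), disp, flag)
  }

  res <- t(apply(counts, 1L, fit_one))
  dimnames(res) <- NULL
  flag <- c("ok", "all_zero", "poisson_limit", "failed")[res[, 6L] + 1L]
  out <- tibble::tibble(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = rowMeans(norm_counts),
    log2fc = res[, 1L], se = res[, 2L], z = res[, 3L], p = res[, 4L],
    dispersion = res[, 5L], flag = flag)
  out$padj <- bh_adjust(out$p)
  out <- out[, c("gene", "base_mean", "log2fc", "se", "z", "p", "padj",
                 "dispersion", "flag")]
  class(out) <- c("nb_de", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
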