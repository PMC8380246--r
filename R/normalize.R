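#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: for each gene with strictly positive
#' counts in every sample, form the ratio of each sample's count to the gene's
#' geometric mean across samples; the size factor is the per-sample median of
#' those ratios.
#'
#' @param counts Nonnegative integer gene x sample matrix.
#' @return Named numeric vector of strictly positive factors, one per sample.
#' @export
#' @examples
#' m <- rbind(a = c(10, 20), b = c(5, 10))
#' size_factors(m)  # (1/sqrt(2), sqrt(2))
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (ncol(counts) == 1L) {
    return(stats::setNames(1, colnames(counts)))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop(paste("no gene has positive counts in every sample;",
               "median-of-ratios normalization needs at least one such gene",
               "(consider filtering samples or using a pseudo-reference)"),
         call. = FALSE)
  }
  lc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- exp(apply(lc - loggeo, 2L, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Log2 normalized expression
#'
#' `log2(count / size_factor + pseudocount)` per cell.  Doubling all counts
#' and all size factors leaves the result unchanged.
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors from [size_factors()] (recycled per column).
#' @param pseudocount Positive offset added before the log (default 1, so
#'   zero counts map to 0 at unit depth).
#' @return Matrix of the same shape.
#' @export
normalize_log2 <- function(counts, sf = size_factors(counts), pseudocount = 1) {
  counts <- as.matrix(counts)
  if (pseudocount <= 0 && any(counts == 0)) {
    stop("pseudocount must be positive when zero counts are present",
         call. = FALSE)
  }
  log2(sweep(counts, 2L, sf, "/") + pseudocount)
}

#' Residualize expression on covariates
#'
#' Per gene, ordinary-least-squares residuals of expression on an intercept
#' plus the given covariates, with the gene's grand mean added back, so
#' adjusted values stay on the expression scale but have (near-)zero linear
#' association with each covariate.
#'
#' @param expr Gene x sample matrix (e.g. from [normalize_log2()]).
#' @param covariates Data frame with one row per sample; all columns are used
#'   (character/factor columns are expanded via `model.matrix`).
#' @return Adjusted matrix of the same shape.
#' @export
residualize <- function(expr, covariates) {
  expr <- as.matrix(expr)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == ncol(expr))
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- t(qr.resid(qrX, t(expr)))
  res + rowMeans(expr)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (sorted ascending, `adj_i = min_{j >= i} p_j * m / j`,
#' capped at 1, returned in input order).  Delegates to
#' `stats::p.adjust(method = "BH")` after validating the input.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA allowed, propagated).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
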