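#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins, no
#' continuity correction, `df = (r - 1)(c - 1)` and an upper-tail p-value —
#' the convention used for the categorical rows of cohort demographic tables.
#'
#' @param table An r x c matrix of nonnegative integer counts (r, c >= 2).
#' @return A tibble: `statistic`, `df`, `p`.
#' @export
#' @examples
#' chi2_independence(rbind(c(10, 19, 5), c(59, 30, 30)))  # p = 0.003
chi2_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need an r x c table (r, c >= 2) of nonnegative counts", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact test summing hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one.
#'
#' @param table A 2 x 2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("fisher_exact_2x2 is for 2 x 2 tables; use chi2_independence otherwise",
         call. = FALSE)
  }
  stats::fisher.test(tab)$p.value
}

#' One-way ANOVA from raw data or summary triples
#'
#' Standard between/within decomposition.  Accepts either a list of numeric
#' vectors or a data frame of per-group summaries (`n`, `mean`, `sd`), so the
#' test can be recomputed from published group summaries; raw data are first
#' reduced to the same triples, making the two input forms exactly equivalent.
#'
#' @param groups List of numeric vectors, or a data frame with columns `n`,
#'   `mean`, `sd`.
#' @return A tibble: `f`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' anova_oneway(data.frame(n = c(69, 49, 35),
#'                         mean = c(36.12, 36.55, 34.57),
#'                         sd = c(13.05, 11.90, 12.39)))  # p = 0.762
anova_oneway <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("n", "mean", "sd") %in% names(groups)))
    s <- groups
  } else {
    if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
    s <- data.frame(n = lengths(groups),
                    mean = vapply(groups, mean, 0),
                    sd = vapply(groups, stats::sd, 0))
  }
  if (any(s$n < 2L)) stop("each group needs n >= 2", call. = FALSE)
  k <- nrow(s)
  N <- sum(s$n)
  grand <- sum(s$n * s$mean) / N
  ssb <- sum(s$n * (s$mean - grand)^2)
  ssw <- sum((s$n - 1) * s$sd^2)
  df1 <- k - 1; df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(f = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range post hoc comparisons after one-way ANOVA (via
#' [stats::TukeyHSD()]).  With fewer than three groups this reduces to a
#' pooled-variance t test (a note is attached).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A tibble: `comparison`, `diff`, `ci_low`, `ci_high`, `p_adj`
#'   (attribute `note` when reduced to a t test).
#' @export
tukey_hsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (length(groups) < 3L) {
    tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
    out <- tibble::tibble(
      comparison = paste(names(groups)[2L], names(groups)[1L], sep = "-"),
      diff = mean(groups[[2L]]) - mean(groups[[1L]]),
      ci_low = -unname(tt$conf.int[2L]), ci_high = -unname(tt$conf.int[1L]),
      p_adj = tt$p.value)
    attr(out, "note") <- "two groups: reduced to pooled-variance t test"
    return(out)
  }
  dat <- data.frame(value = unlist(groups, use.names = FALSE),
                    g = factor(rep(names(groups), lengths(groups)),
                               levels = names(groups)))
  hsd <- stats::TukeyHSD(stats::aov(value ~ g, data = dat))$g
  tibble::tibble(comparison = rownames(hsd), diff = hsd[, "diff"],
                 ci_low = hsd[, "lwr"], ci_high = hsd[, "upr"],
                 p_adj = hsd[, "p adj"])
}

#' Dunnett many-to-one comparisons
#'
#' Compares each treatment group with a designated control using Dunnett's
#' multivariate-t adjustment (via [multcomp::glht()]).
#'
#' @param groups Named list of numeric vectors.
#' @param control Name or index of the control group (default first).
#' @return A tibble: `comparison`, `estimate`, `se`, `t`, `p_adj`.
#' @export
dunnett <- function(groups, control = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ctrl <- if (is.numeric(control)) names(groups)[control] else as.character(control)
  if (!ctrl %in% names(groups) || length(groups[[ctrl]]) == 0L) {
    stop("control group missing or empty", call. = FALSE)
  }
  ord <- c(ctrl, setdiff(names(groups), ctrl))
  dat <- data.frame(value = unlist(groups[ord], use.names = FALSE),
                    g = factor(rep(ord, lengths(groups[ord])), levels = ord))
  fit <- stats::aov(value ~ g, data = dat)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  tibble::tibble(comparison = names(sm$test$coefficients),
                 estimate = unname(sm$test$coefficients),
                 se = unname(sm$test$sigma),
                 t = unname(sm$test$tstat),
                 p_adj = unname(as.vector(sm$test$pvalues)))
}

#' Pooled-variance two-sample t test
#'
#' Two-tailed t test with pooled variance, as used for case-control
#' comparisons of log2 brain expression.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return A tibble: `t`, `df`, `p`, `mean_diff`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero pooled variance", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(a) - mean(b))
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; per condition,
#' `ddCt = mean dCt - mean dCt(control condition)` and fold change
#' `2^-ddCt` (so the control condition has fold change 1 by construction).
#'
#' @param ct Tibble with columns `condition`, `replicate`, `gene`, `ct`.
#' @param target Target gene name.
#' @param reference Endogenous control gene name (e.g. B-actin).
#' @param control_condition Reference condition (e.g. untreated).
#' @return A list of class `ddct_result`: `by_condition` tibble (`condition`,
#'   `n`, `mean_dct`, `ddct`, `fold_change`) and `replicates` tibble
#'   (`condition`, `replicate`, `dct`).
#' @export
#' @examples
#' ct <- tidyr::expand_grid(condition = c("untreated", "drug"),
#'                          replicate = 1:3, gene = c("T", "ACTB"))
#' ct$ct <- ifelse(ct$gene == "ACTB", 15, ifelse(ct$condition == "drug", 24, 25))
#' ddct(ct, "T", "ACTB", "untreated")  # drug fold change 2
ddct <- function(ct, target, reference, control_condition) {
  stopifnot(all(c("condition", "replicate", "gene", "ct") %in% names(ct)))
  wide <- tidyr::pivot_wider(ct[ct$gene %in% c(target, reference), ],
                             names_from = "gene", values_from = "ct")
  if (!reference %in% names(wide) || anyNA(wide[[reference]])) {
    bad <- wide$replicate[is.na(wide[[reference]])]
    stop("missing reference Ct for replicate(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (!target %in% names(wide) || anyNA(wide[[target]])) {
    stop("missing target Ct values", call. = FALSE)
  }
  wide$dct <- wide[[target]] - wide[[reference]]
  if (!control_condition %in% wide$condition) {
    stop("control condition not present in the Ct table", call. = FALSE)
  }
  by_cond <- dplyr::summarise(dplyr::group_by(wide, .data$condition),
                              n = dplyr::n(), mean_dct = mean(.data$dct),
                              .groups = "drop")
  ctrl_dct <- by_cond$mean_dct[by_cond$condition == control_condition]
  by_cond$ddct <- by_cond$mean_dct - ctrl_dct
  by_cond$fold_change <- 2^(-by_cond$ddct)
  structure(list(by_condition = by_cond,
                 replicates = wide[, c("condition", "replicate", "dct")]),
            class = "ddct_result")
}
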