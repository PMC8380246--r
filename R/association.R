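#' Binary logistic regression fit
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) with Wald
#' standard errors from the inverse observed information and two-sided normal
#' p-values.  Fits with diverging coefficients (perfect or quasi-perfect
#' separation) are flagged.
#'
#' @param outcome Binary vector (0/1 or logical).
#' @param design Data frame or matrix of predictors (intercept added).
#' @return A list of class `logistic_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `se`, `z`, `p`), `separation` flag, `converged`, `fit`
#'   (the underlying glm object).
#' @export
logistic_fit <- function(outcome, design) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)))
  df <- as.data.frame(design)
  dat <- cbind(.y = y, df)
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                     family = stats::binomial(),
                                     control = stats::glm.control(
                                       epsilon = 1e-12, maxit = 100)))
  cf <- summary(fit)$coefficients
  eps <- 1e-10
  separation <- !fit$converged ||
    any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  structure(list(
    coefficients = tibble::tibble(term = rownames(cf),
                                  estimate = cf[, "Estimate"],
                                  se = cf[, "Std. Error"],
                                  z = cf[, "z value"],
                                  p = 2 * stats::pnorm(-abs(cf[, "z value"]))),
    separation = separation,
    converged = fit$converged,
    fit = fit), class = "logistic_fit")
}

#' Multinomial logistic regression by Newton-Raphson
#'
#' Fits the baseline-category multinomial logit: for K outcome classes with a
#' designated base category, K - 1 linear predictors
#' `log P(class k) / P(base) = x' beta_k`.  The log-likelihood is concave; it
#' is maximised by full Newton-Raphson on the stacked coefficient vector with
#' step-halving (iterations never decrease the log-likelihood), and standard
#' errors come from the inverse observed information.  Exponentiated
#' coefficients are the relative risk ratios reported in slope-response
#' association tables.
#'
#' @param outcome Factor (or coercible) with K >= 2 levels.
#' @param design Data frame or matrix of predictors (intercept added).
#' @param base Base (reference) category; default the first level.
#' @param tol Convergence tolerance on the gradient max-norm (default 1e-10).
#' @param maxit Maximum Newton iterations.
#' @return A list of class `multinomial_fit`: `coefficients` tibble
#'   (`class`, `term`, `estimate`, `se`, `z`, `p`), `loglik`, `loglik_trace`,
#'   `converged`, `separation` (diverging-coefficient flag), `base`, `vcov`.
#' @export
multinomial_fit <- function(outcome, design, base = NULL, tol = 1e-10,
                            maxit = 200L) {
  y <- as.factor(outcome)
  lev <- levels(y)
  K <- length(lev)
  if (K < 2L) stop("outcome needs at least two classes", call. = FALSE)
  if (any(table(y) == 0L)) stop("empty outcome class", call. = FALSE)
  if (is.null(base)) base <- lev[1L]
  base <- as.character(base)
  if (!base %in% lev) stop("`base` is not an outcome level", call. = FALSE)
  lev_ord <- c(base, setdiff(lev, base))
  y <- factor(y, levels = lev_ord)

  design <- as.data.frame(design)
  X <- if (ncol(design) == 0L) {
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = design)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  Y <- matrix(0, n, K)                       # indicator, col 1 = base
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  beta <- matrix(0, p, K - 1L)
  eta0 <- matrix(0, n, 1L)
  loglik <- function(beta) {
    eta <- cbind(eta0, X %*% beta)
    m <- apply(eta, 1L, max)
    sum(rowSums(Y * eta) - (m + log(rowSums(exp(eta - m)))))
  }
  probs <- function(beta) {
    eta <- cbind(eta0, X %*% beta)
    e <- exp(eta - apply(eta, 1L, max))
    e / rowSums(e)
  }

  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(maxit)) {
    P <- probs(beta)
    # gradient and observed information for the non-base classes
    grad <- as.vector(crossprod(X, Y[, -1L, drop = FALSE] - P[, -1L, drop = FALSE]))
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (k in seq_len(K - 1L)) {
      for (l in seq_len(K - 1L)) {
        w <- P[, k + 1L] * ((k == l) - P[, l + 1L])
        H[(k - 1L) * p + seq_len(p), (l - 1L) * p + seq_len(p)] <-
          crossprod(X, X * w)
      }
    }
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    step <- solve_damped(H, grad)
    if (is.null(step)) break
    halve <- 0
    repeat {
      beta_new <- beta + matrix(step, p, K - 1L)
      ll_new <- loglik(beta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      halve <- halve + 1
      if (halve > 50) break
    }
    if (halve > 50) break
    delta <- ll_new - ll
    beta <- beta_new
    ll <- ll_new
    trace <- c(trace, ll)
    if (abs(delta) < 1e-12 && max(abs(grad)) < 1e-6) { converged <- TRUE; break }
  }
  P <- probs(beta)
  H <- matrix(0, p * (K - 1L), p * (K - 1L))
  for (k in seq_len(K - 1L)) {
    for (l in seq_len(K - 1L)) {
      w <- P[, k + 1L] * ((k == l) - P[, l + 1L])
      H[(k - 1L) * p + seq_len(p), (l - 1L) * p + seq_len(p)] <-
        crossprod(X, X * w)
    }
  }
  V <- tryCatch(solve(H), error = function(e) {
    solve(H + 1e-8 * mean(diag(H)) * diag(nrow(H)))
  })
  separation <- any(abs(beta) > 15) || !converged
  se <- matrix(sqrt(pmax(diag(V), 0)), p, K - 1L)
  est <- beta
  z <- est / se
  coefs <- tibble::tibble(
    class = rep(lev_ord[-1L], each = p),
    term = rep(colnames(X), K - 1L),
    estimate = as.vector(est),
    se = as.vector(se),
    z = as.vector(z),
    p = 2 * stats::pnorm(-abs(as.vector(z))))
  structure(list(coefficients = coefs, loglik = ll, loglik_trace = trace,
                 converged = converged, separation = separation,
                 base = base, vcov = V),
            class = "multinomial_fit")
}

# Newton step with Levenberg-style damping for (near-)singular information
solve_damped <- function(H, g) {
  step <- tryCatch(solve(H, g), error = function(e) NULL)
  damp <- 1e-8 * mean(abs(diag(H)))
  tries <- 0
  while (is.null(step) && tries < 12) {
    step <- tryCatch(solve(H + damp * diag(nrow(H)), g),
                     error = function(e) NULL)
    damp <- damp * 10
    tries <- tries + 1
  }
  step
}

#' Risk ratio with Wald confidence interval
#'
#' From a log risk ratio and its standard error: `RR = exp(log_rr)`, 95% CI
#' `exp(log_rr +/- 1.96 se)` and the two-sided normal Wald p-value.
#'
#' @param log_rr Log risk ratio(s).
#' @param se Standard error(s), strictly positive.
#' @return A tibble: `log_rr`, `se`, `rr`, `ci_low`, `ci_high`, `p`.
#' @export
#' @examples
#' wald_rr(1.064, 0.323)  # RR 2.90, CI 1.54-5.46
wald_rr <- function(log_rr, se) {
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  tibble::tibble(log_rr = log_rr, se = se,
                 rr = exp(log_rr),
                 ci_low = exp(log_rr - 1.96 * se),
                 ci_high = exp(log_rr + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(log_rr / se)))
}

#' Three-step slope-response association analysis
#'
#' Relates per-RNA growth parameters to treatment response:
#' \enumerate{
#'   \item per RNA, a binary logistic model (responder vs nonresponder) on
#'     that RNA's intercept score and standardized slope; RNAs whose slope
#'     Wald p is below `step1_p` advance;
#'   \item one multivariable binary logistic model with all advancing RNAs'
#'     standardized slopes plus covariates (age, sex, anxiety, suicidality),
#'     giving the responders-vs-nonresponders contrast;
#'   \item one multivariable multinomial model (early / later / nonresponder,
#'     base = nonresponder) with the same predictors, giving the
#'     early-vs-nonresponder and later-vs-nonresponder contrasts.
#' }
#' BH FDR is applied to the Wald p-values of the slope terms jointly across
#' the family of (advancing RNAs) x (3 contrasts).
#'
#' @param scores Tibble from [fit_growth_models()]`$scores`: `subject_id`,
#'   `gene`, `intercept_score`, `std_slope`.
#' @param labels Tibble from [classify_response()] (`subject_id`, `label`).
#' @param covariates Tibble with `subject_id`, `age`, `sex`, `anxiety`,
#'   `suicidality` (sex coded male/female or 0/1).
#' @param step1_p Advancement threshold on the step-1 slope p (default 0.05).
#' @return A list of class `association_result`: `step1` tibble (per-RNA
#'   slope/intercept statistics and `advance` flag), `table` (the per-RNA x
#'   contrast association tibble: `gene`, `contrast`, `log_rr`, `se`, `p`,
#'   `fdr`, `rr`, `ci_low`, `ci_high`), `family_size`, `n_per_class`.
#' @export
run_three_step <- function(scores, labels, covariates, step1_p = 0.05) {
  lab <- dplyr::inner_join(labels, covariates, by = "subject_id")
  lab$responder <- as.numeric(lab$label != "nonresponder")
  lab$class3 <- factor(ifelse(lab$label == "nonresponder", "nonresponder",
                              ifelse(lab$label == "early_responder", "early",
                                     "later")),
                       levels = c("nonresponder", "early", "later"))
  sexnum <- if (is.numeric(lab$sex)) lab$sex else as.numeric(lab$sex == "female")
  covar <- data.frame(age = lab$age, sex = sexnum,
                      anxiety = as.numeric(lab$anxiety),
                      suicidality = as.numeric(lab$suicidality))

  genes <- unique(scores$gene)
  # step 1: per-RNA binary logistic on intercept + standardized slope
  step1 <- purrr::map_dfr(genes, function(g) {
    sc <- scores[scores$gene == g, ]
    sc <- sc[match(lab$subject_id, sc$subject_id), ]
    fit <- logistic_fit(lab$responder,
                        data.frame(intercept_score = sc$intercept_score,
                                   std_slope = sc$std_slope))
    cf <- fit$coefficients
    pull1 <- function(col, term) {
      v <- cf[[col]][cf$term == term]
      if (length(v) == 1L && is.finite(v)) v else NA_real_
    }
    tibble::tibble(
      gene = g,
      slope_coef = pull1("estimate", "std_slope"),
      slope_p = pull1("p", "std_slope"),
      intercept_p = pull1("p", "intercept_score"),
      separation = fit$separation)
  })
  step1$advance <- !step1$separation & !is.na(step1$slope_p) &
    step1$slope_p < step1_p
  advancing <- step1$gene[step1$advance]

  n_per_class <- table(lab$class3)
  if (length(advancing) == 0L) {
    return(structure(list(step1 = step1,
                          table = tibble::tibble(gene = character(),
                                                 contrast = character(),
                                                 log_rr = numeric(), se = numeric(),
                                                 p = numeric(), fdr = numeric(),
                                                 rr = numeric(), ci_low = numeric(),
                                                 ci_high = numeric()),
                          family_size = 0L, n_per_class = n_per_class,
                          note = "no RNA advanced past step 1"),
                     class = "association_result"))
  }

  slope_mat <- purrr::map_dfc(advancing, function(g) {
    sc <- scores[scores$gene == g, ]
    stats::setNames(tibble::tibble(sc$std_slope[match(lab$subject_id,
                                                      sc$subject_id)]), g)
  })
  design <- cbind(as.data.frame(slope_mat), covar)

  # step 2: joint binary logistic (responders vs nonresponders)
  fit2 <- logistic_fit(lab$responder, design)
  cf2 <- fit2$coefficients[fit2$coefficients$term %in% advancing, ]
  rows2 <- tibble::tibble(gene = cf2$term,
                          contrast = "responders_vs_nonresponders",
                          log_rr = cf2$estimate, se = cf2$se, p = cf2$p)

  # step 3: joint multinomial, base = nonresponders
  fit3 <- multinomial_fit(lab$class3, design, base = "nonresponder")
  cf3 <- fit3$coefficients[fit3$coefficients$term %in% advancing, ]
  rows3 <- tibble::tibble(
    gene = cf3$term,
    contrast = paste0(cf3$class, "_vs_nonresponders"),
    log_rr = cf3$estimate, se = cf3$se, p = cf3$p)

  tab <- dplyr::bind_rows(rows2, rows3)
  tab$fdr <- bh_adjust(tab$p)
  ci <- wald_rr(tab$log_rr, tab$se)
  tab$rr <- ci$rr; tab$ci_low <- ci$ci_low; tab$ci_high <- ci$ci_high
  tab <- dplyr::arrange(tab, .data$contrast, .data$gene)
  structure(list(step1 = step1, table = tab,
                 family_size = nrow(tab), n_per_class = n_per_class,
                 step2 = fit2, step3 = fit3),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Three-step slope-response association\n")
  cat(sprintf("  %d RNA(s) advanced past step 1; FDR family size %d\n",
              sum(x$step1$advance), x$family_size))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}
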