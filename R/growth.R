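#' Fit a linear latent growth model to three-timepoint expression
#'
#' Fits, by maximum likelihood, the two-factor (random intercept + random
#' slope) structural growth model for one RNA measured at weeks 0, 2 and 8:
#' the implied moments are `mu = Lambda (mu_i, mu_s)'` and
#' `Sigma = Lambda Psi Lambda' + Theta` with loadings fixed at
#' `Lambda = [1 | weeks]`, latent covariance `Psi` (2 x 2, parameterised via
#' its Cholesky factor so it stays positive semidefinite) and diagonal
#' residual variances `Theta` (one per timepoint).  The ML discrepancy
#' `F_ML = ln|Sigma| - ln|S| + tr(S Sigma^-1) - 3 + (ybar - mu)' Sigma^-1 (ybar - mu)`
#' is minimised by a quasi-Newton optimizer with analytic gradient from a
#' method-of-moments start (per-subject OLS
#' intercepts/slopes).  With 9 observed moments and 8 free parameters the
#' model has 1 degree of freedom; the fit statistic is `T = (n - 1) F_ML`
#' (Wishart convention; `chisq_scale = "n"` gives the normal-theory `n F_ML`).
#'
#' @param y Numeric n x 3 matrix: one row per subject, columns in time order.
#'   Complete data; n >= 20 recommended.
#' @param weeks Numeric length-3 vector of measurement times for the slope
#'   loading column (default `c(0, 2, 8)`).
#' @param chisq_scale `"n-1"` (default) or `"n"`; also decides whether S is
#'   the unbiased or the ML covariance.
#' @param control List: `iter.max` (default 500) and `rel.tol` (default
#'   1e-10) passed to [stats::nlminb()]; convergence is additionally accepted
#'   when the gradient max-norm falls below 1e-5.
#' @return An object of class `lgm_fit`: `mu_i`, `mu_s`, `psi` (2 x 2),
#'   `theta` (length 3), `loadings`, `fml`, `chi_square`, `df` (= 1),
#'   `loglik`, `n`, `S`, `ybar`, `sigma_hat` (implied covariance), `mu_hat`,
#'   `converged`, `chisq_scale`.
#' @export
#' @examples
#' set.seed(1)
#' n <- 200
#' ab <- cbind(rnorm(n, 5, 1), rnorm(n, 0.3, 0.2))
#' y <- ab %*% t(cbind(1, c(0, 2, 8))) + matrix(rnorm(n * 3, 0, 0.5), n, 3)
#' fit <- fit_lgm(y)
#' tidy(fit)
fit_lgm <- function(y, weeks = c(0, 2, 8), chisq_scale = c("n-1", "n"),
                    control = list()) {
  chisq_scale <- match.arg(chisq_scale)
  y <- as.matrix(y)
  stopifnot(ncol(y) == 3L, !anyNA(y))
  n <- nrow(y)
  if (n < 4L) stop("too few subjects to fit the growth model", call. = FALSE)
  lam <- cbind(1, weeks)
  ybar <- colMeans(y)
  Sn <- stats::cov(y)            # unbiased
  mult <- if (chisq_scale == "n-1") n - 1 else n
  S <- if (chisq_scale == "n-1") Sn else Sn * (n - 1) / n
  if (!all(is.finite(S)) || det(S) <= 0) {
    stop("singular sample covariance; growth model cannot be fit", call. = FALSE)
  }
  logdetS <- determinant(S)$modulus[1L]

  # method-of-moments start from per-subject OLS
  H <- solve(crossprod(lam), t(lam))      # 2 x 3
  ab <- y %*% t(H)                        # n x 2 (intercept, slope)
  resid <- y - ab %*% t(lam)
  theta0 <- max(sum(resid^2) / n, 1e-4)
  psi0 <- stats::cov(ab) - theta0 * solve(crossprod(lam))
  ev <- eigen(psi0, symmetric = TRUE)
  psi0 <- ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors)
  L0 <- t(chol(psi0))
  par0 <- unname(c(colMeans(ab), L0[1, 1], L0[2, 1], L0[2, 2],
                   rep(log(theta0), 3L)))

  obj <- function(par) {
    mu <- lam %*% par[1:2]
    L <- matrix(c(par[3], par[4], 0, par[5]), 2L, 2L)
    sigma <- lam %*% tcrossprod(L) %*% t(lam) + diag(exp(par[6:8]))
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    sig_inv <- chol2inv(ch)
    d <- ybar - as.vector(mu)
    f <- logdet - logdetS + sum(S * sig_inv) - 3 +
      as.numeric(crossprod(d, sig_inv %*% d))
    if (!is.finite(f)) 1e10 else f
  }
  # analytic gradient: dF/dSigma = P (Sigma - S - dd') P with P = Sigma^-1;
  # chain rule through the Cholesky factor of Psi and the log residual variances
  grad <- function(par) {
    mu <- lam %*% par[1:2]
    L <- matrix(c(par[3], par[4], 0, par[5]), 2L, 2L)
    sigma <- lam %*% tcrossprod(L) %*% t(lam) + diag(exp(par[6:8]))
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, 8L))
    P <- chol2inv(ch)
    d <- ybar - as.vector(mu)
    g_mu <- -2 * as.vector(crossprod(lam, P %*% d))
    G <- P %*% (sigma - S - tcrossprod(d)) %*% P
    GL <- 2 * crossprod(lam, G %*% lam) %*% L
    g_theta <- diag(G) * exp(par[6:8])
    c(g_mu, GL[1, 1], GL[2, 1], GL[2, 2], g_theta)
  }

  ctrl <- utils::modifyList(list(iter.max = 500L, rel.tol = 1e-10), control)
  opt <- stats::nlminb(par0, obj, grad, control = ctrl)
  par <- opt$par
  converged <- opt$convergence == 0L || max(abs(grad(par))) < 1e-5
  opt$value <- opt$objective
  L <- matrix(c(par[3], par[4], 0, par[5]), 2L, 2L)
  psi <- tcrossprod(L)
  theta <- exp(par[6:8])
  sigma_hat <- lam %*% psi %*% t(lam) + diag(theta)
  mu_hat <- as.vector(lam %*% par[1:2])
  fml <- max(opt$value, 0)
  # full MVN log-likelihood at the optimum (ML covariance in the trace term)
  Sml <- Sn * (n - 1) / n
  ch <- chol(sigma_hat)
  d <- ybar - mu_hat
  sig_inv <- chol2inv(ch)
  loglik <- -0.5 * n * (3 * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          sum(Sml * sig_inv) +
                          as.numeric(crossprod(d, sig_inv %*% d)))
  dimnames(psi) <- list(c("intercept", "slope"), c("intercept", "slope"))
  structure(list(mu_i = par[1], mu_s = par[2], psi = psi, theta = theta,
                 loadings = lam, fml = fml, chi_square = mult * fml,
                 df = 1L, loglik = loglik, n = n, S = S, ybar = ybar,
                 sigma_hat = sigma_hat, mu_hat = mu_hat,
                 converged = converged,
                 chisq_scale = chisq_scale),
            class = "lgm_fit")
}

#' Independence baseline model for fit indices
#'
#' Fits the null model with free means, free variances and zero covariances
#' (needed by the CFI/TLI definitions).  Closed form: with
#' `Sigma_b = diag(S)` the discrepancy reduces to
#' `F_b = sum(log diag(S)) - log|S|`, `df_b = 3`.
#'
#' @param y n x 3 data matrix, or an `lgm_fit` (its stored S and n are used).
#' @inheritParams fit_lgm
#' @return A list: `chi_square` (T_b), `df` (3), `fml`.
#' @export
fit_independence_baseline <- function(y, chisq_scale = c("n-1", "n")) {
  chisq_scale <- match.arg(chisq_scale)
  if (inherits(y, "lgm_fit")) {
    S <- y$S; n <- y$n
  } else {
    y <- as.matrix(y)
    n <- nrow(y)
    S <- if (chisq_scale == "n-1") stats::cov(y) else stats::cov(y) * (n - 1) / n
  }
  mult <- if (chisq_scale == "n-1") n - 1 else n
  fb <- sum(log(diag(S))) - determinant(S)$modulus[1L]
  list(chi_square = mult * max(fb, 0), df = 3L, fml = max(fb, 0))
}

#' SEM fit indices for a growth model
#'
#' Computes the chi-square p-value and the incremental/absolute fit indices
#' used to judge each RNA's growth model: CFI, TLI, GFI, RMSEA and SRMR.
#' Conventions: `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`;
#' `TLI = [(T_b/df_b) - (T/df)] / [(T_b/df_b) - 1]` (capped at 1 when the
#' baseline is no worse than saturated);
#' `GFI = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`;
#' `RMSEA = sqrt(max(T - df, 0) / (df (n - 1)))`; SRMR is the root mean square
#' of the 6 unique standardized covariance residuals
#' `(s_ij - sigma_ij) / sqrt(s_ii s_jj)` (covariance entries only; means are
#' saturated up to 2 parameters and excluded by convention here).
#'
#' @param fit An `lgm_fit`.
#' @param baseline Result of [fit_independence_baseline()] (computed from the
#'   fit's stored moments if omitted).
#' @return A tibble: `chi_square`, `df`, `chi_p`, `cfi`, `tli`, `gfi`,
#'   `rmsea`, `srmr`.
#' @export
fit_indices <- function(fit, baseline = fit_independence_baseline(fit)) {
  stopifnot(inherits(fit, "lgm_fit"))
  T1 <- fit$chi_square; df1 <- fit$df
  Tb <- baseline$chi_square; dfb <- baseline$df
  d1 <- max(T1 - df1, 0)
  db <- max(Tb - dfb, d1, 0)
  cfi <- if (db == 0) 1 else 1 - d1 / db
  tli <- if (Tb <= dfb) 1 else {
    val <- ((Tb / dfb) - (T1 / df1)) / ((Tb / dfb) - 1)
    min(val, 1)
  }
  S <- fit$S
  sig_inv <- solve(fit$sigma_hat)
  M <- sig_inv %*% S
  gfi <- 1 - sum(diag((M - diag(3)) %*% (M - diag(3)))) / sum(diag(M %*% M))
  rmsea <- sqrt(d1 / (df1 * (fit$n - 1)))
  resid <- (S - fit$sigma_hat) / sqrt(tcrossprod(diag(S)))
  srmr <- sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2))
  tibble::tibble(chi_square = T1, df = df1,
                 chi_p = stats::pchisq(T1, df1, lower.tail = FALSE),
                 cfi = cfi, tli = tli, gfi = gfi, rmsea = rmsea, srmr = srmr)
}

#' Regression-method factor scores
#'
#' Per-subject empirical estimates of the latent intercept and slope:
#' `eta_hat = mu_eta + Psi Lambda' Sigma^-1 (y - Lambda mu_eta)`.  The slope
#' score is additionally z-scored across subjects (`std_slope`), the scale on
#' which slope-response associations are reported (risk ratios per 1 SD of
#' slope).
#'
#' @param fit An `lgm_fit`.
#' @param y The n x 3 data matrix the model was fit to.
#' @return A tibble: `intercept_score`, `slope_score`, `std_slope` (mean 0,
#'   SD 1).
#' @export
factor_scores <- function(fit, y) {
  stopifnot(inherits(fit, "lgm_fit"))
  y <- as.matrix(y)
  stopifnot(ncol(y) == 3L)
  ch <- tryCatch(chol(fit$sigma_hat), error = function(e) {
    stop("implied covariance is not positive definite", call. = FALSE)
  })
  sig_inv <- chol2inv(ch)
  mu_eta <- c(fit$mu_i, fit$mu_s)
  A <- fit$psi %*% t(fit$loadings) %*% sig_inv    # 2 x 3
  dev <- sweep(y, 2L, as.vector(fit$loadings %*% mu_eta))
  scores <- sweep(dev %*% t(A), 2L, mu_eta, "+")
  dimnames(scores) <- NULL
  slope <- scores[, 2L]
  tibble::tibble(intercept_score = scores[, 1L],
                 slope_score = slope,
                 std_slope = as.vector(scale(slope)))
}

#' Fit growth models for many RNAs
#'
#' Convenience wrapper: fits [fit_lgm()] per gene on a gene x subject x
#' timepoint expression array laid out as three matrices, returning tidy
#' parameter/fit-index rows and a subject x gene table of factor scores.
#'
#' @param expr_by_tp Named list of three gene x subject matrices (`T0`, `T2`,
#'   `T8`), equal dimensions and matching order.
#' @param genes Genes to fit (default: all rows).
#' @inheritParams fit_lgm
#' @return A list: `fits` tibble (gene, parameters, fit indices, converged)
#'   and `scores` tibble (subject row index, gene, intercept_score,
#'   slope_score, std_slope).
#' @export
fit_growth_models <- function(expr_by_tp, genes = rownames(expr_by_tp[[1L]]),
                              weeks = c(0, 2, 8),
                              chisq_scale = c("n-1", "n")) {
  chisq_scale <- match.arg(chisq_scale)
  stopifnot(length(expr_by_tp) == 3L)
  subj <- colnames(expr_by_tp[[1L]])
  rows <- list(); score_rows <- list()
  for (g in genes) {
    y <- cbind(expr_by_tp[[1L]][g, ], expr_by_tp[[2L]][g, ],
               expr_by_tp[[3L]][g, ])
    fit <- fit_lgm(y, weeks = weeks, chisq_scale = chisq_scale)
    idx <- fit_indices(fit)
    rows[[g]] <- dplyr::bind_cols(
      tibble::tibble(gene = g, mu_i = fit$mu_i, mu_s = fit$mu_s,
                     var_i = fit$psi[1, 1], var_s = fit$psi[2, 2],
                     cov_is = fit$psi[1, 2],
                     theta_t0 = fit$theta[1], theta_t2 = fit$theta[2],
                     theta_t8 = fit$theta[3], converged = fit$converged),
      idx)
    sc <- factor_scores(fit, y)
    score_rows[[g]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = subj %||% as.character(seq_len(nrow(y))),
                     gene = g), sc)
  }
  list(fits = dplyr::bind_rows(rows), scores = dplyr::bind_rows(score_rows))
}

#' @export
print.lgm_fit <- function(x, ...) {
  cat(sprintf("Linear latent growth model (n = %d, %s convention)\n",
              x$n, x$chisq_scale))
  cat(sprintf("  mean intercept %.4f, mean slope %.4f per week\n",
              x$mu_i, x$mu_s))
  cat(sprintf("  var(i) %.4f, var(s) %.4f, cov(i,s) %.4f\n",
              x$psi[1, 1], x$psi[2, 2], x$psi[1, 2]))
  cat(sprintf("  chi-square %.4f on %d df (F_ML %.6f)\n",
              x$chi_square, x$df, x$fml))
  invisible(x)
}
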