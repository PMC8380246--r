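# shared fixtures and small independent oracles, built in code at test time

tiny_cohort <- function(seed = 101, n_patients = 40, n_controls = 20,
                        n_genes = 60, n_marker_genes = 3, ...) {
  simulate_cohort(sim_config(n_patients = n_patients, n_controls = n_controls,
                             n_genes = n_genes, n_marker_genes = n_marker_genes,
                             seed = seed, ...))
}

# covariate-adjusted log2 expression per timepoint, columns renamed to subjects
adjusted_by_timepoint <- function(cohort, pseudocount = 1) {
  counts <- cohort$counts
  sf <- size_factors(counts)
  phen <- cohort$phenotypes
  tps <- list(T0 = counts[, grepl("_T0$", colnames(counts)), drop = FALSE],
              T2 = counts[, grepl("_T2$", colnames(counts)), drop = FALSE],
              T8 = counts[, grepl("_T8$", colnames(counts)), drop = FALSE])
  lapply(tps, function(m) {
    ids <- sub("_(T0|T2|T8)$", "", colnames(m))
    cov <- phen[match(ids, phen$subject_id), c("age", "sex", "rin")]
    r <- residualize(normalize_log2(m, sf[colnames(m)], pseudocount), cov)
    colnames(r) <- ids
    r
  })
}

# brute-force two-loop Calinski-Harabasz, independent of the implementation
ch_brute <- function(x, labels) {
  x <- as.matrix(x)
  labs <- unique(labels)
  k <- length(labs)
  n <- nrow(x)
  grand <- colMeans(x)
  B <- 0
  W <- 0
  for (lv in labs) {
    xi <- x[labels == lv, , drop = FALSE]
    ci <- colMeans(xi)
    B <- B + nrow(xi) * sum((ci - grand)^2)
    for (r in seq_len(nrow(xi))) W <- W + sum((xi[r, ] - ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# exact two-sided Fisher p by enumerating all tables with the observed margins
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, 0)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  s / choose(n, 2)
}

# F_ML objective rebuilt independently for optimizer cross-checks
fml_direct <- function(par, S, ybar, lam) {
  logdetS <- determinant(S)$modulus[1L]
  mu <- lam %*% par[1:2]
  L <- matrix(c(par[3], par[4], 0, par[5]), 2L, 2L)
  sg <- lam %*% tcrossprod(L) %*% t(lam) + diag(exp(par[6:8]))
  ch <- tryCatch(chol(sg), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  P <- chol2inv(ch)
  d <- ybar - as.vector(mu)
  2 * sum(log(diag(ch))) - logdetS + sum(S * P) - 3 +
    as.numeric(crossprod(d, P %*% d))
}

# generic optimizer on F_ML: Nelder-Mead with restarts from a remote start
fml_independent_opt <- function(y, lam = cbind(1, c(0, 2, 8))) {
  S <- stats::cov(y)
  ybar <- colMeans(y)
  p <- c(ybar[1] - 1, 0, 0.5, 0.1, 0.3, log(0.5), log(0.4), log(0.3))
  for (i in 1:8) {
    o <- stats::optim(p, fml_direct, S = S, ybar = ybar, lam = lam,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    p <- o$par
  }
  o$value
}

lgm_sim <- function(n, mu = c(5, 0.3), psi = matrix(c(1, 0, 0, 0.04), 2),
                    theta = 0.25, weeks = c(0, 2, 8)) {
  ab <- MASS::mvrnorm(n, mu, psi)
  ab %*% t(cbind(1, weeks)) + matrix(stats::rnorm(n * 3, 0, sqrt(theta)), n, 3)
}
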