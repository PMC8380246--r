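test_that("near-deterministic growth data recover the moment parameters", {
  set.seed(41)
  n <- 400
  ab <- MASS::mvrnorm(n, c(5, 0.3), matrix(c(1, 0.1, 0.1, 0.04), 2))
  y <- ab %*% t(cbind(1, c(0, 2, 8))) +
    matrix(rnorm(n * 3, 0, 1e-4), n, 3)   # vanishing residual noise
  fit <- fit_lgm(y)
  expect_lt(abs(fit$mu_i - mean(ab[, 1])), 1e-4)
  expect_lt(abs(fit$mu_s - mean(ab[, 2])), 1e-4)
  expect_lt(max(abs(fit$psi - cov(ab))), 1e-4)
  expect_lt(max(fit$theta), 1e-5)
})

test_that("the fitted optimum matches an independent generic optimizer", {
  set.seed(42)
  y <- lgm_sim(800)
  fit <- fit_lgm(y)
  expect_true(fit$converged)
  f_ind <- fml_independent_opt(y)
  expect_lt(abs(fit$fml - f_ind), 1e-5)
})

test_that("parameters are recovered within Monte-Carlo error", {
  true <- c(5, 0.3, 1, 0.04, 0, 0.25, 0.25, 0.25)
  est <- matrix(NA_real_, 6, 8)
  set.seed(43)
  for (s in 1:6) {
    y <- lgm_sim(2000)
    f <- fit_lgm(y)
    est[s, ] <- c(f$mu_i, f$mu_s, f$psi[1, 1], f$psi[2, 2], f$psi[1, 2],
                  f$theta)
  }
  mcse <- apply(est, 2, sd) / sqrt(nrow(est))
  z <- abs(colMeans(est) - true) / mcse
  expect_true(all(z < 4))
})

test_that("F_ML is nonnegative and the model df is 1", {
  set.seed(44)
  y <- lgm_sim(300)
  fit <- fit_lgm(y)
  expect_gte(fit$fml, 0)
  expect_equal(fit$df, 1L)
  expect_gte(fit$chi_square, 0)
})

test_that("shifting all values moves only the mean intercept", {
  set.seed(45)
  y <- lgm_sim(500)
  f1 <- fit_lgm(y)
  f2 <- fit_lgm(y + 3)
  expect_equal(f2$mu_i, f1$mu_i + 3, tolerance = 1e-4)
  expect_equal(f2$mu_s, f1$mu_s, tolerance = 1e-4)
  expect_equal(f2$psi, f1$psi, tolerance = 1e-3)
  expect_equal(f2$fml, f1$fml, tolerance = 1e-6)
})

test_that("rescaling the slope loading rescales the slope and not the association scale", {
  set.seed(46)
  y <- lgm_sim(500)
  f1 <- fit_lgm(y, weeks = c(0, 2, 8))
  f2 <- fit_lgm(y, weeks = c(0, 2, 8) / 2)
  expect_equal(f2$mu_s, 2 * f1$mu_s, tolerance = 1e-3)
  s1 <- factor_scores(f1, y)
  s2 <- factor_scores(f2, y)
  expect_equal(s2$std_slope, s1$std_slope, tolerance = 1e-4)
})

test_that("the independence baseline is zero for decorrelated data and mean-invariant", {
  set.seed(47)
  y <- matrix(rnorm(600), 200, 3)
  # whiten so the unbiased sample covariance is exactly diagonal (identity)
  y <- scale(y, scale = FALSE) %*% solve(chol(cov(y)))
  b <- fit_independence_baseline(y)
  expect_equal(b$chi_square, 0, tolerance = 1e-8)
  expect_equal(b$df, 3L)
  y2 <- sweep(y, 2, c(10, -4, 2), "+")
  expect_equal(fit_independence_baseline(y2)$chi_square, b$chi_square,
               tolerance = 1e-8)
})

test_that("fit indices behave at the saturated and boundary cases", {
  fit <- list(chi_square = 0, df = 1L, n = 200, S = diag(3) * 2,
              sigma_hat = diag(3) * 2)
  class(fit) <- "lgm_fit"
  idx <- fit_indices(fit, baseline = list(chi_square = 50, df = 3L))
  expect_equal(idx$cfi, 1)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$srmr, 0)
  expect_equal(idx$gfi, 1)
  # T = df exactly
  fit$chi_square <- 1
  idx2 <- fit_indices(fit, baseline = list(chi_square = 50, df = 3L))
  expect_equal(idx2$cfi, 1)
  expect_equal(idx2$rmsea, 0)
  # baseline no better than the model: capped with CFI/TLI = 1
  idx3 <- fit_indices(fit, baseline = list(chi_square = 2, df = 3L))
  expect_equal(idx3$cfi, 1)
  expect_equal(idx3$tli, 1)
})

test_that("GFI and SRMR match a two-loop hand evaluation on a 3x3 example", {
  S <- matrix(c(2.0, 0.6, 0.4,
                0.6, 1.5, 0.5,
                0.4, 0.5, 1.8), 3, 3)
  Sig <- matrix(c(1.9, 0.7, 0.35,
                  0.7, 1.6, 0.45,
                  0.35, 0.45, 1.7), 3, 3)
  fit <- list(chi_square = 5, df = 1L, n = 150, S = S, sigma_hat = Sig)
  class(fit) <- "lgm_fit"
  idx <- fit_indices(fit, baseline = list(chi_square = 80, df = 3L))
  M <- solve(Sig) %*% S
  gfi_hand <- 1 - sum(diag((M - diag(3)) %*% (M - diag(3)))) /
    sum(diag(M %*% M))
  sr <- 0
  cnt <- 0
  for (i in 1:3) for (j in i:3) {
    sr <- sr + ((S[i, j] - Sig[i, j]) / sqrt(S[i, i] * S[j, j]))^2
    cnt <- cnt + 1
  }
  expect_equal(idx$gfi, gfi_hand, tolerance = 1e-12)
  expect_equal(idx$srmr, sqrt(sr / cnt), tolerance = 1e-12)
})

test_that("factor scores reduce to per-subject OLS slopes as noise vanishes", {
  set.seed(48)
  n <- 200
  ab <- MASS::mvrnorm(n, c(4, 0.2), matrix(c(0.8, 0, 0, 0.05), 2))
  lam <- cbind(1, c(0, 2, 8))
  y <- ab %*% t(lam) + matrix(rnorm(n * 3, 0, 1e-4), n, 3)
  fit <- fit_lgm(y)
  sc <- factor_scores(fit, y)
  ols <- y %*% t(solve(crossprod(lam), t(lam)))
  expect_lt(max(abs(sc$slope_score - ols[, 2])), 1e-3)
  # the population-mean trajectory maps to the mean parameters (fixed point)
  ymean <- matrix(as.vector(lam %*% c(fit$mu_i, fit$mu_s)), 1)
  sc0 <- factor_scores(fit, ymean)
  expect_equal(sc0$intercept_score, fit$mu_i, tolerance = 1e-8)
  expect_equal(sc0$slope_score, fit$mu_s, tolerance = 1e-8)
})

test_that("factor scores shrink and standardized slopes are z-scored", {
  set.seed(49)
  y <- lgm_sim(1500)
  fit <- fit_lgm(y)
  sc <- factor_scores(fit, y)
  expect_lte(var(sc$slope_score), fit$psi[2, 2] + 1e-8)
  expect_equal(mean(sc$std_slope), 0, tolerance = 1e-10)
  expect_equal(sd(sc$std_slope), 1, tolerance = 1e-10)
  # slope scores track the simulated subject slopes
  expect_gt(cor(sc$slope_score, (y[, 3] - y[, 1]) / 8), 0.6)
})

test_that("degenerate inputs are rejected", {
  y <- matrix(1, 50, 3)  # singular sample covariance
  expect_error(fit_lgm(y), "singular")
  expect_error(fit_lgm(matrix(rnorm(9), 3, 3)), "few subjects")
})
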