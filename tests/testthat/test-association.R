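test_that("logistic intercept equals the empirical logit with no predictors", {
  y <- rep(c(0, 1), each = 30)
  fit <- logistic_fit(y, data.frame(x = rep(0, 60)))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 0, tolerance = 1e-8)
})

test_that("logistic regression recovers a known slope coefficient", {
  set.seed(51)
  n <- 4000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 0.8 * x))
  fit <- logistic_fit(y, data.frame(x = x))
  b <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_gt(b, 0.7)
  expect_lt(b, 0.9)
  # null predictor stays within 3 SEs of zero
  z <- rnorm(n)
  fit0 <- logistic_fit(y, data.frame(z = z))
  cf0 <- fit0$coefficients
  expect_lt(abs(cf0$estimate[cf0$term == "z"] / cf0$se[cf0$term == "z"]), 3.5)
})

test_that("perfect separation is flagged", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- logistic_fit(y, data.frame(x = x))
  expect_true(fit$separation)
})

test_that("intercept-only multinomial equals log class-proportion ratios", {
  y <- factor(rep(c("a", "b", "c"), times = c(50, 30, 20)))
  fit <- multinomial_fit(y, data.frame(row.names = 1:100), base = "a")
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$class == "b" & cf$term == "(Intercept)"],
               log(30 / 50), tolerance = 1e-8)
  expect_equal(cf$estimate[cf$class == "c" & cf$term == "(Intercept)"],
               log(20 / 50), tolerance = 1e-8)
})

test_that("two-class multinomial reduces to binary logistic within 1e-6", {
  set.seed(52)
  n <- 400
  x <- rnorm(n)
  w <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.7 * x - 0.4 * w))
  mf <- multinomial_fit(factor(y), data.frame(x = x, w = w), base = "0")
  gf <- logistic_fit(y, data.frame(x = x, w = w))
  expect_lt(max(abs(mf$coefficients$estimate - gf$coefficients$estimate)), 1e-6)
  expect_lt(max(abs(mf$coefficients$se - gf$coefficients$se)), 1e-6)
})

test_that("Newton iterations never decrease the multinomial log-likelihood", {
  set.seed(53)
  n <- 300
  x <- rnorm(n)
  eta <- cbind(0, 0.5 + 0.8 * x, -0.2 + 0.3 * x)
  pr <- exp(eta) / rowSums(exp(eta))
  y <- factor(apply(pr, 1, function(p) sample(3, 1, prob = p)))
  fit <- multinomial_fit(y, data.frame(x = x), base = "1")
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
})

test_that("multinomial estimates agree with nnet as an independent route", {
  set.seed(54)
  n <- 500
  x <- rnorm(n)
  w <- rbinom(n, 1, 0.4)
  eta <- cbind(0, 0.4 + 0.9 * x - 0.5 * w, -0.3 - 0.6 * x + 0.2 * w)
  pr <- exp(eta) / rowSums(exp(eta))
  y <- factor(apply(pr, 1, function(p) sample(3, 1, prob = p)),
              labels = c("base", "up", "down"))
  fit <- multinomial_fit(y, data.frame(x = x, w = w), base = "base")
  nf <- nnet::multinom(y ~ x + w, trace = FALSE, maxit = 500, reltol = 1e-14)
  cf_nnet <- as.vector(t(coef(nf)))
  expect_lt(max(abs(fit$coefficients$estimate - cf_nnet)), 1e-4)
})

test_that("multinomial recovers known class-specific slope effects", {
  set.seed(55)
  n <- 5000
  x <- rnorm(n)
  eta <- cbind(0, 0.8 * x, -0.9 * x)
  pr <- exp(eta) / rowSums(exp(eta))
  y <- factor(apply(pr, 1, function(p) sample(3, 1, prob = p)))
  fit <- multinomial_fit(y, data.frame(x = x), base = "1")
  cf <- fit$coefficients
  b2 <- cf[cf$class == "2" & cf$term == "x", ]
  b3 <- cf[cf$class == "3" & cf$term == "x", ]
  expect_lt(abs(b2$estimate - 0.8) / b2$se, 3)
  expect_lt(abs(b3$estimate + 0.9) / b3$se, 3)
  expect_error(multinomial_fit(factor(c("a", "b")), data.frame(x = 1:2),
                               base = "z"), "not an outcome level")
})

test_that("risk ratios and Wald intervals reproduce the published rows", {
  # CERCAM, responders vs nonresponders
  w <- wald_rr(1.064, 0.323)
  expect_equal(round(w$rr, 2), 2.90)
  expect_equal(round(w$ci_low, 2), 1.54)
  expect_equal(round(w$ci_high, 2), 5.46)
  expect_equal(round(w$p, 3), 0.001)
  # DARS-AS1, early vs nonresponders
  w2 <- wald_rr(-0.879, 0.309)
  expect_equal(round(w2$rr, 2), 0.42)
  expect_equal(round(w2$ci_low, 2), 0.23)
  expect_equal(round(w2$ci_high, 2), 0.76)
  # null effect
  w0 <- wald_rr(0, 0.5)
  expect_equal(w0$rr, 1)
  expect_equal(w0$p, 1)
  # sign symmetry: reciprocal risk ratios
  wp <- wald_rr(0.7, 0.2)
  wn <- wald_rr(-0.7, 0.2)
  expect_equal(wn$rr, 1 / wp$rr)
  expect_equal(wn$p, wp$p)
  expect_error(wald_rr(1, 0), "positive")
})

test_that("the three-step analysis flows scores through to an association table", {
  set.seed(56)
  n <- 600
  subj <- sprintf("S%03d", 1:n)
  cls <- sample(c("early_responder", "later_responder", "nonresponder"), n,
                replace = TRUE, prob = c(0.23, 0.32, 0.45))
  resp <- as.numeric(cls != "nonresponder")
  labels <- tibble::tibble(subject_id = subj, label = cls)
  covariates <- tibble::tibble(subject_id = subj, age = runif(n, 18, 61),
                               sex = sample(c("male", "female"), n, TRUE),
                               anxiety = rbinom(n, 1, 0.5),
                               suicidality = rbinom(n, 1, 0.75))
  mk_scores <- function(gene, slope) {
    tibble::tibble(subject_id = subj, gene = gene,
                   intercept_score = rnorm(n, 5, 0.5),
                   slope_score = slope,
                   std_slope = as.vector(scale(slope)))
  }
  scores <- dplyr::bind_rows(
    mk_scores("signal", 0.05 * resp + rnorm(n, 0, 0.08)),
    mk_scores("null1", rnorm(n, 0, 0.08)),
    mk_scores("null2", rnorm(n, 0, 0.08)))
  res <- run_three_step(scores, labels, covariates)
  expect_true(res$step1$advance[res$step1$gene == "signal"])
  tab <- res$table
  expect_true(all(tab$fdr >= tab$p - 1e-15))
  expect_equal(tab$rr, exp(tab$log_rr))
  expect_true(all(tab$ci_low < tab$rr & tab$rr < tab$ci_high))
  sig <- tab[tab$gene == "signal", ]
  expect_true(all(sig$fdr < 0.05))
  expect_equal(sort(unique(tab$contrast)),
               c("early_vs_nonresponders", "later_vs_nonresponders",
                 "responders_vs_nonresponders"))
  expect_equal(res$family_size, nrow(tab))
})

test_that("an all-null score set rarely advances and can come up empty", {
  set.seed(57)
  n <- 300
  subj <- sprintf("S%03d", 1:n)
  cls <- sample(c("early_responder", "later_responder", "nonresponder"), n,
                replace = TRUE)
  labels <- tibble::tibble(subject_id = subj, label = cls)
  covariates <- tibble::tibble(subject_id = subj, age = runif(n, 18, 61),
                               sex = sample(0:1, n, TRUE),
                               anxiety = rbinom(n, 1, 0.5),
                               suicidality = rbinom(n, 1, 0.75))
  scores <- purrr::map_dfr(1:40, function(i) {
    s <- rnorm(n)
    tibble::tibble(subject_id = subj, gene = paste0("g", i),
                   intercept_score = rnorm(n), slope_score = s,
                   std_slope = as.vector(scale(s)))
  })
  res <- run_three_step(scores, labels, covariates)
  expect_lt(mean(res$step1$advance), 0.15)
  # forcing an impossible threshold empties the table cleanly
  res0 <- run_three_step(scores[scores$gene == "g1", ], labels, covariates,
                         step1_p = 1e-12)
  expect_equal(nrow(res0$table), 0L)
  expect_equal(res0$family_size, 0L)
})
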