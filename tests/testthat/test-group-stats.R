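test_that("chi-square reproduces the cohort demographic p-values at 3 decimals", {
  published <- cohort_demographics()$categorical
  for (i in seq_len(nrow(published))) {
    tab <- demographic_table(published$characteristic[i])
    p <- chi2_independence(tab)$p
    expect_lt(abs(p - published$published_p[i]), 0.001)
  }
})

test_that("chi-square handles degenerate and proportional tables", {
  out <- chi2_independence(rbind(c(10, 20), c(5, 10)))
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  expect_equal(chi2_independence(rbind(c(5, 5), c(5, 5)))$statistic, 0)
  expect_error(chi2_independence(rbind(c(0, 0), c(5, 5))), "margin")
  expect_error(chi2_independence(matrix(1:3, 1)), "r x c")
})

test_that("Fisher's exact test agrees with hypergeometric enumeration", {
  tabs <- list(rbind(c(1, 9), c(11, 3)),
               rbind(c(5, 5), c(5, 5)),
               rbind(c(10, 0), c(0, 10)),
               rbind(c(2, 7), c(8, 2)))
  for (tab in tabs) {
    expect_equal(fisher_exact_2x2(tab), fisher_brute(tab), tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  expect_lt(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))), 1e-4)
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2 x 2")
})

test_that("Fisher matches enumeration across all margins up to 8", {
  set.seed(61)
  for (i in 1:25) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_brute(tab), tolerance = 1e-9)
  }
})

test_that("one-way ANOVA from summaries reproduces the published age comparison", {
  age <- cohort_demographics()$age
  out <- anova_oneway(as.data.frame(age[, c("n", "mean", "sd")]))
  expect_gt(out$p, 0.760)
  expect_lt(out$p, 0.763)
})

test_that("ANOVA from raw data equals ANOVA from its summary triples exactly", {
  set.seed(62)
  groups <- list(rnorm(12, 0), rnorm(15, 0.5), rnorm(9, -0.3))
  raw <- anova_oneway(groups)
  summ <- anova_oneway(data.frame(n = lengths(groups),
                                  mean = sapply(groups, mean),
                                  sd = sapply(groups, sd)))
  expect_identical(raw$f, summ$f)
  expect_identical(raw$p, summ$p)
  # cross-check against stats::aov
  dat <- data.frame(v = unlist(groups),
                    g = factor(rep(1:3, lengths(groups))))
  av <- summary(stats::aov(v ~ g, dat))[[1]]
  expect_equal(raw$f, av[1, "F value"], tolerance = 1e-10)
  expect_equal(raw$p, av[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("two-group ANOVA equals the squared pooled-variance t statistic", {
  set.seed(63)
  a <- rnorm(20)
  b <- rnorm(25, 0.4)
  f <- anova_oneway(list(a, b))
  t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(f$f, unname(t2), tolerance = 1e-10)
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$f, 0)
  expect_error(anova_oneway(list(1, c(2, 3))), "n >= 2")
})

test_that("Tukey HSD respects multiplicity and degenerates sensibly", {
  set.seed(64)
  groups <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  hsd <- tukey_hsd(groups)
  expect_equal(nrow(hsd), 3L)
  # adjusted p at least as large as the raw pairwise t-test p
  for (i in seq_len(nrow(hsd))) {
    pair <- strsplit(hsd$comparison[i], "-")[[1]]
    raw <- stats::t.test(groups[[pair[1]]], groups[[pair[2]]],
                         var.equal = TRUE)$p.value
    expect_gte(hsd$p_adj[i] + 1e-8, raw)
  }
  same <- tukey_hsd(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                         c = c(1, 2, 3, 4)))
  expect_true(all(same$p_adj > 0.99))
  shifted <- tukey_hsd(list(a = rnorm(20), b = rnorm(20), c = rnorm(20) + 10))
  expect_true(all(shifted$p_adj[grepl("c", shifted$comparison)] < 0.001))
  two <- tukey_hsd(list(a = rnorm(10), b = rnorm(10)))
  expect_match(attr(two, "note"), "t test")
})

test_that("Dunnett comparisons are adjusted relative to the control", {
  set.seed(65)
  groups <- list(untreated = rnorm(12), drug1 = rnorm(12), drug2 = rnorm(12) + 3)
  out <- dunnett(groups, control = "untreated")
  expect_equal(nrow(out), 2L)
  raw1 <- stats::t.test(groups$drug1, groups$untreated,
                        var.equal = TRUE)$p.value
  expect_gte(out$p_adj[out$comparison == "drug1 - untreated"] + 0.02, raw1)
  expect_lt(out$p_adj[out$comparison == "drug2 - untreated"], 0.001)
  same <- dunnett(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(same$p_adj > 0.95))
  expect_error(dunnett(groups, control = "missing"), "control")
})

test_that("pooled two-sample t test behaves under identity, swap and the null", {
  a <- c(1, 2, 3, 4)
  same <- two_sample_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_t(c(2, 2, 2), c(2, 2, 2)), "zero pooled variance")
  set.seed(66)
  x <- rnorm(15)
  y <- rnorm(18, 1)
  t1 <- two_sample_t(x, y)
  t2 <- two_sample_t(y, x)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p, t2$p)
  ps <- replicate(400, two_sample_t(rnorm(10), rnorm(10))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("2^-ddCt quantification follows the cycle arithmetic", {
  ct <- tidyr::expand_grid(condition = c("untreated", "drugA", "drugB"),
                           replicate = 1:3, gene = c("TARG", "ACTB"))
  ct$ct <- ifelse(ct$gene == "ACTB", 15,
                  ifelse(ct$condition == "drugA", 24,
                         ifelse(ct$condition == "drugB", 25 + 3.2, 25)))
  res <- ddct(ct, "TARG", "ACTB", "untreated")
  byc <- res$by_condition
  expect_equal(byc$fold_change[byc$condition == "untreated"], 1)
  expect_equal(byc$fold_change[byc$condition == "drugA"], 2)   # ddCt = -1
  expect_equal(byc$fold_change[byc$condition == "drugB"], 2^-3.2)
  expect_true(all(byc$fold_change > 0))
  # missing reference Ct names the replicate
  ct2 <- ct[!(ct$gene == "ACTB" & ct$condition == "drugA" & ct$replicate == 2), ]
  expect_error(ddct(ct2, "TARG", "ACTB", "untreated"), "replicate")
})
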