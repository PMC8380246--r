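test_that("the MADRS change ratio is the later score over baseline", {
  expect_equal(delta_madrs(30, 15), 0.5)
  expect_equal(delta_madrs(30, 30), 1.0)
  expect_equal(delta_madrs(21, 42), 2.0)
  expect_error(delta_madrs(0, 10), "positive")
})

test_that("the 50%-reduction rule classifies early, later and non-response", {
  md <- tibble::tibble(
    subject_id = c("early", "later", "flat", "relapse", "boundary"),
    madrs_w0 = c(30, 30, 30, 30, 30),
    madrs_w2 = c(14, 20, 28, 14, 15),
    madrs_w4 = c(10, 16, 29, 12, 14),
    madrs_w6 = c(8, 14, 27, 20, 14),
    madrs_w8 = c(6, 12, 28, 27, 15))
  lab <- classify_response(md)
  expect_equal(lab$label,
               c("early_responder", "later_responder", "nonresponder",
                 "nonresponder", "early_responder"))
  expect_equal(lab$nr_subtype,
               c("not_applicable", "not_applicable", "flat", "relapse",
                 "not_applicable"))
  # boundary: exactly 50% reduction counts as response at both visits
  expect_equal(lab$delta_madrs_t8[5], 0.5)
})

test_that("classification is invariant to positive rescaling of a row", {
  md <- tibble::tibble(subject_id = "a", madrs_w0 = 30, madrs_w2 = 20,
                       madrs_w4 = 16, madrs_w6 = 14, madrs_w8 = 12)
  md2 <- md
  md2[, -1] <- md[, -1] * 1.7
  expect_equal(classify_response(md)$label, classify_response(md2)$label)
})

test_that("incomplete MADRS panels are rejected", {
  md <- tibble::tibble(subject_id = "a", madrs_w0 = 30, madrs_w2 = NA,
                       madrs_w4 = 16, madrs_w6 = 14, madrs_w8 = 12)
  expect_error(classify_response(md), "complete")
})

test_that("Calinski-Harabasz matches hand evaluation and brute force", {
  # 1-D points {0,1} vs {10,11}: B = 100, W = 1, CH = (100/1)/(1/2) = 200
  x <- matrix(c(0, 1, 10, 11), 4, 1)
  labs <- c(1, 1, 2, 2)
  expect_equal(calinski_harabasz(x, labs), 200)
  expect_equal(calinski_harabasz(x, labs), ch_brute(x, labs))
  # degenerate: zero within-cluster variance
  expect_equal(calinski_harabasz(matrix(c(0, 0, 5, 5), 4, 1), labs), Inf)
  expect_error(calinski_harabasz(x, rep(1, 4)), "2 nonempty")
  # brute-force agreement on random instances with n <= 30
  set.seed(42)
  for (i in 1:5) {
    xr <- matrix(rnorm(30 * 3), 30, 3)
    lr <- sample(1:3, 30, replace = TRUE)
    expect_equal(calinski_harabasz(xr, lr), ch_brute(xr, lr))
  }
})

test_that("random labels on homogeneous data give CH near 1 in expectation", {
  set.seed(8)
  x <- matrix(rnorm(100 * 2), 100, 2)
  vals <- replicate(400, calinski_harabasz(x, sample(1:2, 100, replace = TRUE)))
  expect_lt(abs(mean(vals) - 1), 0.15)
})

test_that("k-means separates two homogeneous trajectory groups with zero inertia", {
  x <- rbind(matrix(rep(c(30, 30, 30, 30, 30), each = 10), 10, 5),
             matrix(rep(c(30, 15, 10, 8, 6), each = 10), 10, 5))
  km <- suppressWarnings(kml_cluster(x, k_candidates = 2, n_restarts = 10,
                                     seed = 3))
  k2 <- km$per_k[km$per_k$k == 2, ]
  expect_equal(k2$best_inertia, 0)
  expect_equal(km$selected_k, 2L)
  expect_error(kml_cluster(x, k_candidates = 25, n_restarts = 2, seed = 1),
               "smaller")
})

test_that("CH prefers the true two-group partition over any three-way split", {
  set.seed(14)
  x <- rbind(matrix(rep(c(30, 30, 30, 30, 30), each = 10), 10, 5),
             matrix(rep(c(30, 15, 10, 8, 6), each = 10), 10, 5)) +
    matrix(rnorm(100, 0, 0.01), 20, 5)
  km <- kml_cluster(x, k_candidates = 2:3, n_restarts = 20, seed = 5)
  ch2 <- km$per_k$calinski_harabasz[km$per_k$k == 2]
  ch3 <- km$per_k$calinski_harabasz[km$per_k$k == 3]
  expect_gt(ch2, ch3)
  expect_equal(km$selected_k, 2L)
})

test_that("kml recovers four well-separated trajectory classes", {
  cfg <- sim_config(n_patients = 400, madrs_noise_sd = 1, seed = 4)
  set.seed(4)
  ph <- simulate_phenotypes(cfg)
  pat <- ph[ph$group == "patient", ]
  md <- simulate_madrs(cfg, stats::setNames(pat$true_class, pat$subject_id))
  km <- kml_cluster(md, k_candidates = 2:6, n_restarts = 20, seed = 99)
  expect_equal(km$selected_k, 4L)
  ri <- rand_index(km$assignments$cluster, as.integer(factor(md$true_class)))
  expect_gt(ri, 0.95)
})

test_that("kml is invariant to subject order given enough restarts", {
  cfg <- sim_config(n_patients = 120, madrs_noise_sd = 1, seed = 6)
  set.seed(6)
  ph <- simulate_phenotypes(cfg)
  pat <- ph[ph$group == "patient", ]
  md <- simulate_madrs(cfg, stats::setNames(pat$true_class, pat$subject_id))
  x <- as.matrix(md[, paste0("madrs_w", c(0, 2, 4, 6, 8))])
  rownames(x) <- md$subject_id
  perm <- sample(nrow(x))
  k1 <- kml_cluster(x, k_candidates = 4, n_restarts = 40, seed = 11)
  k2 <- kml_cluster(x[perm, ], k_candidates = 4, n_restarts = 40, seed = 12)
  a1 <- unname(k1$assignments$cluster)
  a2 <- unname(k2$assignments$cluster[match(k1$assignments$subject_id,
                                            k2$assignments$subject_id)])
  expect_equal(rand_index(a1, a2), 1)
})
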