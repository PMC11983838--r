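test_that("bulkify matches hand arithmetic in both modes", {
  counts <- rbind(c1 = c(1, 2), c2 = c(3, 4))
  colnames(counts) <- c("gA", "gB")
  t <- cell_table(counts, tibble::tibble(cell_id = c("c1", "c2"),
                                         patient_id = "P1",
                                         compartment = "malignant"))
  expect_equal(unname(bulkify(t, "P1", "sum_log1p")), log(c(5, 7)))
  # per-cell TPM: c1 -> (1/3, 2/3)*1e6, c2 -> (3/7, 4/7)*1e6
  expect_equal(unname(bulkify(t, "P1", "mean_tpm")),
               1e6 * c(mean(c(1 / 3, 3 / 7)), mean(c(2 / 3, 4 / 7))))
  single <- filter_cells(t, "c1")
  expect_equal(unname(bulkify(single, "P1", "sum_log1p")), log(c(2, 3)))
  expect_error(bulkify(t, "P9"), "Unknown patient")
})

test_that("degree selection finds the true polynomial degree", {
  x <- seq(-2, 2, length.out = 80)
  expect_equal(select_degree(x, x^2)$degree, 2)
  expect_equal(select_degree(x, 3 * x + 1)$degree, 1)
  # cubic with visible contributions at every order (a pure odd cubic hides
  # its degree from any forward R^2 rule: the quadratic step adds nothing)
  P <- stats::poly(x, 3)
  expect_equal(select_degree(x, P[, 1] + P[, 2] + P[, 3])$degree, 3)
  expect_error(select_degree(x, rep(1, 80)), "zero variance")
  r2 <- select_degree(x, x^2 + rnorm(80, sd = 0.1))$r2_curve
  expect_true(all(diff(r2) >= -1e-12))  # nested models: R^2 non-decreasing
})

test_that("the MT residual statistic recovers additive shifts exactly", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:120)
  genes[1:10] <- sprintf("MT-G%d", 1:10)
  bulk <- stats::setNames(runif(120, 1, 8), genes)
  bulkified <- 0.5 + 1.2 * bulk  # exact linear relation
  mt <- genes[1:10]
  expect_equal(mt_residual_statistic(bulk, bulkified, mt, 1), 0,
               tolerance = 1e-10)
  shifted <- bulkified
  shifted[mt] <- shifted[mt] + 0.7
  expect_equal(mt_residual_statistic(bulk, shifted, mt, 1), 0.7,
               tolerance = 1e-10)
  deflated <- bulkified
  deflated[mt] <- deflated[mt] - 0.7
  expect_equal(mt_residual_statistic(bulk, deflated, mt, 1), -0.7,
               tolerance = 1e-10)
  expect_error(mt_residual_statistic(bulk, bulkified, "absent", 1), "No MT")
})

test_that("the empirical gene-sampling test follows its p-value formula", {
  set.seed(22)
  genes <- c(sprintf("MT-G%d", 1:5), sprintf("g%03d", 1:95))
  bulk <- stats::setNames(runif(100, 2, 9), genes)
  bulkified <- bulk + rnorm(100, sd = 0.05)
  mt <- genes[1:5]
  # an extreme planted excess beats every null draw: p = 1/(B+1)
  big <- bulkified
  big[mt] <- big[mt] + 5
  res <- empirical_gene_sampling_test(bulk, big, mt, degree = 1,
                                      B = 100, pool_size = 50, seed = 7)
  expect_equal(res$p_raw, 1 / 101)
  expect_length(res$null_means, 100)
  expect_gte(res$p_raw, 1 / (res$B + 1))

  # determinism under fixed seed
  res2 <- empirical_gene_sampling_test(bulk, big, mt, degree = 1,
                                       B = 100, pool_size = 50, seed = 7)
  expect_identical(res$null_means, res2$null_means)

  # a statistic at the null median gives p near 0.5
  null_like <- empirical_gene_sampling_test(bulk, bulkified, mt, degree = 1,
                                            B = 200, pool_size = 50, seed = 8)
  med_stat <- median(null_like$null_means)
  # recompute p for an observed value equal to the null median
  p_med <- (1 + sum(null_like$null_means >= med_stat)) / 201
  expect_lt(abs(p_med - 0.5), 0.05)

  expect_error(
    empirical_gene_sampling_test(bulk, big, mt, 1, pool_size = 4, B = 10),
    "More MT genes")
  expect_error(
    empirical_gene_sampling_test(bulk, big, mt, 1, pool_size = 1000, B = 10),
    "pool_size")
})

test_that("p-value adjustment matches the standard definitions", {
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni")[1], 0.05)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
})

test_that("planted MT excess is detected end to end", {
  cfg <- synth_config(n_patients = 2, cells_per_patient = 120, n_genes = 400,
                      junk_fraction = 0,
                      mt_excess = c(P01 = 3), seed = 31)
  sim <- simulate_cohort(cfg)
  pairs <- simulate_bulk_pair(cfg, sim$cells)
  res <- residual_test_patients(pairs, detect_mt_genes(sim$cells),
                                B = 99, pool_size = 200, seed = 1)
  p1 <- res[res$patient_id == "P01", ]
  p2 <- res[res$patient_id == "P02", ]
  expect_gt(p1$mt_mean_residual, 0.5)   # ~log(3) of planted excess
  expect_lt(p1$p_adj, 0.05)
  expect_gt(p2$p_raw, 0.05)
})

test_that("noiseless identity: bulk equals the transform of bulkified", {
  cfg <- synth_config(n_patients = 1, cells_per_patient = 40, n_genes = 120,
                      junk_fraction = 0, bulk_noise_sd = 0,
                      bulk_transform = c(0.3, 1.1, 0.05), seed = 17)
  sim <- simulate_cohort(cfg)
  pairs <- simulate_bulk_pair(cfg, sim$cells)
  b <- pairs$bulkified
  expect_equal(pairs$bulk, 0.3 + 1.1 * b + 0.05 * b^2)
})
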