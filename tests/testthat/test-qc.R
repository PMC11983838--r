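test_that("top_k_fraction follows hand arithmetic and degenerate cases", {
  # 60 genes: 10 genes carry 9 counts each, 50 carry... construct 90/100 split
  counts <- matrix(0, 1, 60, dimnames = list("c1", sprintf("g%02d", 1:60)))
  counts[1, 1:50] <- c(41, rep(1, 49))  # top 50 genes hold 90 of 100
  counts[1, 51:60] <- 1
  t <- cell_table(counts, tibble::tibble(cell_id = "c1", patient_id = "P",
                                         compartment = "TME"))
  expect_equal(unname(top_k_fraction(t, k = 50)), 0.9)

  few <- matrix(c(5, 7, 0, 0), 1, 4,
                dimnames = list("c1", c("a", "b", "c", "d")))
  tf <- cell_table(few, t$cell_meta)
  expect_equal(unname(top_k_fraction(tf, k = 50)), 1.0)

  unif <- matrix(1, 1, 100, dimnames = list("c1", sprintf("u%03d", 1:100)))
  tu <- cell_table(unif, t$cell_meta)
  expect_equal(unname(top_k_fraction(tu, k = 50)), 0.5)
})

test_that("MAD flags match the hand example and the brute-force oracle", {
  # hand example on one metric: [10,12,11,10,50], median 11, MAD 1 -> last out
  m <- c(10, 12, 11, 10, 50)
  med <- median(m); mad_raw <- median(abs(m - med))
  expect_identical(abs(m - med) > 5 * mad_raw, c(F, F, F, F, T))

  # package flags equal the per-patient brute force on random tables
  set.seed(41)
  for (rep in 1:5) {
    t <- random_cell_table(n_cells = 40, n_genes = 30, n_patients = 3,
                           lambda = 20)
    qm <- cell_qc_metrics(t)
    metrics <- cbind(log1p(qm$total_counts), log1p(qm$n_genes), qm$top_k_frac)
    expect_identical(unname(mad_outlier_flags(t)),
                     oracle_mad_flags(metrics, qm$patient_id))
  }

  # all-equal metric: MAD 0, nobody deviates, none flagged
  eq <- matrix(2, 6, 20, dimnames = list(sprintf("c%d", 1:6),
                                         sprintf("g%d", 1:20)))
  te <- cell_table(eq, tibble::tibble(cell_id = rownames(eq),
                                      patient_id = "P1",
                                      compartment = "TME"))
  expect_false(any(mad_outlier_flags(te)))

  # single-cell patient passes with a warning
  t1 <- random_cell_table(n_cells = 3, n_genes = 10, n_patients = 2)
  expect_warning(f <- mad_outlier_flags(t1), "single cell")
  expect_false(any(f))
})

test_that("absolute flags use strict inequalities at the stated bounds", {
  mk <- function(total, ngenes) {
    v <- numeric(600)
    v[seq_len(ngenes)] <- 1
    v[1] <- v[1] + total - ngenes
    v
  }
  counts <- rbind(c1 = mk(1400, 600), c2 = mk(1500, 500),
                  c3 = mk(60000, 600), c4 = mk(2000, 499))
  colnames(counts) <- sprintf("g%03d", 1:600)
  t <- cell_table(counts, tibble::tibble(cell_id = rownames(counts),
                                         patient_id = "P1",
                                         compartment = "TME"))
  flags <- absolute_flags(t)
  expect_identical(unname(flags), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("transcriptome variance is the per-cell population variance", {
  m <- rbind(c1 = c(3, 3, 3), c2 = c(0, 2, 1))
  colnames(m) <- c("a", "b", "c")
  v <- transcriptome_variance(m)
  expect_equal(unname(v[1]), 0)
  expect_equal(unname(v[2]), oracle_variance_pop(c(0, 2, 1)))

  two <- rbind(c1 = c(0, 2)); colnames(two) <- c("a", "b")
  expect_equal(unname(transcriptome_variance(two)), 1.0)

  set.seed(7)
  r <- matrix(runif(60), 6, 10,
              dimnames = list(sprintf("c%d", 1:6), sprintf("g%d", 1:10)))
  expect_equal(unname(transcriptome_variance(r)),
               unname(apply(r, 1, oracle_variance_pop)))
})

test_that("pctMT threshold filter drops cells strictly above the cutoff", {
  counts <- rbind(c1 = c(10, 90), c2 = c(15, 85), c3 = c(16, 84))
  colnames(counts) <- c("MT-A", "g1")
  t <- cell_table(counts, tibble::tibble(cell_id = rownames(counts),
                                         patient_id = "P1",
                                         compartment = "malignant"))
  expect_identical(rownames(pctmt_threshold_filter(t, 15)$counts),
                   c("c1", "c2"))
  expect_equal(n_cells(pctmt_threshold_filter(t, 100)), 3)
  t0 <- pctmt_threshold_filter(t, 0)
  expect_equal(n_cells(t0), 0)
})

test_that("QC flags are one-pass and OR-composable", {
  t <- random_cell_table(n_cells = 30, n_genes = 40, lambda = 50)
  rep <- run_qc(t, min_counts = 100, max_counts = 1e5, min_genes = 5)
  manual <- mad_outlier_flags(t) |
    absolute_flags(t, min_counts = 100, max_counts = 1e5, min_genes = 5)
  expect_identical(rep$flags$keep, unname(!manual))
})

test_that("QC never consults mitochondrial identity", {
  t <- random_cell_table(n_cells = 40, n_genes = 30, lambda = 30)
  rep1 <- run_qc(t, min_counts = 20, max_counts = 1e5, min_genes = 3)
  # relabel which genes are "MT": swap gene names around
  t2 <- t
  colnames(t2$counts) <- rev(colnames(t2$counts))
  rep2 <- run_qc(t2, min_counts = 20, max_counts = 1e5, min_genes = 3)
  expect_identical(rep1$flags$keep, rep2$flags$keep)
})

test_that("QC removes planted junk cells on synthetic cohorts", {
  cfg <- synth_config(n_patients = 3, cells_per_patient = 150,
                      n_genes = 600, junk_fraction = 0.1, seed = 11)
  sim <- simulate_cohort(cfg)
  rep <- run_qc(sim$cells)
  junk_ids <- sim$truth$cell_id[sim$truth$is_junk]
  removed <- rep$flags$cell_id[!rep$flags$keep]
  expect_gte(mean(junk_ids %in% removed), 0.9)
})

test_that("doublet flags from metadata are honored", {
  t <- random_cell_table(n_cells = 10, n_genes = 20, lambda = 50)
  t$cell_meta$doublet_flag <- c(TRUE, rep(FALSE, 9))
  rep <- run_qc(t, min_counts = 1, max_counts = 1e6, min_genes = 1)
  expect_true(rep$flags$doublet[1])
  expect_false(rep$flags$keep[1])
})
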