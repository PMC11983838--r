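test_that("pctMT arithmetic and the complement identity hold", {
  counts <- rbind(c1 = c(5, 0, 15), c2 = c(0, 0, 9), c3 = c(4, 4, 0))
  colnames(counts) <- c("MT-A", "MT-B", "g1")
  t <- cell_table(counts, tibble::tibble(cell_id = rownames(counts),
                                         patient_id = "P1",
                                         compartment = "malignant"))
  pct <- compute_pctmt(t)
  expect_equal(unname(pct), c(25, 0, 100))

  non_mt <- 100 * Matrix::rowSums(t$counts[, "g1", drop = FALSE]) /
    Matrix::rowSums(t$counts)
  expect_equal(unname(pct + non_mt), rep(100, 3))

  # explicit list wins over the MT- prefix
  pct_explicit <- compute_pctmt(t, mt_genes = "MT-A")
  expect_equal(unname(pct_explicit), c(25, 0, 50))
  expect_error(compute_pctmt(t, mt_genes = "NOPE"), "No mitochondrial gene")
})

test_that("HighMT classification is strictly greater-than", {
  expect_identical(classify_highmt(c(15, 15.01, 0, 99)),
                   c("LowMT", "HighMT", "LowMT", "HighMT"))
})

test_that("odds ratio matches hand arithmetic, with continuity correction", {
  expect_equal(patient_odds_ratio(30, 70, 10, 90)$or, 27 / 7)
  expect_false(patient_odds_ratio(30, 70, 10, 90)$corrected)
  expect_equal(patient_odds_ratio(10, 90, 10, 90)$or, 1.0)
  fit <- patient_odds_ratio(5, 95, 0, 100)
  expect_equal(fit$or, (5.5 / 95.5) / (0.5 / 100.5))
  expect_true(fit$corrected)
  expect_error(patient_odds_ratio(0, 0, 0, 0), "All-zero")
  expect_error(patient_odds_ratio(-1, 2, 3, 4), "non-negative")
})

test_that("patient summaries reproduce the hand-derived fixture", {
  t <- add_pctmt(make_mini_table())
  expect_equal(t$cell_meta$pctmt, c(20, 5, 2, 40, 50, 16, 0, 10))
  s <- patient_mt_summary(t)
  p1 <- s[s$patient_id == "P1", ]
  expect_equal(unlist(p1[, c("n_highmt_mal", "n_lowmt_mal",
                             "n_highmt_tme", "n_lowmt_tme")],
                      use.names = FALSE), c(1, 1, 1, 1))
  expect_equal(p1$odds_ratio, 1)
  p2 <- s[s$patient_id == "P2", ]
  expect_equal(unlist(p2[, c("n_highmt_mal", "n_lowmt_mal",
                             "n_highmt_tme", "n_lowmt_tme")],
                      use.names = FALSE), c(2, 1, 0, 1))
  expect_equal(p2$odds_ratio, (2.5 / 1.5) / (0.5 / 1.5))
  expect_true(p2$or_corrected)
  expect_equal(p2$highmt_malignant_fraction, 2 / 3)
})

test_that("case/control rules follow the OR and fraction thresholds", {
  s <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    n_highmt_mal = c(20, 10, 5, 40),
    n_lowmt_mal = c(80, 90, 20, 60),
    n_highmt_tme = c(5, 15, 10, 30),
    n_lowmt_tme = c(95, 95, 90, 70),
    odds_ratio = c(3.0, 3.0, 1.5, 3.0),
    or_corrected = FALSE,
    highmt_malignant_fraction = c(0.20, 0.10, 0.20, 0.40)
  )
  ann <- annotate_case_control(s)
  expect_identical(ann$status, c("case", "control", "excluded", "case"))
  # C excluded: 25 malignant cells < 30
  expect_identical(ann$exclusion_reason[3], "malignant<30")

  # exactly at the fraction threshold counts as a case ("at least 15%")
  s$highmt_malignant_fraction[2] <- 0.15
  expect_identical(annotate_case_control(s)$status[2], "case")
  # OR exactly 2 is not a case (strict)
  s$odds_ratio[1] <- 2
  expect_identical(annotate_case_control(s)$status[1], "control")

  # too few HighMT cells overall
  s2 <- s[4, ]
  s2$n_highmt_mal <- 10; s2$n_highmt_tme <- 5
  expect_identical(annotate_case_control(s2)$status, "excluded")
  expect_identical(annotate_case_control(s2)$exclusion_reason, "highmt<20")
})

test_that("case/control is invariant to cell order and non-MT labels", {
  t <- add_pctmt(make_mini_table())
  s1 <- annotate_case_control(patient_mt_summary(t),
                              min_compartment = 1, min_highmt = 1)
  perm <- sample(n_cells(t))
  t2 <- filter_cells(t, rownames(t$counts)[perm])
  s2 <- annotate_case_control(patient_mt_summary(t2),
                              min_compartment = 1, min_highmt = 1)
  expect_identical(dplyr::arrange(s1, patient_id),
                   dplyr::arrange(s2, patient_id))

  # renaming non-MT genes changes nothing
  t3 <- make_mini_table()
  colnames(t3$counts)[3:5] <- c("z9", "z8", "z7")
  s3 <- annotate_case_control(patient_mt_summary(add_pctmt(t3)),
                              min_compartment = 1, min_highmt = 1)
  expect_identical(dplyr::arrange(s1, patient_id),
                   dplyr::arrange(s3, patient_id))
})

test_that("clinical association uses the exact two-sided Mann-Whitney", {
  s <- tibble::tibble(patient_id = sprintf("P%d", 1:4),
                      highmt_malignant_fraction = c(0.1, 0.2, 0.5, 0.6))
  clin <- tibble::tibble(patient_id = sprintf("P%d", 1:4),
                         label = c("early", "early", "late", "late"))
  res <- clinical_association(s, clin)
  expect_equal(res$u_stat, 0)  # all "early" fractions rank below "late"
  expect_equal(res$p_value, 1 / 3)  # exact two-sided p for U=0 at n=2,2

  # identical groups: p = 1
  s2 <- s; s2$highmt_malignant_fraction <- c(0.1, 0.2, 0.1, 0.2)
  res2 <- suppressWarnings(clinical_association(s2, clin))
  expect_equal(res2$p_value, 1)

  # a group with fewer than two patients is skipped with a warning
  clin3 <- clin; clin3$label[4] <- "solo"
  expect_warning(res3 <- clinical_association(s, clin3), "solo")
  expect_equal(nrow(res3), 0)
})

test_that("case rate rises with the planted malignant pctMT shift", {
  shifts <- c(0.05, 0.15, 0.30)
  case_frac <- vapply(seq_along(shifts), function(i) {
    cfg <- synth_config(n_patients = 4, cells_per_patient = 150,
                        n_genes = 400,
                        pctmt_malignant = list(mean = shifts[i], kappa = 10),
                        pctmt_tme = list(mean = 0.05, kappa = 20),
                        junk_fraction = 0, seed = 100 + i)
    sim <- simulate_cohort(cfg)
    t <- add_pctmt(sim$cells)
    s <- annotate_case_control(patient_mt_summary(t))
    mean(s$status == "case")
  }, numeric(1))
  expect_true(all(diff(case_frac) >= 0))
  expect_gt(case_frac[3], case_frac[1])
})
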