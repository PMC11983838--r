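mini_panel <- function(pctmt, ic50, drug = "d1", type = "t1") {
  tibble::tibble(cell_line = sprintf("L%d", seq_along(pctmt)),
                 cancer_type = type, pctmt = pctmt, drug = drug,
                 ic50 = ic50, category = "other")
}

test_that("per-type correlations match Pearson and the Student t formula", {
  res <- per_type_correlations(mini_panel(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(res$r, 1)
  res2 <- per_type_correlations(mini_panel(c(1, 2, 3), c(6, 4, 2)))
  expect_equal(res2$r, -1)

  # t = r * sqrt((n-2)/(1-r^2)) at r = 0.99, n = 10 -> ~19.85
  expect_equal(0.99 * sqrt(8 / (1 - 0.9801)), 19.85, tolerance = 1e-3)
  set.seed(3)
  x <- rnorm(10); y <- 0.99 * x + rnorm(10, sd = 0.01)
  res3 <- per_type_correlations(mini_panel(x, y))
  r <- res3$r
  expect_equal(res3$t_stat, r * sqrt(8 / (1 - r^2)))
  expect_equal(res3$p_value, 2 * pt(-abs(res3$t_stat), df = 8))

  # degenerate pairs are excluded with a reason, not dropped silently
  small <- per_type_correlations(mini_panel(c(1, 2), c(3, 4)))
  expect_identical(small$excluded, "n<3")
  flat <- per_type_correlations(mini_panel(c(2, 2, 2), c(1, 5, 9)))
  expect_identical(flat$excluded, "constant pctMT")
})

test_that("median ranking selects the top and bottom tails", {
  cors <- tibble::tibble(
    drug = rep(sprintf("d%02d", 1:20), each = 3),
    cancer_type = rep(c("a", "b", "c"), 20),
    n = 10, r = rep(seq(-0.9, 0.9, length.out = 20), each = 3) +
      rep(c(-0.05, 0, 0.05), 20),
    t_stat = 1, p_value = 0.5, excluded = NA_character_
  )
  rk <- rank_by_median(cors, k = 5)
  expect_equal(rk$medians$median_r[rk$medians$drug == "d01"],
               seq(-0.9, 0.9, length.out = 20)[1])
  expect_identical(sort(rk$top$drug), sprintf("d%02d", 16:20))
  expect_identical(sort(rk$bottom$drug), sprintf("d%02d", 1:5))
  expect_length(intersect(rk$top$drug, rk$bottom$drug), 0)

  # equal medians at the cutoff: lexicographic selection, tie flagged
  cors2 <- tibble::tibble(drug = c("aaa", "abb", "zzz"), cancer_type = "t",
                          n = 10, r = c(0.5, 0.5, 0.9), t_stat = 1,
                          p_value = 0.5, excluded = NA_character_)
  rk2 <- rank_by_median(cors2, k = 2)
  expect_identical(sort(rk2$top$drug), c("aaa", "zzz"))
  expect_true(rk2$top$tie[rk2$top$drug == "aaa"])
})

test_that("category enrichment builds the 2x2 and sample odds ratio", {
  all_drugs <- tibble::tibble(
    drug = sprintf("d%03d", 1:100),
    category = c(rep("met", 5), rep("other", 10), rep("met", 10),
                 rep("other", 75))
  )
  selected <- sprintf("d%03d", 1:15)  # 5 in "met", 10 out
  res <- category_enrichment(selected, all_drugs)
  met <- res[res$category == "met", ]
  expect_equal(unlist(met[, c("n_selected_in", "n_selected_out",
                              "n_other_in", "n_other_out")],
                      use.names = FALSE), c(5, 10, 10, 75))
  expect_equal(met$odds_ratio, 3.75)
  expect_equal(met$p_value,
               fisher.test(matrix(c(5, 10, 10, 75), 2, byrow = TRUE))$p.value)

  # selecting every drug makes every category OR 1
  res_all <- category_enrichment(all_drugs$drug, all_drugs)
  expect_true(all(is.na(res_all$odds_ratio) | res_all$odds_ratio == 1))

  # a category absent from the data frame of selected and unselected drugs
  ad2 <- dplyr::bind_rows(all_drugs,
                          tibble::tibble(drug = "dx", category = "ghost"))
  res2 <- category_enrichment(selected, ad2)
  expect_true("ghost" %in% res2$category)
})

test_that("permutation calibration honors the +1 rule and B = 1 edge", {
  cfg <- synth_config(seed = 2)
  cfg$drug_params$n_types <- 2
  cfg$drug_params$lines_per_type <- 10
  cfg$drug_params$drugs <- cfg$drug_params$drugs[1:6, ]
  tab <- simulate_cell_lines(cfg)
  cal <- permutation_calibration(tab, B = 1, seed = 1)
  expect_true(all(cal$p_upper %in% c(0.5, 1)))
  expect_true(all(cal$p_lower %in% c(0.5, 1)))
  cal2 <- permutation_calibration(tab, B = 19, seed = 5)
  expect_gte(min(cal2$p_upper), 1 / 20)
  # determinism
  cal3 <- permutation_calibration(tab, B = 19, seed = 5)
  expect_identical(cal2$null_quantiles, cal3$null_quantiles)
})

test_that("median-r null is symmetric under sign flips on exchangeable data", {
  cfg <- synth_config(seed = 6)
  cfg$drug_params$n_types <- 2
  cfg$drug_params$lines_per_type <- 12
  tab <- simulate_cell_lines(cfg)
  med <- rank_by_median(per_type_correlations(tab))$medians
  flipped <- tab
  flipped$ic50 <- -flipped$ic50
  med_f <- rank_by_median(per_type_correlations(flipped))$medians
  expect_equal(med$median_r, -med_f$median_r)
})

test_that("a planted strong correlation is recovered and ranked on top", {
  cfg <- synth_config(seed = 8)
  cfg$drug_params$n_types <- 1
  cfg$drug_params$lines_per_type <- 200
  cfg$drug_params$drugs$true_r[7] <- 0.6
  tab <- simulate_cell_lines(cfg)
  cors <- per_type_correlations(tab)
  planted <- cors$r[cors$drug == "drug07"]
  expect_lt(abs(planted - 0.6), 0.1)
  rk <- rank_by_median(cors, k = 15)
  expect_true("drug07" %in% rk$top$drug)
})
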