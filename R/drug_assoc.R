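#' Per-(drug, cancer type) correlation between pctMT and IC50
#'
#' For every drug within every cancer type, computes Pearson's correlation
#' between cell-line pctMT and IC50, with significance from Student's t:
#' `t = r * sqrt((n - 2) / (1 - r^2))`, two-sided p on n - 2 degrees of
#' freedom. Pairs with fewer than 3 cell lines or a constant variable are
#' retained in the output with an `excluded` reason instead of statistics.
#'
#' @param table Tibble with columns `cell_line`, `cancer_type`, `pctmt`,
#'   `drug`, `ic50` (and optionally `category`).
#' @param log_ic50 Log-transform IC50 before correlating (default FALSE; the
#'   measurement is used on the scale provided).
#' @return Tibble with `drug`, `cancer_type`, `n`, `r`, `t_stat`, `p_value`,
#'   `excluded` (NA when the pair was analyzed).
#' @export
per_type_correlations <- function(table, log_ic50 = FALSE) {
  if (log_ic50) table$ic50 <- log(table$ic50)
  table |>
    dplyr::group_by(drug = .data$drug, cancer_type = .data$cancer_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      sd_x = stats::sd(.data$pctmt), sd_y = stats::sd(.data$ic50),
      r = if (dplyr::n() >= 3 && stats::sd(.data$pctmt) > 0 &&
              stats::sd(.data$ic50) > 0)
        stats::cor(.data$pctmt, .data$ic50) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      excluded = dplyr::case_when(
        .data$n < 3 ~ "n<3",
        .data$sd_x == 0 ~ "constant pctMT",
        .data$sd_y == 0 ~ "constant IC50",
        TRUE ~ NA_character_
      ),
      t_stat = .data$r * sqrt((.data$n - 2) / (1 - .data$r^2)),
      p_value = 2 * stats::pt(-abs(.data$t_stat), df = .data$n - 2)
    ) |>
    dplyr::select("drug", "cancer_type", "n", "r", "t_stat", "p_value",
                  "excluded")
}

#' Rank drugs by their median correlation across cancer types
#'
#' The per-drug median of valid per-type correlations identifies the `k`
#' drugs most associated with resistance (highest medians: IC50 rises with
#' pctMT) and with sensitivity (lowest medians). Ties at the cutoffs are
#' broken lexicographically by drug name and flagged.
#'
#' @param cors Output of [per_type_correlations()].
#' @param k Number of drugs per tail (default 15).
#' @return List with `medians` (tibble `drug`, `median_r`, `n_types`, `tie`),
#'   `top` and `bottom` (tibbles of the selected drugs).
#' @export
rank_by_median <- function(cors, k = 15) {
  med <- cors |>
    dplyr::filter(is.na(.data$excluded)) |>
    dplyr::group_by(drug = .data$drug) |>
    dplyr::summarise(median_r = stats::median(.data$r),
                     n_types = dplyr::n(), .groups = "drop")
  if (nrow(med) == 0) stop("No drug has a valid correlation.", call. = FALSE)
  k <- min(k, nrow(med))
  top <- med |>
    dplyr::arrange(dplyr::desc(.data$median_r), .data$drug) |>
    utils::head(k)
  bottom <- med |>
    dplyr::arrange(.data$median_r, .data$drug) |>
    utils::head(k) |>
    dplyr::filter(!.data$drug %in% top$drug)
  # flag ties straddling either cutoff
  top$tie <- top$median_r == min(top$median_r) &
    sum(med$median_r == min(top$median_r)) >
    sum(top$median_r == min(top$median_r))
  bottom$tie <- if (nrow(bottom) > 0) {
    bottom$median_r == max(bottom$median_r) &
      sum(med$median_r == max(bottom$median_r)) >
      sum(bottom$median_r == max(bottom$median_r))
  } else logical(0)
  list(medians = med, top = top, bottom = bottom)
}

#' Drug-target category enrichment among selected drugs
#'
#' For each target category, builds the 2x2 table of selected/unselected by
#' in-category/out-of-category and reports the sample (cross-product) odds
#' ratio together with the two-sided Fisher exact p-value. Drugs without a
#' category are pooled as `"other"`.
#'
#' @param selected Character vector of selected drug names (e.g. a top-15).
#' @param all_drugs Tibble with columns `drug` and `category`, one row per
#'   drug, covering every tested drug.
#' @return Tibble per category: the four cell counts, `odds_ratio` (NA when
#'   undefined), `p_value`.
#' @export
category_enrichment <- function(selected, all_drugs) {
  all_drugs <- dplyr::distinct(all_drugs, .data$drug, .keep_all = TRUE)
  all_drugs$category <- dplyr::coalesce(as.character(all_drugs$category),
                                        "other")
  unknown <- setdiff(selected, all_drugs$drug)
  if (length(unknown) > 0) {
    stop("Selected drug(s) not in `all_drugs`: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  is_sel <- all_drugs$drug %in% selected
  purrr::map_dfr(sort(unique(all_drugs$category)), function(cat) {
    in_cat <- all_drugs$category == cat
    a <- sum(is_sel & in_cat); b <- sum(is_sel & !in_cat)
    c <- sum(!is_sel & in_cat); d <- sum(!is_sel & !in_cat)
    or <- if (b == 0 || c == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else (a * d) / (b * c)
    p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                            alternative = "two.sided")$p.value
    tibble::tibble(category = cat, n_selected_in = a, n_selected_out = b,
                   n_other_in = c, n_other_out = d,
                   odds_ratio = or, p_value = p)
  })
}

#' Permutation calibration of the pctMT-IC50 correlation distribution
#'
#' Tests whether the tails of the per-drug median-correlation distribution
#' diverge from what label permutation produces. `B` times, pctMT values are
#' permuted across cell lines within each cancer type (preserving type
#' composition), per-drug median correlations recomputed, and the chosen
#' tail quantiles recorded. Empirical one-sided p-values carry the +1
#' finite-sample correction: upper tail
#' `(1 + #\{null >= observed\}) / (B + 1)`, lower tail with `<=`.
#'
#' @param table Drug-response tibble as in [per_type_correlations()].
#' @param B Number of permutations (default 1000).
#' @param tail_probs Quantiles of the median-r distribution to compare
#'   (default `c(0.05, 0.95)`).
#' @param seed Integer seed.
#' @return Object of class `highmt_drug_calibration`: observed quantiles,
#'   null quantile matrices, `p_lower`, `p_upper`, `B`, `seed`.
#' @export
permutation_calibration <- function(table, B = 1000,
                                    tail_probs = c(0.05, 0.95), seed = 0) {
  if (B < 1) stop("B must be >= 1.", call. = FALSE)
  line_tab <- dplyr::distinct(table, .data$cell_line, .data$cancer_type,
                              .data$pctmt)
  if (max(table(line_tab$cancer_type)) < 3) {
    stop("Too few cell lines per cancer type to permute (need >= 3).",
         call. = FALSE)
  }
  observed_med <- rank_by_median(per_type_correlations(table))$medians
  obs_q <- stats::quantile(observed_med$median_r, tail_probs, names = FALSE)
  null_q <- withr::with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      perm <- line_tab |>
        dplyr::group_by(.data$cancer_type) |>
        dplyr::mutate(pctmt = sample(.data$pctmt)) |>
        dplyr::ungroup()
      ptab <- table |>
        dplyr::select(-"pctmt") |>
        dplyr::left_join(perm, by = c("cell_line", "cancer_type"))
      med <- rank_by_median(per_type_correlations(ptab))$medians
      stats::quantile(med$median_r, tail_probs, names = FALSE)
    }, numeric(length(tail_probs))))
  })
  p_upper <- (1 + colSums(null_q >= rep(obs_q, each = B))) / (B + 1)
  p_lower <- (1 + colSums(null_q <= rep(obs_q, each = B))) / (B + 1)
  structure(list(tail_probs = tail_probs, observed = obs_q,
                 null_quantiles = null_q,
                 p_lower = p_lower, p_upper = p_upper, B = B, seed = seed),
            class = "highmt_drug_calibration")
}

#' @export
print.highmt_drug_calibration <- function(x, ...) {
  cat("<highmt_drug_calibration> B =", x$B, "\n")
  for (i in seq_along(x$tail_probs)) {
    cat(sprintf("  q%.2f: observed %.3f, p_lower %.4f, p_upper %.4f\n",
                x$tail_probs[i], x$observed[i], x$p_lower[i], x$p_upper[i]))
  }
  invisible(x)
}

#' @export
tidy.highmt_drug_calibration <- function(x, ...) {
  tibble::tibble(tail_prob = x$tail_probs, observed = x$observed,
                 p_lower = x$p_lower, p_upper = x$p_upper, B = x$B)
}

#' Full drug-association analysis
#'
#' Chains [per_type_correlations()], [rank_by_median()],
#' [category_enrichment()] for both tails, and [permutation_calibration()].
#'
#' @inheritParams per_type_correlations
#' @param k Tail size for the rankings (default 15).
#' @param B Permutations for calibration (default 1000).
#' @param seed Integer seed.
#' @return List of class `highmt_drug_assoc` with elements `correlations`,
#'   `rankings`, `enrichment_top`, `enrichment_bottom`, `calibration`.
#' @export
drug_association <- function(table, k = 15, B = 1000, log_ic50 = FALSE,
                             seed = 0) {
  cors <- per_type_correlations(table, log_ic50 = log_ic50)
  rankings <- rank_by_median(cors, k = k)
  cats <- if ("category" %in% names(table)) {
    dplyr::distinct(table, .data$drug, .data$category)
  } else {
    tibble::tibble(drug = unique(table$drug), category = "other")
  }
  structure(list(
    correlations = cors,
    rankings = rankings,
    enrichment_top = category_enrichment(rankings$top$drug, cats),
    enrichment_bottom = category_enrichment(rankings$bottom$drug, cats),
    calibration = permutation_calibration(table, B = B, seed = seed)
  ), class = "highmt_drug_assoc")
}

#' @export
print.highmt_drug_assoc <- function(x, ...) {
  cat("<highmt_drug_assoc> ", dplyr::n_distinct(x$correlations$drug),
      " drugs, ", dplyr::n_distinct(x$correlations$cancer_type),
      " cancer types\n", sep = "")
  cat("Top resistance-associated drugs:\n")
  print(utils::head(x$rankings$top, 5))
  invisible(x)
}

#' @export
glance.highmt_drug_assoc <- function(x, ...) {
  tibble::tibble(
    n_drugs = dplyr::n_distinct(x$correlations$drug),
    n_types = dplyr::n_distinct(x$correlations$cancer_type),
    n_excluded_pairs = sum(!is.na(x$correlations$excluded)),
    top_median_r = max(x$rankings$medians$median_r),
    bottom_median_r = min(x$rankings$medians$median_r),
    calib_p_upper = x$calibration$p_upper[length(x$calibration$p_upper)],
    calib_p_lower = x$calibration$p_lower[1]
  )
}
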