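#' Resolve the mitochondrial gene designation
#'
#' MT genes are designated either by an explicit gene list (a [gene_set()] or
#' character vector), or — when `mt_genes` is `NULL` — by the conventional
#' `"MT-"` prefix on gene identifiers. An explicit list always wins. Matching
#' is exact and case-sensitive; datasets differ in whether tRNA/rRNA MT genes
#' are present, so the explicit-list route lets users control exactly which
#' genes count.
#'
#' @param t A `cell_table`.
#' @param mt_genes `NULL`, a character vector, or a `gene_set`.
#' @return Character vector of MT gene ids detected in the table.
#' @export
detect_mt_genes <- function(t, mt_genes = NULL) {
  gene_ids <- colnames(t$counts)
  wanted <- if (is.null(mt_genes)) {
    gene_ids[startsWith(gene_ids, "MT-")]
  } else {
    intersect(as_gene_vector(mt_genes), gene_ids)
  }
  if (length(wanted) == 0) {
    stop("No mitochondrial gene detected in the data.", call. = FALSE)
  }
  wanted
}

#' Percentage of counts in mitochondrial genes, per cell
#'
#' `100 * sum(counts over detected MT genes) / total counts`, reported on the
#' 0-100 (percent) scale used throughout.
#'
#' @inheritParams detect_mt_genes
#' @return Numeric vector in \[0, 100\], one value per cell.
#' @export
compute_pctmt <- function(t, mt_genes = NULL) {
  mt <- detect_mt_genes(t, mt_genes)
  totals <- Matrix::rowSums(t$counts)
  if (any(totals == 0)) {
    stop("Cell(s) with zero total counts; run QC first.", call. = FALSE)
  }
  mt_counts <- Matrix::rowSums(t$counts[, mt, drop = FALSE])
  stats::setNames(100 * as.numeric(mt_counts / totals), rownames(t$counts))
}

#' Classify cells as HighMT or LowMT
#'
#' HighMT iff pctMT is strictly greater than `threshold` percent; a cell at
#' exactly the threshold is LowMT.
#'
#' @param pctmt Numeric vector of pctMT values (percent).
#' @param threshold Percent cutoff (default 15).
#' @return Character vector of `"HighMT"` / `"LowMT"`.
#' @export
classify_highmt <- function(pctmt, threshold = 15) {
  ifelse(pctmt > threshold, "HighMT", "LowMT")
}

#' Append pctMT and HighMT status to a cell table
#'
#' @inheritParams compute_pctmt
#' @param threshold HighMT cutoff in percent (default 15).
#' @return The `cell_table` with `pctmt` (numeric) and `highmt` (logical)
#'   metadata columns.
#' @export
add_pctmt <- function(t, mt_genes = NULL, threshold = 15) {
  t$cell_meta$pctmt <- unname(compute_pctmt(t, mt_genes))
  t$cell_meta$highmt <- t$cell_meta$pctmt > threshold
  t
}

#' Odds ratio of HighMT status between malignant and TME compartments
#'
#' `OR = (n_highmt_mal / n_lowmt_mal) / (n_highmt_tme / n_lowmt_tme)`.
#' If any of the four counts is zero, 0.5 is added to all four
#' (Haldane-Anscombe continuity correction) and `corrected` is set.
#'
#' @param n_highmt_mal,n_lowmt_mal,n_highmt_tme,n_lowmt_tme Non-negative
#'   counts of the 2x2 table.
#' @return List with `or` (numeric) and `corrected` (logical).
#' @export
patient_odds_ratio <- function(n_highmt_mal, n_lowmt_mal,
                               n_highmt_tme, n_lowmt_tme) {
  counts <- c(n_highmt_mal, n_lowmt_mal, n_highmt_tme, n_lowmt_tme)
  if (any(counts < 0)) stop("Counts must be non-negative.", call. = FALSE)
  if (all(counts == 0)) stop("All-zero 2x2 table.", call. = FALSE)
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  list(or = (counts[1] / counts[2]) / (counts[3] / counts[4]),
       corrected = corrected)
}

#' Per-patient HighMT contingency summary
#'
#' Builds, for every patient, the 2x2 table of HighMT/LowMT by
#' malignant/TME, the odds ratio, and the fraction of HighMT cells in the
#' malignant compartment.
#'
#' @param t A `cell_table` whose metadata carries `pctmt` and `highmt`
#'   columns (see [add_pctmt()]).
#' @return Tibble with one row per patient: the four counts
#'   (`n_highmt_mal`, `n_lowmt_mal`, `n_highmt_tme`, `n_lowmt_tme`),
#'   `odds_ratio`, `or_corrected`, `highmt_malignant_fraction`.
#' @export
patient_mt_summary <- function(t) {
  if (!all(c("pctmt", "highmt") %in% names(t$cell_meta))) {
    stop("Run add_pctmt() first.", call. = FALSE)
  }
  t$cell_meta |>
    dplyr::group_by(patient_id = .data$patient_id) |>
    dplyr::summarise(
      n_highmt_mal = sum(.data$highmt & .data$compartment == "malignant"),
      n_lowmt_mal = sum(!.data$highmt & .data$compartment == "malignant"),
      n_highmt_tme = sum(.data$highmt & .data$compartment == "TME"),
      n_lowmt_tme = sum(!.data$highmt & .data$compartment == "TME"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      or_fit = purrr::pmap(list(.data$n_highmt_mal, .data$n_lowmt_mal,
                                .data$n_highmt_tme, .data$n_lowmt_tme),
                           patient_odds_ratio),
      odds_ratio = purrr::map_dbl(.data$or_fit, "or"),
      or_corrected = purrr::map_lgl(.data$or_fit, "corrected"),
      highmt_malignant_fraction =
        .data$n_highmt_mal / (.data$n_highmt_mal + .data$n_lowmt_mal)
    ) |>
    dplyr::select(-"or_fit")
}

#' Case/control annotation of patients by HighMT enrichment
#'
#' A patient is excluded when either compartment holds fewer than
#' `min_compartment` cells or the patient has fewer than `min_highmt` HighMT
#' cells in total. Otherwise the patient is a case iff the odds ratio is
#' strictly above `or_threshold` and the HighMT fraction in the malignant
#' compartment is at least `frac_threshold`; all remaining patients are
#' controls.
#'
#' @param summaries Output of [patient_mt_summary()].
#' @param or_threshold Odds-ratio cutoff (default 2, strict).
#' @param frac_threshold Malignant HighMT-fraction cutoff (default 0.15,
#'   inclusive: "at least 15%").
#' @param min_compartment Minimum cells per compartment (default 30).
#' @param min_highmt Minimum HighMT cells overall (default 20).
#' @return The input tibble with `status` (`"case"`, `"control"`,
#'   `"excluded"`) and `exclusion_reason` columns.
#' @export
annotate_case_control <- function(summaries, or_threshold = 2,
                                  frac_threshold = 0.15,
                                  min_compartment = 30, min_highmt = 20) {
  n_mal <- summaries$n_highmt_mal + summaries$n_lowmt_mal
  n_tme <- summaries$n_highmt_tme + summaries$n_lowmt_tme
  n_highmt <- summaries$n_highmt_mal + summaries$n_highmt_tme
  reason <- dplyr::case_when(
    n_mal < min_compartment ~ sprintf("malignant<%d", min_compartment),
    n_tme < min_compartment ~ sprintf("TME<%d", min_compartment),
    n_highmt < min_highmt ~ sprintf("highmt<%d", min_highmt),
    TRUE ~ NA_character_
  )
  status <- ifelse(
    !is.na(reason), "excluded",
    ifelse(summaries$odds_ratio > or_threshold &
             summaries$highmt_malignant_fraction >= frac_threshold,
           "case", "control")
  )
  summaries |>
    dplyr::mutate(status = status, exclusion_reason = reason)
}

#' Association between per-patient HighMT fraction and a clinical label
#'
#' For every pair of clinical groups, compares the per-patient fraction of
#' HighMT cells in the malignant compartment with a two-sided Mann-Whitney U
#' test. Groups with fewer than 2 patients are skipped with a warning.
#'
#' @param summaries Output of [patient_mt_summary()] (possibly annotated).
#' @param clinical Data frame with columns `patient_id` and `label`.
#' @return Tibble with one row per group pair: group names, sizes, the
#'   Mann-Whitney U statistic (for the first group) and two-sided p-value.
#' @export
clinical_association <- function(summaries, clinical) {
  dat <- dplyr::inner_join(summaries, clinical, by = "patient_id")
  groups <- split(dat$highmt_malignant_fraction, dat$label)
  ok <- vapply(groups, function(g) length(g) >= 2, logical(1))
  if (any(!ok)) {
    warning("Skipping group(s) with <2 patients: ",
            paste(names(groups)[!ok], collapse = ", "), call. = FALSE)
    groups <- groups[ok]
  }
  if (length(groups) < 2) {
    return(tibble::tibble(group1 = character(), group2 = character(),
                          n1 = integer(), n2 = integer(),
                          u_stat = numeric(), p_value = numeric()))
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    g1 <- groups[[pr[1]]]; g2 <- groups[[pr[2]]]
    wt <- stats::wilcox.test(g1, g2, alternative = "two.sided", exact = TRUE)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   n1 = length(g1), n2 = length(g2),
                   u_stat = unname(wt$statistic), p_value = wt$p.value)
  })
}
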