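#' Median score difference between HighMT and LowMT observations
#'
#' `median(score | HighMT) - median(score | LowMT)`. Returns `NA` with a
#' warning when either group is empty.
#'
#' @param score Numeric vector of pathway scores (one per metacell).
#' @param highmt Logical vector: HighMT status of each observation.
#' @return Scalar delta, or `NA_real_`.
#' @export
pathway_delta <- function(score, highmt) {
  stopifnot(length(score) == length(highmt))
  if (!any(highmt) || all(highmt)) {
    warning("One of the HighMT/LowMT groups is empty; delta undefined.",
            call. = FALSE)
    return(NA_real_)
  }
  stats::median(score[highmt]) - stats::median(score[!highmt])
}

#' Pathway dysregulation matrix across studies
#'
#' Scores each pathway on each study's malignant metacells (bin-controlled
#' scoring, per-study binning) and records the HighMT-minus-LowMT median
#' score difference. The result characterizes each pathway by its
#' dysregulation vector across studies.
#'
#' @param metacell_sets Named list of studies; each element a list with
#'   `norm` (normalized metacell matrix) and `meta` (metacell meta tibble with
#'   `highmt_label` and `malignant_label`, see [label_metacells()]).
#' @param pathways Named list of [gene_set()] objects (e.g. from
#'   [read_gmt()]).
#' @param malignant_only Restrict to malignant metacells (default TRUE).
#' @param n_bins,ctrl_size,seed Scoring parameters, see [score_signature()].
#' @return Tibble with columns `pathway`, `study`, `delta`; rows ordered by
#'   each pathway's median delta across studies, descending.
#' @export
pathway_delta_matrix <- function(metacell_sets, pathways,
                                 malignant_only = TRUE,
                                 n_bins = 25, ctrl_size = 50, seed = 0) {
  out <- purrr::imap_dfr(metacell_sets, function(st, study) {
    norm <- st$norm
    meta <- st$meta
    keep <- if (malignant_only) meta$malignant_label else rep(TRUE, nrow(meta))
    norm <- norm[meta$metacell_id[keep], , drop = FALSE]
    highmt <- meta$highmt_label[keep]
    purrr::imap_dfr(pathways, function(pw, pname) {
      present <- length(intersect(as_gene_vector(pw), colnames(norm))) > 0
      delta <- if (!present || !any(highmt) || all(highmt)) NA_real_ else {
        sc <- score_signature(norm, pw, n_bins = n_bins,
                              ctrl_size = ctrl_size, seed = seed)
        suppressWarnings(pathway_delta(sc$score, highmt))
      }
      tibble::tibble(pathway = pname, study = study, delta = delta)
    })
  })
  ord <- out |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(med = stats::median(.data$delta, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$med))
  out |>
    dplyr::mutate(pathway = factor(.data$pathway, levels = ord$pathway)) |>
    dplyr::arrange(.data$pathway, .data$study) |>
    dplyr::mutate(pathway = as.character(.data$pathway))
}

#' Hierarchically cluster pathway dysregulation vectors
#'
#' Ward linkage on Euclidean distances between pathway rows of the delta
#' matrix. Pathways with missing deltas in any study are dropped (with a
#' message) before clustering.
#'
#' @param deltas Long tibble from [pathway_delta_matrix()] (columns
#'   `pathway`, `study`, `delta`), or a numeric matrix with pathways in rows.
#' @return An [stats::hclust] tree (`ward.D2` on Euclidean distances).
#' @export
cluster_pathways <- function(deltas) {
  if (!is.matrix(deltas)) {
    wide <- tidyr::pivot_wider(deltas, id_cols = "pathway",
                               names_from = "study", values_from = "delta")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$pathway
    deltas <- m
  }
  complete <- stats::complete.cases(deltas)
  if (any(!complete)) {
    message("Dropping ", sum(!complete), " pathway(s) with missing deltas.")
    deltas <- deltas[complete, , drop = FALSE]
  }
  if (nrow(deltas) < 2) {
    stop("Need at least two complete pathway rows to cluster.", call. = FALSE)
  }
  stats::hclust(stats::dist(deltas, method = "euclidean"), method = "ward.D2")
}

#' Compare xenobiotic-metabolism phases between HighMT and LowMT metacells
#'
#' Scores each phase gene set (phase I oxidation / CYP, phase II conjugation /
#' UGT-GST, phase III efflux / ABC transporters) on each study's malignant
#' metacells and compares HighMT vs LowMT scores with a two-sided
#' Mann-Whitney U test.
#'
#' @inheritParams pathway_delta_matrix
#' @param phase_sets Named list of phase [gene_set()]s (typically three).
#' @return Tibble with one row per (study, phase): group sizes, median
#'   scores, delta, U statistic and p-value. Phases with no genes in a study,
#'   or studies with an empty HighMT/LowMT group, are skipped with a warning.
#' @export
xenobiotic_phase_comparison <- function(metacell_sets, phase_sets,
                                        malignant_only = TRUE,
                                        n_bins = 25, ctrl_size = 50,
                                        seed = 0) {
  purrr::imap_dfr(metacell_sets, function(st, study) {
    meta <- st$meta
    keep <- if (malignant_only) meta$malignant_label else rep(TRUE, nrow(meta))
    norm <- st$norm[meta$metacell_id[keep], , drop = FALSE]
    highmt <- meta$highmt_label[keep]
    purrr::imap_dfr(phase_sets, function(pw, phase) {
      if (length(intersect(as_gene_vector(pw), colnames(norm))) == 0) {
        warning("Phase '", phase, "' has no genes in study '", study,
                "'; skipped.", call. = FALSE)
        return(NULL)
      }
      if (!any(highmt) || all(highmt)) {
        warning("Study '", study, "' lacks a HighMT or LowMT group; skipped.",
                call. = FALSE)
        return(NULL)
      }
      sc <- score_signature(norm, pw, n_bins = n_bins, ctrl_size = ctrl_size,
                            seed = seed)$score
      wt <- suppressWarnings(
        stats::wilcox.test(sc[highmt], sc[!highmt], exact = FALSE))
      tibble::tibble(
        study = study, phase = phase,
        n_highmt = sum(highmt), n_lowmt = sum(!highmt),
        median_highmt = stats::median(sc[highmt]),
        median_lowmt = stats::median(sc[!highmt]),
        delta = stats::median(sc[highmt]) - stats::median(sc[!highmt]),
        u_stat = unname(wt$statistic), p_value = wt$p.value
      )
    })
  })
}
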