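#' Per-cell quality metrics
#'
#' Computes the three metrics the mitochondria-agnostic QC operates on:
#' total counts, number of genes detected, and the fraction of counts falling
#' in the cell's top-k most expressed genes.
#'
#' @param t A `cell_table`.
#' @param k Number of top genes for the concentration metric.
#' @return Tibble with columns `cell_id`, `patient_id`, `total_counts`,
#'   `n_genes`, `top_k_frac`.
#' @export
cell_qc_metrics <- function(t, k = 50) {
  tibble::tibble(
    cell_id = rownames(t$counts),
    patient_id = t$cell_meta$patient_id,
    total_counts = Matrix::rowSums(t$counts),
    n_genes = Matrix::rowSums(t$counts > 0),
    top_k_frac = top_k_fraction(t, k = k)
  )
}

#' Fraction of counts in the top-k genes of each cell
#'
#' The sum of a cell's `k` largest gene counts divided by its total. Cells
#' expressing `k` or fewer genes score 1 by construction (if total > 0).
#'
#' @param t A `cell_table` or count matrix (cells x genes).
#' @param k Number of top genes (default 50).
#' @return Numeric vector in \[0, 1\], one value per cell.
#' @export
top_k_fraction <- function(t, k = 50) {
  counts <- if (inherits(t, "cell_table")) t$counts else as_sparse(t)
  totals <- Matrix::rowSums(counts)
  # work on the transpose so each cell's nonzeros are contiguous in @p slices
  tc <- Matrix::t(counts)
  p <- tc@p
  x <- tc@x
  n <- ncol(tc)
  top <- numeric(n)
  for (i in seq_len(n)) {
    vals <- x[seq.int(p[i] + 1L, length.out = p[i + 1L] - p[i])]
    if (length(vals) <= k) {
      top[i] <- sum(vals)
    } else {
      top[i] <- sum(sort(vals, decreasing = TRUE)[seq_len(k)])
    }
  }
  out <- ifelse(totals > 0, top / totals, NA_real_)
  stats::setNames(out, colnames(tc))
}

#' Median-absolute-deviation outlier flags, per patient
#'
#' Within each patient, a cell is flagged when any of three metrics deviates
#' from the patient median by more than `n_mads` raw (unscaled) median
#' absolute deviations: log1p total counts, log1p genes detected, or the
#' top-50-gene count fraction. Mitochondrial gene identity is never consulted.
#'
#' @param t A `cell_table`.
#' @param n_mads Number of MADs (default 5).
#' @return Logical vector, one flag per cell (`TRUE` = outlier).
#' @export
mad_outlier_flags <- function(t, n_mads = 5) {
  qm <- cell_qc_metrics(t)
  metrics <- cbind(log1p(qm$total_counts), log1p(qm$n_genes), qm$top_k_frac)
  flags <- logical(nrow(qm))
  for (pat in unique(qm$patient_id)) {
    idx <- which(qm$patient_id == pat)
    if (length(idx) < 2) {
      warning("Patient '", pat, "' has a single cell; MAD flags skipped.",
              call. = FALSE)
      next
    }
    for (j in 1:3) {
      m <- metrics[idx, j]
      med <- stats::median(m)
      mad_raw <- stats::median(abs(m - med))
      flags[idx] <- flags[idx] | (abs(m - med) > n_mads * mad_raw)
    }
  }
  stats::setNames(flags, qm$cell_id)
}

#' Absolute-threshold QC flags
#'
#' Flags cells with fewer than `min_counts` total counts, more than
#' `max_counts` total counts, or fewer than `min_genes` genes detected.
#' All comparisons are strict, so a cell sitting exactly on a bound passes.
#'
#' @param t A `cell_table`.
#' @param min_counts,max_counts,min_genes Thresholds (defaults 1500, 50000,
#'   500).
#' @return Logical vector, one flag per cell (`TRUE` = fails QC).
#' @export
absolute_flags <- function(t, min_counts = 1500, max_counts = 50000,
                           min_genes = 500) {
  totals <- Matrix::rowSums(t$counts)
  ngene <- Matrix::rowSums(t$counts > 0)
  flags <- totals < min_counts | totals > max_counts | ngene < min_genes
  stats::setNames(as.logical(flags), rownames(t$counts))
}

#' Per-cell transcriptome variance
#'
#' Population variance (denominator n) of each cell's normalized expression
#' vector across genes, a droplet-integrity metric.
#'
#' @param n Normalized cells-by-genes matrix (see [normalize_cp10k_log1p()]).
#' @return Numeric vector, one variance per cell.
#' @export
transcriptome_variance <- function(n) {
  n <- as_sparse(n)
  g <- ncol(n)
  mu <- Matrix::rowSums(n) / g
  sumsq <- Matrix::rowSums(n^2)
  stats::setNames(sumsq / g - mu^2, rownames(n))
}

#' Threshold filter on mitochondrial content (comparison mode only)
#'
#' Removes cells whose pctMT is strictly above `threshold` percent. This is
#' the traditional filter the package otherwise avoids; it exists so filtering
#' strategies can be compared.
#'
#' @param t A `cell_table`. If `pctmt` is not yet a metadata column it is
#'   computed via [compute_pctmt()] with `mt_genes`.
#' @param threshold Percent cutoff (default 15).
#' @param mt_genes Mitochondrial gene designation, see [compute_pctmt()].
#' @return Filtered `cell_table`.
#' @export
pctmt_threshold_filter <- function(t, threshold = 15, mt_genes = NULL) {
  if (!"pctmt" %in% names(t$cell_meta)) {
    t$cell_meta$pctmt <- compute_pctmt(t, mt_genes)
  }
  filter_cells(t, t$cell_meta$pctmt <= threshold)
}

#' Run mitochondria-agnostic quality control
#'
#' Combines [mad_outlier_flags()], [absolute_flags()] and (optionally) an
#' input doublet flag into a single keep/remove decision. All flags are
#' computed in one pass on the input table — there is no iterative
#' re-estimation — so flags commute and the removal set equals the OR of the
#' individual flag sets. pctMT is never used.
#'
#' @param t A `cell_table`.
#' @param n_mads MAD multiplier (default 5).
#' @param min_counts,max_counts,min_genes Absolute thresholds.
#' @param use_doublet_flag Honor a logical `doublet_flag` metadata column if
#'   present (default TRUE).
#' @return A list of class `qc_report`: `flags` (tibble of per-cell flags and
#'   `keep`), `filtered` (the retained `cell_table`), `thresholds` (named
#'   list), and `patient_summary` (kept/removed per patient).
#' @export
run_qc <- function(t, n_mads = 5, min_counts = 1500, max_counts = 50000,
                   min_genes = 500, use_doublet_flag = TRUE) {
  mad_f <- mad_outlier_flags(t, n_mads = n_mads)
  totals <- unname(Matrix::rowSums(t$counts))
  ngene <- unname(Matrix::rowSums(t$counts > 0))
  doublet <- if (use_doublet_flag && "doublet_flag" %in% names(t$cell_meta)) {
    isTRUE_v(t$cell_meta$doublet_flag)
  } else {
    rep(FALSE, nrow(t$counts))
  }
  flags <- tibble::tibble(
    cell_id = rownames(t$counts),
    patient_id = t$cell_meta$patient_id,
    mad_outlier = unname(mad_f),
    low_counts = totals < min_counts,
    high_counts = totals > max_counts,
    low_genes = ngene < min_genes,
    doublet = doublet
  )
  flags$keep <- !(flags$mad_outlier | flags$low_counts | flags$high_counts |
                    flags$low_genes | flags$doublet)
  summary <- flags |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_cells = dplyr::n(), n_kept = sum(.data$keep),
                     n_removed = sum(!.data$keep), .groups = "drop")
  structure(list(
    flags = flags,
    filtered = filter_cells(t, flags$keep),
    thresholds = list(n_mads = n_mads, min_counts = min_counts,
                      max_counts = max_counts, min_genes = min_genes),
    patient_summary = summary
  ), class = "qc_report")
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", sum(x$flags$keep), "/", nrow(x$flags),
      " cells kept\n", sep = "")
  print(x$patient_summary)
  invisible(x)
}

#' Summarize one gene's expression across QC groups
#'
#' Generic MALAT1-style diagnostic: compares a single gene's normalized
#' expression between cells removed and retained by QC.
#'
#' @param t A `cell_table`.
#' @param report A `qc_report` from [run_qc()].
#' @param gene Gene identifier.
#' @return Tibble with per-group n, mean, median and the two-sided
#'   Mann-Whitney p-value comparing removed vs kept cells.
#' @export
gene_qc_summary <- function(t, report, gene) {
  if (!gene %in% colnames(t$counts)) stop("Unknown gene: ", gene, call. = FALSE)
  nm <- normalize_cp10k_log1p(t)
  expr <- nm[, gene]
  keep <- report$flags$keep
  groups <- ifelse(keep, "kept", "removed")
  tab <- tibble::tibble(group = groups, expr = expr) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$expr),
                     median = stats::median(.data$expr), .groups = "drop")
  p <- if (all(c("kept", "removed") %in% groups)) {
    stats::wilcox.test(expr[keep], expr[!keep], exact = FALSE)$p.value
  } else {
    NA_real_
  }
  tab$mw_p <- p
  tab
}
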