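#' Bulkify a patient's single cells into one expression vector
#'
#' Aggregates single-cell measurements into a pseudobulk per-gene vector to
#' mimic bulk RNA-seq. Two modes reflect the two library chemistries:
#' `"sum_log1p"` (UMI counts: sum raw counts over cells, then natural
#' `log(1 + x)`) and `"mean_tpm"` (full-length protocols: convert each cell to
#' transcripts-per-million, then average across cells).
#'
#' @param t A `cell_table`.
#' @param patient Patient id; `NULL` aggregates all cells in the table.
#' @param mode `"sum_log1p"` or `"mean_tpm"`.
#' @return Named numeric vector, one value per gene.
#' @export
bulkify <- function(t, patient = NULL, mode = c("sum_log1p", "mean_tpm")) {
  mode <- match.arg(mode)
  counts <- t$counts
  if (!is.null(patient)) {
    if (!patient %in% t$cell_meta$patient_id) {
      stop("Unknown patient: ", patient, call. = FALSE)
    }
    counts <- counts[t$cell_meta$patient_id == patient, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("No cells to bulkify.", call. = FALSE)
  if (mode == "sum_log1p") {
    v <- log1p(Matrix::colSums(counts))
  } else {
    totals <- Matrix::rowSums(counts)
    if (any(totals == 0)) stop("Zero-total cell in TPM mode.", call. = FALSE)
    tpm <- Matrix::Diagonal(x = 1e6 / totals) %*% counts
    v <- Matrix::colMeans(tpm)
  }
  stats::setNames(as.numeric(v), colnames(t$counts))
}

# Least-squares polynomial fit of y on x; returns fitted values for x and a
# prediction closure. Orthogonal polynomial basis keeps nested-model R^2
# monotone in degree.
poly_fit <- function(x, y, degree) {
  basis <- stats::poly(x, degree = degree)
  fit <- stats::lm.fit(cbind(1, basis), y)
  coefs <- attr(basis, "coefs")
  list(
    fitted = fit$fitted.values,
    predict = function(newx) {
      nb <- stats::poly(newx, degree = degree, coefs = coefs)
      as.numeric(cbind(1, nb) %*% fit$coefficients)
    }
  )
}

r_squared <- function(y, fitted) {
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

#' Select polynomial degree by the elbow of the R-squared curve
#'
#' Fits `bulkified ~ poly(bulk, d)` for each candidate degree and returns the
#' smallest degree after which the R-squared improvement falls below
#' `epsilon`; if every step improves by at least `epsilon`, the maximum
#' degree is returned.
#'
#' @param bulk,bulkified Aligned per-gene numeric vectors.
#' @param degrees Candidate degrees (default 1:6).
#' @param epsilon Minimal R-squared improvement still considered meaningful
#'   (default 0.01).
#' @return List with `degree` (selected) and `r2_curve` (named per-degree
#'   R-squared).
#' @export
select_degree <- function(bulk, bulkified, degrees = 1:6, epsilon = 0.01) {
  degrees <- sort(unique(as.integer(degrees)))
  if (length(bulk) < max(degrees) + 2) {
    stop("Need at least max(degree) + 2 genes.", call. = FALSE)
  }
  if (stats::var(bulkified) == 0) {
    stop("Response has zero variance; R-squared undefined.", call. = FALSE)
  }
  r2 <- vapply(degrees, function(d) {
    r_squared(bulkified, poly_fit(bulk, bulkified, d)$fitted)
  }, numeric(1))
  names(r2) <- as.character(degrees)
  sel <- degrees[length(degrees)]
  for (i in seq_len(length(degrees) - 1)) {
    if (r2[i + 1] - r2[i] < epsilon) { sel <- degrees[i]; break }
  }
  list(degree = sel, r2_curve = r2)
}

#' Mean residual of mitochondrial genes under a non-MT-trained model
#'
#' Fits `bulkified ~ poly(bulk, degree)` on non-mitochondrial genes only and
#' reports the mean, over MT genes, of observed minus predicted bulkified
#' expression. Positive values mean the single-cell side carries more MT
#' signal than the bulk-based model predicts.
#'
#' @param bulk,bulkified Aligned named per-gene vectors.
#' @param mt_genes [gene_set()] or character vector of MT gene ids.
#' @param degree Polynomial degree (see [select_degree()]).
#' @return Scalar mean residual.
#' @export
mt_residual_statistic <- function(bulk, bulkified, mt_genes, degree) {
  genes <- names(bulk)
  stopifnot(identical(genes, names(bulkified)))
  mt <- intersect(as_gene_vector(mt_genes), genes)
  if (length(mt) == 0) stop("No MT gene in the shared index.", call. = FALSE)
  is_mt <- genes %in% mt
  fit <- poly_fit(bulk[!is_mt], bulkified[!is_mt], degree)
  mean(bulkified[is_mt] - fit$predict(bulk[is_mt]))
}

#' Empirical gene-sampling test of the MT residual statistic
#'
#' Builds a resampling null for [mt_residual_statistic()]: `B` times, a set of
#' genes the same size as the MT set is drawn from the `pool_size` most
#' expressed genes (ranked by bulkified expression), the model is refit
#' excluding them, and their mean residual recorded. The one-sided p-value is
#' `(1 + #\{null >= observed\}) / (B + 1)` (finite-sample corrected), asking
#' whether MT genes sit higher above the bulk-based prediction than random
#' highly expressed genes do.
#'
#' @inheritParams mt_residual_statistic
#' @param B Number of resampling iterations (default 500).
#' @param pool_size Size of the top-expression gene pool (default 500,
#'   capped at the number of genes).
#' @param seed Integer seed.
#' @return Object of class `highmt_residual_test`: a list with
#'   `mt_mean_residual`, `null_means`, `null_ci95`, `p_raw`, `degree`, `B`,
#'   `n_mt`, `pool_size`, `seed`.
#' @export
empirical_gene_sampling_test <- function(bulk, bulkified, mt_genes, degree,
                                         B = 500, pool_size = 500, seed = 0) {
  genes <- names(bulk)
  stopifnot(identical(genes, names(bulkified)))
  if (pool_size > length(genes)) {
    stop("pool_size exceeds the number of shared genes.", call. = FALSE)
  }
  mt <- intersect(as_gene_vector(mt_genes), genes)
  n_mt <- length(mt)
  if (n_mt == 0) stop("No MT gene in the shared index.", call. = FALSE)
  if (n_mt > pool_size) stop("More MT genes than pool_size.", call. = FALSE)
  observed <- mt_residual_statistic(bulk, bulkified, mt, degree)
  pool <- genes[order(bulkified, decreasing = TRUE)][seq_len(pool_size)]
  null_means <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      drawn <- sample(pool, n_mt)
      mt_residual_statistic(bulk, bulkified, drawn, degree)
    }, numeric(1))
  })
  p_raw <- (1 + sum(null_means >= observed)) / (B + 1)
  structure(list(
    mt_mean_residual = observed,
    null_means = null_means,
    null_ci95 = stats::quantile(null_means, c(0.025, 0.975), names = FALSE),
    p_raw = p_raw,
    degree = degree, B = B, n_mt = n_mt, pool_size = pool_size, seed = seed
  ), class = "highmt_residual_test")
}

#' @export
print.highmt_residual_test <- function(x, ...) {
  cat("<highmt_residual_test> mean MT residual ",
      format(x$mt_mean_residual, digits = 4),
      ", null 95% CI [", format(x$null_ci95[1], digits = 3), ", ",
      format(x$null_ci95[2], digits = 3), "], p = ",
      format(x$p_raw, digits = 4), " (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.highmt_residual_test <- function(x, ...) {
  tibble::tibble(mt_mean_residual = x$mt_mean_residual,
                 null_ci_lo = x$null_ci95[1], null_ci_hi = x$null_ci95[2],
                 p_value = x$p_raw, degree = x$degree, B = x$B, n_mt = x$n_mt)
}

#' @export
#' @importFrom generics glance
glance.highmt_residual_test <- function(x, ...) tidy(x)

#' Multiple-testing correction
#'
#' @param p Numeric vector of raw p-values.
#' @param method `"bonferroni"` (default) or `"bh"` (Benjamini-Hochberg
#'   step-up).
#' @return Adjusted p-values, clipped at 1.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Run the bulk-vs-bulkified residual test across patients
#'
#' For each patient: aligns the paired vectors on their shared gene index,
#' selects the polynomial degree on non-MT genes by the R-squared elbow, runs
#' the empirical gene-sampling test, and corrects p-values across patients.
#'
#' @param pairs Tibble with columns `patient_id`, `gene_id`, `bulk`,
#'   `bulkified`.
#' @param mt_genes MT gene designation.
#' @param degrees,epsilon Passed to [select_degree()].
#' @param B,pool_size,seed Passed to [empirical_gene_sampling_test()]; the
#'   per-patient seed is derived from `seed`.
#' @param correction `"bonferroni"` or `"bh"`.
#' @return Tibble with one row per patient: selected degree, MT residual,
#'   null CI, `p_raw`, `p_adj`, and the fitted test object in a list column.
#' @export
residual_test_patients <- function(pairs, mt_genes, degrees = 1:6,
                                   epsilon = 0.01, B = 500, pool_size = 500,
                                   seed = 0, correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  patients <- unique(pairs$patient_id)
  res <- purrr::imap_dfr(patients, function(pat, i) {
    sub <- pairs[pairs$patient_id == pat, ]
    bulk <- stats::setNames(sub$bulk, sub$gene_id)
    bulkified <- stats::setNames(sub$bulkified, sub$gene_id)
    mt <- intersect(as_gene_vector(mt_genes), sub$gene_id)
    non_mt <- !(sub$gene_id %in% mt)
    sel <- select_degree(bulk[non_mt], bulkified[non_mt],
                         degrees = degrees, epsilon = epsilon)
    fit <- empirical_gene_sampling_test(
      bulk, bulkified, mt, sel$degree,
      B = B, pool_size = min(pool_size, length(bulk)),
      seed = seed + i)
    tibble::tibble(patient_id = pat, degree = sel$degree,
                   mt_mean_residual = fit$mt_mean_residual,
                   null_ci_lo = fit$null_ci95[1],
                   null_ci_hi = fit$null_ci95[2],
                   p_raw = fit$p_raw, fit = list(fit))
  })
  res$p_adj <- adjust_pvalues(res$p_raw, correction)
  res$correction <- correction
  res
}
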