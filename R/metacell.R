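#' Aggregate cells into metacells
#'
#' Builds small disjoint groups of transcriptionally homogeneous cells and
#' sums their counts, reducing per-cell sampling noise before downstream
#' scoring. Within each (patient, cell type) stratum, cells are embedded by
#' PCA of log1p(CP10K) expression (top `n_pcs` components) and partitioned by
#' k-means with `k = ceiling(n / target_size)` clusters, so metacells hold
#' about `target_size` cells. Strata smaller than `target_size` form a single
#' metacell; counts are conserved exactly (metacell counts are sums of member
#' counts). Graph-partition metacell algorithms are deliberately not
#' re-implemented — the surrogate honors the same contract (disjoint,
#' homogeneous, ~`target_size` cells).
#'
#' @param t A QC-passing `cell_table`; if `pctmt`/`highmt` metadata columns
#'   are present, per-metacell HighMT fractions are recorded.
#' @param target_size Intended number of cells per metacell (default 25).
#' @param n_pcs Number of principal components (default 30, capped by the
#'   stratum size and gene count).
#' @param seed Integer seed for k-means initialization (default 0).
#' @param by_patient Stratify by patient as well as cell type (default TRUE);
#'   set FALSE to pool patients within a cell type.
#' @return An object of class `metacell_table`: `counts` (metacells x genes),
#'   `membership` (tibble `cell_id` -> `metacell_id`), and `meta` (tibble with
#'   `metacell_id`, `patient_id`, `cell_type`, `n_cells`, `frac_highmt`,
#'   `frac_malignant`).
#' @export
build_metacells <- function(t, target_size = 25, n_pcs = 30, seed = 0,
                            by_patient = TRUE) {
  meta <- t$cell_meta
  strata_key <- if (by_patient) {
    paste(meta$patient_id, meta$cell_type, sep = "\r")
  } else {
    meta$cell_type
  }
  strata <- split(seq_len(nrow(meta)), strata_key)
  has_mt <- all(c("pctmt", "highmt") %in% names(meta))
  mc_counter <- 0L
  rows <- list()
  members <- list()
  for (sname in names(strata)) {
    idx <- strata[[sname]]
    if (length(idx) == 0) next
    cl <- withr::with_seed(seed, cluster_stratum(
      t$counts[idx, , drop = FALSE], target_size, n_pcs))
    for (k in sort(unique(cl))) {
      mc_counter <- mc_counter + 1L
      mid <- sprintf("mc%04d", mc_counter)
      sel <- idx[cl == k]
      rows[[mc_counter]] <- tibble::tibble(
        metacell_id = mid,
        patient_id = if (by_patient) meta$patient_id[sel[1]] else
          paste(unique(meta$patient_id[sel]), collapse = ";"),
        cell_type = meta$cell_type[sel[1]],
        n_cells = length(sel),
        frac_highmt = if (has_mt) mean(meta$highmt[sel]) else NA_real_,
        frac_malignant = mean(meta$compartment[sel] == "malignant")
      )
      members[[mc_counter]] <- tibble::tibble(
        cell_id = meta$cell_id[sel], metacell_id = mid)
    }
  }
  mc_meta <- dplyr::bind_rows(rows)
  membership <- dplyr::bind_rows(members)
  # sum member counts per metacell via a sparse indicator matrix
  grp <- factor(membership$metacell_id[match(rownames(t$counts),
                                             membership$cell_id)],
                levels = mc_meta$metacell_id)
  ind <- Matrix::sparseMatrix(i = as.integer(grp), j = seq_len(nrow(t$counts)),
                              x = 1, dims = c(nrow(mc_meta), nrow(t$counts)))
  counts <- ind %*% t$counts
  rownames(counts) <- mc_meta$metacell_id
  colnames(counts) <- colnames(t$counts)
  structure(list(counts = methods::as(counts, "CsparseMatrix"),
                 membership = membership, meta = mc_meta),
            class = "metacell_table")
}

# Partition one stratum into clusters of ~target_size cells.
cluster_stratum <- function(counts, target_size, n_pcs) {
  n <- nrow(counts)
  k <- ceiling(n / target_size)
  if (k <= 1 || n < 2) return(rep(1L, n))
  norm <- normalize_cp10k_log1p(counts)
  dn <- as.matrix(norm)
  keep <- which(apply(dn, 2, stats::sd) > 0)
  if (length(keep) == 0) return(chunk_evenly(n, k))
  dn <- dn[, keep, drop = FALSE]
  rank_max <- min(n_pcs, n - 1L, ncol(dn))
  emb <- tryCatch(
    stats::prcomp(dn, rank. = rank_max, center = TRUE, scale. = FALSE)$x,
    error = function(e) NULL)
  if (is.null(emb)) return(chunk_evenly(n, k))
  n_distinct_pts <- nrow(unique(round(emb, 10)))
  if (n_distinct_pts < k) return(chunk_evenly(n, k))
  km <- stats::kmeans(emb, centers = k, nstart = 5, iter.max = 50)
  km$cluster
}

# Fallback when cells are indistinguishable: consecutive chunks of equal size.
chunk_evenly <- function(n, k) {
  as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
}

#' @export
print.metacell_table <- function(x, ...) {
  cat("<metacell_table> ", nrow(x$counts), " metacells, median size ",
      stats::median(x$meta$n_cells), " cells\n", sep = "")
  print(x$meta, n = 5)
  invisible(x)
}

#' Label metacells as HighMT and/or malignant
#'
#' A metacell is HighMT when strictly more than `highmt_frac` of its member
#' cells are HighMT, and malignant when strictly more than `malignant_frac`
#' of its members are malignant.
#'
#' @param m A `metacell_table` from [build_metacells()].
#' @param highmt_frac HighMT member-fraction cutoff (default 0.30, strict).
#' @param malignant_frac Malignant member-fraction cutoff (default 0.50,
#'   strict).
#' @return The `metacell_table` with logical `highmt_label` and
#'   `malignant_label` columns added to `meta`.
#' @export
label_metacells <- function(m, highmt_frac = 0.30, malignant_frac = 0.50) {
  if (all(is.na(m$meta$frac_highmt))) {
    stop("Metacells carry no HighMT fractions; run add_pctmt() on the cells ",
         "before build_metacells().", call. = FALSE)
  }
  m$meta <- m$meta |>
    dplyr::mutate(highmt_label = .data$frac_highmt > highmt_frac,
                  malignant_label = .data$frac_malignant > malignant_frac)
  m
}
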