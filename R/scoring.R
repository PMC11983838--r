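#' Bin-controlled gene-signature score
#'
#' Tirosh-style control-gene scoring, as popularized by the standard
#' single-cell toolkits. Genes are ranked by mean expression across the scored
#' observations and cut into `n_bins` expression bins of (near-)equal size.
#' Each signature gene is paired with control genes from its own bin: the
#' whole bin when the bin holds at most `ctrl_size` genes, otherwise
#' `ctrl_size` genes sampled with replacement (seeded). The per-observation
#' score is
#' `mean over signature genes of expression - mean over signature genes of
#' their control-gene mean`,
#' so an expression shift common to a bin cancels. When the signature covers
#' all genes the control average equals the signature average bin by bin and
#' the score is exactly zero.
#'
#' @param n Normalized cells/metacells-by-genes matrix.
#' @param sig A [gene_set()] or character vector of signature genes.
#' @param n_bins Number of expression bins (default 25).
#' @param ctrl_size Control genes per signature gene (default 50).
#' @param seed Integer seed for control sampling (default 0).
#' @return Tibble with columns `obs_id`, `signature`, `score`; scoring
#'   parameters are attached as the `params` attribute.
#' @export
score_signature <- function(n, sig, n_bins = 25, ctrl_size = 50, seed = 0) {
  genes <- colnames(n)
  if (n_bins > length(genes)) {
    stop("n_bins (", n_bins, ") exceeds the number of genes.", call. = FALSE)
  }
  sig_name <- if (inherits(sig, "gene_set")) sig$name else "signature"
  sig_genes <- intersect(as_gene_vector(sig), genes)
  if (length(sig_genes) == 0) {
    stop("No signature gene present in the matrix.", call. = FALSE)
  }
  mean_expr <- Matrix::colMeans(n)
  # equal-size bins over the expression ranking; ties broken by gene order
  rk <- rank(mean_expr, ties.method = "first")
  bin <- ceiling(n_bins * rk / length(genes))
  sig_idx <- match(sig_genes, genes)
  ctrl_means <- withr::with_seed(seed, {
    vapply(sig_idx, function(gi) {
      members <- which(bin == bin[gi])
      ctrl <- if (length(members) <= ctrl_size) members else
        sample(members, ctrl_size, replace = TRUE)
      as.numeric(Matrix::rowMeans(n[, ctrl, drop = FALSE]))
    }, numeric(nrow(n)))
  })
  sig_expr <- as.matrix(n[, sig_idx, drop = FALSE])
  score <- rowMeans(sig_expr) - rowMeans(ctrl_means)
  out <- tibble::tibble(obs_id = rownames(n), signature = sig_name,
                        score = unname(score))
  attr(out, "params") <- list(n_bins = n_bins, ctrl_size = ctrl_size,
                              seed = seed)
  out
}

#' Meta-signature: intersection of two or more gene sets
#'
#' Used to build consensus programs (e.g. a dissociation-stress
#' meta-signature from independently derived stress signatures): only genes
#' present in every input set are retained.
#'
#' @param sets List of at least two [gene_set()] objects (or character
#'   vectors).
#' @param name Name for the resulting set.
#' @return A [gene_set()] holding the exact intersection.
#' @export
build_meta_signature <- function(sets, name = "meta_signature") {
  if (length(sets) < 2) {
    stop("At least two gene sets are required.", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(sets, as_gene_vector))
  if (length(common) == 0) {
    stop("The gene sets share no gene; supply larger or related sets.",
         call. = FALSE)
  }
  gene_set(name, common)
}

#' Point-biserial correlation between a score and a binary status
#'
#' Pearson correlation of the score with the 0/1-coded group indicator;
#' significance from the t distribution with n - 2 degrees of freedom.
#'
#' @param score Numeric vector.
#' @param group Logical/0-1/two-level vector of the same length.
#' @return Tibble with `r`, `t_stat`, `p_value`, `n`.
#' @export
point_biserial <- function(score, group) {
  if (is.character(group) || is.factor(group)) {
    lev <- sort(unique(as.character(group)))
    if (length(lev) != 2) stop("`group` must have exactly two levels.",
                               call. = FALSE)
    group <- as.character(group) == lev[2]
  }
  g <- as.numeric(group)
  if (length(unique(g)) < 2) {
    stop("Both groups must be non-empty.", call. = FALSE)
  }
  if (stats::sd(score) == 0) {
    stop("Score has zero variance.", call. = FALSE)
  }
  n <- length(score)
  r <- stats::cor(score, g)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  tibble::tibble(r = r, t_stat = t_stat, p_value = p, n = n)
}

#' Assign each observation the label of its maximal score
#'
#' Ties are broken lexicographically by label name and flagged.
#'
#' @param scores Tibble with columns `obs_id`, `signature`, `score` (stacked
#'   output of several [score_signature()] calls), or a matrix of
#'   observations x labels.
#' @return Tibble with `obs_id`, `label`, `tie` (logical).
#' @export
assign_by_max_score <- function(scores) {
  if (is.matrix(scores)) {
    scores <- tibble::tibble(
      obs_id = rep(rownames(scores), times = ncol(scores)),
      signature = rep(colnames(scores), each = nrow(scores)),
      score = as.vector(scores)
    )
  }
  scores |>
    dplyr::group_by(obs_id = .data$obs_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$signature,
                   .by_group = TRUE) |>
    dplyr::summarise(
      label = .data$signature[1],
      tie = sum(.data$score == max(.data$score)) > 1,
      .groups = "drop"
    )
}
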