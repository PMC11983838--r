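#' Assign cells to square spatial patches
#'
#' The field is tiled by an origin-anchored grid of `patch_px` by `patch_px`
#' pixel squares with half-open bounds `[k*p, (k+1)*p)`, so every cell falls
#' in exactly one patch: `(floor(x / p), floor(y / p))`.
#'
#' @param t Tibble of spatial cells with numeric `x`, `y` columns (pixels).
#' @param patch_px Patch side length in pixels (default 1000).
#' @return The input tibble with integer `patch_i`, `patch_j` columns.
#' @export
assign_patches <- function(t, patch_px = 1000) {
  stopifnot(all(c("x", "y") %in% names(t)))
  t |>
    dplyr::mutate(patch_i = as.integer(floor(.data$x / patch_px)),
                  patch_j = as.integer(floor(.data$y / patch_px)))
}

#' Median pctMT of malignant cells per patch
#'
#' Summarizes each occupied patch by the median pctMT over its malignant
#' cells. Patches with fewer than `min_cells` malignant cells are marked
#' excluded (their median is reported as `NA`).
#'
#' @param t Spatial cell tibble with `x`, `y`, `pctmt`, and logical
#'   `malignant` columns.
#' @param patch_px Patch side length in pixels (default 1000).
#' @param min_cells Minimum malignant cells per retained patch (default 10).
#' @return Tibble with one row per occupied patch: `patch_i`, `patch_j`,
#'   patch bounds in px, `n_cells`, `n_malignant`, `median_pctmt`,
#'   `excluded`.
#' @export
patch_median_pctmt <- function(t, patch_px = 1000, min_cells = 10) {
  stopifnot(all(c("pctmt", "malignant") %in% names(t)))
  assign_patches(t, patch_px) |>
    dplyr::group_by(patch_i = .data$patch_i, patch_j = .data$patch_j) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_malignant = sum(.data$malignant),
      median_pctmt = if (sum(.data$malignant) >= min_cells)
        stats::median(.data$pctmt[.data$malignant]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      x_min = .data$patch_i * patch_px, x_max = (.data$patch_i + 1) * patch_px,
      y_min = .data$patch_j * patch_px, y_max = (.data$patch_j + 1) * patch_px,
      excluded = .data$n_malignant < min_cells
    )
}

#' Check whether pctMT is confounded by total counts
#'
#' Rank (Spearman) correlation between pctMT and total detected counts,
#' computed separately for malignant and non-malignant cells. A strong
#' correlation would flag pctMT as a sampling-depth artifact. Pearson is
#' available via `method`.
#'
#' @param t Spatial (or any per-cell) tibble with `pctmt`, `total_counts`,
#'   and logical `malignant` columns.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble with one row per compartment: `n`, `rho`, `p_value`.
#'   Compartments with fewer than 3 cells are skipped.
#' @export
counts_confounder_check <- function(t, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  purrr::map_dfr(c(TRUE, FALSE), function(mal) {
    sub <- t[t$malignant == mal, ]
    if (nrow(sub) < 3) return(NULL)
    ct <- suppressWarnings(
      stats::cor.test(sub$pctmt, sub$total_counts, method = method))
    tibble::tibble(compartment = if (mal) "malignant" else "non-malignant",
                   n = nrow(sub), rho = unname(ct$estimate),
                   p_value = ct$p.value)
  })
}
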