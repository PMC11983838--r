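# Small in-code fixtures and independent brute-force oracles shared by the
# unit and acceptance tests.

# A tiny cell table built by hand: counts fully specified so pctMT, QC
# metrics and contingency tables can be derived on paper.
make_mini_table <- function() {
  counts <- rbind(
    # cell          MT-A MT-B  g1  g2  g3
    P1_mal_hi  = c(  10,  10,  20,  30,  30),  # pctMT 20/100 = 20%
    P1_mal_lo  = c(   2,   3,  35,  30,  30),  # pctMT 5%
    P1_tme_lo1 = c(   1,   1,  38,  30,  30),  # pctMT 2%
    P1_tme_hi  = c(  20,  20,  20,  20,  20),  # pctMT 40%
    P2_mal_hi1 = c(  25,  25,  10,  20,  20),  # pctMT 50%
    P2_mal_hi2 = c(  08,  08,  28,  28,  28),  # pctMT 16%
    P2_mal_lo  = c(   0,   0,  40,  30,  30),  # pctMT 0%
    P2_tme_lo  = c(   5,   5,  30,  30,  30)   # pctMT 10%
  )
  colnames(counts) <- c("MT-A", "MT-B", "g1", "g2", "g3")
  meta <- tibble::tibble(
    cell_id = rownames(counts),
    patient_id = sub("_.*", "", rownames(counts)),
    compartment = ifelse(grepl("_mal_", rownames(counts)), "malignant", "TME"),
    cell_type = ifelse(grepl("_mal_", rownames(counts)), "tumor", "T_cell")
  )
  cell_table(counts, meta)
}

# random cell table for property-style checks
random_cell_table <- function(n_cells = 30, n_genes = 40, n_patients = 2,
                              lambda = 5) {
  counts <- matrix(stats::rpois(n_cells * n_genes, lambda), n_cells, n_genes)
  rownames(counts) <- sprintf("c%03d", seq_len(n_cells))
  colnames(counts) <- c(sprintf("MT-G%d", 1:3),
                        sprintf("g%03d", seq_len(n_genes - 3)))
  zero <- which(rowSums(counts) == 0)
  if (length(zero)) counts[zero, 1] <- 1
  meta <- tibble::tibble(
    cell_id = rownames(counts),
    patient_id = sprintf("P%d", rep_len(seq_len(n_patients), n_cells)),
    compartment = rep_len(c("malignant", "TME"), n_cells),
    cell_type = rep_len(c("tumor", "T_cell"), n_cells)
  )
  cell_table(counts, meta)
}

# --- independent oracles ----------------------------------------------------

oracle_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_variance_pop <- function(v) sum((v - mean(v))^2) / length(v)

oracle_mad_flags <- function(metrics, patient, n_mads = 5) {
  flags <- rep(FALSE, nrow(metrics))
  for (p in unique(patient)) {
    idx <- which(patient == p)
    for (j in seq_len(ncol(metrics))) {
      m <- metrics[idx, j]
      dev <- abs(m - stats::median(m))
      flags[idx] <- flags[idx] | (dev > n_mads * stats::median(dev))
    }
  }
  flags
}

# naive O(n^3) Ward agglomeration via the Lance-Williams update used by
# Ward-on-Euclidean-distances; returns merge heights in order
oracle_ward_heights <- function(X) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestd)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dnew <- sqrt(((ni + nk) * D[i, k]^2 + (nj + nk) * D[j, k]^2 -
                      nk * D[i, j]^2) / (ni + nj + nk))
      D[i, k] <- dnew; D[k, i] <- dnew
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# geometric brute-force patch medians over malignant cells
oracle_patch_medians <- function(df, patch_px, min_cells) {
  out <- list()
  is_ <- floor(df$x / patch_px); js <- floor(df$y / patch_px)
  for (key in unique(paste(is_, js))) {
    ij <- as.numeric(strsplit(key, " ")[[1]])
    inside <- df$x >= ij[1] * patch_px & df$x < (ij[1] + 1) * patch_px &
      df$y >= ij[2] * patch_px & df$y < (ij[2] + 1) * patch_px
    mal <- inside & df$malignant
    out[[key]] <- tibble::tibble(
      patch_i = ij[1], patch_j = ij[2],
      n_malignant = sum(mal),
      median_pctmt = if (sum(mal) >= min_cells)
        stats::median(df$pctmt[mal]) else NA_real_
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), patch_i, patch_j)
}
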