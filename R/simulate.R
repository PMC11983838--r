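#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generators with defaults chosen to emulate a
#' desk-scale cancer cohort: patients with malignant and TME compartments
#' whose mitochondrial fractions differ, a plantable dissociation-stress
#' program, paired bulk/bulkified vectors with optional MT-gene excess,
#' cell-line drug panels with plantable pctMT-IC50 correlations, and spatial
#' fields with regionally varying malignant pctMT.
#'
#' The MT fraction is modeled at the probability level: each cell draws a true
#' fraction `f` from a per-compartment Beta distribution (parameterized by
#' mean and concentration `kappa`) and its counts are multinomial with MT
#' genes receiving total weight `f` — so measured pctMT is a noisy, unbiased
#' estimate of `100 * f`. Thirteen MT genes mirror the protein-coding
#' mitochondrial genome. Program effects (stress, pathways) multiply gene
#' weights within the non-MT block only, leaving the true MT fraction intact.
#'
#' @param n_patients Number of patients (default 8).
#' @param cells_per_patient Good cells per patient (default 400).
#' @param n_genes Total genes including MT (default 1000).
#' @param n_mt_genes Mitochondrial genes, named `MT-G1`... (default 13).
#' @param malignant_fraction Fraction of good cells that are malignant
#'   (default 0.5).
#' @param pctmt_malignant,pctmt_tme Lists `list(mean=, kappa=)` of the Beta
#'   MT-fraction law per compartment (defaults mean 0.15 / kappa 10 and mean
#'   0.05 / kappa 20).
#' @param total_counts_meanlog,total_counts_sdlog Log-normal law of per-cell
#'   totals (defaults log(6000), 0.35).
#' @param cell_weight_shape Shape of the per-cell Gamma jitter multiplying
#'   every gene weight (mean 1), emulating biological expression variability
#'   between cells; smaller = noisier, `Inf` disables (default 3).
#' @param junk_fraction Extra planted junk cells per patient, as a fraction of
#'   `cells_per_patient`: very low totals concentrated on few genes, giving
#'   QC something to remove (default 0.05).
#' @param n_stress_genes Size of the dissociation-stress program (default 30).
#' @param stress_effect Multiplier `exp(stress_effect)` on stress-gene weights
#'   in affected cells (default 0 = off).
#' @param stress_coupled If TRUE the stress program fires in cells whose true
#'   MT fraction exceeds `highmt_threshold/100`; if FALSE it fires in a
#'   random subset of the same expected size (default TRUE).
#' @param highmt_threshold HighMT cutoff in percent used for coupling and
#'   pathway planting (default 15).
#' @param n_pathways,pathway_size Number and size of synthetic pathway gene
#'   sets (defaults 8 and 25).
#' @param planted_pathway_effects Named numeric vector: pathway name ->
#'   log-scale weight shift applied in HighMT malignant cells (default none).
#' @param bulk_noise_sd Gaussian noise sd on the bulk side (default 0.15).
#' @param bulk_transform Numeric `c(a0, a1, a2)` of the monotone map
#'   `bulk = a0 + a1*b + a2*b^2` applied to bulkified expression `b`
#'   (default identity `c(0, 1, 0)`).
#' @param mt_excess Named numeric vector patient -> multiplicative MT
#'   inflation of the single-cell side relative to bulk (default 1 for all).
#' @param drug_params List: `n_types`, `lines_per_type`, and `drugs`, a
#'   tibble with columns `drug`, `true_r`, `category`.
#' @param spatial_params List: `n_cells`, `field_px` (c(width, height)),
#'   `malignant_prob`, `tme_pctmt_mean`, `kappa`, and `regions`, a tibble
#'   with `x_min`, `x_max`, `y_min`, `y_max`, `malignant_pctmt_mean`.
#' @param seed Integer seed; every generator is deterministic given the
#'   config (default 0).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 8,
                         cells_per_patient = 400,
                         n_genes = 1000,
                         n_mt_genes = 13,
                         malignant_fraction = 0.5,
                         pctmt_malignant = list(mean = 0.15, kappa = 10),
                         pctmt_tme = list(mean = 0.05, kappa = 20),
                         total_counts_meanlog = log(6000),
                         total_counts_sdlog = 0.35,
                         cell_weight_shape = 3,
                         junk_fraction = 0.05,
                         n_stress_genes = 30,
                         stress_effect = 0,
                         stress_coupled = TRUE,
                         highmt_threshold = 15,
                         n_pathways = 8,
                         pathway_size = 25,
                         planted_pathway_effects = NULL,
                         bulk_noise_sd = 0.15,
                         bulk_transform = c(0, 1, 0),
                         mt_excess = NULL,
                         drug_params = NULL,
                         spatial_params = NULL,
                         seed = 0) {
  fracs <- c(malignant_fraction, junk_fraction,
             pctmt_malignant$mean, pctmt_tme$mean)
  if (any(fracs < 0 | fracs > 1)) {
    stop("Fractions must lie in [0, 1].", call. = FALSE)
  }
  if (n_mt_genes >= n_genes) {
    stop("n_mt_genes must be smaller than n_genes.", call. = FALSE)
  }
  if (is.null(drug_params)) {
    drug_params <- list(
      n_types = 4, lines_per_type = 30,
      drugs = tibble::tibble(
        drug = sprintf("drug%02d", 1:20),
        true_r = 0,
        category = rep(c("metabolism", "EGFR signaling", "mitosis",
                         "genome integrity", "other"), 4)
      )
    )
  }
  if (any(abs(drug_params$drugs$true_r) > 1)) {
    stop("Drug true correlations must lie in [-1, 1].", call. = FALSE)
  }
  if (is.null(spatial_params)) {
    spatial_params <- list(
      n_cells = 4000, field_px = c(4000, 2000), malignant_prob = 0.5,
      tme_pctmt_mean = 0.04, kappa = 40,
      regions = tibble::tibble(
        x_min = c(0, 2000), x_max = c(2000, 4000),
        y_min = 0, y_max = 2000,
        malignant_pctmt_mean = c(0.20, 0.05)
      )
    )
  }
  structure(list(
    n_patients = n_patients, cells_per_patient = cells_per_patient,
    n_genes = n_genes, n_mt_genes = n_mt_genes,
    malignant_fraction = malignant_fraction,
    pctmt_malignant = pctmt_malignant, pctmt_tme = pctmt_tme,
    total_counts_meanlog = total_counts_meanlog,
    total_counts_sdlog = total_counts_sdlog,
    cell_weight_shape = cell_weight_shape,
    junk_fraction = junk_fraction,
    n_stress_genes = n_stress_genes, stress_effect = stress_effect,
    stress_coupled = stress_coupled, highmt_threshold = highmt_threshold,
    n_pathways = n_pathways, pathway_size = pathway_size,
    planted_pathway_effects = planted_pathway_effects,
    bulk_noise_sd = bulk_noise_sd, bulk_transform = bulk_transform,
    mt_excess = mt_excess, drug_params = drug_params,
    spatial_params = spatial_params, seed = seed
  ), class = "synth_config")
}

rbeta_mean <- function(n, mean, kappa) {
  if (mean == 0) return(rep(0, n))
  if (mean == 1) return(rep(1, n))
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

#' Simulate a single-cell cancer cohort
#'
#' Draws, per patient, malignant and TME cells with compartment-specific MT
#' fractions, optional stress-program and pathway weight shifts in HighMT
#' cells, and planted junk cells, then samples multinomial counts per cell.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return List with `cells` (a [cell_table()]), `truth` (tibble per cell:
#'   `cell_id`, `true_mt_frac`, `stress_on`, `pathway_on`, `is_junk`),
#'   `stress_signature` (a [gene_set()]), and `pathways` (named list of
#'   [gene_set()]s).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  n_mt <- cfg$n_mt_genes
  n_nuc <- cfg$n_genes - n_mt
  mt_ids <- sprintf("MT-G%d", seq_len(n_mt))
  nuc_ids <- sprintf("gene%04d", seq_len(n_nuc))
  gene_ids <- c(mt_ids, nuc_ids)

  # fixed program memberships over nuclear genes
  stress_idx <- seq_len(cfg$n_stress_genes)
  stress_genes <- nuc_ids[stress_idx]
  pw_start <- cfg$n_stress_genes
  pathways <- list()
  for (k in seq_len(cfg$n_pathways)) {
    sel <- pw_start + (k - 1) * cfg$pathway_size + seq_len(cfg$pathway_size)
    if (max(sel) > n_nuc) break
    pathways[[sprintf("pathway%02d", k)]] <-
      gene_set(sprintf("pathway%02d", k), nuc_ids[sel])
  }

  w_mt <- stats::rgamma(n_mt, shape = 2)
  w_mt <- w_mt / sum(w_mt)
  w_nuc <- stats::rgamma(n_nuc, shape = 2)
  w_nuc <- w_nuc / sum(w_nuc)

  # precompute nuclear weight variants; program effects touch only the
  # nuclear block so the drawn MT fraction stays exact
  wn_stress <- w_nuc
  wn_stress[stress_idx] <- wn_stress[stress_idx] * exp(cfg$stress_effect)
  apply_pathway <- function(wn) {
    for (pw in names(cfg$planted_pathway_effects)) {
      gidx <- match(pathways[[pw]]$genes, nuc_ids)
      wn[gidx] <- wn[gidx] * exp(cfg$planted_pathway_effects[[pw]])
    }
    wn
  }
  wn_path <- apply_pathway(w_nuc)
  wn_both <- apply_pathway(wn_stress)

  thr <- cfg$highmt_threshold / 100
  meta_list <- list()
  truth_list <- list()
  count_list <- list()
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    n_mal <- round(cfg$cells_per_patient * cfg$malignant_fraction)
    n_tme <- cfg$cells_per_patient - n_mal
    n_junk <- round(cfg$cells_per_patient * cfg$junk_fraction)
    compartment <- c(rep("malignant", n_mal), rep("TME", n_tme),
                     rep("TME", n_junk))
    is_junk <- c(rep(FALSE, n_mal + n_tme), rep(TRUE, n_junk))
    n_cells_p <- length(compartment)
    f <- numeric(n_cells_p)
    mal <- compartment == "malignant"
    f[mal] <- rbeta_mean(sum(mal), cfg$pctmt_malignant$mean,
                         cfg$pctmt_malignant$kappa)
    f[!mal] <- rbeta_mean(sum(!mal), cfg$pctmt_tme$mean, cfg$pctmt_tme$kappa)
    stress_on <- if (cfg$stress_effect == 0) {
      rep(FALSE, n_cells_p)
    } else if (cfg$stress_coupled) {
      f > thr
    } else {
      stats::runif(n_cells_p) < mean(f > thr)
    }
    pathway_on <- mal & f > thr &
      length(cfg$planted_pathway_effects) > 0
    totals <- round(stats::rlnorm(n_cells_p, cfg$total_counts_meanlog,
                                  cfg$total_counts_sdlog))
    totals[is_junk] <- round(stats::rlnorm(sum(is_junk), log(400), 0.5))
    totals <- pmax(totals, 10)
    cell_type <- ifelse(mal, "tumor",
                        sample(c("T_cell", "macrophage"), n_cells_p,
                               replace = TRUE))
    counts_p <- matrix(0L, n_cells_p, cfg$n_genes)
    for (i in seq_len(n_cells_p)) {
      wn <- if (is_junk[i]) {
        # junk droplets: counts concentrated on a handful of genes
        wn_full <- numeric(n_nuc)
        few <- sample(n_nuc, 15)
        wn_full[few] <- stats::rgamma(15, shape = 0.5) + 1e-6
        wn_full
      } else if (stress_on[i] && pathway_on[i]) {
        wn_both
      } else if (stress_on[i]) {
        wn_stress
      } else if (pathway_on[i]) {
        wn_path
      } else {
        w_nuc
      }
      wm <- w_mt
      if (is.finite(cfg$cell_weight_shape)) {
        # per-cell biological variability: mean-1 Gamma jitter per gene
        jit <- stats::rgamma(cfg$n_genes, shape = cfg$cell_weight_shape,
                             rate = cfg$cell_weight_shape)
        wm <- wm * jit[seq_len(n_mt)]
        wn <- wn * jit[-seq_len(n_mt)]
      }
      # renormalize blocks so the drawn MT fraction stays exact
      probs <- c(wm / sum(wm) * f[i], wn / sum(wn) * (1 - f[i]))
      if (f[i] == 0) probs <- c(numeric(n_mt), wn / sum(wn))
      counts_p[i, ] <- stats::rmultinom(1, totals[i], probs)[, 1]
    }
    cid <- sprintf("%s_c%04d", pid, seq_len(n_cells_p))
    meta_list[[p]] <- tibble::tibble(
      cell_id = cid, patient_id = pid, compartment = compartment,
      cell_type = cell_type)
    truth_list[[p]] <- tibble::tibble(
      cell_id = cid, true_mt_frac = f, stress_on = stress_on,
      pathway_on = pathway_on, is_junk = is_junk)
    count_list[[p]] <- counts_p
  }
  meta <- dplyr::bind_rows(meta_list)
  counts <- do.call(rbind, count_list)
  dimnames(counts) <- list(meta$cell_id, gene_ids)
  list(cells = cell_table(counts, meta),
       truth = dplyr::bind_rows(truth_list),
       stress_signature = gene_set("dissociation_stress", stress_genes),
       pathways = pathways)
}

#' Simulate paired bulk expression for a synthetic cohort
#'
#' For each patient, the single-cell side is bulkified (`sum_log1p`) and the
#' bulk side generated as a monotone polynomial transform of the bulkified
#' value plus Gaussian noise. When `cfg$mt_excess[patient] > 1`, the bulk
#' value of MT genes is computed from the bulkified value deflated by
#' `log(mt_excess)` — i.e. the single-cell MT signal exceeds what the
#' bulk-based model predicts by that factor, the effect the residual test is
#' designed to detect.
#'
#' @param cfg A [synth_config()].
#' @param t The `cell_table` produced by [simulate_cohort()] with the same
#'   config.
#' @return Tibble with columns `patient_id`, `gene_id`, `bulk`, `bulkified`.
#' @export
simulate_bulk_pair <- function(cfg, t) {
  stopifnot(inherits(cfg, "synth_config"))
  patients <- unique(t$cell_meta$patient_id)
  if (!is.null(cfg$mt_excess)) {
    unknown <- setdiff(names(cfg$mt_excess), patients)
    if (length(unknown) > 0) {
      stop("mt_excess names unknown patient(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  a <- cfg$bulk_transform
  mt <- startsWith(colnames(t$counts), "MT-")
  withr::with_seed(cfg$seed + 1L, {
    purrr::map_dfr(patients, function(pid) {
      b <- bulkify(t, pid, mode = "sum_log1p")
      excess <- if (!is.null(cfg$mt_excess) && pid %in% names(cfg$mt_excess)) {
        cfg$mt_excess[[pid]]
      } else 1
      b_for_bulk <- b
      b_for_bulk[mt] <- b[mt] - log(excess)
      bulk <- a[1] + a[2] * b_for_bulk + a[3] * b_for_bulk^2 +
        stats::rnorm(length(b), sd = cfg$bulk_noise_sd)
      tibble::tibble(patient_id = pid, gene_id = names(b),
                     bulk = unname(bulk), bulkified = unname(b))
    })
  })
}

#' Simulate a cell-line drug-response panel
#'
#' Cell lines get a pctMT value per cancer type; for each drug, IC50 is drawn
#' so that its within-type Pearson correlation with pctMT converges to the
#' drug's configured `true_r` (IC50 is a linear blend of standardized pctMT
#' and independent noise).
#'
#' @param cfg A [synth_config()]; see `drug_params`.
#' @return Tibble with columns `cell_line`, `cancer_type`, `pctmt`, `drug`,
#'   `ic50`, `category`.
#' @export
simulate_cell_lines <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  dp <- cfg$drug_params
  if (dp$lines_per_type < 2) {
    stop("Need at least 2 cell lines per cancer type.", call. = FALSE)
  }
  withr::with_seed(cfg$seed + 2L, {
    purrr::map_dfr(seq_len(dp$n_types), function(ty) {
      type <- sprintf("cancer%d", ty)
      lines <- sprintf("%s_line%02d", type, seq_len(dp$lines_per_type))
      # per-type baseline median pctMT between ~4 and ~14 percent
      base_mean <- stats::runif(1, 0.04, 0.14)
      pctmt <- 100 * rbeta_mean(dp$lines_per_type, base_mean, 30)
      z <- as.numeric(scale(pctmt))
      purrr::pmap_dfr(dp$drugs, function(drug, true_r, category) {
        noise <- stats::rnorm(dp$lines_per_type)
        ic50 <- true_r * z + sqrt(1 - true_r^2) * noise
        tibble::tibble(cell_line = lines, cancer_type = type, pctmt = pctmt,
                       drug = drug, ic50 = ic50, category = category)
      })
    })
  })
}

#' Simulate a spatial cell table
#'
#' Cells are placed uniformly in the field; each cell is malignant with the
#' configured probability, and malignant pctMT is drawn from the Beta law of
#' the region containing the cell (TME cells share one baseline law). Total
#' counts are drawn independently of pctMT.
#'
#' @param cfg A [synth_config()]; see `spatial_params`.
#' @return Tibble with columns `cell_id`, `x`, `y`, `pctmt`, `total_counts`,
#'   `malignant`.
#' @export
simulate_spatial <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  sp <- cfg$spatial_params
  withr::with_seed(cfg$seed + 3L, {
    n <- sp$n_cells
    x <- stats::runif(n, 0, sp$field_px[1])
    y <- stats::runif(n, 0, sp$field_px[2])
    malignant <- stats::runif(n) < sp$malignant_prob
    pctmt <- 100 * rbeta_mean(n, sp$tme_pctmt_mean, sp$kappa)
    for (i in seq_len(nrow(sp$regions))) {
      rg <- sp$regions[i, ]
      inside <- malignant & x >= rg$x_min & x < rg$x_max &
        y >= rg$y_min & y < rg$y_max
      pctmt[inside] <- 100 * rbeta_mean(sum(inside),
                                        rg$malignant_pctmt_mean, sp$kappa)
    }
    tibble::tibble(
      cell_id = sprintf("sp%05d", seq_len(n)), x = x, y = y,
      pctmt = pctmt,
      total_counts = round(stats::rlnorm(n, log(800), 0.4)),
      malignant = malignant
    )
  })
}
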