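#' Default pipeline configuration
#'
#' Every analysis constant has a named key with its conventional default:
#' HighMT cutoff 15 (percent), 5 MADs, absolute bounds 1500/50000 counts and
#' 500 genes, metacell HighMT/malignant label fractions 0.30/0.50, metacell
#' target size 25, polynomial degrees 1-6 with elbow epsilon 0.01, residual
#' null B = 500 over a top-500 gene pool, drug tail size 15, spatial patch
#' 1000 px with a 10-malignant-cell minimum.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    highmt_threshold = 15,
    qc = list(n_mads = 5, min_counts = 1500, max_counts = 50000,
              min_genes = 500),
    case_control = list(or_threshold = 2, frac_threshold = 0.15,
                        min_compartment = 30, min_highmt = 20),
    scoring = list(n_bins = 25, ctrl_size = 50),
    metacell = list(target_size = 25, n_pcs = 30,
                    highmt_frac = 0.30, malignant_frac = 0.50),
    bulk = list(degrees = 1:6, epsilon = 0.01, B = 500, pool_size = 500,
                correction = "bonferroni"),
    drugs = list(k = 15, B = 1000),
    spatial = list(patch_px = 1000, min_cells = 10)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a cohort, runs mitochondria-agnostic QC, annotates pctMT and
#' HighMT status, summarizes patients into case/control, scores the stress
#' program, builds and labels metacells, computes the pathway dysregulation
#' matrix, runs the bulk-vs-bulkified residual test, the drug-association
#' analysis, and the spatial patch summary. All randomness derives from
#' `cfg$seed`; identical configurations yield identical outputs.
#'
#' @param cfg A [synth_config()] describing the synthetic inputs.
#' @param config Optional list overriding entries of [default_config()].
#' @param outdir Optional directory; when given, result tables are written as
#'   TSV and the manifest as JSON.
#' @return List of class `highmt_pipeline` with elements `qc_summary`,
#'   `patient_summary`, `stress_scores`, `stress_association`,
#'   `metacell_meta`, `pathway_deltas`, `residual_tests`, `drug_assoc`
#'   (glance row), `spatial_patches`, `confounder_check`, and `manifest`.
#' @export
run_pipeline <- function(cfg, config = list(), outdir = NULL) {
  pc <- merge_config(default_config(), config)
  sim <- simulate_cohort(cfg)

  qc <- run_qc(sim$cells, n_mads = pc$qc$n_mads,
               min_counts = pc$qc$min_counts, max_counts = pc$qc$max_counts,
               min_genes = pc$qc$min_genes)
  cells <- add_pctmt(qc$filtered, threshold = pc$highmt_threshold)

  patients <- patient_mt_summary(cells) |>
    annotate_case_control(or_threshold = pc$case_control$or_threshold,
                          frac_threshold = pc$case_control$frac_threshold,
                          min_compartment = pc$case_control$min_compartment,
                          min_highmt = pc$case_control$min_highmt)

  norm <- normalize_cp10k_log1p(cells)
  stress <- score_signature(norm, sim$stress_signature,
                            n_bins = pc$scoring$n_bins,
                            ctrl_size = pc$scoring$ctrl_size, seed = cfg$seed)
  mal <- cells$cell_meta$compartment == "malignant"
  stress_assoc <- point_biserial(stress$score[mal],
                                 cells$cell_meta$highmt[mal])

  mc <- build_metacells(cells, target_size = pc$metacell$target_size,
                        n_pcs = pc$metacell$n_pcs, seed = cfg$seed) |>
    label_metacells(highmt_frac = pc$metacell$highmt_frac,
                    malignant_frac = pc$metacell$malignant_frac)
  mc_norm <- normalize_cp10k_log1p(mc$counts)
  study <- list(synthetic = list(norm = mc_norm, meta = mc$meta))
  deltas <- pathway_delta_matrix(study, sim$pathways,
                                 n_bins = pc$scoring$n_bins,
                                 ctrl_size = pc$scoring$ctrl_size,
                                 seed = cfg$seed)

  pairs <- simulate_bulk_pair(cfg, cells)
  resid <- residual_test_patients(
    pairs, mt_genes = detect_mt_genes(cells),
    degrees = pc$bulk$degrees, epsilon = pc$bulk$epsilon,
    B = pc$bulk$B, pool_size = min(pc$bulk$pool_size, cfg$n_genes),
    seed = cfg$seed, correction = pc$bulk$correction)

  drug_tab <- simulate_cell_lines(cfg)
  drugs <- drug_association(drug_tab, k = pc$drugs$k, B = pc$drugs$B,
                            seed = cfg$seed)

  sp <- simulate_spatial(cfg)
  patches <- patch_median_pctmt(sp, patch_px = pc$spatial$patch_px,
                                min_cells = pc$spatial$min_cells)
  confound <- counts_confounder_check(sp)

  manifest <- list(
    seed = cfg$seed,
    config = pc,
    synth = cfg[setdiff(names(cfg), c("drug_params", "spatial_params"))],
    n_cells_simulated = nrow(sim$cells$counts),
    n_cells_kept = nrow(cells$counts),
    n_metacells = nrow(mc$counts),
    versions = list(highmt = as.character(utils::packageVersion("highmt")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )

  out <- structure(list(
    qc_summary = qc$patient_summary,
    patient_summary = patients,
    stress_scores = stress,
    stress_association = stress_assoc,
    metacell_meta = mc$meta,
    pathway_deltas = deltas,
    residual_tests = dplyr::select(resid, -"fit"),
    drug_assoc = glance(drugs),
    drug_assoc_full = drugs,
    spatial_patches = patches,
    confounder_check = confound,
    manifest = manifest
  ), class = "highmt_pipeline")

  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

write_pipeline <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("qc_summary", "patient_summary", "stress_scores",
            "metacell_meta", "pathway_deltas", "residual_tests",
            "spatial_patches", "confounder_check")
  for (nm in tabs) {
    readr::write_tsv(x[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(x$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(outdir)
}

#' @export
print.highmt_pipeline <- function(x, ...) {
  cat("<highmt_pipeline> seed", x$manifest$seed, "\n")
  cat("  cells kept:", x$manifest$n_cells_kept, "/",
      x$manifest$n_cells_simulated, "\n")
  cat("  patients:", nrow(x$patient_summary),
      sprintf("(%d case / %d control / %d excluded)",
              sum(x$patient_summary$status == "case"),
              sum(x$patient_summary$status == "control"),
              sum(x$patient_summary$status == "excluded")), "\n")
  cat("  metacells:", x$manifest$n_metacells, "\n")
  invisible(x)
}

#' Compare filtering strategies on one cohort
#'
#' Applies three quality-control strategies to the same cell table — (1)
#' mitochondria-agnostic QC, (2) the same QC plus a pctMT threshold filter,
#' and (3) an externally supplied keep-list — then scores a gene program on
#' each retained population and tests for distribution shifts between
#' strategies (two-sided Mann-Whitney on the per-cell scores). When a program
#' is coupled to HighMT status, the threshold strategy shifts its score
#' distribution relative to the pctMT-free one.
#'
#' @param t A `cell_table` (pre-QC).
#' @param program A [gene_set()] to score (e.g. a stress or state program).
#' @param keep_list Optional character vector of cell ids for the external
#'   strategy; defaults to the pctMT-free QC keep set (an external tool that
#'   agrees with the in-house QC).
#' @param threshold pctMT cutoff for the threshold strategy (default 15).
#' @param malignant_only Restrict scoring to malignant cells (default TRUE).
#' @param n_bins,ctrl_size,seed Scoring parameters.
#' @param ... Passed to [run_qc()].
#' @return List of class `highmt_strategy_comparison`: `scores` (per-cell
#'   scores per strategy), `tests` (pairwise Mann-Whitney results),
#'   `n_kept` (cells retained per strategy).
#' @export
compare_filtering_strategies <- function(t, program, keep_list = NULL,
                                         threshold = 15,
                                         malignant_only = TRUE,
                                         n_bins = 25, ctrl_size = 50,
                                         seed = 0, ...) {
  qc <- run_qc(t, ...)
  base <- add_pctmt(qc$filtered, threshold = threshold)
  strategies <- list(
    pctmt_free = base,
    threshold = pctmt_threshold_filter(base, threshold = threshold),
    keep_list = if (is.null(keep_list)) base else
      add_pctmt(filter_cells(t, keep_list), threshold = threshold)
  )
  scores <- purrr::imap_dfr(strategies, function(cells, strat) {
    if (malignant_only) {
      cells <- filter_cells(cells, cells$cell_meta$compartment == "malignant")
    }
    sc <- score_signature(normalize_cp10k_log1p(cells), program,
                          n_bins = n_bins, ctrl_size = ctrl_size, seed = seed)
    dplyr::mutate(sc, strategy = strat)
  })
  pairs <- utils::combn(names(strategies), 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    s1 <- scores$score[scores$strategy == pr[1]]
    s2 <- scores$score[scores$strategy == pr[2]]
    wt <- suppressWarnings(stats::wilcox.test(s1, s2, exact = FALSE))
    tibble::tibble(strategy1 = pr[1], strategy2 = pr[2],
                   n1 = length(s1), n2 = length(s2),
                   median_shift = stats::median(s1) - stats::median(s2),
                   u_stat = unname(wt$statistic), p_value = wt$p.value)
  })
  structure(list(
    scores = scores, tests = tests,
    n_kept = vapply(strategies, n_cells, numeric(1))
  ), class = "highmt_strategy_comparison")
}

#' @export
print.highmt_strategy_comparison <- function(x, ...) {
  cat("<highmt_strategy_comparison>\n")
  cat("  cells kept:", paste(names(x$n_kept), x$n_kept, sep = "=",
                             collapse = ", "), "\n")
  print(x$tests)
  invisible(x)
}
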