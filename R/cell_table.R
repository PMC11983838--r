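#' Construct a cell table
#'
#' A cell table couples a cells-by-genes count matrix with a per-cell metadata
#' tibble. It is the container every stage of the pipeline consumes: counts
#' stay a (sparse) matrix, while all per-cell quantities derived downstream
#' (total counts, genes detected, pctMT, HighMT status, signature scores) are
#' appended as columns of `cell_meta`.
#'
#' @param counts Non-negative integer matrix, cells in rows and genes in
#'   columns, with unique row (cell) and column (gene) names. A base matrix or
#'   any \pkg{Matrix} sparse class is accepted; it is stored as `dgCMatrix`.
#' @param cell_meta Data frame with one row per cell. Must contain `cell_id`
#'   matching the matrix row names, `patient_id`, and `compartment` (values
#'   `"malignant"` or `"TME"`). `cell_type` and a logical `doublet_flag`
#'   column are optional; `cell_type` defaults to `"unknown"`.
#'
#' @return An object of class `cell_table`: a list with elements `counts`
#'   (sparse matrix) and `cell_meta` (tibble, rows aligned with the matrix).
#' @export
as_sparse <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

cell_table <- function(counts, cell_meta) {
  counts <- as_sparse(counts)
  if (any(counts@x < 0)) {
    stop("`counts` must be non-negative.", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry cell (row) and gene (column) names.", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("Duplicate cell ids in `counts`.", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("Duplicate gene ids in `counts`.", call. = FALSE)
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  required <- c("cell_id", "patient_id", "compartment")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols) > 0) {
    stop("`cell_meta` is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  missing_cells <- setdiff(rownames(counts), cell_meta$cell_id)
  if (length(missing_cells) > 0) {
    stop("Metadata missing for cell(s): ",
         paste(utils::head(missing_cells, 5), collapse = ", "),
         if (length(missing_cells) > 5) " ...", call. = FALSE)
  }
  extra <- setdiff(cell_meta$cell_id, rownames(counts))
  if (length(extra) > 0) {
    warning(length(extra), " metadata row(s) without a matching cell dropped.",
            call. = FALSE)
  }
  cell_meta <- cell_meta[match(rownames(counts), cell_meta$cell_id), ]
  bad <- setdiff(unique(cell_meta$compartment), c("malignant", "TME"))
  if (length(bad) > 0) {
    stop("`compartment` must be 'malignant' or 'TME'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"cell_type" %in% names(cell_meta)) cell_meta$cell_type <- "unknown"
  structure(list(counts = counts, cell_meta = cell_meta), class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x$counts), " cells x ", ncol(x$counts), " genes, ",
      dplyr::n_distinct(x$cell_meta$patient_id), " patient(s)\n", sep = "")
  print(x$cell_meta, n = 5)
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$counts)

#' Number of cells / genes in a cell table
#' @param t A `cell_table`.
#' @return Integer count.
#' @export
n_cells <- function(t) nrow(t$counts)

#' @rdname n_cells
#' @export
n_genes_total <- function(t) ncol(t$counts)

#' Subset a cell table to a set of cells
#'
#' @param t A `cell_table`.
#' @param cells Logical vector over cells, or character vector of cell ids.
#' @return A `cell_table` restricted to the selected cells.
#' @export
filter_cells <- function(t, cells) {
  if (is.logical(cells)) {
    stopifnot(length(cells) == nrow(t$counts))
    keep <- which(cells)
  } else {
    keep <- match(cells, rownames(t$counts))
    if (anyNA(keep)) stop("Unknown cell id(s).", call. = FALSE)
  }
  structure(list(counts = t$counts[keep, , drop = FALSE],
                 cell_meta = t$cell_meta[keep, ]),
            class = "cell_table")
}

#' Read a count matrix plus metadata into a cell table
#'
#' Two on-disk layouts are supported. A directory is read in the 10x
#' convention: `matrix.mtx` (MatrixMarket triplet, genes in rows, cells in
#' columns, 1-based indices), `barcodes.tsv` (one cell id per line) and
#' `features.tsv` (gene id in the first column). A single file is read as a
#' dense TSV with cells in rows: first column `cell_id`, remaining columns one
#' per gene. Both layouts yield identical cell tables on the same data.
#'
#' @param path Directory (sparse 10x layout) or TSV file (dense layout).
#' @param meta_path TSV with columns `cell_id`, `patient_id`, `compartment`
#'   and optionally `cell_type`, `doublet_flag`.
#' @return A [cell_table()].
#' @export
read_counts <- function(path, meta_path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    bc <- file.path(path, "barcodes.tsv")
    ft <- file.path(path, "features.tsv")
    for (f in c(mtx, bc, ft)) {
      if (!file.exists(f)) stop("Missing file: ", f, call. = FALSE)
    }
    m <- Matrix::readMM(mtx)
    barcodes <- readr::read_tsv(bc, col_names = FALSE, show_col_types = FALSE)[[1]]
    features <- readr::read_tsv(ft, col_names = FALSE, show_col_types = FALSE)[[1]]
    if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
      stop("Matrix dimensions (", nrow(m), " x ", ncol(m),
           ") do not match features (", length(features),
           ") x barcodes (", length(barcodes), ").", call. = FALSE)
    }
    counts <- Matrix::t(m)
    dimnames(counts) <- list(barcodes, features)
  } else {
    dense <- readr::read_tsv(path, show_col_types = FALSE)
    if (names(dense)[1] != "cell_id") {
      stop("Dense TSV must have `cell_id` as its first column.", call. = FALSE)
    }
    counts <- as.matrix(dense[, -1, drop = FALSE])
    rownames(counts) <- dense$cell_id
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  if (!"compartment" %in% names(meta)) {
    stop("Metadata file lacks a `compartment` column.", call. = FALSE)
  }
  cell_table(counts, meta)
}

#' Write a cell table to disk (10x sparse layout plus metadata TSV)
#'
#' Inverse of [read_counts()]: `write_cell_table` followed by `read_counts`
#' reproduces counts and metadata exactly.
#'
#' @param t A `cell_table`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cell_table <- function(t, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(t$counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(t$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(t$counts), file.path(dir, "features.tsv"))
  readr::write_tsv(t$cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Construct a gene set
#'
#' @param name Gene-set name.
#' @param genes Character vector of gene identifiers; duplicates are removed.
#'   Matching against expression data is exact and case-sensitive.
#' @param category Optional category label (e.g. a xenobiotic-metabolism phase
#'   or drug-target class).
#' @return An object of class `gene_set` with fields `name`, `genes`,
#'   `category`.
#' @export
gene_set <- function(name, genes, category = NA_character_) {
  genes <- unique(as.character(genes))
  genes <- genes[!is.na(genes) & nzchar(genes)]
  if (length(genes) == 0) stop("Gene set '", name, "' is empty.", call. = FALSE)
  structure(list(name = as.character(name), genes = genes,
                 category = category),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

as_gene_vector <- function(x) {
  if (inherits(x, "gene_set")) x$genes else unique(as.character(x))
}

#' Read gene sets from a GMT file
#'
#' One gene set per line: name, description, then one gene per field,
#' tab-separated. Duplicate genes within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set()] objects, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("Malformed GMT line ", i, ": expected >= 3 tab-separated fields.",
           call. = FALSE)
    }
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)])
  }
  stats::setNames(sets, vapply(sets, function(s) s$name, character(1)))
}

#' Write gene sets to a GMT file
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Library-size normalization: counts per 10k, then log1p
#'
#' Each cell's counts are scaled to 10,000 total and transformed with the
#' natural `log(1 + x)`. A cell with total raw count `T` maps gene count `c`
#' to `log(1 + 10000 * c / T)`, so the result is invariant to per-cell scaling
#' of the raw counts. Zeros stay zero, so sparsity is preserved.
#'
#' @param t A `cell_table`, or a bare cells-by-genes count matrix.
#' @return Sparse cells-by-genes matrix of log1p(CP10K) values.
#' @export
normalize_cp10k_log1p <- function(t) {
  counts <- if (inherits(t, "cell_table")) t$counts else as_sparse(t)
  totals <- Matrix::rowSums(counts)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    stop("Cell(s) with zero total counts (run QC first): ",
         paste(utils::head(rownames(counts)[zero], 5), collapse = ", "),
         call. = FALSE)
  }
  scaled <- Matrix::Diagonal(x = 10000 / totals) %*% counts
  out <- scaled
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}
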