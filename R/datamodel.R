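# Core data container and I/O for the standard formats used throughout the
# package: MatrixMarket / dense count matrices with cell and gene annotation
# tables, GMT gene sets, and survival tables.

REQUIRED_CELL_COLS <- c("tumor_model", "tissue", "platform", "metastatic_potential")
SENTINEL <- "unknown"

#' Construct an expression dataset
#'
#' The universal carrier between pipeline stages: an integer count matrix
#' (cells x genes), a deterministic log-normalized layer, and cell/gene
#' annotation tables. Missing optional cell annotations are filled with the
#' sentinel label `"unknown"`; duplicate gene symbols are made unique by
#' suffixing (and reported with a message).
#'
#' @param counts Integer matrix or sparse `Matrix`, cells in rows, genes in
#'   columns. Entries must be non-negative and integral.
#' @param cell_meta `data.frame` with one row per cell. Recognised columns:
#'   `cell_id`, `tumor_model`, `tissue` (`primary`/`metastasis`), `platform`
#'   (`plate`/`droplet`), `metastatic_potential` (`low`/`moderate`/`high`),
#'   plus any extra columns (e.g. subtype labels).
#' @param gene_meta `data.frame` with one row per gene. Recognised columns:
#'   `symbol`, `chromosome`, `start` (1-based bp).
#' @param scale Library-size scale factor for normalization (default 1e4,
#'   i.e. counts-per-10k).
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `counts`, `normalized`, `cell_meta`, `gene_meta`.
#' @export
expression_dataset <- function(counts, cell_meta = NULL, gene_meta = NULL, scale = 1e4) {
  counts <- as_count_matrix(counts)
  n_cells <- nrow(counts)
  n_genes <- ncol(counts)

  if (is.null(cell_meta)) {
    cell_meta <- data.frame(
      cell_id = rownames(counts) %||% default_ids("cell", n_cells),
      stringsAsFactors = FALSE)
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cell_meta)) {
    cell_meta$cell_id <- rownames(counts) %||% default_ids("cell", n_cells)
  }
  if (nrow(cell_meta) != n_cells) {
    stop(sprintf("cell_meta has %d rows but counts has %d cells", nrow(cell_meta), n_cells),
         call. = FALSE)
  }
  for (col in REQUIRED_CELL_COLS) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- SENTINEL
  }

  if (is.null(gene_meta)) {
    gene_meta <- data.frame(symbol = colnames(counts) %||% default_ids("gene", n_genes))
  }
  gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  if (!"symbol" %in% names(gene_meta)) {
    gene_meta$symbol <- colnames(counts) %||% default_ids("gene", n_genes)
  }
  if (nrow(gene_meta) != n_genes) {
    stop(sprintf("gene_meta has %d rows but counts has %d genes", nrow(gene_meta), n_genes),
         call. = FALSE)
  }
  if (anyDuplicated(gene_meta$symbol)) {
    dups <- unique(gene_meta$symbol[duplicated(gene_meta$symbol)])
    message(sprintf("made %d duplicated gene symbol(s) unique by suffixing: %s",
                    length(dups), paste(utils::head(dups, 5), collapse = ", ")))
    gene_meta$symbol <- make.unique(gene_meta$symbol)
  }
  if (!"chromosome" %in% names(gene_meta)) gene_meta$chromosome <- SENTINEL
  gene_meta$chromosome <- as.character(gene_meta$chromosome)
  if (!"start" %in% names(gene_meta)) gene_meta$start <- NA_integer_

  rownames(counts) <- cell_meta$cell_id
  colnames(counts) <- gene_meta$symbol
  rownames(cell_meta) <- cell_meta$cell_id
  rownames(gene_meta) <- gene_meta$symbol

  ds <- structure(
    list(counts = counts, normalized = NULL, cell_meta = cell_meta,
         gene_meta = gene_meta, scale = scale),
    class = "ExpressionDataset"
  )
  normalize(ds, scale = scale, allow_empty = TRUE)
}

as_count_matrix <- function(counts) {
  if (inherits(counts, "Matrix")) {
    counts <- methods::as(counts, "CsparseMatrix")
    vals <- counts@x
  } else {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    vals <- counts
  }
  if (any(vals < 0)) stop("counts must be non-negative", call. = FALSE)
  off <- abs(vals - round(vals)) > 1e-8
  if (any(off)) {
    stop(sprintf("counts must be integral; %d non-integer entries (first offending value: %g)",
                 sum(off), vals[off][1]), call. = FALSE)
  }
  counts
}

default_ids <- function(prefix, n) sprintf("%s%05d", prefix, seq_len(n))

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  platforms: %s\n", paste(unique(x$cell_meta$platform), collapse = ", ")))
  cat(sprintf("  tissues:   %s\n", paste(unique(x$cell_meta$tissue), collapse = ", ")))
  cat(sprintf("  models:    %d\n", length(unique(x$cell_meta$tumor_model))))
  invisible(x)
}

#' Recompute the log-normalized expression layer
#'
#' `normalized[c, g] = log2(1 + counts[c, g] * scale / library_size(c))` where
#' the library size is the cell's total count. Deterministic in the counts, so
#' recomputation is bit-identical.
#'
#' @param dataset An `ExpressionDataset`.
#' @param scale Scale factor (default 1e4).
#' @param allow_empty Tolerate zero-library cells (their normalized rows stay
#'   zero, with a warning). Default `FALSE`: such cells are a validation
#'   error listing the offending cell ids.
#' @return The dataset with its `normalized` layer (dense matrix) recomputed.
#' @export
normalize <- function(dataset, scale = 1e4, allow_empty = FALSE) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  assert_scalar_number(scale, "scale", lower = 1e-12)
  counts <- dataset$counts
  lib <- if (inherits(counts, "Matrix")) Matrix::rowSums(counts) else rowSums(counts)
  if (any(lib <= 0)) {
    bad <- rownames(counts)[lib <= 0]
    msg <- sprintf("cells with zero library size: %s", paste(bad, collapse = ", "))
    if (!allow_empty) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    lib[lib <= 0] <- 1  # rows are all-zero, so the divisor is immaterial
  }
  dense <- as.matrix(counts)
  dataset$normalized <- log2(1 + dense * (scale / lib))
  dataset$scale <- scale
  dataset
}

#' Mean normalized expression per cell group (pseudobulk)
#'
#' @param dataset An `ExpressionDataset`.
#' @param group_keys Character vector of `cell_meta` column names to group by.
#' @return `data.frame` with the grouping columns, `n_cells`, and one column
#'   per gene holding the group mean of the normalized layer.
#' @export
pseudobulk <- function(dataset, group_keys) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  missing_keys <- setdiff(group_keys, names(dataset$cell_meta))
  if (length(group_keys) == 0L || length(missing_keys) > 0L) {
    stop(sprintf("group_keys must name cell_meta columns; unknown: %s",
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(dataset$cell_meta[group_keys], drop = TRUE, lex.order = TRUE, sep = "\r")
  if (nlevels(key) == 0L) stop("empty group set", call. = FALSE)
  groups <- levels(key)
  mat <- t(vapply(groups, function(g) {
    colMeans(dataset$normalized[key == g, , drop = FALSE])
  }, numeric(ncol(dataset$normalized))))
  parts <- do.call(rbind, strsplit(groups, "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- group_keys
  out$n_cells <- as.integer(table(key)[groups])
  cbind(out, as.data.frame(mat, check.names = FALSE))
}

#' Read a count matrix with annotations
#'
#' @param matrix_path Path to a MatrixMarket coordinate file (genes x cells,
#'   the conventional orientation for single-cell triplet exports) or a dense
#'   delimited table (cells in rows, header of gene symbols).
#' @param cells_path TSV of cell annotations (column `cell_id` plus optional
#'   annotation columns); row order matches matrix cells.
#' @param genes_path TSV of gene annotations (column `symbol` plus optional
#'   `chromosome`, `start`); row order matches matrix genes.
#' @param dialect `"mtx"` or `"dense"`.
#' @param scale Normalization scale factor.
#' @return An `ExpressionDataset`.
#' @export
read_counts <- function(matrix_path, cells_path, genes_path,
                        dialect = c("mtx", "dense"), scale = 1e4) {
  dialect <- match.arg(dialect)
  cell_meta <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  gene_meta <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  if (dialect == "mtx") {
    m <- Matrix::readMM(matrix_path)   # genes x cells on disk
    counts <- Matrix::t(m)
  } else {
    tab <- utils::read.delim(matrix_path, check.names = FALSE,
                             sep = if (grepl("\\.csv$", matrix_path)) "," else "\t")
    counts <- as.matrix(tab)
  }
  if (nrow(cell_meta) != nrow(counts)) {
    stop(sprintf("annotation/matrix dimension mismatch: %d cell rows vs %d matrix cells",
                 nrow(cell_meta), nrow(counts)), call. = FALSE)
  }
  if (nrow(gene_meta) != ncol(counts)) {
    stop(sprintf("annotation/matrix dimension mismatch: %d gene rows vs %d matrix genes",
                 nrow(gene_meta), ncol(counts)), call. = FALSE)
  }
  expression_dataset(counts, cell_meta, gene_meta, scale = scale)
}

#' Write a dataset as MTX triplet plus annotation TSVs
#'
#' @param dataset An `ExpressionDataset`.
#' @param dir Output directory (created if absent). Writes `matrix.mtx`
#'   (genes x cells), `cells.tsv`, `genes.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_counts <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "cells.tsv", "genes.tsv"))
  m <- methods::as(methods::as(Matrix::t(Matrix::Matrix(as.matrix(dataset$counts),
                                                        sparse = TRUE)), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::writeMM(m, paths[1])
  utils::write.table(dataset$cell_meta, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$gene_meta, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read gene signatures from a GMT file
#'
#' One signature per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. The
#' description field is discarded; duplicate symbols within a line are
#' deduplicated with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate symbols in gene set '%s' deduplicated", fields[1]),
              call. = FALSE)
      genes <- unique(genes)
    }
    out[[fields[1]]] <- genes
  }
  out
}

#' Write gene signatures to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' CSV with columns `time` (non-negative, months), `event` (0 censored /
#' 1 event), `subtype`, followed by one column per gene (expression values)
#' or a precomputed score column.
#'
#' @param path CSV path.
#' @return `data.frame` validated as a survival cohort.
#' @export
read_survival <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(tab)
}

validate_cohort <- function(tab) {
  need <- c("time", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("survival table missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(tab$time)) || any(tab$time < 0)) {
    stop("survival times must be finite and >= 0", call. = FALSE)
  }
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  if (!"subtype" %in% names(tab)) tab$subtype <- SENTINEL
  tab
}
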