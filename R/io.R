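#' Read an expression matrix from a Matrix Market bundle or dense TSV
#'
#' The bundle form is the usual `matrix.mtx` (genes x cells, 1-based
#' coordinate entries on disk) plus one-identifier-per-line `genes.tsv` and
#' `cells.tsv`. The dense form is a headered TSV with the gene identifier in
#' the first column and one column per cell. Row and column order is
#' preserved from the files.
#'
#' @param matrix_path Path to the `.mtx` file (bundle form).
#' @param genes_path,cells_path Paths to the identifier lists (bundle form).
#' @param dense_tsv_path Path to a dense TSV (alternative to the bundle).
#' @param dataset_id Dataset label attached to the matrix.
#' @return An [expression_matrix()].
#' @export
read_expression_bundle <- function(matrix_path = NULL, genes_path = NULL,
                                   cells_path = NULL, dense_tsv_path = NULL,
                                   dataset_id = "dataset") {
  if (!is.null(dense_tsv_path)) {
    tab <- readr::read_tsv(dense_tsv_path, show_col_types = FALSE,
                           progress = FALSE)
    genes <- as.character(tab[[1]])
    counts <- as.matrix(tab[-1])
    rownames(counts) <- genes
    return(expression_matrix(counts, dataset_id = dataset_id))
  }
  for (p in c(matrix_path, genes_path, cells_path)) {
    if (!file.exists(p)) abort_format(paste("file not found:", p))
  }
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) abort_format(conditionMessage(e)))
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort_format(sprintf(
      "matrix is %d x %d but %d gene and %d cell identifiers were supplied",
      nrow(m), ncol(m), length(genes), length(cells)))
  }
  counts <- as.matrix(m)
  dimnames(counts) <- list(genes, cells)
  expression_matrix(counts, dataset_id = dataset_id)
}

#' Write an expression matrix as a Matrix Market bundle
#'
#' @param matrix An [expression_matrix()].
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv` and `cells.tsv`.
#' @return Invisibly, the directory.
#' @export
write_expression_bundle <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(unclass(matrix), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(matrix), file.path(dir, "genes.tsv"))
  writeLines(colnames(matrix), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' Duplicate genes within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (possibly empty); descriptions are
#'   kept in the `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) {
    abort_format(sprintf("GMT line %d has fewer than 3 fields",
                         which(short)[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  structure(sets,
            descriptions = setNames(
              vapply(fields, `[[`, character(1), 2), names(sets)))
}

#' Write gene sets to a GMT file in canonical order
#'
#' Genes within each set are sorted (C locale) so that write/read round-trips
#' are byte-identical.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @return Invisibly, the path.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    genes <- sort(unique(sets[[nm]]), method = "radix")
    paste(c(nm, descriptions[[nm]] %||% "na", genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog map TSV
#'
#' Headered TSV with columns `gene_a` and `gene_b`; mapping degrees are
#' computed on load.
#'
#' @param path Path to the TSV.
#' @return An [ortholog_map()] tibble.
#' @export
read_ortholog_map <- function(path) {
  ortholog_map(readr::read_tsv(path, show_col_types = FALSE,
                               progress = FALSE))
}

#' Write an ortholog map TSV
#' @param map An [ortholog_map()] tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ortholog_map <- function(map, path) {
  readr::write_tsv(map[c("gene_a", "gene_b")], path, progress = FALSE)
  invisible(path)
}

#' Read a per-cell CNV segment table
#'
#' Headered TSV with columns `cell_id`, `chrom`, `start`, `end`, `p1`..`p6`;
#' coordinates are BED-convention 0-based half-open on disk and in memory.
#'
#' @param path Path to the TSV.
#' @return A [cnv_segment_table()] tibble.
#' @export
read_cnv_segments <- function(path) {
  cnv_segment_table(readr::read_tsv(path, show_col_types = FALSE,
                                    progress = FALSE))
}

#' Write a per-cell CNV segment table
#' @param segments A [cnv_segment_table()] tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cnv_segments <- function(segments, path) {
  readr::write_tsv(
    segments[c("cell_id", "chrom", "start", "end", paste0("p", 1:6))],
    path, progress = FALSE)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' Headered TSV with columns `sample_id`, `risk_group`, `age_months`,
#' `efs_days`, `efs_event`.
#'
#' @param path Path to the TSV.
#' @return A [clinical_table()] tibble.
#' @export
read_clinical_table <- function(path) {
  clinical_table(readr::read_tsv(path, show_col_types = FALSE,
                                 progress = FALSE))
}

#' Write a clinical covariate table
#' @param clinical A [clinical_table()] tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- clinical
  out$efs_event <- as.integer(out$efs_event)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a cluster assignment TSV
#'
#' Headered TSV with columns `cell_id`, `cluster` and optionally `sample_id`
#' plus grouping columns.
#'
#' @param path Path to the TSV.
#' @return A [cluster_assignment()] tibble.
#' @export
read_cluster_assignment <- function(path) {
  cluster_assignment(readr::read_tsv(path, show_col_types = FALSE,
                                     progress = FALSE))
}

#' Write a cluster assignment TSV
#' @param assignment A [cluster_assignment()] tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cluster_assignment <- function(assignment, path) {
  readr::write_tsv(assignment, path, progress = FALSE)
  invisible(path)
}
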