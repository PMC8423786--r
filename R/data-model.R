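#' Construct a validated expression count matrix
#'
#' Expression matrices are plain numeric matrices with genes as rows and cells
#' as columns, carrying a `dataset_id` attribute. Counts must be finite,
#' non-negative integers and gene/cell identifiers must be unique non-empty
#' strings. Identifiers are opaque and matched case-sensitively throughout the
#' package, so human and mouse symbol conventions never collide silently.
#'
#' @param counts Numeric matrix, genes x cells, with rownames (gene ids) and
#'   colnames (cell ids).
#' @param dataset_id Single string naming the dataset of origin.
#' @return The validated matrix with class `expr_matrix` and attribute
#'   `dataset_id`.
#' @export
expression_matrix <- function(counts, dataset_id = "dataset") {
  counts <- as.matrix(counts)
  validate_ids(rownames(counts), "gene")
  validate_ids(colnames(counts), "cell")
  if (nrow(counts) != length(rownames(counts)) ||
      ncol(counts) != length(colnames(counts))) {
    abort_format("matrix dimensions do not match identifier list lengths")
  }
  if (any(!is.finite(counts))) {
    abort_validation("counts must be finite")
  }
  if (any(counts < 0)) {
    abort_validation("counts must be non-negative")
  }
  if (any(counts != round(counts))) {
    abort_validation("counts must be integers")
  }
  structure(counts, dataset_id = dataset_id,
            class = c("expr_matrix", class(counts)))
}

validate_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    abort_validation(sprintf("%s identifiers must be non-empty strings", what))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort_validation(
      sprintf("duplicate %s identifiers: %s", what,
              paste(utils::head(dup, 5), collapse = ", ")))
  }
  invisible(ids)
}

#' Construct a normalized expression matrix
#'
#' @param values Numeric matrix, genes x cells, with dimnames.
#' @param transform One of `"cp10k"` (counts per 10,000), `"log1p_cp10k"`
#'   (natural log of CP10K + 1) or `"standardized"` (externally supplied
#'   standardized expression magnitudes).
#' @param dataset_id Single string naming the dataset of origin.
#' @return The matrix with class `norm_matrix` and attributes `transform` and
#'   `dataset_id`.
#' @export
normalized_matrix <- function(values,
                              transform = c("cp10k", "log1p_cp10k",
                                            "standardized"),
                              dataset_id = "dataset") {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  validate_ids(rownames(values), "gene")
  validate_ids(colnames(values), "cell")
  if (any(!is.finite(values))) {
    abort_validation("normalized values must be finite")
  }
  if (transform == "cp10k") {
    tot <- colSums(values)
    bad <- tot > 0 & abs(tot - 1e4) > 1e-6
    if (any(bad)) {
      abort_validation("cp10k columns must sum to 10,000 for nonzero cells")
    }
  }
  structure(values, transform = transform, dataset_id = dataset_id,
            class = c("norm_matrix", class(values)))
}

norm_transform <- function(x) attr(x, "transform") %||% "unknown"

#' Validate a cluster assignment table
#'
#' A cluster assignment is a tibble with one row per cell: `cell_id`,
#' `cluster` (non-empty label), and optionally `sample_id` plus per-sample
#' grouping columns (risk group, stage, ...). When a matrix is supplied, every
#' one of its cells must be assigned exactly once.
#'
#' @param assignment Data frame with columns `cell_id` and `cluster`.
#' @param matrix Optional expression or normalized matrix whose cells the
#'   assignment must cover.
#' @return The assignment as a tibble, invisibly validated.
#' @export
cluster_assignment <- function(assignment, matrix = NULL) {
  assignment <- as_tibble(assignment)
  need <- c("cell_id", "cluster")
  missing_cols <- setdiff(need, names(assignment))
  if (length(missing_cols) > 0) {
    abort_format(paste("assignment lacks columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  validate_ids(assignment$cell_id, "cell")
  if (any(is.na(assignment$cluster)) || any(!nzchar(assignment$cluster))) {
    abort_validation("cluster labels must be non-empty")
  }
  if (!is.null(matrix)) {
    missing_cells <- setdiff(colnames(matrix), assignment$cell_id)
    if (length(missing_cells) > 0) {
      abort_validation(
        sprintf("%d matrix cells lack a cluster label", length(missing_cells)))
    }
  }
  assignment
}

#' Validate an ortholog map and compute mapping degrees
#'
#' @param pairs Data frame with character columns `gene_a` and `gene_b`, one
#'   row per ortholog pair. Duplicated rows are dropped.
#' @return Tibble with columns `gene_a`, `gene_b`, `degree_a` (number of pairs
#'   the `gene_a` member participates in) and `degree_b`.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("gene_a", "gene_b") %in% names(pairs))) {
    abort_format("ortholog map needs columns gene_a and gene_b")
  }
  pairs <- distinct(pairs, .data$gene_a, .data$gene_b)
  if (any(is.na(pairs$gene_a)) || any(is.na(pairs$gene_b))) {
    abort_validation("ortholog pairs must not contain missing genes")
  }
  pairs %>%
    group_by(.data$gene_a) %>% mutate(degree_a = dplyr::n()) %>%
    group_by(.data$gene_b) %>% mutate(degree_b = dplyr::n()) %>%
    ungroup()
}

#' Validate a per-cell CNV segment table
#'
#' Each row is one segment called in one cell, with a probability vector over
#' the six copy-number states (1 = complete loss, 2 = single-copy loss,
#' 3 = neutral, 4 = one extra copy, 5 = two extra copies, 6 = more than two
#' extra copies). Coordinates are 0-based half-open (BED convention). The
#' most likely state and the rearrangement likelihood (total probability mass
#' off the neutral state) are derived columns.
#'
#' @param segments Data frame with columns `cell_id`, `chrom`, `start`, `end`
#'   and `p1`..`p6`.
#' @return Tibble with added `most_likely_state` and
#'   `rearrangement_likelihood` columns.
#' @export
cnv_segment_table <- function(segments) {
  segments <- as_tibble(segments)
  pcols <- paste0("p", 1:6)
  need <- c("cell_id", "chrom", "start", "end", pcols)
  missing_cols <- setdiff(need, names(segments))
  if (length(missing_cols) > 0) {
    abort_format(paste("CNV table lacks columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  if (any(segments$start >= segments$end)) {
    abort_validation("CNV segments require start < end (half-open)")
  }
  probs <- as.matrix(segments[pcols])
  if (any(probs < 0)) abort_validation("state probabilities must be >= 0")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    abort_validation("state probabilities must sum to 1 (tolerance 1e-6)")
  }
  segments$most_likely_state <- max.col(probs, ties.method = "first")
  segments$rearrangement_likelihood <- 1 - probs[, 3]
  segments
}

#' Validate a clinical covariate table
#'
#' @param clinical Data frame with columns `sample_id`, `risk_group` (one of
#'   `"high"`, `"intermediate"`, `"low"`), `age_months`, `efs_days` and
#'   `efs_event` (logical or 0/1). Covariate columns a stage does not use may
#'   be `NA`; stages fail fast when a needed covariate is missing.
#' @return The table as a tibble with `efs_event` coerced to logical.
#' @export
clinical_table <- function(clinical) {
  clinical <- as_tibble(clinical)
  need <- c("sample_id", "risk_group", "age_months", "efs_days", "efs_event")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols) > 0) {
    abort_format(paste("clinical table lacks columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  validate_ids(clinical$sample_id, "sample")
  ok_rg <- is.na(clinical$risk_group) |
    clinical$risk_group %in% c("high", "intermediate", "low")
  if (!all(ok_rg)) {
    abort_validation("risk_group must be high, intermediate or low")
  }
  if (any(clinical$efs_days < 0, na.rm = TRUE) ||
      any(clinical$age_months < 0, na.rm = TRUE)) {
    abort_validation("times and ages must be >= 0")
  }
  clinical$efs_event <- as.logical(clinical$efs_event)
  clinical
}

#' Genomic region of interest for CNV enrichment
#'
#' @param name Region label, e.g. `"17q_gain"`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @param expected_direction `"gain"` or `"loss"`.
#' @return One-row tibble describing the region.
#' @export
region_query <- function(name, chrom, start, end,
                         expected_direction = c("gain", "loss")) {
  expected_direction <- match.arg(expected_direction)
  if (start >= end || start < 0) {
    abort_config("region requires 0 <= start < end")
  }
  tibble(name = name, chrom = chrom, start = start, end = end,
         expected_direction = expected_direction)
}
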