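#' Filter cells by number of detected genes
#'
#' A gene counts as detected in a cell when its count is > 0. Cells are kept
#' when their detected-gene count lies in `[min_genes, max_genes]`, inclusive.
#' Presets used for the study tissues: human adrenal gland (3000, 9000);
#' neuroblastoma and mouse adrenal gland (2000, 8000).
#'
#' @param matrix An [expression_matrix()].
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @return The column-subset matrix; warns (not errors) when no cell survives.
#' @export
filter_cells_by_detected_genes <- function(matrix, min_genes, max_genes) {
  if (min_genes > max_genes) abort_config("min_genes must be <= max_genes")
  detected <- colSums(matrix > 0)
  keep <- detected >= min_genes & detected <= max_genes
  if (!any(keep)) warning("all cells removed by detected-gene filter")
  subset_matrix(matrix, cols = keep)
}

#' QC bounds on detected genes for the study tissue presets
#'
#' @param preset `"human_ag"` (human adrenal gland) or `"nb_mouse"`
#'   (neuroblastoma and mouse adrenal gland).
#' @return Named numeric vector with `min_genes` and `max_genes`.
#' @export
detected_gene_bounds <- function(preset = c("human_ag", "nb_mouse")) {
  preset <- match.arg(preset)
  switch(preset,
         human_ag = c(min_genes = 3000, max_genes = 9000),
         nb_mouse = c(min_genes = 2000, max_genes = 8000))
}

#' Filter genes by number of expressing cells
#'
#' Default semantics are strict ("expressed in more than `min_cells` cells"):
#' a gene present in exactly `min_cells` cells is removed.
#'
#' @param matrix An [expression_matrix()] or [normalized_matrix()].
#' @param min_cells Cell-count threshold (default 5).
#' @param strict If `TRUE` (default) keep genes with nonzero counts in
#'   strictly more than `min_cells` cells; if `FALSE`, in at least that many.
#' @return The row-subset matrix.
#' @export
filter_genes_by_cells <- function(matrix, min_cells = 5, strict = TRUE) {
  if (min_cells < 0) abort_config("min_cells must be >= 0")
  n_cells <- rowSums(matrix > 0)
  keep <- if (strict) n_cells > min_cells else n_cells >= min_cells
  subset_matrix(matrix, rows = keep)
}

subset_matrix <- function(m, rows = NULL, cols = NULL) {
  cls <- class(m)
  ds <- attr(m, "dataset_id")
  tr <- attr(m, "transform")
  out <- unclass(m)
  if (!is.null(rows)) out <- out[rows, , drop = FALSE]
  if (!is.null(cols)) out <- out[, cols, drop = FALSE]
  attr(out, "dataset_id") <- ds
  if (!is.null(tr)) attr(out, "transform") <- tr
  class(out) <- cls
  out
}

#' Library-size normalization to counts per 10,000
#'
#' Each cell's counts are scaled so the cell totals 10,000 (CP10K). Cells with
#' zero total counts are excluded with a warning (their scale factor is
#' undefined). With `log_transform = TRUE` the natural logarithm of
#' (CP10K + 1) is returned.
#'
#' @param matrix An [expression_matrix()].
#' @param log_transform Apply `log(x + 1)` after scaling (default `FALSE`).
#' @return A [normalized_matrix()] tagged `"cp10k"` or `"log1p_cp10k"`.
#' @export
cp10k_normalize <- function(matrix, log_transform = FALSE) {
  tot <- colSums(matrix)
  if (any(tot == 0)) {
    warning(sprintf("%d zero-count cells excluded from normalization",
                    sum(tot == 0)))
    matrix <- subset_matrix(matrix, cols = tot > 0)
    tot <- tot[tot > 0]
  }
  values <- sweep(unclass(matrix), 2, tot / 1e4, "/")
  if (log_transform) values <- log1p(values)
  normalized_matrix(values,
                    transform = if (log_transform) "log1p_cp10k" else "cp10k",
                    dataset_id = attr(matrix, "dataset_id") %||% "dataset")
}

#' Welch's two-sample t-test
#'
#' Two-sided Welch test with Satterthwaite degrees of freedom. Degenerate
#' zero-variance inputs follow a deterministic convention: statistic 0 /
#' p = 1 when both groups are constant with equal means, and p = 0 when both
#' are constant with different means.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return One-row tibble with `statistic`, `df` and `p_value`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("each group needs at least 2 values",
                 class = "sigshare_undefined_test_error")
  }
  res <- welch_rows(matrix(x, nrow = 1), matrix(y, nrow = 1))
  tibble(statistic = res$statistic, df = res$df, p_value = res$p_value)
}

# Vectorized Welch test over matrix rows (genes). x, y: genes x cells.
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  zero_var <- se2 == 0
  if (any(zero_var)) {
    same <- zero_var & (mx == my)
    stat[same] <- 0; df[same] <- NA_real_; p[same] <- 1
    diffm <- zero_var & (mx != my)
    stat[diffm] <- sign(mx - my)[diffm] * Inf
    df[diffm] <- NA_real_; p[diffm] <- 0
  }
  list(mean_x = unname(mx), mean_y = unname(my), statistic = unname(stat),
       df = unname(df), p_value = unname(p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped at 1, input order preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

split_by_cluster <- function(norm_matrix, assignment) {
  assignment <- cluster_assignment(assignment, matrix = norm_matrix)
  split(assignment$cell_id, assignment$cluster)
}

#' Genes significantly upregulated in a cluster (definition A)
#'
#' For every gene, the cells of `cluster` are compared against the pooled
#' cells of all other clusters with a Welch t-test on the normalized matrix.
#' A gene is upregulated when its cluster mean strictly exceeds the pooled
#' mean (ties fail) and the BH-adjusted p-value, with the family spanning all
#' genes tested for this cluster, is below `fdr`.
#'
#' @param norm_matrix A [normalized_matrix()] (default analysis uses
#'   log1p-CP10K; externally standardized magnitudes are equally accepted).
#' @param assignment A [cluster_assignment()] covering the matrix cells.
#' @param cluster Cluster label to test.
#' @param fdr BH threshold (default 0.01).
#' @return Tibble with one row per gene: means, Welch statistic, `p_value`,
#'   `q_value` and logical `upregulated`.
#' @export
upregulated_genes <- function(norm_matrix, assignment, cluster, fdr = 0.01) {
  cells <- split_by_cluster(norm_matrix, assignment)
  if (!cluster %in% names(cells)) {
    abort_validation(sprintf("cluster '%s' not present in assignment", cluster))
  }
  if (length(cells) < 2) {
    abort_validation("need at least two clusters to define upregulation")
  }
  in_cells <- cells[[cluster]]
  out_cells <- setdiff(unlist(cells), in_cells)
  x <- unclass(norm_matrix)[, in_cells, drop = FALSE]
  y <- unclass(norm_matrix)[, out_cells, drop = FALSE]
  res <- welch_rows(x, y)
  tibble(gene = rownames(norm_matrix),
         cluster = cluster,
         mean_in = res$mean_x,
         mean_out = res$mean_y,
         statistic = res$statistic,
         p_value = res$p_value,
         q_value = bh_adjust(res$p_value)) %>%
    mutate(upregulated = .data$mean_in > .data$mean_out &
             .data$q_value < fdr)
}

#' Specific gene signature of a cluster (definition B)
#'
#' A gene belongs to the specific signature of `cluster` when, for every
#' other cluster taken one at a time, its mean in `cluster` strictly exceeds
#' its mean in that cluster and the pairwise Welch test is significant after
#' BH correction. The default correction family spans all genes within each
#' pairwise comparison (`family = "per_comparison"`); `family = "global"`
#' pools p-values of all comparisons into one family.
#'
#' @inheritParams upregulated_genes
#' @param family BH family: `"per_comparison"` (default) or `"global"`.
#' @return Tibble with one row per gene x other-cluster comparison plus a
#'   logical `in_signature` column (constant per gene); the signature gene
#'   set is in attribute `"signature"`.
#' @export
specific_signature <- function(norm_matrix, assignment, cluster, fdr = 0.01,
                               family = c("per_comparison", "global")) {
  family <- match.arg(family)
  cells <- split_by_cluster(norm_matrix, assignment)
  if (!cluster %in% names(cells)) {
    abort_validation(sprintf("cluster '%s' not present in assignment", cluster))
  }
  others <- setdiff(names(cells), cluster)
  if (length(others) == 0) {
    abort_validation("need at least two clusters to define a signature")
  }
  x <- unclass(norm_matrix)[, cells[[cluster]], drop = FALSE]
  per <- purrr::map(others, function(k) {
    y <- unclass(norm_matrix)[, cells[[k]], drop = FALSE]
    res <- welch_rows(x, y)
    tibble(gene = rownames(norm_matrix), cluster = cluster, versus = k,
           mean_in = res$mean_x, mean_other = res$mean_y,
           statistic = res$statistic, p_value = res$p_value)
  })
  tests <- bind_rows(per)
  if (family == "per_comparison") {
    tests <- tests %>% group_by(.data$versus) %>%
      mutate(q_value = bh_adjust(.data$p_value)) %>% ungroup()
  } else {
    tests$q_value <- bh_adjust(tests$p_value)
  }
  tests <- tests %>%
    mutate(passes = .data$mean_in > .data$mean_other & .data$q_value < fdr) %>%
    group_by(.data$gene) %>%
    mutate(in_signature = all(.data$passes)) %>%
    ungroup()
  sig <- unique(tests$gene[tests$in_signature])
  structure(tests, signature = sig)
}

#' Per-cluster signature sets for a whole dataset
#'
#' Convenience wrapper computing the specific signature (definition B) or the
#' upregulated set (definition A) for every cluster.
#'
#' @inheritParams specific_signature
#' @param mode `"B"` (specific signature, default) or `"A"` (upregulated).
#' @return Named list of character vectors, one gene set per cluster.
#' @export
signature_sets <- function(norm_matrix, assignment, fdr = 0.01,
                           mode = c("B", "A"),
                           family = c("per_comparison", "global")) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  clusters <- sort(unique(cluster_assignment(assignment)$cluster))
  sets <- purrr::map(clusters, function(cl) {
    if (mode == "B") {
      attr(specific_signature(norm_matrix, assignment, cl, fdr = fdr,
                              family = family), "signature")
    } else {
      res <- upregulated_genes(norm_matrix, assignment, cl, fdr = fdr)
      res$gene[res$upregulated]
    }
  })
  setNames(sets, clusters)
}
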