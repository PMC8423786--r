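#' Per-cluster average expression profiles
#'
#' Arithmetic mean of each gene within each cluster of the normalized (or
#' standardized) matrix. For cross-dataset dendrograms, concatenate profile
#' matrices after restricting both to the shared (ortholog-mapped) gene
#' universe.
#'
#' @param norm_matrix A [normalized_matrix()] (or any genes x cells matrix).
#' @param assignment A [cluster_assignment()] covering the matrix cells.
#' @return Numeric matrix, genes x clusters, with an optional `provenance`
#'   attribute naming the dataset of origin per cluster.
#' @export
cluster_average_profiles <- function(norm_matrix, assignment) {
  assignment <- cluster_assignment(assignment, matrix = norm_matrix)
  x <- unclass(norm_matrix)[, assignment$cell_id, drop = FALSE]
  groups <- factor(assignment$cluster)
  sums <- x %*% stats::model.matrix(~ groups - 1)
  colnames(sums) <- levels(groups)
  prof <- sweep(sums, 2, as.numeric(table(groups)), "/")
  attr(prof, "provenance") <- setNames(
    rep(attr(norm_matrix, "dataset_id") %||% "dataset", ncol(prof)),
    colnames(prof))
  prof
}

#' Quantile-normalize profile columns
#'
#' Classic quantile normalization: each column's sorted values are replaced
#' by the cross-column row means of sorted values; ties share the mean of
#' their tied positions.
#'
#' @param profile_matrix Numeric matrix, genes x clusters (>= 2 columns).
#' @return The normalized matrix (same dimnames).
#' @export
quantile_normalize <- function(profile_matrix) {
  if (ncol(profile_matrix) < 2) abort_validation("need >= 2 columns")
  out <- limma::normalizeQuantiles(unclass(profile_matrix), ties = TRUE)
  dimnames(out) <- dimnames(profile_matrix)
  attr(out, "provenance") <- attr(profile_matrix, "provenance")
  out
}

#' Euclidean distance matrix between profile columns
#'
#' @param profile_matrix Numeric matrix, genes x clusters (>= 2 columns).
#' @return A `dist` object of pairwise L2 distances between columns.
#' @export
euclidean_distance_matrix <- function(profile_matrix) {
  if (ncol(profile_matrix) < 2) abort_validation("need >= 2 columns")
  dist(t(unclass(profile_matrix)), method = "euclidean")
}

#' Ward-2 agglomerative clustering
#'
#' Ward.D2 criterion (Lance-Williams update on squared distances with
#' square-root heights), guaranteeing non-decreasing merge heights.
#'
#' @param distance A `dist` object (e.g. [euclidean_distance_matrix()]).
#' @return An `hclust` merge tree.
#' @export
ward2_linkage <- function(distance) {
  hclust(distance, method = "ward.D2")
}

# Leaf sets (as sorted label strings) of every internal node of an hclust.
tree_clades <- function(hc) {
  labels <- hc$labels
  n <- length(labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) labels[-j] else members[[j]]
    members[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  vapply(members, paste, character(1), collapse = "|")
}

#' Multiscale bootstrap branch support for a profile dendrogram
#'
#' Genes (rows) are resampled with replacement at each scale `r` (sample size
#' `round(r * n_genes)`), the quantile-normalized Euclidean/Ward-2 tree is
#' rebuilt, and each original branch's bootstrap probability BP is the
#' fraction of unit-scale replicates containing its leaf set. The
#' approximately unbiased support AU comes from the multiscale fit: per
#' branch, `qnorm(1 - BP_r)` is regressed on `(sqrt(r), 1/sqrt(r))` by
#' weighted least squares and the fitted tail probability `1 - pnorm(d - c)`
#' is evaluated at the unit scale. Branches with degenerate BP (0 or 1 at
#' every scale) take AU = BP.
#'
#' @param profile_matrix Numeric matrix, genes x clusters (pre
#'   quantile-normalization; normalization is applied inside each replicate).
#' @param n_boot Replicates per scale (default 1000; >= 100 required).
#' @param scales Resampling ratios around 1 (default `seq(0.5, 1.4, 0.1)`).
#' @param seed Integer seed for the resampling stream.
#' @param quantile_norm Quantile-normalize within each replicate
#'   (default `TRUE`, matching the full-data pipeline).
#' @param keep_replicates Store the unit-scale replicate clade lists for
#'   auditing (default `FALSE`).
#' @return Object of class `supported_dendrogram`: the full-data `hclust`
#'   tree and a tibble `support` with one row per internal branch (`clade`,
#'   `n_leaves`, `bp`, `au`, both in percent).
#' @export
bootstrap_branch_support <- function(profile_matrix, n_boot = 1000,
                                     scales = seq(0.5, 1.4, by = 0.1),
                                     seed = 1L, quantile_norm = TRUE,
                                     keep_replicates = FALSE) {
  if (n_boot < 100) {
    warning("n_boot below 100 gives unstable support values")
  }
  n_genes <- nrow(profile_matrix)
  build <- function(m) {
    if (quantile_norm) m <- quantile_normalize(m)
    ward2_linkage(euclidean_distance_matrix(m))
  }
  full <- build(profile_matrix)
  clades <- tree_clades(full)
  counts <- matrix(0L, length(clades), length(scales),
                   dimnames = list(clades, NULL))
  unit <- which.min(abs(scales - 1))
  replicates <- if (keep_replicates) vector("list", n_boot) else NULL
  withr::with_seed(seed, {
    for (si in seq_along(scales)) {
      m_r <- max(2, round(scales[si] * n_genes))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n_genes, m_r, replace = TRUE)
        rep_clades <- tree_clades(build(profile_matrix[idx, , drop = FALSE]))
        hit <- clades %in% rep_clades
        counts[hit, si] <- counts[hit, si] + 1L
        if (keep_replicates && si == unit) replicates[[b]] <- rep_clades
      }
    }
  })
  bp_mat <- counts / n_boot
  au <- vapply(seq_along(clades), function(i) {
    fit_au(bp_mat[i, ], scales, n_boot)
  }, numeric(1))
  support <- tibble(clade = clades,
                    n_leaves = lengths(strsplit(clades, "|", fixed = TRUE)),
                    bp = 100 * unname(bp_mat[, unit]),
                    au = 100 * au)
  structure(list(tree = full, support = support, scales = scales,
                 n_boot = n_boot, bp_by_scale = bp_mat,
                 replicates = replicates),
            class = "supported_dendrogram")
}

# Weighted least-squares fit of the multiscale bootstrap model:
# qnorm(1 - BP_r) = d * sqrt(r) + c / sqrt(r); AU = 1 - pnorm(d - c).
fit_au <- function(bp, scales, n_boot) {
  usable <- bp > 0 & bp < 1
  if (sum(usable) < 3) {
    unit <- which.min(abs(scales - 1))
    return(bp[unit])
  }
  r <- scales[usable]
  z <- qnorm(1 - bp[usable])
  # binomial variance of BP propagated through the normal quantile
  w <- n_boot * stats::dnorm(z)^2 / (bp[usable] * (1 - bp[usable]))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  beta <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w),
                                                           z * sqrt(w))),
                   error = function(e) NULL)
  if (is.null(beta)) {
    unit <- which.min(abs(scales - 1))
    return(bp[unit])
  }
  1 - pnorm(beta[1] - beta[2])
}

#' @export
print.supported_dendrogram <- function(x, ...) {
  cat(sprintf("Ward-2 dendrogram over %d leaves, %d bootstrap replicates x %d scales\n",
              length(x$tree$labels), x$n_boot, length(x$scales)))
  print(x$support, ...)
  invisible(x)
}
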