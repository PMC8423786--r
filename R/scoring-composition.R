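#' Per-cell signature score with a random background control
#'
#' For each cell the score is the mean of (CP10K + 1) over the reference
#' genes minus the mean of (CP10K + 1) over `n` background genes, where
#' `n = max(#reference, 50)`. The background is drawn once per call,
#' uniformly without replacement from the genes not in the reference, using
#' the supplied seed (`scheme = "binned"` instead samples backgrounds matched
#' on mean-expression bins, a common alternative control).
#'
#' @param cp10k_matrix A [normalized_matrix()] with transform `"cp10k"`
#'   (linear scale, not log).
#' @param reference Character vector of reference genes, all present in the
#'   matrix.
#' @param seed Integer seed for the background draw.
#' @param n_floor Background-size floor (default 50).
#' @param scheme `"uniform"` (default) or `"binned"` background sampling.
#' @param n_bins Number of mean-expression bins for `scheme = "binned"`.
#' @return Named numeric vector of per-cell scores; the drawn background is
#'   kept in attribute `"background"`.
#' @export
signature_score <- function(cp10k_matrix, reference, seed = 1L, n_floor = 50,
                            scheme = c("uniform", "binned"), n_bins = 10) {
  scheme <- match.arg(scheme)
  if (length(reference) == 0) abort_validation("reference set is empty")
  if (!is.null(attr(cp10k_matrix, "transform")) &&
      norm_transform(cp10k_matrix) != "cp10k") {
    abort_validation("signature_score expects a linear cp10k matrix")
  }
  missing_genes <- setdiff(reference, rownames(cp10k_matrix))
  if (length(missing_genes) > 0) {
    abort_validation(sprintf("%d reference genes absent from matrix",
                             length(missing_genes)))
  }
  candidates <- setdiff(rownames(cp10k_matrix), reference)
  n_bg <- max(length(reference), n_floor)
  if (length(candidates) < n_bg) {
    abort_validation(sprintf(
      "need %d background candidates, only %d genes outside the reference",
      n_bg, length(candidates)))
  }
  background <- withr::with_seed(seed, {
    if (scheme == "uniform") {
      sample(candidates, n_bg)
    } else {
      sample_binned_background(cp10k_matrix, reference, candidates, n_bg,
                               n_bins)
    }
  })
  vals <- unclass(cp10k_matrix)
  score <- colMeans(vals[reference, , drop = FALSE] + 1) -
    colMeans(vals[background, , drop = FALSE] + 1)
  structure(score, background = background)
}

sample_binned_background <- function(mat, reference, candidates, n_bg,
                                     n_bins) {
  means <- rowMeans(unclass(mat))
  breaks <- unique(stats::quantile(means, probs = seq(0, 1,
                                                      length.out = n_bins + 1)))
  bin <- cut(means, breaks, include.lowest = TRUE)
  ref_tab <- table(bin[reference])
  quota <- round(as.numeric(ref_tab) / length(reference) * n_bg)
  drawn <- unlist(purrr::map2(names(ref_tab), quota, function(b, k) {
    pool <- candidates[bin[candidates] == b]
    sample(pool, min(k, length(pool)))
  }))
  short <- n_bg - length(drawn)
  if (short > 0) drawn <- c(drawn, sample(setdiff(candidates, drawn), short))
  drawn[seq_len(n_bg)]
}

#' Two-sided chi-square test with Yates continuity correction (2x2)
#'
#' Statistic `N * (max(|ad - bc| - N/2, 0))^2 / (m1 m2 n1 n2)` with
#' `df = 1`, where `m` and `n` are the row and column margins.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return One-row tibble with `statistic`, `p_value` and `direction`
#'   (`"over"`, `"under"` or `"none"`, the sign of observed minus expected in
#'   the top-left cell).
#' @export
chi_square_yates_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    abort_validation("table must be 2x2 with non-negative counts")
  }
  rs <- rowSums(table); cs <- colSums(table); N <- sum(table)
  if (any(rs == 0) || any(cs == 0)) {
    rlang::abort("chi-square undefined with a zero margin",
                 class = "sigshare_undefined_test_error")
  }
  det <- table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1]
  num <- max(abs(det) - N / 2, 0)
  stat <- N * num^2 / prod(c(rs, cs))
  expected11 <- rs[1] * cs[1] / N
  direction <- if (num == 0 || table[1, 1] == expected11) "none"
    else if (table[1, 1] > expected11) "over" else "under"
  tibble(statistic = unname(stat),
         p_value = unname(pchisq(stat, df = 1, lower.tail = FALSE)),
         direction = direction)
}

#' Cluster-composition tests against a sample grouping
#'
#' For every (cluster, group) pair the cells are cross-tabulated as
#' in-cluster vs not by in-group vs not and tested with the Yates-corrected
#' two-sided chi-square; BH correction spans all tested pairs. Degenerate
#' tables (a zero margin) are skipped with a warning. `rxc = TRUE` instead
#' runs one uncorrected R x C chi-square per grouping (non-default variant).
#'
#' @param assignment A [cluster_assignment()] with a grouping column.
#' @param group_by Name of the grouping column (e.g. `"risk_group"`,
#'   `"inss_stage"`, `"sample_id"`).
#' @param fdr BH threshold (default 0.01).
#' @param rxc Run a single R x C test instead of per-pair 2x2 tests.
#' @return Tibble with one row per (cluster, group): observed and expected
#'   in-cluster counts, `statistic`, `p_value`, `q_value`, `direction` and
#'   `significant`.
#' @export
composition_test <- function(assignment, group_by, fdr = 0.01, rxc = FALSE) {
  assignment <- cluster_assignment(assignment)
  if (!group_by %in% names(assignment)) {
    abort_format(sprintf("assignment has no '%s' column", group_by))
  }
  groups <- assignment[[group_by]]
  if (length(unique(groups)) < 2) {
    abort_validation("need at least two groups for composition tests")
  }
  tab <- table(assignment$cluster, groups)
  if (rxc) {
    ct <- suppressWarnings(stats::chisq.test(tab))
    return(tibble(statistic = unname(ct$statistic),
                  p_value = unname(ct$p.value),
                  df = unname(ct$parameter)))
  }
  grid <- tidyr::expand_grid(cluster = rownames(tab), group = colnames(tab))
  N <- sum(tab)
  res <- purrr::pmap(grid, function(cluster, group) {
    a <- tab[cluster, group]
    b <- sum(tab[cluster, ]) - a
    c_ <- sum(tab[, group]) - a
    d <- N - a - b - c_
    t22 <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    out <- tibble(cluster = cluster, group = group,
                  observed = unname(a),
                  expected = unname(sum(tab[cluster, ]) * sum(tab[, group]) / N))
    test <- tryCatch(chi_square_yates_2x2(t22), error = function(e) NULL)
    if (is.null(test)) {
      warning(sprintf("degenerate margins for cluster %s x group %s; skipped",
                      cluster, group))
      return(mutate(out, statistic = NA_real_, p_value = NA_real_,
                    direction = NA_character_))
    }
    mutate(out, statistic = test$statistic, p_value = test$p_value,
           direction = test$direction)
  }) %>% bind_rows()
  res$q_value <- NA_real_
  ok <- !is.na(res$p_value)
  res$q_value[ok] <- bh_adjust(res$p_value[ok])
  res$significant <- !is.na(res$q_value) & res$q_value < fdr
  res
}

#' Least-squares deconvolution of a bulk profile into cluster proportions
#'
#' Non-negative least-squares fit of the bulk profile on per-cluster mean
#' CP10K reference profiles, renormalized to proportions summing to one.
#' This is a transparent least-squares stand-in, not the published
#' reference-based decomposition model; any externally produced proportion
#' table can be fed to [expected_cells_from_deconvolution()] instead.
#'
#' @param bulk_profile Named numeric vector (genes).
#' @param cluster_profiles Numeric matrix, genes x clusters, same gene space.
#' @return Tibble with `cluster` and `proportion`; an `ambiguous_fit`
#'   attribute is set (with a warning) when the references are
#'   rank-deficient.
#' @export
ls_deconvolve <- function(bulk_profile, cluster_profiles) {
  genes <- intersect(names(bulk_profile), rownames(cluster_profiles))
  if (length(genes) == 0) abort_validation("no shared genes")
  A <- unclass(cluster_profiles)[genes, , drop = FALSE]
  b <- bulk_profile[genes]
  ambiguous <- qr(A)$rank < ncol(A)
  if (ambiguous) warning("reference profiles are rank-deficient; fit ambiguous")
  fit <- pracma::lsqnonneg(A, as.numeric(b))
  w <- fit$x
  props <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
  structure(tibble(cluster = colnames(A), proportion = props),
            ambiguous_fit = ambiguous)
}

#' Expected per-cluster cell counts in a deconvolved bulk cohort
#'
#' For each risk group the proportional cell total is
#' `c = avg_nuclei(group) * n_bulk_samples(group)`; the expected count of a
#' cluster is `c` times the group-mean predicted cluster proportion.
#' Over-/under-representation across groups is then tested per
#' (cluster, group) with BH-corrected Yates chi-squares on rounded expected
#' counts.
#'
#' @param proportions Tibble with columns `sample_id`, `cluster`,
#'   `proportion` (e.g. stacked [ls_deconvolve()] results).
#' @param clinical A [clinical_table()] giving each sample's risk group.
#' @param nuc_seq_counts Tibble with columns `risk_group` and `avg_nuclei`
#'   (mean high-quality nuclei per single-nuclei sample in that group).
#' @param fdr BH threshold (default 0.01).
#' @return Tibble with one row per (cluster, risk group): `cell_total`,
#'   `mean_proportion`, `expected_cells`, chi-square `statistic`, `p_value`,
#'   `q_value`, `direction`, `significant`.
#' @export
expected_cells_from_deconvolution <- function(proportions, clinical,
                                              nuc_seq_counts, fdr = 0.01) {
  proportions <- as_tibble(proportions)
  clinical <- clinical_table(clinical)
  if (any(is.na(clinical$risk_group))) {
    abort_validation("every bulk sample needs a risk group")
  }
  joined <- left_join(proportions,
                      clinical[c("sample_id", "risk_group")], by = "sample_id")
  if (any(is.na(joined$risk_group))) {
    abort_validation("proportion table contains samples absent from clinical")
  }
  n_samples <- clinical %>% count(.data$risk_group, name = "n_bulk_samples")
  per <- joined %>%
    group_by(.data$risk_group, .data$cluster) %>%
    summarise(mean_proportion = mean(.data$proportion), .groups = "drop") %>%
    left_join(n_samples, by = "risk_group") %>%
    left_join(as_tibble(nuc_seq_counts), by = "risk_group")
  if (any(is.na(per$avg_nuclei))) {
    abort_validation("nuc_seq_counts lacks a risk group present in clinical")
  }
  per <- per %>%
    mutate(cell_total = .data$avg_nuclei * .data$n_bulk_samples,
           expected_cells = .data$cell_total * .data$mean_proportion)
  counts <- round(per$expected_cells)
  tab <- tapply(counts, list(per$cluster, per$risk_group), sum)
  tab[is.na(tab)] <- 0
  N <- sum(tab)
  tests <- purrr::pmap(per[c("cluster", "risk_group")],
                       function(cluster, risk_group) {
    a <- tab[cluster, risk_group]
    t22 <- matrix(c(a, sum(tab[cluster, ]) - a,
                    sum(tab[, risk_group]) - a,
                    N - sum(tab[cluster, ]) - sum(tab[, risk_group]) + a),
                  2, byrow = TRUE)
    test <- tryCatch(chi_square_yates_2x2(t22), error = function(e)
      tibble(statistic = NA_real_, p_value = NA_real_,
             direction = NA_character_))
    test
  }) %>% bind_rows()
  out <- dplyr::bind_cols(per, tests)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_adjust(out$p_value[ok])
  out$significant <- !is.na(out$q_value) & out$q_value < fdr
  out
}
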