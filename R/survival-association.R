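#' Per-sample average standardized expression of a gene set
#'
#' Each gene is z-scored across samples; the score of a sample is the mean z
#' over the set's genes present in the matrix. Genes with zero variance are
#' excluded with a warning. Signatures feeding the survival scan must carry
#' more than two usable genes.
#'
#' @param bulk_matrix Numeric matrix, genes x samples.
#' @param gene_set Character vector of target genes.
#' @param min_genes Minimum usable genes (default 3, the more-than-two-gene
#'   filter applied to scanned signatures; set to 1 for unrestricted use).
#' @return Named numeric vector of per-sample scores.
#' @export
signature_zscore_average <- function(bulk_matrix, gene_set, min_genes = 3) {
  genes <- intersect(gene_set, rownames(bulk_matrix))
  if (length(genes) == 0) abort_validation("no signature genes in the matrix")
  x <- unclass(bulk_matrix)[genes, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant genes excluded from z-scoring",
                    sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < min_genes) {
    abort_validation(sprintf(
      "signature has %d usable genes; scanned signatures need more than two",
      nrow(x)))
  }
  z <- (x - rowMeans(x)) / apply(x, 1, sd)
  colMeans(z)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative follow-up times.
#' @param events Logical (or 0/1) event indicators; `FALSE` is censored.
#' @return Tibble of class `km_curve` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` at the observed times.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) abort_validation("empty survival input")
  if (any(times < 0)) abort_validation("times must be >= 0")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

# Risk/death indicator machinery shared by the log-rank test and the scan.
# Returns per-distinct-event-time totals and per-sample indicator matrices.
logrank_prepare <- function(times, events) {
  events <- as.logical(events)
  ts <- sort(unique(times[events]))
  R <- outer(times, ts, ">=")                       # at risk at t_j
  D <- outer(times, ts, "==") & events              # dies at t_j
  n_j <- colSums(R)
  d_j <- colSums(D)
  c_j <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  list(R = R, D = D, n_j = n_j, d_j = d_j, c_j = c_j, events = events)
}

logrank_from_group <- function(prep, in_group) {
  if (length(prep$n_j) == 0) {
    return(tibble(statistic = 0, p_value = 1, observed = 0, expected = 0))
  }
  n1 <- colSums(prep$R[in_group, , drop = FALSE])
  d1 <- colSums(prep$D[in_group, , drop = FALSE])
  O1 <- sum(d1)
  E1 <- sum(prep$d_j * n1 / prep$n_j)
  V <- sum(prep$c_j * (n1 / prep$n_j) * (1 - n1 / prep$n_j))
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  tibble(statistic = stat,
         p_value = if (V > 0) pchisq(stat, 1, lower.tail = FALSE) else 1,
         observed = O1, expected = E1)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square on one degree of freedom with
#' hypergeometric variance (ties handled). With no events at all the test
#' returns p = 1 by convention.
#'
#' @param times1,events1 Follow-up times and event indicators, group 1.
#' @param times2,events2 Same for group 2.
#' @return One-row tibble with `statistic`, `p_value`, and group-1
#'   `observed` and `expected` event counts.
#' @export
logrank_test <- function(times1, events1, times2, events2) {
  if (length(times1) == 0 || length(times2) == 0) {
    abort_validation("both groups must be non-empty")
  }
  prep <- logrank_prepare(c(times1, times2), c(events1, events2))
  logrank_from_group(prep, seq_along(c(times1, times2)) <= length(times1))
}

# Log-rank chi-square for every candidate cutpoint at once. Samples are
# sorted by score; the low group at cut position k is the first k sorted
# samples, so group-wise at-risk/death counts are cumulative sums.
scan_all_cutpoints <- function(scores, times, events, min_group_fraction,
                               min_group_size = 3) {
  n <- length(scores)
  ord <- order(scores)
  s <- scores[ord]
  min_n <- max(min_group_size, ceiling(min_group_fraction * n))
  k_ok <- which(s[-n] < s[-1])                # boundaries between distinct scores
  k_ok <- k_ok[k_ok >= min_n & (n - k_ok) >= min_n]
  if (length(k_ok) == 0) {
    rlang::abort("no valid cutpoint (scores constant or groups too small)",
                 class = "sigshare_no_cutpoint_error")
  }
  prep <- logrank_prepare(times, events)
  if (length(prep$n_j) == 0) {
    return(list(cut_values = (s[k_ok] + s[k_ok + 1]) / 2, k = k_ok, ord = ord,
                statistic = rep(0, length(k_ok)), p = rep(1, length(k_ok)),
                oe = rep(0, length(k_ok))))
  }
  cum_R <- apply(prep$R[ord, , drop = FALSE], 2, cumsum)
  O1 <- cumsum(prep$events[ord])[k_ok]
  frac <- cum_R[k_ok, , drop = FALSE] /
    matrix(prep$n_j, length(k_ok), length(prep$n_j), byrow = TRUE)
  E1 <- as.numeric(frac %*% prep$d_j)
  V <- as.numeric((frac * (1 - frac)) %*% prep$c_j)
  stat <- ifelse(V > 0, (O1 - E1)^2 / V, 0)
  list(cut_values = (s[k_ok] + s[k_ok + 1]) / 2, k = k_ok, ord = ord,
       statistic = stat,
       p = ifelse(V > 0, pchisq(stat, 1, lower.tail = FALSE), 1),
       oe = O1 - E1)
}

#' Optimal-cutpoint survival scan (scan modus)
#'
#' Evaluates a two-group log-rank test at every cutpoint between consecutive
#' distinct sorted score values (samples with score equal to the cutpoint go
#' to the low group) subject to a minimum group fraction, and returns the
#' cutpoint minimizing the raw p-value. The scan-adjusted p-value is the raw
#' minimum Bonferroni-corrected for the number of cutpoints evaluated; family
#' corrections across signatures are applied by [scan_signatures()].
#'
#' @param scores Per-sample scores (e.g. [signature_zscore_average()]).
#' @param times,events Follow-up times and event indicators.
#' @param min_group_fraction Minimum fraction of samples per group
#'   (default 0.1); at least 3 samples per group always required.
#' @return Object of class `kaplan_scan`: cutpoint, group sizes, log-rank
#'   `statistic`, raw `p_value`, `p_scan_adjusted`, `n_cutpoints`,
#'   `worse_group` (`"high-score"` or `"low-score"`), and the grouped data
#'   for plotting.
#' @export
kaplan_scan <- function(scores, times, events, min_group_fraction = 0.1) {
  if (length(scores) != length(times) || length(times) != length(events)) {
    abort_validation("scores, times and events must have equal length")
  }
  scan <- scan_all_cutpoints(scores, times, events, min_group_fraction)
  best <- which.min(scan$p)
  cut <- scan$cut_values[best]
  low <- scores <= cut
  # oe > 0: low group saw more events than expected, hence worse survival
  worse <- if (scan$oe[best] > 0) "low-score" else "high-score"
  structure(list(cutpoint = cut,
                 n_low = sum(low), n_high = sum(!low),
                 statistic = scan$statistic[best],
                 p_value = scan$p[best],
                 n_cutpoints = length(scan$p),
                 p_scan_adjusted = min(1, scan$p[best] * length(scan$p)),
                 worse_group = worse,
                 data = tibble(score = scores, time = times,
                               event = as.logical(events),
                               group = ifelse(low, "low-score",
                                              "high-score"))),
            class = "kaplan_scan")
}

#' @export
print.kaplan_scan <- function(x, ...) {
  cat(sprintf(
    "Kaplan scan: cutpoint %.4g (%d low / %d high), chi-sq %.3f\n",
    x$cutpoint, x$n_low, x$n_high, x$statistic))
  cat(sprintf("  raw p %.3g, scan-adjusted p %.3g over %d cutpoints; worse: %s\n",
              x$p_value, x$p_scan_adjusted, x$n_cutpoints, x$worse_group))
  invisible(x)
}

#' Scan a collection of signatures against a bulk cohort
#'
#' Runs [signature_zscore_average()] and [kaplan_scan()] for every signature
#' with more than two usable genes and Bonferroni-corrects across the family
#' of signatures tested in the invocation (and, within each scan, the number
#' of cutpoints evaluated — see the methods vignette); the raw minimum p is
#' always reported alongside.
#'
#' @param bulk_matrix Numeric matrix, genes x samples.
#' @param clinical A [clinical_table()] covering the matrix samples.
#' @param signatures Named list of gene sets.
#' @param min_group_fraction Passed to [kaplan_scan()].
#' @return Tibble with one row per scanned signature: `signature`, `n_genes`,
#'   `cutpoint`, `n_low`, `n_high`, `statistic`, `p_value`, `n_cutpoints`,
#'   `adjusted_p`, `correction = "Bonferroni"`, `worse_group`; skipped
#'   signatures (too few genes or no valid cutpoint) are reported with `NA`
#'   statistics.
#' @export
scan_signatures <- function(bulk_matrix, clinical, signatures,
                            min_group_fraction = 0.1) {
  clinical <- clinical_table(clinical)
  idx <- match(colnames(bulk_matrix), clinical$sample_id)
  if (any(is.na(idx))) {
    abort_validation("bulk samples missing from the clinical table")
  }
  times <- clinical$efs_days[idx]
  events <- clinical$efs_event[idx]
  if (any(is.na(times)) || any(is.na(events))) {
    abort_validation("efs_days/efs_event required for survival scans")
  }
  rows <- purrr::imap(signatures, function(genes, nm) {
    scan <- tryCatch({
      score <- signature_zscore_average(bulk_matrix, genes)
      list(n = sum(genes %in% rownames(bulk_matrix)),
           scan = kaplan_scan(score, times, events, min_group_fraction))
    }, error = function(e) e)
    if (inherits(scan, "error")) {
      warning(sprintf("signature '%s' skipped: %s", nm,
                      conditionMessage(scan)))
      return(tibble(signature = nm, n_genes = length(genes),
                    cutpoint = NA_real_, n_low = NA_integer_,
                    n_high = NA_integer_, statistic = NA_real_,
                    p_value = NA_real_, n_cutpoints = NA_integer_,
                    worse_group = NA_character_))
    }
    s <- scan$scan
    tibble(signature = nm, n_genes = scan$n, cutpoint = s$cutpoint,
           n_low = s$n_low, n_high = s$n_high, statistic = s$statistic,
           p_value = s$p_value, n_cutpoints = s$n_cutpoints,
           worse_group = s$worse_group)
  })
  out <- bind_rows(rows)
  n_tested <- sum(!is.na(out$p_value))
  out$adjusted_p <- pmin(1, out$p_value * out$n_cutpoints * n_tested)
  out$correction <- "Bonferroni"
  out
}

#' Per-gene differential expression between clinical groups
#'
#' Expression (RPM or comparable) is log2-transformed with a pseudocount and
#' each gene tested with a classic one-way ANOVA across groups; BH correction
#' spans genes. Significant genes are assigned to the group with the highest
#' mean ("up in" that group). Zero-variance genes take p = 1 by convention.
#'
#' @param bulk_matrix Numeric matrix, genes x samples (linear scale).
#' @param groups Character/factor vector of group labels per sample.
#' @param fdr BH threshold (default 0.01).
#' @param pseudocount Added before log2 (default 1).
#' @return Tibble with `gene`, `statistic` (F), `p_value`, `q_value`,
#'   `top_group`, `significant`.
#' @export
per_gene_group_differential <- function(bulk_matrix, groups, fdr = 0.01,
                                        pseudocount = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort_validation("need at least two groups")
  if (any(table(groups) < 2)) {
    abort_validation("each group needs at least two samples")
  }
  x <- log2(unclass(bulk_matrix) + pseudocount)
  res <- purrr::map(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    if (var(v) == 0) {
      return(tibble(statistic = 0, p_value = 1,
                    top_group = levels(groups)[1]))
    }
    ft <- oneway.test(v ~ groups, var.equal = TRUE)
    means <- tapply(v, groups, mean)
    tibble(statistic = unname(ft$statistic), p_value = unname(ft$p.value),
           top_group = names(which.max(means)))
  }) %>% bind_rows()
  res <- dplyr::bind_cols(tibble(gene = rownames(bulk_matrix)), res)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < fdr
  res
}

#' Per-gene Pearson correlation with age at diagnosis
#'
#' @param bulk_matrix Numeric matrix, genes x samples.
#' @param ages Numeric vector of ages (months) per sample, variance > 0.
#' @param fdr BH threshold (default 0.01).
#' @return Tibble with `gene`, `r`, `p_value`, `q_value`, `direction`
#'   (`"direct"` for r > 0, `"inverse"` for r < 0), `significant`; constant
#'   genes are excluded with a warning.
#' @export
per_gene_age_correlation <- function(bulk_matrix, ages, fdr = 0.01) {
  if (length(ages) != ncol(bulk_matrix)) {
    abort_validation("one age per sample required")
  }
  if (length(ages) < 3 || var(ages) == 0) {
    abort_validation("need >= 3 samples with varying age")
  }
  x <- unclass(bulk_matrix)
  constant <- apply(x, 1, var) == 0
  if (any(constant)) {
    warning(sprintf("%d constant genes excluded from correlation",
                    sum(constant)))
    x <- x[!constant, , drop = FALSE]
  }
  res <- purrr::map(seq_len(nrow(x)), function(i) {
    ct <- cor.test(x[i, ], ages, method = "pearson")
    tibble(r = unname(ct$estimate), p_value = unname(ct$p.value))
  }) %>% bind_rows()
  res <- dplyr::bind_cols(tibble(gene = rownames(x)), res)
  res$q_value <- bh_adjust(res$p_value)
  res$direction <- ifelse(res$r > 0, "direct",
                          ifelse(res$r < 0, "inverse", "none"))
  res$significant <- res$q_value < fdr
  res
}

#' Per-gene optimal-cutpoint survival association
#'
#' Each gene's expression is scanned with [kaplan_scan()]; raw minimum
#' p-values are BH-corrected across genes and significant genes are labeled
#' `"worse_with_high"` or `"better_with_high"` by the scan's worse-survival
#' group. Genes without a valid cutpoint are skipped with a warning.
#'
#' @param bulk_matrix Numeric matrix, genes x samples.
#' @param times,events Follow-up times and event indicators per sample.
#' @param fdr BH threshold (default 0.01).
#' @param min_group_fraction Passed to [kaplan_scan()].
#' @return Tibble with `gene`, `cutpoint`, `statistic`, `p_value`,
#'   `q_value`, `direction`, `significant`.
#' @export
per_gene_survival_groups <- function(bulk_matrix, times, events, fdr = 0.01,
                                     min_group_fraction = 0.1) {
  x <- unclass(bulk_matrix)
  rows <- purrr::map(seq_len(nrow(x)), function(i) {
    scan <- tryCatch(kaplan_scan(x[i, ], times, events, min_group_fraction),
                     error = function(e) NULL)
    if (is.null(scan)) return(NULL)
    tibble(gene = rownames(x)[i], cutpoint = scan$cutpoint,
           statistic = scan$statistic, p_value = scan$p_value,
           direction = ifelse(scan$worse_group == "high-score",
                              "worse_with_high", "better_with_high"))
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    warning(sprintf("%d genes skipped (no valid cutpoint)", skipped))
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0) return(res)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < fdr
  res
}

#' Enrichment of cluster signatures in labeled bulk gene lists
#'
#' Tests every cluster signature against every labeled gene list (risk-group
#' up lists, age-correlation direct/inverse lists, worse/better survival
#' lists) by delegating to [external_set_enrichment()], reproducing the
#' cluster x label grid of enrichment FDRs.
#'
#' @param cluster_signatures Named list of gene sets.
#' @param labeled_gene_lists Named list of gene lists (e.g. `risk_high_up`,
#'   `age_direct`, `surv_worse`, ...).
#' @param universe Character vector, the gene universe.
#' @param fdr Significance threshold (default 0.01).
#' @return Tibble with one row per signature x label.
#' @export
signature_label_enrichment <- function(cluster_signatures, labeled_gene_lists,
                                       universe, fdr = 0.01) {
  purrr::imap(cluster_signatures, function(genes, nm) {
    res <- external_set_enrichment(intersect(genes, universe),
                                   labeled_gene_lists, universe, fdr = fdr)
    dplyr::bind_cols(tibble(signature = nm), res)
  }) %>% bind_rows()
}
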