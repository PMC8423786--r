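#' Restrict a gene set to one-to-one orthologs and translate it
#'
#' Only genes whose mapping degree is 1 on both sides of the ortholog map are
#' translated; every other gene is dropped and reported.
#'
#' @param genes Character vector of gene identifiers.
#' @param map An [ortholog_map()] tibble.
#' @param direction `"a2b"` (translate `gene_a` to `gene_b`) or `"b2a"`.
#' @return List with `genes` (translated set) and `dropped` (input genes that
#'   were not 1:1 or not in the map).
#' @export
restrict_to_one_to_one <- function(genes, map, direction = c("a2b", "b2a")) {
  direction <- match.arg(direction)
  map <- ortholog_map(map)
  one <- map[map$degree_a == 1 & map$degree_b == 1, ]
  from <- if (direction == "a2b") one$gene_a else one$gene_b
  to <- if (direction == "a2b") one$gene_b else one$gene_a
  hit <- genes %in% from
  list(genes = unname(to[match(genes[hit], from)]),
       dropped = genes[!hit])
}

#' One-sided Fisher's exact test for enrichment
#'
#' For a 2x2 table `[[a, b], [c, d]]` the test computes the upper
#' hypergeometric tail `P(X >= a)` with `X ~ Hypergeom(a+b, c+d, a+c)`, i.e.
#' the probability of an overlap at least as large as observed.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble with `statistic` (observed overlap) and `p_value`.
#' @export
fisher_one_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort_validation("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    abort_validation("table cells must be non-negative integers")
  }
  a <- table[1, 1]
  p <- phyper(a - 1, m = table[1, 1] + table[1, 2],
              n = table[2, 1] + table[2, 2],
              k = table[1, 1] + table[2, 1], lower.tail = FALSE)
  tibble(statistic = a, p_value = min(p, 1))
}

overlap_table <- function(query, reference, universe) {
  a <- length(intersect(query, reference))
  matrix(c(a,
           length(query) - a,
           length(reference) - a,
           length(universe) - length(union(query, reference))),
         nrow = 2, byrow = TRUE)
}

#' Signature-sharing enrichment between two sets of cluster signatures
#'
#' Every query x reference signature pair is tested for overlap enrichment
#' over an explicit gene universe with a one-sided Fisher test. Pairs sharing
#' fewer than `min_overlap` genes are reported with their statistics but
#' flagged `passed_min_overlap = FALSE` and excluded from the BH family and
#' from significance calls.
#'
#' @param sig_query,sig_reference Named lists of character vectors (per
#'   cluster gene signatures). For cross-species runs, translate the query
#'   through [restrict_to_one_to_one()] first.
#' @param universe Character vector of the gene universe both signature
#'   collections are drawn from (conventionally the intersection of genes
#'   tested in both datasets).
#' @param min_overlap Minimum shared genes for a pair to enter the BH family
#'   (default 10).
#' @param fdr BH threshold for the `significant` call (default 0.01).
#' @return Tibble with one row per pair: `query`, `reference`,
#'   `universe_size`, `overlap_count`, `overlap_genes` (list column),
#'   `fisher_p`, `q_value`, `passed_min_overlap`, `significant`.
#' @export
signature_sharing <- function(sig_query, sig_reference, universe,
                              min_overlap = 10, fdr = 0.01) {
  check_in_universe(sig_query, universe, "query")
  check_in_universe(sig_reference, universe, "reference")
  grid <- tidyr::expand_grid(query = names(sig_query),
                             reference = names(sig_reference))
  res <- purrr::pmap(grid, function(query, reference) {
    q <- sig_query[[query]]; r <- sig_reference[[reference]]
    ov <- intersect(q, r)
    tibble(query = query, reference = reference,
           universe_size = length(universe),
           overlap_count = length(ov), overlap_genes = list(ov),
           fisher_p = fisher_one_sided(overlap_table(q, r, universe))$p_value,
           passed_min_overlap = length(ov) >= min_overlap)
  }) %>% bind_rows()
  res$q_value <- NA_real_
  if (any(res$passed_min_overlap)) {
    res$q_value[res$passed_min_overlap] <-
      bh_adjust(res$fisher_p[res$passed_min_overlap])
  }
  res$significant <- res$passed_min_overlap & !is.na(res$q_value) &
    res$q_value < fdr
  res[c("query", "reference", "universe_size", "overlap_count",
        "overlap_genes", "fisher_p", "q_value", "passed_min_overlap",
        "significant")]
}

check_in_universe <- function(sets, universe, what) {
  if (length(universe) == 0) abort_validation("gene universe is empty")
  stray <- setdiff(unique(unlist(sets)), universe)
  if (length(stray) > 0) {
    abort_validation(sprintf(
      "%d %s genes are outside the universe (e.g. %s)",
      length(stray), what, paste(utils::head(stray, 3), collapse = ", ")))
  }
  invisible(sets)
}

#' Enrichment of one cluster signature in external reference gene sets
#'
#' Tests a single query signature against each reference set (GO terms,
#' mesenchymal/adrenergic programs, sympathetic noradrenergic and
#' neural-crest-like groups, fetal or 10X-cohort markers, ...) with one-sided
#' Fisher tests, BH-corrected across the reference sets. Results with
#' adjusted values in `[fdr, marginal_fdr)` are tiered `"marginal"`.
#'
#' @param cluster_signature Character vector of query genes.
#' @param reference_sets Named list of character vectors (e.g. from
#'   [read_gene_sets()]); genes outside the universe are ignored.
#' @param universe Character vector, the gene universe.
#' @param fdr Significance threshold (default 0.01).
#' @param marginal_fdr Upper bound of the marginal tier (default 0.05).
#' @return Tibble with one row per reference set, including `tier` in
#'   `"significant"`, `"marginal"`, `"ns"`.
#' @export
external_set_enrichment <- function(cluster_signature, reference_sets,
                                    universe, fdr = 0.01,
                                    marginal_fdr = 0.05) {
  check_in_universe(list(cluster_signature), universe, "query")
  refs <- purrr::map(reference_sets, intersect, universe)
  res <- purrr::imap(refs, function(r, nm) {
    ov <- intersect(cluster_signature, r)
    tibble(reference = nm, universe_size = length(universe),
           reference_size = length(r),
           overlap_count = length(ov), overlap_genes = list(ov),
           fisher_p = fisher_one_sided(
             overlap_table(cluster_signature, r, universe))$p_value)
  }) %>% bind_rows()
  res$q_value <- bh_adjust(res$fisher_p)
  res$tier <- dplyr::case_when(
    res$q_value < fdr ~ "significant",
    res$q_value < marginal_fdr ~ "marginal",
    TRUE ~ "ns")
  res
}
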