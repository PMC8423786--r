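#' Filter CNV segments to likely true rearrangements
#'
#' A segment is kept when its probability mass on the neutral state (state 3)
#' is at most `max_neutral_prob`, i.e. its rearrangement likelihood (summed
#' probability of the five non-neutral states) exceeds
#' `1 - max_neutral_prob`. The default 0.1 keeps segments whose probability
#' of being a true rearrangement is above 0.9.
#'
#' @param segments A [cnv_segment_table()] tibble.
#' @param max_neutral_prob Maximum allowed neutral-state probability
#'   (default 0.1).
#' @return The filtered segment table.
#' @export
filter_cnv_calls <- function(segments, max_neutral_prob = 0.1) {
  segments <- cnv_segment_table(segments)
  segments[segments$p3 <= max_neutral_prob, ]
}

#' Per-cell copy-number state over a genomic region
#'
#' For each cell, the mean of the most likely state over the kept segments
#' overlapping the region (half-open overlap: a segment ending exactly at the
#' region start does not overlap). The call is `"gain"` when the mean exceeds
#' the neutral state 3, `"loss"` below 3, `"neutral"` at exactly 3 and
#' `"no_data"` when no kept segment overlaps.
#'
#' @param segments A filtered [cnv_segment_table()] (see
#'   [filter_cnv_calls()]).
#' @param region One-row tibble from [region_query()].
#' @param cell_ids Cells to report (defaults to the cells in `segments`);
#'   cells without overlapping segments are reported as `"no_data"`.
#' @param direction_restricted If `TRUE`, average only segments whose most
#'   likely state lies on the region's expected side of neutral.
#' @return Tibble with `cell_id`, `region`, `mean_state`, `call`.
#' @export
region_state_per_cell <- function(segments, region, cell_ids = NULL,
                                  direction_restricted = FALSE) {
  segments <- cnv_segment_table(segments)
  cell_ids <- cell_ids %||% unique(segments$cell_id)
  hit <- segments$chrom == region$chrom &
    segments$start < region$end & region$start < segments$end
  seg <- segments[hit, ]
  if (direction_restricted) {
    seg <- if (region$expected_direction == "gain") {
      seg[seg$most_likely_state > 3, ]
    } else {
      seg[seg$most_likely_state < 3, ]
    }
  }
  means <- tapply(seg$most_likely_state, seg$cell_id, mean)
  mean_state <- unname(means[cell_ids])
  call <- dplyr::case_when(
    is.na(mean_state) ~ "no_data",
    mean_state > 3 ~ "gain",
    mean_state < 3 ~ "loss",
    TRUE ~ "neutral")
  tibble(cell_id = cell_ids, region = region$name,
         mean_state = mean_state, call = call)
}

#' Per-cluster rearrangement enrichment within one sample
#'
#' For each sample independently and each (cluster, region), tests whether
#' cells whose regional call matches the region's expected direction are
#' over-represented in the cluster, with a one-sided Fisher test on
#' in-cluster vs not by rearranged vs not; BH correction spans all
#' cluster x region tests within the sample. Cells called neutral or
#' `no_data` count as non-rearranged unless `drop_no_data = TRUE` removes
#' the latter from the table.
#'
#' @param segments A [cnv_segment_table()] (filtered with
#'   [filter_cnv_calls()] beforehand, or pass `max_neutral_prob` to filter
#'   here).
#' @param assignment A [cluster_assignment()] with a `sample_id` column.
#' @param regions Tibble of [region_query()] rows.
#' @param fdr BH threshold for reporting (default 0.05).
#' @param max_neutral_prob Optional likelihood filter applied before testing.
#' @param drop_no_data Exclude cells without regional data from the tables.
#' @return Tibble with one row per sample x region x cluster:
#'   `n_rearranged_in`, `n_cluster`, `n_rearranged_out`, `n_out`,
#'   `fisher_p`, `q_value`, `significant`.
#' @export
cluster_rearrangement_enrichment <- function(segments, assignment, regions,
                                             fdr = 0.05,
                                             max_neutral_prob = NULL,
                                             drop_no_data = FALSE) {
  assignment <- cluster_assignment(assignment)
  if (!"sample_id" %in% names(assignment)) {
    abort_format("assignment needs a sample_id column for per-sample tests")
  }
  if (!is.null(max_neutral_prob)) {
    segments <- filter_cnv_calls(segments, max_neutral_prob)
  }
  out <- purrr::map(split(assignment, assignment$sample_id),
                    function(asg) {
    res <- purrr::map(seq_len(nrow(regions)), function(i) {
      region <- regions[i, ]
      states <- region_state_per_cell(segments, region,
                                      cell_ids = asg$cell_id)
      if (drop_no_data) {
        keep <- states$call != "no_data"
        states <- states[keep, ]
        asg_r <- asg[keep, ]
      } else {
        asg_r <- asg
      }
      rearranged <- states$call == region$expected_direction
      purrr::map(sort(unique(asg_r$cluster)), function(cl) {
        in_cl <- asg_r$cluster == cl
        tab <- matrix(c(sum(rearranged & in_cl), sum(!rearranged & in_cl),
                        sum(rearranged & !in_cl), sum(!rearranged & !in_cl)),
                      2, byrow = TRUE)
        tibble(sample_id = asg$sample_id[1], region = region$name,
               cluster = cl,
               n_rearranged_in = tab[1, 1], n_cluster = sum(in_cl),
               n_rearranged_out = tab[2, 1], n_out = sum(!in_cl),
               fisher_p = fisher_one_sided(tab)$p_value)
      }) %>% bind_rows()
    }) %>% bind_rows()
    res$q_value <- bh_adjust(res$fisher_p)
    res
  }) %>% bind_rows()
  out$significant <- out$q_value < fdr
  out
}
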