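#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_tile geom_segment
#'   geom_text labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' @rdname kaplan_scan
#' @param x A `kaplan_scan` object.
#' @param ... Unused.
#' @export
tidy.kaplan_scan <- function(x, ...) {
  x$data %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), events = sum(.data$event), .groups = "drop")
}

#' @rdname kaplan_scan
#' @export
glance.kaplan_scan <- function(x, ...) {
  tibble(cutpoint = x$cutpoint, n_low = x$n_low, n_high = x$n_high,
         statistic = x$statistic, p_value = x$p_value,
         p_scan_adjusted = x$p_scan_adjusted, n_cutpoints = x$n_cutpoints,
         worse_group = x$worse_group)
}

#' @rdname kaplan_scan
#' @param object A `kaplan_scan` object.
#' @export
autoplot.kaplan_scan <- function(object, ...) {
  curves <- object$data %>%
    group_by(.data$group) %>%
    dplyr::group_modify(~ {
      km <- km_estimate(.x$time, .x$event)
      bind_rows(tibble(time = 0, survival = 1),
                tibble(time = km$time, survival = km$survival))
    }) %>% ungroup()
  ggplot(curves, aes(x = .data$time, y = .data$survival,
                     colour = .data$group)) +
    geom_step() +
    labs(x = "time (days)", y = "event-free survival",
         title = sprintf("Kaplan scan (cut %.3g, raw p %.2g)",
                         object$cutpoint, object$p_value)) +
    theme_minimal()
}

#' @rdname bootstrap_branch_support
#' @param x A `supported_dendrogram` object.
#' @param ... Unused.
#' @export
tidy.supported_dendrogram <- function(x, ...) x$support

#' @rdname bootstrap_branch_support
#' @export
glance.supported_dendrogram <- function(x, ...) {
  tibble(n_leaves = length(x$tree$labels), n_boot = x$n_boot,
         n_scales = length(x$scales),
         min_au = min(x$support$au), max_bp = max(x$support$bp))
}

# hclust -> segment coordinates for a base ggplot dendrogram.
dendrogram_segments <- function(hc) {
  n <- length(hc$labels)
  leaf_x <- setNames(match(seq_len(n), hc$order), seq_len(n))
  xs <- numeric(nrow(hc$merge))
  segs <- list()
  for (i in seq_len(nrow(hc$merge))) {
    pos <- function(j) {
      if (j < 0) c(x = unname(leaf_x[as.character(-j)]), h = 0)
      else c(x = xs[j], h = hc$height[j])
    }
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    xs[i] <- mean(c(a["x"], b["x"]))
    h <- hc$height[i]
    segs[[i]] <- tibble(
      x = c(a["x"], b["x"], a["x"]), xend = c(a["x"], b["x"], b["x"]),
      y = c(a["h"], b["h"], h), yend = c(h, h, h), node = i)
  }
  list(segments = bind_rows(segs),
       nodes = tibble(node = seq_along(xs), x = xs, y = hc$height))
}

#' @rdname bootstrap_branch_support
#' @param object A `supported_dendrogram` object.
#' @export
autoplot.supported_dendrogram <- function(object, ...) {
  geom <- dendrogram_segments(object$tree)
  labels_df <- tibble(x = seq_along(object$tree$order),
                      label = object$tree$labels[object$tree$order])
  nodes <- dplyr::bind_cols(geom$nodes, object$support["au"])
  ggplot() +
    geom_segment(data = geom$segments,
                 aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    geom_text(data = nodes,
              aes(x = .data$x, y = .data$y,
                  label = sprintf("%.0f", .data$au)),
              vjust = -0.4, colour = "darkgreen", size = 3) +
    geom_text(data = labels_df,
              aes(x = .data$x, y = 0, label = .data$label),
              angle = 90, hjust = 1.1, size = 3) +
    labs(y = "Ward-2 merge height", x = NULL,
         title = "Cluster dendrogram with AU branch support (%)") +
    theme_minimal()
}

#' Tile plot of a signature-sharing or enrichment result grid
#'
#' @param enrichment Tibble from [signature_sharing()] or
#'   [signature_label_enrichment()].
#' @param x,y Column names for the grid axes (defaults fit
#'   [signature_sharing()] output).
#' @return A ggplot object mapping -log10 adjusted values to fill.
#' @export
plot_enrichment_grid <- function(enrichment, x = "reference", y = "query") {
  enrichment$neglog_q <- -log10(pmax(enrichment$q_value, 1e-300))
  enrichment$neglog_q[is.na(enrichment$q_value)] <- 0
  ggplot(enrichment, aes(x = .data[[x]], y = .data[[y]],
                         fill = .data$neglog_q)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        name = "-log10 FDR") +
    theme_minimal()
}
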