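#' Simulation configuration for paired synthetic datasets
#'
#' Defaults emulate the structure the pipeline is designed to detect: two
#' related datasets (think tumor and normal tissue) of negative-binomial
#' counts with log-normal baseline means and gene-level overdispersion,
#' cluster-unique marker genes, one signature shared between a designated
#' cluster of each dataset (linked by 1:1 ortholog entries), an ortholog map
#' with a 1:many fraction, a planted CNV clone, and a bulk cohort whose
#' survival and age track the planted signature.
#'
#' @param n_clusters Clusters per dataset (default 4).
#' @param cells_per_cluster Cells per cluster (default 100).
#' @param n_genes Genes per dataset before 1:many extras (default 2000).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline gene means
#'   (defaults 1 and 1, i.e. a median of ~2.7 counts).
#' @param dispersion Negative-binomial dispersion (default 0.1; NB size is
#'   `1/dispersion`).
#' @param unique_markers_per_cluster Planted cluster-unique markers
#'   (default 20).
#' @param unique_log2fc Log2 fold-change of unique markers (default 2).
#' @param shared_signature_size Genes shared between the designated clusters
#'   of the two datasets (default 30).
#' @param shared_log2fc Their log2 fold-change (default 2).
#' @param shared_cluster Cluster label carrying the shared signature in both
#'   datasets (default `"c1"`).
#' @param one_to_many_fraction Fraction of dataset-1 genes given a second
#'   ortholog partner (default 0.1).
#' @param n_samples Samples per dataset for cell-to-sample assignment
#'   (default 4).
#' @param cnv_clone List describing the planted clone: `cluster`, `chrom`,
#'   `start`, `end`, `state` (1-6), `penetrance`.
#' @param bulk_n Bulk cohort size (default 200).
#' @param bulk_background_genes Non-signature genes in the bulk matrix
#'   (default 470).
#' @param hazard_ratio Hazard ratio per standard deviation of the signature
#'   average (default 3; 1 is the null).
#' @param age_correlation Correlation between signature average and age at
#'   diagnosis (default 0.5).
#' @return Validated configuration list of class `sim_config`.
#' @export
simulation_config <- function(n_clusters = 4,
                              cells_per_cluster = 100,
                              n_genes = 2000,
                              baseline_meanlog = 1,
                              baseline_sdlog = 1,
                              dispersion = 0.1,
                              unique_markers_per_cluster = 20,
                              unique_log2fc = 2,
                              shared_signature_size = 30,
                              shared_log2fc = 2,
                              shared_cluster = "c1",
                              one_to_many_fraction = 0.1,
                              n_samples = 4,
                              cnv_clone = list(cluster = "c2",
                                               chrom = "chr17",
                                               start = 3e7, end = 8e7,
                                               state = 5, penetrance = 0.6),
                              bulk_n = 200,
                              bulk_background_genes = 470,
                              hazard_ratio = 3,
                              age_correlation = 0.5) {
  cfg <- as.list(environment())
  if (any(c(n_clusters, cells_per_cluster, n_genes, n_samples) < 1)) {
    abort_config("counts must be positive")
  }
  if (!is.finite(unique_log2fc) || !is.finite(shared_log2fc)) {
    abort_config("fold-changes must be finite")
  }
  planted <- shared_signature_size +
    2 * n_clusters * unique_markers_per_cluster
  if (planted > n_genes) {
    abort_config("planted marker genes exceed n_genes")
  }
  if (planted + round(one_to_many_fraction * n_genes) > n_genes) {
    abort_config("not enough free genes for the 1:many ortholog fraction")
  }
  if (cnv_clone$penetrance < 0 || cnv_clone$penetrance > 1) {
    abort_config("penetrance must lie in [0, 1]")
  }
  if (cnv_clone$start >= cnv_clone$end || cnv_clone$start < 0) {
    abort_config("clone region malformed")
  }
  if (dispersion <= 0) abort_config("dispersion must be > 0")
  structure(cfg, class = "sim_config")
}

plant_indices <- function(config) {
  K <- config$n_clusters
  u <- config$unique_markers_per_cluster
  shared <- seq_len(config$shared_signature_size)
  offset <- config$shared_signature_size
  unique1 <- lapply(seq_len(K), function(j) offset + (j - 1) * u + seq_len(u))
  offset2 <- offset + K * u
  unique2 <- lapply(seq_len(K), function(j) offset2 + (j - 1) * u + seq_len(u))
  list(shared = shared, unique1 = unique1, unique2 = unique2,
       free = setdiff(seq_len(config$n_genes),
                      c(shared, unlist(unique1), unlist(unique2))))
}

simulate_counts <- function(baseline, fc_by_cluster, clusters, dispersion) {
  mu <- baseline * 2^fc_by_cluster[, clusters, drop = FALSE]
  counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu),
                           size = 1 / dispersion),
                   nrow = nrow(mu))
  counts
}

#' Generate a pair of synthetic single-cell datasets with planted structure
#'
#' Counts are negative-binomial with log-normal baseline means; planted
#' marker genes have their mean multiplied by the configured fold-change in
#' the target cluster only. The shared-signature genes are elevated in the
#' designated cluster of both datasets and linked by 1:1 ortholog entries;
#' 1:many entries are planted on non-marker genes only. Cells are assigned
#' round-robin to samples carrying alternating risk-group labels.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return List with `expr1`, `expr2` ([expression_matrix()]), `assign1`,
#'   `assign2` ([cluster_assignment()]), `orthologs` ([ortholog_map()]) and a
#'   `truth` manifest listing every planted gene, the planted cluster pair,
#'   the 1:many genes and the seed.
#' @export
generate_paired_datasets <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  idx <- plant_indices(config)
  K <- config$n_clusters
  clusters <- paste0("c", seq_len(K))
  shared_cl <- config$shared_cluster
  if (!shared_cl %in% clusters) abort_config("shared_cluster not in clusters")

  withr::with_seed(seed, {
    one_dataset <- function(prefix, unique_idx) {
      genes <- sprintf("%s_g%04d", prefix, seq_len(config$n_genes))
      baseline <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                                config$baseline_sdlog)
      fc <- matrix(0, config$n_genes, K, dimnames = list(genes, clusters))
      for (j in seq_len(K)) {
        fc[unique_idx[[j]], clusters[j]] <- config$unique_log2fc
      }
      fc[idx$shared, shared_cl] <- config$shared_log2fc
      cell_cluster <- rep(clusters, each = config$cells_per_cluster)
      cells <- sprintf("%s_%s_cell%03d", prefix, cell_cluster,
                       sequence(rep(config$cells_per_cluster, K)))
      counts <- simulate_counts(baseline, fc, cell_cluster,
                                config$dispersion)
      dimnames(counts) <- list(genes, cells)
      assign <- tibble(
        cell_id = cells, cluster = cell_cluster,
        sample_id = sprintf("%s_s%d", prefix,
                            1 + (seq_along(cells) - 1) %% config$n_samples))
      assign$risk_group <- ifelse(
        as.integer(sub(".*_s", "", assign$sample_id)) <=
          config$n_samples / 2, "high", "low")
      list(expr = expression_matrix(counts, dataset_id = prefix),
           assign = cluster_assignment(assign), genes = genes)
    }
    d1 <- one_dataset("ds1", idx$unique1)
    d2 <- one_dataset("ds2", idx$unique2)

    n_extra <- round(config$one_to_many_fraction * config$n_genes)
    extra_src <- sample(idx$free, n_extra)
    pairs <- tibble(gene_a = d1$genes, gene_b = d2$genes)
    if (n_extra > 0) {
      extra_genes <- sprintf("ds2_x%04d", seq_len(n_extra))
      pairs <- bind_rows(pairs, tibble(gene_a = d1$genes[extra_src],
                                       gene_b = extra_genes))
    }
    truth <- list(
      seed = seed,
      clusters = clusters,
      shared_cluster = shared_cl,
      shared_signature = list(dataset1 = d1$genes[idx$shared],
                              dataset2 = d2$genes[idx$shared]),
      unique_markers = list(
        dataset1 = setNames(lapply(idx$unique1, function(i) d1$genes[i]),
                            clusters),
        dataset2 = setNames(lapply(idx$unique2, function(i) d2$genes[i]),
                            clusters)),
      one_to_many_genes = d1$genes[extra_src])
    list(expr1 = d1$expr, expr2 = d2$expr,
         assign1 = d1$assign, assign2 = d2$assign,
         orthologs = ortholog_map(pairs), truth = truth)
  })
}

#' Generate a per-cell CNV segment table with a planted clone
#'
#' Every cell carries neutral-dominated background segments (including one
#' spanning the clone region). Cells of the clone cluster are carriers with
#' probability `penetrance` (the Bernoulli draws are the first draws of the
#' seeded stream); carriers gain a segment over the configured region with
#' high probability mass on the configured state.
#'
#' @param config A [simulation_config()] (uses its `cnv_clone` entry).
#' @param assignment A [cluster_assignment()]; the clone cluster must exist.
#' @param seed Integer seed.
#' @return A [cnv_segment_table()]; the carrier cell ids are kept in
#'   attribute `"carriers"` (the truth manifest for clone recovery).
#' @export
generate_cnv_table <- function(config, assignment, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  clone <- config$cnv_clone
  assignment <- cluster_assignment(assignment)
  if (!clone$cluster %in% assignment$cluster) {
    abort_config(sprintf("clone cluster '%s' absent from assignment",
                         clone$cluster))
  }
  clone_cells <- assignment$cell_id[assignment$cluster == clone$cluster]
  withr::with_seed(seed, {
    carrier <- clone_cells[rbinom(length(clone_cells), 1,
                                  clone$penetrance) == 1]
  })
  neutral_probs <- c(0.02, 0.02, 0.90, 0.02, 0.02, 0.02)
  clone_probs <- rep(0.015, 6)
  clone_probs[3] <- 0.02
  clone_probs[clone$state] <- 1 - sum(clone_probs[-clone$state])
  background <- tidyr::expand_grid(
    cell_id = assignment$cell_id,
    chrom = c("chr1", clone$chrom)) %>%
    mutate(start = ifelse(.data$chrom == clone$chrom, clone$start, 0),
           end = ifelse(.data$chrom == clone$chrom, clone$end, 5e7))
  probs_mat <- matrix(neutral_probs, nrow(background), 6, byrow = TRUE)
  carrier_rows <- background$cell_id %in% carrier &
    background$chrom == clone$chrom
  if (any(carrier_rows)) {
    probs_mat[carrier_rows, ] <- matrix(clone_probs, sum(carrier_rows), 6,
                                        byrow = TRUE)
  }
  colnames(probs_mat) <- paste0("p", 1:6)
  out <- cnv_segment_table(dplyr::bind_cols(background,
                                            as_tibble(probs_mat)))
  attr(out, "carriers") <- carrier
  out
}

#' Generate a bulk cohort whose survival and age track a planted signature
#'
#' Bulk expression is log-normal around gene baselines; the signature genes
#' share a per-sample activity component. The per-sample signature average
#' (what downstream scoring sees) is standardized and (1) drives an
#' exponential proportional-hazards event time at `hazard_ratio` per
#' standard deviation, with uniform administrative censoring, and (2) sets
#' age at diagnosis at the configured Pearson correlation. Risk groups are
#' the tertiles of the signature average (top = high).
#'
#' @param config A [simulation_config()].
#' @param signature_genes Character vector naming the planted signature genes
#'   (must be a subset of the generated universe, i.e. of
#'   `sprintf("bulk_sig%03d", ...)`, or supply your own names via
#'   `gene_names`).
#' @param seed Integer seed.
#' @param gene_names Optional character vector naming the signature genes in
#'   the bulk matrix (defaults to `signature_genes`).
#' @return List with `matrix` (genes x samples, linear RPM-like scale),
#'   `clinical` (a [clinical_table()]) and `truth` (the standardized
#'   signature activity per sample and the configuration used).
#' @export
generate_bulk_cohort <- function(config, signature_genes, seed = 1L,
                                 gene_names = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$bulk_n
  if (n < 10) abort_config("bulk cohort needs at least 10 samples")
  sig_genes <- gene_names %||% signature_genes
  n_sig <- length(sig_genes)
  if (n_sig == 0) abort_config("signature must be non-empty")
  genes <- c(sig_genes, sprintf("bulk_bg%04d",
                                seq_len(config$bulk_background_genes)))
  samples <- sprintf("pt%03d", seq_len(n))
  withr::with_seed(seed, {
    baseline <- stats::rlnorm(length(genes), meanlog = 3, sdlog = 0.5)
    activity <- rnorm(n)
    logex <- matrix(rnorm(length(genes) * n, sd = 0.3), length(genes), n)
    logex[seq_len(n_sig), ] <- logex[seq_len(n_sig), ] +
      matrix(activity, n_sig, n, byrow = TRUE)
    mat <- baseline * exp(logex)
    dimnames(mat) <- list(genes, samples)
    sig_avg <- colMeans(mat[seq_len(n_sig), , drop = FALSE])
    s_z <- as.numeric(scale(sig_avg))
    lambda0 <- log(2) / 1000
    times <- rexp(n, rate = lambda0 * config$hazard_ratio^s_z)
    censor <- runif(n, 1000, 3000)
    efs_days <- pmin(times, censor)
    efs_event <- times <= censor
    rho <- config$age_correlation
    age_z <- rho * s_z + sqrt(max(0, 1 - rho^2)) * rnorm(n)
    age_months <- pmax(0, 36 + 18 * age_z)
    tert <- stats::quantile(sig_avg, c(1 / 3, 2 / 3))
    risk <- ifelse(sig_avg > tert[2], "high",
                   ifelse(sig_avg > tert[1], "intermediate", "low"))
    clinical <- clinical_table(tibble(
      sample_id = samples, risk_group = risk, age_months = age_months,
      efs_days = efs_days, efs_event = efs_event))
    list(matrix = mat, clinical = clinical,
         truth = list(seed = seed, activity = setNames(s_z, samples),
                      signature_genes = sig_genes,
                      hazard_ratio = config$hazard_ratio,
                      age_correlation = rho))
  })
}

#' Write a simulated bundle to disk in the pipeline's external formats
#'
#' Writes the MTX bundles, assignment and ortholog TSVs and a `truth.json`
#' manifest so a simulation round-trips through the package readers.
#'
#' @param sim Output of [generate_paired_datasets()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_bundle(sim$expr1, file.path(dir, "dataset1"))
  write_expression_bundle(sim$expr2, file.path(dir, "dataset2"))
  write_cluster_assignment(sim$assign1, file.path(dir, "clusters1.tsv"))
  write_cluster_assignment(sim$assign2, file.path(dir, "clusters2.tsv"))
  write_ortholog_map(sim$orthologs, file.path(dir, "orthologs.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
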