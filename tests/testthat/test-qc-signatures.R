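test_that("detected-gene filter keeps cells within inclusive bounds", {
  expect_equal(detected_gene_bounds("human_ag"),
               c(min_genes = 3000, max_genes = 9000))
  expect_equal(detected_gene_bounds("nb_mouse"),
               c(min_genes = 2000, max_genes = 8000))
  m <- expression_matrix(matrix(c(1, 0, 2,
                                  0, 0, 3,
                                  0, 0, 1), 3, byrow = TRUE,
                                dimnames = list(paste0("g", 1:3),
                                                paste0("c", 1:3))))
  kept <- filter_cells_by_detected_genes(m, 1, 2)
  expect_identical(colnames(kept), "c1")   # c2 detects 0 genes, c3 detects 3
  expect_warning(filter_cells_by_detected_genes(m, 5, 6), "all cells removed")
})

test_that("gene filter is strict by default and matches brute-force counting", {
  counts <- matrix(0L, 4, 8,
                   dimnames = list(paste0("g", 1:4), paste0("c", 1:8)))
  counts[1, 1:6] <- 1L   # 6 cells
  counts[2, 1:5] <- 1L   # exactly 5 cells
  counts[3, 1] <- 1L
  m <- expression_matrix(counts)
  expect_identical(rownames(filter_genes_by_cells(m, 5)), "g1")
  expect_identical(rownames(filter_genes_by_cells(m, 5, strict = FALSE)),
                   c("g1", "g2"))
  # min_cells = 0 strict removes only all-zero genes
  expect_identical(rownames(filter_genes_by_cells(m, 0)),
                   c("g1", "g2", "g3"))
  brute <- rownames(counts)[vapply(seq_len(4), function(i)
    sum(counts[i, ] > 0) > 2, logical(1))]
  expect_identical(rownames(filter_genes_by_cells(m, 2)), brute)
})

test_that("cp10k normalization scales each cell to 10,000", {
  m <- expression_matrix(matrix(c(1, 1, 2), 3,
                                dimnames = list(paste0("g", 1:3), "c1")))
  norm <- cp10k_normalize(m)
  expect_equal(as.numeric(norm), c(2500, 2500, 5000))

  counts <- matrix(c(3, 1, 0, 0), 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_warning(norm2 <- cp10k_normalize(expression_matrix(counts)),
                 "zero-count")
  expect_identical(colnames(norm2), "c1")
  expect_true(all(abs(colSums(norm2) - 1e4) < 1e-6))
  logn <- cp10k_normalize(m, log_transform = TRUE)
  expect_equal(as.numeric(logn), log1p(c(2500, 2500, 5000)))
})

test_that("Welch test matches the reference implementation and conventions", {
  res <- welch_t_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  ref <- t.test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p_value, ref$p.value)

  # degenerate constant groups
  expect_equal(welch_t_test(c(1, 1, 1), c(1, 1, 1))$statistic, 0)
  expect_equal(welch_t_test(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  expect_equal(welch_t_test(c(1, 1), c(2, 2))$p_value, 0)

  # two-sided symmetry over random draws
  withr::with_seed(4, for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(7)
    expect_equal(welch_t_test(x, y)$p_value, welch_t_test(y, x)$p_value)
  })
  expect_error(welch_t_test(1, c(1, 2)),
               class = "sigshare_undefined_test_error")
})

test_that("BH adjustment follows the step-up rule and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(9, {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone in p
    expect_true(all(q >= p & q <= 1))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), class = "sigshare_validation_error")
})

test_that("upregulated set A matches an unvectorized per-gene loop", {
  fx <- toy_norm(n_genes = 25, n_cells = 20, shift_genes = 1:4, shift = 1.5)
  expect_equal(formals(upregulated_genes)$fdr, 0.01)
  res <- upregulated_genes(fx$matrix, fx$assignment, "c1")
  # independent loop: per-gene t.test against the pooled complement + p.adjust
  in_cells <- fx$assignment$cell_id[fx$assignment$cluster == "c1"]
  out_cells <- setdiff(fx$assignment$cell_id, in_cells)
  p_loop <- vapply(rownames(fx$matrix), function(g)
    t.test(unclass(fx$matrix)[g, in_cells],
           unclass(fx$matrix)[g, out_cells])$p.value, numeric(1))
  q_loop <- p.adjust(p_loop, "BH")
  up_loop <- names(q_loop)[q_loop < 0.01 &
    rowMeans(unclass(fx$matrix)[, in_cells]) >
      rowMeans(unclass(fx$matrix)[, out_cells])]
  expect_equal(res$p_value, unname(p_loop))
  expect_identical(res$gene[res$upregulated], up_loop)
  expect_true(all(paste0("g0", 1:4) %in% res$gene[res$upregulated]))

  # all-identical expression yields an empty set
  flat <- normalized_matrix(matrix(1, 5, 10,
                                   dimnames = list(paste0("g", 1:5),
                                                   paste0("c", 1:10))),
                            transform = "standardized")
  asg <- cluster_assignment(tibble::tibble(cell_id = paste0("c", 1:10),
                                           cluster = rep(c("a", "b"), 5)))
  expect_equal(sum(upregulated_genes(flat, asg, "a")$upregulated), 0)
})

test_that("specific signature B requires significance against every cluster", {
  # three clusters; gene g01 elevated in c1 and c2 over c3 only
  withr::with_seed(2, {
    m <- matrix(rnorm(20 * 60, sd = 0.3), 20, 60,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("cell%02d", 1:60)))
    cl <- rep(c("c1", "c2", "c3"), each = 20)
    m["g01", cl != "c3"] <- m["g01", cl != "c3"] + 3
    m["g02", cl == "c1"] <- m["g02", cl == "c1"] + 3
  })
  norm <- normalized_matrix(m, transform = "standardized")
  asg <- cluster_assignment(tibble::tibble(cell_id = colnames(m),
                                           cluster = cl))
  expect_equal(formals(specific_signature)$fdr, 0.01)
  a1 <- upregulated_genes(norm, asg, "c1")
  b1 <- specific_signature(norm, asg, "c1")
  expect_true("g01" %in% a1$gene[a1$upregulated])   # beats the pooled rest
  expect_false("g01" %in% attr(b1, "signature"))    # fails c1-vs-c2
  expect_true("g02" %in% attr(b1, "signature"))

  # oracle: explicit pairwise loop with per-comparison BH
  sig_loop <- Filter(function(g) {
    all(vapply(c("c2", "c3"), function(k) {
      x <- m[g, cl == "c1"]; y <- m[g, cl == k]
      p_all <- vapply(rownames(m), function(gg)
        t.test(m[gg, cl == "c1"], m[gg, cl == k])$p.value, numeric(1))
      q <- p.adjust(p_all, "BH")[g]
      mean(x) > mean(y) && q < 0.01
    }, logical(1)))
  }, rownames(m))
  expect_identical(attr(b1, "signature"), sig_loop)
})

test_that("with two clusters definitions A and B coincide", {
  fx <- toy_norm(n_genes = 30, n_cells = 25, shift_genes = 1:5, shift = 1.5,
                 seed = 8)
  a <- upregulated_genes(fx$matrix, fx$assignment, "c1")
  b <- specific_signature(fx$matrix, fx$assignment, "c1")
  expect_identical(sort(a$gene[a$upregulated]), sort(attr(b, "signature")))
})

test_that("planted specific signatures are recovered with controlled FDP", {
  # moderate-size recovery study under the default generator conditions
  hits <- purrr::map(1:5, function(s) {
    cfg <- simulation_config(n_genes = 600, cells_per_cluster = 100,
                             unique_markers_per_cluster = 10,
                             shared_signature_size = 10)
    sim <- generate_paired_datasets(cfg, seed = 100 + s)
    norm <- cp10k_normalize(sim$expr1, log_transform = TRUE)
    sigs <- signature_sets(norm, sim$assign1)
    planted <- purrr::imap(sim$truth$unique_markers$dataset1, function(g, cl)
      if (cl == sim$truth$shared_cluster)
        c(g, sim$truth$shared_signature$dataset1) else g)
    sens <- mean(unlist(planted) %in% unlist(sigs))
    found <- unlist(sigs)
    fdp <- if (length(found) == 0) 0 else
      mean(!found %in% unlist(planted))
    c(sens = sens, fdp = fdp)
  })
  hits <- do.call(rbind, hits)
  expect_true(all(hits[, "sens"] >= 0.9))
  expect_true(all(hits[, "fdp"] <= 0.05))
})

test_that("null data give fdr-level A sets and B no larger than A", {
  res <- purrr::map(1:10, function(s) {
    fx <- toy_norm(n_genes = 60, n_cells = 30, seed = 300 + s)
    a <- upregulated_genes(fx$matrix, fx$assignment, "c1")
    b <- attr(specific_signature(fx$matrix, fx$assignment, "c1"), "signature")
    c(nA = sum(a$upregulated), nB = length(b))
  })
  res <- do.call(rbind, res)
  expect_true(mean(res[, "nA"]) <= 2)          # ~fdr-level false positives
  expect_true(mean(res[, "nB"] <= res[, "nA"]) >= 0.95)
})
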