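test_that("signature z-score averaging matches hand arithmetic", {
  m <- matrix(c(1, 2, 3,
                4, 6, 8), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  sc <- signature_zscore_average(m, c("g1", "g2"), min_genes = 2)
  z1 <- (c(1, 2, 3) - 2) / sd(c(1, 2, 3))
  z2 <- (c(4, 6, 8) - 6) / sd(c(4, 6, 8))
  expect_equal(unname(sc), (z1 + z2) / 2)

  # the more-than-two-genes filter for scanned signatures
  expect_error(signature_zscore_average(m, c("g1", "g2")),
               class = "sigshare_validation_error")
  m2 <- rbind(m, g3 = c(5, 5, 5))
  expect_warning(signature_zscore_average(m2, c("g1", "g2", "g3"),
                                          min_genes = 2), "constant")
})

test_that("Kaplan-Meier estimate follows the product-limit rule", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  all_censored <- km_estimate(c(5, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(all_censored$survival == 1))
  withr::with_seed(3, {
    t <- rexp(40); e <- runif(40) < 0.6
    km2 <- km_estimate(t, e)
    expect_true(all(diff(km2$survival) <= 1e-12))
    expect_true(all(km2$survival >= 0 & km2$survival <= 1))
  })
  expect_error(km_estimate(numeric(0), logical(0)),
               class = "sigshare_validation_error")
})

test_that("log-rank test matches survdiff and an explicit risk-table walk", {
  t1 <- c(1, 2, 3); e1 <- c(1, 1, 1)
  t2 <- c(4, 5, 6); e2 <- c(1, 1, 1)
  res <- logrank_test(t1, e1, t2, e2)
  walk <- logrank_walk(t1, e1, t2, e2)
  expect_equal(res$statistic, walk$statistic)
  expect_equal(res$p_value, walk$p)
  sd <- survival::survdiff(survival::Surv(c(t1, t2), c(e1, e2)) ~
                             rep(1:2, each = 3))
  expect_equal(res$statistic, sd$chisq)

  # identical groups, label swap, and the no-event convention
  expect_equal(logrank_test(t1, e1, t1, e1)$statistic, 0)
  expect_equal(logrank_test(t1, e1, t1, e1)$p_value, 1)
  swap <- logrank_test(t2, e2, t1, e1)
  expect_equal(swap$statistic, res$statistic)
  expect_equal(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))$p_value, 1)

  withr::with_seed(10, for (i in 1:5) {
    ta <- rexp(25); ea <- runif(25) < 0.7
    tb <- rexp(30, 1.5); eb <- runif(30) < 0.7
    mine <- logrank_test(ta, ea, tb, eb)
    ref <- survival::survdiff(survival::Surv(c(ta, tb), c(ea, eb)) ~
                                rep(1:2, c(25, 30)))
    expect_equal(mine$statistic, ref$chisq)
    w <- logrank_walk(ta, ea, tb, eb)
    expect_equal(mine$statistic, w$statistic)
  })
})

test_that("the cutpoint scan equals exhaustive brute force", {
  withr::with_seed(14, {
    n <- 60
    scores <- rnorm(n)
    times <- rexp(n, exp(0.8 * scores) / 500)
    events <- runif(n) < 0.7
  })
  scan <- kaplan_scan(scores, times, events, min_group_fraction = 0.1)
  # brute force: same candidate set, one logrank_test per cutpoint
  s <- sort(scores)
  min_n <- max(3, ceiling(0.1 * n))
  cuts <- (s[-n] + s[-1])[s[-n] < s[-1]] / 2
  cuts <- cuts[vapply(cuts, function(cc)
    sum(scores <= cc) >= min_n && sum(scores > cc) >= min_n, logical(1))]
  ps <- vapply(cuts, function(cc)
    logrank_test(times[scores <= cc], events[scores <= cc],
                 times[scores > cc], events[scores > cc])$p_value,
    numeric(1))
  expect_equal(scan$n_cutpoints, length(cuts))
  expect_equal(scan$p_value, min(ps))
  expect_equal(scan$cutpoint, cuts[which.min(ps)])
  expect_gte(scan$p_scan_adjusted, scan$p_value)

  expect_error(kaplan_scan(rep(1, 20), rexp(20), rep(TRUE, 20)),
               class = "sigshare_no_cutpoint_error")
})

test_that("a clean two-population split is found inside the planted gap", {
  withr::with_seed(15, {
    scores <- c(rnorm(50, -3), rnorm(50, 3))
    rate <- ifelse(scores > 0, 6 / 500, 1 / 500)
    times <- rexp(100, rate); events <- rep(TRUE, 100)
  })
  scan <- kaplan_scan(scores, times, events)
  # the chosen split recovers the planted populations to within two samples
  expect_lte(abs(scan$n_low - 50), 2)
  expect_equal(scan$worse_group, "high-score")
  expect_lt(scan$p_value, 1e-10)
})

test_that("scan_signatures reports a Bonferroni family correction", {
  cfg <- simulation_config(bulk_n = 120)
  bulk <- generate_bulk_cohort(cfg, sprintf("sig%03d", 1:20), seed = 4)
  sigs <- list(planted = sprintf("sig%03d", 1:20),
               tiny = sprintf("sig%03d", 1:2),   # fails the >2-gene filter
               random = sprintf("bulk_bg%04d", 1:15))
  expect_warning(res <- scan_signatures(bulk$matrix, bulk$clinical, sigs),
                 "skipped")
  expect_equal(unique(res$correction), "Bonferroni")
  expect_true(is.na(res$p_value[res$signature == "tiny"]))
  ok <- !is.na(res$p_value)
  expect_true(all(res$adjusted_p[ok] >= res$p_value[ok]))
  expect_true(res$adjusted_p[res$signature == "planted"] < 0.01)
  expect_equal(res$worse_group[res$signature == "planted"], "high-score")
  g <- glance(kaplan_scan(signature_zscore_average(
    bulk$matrix, sprintf("sig%03d", 1:20)),
    bulk$clinical$efs_days, bulk$clinical$efs_event))
  expect_true(all(c("cutpoint", "p_value", "worse_group") %in% names(g)))
})

test_that("per-gene ANOVA equals t-squared and the sum-of-squares oracle", {
  withr::with_seed(16, {
    m <- matrix(rlnorm(30 * 40, 3, 0.4), 30, 40,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:40)))
    groups <- rep(c("high", "low"), each = 20)
    m["g01", groups == "high"] <- m["g01", groups == "high"] * 4
  })
  res <- per_gene_group_differential(m, groups)
  # two groups: F equals the square of the pooled-variance t statistic
  x <- log2(m["g05", groups == "high"] + 1)
  y <- log2(m["g05", groups == "low"] + 1)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$statistic[res$gene == "g05"], unname(tt$statistic)^2)
  # direct ANOVA decomposition for the planted gene
  v <- log2(m["g01", ] + 1)
  grand <- mean(v)
  ssb <- sum(tapply(v, groups, function(z) length(z) * (mean(z) - grand)^2))
  ssw <- sum(tapply(v, groups, function(z) sum((z - mean(z))^2)))
  f <- (ssb / 1) / (ssw / (40 - 2))
  expect_equal(res$statistic[res$gene == "g01"], f)
  expect_true(res$significant[res$gene == "g01"])
  expect_equal(res$top_group[res$gene == "g01"], "high")

  flat <- per_gene_group_differential(
    matrix(5, 3, 8, dimnames = list(paste0("g", 1:3), paste0("s", 1:8))),
    rep(c("a", "b"), 4))
  expect_true(all(flat$p_value == 1))
})

test_that("per-gene age correlation splits direct and inverse lists", {
  ages <- c(2, 10, 18, 30, 55)
  m <- rbind(lin = 3 * ages + 7, neg = -2 * ages + 100,
             noise = c(5, 1, 9, 2, 7))
  colnames(m) <- paste0("s", 1:5)
  res <- per_gene_age_correlation(m, ages)
  expect_equal(res$r[res$gene == "lin"], 1)
  expect_equal(res$r[res$gene == "neg"], -1)
  expect_equal(res$direction[res$gene == "neg"], "inverse")
  ct <- cor.test(m["noise", ], ages)
  expect_equal(res$r[res$gene == "noise"], unname(ct$estimate))
  expect_equal(res$p_value[res$gene == "noise"], ct$p.value)
  expect_warning(per_gene_age_correlation(rbind(m, flat = rep(1, 5)), ages),
                 "constant")
})

test_that("per-gene survival scans assign hazard drivers to the worse-with-high list", {
  cfg <- simulation_config(bulk_n = 100, bulk_background_genes = 30)
  bulk <- generate_bulk_cohort(cfg, sprintf("sig%03d", 1:5), seed = 21)
  driver <- bulk$truth$activity[colnames(bulk$matrix)]
  m <- rbind(bulk$matrix[1:20, ], driver = driver)
  res <- per_gene_survival_groups(m, bulk$clinical$efs_days,
                                  bulk$clinical$efs_event)
  expect_equal(res$direction[res$gene == "driver"], "worse_with_high")
  # direction is invariant to affine rescaling of the gene
  m2 <- m; m2["driver", ] <- 5 + 0.1 * m2["driver", ]
  res2 <- per_gene_survival_groups(m2, bulk$clinical$efs_days,
                                   bulk$clinical$efs_event)
  expect_equal(res2$direction[res2$gene == "driver"],
               res$direction[res$gene == "driver"])
  expect_equal(res2$p_value[res2$gene == "driver"],
               res$p_value[res$gene == "driver"])
})

test_that("signature-label enrichment reproduces the planted associations", {
  uni <- paste0("g", 1:400)
  lists <- list(surv_worse = paste0("g", 1:60),
                age_direct = paste0("g", 10:90))
  sigs <- list(nC3 = paste0("g", 1:40),          # inside both lists
               other = paste0("g", 300:340))
  res <- signature_label_enrichment(sigs, lists, uni)
  expect_true(all(res$tier[res$signature == "nC3"] == "significant"))
  expect_true(all(res$tier[res$signature == "other"] == "ns"))
  self <- signature_label_enrichment(list(s = lists$surv_worse), lists, uni)
  expect_equal(self$reference[which.min(self$q_value)], "surv_worse")
})
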