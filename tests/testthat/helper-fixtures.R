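# Small builders and independent oracles shared across the suite.

toy_counts <- function() {
  m <- matrix(c(1, 0,
                2, 3,
                0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("cell1", "cell2")))
  expression_matrix(m, dataset_id = "toy")
}

# Two-cluster normalized matrix with an optional planted gene shift.
toy_norm <- function(n_genes = 20, n_cells = 30, shift_genes = integer(0),
                     shift = 2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * 2 * n_cells), n_genes, 2 * n_cells)
    m[shift_genes, seq_len(n_cells)] <- m[shift_genes, seq_len(n_cells)] + shift
    dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("cell%03d", seq_len(2 * n_cells)))
    list(matrix = normalized_matrix(m, transform = "standardized"),
         assignment = cluster_assignment(tibble::tibble(
           cell_id = colnames(m),
           cluster = rep(c("c1", "c2"), each = n_cells))))
  })
}

# Independent one-sided Fisher oracle: full enumeration of the upper
# hypergeometric tail via choose().
fisher_enumerate <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - m2):min(m1, k)
  pmf <- choose(m1, xs) * choose(m2, k - xs) / choose(m1 + m2, k)
  sum(pmf[xs >= a])
}

# Independent log-rank oracle: explicit walk of the risk table.
logrank_walk <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- as.logical(c(e1, e2))
  g1 <- seq_along(times) <= length(t1)
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & g1)
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       p = if (V > 0) pchisq(stat, 1, lower.tail = FALSE) else 1)
}

# Brute-force Ward-2 agglomeration: at every step recompute the Ward.D2
# merge cost between all current groups from the original coordinates.
ward2_brute <- function(coords) {
  groups <- as.list(seq_len(nrow(coords)))
  merges <- list()
  cost <- function(a, b) {
    na <- length(a); nb <- length(b)
    ca <- colMeans(coords[a, , drop = FALSE])
    cb <- colMeans(coords[b, , drop = FALSE])
    sqrt(2 * na * nb / (na + nb) * sum((ca - cb)^2))
  }
  while (length(groups) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i < j) {
        h <- cost(groups[[i]], groups[[j]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(groups[[best[1]]], groups[[best[2]]])),
           height = best_h)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  merges
}

hclust_clade_members <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) -j else members[[j]]
    members[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  members
}
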