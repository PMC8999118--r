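# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no fixture files.

# small deterministic count matrix with two obvious cell groups
toy_counts <- function() {
  count_matrix(rbind(c(9, 8, 0, 1),
                     c(7, 9, 1, 0),
                     c(0, 1, 8, 9),
                     c(1, 0, 9, 7),
                     c(2, 2, 2, 2)),
               gene_ids = paste0("g", 1:5),
               cell_ids = paste0("c", 1:4),
               labels = c("A", "A", "B", "B"))
}

rand_counts <- function(m, n, seed, lambda = 3) {
  set.seed(seed)
  count_matrix(matrix(stats::rpois(m * n, lambda), m, n),
               gene_ids = paste0("g", seq_len(m)),
               cell_ids = paste0("c", seq_len(n)))
}

# small, fast simulation used where the full 22,002-gene default is overkill
tiny_sim <- function(seed = 1L, ...) {
  sim_params(n_genes = 500L, cells_per_group = 30L, seed = seed, ...)
}

# nonnegative matrix with two disjoint-support cell groups; K-means on the
# raw columns trivially recovers the split, so it serves as a separation
# oracle for embedding-based clustering
block_matrix <- function(m = 40L, n_per = 10L, seed = 1L) {
  set.seed(seed)
  X <- matrix(0, m, 2L * n_per)
  X[1:(m / 2), 1:n_per] <- 5 + matrix(runif(m / 2 * n_per), m / 2)
  X[(m / 2 + 1):m, (n_per + 1):(2 * n_per)] <-
    5 + matrix(runif(m / 2 * n_per), m / 2)
  list(X = X, labels = rep(c("A", "B"), each = n_per))
}

# --- independent oracles -------------------------------------------------

# brute-force pair-counting ARI: enumerates every pair of items, tallies the
# 2x2 coincidence counts, and applies the pair-count identity directly
oracle_ari <- function(p, q) {
  n <- length(p)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sp <- p[i] == p[j]
    sq <- q[i] == q[j]
    if (sp && sq) n11 <- n11 + 1
    else if (sp) n10 <- n10 + 1
    else if (sq) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

oracle_purity <- function(p, q) {
  s <- 0
  for (cl in unique(p)) s <- s + max(table(q[p == cl]))
  s / length(p)
}

oracle_nmi <- function(p, q) {
  n <- length(p)
  ent <- function(x) {
    pr <- table(x) / n
    -sum(pr * log(pr))
  }
  mi <- 0
  for (a in unique(p)) for (b in unique(q)) {
    pab <- sum(p == a & q == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / (sum(p == a) / n * sum(q == b) / n))
  }
  if (ent(p) + ent(q) == 0) return(1)
  2 * mi / (ent(p) + ent(q))
}

# all set partitions of n items as restricted-growth label vectors
all_partitions <- function(n) {
  res <- list()
  rec <- function(s, mx) {
    if (length(s) == n) {
      res[[length(res) + 1L]] <<- s
      return(invisible())
    }
    for (v in 1:(mx + 1)) rec(c(s, v), max(mx, v))
  }
  rec(1L, 1L)
  res
}
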