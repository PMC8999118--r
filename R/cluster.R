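#' K-means on the learned cell embedding
#'
#' Runs Lloyd's algorithm with k-means++ seeding on the rows of V (one row
#' per cell), keeping the best of \code{n_restarts} runs by total
#' within-cluster sum of squares. Fully deterministic given \code{seed}.
#'
#' @param F a \code{Factorization} (clusters rows of \code{F$V}), or a plain
#'   numeric matrix with one row per observation.
#' @param K number of clusters, \code{1 <= K <= n}.
#' @param seed integer seed.
#' @param n_restarts independent k-means++ restarts (default 10).
#' @return a \code{ClusterResult}: list with \code{assignments} (0-based
#'   cluster index per cell), \code{K}, \code{centers} (K x r),
#'   \code{inertia}.
#' @export
kmeans_embed <- function(F, K, seed = 1L, n_restarts = 10L) {
  V <- if (inherits(F, "Factorization")) F$V else as.matrix(F)
  n <- nrow(V)
  if (K < 1 || K > n) stop(sprintf("K = %d out of range [1, %d]", K, n))
  set.seed(seed)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(V, K)
    km <- suppressWarnings(
      stats::kmeans(V, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(assignments = best$cluster - 1L, K = as.integer(K),
                 centers = best$centers, inertia = best$tot.withinss),
            class = "ClusterResult")
}

# k-means++ seeding: first center uniform, each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(V, K) {
  n <- nrow(V)
  idx <- integer(K)
  idx[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- colSums((t(V) - V[idx[1L], ])^2)
    for (k in 2L:K) {
      if (all(d2 == 0)) {
        idx[k] <- sample.int(n, 1L)
      } else {
        idx[k] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, colSums((t(V) - V[idx[k], ])^2))
    }
  }
  # duplicate rows would make stats::kmeans error on identical centers
  C <- V[idx, , drop = FALSE]
  if (anyDuplicated(C)) {
    dup <- duplicated(C)
    C[dup, ] <- C[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(C), sd = 1e-8), sum(dup), ncol(C))
  }
  C
}

#' Scan cluster numbers around a center value
#'
#' Refits the self-paced model and clusters for every K in
#' \code{[k_center - radius, k_center + radius]} with \code{K >= 2}
#' (smaller values are reported as unavailable), using rank \code{r = K}
#' for each fit. When ground-truth labels are supplied the score is ARI and
#' the best K is the ARI argmax; otherwise only K-means inertia is reported
#' and no best-K flag is set.
#'
#' @param X nonnegative ProcessedMatrix or matrix.
#' @param cfg a [spac_config()]; its \code{r} is overridden per K.
#' @param k_center center of the scan (e.g. an external estimate of the
#'   number of cell types).
#' @param radius half-width of the scan window (default 3).
#' @param labels optional ground-truth labels.
#' @return data.frame with columns \code{K}, \code{available},
#'   \code{score} (ARI or NA), \code{inertia}, \code{best}.
#' @export
scan_k <- function(X, cfg, k_center, radius = 3L, labels = NULL) {
  ks <- (k_center - radius):(k_center + radius)
  rows <- lapply(ks, function(K) {
    if (K < 2)
      return(data.frame(K = K, available = FALSE, score = NA_real_,
                        inertia = NA_real_, best = FALSE))
    cfg_k <- cfg; cfg_k$r <- as.integer(K)
    fit <- spac_fit(X, cfg_k)
    cl <- kmeans_embed(fit$factors, K, seed = cfg$seed)
    sc <- if (!is.null(labels)) ari(cl$assignments, labels) else NA_real_
    data.frame(K = K, available = TRUE, score = sc,
               inertia = cl$inertia, best = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels) && any(out$available))
    out$best[which.max(ifelse(out$available, out$score, -Inf))] <- TRUE
  out
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: K = %d, n = %d, inertia = %.4g\n",
              x$K, length(x$assignments), x$inertia))
  cat("  sizes:", paste(tabulate(x$assignments + 1L, x$K), collapse = ", "),
      "\n")
  invisible(x)
}
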