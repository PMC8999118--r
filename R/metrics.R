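# External clustering indices: adjusted Rand index, purity, and normalized
# mutual information, all computed from the clusters-by-classes contingency
# table. Label vectors may be of any atomic type; only the induced partition
# matters, so every index is invariant to relabeling.

#' Contingency table between two partitions
#'
#' @param pred predicted cluster labels (any atomic vector).
#' @param truth ground-truth class labels, same length.
#' @return list with \code{table} (clusters x classes integer matrix),
#'   \code{a} (row margins), \code{b} (column margins), \code{N}.
#' @export
contingency <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (!length(pred)) stop("empty partitions")
  tab <- table(pred = as.character(pred), truth = as.character(truth))
  tab <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  list(table = tab, a = rowSums(tab), b = colSums(tab), N = length(pred))
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{\tfrac12\left[\sum_i
#'   \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right] - E}, \quad
#'   E = \sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} / \binom{N}{2}.}
#' Identical partitions score 1; independent ones score about 0; values can
#' be negative for worse-than-chance agreement.
#'
#' @inheritParams contingency
#' @return scalar in \code{[-1, 1]}.
#' @export
ari <- function(pred, truth) {
  ct <- contingency(pred, truth)
  if (ct$N < 2) stop("ARI undefined for fewer than 2 items")
  sum_ij <- sum(choose(ct$table, 2))
  sum_a <- sum(choose(ct$a, 2))
  sum_b <- sum(choose(ct$b, 2))
  expected <- sum_a * sum_b / choose(ct$N, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Cluster purity
#'
#' Weighted fraction of each cluster occupied by its majority true class:
#' \code{(1/N) * sum_k max_j n_kj}.
#'
#' @inheritParams contingency
#' @return scalar in \code{[0, 1]}.
#' @export
purity <- function(pred, truth) {
  ct <- contingency(pred, truth)
  sum(apply(ct$table, 1L, max)) / ct$N
}

#' Normalized mutual information
#'
#' \code{2 I(C, Y) / (H(C) + H(Y))} with natural-log entropies computed from
#' the empirical joint distribution. When both partitions are single-cluster
#' the denominator is zero and the value is defined as 1 (the partitions are
#' identical).
#'
#' @inheritParams contingency
#' @return scalar in \code{[0, 1]}.
#' @export
nmi <- function(pred, truth) {
  ct <- contingency(pred, truth)
  p_ij <- ct$table / ct$N
  p_a <- ct$a / ct$N
  p_b <- ct$b / ct$N
  h_a <- -sum(p_a[p_a > 0] * log(p_a[p_a > 0]))
  h_b <- -sum(p_b[p_b > 0] * log(p_b[p_b > 0]))
  if (h_a + h_b == 0) return(1)
  nz <- p_ij > 0
  mi <- sum(p_ij[nz] * log(p_ij[nz] / outer(p_a, p_b)[nz]))
  max(0, min(1, 2 * mi / (h_a + h_b)))
}

#' Full metric report for a clustering result
#'
#' @param pred predicted cluster labels or a \code{ClusterResult}.
#' @param truth ground-truth class labels.
#' @param percent report ARI/purity/NMI multiplied by 100 (the convention
#'   used in summary tables); default \code{FALSE} returns raw values.
#' @return a \code{MetricReport}: list with \code{ari}, \code{purity},
#'   \code{nmi}, \code{contingency}, \code{N}.
#' @export
metric_report <- function(pred, truth, percent = FALSE) {
  if (inherits(pred, "ClusterResult")) pred <- pred$assignments
  ct <- contingency(pred, truth)
  sc <- if (percent) 100 else 1
  structure(list(ari = sc * ari(pred, truth),
                 purity = sc * purity(pred, truth),
                 nmi = sc * nmi(pred, truth),
                 contingency = ct$table, N = ct$N, percent = percent),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  unit <- if (x$percent) " (x100)" else ""
  cat(sprintf("MetricReport%s: ARI = %.4g, purity = %.4g, NMI = %.4g (N = %d)\n",
              unit, x$ari, x$purity, x$nmi, x$N))
  invisible(x)
}
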