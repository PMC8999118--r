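# Gamma-Poisson scRNA-seq count simulator in the style of the Splat model:
# gene base means from a gamma prior, per-group multiplicative differential
# expression, log-normal library sizes, a mean-trended biological
# coefficient of variation giving negative-binomial counts, and logistic
# dropout. Group labels are exported as ground truth for the clustering
# metrics.

#' Simulation parameters
#'
#' Defaults describe a two-group, 200-cell, 22,002-gene experiment in a
#' deliberately hard regime: only a small fraction of genes separate the
#' groups, with modest fold-changes, strong overdispersion and dropout, so
#' that naive clustering sits near chance level while factorization-based
#' methods recover part of the structure.
#'
#' @param n_groups number of cell groups (default 2).
#' @param cells_per_group cells per group (default 100).
#' @param n_genes genes (default 22002).
#' @param de_prob per-group probability that a gene is differentially
#'   expressed (default 0.1).
#' @param de_facscale log-normal sdlog of DE fold-changes (default 0.25);
#'   factors are symmetric in log space, so up- and down-regulation are
#'   equally likely.
#' @param mean_shape,mean_rate gamma prior on gene base means
#'   (defaults 0.6, 0.3).
#' @param lib_loc,lib_scale log-normal meanlog/sdlog of cell library sizes
#'   (defaults 11, 0.4; meanlog 11 is ~60k reads, and sdlog 0.4 gives the
#'   severalfold spread of sequencing depth across cells that makes some
#'   cells much harder to fit than others).
#' @param bcv baseline biological coefficient of variation (default 0.4);
#'   the realized BCV of a gene in a cell is \code{bcv + 1/sqrt(mu)}, so
#'   low-expression genes are noisier.
#' @param dropout_mid,dropout_shape logistic dropout parameters on the
#'   log-mean scale (defaults 0, -1): an entry with expected count mu is
#'   zeroed with probability \code{plogis(dropout_shape * (log(mu) -
#'   dropout_mid))}.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return a \code{SimParams} list.
#' @export
sim_params <- function(n_groups = 2L, cells_per_group = 100L,
                       n_genes = 22002L, de_prob = 0.1, de_facscale = 0.25,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = 11, lib_scale = 0.4, bcv = 0.4,
                       dropout_mid = 0, dropout_shape = -1, seed = 1L) {
  stopifnot(n_groups >= 1, cells_per_group >= 1, n_genes >= 1,
            de_prob >= 0, de_prob <= 1, de_facscale > 0,
            mean_shape > 0, mean_rate > 0, lib_scale > 0, bcv > 0)
  structure(list(n_groups = as.integer(n_groups),
                 cells_per_group = as.integer(cells_per_group),
                 n_genes = as.integer(n_genes), de_prob = de_prob,
                 de_facscale = de_facscale, mean_shape = mean_shape,
                 mean_rate = mean_rate, lib_loc = lib_loc,
                 lib_scale = lib_scale, bcv = bcv,
                 dropout_mid = dropout_mid, dropout_shape = dropout_shape,
                 seed = as.integer(seed)),
            class = "SimParams")
}

#' Simulate a labeled scRNA-seq count matrix
#'
#' Draws gene base means from Gamma(mean_shape, mean_rate); gives each
#' group an independent set of DE genes (probability \code{de_prob} per
#' gene) with multiplicative log-normal(0, de_facscale) factors; draws cell
#' library sizes from log-normal(lib_loc, lib_scale) and rescales each
#' cell's group mean profile to its library size; mixes a gamma noise layer
#' with mean-trended BCV into Poisson sampling (negative-binomial counts);
#' and finally applies logistic dropout. Counts, group labels and all
#' randomness are fully determined by \code{p$seed}.
#'
#' @param p a [sim_params()].
#' @return a [count_matrix()] with \code{labels} set to group names.
#' @export
simulate_counts <- function(p = sim_params()) {
  stopifnot(inherits(p, "SimParams"))
  set.seed(p$seed)
  m <- p$n_genes
  n <- p$n_groups * p$cells_per_group
  base_mean <- stats::rgamma(m, shape = p$mean_shape, rate = p$mean_rate)

  # per-group multiplicative DE factors (1 = not DE)
  group_fac <- matrix(1, m, p$n_groups)
  for (g in seq_len(p$n_groups)) {
    is_de <- stats::runif(m) < p$de_prob
    group_fac[is_de, g] <-
      stats::rlnorm(sum(is_de), meanlog = 0, sdlog = p$de_facscale)
  }
  group_mean <- base_mean * group_fac          # m x n_groups
  group_prop <- sweep(group_mean, 2L, colSums(group_mean), "/")

  group <- rep(seq_len(p$n_groups), each = p$cells_per_group)
  lib <- stats::rlnorm(n, meanlog = p$lib_loc, sdlog = p$lib_scale)
  mu <- group_prop[, group, drop = FALSE] *
    matrix(lib, m, n, byrow = TRUE)            # expected count per entry

  bcv2 <- (p$bcv + 1 / sqrt(pmax(mu, 1e-8)))^2
  lambda <- stats::rgamma(m * n, shape = 1 / bcv2, scale = mu * bcv2)
  counts <- matrix(stats::rpois(m * n, lambda), m, n)

  drop_p <- stats::plogis(p$dropout_shape * (log(pmax(mu, 1e-8)) -
                                               p$dropout_mid))
  keep <- matrix(stats::runif(m * n) >= drop_p, m, n)
  counts <- counts * keep

  count_matrix(counts,
               gene_ids = paste0("gene", seq_len(m)),
               cell_ids = paste0("cell", seq_len(n)),
               labels = paste0("Group", group))
}

#' Plant outlier cells in a count matrix
#'
#' Replaces \code{n_outliers} randomly chosen cells' count vectors with a
#' gene-permuted, intensity-scaled copy of themselves, producing cells whose
#' expression breaks the gene-level structure shared by their group. Labels
#' are retained; the planted cells are flagged in the returned object's
#' \code{outliers} element. With \code{n_outliers = 0} the input is returned
#' unchanged (with an all-FALSE flag vector).
#'
#' @param c a [count_matrix()].
#' @param n_outliers number of cells to corrupt, \code{< ncol}.
#' @param intensity multiplicative count inflation applied to the permuted
#'   profile (default 3).
#' @param seed integer seed.
#' @return a [count_matrix()] with an extra logical element \code{outliers}.
#' @export
plant_outliers <- function(c, n_outliers, intensity = 3, seed = 1L) {
  validate_count_matrix(c)
  n <- ncol(c$counts)
  if (n_outliers >= n) stop("n_outliers must be smaller than the cell count")
  set.seed(seed)
  flag <- rep(FALSE, n)
  if (n_outliers > 0) {
    idx <- sample.int(n, n_outliers)
    flag[idx] <- TRUE
    for (j in idx) {
      perm <- sample.int(nrow(c$counts))
      c$counts[, j] <- round(c$counts[perm, j] * intensity)
    }
  }
  c$outliers <- flag
  validate_count_matrix(c)
  c
}
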