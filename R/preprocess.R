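#' Preprocessing configuration
#'
#' Settings for the four-step preprocessing pipeline: (1) drop genes with no
#' counts anywhere, (2) drop genes expressed in too few cells, (3) keep the
#' top highly variable genes, (4) log-transform and per-gene standardize.
#'
#' @param min_cells_expressed a gene must have a nonzero count in at least
#'   this many cells to survive step 2 (default 3).
#' @param n_hvg number of highly variable genes retained in step 3
#'   (default 1000).
#' @param scale_per_gene standardize each gene row to mean 0, variance 1
#'   after the log transform (default \code{TRUE}).
#' @param nonneg_mode how step 4's standardized (hence partly negative)
#'   matrix is made nonnegative for NMF: \code{"shift"} subtracts each gene
#'   row's minimum, \code{"clip"} zeroes negative entries, \code{"none"}
#'   leaves the matrix as is (only valid when downstream tolerates negatives).
#' @return a \code{PreprocessConfig} list.
#' @export
preprocess_config <- function(min_cells_expressed = 3L, n_hvg = 1000L,
                              scale_per_gene = TRUE,
                              nonneg_mode = c("shift", "clip", "none")) {
  nonneg_mode <- match.arg(nonneg_mode)
  stopifnot(min_cells_expressed >= 0, n_hvg >= 1)
  structure(list(min_cells_expressed = as.integer(min_cells_expressed),
                 n_hvg = as.integer(n_hvg),
                 scale_per_gene = isTRUE(scale_per_gene),
                 nonneg_mode = nonneg_mode),
            class = "PreprocessConfig")
}

#' Filter unexpressed and rarely expressed genes
#'
#' Steps 1 and 2: removes genes with zero total count, then genes with a
#' nonzero count in fewer than \code{min_cells_expressed} cells. The cell set
#' is never changed.
#'
#' @param c a [count_matrix()].
#' @param min_cells_expressed minimum number of expressing cells (step 2);
#'   0 applies step 1 only.
#' @return filtered [count_matrix()].
#' @export
filter_genes <- function(c, min_cells_expressed = 3L) {
  validate_count_matrix(c)
  n_expressing <- rowSums(c$counts > 0)
  keep <- rowSums(c$counts) > 0 & n_expressing >= min_cells_expressed
  if (!any(keep)) stop("all genes removed by filtering")
  out <- count_matrix(c$counts[keep, , drop = FALSE],
                      gene_ids = c$gene_ids[keep], cell_ids = c$cell_ids,
                      labels = c$labels)
  out$outliers <- c$outliers
  out
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Library-size normalizes each cell to the median library size, log1p
#' transforms, computes each gene's dispersion (variance / mean), bins genes
#' into 20 equal-frequency bins by mean expression, z-scores dispersions
#' within each bin, and keeps the \code{n_hvg} genes with the highest
#' normalized dispersion. Input gene order is preserved among the survivors.
#'
#' @param c a [count_matrix()].
#' @param n_hvg number of genes to keep. If the matrix has fewer genes, all
#'   are kept with a warning.
#' @param n_bins number of mean-expression bins (default 20).
#' @return [count_matrix()] restricted to the selected genes.
#' @export
select_hvg <- function(c, n_hvg = 1000L, n_bins = 20L) {
  validate_count_matrix(c)
  m <- nrow(c$counts)
  if (m <= n_hvg) {
    if (m < n_hvg)
      warning(sprintf("requested %d HVGs but only %d genes present; keeping all",
                      n_hvg, m))
    return(c)
  }
  disp <- gene_dispersion(c$counts, n_bins = n_bins)
  ord <- order(disp, decreasing = TRUE)
  keep <- sort(ord[seq_len(n_hvg)])
  out <- count_matrix(c$counts[keep, , drop = FALSE],
                      gene_ids = c$gene_ids[keep], cell_ids = c$cell_ids,
                      labels = c$labels)
  out$outliers <- c$outliers
  out
}

# Normalized dispersion statistic underlying select_hvg. Exposed internally
# for tests; returns one value per gene (higher = more variable than genes
# of similar mean).
gene_dispersion <- function(counts, n_bins = 20L) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  target <- stats::median(lib)
  norm <- sweep(counts, 2L, lib, "/") * target
  lx <- log1p(norm)
  mu <- rowMeans(lx)
  v <- rowMeans(lx^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  # keep ~10 genes per bin so within-bin z-scores stay meaningful on
  # small matrices; large matrices use the full bin count
  n_bins <- max(1L, min(n_bins, length(mu) %/% 10L, length(unique(mu))))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  zd <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    zd[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  zd
}

#' Log-transform and per-gene standardize counts
#'
#' Step 4: \code{X = log(1 + counts)}, then each gene row is centered and
#' scaled to unit variance using the population (1/n) variance convention.
#' Rows with zero post-log variance become all-zero rows rather than NaN.
#' Optionally shifts or clips the result to be nonnegative, as required by
#' NMF.
#'
#' @param c a [count_matrix()].
#' @param cfg a [preprocess_config()].
#' @return a \code{ProcessedMatrix}: list with \code{X} (genes x cells),
#'   \code{gene_ids}, \code{cell_ids}, \code{labels}.
#' @export
log_scale <- function(c, cfg = preprocess_config()) {
  validate_count_matrix(c)
  X <- log1p(c$counts)
  if (cfg$scale_per_gene) {
    mu <- rowMeans(X)
    v <- rowMeans(X^2) - mu^2
    v[v < 0] <- 0           # numeric noise
    s <- sqrt(v)
    X <- (X - mu) / ifelse(s > 0, s, 1)
    X[s == 0, ] <- 0
  }
  X <- make_nonneg(X, cfg$nonneg_mode)
  structure(list(X = X, gene_ids = c$gene_ids, cell_ids = c$cell_ids,
                 labels = c$labels, outliers = c$outliers),
            class = "ProcessedMatrix")
}

#' Shift or clip a matrix to be nonnegative
#'
#' NMF requires \code{X >= 0} but per-gene standardization produces negative
#' values. \code{"shift"} subtracts each row's minimum (preserving all
#' within-gene distances between cells), \code{"clip"} zeroes negatives,
#' \code{"none"} returns the input unchanged.
#'
#' @param X numeric matrix.
#' @param mode \code{"shift"}, \code{"clip"} or \code{"none"}.
#' @return transformed matrix.
#' @export
make_nonneg <- function(X, mode = c("shift", "clip", "none")) {
  mode <- match.arg(mode)
  switch(mode,
         shift = {
           rmin <- apply(X, 1L, min)
           X - pmin(rmin, 0)
         },
         clip = pmax(X, 0),
         none = X)
}

#' Run the full preprocessing pipeline
#'
#' \code{filter_genes} then \code{select_hvg} then \code{log_scale}, logging
#' how many genes each step removes.
#'
#' @param c a [count_matrix()].
#' @param cfg a [preprocess_config()].
#' @param verbose print per-step gene counts.
#' @return a \code{ProcessedMatrix} (see [log_scale()]).
#' @export
preprocess_pipeline <- function(c, cfg = preprocess_config(),
                                verbose = FALSE) {
  validate_count_matrix(c)
  m0 <- nrow(c$counts)
  cf <- filter_genes(c, cfg$min_cells_expressed)
  m1 <- nrow(cf$counts)
  ch <- select_hvg(cf, cfg$n_hvg)
  m2 <- nrow(ch$counts)
  if (verbose)
    message(sprintf("preprocess: %d genes -> %d after filtering -> %d HVGs",
                    m0, m1, m2))
  log_scale(ch, cfg)
}

#' @export
print.ProcessedMatrix <- function(x, ...) {
  cat(sprintf("ProcessedMatrix: %d genes x %d cells, range [%.3f, %.3f]\n",
              nrow(x$X), ncol(x$X), min(x$X), max(x$X)))
  invisible(x)
}
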