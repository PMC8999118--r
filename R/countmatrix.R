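#' Construct a CountMatrix
#'
#' A \code{CountMatrix} bundles a raw genes-by-cells integer count matrix with
#' gene and cell identifiers and, optionally, per-cell ground-truth labels.
#' It is the entry point of the whole pipeline: rows are genes, columns are
#' cells, and every downstream operation preserves that orientation.
#'
#' @param counts numeric matrix, genes in rows and cells in columns. All
#'   entries must be nonnegative integers (dropout zeros included).
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to the matrix rownames, or \code{gene1..geneM} if absent.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column. Defaults to colnames, or \code{cell1..cellN}.
#' @param labels optional character vector of ground-truth cell classes,
#'   aligned 1:1 with \code{cell_ids}.
#'
#' @return An object of class \code{CountMatrix}: a list with elements
#'   \code{counts}, \code{gene_ids}, \code{cell_ids}, \code{labels}.
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL,
                         labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(gene_ids)) {
    gene_ids <- rownames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  dimnames(counts) <- NULL
  obj <- structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         labels = if (is.null(labels)) NULL else as.character(labels)),
    class = "CountMatrix"
  )
  validate_count_matrix(obj)
  obj
}

#' Validate CountMatrix invariants
#'
#' Checks that counts are nonnegative integers, identifiers are unique and of
#' matching length, and labels (if any) align with cells. Called by every
#' constructor and reader; user code rarely needs it directly.
#'
#' @param x object to validate.
#' @return \code{x}, invisibly, if valid; otherwise an error is thrown naming
#'   the first violated invariant.
#' @export
validate_count_matrix <- function(x) {
  if (!inherits(x, "CountMatrix")) stop("not a CountMatrix")
  cnt <- x$counts
  if (!is.matrix(cnt)) stop("counts must be a matrix")
  if (nrow(cnt) < 1L || ncol(cnt) < 1L)
    stop("CountMatrix must have at least one gene and one cell")
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(cnt))
    stop(sprintf(
      "counts must be nonnegative integers; entry [%d, %d] = %s violates this",
      ij[1L], ij[2L], format(cnt[bad[1L]])))
  }
  if (length(x$gene_ids) != nrow(cnt))
    stop("gene_ids length does not match number of rows")
  if (length(x$cell_ids) != ncol(cnt))
    stop("cell_ids length does not match number of columns")
  if (anyDuplicated(x$gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(x$cell_ids)) stop("cell_ids must be unique")
  if (!is.null(x$labels) && length(x$labels) != ncol(cnt))
    stop("labels must align 1:1 with cells")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells\n", nrow(x$counts),
              ncol(x$counts)))
  nz <- mean(x$counts == 0)
  cat(sprintf("  sparsity: %.1f%% zeros\n", 100 * nz))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}
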