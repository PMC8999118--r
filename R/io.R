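#' Read a count matrix from disk
#'
#' Reads either a dense TSV (genes in rows, cells in columns, header row of
#' cell IDs, first column gene IDs) or a MatrixMarket coordinate triplet
#' (\code{matrix.mtx} plus \code{genes.tsv} and \code{barcodes.tsv} sidecars,
#' the layout written by CellRanger-era tools). MTX indices are 1-based on
#' disk; entries absent from the coordinate list are zero.
#'
#' @param path for \code{dense_tsv}, the TSV file; for \code{mtx_triplet},
#'   either the directory containing \code{matrix.mtx}/\code{genes.tsv}/
#'   \code{barcodes.tsv} or the \code{.mtx} file itself (sidecars are then
#'   looked up next to it).
#' @param format one of \code{"dense_tsv"}, \code{"mtx_triplet"}.
#' @param transpose if \code{TRUE} the dense file is cells-by-genes and is
#'   transposed into the canonical genes-by-cells orientation on read.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("dense_tsv", "mtx_triplet"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    if (!file.exists(path)) stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    if (length(header) < 2L)
      stop("malformed header at line 1 of ", path,
           ": expected gene-ID column followed by cell IDs")
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, row.names = NULL,
                            colClasses = c("character",
                                           rep("numeric", length(header) - 1L)))
    cell_ids <- colnames(df)[-1L]
    mat <- as.matrix(df[, -1L, drop = FALSE])
    gene_ids <- df[[1L]]
    if (transpose) {
      mat <- t(mat)
      tmp <- gene_ids; gene_ids <- cell_ids; cell_ids <- tmp
    }
    return(count_matrix(mat, gene_ids = gene_ids, cell_ids = cell_ids))
  }
  # mtx_triplet
  paths <- mtx_triplet_paths(path)
  if (!file.exists(paths$mtx)) stop("file not found: ", paths$mtx)
  m <- as.matrix(Matrix::readMM(paths$mtx))
  gene_ids <- utils::read.table(paths$genes, sep = "\t",
                                colClasses = "character")[[1L]]
  cell_ids <- utils::read.table(paths$barcodes, sep = "\t",
                                colClasses = "character")[[1L]]
  if (length(gene_ids) != nrow(m))
    stop(sprintf("genes.tsv has %d entries but matrix has %d rows",
                 length(gene_ids), nrow(m)))
  if (length(cell_ids) != ncol(m))
    stop(sprintf("barcodes.tsv has %d entries but matrix has %d columns",
                 length(cell_ids), ncol(m)))
  count_matrix(m, gene_ids = gene_ids, cell_ids = cell_ids)
}

mtx_triplet_paths <- function(path) {
  if (dir.exists(path)) {
    list(mtx = file.path(path, "matrix.mtx"),
         genes = file.path(path, "genes.tsv"),
         barcodes = file.path(path, "barcodes.tsv"))
  } else {
    d <- dirname(path)
    list(mtx = path, genes = file.path(d, "genes.tsv"),
         barcodes = file.path(d, "barcodes.tsv"))
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: \code{read_counts(write_counts(m))} reproduces
#' \code{m} exactly in both formats.
#'
#' @param m a [count_matrix()].
#' @param path dense TSV file path, or directory for the MTX triplet.
#' @param format one of \code{"dense_tsv"}, \code{"mtx_triplet"}.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(m, path, format = c("dense_tsv", "mtx_triplet")) {
  format <- match.arg(format)
  validate_count_matrix(m)
  if (format == "dense_tsv") {
    df <- data.frame(gene = m$gene_ids, m$counts, check.names = FALSE)
    colnames(df) <- c("gene", m$cell_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    sp <- Matrix::Matrix(m$counts, sparse = TRUE)
    Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
    writeLines(m$gene_ids, file.path(path, "genes.tsv"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    if (!is.null(m$labels))
      utils::write.table(
        data.frame(cell = m$cell_ids, label = m$labels),
        file.path(path, "labels.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read ground-truth cell labels
#'
#' Accepts either a bare one-label-per-line file or a two-column TSV of
#' (cell_id, label). The two-column form is reordered to match \code{cell_ids}
#' so label order never depends on file order.
#'
#' @param path label file.
#' @param cell_ids cell identifiers to align a two-column file against;
#'   required for the two-column form.
#' @return character vector of labels, in cell order.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- lengths(parts)
  if (all(ncol1 == 1L)) return(vapply(parts, `[`, "", 1L))
  if (!all(ncol1 == 2L))
    stop("label file must have one or two tab-separated columns throughout")
  ids <- vapply(parts, `[`, "", 1L)
  lab <- vapply(parts, `[`, "", 2L)
  if (anyDuplicated(ids))
    stop("duplicate cell_id in label file: ", ids[anyDuplicated(ids)][1L])
  if (is.null(cell_ids))
    stop("cell_ids required to order a two-column label file")
  idx <- match(cell_ids, ids)
  if (anyNA(idx))
    stop("cell_id not found in label file: ", cell_ids[which(is.na(idx))[1L]])
  lab[idx]
}
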