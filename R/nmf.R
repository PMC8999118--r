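# Multiplicative-update NMF core: objectives, per-cell losses, and one-step
# updates for the unweighted and cell-weighted models. X is genes x cells
# (m x n), U is m x r, V is n x r, so X ~ U V^T and row i of V is the
# embedding of cell i. All denominators are guarded by EPS.

EPS <- 1e-10

#' Initialize NMF factors
#'
#' Draws U and V i.i.d. uniform(0, 1) scaled by \code{sqrt(mean(X) / r)} so
#' that \code{U \%*\% t(V)} starts on the scale of X. Entries are strictly
#' positive, which multiplicative updates require (a zero entry can never
#' leave zero).
#'
#' @param X nonnegative numeric matrix (genes x cells) or ProcessedMatrix.
#' @param r factorization rank, \code{1 <= r <= min(dim(X))}.
#' @param seed integer seed; same seed gives identical factors.
#' @return a \code{Factorization}: list with \code{U} (m x r), \code{V}
#'   (n x r), \code{r}.
#' @export
init_factors <- function(X, r, seed = 1L) {
  X <- as_input_matrix(X)
  m <- nrow(X); n <- ncol(X)
  if (r < 1 || r > min(m, n))
    stop(sprintf("rank r = %d out of range [1, %d]", r, min(m, n)))
  set.seed(seed)
  sc <- sqrt(max(mean(X), EPS) / r)
  F <- list(U = matrix(stats::runif(m * r), m, r) * sc,
            V = matrix(stats::runif(n * r), n, r) * sc,
            r = as.integer(r))
  class(F) <- "Factorization"
  F
}

as_input_matrix <- function(X) {
  if (inherits(X, "ProcessedMatrix")) X <- X$X
  if (!is.matrix(X)) X <- as.matrix(X)
  X
}

#' Weighted NMF objective (data-fit term)
#'
#' Frobenius mode: \code{sum_i w_i * ||x_i - U v_i||^2} (weighted sum of
#' squared residual column norms). l21 mode: \code{sum_i w_i *
#' ||x_i - U v_i||_2} (unsquared column norms, the robust variant that
#' down-weights outlier cells). The self-paced regularizer is not included;
#' see [spl_regularizer()].
#'
#' @param X data matrix (genes x cells) or ProcessedMatrix.
#' @param F a \code{Factorization}.
#' @param w per-cell weights in \code{[0, 1]}; defaults to all ones.
#' @param norm \code{"frobenius"} or \code{"l21"}.
#' @return nonnegative scalar.
#' @export
nmf_objective <- function(X, F, w = NULL,
                          norm = c("frobenius", "l21")) {
  norm <- match.arg(norm)
  X <- as_input_matrix(X)
  if (is.null(w)) w <- rep(1, ncol(X))
  if (length(w) != ncol(X)) stop("weight vector length must equal #cells")
  sq <- colSums((X - F$U %*% t(F$V))^2)
  if (norm == "frobenius") sum(w * sq) else sum(w * sqrt(sq))
}

#' Per-cell reconstruction losses
#'
#' The self-paced controller ranks cells by these losses: squared residual
#' norm \code{||x_i - U v_i||^2} in Frobenius mode, unsquared norm in l21
#' mode.
#'
#' @inheritParams nmf_objective
#' @return nonnegative vector, one loss per cell.
#' @export
cell_losses <- function(X, F, norm = c("frobenius", "l21")) {
  norm <- match.arg(norm)
  X <- as_input_matrix(X)
  if (nrow(X) != nrow(F$U) || ncol(X) != nrow(F$V))
    stop("dimension mismatch between X and factors")
  sq <- colSums((X - F$U %*% t(F$V))^2)
  if (norm == "frobenius") sq else sqrt(sq)
}

#' One unweighted multiplicative update step
#'
#' The classical Lee--Seung Frobenius update: U is updated first, then V
#' using the updated U, which makes the Frobenius objective non-increasing
#' at every step. At an exact factorization \code{X = U V^T} every ratio is
#' 1, so exact factorizations are fixed points.
#'
#' @param X nonnegative data matrix or ProcessedMatrix.
#' @param F a \code{Factorization}.
#' @return updated \code{Factorization}.
#' @export
update_unweighted <- function(X, F) {
  X <- as_input_matrix(X)
  U <- F$U; V <- F$V
  U <- U * (X %*% V) / (U %*% crossprod(V) + EPS)
  V <- V * crossprod(X, U) / (V %*% crossprod(U) + EPS)
  F$U <- U; F$V <- V
  F
}

#' One cell-weighted multiplicative update step
#'
#' Applies the diagonal cell-weight matrix \code{W = diag(w)} on the cell
#' axis. In Frobenius mode the update is the weighted Lee--Seung extension
#' (numerators and denominators both carry W, so unit weights reduce exactly
#' to [update_unweighted()]). In l21 mode the V-step uses the trace-form
#' update with denominator \code{W V V^T X^T U}; its objective trace is worth
#' monitoring since, unlike the Frobenius step, it carries no monotonicity
#' guarantee.
#'
#' @inheritParams update_unweighted
#' @param w per-cell weights in \code{[0, 1]}.
#' @param norm \code{"frobenius"} or \code{"l21"}.
#' @return updated \code{Factorization}.
#' @export
update_weighted <- function(X, F, w, norm = c("frobenius", "l21")) {
  norm <- match.arg(norm)
  X <- as_input_matrix(X)
  if (length(w) != ncol(X)) stop("weight vector length must equal #cells")
  U <- F$U; V <- F$V
  wV <- V * w                                  # rows of V scaled by w
  U <- U * (X %*% wV) / (U %*% crossprod(V, wV) + EPS)
  if (norm == "frobenius") {
    V <- V * (w * crossprod(X, U)) / (w * (V %*% crossprod(U)) + EPS)
  } else {
    XtU <- crossprod(X, U)                     # n x r
    V <- V * (w * XtU) / (w * (V %*% crossprod(V, XtU)) + EPS)
  }
  F$U <- U; F$V <- V
  F
}

#' Fit plain (unweighted) NMF
#'
#' Baseline factorization without self-paced weighting: seeded
#' initialization followed by \code{n_iter} unweighted multiplicative
#' updates.
#'
#' @param X nonnegative data matrix or ProcessedMatrix.
#' @param r rank.
#' @param n_iter number of update steps (default 300).
#' @param seed integer seed.
#' @param trace_every record the objective every this many steps
#'   (0 = final only).
#' @return list with \code{factors} (a \code{Factorization}) and
#'   \code{objective} (trace of Frobenius objectives).
#' @export
nmf_fit <- function(X, r, n_iter = 300L, seed = 1L, trace_every = 10L) {
  X <- as_input_matrix(X)
  F <- init_factors(X, r, seed = seed)
  obj <- numeric(0)
  for (it in seq_len(n_iter)) {
    F <- update_unweighted(X, F)
    if (trace_every > 0 && (it %% trace_every == 0L || it == n_iter))
      obj <- c(obj, nmf_objective(X, F))
  }
  if (trace_every == 0) obj <- nmf_objective(X, F)
  list(factors = F, objective = obj)
}

#' @export
print.Factorization <- function(x, ...) {
  cat(sprintf("Factorization: U %d x %d, V %d x %d\n",
              nrow(x$U), x$r, nrow(x$V), x$r))
  invisible(x)
}
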