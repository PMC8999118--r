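# Self-paced learning controller: sample-weight schemes, the pace-parameter
# (lambda) schedule, and the outer fit loop that grows the selected cell set
# from the easiest 60% to all cells.

#' Hard self-paced weights
#'
#' Binary selection: a cell is admitted (\code{w_i = 1}) iff its loss is
#' strictly below the pace parameter lambda.
#'
#' @param losses nonnegative per-cell losses.
#' @param lam pace parameter, > 0.
#' @return 0/1 weight vector.
#' @export
hard_weights <- function(losses, lam) {
  stopifnot(lam > 0)
  as.numeric(losses < lam)
}

#' Mixture (soft) self-paced weights
#'
#' Continuous selection with a soft transition zone: \code{w_i = 1} when
#' \code{l_i <= zeta*lam/(zeta + lam)}, \code{w_i = 0} when \code{l_i >=
#' lam}, and \code{w_i = zeta/l_i - zeta/lam} in between. The scheme is
#' continuous in the loss at both breakpoints and maps into \code{[0, 1]}.
#' A zero loss falls in the first branch, so no division by zero can occur.
#'
#' @param losses nonnegative per-cell losses.
#' @param lam pace parameter, > 0.
#' @param zeta soft-zone parameter, > 0; the default policy ties it to
#'   \code{0.5 * lam}.
#' @return weight vector in \code{[0, 1]}.
#' @export
mixture_weights <- function(losses, lam, zeta = 0.5 * lam) {
  stopifnot(lam > 0, zeta > 0)
  lo <- zeta * lam / (zeta + lam)
  ifelse(losses <= lo, 1,
         ifelse(losses >= lam, 0, zeta / losses - zeta / lam))
}

#' Self-paced regularizer value
#'
#' The penalty term added to the weighted data fit: \code{-lam * sum(w)} for
#' the hard scheme, \code{-sum(zeta * log(w + zeta/lam))} for the mixture
#' scheme. Minimizing data fit plus this term over \code{w in [0,1]^n} yields
#' [hard_weights()] / [mixture_weights()] in closed form.
#'
#' @param w weight vector in \code{[0, 1]}.
#' @param lam pace parameter, > 0.
#' @param zeta mixture soft-zone parameter, > 0.
#' @param scheme \code{"hard"} or \code{"mixture"}.
#' @return scalar regularizer value (nonpositive for the hard scheme).
#' @export
spl_regularizer <- function(w, lam, zeta = 0.5 * lam,
                            scheme = c("mixture", "hard")) {
  scheme <- match.arg(scheme)
  if (scheme == "hard") -lam * sum(w)
  else -sum(zeta * log(w + zeta / lam))
}

#' Schedule the pace parameter for a target selection fraction
#'
#' Sets lambda just above the k-th smallest loss, \code{k =
#' ceiling(target_fraction * n)}, so that under hard weighting exactly the k
#' easiest cells (plus any cells tied with the k-th) satisfy \code{l_i <
#' lambda}. With \code{target_fraction = 1} every cell is selected.
#'
#' @param losses nonnegative per-cell losses.
#' @param target_fraction fraction of cells to admit, in (0, 1].
#' @return lambda > 0.
#' @export
schedule_lambda <- function(losses, target_fraction) {
  if (!length(losses)) stop("empty loss vector")
  stopifnot(target_fraction > 0, target_fraction <= 1)
  k <- ceiling(target_fraction * length(losses))
  kth <- sort(losses, partial = k)[k]
  kth * (1 + 1e-6) + 1e-12
}

#' Self-paced clustering configuration
#'
#' @param norm data-fit norm: \code{"frobenius"} (scSPaC) or \code{"l21"}
#'   (sscSPaC).
#' @param weighting \code{"mixture"} (default) or \code{"hard"}.
#' @param r factorization rank; conventionally set to the expected number of
#'   cell types.
#' @param init_fraction fraction of cells admitted in the first outer
#'   iteration (default 0.6).
#' @param fraction_step percentage-point increment of the admitted fraction
#'   per outer iteration (default 0.1, so the schedule is 0.6, 0.7, 0.8,
#'   0.9, 1.0).
#' @param inner_iters weighted multiplicative updates per outer iteration
#'   (default 50).
#' @param warmup_iters unweighted updates used to obtain the initial losses
#'   before any cell is selected (default 10).
#' @param tol relative objective-change convergence tolerance at full
#'   selection (default 1e-5).
#' @param max_extra_iters outer iterations allowed after full selection
#'   before giving up on \code{tol} (default 20).
#' @param seed integer seed driving initialization.
#' @return a \code{SPaCConfig} list.
#' @export
spac_config <- function(norm = c("frobenius", "l21"),
                        weighting = c("mixture", "hard"),
                        r = 2L, init_fraction = 0.6, fraction_step = 0.1,
                        inner_iters = 50L, warmup_iters = 10L,
                        tol = 1e-5, max_extra_iters = 20L, seed = 1L) {
  norm <- match.arg(norm)
  weighting <- match.arg(weighting)
  stopifnot(init_fraction > 0, init_fraction <= 1,
            fraction_step > 0, fraction_step <= 1, r >= 1)
  structure(list(norm = norm, weighting = weighting, r = as.integer(r),
                 init_fraction = init_fraction, fraction_step = fraction_step,
                 inner_iters = as.integer(inner_iters),
                 warmup_iters = as.integer(warmup_iters),
                 tol = tol, max_extra_iters = as.integer(max_extra_iters),
                 seed = as.integer(seed)),
            class = "SPaCConfig")
}

#' Fit the self-paced NMF model
#'
#' The outer loop of scSPaC/sscSPaC. After a short unweighted warm start to
#' obtain initial losses, lambda is set so the easiest \code{init_fraction}
#' of cells is admitted; each outer iteration then (step 1) runs
#' \code{inner_iters} cell-weighted multiplicative updates with the weights
#' fixed, and (step 2) recomputes per-cell losses, raises the target
#' fraction by \code{fraction_step}, re-derives lambda from the fresh losses
#' (with \code{zeta = 0.5 * lambda}) and recomputes the weights. Once every
#' cell is admitted, outer iterations continue until the relative change of
#' the full objective (data fit plus regularizer) drops below \code{tol}.
#'
#' @param X nonnegative ProcessedMatrix or matrix (genes x cells).
#' @param cfg a [spac_config()].
#' @return list of class \code{SPaCFit}:
#'   \describe{
#'     \item{factors}{final \code{Factorization} (K-means is run on
#'       \code{factors$V}).}
#'     \item{state}{final self-paced state: \code{w}, \code{losses},
#'       \code{lam}, \code{zeta}, \code{selected_fraction}.}
#'     \item{history}{data.frame with one row per outer iteration: lambda,
#'       number of selected cells (\code{w > 0}), data-fit objective, full
#'       objective.}
#'     \item{converged}{logical; \code{FALSE} means the extra-iteration
#'       budget ran out and the best-so-far factors are returned.}
#'   }
#' @export
spac_fit <- function(X, cfg = spac_config()) {
  X <- as_input_matrix(X)
  if (min(X) < 0)
    stop("X must be nonnegative; see make_nonneg() / preprocess_config()")
  n <- ncol(X)
  F <- init_factors(X, cfg$r, seed = cfg$seed)
  for (i in seq_len(cfg$warmup_iters)) F <- update_unweighted(X, F)
  losses <- cell_losses(X, F, cfg$norm)

  frac <- cfg$init_fraction
  lam <- schedule_lambda(losses, frac)
  zeta <- 0.5 * lam
  w <- compute_weights(losses, lam, zeta, cfg$weighting)

  hist <- list()
  prev_obj <- Inf
  converged <- FALSE
  max_outer <- length(seq(cfg$init_fraction, 1, by = cfg$fraction_step)) +
    cfg$max_extra_iters
  for (outer in seq_len(max_outer)) {
    for (i in seq_len(cfg$inner_iters))
      F <- update_weighted(X, F, w, cfg$norm)
    losses <- cell_losses(X, F, cfg$norm)
    fit_obj <- nmf_objective(X, F, w, cfg$norm)
    full_obj <- fit_obj + spl_regularizer(w, lam, zeta, cfg$weighting)
    hist[[outer]] <- data.frame(outer = outer, lambda = lam,
                                fraction = frac, n_selected = sum(w > 0),
                                fit_objective = fit_obj,
                                objective = full_obj)
    at_full <- frac >= 1
    if (at_full) {
      rel <- abs(prev_obj - full_obj) / max(abs(prev_obj), EPS)
      if (is.finite(rel) && rel < cfg$tol) { converged <- TRUE }
    }
    prev_obj <- full_obj
    if (converged) break
    # step 2: raise the pace and re-derive lambda from the fresh losses
    frac <- min(1, frac + if (at_full) 0 else cfg$fraction_step)
    lam <- schedule_lambda(losses, frac)
    zeta <- 0.5 * lam
    w <- compute_weights(losses, lam, zeta, cfg$weighting)
    # a zero-weighted cell's embedding row decays to an exact zero, which
    # multiplicative updates can never revive once the cell is admitted;
    # flooring keeps excluded rows dormant-but-positive so they recover
    F$U <- pmax(F$U, EPS)
    F$V <- pmax(F$V, EPS)
  }
  if (!converged)
    warning("self-paced fit stopped at the outer-iteration budget without ",
            "meeting tol; returning the last iterate")
  structure(list(
    factors = F,
    state = list(w = w, losses = losses, lam = lam, zeta = zeta,
                 selected_fraction = sum(w > 0) / n),
    history = do.call(rbind, hist),
    converged = converged,
    config = cfg), class = "SPaCFit")
}

compute_weights <- function(losses, lam, zeta, weighting) {
  if (weighting == "hard") hard_weights(losses, lam)
  else mixture_weights(losses, lam, zeta)
}

#' @export
print.SPaCFit <- function(x, ...) {
  cat(sprintf("SPaCFit (%s norm, %s weighting, r = %d): %d outer iterations%s\n",
              x$config$norm, x$config$weighting, x$config$r,
              nrow(x$history),
              if (x$converged) ", converged" else " (budget reached)"))
  cat(sprintf("  final objective %.4g, %d/%d cells selected\n",
              x$history$objective[nrow(x$history)],
              sum(x$state$w > 0), length(x$state$w)))
  invisible(x)
}
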