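test_that("hard weights threshold losses at lambda", {
  expect_equal(hard_weights(c(0.1, 0.9), 0.5), c(1, 0))
  expect_equal(hard_weights(1:5, 10), rep(1, 5))
  expect_equal(hard_weights(1:5, 1), rep(0, 5))
})

test_that("mixture weights follow the three-branch soft scheme", {
  # lambda = 2, zeta = 1: breakpoints at 2/3 and 2
  expect_equal(mixture_weights(0.5, 2, 1), 1)
  expect_equal(mixture_weights(2 / 3, 2, 1), 1)
  expect_equal(mixture_weights(1, 2, 1), 0.5)
  expect_equal(mixture_weights(2, 2, 1), 0)
  # continuity at both breakpoints to 1e-12
  lo <- 1 * 2 / (1 + 2)
  expect_lt(abs(mixture_weights(lo + 1e-13, 2, 1) - 1), 1e-12)
  expect_lt(abs(mixture_weights(2 - 1e-13, 2, 1) - 0), 1e-12)
  # zero loss is maximally easy
  expect_equal(mixture_weights(0, 2, 1), 1)
})

test_that("mixture weights are non-increasing in the loss", {
  set.seed(31)
  for (i in 1:20) {
    lam <- runif(1, 0.5, 5)
    l <- sort(runif(50, 0, 2 * lam))
    w <- mixture_weights(l, lam, 0.5 * lam)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("regularizer values match closed forms", {
  expect_equal(spl_regularizer(c(1, 1, 0), lam = 2, scheme = "hard"), -4)
  expect_equal(spl_regularizer(c(0, 0), lam = 2, zeta = 1, scheme = "mixture"),
               -2 * 1 * log(0.5))
  expect_true(is.finite(spl_regularizer(runif(10), lam = 0.3, zeta = 0.15,
                                        scheme = "mixture")))
})

test_that("lambda schedule admits the target fraction of easiest cells", {
  lam <- schedule_lambda(1:10, 0.6)
  expect_equal(sum(hard_weights(1:10, lam)), 6)
  # full fraction admits every cell under both schemes
  lam1 <- schedule_lambda(1:10, 1)
  expect_equal(sum(hard_weights(1:10, lam1)), 10)
  expect_true(all(mixture_weights(1:10, lam1, 0.5 * lam1) > 0))
  # ties: equal losses are all admitted at any fraction
  lamt <- schedule_lambda(rep(2, 7), 0.3)
  expect_equal(sum(hard_weights(rep(2, 7), lamt)), 7)
  # zero losses still yield a positive lambda
  expect_gt(schedule_lambda(rep(0, 4), 0.5), 0)
  expect_error(schedule_lambda(numeric(0), 0.5), "empty")
})

test_that("fit recovers two disjoint-support groups exactly", {
  b <- block_matrix(seed = 21)
  fit <- spac_fit(b$X, spac_config(r = 2, seed = 21))
  cl <- kmeans_embed(fit$factors, 2, seed = 21)
  expect_equal(ari(cl$assignments, b$labels), 1)
})

test_that("the admitted-cell schedule rises from 60% to full selection", {
  b <- block_matrix(seed = 3)
  fit <- spac_fit(b$X, spac_config(r = 2, seed = 3, weighting = "hard"))
  h <- fit$history
  expect_equal(head(h$fraction, 5), c(0.6, 0.7, 0.8, 0.9, 1.0))
  expect_true(all(diff(h$n_selected) >= 0))
  expect_equal(h$n_selected[nrow(h)], ncol(b$X))
  expect_true(all(fit$state$w > 0))
  expect_equal(fit$state$zeta, 0.5 * fit$state$lam)
})

test_that("with everything admitted at once the fit is plain NMF", {
  b <- block_matrix(seed = 13)
  cfg <- spac_config(r = 2, seed = 13, weighting = "hard",
                     init_fraction = 1, inner_iters = 50, tol = Inf)
  fit <- spac_fit(b$X, cfg)
  # warm start (10 unweighted) + outer iterations of all-ones weighted
  # updates must equal the same number of plain unweighted updates
  F <- init_factors(b$X, 2, seed = 13)
  for (i in seq_len(10 + nrow(fit$history) * 50))
    F <- update_unweighted(b$X, F)
  expect_equal(fit$factors$U, F$U, tolerance = 1e-10)
  expect_equal(fit$factors$V, F$V, tolerance = 1e-10)
})

test_that("planted high-loss cells are admitted last", {
  set.seed(17)
  b <- block_matrix(m = 30, n_per = 15, seed = 17)
  X <- b$X
  # corrupt three cells with large unstructured noise
  out_idx <- c(2, 16, 28)
  X[, out_idx] <- X[, out_idx] + matrix(runif(90, 5, 10), 30)
  F <- init_factors(X, 2, seed = 17)
  for (i in 1:10) F <- update_unweighted(X, F)
  l <- cell_losses(X, F)
  expect_true(all(rank(l)[out_idx] > ncol(X) - 6))
  # and the first-admitted 60% excludes them
  lam <- schedule_lambda(l, 0.6)
  expect_equal(sum(hard_weights(l, lam)[out_idx]), 0)
})

test_that("fit rejects matrices with negative entries", {
  X <- matrix(c(-1, 1, 2, 3), 2, 2)
  expect_error(spac_fit(X, spac_config(r = 1)), "nonnegative")
})
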