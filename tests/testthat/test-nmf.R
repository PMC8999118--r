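test_that("initialization is seeded, strictly positive, and range-checked", {
  X <- matrix(runif(40), 8, 5)
  F1 <- init_factors(X, 2, seed = 3)
  F2 <- init_factors(X, 2, seed = 3)
  expect_identical(F1, F2)
  expect_true(all(F1$U > 0) && all(F1$V > 0))
  expect_error(init_factors(X, 6, seed = 1), "out of range")
})

test_that("objective matches hand arithmetic and degenerate cases", {
  # exact factorization -> 0 under both norms
  U <- matrix(c(1, 2, 0, 1), 2, 2)
  V <- matrix(c(1, 0, 1, 1), 2, 2)
  F <- list(U = U, V = V, r = 2L)
  X <- U %*% t(V)
  expect_equal(nmf_objective(X, F, norm = "frobenius"), 0)
  expect_equal(nmf_objective(X, F, norm = "l21"), 0)
  # zero weights null the data term
  expect_equal(nmf_objective(X + 1, F, w = c(0, 0), norm = "frobenius"), 0)
  # 2x2 toy: residual column (0, 1) contributes 1
  Ft <- list(U = matrix(c(1, 0), 2, 1), V = matrix(c(1, 0), 2, 1), r = 1L)
  Xt <- diag(2)
  expect_equal(nmf_objective(Xt, Ft, w = c(1, 1), norm = "frobenius"), 1)
})

test_that("cell losses are squared (frobenius) or plain (l21) column norms", {
  F <- list(U = matrix(0, 2, 1), V = matrix(0, 2, 1), r = 1L)
  X <- cbind(c(3, 4), c(0, 0))
  expect_equal(cell_losses(X, F, "frobenius"), c(25, 0))
  expect_equal(cell_losses(X, F, "l21"), c(5, 0))
  # joint permutation of cells leaves losses permuted identically
  set.seed(1)
  X2 <- matrix(runif(12), 3, 4)
  F2 <- init_factors(X2, 2, seed = 2)
  l <- cell_losses(X2, F2)
  p <- c(3, 1, 4, 2)
  F2p <- F2; F2p$V <- F2$V[p, , drop = FALSE]
  expect_equal(cell_losses(X2[, p], F2p), l[p])
})

test_that("exact factorizations are fixed points of both updates", {
  set.seed(7)
  U <- matrix(runif(12, 0.5, 1.5), 6, 2)
  V <- matrix(runif(8, 0.5, 1.5), 4, 2)
  F <- list(U = U, V = V, r = 2L)
  X <- U %*% t(V)
  Fu <- update_unweighted(X, F)
  expect_equal(Fu$U, U, tolerance = 1e-8)
  expect_equal(Fu$V, V, tolerance = 1e-8)
  Fw <- update_weighted(X, F, w = rep(1, 4), norm = "frobenius")
  expect_equal(Fw$U, U, tolerance = 1e-8)
  expect_equal(Fw$V, V, tolerance = 1e-8)
})

test_that("frobenius objective is non-increasing under its updates", {
  set.seed(11)
  X <- matrix(runif(200), 20, 10)
  F <- init_factors(X, 2, seed = 11)
  prev <- nmf_objective(X, F)
  for (i in 1:200) {
    F <- update_unweighted(X, F)
    ob <- nmf_objective(X, F)
    expect_lte(ob, prev + 1e-9)
    prev <- ob
  }
  # weighted update with a fixed weight vector, same property
  set.seed(12)
  w <- runif(10)
  F <- init_factors(X, 2, seed = 12)
  prev <- nmf_objective(X, F, w)
  for (i in 1:200) {
    F <- update_weighted(X, F, w, "frobenius")
    ob <- nmf_objective(X, F, w)
    expect_lte(ob, prev + 1e-9)
    prev <- ob
  }
})

test_that("unit weights reduce the weighted update to the unweighted one", {
  set.seed(5)
  X <- matrix(runif(60), 10, 6)
  F <- init_factors(X, 3, seed = 5)
  a <- update_unweighted(X, F)
  b <- update_weighted(X, F, w = rep(1, 6), norm = "frobenius")
  expect_equal(a$U, b$U)
  expect_equal(a$V, b$V)
})

test_that("a zero weight removes the cell: its embedding row decays", {
  set.seed(6)
  X <- matrix(runif(40, 1, 2), 8, 5)
  F <- init_factors(X, 2, seed = 6)
  w <- c(1, 1, 0, 1, 1)
  Fw <- update_weighted(X, F, w, "frobenius")
  expect_equal(Fw$V[3, ], c(0, 0))
  # the U-step ignores the zero-weight cell's residual: doubling that
  # cell's data changes nothing
  X2 <- X; X2[, 3] <- X[, 3] * 2
  expect_equal(update_weighted(X2, F, w, "frobenius")$U, Fw$U)
})

test_that("nonnegativity is closed under both updates", {
  set.seed(8)
  X <- matrix(rpois(150, 2), 15, 10)
  F <- init_factors(X, 3, seed = 8)
  for (i in 1:50) {
    F <- update_weighted(X, F, runif(10), sample(c("frobenius", "l21"), 1))
    expect_true(all(F$U >= 0) && all(F$V >= 0))
    expect_false(any(!is.finite(F$U)) || any(!is.finite(F$V)))
  }
})

test_that("plain NMF fit reduces the objective and is seed-reproducible", {
  X <- matrix(rpois(300, 3), 20, 15)
  f1 <- nmf_fit(X, 3, n_iter = 100, seed = 2)
  f2 <- nmf_fit(X, 3, n_iter = 100, seed = 2)
  expect_identical(f1$factors, f2$factors)
  expect_lt(tail(f1$objective, 1), f1$objective[1])
})
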