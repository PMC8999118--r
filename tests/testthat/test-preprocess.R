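test_that("gene filtering removes silent and rarely expressed genes", {
  m <- count_matrix(rbind(c(1, 0, 2), c(0, 0, 0), c(0, 3, 0)),
                    gene_ids = c("g1", "g2", "g3"),
                    cell_ids = c("c1", "c2", "c3"))
  f1 <- filter_genes(m, min_cells_expressed = 1)
  expect_equal(f1$gene_ids, c("g1", "g3"))

  # expressed in 2 cells < threshold 3 -> removed; g1 expressed in 3 kept
  m2 <- count_matrix(rbind(c(1, 1, 1, 1), c(0, 0, 5, 5)),
                    gene_ids = c("g1", "g2"), cell_ids = paste0("c", 1:4))
  expect_equal(filter_genes(m2, 3)$gene_ids, "g1")

  # threshold 0 applies only the silent-gene rule
  expect_equal(filter_genes(m, 0)$gene_ids, c("g1", "g3"))
  expect_error(filter_genes(m2, 10), "all genes removed")
  expect_equal(ncol(filter_genes(m, 1)$counts), 3L)
})

test_that("HVG selection ranks a high-dispersion gene first", {
  # gene 3 swings wildly across cells; the others are near-constant
  m <- count_matrix(rbind(c(5, 5, 5, 6),
                          c(4, 5, 5, 5),
                          c(0, 40, 0, 45),
                          c(5, 6, 5, 5),
                          c(6, 5, 5, 5)),
                    gene_ids = paste0("g", 1:5),
                    cell_ids = paste0("c", 1:4))
  expect_equal(select_hvg(m, 1)$gene_ids, "g3")
  # identity when asking for all genes; warning when asking for more
  expect_equal(select_hvg(m, 5)$gene_ids, m$gene_ids)
  expect_warning(out <- select_hvg(m, 10), "keeping all")
  expect_equal(out$gene_ids, m$gene_ids)
})

test_that("a constant gene never outranks varying genes", {
  m <- count_matrix(rbind(c(3, 3, 3, 3),
                          c(1, 7, 2, 9),
                          c(2, 0, 6, 1)),
                    gene_ids = c("flat", "var1", "var2"),
                    cell_ids = paste0("c", 1:4))
  expect_false("flat" %in% select_hvg(m, 2)$gene_ids)
})

test_that("log-scaling fixes the population variance convention", {
  cfg <- preprocess_config(nonneg_mode = "none")
  # two distinct values standardize to [-1, +1] under the 1/n variance
  # convention (mean 0, population variance exactly 1)
  two <- log_scale(count_matrix(matrix(c(0, 3), 1, 2)), cfg)
  expect_equal(sort(unname(two$X[1, ])), c(-1, 1))
  x <- log1p(c(0, 3))
  expect_equal(unname(log_scale(count_matrix(matrix(c(0, 3), 1, 2)),
                                cfg)$X[1, ]),
               (x - mean(x)) / sqrt(mean(x^2) - mean(x)^2))
  # constant gene maps to a zero row, not NaN
  z <- log_scale(count_matrix(matrix(5, 1, 3)), cfg)
  expect_equal(unname(z$X[1, ]), c(0, 0, 0))
})

test_that("scaled rows have zero mean and unit population variance", {
  m <- rand_counts(30, 12, seed = 4)
  pm <- log_scale(m, preprocess_config(nonneg_mode = "none"))
  mu <- rowMeans(pm$X)
  v <- rowMeans(pm$X^2) - mu^2
  expect_true(all(abs(mu) < 1e-8))
  expect_true(all(abs(v[v > 0] - 1) < 1e-8))
})

test_that("nonnegative modes shift or clip as documented", {
  X <- rbind(c(-2, 0, 2), c(-1, 1, 3))
  expect_equal(make_nonneg(X, "shift"), rbind(c(0, 2, 4), c(0, 2, 4)))
  expect_equal(make_nonneg(X, "clip"), rbind(c(0, 0, 2), c(0, 1, 3)))
  expect_identical(make_nonneg(X, "none"), X)
  # shifting preserves within-gene distances between cells
  s <- make_nonneg(X, "shift")
  expect_equal(as.numeric(dist(t(s))), as.numeric(dist(t(X))))
})

test_that("pipeline output dimensions follow the HVG budget", {
  cm <- simulate_counts(tiny_sim())
  cfg <- preprocess_config(n_hvg = 100)
  pm <- preprocess_pipeline(cm, cfg)
  expect_equal(dim(pm$X), c(100L, 60L))
  expect_true(min(pm$X) >= 0)
  expect_equal(pm$labels, cm$labels)
  # deterministic: rerun gives identical output
  expect_identical(pm$X, preprocess_pipeline(cm, cfg)$X)
})

test_that("pipeline keeps all survivors when the HVG budget exceeds them", {
  cm <- simulate_counts(sim_params(n_genes = 80, cells_per_group = 10))
  expect_warning(pm <- preprocess_pipeline(cm, preprocess_config(n_hvg = 500)),
                 "keeping all")
  expect_lte(nrow(pm$X), 80L)
})
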