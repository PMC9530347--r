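make_counts <- function(mat, cells = sprintf("c%d", seq_len(nrow(mat))),
                        genes = sprintf("g%d", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(cells, genes)
  storage.mode(mat) <- "integer"
  mat
}

make_ann <- function(counts, mito = 0.05, condition = "A") {
  data.frame(cell_id = rownames(counts), condition = condition,
             total_counts = rowSums(counts),
             mito_fraction = rep_len(mito, nrow(counts)),
             stringsAsFactors = FALSE)
}

test_that("cells at or above the mitochondrial cutoff are removed", {
  counts <- make_counts(matrix(5L, nrow = 12, ncol = 2))
  ann <- make_ann(counts, mito = c(0.25, 0.19, rep(0.05, 10)))
  out <- suppressMessages(qc_filter(counts, ann, pipeline_config(min_cells_per_gene = 1)))
  expect_false("c1" %in% rownames(out$counts))   # 0.25 removed
  expect_true("c2" %in% rownames(out$counts))    # 0.19 kept
  ann2 <- make_ann(counts, mito = c(0.20, rep(0.05, 11)))
  out2 <- suppressMessages(qc_filter(counts, ann2, pipeline_config(min_cells_per_gene = 1)))
  expect_false("c1" %in% rownames(out2$counts))  # exactly 20% removed
})

test_that("genes need detection in at least the configured cell count", {
  counts <- matrix(0L, nrow = 15, ncol = 3)
  counts[1:9, 1] <- 1L    # detected in 9 cells -> removed
  counts[1:10, 2] <- 1L   # detected in 10 cells -> kept
  counts[, 3] <- 2L
  counts <- make_counts(counts)
  out <- suppressMessages(qc_filter(counts, make_ann(counts)))
  expect_identical(colnames(out$counts), c("g2", "g3"))
})

test_that("clean input passes through unchanged and the filter is idempotent", {
  counts <- make_counts(matrix(3L, nrow = 12, ncol = 4))
  ann <- make_ann(counts)
  out <- suppressMessages(qc_filter(counts, ann))
  expect_identical(out$counts, counts)
  twice <- suppressMessages(qc_filter(out$counts, out$annotations))
  expect_identical(twice$counts, out$counts)
})

test_that("degenerate filtering errors instead of returning empty output", {
  counts <- make_counts(matrix(1L, nrow = 12, ncol = 2))
  expect_error(suppressMessages(qc_filter(counts, make_ann(counts, mito = 0.5))),
               "cells")
  sparse <- make_counts(matrix(0L, nrow = 12, ncol = 2))
  sparse[1, ] <- 1L
  expect_error(suppressMessages(qc_filter(sparse, make_ann(sparse))), "genes")
})

test_that("identical cells all get size factor 1", {
  counts <- make_counts(matrix(rep(c(3L, 7L, 1L, 4L), each = 60), nrow = 60))
  norm <- normalize_counts(counts)
  expect_equal(unname(norm$size_factors), rep(1, 60), tolerance = 1e-8)
})

test_that("the small-n fallback rescales library sizes to mean 1", {
  counts <- make_counts(matrix(c(50L, 100L, 50L, 100L), nrow = 2))
  norm <- normalize_counts(counts)
  expect_equal(unname(norm$size_factors), c(2 / 3, 4 / 3), tolerance = 1e-12)
})

test_that("normalized values are non-negative and zero exactly at zero counts", {
  set.seed(9)
  counts <- make_counts(matrix(rpois(80, 3), nrow = 8))
  counts[1, 1] <- 0L
  norm <- normalize_counts(counts)
  expect_true(all(norm$values >= 0))
  expect_identical(norm$values == 0, counts == 0)
  expect_equal(mean(norm$size_factors), 1, tolerance = 1e-8)
})

# cells as scaled noisy copies of one profile: the truth the deconvolution
# is supposed to recover
scaled_profile_counts <- function(n = 120, g = 40, seed = 1) {
  set.seed(seed)
  prof <- rpois(g, 10) + 1
  fac <- runif(n, 0.5, 2)
  counts <- sapply(seq_len(g), function(j) rpois(n, fac * prof[j]))
  dimnames(counts) <- list(sprintf("c%d", seq_len(n)),
                           sprintf("g%d", seq_len(g)))
  storage.mode(counts) <- "integer"
  list(counts = counts, truth = fac / mean(fac))
}

test_that("scaling one cell's counts scales its deconvolved factor", {
  d <- scaled_profile_counts()
  k <- 3
  scaled <- d$counts
  scaled[25, ] <- as.integer(round(d$counts[25, ] * k))
  sf0 <- suppressWarnings(normalize_counts(d$counts)$size_factors)
  sf1 <- suppressWarnings(normalize_counts(scaled)$size_factors)
  ratio <- (sf1[25] / sf0[25]) * (mean(sf0) / mean(sf1))
  expect_equal(unname(ratio), k, tolerance = 0.05 * k)
})

test_that("deconvolved factors recover the truth and match the reference", {
  d <- scaled_profile_counts()
  sf <- suppressWarnings(normalize_counts(d$counts)$size_factors)
  expect_gt(cor(sf, d$truth), 0.95)
  skip_if_not_installed("scran")
  ref <- scran::calculateSumFactors(
    SingleCellExperiment::SingleCellExperiment(list(counts = t(d$counts))))
  expect_gt(cor(sf, ref), 0.95)
})

test_that("zero-count cells are rejected by name", {
  counts <- make_counts(matrix(c(0L, 5L, 0L, 5L), nrow = 2))
  expect_error(normalize_counts(counts), "c1")
})

test_that("highly variable genes obey the mean window and dispersion cutoff", {
  set.seed(1)
  n <- 100
  # g1: variable within window; g2: mean above max_mean; g3: constant
  g1 <- rpois(n, 2) * rbinom(n, 1, 0.5)
  g2 <- rpois(n, 60)
  g3 <- rep(1L, n)
  counts <- make_counts(cbind(g1, g2, g3), genes = c("g1", "g2", "g3"))
  norm <- as_norm(log1p(counts))       # unit factors, log1p scale
  cfg <- pipeline_config(n_hvg = 2000, hvg_min_disp = -Inf)
  hvg <- select_hvg(norm, cfg)
  expect_true("g1" %in% hvg)
  expect_false("g2" %in% hvg)          # mean(expm1) ~ 60 > max_mean = 4
  cfg2 <- pipeline_config(hvg_min_disp = 0.1)
  hvg2 <- select_hvg(norm, cfg2)
  expect_false("g3" %in% hvg2)         # zero dispersion
})

test_that("all qualifying genes return when fewer than the cap", {
  b <- cached_benchmark()
  norm <- normalize_counts(b$counts_a)
  hvg <- select_hvg(norm, pipeline_config(hvg_min_disp = -Inf,
                                          hvg_max_mean = Inf))
  expect_equal(sort(hvg), sort(colnames(norm$values)))
})

test_that("well-separated blobs cluster into their two groups", {
  set.seed(3)
  n <- 100; g <- 12
  blob1 <- matrix(rnorm(n * g, 0, 0.3), n, g)
  blob2 <- matrix(rnorm(n * g, 3, 0.3), n, g)
  vals <- rbind(blob1, blob2)
  dimnames(vals) <- list(sprintf("c%d", 1:(2 * n)), sprintf("g%d", 1:g))
  norm <- as_norm(vals)
  cfg <- pipeline_config(n_pcs = 5, seed = 0L)
  labels <- cluster_cells(norm, cfg, genes = colnames(vals))
  expect_equal(length(unique(labels)), 2L)
  truth <- rep(c("x", "y"), each = n)
  expect_equal(length(unique(labels[truth == "x"])), 1L)
  expect_equal(length(unique(labels[truth == "y"])), 1L)
  # reproducibility
  labels2 <- cluster_cells(norm, cfg, genes = colnames(vals))
  expect_identical(labels, labels2)
  # resolution -> 0 collapses a connected graph to one community (a graph
  # with enough neighbours to bridge the blobs)
  cfg0 <- pipeline_config(n_pcs = 5, leiden_resolution = 1e-6,
                          n_neighbors = 120, seed = 0L)
  expect_equal(length(unique(cluster_cells(norm, cfg0, genes = colnames(vals)))),
               1L)
})

test_that("duplicating every cell leaves the partition invariant", {
  set.seed(4)
  n <- 60; g <- 10
  vals <- rbind(matrix(rnorm(n * g, 0, 0.3), n, g),
                matrix(rnorm(n * g, 3, 0.3), n, g))
  dimnames(vals) <- list(sprintf("c%d", 1:(2 * n)), sprintf("g%d", 1:g))
  dup <- rbind(vals, vals)
  rownames(dup) <- sprintf("c%d", 1:(4 * n))
  cfg <- pipeline_config(n_pcs = 5, seed = 0L)
  l1 <- cluster_cells(as_norm(vals), cfg, genes = colnames(vals))
  l2 <- cluster_cells(as_norm(dup), cfg, genes = colnames(vals))
  # every duplicate joins its twin, and no cluster mixes the two blobs
  # (modularity is scale-dependent, so a blob may subdivide on the doubled
  # graph; the symmetry contract is twin co-membership)
  expect_identical(unname(l2[seq_len(2 * n)]), unname(l2[2 * n + seq_len(2 * n)]))
  blob <- rep(rep(c("x", "y"), each = n), 2)
  expect_true(all(vapply(split(blob, l2),
                         function(bl) length(unique(bl)) == 1L, TRUE)))
})

test_that("too few cells for the neighbour graph is an error", {
  vals <- matrix(rnorm(50), 5, 10,
                 dimnames = list(sprintf("c%d", 1:5), sprintf("g%d", 1:10)))
  expect_error(cluster_cells(as_norm(vals), pipeline_config(), genes = colnames(vals)),
               "n_neighbors")
})

test_that("mito fractions can be recovered from gene-name prefixes", {
  counts <- make_counts(matrix(c(1L, 4L, 9L, 6L), nrow = 2),
                        genes = c("MT-CO1", "ACTB"))
  expect_equal(mito_fraction_from_prefix(counts), c(c1 = 0.1, c2 = 0.4))
})
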