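#' Quality-control filtering of cells and genes
#'
#' Removes stressed or dying cells — those with a mitochondrial count
#' fraction at or above `cfg$mito_max` (default: 20% or more) — and then
#' genes detected (count > 0) in fewer than `cfg$min_cells_per_gene` of the
#' surviving cells.  Cells are filtered before genes so detection counts
#' reflect the retained population.  The operation is idempotent.
#'
#' @param counts cells x genes integer matrix.
#' @param ann annotation data.frame covering every cell (`cell_id`,
#'   `mito_fraction`, ...).
#' @param cfg a [pipeline_config()].
#' @return list with filtered `counts` and `annotations`.
#' @export
qc_filter <- function(counts, ann, cfg = pipeline_config()) {
  assert_count_matrix(counts)
  if (!all(rownames(counts) %in% ann$cell_id))
    stop("annotations do not cover all cells")
  ann <- ann[match(rownames(counts), ann$cell_id), , drop = FALSE]
  keep_cells <- ann$mito_fraction < cfg$mito_max
  if (!any(keep_cells)) stop("no cells survive the mitochondrial filter")
  counts <- counts[keep_cells, , drop = FALSE]
  ann <- ann[keep_cells, , drop = FALSE]
  detected <- colSums(counts > 0)
  keep_genes <- detected >= cfg$min_cells_per_gene
  if (!any(keep_genes)) stop("no genes survive the detection filter")
  message(sprintf("qc_filter: removed %d cells (mito >= %.2f), %d genes (< %d cells)",
                  sum(!keep_cells), cfg$mito_max, sum(!keep_genes),
                  cfg$min_cells_per_gene))
  list(counts = counts[, keep_genes, drop = FALSE], annotations = ann)
}

#' Mitochondrial fraction from gene names
#'
#' Fallback for real data whose annotation lacks a `mito_fraction` column:
#' the fraction of counts on genes matching a name prefix (human "MT-").
#'
#' @param counts cells x genes matrix.
#' @param prefix mitochondrial gene-name prefix.
#' @return numeric vector of fractions per cell.
#' @export
mito_fraction_from_prefix <- function(counts, prefix = "MT-") {
  assert_count_matrix(counts)
  mt <- startsWith(colnames(counts), prefix)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("cells with zero total counts: ",
                          paste(head(rownames(counts)[tot == 0]), collapse = ", "))
  rowSums(counts[, mt, drop = FALSE]) / tot
}

#' Normalize counts by pooled size-factor deconvolution
#'
#' Cell-specific size factors in the style of pooled deconvolution: cells
#' are arranged on a ring that alternates small and large libraries, count
#' vectors are summed over sliding pools of sizes \{21, 26, 31, 36, 41\}
#' (clipped to n - 1), each pool's factor is the median ratio of its summed
#' profile to the average cell, and the per-cell factors solve the resulting
#' linear system by least squares (with low-weight library-size anchor
#' rows).  Factors are rescaled to mean 1.  With fewer than 50 cells the
#' estimator falls back to library-size factors.  Normalized values are
#' `log1p(count / size_factor)`.
#'
#' @param counts QC-filtered cells x genes matrix; every cell must have
#'   positive total counts.
#' @param clusters optional labels (condition or cluster) per cell:
#'   deconvolution runs within each cluster and the clusters are then put on
#'   a common scale by the median gene-wise ratio of their pseudo-cell
#'   profiles, which is robust to a minority of differentially expressed
#'   genes.  `NULL` treats all cells as one cluster.
#' @param pool_sizes pool sizes of the deconvolution.
#' @param min_cells_pooling below this many cells (per cluster), use
#'   library-size factors.
#' @return an object of class `normalized_matrix`: list with `values`
#'   (cells x genes, `log1p` scale) and `size_factors` (mean 1).
#' @export
normalize_counts <- function(counts, clusters = NULL,
                             pool_sizes = c(21L, 26L, 31L, 36L, 41L),
                             min_cells_pooling = 50L) {
  assert_count_matrix(counts)
  lib <- rowSums(counts)
  if (any(lib == 0))
    stop("cell(s) with zero total counts: ",
         paste(head(rownames(counts)[lib == 0]), collapse = ", "))
  if (is.null(clusters)) clusters <- rep("all", nrow(counts))
  if (length(clusters) != nrow(counts))
    stop("clusters must have one label per cell")
  clusters <- as.character(clusters)

  sf <- numeric(nrow(counts))
  pseudo <- list()
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    sub <- counts[idx, , drop = FALSE]
    sf_cl <- if (length(idx) < min_cells_pooling) {
      lib[idx] / mean(lib[idx])
    } else {
      deconvolve_size_factors(sub, lib[idx], pool_sizes)
    }
    sf_cl <- sf_cl / mean(sf_cl)
    sf[idx] <- sf_cl
    pseudo[[cl]] <- colMeans(sub / sf_cl)
  }
  # put clusters on a common scale: median gene-wise ratio of pseudo-cells
  ref_cl <- unique(clusters)[1]
  for (cl in unique(clusters)) {
    use <- pseudo[[cl]] > 0 & pseudo[[ref_cl]] > 0
    scale_cl <- median(pseudo[[cl]][use] / pseudo[[ref_cl]][use])
    sf[clusters == cl] <- sf[clusters == cl] * scale_cl
  }

  sf <- sf / mean(sf)
  values <- log1p(counts / sf)
  structure(list(values = values, size_factors = setNames(sf, rownames(counts))),
            class = "normalized_matrix")
}

# Pooled deconvolution of size factors (least-squares solve).
deconvolve_size_factors <- function(counts, lib, pool_sizes) {
  n <- nrow(counts)
  pool_sizes <- pmin(as.integer(pool_sizes), n - 1L)
  pool_sizes <- unique(pool_sizes[pool_sizes >= 2L])
  # ring alternating small and large libraries so pools have balanced depth
  ord <- order(lib)
  ring <- integer(n)
  ring[seq(1L, n, by = 2L)] <- ord[seq_len(ceiling(n / 2))]
  ring[seq(2L, n, by = 2L)] <- rev(ord[seq(ceiling(n / 2) + 1L, n)])
  ref <- colMeans(counts)
  use <- ref > 0

  rows <- list(); cols <- list(); vals <- list(); b <- list()
  r <- 0L
  for (s in pool_sizes) {
    # cumulative sums along the doubled ring give every window in O(n G)
    mat <- counts[ring, use, drop = FALSE]
    cs <- rbind(0, apply(rbind(mat, mat[seq_len(s - 1L), , drop = FALSE]),
                         2, cumsum))
    for (i in seq_len(n)) {
      pooled <- cs[i + s, ] - cs[i, ]
      r <- r + 1L
      members <- ring[((i - 1L):(i + s - 2L)) %% n + 1L]
      rows[[r]] <- rep(r, s); cols[[r]] <- members; vals[[r]] <- rep(1, s)
      b[[r]] <- median(pooled / ref[use])
    }
  }
  # low-weight anchors tying each cell to its library-size factor
  w0 <- 0.05
  lib_sf <- lib / mean(lib)
  for (i in seq_len(n)) {
    r <- r + 1L
    rows[[r]] <- r; cols[[r]] <- i; vals[[r]] <- w0
    b[[r]] <- w0 * lib_sf[i]
  }
  A <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals), dims = c(r, n))
  bb <- unlist(b)
  sf <- tryCatch(
    as.numeric(Matrix::solve(Matrix::crossprod(A),
                             Matrix::crossprod(A, bb))),
    error = function(e) rep(NA_real_, n))
  if (anyNA(sf) || any(!is.finite(sf))) {
    warning("pooled system could not be solved; using library-size factors")
    return(lib_sf)
  }
  if (any(sf <= 0)) {
    warning("non-positive deconvolved size factors; clipping to library-size floor")
    sf[sf <= 0] <- min(lib_sf[sf <= 0], min(sf[sf > 0]))
  }
  sf
}

#' Select highly variable genes
#'
#' Per gene, the mean and dispersion (variance over mean) of
#' `expm1(normalized values)` are computed across cells; dispersions are
#' z-scored within 20 equal-width bins of the mean; genes with mean strictly
#' inside `(hvg_min_mean, hvg_max_mean)` and normalized dispersion at least
#' `hvg_min_disp` qualify, and the top `n_hvg` by normalized dispersion are
#' returned (all qualifying genes when fewer).
#'
#' @param norm a `normalized_matrix` with at least 2 cells.
#' @param cfg a [pipeline_config()].
#' @return character vector of gene ids, by decreasing normalized
#'   dispersion (ties broken by gene id).
#' @export
select_hvg <- function(norm, cfg = pipeline_config()) {
  stopifnot(inherits(norm, "normalized_matrix"))
  x <- expm1(norm$values)
  if (nrow(x) < 2L) stop("need at least 2 cells")
  m <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(m > 0, v / m, 0)

  bins <- cut(m, breaks = 20)
  bin_mean <- tapply(disp, bins, mean)
  bin_sd <- tapply(disp, bins, sd)
  bm <- bin_mean[as.character(bins)]
  bs <- bin_sd[as.character(bins)]
  disp_norm <- ifelse(is.na(bs) | bs == 0, 0, (disp - bm) / bs)

  ok <- m > cfg$hvg_min_mean & m < cfg$hvg_max_mean &
    disp_norm >= cfg$hvg_min_disp
  if (!any(ok)) stop("no genes qualify as highly variable")
  ids <- colnames(norm$values)[ok]
  ord <- order(-disp_norm[ok], ids)
  head(ids[ord], cfg$n_hvg)
}

#' Cluster cells on a nearest-neighbour graph
#'
#' PCA (up to `n_pcs` components) of the per-gene standardized,
#' HVG-restricted normalized values; a kNN graph with `n_neighbors`
#' Euclidean neighbours; community detection by seeded Leiden modularity
#' optimization at `leiden_resolution`.  Labels are `"0"`, `"1"`, ... in
#' decreasing cluster size.
#'
#' @param norm a `normalized_matrix`.
#' @param cfg a [pipeline_config()].
#' @param genes genes to cluster on; defaults to [select_hvg()] output.
#' @return character vector of cluster labels, named by cell id.
#' @export
cluster_cells <- function(norm, cfg = pipeline_config(), genes = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  n <- nrow(norm$values)
  if (n < cfg$n_neighbors + 1L)
    stop("need at least n_neighbors + 1 cells to build the graph")
  if (is.null(genes)) genes <- select_hvg(norm, cfg)
  x <- norm$values[, genes, drop = FALSE]
  keep <- apply(x, 2, sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(cfg$n_pcs, ncol(pc$x))
  emb <- pc$x[, seq_len(k), drop = FALSE]

  d <- as.matrix(dist(emb))
  diag(d) <- Inf
  nbr <- t(apply(d, 1, function(row) order(row)[seq_len(cfg$n_neighbors)]))
  el <- cbind(rep(seq_len(n), cfg$n_neighbors), as.vector(nbr))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))

  memb <- with_seed(stage_seed(cfg$seed, "leiden"), {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = cfg$leiden_resolution,
                           n_iterations = 10L)$membership
  })
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(as.character(seq_along(sizes) - 1L), names(sizes))
  setNames(relabel[as.character(memb)], rownames(norm$values))
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes (log1p scale), size factors mean %.3f\n",
              nrow(x$values), ncol(x$values), mean(x$size_factors)))
  invisible(x)
}
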