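#' Discretize a continuous expression vector
#'
#' Default is equal-width binning with `max(2, ceiling(sqrt(n)))` bins over
#' the observed range (bins right-open except the last); a constant vector
#' yields a single bin.  The alternative `"bayesian_blocks"` method chooses
#' adaptive bin edges by the Scargle dynamic-programming change-point
#' algorithm on the value axis.
#'
#' @param values finite numeric vector (>= 2 values).
#' @param method `"uniform"` or `"bayesian_blocks"`.
#' @param n_bins bin count for the uniform method; default
#'   `max(2, ceiling(sqrt(length(values))))`.
#' @param gene_id optional id carried on the result.
#' @return an object of class `discretized_gene`: list with `gene_id`,
#'   `assignments` (0-based bin index per cell), `bin_edges`, `n_bins`.
#' @export
discretize <- function(values, method = c("uniform", "bayesian_blocks"),
                       n_bins = NULL, gene_id = "gene") {
  method <- match.arg(method)
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("non-finite values cannot be discretized")
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    return(structure(list(gene_id = gene_id,
                          assignments = rep(0L, length(values)),
                          bin_edges = c(lo, hi), n_bins = 1L),
                     class = "discretized_gene"))
  }
  if (method == "uniform") {
    if (is.null(n_bins)) n_bins <- max(2L, ceiling(sqrt(length(values))))
    n_bins <- as.integer(n_bins)
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    a <- pmin(floor((values - lo) / (hi - lo) * n_bins), n_bins - 1L)
  } else {
    edges <- bayesian_block_edges(values)
    n_bins <- length(edges) - 1L
    a <- pmin(findInterval(values, edges, rightmost.closed = TRUE) - 1L,
              n_bins - 1L)
  }
  structure(list(gene_id = gene_id, assignments = as.integer(a),
                 bin_edges = edges, n_bins = as.integer(n_bins)),
            class = "discretized_gene")
}

# Bayesian blocks (event mode): optimal piecewise-constant segmentation of
# the value axis by dynamic programming, fitness N log(N / width) per block
# with a constant change-point prior.
bayesian_block_edges <- function(values, ncp_prior = 4) {
  x <- sort(unique(values))
  k <- length(x)
  counts <- as.numeric(table(factor(values, levels = x)))
  # Voronoi cell edges between distinct values
  edges <- c(x[1], (x[-1] + x[-k]) / 2, x[k])
  block_len <- edges[k + 1] - edges         # length k+1; width to the end
  best <- numeric(k); last <- integer(k)
  for (r in seq_len(k)) {
    widths <- block_len[1:r] - block_len[r + 1]
    widths[widths <= 0] <- .Machine$double.eps
    n_cum <- rev(cumsum(rev(counts[1:r])))
    fit <- n_cum * log(n_cum / widths) - ncp_prior
    fit <- fit + c(0, best[seq_len(r - 1L)])
    last[r] <- which.max(fit)
    best[r] <- fit[last[r]]
  }
  # backtrack change points
  cp <- integer(0)
  r <- k
  while (r > 0L) { cp <- c(last[r], cp); r <- last[r] - 1L }
  sort(unique(c(edges[cp], edges[k + 1])))
}

#' Plug-in mutual information between two discretized genes
#'
#' Maximum-likelihood (plug-in) estimate in bits over the joint contingency
#' table of bin assignments, with the `0 log 0 = 0` convention; tiny
#' negative values from floating-point cancellation are clipped to zero.
#'
#' @param x,y `discretized_gene` objects over the same cells.
#' @return mutual information in bits (>= 0).
#' @export
mutual_information <- function(x, y) {
  tab <- joint_table(x, y)
  mi_from_table(tab)
}

joint_table <- function(x, y) {
  stopifnot(inherits(x, "discretized_gene"), inherits(y, "discretized_gene"))
  if (length(x$assignments) != length(y$assignments))
    stop("assignment length mismatch")
  nx <- x$n_bins; ny <- y$n_bins
  idx <- x$assignments + nx * y$assignments + 1L
  matrix(tabulate(idx, nbins = nx * ny), nrow = nx, ncol = ny)
}

mi_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  e <- outer(px, py)
  mi <- sum(p[nz] * log2(p[nz] / e[nz]))
  max(mi, 0)
}

# Specific information of source S about each outcome y of target Y:
# I_spec(S; Y = y) = sum_s p(s|y) log2(p(s|y) / p(s)), a KL divergence,
# hence >= 0.  Returns the vector over target bins (NA-free; empty target
# bins get 0) plus the target marginal.
specific_information <- function(tab_sy) {
  n <- sum(tab_sy)
  ps <- rowSums(tab_sy) / n
  py <- colSums(tab_sy) / n
  ispec <- numeric(ncol(tab_sy))
  for (yy in seq_len(ncol(tab_sy))) {
    if (py[yy] == 0) next
    cond <- tab_sy[, yy] / sum(tab_sy[, yy])
    nz <- cond > 0
    ispec[yy] <- sum(cond[nz] * log2(cond[nz] / ps[nz]))
  }
  list(ispec = pmax(ispec, 0), py = py)
}

#' Williams-Beer redundancy and unique information for a source pair
#'
#' The redundancy of sources X and Z about target Y is the expected minimum
#' specific information, `I_min = sum_y p(y) min(I_spec(X;y), I_spec(Z;y))`;
#' the unique contribution of X is `I(X;Y) - I_min`, clipped to be
#' non-negative.
#'
#' @param x,z source `discretized_gene`s.
#' @param y target `discretized_gene`.
#' @return list with `redundancy` and `unique_x`, in bits.
#' @export
redundancy_unique <- function(x, z, y) {
  sx <- specific_information(joint_table(x, y))
  sz <- specific_information(joint_table(z, y))
  red <- sum(sx$py * pmin(sx$ispec, sz$ispec))
  list(redundancy = red,
       unique_x = max(mutual_information(x, y) - red, 0))
}

#' Proportional unique contribution (PUC) scores for a gene panel
#'
#' For each unordered gene pair (X, Y), the PUC score accumulates, over
#' every context gene Z, the unique information X carries about Y beyond Z
#' and the unique information Y carries about X beyond Z, each normalized
#' by the pairwise mutual information:
#' `u_xy = sum_Z unique_X(Y|Z) / I(X;Y) + sum_Z unique_Y(X|Z) / I(X;Y)`.
#' Pairs with zero mutual information get `u = 0`.  `u` lies in
#' `[0, 2 (G - 2)]` for a panel of G genes.
#'
#' Only pairwise joint distributions enter the Williams-Beer redundancy, so
#' the computation precomputes specific-information profiles per ordered
#' pair and combines them per triplet.
#'
#' @param panel list of `discretized_gene`s (>= 3) over the same cells.
#' @return data.frame of class `edge_scores`: `gene_a`, `gene_b` (sorted
#'   pair), `mi` (bits), `puc`, `confidence` (`NA` until
#'   [edge_confidence()]).
#' @export
puc_matrix <- function(panel) {
  G <- length(panel)
  if (G < 3L) stop("need at least 3 genes (no context otherwise)")
  ids <- vapply(panel, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids in panel")
  ncells <- unique(vapply(panel, function(g) length(g$assignments), 0L))
  if (length(ncells) != 1L) stop("panel genes cover different cell counts")

  # order-invariant internal layout
  ord <- order(ids)
  panel <- panel[ord]; ids <- ids[ord]

  mi <- matrix(0, G, G)
  ispec <- vector("list", G)          # ispec[[target]][[source]]
  py <- vector("list", G)
  for (t in seq_len(G)) ispec[[t]] <- vector("list", G)
  for (i in seq_len(G - 1L)) {
    for (j in (i + 1L):G) {
      tab <- joint_table(panel[[i]], panel[[j]])
      mi[i, j] <- mi[j, i] <- mi_from_table(tab)
      si <- specific_information(tab)        # source i, target j
      sj <- specific_information(t(tab))     # source j, target i
      ispec[[j]][[i]] <- si$ispec
      ispec[[i]][[j]] <- sj$ispec
      py[[j]] <- si$py
      py[[i]] <- sj$py
    }
  }

  u <- matrix(0, G, G)
  for (t in seq_len(G)) {                      # target gene
    pt_y <- py[[t]]
    sources <- setdiff(seq_len(G), t)
    for (a_i in seq_along(sources)) {
      for (b_i in seq_along(sources)) {
        if (a_i == b_i) next
        s <- sources[a_i]; ctx <- sources[b_i]  # unique of s about t, ctx z
        red <- sum(pt_y * pmin(ispec[[t]][[s]], ispec[[t]][[ctx]]))
        uniq <- max(mi[s, t] - red, 0)
        if (mi[s, t] > 0) u[s, t] <- u[s, t] + uniq / mi[s, t]
      }
    }
  }
  upair <- u + t(u)                            # u_xy over unordered pairs

  idx <- which(upper.tri(upair), arr.ind = TRUE)
  res <- data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                    mi = mi[idx], puc = upair[idx], confidence = NA_real_,
                    stringsAsFactors = FALSE)
  class(res) <- c("edge_scores", "data.frame")
  res
}

#' Per-gene CDF confidence of PUC scores
#'
#' Each gene g defines a distribution over the PUC scores of its G - 1
#' pairs; the confidence of edge (g, h) is `F_g(u_gh) + F_h(u_gh)`, in
#' `[0, 2]`.  The default CDF is empirical — ranks over the gene's scores
#' with ties averaged, divided by G - 1 — matching the deterministic
#' variant; `"gamma"` fits a gamma distribution by moment matching and
#' falls back to empirical (with a warning) for zero-variance scores.
#'
#' @param scores an `edge_scores` table from [puc_matrix()].
#' @param fit `"empirical"` or `"gamma"`.
#' @return the `edge_scores` table with `confidence` filled, sorted by
#'   descending confidence.
#' @export
edge_confidence <- function(scores, fit = c("empirical", "gamma")) {
  fit <- match.arg(fit)
  stopifnot(inherits(scores, "edge_scores"))
  genes <- sort(unique(c(scores$gene_a, scores$gene_b)))
  per_gene <- lapply(setNames(genes, genes), function(g) {
    sel <- scores$gene_a == g | scores$gene_b == g
    if (sum(sel) < 2L) stop("gene ", g, " has fewer than 2 scored partners")
    scores$puc[sel]
  })
  cdf_of <- function(g) {
    u <- per_gene[[g]]
    if (fit == "gamma") {
      m <- mean(u); v <- var(u)
      if (v > 0 && m > 0) {
        shape <- m^2 / v; rate <- m / v
        return(function(q) pgamma(q, shape = shape, rate = rate))
      }
      warning("gamma fit degenerate for gene ", g, "; using empirical CDF")
    }
    # midrank / (G - 1): ties averaged, the maximum attains 1
    function(q) {
      vapply(q, function(qq) {
        (sum(u < qq) + (sum(u == qq) + 1) / 2) / length(u)
      }, 0)
    }
  }
  cdfs <- lapply(setNames(genes, genes), cdf_of)
  conf <- vapply(seq_len(nrow(scores)), function(i) {
    uu <- scores$puc[i]
    cdfs[[scores$gene_a[i]]](uu) + cdfs[[scores$gene_b[i]]](uu)
  }, 0)
  scores$confidence <- conf
  scores[order(-scores$confidence, scores$gene_a, scores$gene_b), ,
         drop = FALSE]
}

#' Choose the gene and TF panels for network inference
#'
#' The gene panel is the signature genes present in the matrix; the TF
#' panel is the `cfg$n_top_tfs` candidate TFs with the largest absolute
#' log fold change (ties broken by gene id) — the "TFs with the highest
#' changes in their gene expression levels".
#'
#' @param norm a `normalized_matrix`.
#' @param sig a `gene_signature`.
#' @param candidate_tfs non-empty TF id vector, all covered by `deg`.
#' @param deg a `deg_table` from [differential_expression()].
#' @param cfg a [pipeline_config()].
#' @return list with `genes` (signature panel), `tfs` (selected TFs), and
#'   `panel` (their union, TFs first).
#' @export
select_network_genes <- function(norm, sig, candidate_tfs, deg,
                                 cfg = pipeline_config()) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(sig, "gene_signature"))
  if (length(candidate_tfs) == 0L) stop("candidate_tfs is empty")
  missing <- setdiff(candidate_tfs, deg$gene_id)
  if (length(missing))
    stop("DEG table does not cover candidate TFs: ",
         paste(missing, collapse = ", "))
  genes <- intersect(sig$genes, colnames(norm$values))
  if (length(genes) < 2L) stop("fewer than 2 signature genes in the matrix")
  cand <- deg[match(candidate_tfs, deg$gene_id), ]
  ord <- order(-abs(cand$logfc), cand$gene_id)
  n_take <- min(cfg$n_top_tfs, length(candidate_tfs))
  if (n_take < cfg$n_top_tfs)
    warning("fewer candidate TFs than n_top_tfs; taking all ", n_take)
  tfs <- cand$gene_id[ord][seq_len(n_take)]
  list(genes = sort(setdiff(genes, tfs)), tfs = tfs,
       panel = c(tfs, sort(setdiff(genes, tfs))))
}

#' Restrict scored edges to the TF-to-target direction and threshold
#'
#' Pairs with no TF endpoint are dropped; pairs with exactly one TF are
#' oriented TF -> target; TF-TF pairs yield both directed edges.  Edges
#' with confidence strictly greater than `cfg$edge_weight_min` are kept.
#' Nodes get hierarchy layers for export: TFs at layer 0, targets at layer
#' 1, grouped by their parent-TF set.
#'
#' @param scores an `edge_scores` table with confidences filled.
#' @param tf_list transcription factor ids.
#' @param cfg a [pipeline_config()].
#' @return an object of class `directed_network`: list with `edges`
#'   (`source`, `target`, `weight`, `mi`, `puc`), `tf_list`, `layers`
#'   (named integer), `groups` (target grouping by parent set).
#' @export
build_directed_network <- function(scores, tf_list, cfg = pipeline_config()) {
  stopifnot(inherits(scores, "edge_scores"))
  if (any(is.na(scores$confidence)))
    stop("scores lack confidences; run edge_confidence() first")
  a_tf <- scores$gene_a %in% tf_list
  b_tf <- scores$gene_b %in% tf_list
  keep <- (a_tf | b_tf) & scores$confidence > cfg$edge_weight_min

  rows <- scores[keep, , drop = FALSE]
  ra <- rows[a_tf[keep], , drop = FALSE]          # a is TF: a -> b
  rb <- rows[b_tf[keep], , drop = FALSE]          # b is TF: b -> a
  edges <- rbind(
    data.frame(source = ra$gene_a, target = ra$gene_b, weight = ra$confidence,
               mi = ra$mi, puc = ra$puc, stringsAsFactors = FALSE),
    data.frame(source = rb$gene_b, target = rb$gene_a, weight = rb$confidence,
               mi = rb$mi, puc = rb$puc, stringsAsFactors = FALSE))
  edges <- edges[order(-edges$weight, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0L)
    warning("no edge exceeds the confidence threshold; empty network")

  nodes <- unique(c(edges$source, edges$target, intersect(tf_list, c(scores$gene_a, scores$gene_b))))
  layers <- setNames(ifelse(nodes %in% tf_list, 0L, 1L), nodes)
  targets <- nodes[layers > 0L]
  groups <- vapply(targets, function(tg) {
    paste(sort(unique(edges$source[edges$target == tg])), collapse = "+")
  }, "")
  structure(list(edges = edges, tf_list = tf_list, layers = layers,
                 groups = setNames(groups, targets)),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d edges from %d TFs over %d nodes\n",
              nrow(x$edges), length(unique(x$edges$source)),
              length(x$layers)))
  invisible(x)
}

#' Extract regulons from a directed network
#'
#' One regulon per TF with at least one outgoing edge; targets are sorted
#' by descending edge weight (ties by gene id).
#'
#' @param net a `directed_network`.
#' @return named list of `regulon` objects (`tf`, `targets`).
#' @export
extract_regulons <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  tfs <- unique(net$edges$source)
  regs <- lapply(setNames(tfs, tfs), function(tf) {
    e <- net$edges[net$edges$source == tf, , drop = FALSE]
    e <- e[order(-e$weight, e$target), , drop = FALSE]
    regulon(tf, e$target)
  })
  regs
}

#' A regulon: a transcription factor and its target gene set
#'
#' @param tf TF id.
#' @param targets non-empty unique target ids (the TF itself is excluded).
#' @return an object of class `regulon`.
#' @export
regulon <- function(tf, targets) {
  targets <- unique(setdiff(as.character(targets), tf))
  if (length(targets) == 0L) stop("regulon needs at least one target")
  structure(list(tf = tf, targets = targets), class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("regulon %s: %d targets\n", x$tf, length(x$targets)))
  invisible(x)
}
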