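#' Per-cell signature score as the mean of gene z-scores
#'
#' Each signature gene present in the matrix is standardized across cells
#' (mean 0, sd 1; constant genes are dropped), and a cell's score is the
#' mean over the standardized genes — the "average expression of the whole
#' signature (z-scores)" convention.  By construction the score column has
#' mean 0 across cells.
#'
#' @param norm a `normalized_matrix` with >= 2 cells.
#' @param sig a `gene_signature`; genes absent from the matrix are dropped
#'   with a warning.
#' @return data.frame of class `signature_scores`: `cell_id`, `signature`,
#'   `score`, `method = "zscore"`.
#' @export
zscore_signature_score <- function(norm, sig) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(sig, "gene_signature"))
  if (nrow(norm$values) < 2L) stop("need at least 2 cells")
  present <- intersect(sig$genes, colnames(norm$values))
  if (length(present) == 0L)
    stop("no signature gene present in the matrix: ", sig$name)
  if (length(present) < length(sig$genes))
    warning(sprintf("signature '%s': %d of %d genes absent, dropped",
                    sig$name, length(sig$genes) - length(present),
                    length(sig$genes)))
  x <- norm$values[, present, drop = FALSE]
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0L) stop("all present signature genes are constant: ", sig$name)
  z <- scale(x)
  scores <- rowMeans(z)
  structure(data.frame(cell_id = rownames(norm$values), signature = sig$name,
                       score = as.numeric(scores), method = "zscore",
                       stringsAsFactors = FALSE),
            class = c("signature_scores", "data.frame"))
}

# Gaussian-kernel CDF statistic per gene: z_j = mean_k Phi((x_j - x_k) / h),
# bandwidth h = sd/4.  Constant genes get the uninformative value 1/2.
gene_kcdf <- function(x) {
  h <- sd(x) / 4
  if (!is.finite(h) || h == 0) return(rep(0.5, length(x)))
  colMeans(pnorm(outer(x, x, FUN = function(a, b) (b - a) / h)))
}

#' GSVA-style single-sample enrichment score
#'
#' Per gene, expression is converted to a Gaussian-kernel cumulative
#' density statistic across cells (bandwidth sd/4); per cell, genes are
#' ranked by this statistic (descending, ties broken by gene id) and the
#' ranks are symmetrized around the middle, `r = |rank - (p + 1)/2|`.  A
#' Kolmogorov-Smirnov-like random walk down the ranked list increments by
#' `|r|^tau` (normalized over the set; `tau = 1`) inside the gene set and
#' decrements uniformly outside it; the score is the maximum positive
#' deviation plus the minimum negative deviation of the walk (the
#' signed-difference statistic), which lies in (-1, 1).
#'
#' @param norm a `normalized_matrix` with >= 3 cells.
#' @param sigs a `gene_signature` or list thereof; each must have at least
#'   one and fewer than all matrix genes present.
#' @param tau rank-weight exponent.
#' @return data.frame of class `signature_scores` with `method = "gsva"`.
#' @export
gsva_score <- function(norm, sigs, tau = 1) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  x <- norm$values
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop("need at least 3 cells")
  gene_ids <- colnames(x)

  kcdf <- apply(x, 2, gene_kcdf)            # cells x genes
  # per-cell ranks, 1 = largest statistic; deterministic tie-break by gene id
  id_order <- order(gene_ids)
  rstat <- matrix(0, n, p, dimnames = list(rownames(x), gene_ids))
  ranks <- matrix(0L, n, p)
  for (j in seq_len(n)) {
    ord <- order(-kcdf[j, ], id_order)
    rk <- integer(p); rk[ord] <- seq_len(p)
    ranks[j, ] <- rk
    rstat[j, ] <- abs(rk - (p + 1) / 2)
  }

  res <- lapply(sigs, function(sig) {
    stopifnot(inherits(sig, "gene_signature"))
    inset <- gene_ids %in% sig$genes
    if (!any(inset)) stop("no signature gene present in the matrix: ", sig$name)
    if (all(inset))
      stop("signature covers every gene (degenerate complement): ", sig$name)
    m <- sum(inset)
    scores <- vapply(seq_len(n), function(j) {
      ord <- order(ranks[j, ])              # walk from rank 1 downwards
      in_ord <- inset[ord]
      w <- rstat[j, ord]^tau
      step <- ifelse(in_ord, w / sum(w[in_ord]), -1 / (p - m))
      walk <- cumsum(step)
      max(c(0, walk)) + min(c(0, walk))
    }, 0)
    data.frame(cell_id = rownames(x), signature = sig$name, score = scores,
               method = "gsva", stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, c(res, make.row.names = FALSE)),
            class = c("signature_scores", "data.frame"))
}

#' Compare signature enrichment between two groups
#'
#' Welch t-test per signature on the per-cell scores, BH adjustment across
#' signatures; the effect size is the difference of group means (scores are
#' already on a log-like scale).
#'
#' @param scores a `signature_scores` table (any method).
#' @param groups two-level labels aligned with the distinct cells of
#'   `scores` — either named by cell id or in the order of
#'   `unique(scores$cell_id)`.
#' @return data.frame: `signature`, `logfc` (mean B - mean A), `p`, `q`.
#' @export
compare_signature_enrichment <- function(scores, groups) {
  stopifnot(inherits(scores, "signature_scores"))
  cells <- unique(scores$cell_id)
  if (!is.null(names(groups))) {
    if (!all(cells %in% names(groups))) stop("groups must cover every cell")
    groups <- groups[cells]
  } else if (length(groups) != length(cells)) {
    stop("groups must align with the distinct cells")
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (min(table(groups)) < 2L) stop("each group needs at least 2 cells")

  out <- lapply(split(scores, scores$signature), function(df) {
    s <- setNames(df$score, df$cell_id)[cells]
    a <- s[groups == levels(groups)[1]]
    b <- s[groups == levels(groups)[2]]
    wt <- welch_test_matrix(matrix(a, ncol = 1), matrix(b, ncol = 1))
    data.frame(signature = df$signature[1], logfc = mean(b) - mean(a),
               p = wt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$q, out$p), , drop = FALSE]
}

#' Write per-cell signature scores as a cell x signature TSV
#'
#' @param scores a `signature_scores` table.
#' @param path output TSV.
#' @export
write_signature_scores <- function(scores, path) {
  wide <- stats::reshape(scores[, c("cell_id", "signature", "score")],
                         idvar = "cell_id", timevar = "signature",
                         direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
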