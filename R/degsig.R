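#' A named gene set
#'
#' @param name signature name.
#' @param genes non-empty character vector; duplicates are removed.
#' @param provenance free-text origin note.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, provenance = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene_signature needs at least one gene")
  structure(list(name = name, genes = genes,
                 provenance = paste(provenance, collapse = "; ")),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Differential expression by per-gene Welch t-test
#'
#' For every gene, a Welch (unequal-variance) t-test on the normalized
#' values between the two groups, BH adjustment across all tested genes,
#' and a fold change computed on the de-logged scale:
#' `logfc = log2((mean(expm1 B) + eps) / (mean(expm1 A) + eps))` with
#' `eps = 1e-9`.  A gene is flagged up in a group when `q < cfg$deg_fdr`
#' and `|logfc| > cfg$deg_logfc` with the matching sign.  Genes constant in
#' both groups get `p = 1` by convention.
#'
#' @param norm a `normalized_matrix`.
#' @param groups two-level labels per cell (factor or character), aligned
#'   with the rows of `norm$values`; the *second* level in sort order (or
#'   factor order) is treated as group B.
#' @param cfg a [pipeline_config()].
#' @return data.frame of class `deg_table`: `gene_id`, `logfc`, `p`, `q`,
#'   `mean_a`, `mean_b`, `significant_up_a`, `significant_up_b`.
#' @export
differential_expression <- function(norm, groups, cfg = pipeline_config()) {
  stopifnot(inherits(norm, "normalized_matrix"))
  x <- norm$values
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("groups must have exactly two levels")
  groups <- droplevels(groups)
  if (length(groups) != nrow(x)) stop("groups must match the number of cells")
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs at least 2 cells")

  welch <- welch_test_matrix(x[ia, , drop = FALSE], x[ib, , drop = FALSE])
  eps <- 1e-9
  mean_a <- colMeans(expm1(x[ia, , drop = FALSE]))
  mean_b <- colMeans(expm1(x[ib, , drop = FALSE]))
  logfc <- log2((mean_b + eps) / (mean_a + eps))
  q <- p.adjust(welch$p, method = "BH")

  n_const <- sum(welch$degenerate & welch$p == 1)
  if (n_const > 0)
    message(sprintf("differential_expression: %d constant gene(s) set to p = 1",
                    n_const))
  res <- data.frame(gene_id = colnames(x), logfc = logfc, p = welch$p, q = q,
                    mean_a = mean_a, mean_b = mean_b,
                    significant_up_b = q < cfg$deg_fdr & logfc > cfg$deg_logfc,
                    significant_up_a = q < cfg$deg_fdr & logfc < -cfg$deg_logfc,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("deg_table", "data.frame")
  res
}

# Vectorized Welch t-test over the columns of two matrices.  Zero-variance
# columns: p = 1 when the means agree, p = 0 otherwise.
welch_test_matrix <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, var); vb <- apply(xb, 2, var)
  se2 <- va / na + vb / nb
  degenerate <- se2 == 0
  tt <- ifelse(degenerate, 0, (mb - ma) / sqrt(se2))
  df <- ifelse(degenerate, 1,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)))
  p <- 2 * pt(-abs(tt), df)
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  list(t = tt, df = df, p = p, degenerate = degenerate)
}

#' Assemble a consensus signature from multiple DEG lists
#'
#' Genes appearing in at least `k` of the input lists, mirroring the
#' assembly of a consensus tolerogenic signature from genes co-upregulated
#' in two or more independent conditions.
#'
#' @param deg_lists named list (>= 2) of gene-id character vectors.
#' @param k minimum number of lists a gene must appear in.
#' @param name name for the resulting signature.
#' @return a `gene_signature`, genes sorted lexicographically; its
#'   `provenance` records the contributing lists per gene.
#' @export
assemble_consensus_signature <- function(deg_lists, k, name = "consensus") {
  if (!is.list(deg_lists) || length(deg_lists) < 2L)
    stop("need at least two DEG lists")
  if (k < 1L) stop("k must be >= 1")
  if (k > length(deg_lists))
    stop("k exceeds the number of lists (", length(deg_lists), ")")
  if (is.null(names(deg_lists)))
    names(deg_lists) <- sprintf("list%d", seq_along(deg_lists))
  membership <- lapply(deg_lists, unique)
  tallies <- table(unlist(membership))
  genes <- sort(names(tallies)[tallies >= k])
  if (length(genes) == 0L)
    stop("no gene appears in >= ", k, " lists; reduce k")
  prov <- vapply(genes, function(g) {
    contrib <- names(membership)[vapply(membership, function(l) g %in% l, TRUE)]
    paste0(g, ":", paste(contrib, collapse = "+"))
  }, "")
  gene_signature(name, genes, provenance = paste(prov, collapse = "; "))
}

#' Overlap of a signature with an expressed-gene universe
#'
#' @param sig a `gene_signature`.
#' @param expressed gene ids expressed in the dataset.
#' @return list with `n_present`, `n_total`, `present` (the intersecting
#'   gene ids), and a preformatted `label` like `"30/64"`.
#' @export
signature_overlap <- function(sig, expressed) {
  stopifnot(inherits(sig, "gene_signature"))
  present <- sort(intersect(sig$genes, expressed))
  list(n_present = length(present), n_total = length(sig$genes),
       present = present,
       label = sprintf("%d/%d", length(present), length(sig$genes)))
}

#' Write a DEG table to TSV
#'
#' Columns: gene, logFC, pval, qval, mean_a, mean_b, up_in
#' ("A", "B" or "ns").
#'
#' @param deg a `deg_table`.
#' @param path output TSV.
#' @export
write_deg_table <- function(deg, path) {
  out <- data.frame(gene = deg$gene_id, logFC = deg$logfc, pval = deg$p,
                    qval = deg$q, mean_a = deg$mean_a, mean_b = deg$mean_b,
                    up_in = ifelse(deg$significant_up_b, "B",
                                   ifelse(deg$significant_up_a, "A", "ns")))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
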