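#' Score a ranked edge list against the gold standard
#'
#' Sweeps the weight threshold over all distinct values of the ranked list
#' and computes the area under the precision-recall curve (average
#' precision with step integration) and under the ROC curve (rank statistic
#' with ties averaged).  The candidate universe is every TF-to-gene pair
#' over the union of genes seen in the ranked list and the gold standard
#' (directed mode) or every unordered gene pair (undirected mode);
#' candidates absent from `ranked_edges` are treated as ranked last
#' (weight `-Inf`).
#'
#' @param ranked_edges data.frame with columns `source`, `target`, `weight`
#'   (finite weights).
#' @param gold a `gold_standard` (see [sample_grn()]).
#' @param mode `"directed"` or `"undirected"`; undirected mode collapses
#'   gold edges to unordered pairs.
#' @return an object of class `recovery_report` with `aupr`, `auroc`,
#'   `prevalence` (gold size over candidate count); `sensitivity` and
#'   `empirical_fdp` are `NA` (they belong to [deg_recovery()]).
#' @export
network_recovery_metrics <- function(ranked_edges, gold,
                                     mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gold, "gold_standard"))
  if (nrow(gold$edges) == 0L) stop("empty gold standard")
  if (!all(c("source", "target", "weight") %in% names(ranked_edges)))
    stop("ranked_edges needs columns source, target, weight")
  if (any(!is.finite(ranked_edges$weight)))
    stop("ranked_edges weights must be finite")

  genes <- sort(unique(c(ranked_edges$source, ranked_edges$target,
                         gold$edges$source, gold$edges$target,
                         gold$tf_list)))
  if (mode == "directed") {
    cand <- expand.grid(source = gold$tf_list, target = genes,
                        stringsAsFactors = FALSE)
    cand <- cand[cand$source != cand$target, , drop = FALSE]
    key <- function(s, t) paste(s, t, sep = "\r")
  } else {
    pairs <- t(utils::combn(genes, 2L))
    cand <- data.frame(source = pairs[, 1], target = pairs[, 2],
                       stringsAsFactors = FALSE)
    key <- function(s, t) paste(pmin(s, t), pmax(s, t), sep = "\r")
  }

  ranked_key <- key(ranked_edges$source, ranked_edges$target)
  if (anyDuplicated(ranked_key)) stop("duplicate pairs in ranked_edges")
  gold_key <- unique(key(gold$edges$source, gold$edges$target))
  cand_key <- key(cand$source, cand$target)
  if (length(setdiff(ranked_key, cand_key)))
    stop("ranked_edges contains pairs outside the candidate universe")
  if (length(setdiff(gold_key, cand_key)))
    stop("gold edges outside the candidate universe")

  w <- rep(-Inf, nrow(cand))
  w[match(ranked_key, cand_key)] <- ranked_edges$weight
  labels <- cand_key %in% gold_key

  structure(list(aupr = average_precision(w, labels),
                 auroc = rank_auroc(w, labels),
                 prevalence = sum(labels) / length(labels),
                 sensitivity = NA_real_, empirical_fdp = NA_real_),
            class = "recovery_report")
}

# Average precision by threshold sweep over distinct weights: precision is
# evaluated after each tie group, recall increments by the true edges the
# group contributes (step integration of the PR curve).
average_precision <- function(w, labels) {
  n_pos <- sum(labels)
  ord <- order(w, decreasing = TRUE)
  w <- w[ord]; labels <- labels[ord]
  grp <- cumsum(!duplicated(w))          # tie-group index, descending weight
  tp_g <- tapply(labels, grp, sum)
  n_g <- tapply(labels, grp, length)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  sum(prec * tp_g) / n_pos
}

# AUROC via the Mann-Whitney rank form with midranks for ties.
rank_auroc <- function(w, labels) {
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("need both positives and negatives")
  r <- rank(w, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score a differential-expression call set against the planted truth
#'
#' @param called gene ids called differentially expressed.
#' @param planted gene ids of the planted effects (non-empty).
#' @param universe all testable gene ids; `called` and `planted` must be
#'   subsets.
#' @return a `recovery_report` with `sensitivity` (recall of planted genes)
#'   and `empirical_fdp` (false discoveries over `max(|called|, 1)`);
#'   network fields are `NA`.
#' @export
deg_recovery <- function(called, planted, universe) {
  if (length(planted) == 0L) stop("planted gene set is empty")
  if (length(setdiff(called, universe)) || length(setdiff(planted, universe)))
    stop("called and planted must be subsets of the universe")
  called <- unique(called); planted <- unique(planted)
  hits <- length(intersect(called, planted))
  structure(list(aupr = NA_real_, auroc = NA_real_, prevalence = NA_real_,
                 sensitivity = hits / length(planted),
                 empirical_fdp = (length(called) - hits) /
                   max(length(called), 1L)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report:",
      paste(sprintf("%s=%.4g", names(unclass(x)),
                    vapply(unclass(x), as.numeric, 0)), collapse = " "),
      "\n")
  invisible(x)
}
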