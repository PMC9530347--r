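# Independent oracle implementations: deliberately written as plain
# exhaustive loops, sharing no code with the package internals.

# plug-in mutual information (bits) from a contingency table, double loop
oracle_mi_table <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) mi <- mi + pij * log2(pij / (px[i] * py[j]))
    }
  }
  mi
}

# specific information I_spec(S; Y = y) for every y, from raw assignment
# vectors (values taken as-is, no binning)
oracle_specific_info <- function(s, y) {
  ys <- sort(unique(y))
  ss <- sort(unique(s))
  n <- length(y)
  out <- numeric(length(ys))
  for (k in seq_along(ys)) {
    sel <- y == ys[k]
    acc <- 0
    for (sv in ss) {
      p_cond <- sum(s[sel] == sv) / sum(sel)
      p_marg <- sum(s == sv) / n
      if (p_cond > 0) acc <- acc + p_cond * log2(p_cond / p_marg)
    }
    out[k] <- acc
  }
  names(out) <- as.character(ys)
  out
}

oracle_mi_vectors <- function(x, y) {
  oracle_mi_table(table(x, y))
}

# Williams-Beer I_min redundancy of sources x, z about target y
oracle_redundancy <- function(x, z, y) {
  ys <- sort(unique(y))
  ix <- oracle_specific_info(x, y)
  iz <- oracle_specific_info(z, y)
  red <- 0
  for (k in seq_along(ys)) {
    p_y <- sum(y == ys[k]) / length(y)
    red <- red + p_y * min(ix[k], iz[k])
  }
  red
}

# equal-width binning: independent implementation of the default scheme
oracle_bin <- function(v, n_bins = NULL) {
  if (is.null(n_bins)) n_bins <- max(2, ceiling(sqrt(length(v))))
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(rep(0L, length(v)))
  edges <- lo + (hi - lo) * seq_len(n_bins - 1) / n_bins
  out <- integer(length(v))
  for (i in seq_along(v)) {
    b <- 0L
    for (e in edges) if (v[i] >= e) b <- b + 1L
    out[i] <- b
  }
  out
}

# full PUC + empirical-confidence pipeline for a small panel, all loops;
# `values` is a cells x genes matrix.  Returns a data.frame keyed by the
# sorted gene pair.
oracle_puc_confidence <- function(values) {
  ids <- colnames(values)
  G <- length(ids)
  bins <- lapply(seq_len(G), function(g) oracle_bin(values[, g]))
  names(bins) <- ids

  mi <- matrix(0, G, G, dimnames = list(ids, ids))
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i != j) mi[i, j] <- oracle_mi_vectors(bins[[i]], bins[[j]])
  }

  u <- matrix(0, G, G, dimnames = list(ids, ids))   # u[s, t]: source, target
  for (t in seq_len(G)) {
    for (s in seq_len(G)) {
      if (s == t) next
      for (z in seq_len(G)) {
        if (z == t || z == s) next
        red <- oracle_redundancy(bins[[s]], bins[[z]], bins[[t]])
        uniq <- max(mi[s, t] - red, 0)
        if (mi[s, t] > 0) u[s, t] <- u[s, t] + uniq / mi[s, t]
      }
    }
  }

  pairs <- list()
  k <- 0L
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    k <- k + 1L
    pairs[[k]] <- data.frame(gene_a = ids[i], gene_b = ids[j],
                             mi = mi[i, j], puc = u[i, j] + u[j, i],
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, pairs)

  # empirical per-gene CDF: midrank over the gene's G - 1 scores
  conf <- numeric(nrow(res))
  for (r in seq_len(nrow(res))) {
    cc <- 0
    for (g in c(res$gene_a[r], res$gene_b[r])) {
      us <- res$puc[res$gene_a == g | res$gene_b == g]
      less <- 0; eq <- 0
      for (v in us) {
        if (v < res$puc[r]) less <- less + 1
        if (v == res$puc[r]) eq <- eq + 1
      }
      cc <- cc + (less + (eq + 1) / 2) / length(us)
    }
    conf[r] <- cc
  }
  res$confidence <- conf
  res
}

# GSVA recipe, step by step with explicit loops
oracle_gsva <- function(values, set_genes, tau = 1) {
  n <- nrow(values); p <- ncol(values)
  ids <- colnames(values)
  z <- matrix(0, n, p)
  for (g in seq_len(p)) {
    h <- sd(values[, g]) / 4
    for (j in seq_len(n)) {
      if (h == 0) { z[j, g] <- 0.5; next }
      acc <- 0
      for (k in seq_len(n)) acc <- acc + pnorm((values[j, g] - values[k, g]) / h)
      z[j, g] <- acc / n
    }
  }
  id_rank <- order(ids)
  scores <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(-z[j, ], id_rank)
    rk <- integer(p); rk[ord] <- seq_len(p)
    rstat <- abs(rk - (p + 1) / 2)
    inset <- ids %in% set_genes
    denom_in <- sum(rstat[inset]^tau)
    walk <- 0; mx <- 0; mn <- 0
    for (g in ord) {
      if (inset[g]) walk <- walk + rstat[g]^tau / denom_in
      else walk <- walk - 1 / (p - sum(inset))
      if (walk > mx) mx <- walk
      if (walk < mn) mn <- walk
    }
    scores[j] <- mx + mn
  }
  scores
}

# recovery-curve AUC by explicit step integration
oracle_aucell <- function(expr, ids, members, top_fraction) {
  G <- length(expr)
  ord <- order(-expr, order(ids))
  k <- ceiling(top_fraction * G)
  m_eff <- min(sum(ids %in% members), k)
  area <- 0; hits <- 0; max_area <- 0
  for (t in seq_len(k)) {
    if (ids[ord[t]] %in% members) hits <- hits + 1
    area <- area + hits
    max_area <- max_area + min(t, m_eff)
  }
  area / max_area
}

# average precision by explicit threshold sweep
oracle_average_precision <- function(w, labels) {
  ths <- sort(unique(w), decreasing = TRUE)
  ap <- 0; prev_recall <- 0
  n_pos <- sum(labels)
  for (th in ths) {
    pred <- w >= th
    prec <- sum(labels & pred) / sum(pred)
    rec <- sum(labels & pred) / n_pos
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# build a normalized_matrix object directly from a values matrix (tests of
# downstream stages that do not exercise normalization itself)
as_norm <- function(values) {
  structure(list(values = values,
                 size_factors = setNames(rep(1, nrow(values)),
                                         rownames(values))),
            class = "normalized_matrix")
}

# assignment vectors realizing multinomial counts over a 3-way joint table
joint_sample_to_assignments <- function(counts_array) {
  d <- dim(counts_array)
  xs <- integer(0); zs <- integer(0); ys <- integer(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    m <- counts_array[i, j, k]
    if (m > 0) {
      xs <- c(xs, rep(i - 1L, m))
      zs <- c(zs, rep(j - 1L, m))
      ys <- c(ys, rep(k - 1L, m))
    }
  }
  list(x = xs, z = zs, y = ys)
}

disc_from_assign <- function(a, id = "g") {
  structure(list(gene_id = id, assignments = as.integer(a),
                 bin_edges = seq(0, max(a) + 1), n_bins = max(a) + 1L),
            class = "discretized_gene")
}
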