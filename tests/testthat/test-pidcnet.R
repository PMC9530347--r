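test_that("discretization covers constants, the sqrt rule, and edge placement", {
  d0 <- discretize(rep(2.5, 10))
  expect_equal(d0$n_bins, 1L)
  expect_true(all(d0$assignments == 0L))

  d1 <- discretize(seq(0, 1, length.out = 16))
  expect_equal(d1$n_bins, 4L)                 # ceiling(sqrt(16))

  d2 <- discretize(c(0, 1, 2, 3), n_bins = 2)
  expect_identical(d2$assignments, c(0L, 0L, 1L, 1L))

  expect_error(discretize(c(1, NA, 2)), "finite")
  expect_error(discretize(3), "2 values")
})

test_that("bayesian-blocks discretization separates well-separated modes", {
  set.seed(31)
  v <- c(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1))
  d <- discretize(v, method = "bayesian_blocks")
  expect_gte(d$n_bins, 2L)
  # the mode centres land in different bins (gap stragglers may share the
  # wide low-density block between the modes)
  bin_near <- function(target) d$assignments[which.min(abs(v - target))]
  expect_false(bin_near(0) == bin_near(10))
  expect_identical(d, discretize(v, method = "bayesian_blocks"))
})

test_that("mutual information reproduces hand-computed tables", {
  x <- disc_from_assign(rep(c(0, 1), each = 4))
  expect_equal(mutual_information(x, x), 1.0, tolerance = 1e-12)

  const <- disc_from_assign(rep(0, 8))
  expect_equal(mutual_information(const, x), 0.0)

  # joint counts ((2,1),(1,2)) over 6 cells
  xa <- disc_from_assign(c(0, 0, 0, 1, 1, 1))
  ya <- disc_from_assign(c(0, 0, 1, 0, 1, 1))
  expected <- (2 / 3) * log2(4 / 3) + (1 / 3) * log2(2 / 3)
  expect_equal(mutual_information(xa, ya), expected, tolerance = 1e-12)
  expect_equal(expected, 0.0817, tolerance = 1e-3)

  expect_error(mutual_information(x, disc_from_assign(0:2)), "length")
})

test_that("plug-in MI matches brute-force summation on random tables", {
  set.seed(32)
  for (i in 1:100) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    tab <- matrix(rpois(nx * ny, 3) + 1, nx, ny)
    ax <- rep(rep(seq_len(nx) - 1L, ny), as.vector(tab))
    ay <- rep(rep(seq_len(ny) - 1L, each = nx), as.vector(tab))
    got <- mutual_information(disc_from_assign(ax), disc_from_assign(ay))
    expect_equal(got, oracle_mi_table(tab), tolerance = 1e-12)
  }
})

test_that("redundancy collapses correctly for independent and duplicate sources", {
  x <- disc_from_assign(c(0, 0, 1, 1, 0, 0, 1, 1))
  y <- disc_from_assign(c(0, 0, 1, 1, 0, 1, 0, 1))
  z_const <- disc_from_assign(rep(0, 8))       # carries nothing about y
  ru <- redundancy_unique(x, z_const, y)
  expect_equal(ru$redundancy, 0, tolerance = 1e-12)
  expect_equal(ru$unique_x, mutual_information(x, y), tolerance = 1e-12)

  dup <- redundancy_unique(x, x, y)
  expect_equal(dup$redundancy, mutual_information(x, y), tolerance = 1e-12)
  expect_equal(dup$unique_x, 0, tolerance = 1e-12)
})

test_that("redundancy matches the exhaustive specific-information oracle", {
  set.seed(33)
  for (i in 1:25) {
    a <- joint_sample_to_assignments(array(rpois(8, 2) + 1, c(2, 2, 2)))
    got <- redundancy_unique(disc_from_assign(a$x), disc_from_assign(a$z),
                             disc_from_assign(a$y))
    expect_equal(got$redundancy, oracle_redundancy(a$x, a$z, a$y),
                 tolerance = 1e-12)
  }
})

test_that("a pair with an independent context gene attains PUC 2", {
  x <- disc_from_assign(c(0, 0, 1, 1, 0, 0, 1, 1))
  y <- x
  z <- disc_from_assign(c(0, 1, 0, 1, 0, 1, 0, 1))  # independent of x, y
  panel <- list(disc_from_assign(x$assignments, "x"),
                disc_from_assign(y$assignments, "y"),
                disc_from_assign(z$assignments, "z"))
  scores <- puc_matrix(panel)
  uxy <- scores$puc[scores$gene_a == "x" & scores$gene_b == "y"]
  expect_equal(uxy, 2.0, tolerance = 1e-10)
})

test_that("zero-MI pairs score zero by convention", {
  panel <- list(disc_from_assign(c(0, 0, 1, 1), "a"),
                disc_from_assign(c(0, 1, 0, 1), "b"),
                disc_from_assign(c(0, 1, 1, 0), "c"))
  scores <- puc_matrix(panel)
  ab <- scores[scores$gene_a == "a" & scores$gene_b == "b", ]
  expect_equal(ab$mi, 0)
  expect_equal(ab$puc, 0)
  expect_error(puc_matrix(panel[1:2]), "3 genes")
})

test_that("PUC and confidence match the exhaustive oracle on random panels", {
  set.seed(34)
  for (rep_i in 1:3) {
    n <- 40
    vals <- matrix(rexp(n * 5), nrow = n,
                   dimnames = list(NULL, c("a", "b", "c", "d", "e")))
    vals[, "b"] <- vals[, "a"] + rnorm(n, 0, 0.2)   # induce structure
    panel <- lapply(colnames(vals), function(g) discretize(vals[, g], gene_id = g))
    got <- edge_confidence(puc_matrix(panel))
    exp_df <- oracle_puc_confidence(vals)
    key <- function(d) paste(d$gene_a, d$gene_b)
    m <- match(key(got), key(exp_df))
    expect_false(anyNA(m))
    expect_equal(got$mi, exp_df$mi[m], tolerance = 1e-10)
    expect_equal(got$puc, exp_df$puc[m], tolerance = 1e-10)
    expect_equal(got$confidence, exp_df$confidence[m], tolerance = 1e-10)
  }
})

test_that("puc_matrix is invariant to gene order and cell permutation", {
  set.seed(35)
  n <- 30
  vals <- matrix(rexp(n * 4), nrow = n,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  mk_panel <- function(v) lapply(colnames(v), function(g)
    discretize(v[, g], gene_id = g))
  s1 <- puc_matrix(mk_panel(vals))
  s2 <- puc_matrix(rev(mk_panel(vals)))
  expect_equal(s1, s2)
  perm <- sample(n)
  s3 <- puc_matrix(mk_panel(vals[perm, ]))
  expect_equal(s1$puc, s3$puc, tolerance = 1e-12)
})

test_that("empirical confidence rewards per-gene maxima and handles ties", {
  # build edge scores directly: 4 genes, one dominant pair
  set.seed(36)
  vals <- matrix(rexp(200), nrow = 50,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  vals[, "b"] <- vals[, "a"]                  # a-b duplicates: dominant edge
  panel <- lapply(colnames(vals), function(g) discretize(vals[, g], gene_id = g))
  conf <- edge_confidence(puc_matrix(panel))
  ab <- conf[conf$gene_a == "a" & conf$gene_b == "b", ]
  expect_equal(ab$confidence, 2.0, tolerance = 1e-12)
  expect_true(all(conf$confidence >= 0 & conf$confidence <= 2))

  flat <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                     mi = 1, puc = 1, confidence = NA_real_)
  class(flat) <- c("edge_scores", "data.frame")
  cf <- edge_confidence(flat)
  expect_equal(unique(cf$confidence), cf$confidence[1])
})

test_that("gamma confidence falls back to empirical on degenerate scores", {
  flat <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                     mi = 1, puc = 1, confidence = NA_real_)
  class(flat) <- c("edge_scores", "data.frame")
  w <- capture_warnings(cf <- edge_confidence(flat, fit = "gamma"))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(is.finite(cf$confidence)))
})

test_that("TF panels pick the largest expression changes", {
  res <- cached_pipeline()
  b <- cached_benchmark()
  deg <- res$deg
  cand <- b$gold$tf_list
  sel <- select_network_genes(res$norm, b$planted_signature, cand, deg,
                              pipeline_config(n_top_tfs = 3))
  ranked <- cand[order(-abs(deg$logfc[match(cand, deg$gene_id)]), cand)]
  expect_identical(sel$tfs, ranked[1:3])
  expect_true("TF1" %in% sel$tfs)             # the activity-elevated TF
  expect_warning(select_network_genes(res$norm, b$planted_signature, cand,
                                      deg, pipeline_config(n_top_tfs = 10)),
                 "fewer candidate TFs")
  expect_error(select_network_genes(res$norm, b$planted_signature, "NOPE",
                                    deg, pipeline_config()), "cover")
})

test_that("edges orient TF to target, TF-TF pairs go both ways, threshold is strict", {
  scores <- data.frame(
    gene_a = c("IRF4", "IRF4", "KLF6", "LGALS1"),
    gene_b = c("LGALS1", "KLF6", "IL4I1", "IL4I1"),
    mi = 1, puc = 1,
    confidence = c(1.5, 1.2, 1.0, 1.4))
  class(scores) <- c("edge_scores", "data.frame")
  net <- build_directed_network(scores, c("IRF4", "KLF6"),
                                pipeline_config(edge_weight_min = 1))
  # IRF4-LGALS1: oriented TF -> target
  expect_true(any(net$edges$source == "IRF4" & net$edges$target == "LGALS1"))
  expect_false(any(net$edges$source == "LGALS1"))
  # IRF4-KLF6 both TFs: both directions
  expect_true(any(net$edges$source == "IRF4" & net$edges$target == "KLF6"))
  expect_true(any(net$edges$source == "KLF6" & net$edges$target == "IRF4"))
  # KLF6-IL4I1 at exactly 1.0 is excluded (strict >); LGALS1-IL4I1 has no TF
  expect_false(any(net$edges$target == "IL4I1"))
  expect_true(all(net$edges$source %in% c("IRF4", "KLF6")))
  expect_equal(unname(net$layers[c("IRF4", "KLF6")]), c(0L, 0L))
})

test_that("thresholding everything yields an empty network with a warning", {
  scores <- data.frame(gene_a = "TF1", gene_b = c("g1", "g2"),
                       mi = 1, puc = 1, confidence = c(0.5, 0.2))
  class(scores) <- c("edge_scores", "data.frame")
  expect_warning(net <- build_directed_network(scores, "TF1",
                                               pipeline_config()),
                 "no edge")
  expect_equal(nrow(net$edges), 0L)
})

test_that("regulons list targets by descending weight and skip childless TFs", {
  edges <- data.frame(source = c("TF1", "TF1", "TF1"),
                      target = c("g1", "g2", "g3"),
                      weight = c(1.2, 1.8, 1.5), mi = 1, puc = 1)
  net <- structure(list(edges = edges, tf_list = c("TF1", "TF2"),
                        layers = c(TF1 = 0L, TF2 = 0L, g1 = 1L, g2 = 1L,
                                   g3 = 1L),
                        groups = c(g1 = "TF1", g2 = "TF1", g3 = "TF1")),
                   class = "directed_network")
  regs <- extract_regulons(net)
  expect_named(regs, "TF1")
  expect_identical(regs$TF1$targets, c("g2", "g3", "g1"))
})

test_that("network export writes GraphML and DOT", {
  res <- cached_pipeline()
  g1 <- withr::local_tempfile(fileext = ".graphml")
  g2 <- withr::local_tempfile(fileext = ".dot")
  export_network_graphml(res$network, g1)
  export_network_dot(res$network, g2)
  expect_gt(file.size(g1), 100)
  expect_gt(file.size(g2), 50)
})
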