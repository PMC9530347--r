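#' Read and write UMI count matrices
#'
#' Counts travel either as a cellranger-style MatrixMarket triplet
#' (`matrix.mtx` genes x cells, `genes.tsv`, `barcodes.tsv`) or as a dense
#' CSV with cells in rows and genes in columns.  Both round-trip exactly.
#'
#' @param counts cells x genes integer matrix with cell ids as rownames and
#'   gene ids as colnames.
#' @param dir directory for the MTX triplet (created if missing).
#' @return `write_*` return the path invisibly; `read_*` return the counts
#'   matrix (cells x genes).
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
write_counts_mtx <- function(counts, dir) {
  assert_count_matrix(counts)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(t(counts), sparse = TRUE)   # genes x cells on disk
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname counts_io
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  counts <- t(as.matrix(m))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cells, genes)
  assert_count_matrix(counts)
}

#' @rdname counts_io
#' @param path CSV file path.
#' @export
write_counts_csv <- function(counts, path) {
  assert_count_matrix(counts)
  utils::write.csv(as.data.frame(counts), path, row.names = TRUE)
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  counts <- as.matrix(df)
  storage.mode(counts) <- "integer"
  assert_count_matrix(counts)
}

#' Read and write cell annotations
#'
#' Tab-separated with header; columns `cell_id` (written as `barcode`),
#' `condition`, `total_counts`, `mito_fraction`, and optionally `cluster`.
#'
#' @param ann annotation data.frame.
#' @param path TSV path.
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
write_cell_annotations <- function(ann, path) {
  stopifnot(all(c("cell_id", "condition", "total_counts", "mito_fraction")
                %in% names(ann)))
  out <- ann
  names(out)[names(out) == "cell_id"] <- "barcode"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_cell_annotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  names(ann)[names(ann) == "barcode"] <- "cell_id"
  ann
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sigs a list of `gene_signature` objects (or a single one).
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of `gene_signature`s.
#' @name gmt_io
NULL

#' @rdname gmt_io
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s) {
    paste(c(s$name, if (nzchar(s$provenance)) s$provenance else "na",
            s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gmt_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_signature(f[1], f[-(1:2)], provenance = f[2])
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  sigs
}

#' Read and write edge lists and gold standards
#'
#' Three-column tab-separated files (`source`, `target`, `weight`) with
#' header.  A gold standard is written with unit weights; reading one needs
#' the TF list, taken as the set of sources unless given.
#'
#' @param edges data.frame with `source`, `target`, `weight`.
#' @param path TSV path.
#' @param gold a `gold_standard`.
#' @param tf_list TF ids for [read_gold_standard()]; defaults to the
#'   distinct sources in the file.
#' @name edges_io
NULL

#' @rdname edges_io
#' @export
write_edges <- function(edges, path) {
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  utils::write.table(edges[, c("source", "target", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname edges_io
#' @export
read_edges <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname edges_io
#' @export
write_gold_standard <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  write_edges(cbind(gold$edges, weight = 1), path)
}

#' @rdname edges_io
#' @export
read_gold_standard <- function(path, tf_list = NULL) {
  e <- read_edges(path)
  if (is.null(tf_list)) tf_list <- sort(unique(e$source))
  structure(list(edges = e[, c("source", "target")], tf_list = tf_list),
            class = "gold_standard")
}

#' Export a directed network for graph tools
#'
#' Writes GraphML or DOT (Graphviz) with edge weights and per-node `layer`
#' attributes, suitable for hierarchical layout in external viewers.
#'
#' @param net a `directed_network` (see [build_directed_network()]).
#' @param path output file path.
#' @name network_io
NULL

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = names(net$layers), layer = net$layers))
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' @rdname network_io
#' @export
export_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname network_io
#' @export
export_network_dot <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "dot")
  invisible(path)
}

#' Write and read a benchmark bundle as plain-text files
#'
#' Persists counts (MTX triplets per condition), annotations, the gold
#' standard, and the planted truth so a benchmark round-trips through the
#' on-disk formats.
#'
#' @param bundle a `benchmark_bundle` from [make_benchmark()].
#' @param dir output directory.
#' @name bundle_io
NULL

#' @rdname bundle_io
#' @export
write_benchmark <- function(bundle, dir) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts_mtx(bundle$counts_a, file.path(dir, "condition_A"))
  write_counts_mtx(bundle$counts_b, file.path(dir, "condition_B"))
  write_cell_annotations(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_gold_standard(bundle$gold, file.path(dir, "gold_standard.tsv"))
  writeLines(bundle$gold$tf_list, file.path(dir, "tf_list.txt"))
  writeLines(bundle$planted_de, file.path(dir, "planted_de.txt"))
  if (!is.null(bundle$planted_signature))
    write_gmt(bundle$planted_signature, file.path(dir, "planted_signature.gmt"))
  invisible(dir)
}

#' @rdname bundle_io
#' @export
read_benchmark <- function(dir) {
  sig_path <- file.path(dir, "planted_signature.gmt")
  structure(list(
    counts_a = read_counts_mtx(file.path(dir, "condition_A")),
    counts_b = read_counts_mtx(file.path(dir, "condition_B")),
    annotations = read_cell_annotations(file.path(dir, "annotations.tsv")),
    gold = read_gold_standard(file.path(dir, "gold_standard.tsv"),
                              tf_list = readLines(file.path(dir, "tf_list.txt"))),
    planted_de = readLines(file.path(dir, "planted_de.txt")),
    planted_signature = if (file.exists(sig_path)) read_gmt(sig_path)[[1]],
    spec = NULL), class = "benchmark_bundle")
}
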