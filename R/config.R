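#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis pipeline.  Defaults follow
#' the published Langerhans-cell workflow: cells with a mitochondrial count
#' fraction of 20% or more are discarded, genes detected in fewer than 10
#' cells are discarded, the top 2000 highly variable genes are selected with
#' mean in (0, 4) and normalized dispersion >= 0.1, the neighbourhood graph
#' uses 10 nearest neighbours on 30 principal components, Leiden clustering
#' runs at resolution 0.5, differential expression is called at BH-adjusted
#' q < 0.01 and |log2 fold change| > 1, regulons are called enriched at
#' z > 0.4, network edges are kept at confidence > 1, and the 5 transcription
#' factors with the largest expression changes enter network inference.
#'
#' @param mito_max maximum tolerated mitochondrial count fraction (cells at
#'   or above this are removed).
#' @param min_cells_per_gene minimum number of cells a gene must be detected
#'   in (count > 0) to be kept.
#' @param n_hvg number of highly variable genes to keep.
#' @param hvg_min_mean,hvg_max_mean open interval for the per-gene mean of
#'   `expm1(normalized)` values.
#' @param hvg_min_disp minimum normalized (bin z-scored) dispersion.
#' @param n_neighbors neighbours in the cell kNN graph.
#' @param n_pcs principal components used for the graph.
#' @param leiden_resolution resolution of the modularity optimization.
#' @param deg_fdr BH-adjusted significance threshold for DEG calls.
#' @param deg_logfc minimum |log2 fold change| for DEG calls.
#' @param regulon_z strict z-score cutoff for regulon enrichment.
#' @param edge_weight_min strict confidence cutoff for network edges.
#' @param n_top_tfs number of TF candidates (ranked by |logFC|) passed to
#'   network inference.
#' @param pidc_condition condition label whose cells are used for network
#'   inference (the study inferred its network from migrated cells only).
#' @param seed integer seed for the stochastic stages (clustering).
#'
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(mito_max = 0.20,
                            min_cells_per_gene = 10,
                            n_hvg = 2000,
                            hvg_min_mean = 0,
                            hvg_max_mean = 4,
                            hvg_min_disp = 0.1,
                            n_neighbors = 10,
                            n_pcs = 30,
                            leiden_resolution = 0.5,
                            deg_fdr = 0.01,
                            deg_logfc = 1.0,
                            regulon_z = 0.4,
                            edge_weight_min = 1.0,
                            n_top_tfs = 5,
                            pidc_condition = "B",
                            seed = 0L) {
  check_fraction(mito_max, "mito_max")
  stopifnot(min_cells_per_gene >= 0, n_hvg >= 1, hvg_min_mean <= hvg_max_mean,
            is.numeric(hvg_min_disp),
            n_neighbors >= 1, n_pcs >= 1, leiden_resolution >= 0,
            deg_fdr > 0, deg_fdr <= 1, deg_logfc >= 0,
            edge_weight_min >= 0, n_top_tfs >= 1)
  cfg <- list(mito_max = mito_max,
              min_cells_per_gene = as.integer(min_cells_per_gene),
              n_hvg = as.integer(n_hvg),
              hvg_min_mean = hvg_min_mean, hvg_max_mean = hvg_max_mean,
              hvg_min_disp = hvg_min_disp,
              n_neighbors = as.integer(n_neighbors),
              n_pcs = as.integer(n_pcs),
              leiden_resolution = leiden_resolution,
              deg_fdr = deg_fdr, deg_logfc = deg_logfc,
              regulon_z = regulon_z, edge_weight_min = edge_weight_min,
              n_top_tfs = as.integer(n_top_tfs),
              pidc_condition = pidc_condition,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path path to a YAML file of `pipeline_config` fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
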