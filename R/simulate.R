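#' Simulation specification for the synthetic two-condition benchmark
#'
#' Describes a TF-driven regulatory system observed through droplet-style
#' UMI counts.  Each cell carries a latent log-normal activity per
#' transcription factor; a target gene's expression rate is its baseline
#' multiplied, for every parent TF, by `1 + beta * hill(activity)` with
#' `hill(a) = a^h / (a^h + 1)`.  Counts are negative binomial around the
#' rate and then zeroed by logistic dropout in the log-rate.  Condition "B"
#' (the migrated-like condition) up-shifts the rates of `module_genes` by
#' `module_fold` and multiplies the latent activity of
#' `active_tfs_condition_b` by `active_tf_fold`; because TF mRNA is emitted
#' in proportion to activity, active TFs are themselves differentially
#' expressed.
#'
#' @param n_tf,n_target number of transcription factors / target genes.
#' @param edge_density probability in (0, 1] that a given TF regulates a
#'   given target.
#' @param hill_coefficient Hill exponent of the activation function.
#' @param regulation_strength_range `(lo, hi)` of the uniform draw for the
#'   per-edge regulation strength beta.
#' @param baseline_rate_range `(lo, hi)` of the uniform draw for per-target
#'   baseline expression rates (mean UMI per cell before regulation).
#' @param nb_dispersion negative binomial dispersion phi
#'   (variance = mu + phi mu^2).
#' @param dropout_midpoint,dropout_slope logistic dropout parameters: a
#'   count is zeroed with probability
#'   `plogis(-dropout_slope * (log(rate) - dropout_midpoint))`.
#' @param n_cells_per_condition cells simulated per condition.
#' @param module_genes gene ids of the planted immunoregulatory module
#'   (must be simulated gene ids).
#' @param module_fold rate multiplier (>= 1) applied to module genes in
#'   condition "B".
#' @param active_tfs_condition_b TF ids whose latent activity is elevated in
#'   condition "B".
#' @param seed integer master seed; per-stage substreams are derived by
#'   stable hashing of (seed, stage name).
#' @param active_tf_fold activity multiplier for active TFs in condition "B".
#' @param activity_meanlog,activity_sdlog log-normal parameters of baseline
#'   TF activity.
#' @param tf_expression_scale expected TF UMI rate per unit of activity, so
#'   observed TF mRNA tracks the latent activity.
#' @param mito_shape Beta shape pair of the baseline mitochondrial fraction.
#' @param contam_fraction fraction of cells drawn from the stressed/dying
#'   subpopulation with elevated mitochondrial content.
#' @param contam_shape Beta shape pair of the contaminated subpopulation.
#'
#' @return an object of class `simulation_spec`.
#' @seealso [default_benchmark_spec()], [sample_grn()], [simulate_counts()],
#'   [make_benchmark()]
#' @export
simulation_spec <- function(n_tf,
                            n_target,
                            edge_density = 0.2,
                            hill_coefficient = 2,
                            regulation_strength_range = c(4, 8),
                            baseline_rate_range = c(2, 10),
                            nb_dispersion = 0.2,
                            dropout_midpoint = -1,
                            dropout_slope = 1,
                            n_cells_per_condition = 600,
                            module_genes = character(),
                            module_fold = 4,
                            active_tfs_condition_b = character(),
                            seed = 0L,
                            active_tf_fold = 12,
                            activity_meanlog = log(0.2),
                            activity_sdlog = 1.0,
                            tf_expression_scale = 20,
                            mito_shape = c(2, 38),
                            contam_fraction = 0.05,
                            contam_shape = c(12, 28)) {
  if (!is.numeric(n_tf) || n_tf < 1) stop("invalid n_tf: must be >= 1")
  if (!is.numeric(n_target) || n_target < 1) stop("invalid n_target: must be >= 1")
  if (!is.numeric(edge_density) || edge_density <= 0 || edge_density > 1)
    stop("invalid edge_density: must be in (0, 1]")
  check_positive(hill_coefficient, "hill_coefficient")
  check_range(regulation_strength_range, "regulation_strength_range")
  check_range(baseline_rate_range, "baseline_rate_range")
  check_positive(nb_dispersion, "nb_dispersion")
  check_positive(dropout_slope, "dropout_slope")
  if (!is.numeric(dropout_midpoint) || length(dropout_midpoint) != 1L)
    stop("invalid dropout_midpoint")
  if (!is.numeric(n_cells_per_condition) || n_cells_per_condition < 1)
    stop("invalid n_cells_per_condition: must be >= 1")
  if (!is.numeric(module_fold) || module_fold < 1)
    stop("invalid module_fold: must be >= 1")
  check_positive(active_tf_fold, "active_tf_fold")
  check_positive(activity_sdlog, "activity_sdlog")
  check_positive(tf_expression_scale, "tf_expression_scale")
  check_fraction(contam_fraction, "contam_fraction")

  spec <- list(n_tf = as.integer(n_tf), n_target = as.integer(n_target),
               edge_density = edge_density,
               hill_coefficient = hill_coefficient,
               regulation_strength_range = regulation_strength_range,
               baseline_rate_range = baseline_rate_range,
               nb_dispersion = nb_dispersion,
               dropout_midpoint = dropout_midpoint,
               dropout_slope = dropout_slope,
               n_cells_per_condition = as.integer(n_cells_per_condition),
               module_genes = as.character(module_genes),
               module_fold = module_fold,
               active_tfs_condition_b = as.character(active_tfs_condition_b),
               seed = as.integer(seed),
               active_tf_fold = active_tf_fold,
               activity_meanlog = activity_meanlog,
               activity_sdlog = activity_sdlog,
               tf_expression_scale = tf_expression_scale,
               mito_shape = mito_shape,
               contam_fraction = contam_fraction,
               contam_shape = contam_shape)
  class(spec) <- "simulation_spec"

  ids <- sim_gene_ids(spec)
  bad <- setdiff(spec$module_genes, ids$genes)
  if (length(bad))
    stop("invalid module_genes: not simulated gene ids: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(spec$active_tfs_condition_b, ids$tfs)
  if (length(bad))
    stop("invalid active_tfs_condition_b: not simulated TF ids: ",
         paste(bad, collapse = ", "))
  spec
}

# Gene id universe implied by a spec: TFs first, then targets.
sim_gene_ids <- function(spec) {
  tfs <- sprintf("TF%d", seq_len(spec$n_tf))
  targets <- sprintf("G%02d", seq_len(spec$n_target))
  list(tfs = tfs, targets = targets, genes = c(tfs, targets))
}

#' The default packaged benchmark specification
#'
#' Five transcription factors regulating 25 targets at edge density 0.2,
#' 600 cells per condition, a planted 6-gene immunoregulatory module
#' up-shifted 4-fold in condition "B", and one activity-elevated TF in
#' condition "B" — a desk-scale stand-in for the steady-state vs migrated
#' Langerhans-cell comparison.
#'
#' @param seed integer master seed.
#' @return a `simulation_spec`.
#' @export
default_benchmark_spec <- function(seed = 0L) {
  simulation_spec(n_tf = 5, n_target = 25, edge_density = 0.2,
                  n_cells_per_condition = 600,
                  module_genes = sprintf("G%02d", 20:25),
                  module_fold = 4,
                  active_tfs_condition_b = "TF1",
                  seed = seed)
}

#' Sample a gold-standard regulatory network
#'
#' Draws the bipartite TF-to-target wiring of the simulator: every
#' (TF, target) edge is included independently with probability
#' `spec$edge_density`, and any target left without a parent is assigned one
#' uniformly chosen TF so that all targets are regulated.  Deterministic
#' under `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @return an object of class `gold_standard`: a list with `edges` (a
#'   data.frame of `source`, `target`) and `tf_list`.
#' @export
sample_grn <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  ids <- sim_gene_ids(spec)
  with_seed(stage_seed(spec$seed, "grn"), {
    keep <- matrix(runif(spec$n_tf * spec$n_target) < spec$edge_density,
                   nrow = spec$n_tf)
    orphans <- which(colSums(keep) == 0L)
    for (j in orphans) keep[sample.int(spec$n_tf, 1L), j] <- TRUE
    idx <- which(keep, arr.ind = TRUE)
    edges <- data.frame(source = ids$tfs[idx[, 1]],
                        target = ids$targets[idx[, 2]],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
    structure(list(edges = edges, tf_list = ids$tfs),
              class = "gold_standard")
  })
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d edges, %d TFs\n",
              nrow(x$edges), length(x$tf_list)))
  invisible(x)
}

# Per-gene generative parameters shared by both conditions (substream
# "params" of the master seed, independent of condition).
sim_parameters <- function(grn, spec) {
  ids <- sim_gene_ids(spec)
  if (!identical(grn$tf_list, ids$tfs) ||
      length(setdiff(grn$edges$source, ids$tfs)) ||
      length(setdiff(grn$edges$target, ids$genes)))
    stop("grn/spec mismatch: gold-standard ids are not the spec's gene universe")
  with_seed(stage_seed(spec$seed, "params"), {
    baseline <- runif(spec$n_target,
                      spec$baseline_rate_range[1], spec$baseline_rate_range[2])
    names(baseline) <- ids$targets
    beta <- runif(nrow(grn$edges),
                  spec$regulation_strength_range[1],
                  spec$regulation_strength_range[2])
    list(baseline = baseline, beta = beta)
  })
}

#' Simulate UMI counts for one condition
#'
#' Draws latent TF activities, propagates them through the gold-standard
#' wiring with a Hill activation function, and observes the resulting rates
#' as negative-binomial UMI counts with logistic dropout.  Cell-level noise
#' is drawn from a substream shared by both conditions (common random
#' numbers), so a null specification (`module_fold = 1`, no active TFs)
#' produces bit-identical matrices for conditions "A" and "B".
#'
#' @param grn a [sample_grn()] result consistent with `spec`.
#' @param spec a [simulation_spec()].
#' @param condition `"A"` (steady-state-like) or `"B"` (migrated-like).
#' @return a list with `counts` (cells x genes integer matrix) and
#'   `annotations` (data.frame: `cell_id`, `condition`, `total_counts`,
#'   `mito_fraction`).
#' @export
simulate_counts <- function(grn, spec, condition) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(grn, "gold_standard"))
  if (!condition %in% c("A", "B"))
    stop("unknown condition label: ", condition, " (expected \"A\" or \"B\")")
  ids <- sim_gene_ids(spec)
  par <- sim_parameters(grn, spec)
  n <- spec$n_cells_per_condition
  G <- length(ids$genes)

  with_seed(stage_seed(spec$seed, "counts"), {
    # latent TF activities: same standard normals in both conditions, the
    # location shifts for active TFs in condition B
    zmat <- matrix(rnorm(n * spec$n_tf), nrow = n)
    meanlog <- rep(spec$activity_meanlog, spec$n_tf)
    names(meanlog) <- ids$tfs
    if (condition == "B")
      meanlog[spec$active_tfs_condition_b] <-
        meanlog[spec$active_tfs_condition_b] + log(spec$active_tf_fold)
    activity <- exp(sweep(zmat * spec$activity_sdlog, 2, -meanlog))
    colnames(activity) <- ids$tfs

    # expression rates, cells x genes
    mu <- matrix(0, nrow = n, ncol = G, dimnames = list(NULL, ids$genes))
    mu[, ids$tfs] <- spec$tf_expression_scale * activity
    h <- spec$hill_coefficient
    hill <- activity^h / (activity^h + 1)
    mu[, ids$targets] <- matrix(par$baseline, nrow = n, ncol = spec$n_target,
                                byrow = TRUE)
    for (e in seq_len(nrow(grn$edges))) {
      src <- grn$edges$source[e]
      tgt <- grn$edges$target[e]
      mu[, tgt] <- mu[, tgt] * (1 + par$beta[e] * hill[, src])
    }
    if (condition == "B" && length(spec$module_genes))
      mu[, spec$module_genes] <- mu[, spec$module_genes] * spec$module_fold

    counts <- matrix(rnbinom(n * G, mu = mu, size = 1 / spec$nb_dispersion),
                     nrow = n)
    p_drop <- stats::plogis(-spec$dropout_slope *
                              (log(mu) - spec$dropout_midpoint))
    counts <- counts * (matrix(runif(n * G), nrow = n) >= p_drop)
    storage.mode(counts) <- "integer"

    contam <- runif(n) < spec$contam_fraction
    mito <- ifelse(contam,
                   rbeta(n, spec$contam_shape[1], spec$contam_shape[2]),
                   rbeta(n, spec$mito_shape[1], spec$mito_shape[2]))

    cell_ids <- sprintf("%s_cell%04d", condition, seq_len(n))
    dimnames(counts) <- list(cell_ids, ids$genes)
    ann <- data.frame(cell_id = cell_ids, condition = condition,
                      total_counts = as.integer(rowSums(counts)),
                      mito_fraction = mito, stringsAsFactors = FALSE)
    list(counts = counts, annotations = ann)
  })
}

#' Assemble the full synthetic benchmark
#'
#' Samples the gold-standard network, simulates both conditions, and records
#' the planted truth: `planted_de` is the union of the module genes, the
#' targets of the activity-elevated TFs, and those TFs themselves (TF mRNA
#' tracks activity, so an elevated TF is a genuine expression effect);
#' `planted_signature` is the module.
#'
#' @param spec a [simulation_spec()].
#' @return an object of class `benchmark_bundle`: list with `counts_a`,
#'   `counts_b`, `annotations` (both conditions, row-bound), `gold`,
#'   `planted_de`, `planted_signature`, and `spec`.
#' @export
make_benchmark <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  gold <- sample_grn(spec)
  a <- simulate_counts(gold, spec, "A")
  b <- simulate_counts(gold, spec, "B")
  stopifnot(identical(colnames(a$counts), colnames(b$counts)))
  active <- spec$active_tfs_condition_b
  active_targets <- gold$edges$target[gold$edges$source %in% active]
  planted_de <- sort(unique(c(spec$module_genes, active_targets, active)))
  sig <- if (length(spec$module_genes)) {
    gene_signature("planted_module", spec$module_genes,
                   provenance = "simulated immunoregulatory module")
  } else {
    warning("module_genes empty: planted signature is empty")
    NULL
  }
  structure(list(counts_a = a$counts, counts_b = b$counts,
                 annotations = rbind(a$annotations, b$annotations),
                 gold = gold, planted_de = planted_de,
                 planted_signature = sig, spec = spec),
            class = "benchmark_bundle")
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat(sprintf(paste0("benchmark_bundle: %d + %d cells, %d genes, ",
                     "%d gold edges, %d planted DE genes\n"),
              nrow(x$counts_a), nrow(x$counts_b), ncol(x$counts_a),
              nrow(x$gold$edges), length(x$planted_de)))
  invisible(x)
}
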