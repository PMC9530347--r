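# pidcell

Directional PIDC gene-regulatory-network inference and tolerogenic
signature scoring for two-condition single-cell RNA-seq.

## The problem

Migratory antigen-presenting cells (the motivating system is human
Langerhans cells leaving the epidermis) switch transcriptional state
between a steady-state and a migrated condition, up-regulating an
immunoregulatory ("tolerogenic") gene programme.  Analysing such data
requires a chain of steps — droplet QC, size-factor normalization,
clustering, differential expression, signature scoring — and, to get at
mechanism, inference of which transcription factors (TFs) drive the
programme.  `pidcell` implements that chain for R users, with the network
inference step built from first principles:

**PIDC (partial information decomposition in context)** scores a gene
pair (X, Y) by how much of their mutual information is *unique* rather
than redundant with every other gene Z in the panel.  With the
Williams–Beer redundancy

```
I_spec(S; y) = Σ_s p(s|y) log2[ p(s|y) / p(s) ]
R(X,Z;Y)     = Σ_y p(y) · min( I_spec(X;y), I_spec(Z;y) )
U_X(Y|Z)     = I(X;Y) − R(X,Z;Y)
```

the proportional unique contribution accumulates over contexts in both
directions:

```
u_XY = Σ_Z U_X(Y|Z)/I(X;Y)  +  Σ_Z U_Y(X|Z)/I(X;Y)
```

Each gene then rescales its pair scores through its own empirical CDF,
and an edge's confidence is the sum of the two endpoint CDFs — a weight
in [0, 2].  Finally the network is restricted to the direction of
regulatory information flow (TF → target; TF–TF pairs keep both
directions) and thresholded at confidence strictly above 1.

Around the core, the package provides pooled-deconvolution
normalization, dispersion-based HVG selection, Leiden clustering, Welch
differential expression (q < 0.01, |log2FC| > 1), consensus-signature
assembly (genes shared by ≥ k DEG lists), per-cell signature scoring
(z-score averages and a GSVA-style rank statistic), AUCell-style regulon
activity with z-score enrichment at the strict 0.4 cutoff, and a
synthetic two-condition benchmark generator with a known gold-standard
network for end-to-end evaluation.

## Worked example

```r
library(pidcell)

# a seeded two-condition benchmark: 5 TFs, 25 targets, 600 cells/condition
spec <- default_benchmark_spec(seed = 0L)
bundle <- make_benchmark(spec)
bundle
#> benchmark_bundle: 600 + 600 cells, 30 genes, 33 gold edges, 10 planted DE genes

# end-to-end pipeline: QC, normalization, clustering, DEG, PIDC, regulons
res <- run_pipeline(bundle)

# differential expression against the planted truth
called <- res$deg$gene_id[res$deg$significant_up_a | res$deg$significant_up_b]
deg_recovery(called, bundle$planted_de, res$deg$gene_id)
#> recovery_report: aupr=NA auroc=NA prevalence=NA sensitivity=1 empirical_fdp=0

# the directional network at confidence > 1
res$network
#> directed_network: 89 edges from 5 TFs over 30 nodes
head(res$network$edges, 5)
#>   source target   weight        mi      puc
#> 1    TF1    G05 2.000000 0.5649127 17.75871
#> 2    TF2    G15 2.000000 0.5166566 16.83777
#> 3    TF4    G13 2.000000 0.6153834 19.64033
#> 4    TF5    G21 2.000000 0.5085589 15.54689
#> 5    TF1    G25 1.965517 0.5165437 17.59626

# network recovery against the gold standard
ranked <- res$network$edges[, c("source", "target", "weight")]
network_recovery_metrics(ranked, bundle$gold, mode = "directed")
#> recovery_report: aupr=0.8008 auroc=0.8731 prevalence=0.2276 sensitivity=NA empirical_fdp=NA

# planted-module enrichment between conditions
res$signature_comparison
#>        signature    logfc p q method
#> 1 planted_module 1.522909 0 0 zscore
#> 2 planted_module 1.006505 0 0   gsva
```

Reading the numbers: all 10 planted differentially expressed genes are
recovered with no false discoveries at the q < 0.01, |log2FC| > 1
thresholds; the thresholded directional network ranks true TF→target
edges far above chance (AUPR 0.80 against a prevalence of 0.23); and the
planted immunoregulatory module scores significantly higher in the
migrated-like condition under both scoring methods.

Counts, annotations, gene sets, and networks travel through standard
formats: MatrixMarket triplets or dense CSV for counts, TSV for
annotations and edge lists, GMT for signatures and regulons, and
GraphML/DOT for hierarchical network layouts (see `?write_counts_mtx`,
`?read_gmt`, `?export_network_graphml`).

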