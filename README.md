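# guildscan

Guild-based analysis of gut-microbiota count data: finds **co-abundant
groups** (CAGs, "guilds") of amplicon sequence variants and links them to
host phenotypes.

Microbiome interventions — prebiotics, diets, drugs — rarely act on single
taxa. Bacteria that co-vary across samples behave as functional units, and
analysing those units instead of hundreds of individual ASVs both respects
the ecology and shrinks the multiple-testing burden. `guildscan` is for
microbiome researchers who have a denoised ASV count table (e.g. a QIIME2 /
DADA2 export), sample metadata, and per-sample phenotype measurements, and
want a reproducible guild-level analysis.

## What it computes

1. **Preprocessing** — rarefaction to even depth (default 16,500 reads,
   shallower samples dropped and reported) and a 20%-prevalence ASV filter.
2. **SparCC basis correlations** for compositional counts: from log-ratio
   variances `t_ij = var log(x_i/x_j)` and the sparsity approximation
   `sum_j rho_ij ~ 0`, solve `((D-2)I + 11') w = t_+` for the basis
   variances, then `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`, with
   iterative exclusion of strong pairs, Dirichlet-posterior resampling for
   zeros, and permutation pseudo p-values.
3. **Guild detection** — Ward (ward.D2) clustering of the distance
   `d = 1 - rho`, then a top-down recursive PERMANOVA cut: each node's two
   subtrees are compared (999 permutations) and the node collapses into one
   CAG when `p > 0.001`.
4. **Community statistics** — Shannon (bits) and observed ASVs with
   per-timepoint Kruskal–Wallis + BH; Bray–Curtis, PCoA, pairwise PERMANOVA
   (9,999 permutations) + BH.
5. **Association** — Spearman correlation of guild abundances with
   phenotypes/SCFAs and Mann–Whitney differential guild abundance between
   groups, both BH-corrected; Z-score summaries of group means.
6. **Outputs** — TSV tables, a Newick cluster tree, and a Cytoscape-ready
   co-abundance network (GraphML/SIF; edges shown at `|rho| >= 0.6`).

A synthetic-data generator (`simulation_config()` / `generate_dataset()`)
plants known guild structure, group effects and phenotype couplings, so the
whole pipeline is verifiable end-to-end; `evaluate_recovery()` scores a
found partition against the planted truth by adjusted Rand index.

## Worked example

```r
library(guildscan)

cfg <- simulation_config(D = 60, K = 6, n_mice_per_group = 10,
                         timepoints = c("d0", "d105"), rng_seed = 1)
ds  <- generate_dataset(cfg)      # counts + metadata + phenotypes + truth

res <- run_pipeline(ds, config = pipeline_config(
  sparcc = list(compute_pvalues = FALSE), seed = 1))

length(unique(res$assignment$cag))
#> [1] 5
evaluate_recovery(res$assignment, ds$truth$guilds[res$assignment$asv_id])
#> [1] 0.8102894

sig <- subset(res$association, fdr < 0.05)
head(sig[order(sig$fdr), ], 5)
#>     cag   variable    rho  n  p_value      fdr
#>    CAG3   TG_liver  0.736 30 3.62e-06 3.98e-05
#>    CAG3   TC_serum  0.749 30 1.96e-06 3.98e-05
#>    CAG1 total_SCFA  0.727 30 5.30e-06 3.98e-05
#>    CAG3 total_SCFA -0.733 30 4.00e-06 3.98e-05
#>    CAG1   butyrate  0.706 30 1.31e-05 7.88e-05
```

Five guilds are recovered from six planted ones (two weakly separated
guilds merge; adjusted Rand index 0.81). CAG3 — a suppressed guild —
correlates positively with hepatic triglyceride and serum cholesterol and
negatively with total SCFA, while promoted CAG1 shows the mirror pattern:
exactly the planted phenotype couplings. `run_pipeline(..., config =
pipeline_config(out_dir = "out"))` additionally writes every table, the
tree, the network files and a JSON manifest that records seed, config and
per-stage dimensions.

A thin command-line wrapper with subcommands `simulate`, `sparcc`,
`guilds`, `diversity`, `assoc` and `run` is installed at
`inst/cli/guildscan.R`.

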