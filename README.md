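# tauatlas

Tissue-specificity analysis of multi-tissue bulk RNA-seq expression
atlases, for researchers building gene catalogues of non-model organisms:
which genes are confined to one tissue, enriched in a small group of
tissues, expressed everywhere, or none of the above — and how that
structure propagates into co-expression modules and protein–protein
interaction (PPI) networks.

The pipeline starts from a genes × samples TPM matrix, a raw count
matrix and a sample→tissue design, and runs:

* **τ index and classification.** For tissue means $x_{g,i}$ over $N$
  tissues, $\tau_g = \sum_i (1 - x_{g,i}/\max_i x_{g,i}) / (N-1)$, after
  removing genes with grand mean ≤ 1 TPM. Genes are classified, in
  precedence order, as **TissueSpecific** (τ > 0.85, top tissue ≥ 5× every
  other tissue), **GroupEnriched** (τ > 0.5, a 2–7 tissue group ≥ 5× the
  rest), **ExpressedInAll** (≥ 1 TPM in every tissue), or **Mixed**.
* **One-vs-all differential expression.** Per tissue, a negative-binomial
  GLM likelihood-ratio test with library-size offsets and
  method-of-moments dispersions with common-value shrinkage; DEGs require
  log2FC > 3 and p < 0.05 (both strict).
* **Co-expression modules.** Weighted adjacency |r|^β, topological
  overlap, average-linkage clustering with a static cut; per-tissue module
  activity as a permutation-normalized enrichment score (NES); intramodule
  hubs by connectivity.
* **Tissue-specific PPI networks.** A STRING-style interactome filtered at
  combined score > 0.7; a tissue's network is the induced subgraph over
  proteins that are tissue-specific for it *and* members of a module
  significantly active in it, keeping components of ≥ 3 proteins.
* **Label-set association.** Comparisons of supplied gene sets (genes
  under positive selection, transcription factors, …) against τ and
  expression, with hand-implemented Kruskal–Wallis and one-way ANOVA.

A seeded synthetic-atlas generator with planted ground truth
(`simulate_atlas()`, `simulate_ppi()`) backs the test suite end to end.
See the methods vignette (`vignettes/tauatlas-methods.Rmd`) for models,
parameter choices and limitations.

## Worked example

```r
library(tauatlas)

sim     <- simulate_atlas(sim_config(n_genes = 2000, seed = 42))
profile <- filter_genes(average_replicates(sim$atlas))
tau     <- classify_genes(profile, compute_tau(profile))
table(tau$category)
#> TissueSpecific  GroupEnriched ExpressedInAll          Mixed
#>            295            390            601            708
```

About 15% of retained genes are tissue-specific — the planted proportions.
Each classified gene carries its τ, top tissue, and enrichment fold:

```r
head(tau[tau$category == "TissueSpecific", ], 3)
#>             gene_id    tau max_tissue max_tpm fold_over_rest
#> gene00008 gene00008 0.9862   tissue02    6870          65.22
#> gene00011 gene00011 0.9610   tissue02    1490          19.63
#> gene00015 gene00015 0.9726   tissue01    2646          19.66

fc <- foldchange_tau_correlation(tau)
sprintf("Spearman rho(log2 fold, tau) = %.3f (p = %.3g)", fc$rho, fc$p)
#> "Spearman rho(log2 fold, tau) = 0.666 (p = 2.41e-255)"
```

The positive rank correlation between enrichment fold and τ confirms that
high-τ genes are exactly the ones upregulated in a single tissue. The full
pipeline — simulation, classification, differential expression, modules,
networks — runs from one call and writes a reproducible run directory:

```r
out <- run_pipeline(run_config(simulate = TRUE, sim = list(n_genes = 2000),
                               seed = 42, n_perm = 500), "run42")
summarize_run("run42")$networks
#>     tissue n_nodes n_edges
#> 1 tissue01       5      10
#> 2 tissue03       5      10
#> 3 tissue05       5      10
#> 4 tissue10       5      10
```

Four tissues carry a tissue-specific PPI subnetwork — each one exactly the
5-protein clique (10 edges) planted by the simulator inside a module active
in that tissue.

A command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/atlas-pipeline.R --simulate --seed 7 --outdir out/
Rscript inst/scripts/atlas-pipeline.R --config run.yaml --outdir out/
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "tauatlas",
                               load_package = "installed")'
```

The suite covers every stage against independent oracles (scalar-loop τ,
brute-force likelihood maximization, reference rank tests), planted-truth
recovery, calibration of type-I error and permutation nulls, and
byte-level determinism.

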