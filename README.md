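# generisk

Supervised prioritization of neurodevelopmental disease risk genes — autism
spectrum disorder (ASD) is the motivating application — from three kinds of
gene-level evidence:

* **spatiotemporal brain expression**: log2(RPKM + 1) profiles across brain
  regions × developmental stages, one feature per sample;
* **network topology**: ten node-level features (degree, closeness,
  betweenness, Bonacich power, eigenvector and alpha centrality, PC1 loading,
  hub score, coreness, PageRank) of a protein–protein interaction network
  whose edges are weighted by the Fisher z-transformed co-expression
  `z = atanh(r)` of their endpoints, with kNN imputation for genes outside
  the network;
* **mutational constraint**: the six constraint metrics (`syn_z`, `mis_z`,
  `lof_z`, `pLI`, `pRec`, `pNull`) plus ten gene-variation features.

Four classifier families (L2 logistic regression, Gaussian-kernel SVM,
random forest, gradient boosted trees) are trained under stratified 5-fold
cross-validation with a nested 3-fold grid search maximizing AUC-ROC; the
best family (argmax mean AUC-ROC, ties by AUC-PRC) is refit on all labeled
genes to score the rest of the genome. Labeled genes keep **out-of-fold**
scores, the joint ranking is cut into deciles, and genes are classified at
the threshold maximizing F1 = 2PR/(P + R) on the out-of-fold scores.

The ranking is then validated the way the field validates such rankings:

* **permutation DGE enrichment** — is the predicted risk set enriched for
  differential-expression evidence (p < 0.05) relative to random gene sets of
  the same size? `fold = observed / mean(null)`, empirical
  `p = (#{null ≥ obs} + 1)/(n_perm + 1)`;
* **binomial first-decile enrichment** — do independent candidate lists
  (e.g. de novo LoF genes from probands) land in the first decile more often
  than the expected proportion `p0 = 0.166`? One-sided exact binomial
  `P(X ≥ k | n, p0)`;
* **ranking comparison** — median rank and first-decile proportion of
  candidates across arbitrary scoring systems;
* **GO enrichment** — two-sided Fisher exact tests of risk vs non-risk genes
  per gene set (sets overlapping the tested universe by 20–2,000 genes,
  Bonferroni-corrected), with significant terms clustered on `1 − R` of
  their overlap profiles using Ward linkage.

Because the real data sources (brain atlas, constraint release, PPI
catalogue, cohort gene lists) cannot ship with a package, `generisk`
includes a first-class, seeded synthetic-data generator that emulates all of
them with planted, recoverable effects; see the methods vignette
(`vignettes/methods.Rmd`) for what it does and does not emulate.

## Worked example

```r
library(generisk)

ds <- generate_dataset(synthetic_config(seed = 1))     # default benchmark
expr     <- log_transform(ds$expression)
net      <- build_network(ds$ppi_edges, expr)
features <- assemble_features(expr, topology_features(net),
                              ds$constraint, ds$labels)

cv <- run_cv(features, model_spec("gradient_boosted_trees"), seed = 1)
cv
#> <cv_result> gradient_boosted_trees: mean AUC-ROC 0.961, mean AUC-PRC 0.853 over 5 folds

model <- fit_final_and_score(features, cv, seed = 1)
model
#> <risk_model> gradient_boosted_trees: 2000 genes scored, threshold 0.381 (F1 0.775), 252 predicted risk

risk <- model$scores$gene[model$scores$predicted_class == "risk"]
dge_enrichment(risk, ds$dge_tables$asd, n_perm = 10000, seed = 1, phenotype = "asd")
#> <dge_enrichment> [asd] 23/252 genes with DGE evidence (null 15.71 +/- 3.63): fold 1.46, p 0.0346 (10000 perms, direction any)
dge_enrichment(risk, ds$dge_tables$ibd, n_perm = 10000, seed = 1, phenotype = "ibd")
#> <dge_enrichment> [ibd] 5/252 genes with DGE evidence (null 12.30 +/- 3.19): fold 0.41, p 0.997 (10000 perms, direction any)

decile_enrichment(model, ds$validation_lists$proband, list_name = "proband")
#>   list_name     n     k proportion    p0    p_value n_dropped
#> 1 proband     120    41      0.342 0.166 0.00000221         0
```

Reading the numbers: the cross-validated model separates held-out labeled
genes well (AUC-ROC 0.961 under class imbalance, hence the lower AUC-PRC of
0.853); 252 genes clear the F1-optimal risk threshold of 0.381. That
predicted risk set carries 1.46× the differential-expression evidence of
size-matched random sets in the ASD-analog phenotype (p = 0.03) but is, as
it should be, at chance in the IBD-analog control (fold 0.41, p ≈ 1). Of the
120 proband-list genes, 34% sit in the first decile of the ranking versus
the 16.6% expected under the sibling-calibrated null (binomial p ≈ 2e-6).

The whole chain — plus GO enrichment and term clustering — also runs as one
call from a config object or YAML file:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
glance(res$model)
autoplot(res$validation$dge$asd)
```

Every result type has `tidy()`/`glance()` accessors and `autoplot()`
methods; file outputs (`scores.tsv`, enrichment tables, a JSON run manifest
with seeds and checksums) land in `out_dir`, and reruns with an identical
config and seed are byte-identical. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

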