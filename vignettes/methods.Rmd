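---
title: "Ranking risk genes from brain expression, network topology, and constraint: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking risk genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(generisk)
library(dplyr)
```

## The problem and the model

`generisk` prioritizes candidate disease risk genes — autism spectrum
disorder is the motivating application — under a guilt-by-association
premise: genes that confer risk share distinguishing, measurable properties.
Three property families enter the model:

1. **Spatiotemporal brain expression.** Each (region, developmental stage,
   donor) sample of a brain transcriptome atlas contributes one feature per
   gene, on the log2(RPKM + 1) scale. Risk genes tend to be expressed more
   highly, and the contrast concentrates in early-to-mid prenatal stages.
2. **Network topology.** Genes with protein–protein interaction (PPI)
   evidence are connected in an undirected graph whose edges are weighted by
   the Fisher z-transformed Pearson correlation of the two genes' expression
   profiles. Ten node-level features summarize each gene's position: degree,
   closeness, betweenness, Bonacich power centrality, eigenvector centrality,
   alpha centrality, the leading-eigenvector (PC1) loading of the weighted
   adjacency, hub score, k-core coreness, and PageRank. Genes with expression
   but no PPI evidence receive k-nearest-neighbour imputed topology features
   (neighbours in standardized expression space).
3. **Mutational constraint and gene variation.** Six constraint metrics
   (`syn_z`, `mis_z`, `lof_z`, `pLI`, `pRec`, `pNull`) and ten general
   variation features (coding length, per-transcript mutation probabilities,
   observed and expected rare-variant counts).

A labeled training set (known risk genes vs genes implicated only in
non-mental-health disease) supervises four classifier families: L2 logistic
regression, a Gaussian-kernel SVM, a probability random forest, and gradient
boosted trees. Performance is estimated by stratified 5-fold cross-validation
with a nested, stratified 3-fold grid search maximizing AUC-ROC inside each
training fold, so hyperparameters never see their hold-out fold. Because the
labels are heavily imbalanced, AUC-PRC is reported next to AUC-ROC; the
winning family is the argmax of mean AUC-ROC (ties: mean AUC-PRC, then a
fixed family order).

Labeled genes keep **out-of-fold** scores — each gene is scored by the one
model whose training fold excluded it — while unlabeled genes are scored by a
final model re-tuned and fit on all labeled genes. The combined table is
ranked jointly (rank 1 = best), cut into deciles (decile 1 holds the top
⌈n/10⌉ genes), and dichotomized at the threshold that maximizes F1 on the
out-of-fold scores. Out-of-fold scores are used for the threshold search to
avoid the optimism a refit model would introduce.

## Validation statistics

Three statistics probe whether the ranking behaves like a risk-gene ranking:

* **Size-matched permutation DGE enrichment.** Given per-gene differential
  expression summary statistics (beta, p) for a phenotype, count predicted
  risk genes with p < 0.05 (optionally restricted to down-regulation), and
  compare against random gene sets of the same cardinality drawn from the
  universe of genes with DGE statistics. "Size-matched" is read as matching
  the *number* of genes; the fold is observed/null-mean and the empirical
  p-value uses the add-one estimator (#{null ≥ observed} + 1)/(n_perm + 1),
  which can never be exactly zero — a zero-exceedance result at 100,000
  permutations reports p < 1e-5. Control phenotypes with no expected signal
  (an inflammatory-bowel-disease analog and two psychiatric-disorder analogs)
  should stay null.
* **Binomial first-decile enrichment.** For an independent candidate list
  (e.g. genes hit by de novo loss-of-function mutations in probands), test
  whether more members fall in the first decile than the expected proportion
  p0 = 0.166 with a one-sided exact binomial test. The default p0 is the
  first-decile rate of synonymous de novo mutation carriers in unaffected
  siblings — a mutation-opportunity-calibrated null rather than 0.10.
* **Ranking comparison.** For any set of scoring systems (entered simply as
  gene/score tables), candidates' median rank and first-decile proportion.

GO enrichment contrasts predicted risk genes against predicted non-risk
genes (the prediction universe, not all annotated genes) per gene set with a
two-sided Fisher exact test, keeping sets that overlap the tested universe by
20–2,000 genes (inclusive) and Bonferroni-correcting over the number of
surviving sets. Significant terms are clustered on 1 − R, where R is the
Pearson correlation between rows of the pairwise overlap-count matrix, with
classic Ward linkage (`ward.D`), cut into 5 clusters by default.

## What the synthetic generator emulates

Real atlases, constraint releases, and PPI catalogues cannot ship with a
package, so `generate_dataset()` builds a statistically analogous benchmark
whose planted structure is known:

```{r quick-look}
cfg <- synthetic_config(n_genes = 300, n_positive = 40, n_negative = 160,
                        n_hidden_risk = 30, n_regions = 4, n_stages = 5,
                        go_n_terms = 10, go_planted_terms = 2,
                        n_proband = 40, n_sibling = 30, seed = 1)
ds <- generate_dataset(cfg)
ds$expression
table(ds$labels$label)
```

* **Expression**: per-gene log-normal baseline (gene mean ~ N(3.5, 1.5²) on
  the log2 scale, sample noise sd 0.8), additive context effects, then
  back-transformed to RPKM. Risk genes gain `expr_effect_prenatal` (default
  1.0 log2 units) in the first 40% of stages — flagged prenatal to emulate
  the 12–21 post-conceptional-week window — and `expr_effect_postnatal`
  (default 0.3) elsewhere. The default 8 regions × 10 stages × 1 donor keeps
  runs desk-scale; the real atlas dimensionality (31 regions × 13 stages) is
  reachable through the config.
* **Labels**: 150 positives and 850 negatives among 2,000 genes by default
  (~15% positives among labeled genes, close to the 121/963 imbalance of the
  curated training set this emulates). An additional `n_hidden_risk` = 150
  genes are truly risk but left unlabeled: they carry the same planted
  signal and are what genome-wide prediction is supposed to surface; without
  them the proband-list validation would have nothing to find.
* **Constraint**: the (pLI, pRec, pNull) triple is a softmax of latent
  normals, so the probabilities are automatically in [0, 1] and sum to one;
  risk genes shift toward high pLI and low pNull. Remaining features are
  (log-)normal or Poisson with fixed signed shifts scaled by
  `constraint_shift`: higher `mis_z`, `lof_z`, longer genes, higher mutation
  probabilities and more rare synonymous/missense variants, but *fewer*
  observed LoF variants — the canonical constraint signature. `syn_z` carries
  no planted shift.
* **PPI**: a preferential-attachment (scale-free) graph over 85% of genes;
  risk genes get a mild bias toward early attachment slots (hubs). The
  remaining 15% of genes exercise the kNN imputation path.
* **DGE tables**: per phenotype, each gene is significant (p < 0.05)
  independently with probability 0.05 (background) or
  `dge_enrichment_rate` = 0.10 (risk genes, ASD-analog phenotype only), so
  the planted enrichment fold is 2.0; significant risk effects are negative
  (down-expressed) with probability 0.8. Control phenotypes use the
  background rate everywhere.
* **Validation lists**: the proband list samples hidden-risk genes with
  probability `proband_top_rate` = 0.5 and unlabeled non-risk genes
  otherwise; the sibling list is uniform. Training positives are excluded
  from both, mirroring the independence filter applied to real cohorts.
* **GO sets**: `go_planted_terms` = 10 of 50 sets are built to hit a
  population odds ratio of `go_planted_or` = 10 (within ±10%, by solving for
  the risk-member count); the rest are uniform draws.

Everything is a deterministic function of the configuration (seed included),
and the generator restores the caller's RNG state.

**What it does not emulate** — and hence what passing tests do *not* show
about real data: features are conditionally independent given risk status
(no co-expression modules beyond the planted mean shifts, no
constraint–expression correlation), expression noise is Gaussian on the log
scale with a single shared sd, donors are exchangeable (no covariates or
batch structure), the PPI graph has no false-positive/false-negative edge
structure, and DGE p-values are exactly uniform under the null. Recovery of
planted effects demonstrates the pipeline's correctness and statistical
calibration, not real-world predictive performance.

## Numerical choices

* **Edge weights**: Pearson r is clamped to ±(1 − 1e−6) before atanh, so
  identical profiles stay finite; constant profiles (undefined correlation)
  get weight 0 with a warning. Algorithms that need non-negative weights use
  the derived weight |z| — the magnitude of co-expression is the strength
  signal, and centrality/PageRank/shortest-path algorithms are undefined for
  negative weights. A floor of 1e−8 is applied where a strictly positive
  weight is required (path lengths 1/|z|, PageRank).
* **Spectral parameters**: Bonacich power exponent β = 0.9/λ_max and alpha
  centrality α = 0.5/λ_max (exogenous term 1), with λ_max the leading
  eigenvalue of the |z|-weighted adjacency obtained by power iteration; both
  keep the resolvent (I − cA)⁻¹ convergent. The PC1 loading is the leading
  eigenvector of the same matrix, with its sign fixed so the
  largest-magnitude loading is positive (removing the eigenvector sign
  ambiguity). PageRank uses damping 0.85 with weighted transitions.
  `igraph::power_centrality()` ignores edge weights, so the weighted Bonacich
  centrality is computed directly by sparse solve, using igraph's
  sum-of-squares-equals-n rescaling (the two agree on unit-weight graphs).
* **Disconnected graphs**: closeness is computed within components;
  eigenvector and hub scores are computed on the largest component and set
  to 0 elsewhere. Single-node networks return zero centralities with a
  warning.
* **kNN imputation**: k = 5 by default; distances are Euclidean in
  standardized expression space, ties broken by gene identifier so the
  result is order-independent.
* **Classifier details**: features are standardized with training-fold
  statistics for the linear and kernel families; tree families consume raw
  features (their splits are invariant to monotone transforms, a property the
  tests assert). SVM decision values are mapped through `plogis()` so every
  reported score lives in [0, 1]; the map is monotone, leaving ranks and AUC
  untouched. Boosted-tree round counts come from early stopping (patience
  20, cap 500) against the inner validation folds. Grids: logistic λ ∈
  {0.01, 0.1, 1, 10}; SVM γ ∈ 1/p × {0.5, 1, 2}, cost ∈ {0.1, 1, 10};
  random forest 500 trees, mtry ∈ {√p, 0.3p}; boosted trees depth ∈
  {3, 4, 6}, learning rate ∈ {0.05, 0.1}. No class reweighting is applied;
  AUC-PRC is reported to expose the imbalance.
* **AUC-PRC** uses step-wise integration (precision at each distinct-score
  recall step, no interpolation); tied scores collapse into a single step.
* **F1 threshold**: the scan visits midpoints of adjacent distinct score
  values; ties resolve to the lowest threshold, and F1 is defined as 0 when
  no positive is predicted.
* **Fisher test**: two-sided by the minimum-likelihood rule with the
  conditional-MLE odds ratio and exact conditional CI (`stats::fisher.test`).
  The reported top-table arithmetic (p × m = p_adj) pins down the Bonferroni
  denominator but not the sidedness, so sidedness is a documented choice.
  Zero-margin tables are flagged degenerate with p = 1.
* **Ward variant**: `ward.D` (distances not squared), matching the classic
  behavior of `hclust`'s historical "ward" method; `ward.D2` is available via
  a flag. Terms with constant overlap profiles get correlation 0, flagged.
* **Wilcoxon comparisons** are exact for untied groups of ≤ 50, otherwise
  normal-approximated with tie correction; degenerate all-identical inputs
  return p = 1 with a flag.

## Design decisions where the design was open

* "Gene size" matching in the permutation enrichment is read as set
  *cardinality*; the sampling universe defaults to every gene with DGE
  statistics and is configurable.
* The headline DGE statistic counts p < 0.05 regardless of effect sign;
  down-regulation is exposed as `direction = "down"` for secondary analyses.
* Gene identifiers are symbols, matched case-insensitively after trimming;
  duplicate rows keep the copy with fewer missing values. Genes missing
  constraint data are dropped rather than imputed, mirroring the
  availability filter that defines the training set.
* Hyperparameters are tuned per outer fold (true nested CV) rather than once.

## Problem sizes used by the checks

The test-suite and acceptance checks run at sizes chosen for statistical
resolution of each contract: the supervised-recovery and end-to-end checks
use the default 2,000-gene configuration; the planted DGE-fold recovery uses
2,000 risk genes in a 40,000-gene universe (keeping the Monte-Carlo sd of the
fold estimate near 0.1, where a ±0.3 recovery band is meaningful — at a
300-gene set the binomial noise alone has sd ≈ 0.3); the phenotype
specificity contract uses 1,000-gene risk sets in 10,000-gene universes,
where the permutation test's power exceeds 99% (at a 300-gene set it is only
~86%, so a 90%-of-seeds detection contract would measure noise, not
correctness); null calibrations use 200 random test sets at 2,000
permutations and 20 label permutations for the cross-validated AUC.

## Limitations

Synthetic recovery is a necessary but weak proxy for real performance: the
planted effects are additive, independent, and Gaussian-ish, which flatters
linear models (on the default benchmark logistic regression edges out the
tree families; with real, interaction-rich data tree ensembles are the
expected winners). The permutation enrichment treats genes as exchangeable
within the universe — a gene-length-matched null is not implemented beyond
cardinality matching. GO clustering operates on overlap profiles of the
significant terms only and inherits their selection. The binomial decile
test assumes list members are independent draws, which real cohorts violate
when genes recur across studies.
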