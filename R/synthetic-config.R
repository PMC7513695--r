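#' Configuration for the synthetic benchmark generator
#'
#' Bundles every tunable of [generate_dataset()] with validated defaults. The
#' defaults define a desk-scale benchmark: 2,000 genes with 150 labeled
#' positives and 850 labeled negatives (~15% positives among labeled genes,
#' close to the 121/963 imbalance of the real training set this emulates),
#' observed over 8 brain regions x 10 developmental stages x 1 donor. The
#' first 40% of stages are flagged prenatal, emulating the early-to-mid
#' prenatal window where risk-gene expression differences concentrate.
#'
#' @param n_genes total number of genes.
#' @param n_positive,n_negative labeled true-positive / true-negative counts.
#' @param n_hidden_risk truly-risk genes left unlabeled; these carry the same
#'   planted expression/constraint/DGE signal as positives and are what the
#'   genome-wide prediction step should surface.
#' @param n_regions,n_stages,n_donors_per_context sampling design of the
#'   expression atlas; one sample per (region, stage, donor).
#' @param expr_effect_prenatal standardized mean shift (log2 units) of risk
#'   gene expression in prenatal-flagged stages.
#' @param expr_effect_postnatal same for the remaining stages.
#' @param constraint_shift scalar multiplier on the per-metric standardized
#'   constraint shifts for risk genes (signs fixed internally: higher mis_z,
#'   lof_z, pLI; lower pRec, pNull, n_lof; longer genes with higher mutation
#'   probabilities and more rare synonymous/missense variants).
#' @param ppi_attachment preferential-attachment parameter (edges added per
#'   node) of the scale-free PPI graph.
#' @param ppi_coverage fraction of genes present in the PPI layer; genes
#'   outside it exercise the kNN network-feature imputation path.
#' @param dge_rate_bg probability a background gene is differentially
#'   expressed (p < 0.05) in any phenotype; 0.05 corresponds to uniform
#'   null p-values.
#' @param dge_enrichment_rate probability a risk gene has DGE p < 0.05 in the
#'   ASD-analog phenotype (planted enrichment fold =
#'   `dge_enrichment_rate / dge_rate_bg`).
#' @param dge_down_fraction probability a significant risk-gene effect is
#'   down-expression (beta < 0).
#' @param proband_top_rate probability a proband validation-list gene is drawn
#'   from the hidden-risk pool rather than uniformly from unlabeled genes.
#' @param n_proband,n_sibling validation list sizes.
#' @param go_n_terms number of GO-like gene sets emitted.
#' @param go_planted_terms how many of them carry a planted association with
#'   risk status.
#' @param go_planted_or target odds ratio of the planted terms (hit within
#'   +/-10% by construction).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   full configuration including the seed.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_positive = 150L,
                             n_negative = 850L,
                             n_hidden_risk = 150L,
                             n_regions = 8L,
                             n_stages = 10L,
                             n_donors_per_context = 1L,
                             expr_effect_prenatal = 1.0,
                             expr_effect_postnatal = 0.3,
                             constraint_shift = 0.8,
                             ppi_attachment = 3L,
                             ppi_coverage = 0.85,
                             dge_rate_bg = 0.05,
                             dge_enrichment_rate = 0.10,
                             dge_down_fraction = 0.8,
                             proband_top_rate = 0.5,
                             n_proband = 120L,
                             n_sibling = 80L,
                             go_n_terms = 50L,
                             go_planted_terms = 10L,
                             go_planted_or = 10,
                             seed = 1L) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    n_positive = assert_count(n_positive, "n_positive"),
    n_negative = assert_count(n_negative, "n_negative"),
    n_hidden_risk = assert_count(n_hidden_risk, "n_hidden_risk", min = 0L),
    n_regions = assert_count(n_regions, "n_regions"),
    n_stages = assert_count(n_stages, "n_stages"),
    n_donors_per_context = assert_count(n_donors_per_context, "n_donors_per_context"),
    expr_effect_prenatal = assert_number(expr_effect_prenatal, "expr_effect_prenatal"),
    expr_effect_postnatal = assert_number(expr_effect_postnatal, "expr_effect_postnatal"),
    constraint_shift = assert_number(constraint_shift, "constraint_shift"),
    ppi_attachment = assert_count(ppi_attachment, "ppi_attachment"),
    ppi_coverage = assert_prob(ppi_coverage, "ppi_coverage"),
    dge_rate_bg = assert_prob(dge_rate_bg, "dge_rate_bg"),
    dge_enrichment_rate = assert_prob(dge_enrichment_rate, "dge_enrichment_rate"),
    dge_down_fraction = assert_prob(dge_down_fraction, "dge_down_fraction"),
    proband_top_rate = assert_prob(proband_top_rate, "proband_top_rate"),
    n_proband = assert_count(n_proband, "n_proband"),
    n_sibling = assert_count(n_sibling, "n_sibling"),
    go_n_terms = assert_count(go_n_terms, "go_n_terms", min = 0L),
    go_planted_terms = assert_count(go_planted_terms, "go_planted_terms", min = 0L),
    go_planted_or = assert_number(go_planted_or, "go_planted_or"),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$n_positive + cfg$n_negative > cfg$n_genes) {
    abort("`n_positive` + `n_negative` must not exceed `n_genes`.")
  }
  if (cfg$n_positive + cfg$n_negative + cfg$n_hidden_risk > cfg$n_genes) {
    abort("`n_hidden_risk` leaves no unlabeled non-risk genes; reduce it.")
  }
  if (cfg$go_planted_terms > cfg$go_n_terms) {
    abort("`go_planted_terms` must not exceed `go_n_terms`.")
  }
  if (cfg$go_planted_or <= 0) abort("`go_planted_or` must be positive.")
  structure(cfg, class = "synthetic_config")
}

#' @export
#' @method print synthetic_config
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    paste0("<synthetic_config> %d genes (%d pos / %d neg labeled, %d hidden risk), ",
           "%d regions x %d stages x %d donors, seed %d\n"),
    x$n_genes, x$n_positive, x$n_negative, x$n_hidden_risk,
    x$n_regions, x$n_stages, x$n_donors_per_context, x$seed
  ))
  invisible(x)
}
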