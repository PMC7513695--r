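#' Generate a synthetic benchmark dataset
#'
#' Emulates, at desk scale, every input of the risk-gene ranking pipeline:
#' a spatiotemporal RPKM expression atlas in which risk genes are
#' over-expressed (more strongly in prenatal stages), a gene-level
#' constraint/variation table with group shifts in the canonical directions
#' (risk genes more missense/LoF-constrained, higher pLI, lower pNull), a
#' scale-free PPI edge list, labeled positive/negative gene sets, per-gene
#' differential-expression summary statistics with planted down-expression
#' signal in the ASD-analog phenotype only, proband/sibling validation lists,
#' and GO-like gene sets with planted odds ratios. A `truth` record carries
#' the planted parameters for recovery tests.
#'
#' The dataset is a deterministic function of the configuration (including
#' its seed) and leaves the caller's RNG state untouched.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `expression`
#'   ([expr_matrix()], RPKM scale), `constraint` (tibble), `ppi_edges`
#'   (tibble `gene_a`, `gene_b`), `labels` (tibble `gene`, `label`),
#'   `dge_tables` (named list of tibbles `gene`, `beta`, `p`),
#'   `validation_lists` (named list of gene vectors), `go_sets` (named list
#'   of gene vectors), and `truth`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_genes = 200, n_positive = 20,
#'                                         n_negative = 100, n_hidden_risk = 20,
#'                                         seed = 7))
#' ds$expression
#' table(ds$labels$label)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))

    # --- planted risk status and labels -------------------------------------
    n_risk <- config$n_positive + config$n_hidden_risk
    risk_genes <- sort(sample(genes, n_risk))
    positives <- sort(sample(risk_genes, config$n_positive))
    hidden_risk <- setdiff(risk_genes, positives)
    nonrisk <- setdiff(genes, risk_genes)
    negatives <- sort(sample(nonrisk, config$n_negative))
    label <- rep("unlabeled", config$n_genes)
    names(label) <- genes
    label[positives] <- "positive"
    label[negatives] <- "negative"
    labels <- tibble(gene = genes, label = unname(label))
    is_risk <- genes %in% risk_genes

    # --- spatiotemporal expression ------------------------------------------
    expression <- simulate_expression(genes, is_risk, config)

    # --- constraint / variation features ------------------------------------
    constraint <- simulate_constraint(genes, is_risk, config$constraint_shift)

    # --- scale-free PPI layer -----------------------------------------------
    ppi_edges <- simulate_ppi(genes, is_risk, config)

    # --- DGE summary statistics ---------------------------------------------
    risk_tbl <- tibble(gene = genes, is_risk = is_risk)
    phenotypes <- c("asd", "ibd", "bipolar", "schizophrenia")
    dge_tables <- lapply(phenotypes, function(ph) {
      rate_risk <- if (ph == "asd") config$dge_enrichment_rate else config$dge_rate_bg
      generate_dge_table(risk_tbl,
                         rate_bg = config$dge_rate_bg,
                         rate_risk = rate_risk,
                         down_fraction = config$dge_down_fraction,
                         seed = NULL)
    })
    names(dge_tables) <- phenotypes

    # --- validation lists (training positives excluded) ---------------------
    unlabeled_nonrisk <- setdiff(nonrisk, negatives)
    n_top <- rbinom(1, config$n_proband, config$proband_top_rate)
    n_top <- min(n_top, length(hidden_risk))
    proband <- c(sample(hidden_risk, n_top),
                 sample(unlabeled_nonrisk, config$n_proband - n_top))
    sibling <- sample(setdiff(genes, positives), config$n_sibling)
    validation_lists <- list(proband = sort(proband), sibling = sort(sibling))

    # --- GO-like gene sets ---------------------------------------------------
    go <- simulate_go_sets(genes, risk_genes, config)

    truth <- list(
      risk_genes = risk_genes,
      hidden_risk_genes = hidden_risk,
      planted_go_terms = go$planted,
      phenotype_signal = c(asd = TRUE, ibd = FALSE, bipolar = FALSE,
                           schizophrenia = FALSE),
      planted_dge_fold = config$dge_enrichment_rate / config$dge_rate_bg,
      config = config
    )

    structure(
      list(expression = expression, constraint = constraint,
           ppi_edges = ppi_edges, labels = labels, dge_tables = dge_tables,
           validation_lists = validation_lists, go_sets = go$sets,
           truth = truth),
      class = "synthetic_dataset"
    )
  })
}

# Log-normal expression baseline per gene; context effects additive on the
# log2 scale, then back-transformed to RPKM (floored at zero, which only
# touches the far-left tail).
simulate_expression <- function(genes, is_risk, config) {
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  stages <- sprintf("S%02d", seq_len(config$n_stages))
  n_prenatal <- ceiling(0.4 * config$n_stages)
  prenatal_stages <- stages[seq_len(n_prenatal)]
  donors <- sprintf("D%02d", seq_len(config$n_donors_per_context))
  meta <- expand.grid(donor = donors, stage = stages, region = regions,
                      stringsAsFactors = FALSE)
  meta <- tibble(
    sample_id = sprintf("%s_%s_%s", meta$region, meta$stage, meta$donor),
    region = meta$region, stage = meta$stage, donor = meta$donor,
    prenatal = meta$stage %in% prenatal_stages
  )
  n_g <- length(genes)
  n_s <- nrow(meta)
  base <- rnorm(n_g, mean = 3.5, sd = 1.5)
  effect <- outer(
    as.numeric(is_risk),
    ifelse(meta$prenatal, config$expr_effect_prenatal, config$expr_effect_postnatal)
  )
  log2_vals <- base + effect + matrix(rnorm(n_g * n_s, sd = 0.8), n_g, n_s)
  rpkm <- pmax(2^log2_vals - 1, 0)
  dimnames(rpkm) <- list(genes, meta$sample_id)
  expr_matrix(rpkm, meta, scale = "rpkm")
}

# Constraint metrics: the (pLI, pRec, pNull) triple comes from a softmax of
# latent normals so the probabilities always lie in [0,1] and sum to 1;
# remaining features are (log-)normal or Poisson with standardized shifts of
# fixed sign scaled by `shift`.
simulate_constraint <- function(genes, is_risk, shift) {
  n <- length(genes)
  s <- shift * as.numeric(is_risk)
  l_pli <- rnorm(n, -1, 2) + 2.5 * s
  l_prec <- rnorm(n, 0.5, 1) - 0.5 * s
  l_pnull <- rnorm(n, 1, 2) - 2.5 * s
  denom <- exp(l_pli) + exp(l_prec) + exp(l_pnull)
  mu_syn <- exp(rnorm(n, -12.2 + 0.4 * s, 0.5))
  mu_mis <- exp(rnorm(n, -11.8 + 0.4 * s, 0.5))
  mu_lof <- exp(rnorm(n, -13.5 + 0.4 * s, 0.5))
  # expected rare-variant counts on a realistic scale (tens of variants)
  exp_syn <- mu_syn * 3e6 * exp(rnorm(n, 0, 0.2))
  exp_mis <- mu_mis * 3e6 * exp(rnorm(n, 0, 0.2))
  exp_lof <- mu_lof * 3e6 * exp(rnorm(n, 0, 0.2))
  tibble(
    gene = genes,
    syn_z = rnorm(n, 0, 1),
    mis_z = rnorm(n, 0, 1) + 1.0 * s,
    lof_z = rnorm(n, 0, 1) + 1.2 * s,
    pLI = exp(l_pli) / denom,
    pRec = exp(l_prec) / denom,
    pNull = exp(l_pnull) / denom,
    bp = pmax(150L, as.integer(round(exp(rnorm(n, 7.3 + 0.45 * s, 0.6))))),
    mu_syn = mu_syn, mu_mis = mu_mis, mu_lof = mu_lof,
    n_syn = rpois(n, exp_syn),
    n_mis = rpois(n, exp_mis),
    n_lof = rpois(n, exp_lof * exp(-1.2 * s)),
    exp_syn = exp_syn, exp_mis = exp_mis, exp_lof = exp_lof
  )
}

# Preferential-attachment PPI graph over a `ppi_coverage` subset of genes;
# risk genes get a mild bias toward early attachment slots (hubs).
simulate_ppi <- function(genes, is_risk, config) {
  n_nodes <- max(config$ppi_attachment + 1L,
                 round(config$ppi_coverage * length(genes)))
  priority <- runif(length(genes)) - 0.15 * as.numeric(is_risk)
  node_genes <- genes[order(priority)][seq_len(n_nodes)]
  g <- igraph::sample_pa(n_nodes, power = 1, m = config$ppi_attachment,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  tibble(gene_a = node_genes[el[, 1]], gene_b = node_genes[el[, 2]]) |>
    filter(.data$gene_a != .data$gene_b) |>
    dplyr::distinct()
}

simulate_go_sets <- function(genes, risk_genes, config) {
  if (config$go_n_terms == 0L) return(list(sets = list(), planted = character()))
  nonrisk <- setdiff(genes, risk_genes)
  k_risk <- length(risk_genes)
  k_non <- length(nonrisk)
  sets <- vector("list", config$go_n_terms)
  names(sets) <- sprintf("GO_SET_%04d", seq_len(config$go_n_terms))
  planted <- names(sets)[seq_len(config$go_planted_terms)]
  for (i in seq_len(config$go_n_terms)) {
    size <- sample(30:80, 1)
    if (i <= config$go_planted_terms) {
      a <- planted_overlap(size, k_risk, k_non, config$go_planted_or)
      sets[[i]] <- sort(c(sample(risk_genes, a), sample(nonrisk, size - a)))
    } else {
      sets[[i]] <- sort(sample(genes, size))
    }
  }
  list(sets = sets, planted = planted)
}

# Number of risk-gene members that realizes a population odds ratio closest
# to the target (and within +/-10% whenever the size grid allows it).
planted_overlap <- function(size, k_risk, k_non, target_or) {
  a <- seq(max(1L, size - k_non + 1L), min(size - 1L, k_risk - 1L))
  or <- (a / (k_risk - a)) / ((size - a) / (k_non - (size - a)))
  a[which.min(abs(log(or) - log(target_or)))]
}

#' Generate a per-gene differential-expression summary table
#'
#' Plants Bernoulli significance: each non-risk gene is significant
#' (p < 0.05) with probability `rate_bg`, each risk gene with probability
#' `rate_risk`; the planted enrichment fold of the risk set is therefore
#' `rate_risk / rate_bg`. Significant risk-gene effects are down-expression
#' (beta < 0) with probability `down_fraction`.
#'
#' @param gene_labels data frame with columns `gene` and logical `is_risk`.
#' @param rate_bg,rate_risk,down_fraction probabilities in `[0, 1]`.
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @return A tibble with columns `gene`, `beta`, `p`.
#' @export
generate_dge_table <- function(gene_labels, rate_bg, rate_risk, down_fraction,
                               seed = NULL) {
  if (is.null(gene_labels) || nrow(gene_labels) == 0) {
    abort("`gene_labels` must contain at least one gene.")
  }
  if (!all(c("gene", "is_risk") %in% names(gene_labels))) {
    abort("`gene_labels` needs columns `gene` and `is_risk`.")
  }
  assert_prob(rate_bg, "rate_bg")
  assert_prob(rate_risk, "rate_risk")
  assert_prob(down_fraction, "down_fraction")
  with_seed(seed, {
    n <- nrow(gene_labels)
    rate <- ifelse(gene_labels$is_risk, rate_risk, rate_bg)
    sig <- runif(n) < rate
    p <- ifelse(sig, runif(n, 0, 0.05), runif(n, 0.05, 1))
    magnitude <- abs(rnorm(n, mean = ifelse(sig, 0.5, 0.1), sd = 0.15))
    down <- ifelse(sig & gene_labels$is_risk,
                   runif(n) < down_fraction,
                   runif(n) < 0.5)
    tibble(gene = gene_labels$gene,
           beta = ifelse(down, -magnitude, magnitude),
           p = p)
  })
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Emits the TSV matrices, TSV tables, GMT gene sets, one-gene-per-line
#' validation lists, and a JSON truth record that the ingestion functions
#' read back.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    sample_meta = file.path(dir, "sample_meta.tsv"),
    constraint = file.path(dir, "constraint.tsv"),
    ppi_edges = file.path(dir, "ppi_edges.tsv"),
    labels = file.path(dir, "labels.tsv"),
    go_sets = file.path(dir, "go_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_expression(dataset$expression, paths["expression"], paths["sample_meta"])
  readr::write_tsv(dataset$constraint, paths["constraint"], progress = FALSE)
  readr::write_tsv(dataset$ppi_edges, paths["ppi_edges"], progress = FALSE)
  readr::write_tsv(dataset$labels, paths["labels"], progress = FALSE)
  write_gmt(dataset$go_sets, paths["go_sets"])
  for (ph in names(dataset$dge_tables)) {
    p <- file.path(dir, sprintf("dge_%s.tsv", ph))
    readr::write_tsv(dataset$dge_tables[[ph]], p, progress = FALSE)
    paths[paste0("dge_", ph)] <- p
  }
  for (nm in names(dataset$validation_lists)) {
    p <- file.path(dir, sprintf("list_%s.txt", nm))
    writeLines(dataset$validation_lists[[nm]], p)
    paths[paste0("list_", nm)] <- p
  }
  truth <- dataset$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
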