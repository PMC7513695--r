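#' Size-matched permutation enrichment of DGE evidence
#'
#' Tests whether a gene set carries more differential-gene-expression
#' evidence (p < `sig_level`, optionally restricted by effect direction) than
#' random gene sets of the same size. The null distribution is built from
#' `n_perm` sets drawn uniformly without replacement from the universe;
#' the enrichment fold is the observed count over the null mean, and the
#' empirical p-value uses the add-one estimator
#' `(#\{null >= observed\} + 1) / (n_perm + 1)`, so it is never exactly 0 --
#' with 100,000 permutations a zero-exceedance result reports p < 1e-5.
#'
#' @param test_set character vector of genes (must be inside `universe`).
#' @param dge_table data frame with columns `gene`, `beta`, `p`.
#' @param universe genes eligible for the random sets; defaults to every gene
#'   in `dge_table`. "Size-matched" means matched for the number of genes.
#' @param n_perm number of random sets (the headline analysis uses 100,000).
#' @param seed integer seed.
#' @param direction `"any"` counts p < `sig_level` regardless of sign (the
#'   headline statistic); `"down"`/`"up"` additionally require beta < 0 /
#'   beta > 0.
#' @param sig_level DGE significance cutoff (default 0.05).
#' @param phenotype optional label stored in the result.
#' @return An object of class `dge_enrichment`: observed count, null
#'   mean/sd, fold, empirical p, and the null counts (for plotting).
#' @export
dge_enrichment <- function(test_set, dge_table, universe = NULL,
                           n_perm = 100000L, seed = 1L,
                           direction = c("any", "down", "up"),
                           sig_level = 0.05, phenotype = NA_character_) {
  direction <- match.arg(direction)
  # canonical universe order makes the statistic invariant to input order
  universe <- sort(unique(universe %||% dge_table$gene))
  missing_stats <- setdiff(universe, dge_table$gene)
  if (length(missing_stats)) {
    abort(sprintf("Universe gene(s) lack DGE statistics: %s",
                  paste(head(missing_stats, 5), collapse = ", ")))
  }
  test_set <- unique(test_set)
  if (!all(test_set %in% universe)) {
    abort("`test_set` must be a subset of `universe`.")
  }
  m <- length(test_set)
  if (m == 0) abort("`test_set` is empty.")
  if (m > length(universe)) abort("`test_set` larger than `universe`.")

  idx <- match(universe, dge_table$gene)
  sig <- dge_table$p[idx] < sig_level
  if (direction == "down") sig <- sig & dge_table$beta[idx] < 0
  if (direction == "up") sig <- sig & dge_table$beta[idx] > 0

  observed <- sum(sig[match(test_set, universe)])
  n_univ <- length(universe)
  null_counts <- with_seed(seed, vapply(
    seq_len(n_perm),
    function(i) sum(sig[sample.int(n_univ, m)]),
    integer(1)
  ))
  null_mean <- mean(null_counts)
  fold <- if (null_mean == 0) NA_real_ else observed / null_mean
  if (null_mean == 0) {
    warn("Null mean is 0; enrichment fold undefined.")
  }
  structure(
    list(observed_count = observed, null_mean = null_mean,
         null_sd = sd(null_counts), fold = fold,
         empirical_p = (sum(null_counts >= observed) + 1) / (n_perm + 1),
         n_perm = n_perm, test_set_size = m, universe_size = n_univ,
         direction = direction, sig_level = sig_level, phenotype = phenotype,
         null_counts = null_counts, seed = seed),
    class = "dge_enrichment"
  )
}

#' @export
#' @method print dge_enrichment
print.dge_enrichment <- function(x, ...) {
  cat(sprintf(
    "<dge_enrichment>%s %d/%d genes with DGE evidence (null %.2f +/- %.2f): fold %.2f, p %s (%d perms, direction %s)\n",
    if (is.na(x$phenotype)) "" else paste0(" [", x$phenotype, "]"),
    x$observed_count, x$test_set_size, x$null_mean, x$null_sd, x$fold,
    format(x$empirical_p, digits = 3), x$n_perm, x$direction
  ))
  invisible(x)
}

#' Binomial first-decile enrichment of a validation gene list
#'
#' Tests whether more genes of an independent candidate list fall in the
#' first decile of the ranking than expected, with a one-sided exact binomial
#' test P(X >= k | n, p0). The default expected proportion p0 = 0.166 is the
#' first-decile rate observed for genes with synonymous de novo mutations in
#' unaffected siblings, i.e. a mutation-opportunity-calibrated null.
#'
#' @param scores a `risk_model` scores table (or any data frame with `gene`
#'   and `decile` columns).
#' @param gene_list candidate genes; members absent from the score table are
#'   dropped and counted in `n_dropped`.
#' @param p0 expected first-decile proportion under the null.
#' @param list_name optional label stored in the result.
#' @return One-row tibble of class `decile_enrichment`: `n`, `k`,
#'   `proportion`, `p0`, `p_value`, `n_dropped`, `list_name`.
#' @export
decile_enrichment <- function(scores, gene_list, p0 = 0.166,
                              list_name = NA_character_) {
  if (inherits(scores, "risk_model")) scores <- scores$scores
  assert_prob(p0, "p0")
  gene_list <- unique(gene_list)
  present <- intersect(gene_list, scores$gene)
  n_dropped <- length(gene_list) - length(present)
  if (length(present) == 0) abort("No gene of `gene_list` is scored.")
  dec <- scores$decile[match(present, scores$gene)]
  k <- sum(dec == 1L)
  n <- length(present)
  p <- binom.test(k, n, p = p0, alternative = "greater")$p.value
  structure(
    tibble(list_name = list_name, n = n, k = k, proportion = k / n,
           p0 = p0, p_value = p, n_dropped = n_dropped),
    class = c("decile_enrichment", "tbl_df", "tbl", "data.frame")
  )
}

#' Compare candidate-gene placement across ranking systems
#'
#' For each scoring system, extracts the ranks of the candidate genes and
#' summarises the median rank (smaller = better) and the proportion of
#' candidates in the system's first decile.
#'
#' @param score_tables named list of score tables (each a `risk_model` or a
#'   data frame with `gene`, `rank` and optionally `decile`; `score` is used
#'   to derive ranks when `rank` is missing).
#' @param candidate_genes character vector of candidate genes.
#' @return Tibble of class `ranking_comparison`: one row per system with
#'   `median_rank`, `first_decile_proportion`, `n_scored`, `n_total`.
#'   Systems scoring no candidate are dropped with a warning.
#' @export
compare_rankings <- function(score_tables, candidate_genes) {
  if (length(score_tables) == 0) abort("Need at least one scoring system.")
  if (is.null(names(score_tables))) {
    names(score_tables) <- paste0("system_", seq_along(score_tables))
  }
  candidate_genes <- unique(candidate_genes)
  rows <- imap(score_tables, function(tab, nm) {
    if (inherits(tab, "risk_model")) tab <- tab$scores
    if (!"rank" %in% names(tab)) {
      tab$rank <- score_ranks(tab$score, tab$gene)
    }
    if (!"decile" %in% names(tab)) {
      tab$decile <- rank_decile(tab$rank, nrow(tab))
    }
    hit <- match(intersect(candidate_genes, tab$gene), tab$gene)
    if (length(hit) == 0) {
      warn(sprintf("System '%s' scores no candidate gene; dropped.", nm))
      return(NULL)
    }
    tibble(system = nm,
           median_rank = median(tab$rank[hit]),
           first_decile_proportion = mean(tab$decile[hit] == 1L),
           n_scored = length(hit),
           n_total = length(candidate_genes))
  })
  out <- bind_rows(compact(rows))
  if (nrow(out) == 0) abort("No system scored any candidate gene.")
  structure(out, class = c("ranking_comparison", class(tibble())))
}
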