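#' Filter gene sets by overlap with the tested universe
#'
#' Keeps terms overlapping at least `min_overlap` and at most `max_overlap`
#' genes of the tested universe (both bounds inclusive); the number of
#' surviving terms is the Bonferroni denominator of the enrichment scan.
#'
#' @param go_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param tested_genes the prediction universe (risk plus non-risk genes).
#' @param min_overlap,max_overlap inclusive overlap bounds (defaults 20 and
#'   2,000).
#' @return List with `sets` (the surviving terms, unrestricted) and `m`
#'   (their count).
#' @export
filter_go_terms <- function(go_sets, tested_genes, min_overlap = 20L,
                            max_overlap = 2000L) {
  if (length(tested_genes) == 0) abort("`tested_genes` is empty.")
  ov <- map_int(go_sets, ~ length(intersect(.x, tested_genes)))
  keep <- ov >= min_overlap & ov <= max_overlap
  if (!any(keep)) {
    warn("No gene set survives the overlap filter; downstream tests skipped.")
  }
  list(sets = go_sets[keep], m = sum(keep))
}

#' Fisher's exact enrichment of one gene set
#'
#' Two-sided Fisher's exact test on the 2x2 table of (risk vs non-risk) x
#' (in-term vs not-in-term), with the conditional maximum-likelihood odds
#' ratio and exact conditional 95% CI, and Bonferroni adjustment over `m`
#' tested terms.
#'
#' @param risk_genes,nonrisk_genes disjoint, non-empty gene vectors forming
#'   the tested universe.
#' @param term_genes the gene set.
#' @param m Bonferroni denominator (number of terms tested).
#' @param term optional term name.
#' @return One-row tibble: counts `a` (risk in term), `b`, `c`, `d`, odds
#'   ratio with CI, `p_value`, `p_adj`, and a `degenerate` flag for
#'   zero-margin tables (p fixed at 1).
#' @export
fisher_term_test <- function(risk_genes, nonrisk_genes, term_genes, m = 1L,
                             term = NA_character_) {
  if (length(risk_genes) == 0 || length(nonrisk_genes) == 0) {
    abort("Both risk and non-risk gene sets must be non-empty.")
  }
  if (length(intersect(risk_genes, nonrisk_genes))) {
    abort("`risk_genes` and `nonrisk_genes` must be disjoint.")
  }
  a <- length(intersect(risk_genes, term_genes))
  b <- length(risk_genes) - a
  c_ <- length(intersect(nonrisk_genes, term_genes))
  d <- length(nonrisk_genes) - c_
  if (a + c_ == 0 || b + d == 0) {
    return(tibble(term = term, a = a, b = b, c = c_, d = d,
                  odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  p_value = 1, p_adj = 1, degenerate = TRUE))
  }
  ht <- fisher.test(matrix(c(a, c_, b, d), nrow = 2), conf.int = TRUE,
                    conf.level = 0.95)
  tibble(term = term, a = a, b = b, c = c_, d = d,
         odds_ratio = unname(ht$estimate),
         ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
         p_value = ht$p.value,
         p_adj = min(1, ht$p.value * m),
         degenerate = FALSE)
}

#' GO-term enrichment of predicted risk genes
#'
#' Applies the overlap filter, then tests each surviving term for enrichment
#' of risk versus non-risk genes with Fisher's exact test, Bonferroni-
#' corrected over the number of tested terms. The background universe is the
#' prediction universe (risk plus non-risk genes), not all annotated genes.
#'
#' @inheritParams fisher_term_test
#' @param go_sets named list of gene vectors.
#' @param min_overlap,max_overlap inclusive overlap bounds for
#'   [filter_go_terms()].
#' @return Tibble of class `go_enrichment_result`, one row per tested term,
#'   ordered by p-value; `m` recorded as an attribute.
#' @export
go_enrichment <- function(risk_genes, nonrisk_genes, go_sets,
                          min_overlap = 20L, max_overlap = 2000L) {
  tested <- union(risk_genes, nonrisk_genes)
  filt <- filter_go_terms(go_sets, tested, min_overlap, max_overlap)
  rows <- imap(filt$sets, function(set, nm) {
    fisher_term_test(risk_genes, nonrisk_genes, set, m = filt$m, term = nm)
  })
  out <- bind_rows(rows) |> arrange(.data$p_value)
  structure(out,
            class = c("go_enrichment_result", class(tibble())),
            m = filt$m)
}

#' Cluster significant GO terms by overlap profile
#'
#' Terms are represented by their row of the pairwise gene-overlap-count
#' matrix (diagonal = set size); the distance between two terms is 1 - R,
#' with R the Pearson correlation of their overlap profiles; agglomerative
#' Ward clustering (classic `"ward.D"`, unsquared distances) is cut into `k`
#' clusters.
#'
#' @param terms character vector of (significant) term names; needs >= 2.
#' @param go_sets named list of gene vectors covering `terms`.
#' @param k number of clusters to cut (default 5).
#' @param ward_variant `"ward.D"` (default) or `"ward.D2"`.
#' @return Object of class `go_term_clustering`: `terms`, `overlap` matrix,
#'   `distance` matrix, the `hclust` tree, and `clusters` labels.
#' @export
cluster_go_terms <- function(terms, go_sets, k = 5L,
                             ward_variant = c("ward.D", "ward.D2")) {
  ward_variant <- match.arg(ward_variant)
  if (length(terms) < 2) abort("Clustering needs at least two terms.")
  absent <- setdiff(terms, names(go_sets))
  if (length(absent)) {
    abort(sprintf("Term(s) missing from `go_sets`: %s",
                  paste(head(absent, 5), collapse = ", ")))
  }
  sets <- go_sets[terms]
  n <- length(sets)
  overlap <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      overlap[i, j] <- overlap[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  constant <- apply(overlap, 1, function(r) var(r) == 0)
  if (any(constant)) {
    warn(sprintf("%d term(s) have constant overlap profiles; their correlations are set to 0.",
                 sum(constant)))
  }
  r_mat <- suppressWarnings(cor(t(overlap)))
  r_mat[!is.finite(r_mat)] <- 0
  dist_mat <- 1 - r_mat
  diag(dist_mat) <- 0
  tree <- hclust(as.dist(dist_mat), method = ward_variant)
  clusters <- cutree(tree, k = min(k, n))
  structure(
    list(terms = terms, overlap = overlap, distance = dist_mat,
         hclust = tree, clusters = clusters, k = min(k, n)),
    class = "go_term_clustering"
  )
}

#' @export
#' @method print go_term_clustering
print.go_term_clustering <- function(x, ...) {
  cat(sprintf("<go_term_clustering> %d terms in %d clusters (%s linkage)\n",
              length(x$terms), x$k, x$hclust$method))
  print(table(x$clusters))
  invisible(x)
}
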