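constraint_columns <- c(
  "syn_z", "mis_z", "lof_z", "pLI", "pRec", "pNull", "bp",
  "mu_syn", "mu_mis", "mu_lof", "n_syn", "n_mis", "n_lof",
  "exp_syn", "exp_mis", "exp_lof"
)

network_feature_names <- c(
  "degree", "closeness", "betweenness", "bonacich_power", "eigenvector",
  "alpha_centrality", "pc1_loading", "hub_score", "coreness", "pagerank"
)

# Gene symbols are matched case-insensitively after whitespace trimming;
# duplicate rows keep the one with fewest missing values.
normalize_genes <- function(tab, what) {
  tab$gene <- toupper(trimws(as.character(tab$gene)))
  if (anyDuplicated(tab$gene)) {
    tab <- tab |>
      mutate(.n_missing = rowSums(is.na(dplyr::pick(dplyr::everything())))) |>
      arrange(.data$gene, .data$.n_missing) |>
      filter(!duplicated(.data$gene)) |>
      select(-".n_missing")
  }
  tab
}

#' Read a gene-level constraint/variation table
#'
#' Expects the 6 constraint metrics (`syn_z`, `mis_z`, `lof_z`, `pLI`,
#' `pRec`, `pNull`) and 10 variation features (`bp`, `mu_*`, `n_*`, `exp_*`)
#' under their canonical column names, one row per gene symbol.
#'
#' @param path TSV path with a `gene` column plus the 16 feature columns.
#' @return A tibble, deduplicated by gene.
#' @export
read_constraint <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  missing_cols <- setdiff(c("gene", constraint_columns), names(tab))
  if (length(missing_cols)) {
    abort(sprintf("'%s': missing constraint column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  bad_prob <- constraint_columns[4:6][vapply(
    constraint_columns[4:6],
    function(cn) any(tab[[cn]] < 0 | tab[[cn]] > 1, na.rm = TRUE), TRUE)]
  if (length(bad_prob)) {
    abort(sprintf("'%s': probabilities outside [0,1] in: %s", path,
                  paste(bad_prob, collapse = ", ")))
  }
  normalize_genes(tab[, c("gene", constraint_columns)], "constraint")
}

#' Read a gene label table
#'
#' @param path TSV with columns `gene` and `label`
#'   (positive / negative / unlabeled).
#' @return A tibble with `label` as a character column.
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "label") %in% names(tab))) {
    abort(sprintf("'%s': expected columns `gene` and `label`.", path))
  }
  bad <- setdiff(unique(tab$label), c("positive", "negative", "unlabeled"))
  if (length(bad)) {
    abort(sprintf("'%s': unknown label value(s): %s", path,
                  paste(bad, collapse = ", ")))
  }
  normalize_genes(tab, "labels")
}

#' Read an undirected PPI edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b` (gene symbols).
#' @return A tibble of edges; self-loops dropped.
#' @export
read_ppi_edges <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab))) {
    abort(sprintf("'%s': expected columns `gene_a` and `gene_b`.", path))
  }
  tab$gene_a <- toupper(trimws(tab$gene_a))
  tab$gene_b <- toupper(trimws(tab$gene_b))
  filter(tab, .data$gene_a != .data$gene_b)
}

#' Read a per-gene DGE summary statistics table
#'
#' @param path TSV with columns `gene`, `beta`, `p`.
#' @return A tibble.
#' @export
read_dge_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (!all(c("gene", "beta", "p") %in% names(tab))) {
    abort(sprintf("'%s': expected columns `gene`, `beta`, `p`.", path))
  }
  normalize_genes(tab, "dge")
}

#' Read a one-gene-per-line validation list
#'
#' @param path text file, one gene symbol per line.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  unique(toupper(trimws(readLines(path, warn = FALSE))))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (tab-separated: term, description, member genes).
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param descriptions optional character vector of term descriptions
#'   (defaults to `"na"`).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list.")
  }
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble the per-gene feature table
#'
#' Inner-joins genes possessing both expression and constraint data (mirroring
#' the availability filter used to define the training set), attaches the 10
#' network-topology features -- imputing them via [impute_network_features()]
#' for genes absent from the network -- and the label column. Each expression
#' sample becomes one feature column (`expr_<sample_id>`).
#'
#' @param expr an [expr_matrix()] on the log2 scale.
#' @param network_feats tibble from [topology_features()]; genes missing from
#'   it (e.g. outside the PPI network) are imputed here.
#' @param constraint tibble from [read_constraint()] or the synthetic
#'   generator.
#' @param labels tibble with columns `gene`, `label`.
#' @param impute_k neighbours used when imputing network features for genes
#'   missing from `network_feats`.
#' @return A tibble of class `gene_feature_table`: `gene`, `label`, one column
#'   per feature, plus a `network_provenance` flag. The ordered feature names
#'   are recorded in `attr(, "feature_names")` and the join bookkeeping in
#'   `attr(, "join_report")`.
#' @export
assemble_features <- function(expr, network_feats, constraint, labels,
                              impute_k = 5L) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "log2") {
    abort("`expr` must be log2-scale (see `log_transform()`).")
  }
  expr_genes <- rownames(expr$values)
  constraint <- as_tibble(constraint)
  keep <- intersect(expr_genes, constraint$gene[complete.cases(constraint)])
  if (length(keep) == 0) {
    abort("No genes have both expression and complete constraint data.")
  }
  report <- list(
    kept = length(keep),
    dropped_no_constraint = setdiff(expr_genes, keep),
    dropped_no_expression = setdiff(constraint$gene, expr_genes)
  )

  missing_net <- setdiff(keep, network_feats$gene)
  if (length(missing_net)) {
    network_feats <- impute_network_features(
      network_feats, all_genes = keep,
      predictor_space = expr, k = impute_k
    )
  }

  expr_tab <- as_tibble(expr$values[keep, , drop = FALSE], rownames = "gene")
  names(expr_tab)[-1] <- paste0("expr_", names(expr_tab)[-1])
  out <- expr_tab |>
    inner_join(network_feats, by = "gene") |>
    inner_join(constraint, by = "gene") |>
    left_join(labels, by = "gene") |>
    mutate(label = factor(
      ifelse(is.na(.data$label), "unlabeled", .data$label),
      levels = c("positive", "negative", "unlabeled")
    )) |>
    rename(network_provenance = "provenance") |>
    relocate("gene", "label")

  feature_names <- c(names(expr_tab)[-1], network_feature_names,
                     constraint_columns)
  labeled <- out$label != "unlabeled"
  if (any(is.na(out[labeled, feature_names]))) {
    abort("Labeled genes still carry missing feature values after imputation.")
  }
  structure(out,
            class = c("gene_feature_table", class(out)),
            feature_names = feature_names,
            join_report = report)
}

#' Compare a feature between labeled gene groups
#'
#' Wilcoxon rank-sum comparison of a feature between the positive and
#' negative labeled genes (or any two label groups), exact for small groups
#' without ties and normal-approximated with tie correction otherwise.
#'
#' @param features a [assemble_features()] table (or any data frame with a
#'   `label` column and the feature).
#' @param feature_name feature column to compare.
#' @param groups the two label groups compared (first vs second).
#' @param exact_cutoff use the exact null distribution when both groups are
#'   at most this large and untied.
#' @param alternative passed to [stats::wilcox.test()].
#' @return One-row tibble: group medians, rank-sum statistic `W`, p-value,
#'   method, and a `degenerate` flag (p fixed at 1 when every value is
#'   identical in both groups).
#' @export
compare_groups <- function(features, feature_name,
                           groups = c("positive", "negative"),
                           exact_cutoff = 50L,
                           alternative = "two.sided") {
  if (!feature_name %in% names(features)) {
    abort(sprintf("Unknown feature '%s'.", feature_name))
  }
  x <- features[[feature_name]][features$label == groups[1]]
  y <- features[[feature_name]][features$label == groups[2]]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Each group needs at least one non-missing value.")
  }
  if (length(unique(c(x, y))) == 1L) {
    return(tibble(feature = feature_name,
                  median_1 = median(x), median_2 = median(y),
                  statistic = length(x) * length(y) / 2,
                  p_value = 1, method = "degenerate", degenerate = TRUE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_cutoff && length(y) <= exact_cutoff
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact, correct = TRUE)
  )
  tibble(feature = feature_name,
         median_1 = median(x), median_2 = median(y),
         statistic = unname(ht$statistic),
         p_value = ht$p.value,
         method = if (exact) "exact" else "normal_approx",
         degenerate = FALSE)
}
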