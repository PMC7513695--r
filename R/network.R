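#' Fisher z-transformed co-expression weight
#'
#' The edge weight of the co-expression-weighted PPI network:
#' `atanh(r)` with `r` the Pearson correlation of the two genes' expression
#' profiles, clamped to +/-(1 - 1e-6) so identical profiles stay finite.
#'
#' @param x,y numeric expression vectors of equal length >= 3.
#' @return The Fisher z value; 0 (with a warning) when either vector is
#'   constant, where the correlation is undefined.
#' @export
coexpression_weight <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant expression vector: correlation undefined, weight set to 0.")
    return(0)
  }
  r <- cor(x, y)
  atanh(max(min(r, 1 - 1e-6), -(1 - 1e-6)))
}

#' Build the co-expression-weighted PPI network
#'
#' Restricts the PPI edge list to pairs where both genes have expression,
#' weights each retained edge by the Fisher z-transformed Pearson correlation
#' of the two genes' profiles across all samples, and returns an undirected
#' [igraph::graph] with edge attributes `weight` (signed z) and `weight_abs`
#' (the non-negative derived weight `|z|` consumed by the topology
#' algorithms). Genes with expression but no retained PPI edge are not nodes;
#' they are handled downstream by [impute_network_features()].
#'
#' @param ppi_edges data frame with columns `gene_a`, `gene_b`.
#' @param expr an [expr_matrix()] on the log2 scale.
#' @return An igraph object.
#' @export
build_network <- function(ppi_edges, expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "log2") {
    abort("`expr` must be log2-scale (see `log_transform()`).")
  }
  edges <- as_tibble(ppi_edges)
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort("`ppi_edges` needs columns `gene_a` and `gene_b`.")
  }
  genes <- rownames(expr$values)
  edges <- edges |>
    filter(.data$gene_a != .data$gene_b,
           .data$gene_a %in% genes, .data$gene_b %in% genes)
  # canonical orientation, then dedupe unordered pairs
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  edges <- dplyr::distinct(edges)
  if (nrow(edges) == 0) {
    abort("No PPI edge has expression for both endpoints; network is empty.")
  }

  vals <- expr$values
  centered <- vals - rowMeans(vals)
  ss <- sqrt(rowSums(centered^2))
  a <- centered[edges$gene_a, , drop = FALSE]
  b <- centered[edges$gene_b, , drop = FALSE]
  denom <- ss[edges$gene_a] * ss[edges$gene_b]
  r <- ifelse(denom == 0, 0, rowSums(a * b) / denom)
  if (any(denom == 0)) {
    warn("Constant expression profile(s); affected edge weights set to 0.")
  }
  z <- atanh(pmax(pmin(r, 1 - 1e-6), -(1 - 1e-6)))

  g <- igraph::graph_from_data_frame(
    cbind(edges, weight = z, weight_abs = abs(z)),
    directed = FALSE
  )
  g
}

# leading eigenpair of a symmetric non-negative sparse matrix, by power
# iteration; sign fixed so the largest-magnitude loading is positive
leading_eigen <- function(adj, tol = 1e-10, max_iter = 2000L) {
  n <- nrow(adj)
  v <- rep(1 / sqrt(n), n)
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- as.numeric(adj %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(list(values = 0, vector = rep(0, n)))
    w <- w / nw
    if (sum(abs(w - v)) < tol) {
      v <- w
      lambda <- nw
      break
    }
    v <- w
    lambda <- nw
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  list(values = lambda, vector = v)
}

# Bonacich power centrality on the weighted adjacency:
# c(beta) = (I - beta A)^-1 A 1, rescaled so sum of squares equals n
# (matching igraph's convention on unweighted graphs).
bonacich_power_weighted <- function(adj, beta) {
  n <- nrow(adj)
  id <- Matrix::Diagonal(n)
  c_raw <- as.numeric(Matrix::solve(id - beta * adj, adj %*% rep(1, n)))
  scl <- sqrt(n / sum(c_raw^2))
  if (!is.finite(scl)) scl <- 0
  c_raw * scl
}

#' Node-level topology features of the weighted gene network
#'
#' Computes the 10 per-gene topology features: degree, closeness,
#' betweenness, Bonacich power centrality, eigenvector centrality, alpha
#' centrality, leading-eigenvector (PC1) loading of the weighted adjacency,
#' hub score, k-core coreness, and PageRank. Distance-based measures use edge
#' length `1 / weight_abs`; spectral measures use the `weight_abs` adjacency;
#' coreness uses the unweighted k-core decomposition; PageRank uses damping
#' 0.85 with weighted transitions.
#'
#' Disconnected graphs: closeness is computed within components;
#' eigenvector and hub scores are computed on the largest component and are 0
#' elsewhere.
#'
#' @param net an igraph network from [build_network()] (edge attribute
#'   `weight_abs`; absent weights are treated as 1).
#' @return Tibble: `gene`, the 10 features, and `provenance = "computed"`.
#' @export
topology_features <- function(net) {
  stopifnot(inherits(net, "igraph"))
  n <- igraph::vcount(net)
  if (n == 0) abort("Empty network.")
  genes <- igraph::V(net)$name %||% as.character(seq_len(n))
  if (n == 1) {
    warn("Single-node network: centralities defined as 0.")
    return(tibble(gene = genes, degree = 0, closeness = 0, betweenness = 0,
                  bonacich_power = 0, eigenvector = 0, alpha_centrality = 0,
                  pc1_loading = 0, hub_score = 0, coreness = 0, pagerank = 1,
                  provenance = "computed"))
  }
  w <- igraph::edge_attr(net, "weight_abs") %||% rep(1, igraph::ecount(net))
  w_pos <- pmax(w, 1e-8)  # zero-weight edges: tiny positive for 1/w distances
  dist_len <- 1 / w_pos

  degree <- igraph::degree(net)
  betweenness <- igraph::betweenness(net, weights = dist_len, normalized = FALSE)
  pagerank <- igraph::page_rank(net, damping = 0.85, weights = w_pos)$vector
  coreness <- igraph::coreness(net)

  comp <- igraph::components(net)
  closeness <- rep(0, n)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1) next
    sub <- igraph::induced_subgraph(net, idx)
    sw <- igraph::edge_attr(sub, "weight_abs") %||% rep(1, igraph::ecount(sub))
    closeness[idx] <- igraph::closeness(sub, weights = 1 / pmax(sw, 1e-8))
  }

  adj <- igraph::as_adjacency_matrix(net, attr = "weight_abs", sparse = TRUE)
  eig <- leading_eigen(adj)
  lambda_max <- max(eig$values, 1e-8)
  pc1_loading <- eig$vector

  eigenvector <- rep(0, n)
  hub_score <- rep(0, n)
  big <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(net, big)
  sw <- igraph::edge_attr(sub, "weight_abs") %||% rep(1, igraph::ecount(sub))
  sw <- pmax(sw, 1e-8)
  eigenvector[big] <- igraph::eigen_centrality(sub, weights = sw)$vector
  hub_score[big] <- igraph::hits_scores(sub, weights = sw)$hub

  bonacich_power <- bonacich_power_weighted(adj, beta = 0.9 / lambda_max)
  alpha_centrality <- igraph::alpha_centrality(
    net, alpha = 0.5 / lambda_max, exo = 1, weights = w_pos, sparse = TRUE
  )

  tibble(gene = genes, degree = as.numeric(degree),
         closeness = as.numeric(closeness),
         betweenness = as.numeric(betweenness),
         bonacich_power = as.numeric(bonacich_power),
         eigenvector = as.numeric(eigenvector),
         alpha_centrality = as.numeric(alpha_centrality),
         pc1_loading = as.numeric(pc1_loading),
         hub_score = as.numeric(hub_score),
         coreness = as.numeric(coreness),
         pagerank = as.numeric(pagerank),
         provenance = "computed")
}

#' Impute network features for genes absent from the network
#'
#' Genes with expression but no PPI evidence receive the unweighted mean of
#' the network features of their `k` nearest neighbours, nearest by Euclidean
#' distance in standardized expression-feature space. Distance ties are
#' broken deterministically by gene identifier.
#'
#' @param feats tibble from [topology_features()].
#' @param all_genes every gene that must end up with features.
#' @param predictor_space an [expr_matrix()] (log2) or a numeric matrix of
#'   predictor features with gene rownames covering `all_genes`.
#' @param k number of neighbours (must not exceed the number of genes with
#'   computed features).
#' @return `feats` extended with one `provenance = "imputed"` row per missing
#'   gene.
#' @export
impute_network_features <- function(feats, all_genes, predictor_space, k = 5L) {
  k <- assert_count(k, "k")
  space <- if (inherits(predictor_space, "expr_matrix")) {
    predictor_space$values
  } else {
    predictor_space
  }
  if (is.null(rownames(space))) abort("`predictor_space` needs gene rownames.")
  donors <- intersect(feats$gene, rownames(space))
  if (k > length(donors)) {
    abort(sprintf("k = %d exceeds the %d genes with computed features.",
                  k, length(donors)))
  }
  missing <- setdiff(all_genes, feats$gene)
  if (length(missing) == 0) return(feats)
  absent <- setdiff(missing, rownames(space))
  if (length(absent)) {
    abort(sprintf("No predictor features for gene(s): %s",
                  paste(head(absent, 5), collapse = ", ")))
  }

  sub <- space[c(donors, missing), , drop = FALSE]
  mu <- colMeans(sub)
  sigma <- apply(sub, 2, sd)
  sigma[sigma == 0] <- 1
  std <- sweep(sweep(sub, 2, mu), 2, sigma, "/")
  donor_mat <- std[donors, , drop = FALSE]
  feat_mat <- as.matrix(feats[match(donors, feats$gene), network_feature_names])

  imputed <- vapply(missing, function(g) {
    d <- sqrt(rowSums(sweep(donor_mat, 2, std[g, ])^2))
    nn <- donors[order(d, donors)][seq_len(k)]
    colMeans(feat_mat[match(nn, donors), , drop = FALSE])
  }, numeric(length(network_feature_names)))

  new_rows <- as_tibble(t(imputed)) |>
    mutate(gene = missing, provenance = "imputed") |>
    relocate("gene")
  bind_rows(feats, new_rows)
}
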