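# Small shared fixtures, all generated in code.

tiny_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_genes = 300L, n_positive = 40L, n_negative = 160L,
         n_hidden_risk = 30L, n_regions = 4L, n_stages = 5L,
         go_n_terms = 20L, go_planted_terms = 4L,
         n_proband = 40L, n_sibling = 30L, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

# one shared tiny dataset + derived objects, built once per test run
.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$ds)) .fixture_env$ds <- generate_dataset(tiny_config())
  .fixture_env$ds
}

tiny_features <- function() {
  if (is.null(.fixture_env$features)) {
    ds <- tiny_dataset()
    expr <- log_transform(ds$expression)
    net <- build_network(ds$ppi_edges, expr)
    .fixture_env$features <- assemble_features(
      expr, topology_features(net), ds$constraint, ds$labels)
  }
  .fixture_env$features
}

# small labeled feature table with a planted linear signal, for fast CV tests
toy_feature_table <- function(n = 120, p = 8, signal = 1.5, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("positive", "negative"), c(n / 3, n - n / 3))
    x <- matrix(rnorm(n * p), n, p)
    x[, 1] <- x[, 1] + signal * (y == "positive")
    colnames(x) <- paste0("f", seq_len(p))
    tab <- dplyr::bind_cols(
      tibble::tibble(gene = sprintf("G%04d", seq_len(n)),
                     label = factor(y, levels = c("positive", "negative",
                                                  "unlabeled"))),
      tibble::as_tibble(x))
    structure(tab, class = c("gene_feature_table", class(tab)),
              feature_names = colnames(x))
  })
}

# unit-weight igraph from a 0/1 adjacency matrix, with gene names
graph_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("g", seq_len(nrow(adj)))
  igraph::E(g)$weight <- 1
  igraph::E(g)$weight_abs <- 1
  g
}

random_adjacency <- function(n, p_edge = 0.4, seed = 1) {
  withr::with_seed(seed, {
    adj <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
    }
    # ensure no isolated vertex so every centrality is defined
    for (i in which(rowSums(adj) == 0)) {
      j <- if (i == 1) 2L else i - 1L
      adj[i, j] <- adj[j, i] <- 1L
    }
    adj
  })
}
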