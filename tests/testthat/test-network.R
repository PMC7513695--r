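test_that("co-expression weights follow the Fisher z transform", {
  # mean-centered orthogonal vectors: r = 0 -> z = 0
  expect_equal(coexpression_weight(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  # odd symmetry
  x <- c(0.2, 1.4, -0.8, 2.2, 0.1)
  y <- c(1.1, 0.3, -0.2, 1.9, 0.4)
  expect_equal(coexpression_weight(x, -y), -coexpression_weight(x, y))
  # closed form: r = 0.9 -> atanh(0.9) = 1.4722 (4 dp)
  xy <- local({
    a <- scale(1:10)[, 1]
    b <- 0.9 * a + sqrt(1 - 0.81) * scale(stats::resid(stats::lm(rnorm(10) ~ a)))[, 1]
    list(a = a, b = b)
  })
  expect_equal(round(coexpression_weight(xy$a, xy$b), 4), 1.4722)
  # identical profiles hit the clamp boundary
  expect_equal(coexpression_weight(x, x), atanh(1 - 1e-6))
  # constant vector: undefined correlation -> 0 with warning
  expect_warning(w <- coexpression_weight(rep(1, 5), y), "Constant")
  expect_equal(w, 0)
  expect_error(coexpression_weight(1:2, 1:2), "length")
})

test_that("network construction restricts edges to expressed genes", {
  ds <- tiny_dataset()
  expr <- log_transform(ds$expression)
  net <- build_network(ds$ppi_edges, expr)
  edge_genes <- unique(c(ds$ppi_edges$gene_a, ds$ppi_edges$gene_b))
  expect_setequal(igraph::V(net)$name, edge_genes)
  expect_false(any(igraph::which_loop(net)))
  expect_false(any(igraph::which_multiple(net)))
  expect_true(all(is.finite(igraph::E(net)$weight)))

  # an edge touching a gene without expression is dropped and the gene routed
  # to imputation (it is no longer a node)
  sub_expr <- expr
  keep <- setdiff(rownames(expr$values), edge_genes[1])
  sub_expr$values <- sub_expr$values[keep, ]
  net2 <- build_network(ds$ppi_edges, sub_expr)
  expect_false(edge_genes[1] %in% igraph::V(net2)$name)

  expect_error(build_network(ds$ppi_edges[0, ], expr), "empty")
  expect_error(build_network(ds$ppi_edges, ds$expression), "log2")
})

test_that("topology features match unweighted oracles on small graphs", {
  # 4-node path a-b-c-d: betweenness (0, 2, 2, 0), unnormalized
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  adj[3, 4] <- adj[4, 3] <- 1
  tf <- topology_features(graph_from_adj(adj))
  expect_equal(tf$betweenness, c(0, 2, 2, 0))
  expect_equal(tf$degree, c(1, 2, 2, 1))

  # random unit-weight graphs (<= 8 nodes): closeness and betweenness equal
  # the exhaustive shortest-path oracles; pagerank sums to 1; coreness <= degree
  for (s in 1:6) {
    adj <- random_adjacency(sample(4:8, 1), p_edge = 0.45, seed = s)
    tf <- topology_features(graph_from_adj(adj))
    expect_equal(tf$betweenness, oracle_betweenness(adj), tolerance = 1e-9)
    expect_equal(tf$closeness, oracle_closeness(adj), tolerance = 1e-9)
    expect_equal(sum(tf$pagerank), 1, tolerance = 1e-9)
    expect_true(all(tf$coreness <= tf$degree))
  }
})

test_that("bonacich power centrality agrees with igraph on unit weights", {
  for (s in 1:4) {
    adj <- random_adjacency(6, p_edge = 0.5, seed = 10 + s)
    g <- graph_from_adj(adj)
    lambda <- max(abs(eigen(adj, symmetric = TRUE)$values))
    tf <- topology_features(g)
    ref <- igraph::power_centrality(g, exponent = 0.9 / lambda)
    expect_equal(tf$bonacich_power, unname(ref), tolerance = 1e-6)
  }
})

test_that("symmetry and permutation equivariance hold", {
  # complete graph with equal weights: every feature identical across nodes
  adj <- matrix(1, 5, 5) - diag(5)
  tf <- topology_features(graph_from_adj(adj))
  for (f in setdiff(names(tf), c("gene", "provenance"))) {
    expect_equal(var(tf[[f]]), 0, tolerance = 1e-12)
  }

  # relabeling nodes permutes every feature vector identically
  adj <- random_adjacency(7, p_edge = 0.4, seed = 3)
  g1 <- graph_from_adj(adj)
  perm <- withr::with_seed(4, sample(7))
  g2 <- graph_from_adj(adj[perm, perm])
  igraph::V(g2)$name <- paste0("g", perm)  # same gene names, new order
  tf1 <- topology_features(g1) |> dplyr::arrange(gene)
  tf2 <- topology_features(g2) |> dplyr::arrange(gene)
  for (f in setdiff(names(tf1), c("gene", "provenance"))) {
    expect_equal(tf1[[f]], tf2[[f]], tolerance = 1e-6)
  }
})

test_that("single-node networks degrade to zero centralities with a warning", {
  g <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g)$name <- "g1"
  expect_warning(tf <- topology_features(g), "Single-node")
  expect_equal(tf$degree, 0)
  expect_equal(tf$pagerank, 1)
})

test_that("kNN imputation matches identity, symmetry and brute force", {
  ds <- tiny_dataset()
  expr <- log_transform(ds$expression)
  feats <- topology_features(build_network(ds$ppi_edges, expr))
  all_genes <- rownames(expr$values)
  missing <- setdiff(all_genes, feats$gene)
  expect_gt(length(missing), 0)

  # k = 1 with an identical expression profile: exact copy
  donor <- feats$gene[1]
  fake_expr <- expr$values
  fake_expr[missing[1], ] <- fake_expr[donor, ]
  out <- impute_network_features(feats, all_genes, fake_expr, k = 1)
  got <- out[out$gene == missing[1], 2:11]
  want <- feats[feats$gene == donor, 2:11]
  expect_equal(as.numeric(got), as.numeric(want))
  expect_equal(out$provenance[out$gene == missing[1]], "imputed")

  # k = 3 against a brute-force all-pairs scan in the standardized space
  out <- impute_network_features(feats, all_genes, expr, k = 3)
  donors <- feats$gene
  sub <- expr$values[c(donors, missing), ]
  std <- scale(sub)
  std[, attr(std, "scaled:scale") == 0] <- 0
  target <- missing[2]
  d <- sqrt(rowSums((std[donors, ] - matrix(std[target, ], length(donors),
                                            ncol(std), byrow = TRUE))^2))
  nn <- donors[order(d, donors)][1:3]
  want <- colMeans(as.matrix(feats[match(nn, feats$gene), 2:11]))
  got <- as.numeric(out[out$gene == target, 2:11])
  expect_equal(got, unname(want), tolerance = 1e-9)

  expect_error(impute_network_features(feats, all_genes, expr,
                                       k = nrow(feats) + 1), "exceeds")
})
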