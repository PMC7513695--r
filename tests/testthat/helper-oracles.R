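# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Exact Wilcoxon rank-sum p by full enumeration of all C(n1+n2, n1) group
# assignments (no ties assumed). Returns the two-sided p under the doubled
# smaller-tail rule.
oracle_wilcoxon <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_less <- mean(u_all <= u_obs)
  p_greater <- mean(u_all >= u_obs)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# AUC-ROC as the proportion of concordant positive/negative pairs (ties 0.5).
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by full hypergeometric enumeration with the
# minimum-likelihood rule (all tables at most as probable as the observed).
oracle_fisher <- function(a, b, c, d) {
  m <- a + c          # margin: in-term
  k <- a + b          # margin: risk genes
  n <- a + b + c + d
  lo <- max(0, k + m - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n - m, k)
  p_obs <- stats::dhyper(a, m, n - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_binom_tail <- function(k, n, p0) {
  sum(stats::dbinom(k:n, n, p0))
}

# All-pairs shortest path lengths on a unit-weight undirected graph
# (adjacency matrix in, Floyd-Warshall).
oracle_dists <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Unnormalized betweenness by counting shortest paths (unit weights):
# sigma via DP over distance levels.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_dists(adj)
  sigma <- matrix(0, n, n)          # number of shortest paths i -> j
  for (i in seq_len(n)) {
    sigma[i, i] <- 1
    for (dist in sort(unique(d[i, is.finite(d[i, ]) & d[i, ] > 0]))) {
      for (j in which(d[i, ] == dist)) {
        preds <- which(adj[, j] > 0 & d[i, ] == dist - 1)
        sigma[i, j] <- sum(sigma[i, preds])
      }
    }
  }
  bt <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        bt[v] <- bt[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  bt
}

# igraph-style closeness on unit weights: 1 / sum(distances to the other
# vertices of the same component).
oracle_closeness <- function(adj) {
  d <- oracle_dists(adj)
  vapply(seq_len(nrow(adj)), function(i) {
    reach <- is.finite(d[i, ]) & seq_len(ncol(d)) != i
    if (!any(reach)) return(0)
    1 / sum(d[i, reach])
  }, numeric(1))
}

# Exhaustive F1 scan over every classification reachable by a midpoint
# threshold (i.e. every cutoff at a distinct score value above the minimum).
oracle_best_f1 <- function(scores, labels) {
  labels <- as.logical(labels)
  best <- 0
  for (t in sort(unique(scores))[-1]) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    if (tp == 0) next
    f1 <- 2 * tp / (sum(pred) + sum(labels))
    if (f1 > best) best <- f1
  }
  best
}
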