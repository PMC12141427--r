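# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (loops, enumeration) so it cannot
# share a code path with the implementation it checks.

# random attributed graph with 0-based directed edges (duplicates excluded)
rand_graph <- function(n_nodes, n_edges, d_n = 3L, d_e = 2L,
                       coords = FALSE) {
  all_pairs <- expand.grid(src = 0:(n_nodes - 1L), tgt = 0:(n_nodes - 1L))
  pick <- all_pairs[sample.int(nrow(all_pairs), min(n_edges, nrow(all_pairs))),
                    , drop = FALSE]
  ei <- as.matrix(pick)
  graph(matrix(rnorm(n_nodes * d_n), n_nodes, d_n),
        ei,
        edge_features = if (d_e > 0L)
          matrix(rnorm(nrow(ei) * d_e), nrow(ei), d_e),
        coords = if (coords) matrix(rnorm(n_nodes * 3), n_nodes, 3L))
}

# random simple undirected graph, stored bidirectionally
rand_undirected <- function(n_nodes, p_edge = 0.4, d_n = 2L) {
  ei <- NULL
  for (i in 0:(n_nodes - 2L)) for (j in (i + 1L):(n_nodes - 1L))
    if (runif(1) < p_edge) ei <- rbind(ei, c(i, j))
  if (is.null(ei)) ei <- matrix(integer(0), ncol = 2L)
  canonicalize_undirected(
    graph(matrix(rnorm(n_nodes * d_n), n_nodes, d_n), ei))
}

# brute-force shared-endpoint predicate over all edge pairs
oracle_edge_adjacency <- function(ei) {
  m <- nrow(ei)
  out <- matrix(FALSE, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    out[a, b] <- ei[a, 1L] == ei[b, 1L] || ei[a, 2L] == ei[b, 2L] ||
      ei[a, 1L] == ei[b, 2L] || ei[a, 2L] == ei[b, 1L]
  }
  out
}

# dense node adjacency (either direction) plus self-pairs
oracle_node_adjacency <- function(n, ei) {
  out <- diag(n) > 0
  for (r in seq_len(nrow(ei))) {
    out[ei[r, 1L] + 1L, ei[r, 2L] + 1L] <- TRUE
    out[ei[r, 2L] + 1L, ei[r, 1L] + 1L] <- TRUE
  }
  out
}

# scalar-loop masked softmax attention
oracle_sdpa <- function(Q, K, V, M = NULL) {
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) {
      s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(Q))
      if (!is.null(M)) s[j] <- s[j] + M[i, j]
    }
    e <- exp(s - max(s))
    a <- e / sum(e)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

# queue-free quadratic BFS (independent of the generator's implementation)
oracle_bfs <- function(n, ei, source) {
  dist <- rep(Inf, n)
  dist[source + 1L] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(ei))) {
      a <- ei[r, 1L] + 1L; b <- ei[r, 2L] + 1L
      if (dist[a] + 1 < dist[b]) { dist[b] <- dist[a] + 1; changed <- TRUE }
      if (dist[b] + 1 < dist[a]) { dist[a] <- dist[b] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

# brute-force triangle count by 3-subset enumeration
oracle_triangles <- function(g) {
  n <- n_nodes(g)
  adj <- matrix(FALSE, n, n)
  if (n_edges(g) > 0L) {
    adj[g$edge_index + 1L] <- TRUE
    adj <- adj | t(adj)
  }
  cnt <- 0L
  if (n >= 3L) {
    for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n)
      if (adj[i, j] && adj[j, k] && adj[i, k]) cnt <- cnt + 1L
  }
  cnt
}

# apply a node relabeling (permutation, 0-based) and an edge reordering to a
# graph; returns the permuted graph and the edge permutation used
permute_graph <- function(g, node_perm = NULL, edge_perm = NULL) {
  n <- n_nodes(g)
  if (is.null(node_perm)) node_perm <- sample.int(n) - 1L
  ne <- n_edges(g)
  if (is.null(edge_perm)) edge_perm <- sample.int(ne)
  new_nodes <- g$node_features
  new_nodes[node_perm + 1L, ] <- g$node_features
  new_coords <- NULL
  if (!is.null(g$coords)) {
    new_coords <- g$coords
    new_coords[node_perm + 1L, ] <- g$coords
  }
  ei <- matrix(node_perm[g$edge_index + 1L], ncol = 2L)[edge_perm, ,
                                                        drop = FALSE]
  ef <- g$edge_features[edge_perm, , drop = FALSE]
  y <- g$y
  if (!is.null(y) && length(y) == n) y[node_perm + 1L] <- g$y
  list(g = graph(new_nodes, ei, ef, coords = new_coords, y = y),
       node_perm = node_perm, edge_perm = edge_perm)
}

# tiny model builders shared by model/attention tests
tiny_graph_model <- function(in_dim, layer_string = "MSP", d = 8L, h = 2L,
                             k = 3L, seed = 1L, ...) {
  esa_model(esa_config(layer_string, task = "graph_regression",
                       hidden_dim = d, heads = h, k = k, ...),
            in_dim, seed = seed)
}

tiny_node_model <- function(in_dim, layer_string = "MS", d = 8L, h = 2L,
                            out_dim = 3L, seed = 1L, ...) {
  esa_model(esa_config(layer_string, task = "node_classification",
                       hidden_dim = d, heads = h, out_dim = out_dim, ...),
            in_dim, seed = seed)
}
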