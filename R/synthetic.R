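#' Synthetic task specification
#'
#' Bundles the arguments of a synthetic-graph generator together with its
#' seed, so a dataset is a pure function of its spec (byte-identical repeat
#' runs). Used by the generators and by the `esa synth` CLI manifest.
#'
#' @param generator one of `"er"`, `"shortest_path"`, `"counting"`.
#' @param n_graphs number of graphs.
#' @param seed integer RNG seed; fully determines the output.
#' @param ... generator-specific fields (`n_range`, `p_edge`, `n_classes`,
#'   `target`, ...).
#' @return a `synth_spec` object (named list).
#' @export
synth_spec <- function(generator, n_graphs, seed, ...) {
  stopifnot(n_graphs >= 1L)
  structure(c(list(generator = generator, n_graphs = as.integer(n_graphs),
                   seed = as.integer(seed)), list(...)),
            class = "synth_spec")
}

# node features: constant 1, optionally followed by a one-hot of the
# (clipped) undirected degree — the usual stand-in when a dataset has no
# native node features.
er_node_features <- function(n, ei_undirected, degree_onehot, max_degree) {
  feats <- matrix(1, n, 1L)
  if (degree_onehot) {
    deg <- tabulate(c(ei_undirected[, 1L], ei_undirected[, 2L]) + 1L, n)
    deg <- pmin(deg, max_degree)
    oh <- matrix(0, n, max_degree + 1L)
    oh[cbind(seq_len(n), deg + 1L)] <- 1
    feats <- cbind(feats, oh)
  }
  feats
}

# sample one undirected ER edge set (0-based, src < tgt)
sample_er_edges <- function(n, p_edge) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  cbind(pairs[keep, 1L] - 1L, pairs[keep, 2L] - 1L)
}

#' Seeded Erdős–Rényi graph generator
#'
#' Samples undirected G(n, p) graphs, canonicalized to bidirectional edge
#' lists (one token per direction). Node features are a constant 1 plus an
#' optional one-hot of the clipped degree. Disconnected samples are kept —
#' there is no rejection.
#'
#' @param n_graphs number of graphs.
#' @param n_range integer vector of candidate node counts (sampled
#'   uniformly), or a single count.
#' @param p_edge edge probability in (0, 1]; `p_edge = 1` yields complete
#'   graphs.
#' @param seed integer seed.
#' @param degree_onehot append a one-hot degree feature block.
#' @param max_degree degrees are clipped here before one-hot encoding.
#' @return list of `esa_graph`.
#' @export
gen_er_graphs <- function(n_graphs, n_range, p_edge, seed,
                          degree_onehot = TRUE, max_degree = 12L) {
  stopifnot(p_edge > 0, p_edge <= 1, all(n_range >= 1L))
  set.seed(seed)
  lapply(seq_len(n_graphs), function(i) {
    n <- if (length(n_range) > 1L) sample(n_range, 1L) else n_range
    ei <- sample_er_edges(n, p_edge)
    g <- graph(er_node_features(n, ei, degree_onehot, max_degree), ei)
    canonicalize_undirected(g)
  })
}

# breadth-first distances from `source` (0-based) on a bidirectional edge
# list; unreachable nodes get Inf
bfs_distances <- function(n, edge_index, source) {
  adj <- vector("list", n)
  if (nrow(edge_index) > 0L) {
    for (r in seq_len(nrow(edge_index))) {
      i <- edge_index[r, 1L] + 1L
      adj[[i]] <- c(adj[[i]], edge_index[r, 2L])
    }
  }
  dist <- rep(Inf, n)
  dist[source + 1L] <- 0
  frontier <- source
  depth <- 0
  while (length(frontier) > 0L) {
    depth <- depth + 1
    nxt <- unique(unlist(adj[frontier + 1L]))
    nxt <- nxt[is.infinite(dist[nxt + 1L])]
    dist[nxt + 1L] <- depth
    frontier <- nxt
  }
  dist
}

#' Shortest-path node-classification task
#'
#' An "infected" Erdős–Rényi surrogate: one random source node per graph is
#' marked with a one-hot feature, and each node's label is its BFS distance
#' to the source, clipped to `n_classes - 1` (unreachable nodes land in the
#' top class). Labels are recomputable by any shortest-path oracle.
#'
#' @param n_graphs number of graphs.
#' @param n_nodes nodes per graph (single count or range).
#' @param p_edge ER edge probability.
#' @param n_classes number of distance classes, at least 2.
#' @param seed integer seed.
#' @return list of `esa_graph` with node features
#'   `[1, source-flag]` and integer node labels `0..n_classes-1` in `y`.
#' @export
gen_shortest_path_task <- function(n_graphs, n_nodes, p_edge, n_classes,
                                   seed) {
  stopifnot(n_classes >= 2L)
  set.seed(seed)
  lapply(seq_len(n_graphs), function(i) {
    n <- if (length(n_nodes) > 1L) sample(n_nodes, 1L) else n_nodes
    ei <- sample_er_edges(n, p_edge)
    src <- sample.int(n, 1L) - 1L
    feats <- matrix(0, n, 2L)
    feats[, 1L] <- 1
    feats[src + 1L, 2L] <- 1
    g <- canonicalize_undirected(graph(feats, ei))
    d <- bfs_distances(n, g$edge_index, src)
    g$y <- as.integer(pmin(d, n_classes - 1L))
    g
  })
}

#' Graph-level counting task
#'
#' ER graphs labelled with an exactly computed scalar: the undirected edge
#' count, or the triangle count via `trace(A^3) / 6` on the simple undirected
#' adjacency matrix.
#'
#' @inheritParams gen_er_graphs
#' @param target `"edge_count"` or `"triangle_count"`.
#' @return list of `esa_graph` with scalar `y`.
#' @export
gen_counting_task <- function(n_graphs, n_range, p_edge, seed,
                              target = c("triangle_count", "edge_count"),
                              degree_onehot = TRUE, max_degree = 12L) {
  target <- match.arg(target)
  gs <- gen_er_graphs(n_graphs, n_range, p_edge, seed, degree_onehot,
                      max_degree)
  lapply(gs, function(g) {
    g$y <- if (target == "edge_count") n_edges(g) / 2
    else count_triangles(g)
    g
  })
}

#' Exact triangle count of a simple undirected graph
#' @param g an `esa_graph` (bidirectional storage).
#' @return number of triangles, `trace(A^3) / 6`.
#' @export
count_triangles <- function(g) {
  n <- n_nodes(g)
  a <- matrix(0, n, n)
  if (n_edges(g) > 0L) a[g$edge_index + 1L] <- 1
  a <- pmax(a, t(a))
  diag(a) <- 0
  sum(diag(a %*% a %*% a)) / 6
}

#' 1-WL-hard fixture pair
#'
#' Returns the decalin skeleton (two fused hexagons sharing an edge) and the
#' bicyclopentyl skeleton (two pentagons joined by a bridge edge): 10 nodes
#' and 11 undirected edges each, uniform unit node features, identical degree
#' sequences, non-isomorphic. Classic pair that 1-WL color refinement cannot
#' distinguish — but whose line graphs it can, which is exactly the extra
#' expressivity edge tokens buy.
#'
#' @return list of two `esa_graph` objects named `decalin` and
#'   `bicyclopentyl` (bidirectional storage).
#' @export
fixture_wl_pair <- function() {
  decalin_edges <- rbind(
    c(0, 1), c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 0),   # hexagon
    c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 4)             # fused hexagon
  )
  bicyclo_edges <- rbind(
    c(0, 1), c(1, 2), c(2, 3), c(3, 4), c(4, 0),            # pentagon
    c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 5),            # pentagon
    c(0, 5)                                                 # bridge
  )
  mk <- function(ei) canonicalize_undirected(graph(matrix(1, 10, 1L), ei))
  list(decalin = mk(decalin_edges), bicyclopentyl = mk(bicyclo_edges))
}

#' Line graph of the undirected support
#'
#' Vertices are the unordered edges of `g`; two are adjacent iff they share
#' an endpoint. Uniform unit node features. Matches (off the diagonal) the
#' edge-adjacency attention mask restricted to one direction per pair.
#'
#' @param g an `esa_graph`.
#' @return an `esa_graph` storing the line graph bidirectionally.
#' @export
line_graph <- function(g) {
  ei <- g$edge_index
  und <- unique(cbind(pmin(ei[, 1L], ei[, 2L]), pmax(ei[, 1L], ei[, 2L])))
  m <- nrow(und)
  if (m == 0L)
    return(graph(matrix(1, 1L, 1L), matrix(integer(0), ncol = 2L)))
  share <- outer(und[, 1L], und[, 1L], "==") |
    outer(und[, 2L], und[, 2L], "==") |
    outer(und[, 1L], und[, 2L], "==") |
    outer(und[, 2L], und[, 1L], "==")
  diag(share) <- FALSE
  hit <- which(share & upper.tri(share), arr.ind = TRUE)
  lg <- graph(matrix(1, m, 1L), cbind(hit[, 1L] - 1L, hit[, 2L] - 1L))
  canonicalize_undirected(lg)
}

#' 1-WL color refinement
#'
#' Iterated neighbor-multiset hashing: each round, a node's color becomes the
#' (canonicalized) pair of its current color and the sorted multiset of its
#' neighbors' colors, until the partition stabilizes or `max_rounds` is hit.
#' All nodes start with one color. Returns the color histogram: class sizes
#' indexed by canonical color rank.
#'
#' @param g an `esa_graph` (edges interpreted as undirected support).
#' @param max_rounds cap on refinement rounds; default `n_nodes(g)`.
#' @return named integer vector (color rank -> class size), sorted by rank.
#' @export
color_refinement <- function(g, max_rounds = n_nodes(g)) {
  n <- n_nodes(g)
  ei <- g$edge_index
  und <- rbind(ei, ei[, c(2L, 1L)])
  adj <- lapply(seq_len(n), function(i)
    unique(und[und[, 1L] == i - 1L, 2L]) + 1L)
  colors <- rep(1L, n)
  for (round in seq_len(max_rounds)) {
    sig <- vapply(seq_len(n), function(i)
      paste0(colors[i], "|",
             paste(sort(colors[adj[[i]]]), collapse = ",")),
      character(1))
    new_colors <- match(sig, sort(unique(sig)))
    stable <- length(unique(new_colors)) == length(unique(colors))
    colors <- new_colors      # refinement never coarsens a partition
    if (stable) break
  }
  tab <- table(colors)
  stats::setNames(as.integer(tab), names(tab))
}

#' Can 1-WL distinguish two graphs?
#'
#' Runs color refinement on the disjoint union (so colors are shared between
#' the graphs) and compares the per-graph color histograms; `TRUE` means the
#' histograms differ, i.e. 1-WL separates the pair.
#'
#' @param g1,g2 `esa_graph` objects.
#' @param max_rounds cap on refinement rounds.
#' @return logical scalar.
#' @export
wl_distinguishable <- function(g1, g2,
                               max_rounds = n_nodes(g1) + n_nodes(g2)) {
  n1 <- n_nodes(g1)
  union_ei <- rbind(g1$edge_index, g2$edge_index + n1)
  u <- graph(matrix(1, n1 + n_nodes(g2), 1L), union_ei)
  n <- n_nodes(u)
  ei <- u$edge_index
  und <- rbind(ei, ei[, c(2L, 1L)])
  adj <- lapply(seq_len(n), function(i)
    unique(und[und[, 1L] == i - 1L, 2L]) + 1L)
  colors <- rep(1L, n)
  for (round in seq_len(max_rounds)) {
    sig <- vapply(seq_len(n), function(i)
      paste0(colors[i], "|",
             paste(sort(colors[adj[[i]]]), collapse = ",")),
      character(1))
    new_colors <- match(sig, sort(unique(sig)))
    stable <- length(unique(new_colors)) == length(unique(colors))
    colors <- new_colors
    if (stable) break
  }
  h1 <- sort(colors[seq_len(n1)])
  h2 <- sort(colors[n1 + seq_len(n_nodes(g2))])
  !identical(h1, h2)
}
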