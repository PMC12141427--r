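#' Attributed graph
#'
#' Constructs an attributed graph: a node feature matrix, a directed edge
#' list, optional edge features, optional 3D coordinates and an optional
#' target. Node ids are 0-based and edge order is significant — edge tokens
#' and attention masks are built in edge-list order. Undirected graphs are
#' stored with both directed edges (see [canonicalize_undirected()]); every
#' stored direction becomes one edge token.
#'
#' @param node_features numeric matrix, `N_n x d_n` (a vector is treated as a
#'   one-column matrix).
#' @param edge_index integer matrix with `N_e` rows and two columns
#'   `(source, target)`, 0-based node ids. May have zero rows.
#' @param edge_features optional numeric matrix with `N_e` rows; `NULL` means
#'   no edge features (`d_e = 0`).
#' @param coords optional `N_n x 3` numeric matrix of positions in Angstrom.
#' @param y optional target: a vector/scalar for graph-level tasks or a
#'   matrix/vector with `N_n` rows for node-level tasks.
#' @return an object of class `esa_graph`.
#' @export
graph <- function(node_features, edge_index, edge_features = NULL,
                  coords = NULL, y = NULL) {
  node_features <- as_matrix(node_features)
  if (nrow(node_features) < 1L)
    stop("invalid graph: need at least one node", call. = FALSE)
  edge_index <- as_edge_index(edge_index)
  n_n <- nrow(node_features)
  n_e <- nrow(edge_index)
  if (n_e > 0L && (min(edge_index) < 0L || max(edge_index) >= n_n))
    stop("invalid graph: edge_index refers to node ids outside [0, N_n)",
         call. = FALSE)
  if (!is.null(edge_features)) {
    edge_features <- as_matrix(edge_features)
    if (nrow(edge_features) != n_e)
      stop("invalid graph: edge_features must have exactly N_e rows",
           call. = FALSE)
  } else {
    edge_features <- matrix(numeric(0), nrow = n_e, ncol = 0L)
  }
  if (!is.null(coords)) {
    coords <- as_matrix(coords)
    stopifnot(nrow(coords) == n_n, ncol(coords) == 3L)
  }
  structure(
    list(node_features = node_features, edge_index = edge_index,
         edge_features = edge_features, coords = coords, y = y),
    class = "esa_graph"
  )
}

#' @export
print.esa_graph <- function(x, ...) {
  cat(sprintf("<esa_graph> %d nodes (d_n=%d), %d directed edges (d_e=%d)%s%s\n",
              n_nodes(x), ncol(x$node_features), n_edges(x),
              ncol(x$edge_features),
              if (is.null(x$coords)) "" else ", 3D coords",
              if (is.null(x$y)) "" else ", with targets"))
  invisible(x)
}

#' Number of nodes / edges of a graph
#' @param g an `esa_graph`.
#' @return integer count.
#' @export
n_nodes <- function(g) nrow(g$node_features)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edge_index)

as_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  x
}

as_edge_index <- function(edge_index) {
  if (is.null(edge_index) || length(edge_index) == 0L)
    return(matrix(integer(0), ncol = 2L))
  if (is.list(edge_index))
    edge_index <- do.call(rbind, lapply(edge_index, as.integer))
  edge_index <- as.matrix(edge_index)
  if (ncol(edge_index) != 2L)
    stop("edge_index must have two columns (source, target)", call. = FALSE)
  storage.mode(edge_index) <- "integer"
  dimnames(edge_index) <- NULL
  edge_index
}

#' Edge tokens of a graph
#'
#' Builds the edge-token matrix: row `i` is the concatenation of the source
#' node features, the target node features and the edge features of directed
#' edge `i`, in edge-list order. With no edge features the tokens are
#' `2 * d_n` wide.
#'
#' @param g an `esa_graph`.
#' @return an `esa_edge_tokens` object with fields `tokens`
#'   (`N_e x (2 d_n + d_e)` matrix) and `origin` (the input graph).
#' @export
build_edge_tokens <- function(g) {
  stopifnot(inherits(g, "esa_graph"))
  src <- g$edge_index[, 1L] + 1L
  tgt <- g$edge_index[, 2L] + 1L
  tokens <- cbind(
    g$node_features[src, , drop = FALSE],
    g$node_features[tgt, , drop = FALSE],
    g$edge_features
  )
  dimnames(tokens) <- NULL
  structure(list(tokens = tokens, origin = g), class = "esa_edge_tokens")
}

#' Canonicalize an undirected graph to bidirectional storage
#'
#' Expands a graph stored with one direction per unordered pair so that both
#' `(i, j)` and `(j, i)` are present, duplicating edge features. Output order
#' is deterministic: all original edges first, then all reversals. Self-loops
#' are kept single (reversal would duplicate them).
#'
#' @param g an `esa_graph` with at most one stored direction per pair.
#' @return an `esa_graph` with both directions stored.
#' @export
canonicalize_undirected <- function(g) {
  stopifnot(inherits(g, "esa_graph"))
  ei <- g$edge_index
  if (nrow(ei) > 0L) {
    key <- paste(ei[, 1L], ei[, 2L])
    if (anyDuplicated(key))
      stop("duplicate directed edge in input graph", call. = FALSE)
    rkey <- paste(ei[, 2L], ei[, 1L])
    if (any(rkey %in% key & ei[, 1L] != ei[, 2L]))
      stop("input already stores both directions for some pair", call. = FALSE)
  }
  keep <- ei[, 1L] != ei[, 2L]
  ei2 <- rbind(ei, ei[keep, c(2L, 1L), drop = FALSE])
  ef2 <- rbind(g$edge_features, g$edge_features[keep, , drop = FALSE])
  graph(g$node_features, ei2, ef2, coords = g$coords, y = g$y)
}

#' Batch graphs into a padded token tensor
#'
#' Stacks the edge tokens (or node feature rows, for the node-token variant)
#' of a list of graphs into a `B x L x d` array, padded with zero rows to the
#' maximum token count `L` over the batch. Real tokens are left-aligned;
#' padding is additionally excluded from attention via masks — zeroing alone
#' is never trusted.
#'
#' @param gs nonempty list of `esa_graph` objects sharing feature widths.
#' @param tokenizer `"edge"` (edge tokens) or `"node"` (node feature rows).
#' @return an `esa_token_batch` with fields `tokens` (`B x L x d` array),
#'   `pad` (`B x L` logical, `TRUE` = real token), `graph_map` (integer, for
#'   each real token in row-major batch order, the 1-based index of its source
#'   graph), `node_map` (for each node of the concatenated batch, its source
#'   graph), `counts`, `tokenizer` and `graphs`.
#' @export
batch_graphs <- function(gs, tokenizer = c("edge", "node")) {
  tokenizer <- match.arg(tokenizer)
  if (!is.list(gs) || length(gs) == 0L)
    stop("batch_graphs needs a nonempty list of graphs", call. = FALSE)
  stopifnot(all(vapply(gs, inherits, logical(1), "esa_graph")))
  dn <- vapply(gs, function(g) ncol(g$node_features), integer(1))
  de <- vapply(gs, function(g) ncol(g$edge_features), integer(1))
  if (length(unique(dn)) != 1L || length(unique(de)) != 1L)
    stop("batch-incompatible graphs: feature widths differ", call. = FALSE)

  mats <- if (tokenizer == "edge") {
    lapply(gs, function(g) build_edge_tokens(g)$tokens)
  } else {
    lapply(gs, function(g) g$node_features)
  }
  counts <- vapply(mats, nrow, integer(1))
  b <- length(gs)
  l <- max(1L, max(counts))          # keep L >= 1 so shapes stay well-formed
  d <- ncol(mats[[1L]])
  tokens <- array(0, dim = c(b, l, d))
  pad <- matrix(FALSE, b, l)
  for (i in seq_len(b)) {
    if (counts[i] > 0L) {
      tokens[i, seq_len(counts[i]), ] <- mats[[i]]
      pad[i, seq_len(counts[i])] <- TRUE
    }
  }
  node_map <- rep(seq_len(b), vapply(gs, n_nodes, integer(1)))
  structure(
    list(tokens = tokens, pad = pad,
         graph_map = rep(seq_len(b), counts),
         node_map = node_map, counts = counts,
         tokenizer = tokenizer, graphs = gs),
    class = "esa_token_batch"
  )
}

#' Recover per-graph token matrices from a batch
#'
#' Inverse of [batch_graphs()] on the token tensor: strips padding and
#' returns one token matrix per graph, in input order.
#'
#' @param batch an `esa_token_batch`.
#' @return list of matrices.
#' @export
unbatch_tokens <- function(batch) {
  stopifnot(inherits(batch, "esa_token_batch"))
  lapply(seq_along(batch$counts), function(i) {
    k <- batch$counts[i]
    m <- batch$tokens[i, seq_len(k), , drop = FALSE]
    matrix(m, nrow = k, ncol = dim(batch$tokens)[3L])
  })
}

#' Radius graph from 3D coordinates
#'
#' Connects every ordered pair of distinct points within `cutoff` Angstrom
#' (Euclidean). No self-loops; the output is symmetric as a directed relation
#' and lexicographically ordered by `(source, target)`.
#'
#' @param coords `N_n x 3` numeric matrix (Angstrom).
#' @param cutoff positive distance threshold (Angstrom).
#' @return 0-based integer edge-index matrix (`N_e x 2`).
#' @export
radius_graph <- function(coords, cutoff) {
  coords <- as_matrix(coords)
  stopifnot(ncol(coords) == 3L)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates", call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive scalar", call. = FALSE)
  d2 <- as.matrix(stats::dist(coords))^2
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  hit <- hit[hit[, 1L] != hit[, 2L], , drop = FALSE]
  ei <- cbind(hit[, 1L] - 1L, hit[, 2L] - 1L)
  ei <- ei[order(ei[, 1L], ei[, 2L]), , drop = FALSE]
  as_edge_index(ei)
}

#' Gaussian basis expansion of an interatomic distance
#'
#' Featurizes a scalar distance as `exp(-(dist - center_c)^2 / (2 width^2))`
#' over a grid of centers — the standard smooth distance encoding for 3D
#' atomic systems. Defaults put 128 evenly spaced centers on `[0, cutoff]`
#' with width equal to the center spacing.
#'
#' @param dist numeric vector of distances (Angstrom).
#' @param centers numeric vector of basis centers (Angstrom); nonempty.
#' @param width positive Gaussian width (Angstrom).
#' @return matrix `length(dist) x length(centers)` (a vector input of length
#'   one yields a one-row matrix).
#' @export
gaussian_basis_expansion <- function(dist, centers, width) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be a positive scalar", call. = FALSE)
  if (length(centers) == 0L) stop("centers must be nonempty", call. = FALSE)
  out <- exp(-outer(dist, centers, "-")^2 / (2 * width^2))
  dimnames(out) <- NULL
  out
}

#' Default Gaussian basis grid for a cutoff radius
#'
#' @param cutoff positive cutoff (Angstrom).
#' @param n_centers number of evenly spaced centers on `[0, cutoff]`.
#' @return list with `centers` and `width` (= center spacing).
#' @export
gaussian_basis_grid <- function(cutoff, n_centers = 128L) {
  stopifnot(cutoff > 0, n_centers >= 2L)
  centers <- seq(0, cutoff, length.out = n_centers)
  list(centers = centers, width = centers[2L] - centers[1L])
}

#' Read / write graphs as JSON lines
#'
#' One graph per line: an object with `node_features`, `edge_index`
#' (0-based), optional `edge_features`, optional `coords`, optional `y`.
#' This is the fixture format used by the synthetic-task CLI.
#'
#' @param gs list of `esa_graph` objects.
#' @param path file path.
#' @return `write_graphs_jsonl` returns `path` invisibly; `read_graphs_jsonl`
#'   returns a list of `esa_graph` objects.
#' @export
write_graphs_jsonl <- function(gs, path) {
  lines <- vapply(gs, function(g) {
    obj <- list(node_features = g$node_features,
                edge_index = g$edge_index)
    if (ncol(g$edge_features) > 0L) obj$edge_features <- g$edge_features
    if (!is.null(g$coords)) obj$coords <- g$coords
    if (!is.null(g$y)) obj$y <- g$y
    jsonlite::toJSON(obj, digits = NA, matrix = "rowmajor")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graphs_jsonl
#' @export
read_graphs_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    obj <- jsonlite::fromJSON(line, simplifyMatrix = TRUE)
    ei <- obj$edge_index
    if (is.null(ei) || length(ei) == 0L) ei <- matrix(integer(0), ncol = 2L)
    graph(as_matrix(obj$node_features), ei,
          edge_features = if (!is.null(obj$edge_features))
            as_matrix(obj$edge_features),
          coords = if (!is.null(obj$coords)) as_matrix(obj$coords),
          y = obj$y)
  })
}
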