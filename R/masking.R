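#' Attention masks
#'
#' An attention mask records which token pairs may attend to each other.
#' Boolean form holds `allowed` as a logical `L x L` matrix (single graph) or
#' `B x L x L` array (batch); additive form holds `0` for allowed pairs and a
#' large finite negative value for censored pairs, ready to be added to the
#' pre-softmax attention scores. The additive value is finite (not `-Inf`) so
#' that a fully censored row — e.g. a padded query — still softmaxes to a
#' finite (uniform) distribution instead of NaN.
#'
#' @param allowed logical matrix or 3D array.
#' @param form `"boolean"` or `"additive"`.
#' @param additive_value negative scalar used for censored pairs in additive
#'   form.
#' @return an `esa_mask` object.
#' @export
attention_mask <- function(allowed, form = "boolean",
                           additive_value = esa_neg_value()) {
  structure(list(allowed = allowed, form = form,
                 additive_value = additive_value),
            class = "esa_mask")
}

#' Default additive mask magnitude
#'
#' Half of the most negative representable double: large enough that
#' `exp(score + value - max)` underflows to exactly zero for censored pairs
#' whenever at least one pair in the row is allowed, yet finite so all-censored
#' rows stay NaN-free.
#' @return negative scalar.
#' @export
esa_neg_value <- function() -.Machine$double.xmax / 2

#' Edge-adjacency mask of a single graph
#'
#' Two directed edges may attend to each other iff they share at least one
#' endpoint: `src_a == src_b`, `tgt_a == tgt_b`, `src_a == tgt_b` or
#' `tgt_a == src_b`. Built with vectorized outer comparisons over the source
#' and target id vectors; the diagonal is always allowed (every edge shares
#' both endpoints with itself). Off the diagonal this is exactly the adjacency
#' matrix of the line graph of the input.
#'
#' @param edge_index 0-based integer edge list (`N_e x 2`); an `esa_graph` is
#'   also accepted.
#' @return boolean `esa_mask` of shape `N_e x N_e` (0 x 0 for an edgeless
#'   graph).
#' @export
edge_adjacency_single <- function(edge_index) {
  if (inherits(edge_index, "esa_graph")) edge_index <- edge_index$edge_index
  ei <- as_edge_index(edge_index)
  src <- ei[, 1L]
  tgt <- ei[, 2L]
  allowed <- outer(src, src, "==") | outer(tgt, tgt, "==") |
    outer(src, tgt, "==") | outer(tgt, src, "==")
  attention_mask(allowed)
}

#' Batched edge-adjacency mask
#'
#' Builds the `B x L x L` boolean mask for a batch of graphs from the
#' concatenated edge list and the node-to-graph map, reproducing
#' [edge_adjacency_single()] per graph in token order. Entries touching
#' padded positions are disallowed and no adjacency crosses graphs.
#'
#' @param edge_index_concat edge list over the concatenated node numbering
#'   (0-based), or an `esa_token_batch` built with the edge tokenizer.
#' @param node_map integer vector mapping each node of the concatenated batch
#'   to its (1-based) graph index; nondecreasing.
#' @param L padded token count (max edges over the batch, at least 1).
#' @return boolean `esa_mask` of shape `B x L x L`.
#' @export
edge_adjacency_batched <- function(edge_index_concat, node_map = NULL,
                                   L = NULL) {
  if (inherits(edge_index_concat, "esa_token_batch")) {
    batch <- edge_index_concat
    stopifnot(batch$tokenizer == "edge")
    offs <- c(0L, cumsum(vapply(batch$graphs, n_nodes, integer(1))))
    eis <- lapply(seq_along(batch$graphs), function(i)
      batch$graphs[[i]]$edge_index + offs[i])
    edge_index_concat <- do.call(rbind, eis)
    node_map <- batch$node_map
    L <- dim(batch$tokens)[2L]
  }
  ei <- as_edge_index(edge_index_concat)
  stopifnot(!is.null(node_map), !is.null(L))
  b <- max(node_map, 1L)
  allowed <- array(FALSE, dim = c(b, L, L))
  if (nrow(ei) > 0L) {
    egraph <- node_map[ei[, 1L] + 1L]            # graph of each edge
    if (any(egraph != node_map[ei[, 2L] + 1L]))
      stop("corrupt batch: edge spans two graphs", call. = FALSE)
    for (g in seq_len(b)) {
      rows <- which(egraph == g)
      if (length(rows) == 0L) next
      if (length(rows) > L)
        stop("corrupt batch: more edges than padded length L", call. = FALSE)
      m <- edge_adjacency_single(ei[rows, , drop = FALSE])$allowed
      allowed[g, seq_along(rows), seq_along(rows)] <- m
    }
  }
  attention_mask(allowed)
}

#' Batched node-adjacency mask
#'
#' Entry `(i, j)` of slice `b` is `TRUE` iff nodes `i` and `j` of graph `b`
#' are linked by a directed edge in either direction, or `i == j`
#' (self-attention is always allowed for real tokens). Padded positions are
#' disallowed.
#'
#' @inheritParams edge_adjacency_batched
#' @param L padded node count; defaults to the maximum node count.
#' @return boolean `esa_mask` of shape `B x N_max x N_max`.
#' @export
node_adjacency_batched <- function(edge_index_concat, node_map = NULL,
                                   L = NULL) {
  if (inherits(edge_index_concat, "esa_token_batch")) {
    batch <- edge_index_concat
    stopifnot(batch$tokenizer == "node")
    offs <- c(0L, cumsum(vapply(batch$graphs, n_nodes, integer(1))))
    eis <- lapply(seq_along(batch$graphs), function(i)
      batch$graphs[[i]]$edge_index + offs[i])
    edge_index_concat <- do.call(rbind, eis)
    node_map <- batch$node_map
    L <- dim(batch$tokens)[2L]
  }
  ei <- as_edge_index(edge_index_concat)
  stopifnot(!is.null(node_map))
  counts <- tabulate(node_map)
  b <- length(counts)
  if (is.null(L)) L <- max(1L, counts)
  allowed <- array(FALSE, dim = c(b, L, L))
  offs <- c(0L, cumsum(counts))
  if (nrow(ei) > 0L) {
    egraph <- node_map[ei[, 1L] + 1L]
    if (any(egraph != node_map[ei[, 2L] + 1L]))
      stop("corrupt batch: edge spans two graphs", call. = FALSE)
  }
  for (g in seq_len(b)) {
    n <- counts[g]
    if (n == 0L) next
    a <- diag(TRUE, n)
    if (nrow(ei) > 0L) {
      rows <- which(node_map[ei[, 1L] + 1L] == g)
      if (length(rows) > 0L) {
        loc <- ei[rows, , drop = FALSE] - offs[g]
        a[loc + 1L] <- TRUE
        a[loc[, c(2L, 1L), drop = FALSE] + 1L] <- TRUE
      }
    }
    allowed[g, seq_len(n), seq_len(n)] <- a
  }
  attention_mask(allowed)
}

#' Convert a boolean mask to additive form
#'
#' Allowed pairs map to `0`, censored pairs to the large finite negative
#' `additive_value`, so the result can be added to pre-softmax scores.
#' Converting an already-additive mask is an error (idempotency guard).
#'
#' @param m a boolean `esa_mask`.
#' @param additive_value negative scalar for censored pairs.
#' @return additive `esa_mask` of the same shape.
#' @export
to_additive <- function(m, additive_value = esa_neg_value()) {
  stopifnot(inherits(m, "esa_mask"))
  if (m$form != "boolean")
    stop("mask is already in additive form", call. = FALSE)
  add <- array(additive_value, dim = dim(m$allowed))
  add[m$allowed] <- 0
  attention_mask(add, form = "additive", additive_value = additive_value)
}

# Additive padding-only mask rows for one batch element: a 1 x L row vector
# censoring padded key positions (broadcast over queries by the attention code).
pad_key_mask <- function(pad_row, additive_value = esa_neg_value()) {
  v <- rep(0, length(pad_row))
  v[!pad_row] <- additive_value
  v
}
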