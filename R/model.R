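#' Parse an interleaving configuration string
#'
#' The vertical layout of the model is a string over the alphabet `{M, S, P}`:
#' `M` a masked attention block, `S` a self-attention block, `P` the pooling
#' (PMA) module. Graph-level tasks contain exactly one `P`; the `S` blocks
#' after `P` become the PMA's internal SABs (their count is `p`). Node-level
#' tasks use the whole string as the encoder and admit no `P`.
#'
#' @param layer_string string over `{M, S, P}`; whitespace ignored.
#' @param task one of `"graph_regression"`, `"graph_classification"`,
#'   `"node_classification"`.
#' @return list with `encoder` (character vector of `"M"`/`"S"`), `use_pma`
#'   (logical) and `p` (number of post-pooling SABs).
#' @export
parse_config <- function(layer_string,
                         task = c("graph_regression", "graph_classification",
                                  "node_classification")) {
  task <- match.arg(task)
  chars <- strsplit(gsub("\\s", "", layer_string), "")[[1L]]
  if (length(chars) == 0L)
    stop("config error: empty layer string", call. = FALSE)
  if (!all(chars %in% c("M", "S", "P")))
    stop("config error: unknown character in layer string", call. = FALSE)
  npma <- sum(chars == "P")
  node_task <- task == "node_classification"
  if (node_task) {
    if (npma > 0L)
      stop("config error: P not allowed in a node-level task", call. = FALSE)
    return(list(encoder = chars, use_pma = FALSE, p = 0L))
  }
  if (npma != 1L)
    stop("config error: graph-level tasks need exactly one P", call. = FALSE)
  pos <- which(chars == "P")
  after <- chars[seq_along(chars) > pos]
  if (any(after != "S"))
    stop("config error: only S blocks may follow P", call. = FALSE)
  list(encoder = chars[seq_len(pos - 1L)], use_pma = TRUE,
       p = length(after))
}

#' Model configuration
#'
#' Collects the architecture hyperparameters: the `{M,S,P}` layer string,
#' widths, head count, number of pooling seeds `k`, normalization and MLP
#' choices, dropout and the task type.
#'
#' @param layer_string interleaving string, see [parse_config()].
#' @param task task type; decides the loss and output head.
#' @param hidden_dim width `d` of every block; must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param k number of learnable PMA seed vectors (graph tasks).
#' @param out_dim output width (1 for scalar regression, class count for
#'   classification; 1 for binary classification with a logit output).
#' @param norm_kind `"layer"` or `"batch"` normalization.
#' @param norm_placement `"pre"` or `"post"` norm residual blocks.
#' @param mlp_variant `"standard"` (2-layer GELU, expansion 2) or `"gated"`
#'   (GEGLU).
#' @param dropout single rate applied to attention weights and MLP outputs
#'   during training.
#' @param token_mode `"edge"` (edge tokens; default for graph tasks) or
#'   `"node"` (node tokens; forced for node tasks).
#' @param pool `"mean"` or `"sum"` aggregation over the k seed outputs.
#' @return an `esa_config` object.
#' @export
esa_config <- function(layer_string,
                       task = c("graph_regression", "graph_classification",
                                "node_classification"),
                       hidden_dim = 64L, heads = 4L, k = 32L, out_dim = 1L,
                       norm_kind = c("layer", "batch"),
                       norm_placement = c("pre", "post"),
                       mlp_variant = c("standard", "gated"),
                       dropout = 0, token_mode = NULL,
                       pool = c("mean", "sum")) {
  task <- match.arg(task)
  norm_kind <- match.arg(norm_kind)
  norm_placement <- match.arg(norm_placement)
  mlp_variant <- match.arg(mlp_variant)
  pool <- match.arg(pool)
  if (hidden_dim %% heads != 0L)
    stop("config error: hidden_dim must be divisible by heads", call. = FALSE)
  plan <- parse_config(layer_string, task)
  node_task <- task == "node_classification"
  if (is.null(token_mode)) token_mode <- if (node_task) "node" else "edge"
  if (node_task && token_mode != "node")
    stop("config error: node tasks use node tokens", call. = FALSE)
  structure(list(layer_string = layer_string, task = task,
                 hidden_dim = as.integer(hidden_dim),
                 heads = as.integer(heads), k = as.integer(k),
                 out_dim = as.integer(out_dim), norm_kind = norm_kind,
                 norm_placement = norm_placement, mlp_variant = mlp_variant,
                 dropout = dropout, token_mode = token_mode, pool = pool,
                 plan = plan),
            class = "esa_config")
}

#' Build an (untrained) ESA / NSA model
#'
#' Instantiates all parameters for the configured stack: the input embedding
#' (token width to `hidden_dim`), the interleaved encoder blocks, the PMA
#' pooling module (graph tasks) and a 2-layer MLP output head. Seeds and
#' weights are drawn from scaled normals; pass `seed` for reproducibility.
#'
#' @param config an [esa_config()].
#' @param in_dim input token width: `2 d_n + d_e` for edge tokens, `d_n` for
#'   node tokens.
#' @param seed optional integer RNG seed for initialization.
#' @return an `esa_model` object.
#' @export
esa_model <- function(config, in_dim, seed = NULL) {
  stopifnot(inherits(config, "esa_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$hidden_dim
  params <- list(
    embed = linear_init(in_dim, d),
    blocks = lapply(config$plan$encoder, function(type)
      mab_init(d, config$mlp_variant, config$norm_kind)),
    pma = if (config$plan$use_pma)
      pma_init(d, config$k, config$plan$p, config$mlp_variant,
               config$norm_kind),
    head = list(fc1 = linear_init(d, d), fc2 = linear_init(d, config$out_dim))
  )
  structure(list(config = config, params = params, in_dim = as.integer(in_dim)),
            class = "esa_model")
}

#' @export
print.esa_model <- function(x, ...) {
  cat(sprintf("<esa_model> '%s' (%s), d=%d h=%d k=%d, %s tokens, %d parameters\n",
              x$config$layer_string, x$config$task, x$config$hidden_dim,
              x$config$heads, x$config$k, x$config$token_mode,
              n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `esa_model`.
#' @return integer.
#' @export
n_parameters <- function(model) param_count(model$params)

# --- batched forward / backward --------------------------------------------

flat_tokens <- function(tk) {
  b <- dim(tk)[1L]; l <- dim(tk)[2L]; d <- dim(tk)[3L]
  matrix(aperm(tk, c(2L, 1L, 3L)), nrow = b * l, ncol = d)
}

# additive masks per graph for one batch: list over b, NULL entries mean
# "padding only" handled via `padmasks`
prepare_masks <- function(batch, config) {
  madd <- NULL
  if (any(config$plan$encoder == "M")) {
    bool <- if (config$token_mode == "edge") edge_adjacency_batched(batch)
    else node_adjacency_batched(batch)
    madd <- to_additive(bool)$allowed
  }
  padmasks <- lapply(seq_len(nrow(batch$pad)), function(b)
    pad_key_mask(batch$pad[b, ]))
  list(adj = madd, pad = padmasks)
}

# one encoder block over the flat token matrix; attention looped per graph
block_fwd <- function(x, type, masks, padflat, bsz, l, p, config,
                      training = FALSE, record = FALSE) {
  h <- config$heads
  placement <- config$norm_placement
  dropout <- config$dropout
  rows <- which(padflat)
  pre <- placement == "pre"
  if (pre) {
    n1 <- norm_fwd(x, p$norm1, rows = rows, training = training)
    src <- n1$out
  } else {
    n1 <- NULL
    src <- x
  }
  mhout <- matrix(0, nrow(x), ncol(x))
  att_caches <- vector("list", bsz)
  scores <- if (record) vector("list", bsz)
  for (b in seq_len(bsz)) {
    idx <- ((b - 1L) * l + 1L):(b * l)
    mask_b <- if (type == "M") masks$adj[b, , ] else masks$pad[[b]]
    mh <- multihead_fwd(src[idx, , drop = FALSE], src[idx, , drop = FALSE],
                        mask_b, p$att, h, dropout, training, record)
    mhout[idx, ] <- mh$out
    att_caches[[b]] <- mh$cache
    if (record) scores[[b]] <- mh$scores
  }
  mhout[!padflat, ] <- 0
  if (pre) {
    hmat <- n1$out + mhout       # residual from the normalized input
    hmat[!padflat, ] <- 0
    n2 <- norm_fwd(hmat, p$norm2, rows = rows, training = training)
    ml <- mlp_fwd(n2$out, p$mlp)
    mlo <- ml$out
    drop2 <- NULL
    if (training && dropout > 0) {
      drop2 <- matrix(stats::rbinom(length(mlo), 1L, 1 - dropout),
                      nrow(mlo), ncol(mlo)) / (1 - dropout)
      mlo <- mlo * drop2
    }
    out <- hmat + mlo
    out[!padflat, ] <- 0
    list(out = out, scores = scores,
         cache = list(pre = TRUE, n1 = n1, att_caches = att_caches, n2 = n2,
                      ml = ml, drop2 = drop2, padflat = padflat, bsz = bsz,
                      l = l, type = type))
  } else {
    n1 <- norm_fwd(x + mhout, p$norm1, rows = rows, training = training)
    ml <- mlp_fwd(n1$out, p$mlp)
    mlo <- ml$out
    drop2 <- NULL
    if (training && dropout > 0) {
      drop2 <- matrix(stats::rbinom(length(mlo), 1L, 1 - dropout),
                      nrow(mlo), ncol(mlo)) / (1 - dropout)
      mlo <- mlo * drop2
    }
    n2 <- norm_fwd(n1$out + mlo, p$norm2, rows = rows, training = training)
    out <- n2$out
    out[!padflat, ] <- 0
    list(out = out, scores = scores,
         cache = list(pre = FALSE, n1 = n1, att_caches = att_caches, n2 = n2,
                      ml = ml, drop2 = drop2, padflat = padflat, bsz = bsz,
                      l = l, type = type))
  }
}

block_bwd <- function(dout, cache, p, config) {
  padflat <- cache$padflat
  dout[!padflat, ] <- 0
  att_bwd_all <- function(dmh) {
    dmh[!padflat, ] <- 0
    dsrc <- matrix(0, nrow(dmh), ncol(dmh))
    gatt <- NULL
    for (b in seq_len(cache$bsz)) {
      idx <- ((b - 1L) * cache$l + 1L):(b * cache$l)
      bb <- multihead_bwd(dmh[idx, , drop = FALSE], cache$att_caches[[b]],
                          p$att)
      dsrc[idx, ] <- bb$dxq + bb$dxkv
      gatt <- add_grads(gatt, bb$grads)
    }
    list(dsrc = dsrc, gatt = gatt)
  }
  if (cache$pre) {
    dml <- if (is.null(cache$drop2)) dout else dout * cache$drop2
    bm <- mlp_bwd(dml, cache$ml$cache, p$mlp)
    bn2 <- norm_bwd(bm$dx, cache$n2$cache, p$norm2)
    dh <- dout + bn2$dx
    dh[!padflat, ] <- 0
    ab <- att_bwd_all(dh)
    bn1 <- norm_bwd(dh + ab$dsrc, cache$n1$cache, p$norm1)
    dx <- bn1$dx
    dx[!padflat, ] <- 0
    list(dx = dx, grads = list(norm1 = bn1$grads, norm2 = bn2$grads,
                               att = ab$gatt, mlp = bm$grads))
  } else {
    bn2 <- norm_bwd(dout, cache$n2$cache, p$norm2)
    dml <- if (is.null(cache$drop2)) bn2$dx else bn2$dx * cache$drop2
    bm <- mlp_bwd(dml, cache$ml$cache, p$mlp)
    dn1out <- bn2$dx + bm$dx
    bn1 <- norm_bwd(dn1out, cache$n1$cache, p$norm1)
    ab <- att_bwd_all(bn1$dx)
    dx <- bn1$dx + ab$dsrc
    dx[!padflat, ] <- 0
    list(dx = dx, grads = list(norm1 = bn1$grads, norm2 = bn2$grads,
                               att = ab$gatt, mlp = bm$grads))
  }
}

# full forward over a list of graphs; returns predictions and (optionally)
# the cache needed for the backward pass and recorded attention scores
forward_batch <- function(model, gs, training = FALSE, record = FALSE,
                          keep_cache = FALSE) {
  config <- model$config
  p <- model$params
  batch <- batch_graphs(gs, tokenizer = config$token_mode)
  bsz <- dim(batch$tokens)[1L]
  l <- dim(batch$tokens)[2L]
  x0 <- flat_tokens(batch$tokens)
  padflat <- as.vector(t(batch$pad))
  masks <- prepare_masks(batch, config)

  femb <- linear_fwd(x0, p$embed)
  xemb <- femb$out
  xemb[!padflat, ] <- 0

  x <- xemb
  block_caches <- vector("list", length(config$plan$encoder))
  rec_layers <- if (record) list()
  for (i in seq_along(config$plan$encoder)) {
    r <- block_fwd(x, config$plan$encoder[i], masks, padflat, bsz, l,
                   p$blocks[[i]], config, training, record)
    block_caches[[i]] <- r$cache
    if (record) rec_layers[[i]] <- r$scores
    x <- r$out
  }

  if (config$plan$use_pma) {
    xr <- x + xemb                       # Z_out = PMA(Encoder(X, M) + X)
    pooled <- matrix(0, bsz, config$hidden_dim)
    pma_caches <- vector("list", bsz)
    rec_pma <- if (record) vector("list", bsz)
    for (b in seq_len(bsz)) {
      idx <- ((b - 1L) * l + 1L):(b * l)
      r <- pma_fwd_one(xr[idx, , drop = FALSE], batch$pad[b, ], p$pma,
                       config$heads, config$norm_placement, config$dropout,
                       training, record)
      pma_caches[[b]] <- r$cache
      if (record) rec_pma[[b]] <- r$scores
      pooled[b, ] <- pool_seeds(r$out, config$pool)
    }
    f1 <- linear_fwd(pooled, p$head$fc1)
    hac <- gelu(f1$out)
    f2 <- linear_fwd(hac, p$head$fc2)
    pred <- f2$out
    cache <- if (keep_cache)
      list(batch = batch, x0 = x0, padflat = padflat, femb = femb,
           block_caches = block_caches, pma_caches = pma_caches,
           f1 = f1, f2 = f2, bsz = bsz, l = l)
    list(pred = pred, cache = cache, batch = batch,
         scores = if (record) list(encoder = rec_layers, pma = rec_pma))
  } else {
    f1 <- linear_fwd(x, p$head$fc1)
    hac <- gelu(f1$out)
    f2 <- linear_fwd(hac, p$head$fc2)
    pred_flat <- f2$out
    pred <- pred_flat[padflat, , drop = FALSE]
    cache <- if (keep_cache)
      list(batch = batch, x0 = x0, padflat = padflat, femb = femb,
           block_caches = block_caches, f1 = f1, f2 = f2, bsz = bsz, l = l)
    list(pred = pred, cache = cache, batch = batch,
         scores = if (record) list(encoder = rec_layers))
  }
}

backward_batch <- function(model, cache, dpred) {
  config <- model$config
  p <- model$params
  padflat <- cache$padflat
  grads <- list(embed = NULL, blocks = vector("list", length(p$blocks)),
                pma = NULL, head = NULL)

  if (config$plan$use_pma) {
    dhac <- dpred %*% t(p$head$fc2$W)
    g_fc2 <- list(W = crossprod(gelu(cache$f1$out), dpred),
                  b = colSums(dpred))
    df1 <- dhac * gelu_grad(cache$f1$out)
    b1 <- linear_bwd(df1, cache$f1$cache, p$head$fc1)
    grads$head <- list(fc1 = b1$grads, fc2 = g_fc2)
    dpooled <- b1$dx

    k <- nrow(p$pma$seeds)
    dxr <- matrix(0, cache$bsz * cache$l, config$hidden_dim)
    gp <- NULL
    for (b in seq_len(cache$bsz)) {
      du <- matrix(rep(dpooled[b, ], each = k), k, config$hidden_dim)
      if (config$pool == "mean") du <- du / k
      bb <- pma_bwd_one(du, cache$pma_caches[[b]], p$pma, config$heads)
      gp <- add_grads(gp, bb$grads)
      if (!is.null(bb$dz)) {
        idx <- ((b - 1L) * cache$l + 1L):(b * cache$l)
        dxr[idx, ] <- bb$dz
      }
    }
    grads$pma <- gp
    dxr[!padflat, ] <- 0
    dx <- dxr               # into last encoder block
    demb_extra <- dxr       # residual path into the embedding
  } else {
    dpred_flat <- matrix(0, cache$bsz * cache$l, config$out_dim)
    dpred_flat[padflat, ] <- dpred
    dhac <- dpred_flat %*% t(p$head$fc2$W)
    g_fc2 <- list(W = crossprod(gelu(cache$f1$out), dpred_flat),
                  b = colSums(dpred_flat))
    df1 <- dhac * gelu_grad(cache$f1$out)
    b1 <- linear_bwd(df1, cache$f1$cache, p$head$fc1)
    grads$head <- list(fc1 = b1$grads, fc2 = g_fc2)
    dx <- b1$dx
    dx[!padflat, ] <- 0
    demb_extra <- NULL
  }

  for (i in rev(seq_along(p$blocks))) {
    bb <- block_bwd(dx, cache$block_caches[[i]], p$blocks[[i]], config)
    grads$blocks[[i]] <- bb$grads
    dx <- bb$dx
  }
  demb <- if (is.null(demb_extra)) dx else dx + demb_extra
  demb[!padflat, ] <- 0
  be <- linear_bwd(demb, cache$femb$cache, p$embed)
  grads$embed <- be$grads
  grads
}

#' Graph-level forward pass
#'
#' Runs the full pipeline on a batch of graphs: edge tokens, input embedding,
#' interleaved encoder, an input residual into the pooling stage
#' (`PMA(Encoder(X, M) + X)`, with the residual taken in embedding space),
#' PMA, seed pooling and the output head. One prediction row per graph, in
#' input order. Regression returns values; classification returns logits.
#'
#' @param gs list of `esa_graph` (or a single graph).
#' @param model an `esa_model` with a graph-level task config.
#' @return numeric matrix `B x out_dim`.
#' @export
esa_forward <- function(gs, model) {
  stopifnot(inherits(model, "esa_model"))
  if (inherits(gs, "esa_graph")) gs <- list(gs)
  if (!model$config$plan$use_pma)
    stop("model is configured for a node-level task; use nsa_forward()",
         call. = FALSE)
  forward_batch(model, gs)$pred
}

#' Node-level forward pass
#'
#' Node-set attention: node feature rows are the tokens, the mask is the
#' (batched) node adjacency, and there is no pooling block. Predictions are
#' per node, ordered by graph then by node id.
#'
#' @param gs list of `esa_graph` (or a single graph).
#' @param model an `esa_model` with a node-level task config.
#' @return numeric matrix with one row per node of the batch.
#' @export
nsa_forward <- function(gs, model) {
  stopifnot(inherits(model, "esa_model"))
  if (inherits(gs, "esa_graph")) gs <- list(gs)
  if (model$config$plan$use_pma)
    stop("model is configured for a graph-level task; use esa_forward()",
         call. = FALSE)
  forward_batch(model, gs)$pred
}

#' Encoder-only forward on a prepared token batch
#'
#' Applies the interleaved encoder blocks to an already-built token batch:
#' `M` blocks receive the adjacency mask, `S` blocks the padding-only mask.
#' Output shape equals input shape. Mostly useful for testing and analysis;
#' the end-to-end entry points are [esa_forward()] and [nsa_forward()].
#'
#' @param batch an `esa_token_batch` whose token width equals the model's
#'   `in_dim`.
#' @param model an `esa_model`.
#' @return `B x L x hidden_dim` array of token representations (embedded,
#'   then encoded; padded rows zero).
#' @export
encoder_forward <- function(batch, model) {
  stopifnot(inherits(batch, "esa_token_batch"), inherits(model, "esa_model"))
  config <- model$config
  stopifnot(batch$tokenizer == config$token_mode)
  p <- model$params
  bsz <- dim(batch$tokens)[1L]
  l <- dim(batch$tokens)[2L]
  x0 <- flat_tokens(batch$tokens)
  padflat <- as.vector(t(batch$pad))
  masks <- prepare_masks(batch, config)
  x <- linear_fwd(x0, p$embed)$out
  x[!padflat, ] <- 0
  for (i in seq_along(config$plan$encoder)) {
    x <- block_fwd(x, config$plan$encoder[i], masks, padflat, bsz, l,
                   p$blocks[[i]], config)$out
  }
  out <- array(0, dim = c(bsz, l, config$hidden_dim))
  for (b in seq_len(bsz))
    out[b, , ] <- x[((b - 1L) * l + 1L):(b * l), , drop = FALSE]
  out
}

# --- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding every parameter array plus
#' the model configuration, so it is portable and diff-able. Batch-norm
#' running statistics are included.
#'
#' @param model an `esa_model`.
#' @param path file path (`.json`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `esa_model`.
#' @export
save_checkpoint <- function(model, path) {
  ser <- function(x) {
    if (is.environment(x))
      list(.bn_state = TRUE, mean = x$mean, var = x$var,
           momentum = x$momentum)
    else if (is.list(x)) lapply(x, ser)
    else x
  }
  cfg <- unclass(model$config)
  cfg$plan <- NULL
  obj <- list(config = cfg, in_dim = model$in_dim,
              params = ser(model$params))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  cfg <- do.call(esa_config, obj$config[setdiff(names(obj$config),
                                                c("plan"))])
  model <- esa_model(cfg, in_dim = obj$in_dim)
  de <- function(tpl, x) {
    if (is.environment(tpl)) {
      tpl$mean <- as.numeric(x$mean); tpl$var <- as.numeric(x$var)
      tpl$momentum <- as.numeric(x$momentum)
      return(tpl)
    }
    if (is.list(tpl)) {
      keys <- names(tpl)
      for (i in seq_along(tpl)) {
        xi <- if (!is.null(keys) && nzchar(keys[i])) x[[keys[i]]]
        else x[[i]]
        tpl[i] <- list(de(tpl[[i]], xi))
      }
      return(tpl)
    }
    if (is.character(tpl)) return(x)
    if (is.matrix(tpl)) {
      m <- if (is.matrix(x)) x
      else matrix(as.numeric(unlist(x)), nrow(tpl), ncol(tpl), byrow = TRUE)
      storage.mode(m) <- "double"
      dimnames(m) <- NULL
      return(m)
    }
    as.numeric(unlist(x))
  }
  model$params <- de(model$params, obj$params)
  model
}
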