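#' Masked scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k) + M) V` exactly (dense). `M` is an
#' additive mask: `0` leaves an attention score unchanged, a large negative
#' value censors the pair. With the finite default censoring value an
#' all-censored query row softmaxes to a uniform, finite distribution.
#'
#' @param Q,K,V numeric matrices: `L_q x d_k`, `L_k x d_k`, `L_k x d_v`.
#' @param M additive mask, broadcastable to `L_q x L_k`: a matrix, a length
#'   `L_k` vector (same censoring for every query), a scalar, or `NULL`
#'   (no mask).
#' @param return_scores also return the post-softmax attention matrix.
#' @return the `L_q x d_v` output matrix; if `return_scores`, a list with
#'   `out` and `scores`.
#' @export
masked_sdpa <- function(Q, K, V, M = NULL, return_scores = FALSE) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  s <- Q %*% t(K) / sqrt(ncol(Q))
  if (!is.null(M)) {
    if (is.matrix(M)) {
      stopifnot(nrow(M) == nrow(s), ncol(M) == ncol(s))
      s <- s + M
    } else if (length(M) == ncol(s)) {
      s <- sweep(s, 2L, M, "+")
    } else if (length(M) == 1L) {
      s <- s + M
    } else stop("mask not broadcastable to the score matrix", call. = FALSE)
  }
  a <- softmax_rows(s)
  out <- a %*% V
  if (return_scores) list(out = out, scores = a) else out
}

# ---------------------------------------------------------------------------
# Multi-head attention with parameters. `mask` is NULL, a length-L_k additive
# vector (padding-only; broadcast over queries), or an L_q x L_k additive
# matrix. Heads are column slices of the d-wide projections (d = h * d_k).

multihead_init <- function(d) {
  list(Wq = linear_init(d, d), Wk = linear_init(d, d),
       Wv = linear_init(d, d), Wo = linear_init(d, d))
}

multihead_fwd <- function(xq, xkv, mask, p, h, dropout = 0,
                          training = FALSE, record = FALSE) {
  d <- ncol(p$Wq$W)
  stopifnot(d %% h == 0L)
  dk <- d %/% h
  fq <- linear_fwd(xq, p$Wq); fk <- linear_fwd(xkv, p$Wk)
  fv <- linear_fwd(xkv, p$Wv)
  lq <- nrow(xq); lk <- nrow(xkv)
  concat <- matrix(0, lq, d)
  heads <- vector("list", h)
  madd <- NULL
  if (!is.null(mask)) {
    madd <- if (is.matrix(mask)) mask
    else matrix(mask, lq, lk, byrow = TRUE)
  }
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    qh <- fq$out[, cols, drop = FALSE]
    kh <- fk$out[, cols, drop = FALSE]
    vh <- fv$out[, cols, drop = FALSE]
    s <- qh %*% t(kh) / sqrt(dk)
    if (!is.null(madd)) s <- s + madd
    a <- softmax_rows(s)
    drop_mask <- NULL
    if (training && dropout > 0) {
      drop_mask <- matrix(stats::rbinom(lq * lk, 1L, 1 - dropout), lq, lk) /
        (1 - dropout)
      a_used <- a * drop_mask
    } else a_used <- a
    concat[, cols] <- a_used %*% vh
    heads[[i]] <- list(a = a, a_used = a_used, drop_mask = drop_mask,
                       qh = qh, kh = kh, vh = vh, cols = cols)
  }
  fo <- linear_fwd(concat, p$Wo)
  cache <- list(fq = fq, fk = fk, fv = fv, fo = fo, heads = heads,
                concat = concat, h = h, dk = dk)
  scores <- if (record) {
    arr <- array(0, dim = c(h, lq, lk))
    for (i in seq_len(h)) arr[i, , ] <- heads[[i]]$a
    arr
  }
  list(out = fo$out, cache = cache, scores = scores)
}

multihead_bwd <- function(dout, cache, p) {
  bo <- linear_bwd(dout, cache$fo$cache, p$Wo)
  dconcat <- bo$dx
  dk <- cache$dk
  dq <- matrix(0, nrow(dconcat), ncol(p$Wq$W))
  dkm <- matrix(0, nrow(cache$fk$out), ncol(p$Wk$W))
  dv <- matrix(0, nrow(cache$fv$out), ncol(p$Wv$W))
  for (hd in cache$heads) {
    cols <- hd$cols
    doh <- dconcat[, cols, drop = FALSE]
    da_used <- doh %*% t(hd$vh)
    dv[, cols] <- crossprod(hd$a_used, doh)
    da <- if (is.null(hd$drop_mask)) da_used else da_used * hd$drop_mask
    ds <- hd$a * (da - rowSums(da * hd$a))
    dq[, cols] <- ds %*% hd$kh / sqrt(dk)
    dkm[, cols] <- crossprod(ds, hd$qh) / sqrt(dk)
  }
  bq <- linear_bwd(dq, cache$fq$cache, p$Wq)
  bk <- linear_bwd(dkm, cache$fk$cache, p$Wk)
  bv <- linear_bwd(dv, cache$fv$cache, p$Wv)
  list(dxq = bq$dx, dxkv = bk$dx + bv$dx,
       grads = list(Wq = bq$grads, Wk = bk$grads, Wv = bv$grads,
                    Wo = bo$grads))
}

# ---------------------------------------------------------------------------
# MAB: the masked pre/post-norm residual transformer block.
#   pre-LN : Xb = Norm(X); H = X + MultiHead(Xb, Xb, Xb, M);
#            out = H + MLP(Norm(H))
#   post-LN: H = Norm(X + MultiHead(X, X, X, M)); out = Norm(H + MLP(H))
# A SAB is a MAB whose mask censors nothing beyond padding.

mab_init <- function(d, mlp_variant = "standard", norm_kind = "layer") {
  list(norm1 = norm_init(d, norm_kind), norm2 = norm_init(d, norm_kind),
       att = multihead_init(d), mlp = mlp_init(d, mlp_variant))
}

# x: L x d matrix for one set of tokens; mask as in multihead_fwd.
mab_fwd <- function(x, mask, p, h, placement = "pre", dropout = 0,
                    training = FALSE, record = FALSE, rows = NULL) {
  if (placement == "pre") {
    n1 <- norm_fwd(x, p$norm1, rows = rows, training = training)
    mh <- multihead_fwd(n1$out, n1$out, mask, p$att, h, dropout, training,
                        record)
    hmat <- n1$out + mh$out        # residual from the *normalized* input
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
    list(out = out, scores = mh$scores,
         cache = list(placement = "pre", n1 = n1, mh = mh, n2 = n2, ml = ml,
                      drop2 = drop2))
  } else {
    mh <- multihead_fwd(x, x, mask, p$att, h, dropout, training, record)
    n1 <- norm_fwd(x + mh$out, p$norm1, rows = rows, training = training)
    ml <- mlp_fwd(n1$out, p$mlp)
    mlo <- ml$out
    drop2 <- NULL
    if (training && dropout > 0) {
      drop2 <- matrix(stats::rbinom(length(mlo), 1L, 1 - dropout),
                      nrow(mlo), ncol(mlo)) / (1 - dropout)
      mlo <- mlo * drop2
    }
    n2 <- norm_fwd(n1$out + mlo, p$norm2, rows = rows, training = training)
    list(out = n2$out, scores = mh$scores,
         cache = list(placement = "post", n1 = n1, mh = mh, n2 = n2, ml = ml,
                      drop2 = drop2))
  }
}

mab_bwd <- function(dout, cache, p) {
  if (cache$placement == "pre") {
    dml <- if (is.null(cache$drop2)) dout else dout * cache$drop2
    bm <- mlp_bwd(dml, cache$ml$cache, p$mlp)
    bn2 <- norm_bwd(bm$dx, cache$n2$cache, p$norm2)
    dh <- dout + bn2$dx
    bmh <- multihead_bwd(dh, cache$mh$cache, p$att)
    dn1 <- dh + bmh$dxq + bmh$dxkv   # residual + attention paths
    bn1 <- norm_bwd(dn1, cache$n1$cache, p$norm1)
    dx <- bn1$dx
    list(dx = dx,
         grads = list(norm1 = bn1$grads, norm2 = bn2$grads,
                      att = bmh$grads, mlp = bm$grads))
  } else {
    bn2 <- norm_bwd(dout, cache$n2$cache, p$norm2)
    dml <- if (is.null(cache$drop2)) bn2$dx else bn2$dx * cache$drop2
    bm <- mlp_bwd(dml, cache$ml$cache, p$mlp)
    dn1out <- bn2$dx + bm$dx
    bn1 <- norm_bwd(dn1out, cache$n1$cache, p$norm1)
    bmh <- multihead_bwd(bn1$dx, cache$mh$cache, p$att)
    dx <- bn1$dx + bmh$dxq + bmh$dxkv
    list(dx = dx,
         grads = list(norm1 = bn1$grads, norm2 = bn2$grads,
                      att = bmh$grads, mlp = bm$grads))
  }
}

#' Masked / self attention block on a token matrix
#'
#' Functional, single-set interface to the MAB used throughout the encoder:
#' pre-norm residual attention plus a residual MLP,
#' `out = H + MLP(Norm(H))` with `H = Norm(X) + MultiHead(Norm(X), ., ., M)`
#' (post-norm placement is also available). [sab()] is exactly [mab()] with a
#' zero additive mask — the same code path.
#'
#' @param x `L x d` token matrix.
#' @param mask additive mask (`L x L` matrix, length-`L` vector, or `NULL`
#'   for a zero mask).
#' @param params block parameters from the internal initializer; pass a model
#'   block or build one with `esa_model()`. Mostly useful for testing; models
#'   call the internal path directly.
#' @param heads number of attention heads.
#' @param placement `"pre"` or `"post"` normalization.
#' @return `L x d` matrix.
#' @export
mab <- function(x, mask, params, heads = 1L, placement = "pre") {
  mab_fwd(x, mask, params, heads, placement)$out
}

#' @rdname mab
#' @export
sab <- function(x, params, heads = 1L, placement = "pre") {
  mab(x, NULL, params, heads, placement)
}

# ---------------------------------------------------------------------------
# PMA: pooling by multi-head attention.
#   Sbar = Norm(MultiHead(S_k, Z, Z, padding-mask));
#   out  = SAB^p(Sbar + MLP(Sbar))
# Z with zero real tokens (edgeless graph): the cross-attention output for
# that graph is replaced by the raw seeds, so the graph representation
# degrades to the pooled seeds through the MLP/SAB path.

pma_init <- function(d, k, p_sabs = 0L, mlp_variant = "standard",
                     norm_kind = "layer") {
  list(seeds = rng_matrix(k, d, sd = 1),
       att = multihead_init(d),
       norm = norm_init(d, norm_kind),
       mlp = mlp_init(d, mlp_variant),
       sabs = if (p_sabs > 0L)
         lapply(seq_len(p_sabs), function(i) mab_init(d, mlp_variant,
                                                      norm_kind)))
}

# z: L x d tokens of ONE graph (padded rows included); pad: logical length L.
pma_fwd_one <- function(z, pad, p, h, placement = "pre", dropout = 0,
                        training = FALSE, record = FALSE) {
  k <- nrow(p$seeds)
  empty <- !any(pad)
  if (empty) {
    mh <- NULL
    sb_in <- p$seeds
  } else {
    mh <- multihead_fwd(p$seeds, z, pad_key_mask(pad), p$att, h, dropout,
                        training, record)
    sb_in <- mh$out
  }
  nf <- norm_fwd(sb_in, p$norm, training = training)
  ml <- mlp_fwd(nf$out, p$mlp)
  u <- nf$out + ml$out
  sab_caches <- list()
  sc_list <- list()
  if (!is.null(p$sabs)) {
    for (i in seq_along(p$sabs)) {
      r <- mab_fwd(u, NULL, p$sabs[[i]], h, placement, dropout, training,
                   record)
      sab_caches[[i]] <- r$cache
      if (record) sc_list[[i]] <- r$scores
      u <- r$out
    }
  }
  list(out = u,
       cache = list(empty = empty, mh = mh, nf = nf, ml = ml,
                    sab_caches = sab_caches),
       scores = if (record) list(cross = if (!empty) mh$scores,
                                 sabs = sc_list))
}

pma_bwd_one <- function(dout, cache, p, h) {
  grads <- list(seeds = matrix(0, nrow(p$seeds), ncol(p$seeds)),
                att = NULL, norm = NULL, mlp = NULL, sabs = NULL)
  du <- dout
  if (!is.null(p$sabs)) {
    grads$sabs <- vector("list", length(p$sabs))
    for (i in rev(seq_along(p$sabs))) {
      b <- mab_bwd(du, cache$sab_caches[[i]], p$sabs[[i]])
      grads$sabs[[i]] <- b$grads
      du <- b$dx
    }
  }
  bm <- mlp_bwd(du, cache$ml$cache, p$mlp)
  grads$mlp <- bm$grads
  dnf <- du + bm$dx
  bn <- norm_bwd(dnf, cache$nf$cache, p$norm)
  grads$norm <- bn$grads
  if (cache$empty) {
    grads$seeds <- bn$dx
    dz <- NULL
  } else {
    bmh <- multihead_bwd(bn$dx, cache$mh$cache, p$att)
    grads$att <- bmh$grads
    grads$seeds <- bmh$dxq
    dz <- bmh$dxkv
  }
  list(dz = dz, grads = grads)
}

#' Pool PMA seed outputs into one graph vector
#'
#' Aggregates the `k x d` matrix of refined seed representations into a
#' single `d`-vector by mean (default) or sum.
#'
#' @param pma_out `k x d` matrix (one graph).
#' @param method `"mean"` or `"sum"`.
#' @return numeric vector of length `d`.
#' @export
pool_seeds <- function(pma_out, method = c("mean", "sum")) {
  method <- match.arg(method)
  if (method == "mean") colMeans(pma_out) else colSums(pma_out)
}
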