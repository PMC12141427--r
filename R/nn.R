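# Low-level differentiable layers. Each layer has an *_init() returning a
# named list of parameter arrays, a *_fwd() returning list(out, cache), and a
# *_bwd(dout, cache, p) returning list(dx, grads) with grads shaped like the
# parameters. Token matrices are dense doubles; batches are handled by the
# callers (attention loops over batch elements, row-wise layers operate on the
# flattened (B*L) x d matrix).

rng_matrix <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

linear_init <- function(d_in, d_out, zero = FALSE) {
  list(W = if (zero) matrix(0, d_in, d_out)
       else rng_matrix(d_in, d_out, sd = 1 / sqrt(d_in)),
       b = rep(0, d_out))
}

linear_fwd <- function(x, p) {
  out <- x %*% p$W
  out <- sweep(out, 2L, p$b, "+")
  list(out = out, cache = x)
}

linear_bwd <- function(dout, cache, p) {
  list(dx = dout %*% t(p$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

layernorm_init <- function(d) list(gamma = rep(1, d), beta = rep(0, d))

layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  out <- sweep(xhat * rep(1, nrow(x)) %o% p$gamma, 2L, p$beta, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dout, cache, p) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, p$gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx,
       grads = list(gamma = colSums(dout * xhat), beta = colSums(dout)))
}

# Batch (set) normalization over real token rows; `rows` selects the rows
# that contribute to the statistics (padded rows are excluded). Running stats
# live in an environment inside the parameter list so they update in place.
batchnorm_init <- function(d) {
  state <- new.env(parent = emptyenv())
  state$mean <- rep(0, d)
  state$var <- rep(1, d)
  state$momentum <- 0.9
  list(gamma = rep(1, d), beta = rep(0, d), state = state)
}

batchnorm_fwd <- function(x, p, rows = NULL, training = TRUE, eps = 1e-5) {
  if (is.null(rows)) rows <- seq_len(nrow(x))
  if (training && length(rows) > 1L) {
    xr <- x[rows, , drop = FALSE]
    mu <- colMeans(xr)
    va <- colMeans(sweep(xr, 2L, mu)^2)
    st <- p$state
    st$mean <- st$momentum * st$mean + (1 - st$momentum) * mu
    st$var <- st$momentum * st$var + (1 - st$momentum) * va
  } else {
    mu <- p$state$mean
    va <- p$state$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(x, 2L, mu), 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(out = out,
       cache = list(xhat = xhat, inv = inv, rows = rows,
                    training = training && length(rows) > 1L))
}

batchnorm_bwd <- function(dout, cache, p) {
  xhat <- cache$xhat
  rows <- cache$rows
  n <- length(rows)
  dxhat <- sweep(dout, 2L, p$gamma, "*")
  dx <- sweep(dxhat, 2L, cache$inv, "*")
  if (cache$training) {
    # only `rows` took part in the batch statistics; only their upstream
    # gradients couple through mean/var (padded rows are zeroed upstream)
    s1 <- colSums(dxhat[rows, , drop = FALSE]) / n
    s2 <- colSums((dxhat * xhat)[rows, , drop = FALSE]) / n
    corr <- sweep(xhat[rows, , drop = FALSE], 2L, s2, "*")
    corr <- sweep(corr, 2L, s1, "+")
    dx[rows, ] <- dx[rows, ] - sweep(corr, 2L, cache$inv, "*")
  }
  list(dx = dx,
       grads = list(gamma = colSums(dout * xhat), beta = colSums(dout)))
}

# Unified normalization dispatcher used by the attention blocks.
norm_init <- function(d, kind = c("layer", "batch")) {
  kind <- match.arg(kind)
  p <- if (kind == "layer") layernorm_init(d) else batchnorm_init(d)
  c(p, list(kind = kind))
}

norm_fwd <- function(x, p, rows = NULL, training = TRUE) {
  if (p$kind == "layer") layernorm_fwd(x, p)
  else batchnorm_fwd(x, p, rows = rows, training = training)
}

norm_bwd <- function(dout, cache, p) {
  r <- if (p$kind == "layer") layernorm_bwd(dout, cache, p)
  else batchnorm_bwd(dout, cache, p)
  r$grads$kind <- NULL
  r
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Two-layer MLP, expansion factor 2, GELU. Gated variant is a GEGLU:
# (gelu(x Wa) * (x Wb)) Wo.
mlp_init <- function(d, variant = c("standard", "gated"), expansion = 2L) {
  variant <- match.arg(variant)
  dh <- d * expansion
  if (variant == "standard") {
    list(variant = "standard",
         fc1 = linear_init(d, dh), fc2 = linear_init(dh, d))
  } else {
    list(variant = "gated",
         fca = linear_init(d, dh), fcb = linear_init(d, dh),
         fc2 = linear_init(dh, d))
  }
}

mlp_fwd <- function(x, p) {
  if (p$variant == "standard") {
    f1 <- linear_fwd(x, p$fc1)
    h <- gelu(f1$out)
    f2 <- linear_fwd(h, p$fc2)
    list(out = f2$out, cache = list(f1 = f1, pre = f1$out, f2 = f2))
  } else {
    fa <- linear_fwd(x, p$fca)
    fb <- linear_fwd(x, p$fcb)
    h <- gelu(fa$out) * fb$out
    f2 <- linear_fwd(h, p$fc2)
    list(out = f2$out, cache = list(fa = fa, fb = fb, f2 = f2))
  }
}

mlp_bwd <- function(dout, cache, p) {
  if (p$variant == "standard") {
    b2 <- linear_bwd(dout, cache$f2$cache, p$fc2)
    dh <- b2$dx * gelu_grad(cache$pre)
    b1 <- linear_bwd(dh, cache$f1$cache, p$fc1)
    list(dx = b1$dx, grads = list(variant = NULL, fc1 = b1$grads,
                                  fc2 = b2$grads))
  } else {
    b2 <- linear_bwd(dout, cache$f2$cache, p$fc2)
    ga <- gelu(cache$fa$out)
    da <- b2$dx * cache$fb$out * gelu_grad(cache$fa$out)
    db <- b2$dx * ga
    ba <- linear_bwd(da, cache$fa$cache, p$fca)
    bb <- linear_bwd(db, cache$fb$cache, p$fcb)
    list(dx = ba$dx + bb$dx,
         grads = list(variant = NULL, fca = ba$grads, fcb = bb$grads,
                      fc2 = b2$grads))
  }
}

# Row softmax with numerical max-shift; rows that are entirely censored by a
# finite additive mask come out uniform (and finite).
softmax_rows <- function(s) {
  mx <- apply(s, 1L, max)
  e <- exp(s - mx)
  e / rowSums(e)
}

# --- nested parameter list <-> flat vector utilities (for Adam) ------------

flatten_params <- function(p) {
  acc <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      keys <- names(x)
      if (is.null(keys)) keys <- as.character(seq_along(x))
      for (i in seq_along(x))
        walk(x[[i]], paste0(prefix, ".",
                            if (nzchar(keys[i])) keys[i] else i))
    } else if (is.numeric(x)) {
      acc[[prefix]] <<- x
    }
  }
  walk(p, "p")
  acc
}

param_count <- function(p) sum(vapply(flatten_params(p), length, integer(1)))

# elementwise map over matching nested numeric leaves (unnamed sublists are
# matched positionally)
map_params <- function(f, ...) {
  ps <- list(...)
  rec <- function(...) {
    xs <- list(...)
    x1 <- xs[[1L]]
    if (is.list(x1)) {
      out <- x1
      for (i in seq_along(x1))
        out[i] <- list(do.call(rec, lapply(xs, `[[`, i)))  # keeps NULLs
      out
    } else if (is.numeric(x1)) {
      do.call(f, xs)
    } else x1
  }
  do.call(rec, ps)
}

zero_like <- function(p) map_params(function(x) x * 0, p)

# structure-tolerant gradient accumulation (either side may have NULL leaves,
# e.g. PMA cross-attention grads are absent for an edgeless graph)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a))
      a[i] <- list(add_grads(a[[i]], b[[i]]))
    return(a)
  }
  if (is.numeric(a) && is.numeric(b)) return(a + b)
  a
}
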