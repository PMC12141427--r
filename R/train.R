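# Losses: each returns list(loss, dpred). Classification expects 0-based
# integer labels; predictions are logits.

loss_mse <- function(pred, y) {
  y <- matrix(as.numeric(y), nrow(pred), ncol(pred))
  err <- pred - y
  list(loss = mean(err^2), dpred = 2 * err / length(err))
}

loss_cross_entropy <- function(pred, y, class_weights = NULL) {
  n <- nrow(pred)
  p <- softmax_rows(pred)
  yi <- cbind(seq_len(n), as.integer(y) + 1L)
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[yi[, 2L]]
  wsum <- sum(w)
  loss <- sum(-w * log(pmax(p[yi], 1e-12))) / wsum
  dlogit <- p
  dlogit[yi] <- dlogit[yi] - 1
  list(loss = loss, dpred = dlogit * (w / wsum))
}

loss_bce <- function(pred, y) {
  z <- pred[, 1L]
  y <- as.numeric(y)
  # softplus(z) - y z, numerically stable
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  s <- 1 / (1 + exp(-z))
  list(loss = mean(sp - y * z),
       dpred = matrix((s - y) / length(z), ncol = 1L))
}

task_loss <- function(pred, y, task, class_weights = NULL, out_dim = 1L) {
  switch(task,
         graph_regression = loss_mse(pred, y),
         node_classification = ,
         graph_classification = if (out_dim == 1L) loss_bce(pred, y)
         else loss_cross_entropy(pred, y, class_weights))
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      keys <- names(p)
      for (i in seq_along(p)) {
        # grads may omit non-trainable fields (e.g. a norm's `kind` tag);
        # match by name when the parameter list is named
        gi <- if (!is.null(keys) && nzchar(keys[i])) g[[keys[i]]] else g[[i]]
        r <- rec(p[[i]], gi, m[[i]], v[[i]])
        p[i] <- list(r$p); m[i] <- list(r$m); v[i] <- list(r$v)
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.numeric(p) && is.numeric(g)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
    }
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

# --- evaluation helpers -----------------------------------------------------

targets_of <- function(gs, node_level) {
  if (node_level) unlist(lapply(gs, function(g) as.vector(g$y)))
  else vapply(gs, function(g) as.numeric(g$y[1L]), numeric(1))
}

predict_in_chunks <- function(model, gs, batch_size = 32L) {
  out <- lapply(split(seq_along(gs), ceiling(seq_along(gs) / batch_size)),
                function(idx) forward_batch(model, gs[idx])$pred)
  do.call(rbind, out)
}

#' Predict on graphs with a (possibly trained) model
#'
#' Chunked forward pass. For regression models trained with target
#' standardization the predictions are mapped back to the original scale;
#' classification models return the argmax class (0-based) unless
#' `type = "logits"`.
#'
#' @param model an `esa_model` (as returned by [train_model()], which may
#'   attach a target scaling).
#' @param gs list of graphs.
#' @param type `"response"` or `"logits"`.
#' @param batch_size graphs per forward chunk.
#' @return vector (response) or matrix (logits); node-level models return one
#'   entry per node.
#' @export
predict_graphs <- function(model, gs, type = c("response", "logits"),
                           batch_size = 32L) {
  type <- match.arg(type)
  if (inherits(gs, "esa_graph")) gs <- list(gs)
  pred <- predict_in_chunks(model, gs, batch_size)
  if (model$config$task == "graph_regression") {
    if (!is.null(model$y_scale))
      pred <- pred * model$y_scale$sd + model$y_scale$mean
    return(drop(pred))
  }
  if (type == "logits") return(pred)
  if (model$config$out_dim == 1L) as.integer(pred[, 1L] > 0)
  else max.col(pred, ties.method = "first") - 1L
}

eval_metrics <- function(model, gs, batch_size = 32L) {
  node_level <- model$config$task == "node_classification"
  y <- targets_of(gs, node_level)
  if (model$config$task == "graph_regression") {
    pred <- predict_graphs(model, gs, batch_size = batch_size)
    regression_metrics(y, pred)
  } else {
    pred <- predict_graphs(model, gs, batch_size = batch_size)
    list(mcc = matthews_cc(y, pred),
         accuracy = mean(pred == y))
  }
}

# --- training loop ----------------------------------------------------------

#' Train a model
#'
#' Seeded mini-batch Adam training with early stopping on the validation
#' loss and best-checkpoint restore. Splits are taken from `opt$split`
#' (a list of index vectors `train`/`val`/`test`) or generated from
#' `opt$val_frac` / `opt$test_frac`. Regression targets are standardized on
#' the training split by default (`opt$standardize_y`); predictions from
#' [predict_graphs()] are mapped back automatically.
#'
#' @param model an `esa_model`.
#' @param data list of `esa_graph` with targets in `y`.
#' @param opt list of options: `lr` (1e-3), `epochs` (50), `batch_size` (32),
#'   `patience` (20), `seed` (0), `val_frac` (0.15), `test_frac` (0.15),
#'   `split`, `class_weights` (`NULL` or `"balanced"` or a vector),
#'   `lr_schedule` (`"none"`, `"cosine"`, `"plateau"`), `standardize_y`
#'   (TRUE for regression), `verbose`, `stop_fn` (optional callback
#'   `function(epoch, model, record)` returning TRUE to stop early, e.g. a
#'   target-metric check).
#' @return an `esa_run`: list with `model` (best checkpoint), `record`
#'   (config snapshot, seed, per-epoch losses/metrics, final test metrics,
#'   wall clock).
#' @export
train_model <- function(model, data, opt = list()) {
  o <- utils::modifyList(
    list(lr = 1e-3, epochs = 50L, batch_size = 32L, patience = 20L,
         seed = 0L, val_frac = 0.15, test_frac = 0.15, split = NULL,
         class_weights = NULL, lr_schedule = "none",
         standardize_y = TRUE, verbose = FALSE, stop_fn = NULL),
    opt)
  set.seed(o$seed)
  t0 <- proc.time()[["elapsed"]]
  n <- length(data)
  if (is.null(o$split)) {
    idx <- sample.int(n)
    n_test <- floor(n * o$test_frac)
    n_val <- floor(n * o$val_frac)
    o$split <- list(test = idx[seq_len(n_test)],
                    val = idx[n_test + seq_len(n_val)],
                    train = idx[(n_test + n_val + 1L):n])
  }
  tr <- data[o$split$train]
  va <- data[o$split$val]
  te <- data[o$split$test]

  node_level <- model$config$task == "node_classification"
  regression <- model$config$task == "graph_regression"

  if (regression && isTRUE(o$standardize_y)) {
    ys <- targets_of(tr, FALSE)
    sc <- list(mean = mean(ys), sd = max(stats::sd(ys), 1e-8))
    scale_y <- function(g) { g$y <- (g$y - sc$mean) / sc$sd; g }
    tr <- lapply(tr, scale_y); va <- lapply(va, scale_y)
    model$y_scale <- sc
  }

  cw <- o$class_weights
  if (identical(cw, "balanced")) {
    yall <- targets_of(tr, node_level)
    tab <- table(factor(yall, levels = 0:(model$config$out_dim - 1L)))
    cw <- as.numeric(sum(tab) / (length(tab) * pmax(tab, 1)))
  }

  batch_loss <- function(gs_batch, training) {
    fb <- forward_batch(model, gs_batch, training = training,
                        keep_cache = training)
    y <- targets_of(gs_batch, node_level)
    lo <- task_loss(fb$pred, y, model$config$task, cw, model$config$out_dim)
    list(fb = fb, loss = lo$loss, dpred = lo$dpred)
  }

  dataset_loss <- function(gs_all) {
    if (length(gs_all) == 0L) return(NA_real_)
    chunks <- split(seq_along(gs_all),
                    ceiling(seq_along(gs_all) / o$batch_size))
    tot <- 0; cnt <- 0
    for (ch in chunks) {
      r <- batch_loss(gs_all[ch], training = FALSE)
      w <- if (node_level) sum(vapply(gs_all[ch], n_nodes, integer(1)))
      else length(ch)
      tot <- tot + r$loss * w
      cnt <- cnt + w
    }
    tot / cnt
  }

  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  history <- list()
  epochs_run <- 0L
  for (epoch in seq_len(o$epochs)) {
    lr <- switch(o$lr_schedule,
                 cosine = o$lr * 0.5 * (1 + cos(pi * (epoch - 1) / o$epochs)),
                 o$lr)
    perm <- sample.int(length(tr))
    chunks <- split(perm, ceiling(seq_along(perm) / o$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (ch in chunks) {
      r <- batch_loss(tr[ch], training = TRUE)
      if (!is.finite(r$loss))
        stop(sprintf(paste0("NaN/Inf training loss at epoch %d ",
                            "(lr=%.2g, mask value=%.3g): aborting"),
                     epoch, lr, esa_neg_value()), call. = FALSE)
      grads <- backward_batch(model, r$fb$cache, r$dpred)
      st <- adam_step(model$params, grads, state, lr)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + r$loss * length(ch)
      ep_n <- ep_n + length(ch)
    }
    val_loss <- dataset_loss(va)
    history[[epoch]] <- list(epoch = epoch, lr = lr,
                             train_loss = ep_loss / ep_n,
                             val_loss = val_loss)
    epochs_run <- epoch
    if (o$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / ep_n, val_loss))
    monitor <- if (length(va) > 0L) val_loss else ep_loss / ep_n
    if (is.finite(monitor) && monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, params = model$params, epoch = epoch)
    } else if (epoch - best$epoch >= o$patience) {
      break
    }
    if (!is.null(o$stop_fn)) {
      probe <- model
      probe$params <- best$params
      if (isTRUE(o$stop_fn(epoch, probe,
                           list(history = history)))) break
    }
  }
  model$params <- best$params
  test_metrics <- if (length(te) > 0L) eval_metrics(model, te, o$batch_size)
  record <- list(config = unclass(model$config), seed = o$seed,
                 split_sizes = vapply(o$split, length, integer(1)),
                 history = history, epochs_run = epochs_run,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 test_metrics = test_metrics,
                 wall_clock_s = proc.time()[["elapsed"]] - t0)
  structure(list(model = model, record = record, split = o$split),
            class = "esa_run")
}

#' @export
print.esa_run <- function(x, ...) {
  r <- x$record
  cat(sprintf("<esa_run> %d epochs (best %d, val loss %.4f), %.1fs\n",
              r$epochs_run, r$best_epoch, r$best_val_loss, r$wall_clock_s))
  if (!is.null(r$test_metrics)) {
    m <- r$test_metrics
    cat("  test:", paste(sprintf("%s=%.4f", names(m), unlist(m)),
                         collapse = "  "), "\n")
  }
  invisible(x)
}

# --- attention extraction and Gini analysis ---------------------------------

#' Extract post-softmax attention scores
#'
#' Runs a recording forward pass and returns the attention matrices of one
#' encoder layer: per graph, the per-head `h x L_q x L_k` score array
#' restricted to real tokens, plus the head-averaged matrix used for
#' concentration analysis.
#'
#' @param model an `esa_model`.
#' @param gs list of graphs (a batch).
#' @param layer_index 1-based encoder layer index.
#' @return list with one element per graph: `list(scores = h x L x L array,
#'   head_mean = L x L matrix)`.
#' @export
extract_attention <- function(model, gs, layer_index) {
  if (inherits(gs, "esa_graph")) gs <- list(gs)
  nl <- length(model$config$plan$encoder)
  if (layer_index < 1L || layer_index > nl)
    stop(sprintf("layer_index out of range (model has %d encoder layers)",
                 nl), call. = FALSE)
  fb <- forward_batch(model, gs, record = TRUE)
  counts <- fb$batch$counts
  lapply(seq_along(gs), function(b) {
    arr <- fb$scores$encoder[[layer_index]][[b]]   # h x L x L
    l <- counts[b]
    sc <- arr[, seq_len(l), seq_len(l), drop = FALSE]
    hm <- apply(sc, c(2L, 3L), mean)
    list(scores = sc, head_mean = matrix(hm, l, l))
  })
}

#' Per-layer Gini concentration of attention scores
#'
#' For every encoder layer and graph, averages the post-softmax scores over
#' heads and summarizes their concentration with the Gini coefficient —
#' near 0 when attention is spread evenly, approaching 1 when a few pairs
#' dominate.
#'
#' @param model an `esa_model`.
#' @param gs list of graphs.
#' @return numeric matrix `length(gs) x n_layers`.
#' @export
attention_gini <- function(model, gs) {
  if (inherits(gs, "esa_graph")) gs <- list(gs)
  nl <- length(model$config$plan$encoder)
  out <- matrix(NA_real_, length(gs), nl)
  for (li in seq_len(nl)) {
    att <- extract_attention(model, gs, li)
    out[, li] <- vapply(att, function(a) gini(as.vector(a$head_mean)),
                        numeric(1))
  }
  out
}
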