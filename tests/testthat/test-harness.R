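test_that("Matthews correlation coefficient: closed cases and oracle", {
  expect_equal(matthews_cc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  expect_equal(matthews_cc(c(0, 1, 0, 1), c(1, 1, 1, 1)), 0.0)  # constant
  expect_error(matthews_cc(c(0, 1), c(0)), "equal length")

  # TP=3 TN=4 FP=1 FN=2 against the contingency formula
  y_true <- c(rep(1, 3), rep(0, 4), rep(0, 1), rep(1, 2))
  y_pred <- c(rep(1, 3), rep(0, 4), rep(1, 1), rep(0, 2))
  tp <- 3; tn <- 4; fp <- 1; fn <- 2
  manual <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(matthews_cc(y_true, y_pred), manual)

  # binary contingency equals the generalized multiclass form, and the
  # multiclass form matches a direct covariance computation
  set.seed(41)
  yt <- sample(0:2, 60, replace = TRUE)
  yp <- ifelse(runif(60) < 0.6, yt, sample(0:2, 60, replace = TRUE))
  cm <- table(factor(yt, 0:2), factor(yp, 0:2))
  s <- sum(cm); c_ <- sum(diag(cm))
  pk <- colSums(cm); tk <- rowSums(cm)
  ref <- (c_ * s - sum(pk * tk)) /
    (sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2)))
  expect_equal(matthews_cc(yt, yp), ref, tolerance = 1e-12)
  expect_gt(matthews_cc(yt, yp), 0)
})

test_that("regression metrics match scalar-loop oracles", {
  y <- c(1, 2, 3, 4)
  expect_equal(regression_metrics(y, y),
               list(mae = 0, rmse = 0, r2 = 1))
  m <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m$r2, 0)

  set.seed(42)
  yt <- rnorm(10); yp <- rnorm(10)
  mm <- regression_metrics(yt, yp)
  mae <- 0; sse <- 0; sst <- 0
  for (i in 1:10) {
    mae <- mae + abs(yt[i] - yp[i]) / 10
    sse <- sse + (yt[i] - yp[i])^2
    sst <- sst + (yt[i] - mean(yt))^2
  }
  expect_equal(mm$mae, mae, tolerance = 1e-8)
  expect_equal(mm$rmse, sqrt(sse / 10), tolerance = 1e-8)
  expect_equal(mm$r2, 1 - sse / sst, tolerance = 1e-8)

  expect_warning(r <- regression_metrics(c(2, 2), c(1, 3)), "undefined")
  expect_true(is.nan(r$r2))
})

test_that("gini: uniform 0, one-hot (n-1)/n, pairwise formula", {
  expect_equal(gini(rep(3, 7)), 0)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75)
  for (n in c(2, 5, 10)) expect_equal(gini(c(1, rep(0, n - 1))), (n - 1) / n)
  expect_equal(gini(c(1, 2, 3)), 8 / 36)

  # random vectors vs the O(n^2) pairwise-difference oracle
  set.seed(43)
  for (rep in 1:5) {
    x <- runif(sample(3:20, 1))
    n <- length(x)
    tot <- 0
    for (i in 1:n) for (j in 1:n) tot <- tot + abs(x[i] - x[j])
    expect_equal(gini(x), tot / (2 * n^2 * mean(x)), tolerance = 1e-10)
  }

  expect_error(gini(numeric(0)), "empty")
  expect_error(gini(c(-1, 2)), "nonnegative")
  expect_error(gini(c(0, 0)), "all-zero")
})

test_that("extract_attention returns row-stochastic, mask-respecting scores", {
  set.seed(44)
  gs <- replicate(3, rand_undirected(5, 0.5), simplify = FALSE)
  model <- tiny_graph_model(4, "MSP", seed = 10)
  att <- extract_attention(model, gs, layer_index = 1)
  madd <- edge_adjacency_single(gs[[1]]$edge_index)$allowed
  a <- att[[1]]
  # each real query row sums to 1, per head
  sums <- apply(a$scores, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-6)
  # masked pairs carry (essentially) zero score in the M layer
  expect_true(all(a$head_mean[!madd] <= 1e-6))
  # head averaging is the plain mean over heads
  expect_equal(a$head_mean, apply(a$scores, c(2, 3), mean), tolerance = 1e-12)

  expect_error(extract_attention(model, gs, 99), "out of range")

  # end-to-end Gini smoke: one value per graph and layer, inside [0, 1)
  gm <- attention_gini(model, gs)
  expect_equal(dim(gm), c(3L, 2L))
  expect_true(all(gm >= 0 & gm < 1))
})

test_that("training contracts: lr 0, seeding, single-sample overfit", {
  set.seed(45)
  gs <- gen_counting_task(12, 5:7, 0.5, seed = 50, target = "edge_count")
  cfg <- esa_config("MP", task = "graph_regression", hidden_dim = 8,
                    heads = 2, k = 2)
  in_dim <- 2 * ncol(gs[[1]]$node_features)

  # lr = 0: parameters unchanged, loss constant
  model <- esa_model(cfg, in_dim, seed = 11)
  before <- esagraph:::flatten_params(model$params)
  run0 <- train_model(model, gs, list(lr = 0, epochs = 3, batch_size = 4,
                                      seed = 1, standardize_y = FALSE,
                                      patience = 10))
  after <- esagraph:::flatten_params(run0$model$params)
  expect_equal(before, after, tolerance = 1e-15)
  losses <- vapply(run0$record$history, `[[`, numeric(1), "train_loss")
  expect_equal(diff(losses), rep(0, 2), tolerance = 1e-12)

  # same seed twice: identical epoch-0 loss (and full history)
  runA <- train_model(esa_model(cfg, in_dim, seed = 11), gs,
                      list(lr = 1e-3, epochs = 2, batch_size = 4, seed = 9))
  runB <- train_model(esa_model(cfg, in_dim, seed = 11), gs,
                      list(lr = 1e-3, epochs = 2, batch_size = 4, seed = 9))
  expect_identical(runA$record$history, runB$record$history)

  # single-sample dataset: loss decreases monotonically for >= 5 steps
  one <- gs[1]
  model1 <- esa_model(cfg, in_dim, seed = 12)
  run1 <- train_model(model1, c(one, one, one), # train=val=test copies
                      list(lr = 5e-3, epochs = 6, batch_size = 1, seed = 2,
                           split = list(train = 1L, val = 2L, test = 3L),
                           standardize_y = FALSE, patience = 20))
  l1 <- vapply(run1$record$history, `[[`, numeric(1), "train_loss")
  expect_length(l1, 6L)
  expect_true(all(diff(l1) < 0))
})

test_that("class weights and checkpoint restore work end to end", {
  gs <- gen_shortest_path_task(12, 15, 0.15, 3, seed = 60)
  cfg <- esa_config("M", task = "node_classification", hidden_dim = 8,
                    heads = 2, out_dim = 3)
  model <- esa_model(cfg, 2, seed = 13)
  run <- train_model(model, gs, list(lr = 2e-3, epochs = 3, batch_size = 4,
                                     seed = 3, class_weights = "balanced"))
  expect_s3_class(run, "esa_run")
  expect_true(is.finite(run$record$best_val_loss))
  preds <- predict_graphs(run$model, gs[1:2])
  expect_length(preds, n_nodes(gs[[1]]) + n_nodes(gs[[2]]))
  expect_true(all(preds %in% 0:2))
})

test_that("the CLI generates, trains and evaluates from JSON configs", {
  dir <- withr::local_tempdir()
  synth_cfg <- file.path(dir, "synth.json")
  jsonlite::write_json(list(synth = list(generator = "counting",
                                         n_graphs = 8, n_range = 5,
                                         p_edge = 0.5,
                                         target = "edge_count")),
                       synth_cfg, auto_unbox = TRUE)
  expect_message(esa_cli(c("synth", "--config", synth_cfg, "--out", dir,
                           "--seed", "5")), "wrote 8 graphs")
  expect_true(file.exists(file.path(dir, "graphs.jsonl")))

  train_cfg <- file.path(dir, "train.json")
  jsonlite::write_json(list(
    data = list(path = file.path(dir, "graphs.jsonl")),
    model = list(layer_string = "MP", task = "graph_regression",
                 hidden_dim = 8, heads = 2, k = 2),
    optimizer = list(lr = 0.001, epochs = 2, batch_size = 4,
                     val_frac = 0.25, test_frac = 0.25)),
    train_cfg, auto_unbox = TRUE)
  esa_cli(c("train", "--config", train_cfg, "--out", dir, "--seed", "5"))
  expect_true(file.exists(file.path(dir, "checkpoint.json")))
  expect_true(file.exists(file.path(dir, "metrics.json")))
  log <- readLines(file.path(dir, "train.log"))
  expect_match(log[1], "config_hash")

  eval_cfg <- file.path(dir, "eval.json")
  jsonlite::write_json(list(
    data = list(path = file.path(dir, "graphs.jsonl")),
    checkpoint = file.path(dir, "checkpoint.json")),
    eval_cfg, auto_unbox = TRUE)
  esa_cli(c("eval", "--config", eval_cfg, "--out", dir))
  m <- jsonlite::fromJSON(file.path(dir, "metrics.json"))
  expect_true(is.finite(m$mae))
})
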