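test_that("parse_config implements the {M,S,P} grammar", {
  plan <- parse_config("MMMMMMSPS", "graph_regression")
  expect_equal(plan$encoder, c("M", "M", "M", "M", "M", "M", "S"))
  expect_true(plan$use_pma)
  expect_equal(plan$p, 1L)

  plan2 <- parse_config("MSP", "graph_regression")
  expect_equal(plan2$encoder, c("M", "S"))
  expect_equal(plan2$p, 0L)

  expect_error(parse_config("MMSPPS", "graph_regression"), "one P")
  expect_error(parse_config("MSPM", "graph_regression"), "only S")
  expect_error(parse_config("MSP", "node_classification"), "not allowed")
  expect_error(parse_config("MS", "graph_regression"), "one P")
  expect_error(parse_config("MXP", "graph_regression"), "unknown")
  expect_error(parse_config("", "graph_regression"), "empty")
  # whitespace ignored; node task takes the whole string as encoder
  expect_equal(parse_config(" M S M ", "node_classification")$encoder,
               c("M", "S", "M"))
})

test_that("esa_config validates widths and task/token compatibility", {
  expect_error(esa_config("MSP", hidden_dim = 10, heads = 4), "divisible")
  expect_error(esa_config("MS", task = "node_classification",
                          token_mode = "edge"), "node tokens")
  cfg <- esa_config("MSP", hidden_dim = 8, heads = 2)
  expect_s3_class(cfg, "esa_config")
  expect_equal(cfg$token_mode, "edge")
})

test_that("encoder with zero blocks is the identity on embedded tokens", {
  set.seed(8)
  g <- rand_undirected(5, 0.5)
  b <- batch_graphs(list(g), "edge")
  model <- tiny_graph_model(ncol(b$tokens[1, , ]), "P", d = 8, k = 2)
  enc <- encoder_forward(b, model)
  # embed by hand
  x0 <- matrix(b$tokens[1, , ], dim(b$tokens)[2], dim(b$tokens)[3])
  emb <- sweep(x0 %*% model$params$embed$W, 2, model$params$embed$b, "+")
  expect_equal(matrix(enc[1, , ], nrow = dim(enc)[2]), emb, tolerance = 1e-12)
})

test_that("all-M encoder cannot mix disjoint line-graph components", {
  set.seed(9)
  # two disjoint edges: their tokens never attend to each other
  g <- graph(matrix(rnorm(8), 4, 2), rbind(c(0, 1), c(2, 3)))
  cfge <- esa_config("MP", task = "graph_regression", hidden_dim = 8,
                     heads = 2, k = 2)
  me <- esa_model(cfge, in_dim = 4, seed = 3)
  b_full <- batch_graphs(list(g), "edge")
  enc_full <- encoder_forward(b_full, me)

  # forward each single-edge subgraph alone; tokens must match exactly
  g1 <- graph(g$node_features[1:2, ], rbind(c(0, 1)))
  g2 <- graph(g$node_features[3:4, ], rbind(c(0, 1)))
  enc1 <- encoder_forward(batch_graphs(list(g1), "edge"), me)
  enc2 <- encoder_forward(batch_graphs(list(g2), "edge"), me)
  expect_equal(enc_full[1, 1, ], enc1[1, 1, ], tolerance = 1e-10)
  expect_equal(enc_full[1, 2, ], enc2[1, 1, ], tolerance = 1e-10)
})

test_that("graph-level ESA output is permutation invariant", {
  set.seed(10)
  gs <- replicate(4, rand_undirected(sample(4:7, 1), 0.5), simplify = FALSE)
  model <- tiny_graph_model(2 * 2, "MSPS", seed = 4)
  base <- esa_forward(gs, model)
  for (i in seq_along(gs)) {
    pg <- permute_graph(gs[[i]])
    out <- esa_forward(list(pg$g), model)
    expect_equal(out[1, ], base[i, ], tolerance = 1e-4)
  }
})

test_that("batched ESA forward equals per-graph forwards", {
  set.seed(11)
  gs <- replicate(6, rand_undirected(sample(3:8, 1), 0.5), simplify = FALSE)
  model <- tiny_graph_model(4, "MSP", seed = 5)
  batched <- esa_forward(gs, model)
  for (i in seq_along(gs)) {
    expect_equal(esa_forward(gs[i], model)[1, ], batched[i, ],
                 tolerance = 1e-4)
  }
  # batch of one equals single forward trivially
  expect_equal(esa_forward(gs[[1]], model), esa_forward(gs[1], model))
})

test_that("NSA predictions are permutation equivariant", {
  set.seed(12)
  g <- rand_undirected(6, 0.5)
  model <- tiny_node_model(2, "MSM", seed = 6)
  base <- nsa_forward(list(g), model)
  for (rep in 1:5) {
    pg <- permute_graph(g, edge_perm = seq_len(n_edges(g)))
    out <- nsa_forward(list(pg$g), model)
    # node i of the original sits at position node_perm[i] now
    expect_equal(out[pg$node_perm + 1, ], base, tolerance = 1e-4)
  }

  # 1-node graph: head(encoder(embed(n0)))
  g1 <- graph(matrix(c(0.3, -1), 1, 2), matrix(integer(0), ncol = 2))
  out1 <- nsa_forward(list(g1), model)
  expect_equal(dim(out1), c(1L, 3L))
  expect_true(all(is.finite(out1)))

  # P3 with identical features: the automorphism swapping the ends fixes
  # the middle, so nodes 0 and 2 get identical predictions
  p3 <- canonicalize_undirected(graph(matrix(1, 3, 2),
                                      rbind(c(0, 1), c(1, 2))))
  outp <- nsa_forward(list(p3), model)
  expect_equal(outp[1, ], outp[3, ], tolerance = 1e-10)
})

test_that("edgeless graphs take the seed fallback and stay finite", {
  g0 <- graph(matrix(1, 3, 4), matrix(integer(0), ncol = 2))
  model <- tiny_graph_model(8, "MSP", seed = 7)
  out <- esa_forward(list(g0), model)
  expect_true(all(is.finite(out)))
  # mixed batch: non-empty graphs unaffected by the empty one
  set.seed(13)
  g1 <- rand_undirected(4, 0.8, d_n = 4)
  mixed <- esa_forward(list(g1, g0), model)
  expect_equal(mixed[1, ], esa_forward(list(g1), model)[1, ],
               tolerance = 1e-6)
})

test_that("parameter count is a pure function of the config", {
  mk <- function(seed) tiny_graph_model(6, "MMSPS", d = 16, h = 4, k = 8,
                                        seed = seed)
  expect_identical(n_parameters(mk(1)), n_parameters(mk(99)))
  # regression pin: embed(6->16) + 3 blocks + PMA(k=8, 1 SAB) + head
  expect_identical(n_parameters(mk(1)), 11617L)
  # gated MLP adds one projection per block
  gated <- tiny_graph_model(6, "MMSPS", d = 16, h = 4, k = 8, seed = 1,
                            mlp_variant = "gated")
  expect_gt(n_parameters(gated), n_parameters(mk(1)))
})

test_that("checkpoint save/load round-trips predictions", {
  set.seed(14)
  gs <- replicate(3, rand_undirected(4, 0.6), simplify = FALSE)
  model <- tiny_graph_model(4, "MSP", seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(esa_forward(gs, back), esa_forward(gs, model),
               tolerance = 1e-12)
})

test_that("batch-norm and post-norm variants run and stay finite", {
  set.seed(15)
  gs <- replicate(3, rand_undirected(5, 0.5), simplify = FALSE)
  for (nk in c("layer", "batch")) for (pl in c("pre", "post")) {
    model <- tiny_graph_model(4, "MSP", seed = 9, norm_kind = nk,
                              norm_placement = pl)
    out <- esa_forward(gs, model)
    expect_true(all(is.finite(out)), info = paste(nk, pl))
  }
})
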