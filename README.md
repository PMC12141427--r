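# esagraph — Edge-Set Attention for Graph Learning

`esagraph` is an R implementation of a purely attention-based architecture
for learning on graphs, aimed at molecular property prediction and related
graph-level / node-level tasks. Instead of message passing over nodes, a
graph is treated as a **set of edge tokens**: each directed edge `(i, j)`
becomes the feature vector

```
x_ij = n_i ∥ n_j ∥ e_ij
```

(source-node, target-node and edge features concatenated). The token set is
processed by a vertical stack of

- **MAB** — masked attention blocks, where scaled dot-product attention
  `softmax(QKᵀ/√d_k + M) V` is censored by an additive mask `M` built from
  the *edge adjacency*: two edges may attend to each other iff they share an
  endpoint (the line-graph structure of the input);
- **SAB** — self-attention blocks, identical but with a zero mask
  (`SAB(X) = MAB(X, 0)`), letting the model expand beyond the graph prior;
- **PMA** — pooling by multi-head attention: `k` learnable seed vectors
  cross-attend to the token set and are refined by `p` SABs, giving a
  permutation-invariant graph representation.

The stack is described by a configuration string over `{M, S, P}` (e.g.
`"MMSPS"`: two masked blocks, one self-attention block, pooling, one
post-pooling SAB). Node-level tasks use the node-token variant (**NSA**):
node features as tokens, node-adjacency mask, no pooling block.

Everything is implemented in base R (dense linear algebra, hand-written
backprop, Adam) with no deep-learning framework dependency, at "desk scale":
exact dense attention, graphs up to a few hundred edges, CPU training in
seconds to minutes.

## What is in the box

| module | entry points |
|---|---|
| data model | `graph()`, `build_edge_tokens()`, `canonicalize_undirected()`, `batch_graphs()`, `radius_graph()`, `gaussian_basis_expansion()`, JSON-lines IO |
| masks | `edge_adjacency_single()`, `edge_adjacency_batched()`, `node_adjacency_batched()`, `to_additive()` |
| model | `esa_config()`, `esa_model()`, `esa_forward()`, `nsa_forward()`, `masked_sdpa()`, `mab()`/`sab()`, `pool_seeds()`, checkpoints |
| synthetic tasks | `gen_er_graphs()`, `gen_counting_task()`, `gen_shortest_path_task()`, `fixture_wl_pair()`, `color_refinement()` |
| harness | `train_model()`, `predict_graphs()`, `matthews_cc()`, `regression_metrics()`, `gini()`, `extract_attention()`, `attention_gini()`, `esa_cli()` |

## Worked example

Train a small edge-set model to count triangles in Erdős–Rényi graphs —
a task whose labels are computed exactly (`trace(A³)/6`), so every number
below is reproducible:

```r
library(esagraph)

gs  <- gen_counting_task(300, 6:10, 0.3, seed = 7, target = "triangle_count")
gs[[1]]
#> <esa_graph> 7 nodes (d_n=14), 20 directed edges (d_e=0), with targets

cfg   <- esa_config("MSP", task = "graph_regression",
                    hidden_dim = 32, heads = 4, k = 8)
model <- esa_model(cfg, in_dim = 2 * ncol(gs[[1]]$node_features), seed = 7)
model
#> <esa_model> 'MSP' (graph_regression), d=32 h=4 k=8, edge tokens, 27841 parameters

run <- train_model(model, gs, list(lr = 2e-3, epochs = 8, batch_size = 32,
                                   seed = 7))
run
#> <esa_run> 8 epochs (best 6, val loss 0.0880), 13.1s
#>   test: mae=0.6427  rmse=0.8879  r2=0.7121

te    <- gs[run$split$test]
pred  <- predict_graphs(run$model, te)
truth <- sapply(te, `[[`, "y")
rbind(truth = truth[1:8], pred = round(pred[1:8], 2))
#>       [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8]
#> truth  1.0 2.00 1.00 3.00 6.00 1.00 1.00 0.00
#> pred   0.5 0.76 1.42 1.78 4.28 0.91 0.95 0.51
```

The test MAE (0.64 triangles) and `R²` (0.71) mean the model has learnt a
structure-counting signal far beyond the constant-mean baseline after a few
CPU-seconds — the acceptance suite runs the same task with the stricter
"halve the baseline MAE" bar. Attention concentration per encoder layer can
be summarized with the Gini coefficient (0 = evenly spread, →1 = a few
dominant pairs):

```r
round(colMeans(attention_gini(run$model, te[1:10])), 3)
#> [1] 0.577 0.172
```

## CLI

A thin command-line driver (installed under `exec/`) covers fixture
generation, training and evaluation from JSON configs:

```sh
esa synth --config synth.json --out data/
esa train --config train.json --out runs/exp1 --seed 3
esa eval  --config eval.json  --out runs/exp1
```
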