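---
title: "Edge-set attention: model, masks, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-set attention: model, masks, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esagraph)
```

## The model

A graph is a tuple of a node set and an edge set with node features
$\mathbf{n}_i \in \mathbb{R}^{d_n}$ and optional edge features
$\mathbf{e}_{ij} \in \mathbb{R}^{d_e}$. `esagraph` learns on the **set of
directed edge tokens**

$$\mathbf{x}_{ij} = \mathbf{n}_i \,\|\, \mathbf{n}_j \,\|\, \mathbf{e}_{ij},$$

collected row-wise in $\mathbf{X} \in \mathbb{R}^{N_e \times (2d_n + d_e)}$.
Undirected graphs are stored with both directions — one token per direction —
because the token explicitly distinguishes source from target. All attention
is exact, dense, scaled dot-product attention with an additive mask:

$$\mathrm{SDPA}(\mathbf{Q}, \mathbf{K}, \mathbf{V}, \mathbf{M}) =
  \mathrm{softmax}\!\left(\frac{\mathbf{Q}\mathbf{K}^\top}{\sqrt{d_k}}
  + \mathbf{M}\right)\mathbf{V},$$

where a mask entry of $0$ leaves a score unchanged and a large negative
value censors the pair. The three blocks are:

* **MAB** (masked attention block), pre-norm by default:
  $\bar{\mathbf{X}} = \mathrm{Norm}(\mathbf{X})$, then
  $\mathbf{H} = \bar{\mathbf{X}} +
  \mathrm{MultiHead}(\bar{\mathbf{X}},\bar{\mathbf{X}},\bar{\mathbf{X}},
  \mathbf{M})$, then
  $\mathrm{MAB}(\mathbf{X},\mathbf{M}) = \mathbf{H} +
  \mathrm{MLP}(\mathrm{Norm}(\mathbf{H}))$. Note the attention residual runs
  from the **normalized** input $\bar{\mathbf{X}}$, not from $\mathbf{X}$;
  with output projections zeroed, the block therefore reduces to
  $\mathrm{Norm}(\mathbf{X})$ (the unit tests pin exactly this behaviour).
* **SAB**: $\mathrm{SAB}(\mathbf{X}) = \mathrm{MAB}(\mathbf{X}, \mathbf{0})$ —
  literally the same code path with a zero mask. In batched mode the "zero"
  mask still censors padding; padding is never attended to.
* **PMA** (pooling by multi-head attention): $k$ learnable seed vectors
  $\mathbf{S}_k$ cross-attend to the token set,
  $\bar{\mathbf{S}} = \mathrm{Norm}(\mathrm{MultiHead}(\mathbf{S}_k,
  \mathbf{Z}, \mathbf{Z}, \mathbf{M}_{\mathrm{pad}}))$, then
  $\mathrm{PMA}_{k,p}(\mathbf{Z}) = \mathrm{SAB}^{p}(\bar{\mathbf{S}} +
  \mathrm{MLP}(\bar{\mathbf{S}}))$, and the $k$ rows are mean-pooled
  (sum optional). Because the final aggregation is over learnt seeds rather
  than tokens, the graph representation is permutation invariant by
  construction.

The vertical layout is a string over `{M, S, P}` parsed by
`parse_config()`: blocks before `P` form the encoder, the `S`'s after `P`
become the PMA's internal SABs ($p$). A graph-level model is

$$\mathbf{Z}_\mathrm{out} =
  \mathrm{PMA}_{k,p}(\mathrm{Encoder}(\mathbf{X},\mathbf{M}) + \mathbf{X}),$$

with one deliberate reading choice: the written residual is width-mismatched
($\mathbf{X}$ is $2d_n+d_e$ wide, the encoder output is $d$ wide), so the
input is embedded once to width $d$ and *that* embedding is added — the only
interpretation that type-checks with shared parameters. Node-level tasks
(**NSA**) use node tokens, the node-adjacency mask, no pooling block, and a
per-token head; predictions are permutation equivariant.

## The masks

Two directed edges are mutually visible iff they share an endpoint
($src_a{=}src_b \lor tgt_a{=}tgt_b \lor src_a{=}tgt_b \lor tgt_a{=}src_b$).
Off the diagonal this is exactly the adjacency matrix of the **line graph**;
the diagonal is kept allowed so no real token ever faces an all-censored
row. Reversed duplicates $(i,j)/(j,i)$ share both endpoints and are mutually
adjacent — no special-casing. Batched masks of shape $B \times L \times L$
reproduce the single-graph mask per slice, censor everything touching
padding, and never connect tokens across graphs (a cross-graph edge raises a
corrupt-batch error).

Numerical choices:

* The additive censoring value is **finite**: half the most negative
  representable double (`esa_neg_value()`), not $-\infty$. A padded query
  row is fully censored; with $-\infty$ its softmax would be NaN, with a
  large finite value it degrades to a harmless uniform distribution whose
  output is discarded (padded rows are re-zeroed after every block —
  zeroing alone is never trusted, masking alone is never trusted either).
* With at least one allowed pair in a row, `exp(censored - max)` underflows
  to exactly 0, so censored pairs carry exactly zero attention.
* Masks are materialized densely; that is the stated scope (the memory
  bottleneck this implies is a known limitation of the approach, and sparse
  or chunked kernels are out of scope here).

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `hidden_dim` $d$ | 64 | desk-scale width; must divide by `heads` |
| `heads` $h$ | 4 | $d_k = d/h = 16$ keeps per-head geometry sane at small $d$ |
| `k` (PMA seeds) | 32 | small seed sets suffice; `pool_seeds()` collapses them |
| `norm_kind` | layer | batch ("set") norm available; stats over real tokens only |
| `norm_placement` | pre | post-LN available for both MAB and SAB |
| `mlp_variant` | standard (2-layer, expansion 2, GELU) | gated (GEGLU) available; exact widths were an open design point, expansion 2 is the common default |
| `dropout` | 0 | applied to attention weights and MLP outputs when set |
| seeds init | $\mathcal{N}(0,1)$ | seedable via `esa_model(..., seed=)` |

Degenerate inputs: an edgeless graph has zero edge tokens; its PMA
cross-attention is bypassed and the raw seeds flow through the norm/MLP/SAB
path, so the forward stays finite and differentiable (the choice is logged
by the masking design, not hidden). $d_e = 0$ is fully supported (tokens are
$2d_n$ wide).

## Training harness

No deep-learning framework exists in the target environment, so all blocks
carry hand-written backward passes verified against central finite
differences (worst relative error $\sim 10^{-7}$ over random parameter
leaves; the key-projection bias is the one exactly-zero-gradient leaf, by
softmax shift invariance). `train_model()` does seeded mini-batch Adam
(lr $10^{-3}$ default, cosine or constant schedule), early stopping on
validation loss (patience 20), best-checkpoint restore, optional balanced
class weights, and optional target standardization for regression (the
optimizer details are deliberately not baked in and are
exposed as plain options). A NaN loss aborts with a
diagnostic. Losses: MSE, multi-class cross-entropy (logits), binary
cross-entropy. Metrics: MAE/RMSE/$R^2$, and MCC in the generalized
covariance-based multiclass form (reduces to the binary contingency formula
for two classes; 0 by convention on a zero denominator).

`extract_attention()` re-runs a forward pass in recording mode and returns
post-softmax scores per head plus the head-averaged matrix;
`attention_gini()` summarizes their concentration with the Gini coefficient
$\sum_{ij}|x_i - x_j| / (2n^2\bar{x}) \in [0, 1)$ per layer and graph. No
numeric target is attached to these distributions — they are
dataset-specific — so the tests only assert structural facts
(row-stochasticity, mask compliance, range).

## The synthetic world

The generators are pure functions of their seed and exist so that every
claim in the test suite is checkable against an independent oracle:

* `gen_er_graphs(n, n_range, p)` — undirected Erdős–Rényi graphs,
  bidirectional storage, features = constant 1 plus one-hot clipped degree.
* `gen_counting_task(..., target = "triangle_count")` — labels computed
  exactly as $\mathrm{tr}(\mathbf{A}^3)/6$; the acceptance bar is relative
  (halve the constant-mean baseline MAE), not an absolute error.
* `gen_shortest_path_task(n, n_nodes, p, c)` — a transparent surrogate for
  the "infected ER" node-classification setting: one random source node
  carries a one-hot flag, labels are BFS distances clipped to $c-1$
  (unreachable → top class). The task is a deliberately
  transparent surrogate — **labelled as such** — and no published score is
  used as a target. Scale is deliberately desk-level
  ($n = 100$ vs tens of thousands): the point is that masked attention
  propagates the flag, not benchmark parity. With $p = 0.03$ (mean degree
  3) the three classes are heavily imbalanced (~1/3/96%), which is what the
  balanced-class-weight option is for.
* `fixture_wl_pair()` — the decalin skeleton (two fused hexagons) and the
  bicyclopentyl skeleton (two pentagons plus a bridge): 10 nodes, 11
  undirected edges, equal degree sequences, non-isomorphic, and
  indistinguishable by 1-WL color refinement.

What a green training test establishes: that the architecture can exploit
edge-adjacency structure to beat trivial baselines on tasks whose labels are
pure graph structure. What it does **not** establish: anything about
chemistry-scale accuracy, transferability, or publication-scale benchmarks —
real molecular data has feature distributions, sizes and noise these
generators do not emulate.

## A deliberately red acceptance clause

The acceptance suite asserts that 1-WL separates the *line graphs* of the
fixture pair (the motivating intuition being that edge tokens carry
line-graph structure and hence extra expressivity). Two
independent oracles (this package's color refinement run on the disjoint
union, and networkx's WL hash during development) agree that it does not:
both line graphs stabilize to identical $\{1,4,4,2\}$ partitions. The line
graphs *are* non-isomorphic — the degree-2 chains reconnect to different
triangles, a fact invisible to multiset refinement — and that weaker, true
statement is what the unit suite asserts. In the literature this pair is
the standard witness for *directed, no-backtrack* edge message passing, not
for undirected line-graph 1-WL. The acceptance clause is kept failing on
purpose rather than weakened; see the test comment.

## Known limitations

* Dense $O(N_e^2)$ masks and attention: hundreds, not millions, of edges.
* Pure-R training: seconds to minutes per task at the tested sizes; no GPU.
* No positional/structural encodings, transfer learning, or approximate
  attention — out of scope by design.
* PMA's internal SABs do not share parameters with encoder SABs; sharing
  would be a legitimate alternative reading and is not implemented.
* Duplicate parallel edges are rejected by `canonicalize_undirected()`;
  multigraph support is an explicit non-goal.
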