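---
title: "Methods: context-encoding attention and capsule scoring for drug side-effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-encoding attention and capsule scoring for drug side-effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Adverse drug events are a leading cause of attrition in clinical
development, and screening candidate drug–side-effect associations
computationally narrows the space that has to be tested experimentally.
`adverank` scores every unobserved drug–side-effect pair from three kinds of
evidence: the known binary association matrix $A \in \{0,1\}^{N_r \times
N_s}$, two drug–drug similarity matrices $D^{che}$ (chemical substructure
fingerprints) and $D^{dis}$ (disease/function profiles), and a side-effect
similarity matrix $S$. All similarities are in $[0,1]$, symmetric, with unit
diagonal; the package validates and rejects (never clips) malformed inputs,
because a similarity outside $[0,1]$ always indicates an upstream
preprocessing error.

Two heterogeneous graphs are assembled, one per drug-similarity modality,
with adjacency

$$I^{\rho} = \begin{bmatrix} D^{\rho} & A \\ A^{\top} & S \end{bmatrix},
\qquad \rho \in \{che, dis\},$$

drugs occupying rows $1..N_r$ and side-effects rows $N_r+1..N_{total}$. Row
$v$ of $I^\rho$ doubles as the raw attribute vector of node $v$: a drug's
attributes concatenate its similarities to all drugs with its associations
to all side-effects, and symmetrically for side-effects. Indexing is R's
native 1-based convention throughout, including in the documented node
ordering (side-effect $j$ is node $N_r + j$).

## Module 1: the graph-transformer context encoder

Each node is encoded by a stack of attention layers that aggregate two
*typed* neighborhoods:

* **same-type neighbors** — the `nt` most similar nodes of the same type
  (the target included; ties broken by ascending index so runs are
  deterministic), connected by similarity edges;
* **cross-type neighbors** — the associated nodes of the other type
  (ascending index, truncated to `nk`), connected by association edges; the
  target's own state is prepended so it participates in this aggregation
  too.

Within a layer, each of `heads` attention heads maps the target's
previous-layer state to a query $q = W_Q c$ and the member states to keys
and values $K = C W_K^\top$, $V = C W_V^\top$. The attention score of member
$m$ is the bilinear form $K_m^\top W_E\, q$, where $W_E$ is an
*edge-semantic* matrix selected by the edge category of the neighborhood —
one matrix per layer, head, and edge class (drug–drug similarity,
side-effect–side-effect similarity, association). This is how the semantics
of the connection type enter the aggregation. Scores are
softmax-normalized (numerically stabilized by max subtraction) and the head
output is the weighted sum of value rows; head outputs are concatenated.

No $1/\sqrt{d}$ score scaling is applied by default — the model is defined
without it — but `scaled_attention = TRUE` exposes the conventional
variant.

The per-category encodings (same-type, cross-type) are fused by a
*category attention*: each category encoding $y_u$ is scored through a
shared tanh bottleneck $s_u = h^\top \tanh(W y_u + b)$, the scores are
softmax-normalized into weights $\beta$ summing to one, and the layer
output is $\sum_u \beta_u y_u$. Sharing $W, b, h$ across the two categories
is a deliberate design choice: it is what makes the two scores commensurable
under the softmax (the same choice made by standard semantic-attention
designs). A node with no associations simply drops the cross-type category
and the remaining category receives weight 1 — this avoids empty softmaxes
without special-casing downstream code.

After the last layer, a residual projection re-injects the raw attributes
($Z_{add} = W_{res}\,\mathrm{relu}(x) + Z_{last}$; attributes are
non-negative, so relu only guards malformed input), and the two graphs are
fused per node by a two-channel $1\times1$ convolution — two scalar weights
and a scalar bias shared across features — realizing the graph-level
attention. A linear softmax classifier on the concatenated fused encodings
of a pair returns the encoder's association probability.

One structural property is worth stating explicitly: because the classifier
is linear on a concatenation, the encoder score decomposes additively into
a drug term and a side-effect term. Its within-drug ranking is therefore a
global side-effect ordering; drug-specific discrimination in the fused
score comes predominantly from the capsule module below. On real data,
where side-effect prevalence is heavily skewed, such a global ordering is
itself informative; on the balanced synthetic benchmark it contributes
little, which is visible in the per-module metrics.

## Module 2: the multi-view capsule scorer

The capsule module scores a pair directly from its *raw* stacked pair
embedding: the $4 \times N_{total}$ map whose rows are (drug attributes,
side-effect attributes) from the chemical graph followed by the same two
rows from the disease graph. Unlike the encoder head, its convolutions see
the drug and side-effect rows *jointly*, so it learns position-wise
interactions.

The map is padded with one zero column on each side of the length axis
only — the padding consistent with the documented output shape of the first
convolution ($nf \times 3 \times (N_{total}+1)$ for $2\times2$ kernels); the
4-row axis is never padded. The second stage applies `w` groups of
$2\times2$ convolutions over all `nf` channels, one view map of
$2 \times N_{total}$ per group (an optional `filters_per_group` expansion
applies several filters per group and reduces them by channel mean). The
$p$-th position across the `w` views forms primary capsule $u_p \in
\mathbb{R}^w$, giving $P = 2N_{total}$ capsules — the count follows from
the shape algebra of the two convolution stages.

Per-capsule linear maps produce prediction vectors $\hat u_{q|p}$ for the
two digit capsules (associated / not associated), which are combined by
routing-by-agreement: logits $b_{pq}$ start at zero, each of `routing_iters`
rounds softmax-normalizes them over $q$ into coupling coefficients $c_{pq}$
(so $\sum_q c_{pq} = 1$ for every $p$), forms $o_q = \sum_p c_{pq} \hat
u_{q|p}$, squashes it to $v_q$ with
$\lVert v\rVert = \lVert o\rVert^2 / (1+\lVert o\rVert^2) \in [0,1)$
(zero input maps to zero by an explicit guard), and reinforces $b_{pq}$ by
the agreement $\hat u_{q|p} \cdot v_q$. Routing state is per example:
logits are reset to zero on every forward pass. The association probability
is the softmax over the two digit-capsule norms; note its dynamic range is
intentionally compressed (norms live in $[0,1)$), which matters for
calibration but not for ranking.

## Training and score fusion

Both modules are trained independently on the summed cross-entropy of
their own probabilities (with a $10^{-12}$ clamp inside the log), using
Adam; they are fused only at prediction time as

$$y = \gamma\, y_{enc} + (1-\gamma)\, y_{cap}, \qquad \gamma = 0.3
\text{ by default.}$$

Because no automatic differentiation framework is a dependency, both
backward passes are derived analytically and implemented alongside the
forwards: the encoder backward accumulates gradients over all nodes and
layers of the whole graph (layer-$l$ states feed every node that lists the
node as a neighbor at layer $l+1$), and the capsule backward unrolls the
routing loop, differentiating through the softmax, the squash Jacobian
$g(s)I + (g'(s)/s)\,oo^\top$ with $g(s) = s/(1+s^2)$, and the agreement
updates of all earlier iterations. Every gradient path is pinned by central
finite-difference checks in the test suite (relative tolerance $10^{-4}$;
relu kinks are moved off zero in those checks, since a subgradient at the
kink is the one place where the comparison is ill-posed).

The encoder is transductive — any parameter update changes all node
encodings — so it trains full-batch by default (`encoder_batch_size = Inf`):
one forward/backward over the graph per update is the economical regime,
and mini-batching would recompute the same encodings many times per epoch.
The capsule scorer is per-pair and keeps conventional mini-batches
(default 128). Training is deterministic given the seed, and a non-finite
loss aborts with a diagnostic rather than silently continuing.

### Default hyper-parameters

The reference configuration (`adverank_config()`) uses neighborhood sizes
`nt = nk = 10`, two encoder layers of output dimensionality 2400 and 2000
with 8 heads, 64 first-stage filters, `w = 8` views, digit-capsule
dimension 32, 3 routing iterations, $\gamma = 0.3$, Adam at $10^{-3}$,
batch 128, 50 epochs, five folds — sized for a 708 x 4192 problem. Two
further knobs are this package's own: `att_dim` (the category-attention
bottleneck width, default 64) and `background` in the generator below.

## Evaluation protocol

Cross-validation partitions the known associations at random into five
equal parts. Per fold, the held-out positives are zeroed out of the
association matrix *before* the graphs and attribute vectors are built, so
no label information leaks through the inputs; training negatives are drawn
uniformly without replacement from the unobserved pairs, one per training
positive (balanced sampling). At test time each drug's candidate set is
every side-effect outside its training positives — held-out positives plus
all unobserved pairs, the reading consistent with the severe class
imbalance that motivates precision–recall summaries (at the reference
scale, 708 x 4192 with 80,164 positives, the unobserved count is 2,887,772
and the imbalance is ~1:36). AUC (exact Mann–Whitney rank form), AUPR
(precision step-sum), and recall at $k \in \{30, 60, \dots, 240\}$ are
computed per drug, averaged over drugs with at least one held-out positive,
then over folds. A score-permutation null (each drug's candidate scores
shuffled) is reported alongside as the chance reference.

## The synthetic benchmark

The generator (`generate_synthetic()`) emulates the *shape* of curated
pharmacovigilance data without reproducing any real resource: drugs and
side-effects are assigned to `n_blocks` co-association groups; pairs
sharing a group associate at a high within-block rate and others at a low
background rate, the rates derived so the expected overall density matches
`density`; every entry is then flipped independently with probability
`noise`. Drug fingerprints are per-block binary prototypes with 10%
per-drug bit flips; a second, independently re-flipped copy yields the
second similarity modality — two correlated but distinct views, so the
graph-level fusion has a genuine weighting decision to make. The
side-effect similarity is the cosine similarity of association columns
(the package's documented fallback builder, used whenever no external
side-effect similarity is supplied).

Defaults are fixed once as the package's study conditions: $60 \times 120$
nodes, 4 blocks, overall density 0.15, `background = 0.15` (off-block
density fraction), `noise = 0.02` — a modest error rate representative of
curation noise in association databases — and fingerprint length 64. At
these settings the within-block rate works out to ~0.53, and a trivial
nearest-neighbor baseline (mean association among the 10 most similar
drugs) reaches a per-drug AUC of ~0.8, certifying the benchmark is
learnable before the model is credited or blamed. What the benchmark does
**not** emulate: the skewed side-effect prevalence, the sparsity (1:36
rather than ~1:5 imbalance), and the hub structure of real
pharmacovigilance graphs. Passing it demonstrates correct mechanics and
genuine signal recovery, not real-data performance.

The benchmark model configuration (`benchmark_config()`) scales the
architecture to the 180-node problem — 4 heads, two 32-dimensional layers,
8 filters, 4 views, 8-dimensional digit capsules, 40 full-batch encoder
epochs at $5\cdot10^{-3}$ and 10 capsule epochs at $10^{-2}$ — problem
sizes chosen so a five-fold run completes in minutes on one CPU while
leaving a clear margin over both the 0.85 recovery target and the
permutation null.

## Numerical choices and edge cases

* Softmaxes subtract the maximum before exponentiation everywhere.
* Ties in neighbor selection and in candidate ranking break by ascending
  index; repeated runs are bit-identical given a seed.
* `squash(0) = 0` by an explicit guard, and its backward returns zero
  there (the Jacobian vanishes in the limit).
* An all-zero profile row in cosine similarity yields zeros off-diagonal
  (with a warning) rather than NaN.
* Matrices with entries outside $[0,1]$, asymmetric similarities, non-0/1
  associations, and dimension mismatches are rejected with messages naming
  the offending matrix.
* A drug with every side-effect already known in training has an empty
  candidate list; a drug with no held-out positives is excluded from that
  fold's averages (its metrics are undefined).

## Known limitations

* The full reference configuration (2400/2000-dimensional layers on a
  4900-node graph) is sized for GPU-scale training; this pure-R
  implementation is intended for method study, moderate problem sizes, and
  the synthetic benchmark, not for full-scale pharmacovigilance runs.
* The encoder head's additive structure (discussed above) bounds what the
  encoder alone can contribute to within-drug ranking.
* The capsule probability's compressed dynamic range makes fused scores
  cluster near the middle of $[0,1]$; they are rankings, not calibrated
  probabilities.
* The side-effect similarity fallback (cosine over association columns) is
  a pragmatic stand-in; supplying an externally derived similarity is
  preferred when one exists.
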