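---
title: "Meta-path contrastive learning for DDI event prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-path contrastive learning for DDI event prediction: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mphgcl)
```

## The prediction problem

A drug–drug interaction (DDI) *event* is a typed outcome of combining two
drugs — "the metabolism decreases", "the serum concentration increases", and
so on. Given a catalogue of known labeled pairs over an event vocabulary of
size $|E|$, the task is multi-class: predict which event a drug pair belongs
to. Event frequencies are strongly long-tailed — a handful of events account
for most labeled pairs while many events have few instances — which is why
macro-averaged metrics and frequency-grouped reporting matter as much as
accuracy.

The model works on a *drug heterogeneous graph* with five node types — drug
(D), chemical substructure (C), target protein (P), enzyme (E), transport
pathway (T) — and edge types {D–C, D–P, D–E, D–T, P–P}. Direct attributes
connect drugs to the four attribute node sets; protein–protein interactions
(PPIs) contribute indirect drug relations through interacting targets.

## From meta-paths to drug sub-graphs

Five meta-paths connect drugs through shared intermediaries: DCD, DPD, DED,
DTD (2-hop) and DPPD (3-hop through a PPI edge). For each meta-path, the
path-instance count matrix is the incidence-chain product
(e.g. $M_{DC} M_{DC}^\top$ for DCD), and pairwise similarity is PathSim

$$ s(i,j) = \frac{2\,p_{i \to j}}{p_{i \to i} + p_{j \to j}}, $$

with $s = 0$ when the denominator vanishes. Each drug keeps its top-$K$
most similar neighbors (zero similarities are never kept), and the per-drug
selections are union-symmetrized into a binary sub-graph per meta-path.

Numerical choices worth recording:

* **DPPD self-loops.** The 3-hop chain uses $M_{DP}(M_{PP}+I)M_{DP}^\top$.
  With strict PPI chains a drug's diagonal count can be zero while
  off-diagonal counts are positive, making PathSim degenerate; adding protein
  self-loops guarantees $s(i,i)=1$ for every target-bearing drug. A side
  effect is that shared-target paths are subsumed into DPPD counts, and the
  symmetric bound $2p_{ij} \le p_{ii}+p_{jj}$ can be violated by interacting
  protein pairs, so DPPD similarities are truncated at 1. Truncation collapses
  the ordering among the (rare) pairs whose raw ratio exceeds 1; those pairs
  are the strongest neighbors either way.
* **Default $K$.** The average number of connections per drug under the
  meta-path: the count of nonzero off-diagonal similarity entries divided by
  $|D|$, rounded half away from zero, floored at 1. It is computed on the
  nonzero-similarity graph (computing it before zero-filtering would count
  structural zeros as connections); a per-meta-path override is exposed.
* **Ties** in top-$K$ selection break toward the smaller drug index, making
  sub-graphs a pure function of the inputs.
* Per-drug selection is directed; the encoder needs an undirected graph, so
  an edge survives if either endpoint selected the other.

## Two contrastive views and three masking levels

The *average view* is the mean of the clean sub-graph adjacencies
$M_C = \tfrac{1}{l}\sum_i M_{DD}^{P_i}$ — a coarse "are these drugs
connected" signal. The *augmented view* fuses the per-meta-path sub-graphs
after masking, with semantic attention over meta-paths — a fine "how are they
connected" signal. Each training epoch corrupts the data at three levels:

1. **Feature masking** removes a fraction $a_f$ of attribute *nodes* per type
   (zeroing their incidence columns; PPI rows of removed targets are zeroed
   too). Removing an attribute node deletes every path through it, which is
   the semantics the path-recount tests assert. The drug feature matrix X is
   untouched. Sub-graphs are rebuilt on the corrupted graph with the clean
   graph's $K$ values, so neighborhood sizes stay comparable across epochs
   (re-deriving $K$ per epoch would confound masking strength with
   neighborhood size; a rebuild-free variant can be had by passing
   `aug_config(mode = "e")`).
2. **Sub-graph masking** drops one uniformly chosen sub-graph with
   probability $a_g$ (never the last one).
3. **Edge masking** removes a fraction $a_e$ of the surviving sub-graphs'
   edges.

The drop decision is taken before edge masking (masking edges of a graph
about to be discarded is wasted work; the distribution of the corrupted set
is unchanged). Mask counts round half away from zero and never remove 100%
of anything. Defaults $(a_f, a_e, a_g) = (0.2, 0.3, 0.2)$ follow the
sensitivity analysis of the reference experiments; ablation modes `none`,
`f`, `e`, `g` switch individual levels for the noMask/fMask/eMask/gMask
variants, and `ablation = "noPPI"` drops the DPPD meta-path instead.
Augmentation is a training-time regularizer only: inference encodes the
clean set in both views.

## Encoder

Drug features are binary substructure-presence vectors from a byte-pair
style vocabulary fitted on the SMILES corpus (most frequent adjacent token
pair merged while its count is at least `min_freq`, ties lexicographic,
vocabulary capped at `max_size`; encoding is greedy longest-match). The
encoder is:

* **Feature transform** $h_i = \sigma(Wx_i + b)$ with $\sigma$ = ELU. The
  activation is unspecified in the reference description; ELU is smooth,
  avoids dead units in sparse binary inputs, and is configurable in code.
* **Per-graph multi-head attention.** For each graph (the average view plus
  each meta-path sub-graph) an independent parameter set; per head $k$,
  logits $e_{ij} = \mathrm{LeakyReLU}(a_k^\top [h_i \| h_j])$ over the
  neighborhood, softmax-normalized, then
  $\mathrm{PReLU}(\sum_j \alpha_{ij} W_k h_j + b)$ with head dimension
  $d/H$; the $H$ heads concatenate to dimension $d$. Self-loops are always
  added so isolated drugs (possible for cold-start drugs in masked graphs)
  still receive an embedding. We aggregate neighbor embeddings $h_j$; the
  printed recurrences of some graph-attention write-ups put $h_i$ inside the
  sum, which would be self-aggregation — both behaviors are a one-line switch
  but neighbor aggregation is the standard semantics. The bias and PReLU
  slope are shared across heads within a graph.
* **Average-view neighborhoods** are the nonzero support of $M_C$; the
  fractional weights are not multiplied into attention (attention re-learns
  edge importance). `use_edge_weights = TRUE` folds them into the logits as
  $\log w$, which is exactly softmax re-weighting.
* **Semantic attention** over sub-graph embeddings:
  $s_P = \mathrm{mean}_i \tanh(W_1 z_i^P + b_1)$, $e_P = q_1^\top s_P$,
  $\beta = \mathrm{softmax}(e)$, $z_i^F = \sum_P \beta_P z_i^P$. Dropping a
  sub-graph renormalizes $\beta$ over the survivors.

## Objectives

With $z^C$ (average view) and $z^F$ (augmented view):

* **Cross-view InfoNCE** with cosine similarity and temperature $\tau$: the
  positive for drug $i$ in one view is drug $i$ in the other; denominators
  run over all $|D|$ candidates of the other view (positive included), and
  the two directions average with the $1/(2|D|)$ factor. Anchor
  self-similarity within a view is not contrasted.
* **Supervised contrastive loss** over mini-batch pair embeddings
  $z_{(i,j)} = z_i^C \| z_i^F \| z_j^C \| z_j^F$: positives are other batch
  members with the same event label; the anchor is excluded from both the
  positive set and the denominator (including it bounds the loss trivially).
  Anchors without positives are excluded from the outer average.
* **Prediction loss**: mean cross-entropy of the softmax MLP head over the
  batch (the mean makes the loss scale-invariant in batch size without
  changing the optimizer direction).
* **Total**: $L = L_s + \alpha (L_{uc} + L_{sc})$.

Defaults $\tau = 0.05$ and $\alpha = 0.1$ follow the reference
hyper-parameter analysis. Closed forms used as regression anchors: identical
embeddings across views give $L_{uc} = \log |D|$ at any $\tau$; an all-same
class batch of identical embeddings gives $L_{sc} = \log(N-1)$; uniform
predictions give $L_s = \log |E|$.

## Training, splits and evaluation

Every labeled pair is presented in both orders (the concatenation is
order-dependent but the labels are undirected); at evaluation the two
orders' probability vectors are averaged. Parameters are Glorot-initialized
and optimized with Adam (learning rate $10^{-3}$); the graphs are encoded in
full at every step and the pair losses are mini-batched (512 pairs). Per
epoch the corrupted sub-graph set is resampled and `batches_per_epoch`
(default 2) mini-batch steps are taken from a fresh shuffle — successive
epochs cycle through all pairs, and the cap keeps a 200-epoch run on a
single CPU in minutes at the package's study scale (200 drugs, ~4,000
labeled pairs). All randomness derives from one seed; two runs with the same
configuration are identical.

Three evaluation tasks: Task 1 splits *instances* 7:1:2 stratified per event;
Tasks 2 and 3 split *drugs* 7:1:2 — a test pair has exactly one (Task 2) or
both (Task 3) drugs unseen in training. Pairs mixing validation and test
drugs fit neither contract and are discarded with a logged count. Metrics:
accuracy, micro-averaged one-vs-rest AUPR (step-wise average-precision
convention; macro-AUPR is a flag away), and macro precision/recall/F1 over
the event classes present in the test labels (events absent from a split are
excluded from macro averages rather than scored zero). Frequency-grouped
macro-F1 uses half-open bins — the first bin closed, e.g.
$[1,10], (10,50], (50,100], (100,300], (300,\infty)$.

## Synthetic data: what it emulates and what it does not

`generate_synthetic()` plants recoverable structure shaped like the real
datasets: drugs belong to latent clusters; each attribute node is owned by a
cluster and drug–attribute edges appear with probability `p_in` within the
owner cluster versus `p_out` outside; PPI edges are denser within a
cluster's target set; the event label of a pair is a deterministic function
of its cluster pair (so both contrastive views carry label signal), flipped
with probability `label_noise`; the cluster-pair-to-event map is drawn from
a power law so event frequencies are long-tailed. Defaults — 200 drugs, 4
clusters, 4 events, `p_in = 0.6`, `p_out = 0.05`, `label_noise = 0.05`,
pair density 0.2 (the labeled-pair density of the larger reference
catalogues), attribute counts C=40, P=30, E=20, T=15 mirroring the per-type
relation ordering of real data — are the package's fixed study conditions.
SMILES are random token strings: the featurization path treats SMILES as
plain sequences, so chemical validity is irrelevant to what the tests
exercise.

What passing on this generator does *not* show: real attribute matrices are
much sparser and higher-dimensional, real event labels are not a function of
any latent clustering, real catalogues have hundreds of events with extreme
tails, and SMILES carry real chemistry. Results on the synthetic fixtures
validate the machinery (exact similarity layer, normalized attention,
calibrated augmentation, learnable planted signal), not clinical
performance.

## Numerical engine

No deep-learning framework is used: the package ships a small reverse-mode
automatic differentiation tape (`R/autodiff.R`). Every operation accepts
plain numeric arrays (returning plain results — the inference and test path)
or tape nodes (the training path), so the encoder and losses are written
once. The graph-attention head is a single fused tape operation with a
hand-derived vectorized backward — the dominant cost at a few hundred drugs
— and the whole gradient is validated against central finite differences
through the full combined loss. Degenerate cases are pinned down explicitly:
fully masked softmax rows return zero rows; zero-norm embeddings are an
error (cosine undefined); probabilities are clipped at $10^{-12}$ before
logs; a non-finite training loss aborts with diagnostics rather than
continuing.

## Known limitations

* Dense $|D| \times |D|$ attention limits practical graph sizes to a few
  thousand drugs; the reference-scale datasets would want sparse kernels or
  a compiled backend.
* One attention layer per graph (by design); no stacking.
* The BPE featurizer is sequence-based; it does not canonicalize SMILES or
  perceive rings/aromaticity.
* Cold-start (Task 3) performance is intrinsically weak — both drugs unseen —
  and the synthetic fixtures reproduce the *shape* of that difficulty, not
  its clinical magnitude.
* On the synthetic fixtures the masking augmentation acts mostly as a
  convergence brake rather than a generalization aid: the planted labels are
  nearly noise-free and the signal is strong, so the noMask variant can match
  or exceed the full model there. The regime where augmentation is expected
  to pay off — sparse, rare-event-heavy real catalogues — is exactly what the
  generator does not emulate.
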