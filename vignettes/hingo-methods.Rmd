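---
title: "Annotating circRNAs from heterogeneous network embeddings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating circRNAs from heterogeneous network embeddings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingo)
```

# The model

`hingo` predicts Gene Ontology (GO) biological-process functions for
circular RNAs (circRNAs), which have essentially no curated annotations
of their own. The method rests on two biological hypotheses: circRNAs
with similar expression profiles tend to share function, and circRNAs
share function with the proteins they associate with. Both are encoded as
edges of a single typed network, and function is transferred across it in
embedding space rather than by direct neighborhood voting, so that
multi-hop, type-crossing relationships contribute.

## The heterogeneous network

Three layers are integrated into one undirected network with node types
`circRNA` and `protein`:

* **co_expr** edges between circRNAs whose expression profiles have
  Pearson correlation at or above a threshold `tau`;
* **circ_prot** association edges between circRNAs and proteins;
* **ppi** edges between proteins, gated on a STRING-style confidence
  score.

Association and interaction sources are cross-filtered against each
other — a PPI entry is kept only if both proteins occur in the
associations, and an association only if its protein retains at least one
PPI edge — iterated to a fixed point, mirroring how such multi-source
compendia are reconciled by protein identifier. Duplicate entries keep
their maximum score. Edge weights are stored, but random walks treat
neighborhoods uniformly: the embedding model below defines no weighted
transition, and adding one would silently change the meta-path
distribution (a weighted mode remains possible through the stored
weights, but is deliberately not the default).

## Meta-path embeddings

Node representations are learned from the network's meta-path structure.
For every node, `walksPerNode` random walks of `walkLength` nodes are
sampled; within each walk, every ordered pair of positions at hop
distance 1..`window` yields a positive tuple `(a, b, z)`, where the
relation `z` is the alternating node-type/edge-type sequence of the
traversed segment (e.g. `C-circ_prot-P-ppi-P`). Since an edge's type is
determined by its endpoint types in this network, the relation vocabulary
is derived from node types alone. Each positive spawns `negRatio`
negatives by replacing `b` with a uniform node of the same type (a
collision with a known positive is resampled up to 10 times, then
accepted — the standard negative-sampling tolerance).

A binary classifier scores whether relation `z` holds between `a` and
`b`:

$$P(z \mid a, b) = \sigma\Big(\sum_i W_A[a]_i \, W_A[b]_i \,
f_{01}(W_Z[z])_i\Big),$$

and training maximizes $\sum R \log P + (1 - R)\log(1 - P)$ by
stochastic gradient descent over shuffled tuples. Design points:

* **One node table.** The two node inputs share `W_A`. The read-out of
  the model is a single N×d node matrix, and tying makes the score
  symmetric in `a` and `b`, which matches the undirected network.
* **`f01`.** The relation vector is constrained into (0, 1) before
  binding so that relations act as soft coordinate masks rather than
  signed factors. The default map is the elementwise logistic (smooth,
  differentiable everywhere); a hard clip into [1e-6, 1-1e-6] is
  available behind `f01Method = "clip"`, with subgradient 0 outside the
  band.
* **One-hot layers are index lookups.** The conceptual one-hot inputs
  are never materialized; gradients touch only the three rows involved
  in a tuple.
* **Initialization** is uniform in ±0.5/d; the inner SGD loop is
  compiled (Rcpp) with the vectors stored column-contiguously, and
  shuffling uses a dedicated generator seeded from the stage seed so the
  trajectory is bit-reproducible.

Defaults are d = 64, window 2, 10 walks of 80 nodes per node, 5
negatives per positive, 5 epochs at learning rate 0.025. Dimension 64
and window 2 are the scale at which this family of embeddings typically
peaks; the walk budget is a desk-scale compromise — corpus-hungry
configurations (walks of a thousand-plus nodes) are reachable through
the same parameters when the network warrants it.

## The hierarchical classifier

Proteins are the only training entities: their propagated GO annotations
(true-path rule over `is_a`/`part_of`) are encoded as binary marker
vectors over a vocabulary of terms annotated to at least `minCount`
entities, ordered parents-first. The network is a shared fully connected
rectifier layer (width `hidden`, default 256) over the embedding, one
sigmoid head per vocabulary term, and a **max-merge** layer: processed
leaves-first, each term's score becomes the maximum over its own head and
its children's merged scores, so a parent's score is exactly the maximum
raw score over its descendant cone and predictions can never violate the
DAG.

* **Loss.** Mean of independent per-term binary cross-entropies on the
  *post-merge* scores — the targets are binary marker vectors, so the
  multi-label reading of cross entropy applies, and merging inside the
  model lets the hierarchy constraint shape the gradients (subgradient of
  the max; ties between a term and its best child route to the term).
  A `preMergeLoss` flag moves the merge outside training.
* **Optimizer.** RMSProp (decay 0.9), batch 64, learning rate 0.01,
  dropout 0.2 on the shared layer, uniform (Glorot-style) initial
  weights; optional early stopping on a held-out split
  (`validationFraction`, patience 20).
* **Heads, not chains.** All terms share only the first layer; per-term
  subnetworks are single affine heads. Feeding parent activations into
  child subnetworks is a plausible deeper variant, but with max-merge
  already enforcing consistency the added coupling is not needed and
  would multiply parameters by the DAG depth.
* The DAG restricted to the vocabulary is its transitive reduction, so
  merge work is linear in the reduced edge set.

Trained on proteins, the model is applied unchanged to circRNA
embeddings — both node types live in the same embedding space, which is
what makes the transfer coherent.

## Evaluation

For entity *j* and threshold *k*, the prediction set `Pc_j(k)` is the set
of terms scoring ≥ k together with all their `is_a`/`part_of` ancestors;
the verified set `V_j` is the propagated truth. Both exclude the
namespace root, which every entity trivially possesses — counting it
would inflate precision for free. Precision `|Pc ∩ V|/|Pc|` is averaged
over the `h(k)` entities with non-empty predictions; recall
`|Pc ∩ V|/|V|` over all N entities (empty predictions contribute 0); the
maximum over a 101-point grid k = 0, 0.01, …, 1 of the harmonic mean is
`Fmax`, with ties broken toward the smaller threshold. Coverage counts
entities with at least one correct predicted term, at the Fmax-optimal
threshold unless overridden. Entities whose verified set is empty after
root removal are skipped with a warning.

A property worth keeping in mind when reading absolute `Fmax` values: at
k = 0 every scored term and its ancestors are predicted, so every entity
has recall 1 and precision `|V_j| / |E'|` (with `E'` the predictable term
set). `Fmax` is therefore bounded below by the "predict everything"
point, roughly `2ρ/(1+ρ)` for a typical truth fraction ρ. Uninformative
scores do not give `Fmax` near 0 — they give this floor, and label
permutations land exactly on it. Comparisons against shuffled or ablated
controls should be read as distances above the floor, not ratios.

# The synthetic world

`makeWorld()` generates all five pipeline inputs from one seed:

* a balanced ontology of depth `dagDepth` and branching `dagBranching`
  (`is_a` tree; the multi-parent case is exercised separately in tests,
  since the generator's role is controlled signal, not topological
  realism);
* `nGroups` functional groups, each owning a distinct block of leaves;
  group proteins are annotated with their block (then propagated), and
  group circRNAs carry the same propagated branch as withheld ground
  truth — truth never enters training, mirroring the transfer setting;
* expression: one standard-normal latent profile per group and sample,
  plus N(0, `exprNoiseSd`) noise per circRNA, giving directly tunable
  within-group correlation;
* associations and PPIs: Bernoulli edges with probability `pIn` within a
  group and `pOut` across; PPI confidences are STRING-style integers in
  500–999.

Defaults (4 groups × 20 circRNAs + 40 proteins, 10 samples, sd 0.1,
`pIn` 0.3, `pOut` 0.01, depth 3, branching 2) define the package's study
configuration, also used by `scripts/acceptance.R`. At these settings the
planted signal is strong: within-group expression correlation is ≈ 0.99,
so the co-expression layer alone nearly determines the groups, and the
pipeline recovers circRNA function essentially perfectly. Two
consequences, verified by the test suite and worth stating plainly:
passing these recovery tests shows the machinery is correct, **not** that
real, sparse, noisy data would reach similar scores; and ablations
(removing or randomizing the PPI layer, `dropEdgeType()` /
`randomizePPI()`) can fail to degrade performance here because the
remaining layers still saturate the task — on real compendia the same
ablation is reported to matter a great deal. The generator deliberately
does not model circRNA biogenesis, sequence features, miRNA sponging, or
realistic degree distributions.

# Numerical and degenerate-case choices

* Pearson similarity is clipped to [-1, 1] against rounding; rows with
  zero variance are excluded from the co-expression layer (their
  correlation is undefined) but may still enter via associations.
* Walks truncate at neighborless nodes; an isolated node yields
  single-node walks and no tuples.
* Probabilities are clipped away from {0, 1} (1e-12 in the embedding
  loss, 1e-7 in the classifier) before logs and in the cross-entropy
  denominator; non-finite losses abort with the epoch number.
* `selectTerms` breaks topological-order ties lexicographically, so the
  vocabulary is stable across platforms.
* One global seed derives per-stage seeds by hashing the stage name;
  every stage is therefore individually reproducible, and the pipeline
  records md5 hashes of the walk corpus, network, embeddings, and
  scores.
* Problem sizes in the test suite (worlds of 10–240 nodes, embeddings of
  dimension 4–32, classifiers of tens to hundreds of entities) were
  chosen as the smallest scales at which each property is
  non-degenerate.

# Known limitations

* Pairwise Pearson similarity is quadratic in the number of circRNAs;
  beyond ~10⁴ circRNAs a blocked or approximate scheme would be needed.
* The "has-a"-style second propagation relation is taken to be GO
  `part_of`; regulates-type relations are not propagated.
* Evaluation is namespace-restricted (biological process by default);
  cross-namespace annotation is out of scope.
* The per-term heads share only one hidden layer; very large
  vocabularies may benefit from the deeper DAG-chained variant this
  package intentionally omits.
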