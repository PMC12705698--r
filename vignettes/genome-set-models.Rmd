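---
title: "Genome language models over protein sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome language models over protein sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`genomeset` treats a genome as an ordered set of proteins, each protein
represented by a fixed, externally produced embedding vector (in practice a
protein-language-model embedding; in this package's experiments, synthetic
vectors with planted structure).  Two small learnable lookup tables supply a
positional feature (within-scaffold rank, clamped at `max_pos`) and a strand
feature (two entries); both are concatenated onto the protein embedding, so
the model width is `d_model = d_in + pos_dim + strand_dim`.

A minibatch of genomes is stacked into a single matrix with no padding.
Each scaffold is cut into contiguous, fully connected subgraphs of at most
`chunk_size` proteins (a trailing single protein is merged into the previous
subgraph, so no subgraph of a multi-protein scaffold has fewer than two
nodes and none exceeds `chunk_size + 1`).  Attention edges — including
self-loops — exist only within a subgraph.

The **encoder** applies `n_layers` pre-normalization blocks:

1. per-genome feature standardization (GraphNorm: learnable mean-scale
   `alpha`, scale `gamma`, shift `beta`, epsilon `1e-5`),
2. multi-head scaled-dot-product graph attention.  Scores are computed only
   on within-subgraph edges; the softmax is normalized, by default, over
   *all* edges whose query protein belongs to the same genome
   (`softmax_scope = "genome"`).  The published description is ambiguous
   between this genome-scoped reading and the classical per-query softmax,
   so both are implemented behind a config switch; note the genome scope
   makes individual query rows non-stochastic by design.
   The updated protein is `W^Q x_i + sum_j alpha_ij W^V x_j`,
3. a residual connection, a second normalization, a 2-layer GELU
   feed-forward block with dropout, and a second residual.

A final per-genome normalization closes the encoder; its output is the
contextualized protein embedding matrix used for protein-level analyses.

The **decoder** pools proteins into genome embeddings with multi-head
attention against a single learnable seed vector (shared across heads and
split into head slices).  Per head, each genome's attention over its
proteins sums to exactly one; the head-mean attention is the per-protein
importance score used in the attention analyses.  The re-weighted values
pass through residual/normalization/feed-forward blocks, are mean-pooled
per genome, and projected by a final feed-forward to `d_out`.  For
fragmented genomes the same machinery can be run per scaffold and the
scaffold embeddings averaged (`pool_scaffolds`).

All trainable parts run on a small reverse-mode autodiff tape implemented
in the package (`R/ad-tape.R`); the test suite verifies every primitive and
the full model against central finite differences (relative error below
1e-3 for the seed-vector gradient, far tighter for individual ops).

## Training objectives

**Triplet objective.**  For each minibatch genome (the anchor), the
positive is the genome with the smallest Chamfer distance — the symmetric
mean of nearest-neighbour squared distances between the two protein sets —
computed in the *input* embedding space, before positional/strand features
are attached.  The negative is mined in the *current model's* genome
embedding space by the semi-hard rule: the nearest candidate farther than
the positive, falling back to the candidate whose distance is closest to
the anchor–positive distance.  The hinge term is
`max(0, d²(a,p) − ω d²(a,n) + margin)` with
`ω = exp(−CD(a,n) / (2 (c σ)²))`, `σ` the standard deviation of the
minibatch's Chamfer distances (all anchor–candidate pairs evaluated during
mining; `σ = 0` is guarded to `ω = 1`).  PointSwap augmentation swaps each
anchor protein for its matched positive-genome protein with probability
`swap_rate`; the augmented triplet (anchor, its hybrid, a semi-hard
negative mined among the hybrids, with `ω` recomputed from the
anchor–hybrid-negative Chamfer distance) is averaged with the real one and
optionally weighted by inverse class abundance.

**Masked objective.**  The encoder-only variant zeroes the embedding slice
of a random protein subset (rate `mask_rate`, at least one protein) while
keeping positional/strand features, and minimizes
`1/(2 n_m) Σ (‖Y_pred − Y_target‖² + ‖Y_pos − Y_target‖²)` over masked
rows, where `Y_pos` comes from a second pass whose inputs are each
protein's non-self nearest neighbour (masked at the same rows — the
published description leaves this open; masking both streams keeps the two
error terms comparable).  Targets snapshot the current positional/strand
features.

**Optimization.**  Adam with elementwise gradient clipping at magnitude 1
and an optional linear learning-rate decay.  Desk-scale defaults, chosen by
running the package on its own synthetic data: minibatches of 16 genomes,
lr 0.01, margin 20, scale factor `c = 1`, swap rate 0.5, mask rate 0.15,
dropout 0.1.  Two of these matter more than the rest.  The margin sets the
Euclidean spread of the learned genome embeddings, and because the
downstream analyses use *angular* similarity — to which the
translation-invariant triplet loss is indifferent — that spread must be
large relative to the common offset the feed-forward blocks induce, or
unrelated genomes end up inside one narrow cone; small margins satisfy the
hinge long before families separate angularly.  Dropout is the
regularizer that keeps small-batch semi-hard mining from locking pairs of
families together early in training; without it family merges survive to
the end of a short run.

## Evaluation statistics

* `angular_similarity`: `1 − arccos(cos)/π` on L2-normalized vectors.
* `knn_similarity_graph`: exact k-nearest-neighbour search (k = 15),
  edges weighted by angular similarity, dropped below 0.9, symmetrized by
  union.  The published pipeline uses an inverted-index approximation purely
  for scale; exactness here is tested against brute force.
* `leiden_clusters`: igraph's Leiden implementation (modularity objective,
  resolution 0.9 by default), RNG reset and seeded before each run so
  clusterings reproduce exactly; singleton clusters are flagged and excluded
  from all downstream statistics.  The source text conflates a "similarity
  threshold of 0.9" with a "resolution of 0.9"; both knobs exist here and
  both default to 0.9.
* `purity`: information gain ratio `I = (H_bg − Σ w_i H_i)/H_bg`, base-2
  entropies; unlabeled items are excluded from the entropies but counted in
  the cluster-size weights; the background is either the single-cluster
  label distribution (taxonomy mode) or a supplied category profile
  (function mode).  A pure background makes `I` undefined and raises an
  error.
* `attention_rescale`: per-genome attention is rescaled by
  `D = (log2 n − H(A))/log2 n`, the normalized KL divergence from uniform;
  `n = 1` genomes get `D = 0`.  The 4-protein worked example
  `[0.5, 0.3, 0.05, 0.15] → [0.0881, 0.0528, 0.0088, 0.0264]` is a unit
  and acceptance test.
* `annotation_improvement`: for each unannotated protein, a hit at `k` if
  any of the `k` nearest neighbours is annotated (`mode = "any"`), or if at
  least one is annotated and all annotated ones share a category
  (`mode = "same_category"`; unannotated neighbours never penalize).
* `cooccurrence_enrichment`: within-cluster category pair counts
  `n_u × n_v`, summed over clusters; both the observed pair distribution
  and the background built from profile abundances are normalized over the
  pair set before the ratio, so a composition proportional to the
  background scores `E = 1` exactly (the source defines the ratio but not
  its normalization; this reading makes it scale-free).  The enrichment
  graph is clustered with Leiden at resolution 1.25.
* `detect_modules`: a cluster represents a module if all its annotated
  members lie in the module's categories and at least two of those
  categories occur; presets for the late-gene and DNA-interacting modules
  under the curated PHROG and VOG schemes ship with the package.
* `harmonic_pair_score`, `dice_similarity`, `protein_diversity_groups`:
  the identity/shared-gene aggregate, dice scores over protein-cluster
  presence profiles, and the greedy 4-group construction (largest
  components seed groups, per-seed priority queues by mean dice,
  round-robin popping, isolated genomes to the smallest group).
* `tetranucleotide_frequencies`: overlapping 4-mer frequencies over ACGT
  (U read as T, other characters removed before counting so windows span
  the junctions), averaged over scaffolds.

## Virus–host link prediction

The interaction graph is bipartite (virus and host nodes with genome
embedding features) plus virus–virus similarity edges: angular similarity
at least 0.75, pruned to each virus's 15 most similar neighbours
(embedding mode), or complete graphs within Leiden communities (resolution
0.1) of the dice gene-sharing graph after removing singleton protein
clusters (gene-sharing mode).

The encoder stacks graph-convolution layers with symmetric normalization
`D^{-1/2}(A + I)D^{-1/2}` and *separate weights per edge type*
(virus–virus, virus→host, host→virus; host→virus edges make message
passing reciprocal).  Self-loops route through the virus–virus weights for
virus nodes and the host→virus weights for host nodes — the edge-type set
defines no self type, so this convention is fixed and mirrored by the
tests' dense oracle.  The decoder scores the directed difference
`z_v − z_h` through a 2-layer feed-forward network ending in a logistic
unit.  Training: 80:20 edge split, uniform negative sampling with
`|E'| = |E|` resampled every epoch, optional disjoint 70:30
message-passing/supervision split of the training edges, binary
cross-entropy with test-virus edges masked from the loss, dropout 0.25,
Adam with decoupled weight decay 0.02 and a linearly decaying learning
rate (without both, the small planted graphs overfit within the 200-epoch
budget and validation AUROC decays), an early-stopping-style checkpoint
rule that keeps the parameters of the lowest smoothed-training-loss epoch,
hidden width 64 and decoder hidden width 64 (the decoder scores the
difference vector and needs enough rectified directions to approximate a
norm-like decision function).

## Synthetic data: what it emulates, and what it does not

`generate_embedding_dataset` plants `n_families` genome families at the
vertices of a scaled simplex (`family_separation` noise standard deviations
apart; a unit scale when `noise_sd = 0`), gives each family
`n_protein_clusters` centroids (2-SD within-family spread), and builds each
genome as an ordered centroid walk with a 10% same-family substitution rate
plus isotropic noise — so genomes of one family share ≥ ~80% of their
centroid repertoire and are each other's Chamfer nearest neighbours, which
is precisely the structure the mining assumptions need.  Functional
categories attach to centroids, 70% `"unknown"` by default to mirror the
70–90% unannotated regime of real viromes.  Strands flip between adjacent
proteins with probability 0.1.  Defaults: 5 families × 10 genomes, 5–30
proteins per genome, `d_in = 16`, separation 8, noise 0.25.

`generate_virus_host_graph` places host centres in random directions at
norm `separation × noise_sd` (default separation 12) and samples each virus
as its host's centre plus noise, so same-host viruses are angularly similar
enough (~0.8) to clear the interaction network's 0.75 edge threshold while
cross-host pairs are not.  Defaults: 40 hosts × 5 viruses each, noise 1,
20% of viruses held out.

What passing tests on these data do **not** show: real protein-language-
model embeddings are anisotropic, heavy-tailed and carry much weaker and
overlapping family structure; real genomes share proteins across families;
real virus–host graphs are sparse, noisy and biased.  The synthetic
experiments validate the machinery (mining, losses, gradients, graph
construction, statistics), not biological performance.

## Numerical choices and degenerate inputs

Base-2 entropies throughout; GraphNorm epsilon 1e-5; softmax scores shifted
by the per-group maximum; probabilities clipped at 1e-7 in the numeric
cross-entropy (training uses a softplus logit formulation instead); ties in
all argmin/argmax selections break to the lowest index; `σ = 0` Chamfer
batches give `ω = 1`; masking always retains at least one protein;
single-protein scaffolds are allowed (self-attention only) and
single-protein genomes get pooling-attention rescale factor `D = 0`.
Problem sizes in the test suite (50-genome training runs, 240-node
interaction graphs, ≤ 30-item oracles) are the package's desk-scale
defaults chosen so the full suite runs in minutes on one CPU.

## Known limitations

* Full-scale pretraining (100k+ genomes) is out of scope; the training
  loop is full-precision, single-threaded and keeps the whole dataset in
  memory.
* The encoder softmax scope of the published weights cannot be determined
  from the text; both scopes are provided, genome scope is the default.
* Checkpoints are plain RDS archives; no interoperability with the
  published PyTorch weights.
* The embedding store is TSV, chosen for transparency at desk scale; a
  binary store can be slotted behind the same read/write surface.
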