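---
title: "graphvir: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{graphvir: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its method: the sequence graph,
the embedding cascade, the attention classifier, the synthetic data used
to exercise them, and the places where the design was genuinely open and
a choice had to be made.

## The multilayer sequence graph

A query sequence is normalized to the alphabet `A C G T N 0`: lowercase
is uppercased, every IUPAC ambiguity code (R, Y, S, W, K, M, B, D, H, V)
and any stray letter becomes `N`, and `0` is the pad symbol. Padding and
`N` are deliberately distinct symbols: `N` is a real, if uninformative,
base that participates in the graph, while pad positions are masked out
of every attention neighborhood. Sequences shorter than 90 bp are
rejected — the finest useful graph needs at least one 90-mer.

Length normalization has three regimes. Sequences that pad (to a
multiple of 90) to less than 900 bp keep a short graph of their own
(500 bp pads to 540 bp: six 90-mers, sixty 9-mers, 540 bases, no E4
edges). Sequences between 900 and 9000 bp are zero-padded to 9000 bp.
Longer sequences contribute one contiguous 9000 bp window whose start
offset is drawn uniformly from the valid range under the run seed; a
deterministic centered window is available as an option.

The graph's nodes are the segments of the four levels (10/10/10/9
children per parent; 10 110 nodes for a 9000 bp input). Edge rules, with
`j9 = floor(p/9)`, `j90 = floor(p/90)`, `j900 = floor(p/900)` for the
base at 0-based position `p`:

* direct: parent–child at adjacent levels;
* E1: bases `i`, `j` with `0 < |i - j| <= k`, default `k = 4`;
* E2: base `p` to 9-mers `j9 .. j9 + 9` (the containing 9-mer anchors
  the span);
* E3: base `p` to 90-mers `j90 + 1 .. j90 + 6` — the containing 90-mer
  is skipped because its neighborhood is already reached through E2;
* E4: base `p` to 900 bp segments `j900 + 1 .. j900 + 3`, skipping the
  containing one for the same reason.

This "containing unit plus rightward span" anchoring is the one rule
that yields exactly 10/6/3 targets for interior bases while keeping the
E2/E3 overlap exclusions. All spans clip at the right end of their
level.

Hierarchy and segment edges are materialized in both directions by
default (`bidirectional_segment_edges`). The graph is nominally directed
and a strictly rightward reading is expressible by turning the flag off,
but attention needs information to flow both up and down the hierarchy,
and under a strictly rightward reading the claim that any two nodes sit
within three hops is provably unreachable for distant base pairs.
`graph_stats()` therefore reports measured BFS eccentricities on the
undirected view instead of asserting a diameter; on the defaults the
sampled eccentricity of a full 9000 bp graph is 4. At `k = 4` a 9000 bp
graph carries 418 790 directed edges (209 395 unordered pairs), within a
factor of two of the nominal 18 000 x (k + 10) = 252 000, and the edge
list is reproduced exactly by a brute-force enumeration oracle in the
test suite.

Each edge stores a clipped signed relative offset (default clip 16), the
index distance between the two endpoints measured in the coarser
endpoint's units (base positions for E1, the child index within the
parent for direct edges, the span offset for E2–E4; reverse edges negate
it). These offsets index the relative-position embedding of the
classifier, so the clip bounds that table.

Whether the whole 9000 bp sequence is itself a node was open; the
10 110-node count excludes it and the readout merges the ten 900 bp
vectors, so no root node is built. Edges between two fully padded nodes
never exist; E1–E4 edges touching any padded node are dropped outright,
direct edges survive with one padded endpoint so the hierarchy stays
structurally complete, and padded nodes are excluded from every
attention neighborhood regardless.

## The embedding cascade

One-hot encodings over these vocabularies are implicit everywhere: a
one-hot vector times a weight matrix is a row lookup, so bases and
9-mers carry integer ids (base-4 code, UNK = 4^9, PAD = 4^9 + 1) and the
tables own the rows. For 90-mers and 900 bp segments no finite
vocabulary exists, which drives two design decisions below.

Four two-layer GCNs are trained in order, coarse to fine, on bipartite
corpus graphs: whole (padded) sequences over their 900 bp segments,
900 bp segments over 90-mers, 90-mers over 9-mers, 9-mers over bases.
Tokens are deduplicated by string; parent–child edge weights are
TF-IDF-scaled occurrence counts (binary weights are a config option for
ablation). Each stage is
supervised by the parent sequence's class through a softmax head on the
30-dimensional second-layer output; supervising every stage with the
inherited sequence label is the design choice made here (segments could
in principle carry their own labels, but none exist). The GCN layer is
`activation(D^-1/2 (A + I) D^-1/2 X W)` with ReLU on layer 1 and
identity on layer 2; the first-layer width is a free choice, 64 by
default. Child input features are a learned row table; the first
stage's parents get learned rows too, later stages' parents are fixed to
the previous stage's child vectors. Training is Adam (lr 0.003, batch of
200 parent nodes per step, 200 epochs) with an early stop when the
epoch loss moves by less than 1e-4 relative over 10 epochs.

At inference a novel 90-mer or 900 bp segment cannot be looked up, so
its vector is composed: a star graph of the parent (zero input) and its
children (their final vectors, deduplicated with count weights) is
propagated through the trained stage's two layers and the parent row of
the second layer is read off. This is the only way trained-embedding
initialization can work for novel query sequences, and it keeps a
useful invariant: identical 90 bp blocks get identical
vectors wherever they occur. 9-mers unseen in training fall back to an
UNK vector (the trained vector of the N-token when one was observed,
otherwise the mean of the observed rows); pad rows are frozen at zero.

After training, all vector tables are rescaled by one global constant so
the observed 9-mer rows have unit mean norm. Cascade outputs are
otherwise unbounded and their magnitude varies from run to run, while
the classifier's initialization assumes O(1) inputs; because ReLU
propagation is positively homogeneous, the rescale carries exactly
through the compositional inference and changes nothing but the overall
scale. Without it, occasional runs started with saturated readout logits
and failed to train.

The flat ablation (`variant1`) trains only the finest stage and forms
higher-level vectors by degree-normalized averaging of child vectors.
Concatenating child vectors would change the dimension while the
attention weights are shared across levels at d = 30, so a
dimension-preserving merge is used instead.

## The attention classifier

One graph self-attention layer (stacking is a config option) updates
every active node: queries from the node, keys and values from its
neighbors, six heads of width 5 over d = 30, logits
`q · (k + r) / sqrt(d)` with the relative-position row `r` added to the
key. The default scaling divides by the full width d; dividing by the
per-head width instead is available as `scale_by_head`. Nodes with no active
neighbors pass through unchanged. Head outputs are concatenated and
projected by `W^O`. Residual connections and row normalization are off
by default, keeping the update in its plain form; a config switch
enables these common stabilizers.

The readout concatenates the ten 900 bp node vectors in positional
order (short mode: the 90-mer vectors, right-padded with zero slots to
the same 300-dim width, so one readout serves both modes), applies a
20-unit ReLU layer and a softmax over {host, virus}; the virus-class
probability is the score. Training minimizes cross-entropy with Adam
(lr 0.0002, batch 128, 50 epochs at full scale), with inverse-frequency
class weights by default since real corpora are heavily host-skewed.
The classifier ablation (`variant2`) replaces the attention stack with a
plain two-layer GCN (width 30 hidden) over the same graph and readout.

Numerics worth knowing: with one attention layer and the readout at the
900 bp level, only the readout nodes' neighborhoods (and, for the GCN
variant, their two-hop neighborhoods) influence the loss. The trainers
exploit this with per-record restricted views batched into single matrix
operations per Adam step; the arithmetic is identical to the full-graph
update (the tests compare both against dense oracles) and only dead
computation is skipped. Grouped softmaxes subtract per-group maxima, so
attention never overflows. All randomness (initialization, batch
shuffles, window draws) derives from the run seed through fixed streams;
two runs with the same seed produce bit-identical checkpoints,
predictions and metrics.

## Synthetic data

The generator stands in for the RefSeq training corpus, which is not
shipped. Both classes draw from order-2 Markov chains (codon-scale bias
at minimal cost; the order is configurable). A shared transition matrix
is drawn once per run from a concentrated Dirichlet; each class
interpolates between it and an independent flat-Dirichlet draw with
weight δ, so δ = 0 makes the classes literally identical and δ = 1 makes
them independent chains. Optionally a motif set (four random 9-mers by
default) is planted into the virus class at Poisson rate λ per kb,
overwriting the background at uniform positions. A GC-offset knob adds a
third, simpler axis of divergence. The manifest records matrices, motif
positions and the seed.

What the simulator reproduces: class-specific k-mer composition at every
scale the graph sees, and enriched exact motifs. What it does not: gene
structure, shared homology blocks between related genomes, chimeric
contigs, real length distributions, sequencing error. Passing the
recovery tests therefore shows the pipeline can extract compositional
and motif signal end to end — not that it reaches any particular
accuracy on real metagenomes.

## Desk-scale study conditions

The test suite and `scripts/acceptance.R` run the pipeline end to end at
a scale chosen once for a single CPU: 200 records per class at a fixed
1800 bp, split 75/25, with the strong-signal condition δ = 0.5 plus four
motifs at λ = 5/kb (both signal knobs exercised at once), and a null
condition δ = 0, λ = 0 over three seeds. The desk training profile
shrinks the schedules — embedding 30 epochs with corpus stages capped at
2000 parents, classifier 15 epochs at batch 32 — and raises the
classifier learning rate to 0.002, because desk-scale training takes two
orders of magnitude fewer Adam steps than the full-scale schedule the
0.0002 default is sized for. Under these conditions the full model's
held-out AUC exceeds 0.9, the null runs sit at chance, and the ablation
ordering (full, then the GCN classifier, then the flat embedding) is
reproduced qualitatively.

One visible desk-scale artifact: with ~10^5 distinct 9-mers in a small
training corpus, most query 9-mers are unseen and map to the UNK vector,
which shifts held-out scores toward the host side without disturbing
their ordering. AUC — the threshold-free metric — is unaffected, but
accuracy at the fixed 0.5 threshold understates the separation. At
realistic corpus sizes 9-mer coverage approaches completeness and the
effect vanishes.

## Known limitations

* With one attention layer and a 900 bp-level readout, E1 and E2 edges
  cannot influence predictions (their information enters only through
  deeper stacks); they are still built, and `layers > 1` uses them.
* The embedding cascade is supervised at every level with the inherited
  sequence label; segments shared verbatim between classes get the
  majority label.
* Score calibration at desk scale is conservative (see above); decision
  thresholds other than 0.5 may be preferable on small corpora.
* Full-scale benchmark results on RefSeq, CAMI or real gut metagenomes
  require the external corpora and full-scale training and are out of
  scope here; the package's checks are the combinatorial,
  oracle-equivalence and synthetic-recovery properties above.
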