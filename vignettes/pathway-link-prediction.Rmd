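---
title: "Predicting pathway links from literature co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pathway links from literature co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litpath)
```

## The model

`litpath` treats relation extraction as link prediction on a text-derived
network. Three stages:

1. **Mining.** Abstracts are split into sentences; gene mentions are found
   by case-insensitive dictionary matching at token boundaries, resolved
   longest-match-first, and merged to canonical identifiers (so `IRS1` and
   `IRS` can map to one node `IRS1/IRS`). Two entities are linked whenever
   they co-occur in one sentence; the edge weight is the number of such
   sentences over the corpus. The underlying assumption is that same-sentence
   co-mention is a much stronger relatedness signal than same-abstract
   co-mention, which is why entities mentioned only in different sentences of
   one abstract share no edge. Titles are treated as sentence 0 of a record.

2. **Embedding.** node2vec samples second-order random walks on the weighted
   network. Standing at node $c$ having arrived from $t$, the unnormalized
   probability of stepping to neighbor $x$ is
   $\alpha_{pq}(t, x)\, w_{cx}$ with $\alpha = 1/p$ if $x = t$, $\alpha = 1$
   if $x$ is adjacent to $t$, and $\alpha = 1/q$ otherwise. A skip-gram model
   with negative sampling is trained on the walks: every pair of nodes within
   $k$ positions is a positive example, contrasted against negatives drawn
   from the unigram distribution raised to 0.75, optimized by per-pair SGD
   with a linearly decaying learning rate. DeepWalk is the $p = q = 1$
   special case, run with the same parameters for comparability.

3. **Ranking and evaluation.** For each start gene, all other embedded
   gene-typed nodes are ranked by cosine similarity; a pathway link is
   *captured* when the target appears in the top $K$ (default 100). Known
   interactions come from a typed pathway model whose indirect edges are
   expanded through auxiliary pathways into chains of direct links; the
   evaluation reports capture counts, within-threshold counts, head-to-head
   win/loss/tie triples over links captured by both methods, forward versus
   reversed ranks, and degree centrality of the extended network.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `p` | 1 | return bias; walks revisit the previous node with weight $1/p$ |
| `q` | 0.5 | in-out bias; $q<1$ pushes walks outward, favoring community structure |
| `r`, `l` | 10, 10 | walks per node and walk length in nodes ($l$ nodes = $l-1$ steps) |
| `d` | 128 | embedding dimension |
| `k` | 10 | skip-gram context window |
| `K` | 100 | candidate list size defining "captured" |

`q = 0.5` encodes the goal of the analysis: genes in the same pathway form
densely interconnected communities, and homophily-biased walks place them in
similar contexts. The skip-gram internals the walk papers leave unstated are
fixed at word2vec conventions (5 negatives, 5 epochs, initial learning rate
0.025 decaying linearly to 1e-4 of itself, unigram^0.75 negative
distribution) and recorded in `train_config()` for reproducibility.

Transitions are weighted by co-mention counts by default (`weighted = TRUE`
in `walk_config()`), since the input network is weighted; the binary
alternative is a flag. Walk length counts nodes, not edges. Ties in any
ranking are broken lexicographically by identifier so that results are
reproducible; candidate pools are restricted to gene-typed nodes by default,
and nodes already adjacent in the co-occurrence network are deliberately
*not* excluded from candidates, because the evaluation asks for the rank of
known pathway partners.

## Numerical and degeneracy choices

* Walk sampling uses precomputed alias tables per directed (previous,
  current) node pair — O(1) per step — built once per simulation.
* All stochastic stages (walk-start shuffling, step sampling, SGD
  initialisation, negative draws, corpus generation) are driven by integer
  seeds through a dedicated deterministic generator, so identical seeds give
  byte-identical corpora, walks and embeddings, independent of R's global
  RNG state.
* Isolated nodes yield length-1 walks; they still receive (near-random)
  vectors. Nodes that occur in *no* walk get no vector at all, and ranking
  such a start (or looking for such a target) reports the `NOT_CAPTURED`
  sentinel rather than a zero vector, whose cosine would be undefined.
* Sentence splitting protects a fixed abbreviation list (i.e., e.g., et al.,
  Fig., ...) and requires the next sentence to open with a capital or digit;
  concatenating the output always recovers the input modulo whitespace.

## The synthetic study conditions

The generator emulates a keyword-restricted abstract corpus whose
co-mentions are driven by a planted truth network. The default conditions,
fixed once for all analyses and tests:

* 30 genes in 3 planted-partition blocks, edge probability 0.5 within and
  0.05 between blocks — dense pathway-like communities with sparse
  cross-talk;
* 2,000 abstracts of 8 sentences — enough sentence slots that pair events
  are sparse per sentence, as in real abstracts;
* expected co-mentions per true edge `lambda_direct = 50`, chosen as a
  desk-scale stand-in for the count range published for strongly co-cited
  gene pairs (thousands of co-mentions in ~100k abstracts scale down to
  tens in 2,000);
* background rate `lambda_noise = 0.5` per non-edge pair, so noise pairs
  exist but are separated from true edges by two orders of magnitude;
* synonym usage probability 0.2, exercising canonicalization;
* 2 *hidden* genes whose every incident edge is flagged absent and which
  never appear in the corpus.

Hidden genes model the observed failure mode of abstract-only mining: some
interacting gene pairs appear exclusively in full text, so their entities
never enter the co-occurrence network and no embedding method can rank
them. Pair-level absence alone would not guarantee this — an absent pair
between two otherwise well-connected genes can still be recovered through
shared neighborhoods, which is precisely the point of the embedding — so
the failure mode is attached to entities, not pairs.

Each co-mention event is placed in a uniformly chosen free sentence slot
and a sentence carries at most one planted pair (plus optional singleton
mentions), keeping per-pair counts independent Poisson draws. Sentences are
generated from a small template set; the generator makes no attempt to
model realistic biomedical prose, MeSH annotations, or publication dates.
Consequently, passing the synthetic benchmark demonstrates that the
*pipeline* recovers a planted signal under literature-like sparsity — it
does not certify performance on real abstracts, where mention ambiguity,
species variation and NER errors dominate. On these friendly conditions the
plain co-occurrence baseline is essentially perfect (the planted counts
*are* the signal); the embedding's added value shows where counts are
absent or diluted, which is what the capture-vs-hidden-pair contrast
isolates.

## Encoded pathway tables

The shipped type 2 diabetes fixture encodes the insulin-resistance slice of
the KEGG pathway: 19 entities, 18 gene-gene interactions (9 indirect), the
expansion chains through the insulin and adipocytokine signaling pathways,
and the published per-method rankings of the resulting 30 direct links.
Three encoding decisions:

* The printed expansion table is typographically garbled in the source; the
  chains here are reconstructed so that their consecutive pairs reproduce
  the authoritative 30-row ranking table exactly. Five chain pairs
  (mTOR–TRAF2, TRAF2–JNK, TRAF2–IKK, GLUT4–AMPK, ADIPOR–AMPKK) are marked
  undirected: they enter the 29-gene/35-edge extended network but not the
  directed evaluation set.
* A chain may connect its indirect edge's endpoints in either orientation,
  because published chains follow signaling flow (e.g. the ERK-to-IRS
  expansion runs IRS1/IRS → GRB2 → … → ERK1/2).
* Entity labels are normalized as in the source tables: IRS1 and IRS merge
  to `IRS1/IRS`, TNF-alpha to `TNFA`, PKC variants stay distinct as `PKCZ`
  and `PKCD/E`, and ERK is written `ERK1/2` on edges; the entity list keeps
  the 19 printed rows.

The PI3K→GLUT4 expansion keeps exactly two chains (via PDK1/2 and AKT, and
via PDK1/2 and PKC), following the biological argument that PDK1/2
phosphorylates the AGC kinases downstream of PI3K; repeated links across
chains (IRS–GRB2, PI3K–PDK1/2) collapse to one evaluation row per unique
ordered pair.

## Problem sizes

The test suite and acceptance script run the full synthetic study (30
genes, 2,000 abstracts, 128-dimensional embeddings) in well under a minute,
and verify the walk sampler against brute-force enumerated second-order
distributions with at least $10^5$ sampled transitions per parameter
setting on a suite of graphs with at most 8 nodes — sizes at which exact
enumeration is trivial while sampling error is already below a percent.

## Known limitations

* Dictionary matching stands in for statistical NER: no abbreviation
  disambiguation, no species resolution, no novel-entity discovery. The
  dictionary's semantic-type field keeps the gene/protein type filtering
  representable.
* Whether real mining pipelines should count co-mentions per sentence or
  per abstract is not settled; this package counts per sentence, matching
  its linking rule.
* Cosine ranking is the only scorer; learned edge features (Hadamard, L2)
  are out of scope.
* The direction-reversal analysis demonstrates a mechanism — the competitor
  set changes with the starting node, so an undirected embedding can still
  rank directions asymmetrically — not a calibrated direction classifier.
* Exact reproduction of the published real-corpus rank values would require
  the original 99,689-abstract collection, which has no accession; the
  package reproduces every statistic derivable from the published tables
  and validates the computational core on synthetic data instead.
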