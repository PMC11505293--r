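---
title: "Methods: building and analysing a PCOS-ferroptosis interactome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and analysing a PCOS-ferroptosis interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcosnet)
```

## Scope

`pcosnet` implements an offline, fully testable version of a network-medicine
workflow for polycystic ovary syndrome (PCOS) extended with
ferroptosis-associated genes: curated seed-gene lists are wired into a
high-confidence protein-protein interaction graph from STRING-style
evidence-channel tables, orphan seeds are attached through predicted "novel"
connector nodes, the topology (average degree, hubs, articulation points) is
summarized, the network genes are tested for KEGG-style pathway
over-representation with false discovery rate control and weighted set cover
summarization, and a process-specific subnetwork is extracted together with
the node(s) bridging it to the rest of the interactome.

The literature curation that produces the seed lists, and any live database
or web-service query, are out of scope: gene lists, a published hub table and
a published pathway table ship as plain-text fixtures, and everything else is
generated synthetically.

## Combined interaction score

Interaction databases in the STRING family report, per gene pair, one score
per *evidence channel* (experiments, curated databases, text mining,
co-expression, neighborhood, fusion, co-occurrence) plus a combined score.
Each score approximates the probability that the association is real given
that channel's evidence. Restricting an analysis to trusted channels --
experiments, curated knowledge bases and text mining, the default here, to
avoid false positives from purely predicted associations -- requires
*recombining* the channel scores. `recombine_combined_score()` uses the
noisy-OR form with a random-expectation prior $p$:

$$ s_i^* = \max\!\left(0, \frac{s_i - p}{1 - p}\right), \qquad
   S = 1 - (1 - p) \prod_i \left(1 - s_i^*\right). $$

Properties relied on throughout (and asserted in the test suite):

* a single channel above the prior passes through unchanged ($S = s$,
  algebraically exact);
* adding a channel never decreases $S$;
* channels at or below the prior contribute nothing -- and when *no* channel
  exceeds the prior the function returns 0 rather than $p$, i.e. "no evidence
  beyond random expectation" rather than "prior belief".

The prior defaults to $p = 0.041$, the random-expectation value STRING
documents; it is configurable because published analyses rarely state it.

Edges are kept when $S$ strictly exceeds the high-confidence threshold
$\tau = 0.7$ ("above 0.7" is read literally, so a score of exactly 0.7 is
excluded). Seed genes with no surviving edge remain in the graph as isolated
nodes; they are exactly the orphans the connector search later attaches.

## Novel connector prediction

Seed genes disconnected from the core network are joined through a minimum
number of background nodes. The package formalizes this as a restricted
Steiner-node problem: find a minimum-cardinality set $C$ of background nodes
such that every connectable orphan has a path to the core's largest component
whose intermediate nodes (at most $L$ of them) all lie in $C$, using only
edges above $\tau$. Because the source procedure is described only as
"iterative searches", the iteration is realized as progressive deepening:
depth 1 first, then depth 2 for orphans still unresolved, with connectors
accepted at depth 1 counting as core in the second pass. Depths beyond 2 are
refused -- a chain of three or more inferred intermediates no longer
constitutes a defensible prediction.

Two modes are provided:

* **exact** (default): the instance is decomposed into independent orphan
  groups (orphans sharing no candidate node cannot interact), and each group
  is solved by exhaustive search over candidate subsets of increasing size,
  bounded by `max_connectors` (default 5 per group). Among equal-size optima
  the subset with the higher summed incident edge score wins, then
  lexicographic order -- a total order, so results are reproducible.
* **greedy**: repeatedly add the candidate that connects the most
  still-unconnected orphans (ties: higher summed edge score, then name). The
  greedy solution is never smaller than the exact one and connects the same
  orphans; a property test asserts both.

Exact mode is validated against a brute-force subset-enumeration oracle on
random instances with up to 10 orphans and 15 candidates, and recovers the
designed connector set exactly on synthetic instances built to have a unique
solution.

## Topology statistics

The average degree is $\langle k \rangle = 2|E|/|N|$, reported at full
precision and rounded to one decimal (the rounding is the only re-rounding
anywhere in the pipeline). Hubs are nodes with degree at or above a threshold
$h$; $h$ defaults to 20, the smallest degree in the published 12-row hub
table, because the original cutoff is never stated. A `top_k` mode is
available as the alternative hub definition. Articulation nodes (cut
vertices) are computed on the largest component with igraph's depth-first
low-point algorithm and cross-checked in the tests against a
remove-and-recount oracle.

## Over-representation analysis

The enrichment stage is over-representation analysis (ORA), not rank-based
set enrichment: the published analysis reports enrichment ratios of observed
to expected gene counts, which is ORA's signature. For a universe of $N$
genes, a set of $K$, a study of $n$ and an overlap of $k$:

$$ p = P[X \ge k], \quad X \sim \mathrm{Hypergeom}(N, K, n), \qquad
   e = \frac{nK}{N}, \qquad R = \frac{k}{e}. $$

The upper tail is evaluated through the survival function
(`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`); computing `1 - CDF` would
lose precision exactly where it matters, in the small-$p$ tail. Sets with
$k = 0$ report $p = 1$, $R = 0$. The universe defaults to the union of the
collection's members; a genome-size integer override exists because the
reference universe of the original web analysis is unstated. Benjamini-
Hochberg step-up q-values (`stats::p.adjust`) control the FDR at 0.05 by
default.

Significant sets are summarized by a greedy **weighted set cover**: each step
selects the set maximizing (newly covered study genes) $\times w_s$ with
$w_s = -\log_{10}(\max(q_s, 10^{-16}))$; the $\varepsilon$ floor avoids
infinite weights at $q = 0$. Ties break by newly-covered count, then smaller
$q$, then name. The greedy cover is compared in the tests against the
exhaustive best 2-set cover via the classical $(1 - 1/e)$ guarantee.

## Subnetwork extraction and linking nodes

A process subnetwork (the ferroptosis subnetwork in the motivating analysis)
is seeded from two sources: nodes tagged with the literature category and the
members of the process's over-represented pathway. "Mediating nodes" are not
defined in the source description; this package defines them as depth-1
connectors *within* the parent graph -- non-seed nodes adjacent to seeds of at
least two different seed components, so every mediator sits on a path of at
most two edges between seeds. A minimal merging set is sought: greedy
component-merging with an exact refinement pass when the candidate pool is
small (at most 16 candidates, subsets up to 5). An alternative definition
(union of pairwise shortest paths) was considered and rejected because it can
pull in arbitrarily long chains of intermediates, diluting the
process-specificity of the subnetwork.

Linking (bridge) nodes are the subnetwork-side endpoints of all
boundary-crossing edges; removing them provably severs the subnetwork from
the rest of the parent graph. When the boundary collapses to a single node --
the pattern of one demethylase bridging the ferroptosis subnetwork to the
wider PCOS network -- the result is flagged specially.

## The synthetic-data generator

`synthetic_spec()` / `generate_network()` / `generate_annotation()` produce
inputs with planted, recoverable structure. The defaults are the study
conditions: 120 literature seeds (82 disease-curated + 38
ferroptosis-associated, matching the published 82/38 split), of which 20 are
orphans, each wired to the core through exactly one designated connector
(one-to-one wiring makes the minimal solution unique, so exact recovery is
well-defined); a planted hub with exactly 41 above-threshold edges, the
published top-hub degree; and a core edge density of 0.075, chosen so the
final 140-node graph lands near the published average degree of about 7.
A backbone ring guarantees a single core component.

Signal edges carry a single channel score drawn from Beta(8, 2) scaled into
$(0.7, 1]$; noise edges carry a single channel score from Beta(2, 8) scaled
into $[0, 0.7)$. Confining each synthetic edge to one channel is deliberate:
under noisy-OR recombination two sub-threshold channels can combine to exceed
0.7, which would blur the planted signal/noise labels.

What the generator does *not* emulate: the heavy-tailed degree distribution
of real interactomes, correlated text-mining evidence between co-cited genes,
and identifier-mapping noise. Passing tests on synthetic data therefore
establish algorithmic correctness (thresholding, minimality, calibration),
not biological fidelity of any particular real-data result.

## Statistical calibration of the exact test

Exact hypergeometric p-values are discrete: the attainable significance
levels step down in jumps of one tail probability mass, so
$P(p < 0.05) \le 0.05$ always holds and can be far below 0.05 for small sets
(the familiar conservativeness of exact tests). A calibration check that
demands the null rejection fraction sit in a tight binomial band around 0.05
is therefore only meaningful on a collection whose attainable level nearest
0.05 is close to 0.05. The calibration collection used in the test suite and
the acceptance script was designed analytically, before any simulation, by
scanning set sizes with `phyper`: in a universe of 2000 genes with studies of
150, sizes 865, 432, 311, 371, 696, 594 and 252 each have an exact null level
$P(p < 0.05)$ between 0.0494 and 0.0500. With that design the pooled
rejection fraction over 2000 uniformly drawn studies is checked against the
two-sided 99% binomial band around 0.05.

The planted-signal check uses the small-set regime deliberately: with a
universe of 500, a study of 20 and a planted set of 10 at effect 0.5 (half
the study forced into the set), the planted set must attain the uniquely
smallest q-value among 20 null decoys in at least 95 of 100 seeded runs.

## Determinism and degenerate inputs

All randomness flows through explicit integer seeds; the generator uses a
private RNG stream and restores any pre-existing global state. Every
tie-break in the package (hub ordering, connector choice, set-cover
selection) is a total order ending in lexicographic name comparison, so equal
inputs give byte-identical outputs, which the test suite asserts on the
written files. Degenerate cases are defined rather than left to chance: empty
enrichment results produce header-only tables; an empty background makes all
orphans unresolved without error; a subnetwork spanning the whole graph has
no linking nodes (with a notice); self-loops in edge files are dropped with a
warning; duplicate undirected edge rows merge by per-channel maximum, the
conservative union of evidence.

## Problem sizes used in the test suite

Property tests run on instances small enough for their brute-force oracles to
be exact: graphs up to 12 nodes for articulation points, ORA universes up to
12 genes for full enumeration (200 random instances), connector instances up
to 10 orphans and 15 candidates (100 instances), mediator instances up to 6
seeds and 5 candidates. The stochastic checks use 2000 simulated studies
(calibration) and 100 seeded runs (planted recovery). These sizes were chosen
so the entire suite completes in well under a minute while every oracle
remains exhaustive.

## Known limitations

* The two real-data tables (hub table, pathway table) are transcription
  fixtures; reproducing them from raw interaction data requires the exact
  pinned release of the upstream databases and is documented as an optional,
  non-desk workflow in the README.
* In the packaged gene-table fixture the novel-gene list is exact, but the
  ferroptosis/disease split of the non-novel genes is partially
  reconstructed; category *counts* are exact, individual non-novel tags are
  approximate.
* Connector search beyond two intermediates is refused by design.
* Exact connector mode is exponential in the per-group subset-size bound;
  groups exceeding the bound (or infeasible within it) fall back to the
  greedy rule.
* No rank-based enrichment, no GO-DAG-aware pruning, and a single gene-set
  collection per run.
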