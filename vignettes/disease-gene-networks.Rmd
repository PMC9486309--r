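---
title: "Disease-gene networks: enrichment, crosstalk, and seed-pair betweenness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-gene networks: enrichment, crosstalk, and seed-pair betweenness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdnet)
```

amdnet implements a three-stage analysis for a curated disease gene set —
the kind of symbol list assembled from genetic-association literature, as
has been done for age-related macular degeneration (AMD). This vignette
explains the statistical model of each stage, the tunable parameters and
their defaults, what the synthetic-study generator emulates (and what it
does not), and the numerical conventions the package commits to.

## Over-representation analysis

For a query set of $n$ genes inside a background universe of $N$ genes,
and a pathway annotating $K$ of the background genes, the number $k$ of
query genes in the pathway is hypergeometric under the null of uniform
draws. `hypergeom_upper_tail(k, K, n, N)` returns $P(X \ge k)$, the
one-sided Fisher exact p-value for over-representation; over-representation
is the only direction tested, because depletion of a curated disease set
in a pathway is not the question these analyses ask. The computation uses
R's `phyper`, which works on log scale internally; the test suite checks
it against exhaustive enumeration of all $\binom{N}{n}$ draws for every
$N \le 15$.

`enrich()` applies three explicit conventions:

* **Background.** Defaults to the union of all genes in the annotation
  collection. Curated studies typically delegate this choice to a web
  service whose snapshot is unreproducible; the union convention is the
  standard offline choice and is configurable via `background =`.
* **Retention before testing.** Pathways containing fewer than
  `min_observed = 2` query genes are dropped *before* testing, and the
  Benjamini–Hochberg correction runs over exactly the retained tests.
  This mirrors the filter convention of pathway-crosstalk studies, where
  one-gene pathways carry too little information to interpret.
* **Flat sets.** GO terms and pathways are treated as flat GMT gene sets;
  no ontology up-propagation is attempted.

Significance defaults to BH-adjusted $p < 0.05$ (`alpha`); the stricter
joint rule (raw $p$ *and* adjusted $p$ below `alpha`), which some
analyses apply to GO terms, is available as `require_raw_p = TRUE` rather
than guessed as a default.

BH adjustment itself is the step-up rule
$q_{(i)} = \min_{j \ge i} p_{(j)} \, m / j$ clipped at 1, delegated to
`stats::p.adjust(method = "BH")` and verified in the tests against
hand-evaluated vectors.

## Pathway crosstalk

Two significant pathways crosstalk when they share at least
`min_shared = 2` candidate genes. Each retained pair is scored
$$\mathrm{score}(A, B) = \tfrac12\left(\frac{|A \cap B|}{|A \cup B|} +
\frac{|A \cap B|}{\min(|A|, |B|)}\right),$$
the mean of the Jaccard and overlap coefficients, which always satisfy
$0 \le \mathrm{JC} \le \mathrm{OC} \le 1$.

**Which sets are A and B?** By default the pathways' *observed
candidate-gene sets* (query ∩ pathway): the shared-gene filter counts
shared candidate genes, and candidate sets are the only operands
reproducible without the annotation snapshot the original databases
provided. Scoring full pathway memberships instead is available via
`build_crosstalk_edges(use = "members")`. Published score tables are not
asserted against either mode: the published rendering of the reference
crosstalk table is corrupted, and which operand convention produced it is
ambiguous.

**Top-fraction filter.** `select_top_fraction(edges, 0.5)` keeps the
$\lceil f \cdot |E| \rceil$ highest-scoring edges and additionally keeps
any edge tying the cutoff score. Ceiling plus tie-retention makes the
filter deterministic, order-independent, idempotent, and monotone in $f$;
the convention itself is a package choice, since published descriptions
of "top 50%" filters rarely state their rounding.

**Modules.** `detect_modules()` clusters the retained edges with greedy
modularity maximization (igraph's fast-greedy agglomeration, scores as
weights) rather than connected components, because a single connector
pathway joining two modules would otherwise merge them. Two numerical
conventions make it deterministic: nodes enter the graph in sorted
pathway-id order, and the dendrogram is cut at the *coarsest* partition
achieving maximal modularity, so exact ties (a lone clique has $Q = 0$
both as one community and under some splits) resolve to the merged
partition. The test suite verifies the cut against exhaustive partition
search on a 7-node toy. Nodes whose closed neighbourhood spans two or
more modules are flagged as bridges — the connector pathways.

## Seed-pair betweenness and the permutation FDR

For an unweighted, undirected, simple interactome and a seed set $S$, the
statistic for gene $v$ is
$$B(v) = \sum_{\{s,t\} \subseteq S,\; s \ne t} \sigma_{st}(v),$$
the number of geodesics between all unordered seed pairs on which $v$ is
an *interior* node. All geodesics per pair count (equivalent to a
$K$-shortest-path search with unbounded $K$ restricted to minimal
length); distances are hop counts; disconnected pairs contribute nothing;
endpoints score zero for their own pairs, but a seed can score as an
interior node of other pairs' geodesics — which is why seed genes may
legitimately appear in the candidate output. Unordered pairs are used;
ordered pairs would double every count and leave selection invariant at a
doubled threshold.

The implementation (C++ via Rcpp) runs one BFS per seed to obtain
distances $d_s(\cdot)$ and geodesic counts $\sigma_s(\cdot)$, then uses
$\sigma_{st}(v) = \sigma_s(v)\,\sigma_t(v)$ iff $d_s(v) + d_t(v) =
d(s,t)$. Counts are accumulated in doubles (exact for integers up to
$2^{53}$). The tests check equality with brute-force enumeration of all
geodesics on hundreds of random graphs, plus the conservation identity
$\sum_v \sigma_{st}(v) = \sigma_{st}(d(s,t) - 1)$ per pair.

**Permutation null.** `permutation_null()` redraws $|S|$ nodes uniformly
at random from the whole graph (the convention when no degree model is
stated), `n_perm = 100` times, and recomputes every gene's statistic.
Replicate $r$ derives its RNG stream from (master seed, $r$), so results
are bit-reproducible and independent of evaluation order. A
degree-stratified mode (sampling within degree deciles to match the real
seeds' degree profile) is available but not the default.

**Selection.** `select_candidates()` keeps genes with
$B(v) > b_{\min}$, $\mathrm{FDR}_v < 0.05$ and nonzero null betweenness
in fewer than `hub_max = 50` of the 100 replicates — all strict
inequalities, as the rules are stated. The FDR is the strict count
$\#\{r : B^{(r)}_{\mathrm{null}}(v) > B(v)\}/n_\mathrm{perm}$, so its
values lie on the grid $\{0, 1/R, \dots, 1\}$. The hub rule interprets
"count(betweenness_random) < 50" as *the gene lies on random-seed
geodesics in fewer than half the replicates*: hub genes are exactly those
that appear in most null draws regardless of seed placement. Both the
comparison and the threshold are configurable, since the source
convention is not fully specified. The default $b_{\min} = 1000$ is
calibrated to a $\sim$13,000-node interactome with $\sim$176 seeds;
betweenness scales roughly with $|S|^2$ and graph size, so smaller or
synthetic graphs need a smaller absolute threshold or a percentile-based
one (the synthetic validation uses the 99th percentile of the empirical
betweenness distribution).

## The synthetic-study generator

`generate_study(synth_config(), dir)` produces a complete offline study:
an interactome edge list, a seed gene list, a pathway GMT, the generating
config (YAML) and the ground truth (JSON). The desk-scale defaults are
the package's validation conditions:

| parameter | default | meaning |
|---|---|---|
| `n_nodes` | 2000 | background graph size |
| `attachment_m` | 3 | edges per new node (preferential attachment) |
| `n_seeds` | 60 | planted seed genes (added as new nodes) |
| `n_linkers` | 20 | hidden linker genes (background nodes) |
| `linker_attach` | 2 | distinct linkers per seed |
| `n_pathways` | 30 | annotation sets |
| `pathway_size_range` | 10–40 | set sizes (uniform) |
| `enriched_fraction` | 0.3 | sets seeded with disease genes |
| `overlap_rate` | 3 | forced shared genes per designated pair |

The background is scale-free (preferential attachment) because the hub
exclusion rule only has bite on heavy-tailed degree distributions; an
Erdős–Rényi mode with matched edge count exists for null experiments.

The planted module is built so its ground truth is unambiguous and so
that planted linkers are what the method looks for — peripheral genes
that become central only because of where the seeds sit:

* The linker scaffold is one connector node plus `n_linkers - 1`
  low-degree nodes from its neighbourhood. Using low-degree leaves is
  deliberate: a hidden linker is the opposite of a topological hub, and a
  generator that planted its linkers on hubs would have its own truth
  removed by the hub-exclusion rule it is meant to validate.
* Each seed is a *new* pendant-style node attached to `linker_attach`
  distinct linkers only (planted mode), so every seed–seed geodesic
  traverses linkers. Seeds are assigned round-robin over a randomly
  permuted linker order, which guarantees every linker at least two
  seeds whenever `n_seeds * linker_attach >= 2 * n_linkers` — and a
  linker with two seeds lies on their length-2 geodesic, making the
  planted-truth invariant (every linker on at least one seed-pair
  geodesic) hold by construction.
* A `diluted` mode additionally wires seeds into the background, for
  harder recovery experiments.

Annotation sets draw uniformly from the universe; enriched sets replace a
third of their members with seed genes (at least two), a
hypergeometric-null violation of known size, and designated consecutive
pairs share at least `overlap_rate` forced genes. With
`enriched_fraction = 0` the per-set seed count follows the hypergeometric
null exactly — a property the tests check against the closed-form mean —
and a `disjoint` mode partitions the universe so that no crosstalk edge
can arise.

**What the generator does not emulate:** the true interactome's size
(13,460 proteins, 138,427 interactions), its exact degree sequence, edge
correlations from experimental ascertainment, literature-curation noise
in the seed list, or annotation redundancy across databases. Passing the
recovery suite therefore shows the machinery is correct and calibrated at
desk scale, not that any particular biological candidate list is right.

## Validation protocol and problem sizes

The packaged validation (test suite and `scripts/acceptance.R`) uses:
exhaustive-enumeration oracles (all $N \le 15$ for the hypergeometric;
200 random graphs of up to 12 nodes for betweenness; exhaustive partition
search on 7 nodes for modularity); the worked-example fixture tables (176
seed genes, 24 pathways, 42 candidates, a 7-gene seed overlap, smallest
retained betweenness 1044); and 10 desk-scale synthetic studies with 100
permutations each for recovery (median planted linker above the 95th
background percentile; precision $\ge 0.6$ and recall $\ge 0.5$ at the
99th-percentile betweenness cutoff with FDR $< 0.05$ and hub count
$< 50$) plus 10 unplanted studies for type-I control (at most 5% of genes
flagged on average). These sizes keep a full run in tens of seconds while
leaving every statistic's sampling grid (FDR steps of 0.01) identical to
the full-scale setting.

## Known limitations

* Published GO/pathway p-values and crosstalk scores from 2020-era
  database snapshots cannot be reproduced offline; the package audits its
  transcribed fixtures for internal consistency instead and never asserts
  those published statistics.
* Candidate betweenness values from the original 13,460-protein
  interactome require that proprietary snapshot; the packaged candidate
  table is used as a worked-example input, not recomputed.
* Symbol handling is uppercase-plus-strip only; synonyms need a
  user-supplied alias table.
* Edges are unweighted and undirected; confidence-weighted or directed
  interactomes are out of scope.
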