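---
title: "Methods: seed-based shortest-path gene prioritization"
author: "seedpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based shortest-path gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Genes annotated to a biological process of interest ("validated" or
*seed* genes) rarely exhaust the process: many participants are
unannotated. A guilt-by-association argument on a protein-protein
interaction (PPI) network says that if two proteins are endpoints of a
confident interaction they tend to share function, and, transitively,
that the genes lying *between* two seed genes along strong interaction
chains are good functional candidates.

`seedpath` operationalizes this on a weighted undirected network. Each
interaction carries an integer confidence score
$Q(p_1, p_2) \in [150, 999]$ (the STRING combined-score convention:
higher means better-supported). Because shortest-path search prefers
*light* edges, confidence is converted to a weight

$$w(e) = 1000 - Q(p_1, p_2) \in [1, 850],$$

so a chain of high-confidence interactions is a low-weight path. For
every unordered pair of seed genes $(s, t)$ present in the network, all
minimum-weight $s$–$t$ paths are considered, and every *inner* node
(a node on such a path other than $s$ and $t$) is credited. A gene's
total credit over all seed pairs is its **seed-pair path betweenness**
— note this is restricted to seed pairs and left unnormalized, which is
deliberately not the classical all-pairs betweenness centrality.

High betweenness alone is not evidence: topological hubs intercept
shortest paths for *any* gene set. The null model is therefore direct
resampling: $N$ random gene sets of the same size as the seed set are
drawn uniformly from the network's nodes, the identical betweenness
computation is run for each, and each observed gene $g$ gets a
permutation false discovery rate

$$\mathrm{FDR}(g) = M / N,$$

where $M$ counts the random sets whose betweenness for $g$ exceeds the
observed value. Genes with $\mathrm{FDR}(g)$ strictly below the
threshold (default $0.05$) are reported as candidates, partitioned into
*validated* (already seeds) and *novel* genes.

## Counting all tied shortest paths

Integer weights make ties common, and "all shortest paths" is read
literally: every minimum-weight path counts. Enumerating them would be
exponential, so the engine counts combinatorially. A Dijkstra sweep
from each seed $s$ yields distances $d_s(\cdot)$ and path
multiplicities $\sigma_s(v)$ — the number of distinct minimum-weight
$s$–$v$ paths, accumulated over the shortest-path DAG
($\sigma_s(v) = \sum_u \sigma_s(u)$ over predecessors $u$ with
$d_s(u) + w(u,v) = d_s(v)$). A node $v$ lies on a shortest $s$–$t$ path
iff $d_s(v) + d_t(v) = d_s(t)$, and the number of such paths through
$v$ is exactly $\sigma_s(v)\,\sigma_t(v)$, which is the credit assigned
in the default `"all-paths"` mode.

The wording "number of paths containing each gene" is also consistent
with pipelines that keep one representative path per pair, so a
`"per-pair"` mode (credit 1 per seed pair whose shortest paths contain
$v$) is provided; the mode in force is echoed into every output table.
`"all-paths"` dominates `"per-pair"` pointwise and both are validated
against a brute-force path enumerator on small graphs in the test
suite.

Endpoints are never credited for their own pair, but a seed gene lying
strictly inside another pair's shortest path is credited like any other
gene — re-discovering seeds this way is a useful internal consistency
signal, reported as the "extracted validated" count.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mode` | `"all-paths"` | inner-node credit: per tied path, or per pair |
| `n_permutations` | 1000 | random sets $N$; FDR resolution is $1/N$ |
| `threshold` | 0.05 | strict (<) FDR cutoff for candidates |
| `comparison` | `"gt"` | `M` counts strict exceedances; `"ge"` counts ties too |
| `universe` | `"all-nodes"` | random sets may include seed genes; `"non-seed-nodes"` excludes them |
| `rng_seed` | 1 | drives the random sets; fixes the whole run |

Three conventions deserve comment, since the procedure is often stated
without them:

* **Per-gene comparison.** $\mathrm{FDR}$ is indexed by gene: each
  gene's observed betweenness is compared with *that same gene's*
  betweenness across random runs (a gene absent from a run counts 0
  there). No set-level scalar is ever formed.
* **Exceedance strictness.** The definition of $M$ is "greater than",
  so the default is the strict `>`; `>=` is available as the more
  conservative standard permutation-p convention, and
  $\mathrm{FDR}_{>}(g) \le \mathrm{FDR}_{\ge}(g)$ always.
* **No pseudocount.** $M/N$ is reported exactly as defined, so an FDR
  of 0 is attainable. The $(M+1)/(N+1)$ smoothing common in permutation
  testing is *not* applied, keeping reported values on the grid
  $\{0, 1/N, \dots, 1\}$ with $\mathrm{FDR}(g) \cdot N = M$ exactly.

## Numerical and degenerate-input choices

* Scores are validated to $[150, 999]$; out-of-range values are errors,
  not clamps, so a dialect mismatch surfaces immediately. Weights are
  therefore integers in $[1, 850]$ and all distance comparisons are
  exact — no floating-point tolerances exist anywhere in the method.
* Path multiplicities can grow combinatorially; they are held in C
  doubles, exact for integers up to $2^{53}$, far beyond what the
  problem sizes here produce.
* Duplicate records for one pair keep the **maximum** score (minimum
  weight), preserving the strongest evidence; reciprocal
  `a b` / `b a` lines collapse to one undirected edge; self-loops are
  dropped. All three events are counted and reported, and the raw
  directed record count is kept alongside the deduplicated edge count
  so either can be reconciled with published totals.
* Disconnected seed pairs are skipped, tallied, and surfaced in the run
  report; a seed list with fewer than two in-network members is a hard
  error.
* All tables are written with deterministic ordering (descending
  betweenness, then lexicographic gene ID) and embed the effective
  configuration, so equal inputs and `rng_seed` give byte-identical
  files.

## The synthetic benchmark

`synthetic_spec()` / `generate_synthetic()` produce a STRING-dialect
links file with known ground truth: a sparse Erdős–Rényi background
(400 nodes, edge probability 0.02, scores uniform on $[150, 400]$)
plus a planted dense module (30 nodes, edge probability 0.6, scores
uniform on $[850, 999]$), every module node wired to the background by
at least one background-strength bridge. Fifteen module members are
designated seeds; the other fifteen are *hidden* members the method
should recover; optional decoy seeds are background nodes added to the
seed list. These sizes keep a full 200-permutation run in the order of
seconds on one core while leaving the module large enough for rank
statistics across generator seeds.

Score distributions are uniform on intervals rather than fit to an
empirical STRING score distribution: the method depends only on the
ordering of path weights, so the controlled variable is the separation
between the weak background interval and the strong module interval
(the constructor warns when they overlap). What the generator does
*not* emulate: genome-scale size (tens of thousands of nodes, millions
of edges), degree heterogeneity / hub structure of real interactomes,
score-degree correlations, and multi-module overlap. Passing the
benchmark therefore shows the pipeline recovers a planted
high-confidence module against a uniform background — it does not by
itself certify performance on a real interactome, where the permutation
null is precisely the guard against hub effects the generator lacks.

Recovery is scored by `recovery_metrics()`: recall of hidden members
among candidates, and precision over non-seed candidates. The
acceptance checks compare recall against size-matched random candidate
sets across ten generator seeds with a rank-based (paired Wilcoxon)
comparison rather than a fixed numeric bar.

## Scale and checkpointing

The test suite and acceptance script run at desk scale by design:
oracle comparisons use graphs of at most 12 nodes (where exhaustive
path enumeration is feasible), and benchmark runs use the 430-node
synthetic network with 200 permutations. A full-scale study —
a ~25,000-node, ~3-million-edge interactome, ~1,000 seeds and 1,000
permutations — implies on the order of $10^6$ single-source
shortest-path sweeps. The fit function supports this honestly rather
than quickly: with `checkpoint_dir` each permutation's betweenness
table is persisted as TSV the moment it is computed, `max_compute`
bounds the work of one invocation, and a rerun with the same
configuration resumes where it stopped (a configuration mismatch
against an existing checkpoint is refused). Because the random sets are
all derived up front from `rng_seed`, a resumed run is bit-identical to
an uninterrupted one.

## Known limitations

* The method sees only the network: a gene absent from the PPI source
  can never be proposed, and ID normalization (taxon-prefix stripping,
  isoform collapsing) must match between links file and seed list.
* Betweenness concentrates on short, strong chains; genes linked to the
  process through long or weak paths are invisible to it.
* With $N$ permutations the smallest nonzero FDR is $1/N$; at the
  default threshold the test cannot distinguish genes below
  $0.05$ more finely than the grid allows.
* The uniform resampling null controls for generic hubness but not for
  degree-matched confounding; a degree-preserving null is out of scope
  here.
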