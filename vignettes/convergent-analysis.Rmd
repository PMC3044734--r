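---
title: "Convergent candidate-gene prioritization with ConvergeNet"
author: "ConvergeNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent candidate-gene prioritization with ConvergeNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Disease gene discovery often produces several independent candidate lists
that barely overlap: genes residing in patient copy-number-variant (CNV)
regions, and genes accumulated by years of association studies, rarely
intersect directly. ConvergeNet implements a convergence argument instead:
if a disease emerges from perturbation of a molecular machine, its
candidate genes should sit close together in the protein-protein
interaction (PPI) network even when the lists themselves do not intersect.
The pipeline therefore

1. expands each seed list into a connected PPI subnetwork that spans as
   many seeds as possible while recruiting as few non-seed *linker*
   proteins as possible,
2. declares genes present in **both** subnetworks high-priority
   (terminals and linkers alike — a gene recruited independently by both
   constructions is structurally necessary for both),
3. optionally attaches case-control differential expression evidence, and
4. characterizes each subnetwork functionally by pathway
   over-representation and a pathway crosstalk map.

The assumptions are explicit: the interactome is an unweighted, undirected
simple graph of gene symbols; proximity in it is biologically meaningful;
and seed lists are trusted as-is (no alias resolution, no weighting by
evidence strength).

## Subnetwork construction

Finding the connected subgraph spanning a terminal set with the fewest
extra nodes is the node-weighted Steiner tree problem (weight 0 for seeds,
1 for non-seeds), which is NP-hard. `steinerSubnetwork()` uses
spider-merging in the style of Klein and Ravi: every seed starts as its
own component, and each round merges the cheapest "spider" — a center
node plus shortest paths to two or more components — measured as newly
recruited non-seeds per merged component. This greedy is guaranteed to
recruit at most `2·ln(k)` times the optimal number of linkers for `k`
seeds, and the package ships an exhaustive oracle
(`exactSteinerOracle()`, networks up to 15 nodes) against which both
exactness on trees and the bound on general graphs are tested.

Numerical and procedural choices:

* **Paths** are unweighted breadth-first paths; among equal-hop paths the
  one introducing the fewest new non-seeds is taken, then ties fall back
  to the lexicographically smallest predecessor. All other ties (centers,
  components) are lexicographic too, so results are byte-reproducible.
* **Ratio-0 merges** (components already touching through selected nodes)
  recruit nothing, so they are collapsed together in a single union-find
  pass per round; the final node set is provably unchanged and the
  construction is several-fold faster.
* **The cost cap** `maxMergeCost` (default 2 linkers per merged
  component) is the package's explicit version of the usual informal rule
  that a seed demanding too many unrelated connectors should be left out.
  Seeds excluded this way are reported as `too-costly`, distinct from
  `not-in-network` and `unreachable`, because silent exclusions make
  convergence counts impossible to audit. Raising the cap can only add
  terminals (tested property).
* When seeds span several graph components, the component retaining the
  most seeds is returned (`union = TRUE` returns all of them).
* The summed per-path spider cost can count a shared interior node twice
  when paths overlap; the executed merge recruits the de-duplicated
  union, so the greedy is conservative, never wasteful.

## Convergence and origin classes

`convergeSubnetworks()` intersects subnetwork **node** sets. The
alternative — intersecting only terminals — would discard exactly the
most interesting finds: genes that neither list nominated but that both
constructions needed. `annotateOrigin()` classifies each convergent gene
as `both-seeds`, `cnv-only-seed`, `huge-only-seed`, or `linker-only`;
the four classes partition the table. Genes present in both *seed lists*
but absent from a subnetwork are deliberately **not** high-priority:
list membership without structural support is weaker evidence and is
reported separately by the seed-list flags.

## Differential expression

Expression input is taken as already normalized; the package never
rescales. `collapseProbes()` keeps, per gene, the probe with the highest
mean intensity across all samples (ties: lexicographically smaller probe
identifier). The mean across samples was chosen over the single-sample
maximum because it is robust to one outlying array; the choice is
recorded in the result. `tTestDE()` performs a two-sided two-sample
t-test per gene, Welch by default — with 7 vs 8 samples an equal-variance
assumption buys little and costs robustness — with `"pooled"` available
and recorded in the `DEResult`. P-values are raw: the downstream use is
ranking convergent genes, not genome-wide discovery; Benjamini-Hochberg
is available behind `deGenes(..., adjust = "BH")`. Rows with zero
variance in both groups are flagged `degenerate` (t = 0, p = 1 for equal
means) rather than propagating NaN.

## Pathway enrichment and crosstalk

`fisherEnrich()` computes the one-sided hypergeometric upper tail
`P(X >= k)` — over-representation, the enrichment semantics of pathway
tools — after intersecting pathways with the background universe.
Significance requires both `p < 0.01` and at least 5 genes of interest,
so single-gene coincidences in tiny pathways cannot pass. The background
defaults to all interactome genes, the universe from which subnetwork
genes were actually drawn; it is a parameter because no universally
correct universe exists.

`crosstalkScore()` returns the Jaccard coefficient
`JC = |A∩B|/|A∪B|`, the overlap coefficient
`OC = |A∩B|/min(|A|,|B|)` (always `>= JC`), and their mean as the edge
score. `buildCrosstalkGraph()` scores all pairs of significant pathways
sharing at least 3 genes, retains per enrichment result the edges scoring
at or above the `1 - topFraction` quantile of that result's candidate
scores (defaults 1% and 5%; ties at the threshold are kept — dropping
them would make results depend on sort order), and unions the two
filtered graphs. When the same pair survives from both results the
higher-scoring version supplies the edge attributes. Overlaps are
computed on each pathway's *genes of interest* (enrichment hits) by
default — crosstalk between pathways should reflect the genes that put
them on the map — with `fullSets = TRUE` switching to entire pathway
gene sets. Functional groups are simply the connected components with at
least two pathways: no clustering algorithm, no resolution parameter,
easy to audit.

## The synthetic study generator

`simulateStudy("paperlike")` generates, at desk scale, inputs with the
statistical structure the analysis assumes:

* a 1000-node scale-free (preferential attachment) interactome with mean
  degree 10 — the edges-per-node ratio of large curated PPI databases —
  at a size that keeps the full test suite fast;
* seed lists of 40 and 20 genes (preserving the roughly 2:1 ratio of a
  CNV-region list versus a curated association list) sharing 5 genes;
* 4 planted *bridge* linkers. A bridge is an existing node chosen with
  three of its neighbors per module as seeds such that the bridge is the
  unique common neighbor of every pair of the triple, and subsequent seed
  picks are constrained so no other node becomes adjacent to three seeds
  of one list. Connecting a triple through its bridge then costs 1/3 of
  a linker per component while every alternative costs at least 1/2, so
  the construction must recruit the bridge. Overlap genes are placed as
  further bridge neighbors and attach at no extra cost. The graph itself
  is never rewired, so generated interactomes remain honestly scale-free;
* a 7-case / 8-control expression matrix, Normal(8, 1) baseline on a
  log-like scale, 5% of genes shifted by 2 SD in cases, and a second,
  dimmer probe for 10% of genes to exercise probe collapse;
* 40 equal-size pathways with four planted crosstalk clusters (shared
  cores of 4 genes within a cluster, all other members unique), so
  cross-cluster sharing stays below the 3-gene edge threshold by
  construction.

What the generator does **not** emulate: real gene symbol aliasing,
genomic CNV coordinates, correlated expression between interacting
genes, array batch effects, and the curation biases of real pathway
databases. Passing tests therefore demonstrate that the machinery
recovers planted structure under its own model assumptions — not that
any particular biological list will converge.

Problem sizes used by the test suite and acceptance script (oracle
comparisons on graphs of up to 15 nodes, calibration at 1000–2000 genes,
10–20 pipeline replicates) were chosen so each check has enough
resolution for its stated tolerance while the whole suite stays fast.

## Known limitations

* The Steiner heuristic is deterministic but greedy: on adversarial
  graphs it can recruit up to `2·ln(k)` times the optimal linker count.
* The cost cap is a per-merge rule, not a global budget; a different
  exclusion policy (e.g. dropping seeds before growth) would give
  different terminal sets.
* Probe collapse keeps one probe per gene; genes with genuinely bimodal
  probe behavior (alternative transcripts) lose information.
* The permutation-test cross-check of the t-test agrees only in
  aggregate at these sample sizes: an exhaustive 4-vs-4 permutation
  distribution has granularity 1/70, so pointwise agreement with a
  continuous parametric p-value is structurally loose.
* Functional groups are connected components; a single spurious edge can
  merge two otherwise distinct groups. The top-fraction filter is the
  only guard.
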