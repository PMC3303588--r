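---
title: "Methods: concept-profile cohesion and interaction-network validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concept-profile cohesion and interaction-network validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gcpnet` asks two linked questions about a set of related diseases. First,
do their literature gene profiles cluster — i.e., are some diseases written
about with the same genes far more than chance would predict? Second, do
the genes that drive those clusters encode proteins whose interactions are
specific to one another? This vignette explains the models behind both
stages, the parameters that matter, what the synthetic generators do and do
not emulate, and the design decisions taken where the methodology was
genuinely open.

## Stage 1: genetic concept profiles

### The occurrence model

The corpus is reduced to binary document-level occurrence: a concept either
appears in a document or it does not, and term frequencies are ignored.
This is the simplest model under which "documents that mention both the
disease and the gene" is well defined, and it makes every downstream
statistic a function of 2×2 contingency tables over the T corpus documents.

### Association weights

For disease c and gene g with joint document counts (a, b, c, d), the
default weight is the symmetric uncertainty coefficient

$$U = \frac{2\,\mathrm{MI}}{H_1 + H_2},$$

with natural logarithms and the 0·log 0 ≡ 0 convention, clamped to zero
whenever the observed co-occurrence rate a/T is at or below the
independence expectation. U was chosen over alternatives because it is
bounded in [0, 1], symmetric in the two concepts, equals 1 exactly at
perfect co-occurrence, and vanishes at (or below) independence — the
properties one wants of a "strength of association" score that will later
be compared across diseases of very different corpus prevalence. Positive
pointwise mutual information (`pmi`) and the raw co-occurrence count
(`raw`) are provided as config-switchable alternatives; none of the three
is claimed to replicate the internals of any particular text-mining engine.

A profile collects one weight per gene-class thesaurus entry and is then
L2-normalised. Two consequences are worth stating. Matching scores (inner
products) and hence cohesion live in [0, 1], with 1 reached only by
identical profiles; and a disease mentioned in many documents gains no
mechanical advantage over a rare one. A gene concept's own self-dimension
is zeroed before normalisation — a gene trivially co-occurs with itself,
and leaving that weight in would make every gene profile a near-unit vector
on its own axis, rendering the permutation universe (below) useless.

Profiles that end up all-zero (no positively associated gene) are flagged
degenerate and excluded from every inner-product computation, with a
warning naming them.

### Cohesion, contributions, permutation P

The cohesion of a group of m profiles is the mean of all C(m, 2) pairwise
inner products. Because the profiles are non-negative unit vectors, each
gene g contributes the mean over pairs of $w_i(g)\,w_j(g)$; expressed as a
percentage of the cohesion score these contributions are non-negative and
sum to exactly 100 whenever the score is positive (they are undefined at
zero cohesion, which the code treats as an error rather than returning
NaNs).

The permutation P-value of a group is the fraction of `iterations` random
same-size groups whose cohesion is at least the observed score. Three
conventions are fixed deliberately:

* **p = r/n, not (r+1)/(n+1).** P-values are exact multiples of
  1/iterations (default 200).
* **Draws may overlap the observed group.** Random groups are uniform
  subsets of the universe with no exclusions, sampled without replacement
  within a draw.
* **The comparison universe is every non-degenerate concept profile in the
  corpus, genes included — not just the diseases under study.** With a
  universe of only the (say) seven compared diseases, the observed pair is
  itself one of C(7, 2) = 21 subsets, so no pair could ever have an
  expected P below 1/21 ≈ 0.048, and the second- and third-ranked of
  several genuinely cohesive pairs would be pushed above any conventional
  threshold by each other's presence. Published cohesion P-values of 0.02
  at 200 iterations are only arithmetically possible when random groups
  are drawn from a concept universe much larger than the analysed set,
  which is what this package does by default. `permutation_pvalue()`
  nevertheless takes the universe as an explicit argument, so any other
  convention is one call away.

### Clustering and projection

Similarities are turned into distances as d = 1 − s, which is 0 iff two
profiles are identical and bounded by 1. Clustering is agglomerative with
average linkage (UPGMA) by default — no linkage is canonical for this
problem; average linkage is the least committal for compact, similarly
sized groups, and `complete`/`single` are available. Concepts are sorted
lexicographically before clustering so tied merges resolve
deterministically. The 2-D projection is classical (Torgerson) metric MDS:
double-centre the squared-distance matrix, eigendecompose, keep the top
two coordinates. The embedding is defined only up to rotation, reflection
and translation; the returned object carries the full eigenvalue spectrum
(negative eigenvalues flag non-Euclidean distance structure) and a
relative stress value so users can judge how faithful the plane is.

## Stage 2: interaction-network validation

### Reference filter

Interaction records arrive as undirected edges with supporting reference
ids. Any reference supporting more than `max_links_per_reference` (default
4) edges is treated as a high-throughput artifact and invalidated
*everywhere*; an edge survives if at least one valid reference remains.
There is deliberately no minimum-reference filter beyond one. Where a
record mixes a hub reference with a specific one, the edge is kept — the
filter targets references, not edges; this "keep if any valid reference"
reading is an interpretation, stated here because the alternative (drop
any edge a hub reference touches) is defensible too. The filter is
idempotent, and self-loops are dropped at parse time with duplicate
records merged (references unioned).

### Subnetwork and the z statistic

With path length capped at 2, the only way a non-seed node can join the
subnetwork is as an **intermediate** adjacent to at least two *distinct*
seeds; the subnetwork is the background graph induced on seeds plus
intermediates. K counts the induced edges (a config flag excludes
intermediate–intermediate edges from K for users who prefer the stricter
reading; the default includes them). Each intermediate is scored with the
one-sample binomial-proportion statistic

$$z = \frac{k/n - p_0}{\sqrt{p_0 (1 - p_0) / n}}, \qquad p_0 = K/N,$$

where n is the node's degree in the *filtered background* (not its
subnetwork degree — the published count columns only make sense that way),
k its number of distinct-seed neighbours, and N the background link count.
This formula is a reconstruction validated against a shipped 20-row
reference table of intermediate counts: the recomputed z agrees with every
published value within 0.001 (`verify_table4()` recomputes this), sorts
into the same row order, and reproduces the 19-of-20 significant count at
the 2.5 cutoff. Pooled two-sample variants of the proportion test do not
reproduce that table and were rejected. Significance is strict (z > 2.5):
the published table's only non-significant node sits at 2.457 and no value
equals the cutoff exactly, so the boundary convention is unobservable
there; strictness is the conservative choice.

### Pipeline gluing

`run_pipeline()` evaluates every pair of mapped diseases, calls a pair
significant at P ≤ `p_threshold` (default 0.05), shortlists the genes
contributing more than `contribution_cutoff` (default 0.1%) to any
significant pair, and uses the shortlist as the seed list of the network
stage. Evaluating pairs (rather than cutting the dendrogram at some
height) matches the two-disease cluster structure the cohesion statistic
is most sensitive to; for larger groups, `permutation_pvalue()` accepts
any group size directly.

## The synthetic generators

`simulate_corpus()` emulates a MedLine-like corpus: each document mentions
exactly one disease (uniformly assigned), and gene mentions are
independent Bernoulli draws — probability `p_comention_shared` (default
0.05) for the 20-gene shared pool of a planted disease pair,
`p_comention_background` (default 0.005) otherwise. Defaults are 7
diseases, 3 disjoint planted pairs, 500 genes, 20 000 documents, seed 17;
with them the full stage-1 analysis runs in a few seconds. Setting the two
probabilities equal gives the null generator. What the generator does
*not* emulate: real marginal frequency distributions (MedLine is heavily
skewed), multi-disease documents, synonym noise in entity recognition, and
corpus-wide topic correlation. Passing tests on this generator therefore
demonstrates that the statistics detect planted co-mention structure at
realistic rates — not that any particular real corpus would yield the same
clusters.

`simulate_network()` generates an Erdős–Rényi background (300 proteins,
edge probability 0.01) in which every edge carries its own reference, then
plants 3 intermediates wired to 5 distinct seeds each (of 10), and
reassigns 2 hub references to 8 background edges each so the reference
filter has something to purge. Five seed links per intermediate were
chosen from a power analysis of the z statistic: a chance degree-2 node
adjacent to two seeds scores $z \approx \sqrt{2(1-p_0)/p_0}$, and the
planted configuration's expected z clears that by a comfortable margin,
so recovery is a property of the statistic rather than luck. Degree
distributions of real interactomes (scale-free hubs) are deliberately not
modelled; the z statistic's degree correction is exercised by the planted
contrast, not by realistic topology.

## Numerical choices and degenerate inputs

* 0·log 0 ≡ 0 throughout the entropy computations; degenerate marginals
  (zero total entropy) yield weight 0 with a warning.
* Unit-norm validation tolerates 1e-9; similarity matrices are clamped to
  [0, 1] and symmetrised against floating-point drift before use.
* Permutation draws compare with ≥ on scores computed from one shared
  similarity matrix, so a redrawn observed group ties exactly.
* Ties in clustering are broken by lexicographic concept id order;
  dendrogram and projection are invariant to input order (up to rigid
  motion).
* cmdscale is asked for min(2, n−1) coordinates and the result is
  zero-padded, so two-concept inputs project to two points exactly their
  distance apart; rank-zero inputs (all concepts identical) project to the
  origin with a warning.
* All randomness flows through explicit integer seeds; callers' RNG state
  is saved and restored.

## Problem sizes used by the test suite

Unit tests run on corpora of a few documents up to 2 500, and on profile
sets of 3–7 concepts over 20–80 genes, where brute-force oracles
(double-loop cohesion, exhaustive subset enumeration, naive O(n³) UPGMA,
two-pass reference counting) are exact and fast. The acceptance checks run
the generators at their default scale — 20 000-document corpora across 20
seeds, and the 300-protein network — which completes in about two minutes
on one CPU.

## Known limitations

* Profile quality is bounded by the thesaurus: mapping is case-insensitive
  exact matching over names and synonyms; no fuzzy matching or named-entity
  recognition is attempted, and ambiguous names are excluded rather than
  disambiguated.
* The permutation P is not corrected for testing multiple groups, matching
  the single-group convention of the underlying methodology; users
  comparing many groups should apply their own correction.
* The z statistic assumes the binomial approximation is adequate for the
  node's degree n; at very small n (2–3) the normal approximation is
  rough, which is visible in the reference table's largest z values.
* The pipeline treats the corpus and the interaction network as fixed
  inputs; no uncertainty propagates between stages.
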