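---
title: "Methods: network models of collection data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network models of collection data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collnet)
```

## The two models

An occurrence record is a social document as much as a biological one: it
says which taxon was recorded and which people recorded it together.
`collnet` formalises the two relations this induces.

The **species-collector network** is bipartite. Collector u_i and taxon
v_j are linked with weight a_ij equal to the number of records on which
they co-occur; a record with n collectors therefore increments n cells of
the biadjacency matrix A. Two derived vectors carry most of the
interpretive weight: the *species bag* of a collector (their row of A,
whose sum is exactly their record count — the sharpest internal
consistency check the model offers, and one the test suite asserts on
every synthetic dataset) and the *quorum* of a taxon (its column of A).
One semantic subtlety is worth stating precisely: the quorum sum counts
(record, collector) *incidences*, not records. On a dataset where every
record has a single collector the two coincide; with multi-collector
records each record contributes once per collector. This package
implements and documents the literal column-sum semantics rather than
silently reinterpreting it as a record count.

*Taxonomic aggregation* collapses species columns into higher-rank
columns by summing quorum vectors within each group. It conserves the
matrix total and every collector row sum — both asserted in the tests —
and requires the taxonomy to cover every species node (partial maps fail
loudly listing the orphans). All taxon nodes of a model share one rank
(its *resolution*): mixing a species node with a family node would make
edge weights incomparable.

The **collector coworking network** is unipartite over the same collector
set. Each record with team size n ≥ 2 is one collaboration act. Under
hyperbolic weighting it adds 1/(n − 1) to every one of its n(n − 1)/2
pairs, reflecting that ties formed in large teams are individually
weaker; a two-person record contributes the maximum, 1, and a size-n team
contributes n/2 in total — an exact identity the acceptance tests check
for n = 2…8. The rule is singular at n = 1, so single-collector records
contribute no weight; they still create nodes, which is deliberate:
degree-zero nodes are the *individualists*, and their share is itself an
interesting statistic. Full-count weighting (1 per co-appearance) is kept
as the classical alternative; outputs always carry the scheme label
because the two are not comparable edge-for-edge.

Both models are temporally and geographically invariant: dates and
coordinates are parsed leniently, never filtered on, and never used.

## Name cleaning

Collector strings are the weakest field in real collection tables, and
the cleaning chain is therefore explicit and configurable at every step.

*Atomization* splits `recordedBy` on a configurable ordered delimiter
inventory, defaulting to `";"`, `"|"`, `"&"`, `" e "`, `" and "`. The
bare comma is intentionally absent: under the dominant
`"Surname, Initials"` convention a comma splits a name, not a list.
"et al." markers are removed and flagged rather than parsed — they assert
the *existence* of unnamed co-collectors, which no parser can recover, so
they contribute no coworking ties (exactly the information loss the
marker causes in real data).

*Normalization* maps a name to the token `surname,initials`, lowercase,
diacritics transliterated, from either layout (`"Proença, C.E.B."` and
`"c. e. b. proenca"` both give `proenca,ceb`). Strings already in
canonical form pass through unchanged, which makes the function
idempotent — without that rule the token `proenca,ceb` would re-parse its
initials block as a given name and collapse to `proenca,c`. Rejection
rules (fewer than two letters, no alphabetic content, a stop-list with
entries like `sn`, configurable) discard non-name tokens with a recorded
reason.

*Resolution* applies a user-supplied variant→canonical name map, then
de-duplicates ids within each record in first-appearance order. That
de-duplication is what guarantees the coworking adjacency has a zero
diagonal. Two distinct people normalizing to one token remains a known,
accepted limitation — only an external name map can disambiguate it.

## Analytics choices

* **Betweenness** uses the standard Freeman shortest-path definition
  (endpoints excluded, disconnected pairs contributing zero), computed by
  igraph, *unweighted* and *normalized* by (n−1)(n−2)/2 by default:
  collaboration weights measure tie strength, not distance, and
  normalized scores are comparable across networks of different sizes.
* **Louvain** maximizes Newman modularity with edge weights as strengths.
  The heuristic is randomized, so `detect_communities()` applies its
  `seed` argument immediately before the run; a fixed seed is
  bit-reproducible, and the seed and resolution are recorded in the
  returned partition.
* **Components** are ordered by decreasing size with ties broken by the
  lexicographically smallest member, so c_1, c_2, … labels are stable.
* **Density** is |E|/(nm) for bipartite graphs and 2|E|/(n(n−1))
  otherwise; scoping to the giant component answers "how dense is the
  connected core", and is always ≥ the whole-graph value when isolates
  exist.
* **Island filtering** (drop edges below a weight floor, score the
  resulting components by summing a node weight, drop low-scoring
  islands) defaults its node weight to the collector's record count —
  the natural notion of node importance in a collection, and the quantity
  node sizes encode in standard visualisations — but accepts any named
  vector. All thresholds are explicit arguments, echoed in the run log.

## The synthetic generator

Real collection datasets drift and their cleaning rules are rarely
published, so the package tests against generated data with known ground
truth instead. `generator_config()` defaults encode the study conditions
the models target:

* **Team sizes** follow a geometric law truncated at 8 with success
  probability 1/1.73: mean team size ≈ 1.73 and per-size record counts
  that decay log-linearly, matching large herbarium datasets.
* **Individualist fraction** 0.395 of collectors only ever record alone.
* **Record propensities** are lognormal(0, 1), producing the heavy-tailed
  per-collector record counts that make hub collectors emerge.
* **Interest/coworking communities** (4 by default, over 200 collectors,
  400 species, 20 families): families are partitioned among communities,
  each collector gets one preferred family from their community's block,
  co-collectors are drawn from the lead's community with probability 0.9
  (`team_affinity`), and the recorded species comes from the preferred
  family of a uniformly chosen team member with probability 0.9
  (`concentration`). Tying the species to a random *member* rather than
  the lead keeps every collector's bag dominated by their own preferred
  family regardless of how often they lead records, which is what makes
  dominant-family recovery a fair test of aggregation rather than of the
  lead-sampling distribution.
* **Name noise** emulates the documented failure modes of `recordedBy`:
  variant spellings (dropped final initial, reordered layout) at rate
  0.05, "et al." truncation at 0.03, mixed delimiters. The generator
  emits the name map that undoes its own variants, so noise-free recovery
  is exact and noisy recovery is exact *given the map* — mirroring how a
  curator's authority file functions.

What the generator does **not** emulate: temporal or spatial structure
(dates and coordinates are filler), taxonomic nomenclature (names are
synthetic binomials), collector careers (propensities are static), and
unmapped variants (every emitted variant is in the map). Passing tests
therefore demonstrate correctness of the models and pipeline, not
robustness to cleaning rules the data does not declare.

Recovery is scored by `ground_truth_eval()`: greedy one-to-one matching
of detected communities to planted groups by descending overlap, fraction
of nodes matched — permutation-invariant, 1 for perfect recovery, ~0.5
for random labels over two equal groups. Community recovery is evaluated
over collectors holding at least one collaborative tie: a degree-zero
node carries no community signal in any coworking network, so including
individualists would measure their share, not the detector.

## Numerical and determinism choices

* The CWN adjacency is accumulated on the upper triangle and mirrored, so
  a_ij and a_ji are bit-identical; independently summed mirrored triplets
  can differ by an ulp, which strict symmetry checks rightly reject.
* Hyperbolic weights are sums of 1/(n−1) kept as doubles; the analytic
  identities (weight 1 for pairs, n/2 per team) are asserted exactly for
  team sizes whose reciprocals are exactly representable and to 1e-12
  otherwise.
* The GraphML writer serializes weights with 17 significant digits, the
  round-trip-exact format for IEEE doubles, so write→read reproduces
  every weight bit-for-bit. Edge lists and node tables are emitted in
  sorted order; matrix row/column order is first-appearance, making every
  artifact byte-stable for a fixed input and seed.
* Dominant-family ties (equal counts in two families) break toward the
  first column in first-appearance order — explicit, if arbitrary;
  relevant only for collectors with a handful of records.
* Degenerate inputs: empty record sets give 0×0 models; density is
  refused (with an error, not NaN) on empty graphs, single-node
  unipartite graphs, and bipartite graphs with an empty part.

## Problem sizes

The test suite exercises: 200 random SCN fixtures of ≤ 50 records and 40
CWN fixtures against brute-force tallies; components/density/degree
oracles on graphs of ≤ 30 nodes and exhaustive-enumeration betweenness on
≤ 12 nodes; conservation identities at 1,500 records; and planted-
structure recovery (Louvain agreement ≥ 0.9, dominant-family match
≥ 90%) at 10,000 records and 200 collectors. These sizes give stable
statistics for the stochastic checks while keeping the whole suite under
a minute on one CPU.

## Limitations

The models inherit the quality of `recordedBy` and `scientificName`:
non-atomized names merge people, unmapped variants split them, and both
distortions propagate to every downstream statistic. Id collisions are
accepted (see above). The quorum-sum semantics deserve attention whenever
records are multi-authored. Exact counts from published case studies on
external datasets are not reproducible in principle without the original
cleaning rules, which is why the package's guarantees are stated as
identities, oracle equivalences, and recovery rates on generated data.
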