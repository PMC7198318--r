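---
title: "Stress measures, authorship clustering and citation-summary planning"
author: "citesum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress measures, authorship clustering and citation-summary planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citesum)
```

## The problem

A curated database is organised as a hierarchy: a handful of top-level
*groups*, nested *families*, and leaf *objects* (the curated things
themselves).  Contributors are recorded per family or object, and each node
carries outgoing bibliographic references.  To make this work visible to
citation analyzers, parts of the database — *views*, meaning a node together
with its descendants — are published as short conventional documents
("citation summaries").  Two questions drive the design:

1. **Granularity.** One summary per authored node produces far too many
   near-identical documents; one summary for the whole database miscredits
   everyone for everything.  Where between these extremes should summary
   roots sit?
2. **Evolution.** The database changes continuously.  When does a published
   summary stop being an adequate citation target, forcing a new version?

`citesum` answers the first with set-based *stress measures* and two
complementary procedures (correlation clustering and a bottom-up
recommendation sweep), and the second with a four-item snapshot ledger.

## Stress of an authorship family

Author sets are unordered; all measures ignore contributor order and
multiplicity.  For a multiset $T$ of author sets,

$$\mathrm{stress}(T) = 1 - \frac{|\bigcap T|}{|\bigcup T|},$$

the multiset generalisation of the Jaccard distance.  It is 0 iff all
members agree exactly, and *monotone under multiset inclusion*:
$S \subseteq T \Rightarrow \mathrm{stress}(S) \le \mathrm{stress}(T)$.
Monotonicity matters operationally — it guarantees that merging more
subtrees into a candidate summary can only look worse, never spuriously
better, so a bottom-up sweep can stop at the first level where stress
exceeds a threshold.

Requiring membership in *every* set is harsh: an author present in all but
one of twenty sets counts for nothing.  The weighted relaxation

$$\mathrm{stress}_\alpha(T) = 1 - \frac{\sum_{i=1}^{|T|}
  \alpha(|T|, i)\,|F(T, i)|}{|\bigcup T|}$$

credits authors by the number $i$ of members they contributed to, where
$F(T,i)$ is the set of authors in exactly $i$ members (these classes
partition $\bigcup T$, and $F(T,|T|) = \bigcap T$).  Built-in weights,
selectable by name everywhere a weight is accepted:

| name          | $\alpha(n,i)$   | character                          |
|---------------|-----------------|------------------------------------|
| `indicator`   | $1$ iff $i=n$   | recovers plain stress              |
| `linear`      | $1/(n+1-i)$     | harmonic decay per missed member   |
| `exponential` | $2^{\,i-n}$     | credit halves per missed member    |

### When is the weighted measure monotone?

Not every weight preserves monotonicity.  `check_alpha_monotone()` verifies
by enumeration the two conditions

$$\alpha(n+1, i+1) \le \alpha(n, i)
  \quad\text{and}\quad
  \alpha(n+1, i) \le \alpha(n, i),$$

i.e. when the family grows by one member, an author's weight must not
increase — neither when the author belongs to the new member (count moves
from $i$ to $i+1$) nor when they do not (count stays $i$).  This is the
direction that the three built-ins satisfy (with equality in the first
condition for `linear` and `exponential`) and that the property suite
confirms empirically: a weight such as $\alpha(n,i) = i/n$, which *grows*
along the first condition, fails the check and indeed produces
non-monotone behaviour.  One caveat, stated for honesty: the two
inequalities are the package's working conditions, verified against the
built-ins and by randomized property tests; for weights that are not
non-decreasing in $i$ the dilution effect of brand-new authors (who enter
at weight $\alpha(n+1,1)$) is not covered by them, so exotic weights should
be validated with the property tests before use.

## Correlation clustering of authorship

`build_signed_graph()` forms the complete graph over authored items and
labels an edge positive when the Jaccard distance between the two author
sets is **strictly below** the threshold (default 0.5), negative otherwise.
The strict comparison takes the natural reading of "distance less than the
threshold"; because boundary ties at exactly 0.5 are common with small
author sets (two 3-element sets sharing 2 authors sit exactly at 0.5), the
`comparison = "le"` switch is provided and the choice is worth an explicit
look on real data.  Items with no recorded contributors are excluded from
the graph rather than treated as maximally distant: similarity of unknown
authorship to anything is undefined, and in practice only a minority of
nodes carry contributors.

Partitions are scored by *disagreements*: negative edges inside blocks plus
positive edges across blocks.  Two solvers are provided:

* `cluster_exact()` enumerates all set partitions (restricted-growth
  strings, cached per size; capped at 10 vertices ≈ 115&nbsp;975
  partitions) and breaks ties by fewer blocks, then lexicographic
  encoding.  It is the oracle for everything else.
* `cluster_pivot()` is the standard randomized pivot heuristic — a random
  unclustered vertex absorbs its unclustered positive neighbours — with
  restarts, followed by best-one-element-move local search.  The local
  search is part of the package's algorithm by design: on uniform random
  signed graphs with 4–9 vertices, pivot alone with 50 restarts matches
  the exact optimum only about 80% of the time, while pivot plus local
  search matched it on every instance we enumerated; the test suite pins
  ≥ 95% agreement on 200 seeded instances.  Local search can be disabled
  (`refine = FALSE`) for very large graphs, where the plain pivot is used
  with a couple of restarts.

`classify_clusters()` labels each block against the hierarchy —
`superfamily` (a family plus all of its clustered descendants),
`sibling_subset`, `parent_partial_children`,
`siblings_plus_other_relatives`, `multi_parent_anomaly` (a member whose
several parents were separated into different blocks), `singleton`,
`unrelated`.  Because clustering runs over *authored* items only, the
superfamily test compares against descendants restricted to the clustered
universe.

Pairwise clustering has a known blind spot that motivates the stress-based
procedure: a parent with authors $\{a_3, a_4\}$ and children
$\{a_1,a_2,a_3\}$, $\{a_1,a_2,a_4\}$ (the `example_family_triple()`
fixture) yields no positive edge at threshold 0.5 under the strict rule,
yet the *combined* authorship of the three nodes is arguably one
collaboration.  Pairwise distances cannot see it; the family-wise measure
can be tuned to.

## The bottom-up recommendation sweep

`stress_report()` annotates every node with its **sub-stress** (weighted
stress of the author sets of all authored descendants) and its **stress**
(the same multiset plus the node's own author set when non-empty); both are
`NA` where the underlying multiset is empty — stress of nothing is
undefined, not zero, so authorless subtrees carry no signal rather than a
spuriously perfect one.  By monotonicity, sub-stress ≤ stress wherever both
are defined.  `level_table()` condenses the report to per-level means.

`recommend_views()` walks families in post-order.  For a node $N$ with
child subtrees $N_1,\dots,N_k$ (each represented by its *effective* author
set — its own if non-empty, else the union over its descendants):

* $N$ authorless, every child's stress ≤ `low` **and** the joint stress of
  the children's sets ≤ `low` → one summary rooted at $N$ (**case 1a**,
  flagged `needs_review`: the root's authorship has to be imputed);
* $N$ authorless otherwise → children keep their roots (**case 1b**);
* $N$ authored and the joint stress including $N$'s own set ≤ `low` → one
  summary at $N$ (**case 2a**, automatic);
* $N$ authored but the joint stress is high (**case 2b**) → children keep
  their roots and $N$ is flagged `needs_review`.

Resolutions of points the procedure leaves open, made once and applied
uniformly:

* **Joint stress is family-wise.**  "The stress of the combined children"
  is evaluated as the stress of the *multiset of their author sets*, not of
  the single unioned set (which is identically 0 and would make the
  procedure trivial).
* **Case 2b does not root $N$ itself.**  Reading 2b as "a summary for $N$
  *and* each child" would place a root above other roots and break the
  plan's antichain invariant (every authored bottom-level family under
  exactly one root).  The package keeps the child roots and flags $N$; its
  uncovered own authorship is precisely what the curators are asked to
  review.
* **Objects never become roots**, so a bottom-level family is the lowest
  permissible granularity; when its internal stress is high the family
  still roots a summary but is flagged.
* **Top-level groups never become roots.**  Authorship is not recorded at
  group level, and without this rule an authorless group over a single
  coherent family would absorb it via case 1a, defeating the bottom-level
  starting granularity.
* **Imputed authorship** for authorless roots is the union of descendant
  author sets (the curator-attribution alternative is a configuration
  concern outside the sweep).

The default `low = 0.3` adopts the conventional reading of "very low
stress" for this measure; it is a configuration knob (`--low-stress`), and
the suite checks the *monotone response* that makes it safe to tune:
lowering `low` never decreases the number of roots.

## What the synthetic generator emulates

`simulate_database()` plants authorship blocks in a generated hierarchy:
every bottom-level family and its objects share one core author set drawn
from a common pool; with probability `noise` a node drops one core author
or adds one pool author (the simplest perturbation that produces a mixture
of zero-stress families and outliers).  References are drawn per node,
partly from a block-shared pool (15% of draws) so that members of a block
share citations, the rest globally fresh.  The
`gtopdb_scale_params()` preset fixes the study conditions: 7 groups,
branching 10 × 11 (770 bottom-level families), Poisson(2.6) objects per
family (~2000), an author pool of 1000 with long-tailed core-set sizes
(negative binomial, mean 3.5, capped at 33 — the distributional detail is a
stand-in, since only the maximum is known for real data), Poisson(12)
outgoing references per node (~33&nbsp;000 distinct), and a 1% chance of a
second parent for an object.  All draws flow from a single seed.

What it does **not** emulate, hence what green tests do not show about real
data: real contributor sets are not block-constant with symmetric one-author
perturbations; real hierarchies have authored intermediate families and
large swathes of entirely authorless nodes; reference sharing follows
topic structure, not block membership; and multi-parent links are not
uniform.  Recovery results on the preset (planted blocks recovered exactly
at `noise = 0`; clustering-vs-block adjusted Rand index ≥ 0.9 at
`noise = 0.05`) are calibration checks of the machinery, not predictions of
curator agreement on a production database.

## Summaries, metadata and change detection

`collect_view()` materialises a root: members in deterministic depth-first
order, merged authors ordered by contribution count then name (author
ordering in merged views needs *some* deterministic rule; contribution
count is transparent and reproducible), references deduplicated by id and
ordered by year, first author, title.  `render_summary()` emits a
document pair (portable Markdown plus an HTML sibling) carrying the eight
content elements — title containing the database version, authors with
affiliations, abstract (falling back to a generated sentence naming the
view when the database has no description), database links, publisher,
a fixed rationale statement, the numbered reference list, and a DOI
(caller-supplied or a deterministic placeholder) — and is a pure function
of its inputs, so re-rendering is byte-identical.  Exports:
BibTeX/RIS/plain citations and a Dublin-Core-flavoured XML record.

Provenance is deliberately split: the version appears in the *title* (so
citation analyzers distinguish successive summaries) while the full
snapshot payload lives in the *metadata record*, where it cannot confuse
text-mining indexers.  That payload is the four-item ledger — database
version, author ids, reference ids, canonical view encoding — mirrored to
a local JSON file for offline operation.  `needs_new_summary()` triggers
regeneration exactly when the author set, reference set or membership
changed (or on `force`); description-only edits are deemed insignificant.
Version labels are strictly increasing under an integer scheme or a
database-coupled dotted scheme (`"2020.1"` → `"2020.2"`).  Whether a
retrieval date is part of a reference or of its annotation is left
open — the metadata stores both the database version and the summary
version, taking no position.

## Numerical and testing choices

* Empty unions raise classed errors rather than returning 0; `NA` marks
  undefined stress in reports.
* Tolerances of `1e-12` absorb floating-point noise in inequality checks;
  the worked-example value 0.5 is exact in binary and asserted exactly.
* Exhaustive clustering caps at 10 vertices; the Bell-number growth makes
  larger instances pointless when the refined pivot heuristic agrees with
  the oracle on small ones.
* Problem sizes in the test suite are the package's own choices: property
  suites run 1000 randomized instances per invariant; oracle-vs-heuristic
  agreement uses 200 instances of 4–9 vertices; full-scale checks use the
  preset (≈ 2870 nodes) with 1 noiseless recovery run, 20 seeded noisy
  clustering runs, and one end-to-end pipeline run.

## Known limitations

* Author identifiers are opaque strings: no name disambiguation or ORCID
  resolution.
* The antichain/coverage guarantees of a plan assume families have single
  parents (multi-parent *objects* are handled; multi-parent families could
  be double-covered and are rare enough in practice to leave to
  validation).
* Plain stress on large heterogeneous families saturates at 1 quickly; the
  weighted variants are the practical tools at group scale.
* The BibTeX/RIS writers cover the summary-citation subset of those
  formats, not arbitrary records, and the bundled parser exists to
  round-trip-check the writer's own output.
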