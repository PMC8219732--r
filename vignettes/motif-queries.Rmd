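---
title: "Motif queries on attributed graphs: models, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif queries on attributed graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifquery)
```

## The problem

A connectome is a directed graph: nodes are neurons, edges are synapses, and
both carry attributes (cell type, soma radius, neurotransmitter, synaptic
weight). Many circuit-level hypotheses reduce to a question of the form "how
often does this small wiring pattern occur, and is that more often than
chance?" Answering it requires (i) a precise way to *state* the pattern,
(ii) a complete *search* for it, (iii) *deduplication* of symmetric answers,
and (iv) *null models* against which counts can be compared. `motifquery`
implements that pipeline: a text DSL is parsed into a motif, validated,
optimized, and executed as a subgraph search; census tooling enumerates
whole families of small motifs; five random-graph models provide
density-calibrated baselines.

## Match semantics

Given a motif $H = (V_H, E_H)$ and a host $G = (V, E)$, a **monomorphism**
is an injective map $f: V_H \to V$ with $(u,v) \in E_H \Rightarrow
(f(u), f(v)) \in E$; extra host edges among the mapped nodes are allowed.
An **isomorphism** match (node-induced, `exact_match`) additionally forbids
host edges between mapped pairs that the motif does not require. On top of
the edge condition, a match must place no host edge on any forbidden pair
(`A !> B`), and every node/edge attribute constraint must evaluate to true.
Monomorphism is the default, matching the convention in connectome motif
counting; isomorphism-mode results are always a subset of monomorphism-mode
results.

Constraint evaluation is deliberately forgiving in one direction only:
comparing incompatible types (a number against a string) or a missing
attribute *fails the constraint* rather than raising an error. Queries
therefore never abort mid-search on heterogeneous data; they simply do not
match. The operator set is fixed at `=, !=, <, <=, >, >=, in, contains`.
Other tools in this space may support different operator sets; the grammar
file (`inst/grammar/motif.ebnf`) is normative for this package.

## The search algorithm

The engine keeps its state space in a one-dimensional queue of partial
mappings. Each state assigns a prefix of the motif nodes; expanding a state
tries every unused host node for the next motif node and keeps only children
that satisfy *all* checks decidable at that depth (edges and non-edges into
the assigned set, attribute constraints whose participants are assigned,
ordering constraints, induced-subgraph checks in isomorphism mode). Dead
states are never enqueued, so the queue contains only consistent partial
mappings and complete states are exactly the matches.

Two choices here are heuristic and verified to be result-neutral:

* **Assignment order.** Motif nodes are ordered most-constrained-first
  (constraint count plus degree, with extra weight on adjacency into the
  already-ordered set; ties broken by declaration order). This shrinks the
  branching factor early but cannot change the result set, which the test
  suite confirms against a brute-force oracle.
* **Queue discipline.** FIFO is the default; LIFO (depth-first) is available
  and uses less memory on match-rich hosts. The result set is identical
  under both (tested), because child generation, not pop order, decides
  membership.

Correctness is established empirically against an independent oracle that
enumerates *all* injective tuples and filters them by the definition above:
several hundred randomized motif/host instances per run, in both modes, must
agree exactly. Typical suite sizes are motifs of 2–4 nodes against hosts of
6–12 attributed nodes — small enough that the oracle is itself trustworthy,
large enough to exercise every code path (forbidden edges, inter-node
comparisons, direction-ignoring motifs, induced mode).

## Automorphisms and one-match-per-class

A motif with symmetry produces duplicate answers: the mutual pair
`A -> B, B -> A` matches every reciprocally connected host pair twice. The
package detects the motif's automorphism group exactly — permutations
preserving required edges, forbidden edges, and the constraint multiset
under renaming — by exhaustive backtracking with partition pruning, guarded
at 10 motif nodes (beyond that the factorial search is declined with an
explicit error; published connectome motifs are ≤ 6 nodes).

Deduplication then combines two mechanisms:

* **Ordering constraints** `id(A) < id(B)` are added for every node pair
  whose transposition is in the group. These prune during the search and
  are sound: if swapping A and B is an automorphism, every match class
  contains exactly one member with the images in increasing host order.
* **Lex-min orbit filtering** keeps a completed mapping only when it is
  lexicographically minimal among its images under the full group. This is
  what guarantees *exactly one representative per class for every group* —
  pairwise orderings alone cannot break cyclic symmetries (the directed
  3-cycle motif has automorphism group C₃ with no transpositions at all).

Because the group acts freely on injective mappings, every equivalence
class has exactly group-order many members; the invariant
`raw count = dedup count × |Aut|` is asserted throughout the tests (e.g.
the direction-ignored triangle in K₄: 24 raw injections, group order 6,
4 representatives). The same ordering predicates are emitted by the Cypher
transpiler so that a graph database returns the same deduplicated set.

## The DSL

Statements are newline- or semicolon-separated; whitespace is otherwise
ignored; `#` starts a comment. A leading comment block of `# key: value`
lines is parsed as provenance metadata (author, date, free comments), and
the two keys `exact_match` / `ignore_direction` set the match-mode flags, so
a `.motif` file round-trips through `parse_motif()` / `serialize_motif()`
with structure, constraints, interchangeability declarations, flags and
provenance intact (macros are expanded at parse time, so round-trips compare
expanded forms).

Macros are parameterized statement blocks, expanded innermost-first. A macro
body may reference only its own parameters (and call other macros); this is
enforced at definition time. The stricter rule makes substitution trivially
capture-avoiding — no local can collide with a motif participant because no
local distinct from the parameters may exist — and guarantees that macro
expansion never adds participants beyond the caller's arguments. Recursive
macro chains are rejected with the cycle listed.

## Validation

Validators return violations as data rather than raising, and an invalid
motif still runs (it simply matches nothing — a cross-module property the
suite checks). Three validators ship:

* **Structure** — a pair required *and* forbidden; nodes on no edge.
* **Constraint feasibility** — per node/edge and attribute, the conjunction
  of constraints must admit at least one value. Numeric bounds are collapsed
  to the tightest interval and probed at its endpoints, midpoint and
  neighbouring values; equalities and membership lists are checked by direct
  evaluation, which makes the check exactly as strict as the match-time
  semantics. Inter-node comparisons are checked pairwise (`A.r > B.r` with
  `B.r > A.r` is caught); full constraint-network consistency is
  deliberately out of scope — single-attribute contradictions are the
  practically occurring failure mode, and full CSP solving buys little for
  query graphs this small.
* **Biology (optional)** — a rule file declares mutually exclusive edge
  attribute classes (e.g. inhibitory vs excitatory transmitter types); a
  node whose outgoing edges demand values from two exclusive classes draws a
  warning. Rules are optional and user-modifiable; an empty rule set
  validates everything. A plugin-style hook is the rule list itself: any
  number of rules over any attributes.

## Null models and calibration

Five models, all seed-deterministic:

| model | parameters | calibration to density D |
|---|---|---|
| Erdős–Rényi | `p` | `p = D` (exact in expectation) |
| geometric (unit square) | `r` | bisection on a Monte-Carlo density estimate, tolerance ±0.005 |
| Watts–Strogatz | `k`, `rewire` | `k` = nearest even integer to `D (n−1)`; `rewire` stays free |
| Barabási–Albert | `m` | `m = round(D (n−1) / 2)` |
| X-swap | source graph, `n_swaps` | inherits the source's density exactly |

Calibration targets the undirected density $D = 2|E| / (|V|(|V|-1))$, the
characteristic most directly tied to expected motif counts. The geometric
model uses a 2-D unit square with hard boundaries (no torus); nodes are
uniform points, edges connect pairs within radius `r`. The Watts–Strogatz
rewiring probability cannot be set from density (density is fixed by `k`),
so it is exposed as a sweep parameter — its value moves triangle counts
across a wide range, which is exactly why the model is informative. The
first four models produce undirected samples (used for undirected censuses);
an independent-ordered-pair directed variant of Erdős–Rényi is available via
`directed = TRUE` for directed censuses.

X-swap randomization repeatedly replaces random edge pairs
$\{u_1 v_1\}, \{u_2 v_2\}$ with $\{u_1 v_2\}, \{u_2 v_1\}$, rejecting
proposals that would create a self-loop or duplicate edge. Every node's in-
and out-degree is preserved exactly, so single-edge counts are invariant
while higher-order structure mixes. The default of 10·|E| accepted swaps is
a common mixing heuristic and configurable; the package makes no claim of
exactly uniform sampling from the degree-sequence configuration space.

## Census and enumeration

`atlas_graphs()` enumerates undirected graphs of up to 6 nodes by exhaustive
edge-subset enumeration with bitmask canonical forms (minimum of the
permuted bitmask over all node permutations), ordered by node count, then
edge count, then ascending lexicographic sorted degree sequence, then
descending automorphism-group order. The published atlas's full tie-break
rules are not reproduced anywhere convenient; this ordering is pinned by
three anchors that are asserted in the tests — id 7 is the triangle, id 16
the 4-cycle, id 208 is K₆ — and any residual within-(n, m, degseq) ambiguity
does not affect those anchors. Ids are assigned within the *full* atlas
(disconnected classes included) and the census then uses the connected
members, so id gaps are meaningful.

`connected_digraphs()` enumerates directed graphs the same way: all
$2^{n(n-1)}$ arc sets, canonicalized under all $n!$ permutations, filtered
to *weak* connectivity (underlying undirected graph connected), which is the
convention consistent with the known class counts 13 (n=3), 199 (n=4),
9364 (n=5). The n=5 enumeration canonicalizes about a million bitmasks under
120 permutations in roughly a dozen seconds on one CPU; n=6 (over 1.5
million classes) is declined with an explicit capability error.

A census counts each motif with deduplicated monomorphisms. For undirected
motif sets against a directed host, the host is symmetrized once per census
run (not per motif); counts are invariant under host relabeling and under
reversing every edge, both asserted in the tests. For the triangle, the
census is additionally checked against a closed-form triple-enumeration
oracle.

## The fixture generator

`generate_fixture()` emulates the *statistical surface* of an attributed
connectome for testing: a directed Erdős–Rényi background at a chosen
density; categorical `cell_type` and lognormal positive `radius` on nodes;
categorical transmitter `type` and lognormal positive `weight` on edges;
and optional planted motifs. Planted motifs occupy disjoint fresh nodes
that receive no background edges, so the planted multiplicity is a
guaranteed lower bound on the census count, and their attributes are set to
satisfy the motif's literal constraints. Defaults (lognormal radius around
8 µm-scale values, weights around 5, three cell types, three transmitter
types) are one-time choices of plausible magnitudes, not fits to any
dataset.

What the fixture deliberately does *not* emulate: degree heterogeneity,
spatial structure, reciprocity excess, community structure, or correlated
attributes — all prominent in real connectomes. Passing tests on fixtures
therefore demonstrates *algorithmic correctness* (complete search, exact
deduplication, faithful constraint semantics), not that any scientific
conclusion transfers to real tissue. The real-connectome counts quoted in
the documentation are wired as optional integration tests that run only
when a user supplies the downloaded datasets.

## Degenerate inputs and numerical notes

* Density is undefined below 2 nodes and errors explicitly; an empty graph
  has density 0.
* A motif larger than its host yields an empty result, not an error.
* Graphs with no valid X-swap (e.g. a single edge) are returned unchanged.
* Host node order (for symmetry-breaking comparisons) is the internal
  vertex index — any fixed total order works, and representatives may
  differ between labelings while counts never do.
* Node identifiers are always strings end-to-end: connectome body IDs
  overflow 32-bit integers.
* Bitmask canonicalization stores masks as doubles; the largest mask used
  ($2^{20}-1$) is far below the 2⁵³ exact-integer limit.

## Problem sizes in the shipped tests

The suite verifies oracle equivalence on ~500 randomized instances (motifs
≤ 4 nodes, hosts ≤ 12 nodes), runs the full 6-node atlas and 5-node digraph
enumerations with independent igraph-based isomorphism oracles, and checks
calibration/degree-preservation on hosts of 100–200 nodes. These sizes keep
the complete suite in the low minutes while covering every code path; all
algorithms accept larger inputs, with runtime governed by the usual
NP-completeness of subgraph matching.

## Known limitations

* Exhaustive automorphism detection is exponential and guarded at 10 motif
  nodes; no canonical-labeling (nauty-style) shortcut is attempted.
* Cypher output is text-only; the package never connects to a database, and
  direction-ignoring motifs are not transpiled.
* Parallel edges are not representable (multi-synapse pairs belong in a
  `weight`/count edge attribute); self-loops are off by default and
  enabled by a flag.
* The search is single-threaded; the queue representation would admit a
  parallel work-stealing variant, which is left as future work.
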