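---
title: "Inferring segmental duplication-loss histories of syntenies"
author: "superrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring segmental duplication-loss histories of syntenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superrec)
```

## The problem and the model

Gene families that sit next to each other on a chromosome — syntenic
blocks, or paralogons when several homologous copies of the block exist —
often descend from a single ancestral region through duplications and
losses of whole segments. Reconciling each family's gene tree with the
species tree independently misses this: it explains one concerted
segmental duplication as several coincidental single-gene duplications
that happen to preserve neighborhood.

`superrec` models a set of syntenies as evolving from one ancestral
synteny through three events:

* `Spe(X, [1, l])` — a speciation copies the synteny `X` into both child
  species of `s(X)`; it costs nothing.
* `Dup(X, [i, j])` — a segmental duplication copies the substring
  `X[i..j]` elsewhere in the same genome; cost 1.
* `Loss(X, [i, j])` — a segmental loss removes the substring; a loss of
  the whole synteny (`fLoss`) terminates the lineage, a partial loss
  (`pLoss`) truncates it; cost 1 each.

Histories are partially binary trees: speciations and duplications are
binary, partial losses unary, and full losses and extant syntenies are
leaves. A *Super-Reconciliation* is such a history that extends every
input synteny tree (each gene tree with its leaves renamed by their
syntenies). Two assumptions are built into the model and inherited by
everything downstream:

* **one gene per family per synteny** — tandem duplications are out of
  scope, so syntenies shrink monotonically along every lineage;
* **no rearrangements in the ordered mode** — a synteny can only lose
  genes, never reorder them, so every ancestral synteny must contain every
  extant one as a subsequence.

## Existence conditions

The ordered model can be outright infeasible, and the package checks the
two conditions before any optimization:

* `build_precedence_graph()` / `is_order_consistent()`: the directed graph
  on families with an edge `i -> j` whenever some synteny places a
  family-`i` gene *anywhere* before a family-`j` gene. We insert all
  ordered pairs rather than only adjacencies — acyclicity is equivalent,
  but the all-pairs graph matches the definition of precedence literally
  and makes the sort/subsequence property self-evident.
  `enumerate_ancestral_orders()` emits the topological sorts depth-first
  with alphabetically sorted sources, so enumeration order is
  reproducible; counting sorts exactly is intractable in general, so a
  `limit` (default 10,000) truncates with a warning and a flag.
* `triplet_consistent()` / `build_supertree()`: rooted trees are
  compatible iff BUILD succeeds; the pairwise triplet check is the cheap
  necessary screen. Supertree *enumeration*
  (`enumerate_binary_supertrees()`) generates all rooted binary topologies
  and filters them by the display test. This is deliberately oracle-grade:
  it is exact, trivially auditable, and sufficient for the leaf counts
  where exhaustive search over (order, supertree) pairs is meaningful at
  all; it refuses more than 8 leaves. For larger instances a backbone
  topology must be supplied explicitly (`super_reconcile(supertree = )`),
  which is also the natural protocol for simulation studies where the true
  topology is known.

One consequence of taking the display definition seriously: a two-leaf
synteny tree is displayed by *every* supertree containing its leaves, so
cherries constrain nothing by themselves. The enumeration therefore
returns all three topologies for a cherry plus a free leaf, not just the
one keeping the cherry intact.

## The ordered dynamic program

For a fixed supertree and ancestral order `A` over `t` families, nodes are
LCA-mapped into the species tree, labeled `Spe`/`Dup` by the separation
criterion, and full-loss leaves are grafted one per skipped species-tree
edge (grafted nodes are speciations; losses sit closest to the parent).
`small_phylogeny_ordered()` then assigns every node a subsequence of `A`,
encoded as a bitmask over positions of `A` — `2^t` states per node, which
is what makes the method fixed-parameter tractable in `t` and linear in
the number of nodes. Transition costs use two loss distances, both `O(t)`
because families within a synteny are unique:

* `loss_dist_total(X, Y)` (`D^T`): the number of maximal runs of `X`
  positions absent from `Y` — one segmental loss per run;
* `loss_dist_partial(X, Y)` (`D^P`): the same count ignoring the prefix
  and suffix runs, because a duplication may copy a substring that simply
  starts and ends inside `X`. At a duplication, at most one child may use
  `D^P`; both orientations are tried.

Numerical conventions, chosen once and used everywhere:

* segments are closed 1-based intervals `[i, j]`;
* grafted full-loss leaves carry the empty synteny; assigning the empty
  synteny anywhere else is forbidden (the recurrence admits it formally,
  and the brute-force oracle confirms on small instances that excluding it
  never changes the optimum — an empty internal assignment could only be
  reached by a full loss, which terminates the lineage);
* `D^T(X, ∅) = 1` is exactly the full-loss event, which unifies grafted
  leaves with the recurrence without a separate counter;
* a single-leaf backbone keeps the root order `A` and pays the unary
  partial-loss chain from `A` down to the extant synteny (degenerate in
  the pipeline, where `A` always matches a lone synteny's order);
* backtracking ties: the smallest submask wins, the left child receives
  the partial copy on ties, and the reported duplication segment is the
  minimal (leftmost) substring covering the child's assignment. Ties are
  therefore resolved deterministically, and repeated runs are identical.

The state-space guard (`max_states`, default `2^22` table entries) turns
the exponential growth in `t` into an explicit resource error naming the
offending family count instead of an open-ended computation.

## The unordered variant

When gene orders conflict — the usual situation across distant genomes,
where rearrangements shuffle blocks — the package offers the unordered
model: rearrangements are free, only duplication and loss events are
counted, and syntenies reduce to their family sets. Two structural facts
make this polynomial. First, a single partial loss can remove an arbitrary
subset when order is irrelevant, so at most one loss is ever needed per
edge. Second, the *identity* of content assigned beyond a node's
`lca_set` (the union of families below it) never affects the cost — only
whether there is any. Each node therefore carries two values, `C_lca` and
`C_star`, combined by a four-case recurrence in which a speciation pays
one loss per shrinking child while a duplication absorbs one child's
shrink into the partial copy. `usr_min_cost()` runs in `O(|V|·|F|)`.

The `C_lca` case analysis is stated in the package's own derivation and
is **not** taken on trust: the test suite proves it against an exhaustive
oracle that enumerates every per-node set between `lca_set(v)` and the
full family set (1,000 random instances in the acceptance suite, plus the
subtree-level invariance check that pinning a subtree root to different
strict supersets of its `lca_set` leaves the optimum unchanged).
Backtracking prefers the `lca_set` assignment on ties, avoiding phantom
content. The root always carries the full family set; when the universe
passed in strictly exceeds the content below the root (possible only with
an explicitly supplied family universe), the root cost is `C_star` by the
same invariance.

## The simulator

`simulate_history()` implements a five-parameter protocol: `t` families in
the ancestral synteny; a balanced species tree of depth `d`; each node of
the evolving tree is a segmental duplication with probability `p_dupl`,
else a speciation; a loss occurs on a branch with probability `p_loss`;
loss lengths are shifted geometric, `P(K = k) = (1 - p_length)^(k-1)
p_length`, truncated to the genes available from a uniform start position.
Defaults are `t = 5, d = 5, p_dupl = p_loss = p_length = 0.5`, the
parameter point used throughout the acceptance suite.

Where the protocol leaves detail open, the package fixes it explicitly:

* "a loss under a node" is implemented as *per child branch*,
  independently with probability `p_loss`, at most one loss per branch —
  the simplest reading consistent with the trees the model can express;
* loss start positions are uniform over valid positions;
* duplication segments draw their start uniformly and their length from
  the same shifted geometric (the protocol is silent on both);
* a loss consuming the whole synteny becomes a full-loss leaf; a lineage
  whose synteny empties can therefore die out, and a simulation in which
  *every* lineage dies raises a distinct `superrec_extinct` error that
  sweeps simply skip.

`strip_to_input()` produces what an inference method may legitimately see:
extant syntenies (as a gene table with generated ids), per-family gene
trees (restrictions of the true tree to surviving genes, unary nodes
suppressed; families with no survivor are dropped with a message), and the
true backbone topology over extant syntenies. Stripped inputs are
order-consistent and tree-consistent *by construction*, which is exactly
what the existence-condition checks certify on them.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: sequence evolution and gene-tree estimation
error (input trees are true restrictions, never misinferred),
rearrangements (the ordered model would reject most real distant-genome
orders, as the unordered mode exists to handle), tandem duplications,
unbalanced species trees, and any rate heterogeneity across lineages or
families.

## Validation strategy and problem sizes

Every optimization routine is checked against an independent brute-force
oracle rather than against itself: `oracle_ordered()` enumerates all valid
bitmask assignments and counts events per edge with loss distances
obtained by explicit search over interval-removal sequences;
`oracle_unordered()` enumerates all set assignments. The acceptance suite
runs, on one CPU: an exhaustive ordered sweep (all topologies on up to 4
syntenies with all subsequence leaf assignments at `t = 3` in one genome,
plus the mixed-species sweep at `t = 2` and 500 random mixed instances at
`t ≤ 4`, ~38,000 instances), 1,000 random unordered instances, 200
single-family reductions to classical duplication-loss cost, 100 simulated
seeds at the default parameter point for the parsimony bound (inferred ≤
true cost; minimization over all enumerated ancestral orders, which
include the true one), a depth sweep `d = 3..8` at `t = 5` confirming the
DP completes with bounded per-node time, the exhaustive distance
identities up to length 8, and the simulator calibration (chi-square on
10,000 loss lengths at α = 0.01; duplication fraction within 3 standard
errors over ≥ 1,000 decision nodes). These sizes were chosen as the
largest at which the oracles remain exactly enumerable; they are the
package's definition of desk-scale.

## Known limitations

* Exact search only: no heuristics for many families (the DP table guard
  refuses them) or for large supertree spaces (enumeration is capped and
  truncation is always flagged). The underlying optimization problem is
  NP-hard, so this is a scope decision, not an oversight.
* The ordered mode is brittle on real distant genomes by design — order
  inconsistency is a property of the data, and the distinct error class
  tells the caller that the unordered mode is the remedy.
* Multi-copy syntenies (tandem arrays) and transfer events are outside the
  model; unrooted or multifurcating input trees are rejected at parse
  time.
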