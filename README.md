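# superrec — Super-Reconciliation under segmental duplication and loss

Classical gene tree / species tree reconciliation explains the
incongruence of *one* gene family by single-gene duplications and losses,
treating each family as evolving independently. Genes that sit together in
**syntenies** (ordered blocks of neighboring genes — paralogons such as the
Hox clusters or the opioid-receptor regions) more plausibly evolved in
concert: whole segments were duplicated and lost together. `superrec` is
for molecular evolutionists who want to reconcile a *set* of gene trees
with a species tree under that segmental model, inferring a minimum-cost
history of segmental duplications (`Dup`), full losses (`fLoss`) and
partial losses (`pLoss`) that starts from a single ancestral synteny.

## The model in brief

The input is a species tree *S*, a set of gene families 𝓕 = {Γ₁, …, Γₜ}
organized into syntenies 𝓧 (one gene per family per synteny; each gene in
exactly one synteny), and one rooted binary gene tree per family. Each gene
tree, with leaves relabeled by their syntenies, becomes a synteny tree; a
**Super-Reconciliation** is a labeled extension of all of these trees that
is a valid history: a speciation `Spe(X, [1,l])` copies a synteny into the
two child species; a segmental duplication `Dup(X, [i,j])` copies the
substring *X[i..j]* within its genome; a segmental loss removes a substring,
either all of *X* (`fLoss`) or part of it (`pLoss`). The cost is the number
of `Dup + fLoss + pLoss` events; speciations are free.

A history exists only under two conditions, both checked by the package:

* **Order consistency** — the directed *precedence graph* on families
  (edge *i → j* when some synteny places a Γᵢ-gene before a Γⱼ-gene) must
  be acyclic; its topological sorts are exactly the candidate ancestral
  gene orders *A*.
* **Tree consistency** — the synteny trees must agree on every shared leaf
  triplet; the BUILD algorithm then assembles supertrees displaying them
  all.

Inference explores (ancestral order *A*) × (binary supertree *T̃*) pairs.
For each pair, nodes of *T̃* are LCA-mapped into *S*, labeled `Spe`/`Dup`
by the separation criterion, full losses are grafted, and an exact dynamic
program assigns a subsequence of *A* to every node (root = *A*), paying

* at a speciation, `D^T(X, X_c)` per child — the number of maximal runs of
  *X* absent from the child's synteny (one segmental loss each);
* at a duplication, one event plus, on at most one child, the cheaper
  `D^P(X, X_c)` that lets the copied substring shed its prefix and suffix
  for free.

The DP is exponential in the family count *t* (states are the `2^t`
subsequences of *A*) but linear in the number of nodes — exact inference is
practical whenever the syntenic block is modest, which is the biologically
common case. Because finding a minimum-cost supertree is NP-hard, the
supertree/order search is exhaustive with explicit caps rather than
heuristic.

When gene orders conflict (rearrangements), the **unordered** variant drops
orders entirely and minimizes the same events over gene *contents*; it runs
in polynomial time via a two-state recurrence (`C_lca`, `C*`) per node.

A five-parameter simulator (`t`, `d`, `p_dupl`, `p_loss`, `p_length`, with
shifted-geometric loss lengths) generates ground-truth histories on
balanced species trees for testing and calibration, and brute-force oracles
recompute every optimum by explicit enumeration at small scale.

## Worked example

A two-genome instance with three families `x, y, z` in four syntenies —
`A1 = x y z`, `A2 = x z` (species `spA`), `B1 = x y z`, `B2 = x`
(species `spB`) — ships with the package:

```r
library(superrec)
ext <- system.file("extdata", package = "superrec")
S   <- read_species_tree(file.path(ext, "species.nwk"))
gts <- read_gene_trees(file.path(ext, "gene_trees.nwk"))
syn <- read_synteny_table(file.path(ext, "syntenies.tsv"))

res <- super_reconcile(S, gts, syn, mode = "ordered")
res
#> <sr_result> ordered mode: minimum cost 3 (1 optimal histories;
#>   1 ancestral orders x 1 supertrees explored)
res$optima[[1]]$order
#> [1] "x" "y" "z"
res$optima[[1]]$history
#> <sr_history> cost 3 (1 Dup, 2 pLoss, 0 fLoss; 2 Spe, 4 extant)
```

The single consistent ancestral order is `x y z`; the optimal history
duplicates the full ancestral synteny before the speciation (the two blocks
per genome descend from one ancestral region, not from convergent
single-gene events), then loses `y` on the copied lineage and `z` in `B2` —
3 events in total. `history_event_log()` flattens the history to a table,
`write_history()` saves it as annotated Newick plus a TSV event log. The
unordered mode finds cost 2 for the same instance (ignoring order, one
partial duplication of `{x,z}` replaces the copy-plus-loss):

```r
super_reconcile(S, gts, syn, mode = "unordered")$cost
#> [1] 2
```

The same pipeline is scriptable from a shell through `exec/superrec`
(`check`, `supertree`, `reconcile`, `reconcile-unordered`, `simulate`).

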