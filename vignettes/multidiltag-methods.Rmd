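---
title: "Inferring evolutionary histories of orthologous tandem gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring evolutionary histories of orthologous tandem gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multidiltag)
```

## The problem

Tandemly arrayed gene (TAG) clusters are runs of paralogous genes adjacent
on a chromosome, created mainly by unequal crossing-over.  Given

* one signed gene order per extant genome (sign = transcriptional
  orientation),
* a rooted binary gene tree for the whole family, and
* a rooted binary species tree,

the package reconstructs a most-parsimonious evolutionary history that
starts from a single ancestral gene and explains the observed clusters by
five event types: tandem duplications of one or several contiguous genes
(`DUP`), inverted tandem duplications in which one copy block is reversed
and sign-flipped (`INV_DUP`), inversions (`INV`), deletions (`DEL`) and
speciations (`SPEC`).  A duplication replaces the affected span
`u_p..u_q` by the two copy blocks and replaces each leaf `u_x` of the gene
tree by a cherry `(l_x, r_x)`; a speciation does the same to a whole
genome.  A history is therefore simultaneously a sequence of signed gene
orders and a growth process of the gene tree, and `validate_history()`
checks any inferred history by forward replay against both.

## Cost model

Each event of type `e` acting on `m` genes costs `alpha_e + m * beta_e`
(`cost_model()`).  The defaults — duplications opening at 100, deletions
and inversions at 500, extension 1 for every type — encode the usual
working assumption that single large events are more plausible than many
small ones and that duplications are the dominant mechanism in TAG
clusters.  Speciations are free.  Event types can be disabled (they then
cost `Inf` and are skipped during search); this is how clusters whose
biology forbids inversions are analysed.

## The backward search on one branch

Histories are searched backwards from the observed state.  A vertex of the
history graph is an ordered gene tree; an edge is one event.  Working
backwards, the search undoes events:

* a *duplication undo* collapses a pattern of `2m` contiguous genes whose
  halves pair into sign-consistent cherries;
* an *inverted-duplication undo* does the same for the two mirrored
  placements;
* an *inversion undo* reverses and negates any span (the tree is
  untouched);
* a *duplication-with-deletion undo* handles the compound "duplicate `m`
  genes, then delete a contiguous run of `k < m` copies inside one block".
  Deletions appear only inside such compounds: allowing free insertions
  backwards would make the graph infinite.  A copy whose partner was
  deleted simply keeps its identity in the predecessor — it stands for the
  ancestral gene.

Within one branch the working gene tree never has to be materialised:
the reconciliation forest of the branch (below) is static, and a search
state is fully described by the signed order of currently uncollapsed
forest vertices.  Stopping at `g` genes, where `g` is the number of forest
roots, provably lands exactly on the root set, because an antichain of
size `g` covering all leaves of a forest with `g` roots must be the roots
themselves.  This is what makes per-branch results gluable across the
species tree.

`diltag()` explores this graph best-first, keeping a greedy queue
(default capacity 1000) of the most promising partial histories.  Partial
histories are ranked by accumulated cost plus an admissible completion
bound: undoing one duplication lowers the deepest chain of uncollapsed
duplication vertices by at most one level, so at least
`max_depth * alpha_min + surplus * beta_min` more cost is always needed.
The bound never overestimates, so whenever the queue and work budget are
not exhausted the first solution found is optimal; past them the search is
greedy exactly where the published method is.  Ties are broken
deterministically (deepest partial history first, then lexicographically
smallest order), so results are reproducible.

Before the queue starts, a constructive rollout builds one complete
schedule — always collapse the largest available duplication pattern, and
when nothing is adjacent pay one inversion to bring the deepest remaining
cherry together (an adjacent sibling pair always matches either a direct
or an inverted duplication undo, so this always terminates).  Its cost
seeds the running minimum, which activates pruning from the first
expansion; near the bound whole operator families are skipped (an
inversion or a compound's deletion part raises the ranking value by at
least its own cost).  A total work budget (`max_expansions`, default 2000
expanded states per branch search) bounds runtime on adversarial
instances; if the capped search loses every solution, the rollout schedule
itself is returned.  Without such a budget, clusters of ~25 genes can
demand enumerating millions of equal-cost partial histories.

## Reconciliation and the multi-species glue

`lca_reconcile()` embeds the gene tree into the species tree by LCA
mapping: an internal gene vertex maps to the LCA of its children's images
and is a duplication iff its image equals a child's image.  From the
embedding we read, for every species vertex `A`:

* the genome set `G(A)` — the gene copies present at speciation `A`
  (speciation vertices mapping to `A`, plus gene-tree edges whose lineage
  crosses `A`; a crossing edge implies a loss on the branch it skips);
* the pre-speciation set `PG(A)` — the members of the parent's genome set
  that survive into the branch toward `A`;
* the branch forest — leaves `G(A)`, internal vertices the duplications
  assigned to the branch above `A`, roots in bijection with `PG(A)`.

`multi_diltag()` then traverses the species tree bottom-up.  At each
internal vertex it runs the backward search on both child branches from
every element of the child's solution set, stops at `|PG(child)|` genes,
keeps only minimum-cost ancestral orders (per-branch truncation, as
published — this greediness deliberately forfeits global optimality),
reinserts the genes lost on the branch at every position with either sign,
and unions the two sides into the solution set `E(A)`.  Speciation edges
are labelled with the minimum inversions+deletions (ID) distance between
the parent candidate and the child-side order.  Above the species root the
search continues to a single ancestral gene.  Finally one minimum-cost
history is traced back, the ID labels are converted into explicit
inversion/deletion events, and the whole history is validated by replay.

Two accounting conventions are exposed because the choice is genuinely
open: by default (`id_label_costs = TRUE`) the total cost converts the
ID-realizing events into the cost model, giving one commensurate
objective; with `id_label_costs = FALSE` the total is the sum of branch
minima only and edges carry plain event counts.  Edge *selection* always
uses plain counts.

### Loss reinsertion is exponential

Reinserting `k` lost genes into a length-`n` order yields
`2^k (n+1)...(n+k)` candidates.  This combinatorial closure is the
method's known bottleneck; `extend_with_losses()` enforces a configurable
cap (default 10^4 orders per branch) and fails loudly rather than
silently subsampling.

## ID distance

The ID distance between signed orders `x` and `y` (gene content of `y`
contained in `x`) is the minimum number of inversions plus deletions
transforming `x` into `y`.  The implementation first builds an upper-bound
schedule — delete each maximal run of absent genes, then sort the
remainder by reversals using the better of a breakpoint-descent and a
positional greedy schedule — and then certifies it by a bidirectional
breadth-first search that is complete up to one level below the bound
(plain forward BFS when more than three genes are absent).  For orders up
to `id_bound` genes (default 8) the result is exact; beyond that the
upper-bound schedule is reported and flagged.  The exact
polynomial-time algorithm for this distance is deliberately out of scope;
at the cluster sizes where the search itself is feasible, the capped exact
search is both fast and certified.

## The simulator

`simulate_history()` generates ground-truth histories consistent with a
species tree: starting from one positive gene it walks the tree root to
leaves, applies each branch's event budget, and speciates at every
internal vertex.  Event sizes follow a geometric distribution with
`p = 0.5` truncated at the current cluster size (small events dominate, as
in real data); span starts are uniform over valid positions;
inverted-duplication placements are uniform; the within-branch event order
is shuffled.  Each of those conventions that the underlying experimental
designs leave open (interleaving, span position, placement side) uses the
least-informative uniform choice.  A deletion drawn while the genome has a
single gene is deferred behind the next event of the branch, since the
model never deletes a whole cluster.

Three named designs are built in (`named_design()`):

* `fig5` — `n` simple plus `n` double duplications and two inversions per
  branch; extant genomes then hold exactly `3dn + 1` genes at depth `d`
  (the pre-root lineage counts as a branch).  The fixed duplication sizes
  exist only to pin the genome size.
* `fig6` — a total of `x` duplications, half direct and half inverted,
  plus `0`, `x/2` or `x` inversions, spread evenly over the branches
  (round-robin for remainders, which the design leaves unspecified).
* `fig7` — per branch: 4 duplications, 1 inverted duplication,
  1 inversion and 1 deletion of size 1 or 2.  The deletion size follows
  the globally stated truncated geometric law additionally truncated at 2
  (P(1) = 2/3, P(2) = 1/3), the reading most consistent with "unless
  stated otherwise" size sampling.

The simulator emulates event counts, sizes and placements, not sequence
evolution: there is no mutation, no rate heterogeneity, no branch-length
information, and the gene tree handed to the inference is the *true* tree.
Passing tests therefore demonstrate that the search recovers histories
when the tree is right; they say nothing about robustness to gene-tree
estimation error, which on real data is handled upstream (e.g. by running
the method over a posterior sample of trees).

## Evaluation studies and reference scales

`run_duplication_count_experiment()` measures recovery of the total
number of duplications (direct + inverted) under the `fig6` design;
`run_size_distribution_experiment()` measures recovery of the
duplication-size distribution under the `fig7` design (total-variation
distance plus the size-1 and size-2 frequency biases).  The package's
reference conditions use two extant genomes, `x in {2, 4, 6}` and 20
replicates per condition; the originating studies used up to eight genomes
and 50 replicates, and both experiments expose `leaves`, `x_values` and
`replicates` for larger runs.  Every replicate's traced-back history is
validated by replay, and reports are pure functions of `(config, seed)`.

## Numerical choices and degenerate inputs

* Spans are 1-based inclusive `(p, q)`, matching the standard notation for
  subsequences `u_p..u_q`.
* Copies are named deterministically (`u.1`, `u.2`) by a label factory, so
  replays are bit-reproducible; gene names never carry meaning.
* Deleting the last gene of a genome is rejected unless explicitly allowed
  (`allow_empty_genome`), since the model describes a cluster's evolution,
  not its extinction; an empty *observed* order is accepted with a warning
  and simply contributes losses.
* Non-binary or unrooted trees are rejected, not resolved.
* With all duplication types disabled the backward search reports an empty
  result with a diagnostic instead of looping.

## Known limitations

* Per-branch truncation to minimum cost (as published) can discard the
  globally optimal combination across branches.
* Deletions are only proposed inside duplication-with-deletion compounds
  with a single contiguous deleted run; longer loss patterns emerge as
  successive compounds or as speciation-edge deletions.
* The loss-reinsertion closure grows exponentially with the number of
  losses on a branch; the cap makes this failure explicit.
* Above the ID-distance bound, speciation-edge labels are certified upper
  bounds, not exact distances.
* Runtime grows quickly with cluster size; the queue capacity trades
  completeness for time exactly as in the published heuristic.
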