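---
title: "Building MRP supertrees with curated input-tree collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building MRP supertrees with curated input-tree collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpsupertree)
```

## The problem

A supertree synthesises many published phylogenies ("input trees") with
partially overlapping taxon sets into one inclusive tree. The dominant
method is matrix representation with parsimony (MRP): every clade of
every input tree becomes one binary character — taxa inside the clade
are scored 1, taxa present in that tree but outside the clade 0, and
taxa absent from the tree `?` — and the combined matrix is analysed by
weighted parsimony, exactly as a morphological matrix would be. This
package implements that workflow end to end for rooted, genus- or
species-level collections such as the published phylogenies of a
regional moth fauna: curation of the collection, Baum–Ragan encoding,
tree search, consensus, per-clade support, and nested data partitions.

Everything is topological. Branch lengths and internal node labels are
read and discarded, and trees are taken as rooted exactly as published,
because clade-based coding presumes rootedness. No rerooting is ever
attempted.

## Curating the input-tree collection

Published trees are not independent samples: authors reuse the same
genes and the same matrices. Including several trees built from the
same underlying data lets that data vote repeatedly. `curate()` applies
a three-step protocol:

1. **Pseudoreplication resolution** (`resolve_pseudoreplication()`).
   Two trees are suspect when they share a data-type tag *and* their
   taxon overlap exceeds 50% in either direction — equivalently, both
   trees are kept only when at least half the taxa of each are not
   found in the other. Violating pairs are closed transitively into
   conflict sets so the outcome cannot depend on comparison order.
   Within a set, the most comprehensive tree (largest published leaf
   count) is kept at weight 1; when the largest trees tie — typically
   alternative trees offered by a single study — all $n$ tied trees are
   kept, each at weight $1/n$ (two alternatives get 50% each, four get
   25% each). Weights are stored as exact rationals (integer numerator
   and denominator), never floats.
2. **Singleton removal** (`remove_singletons()`). A taxon appearing in
   only one retained tree cannot be placed relative to the rest of the
   data and is pruned. Pruning can leave a tree with fewer than 3
   leaves — such trees carry no character and are dropped — which can
   demote further taxa to singletons, so the census is recomputed and
   the rule applied to a fixed point.
3. **Connectivity check** (`connectivity_check()`). Two trees must
   share at least 2 taxa for one to carry information about the other.
   The connected components of that overlap graph are reported; more
   than one component means the supertree cannot resolve relationships
   across components, and the pipeline warns rather than stops.

A fourth, matrix-level filter (`representation_filter()`) removes taxa
that survive curation but are still represented by too few informative
cells for the search to place them: the defaults require a taxon to
occur in at least `min_trees = 2` trees and to carry at least
`min_cells = 2` non-missing cells. The literature reports that such
removals are needed but not the exact threshold, so both are exposed
configuration keys, re-applied to a fixed point by `run_pipeline()`.

Every decision — tree retained or discarded with a reason code, taxon
removed with a reason code — is accumulated in a `curation_report`, and
the report is exhaustive by construction.

## Encoding and the outgroup convention

`encode_matrix()` produces one character per non-root internal node per
tree, with the character weight copied from the tree's curation weight.
A synthetic all-zero row `MRP_OUTGROUP` is added: scoring is done on
unrooted trees, and an all-zero outgroup is the standard device that
makes the rooted clade coding meaningful. The outgroup is stripped from
every reported tree. Characters are informative by construction (at
least two 1s and a 0), and the character count always equals the summed
cluster counts of the retained trees.

For interoperability the matrix can be written as NEXUS
(`write_nexus()`), with weights scaled by the least common multiple of
their denominators to integers — a weight pair (1, 1/2) becomes (2, 1) —
so relative weights survive exactly in a format that only carries
integer weight sets. Monophyly constraints are emitted as PAUP-dialect
commands.

## Parsimony scoring and tree search

`fitch_score()` computes the weighted minimum number of state changes
with `?` as full ambiguity. Because all characters are binary, the
two-state dynamic program (cost of each state at each node, summing
`min(stay, switch + 1)` over children) is exact on multifurcating trees
as well; scores are integer step counts times exact rational weights.

`heuristic_search()` follows the classic two-phase heuristic: for each
replicate, taxa are added in a random order, each insertion point
chosen to minimise the score (ties broken by the replicate's seeded
randomness); the resulting tree is improved by first-improvement
branch swapping under NNI, SPR or TBR (default TBR, implemented as
bisection at every edge and reconnection across all attachment-point
pairs of the two parts). Candidate reconnections are scored in
O(characters) via attachment-cost vectors computed by a directed-edge
dynamic program, so full TBR sweeps are cheap. After all replicates,
the set of best trees is closed under equal-score swaps — bounded by
`max_trees` (default 10000, with a flag when hit) — to harvest the set
of most-parsimonious trees (MPTs). All returned trees are distinct by
cluster-set identity and deterministic given the seed.

Replicates matter: weighted MRP landscapes have genuine TBR local
optima even at 8 ingroup taxa (we measured single-replicate failure
rates above 30% on adversarial random matrices), which is why the
classic protocol runs hundreds of addition sequences. The default is
1000 replicates; the validation suites use 10–50 because the instances
there are small or strongly determined.

Monophyly constraints are enforced through high-weight indicator
characters: a constrained set costs exactly one step on its indicator
if and only if it is monophyletic, and the penalty weight exceeds the
total data weight, so every optimal tree satisfies all (pairwise nested
or disjoint, hence satisfiable) constraints; the penalty is subtracted
from reported scores and compliance is re-verified on every returned
tree.

`exhaustive_search()` enumerates every topology by branch-and-bound
(partial-tree scores are monotone, so subtrees above the incumbent are
pruned) for problems up to 9 taxa including the outgroup. It exists as
an exact oracle: the test suite checks that the heuristic attains the
exhaustive optimum on hundreds of random weighted matrices with
missing data.

## Consensus and clade support

`strict_consensus()` and `majority_consensus()` assemble the clusters
present in all, or in strictly more than half, of the MPTs. The
strictly-greater-than rule at the 0.5 boundary is the standard
convention (a cluster in exactly half the trees is excluded);
thresholds below 0.5 are rejected because cluster compatibility is then
no longer guaranteed. No majority-rule-extended variant is offered.
Both implementations are cross-checked against `ape::consensus()` in
the tests.

Consensus frequencies answer "how often did the search find this
clade", not "how much evidence supports it". For the latter the package
scores each supertree clade against the input trees
(`score_supertree()`): an input tree *supports* a clade when the
clade's sampled members form a clade of the input tree restricted to
the relevant taxa; it *conflicts* when one of its clusters properly
overlaps the clade's members; it *permits* when neither holds (for
example across an unresolved polytomy); and it is *irrelevant* when it
samples fewer than two members or no outside taxon. With $s$, $q$ and
$p$ the supporting, conflicting and permitting counts:

$$V = \frac{s - q}{s + q}, \qquad V^+ = \frac{s + p - q}{s + p + q}$$

both running from $-1$ (no support in the input-tree set) to $+1$ (full
support), with $V$ undefined when $s + q = 0$ and $V^+$ undefined when
$s + p + q = 0$. Weights deliberately do not enter these counts — each
retained tree votes once — matching the verbal definition of the
indices; a `weighted = TRUE` flag exists as an extension. A clade with
$V = V^+ = -1$ is *novel*: it appears in no input tree and is an
artefact of character interaction in the matrix. Such clades should not
be read as results, and `collapse_novel()` removes them by collapsing
each into a polytomy; re-scoring after collapse reports zero novel
clades, which the tests assert on a frozen two-tree conflict fixture.

## Nested partitions

Very sparse matrices can stall a parsimony search. The classical remedy
is to split the analysis into nested partitions: solve a clade on its
own, then the enclosing group with that clade as a single placeholder
taxon, and so on, finally grafting the sub-supertrees back into the
backbone. `run_partitioned()` automates this for a `partition_spec()`
(named taxon sets, innermost first, pairwise nested or disjoint).

`reduce_tree()` replaces a set of members by one placeholder leaf: on
the members' stem edge when they are monophyletic in that input tree;
otherwise — the literature is silent on its manual procedure here — the
placeholder is attached at the parent of the members' most recent
common ancestor with a warning (or an error in strict mode), which
keeps the tree's remaining information while acknowledging the
ambiguity. `graft()` splices a sub-supertree back over its placeholder
leaf, so each partition's members form a clade of the final tree by
construction; these constrained clades receive no V score, since their
monophyly was imposed rather than inferred. On conflict-free
collections where the partition is a true clade, the partitioned and
unpartitioned pipelines return identical trees (asserted in the tests).

## The synthetic-data generator

No machine-readable input-tree collection accompanies the source
literature, so validation rests on synthetic collections with a known
truth (`generate_model_tree()`, `sample_input_trees()`). The generator
emulates the structure of a real collection:

* a model phylogeny grown by uniform lineage splitting (Yule–Harding);
* *monograph* studies that sample one clade block of the model densely
  plus one flagship representative of every other block — the way
  revisions of a family sample their group plus anchor outgroups;
* one or two *backbone* studies sampling the representatives across the
  whole tree, as higher-level molecular studies do, entered as
  alternative trees of a single study with a dedicated data type;
* topological noise as random NNI moves (`perturb_moves`), soft
  polytomies as random edge collapses (`collapse_prob`);
* optional pseudoreplicate groups: near-duplicate trees sharing a study
  and data-type tag, built by jittering one taxon set — the deliberate
  target of the curation protocol;
* metadata (study ids, years in 1990–2020, data-type tags from a small
  vocabulary: COI, multilocus, mitogenome, morphology).

The block design is not cosmetic. For the no-noise recovery property —
run the full pipeline on noise-free samples of a known model and get
the model back exactly — the collection must *determine* the model:
every rooted triplet of retained taxa must be observed in some tree or
entailed by the observed ones. Blocks are exact clades, each study
contains its whole block plus all other blocks' representatives, and a
four-point argument then forces every cross-block triplet, while
within-block triplets are observed directly. Uniform random subsampling
does not have this property (a 32-taxon model sampled by 12 uniform
10–14-taxon trees leaves many clades undetermined, and the strict
consensus is correspondingly unresolved — an honest property of MRP,
not an implementation artefact). Repeat visits to a block reuse the
same taxon set under rotating data types, so curation either keeps them
as independent evidence or ties them at $1/n$, never silently deleting
a block's only coverage.

What the generator does *not* emulate: estimation error correlated with
branch length (noise is uniform NNI), taxon-sampling biases toward
charismatic groups, name synonymy across studies (the pipeline accepts
a rename table for real data instead), and any model of sequence
evolution. Passing the synthetic suites therefore shows that the
machinery is correct and that the protocol behaves as designed on
structured collections; it does not certify accuracy on any particular
empirical fauna.

## Numerical and convention choices

* Weights and scores are exact rationals throughout; NEXUS emission
  scales by the LCM of denominators. No floating-point accumulation
  can reorder equally parsimonious trees.
* Stepwise-addition ties are broken by the replicate's seeded RNG;
  runs are bit-reproducible given the seed, and the pipeline manifest
  records an MD5 hash of every artifact so reruns are verifiable.
* The 50% overlap rule is "both fractions at most one half keeps both
  trees": the boundary value 0.5 is allowed, exceeding it in either
  direction triggers the rule.
* Majority rule keeps clusters with frequency strictly above the
  threshold.
* Taxon labels are normalized (whitespace to underscores, quotes
  stripped) before matching; no fuzzy synonym matching is attempted.
* Degenerate inputs: trees need 2 leaves to parse and 3 to carry a
  character; a pruning that leaves fewer than 2 leaves returns nothing;
  an all-star collection cannot be encoded and errors with advice.

## Problem sizes used in the validation suites

The test suite runs: oracle-equivalence on 200 random weighted matrices
with 4–8 ingroup taxa (20 addition replicates each against the
branch-and-bound optimum); full-pipeline recovery on a 32-taxon model
with 12 input trees of 10–14 taxa at 50 TBR replicates; partition
consistency on a 16-taxon model with 8 trees; and the frozen conflict
fixture for support scoring. These sizes were chosen as the smallest
that exercise each property convincingly; the package itself has no
such limits, and the search engine's attachment-vector TBR keeps
hundred-taxon matrices practical.

## Known limitations

* Only standard (Baum–Ragan) MRP coding is provided — no Purvis or
  irreversible variants, and no matrix representation with
  compatibility.
* Support indices are V and V+ only; no bootstrap or jackknife of the
  matrix, and no other supertree indices (rQS, QS).
* The transitive closure of pairwise overlap violations can, on
  pathological collections, chain many trees into one conflict set and
  keep only the most comprehensive; the report makes such cascades
  visible.
* The search collects at most `max_trees` MPTs; when the flag is set,
  consensus trees summarise a sample of the optimal set, exactly as in
  capped PAUP* runs.
* Placeholder attachment for non-monophyletic partition members keeps
  information but is a heuristic; strict mode exists for audit runs.
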