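---
title: "Methods: equal-weights parsimony analysis of morphological matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equal-weights parsimony analysis of morphological matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

maxpars implements the classical cladistic workflow for discrete
morphological data under equal-weights maximum parsimony: score trees by the
minimum number of character-state changes they require, search tree space
heuristically for the shortest trees, summarize the result by strict
consensus, and map character evolution onto the shortest trees. This
vignette documents the model, the algorithmic choices, and the places where
a convention had to be fixed because the field uses several.

## The optimality criterion

A character with states coded 0--4 is *unordered*: a change between any two
states costs one step. The length of a tree is the sum over characters of
the minimum number of changes needed to explain the tip states, computed by
the Fitch--Hartigan downpass (`fitch_length()`). On binary nodes this is
Fitch's intersection/union rule; on polytomies the Hartigan counting rule
(children minus the maximal state multiplicity) is used, which is exact for
unit costs. Two independent checks guard the scorer: a Sankoff dynamic
program over states (`sankoff_length()`, a separate code path) and, in the
test suite, direct enumeration of all ancestral assignments on small trees.

Missing (`?`) and inapplicable (`-`) cells are both *equivocal*: they are
expanded to the full set of states observed in that character. The two
tokens are kept distinct in the data model so the source data survive a
round trip, but no analysis distinguishes them. Equivocal expansion uses
the observed alphabet rather than all five theoretical states; states never
observed in a character cannot reduce its length, so the two conventions
give identical scores while the observed alphabet keeps the state sets
small. Inapplicability is thereby approximated as ignorance. This is the
behaviour of the established parsimony programs, and it is what the study
this package replicates specifies, but it is worth knowing that
"inapplicable = equivocal" can in principle let a reconstruction assign a
state to a taxon for which the character does not exist.

Per character, the minimum conceivable steps $m_i$ (observed states minus
one) and the maximum conceivable steps $g_i$ (scored taxa minus the modal
state frequency; the star-tree length) bound the observed steps $s_i$. The
ensemble indices are
$\mathrm{CI} = \sum_i m_i / \sum_i s_i$ and
$\mathrm{RI} = (\sum_i g_i - \sum_i s_i)/(\sum_i g_i - \sum_i m_i)$.
Programs differ in whether parsimony-uninformative characters enter the
sums; `ensemble_indices()` includes them by default and offers
`exclude_uninformative = TRUE`. For the bundled matrix the two conventions
agree to well past two decimals, so the question the replication left open
(which convention the published CI = 0.33 / RI = 0.58 used) turns out not
to matter at the printed precision.

## The two-step heuristic search

`heuristic_search()` follows the classical PAUP-style protocol:

1. **Random addition replicates.** Each replicate draws a random taxon
   order from a single seeded stream (replicate $r$ always uses the $r$-th
   permutation, so short runs are prefixes of long ones), builds trees by
   stepwise insertion of each taxon on every branch of every held tree, and
   keeps the `hold` (default 5) best distinct partial trees; ties are broken
   stably in favour of the first-encountered placement, which keeps the
   search deterministic under a fixed seed.
2. **TBR branch swapping.** The distinct trees held across all replicates
   are pooled and each is swapped by tree bisection--reconnection: cut any
   branch, then rejoin every branch of one fragment to every branch of the
   other. Each start descends by first improvement to a TBR local optimum;
   whenever a tree ties the best length seen so far, its equally long TBR
   neighbors are collected too, and every newly discovered shortest tree is
   itself swapped. The search therefore returns the set of shortest trees
   closed under equal-or-better TBR moves from every start, capped by
   `max_trees` (the result is flagged `truncated` if the cap bites).

Bisection is applied at *every* branch, pendant branches included, so
single-leaf SPR moves are a subset of the neighborhood; restricting
bisection to internal branches would make even the three quartet topologies
mutually unreachable. The sweep is evaluated incrementally: for each
bisection the two fragments are summarized by their (rooting-invariant)
lengths and by per-branch Fitch state sets, after which every reconnection
pair scores in one pass over characters. The default of 1,000 addition
replicates (the study prescribing this analysis used 100,000, which remains
one `search_config()` call away) was chosen because on the bundled matrix
every equal-length island is reached from the pooled starts well within
that budget across seeds; the step-2 pool deliberately keeps *all* held
trees, not only the globally best ones, because starts of slightly
suboptimal length often descend into different islands of shortest trees.

`exhaustive_search()` enumerates all $(2n-5)!!$ unrooted binary topologies
for 4--9 taxa by sequential insertion and is the oracle the heuristic is
tested against.

## Counting "distinct" shortest trees

How many most-parsimonious trees an analysis "finds" depends on a
branch-collapse convention, and published counts rarely state it.
`collapse_and_dedupe()` implements both PAUP-style rules. For each branch
the minimum and maximum number of changes over *all* minimum-length
reconstructions is computed exactly by a two-directional Sankoff pass
(`total cost with the branch's endpoints pinned to each state pair`), so
`min_length_zero` collapses every branch that can have zero length in some
minimal reconstruction, and `max_length_zero` only branches that have zero
length in all of them. On the bundled matrix the search finds 15 distinct
binary trees of 202 steps; they collapse to 3 distinct trees under
`min_length_zero` (the package default, and the convention that reproduces
the published count of three), 5 under `max_length_zero`, and remain 15
uncollapsed. The replication report (`run_replication()`) always records
all three counts side by side.

## Consensus, rooting and ACCTRAN mapping

`strict_consensus()` retains exactly the bipartitions common to all input
trees (delegated to ape's consensus; the bipartition-intersection property
is asserted in the tests). `root_with_outgroup()` roots on the branch
separating the outgroup from the ingroup; if the outgroup is not
monophyletic on a given tree, the branch misplacing the fewest taxa is
used and the result is flagged.

`acctran_reconstruct()` resolves the ambiguity of minimum-length
reconstructions by accelerated transformation. Rather than the traditional
two-pass-with-folklore-tie-breaks formulation, ACCTRAN is defined here as
an optimization problem and solved exactly: among all minimum-change
assignments, minimize the summed root-distance of the branches carrying
changes (changes as close to the root as possible, so early gains with
later reversals are preferred over delayed parallel gains). A lexicographic
dynamic program (changes first, depth sum second) computes this in one
postorder/preorder pass per character; the test suite checks it against
complete enumeration of minimal reconstructions on small trees. Remaining
ties are fixed deterministically: an ambiguous root takes the outgroup's
observed state when that is unique, otherwise the lowest state code; along
a branch the parental state is kept when possible, then the lowest code.
Reconstruction is only defined on binary rooted trees; mapping on a
consensus with polytomies is refused rather than approximated.

`classify_homoplasy()` summarizes each (character, derived state) pair by
its number of independent origins and of reversals (a change whose derived
state recurs from an ancestor of the branch): a single unreversed origin is
non-homoplastic; multiple origins are convergent; note that under ACCTRAN a
pattern that DELTRAN would render as two parallel gains may legitimately
map as one early gain plus a reversal. Per-branch annotations
(`annotate_internodes()`) carry these classes and always sum to the tree
length.

## The synthetic-data generator

`simulate_matrix()` evolves each character independently down a random
topology from a uniform-random root state, changing on each branch with a
fixed probability `change_prob` to a uniformly chosen different state --- an
Mk-style model without branch lengths, which is the right level of detail
for a topology-only parsimony pipeline. Missing and inapplicable tokens are
injected independently per cell; inapplicability is *not* modelled as a
hierarchical dependency between characters, since the analysis treats it as
equivocal anyway. `random_topology()` draws uniformly over unrooted binary
topologies by sequential random branch insertion.

Two calibrated presets matter:

* `study_like_matrix()` emulates the bundled matrix: 38 taxa, 48 characters
  with the study's per-character state counts, its ~9% inapplicable cells,
  and `change_prob = 0.065`, calibrated once so that the true tree's
  ensemble CI averages about 0.33 --- the study's homoplasy level.
* The topology-recovery experiments use 8 taxa, 200 binary characters and
  `change_prob = 0.02`; at these settings the exhaustive optimum contains
  the generating topology, and the heuristic's strict consensus is
  compatible with it, in ≥95% of replicates. These settings were fixed by a
  calibration run before the recovery tests were frozen.

What passing recovery tests show is that the pipeline is a consistent
estimator under its own generating model at low homoplasy; real
morphological data violate that model (correlated characters, hierarchical
inapplicability, rate heterogeneity, non-random missingness), so they
validate the machinery, not morphology-based inference itself.

## Numerical conventions and problem sizes

* Trees are ape `phylo` objects; leaf sets are limited to 64 taxa (splits
  are packed into 64-bit words for hashing and comparison).
* Topology identity everywhere means equality of non-trivial bipartition
  sets (`topology_key()`); `compare_trees()` is the Robinson--Foulds
  symmetric difference on the same representation.
* All randomness (addition orders, simulations) flows from explicit seeds;
  generators restore the caller's RNG state.
* The test suite runs the full study search at 1,000 replicates (~30 s),
  oracle cross-checks on hundreds of ≤8-taxon instances, ACCTRAN
  enumeration checks on ≤6-taxon trees, and the 40-replicate recovery
  experiment; the complete suite takes a few minutes on one core.

## Known limitations

Only unordered, equally weighted characters are supported (no step
matrices, ordered characters, or implied weighting); polymorphic cells
(`{01}`) are not parsed; branch swapping implements TBR only (its SPR and
NNI subsets are not exposed as separate strategies); DELTRAN and full MPR
set reconstruction are available only implicitly through the brute-force
oracle in the tests; and support values (bootstrap, Bremer) are out of
scope, as in the analysis this package replicates.
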