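---
title: "Methods: species-overlap orthology, reconciliation and alignment consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-overlap orthology, reconciliation and alignment consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomekit)
```

phylomekit implements the analytical core of phylome analysis: given a
collection of gene trees (one per seed gene of a genome), it annotates
each tree with duplication and speciation events, derives typed
orthology and paralogy calls, dates nodes phylostratigraphically,
reconciles gene trees with a reference species tree, compares tree and
orthology sets across releases, and filters alignment columns by their
consistency across alternative alignments. A duplication--loss
simulator with ground-truth event logs provides a closed benchmarking
loop, so none of the package's claims depend on external data.

## The species-overlap rule

An internal node of a rooted gene tree is called a **duplication** when
its children's species sets overlap: genes from the same species on
both sides of a split can only be explained by a gene duplication
(barring horizontal transfer or deep incomplete lineage sorting, which
this model ignores). For a binary node with children species sets $A$
and $B$ the overlap score is the Jaccard index

$$ s = \frac{|A \cap B|}{|A \cup B|}, $$

and the node is a duplication iff $s > t$ for threshold $t \in [0,1)$.
The default $t = 0$ means any shared species implies a duplication.
Two choices here were genuinely open:

* **Normalization.** Overlap could be normalized by the union (Jaccard)
  or by the smaller child set. We use Jaccard; with the default $t = 0$
  the two coincide (both reduce to "is the intersection non-empty"), so
  the choice only matters for non-zero thresholds.
* **Multifurcations.** Gene trees are usually binary (maximum
  likelihood output), but the labeling tolerates polytomies by taking
  the **maximum** Jaccard over all child pairs -- the most
  duplication-sensitive extension consistent with the binary rule.
* **Boundary.** The inequality is strict ($s > t$), so a node scoring
  exactly the threshold is a speciation; this is what makes $t = 0$
  mean "any overlap".

On simulated trees free of gene loss, species-overlap labeling with
$t = 0$ is provably exact: children of a true speciation node live in
disjoint species subtrees (overlap 0), and children of a true
duplication node both cover the full species set below the branch
(overlap 1). The test suite confirms 100% event recovery across 1000
loss-free simulations with duplication rates 0.1--1.0 over 5--15
species. With losses, a duplication node whose two child lineages lose
complementary species can masquerade as a speciation; this is the only
error mode, which is why precision of ortholog calls degrades slightly
under loss while recall (relative to pairs observable in the surviving
tree) stays exact.

## Rooting

Gene-centric trees must be rooted relative to their seed gene. The
default `farthest_taxon` strategy roots on the edge separating the
seed-free clade whose species are taxonomically most distant from the
seed: the candidate clade whose species-set LCA with the seed species
lies closest to the species-tree root wins; ties go to the larger
clade, then to the lexicographically smallest leaf label, so rooting is
deterministic. `midpoint` rooting (half of the longest leaf-to-leaf
path) is offered as a fallback and is used automatically -- with a
notice -- when every leaf belongs to one species, where taxonomy is
uninformative. Midpoint requires branch lengths and errors without
them; a missing length is treated as absent, never as zero. When
rerooting suppresses the old degree-two root, its two half-edges are
merged by summing lengths.

## Orthology calls, typing and the close2seed filter

Two genes are **orthologs** when the event at their last common
ancestor is a speciation, **paralogs** when it is a duplication; pairs
from the same species are always paralogs. Ortholog types come from
co-ortholog counts restricted to the LCA's two child clades: with
$n_a$ genes of $a$'s species on $a$'s side and $n_b$ of $b$'s species
on $b$'s side, $(1,1)$ is one-to-one, $(1,>1)$ one-to-many, and so on.
Counting genes *of the pair's own species* (rather than all genes on
each side) is deliberate: it matches how one-to-one/one-to-many labels
are used downstream (per species pair), and keeps a HUMAN--RAT call
one-to-one even when a MOUSE co-ortholog sits on the human side.

The **close2seed** filter retains a call only if at least one member is
among the $k$ sequences nodally closest to the seed (default
$k = 30$). Ranking is by nodal distance (edges on the leaf-to-leaf
path), with ties broken by branch-length distance and then by sequence
ID, making the retained set deterministic. The seed is always in the
retained set and by default does not consume one of the $k$ slots
(`include_seed = TRUE` makes it count). The filter's output is
monotone in $k$ by construction.

**Consistency scores** aggregate a pair over a tree collection: the
score is the fraction of trees containing both genes in which their LCA
is a speciation, with the same same-species-implies-paralog override
used for calls, so a score is always interpretable as "fraction of
trees supporting orthology". Pairs co-occurring in no tree are
omitted rather than scored 0: absence of evidence is not negative
evidence.

**OrthoXML** export writes species/database/gene sections and nested
orthologGroup/paralogGroup elements that mirror the labeled gene tree
restricted to the called genes, so the innermost group containing two
genes encodes their relation and parsing the document back reproduces
the call set exactly. One deliberate deviation: when the most recent
common ancestor of the exported genes is itself a duplication, the
top-level element is a paralogGroup, which the 0.3 schema does not
foresee at that position. Emitting it anyway is what keeps the round
trip lossless; the reader accepts both forms.

## Phylostratigraphic ages

The lineage map orders the ancestor clades of the seed species from the
species itself (level 0) to the species-tree root, each with its
species set. A node's relative age is the smallest level whose species
set contains every species below the node. Because the level sets are
nested, ages are non-decreasing toward the root -- a property the test
suite asserts. Ages are computed for every node, not only
duplications; consumers may filter. Species absent from the reference
species tree are a hard error: silently dropping them would bias
overlap scores and ages.

## Reconciliation and gene-tree parsimony

LCA reconciliation maps each gene-tree node to the species-tree LCA of
its descendant species. A node is a duplication iff its mapping equals
the mapping of at least one child. Losses are counted per gene-tree
edge $v \to c$ as $d(M(v), M(c)) - 1$ when $v$ is a speciation and
$d(M(v), M(c))$ when $v$ is a duplication, where $d$ is the edge
distance in the species tree; this is the standard duplication--loss
parsimony bookkeeping, stated explicitly here because "gene tree
parsimony" alone underdetermines it. Reconciliation requires binary
trees (species-overlap labeling is the multifurcation-tolerant path);
multifurcating input is refused rather than silently resolved.

`search_species_trees()` scores every rooted binary species-tree
topology over up to 8 species -- $(2n-3)!!$ candidates, 105 for five
species -- against a gene-tree collection and returns the cost-minimal
tree, with ties broken by lexicographic Newick string and all co-optima
reported. The default cost is duplications plus losses;
duplication-only parsimony is available. Gene trees are unweighted --
no support-based filtering or weighting is applied. For the recovery
benchmark the package simulates duplication- and loss-free families, the
only regime in which the generating tree provably attains cost 0 (a
reconciliation costs 0 iff the gene tree is congruent with the species
tree), so recovery there is a correctness check of the search machinery
rather than a statistical claim.

## Tree and orthology-set comparison

`rf_distance()` compares unrooted non-trivial bipartitions and
normalizes by the total number of non-trivial splits in both trees --
$2(n-3)$ for two binary trees, and still well-defined for
multifurcating ones, which is why this denominator was chosen. Strict
mode demands identical leaf sets; `prune_to_shared` restricts both
trees to their intersection first (at least 4 leaves), which is the
mode needed when comparing tree versions built from different proteome
releases. `ortholog_conservation()` intersects unordered pair sets,
with the denominator (first release vs union) exposed as an explicit
option, and any cross-release ID mapping supplied by the caller --
never inferred.

## Alignment consistency trimming

The heads-or-tails strategy aligns the same sequences several times
(different programs, forward and reversed orientation);
`reverse_alignment()` provides the orientation flip and validation is
by exact ungapped-sequence equality, not heuristics. For each
consensus column, every co-aligned residue pair is looked up in the
$K$ alternative alignments; its support is the number of alternatives
that also co-align it. Three conventions, chosen once and recorded
here because the underlying idea underdetermines them:

* The consensus does not vote for itself (otherwise every pair would
  trivially reach support 1).
* A pair present in the consensus but in no alternative has raw
  support 0; strict mode treats it like support 1 ("observed in just
  one underlying alignment"), while fraction mode scores it $0/K$.
* Gap--residue and gap--gap pairs carry no votes, and columns with
  fewer than two residues are always kept (mean support defined as 1).

`strict` mode (default) drops any column containing a support-1 pair;
`fraction` mode drops columns whose mean support falls below
`min_fraction` (default 0.5). Raising `min_fraction` never enlarges
the kept set, and re-applying the filter after projecting the
alternatives onto the kept residues is a no-op. Filtering removes
columns only -- residues are never edited. Consensus construction
itself (M-Coffee-style) is out of scope; the consensus is an input.

## The simulator and what passing tests mean

`simulate_species_tree()` draws Yule trees (uniform lineage splits,
exponential waiting times) rescaled to unit depth.
`simulate_gene_tree()` walks a single gene lineage down the species
tree; along each branch duplications (rate $\lambda$ per lineage per
unit length) fork the lineage and losses (rate $\mu$) kill it, and at
species splits the lineage enters both daughters. Every event is
logged at generation time, so ground truth is never re-inferred from
the output -- the evaluation loop is circularity-free. Extinct
subtrees are pruned and pass-through nodes collapsed, which emulates
the missing-gene noise of low-coverage or transcriptome-derived
proteomes. A configurable stem edge above the species root (default
0) lets pre-root duplications create out-paralog structure.

The benchmark conditions used throughout the tests -- 1000 loss-free
trees with $\lambda \in \{0.1, 0.5, 1.0\}$ over 5--15 species, and 500
trees with $\mu = 0.3$ for the degradation measurement -- were fixed
once as representative of gene-family evolution at phylome scale
(duplication rates below one event per lineage per tree depth; loss
rates of the same order). Under loss, precision is macro-averaged over
trees, skipping trees with no ortholog calls (precision is undefined
there); recall is measured against pairs observable in the surviving
tree, which is why it stays exact while precision dips (see the error
mode discussed above). Other problem sizes used by the checks: 10 000
random tree pairs of 4--8 leaves for the Robinson--Foulds oracle, 200
random alignment bundles (2--5 sequences, up to ~18 columns,
$K \in 2..6$) for the trimming oracle, and 100 independent 50-tree
batches for species-tree recovery.

What the simulator does **not** model bounds what the green suite
shows: gene trees are true topologies, so the tests certify the
algorithms, not their robustness to phylogenetic reconstruction error,
alignment error, horizontal transfer or incomplete lineage sorting.
Sequence evolution is not simulated at all.

## Numerical and formatting choices

Branch lengths are written with 6 significant digits (round-trip
equality is asserted at that precision); overlap scores are written at
full double precision in NHX (`sos` tag) so annotated round trips are
exact. Internal Newick labels are read as support when numeric and as
clade names otherwise. Duplicate (seq_id, species) leaf pairs are
rejected at parse time -- silent renaming would corrupt orthology
output. All tabular coordinates (alignment columns, kept indices) are
0-based half-open; Newick/NHX is left untouched. Determinism: every
stochastic routine takes an explicit seed, and identical seeds give
byte-identical Newick/TSV output on a given R version.

## Known limitations

* Exhaustive species-tree search stops at 8 species by design; larger
  sets need external heuristic gene-tree-parsimony tools.
* Consistency scoring treats all trees equally -- no evidence-level or
  tree-quality weighting across source databases.
* The OrthoXML reader targets documents this package writes (and the
  nesting conventions above); it is not a general-purpose validator.
* The species tree is always user-supplied Newick; there is no
  taxonomy download or synchronization.
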