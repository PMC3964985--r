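# phylomekit

Analytical toolkit for **phylomes** — complete collections of gene
phylogenies, one tree per seed gene of a genome. It is aimed at
comparative genomicists who already have gene trees (e.g. from a
phylogenomic pipeline or a PhylomeDB-style export) and need the
downstream analysis: which nodes are duplications, who is orthologous
to whom and how reliably, how old each node is, how well gene trees fit
a species tree, how much two releases of the same phylome differ, and
which alignment columns deserve trust.

## What it computes

**Species-overlap event labeling.** An internal node of a rooted gene
tree with children species sets *A* and *B* gets the overlap score

    s = |A ∩ B| / |A ∪ B|

and is a **duplication** iff `s > t` (default threshold `t = 0`: any
shared species implies a duplication), otherwise a **speciation**.
Orthologs are pairs whose LCA is a speciation; paralogs diverged by
duplication; types (one-to-one, one-to-many, many-to-many) come from
co-ortholog counts at the LCA. On top of this sit:

* the **close2seed** filter (keep calls touching the *k* = 30 sequences
  nodally closest to the seed),
* **consistency scores** across tree collections (fraction of trees
  containing a pair in which it is orthologous),
* **phylostratigraphic ages** (smallest named clade of the seed lineage
  containing all species under a node),
* **LCA reconciliation** with duplication/loss counts and exhaustive
  **gene-tree-parsimony** species-tree search (≤ 8 species),
* normalized **Robinson–Foulds** distances and ortholog-set
  conservation between releases,
* **consistency-based alignment trimming** across alternative
  alignments of the same sequences (heads-or-tails style), and
* a **duplication–loss simulator** with ground-truth event logs.

Formats: Newick/NHX (tags `Ev`, `S`, `sos`, `age`), FASTA alignments,
OrthoXML 0.3, TSV. See the methods vignette
(`vignettes/phylome-methods.Rmd`) for the models, conventions and
design decisions.

## Worked example

Label a small p53-family tree against a reference taxonomy, date its
nodes and extract orthology calls for the human seed:

```r
library(phylomekit)

sp <- parse_newick("(((HUMAN,PANTR)Primates,MOUSE)Mammalia,YEAST)Eukaryota;",
                   naming = "none")
tr <- parse_newick(
  "(((TP53_HUMAN,TP53_PANTR),(TP53_MOUSE,Trp63_MOUSE)),TP53_YEAST);")
tr <- label_events(tr, threshold = 0)
tr <- assign_relative_ages(tr, lineage_map(sp, "HUMAN"))
cat(write_newick(tr, annotated = TRUE))
#> (((TP53_HUMAN[&&NHX:age=0:S=HUMAN],TP53_PANTR[&&NHX:age=1:S=PANTR])[&&NHX:Ev=S:sos=0:age=1],
#>  (TP53_MOUSE[&&NHX:age=2:S=MOUSE],Trp63_MOUSE[&&NHX:age=2:S=MOUSE])[&&NHX:Ev=D:sos=1:age=2])
#>  [&&NHX:Ev=S:sos=0:age=2],TP53_YEAST[&&NHX:age=3:S=YEAST])[&&NHX:Ev=S:sos=0:age=3];

infer_orthology(tr, seed_leaf = "TP53_HUMAN")[,
  c("seq_b", "species_b", "relation", "type", "sos")]
#>   seq_b species_b relation        type sos
#> 1  TP53     MOUSE ortholog one-to-many   0
#> 2  TP53     PANTR ortholog  one-to-one   0
#> 3  TP53     YEAST ortholog  one-to-one   0
#> 4 Trp63     MOUSE ortholog one-to-many   0
```

The mouse-only cherry is a duplication (`Ev=D`, overlap score 1), so
both mouse copies are one-to-many co-orthologs of human TP53; ages run
from 0 (HUMAN) through 1 (Primates) and 2 (Mammalia) to 3 (Eukaryota).

Reconciliation counts duplications and losses against the species
tree:

```r
lca_reconcile(parse_newick("((A_a,C_c),(B_b,C2_c));"),
              parse_newick("((a,b),c);", naming = "none"))
#> <reconciliation: 1 duplications, 2 losses over 4 leaves>
```

The same functionality is scriptable through the bundled CLI
(`inst/scripts/phylomekit`): `convert`, `label`, `orthologs`,
`consistency`, `reconcile`, `gtp-search`, `rf`, `conserved-pairs`,
`trim`, `simulate`, e.g.

```sh
phylomekit label --tree t.nwk --species-tree sp.nwk \
    --seed TP53_HUMAN --threshold 0 --out t.labeled.nhx
```

Every run with file output also writes a JSON provenance log (tool
version, configuration, input checksums).

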