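# phylotastic

Custom phylogenies from megatrees: name resolution, pruning, grafting and
age scaling, offline.

## The problem

Most comparative analyses need a phylogeny for a specific list of species,
yet almost nobody infers one from scratch: the practical route is to derive
it from a large, published expert tree (a *megatree* — e.g. a 4,510-species
mammal supertree or a 55,473-species plant phylogeny).  Getting from "my
list of names" to "a usable tree with branch lengths" takes several steps,
each with its own pitfalls:

1. **Name resolution (TNRS)** — user lists carry typos, deprecated
   synonyms and inconsistent capitalization; names are the join key of the
   whole exercise.
2. **Source selection** — with several candidate megatrees, pick the one
   covering most of the query.
3. **Pruning** — cut the megatree down to the queried tips, collapsing the
   unifurcations left behind (summing their edge lengths so patristic
   distances are preserved).
4. **Grafting** — attach queried taxa the megatree lacks onto their
   least-inclusive matching higher taxon (genus before family before
   order), Phylomatic-style, from derivations like
   `order/family/genus/genus species`.
5. **Scaling** — many megatrees have no branch lengths; assign node ages
   either by *bladj*-style even spacing between calibrated nodes, or from
   a store of published time-calibrated trees (chronograms).

This package implements that pipeline as a plain R library plus a thin CLI,
entirely offline: taxonomies are local CSV tables, source trees are Newick
files, chronograms are a local store.

## The core algorithms

**Path-store pruning.** A megatree is denormalized once into one record per
tip: the ordered chain of ancestors with edge lengths (*taxon-to-root
path*).  A pruning query then touches only the queried tips' paths: take
the union of their node sets, keep the nodes with ≥ 2 children in that
union (plus the tips), sum edge lengths across the collapsed chains, and
rebuild.  Work scales with the query size and path depths, not with the
megatree's tip count.

**bladj age interpolation.** Calibrated nodes keep their exact ages; every
other node is placed so branchings are evenly spaced.  Processing nodes
root-to-tip, a node with parent age `a_top` and nearest fixed descendant of
age `a_bot` at `k` edges below gets
`age = a_top - (a_top - a_bot)/(k + 1)`, choosing among fixed descendants
the one with the most intervening nodes.  Branch lengths are then parent
age minus child age.

**Matrix-based age queries.** Each chronogram is pre-processed into a
patristic distance matrix; the MRCA age of a taxon set is
`max d(i,j) / 2` over matched pairs (exact on an ultrametric tree), so a
query is row-name matching and array subsetting, with ranges across sources
and across posterior sample trees.

**Scored name matching.** Three techniques in order: exact binomial against
Genus+Species (score 1.0); italic-tagged synonyms indexed from the other
columns (0.9); cross-field assembly of the query's words within a single
row (0.8).  Optional fuzzy fallback: candidates within Levenshtein
distance 2, scored `1 - d / max(len)`.  An asynchronous `submit`/`retrieve`
token API aggregates any number of CSV-backed sources without merging
them — choosing between sources stays with the caller.

## Worked example

```r
library(phylotastic)

fx <- mammal_fixture()            # packaged 20-tip mammal tree + taxonomy
cfg <- workflow_config(trees      = list(mammals = fx$tree),
                       taxonomies = fx$taxonomy,
                       resolution = "fuzzy")
res <- run_pipeline(c("Homo sapien",          # note the typo
                      "Pan troglodytes",
                      "Mus musculus"), cfg)
write_newick(res$tree)
#> [1] "((Homo_sapiens,Pan_troglodytes),Mus_musculus);"
unlist(res$provenance$ledger)
#>          submitted               kept         unresolved            in_tree
#>                  3                  3                  0                  3
#> not_in_source_tree
#>                  0
```

The misspelled `"Homo sapien"` is recovered by fuzzy matching at score
`1 - 1/12 ≈ 0.917` (edit distance 1 over the 12-character accepted name),
the mammal source tree is selected automatically (coverage 3 of 3), and
pruning returns the two great apes as sisters with the mouse outside —
the provenance JSON records every decision along the way.

Each stage is callable standalone (`prune_tree()`, `graft()`, `bladj()`,
`query_ages()`, `tnrs_resolve()`), and a CLI wrapping them ships at
`inst/cli/phylotastic.R`:

```sh
Rscript inst/cli/phylotastic.R prune --tree megatree.nwk \
    --species "Homo_sapiens,Pan_troglodytes,Mus_musculus"
```

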