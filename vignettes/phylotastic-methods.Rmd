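---
title: "Methods: from a species list to a custom phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a species list to a custom phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotastic)
```

This vignette is the package's own account of its methods: the data model,
each algorithm with its assumptions and tunable parameters, the numerical
and design choices made where the problem left them open, what the
synthetic-data generators do and do not emulate, and known limitations.

## Data model

Trees are rooted `ape::phylo` objects throughout.  Two conventions matter:

* **Absent is not zero.**  A branch length of `NA` means *unknown* (e.g. a
  freshly grafted edge, or a taxonomy-derived megatree with no lengths at
  all); `0` is a real, zero-duration branch.  The Newick writer emits no
  `:length` suffix for `NA`, and `read_newick()` preserves per-edge
  absence.  `ape` itself marks these edges `NaN` and prints `:NaN`, which
  is one reason the package carries its own reader and writer.
* **Underscores are significant.**  `Homo_sapiens` is the canonical tip
  form; nothing silently converts underscores to spaces (a reader option
  `underscores_to_spaces` exists, default off).  Cross-component matching
  (tips vs taxonomy vs queries) is case- and underscore/space-insensitive
  via one shared normalization, but stored labels are never rewritten.

Duplicate tip labels are a hard error everywhere: names are the join key
of the entire system, and a duplicated key has no usable semantics.
Parsing is strict — unbalanced parentheses are reported with a character
position, negative lengths name the offending edge — because megatree
files are large enough that silent misparses are otherwise found much too
late.  Writing is deterministic: children in stored order, plain decimal
numbers (15 significant digits, no scientific notation), quoting only when
a label contains Newick metacharacters.  `write(parse(x))` is a fixed
point, which the tests exploit for byte-exact comparisons.

## Path-store pruning

Pruning a handful of tips out of a 10^4–10^5-tip megatree is the pipeline's
hot spot, and re-traversing (or worse, re-parsing) the megatree per query
is what makes naive implementations slow.  The package instead
denormalizes the tree once (`build_path_store()`) into one record per tip:
the ordered chain of ancestor ids with the length of each traversed edge.
A query (`prune()`) then:

1. collects the queried tips' paths (work ∝ query size × path depth);
2. takes the union of their node sets — each node's parent and edge length
   come from whichever path first recorded it, and shared path suffixes
   are skipped;
3. retains the query tips plus every union node with ≥ 2 union children
   (everything else is a unifurcation to be collapsed);
4. reconnects each retained node to its nearest retained ancestor, summing
   the collapsed edge lengths, so patristic distances among retained tips
   are exactly conserved;
5. rebuilds a `phylo`, ordering siblings by their stored child rank in the
   source tree, so output is byte-deterministic.

Choices worth stating:

* Collapsed nodes' internal labels are discarded; each retained node keeps
  its own label.
* A queried label that matches only an *internal* node is reported as
  "not found (internal)", never expanded to its subtree — higher-taxon
  expansion is deliberately the grafter's job, keeping pruning semantics
  exact.
* A query intersecting the tip set in exactly one label returns a
  single-tip tree with a warning; an empty intersection is an error.
* The store serializes to a versioned tab-separated text format (one line
  per tip, `node:len|node:len|…`) that round-trips byte-identically.

The tests hold this implementation against an independent oracle that
prunes by repeated leaf deletion plus unifurcation collapse on plain
parent arrays, across hundreds of random trees (binary and polytomous,
with and without lengths), and against `ape::keep.tip` on a generated
50,000-tip megatree — a size chosen to be of the same order as the largest
published species megatrees while keeping the full test suite comfortably
runnable on one CPU.

## Taxonomic grafting

`graft()` places each queried taxon absent from the tree as a new child of
the node labeled with the least-inclusive rank of its slash-delimited
derivation that occurs in the tree (genus before family before order).
Matching is case-insensitive and **exact**: fuzzy matching belongs
upstream in name resolution, where scores make the uncertainty explicit.

Open points the implementation had to decide:

* **Ambiguity**: if several tree nodes share the matched rank label the
  call errors rather than guessing — silently picking one of two
  homonymous genera would corrupt downstream analyses invisibly.
* **Order independence**: placements are resolved against the original
  tree and applied afterwards, with same-node additions sorted
  alphabetically, so the result is a function of the path *set*.
* **Grafting onto a tip** converts it to an internal node that keeps its
  label, with the original taxon retained as a same-named child tip —
  preserving the distinction between the framework taxon and the placed
  one.
* **New edges get no length** (absent, not zero): topology and scaling are
  separate concerns, and the scaling step is where lengths come from.
* A bare binomial (path of length 1) falls back to matching its genus
  word, mirroring how practitioners use taxonomic grafting tools with
  plain species lists.

## bladj-style age interpolation

`bladj()` fixes the ages of calibrated nodes (matched by node label) and
spaces the remaining branchings evenly.  "Evenly spaced" famously
underdetermines the algorithm, so this package's reading is documented
precisely:

* Tips default to age 0 (extant taxa; `default_tip_age` and per-tip
  calibrations accommodate fossils).  The root's age must be calibrated;
  fixed ages must be mutually consistent (no fixed descendant older than a
  fixed ancestor) — both are checked up front with the offending labels
  named.
* Internal nodes are processed in preorder (root to tips), so a node's
  parent age `a_top` is always set.  Among the nearest *originally fixed*
  descendants down every chain, the one with the most intervening nodes is
  chosen (ties toward the larger age); with `k` edges down to that
  descendant of age `a_bot`,
  `age(v) = a_top − (a_top − a_bot)/(k + 1)`.
  On a chain between two fixed nodes this yields exactly even spacing
  (root 10 / tip 0 with one intermediate gives 5; root 9 with two gives 6
  and 3), and on branching trees it spaces along the longest chain.
* Because the chosen chain need not pass through every fixed descendant,
  the interpolated age could in principle fall below a fixed age on
  another chain; the age is then clamped up to it (and never above the
  parent), a warning reports the collision, and the resulting zero-length
  branch is permitted.  This guarantees the output invariants: ages
  monotone root-to-tip, every branch length ≥ 0, and root-to-tip path
  lengths equal to root age minus tip age.
* Calibrated nodes are exact fixed points, so the procedure is idempotent,
  and a fully calibrated tree reproduces the direct age differences.

The tie rule (larger age first, preorder processing) is this package's
documented choice, not asserted to replicate any particular prior
implementation's tie-breaking.

## Chronogram store and age queries

`build_chronogram_store()` pre-processes each source (one or more
ultrametric trees per record — several when a study ships posterior
samples) into patristic matrices, rejecting non-ultrametric trees with the
deviating tip named (tolerance `1e-6` × tree depth, scale-free so deep and
shallow chronograms are treated alike).  `query_ages()` is then row-name
matching and subsetting: for ≥ 2 matched taxa the MRCA age is
`max d(i,j)/2`, exact on ultrametric trees and requiring no traversal at
query time.  Records matching fewer than two taxa are listed as
"no estimate"; every sample tree contributes its age, and the overall
range bounds all of them (so adding a source can only widen it).

A record's point estimate summarizes its samples as the **median** (with
min and max alongside); the median is this package's addition — a "range
of dates" needs a center for single-number consumers — and it is labeled
as such in the output.  Newick rendering picks the best-covering source
(most matched taxa, ties to the lexicographically smaller id) and emits a
star tree scaled to its MRCA age; JSON output follows the schema shipped
in `inst/schema/`.  Names must be resolved *before* querying — the store
does not reconcile conflicting taxonomies between sources, by design.

## Name resolution

The resolver is built from CSV-backed adaptors so it runs entirely
offline; the adaptor surface (a table plus a source id) is deliberately
minimal so a networked source could be wrapped without touching the
matcher.  For each table:

1. **exact** — the query binomial equals Genus + Species: score 1.0;
2. **synonym** — the query equals a name extracted at load time from
   `<i>…</i>` markup anywhere in the other columns: score 0.9;
3. **cross-field** — every word of the query occurs somewhere in a single
   row (e.g. epithet in Species, genus only in the synonym text):
   score 0.8.

The first technique that hits determines the match set.  The graded
0.9/0.8 values are this package's choice within the required [0, 1] scale
(an adaptor emitting only 0/1 also conforms): they keep "certain but not
the accepted spelling" distinguishable from exact hits without pretending
to a calibrated probability.  Fuzzy fallback considers accepted binomials
within Levenshtein distance ≤ 2 and scores `1 − d / max(len(query),
len(candidate))` — distance 1 against a 12-character name gives ≈ 0.917 —
sorted by score with alphabetical tie-break.  The distance-2 cutoff keeps
the candidate set small and the false-positive rate negligible for
binomial-length strings; it is a spelling-correction device, not a
taxonomic inference.

The `submit`/`retrieve` token API mirrors how such services run remotely
(expensive fuzzy jobs complete lazily at first retrieval; tokens are
unique per submission; a pending job reports `pending` with no partial
ranking) while staying an in-process registry here.  Aggregation over
adaptors is a pure union — no cross-source deduplication, results sorted
deterministically so adaptor order and batching are irrelevant — because
choosing among sources (including genuine homonyms) is the caller's
decision, not the service's.

## Controller

`run_pipeline()` chains resolve → select → (graft) → prune → scale.
Points left open by the general design, decided here:

* **Selection** maximizes `|resolved names ∩ tips|`, ties to the smaller
  tree (a tie means the extra tips buy nothing), then lexicographic id.
  A user-supplied `tree_id` is mandatory when given.
* **Ambiguous matches** under the fuzzy policy: highest score wins, exact
  ties resolved alphabetically and flagged in provenance; under the strict
  policy ambiguity (or any score < 1) drops the name with a warning.
* **Provenance** is a sidecar JSON record (schema in `inst/schema/`), not
  inline Newick comments, keeping the tree consumable by standard tools.
  It names the source tree and citation, every operation with parameters,
  and each name's resolution decision.
* A **name-conservation ledger** is asserted on every run:
  `|submitted| = |kept| + |unresolved|` and
  `|kept| = |in tree| + |not in source tree|` (counted per submitted name).
  Pipelines that lose names silently are the failure mode this guards
  against.
* **datelife scaling** of a pruned tree is a hybrid: each internal node
  whose tip set the chronogram store can date gets that (median) age as a
  calibration, inconsistent calibrations are dropped rootward-first, and
  bladj interpolation fills the rest.  This composition goes beyond
  either method alone and is flagged as an extension.

## Synthetic data

The generators exist so every module is testable without downloads, and
they are pure functions of their arguments (the seed fully determines the
output; the caller's RNG state is untouched):

* `random_tree()` — equal-rates random branching with unique binomial-like
  labels, optional polytomies and uniform lengths.  It emulates tree
  *shape*, not any diversification process: test scaffolding, not science.
* `random_ultrametric_tree()` — coalescent shapes rescaled to an exact
  root age (default 10 time units), standing in for chronograms.
* `random_taxonomy()` — Genus/Species rows, a Family column grouping
  genera, and italic-tagged synonyms embedded in free text for a set
  fraction of rows (default 0.3), optionally consistent with a companion
  tree's tips.
* `corrupt_name()` — exactly *n* character edits, re-drawn until the
  verified edit distance equals *n*.
* `mammal_fixture()` — a fixed 20-tip mammal tree (great apes, Old World
  monkeys, rodents, carnivores, ungulates, and outgroups down to the
  platypus) with a matching taxonomy table.  It carries no branch lengths
  and no internal labels, the shape of a taxonomy-derived megatree — which
  is also what makes its three-species pruning byte-exact.

What passing tests on these fixtures does **not** show: robustness to the
messiness of real taxonomies (authority strings with embedded binomials,
subspecific ranks, homonyms across nomenclatural codes), to genuinely
conflicting chronologies between chronogram sources, or to megatrees with
reticulate or unrooted semantics.  The generators produce clean, valid
instances by construction; the error paths are exercised by dedicated
hand-built cases instead.

## Problem sizes and numerics

The shipped tests run, per suite execution: ~500 random pruner cases up to
1,000 tips against the leaf-deletion oracle plus one 50,000-tip smoke
test; 200 random calibration subsets for the age interpolation; 500
matrix-vs-traversal age queries over 100 random chronograms; 1,000
one-edit recovery cases for the resolver; and 100 end-to-end pipeline
runs.  These sizes were picked to exercise the asymptotic behavior each
module claims while keeping a full run practical on a single CPU.

Floating-point policy: patristic conservation and ultrametricity are
asserted to `1e-9` absolute; the store's ultrametricity gate is relative
(`1e-6` × depth); serialized numbers carry 15 significant digits so
read-write round trips are exact at the asserted tolerances; age
differences below `1e-12` are snapped to zero-length branches.

## Limitations

* One tree per answer: no supertree synthesis across partially overlapping
  sources, and no phylogenetic placement of taxa the taxonomy cannot
  graft.
* Higher-taxon query expansion (a family name standing for its species) is
  out of scope at the pruner; the grafter's rank matching is the supported
  route.
* The resolver does not disambiguate valid homonyms across nomenclatural
  codes; it returns both candidates side by side.
* Newick and the NEXUS TREES block are the only tree formats read, and
  plain Newick the only one written (the NEXUS writer wraps it); richer
  XML/RDF tree formats are deliberately unsupported.
* Chronogram coverage is whatever the local store holds; the hybrid
  datelife scaling fails cleanly when no source dates the pruned root.
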