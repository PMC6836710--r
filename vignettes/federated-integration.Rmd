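---
title: "Ontology-driven federation over heterogeneous biological stores: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven federation over heterogeneous biological stores: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlink)
```

`vlink` integrates three heterogeneous data stores — a relational
gene-expression database, an orthology store derived from hierarchical
orthologous groups, and a protein store — under one query language, by
mapping relational data into a virtual RDF graph and federating
conjunctive queries across the stores along formally described "virtual
links". This vignette explains the models, the parameters that matter,
the numerical and design choices, and what the synthetic test surface
does and does not demonstrate.

## The RDF core and its query dialect

Terms are interned as canonical N-Triples-encoded strings, so term
equality is string equality and a graph is a unique-row triple table;
two literals are equal exactly when lexical form, datatype and language
tag all agree, which is the semantics literal-level virtual links need.
N-Triples serialization is canonical (statements sorted byte-wise), so
graph equality, file diffs and reproducibility checks all reduce to
byte comparison.

The query dialect is deliberately small: `SELECT [DISTINCT]`, basic
graph patterns, `FILTER` with `=`, `!=`, `<`, `>` and case-insensitive
`CONTAINS`, `SERVICE` blocks and `LIMIT`. That is sufficient for every
conjunctive question in the template catalogue, and small enough that
the evaluator can be checked against exhaustive binding enumeration.
Anything outside the dialect (OPTIONAL, UNION, subqueries, property
paths, aggregates) is rejected with an explicit "unsupported feature"
error rather than ignored — silent partial support is how federated
engines return subtly wrong answers. Comparison filters evaluate
numerically when both operands parse as decimals and lexicographically
otherwise; solution order is unspecified and all equivalence checks in
the package compare solution multisets.

Blank nodes are legal in data but can never form virtual links or join
points: they are document-scoped identifiers, and cross-dataset joins
require globally stable IRIs.

## Ontology-based data access

A mapping rule is a relational `SELECT` plus triple templates with
`{column}` placeholders; `{fn(column)}` applies a named transformation
from a fixed registry. Two transformations carry the integration
semantics:

* `uberon_local` rewrites an anatomical-entity CURIE
  (`UBERON:0000955`, the brain) into the ontology IRI local name
  (`UBERON_0000955`), aligning database identifiers with the anatomy
  ontology. It is invertible, and the inverse is registered.
* scientific names are formed by concatenating the `genus` and
  `species` columns (`"Homo" + " " + "sapiens"`), producing literals
  byte-identical to the protein store's `scientificName` values — the
  literal-level join contract for organisms.

`materialize()` expands every rule over every source row into a set
union. `answer_bgp_virtual()` instead answers each triple pattern by
unifying it with every triple template: constant-vs-constant slots must
match, variables become column selections, and a constant against a
template slot is inverted into a relational constraint when the
template has a single placeholder and an invertible transformation.
Otherwise (multi-placeholder templates such as condition IRIs, or
non-invertible transformations) the engine falls back to post-filtering
that rule's expanded candidates — correctness first; the fallback only
touches the one rule involved. `NULL` in any referenced column
suppresses that single triple (R2RML-style semantics), which prevents
malformed IRIs; placeholder values in IRI templates are
percent-encoded for the same reason. The load-bearing invariant,
exercised by the tests on the full catalogue and hundreds of randomized
pattern queries, is that the two routes agree exactly:
`answer_bgp_virtual(v, q)` equals `match_bgp(materialize(v), q)` as
multisets.

The embedded relational layer is a data-frame store with an ANSI-subset
`SELECT` interpreter (projections, inner joins, `WHERE` equalities and
`IS [NOT] NULL`). That subset is exactly what mapping sources use, it
keeps the whole engine dependency-free and testable, and its plain-text
SQL dump is the reproducibility artifact for the expression database.

## Expression semantics

Expression calls follow a condition-based model: the three relations
*is expressed in*, *is absent in* and *is highly expressed in* point
from a gene to an expression-condition node that pairs an anatomical
entity with a developmental stage. Queries therefore traverse one hop
(`gene -> condition -> anatomical entity / stage`), which is what lets
a single model serve both "expressed in the liver" and "expressed in
the brain during the infant stage" questions. The database stores the
call type and level as explicit columns (`present`/`absent`,
`high`/`low` with SQL `NULL` for absent calls): real expression
databases assert these relations from rank statistics under
database-specific criteria, and those criteria are precisely what the
integration layer should *not* re-derive.

## Orthology from HOGs

A hierarchical orthologous group is a tree whose internal nodes carry a
speciation (with the ancestral taxon) or duplication event and whose
leaves are extant genes. The pairwise classification is the textbook
rule: a leaf pair is orthologous iff its lowest common ancestor is a
speciation. `derive_pairwise()` computes this by recursive
cross-products at each internal node, which classifies every pair
exactly once; the tests check it against an independent brute-force
LCA oracle over root-to-leaf paths on random trees. Validity demands
that speciation children cover disjoint taxon sets (a speciation
separates lineages) while duplication children may share taxa; a gene
may occur in at most one leaf.

The emitted orthology graph contains, per gene: class membership,
label, taxon link and a cross-reference to its protein where one
exists; ortholog/paralog assertions are emitted in both directions
(the relations are symmetric). One-to-one orthology is not
distinguished from many-to-many: no catalogue question needs the
distinction, and collapsing it keeps the graph schema minimal. Taxon
lineage is encoded as `rdfs:subClassOf` triples from each species taxon
to all ancestor clades, as protein-store taxonomies do, so restricting
a question to a clade ("in primates") is a single extra triple pattern
rather than an enumeration.

## Virtual links

Discovery compares two materialized graphs: one shared-instance link
per class with at least one common IRI-identified instance (cardinality
= the number of shared instances), and one literal-match link per
candidate predicate pair sharing at least one literal value. The
candidate list defaults to label-like and identifier-like predicates;
comparing all predicate pairs would be quadratic and mostly noise.
Gene and taxon IRIs are minted once and reused verbatim across stores —
deliberately avoiding `owl:sameAs` bridging, which would push entailment
obligations into every engine that touches the data.

Link metadata serializes into VoID plus a package VoIDext namespace
(link kind, class or predicate pair, optional transformation,
cardinality, status); parsing is the exact inverse. Validation re-counts
each link through endpoint queries: zero intersection flips the link to
`broken` (the signature of schema drift or rewritten IRIs), a positive
count refreshes the cardinality, and an unreachable endpoint leaves the
link `unverified` — absence of evidence is not evidence of breakage. A
shrunk-but-nonzero intersection stays `active`: ordinary data evolution
is not drift.

## Federation

Source selection assigns each triple pattern to a dataset whose
description covers its predicate (or its class, for `rdf:type` patterns
with a constant class); ties go to the dataset already holding the most
patterns, maximizing subquery size. Variable predicates are rejected in
federation — no description can cover them. Explicit `SERVICE` blocks
bypass selection entirely, so hand-decomposed queries (like the worked
example) run exactly as written.

Planning groups patterns into maximal per-dataset stages and orders
them greedily by a selectivity score (number of constant terms plus
filters fully applicable at the stage). The first stage is the highest
scorer; each subsequent stage must share at least one *link-covered*
variable with the already-planned prefix, otherwise planning fails with
a "missing virtual link" error naming the dataset pair. Checking
against the accumulated prefix rather than strictly consecutive stages
is intentional: bind joins consume the union of prior bindings, and a
strict pairwise rule would reject valid plans for ordering reasons.
A join variable counts as covered by a shared-instance link when the
query `rdf:type`-constrains it (anywhere) to the link's class, and by a
literal-match link when it sits in object position of the two linked
predicates on the two sides. This is a conservative, metadata-decidable
rule: a variable the query leaves untyped cannot be certified as a join
point, and the planner refuses rather than guesses — removing a link
can only turn answers into errors, never change them.

Execution is a bind join: stage one runs as written; each later stage
receives the accumulated bindings of its shared variables as enumerated
value constraints, in batches (default 50 bindings per subquery).
Batching bounds intermediate results — the cost driver in federated
querying — and is result-invariant by construction (checked for batch
sizes 1, 10 and 100). An intermediate-result cap (default 10,000
bindings, disableable) aborts runaway executions with advice to refine
the query; the clade-restricted catalogue variants exist precisely to
demonstrate that a more specific query shrinks the intermediate
results. The correctness contract, tested on the catalogue and on
randomized 2- and 3-dataset queries, is equality with centralized
evaluation over the union of the materialized endpoint graphs.

One consequence of pattern-level source assignment deserves a note: a
pattern is evaluated only at its assigned endpoint, so federated and
centralized answers coincide when the stores agree on the extents of
the predicates they share. The fixture generator guarantees this by
construction (the orthology store covers every expression-store gene;
proteins are typed consistently wherever they appear), mirroring the
modelling decisions that real integrated resources make for the same
reason.

## The synthetic stores

`fixture_spec()` fixes the study conditions; defaults were chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 6 | the organisms the catalogue's questions mention (human, mouse, rat, zebrafish, fruit fly, rabbit) |
| `n_genes_per_species` | 24 | large enough for ~10 multi-species families plus anchors, small enough for exhaustive oracles |
| `n_anat_entities` | 6 | brain, liver, pancreas (needed by the questions) plus three decoys |
| `n_stages` | 4 | embryo, infant, juvenile, adult; infancy is queried explicitly |
| `p_expressed` / `p_absent` | 0.25 / 0.10 | a sparse call matrix: most gene-condition pairs have no call, absent calls are rarer than present ones |
| `p_high` | 0.08 | a minority of present calls are high-level |
| `p_protein` | 0.8 | the protein store does not cover all orthology genes — the coverage asymmetry the federation must tolerate |
| `p_disease_annotated` | 0.15 | disease annotations are the exception, not the rule |

Deterministic anchor families (an insulin family, a haemoglobin family
with the mouse *HBB-Y* gene, a *Tp53*/*Tp63* pair under a duplication
root, a fly-brain family, and an EGFR family whose human protein is
glioblastoma-annotated) make every catalogue question non-vacuous by
construction, independent of the random draws. The worked example is a
separate, seed-free 7-gene instance whose expected answer (one
human–rat pair) is declared in the object itself.

Ground truth is computed by a brute-force recursive enumerator that
shares no code with the pattern evaluator, the OBDA engine or the
federation engine. Identical seed and spec give byte-identical SQL
dumps, N-Triples files and ground-truth tables; the generator draws all
randomness under a locally scoped RNG so it neither reads nor disturbs
the session's random state.

What the fixtures emulate: the storage-model heterogeneity (relational
vs. graph), the identifier-reuse contract, the coverage asymmetries
between stores, and the query workload shape. What they do not emulate:
the scale of the real resources (billions of triples), rank-based
expression call criteria, identifier ambiguity and gene-name synonymy,
schema evolution in the wild, and network behaviour of remote
endpoints (endpoints here are in-process; downtime is simulated by a
flag). Passing tests therefore demonstrate the correctness of the
integration machinery, not the performance or curation quality of any
real resource; runtimes on live federations are dominated by effects
this package deliberately excludes.

## Numerical and degenerate-input choices

* Term order and solution order are unspecified; every equivalence in
  tests and acceptance compares sorted multisets.
* The empty BGP answers with exactly one empty solution (the join
  unit); an up endpoint must answer it, which is what the availability
  probe sends.
* `LIMIT 0` is legal and returns nothing; templates attach a default
  limit of 1000, far above any fixture answer, so limiting never
  truncates ground-truth comparisons but still protects interactive
  use (callers can turn it off).
* Numeric-vs-lexicographic filter comparison is decided per value pair,
  not per column; mixed-type comparisons therefore never error.
* Percent-encoding uses the conservative unreserved set; decoding
  happens only during constraint inversion, never on stored data.
* Empty inputs (empty database, empty catalogue, empty clade set,
  single-leaf HOGs) all return empty results rather than erroring;
  errors are reserved for contract violations (duplicate gene leaves,
  dangling dataset references, unknown transformations).

## Problem sizes

The default test and acceptance workload uses the 6-species fixture
(144 genes, ~1,200 expression calls, ~2,000–2,300 triples per store),
200 randomized pattern queries for the OBDA oracle check, 100
randomized link-covered federated queries (60 two-dataset, 40
three-dataset), and 100 random HOGs of up to 12 leaves for the
orthology oracle. These sizes keep every oracle exhaustive or
brute-force — the point of a desk-scale reimplementation — while
exercising all code paths; the generator scales to larger settings via
`fixture_spec()` if heavier stress runs are wanted.

## Known limitations

* The SPARQL subset excludes OPTIONAL/UNION; questions needing
  negation or disjunction cannot be posed.
* Federation requires constant predicates and typed join variables;
  untyped joins are rejected even when data would support them.
* The selectivity heuristic counts constants and filters; it has no
  cardinality statistics, so adversarial catalogues could order stages
  badly (never incorrectly).
* The mapping language supports inner joins and conjunctive `WHERE`
  only — enough for the shipped schema, not for arbitrary warehouses.
* HTTP endpoints are out of scope; the endpoint contract is in-process
  by design, and the test suite never touches the network.
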