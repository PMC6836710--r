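# vlink

Virtual-link federated semantic queries across heterogeneous biological
databases, at desk scale.

## The problem

Answering a question like *"which human genes have a known association to
glioblastoma and an ortholog expressed in the rat brain?"* requires three
databases at once: a protein knowledge base (disease annotations), an
orthology resource (evolutionary relationships derived from hierarchical
orthologous groups), and a curated gene-expression database (anatomical
expression calls). These resources differ in storage model (RDF store,
HDF5-style orthology data, relational SQL), in syntax, and in semantics.
`vlink` implements an ontology-driven federation over three simulated
stores of exactly these kinds, for people who want to study, teach or
extend the machinery itself — every layer is inspectable R code with a
correctness oracle next to it.

The stack has three layers:

1. **Data-store layer (OBDA).** A relational gene-expression database is
   exposed as a *virtual RDF graph* through declarative relational-to-RDF
   mappings. A mapping rule pairs a SQL `SELECT` (*source*) with triple
   templates (*target*), e.g.

   ```
   mappingId  expressed-in
   source     SELECT geneId, anatEntityId, stageId FROM expression
              WHERE callType = 'present'
   target     gene:{geneId} genex:isExpressedIn cond:{uberon_local(anatEntityId)}-{stageId} .
   ```

   Triple-pattern queries are answered directly against the database by
   unifying patterns with templates and pushing constants down as
   relational constraints (inverting named transformations such as
   `UBERON:0000955 -> UBERON_0000955` where invertible); alternatively
   the whole graph can be materialized. The two routes provably agree:
   `answer_bgp_virtual(v, q)` equals `match_bgp(materialize(v), q)`.
   Orthology data is handled by deriving pairwise ortholog/paralog
   relations from hierarchical orthologous groups (HOGs): two genes are
   orthologs iff the lowest common ancestor in the group's tree is a
   speciation event, paralogs iff it is a duplication.

2. **Structured-query-interface layer (virtual links).** An intersection
   data point between two datasets — class instances shared by IRI, or
   identical literals under a predicate pair — is a *virtual link*, the
   join contract for federation. Links are discovered from data,
   described in an RDF vocabulary extending VoID (kind, cardinality,
   transformation, status), and re-validated against endpoints so that
   identifier drift flips a link to `broken` instead of silently
   emptying joins. The federation engine assigns each triple pattern to
   a covering dataset, groups patterns into per-endpoint subqueries,
   orders stages by a constant-counting selectivity heuristic, rejects
   plans whose join variables no link covers, and executes with bind
   joins (accumulated bindings shipped into the next stage in batches).

3. **Application layer.** A catalogue of 13 federated query templates in
   plain English with editable slots (gene label, taxon, anatomical
   entity, stage, clade, keyword), keyword search, default result
   limits, and endpoint availability labels.

A seeded synthetic-fixture generator produces the three coupled stores
(144 genes across human, mouse, rat, zebrafish, fruit fly and rabbit by
default) with deterministic anchor gene families so every catalogue
question has a non-empty, by-construction answer.

## Worked example

```r
library(vlink)

we <- worked_example()          # fixed 7-gene human/rat instance
federate(we$fed, we$query)
#>                                   humanGene
#> 1 <http://purl.example.org/vlink/gene/WEH1>
#>                                     ratGene
#> 1 <http://purl.example.org/vlink/gene/WER1>
```

The instance contains exactly three glioblastoma-annotated human genes;
two have rat orthologs and exactly one of those orthologs has a present
expression call in the rat brain (`UBERON:0000955`) — the single pair
above. Swapping the anatomical term for the liver returns zero rows.

On the full synthetic stores:

```r
st <- fixture_stores()          # expression DB + orthology + protein stores
st$db
#> <rel_db> 5 tables
#>   species: 6 rows (speciesId, genus, species)
#>   gene: 144 rows (geneId, geneName, speciesId)
#>   ...
st$links[[1]]
#> <virtual_link_set> shared-instance <http://purl.org/net/orth#Gene> |
#>   ...dataset/bgee <-> ...dataset/oma | n = 144 | active

catalogue <- load_catalogue(default_catalogue_path())
q4 <- render_template(catalogue[[4]])   # "mouse genes expressed in the
federate(st$fed, q4)                    #  liver, orthologous to human INS"
#>                                           gene
#> 1 <http://purl.example.org/vlink/gene/MMU0001>
```

The answer is the mouse *Ins2* gene: its IRI is shared verbatim between
the expression and orthology stores, which is precisely the virtual link
the planner exploited.

A thin command-line front end over the same functions is installed at
`inst/scripts/vlink.R` (verbs: `make-fixtures`, `materialize`, `query`,
`derive-orthology`, `discover-links`, `validate-links`, `fedquery`,
`templates list|search|show|run`, `check-availability`).

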