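Package: vlink
Title: Virtual-Link Federated Semantic Queries Across Biological Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale ontology-driven data-integration stack for
    heterogeneous biological databases. Exposes a relational gene-expression
    database as a virtual RDF graph through declarative relational-to-RDF
    mappings (ontology-based data access), derives pairwise ortholog and
    paralog relations from hierarchical orthologous groups and emits them as
    an RDF graph, formally describes the intersection points ("virtual
    links") between datasets with a VoID-extension vocabulary, and executes
    conjunctive SPARQL-subset queries federated across three simulated data
    stores (expression, orthology, protein) using source selection and bind
    joins. Ships a seeded synthetic-fixture generator with by-construction
    ground truth and a catalogue of natural-language query templates with
    editable slots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
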