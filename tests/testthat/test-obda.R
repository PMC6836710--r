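test_that("named transformations match the published identifier rules", {
  # CURIE -> ontology IRI: ':' becomes '_' in the local name
  expect_match(iri_value(transform_uberon("UBERON:0000955")),
               "UBERON_0000955$")
  expect_match(iri_value(transform_uberon("UBERON:0002107")),
               "UBERON_0002107$")
  expect_error(transform_uberon("0000955"), "CURIE")
  # the registered inverse undoes the transformation on valid CURIEs
  for (curie in c("UBERON:0000955", "CL:0000540", "GO:0008150")) {
    local <- sub("^.*[/#]", "", iri_value(transform_uberon(curie)))
    expect_identical(uberon_curie(local), curie)
  }
  # scientific name is the plain genus+space+species concatenation
  expect_equal(transform_scientific_name("Homo", "sapiens"),
               literal("Homo sapiens"))
  expect_equal(transform_scientific_name("Rattus", "norvegicus"),
               literal("Rattus norvegicus"))
  expect_error(transform_scientific_name("", "sapiens"), "non-empty")
})

test_that("the mapping dialect loads, validates and rejects bad rules", {
  expect_length(load_mappings(""), 0L)
  maps <- get_stores()$mappings
  ids <- vapply(maps, `[[`, "", "id")
  expect_true(all(c("gene-class", "taxon-class", "anat-entity",
                    "expressed-in", "absent-in", "highly-expressed-in") %in%
                    ids))
  expect_error(
    build_mapping_rule("bad", "SELECT geneName FROM gene",
                       "gene:{geneId} a orth:Gene ."),
    "geneId")
  expect_error(
    build_mapping_rule("bad2", "SELECT geneId FROM gene",
                       "gene:{geneId} orth:{geneId} orth:Gene ."),
    "predicate")
  dup <- paste(
    "[MappingDeclaration]",
    "", "mappingId  m1", "source     SELECT geneId FROM gene",
    "target     <http://e.org/{geneId}> a <http://e.org/C> .",
    "", "mappingId  m1", "source     SELECT geneId FROM gene",
    "target     <http://e.org/{geneId}> a <http://e.org/D> .",
    sep = "\n")
  expect_error(load_mappings(dup), "duplicate")
})

test_that("rule expansion substitutes, transforms, encodes and skips NULLs", {
  rule <- build_mapping_rule(
    "demo",
    "SELECT geneId, geneName, anatEntityId FROM expression",
    paste("gene:{geneId} rdfs:label \"{geneName}\" ;",
          "genex:isExpressedIn obo:{uberon_local(anatEntityId)} ."))
  tr <- expand_rule(rule, list(geneId = "G1", geneName = "INS",
                               anatEntityId = "UBERON:0000955"))
  expect_length(tr, 2L)
  expect_equal(tr[[1]][3], literal("INS"))
  expect_match(tr[[2]][3], "UBERON_0000955>$")
  # NULL in a placeholder suppresses that triple only
  tr2 <- expand_rule(rule, list(geneId = "G1", geneName = NA,
                                anatEntityId = "UBERON:0000955"))
  expect_length(tr2, 1L)
  expect_match(tr2[[1]][2], "isExpressedIn")
  # IRI-unsafe characters are percent-encoded
  tr3 <- expand_rule(rule, list(geneId = "G 1/x", geneName = "n",
                                anatEntityId = "UBERON:0000955"))
  expect_match(tr3[[1]][1], "G%201%2Fx")
  expect_error(expand_rule(rule, list(geneId = "G1")), "missing column")
})

test_that("materialization is a deterministic set union over all rules", {
  st <- get_stores()
  # empty database -> empty graph
  empty_db <- rel_db(lapply(st$db$tables, function(t) t[0L, , drop = FALSE]))
  expect_equal(graph_size(materialize(virtual_graph(empty_db, st$mappings))),
               0L)
  # one gene-class membership triple per gene row
  voc <- genex_vocabulary()
  n_genes <- nrow(st$db$tables$gene)
  expect_length(class_instances(st$bgee_graph, voc$gene_class), n_genes)
  # two rules emitting the same triple count once
  maps2 <- c(st$mappings, list(build_mapping_rule(
    "gene-class-copy", "SELECT geneId FROM gene",
    "gene:{geneId} a orth:Gene .")))
  g2 <- materialize(virtual_graph(st$db, maps2))
  expect_true(graph_equal(st$bgee_graph, g2))
  # byte-identical canonical output across calls
  expect_identical(serialize_graph(materialize(st$vg)),
                   serialize_graph(st$bgee_graph))
})

test_that("virtual answering handles constants, inversion and dead ends", {
  st <- get_stores()
  voc <- genex_vocabulary()
  # gene-class pattern enumerates exactly the database genes
  q <- sparql_query("g", list(c("?g", voc$rdf_type, voc$gene_class)))
  got <- sort(answer_bgp_virtual(st$vg, q)$g)
  expect_equal(got, sort(gene_iri(st$db$tables$gene$geneId)))
  # predicate no template produces -> empty, not an error
  q2 <- sparql_query("s", list(c("?s", iri("http://nothing.org/p"), "?o")))
  expect_equal(nrow(answer_bgp_virtual(st$vg, q2)), 0L)
  # constant object hits the inverted uberon transformation
  brain_cond <- sparql_query(
    "c", list(c("?c", voc$has_anat_entity, transform_uberon("UBERON:0000955"))))
  expect_true(nrow(answer_bgp_virtual(st$vg, brain_cond)) > 0L)
  expect_true(solutions_equal(answer_bgp_virtual(st$vg, brain_cond),
                              match_bgp(st$bgee_graph, brain_cond)))
})

test_that("virtual answering equals materialize-then-match on a liver query", {
  st <- get_stores()
  q <- parse_query(paste(
    "PREFIX orth: <http://purl.org/net/orth#>",
    "PREFIX genex: <http://purl.org/genex#>",
    "PREFIX obo: <http://purl.obolibrary.org/obo/>",
    "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>",
    "SELECT ?g WHERE {",
    "  ?h a orth:Gene . ?h rdfs:label \"INS\" .",
    "  ?h obo:RO_0002162 <http://purl.uniprot.org/taxonomy/9606> .",
    "  ?g genex:isExpressedIn ?c .",
    "  ?c genex:hasAnatomicalEntity obo:UBERON_0002107 .",
    "}"))
  a <- answer_bgp_virtual(st$vg, q)
  b <- match_bgp(st$bgee_graph, q)
  expect_true(nrow(a) > 0L)
  expect_true(solutions_equal(a, b))
})

test_that("virtual answering equals the oracle on randomized BGPs", {
  st <- get_stores()
  set.seed(404)
  for (i in 1:60) {
    q <- random_bgp_query(st$bgee_graph, npat = sample(1:3, 1))
    expect_true(solutions_equal(answer_bgp_virtual(st$vg, q),
                                match_bgp(st$bgee_graph, q)),
                info = paste("case", i))
  }
})
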