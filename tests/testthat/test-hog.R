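tx <- function(i) iri(paste0("http://example.org/taxon/", i))
gn <- function(i) iri(paste0("http://example.org/gene/", i))

test_that("pairwise derivation classifies by the event at the LCA", {
  # smallest case: one speciation, two leaves -> one ortholog pair
  h <- hog_node("speciation",
                list(hog_leaf(gn("a"), tx(1)), hog_leaf(gn("b"), tx(2))),
                taxon = tx(9))
  rel <- derive_pairwise(h)
  expect_equal(nrow(rel), 1L)
  expect_equal(rel$relation, "ortholog")
  # single leaf -> no pairs
  expect_equal(nrow(derive_pairwise(hog_leaf(gn("solo"), tx(1)))), 0L)
  # duplication over two 2-leaf speciation subtrees:
  # 4 cross-subtree paralog pairs + 2 within-subtree ortholog pairs
  h2 <- hog_node("duplication", list(
    hog_node("speciation",
             list(hog_leaf(gn("a1"), tx(1)), hog_leaf(gn("b1"), tx(2))),
             taxon = tx(9)),
    hog_node("speciation",
             list(hog_leaf(gn("a2"), tx(1)), hog_leaf(gn("b2"), tx(2))),
             taxon = tx(9))))
  rel2 <- derive_pairwise(h2)
  expect_equal(nrow(rel2), 6L)  # all C(4,2) pairs classified
  expect_equal(sum(rel2$relation == "paralog"), 4L)
  expect_equal(sum(rel2$relation == "ortholog"), 2L)
  expect_identical(normalize_pairs(rel2), normalize_pairs(lca_oracle_pairs(h2)))
})

test_that("HOG invariants are enforced", {
  dup_gene <- hog_node("speciation",
                       list(hog_leaf(gn("x"), tx(1)), hog_leaf(gn("x"), tx(2))),
                       taxon = tx(9))
  expect_error(derive_pairwise(dup_gene), "more than one")
  same_taxon <- hog_node("speciation",
                         list(hog_leaf(gn("p"), tx(1)),
                              hog_leaf(gn("q"), tx(1))),
                         taxon = tx(9))
  expect_error(validate_hog(same_taxon), "same taxon")
  # duplication children may share taxa
  dup_ok <- hog_node("duplication",
                     list(hog_leaf(gn("p"), tx(1)), hog_leaf(gn("q"), tx(1))))
  expect_true(validate_hog(dup_ok))
})

test_that("derivation agrees with the brute-force LCA oracle on random HOGs", {
  set.seed(405)
  for (i in 1:100) {
    h <- random_hog(max_leaves = 12L)
    rel <- derive_pairwise(h)
    n <- nrow(hog_leaves(h))
    # partition: every unordered pair classified exactly once
    expect_equal(nrow(rel), choose(n, 2))
    expect_false(any(duplicated(rel[, c("geneA", "geneB")])))
    expect_true(all(rel$geneA < rel$geneB))
    expect_identical(normalize_pairs(rel),
                     normalize_pairs(lca_oracle_pairs(h)),
                     info = paste("case", i))
  }
})

test_that("clade restriction equals brute-force partner filtering", {
  h <- hog_node("speciation", list(
    hog_leaf(gn("fly"), tx("fly")),
    hog_node("speciation",
             list(hog_leaf(gn("hum"), tx("hum")),
                  hog_leaf(gn("rat"), tx("rat"))),
             taxon = tx(8))), taxon = tx(9))
  rel <- derive_pairwise(h)
  expect_equal(nrow(restrict_to_clade(rel, character(0))), 0L)
  all_taxa <- unique(c(rel$taxonA, rel$taxonB))
  expect_equal(nrow(restrict_to_clade(rel, all_taxa)), nrow(rel))
  sub <- restrict_to_clade(rel, tx("rat"))
  expect_identical(sub, {
    x <- rel[rel$taxonB == tx("rat"), ]; rownames(x) <- NULL; x
  })
  expect_error(restrict_to_clade(rel, "not-an-iri"), "taxon IRI")
})

test_that("the emitted orthology graph carries genes, taxa and symmetry", {
  expect_equal(graph_size(emit_orth_graph(list())), 0L)
  st <- get_stores()
  voc <- genex_vocabulary()
  n_genes <- nrow(st$db$tables$gene)
  expect_length(class_instances(st$oma_graph, voc$gene_class), n_genes)
  # symmetric property assertions: both directions present
  t <- st$oma_graph$triples
  for (prop in c(voc$has_ortholog, voc$has_paralog)) {
    fw <- t[t$p == prop, ]
    expect_true(nrow(fw) > 0L)
    expect_true(all(paste(fw$o, fw$s) %in% paste(fw$s, fw$o)))
  }
})

test_that("HOG JSON and OrthoXML readers reconstruct the tree", {
  set.seed(406)
  hogs <- lapply(1:5, function(i) random_hog(max_leaves = 8L))
  path <- withr::local_tempfile(fileext = ".json")
  write_hogs_json(hogs, path)
  back <- read_hogs_json(path)
  for (i in seq_along(hogs)) {
    expect_identical(normalize_pairs(derive_pairwise(back[[i]])),
                     normalize_pairs(derive_pairwise(hogs[[i]])))
  }
  xml <- '<?xml version="1.0"?>
  <orthoXML xmlns="http://orthoXML.org/2011/" version="0.3">
    <species name="Homo sapiens" NCBITaxId="9606">
      <database name="db" version="1"><genes>
        <gene id="1" geneId="TP53"/><gene id="2" geneId="TP63"/>
      </genes></database>
    </species>
    <species name="Rattus norvegicus" NCBITaxId="10116">
      <database name="db" version="1"><genes>
        <gene id="3" geneId="Tp53"/>
      </genes></database>
    </species>
    <groups>
      <orthologGroup>
        <property name="TaxId" value="32524"/>
        <paralogGroup>
          <geneRef id="2"/>
          <orthologGroup>
            <geneRef id="1"/>
            <geneRef id="3"/>
          </orthologGroup>
        </paralogGroup>
      </orthologGroup>
    </groups>
  </orthoXML>'
  xpath <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, xpath)
  hx <- read_orthoxml(xpath)
  expect_length(hx, 1L)
  rel <- derive_pairwise(hx[[1L]])
  expect_equal(nrow(rel), 3L)
  expect_equal(sum(rel$relation == "ortholog"), 1L)
  expect_equal(sum(rel$relation == "paralog"), 2L)
})
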