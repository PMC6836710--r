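mk_ds <- function(tag) {
  dataset_description(
    id = iri(paste0("http://example.org/dataset/", tag)),
    endpoint = tag,
    classes = iri(paste0("http://example.org/class/", c("A", "B"))),
    predicates = iri(paste0("http://example.org/pred/", c("p", "q"))))
}

random_links <- function(n, dsA, dsB) {
  lapply(seq_len(n), function(i) {
    kind <- sample(c("shared-instance", "literal-match"), 1L)
    virtual_link_set(
      id = iri(paste0("http://example.org/link/", i)),
      datasetA = dsA$id, datasetB = dsB$id, kind = kind,
      class = if (kind == "shared-instance") {
        iri(paste0("http://example.org/class/C", i))
      },
      predicateA = if (kind == "literal-match") {
        iri(paste0("http://example.org/pred/a", i))
      },
      predicateB = if (kind == "literal-match") {
        iri(paste0("http://example.org/pred/b", i))
      },
      transformation = if (stats::runif(1) < 0.3) "uberon_local",
      cardinality = sample(0:500, 1L),
      status = sample(c("active", "broken", "unverified"), 1L))
  })
}

test_that("virtual-link constructors enforce the metadata contract", {
  a <- mk_ds("a"); b <- mk_ds("b")
  expect_error(virtual_link_set(iri("http://e.org/l"), a$id, a$id,
                                "shared-instance",
                                class = iri("http://e.org/C")),
               "distinct")
  expect_error(virtual_link_set(iri("http://e.org/l"), a$id, b$id,
                                "shared-instance"),
               "exactly one class")
  expect_error(virtual_link_set(iri("http://e.org/l"), a$id, b$id,
                                "literal-match",
                                predicateA = iri("http://e.org/p")),
               "exactly two predicates")
  expect_error(dataset_description(iri("http://e.org/d"), "x",
                                   character(0), iri("http://e.org/p")),
               "non-empty")
})

test_that("discovery finds the shared-instance and literal intersections", {
  # disjoint graphs -> nothing
  ga <- parse_ntriples(
    '<http://a.org/x> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://a.org/C> .')
  gb <- parse_ntriples(
    '<http://b.org/y> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://b.org/D> .')
  expect_length(discover_links(ga, gb, mk_ds("a"), mk_ds("b")), 0L)

  st <- get_stores()
  voc <- genex_vocabulary()
  by_kind <- function(links, kind) Filter(function(l) l$kind == kind, links)
  bgee_oma <- discover_links(st$bgee_graph, st$oma_graph,
                             st$datasets$bgee, st$datasets$oma)
  shared <- by_kind(bgee_oma, "shared-instance")
  classes <- vapply(shared, `[[`, "", "class")
  # the expression and orthology stores intersect on gene instances...
  expect_true(voc$gene_class %in% classes)
  gene_link <- shared[[which(classes == voc$gene_class)]]
  expect_equal(gene_link$cardinality, nrow(st$db$tables$gene))
  # ...and the expression and protein stores on taxon instances
  bgee_up <- discover_links(st$bgee_graph, st$protein_graph,
                            st$datasets$bgee, st$datasets$uniprot)
  classes_up <- vapply(by_kind(bgee_up, "shared-instance"), `[[`, "", "class")
  expect_true(voc$taxon_class %in% classes_up)
  taxon_link <- by_kind(bgee_up, "shared-instance")[[
    which(classes_up == voc$taxon_class)]]
  expect_equal(taxon_link$cardinality, nrow(st$db$tables$species))
})

test_that("discovery is symmetric up to dataset-slot swap", {
  st <- get_stores()
  ab <- discover_links(st$bgee_graph, st$oma_graph,
                       st$datasets$bgee, st$datasets$oma)
  ba <- discover_links(st$oma_graph, st$bgee_graph,
                       st$datasets$oma, st$datasets$bgee)
  sig <- function(l, swap = FALSE) {
    paste(l$kind, l$class %||% "",
          if (swap) paste(l$predicateB %||% "", l$predicateA %||% "") else
            paste(l$predicateA %||% "", l$predicateB %||% ""),
          l$cardinality)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  expect_setequal(vapply(ab, sig, ""),
                  vapply(ba, sig, "", swap = TRUE))
})

test_that("VoIDext serialization round-trips and rejects malformed graphs", {
  a <- mk_ds("a"); b <- mk_ds("b")
  # empty links, datasets only
  g0 <- serialize_voidext(list(), list(a, b))
  back0 <- parse_voidext(g0)
  expect_length(back0$links, 0L)
  expect_length(back0$datasets, 2L)
  # one link -> exactly one link-set node
  l1 <- random_links(1L, a, b)
  g1 <- serialize_voidext(l1, list(a, b))
  expect_length(class_instances(g1, iri(paste0(
    "http://purl.example.org/vlink/voidext#VirtualLinkSet"))), 1L)
  # random round-trips
  set.seed(407)
  for (i in 1:20) {
    links <- random_links(sample(0:6, 1L), a, b)
    g <- serialize_voidext(links, list(a, b))
    back <- parse_voidext(g)
    expect_equal(length(back$links), length(links))
    key <- function(ls) sort(vapply(ls, function(l) {
      paste(l$id, l$kind, l$cardinality, l$status)
    }, ""))
    expect_identical(key(back$links), key(links))
    ids <- vapply(back$datasets, `[[`, "", "id")
    expect_setequal(ids, c(a$id, b$id))
  }
  # dangling dataset reference
  expect_error(serialize_voidext(random_links(1L, a, b), list(a)),
               "unregistered dataset")
  # missing / unknown kind
  gk <- serialize_voidext(random_links(1L, a, b), list(a, b))
  voc <- genex_vocabulary()
  kind_p <- iri("http://purl.example.org/vlink/voidext#linkKind")
  gk$triples$o[gk$triples$p == kind_p] <- iri("http://example.org/NotAKind")
  expect_error(parse_voidext(gk), "unknown kind")
  gk$triples <- gk$triples[gk$triples$p != kind_p, ]
  expect_error(parse_voidext(gk), "no link kind")
})

test_that("validation refreshes, breaks and withholds judgement correctly", {
  st <- get_stores()
  eps <- list()
  for (d in st$datasets) eps[[d$id]] <- st$fed$endpoints[[d$endpoint]]
  # unperturbed: everything active, cardinalities reproduce discovery
  val <- validate_links(st$links, eps)
  expect_true(all(val$report$status == "active"))
  expect_identical(val$report$after, val$report$before)
  # rewriting every gene IRI in one store breaks the gene link only
  g2 <- st$oma_graph
  g2$triples$s <- gsub("vlink/gene/", "vlink/elsewhere/", g2$triples$s,
                       fixed = TRUE)
  g2$triples$o <- gsub("vlink/gene/", "vlink/elsewhere/", g2$triples$o,
                       fixed = TRUE)
  eps2 <- eps
  eps2[[st$datasets$oma$id]] <- graph_endpoint("oma", g2)
  val2 <- validate_links(st$links, eps2)
  voc <- genex_vocabulary()
  broken <- val2$links[vapply(val2$links, `[[`, "", "status") == "broken"]
  expect_length(broken, 1L)
  expect_equal(broken[[1L]]$class, voc$gene_class)
  # unreachable endpoint: links touching it become unverified, not broken
  eps3 <- eps
  eps3[[st$datasets$uniprot$id]]$up <- FALSE
  val3 <- validate_links(st$links, eps3)
  touches_up <- vapply(val3$links, function(l) {
    st$datasets$uniprot$id %in% c(l$datasetA, l$datasetB)
  }, TRUE)
  expect_true(all(vapply(val3$links[touches_up], `[[`, "", "status") ==
                    "unverified"))
  expect_true(all(vapply(val3$links[!touches_up], `[[`, "", "status") ==
                    "active"))
})
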