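test_that("term constructors enforce the data model", {
  expect_equal(iri("http://example.org/x"), "<http://example.org/x>")
  expect_error(iri("relative/path"), "relative")
  expect_error(iri("http://bad iri/with space"), "forbidden")
  # literal identity: lexical form, datatype and language all count
  l1 <- literal("5")
  l2 <- literal("5", datatype = "http://www.w3.org/2001/XMLSchema#integer")
  l3 <- literal("5", lang = "en")
  expect_true(l1 != l2 && l1 != l3 && l2 != l3)
  expect_identical(literal("a\"b\nc"), literal("a\"b\nc"))
  expect_equal(literal_parts(l2)$datatype,
               "http://www.w3.org/2001/XMLSchema#integer")
  expect_equal(literal_parts(literal("x", lang = "en"))$lang, "en")
  expect_error(literal("x", datatype = "http://x.org/t", lang = "en"))
  expect_error(bnode("-bad"))
  # predicates must be IRIs, subjects must not be literals
  expect_error(rdf_graph(literal("s"), iri("http://p.org/p"), literal("o")),
               "subject")
  expect_error(rdf_graph(iri("http://s.org/s"), literal("p"), literal("o")),
               "predicate")
})

test_that("graphs have set semantics", {
  g <- demo_graph()
  expect_equal(graph_size(g), 4L)
  g2 <- graph_add(g, g$triples$s[1], g$triples$p[1], g$triples$o[1])
  expect_equal(graph_size(g2), 4L)  # duplicate insert is a no-op
  g3 <- graph_add(g, iri("http://example.org/g3"),
                  genex_vocabulary()$rdfs_label, literal("new"))
  expect_equal(graph_size(g3), 5L)
  expect_true(graph_equal(g, g2))
  expect_false(graph_equal(g, g3))
})

test_that("N-Triples parsing handles the trivial cases and bad input", {
  expect_equal(graph_size(parse_ntriples("")), 0L)
  g <- parse_ntriples(
    '<http://example.org/s> <http://example.org/p> "hello" .')
  expect_equal(graph_size(g), 1L)
  expect_error(parse_ntriples("<http://a.org/s> <http://a.org/p> ."),
               "line 1")
  expect_error(parse_ntriples("this is not rdf"), "malformed")
  expect_error(parse_ntriples("<rel/s> <http://a.org/p> <http://a.org/o> ."),
               "relative")
})

test_that("serialization is canonical and round-trips", {
  expect_equal(serialize_graph(rdf_graph()), "")
  g <- demo_graph()
  doc <- serialize_graph(g)
  expect_equal(length(strsplit(doc, "\n")[[1]]), graph_size(g))
  expect_identical(doc, serialize_graph(parse_ntriples(doc)))
  expect_error(serialize_graph(g, "rdfxml"), "unknown")
  # single-triple graph -> exactly one statement line
  g1 <- parse_ntriples('<http://e.org/s> <http://e.org/p> "x" .')
  expect_equal(sum(strsplit(serialize_graph(g1), "\n")[[1]] != ""), 1L)
})

test_that("round-trip identity holds for randomized graphs in both formats", {
  set.seed(401)
  for (i in 1:25) {
    g <- random_graph(n_triples = sample(3:40, 1))
    expect_true(graph_equal(g, parse_ntriples(serialize_graph(g))))
    expect_true(graph_equal(g, parse_turtle(serialize_graph(g, "turtle"))))
  }
  big <- random_graph(n_triples = 200L, n_nodes = 40L, n_preds = 8L)
  expect_true(graph_equal(big, parse_ntriples(serialize_graph(big))))
})

test_that("the Turtle subset reader understands prefixes, 'a' and lists", {
  g <- parse_turtle('
    @prefix ex: <http://example.org/> .
    PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
    ex:s a ex:Class ;
        rdfs:label "one", "two" ;
        ex:p ex:o .
  ')
  expect_equal(graph_size(g), 4L)
  expect_true(graph_contains(
    g, iri("http://example.org/s"),
    iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"),
    iri("http://example.org/Class")))
  expect_error(parse_turtle("ex:s ex:p ex:o ."), "unknown prefix")
})

test_that("the SPARQL-subset parser accepts the dialect and nothing more", {
  q <- parse_query("SELECT ?s WHERE { ?s ?p ?o }")
  expect_length(q$bgp, 1L)
  expect_equal(q$vars, "s")
  expect_false(q$distinct)

  q2 <- parse_query('
    PREFIX ex: <http://example.org/>
    SELECT DISTINCT ?s ?o WHERE {
      ?s ex:p ?o .
      FILTER(?o > 3)
      FILTER(CONTAINS(?o, "abc"))
    } LIMIT 7')
  expect_true(q2$distinct)
  expect_equal(q2$limit, 7L)
  expect_length(q2$filters, 2L)
  expect_equal(q2$filters[[1]]$op, ">")

  for (kw in c("OPTIONAL", "UNION", "MINUS")) {
    expect_error(
      parse_query(paste0("SELECT ?s WHERE { ?s ?p ?o ", kw,
                         " { ?s ?q ?z } }")),
      "unsupported feature")
  }
  expect_error(parse_query("SELECT ?s WHERE { ?s ex:p ?o }"),
               "unknown prefix")
  expect_error(sparql_query(vars = "nope", bgp = list(c("?s", "?p", "?o"))),
               "not bound")
})

test_that("the worked-example template text parses into three service blocks", {
  t <- template_by_id("WE")
  q <- render_template(t)
  expect_length(q$services, 3L)
  expect_length(q$bgp, 0L)
  expect_true(all(c("humanGene", "ratGene") %in% q$vars))
})

test_that("match_bgp covers the algebraic corner cases", {
  g <- demo_graph()
  # empty BGP -> exactly one empty solution
  empty <- match_bgp(g, sparql_query(vars = character(0), bgp = list()))
  expect_equal(nrow(empty), 1L)
  expect_equal(ncol(empty), 0L)
  # a unique label yields exactly one binding
  q <- parse_query(paste0(
    "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#> ",
    'SELECT ?g WHERE { ?g rdfs:label "HBB-Y" }'))
  sol <- match_bgp(g, q)
  expect_equal(sol$g, "<http://example.org/g1>")
  # no match -> empty solution set, not an error
  qn <- parse_query(paste0(
    "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#> ",
    'SELECT ?g WHERE { ?g rdfs:label "ABSENT" }'))
  expect_equal(nrow(match_bgp(g, qn)), 0L)
  # repeated variable in a pattern forces slot equality
  gl <- graph_add(g, iri("http://example.org/self"),
                  iri("http://example.org/rel"), iri("http://example.org/self"))
  qr <- sparql_query("x", list(c("?x", iri("http://example.org/rel"), "?x")))
  expect_equal(match_bgp(gl, qr)$x, "<http://example.org/self>")
})

test_that("match_bgp equals exhaustive binding enumeration on random cases", {
  set.seed(402)
  for (i in 1:200) {
    g <- random_graph(n_triples = sample(5:50, 1))
    q <- random_bgp_query(g, npat = sample(1:2, 1), p_var = 0.6)
    if (length(query_variables(q)) > 3L) next
    expect_true(solutions_equal(match_bgp(g, q), exhaustive_answers(g, q)),
                info = paste("case", i))
  }
})

test_that("solutions behave as multisets with distinct and limit", {
  g <- demo_graph()
  q_all <- sparql_query("c", list(c("?g", genex_vocabulary()$rdf_type, "?c")))
  expect_equal(nrow(match_bgp(g, q_all)), 2L)  # two genes, one class each
  q_d <- sparql_query("c", list(c("?g", genex_vocabulary()$rdf_type, "?c")),
                      distinct = TRUE)
  expect_equal(nrow(match_bgp(g, q_d)), 1L)
  q_l <- sparql_query("c", list(c("?g", genex_vocabulary()$rdf_type, "?c")),
                      limit = 1L)
  expect_equal(nrow(match_bgp(g, q_l)), 1L)
  q_l0 <- sparql_query("c", list(c("?g", genex_vocabulary()$rdf_type, "?c")),
                       limit = 0L)
  expect_equal(nrow(match_bgp(g, q_l0)), 0L)
})

test_that("adding triples never removes solutions of a filter-free query", {
  set.seed(403)
  for (i in 1:25) {
    g <- random_graph(n_triples = 12L)
    q <- random_bgp_query(g, npat = 2L)
    before <- match_bgp(g, q)
    g2 <- graph_add(g, iri("http://example.org/extra/s"),
                    iri("http://example.org/extra/p"), literal("extra"))
    extra <- random_graph(n_triples = 5L)
    g2 <- graph_union(g2, extra)
    after <- match_bgp(g2, q)
    key <- function(df) do.call(paste, c(df[sort(names(df))], sep = "\r"))
    expect_true(all(key(before) %in% key(after)), info = paste("case", i))
  }
})

test_that("filters compare numerically when both sides parse as numbers", {
  ex <- function(x) iri(paste0("http://example.org/", x))
  g <- rdf_graph(
    s = c(ex("a"), ex("b"), ex("c")),
    p = rep(ex("score"), 3),
    o = c(literal("9"), literal("10"), literal("banana")))
  q <- sparql_query("s", list(c("?s", ex("score"), "?v")),
                    filters = list(sparql_filter(">", "v", literal("9"))))
  # numeric: 10 > 9, but "banana" falls back to lexicographic ("banana" > "9")
  expect_setequal(match_bgp(g, q)$s, c(ex("b"), ex("c")))
  qc <- sparql_query("s", list(c("?s", ex("score"), "?v")),
                     filters = list(sparql_filter("contains", "v", "BANA")))
  expect_equal(match_bgp(g, qc)$s, ex("c"))  # case-insensitive
})
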