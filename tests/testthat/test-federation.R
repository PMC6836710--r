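test_that("endpoints answer probes and report availability", {
  g <- demo_graph()
  ep <- graph_endpoint("demo", g)
  probe <- sparql_query(character(0), list())
  expect_equal(nrow(endpoint_answer(ep, probe)), 1L)
  down <- graph_endpoint("dead", g, up = FALSE)
  expect_error(endpoint_answer(down, probe), "endpoint down: dead")
  rep <- check_availability(list(demo = ep, dead = down))
  expect_equal(rep$status[rep$id == "demo"], "up")
  expect_equal(rep$status[rep$id == "dead"], "down")
  expect_equal(nrow(check_availability(list())), 0L)
})

test_that("source selection assigns patterns to covering datasets", {
  st <- get_stores()
  voc <- genex_vocabulary()
  # all patterns answerable by one dataset -> single-endpoint assignment
  q1 <- sparql_query("p", list(
    c("?p", voc$rdf_type, voc$protein_class),
    c("?p", voc$existence, "?e")))
  a1 <- select_sources(q1, st$fed)
  expect_equal(unique(a1$dataset), st$datasets$uniprot$id)
  # the disease->orthology->expression question spans all three stores
  q12 <- render_template(template_by_id("Q12"))
  a12 <- select_sources(q12, st$fed)
  expect_setequal(unique(a12$dataset),
                  vapply(st$datasets, `[[`, "", "id"))
  # disease/organism patterns end up on the protein store,
  # orthology on the orthology store, expression on the expression store
  pat_ds <- function(pred) {
    unique(a12$dataset[vapply(a12$patterns, `[[`, "", 2L) == pred])
  }
  expect_equal(pat_ds(voc$disease_annotation), st$datasets$uniprot$id)
  expect_equal(pat_ds(voc$has_ortholog), st$datasets$oma$id)
  expect_equal(pat_ds(voc$is_expressed_in), st$datasets$bgee$id)
  # variable predicates and uncovered predicates are rejected
  expect_error(select_sources(
    sparql_query("s", list(c("?s", "?p", "?o"))), st$fed),
    "variable predicate")
  expect_error(select_sources(
    sparql_query("s", list(c("?s", iri("http://nowhere.org/p"), "?o"))),
    st$fed),
    "unanswerable pattern")
})

test_that("explicit SERVICE blocks override automatic selection", {
  we <- get_worked()
  a <- select_sources(we$query, we$fed)
  expect_setequal(unique(a$dataset), vapply(we$datasets, `[[`, "", "id"))
  bad <- sparql_query("s", services = list(list(
    endpoint = iri("http://unregistered.example.org/sparql"),
    bgp = list(c("?s", genex_vocabulary()$rdf_type, "?o")))))
  expect_error(select_sources(bad, we$fed), "not registered")
})

test_that("planning orders by selectivity and demands link coverage", {
  st <- get_stores()
  q12 <- render_template(template_by_id("Q12"))
  a12 <- select_sources(q12, st$fed)
  plan <- plan_federated(q12, a12, st$fed)
  # the plan partitions the patterns: none lost, none duplicated
  n_stage_pats <- sum(vapply(plan$stages, function(s) length(s$patterns), 1L))
  expect_equal(n_stage_pats, length(q12$bgp))
  # the disease-constrained protein stage carries the most constants
  scores <- vapply(plan$stages, `[[`, 0, "score")
  expect_equal(plan$stages[[1L]]$dataset,
               plan$stages[[which.max(scores)]]$dataset)
  # single-endpoint queries plan to a single stage
  voc <- genex_vocabulary()
  q1 <- sparql_query("p", list(c("?p", voc$existence, "?e")))
  p1 <- plan_federated(q1, select_sources(q1, st$fed), st$fed)
  expect_length(p1$stages, 1L)
  # stripping the links turns the plan into a metadata error
  fed_nolinks <- st$fed
  fed_nolinks$links <- list()
  expect_error(plan_federated(q12, a12, fed_nolinks), "missing virtual link")
})

test_that("federated execution equals centralized evaluation", {
  st <- get_stores()
  u <- union_graph(st)
  q12 <- render_template(template_by_id("Q12"))
  expect_true(solutions_equal(federate(st$fed, q12),
                              brute_force_answers(u, q12)))
  set.seed(408)
  for (i in 1:40) {
    q <- random_federated_query(st, n_datasets = sample(2:3, 1))
    expect_true(solutions_equal(federate(uncapped(st$fed), q),
                                match_bgp(u, q)),
                info = paste("case", i))
  }
})

test_that("bind-join batching is result-invariant", {
  st <- get_stores()
  set.seed(409)
  q <- random_federated_query(st, n_datasets = 3L)
  res <- lapply(c(1L, 10L, 100L), function(b) {
    fed <- uncapped(st$fed)
    fed$batch_size <- b
    federate(fed, q)
  })
  expect_true(solutions_equal(res[[1L]], res[[2L]]))
  expect_true(solutions_equal(res[[2L]], res[[3L]]))
})

test_that("execution reports downtime and the intermediate-result cap", {
  st <- get_stores()
  fed2 <- st$fed
  fed2$endpoints$oma$up <- FALSE
  q12 <- render_template(template_by_id("Q12"))
  expect_error(federate(fed2, q12), "endpoint down: oma")
  fed3 <- st$fed
  fed3$cap <- 5L
  voc <- genex_vocabulary()
  wide <- sparql_query(c("g", "h"), list(
    c("?g", voc$rdf_type, voc$gene_class),
    c("?g", voc$has_ortholog, "?h")), distinct = TRUE)
  expect_error(federate(fed3, wide), "result cap exceeded")
})

test_that("removing a virtual link can only reject plans, never change results", {
  st <- get_stores()
  set.seed(410)
  for (i in 1:10) {
    q <- random_federated_query(st, n_datasets = 2L)
    full <- federate(uncapped(st$fed), q)
    fed2 <- uncapped(st$fed)
    drop <- sample(seq_along(fed2$links), 1L)
    fed2$links <- fed2$links[-drop]
    res <- tryCatch(federate(fed2, q), error = function(e) e)
    if (inherits(res, "error")) {
      expect_match(conditionMessage(res), "missing virtual link")
    } else {
      expect_true(solutions_equal(res, full))
    }
  }
})
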