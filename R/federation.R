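#' @title Federated query execution over virtual links
#'
#' @description
#' The structured-query-interface layer: a conjunctive query spanning
#' several datasets is decomposed into per-endpoint subqueries (source
#' selection driven by the dataset descriptions), ordered by a selectivity
#' heuristic, checked against the declared virtual links (a join variable
#' with no covering link rejects the plan rather than silently returning
#' wrong results), and executed with bind joins that ship accumulated
#' bindings into the next stage in batches.
#'
#' @name federation
NULL

#' In-process SPARQL endpoints
#'
#' An endpoint wraps something that can answer service-free queries: a
#' materialized [rdf_graph()] or a [virtual_graph()] (the expression store
#' answers straight off the relational database). `up = FALSE` simulates
#' an unreachable endpoint.
#'
#' @param id endpoint identifier (matches
#'   [dataset_description()]`$endpoint`).
#' @param graph an [rdf_graph()] (for `graph_endpoint`) or
#'   [virtual_graph()] (for `virtual_endpoint`).
#' @param service_iri optional IRI term under which SPARQL `SERVICE`
#'   blocks address this endpoint.
#' @param up availability flag.
#' @return an `endpoint` object.
#' @export
graph_endpoint <- function(id, graph, service_iri = NULL, up = TRUE) {
  stopifnot(inherits(graph, "rdf_graph"))
  structure(list(id = id, kind = "graph", data = graph,
                 service_iri = service_iri, up = isTRUE(up)),
            class = "endpoint")
}

#' @rdname graph_endpoint
#' @export
virtual_endpoint <- function(id, graph, service_iri = NULL, up = TRUE) {
  stopifnot(inherits(graph, "virtual_graph"))
  structure(list(id = id, kind = "virtual", data = graph,
                 service_iri = service_iri, up = isTRUE(up)),
            class = "endpoint")
}

#' Answer a query on an endpoint
#'
#' @param ep an endpoint.
#' @param q a [sparql_query()] without service blocks.
#' @return a solution data frame; errors if the endpoint is down.
#' @export
endpoint_answer <- function(ep, q) {
  if (!ep$up) stop("endpoint down: ", ep$id, call. = FALSE)
  if (ep$kind == "graph") {
    match_bgp(ep$data, q)
  } else {
    answer_bgp_virtual(ep$data, q)
  }
}

#' Probe endpoint availability
#'
#' Each endpoint is probed with the empty-BGP query (which an up endpoint
#' answers with exactly one empty solution); failures are reported as
#' down, mirroring the green/yellow source labels of a federation UI.
#'
#' @param endpoints named list of endpoints.
#' @return data frame with columns `id`, `status` (`"up"`/`"down"`).
#' @export
check_availability <- function(endpoints) {
  probe <- sparql_query(vars = character(0), bgp = list())
  status <- vapply(endpoints, function(ep) {
    ok <- tryCatch(nrow(endpoint_answer(ep, probe)) == 1L,
                   error = function(e) FALSE)
    if (ok) "up" else "down"
  }, character(1))
  data.frame(id = vapply(endpoints, `[[`, "", "id"),
             status = unname(status),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a federation system
#'
#' @param endpoints list of endpoints (named by their ids, or names are
#'   taken from the objects).
#' @param datasets list of [dataset_description()]s; each `endpoint` field
#'   must name a registered endpoint.
#' @param links list of [virtual_link_set()]s.
#' @param batch_size bind-join batch size (bindings shipped per subquery).
#' @param cap intermediate-result cap; `Inf` disables it.
#' @return object of class `federation_system`.
#' @export
federation_system <- function(endpoints, datasets, links,
                              batch_size = 50L, cap = 10000L) {
  if (is.null(names(endpoints)) || any(!nzchar(names(endpoints)))) {
    names(endpoints) <- vapply(endpoints, `[[`, "", "id")
  }
  for (d in datasets) {
    if (!d$endpoint %in% names(endpoints)) {
      stop("dataset ", d$id, " names unregistered endpoint '", d$endpoint,
           "'", call. = FALSE)
    }
  }
  structure(list(endpoints = endpoints, datasets = datasets, links = links,
                 batch_size = as.integer(batch_size), cap = cap),
            class = "federation_system")
}

dataset_by_id <- function(fed, id) {
  for (d in fed$datasets) if (d$id == id) return(d)
  NULL
}

# Classes each variable is rdf:type-constrained to, over the whole query.
query_type_map <- function(patterns) {
  voc <- genex_vocabulary()
  tm <- list()
  for (pat in patterns) {
    if (pat[2] == voc$rdf_type && is_variable(pat[1]) && !is_variable(pat[3])) {
      v <- sub("^\\?", "", pat[1])
      tm[[v]] <- union(tm[[v]], pat[3])
    }
  }
  tm
}

#' Assign each triple pattern to a source dataset
#'
#' A pattern is answerable by a dataset whose description covers its
#' predicate (or, for `rdf:type` patterns with a constant class, the
#' class). Ties are broken toward the dataset already holding the most
#' patterns, maximizing subquery size and minimizing remote joins.
#' Explicit `SERVICE` blocks override selection entirely.
#'
#' @param q a [sparql_query()].
#' @param fed a [federation_system()].
#' @return list with `patterns` (list of patterns) and `dataset` (character
#'   vector of dataset ids, parallel to `patterns`).
#' @export
select_sources <- function(q, fed) {
  voc <- genex_vocabulary()
  if (length(q$services) > 0L) {
    pats <- list(); ds <- character(0)
    for (sv in q$services) {
      hit <- NULL
      for (d in fed$datasets) {
        ep <- fed$endpoints[[d$endpoint]]
        if (!is.null(ep$service_iri) && ep$service_iri == sv$endpoint) {
          hit <- d; break
        }
      }
      if (is.null(hit)) {
        stop("SERVICE endpoint not registered: ", sv$endpoint, call. = FALSE)
      }
      for (pat in sv$bgp) {
        pats[[length(pats) + 1L]] <- pat
        ds <- c(ds, hit$id)
      }
    }
    for (pat in q$bgp) {
      # top-level patterns fall through to automatic selection below
      stop("mixing SERVICE blocks with top-level patterns is not supported",
           call. = FALSE)
    }
    return(list(patterns = pats, dataset = ds))
  }
  cands <- lapply(q$bgp, function(pat) {
    if (is_variable(pat[2])) {
      stop("variable predicates are unsupported in federation: ", pat[2],
           call. = FALSE)
    }
    ids <- character(0)
    for (d in fed$datasets) {
      covered <- if (pat[2] == voc$rdf_type && !is_variable(pat[3])) {
        pat[3] %in% d$classes
      } else {
        pat[2] %in% d$predicates
      }
      if (covered) ids <- c(ids, d$id)
    }
    if (length(ids) == 0L) {
      stop("unanswerable pattern: no dataset covers predicate ", pat[2],
           call. = FALSE)
    }
    ids
  })
  assigned <- rep(NA_character_, length(q$bgp))
  counts <- stats::setNames(integer(length(fed$datasets)),
                            vapply(fed$datasets, `[[`, "", "id"))
  single <- vapply(cands, length, 1L) == 1L
  for (i in which(single)) {
    assigned[i] <- cands[[i]]
    counts[assigned[i]] <- counts[assigned[i]] + 1L
  }
  for (i in which(!single)) {
    best <- cands[[i]][order(-counts[cands[[i]]])][1]
    assigned[i] <- best
    counts[best] <- counts[best] + 1L
  }
  list(patterns = q$bgp, dataset = assigned)
}

pattern_vars <- function(pats) {
  slots <- unlist(pats, use.names = FALSE)
  if (length(slots) == 0L) return(character(0))
  unique(sub("^\\?", "", slots[is_variable(slots)]))
}

# Is join variable `v` covered by a declared active link between the two
# datasets, given the stages' patterns and the query-wide type map?
var_link_covered <- function(v, dsA, dsB, patsA, patsB, links, type_map) {
  obj_preds <- function(pats) {
    ps <- vapply(pats, `[[`, "", 2L)
    ps[vapply(pats, function(p) identical(p[3], paste0("?", v)), TRUE)]
  }
  for (l in links) {
    if (l$status != "active") next
    pair_ok <- (l$datasetA == dsA && l$datasetB == dsB) ||
      (l$datasetA == dsB && l$datasetB == dsA)
    if (!pair_ok) next
    if (l$kind == "shared-instance") {
      if (l$class %in% type_map[[v]]) return(TRUE)
    } else {
      pa <- obj_preds(patsA); pb <- obj_preds(patsB)
      if ((l$predicateA %in% pa && l$predicateB %in% pb) ||
          (l$predicateA %in% pb && l$predicateB %in% pa)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Build a federated execution plan
#'
#' Patterns are grouped into maximal per-dataset subqueries; stages are
#' ordered greedily by descending selectivity (count of constant terms
#' plus filters fully applicable at the stage), each subsequent stage
#' required to share at least one link-covered variable with the already
#' planned prefix. A join variable no declared virtual link covers
#' rejects the plan.
#'
#' @param q a [sparql_query()].
#' @param assignment result of [select_sources()].
#' @param fed a [federation_system()].
#' @return object of class `federated_plan`.
#' @export
plan_federated <- function(q, assignment, fed) {
  ds_ids <- unique(assignment$dataset)
  stages <- lapply(ds_ids, function(id) {
    pats <- assignment$patterns[assignment$dataset == id]
    vars <- pattern_vars(pats)
    nconst <- sum(vapply(pats, function(p) sum(!is_variable(p)), 1L))
    filt <- Filter(function(f) {
      fv <- f$var
      if (is_variable(f$value %||% "")) {
        fv <- c(fv, sub("^\\?", "", f$value))
      }
      all(fv %in% vars)
    }, q$filters)
    d <- dataset_by_id(fed, id)
    list(dataset = id, endpoint = d$endpoint, patterns = pats,
         vars = vars, filters = filt,
         score = nconst + length(filt))
  })
  if (length(stages) == 1L) {
    return(structure(list(stages = stages, query = q),
                     class = "federated_plan"))
  }
  type_map <- query_type_map(assignment$patterns)
  ordered <- list()
  remaining <- stages[order(-vapply(stages, `[[`, 0, "score"))]
  ordered[[1L]] <- remaining[[1L]]
  remaining <- remaining[-1L]
  while (length(remaining) > 0L) {
    pick <- NA_integer_
    for (i in seq_along(remaining)) {
      cand <- remaining[[i]]
      ok <- FALSE
      for (prev in ordered) {
        shared <- intersect(cand$vars, prev$vars)
        for (v in shared) {
          if (var_link_covered(v, prev$dataset, cand$dataset,
                               prev$patterns, cand$patterns,
                               fed$links, type_map)) {
            ok <- TRUE; break
          }
        }
        if (ok) break
      }
      if (ok) { pick <- i; break }
    }
    if (is.na(pick)) {
      stop("missing virtual link between ", ordered[[1L]]$dataset, " and ",
           remaining[[1L]]$dataset,
           ": no declared link covers a shared join variable", call. = FALSE)
    }
    ordered[[length(ordered) + 1L]] <- remaining[[pick]]
    remaining <- remaining[-pick]
  }
  structure(list(stages = ordered, query = q), class = "federated_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.federated_plan <- function(x, ...) {
  cat("<federated_plan>", length(x$stages), "stages\n")
  for (i in seq_along(x$stages)) {
    st <- x$stages[[i]]
    cat(sprintf("  %d. %s (%d patterns, score %d)\n", i, st$dataset,
                length(st$patterns), st$score))
  }
  invisible(x)
}

stage_query <- function(st, values = NULL) {
  sparql_query(vars = st$vars, bgp = st$patterns, filters = st$filters,
               values = values)
}

#' Execute a federated plan with bind joins
#'
#' The first stage runs as-is; each later stage receives the accumulated
#' bindings of its shared variables as enumerated value constraints, in
#' batches of `fed$batch_size`. Results are naturally joined and finally
#' projected/filtered per the original query.
#'
#' @param plan a [plan_federated()] result.
#' @param fed the [federation_system()].
#' @param verbose log per-stage binding counts.
#' @return a solution data frame equal (for link-covered queries) to
#'   centralized evaluation over the union of the endpoint graphs.
#' @export
execute_federated <- function(plan, fed, verbose = FALSE) {
  q <- plan$query
  sols <- unit_solutions()
  for (k in seq_along(plan$stages)) {
    st <- plan$stages[[k]]
    ep <- fed$endpoints[[st$endpoint]]
    if (is.null(ep)) stop("no endpoint registered: ", st$endpoint,
                          call. = FALSE)
    shared <- intersect(names(sols), st$vars)
    res <- if (k == 1L || length(shared) == 0L) {
      endpoint_answer(ep, stage_query(st))
    } else {
      bindings <- unique_rows(sols[, shared, drop = FALSE])
      if (nrow(bindings) == 0L) {
        empty_solutions(st$vars)
      } else {
        batches <- split(seq_len(nrow(bindings)),
                         ceiling(seq_len(nrow(bindings)) / fed$batch_size))
        parts <- lapply(batches, function(idx) {
          endpoint_answer(ep, stage_query(
            st, values = bindings[idx, , drop = FALSE]))
        })
        unique_rows(do.call(rbind, parts))
      }
    }
    if (verbose) {
      message(sprintf("stage %d [%s]: %d bindings", k, st$dataset, nrow(res)))
    }
    sols <- join_solutions(sols, res)
    if (nrow(sols) > fed$cap) {
      stop("result cap exceeded (", nrow(sols), " > ", fed$cap,
           " intermediate bindings): refine the query to be more specific",
           call. = FALSE)
    }
  }
  finalize_solutions(sols, q)
}

#' One-call federated query
#'
#' Source selection, planning and bind-join execution in one step.
#'
#' @param fed a [federation_system()].
#' @param q a [sparql_query()] or query text.
#' @param verbose log per-stage binding counts.
#' @return a solution data frame.
#' @export
federate <- function(fed, q, verbose = FALSE) {
  if (is.character(q)) q <- parse_query(q)
  assignment <- select_sources(q, fed)
  plan <- plan_federated(q, assignment, fed)
  execute_federated(plan, fed, verbose = verbose)
}

#' Flatten a query's SERVICE blocks into its top-level BGP
#'
#' Used to evaluate a federated query centrally (the correctness oracle).
#'
#' @param q a [sparql_query()].
#' @return an equivalent service-free query.
#' @export
flatten_query <- function(q) {
  sparql_query(vars = q$vars, bgp = all_patterns(q), filters = q$filters,
               distinct = q$distinct, limit = q$limit)
}
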