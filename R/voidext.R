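#' @title Virtual-link metadata (a VoID extension)
#'
#' @description
#' A *virtual link* is an intersection data point between two datasets —
#' either instances of a class shared by IRI, or identical literal values
#' under a pair of predicates — that can act as a join point for federated
#' queries. Links are first-class metadata: discovered from data,
#' serialized in an RDF vocabulary extending VoID, and re-validated
#' against live endpoints so that schema drift is detected instead of
#' silently returning empty joins.
#'
#' @name voidext
NULL

#' Describe a dataset for the federation metadata
#'
#' @param id dataset IRI term.
#' @param endpoint endpoint identifier (plain string, resolved against the
#'   endpoint registry at query time).
#' @param classes character vector of class IRI terms the dataset serves.
#' @param predicates character vector of predicate IRI terms.
#' @return object of class `dataset_description`.
#' @export
dataset_description <- function(id, endpoint, classes, predicates) {
  stopifnot(is_iri(id), is.character(endpoint), length(endpoint) == 1L)
  if (length(classes) == 0L || length(predicates) == 0L) {
    stop("registered datasets must declare non-empty class and predicate sets",
         call. = FALSE)
  }
  stopifnot(all(is_iri(classes)), all(is_iri(predicates)))
  structure(list(id = id, endpoint = endpoint,
                 classes = sort(unique(classes), method = "radix"),
                 predicates = sort(unique(predicates), method = "radix")),
            class = "dataset_description")
}

#' Construct a virtual-link set
#'
#' @param id link IRI term.
#' @param datasetA,datasetB IRI terms of the two linked datasets (must
#'   differ).
#' @param kind `"shared-instance"` or `"literal-match"`.
#' @param class class IRI term (shared-instance links name exactly one).
#' @param predicateA,predicateB predicate IRI terms (literal-match links
#'   name exactly two).
#' @param transformation optional registered transformation name relating
#'   the two literal forms.
#' @param cardinality non-negative intersection size estimate.
#' @param status `"active"`, `"broken"` or `"unverified"`.
#' @return object of class `virtual_link_set`.
#' @export
virtual_link_set <- function(id, datasetA, datasetB,
                             kind = c("shared-instance", "literal-match"),
                             class = NULL, predicateA = NULL,
                             predicateB = NULL, transformation = NULL,
                             cardinality = 0L,
                             status = c("active", "broken", "unverified")) {
  kind <- match.arg(kind)
  status <- match.arg(status)
  stopifnot(is_iri(id), is_iri(datasetA), is_iri(datasetB))
  if (datasetA == datasetB) {
    stop("a virtual link connects two distinct datasets", call. = FALSE)
  }
  if (kind == "shared-instance") {
    if (is.null(class) || !is.null(predicateA) || !is.null(predicateB)) {
      stop("shared-instance links name exactly one class", call. = FALSE)
    }
    stopifnot(is_iri(class))
  } else {
    if (!is.null(class) || is.null(predicateA) || is.null(predicateB)) {
      stop("literal-match links name exactly two predicates", call. = FALSE)
    }
    stopifnot(is_iri(predicateA), is_iri(predicateB))
  }
  cardinality <- as.integer(cardinality)
  stopifnot(!is.na(cardinality), cardinality >= 0L)
  structure(list(id = id, datasetA = datasetA, datasetB = datasetB,
                 kind = kind, class = class, predicateA = predicateA,
                 predicateB = predicateB, transformation = transformation,
                 cardinality = cardinality, status = status),
            class = "virtual_link_set")
}

#' @export
print.virtual_link_set <- function(x, ...) {
  cat("<virtual_link_set>", x$kind,
      if (x$kind == "shared-instance") x$class else
        paste(x$predicateA, "~", x$predicateB),
      "|", x$datasetA, "<->", x$datasetB,
      "| n =", x$cardinality, "|", x$status, "\n")
  invisible(x)
}

#' Predicates considered when discovering literal-match links
#'
#' Label-like and identifier-like predicates; all-pairs comparison over
#' every predicate would be quadratic and mostly noise.
#' @return character vector of predicate IRI terms.
#' @export
default_link_predicates <- function() {
  c(iri(paste0(NS$rdfs, "label")),
    iri(paste0(NS$up, "scientificName")),
    iri(paste0(NS$up, "mnemonic")))
}

link_local <- function(t) {
  v <- iri_value(t)
  gsub("[^A-Za-z0-9_-]", "_", sub("^.*[/#]", "", v))
}

#' Discover virtual links between two materialized graphs
#'
#' Emits one shared-instance link per class with at least one common
#' (IRI-identified) instance in both graphs, and one literal-match link
#' per candidate predicate pair sharing at least one identical literal
#' value. Blank nodes never form links: they are document-scoped.
#'
#' @param gA,gB materialized [rdf_graph()]s.
#' @param datasetA,datasetB the corresponding [dataset_description()]s.
#' @param candidate_predicates predicates considered for literal matches.
#' @return list of [virtual_link_set()]s (status `"active"`).
#' @export
discover_links <- function(gA, gB, datasetA, datasetB,
                           candidate_predicates = default_link_predicates()) {
  voc <- genex_vocabulary()
  links <- list()
  mint <- function(...) {
    iri(paste0(NS$meta, "link/", paste(..., sep = "/")))
  }
  pairtag <- paste(link_local(datasetA$id), link_local(datasetB$id),
                   sep = "--")
  classesA <- unique(gA$triples$o[gA$triples$p == voc$rdf_type])
  classesB <- unique(gB$triples$o[gB$triples$p == voc$rdf_type])
  for (cl in sort(intersect(classesA, classesB), method = "radix")) {
    shared <- intersect(class_instances(gA, cl), class_instances(gB, cl))
    if (length(shared) == 0L) next
    links[[length(links) + 1L]] <- virtual_link_set(
      id = mint(pairtag, "shared-instance", link_local(cl)),
      datasetA = datasetA$id, datasetB = datasetB$id,
      kind = "shared-instance", class = cl,
      cardinality = length(shared), status = "active")
  }
  predsA <- intersect(unique(gA$triples$p), candidate_predicates)
  predsB <- intersect(unique(gB$triples$p), candidate_predicates)
  for (pa in sort(predsA, method = "radix")) {
    va <- gA$triples$o[gA$triples$p == pa]
    va <- unique(va[is_literal(va)])
    if (length(va) == 0L) next
    for (pb in sort(predsB, method = "radix")) {
      vb <- gB$triples$o[gB$triples$p == pb]
      vb <- unique(vb[is_literal(vb)])
      shared <- intersect(va, vb)
      if (length(shared) == 0L) next
      links[[length(links) + 1L]] <- virtual_link_set(
        id = mint(pairtag, "literal-match",
                  paste(link_local(pa), link_local(pb), sep = "--")),
        datasetA = datasetA$id, datasetB = datasetB$id,
        kind = "literal-match", predicateA = pa, predicateB = pb,
        cardinality = length(shared), status = "active")
    }
  }
  links
}

VOIDEXT_TERMS <- function() {
  v <- function(x) iri(paste0(NS$voidext, x))
  list(
    Dataset = iri(paste0(NS$void, "Dataset")),
    void_class = iri(paste0(NS$void, "class")),
    void_property = iri(paste0(NS$void, "property")),
    VirtualLinkSet = v("VirtualLinkSet"),
    endpoint_id = v("endpointId"),
    source_dataset = v("sourceDataset"),
    target_dataset = v("targetDataset"),
    link_kind = v("linkKind"),
    SharedInstance = v("SharedInstance"),
    LiteralMatch = v("LiteralMatch"),
    link_class = v("linkClass"),
    source_predicate = v("sourcePredicate"),
    target_predicate = v("targetPredicate"),
    transformation = v("transformation"),
    cardinality = v("cardinality"),
    status = v("status")
  )
}

#' Serialize virtual-link metadata as RDF
#'
#' @param links list of [virtual_link_set()]s.
#' @param datasets list of [dataset_description()]s; every dataset a link
#'   references must be present.
#' @return an [rdf_graph()] using VoID plus the package's VoIDext terms.
#' @export
serialize_voidext <- function(links, datasets) {
  vt <- VOIDEXT_TERMS()
  voc <- genex_vocabulary()
  ids <- vapply(datasets, `[[`, "", "id")
  s <- p <- o <- character(0)
  add <- function(ss, pp, oo) {
    s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo)
  }
  for (d in datasets) {
    add(d$id, voc$rdf_type, vt$Dataset)
    add(d$id, vt$endpoint_id, literal(d$endpoint))
    add(rep(d$id, length(d$classes)), rep(vt$void_class, length(d$classes)),
        d$classes)
    add(rep(d$id, length(d$predicates)),
        rep(vt$void_property, length(d$predicates)), d$predicates)
  }
  for (l in links) {
    for (ref in c(l$datasetA, l$datasetB)) {
      if (!ref %in% ids) {
        stop("link ", l$id, " references unregistered dataset ", ref,
             call. = FALSE)
      }
    }
    add(l$id, voc$rdf_type, vt$VirtualLinkSet)
    add(l$id, vt$source_dataset, l$datasetA)
    add(l$id, vt$target_dataset, l$datasetB)
    add(l$id, vt$link_kind,
        if (l$kind == "shared-instance") vt$SharedInstance else vt$LiteralMatch)
    if (l$kind == "shared-instance") {
      add(l$id, vt$link_class, l$class)
    } else {
      add(l$id, vt$source_predicate, l$predicateA)
      add(l$id, vt$target_predicate, l$predicateB)
    }
    if (!is.null(l$transformation)) {
      add(l$id, vt$transformation, literal(l$transformation))
    }
    add(l$id, vt$cardinality,
        literal(as.character(l$cardinality),
                datatype = paste0(NS$xsd, "integer")))
    add(l$id, vt$status, literal(l$status))
  }
  rdf_graph(s, p, o)
}

#' Parse virtual-link metadata from RDF
#'
#' Inverse of [serialize_voidext()].
#'
#' @param g an [rdf_graph()] using the VoIDext vocabulary.
#' @return list with elements `datasets` and `links`, each sorted by id.
#' @export
parse_voidext <- function(g) {
  vt <- VOIDEXT_TERMS()
  voc <- genex_vocabulary()
  t <- g$triples
  objs <- function(id, pred) sort(t$o[t$s == id & t$p == pred],
                                  method = "radix")
  obj1 <- function(id, pred) {
    v <- t$o[t$s == id & t$p == pred]
    if (length(v) == 0L) NULL else v[1]
  }
  lex1 <- function(id, pred) {
    v <- obj1(id, pred)
    if (is.null(v)) NULL else literal_parts(v)$lex
  }
  ds_ids <- sort(class_instances(g, vt$Dataset), method = "radix")
  datasets <- lapply(ds_ids, function(id) {
    dataset_description(id = id,
                        endpoint = lex1(id, vt$endpoint_id),
                        classes = objs(id, vt$void_class),
                        predicates = objs(id, vt$void_property))
  })
  link_ids <- sort(class_instances(g, vt$VirtualLinkSet), method = "radix")
  links <- lapply(link_ids, function(id) {
    kind_iri <- obj1(id, vt$link_kind)
    if (is.null(kind_iri)) {
      stop("virtual link ", id, " has no link kind", call. = FALSE)
    }
    kind <- if (kind_iri == vt$SharedInstance) {
      "shared-instance"
    } else if (kind_iri == vt$LiteralMatch) {
      "literal-match"
    } else {
      stop("virtual link ", id, " has unknown kind ", kind_iri, call. = FALSE)
    }
    virtual_link_set(
      id = id,
      datasetA = obj1(id, vt$source_dataset),
      datasetB = obj1(id, vt$target_dataset),
      kind = kind,
      class = if (kind == "shared-instance") obj1(id, vt$link_class),
      predicateA = if (kind == "literal-match") obj1(id, vt$source_predicate),
      predicateB = if (kind == "literal-match") obj1(id, vt$target_predicate),
      transformation = lex1(id, vt$transformation),
      cardinality = as.integer(lex1(id, vt$cardinality)),
      status = lex1(id, vt$status))
  })
  list(datasets = datasets, links = links)
}

#' Re-validate virtual links against endpoints
#'
#' Re-counts each link's intersection through BGP queries on the two
#' endpoints. A zero intersection marks the link `broken` (schema drift or
#' rewritten IRIs); a positive count refreshes the cardinality and keeps
#' the link `active`; an unreachable endpoint leaves the link
#' `unverified`, not broken.
#'
#' @param links list of [virtual_link_set()]s.
#' @param endpoints named list: dataset IRI term -> endpoint object (see
#'   [graph_endpoint()]).
#' @return list with `links` (updated copies) and `report` (data frame of
#'   per-link before/after cardinalities and statuses).
#' @export
validate_links <- function(links, endpoints) {
  voc <- genex_vocabulary()
  count_link <- function(l) {
    epA <- endpoints[[l$datasetA]]
    epB <- endpoints[[l$datasetB]]
    if (is.null(epA) || is.null(epB)) {
      stop("no endpoint registered for dataset", call. = FALSE)
    }
    if (l$kind == "shared-instance") {
      q <- sparql_query(vars = "x",
                        bgp = list(c("?x", voc$rdf_type, l$class)),
                        distinct = TRUE)
      a <- endpoint_answer(epA, q)$x
      b <- endpoint_answer(epB, q)$x
      length(intersect(a[is_iri(a)], b[is_iri(b)]))
    } else {
      qa <- sparql_query(vars = "v",
                         bgp = list(c("?s", l$predicateA, "?v")),
                         distinct = TRUE)
      qb <- sparql_query(vars = "v",
                         bgp = list(c("?s", l$predicateB, "?v")),
                         distinct = TRUE)
      a <- endpoint_answer(epA, qa)$v
      b <- endpoint_answer(epB, qb)$v
      length(intersect(a[is_literal(a)], b[is_literal(b)]))
    }
  }
  report <- data.frame(id = character(), kind = character(),
                       before = integer(), after = integer(),
                       status = character(), stringsAsFactors = FALSE)
  out <- vector("list", length(links))
  for (i in seq_along(links)) {
    l <- links[[i]]
    before <- l$cardinality
    n <- tryCatch(count_link(l), error = function(e) NA_integer_)
    if (is.na(n)) {
      l$status <- "unverified"
    } else if (n == 0L) {
      l$status <- "broken"
      l$cardinality <- 0L
    } else {
      l$status <- "active"
      l$cardinality <- n
    }
    out[[i]] <- l
    report <- rbind(report, data.frame(
      id = l$id, kind = l$kind, before = before,
      after = if (is.na(n)) NA_integer_ else n,
      status = l$status, stringsAsFactors = FALSE))
  }
  list(links = out, report = report)
}
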