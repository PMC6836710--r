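#' Create an RDF graph
#'
#' A graph is a *set* of triples held as a unique-row data frame of encoded
#' terms (columns `s`, `p`, `o`). Inserting a duplicate triple leaves the
#' cardinality unchanged.
#'
#' @param s,p,o equal-length vectors of encoded terms (see [iri()],
#'   [literal()], [bnode()]).
#' @param name optional graph name (IRI term).
#' @return object of class `rdf_graph`.
#' @export
rdf_graph <- function(s = character(), p = character(), o = character(),
                      name = NULL) {
  stopifnot(length(s) == length(p), length(p) == length(o))
  validate_triples(s, p, o)
  df <- unique(data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(list(triples = df, name = name), class = "rdf_graph")
}

validate_triples <- function(s, p, o) {
  if (length(s) == 0L) return(invisible(TRUE))
  bad <- !(is_iri(s) | is_bnode(s))
  if (any(bad)) stop("triple subject must be an IRI or blank node: ", s[bad][1],
                     call. = FALSE)
  bad <- !is_iri(p)
  if (any(bad)) stop("triple predicate must be an IRI: ", p[bad][1],
                     call. = FALSE)
  bad <- !(is_iri(o) | is_bnode(o) | is_literal(o))
  if (any(bad)) stop("triple object must be an IRI, blank node or literal: ",
                     o[bad][1], call. = FALSE)
  invisible(TRUE)
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph> ", graph_size(x), " triples",
      if (!is.null(x$name)) paste0(" (", x$name, ")"), "\n", sep = "")
  invisible(x)
}

#' Number of triples in a graph
#' @param g an `rdf_graph`.
#' @return integer count.
#' @export
graph_size <- function(g) nrow(g$triples)

#' Add triples to a graph (set semantics)
#' @param g an `rdf_graph`.
#' @param s,p,o encoded term vectors.
#' @return the enlarged graph.
#' @export
graph_add <- function(g, s, p, o) {
  validate_triples(s, p, o)
  df <- unique(rbind(g$triples,
                     data.frame(s = s, p = p, o = o, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  g$triples <- df
  g
}

#' Union of graphs
#' @param ... `rdf_graph` objects.
#' @param name optional name of the union graph.
#' @return an `rdf_graph` containing every triple of every argument.
#' @export
graph_union <- function(..., name = NULL) {
  gs <- list(...)
  df <- unique(do.call(rbind, lapply(gs, function(g) g$triples)))
  if (is.null(df)) df <- data.frame(s = character(), p = character(),
                                    o = character(), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(list(triples = df, name = name), class = "rdf_graph")
}

#' Set equality of two graphs
#' @param a,b `rdf_graph` objects.
#' @return `TRUE` iff both contain exactly the same triples.
#' @export
graph_equal <- function(a, b) {
  ka <- canonical_lines(a)
  kb <- canonical_lines(b)
  identical(ka, kb)
}

canonical_lines <- function(g) {
  if (graph_size(g) == 0L) return(character(0))
  sort(paste(g$triples$s, g$triples$p, g$triples$o, "."), method = "radix")
}

#' Does the graph contain a triple?
#' @param g an `rdf_graph`.
#' @param s,p,o encoded terms.
#' @return logical vector.
#' @export
graph_contains <- function(g, s, p, o) {
  paste(s, p, o) %in% paste(g$triples$s, g$triples$p, g$triples$o)
}

#' Distinct subject IRIs typed into a class
#' @param g an `rdf_graph`.
#' @param class_iri encoded IRI term of the class.
#' @return character vector of encoded instance IRIs (blank nodes excluded).
#' @export
class_instances <- function(g, class_iri) {
  t <- g$triples
  hit <- t$p == iri(paste0(NS$rdf, "type")) & t$o == class_iri & is_iri(t$s)
  sort(unique(t$s[hit]), method = "radix")
}
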