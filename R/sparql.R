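#' Construct a SPARQL-subset query programmatically
#'
#' The dialect covers exactly what conjunctive federated queries over the
#' three stores need: `SELECT [DISTINCT] ?vars WHERE { patterns, FILTER,
#' SERVICE <iri> { ... } } LIMIT n`.
#'
#' @param vars character vector of projected variable names (no `?`).
#' @param bgp list of triple patterns; each a list/character of length 3
#'   whose slots are encoded terms or `?var` strings.
#' @param filters list of filters as produced by [sparql_filter()].
#' @param distinct logical.
#' @param limit optional non-negative integer.
#' @param services list of service blocks, each `list(endpoint = <iri term>,
#'   bgp = <pattern list>)`.
#' @param values internal: a data frame of enumerated bindings (encoded
#'   terms, columns named by variable) injected by the bind-join executor.
#' @return object of class `sparql_query`.
#' @export
sparql_query <- function(vars, bgp = list(), filters = list(),
                         distinct = FALSE, limit = NULL, services = list(),
                         values = NULL) {
  bgp <- lapply(bgp, as.character)
  stopifnot(all(vapply(bgp, length, 1L) == 3L))
  if (!is.null(limit)) {
    limit <- as.integer(limit)
    if (is.na(limit) || limit < 0L) stop("LIMIT must be non-negative",
                                         call. = FALSE)
  }
  q <- structure(list(vars = vars, bgp = bgp, filters = filters,
                      distinct = isTRUE(distinct), limit = limit,
                      services = services, values = values),
                 class = "sparql_query")
  avail <- query_variables(q)
  missing <- setdiff(vars, avail)
  if (length(missing) > 0L) {
    stop("projected variable not bound in query body: ?", missing[1],
         call. = FALSE)
  }
  q
}

#' Build a filter expression
#'
#' @param op one of `"="`, `"!="`, `"<"`, `">"`, `"contains"`.
#' @param var variable name (no `?`).
#' @param value encoded term (comparisons) or plain string (`contains`).
#' @return a filter list usable in [sparql_query()].
#' @export
sparql_filter <- function(op, var, value) {
  op <- match.arg(op, c("=", "!=", "<", ">", "contains"))
  list(op = op, var = var, value = value)
}

#' Variables bound anywhere in a query's BGP or service blocks
#' @param q a `sparql_query`.
#' @return character vector of variable names.
#' @export
query_variables <- function(q) {
  pats <- c(q$bgp, unlist(lapply(q$services, `[[`, "bgp"), recursive = FALSE))
  slots <- unlist(pats, use.names = FALSE)
  if (length(slots) == 0L) return(character(0))
  unique(sub("^\\?", "", slots[is_variable(slots)]))
}

all_patterns <- function(q) {
  c(q$bgp, unlist(lapply(q$services, `[[`, "bgp"), recursive = FALSE))
}

#' @export
print.sparql_query <- function(x, ...) {
  cat("<sparql_query> SELECT", if (x$distinct) "DISTINCT",
      paste0("?", x$vars, collapse = " "),
      "|", length(x$bgp), "patterns,",
      length(x$services), "service blocks,",
      length(x$filters), "filters",
      if (!is.null(x$limit)) paste("LIMIT", x$limit), "\n")
  invisible(x)
}

UNSUPPORTED_KEYWORDS <- c("OPTIONAL", "UNION", "GRAPH", "ORDER", "GROUP",
                          "HAVING", "BIND", "VALUES", "MINUS", "EXISTS",
                          "NOT", "ASK", "CONSTRUCT", "DESCRIBE", "OFFSET",
                          "ASC", "DESC")

#' Parse a SPARQL-subset query
#'
#' Supported: `PREFIX`, `SELECT [DISTINCT]`, `WHERE` with triple patterns,
#' `FILTER` (`=`, `!=`, `<`, `>`, `CONTAINS`), `SERVICE <iri> { ... }` and
#' `LIMIT`. Anything else in SPARQL 1.1 (OPTIONAL, UNION, subqueries,
#' aggregates, property paths...) is rejected explicitly, never ignored.
#'
#' @param text query text (character scalar).
#' @return a [sparql_query()].
#' @export
#' @examples
#' parse_query("SELECT ?s WHERE { ?s ?p ?o }")
parse_query <- function(text) {
  toks <- tokenize_sparql(paste(text, collapse = "\n"))
  st <- new.env(parent = emptyenv())
  st$i <- 1L; st$toks <- toks; st$n <- length(toks$type)
  peek <- function() if (st$i <= st$n) st$toks$text[st$i] else ""
  ptype <- function() if (st$i <= st$n) st$toks$type[st$i] else "eof"
  peek_kw <- function() toupper(peek())
  advance <- function() { tk <- peek(); st$i <- st$i + 1L; tk }
  expect <- function(txt) {
    if (toupper(peek()) != toupper(txt)) {
      stop("SPARQL parse error: expected '", txt, "' but found '", peek(),
           "'", call. = FALSE)
    }
    advance()
  }
  check_supported <- function() {
    if (ptype() == "word" && peek_kw() %in% UNSUPPORTED_KEYWORDS) {
      stop("unsupported feature: ", peek_kw(), call. = FALSE)
    }
  }

  prefixes <- list()
  while (peek_kw() == "PREFIX") {
    advance()
    if (ptype() != "pname_ns") stop("SPARQL: expected prefix name after PREFIX",
                                    call. = FALSE)
    pn <- advance()
    pfx <- substr(pn, 1L, nchar(pn) - 1L)
    if (ptype() != "iriref") stop("SPARQL: expected IRI in PREFIX", call. = FALSE)
    prefixes[[pfx]] <- substr(peek(), 2L, nchar(peek()) - 1L)
    advance()
  }

  check_supported()
  expect("SELECT")
  distinct <- FALSE
  if (peek_kw() == "DISTINCT") { distinct <- TRUE; advance() }
  vars <- character(0)
  while (ptype() == "var") vars <- c(vars, sub("^\\?", "", advance()))
  if (length(vars) == 0L) stop("SPARQL: SELECT needs at least one variable",
                               call. = FALSE)
  check_supported()
  expect("WHERE")

  resolve_term <- function(tok, type) {
    force(tok)
    switch(type,
      var = tok,
      iriref = iri(substr(tok, 2L, nchar(tok) - 1L)),
      pname = expand_pname(tok, prefixes),
      literal = recode_term(tok, NA),
      number = if (grepl(".", tok, fixed = TRUE)) {
        literal(tok, datatype = paste0(NS$xsd, "decimal"))
      } else {
        literal(tok, datatype = paste0(NS$xsd, "integer"))
      },
      stop("SPARQL: unexpected token '", tok, "'", call. = FALSE))
  }
  next_term <- function() {
    type <- ptype()
    tok <- advance()
    resolve_term(tok, type)
  }

  parse_filter <- function() {
    expect("(")
    if (peek_kw() == "CONTAINS") {
      advance(); expect("(")
      if (ptype() != "var") stop("SPARQL: CONTAINS expects a variable",
                                 call. = FALSE)
      v <- sub("^\\?", "", advance())
      expect(",")
      if (ptype() != "literal") stop("SPARQL: CONTAINS expects a string literal",
                                     call. = FALSE)
      str <- literal_parts(recode_term(advance(), NA))$lex
      expect(")"); expect(")")
      return(sparql_filter("contains", v, str))
    }
    if (ptype() != "var") stop("SPARQL: FILTER comparisons start with a variable",
                               call. = FALSE)
    v <- sub("^\\?", "", advance())
    if (!ptype() %in% c("op")) stop("SPARQL: expected comparison operator",
                                    call. = FALSE)
    op <- advance()
    rhs <- next_term()
    expect(")")
    sparql_filter(op, v, rhs)
  }

  parse_group <- function(in_service) {
    expect("{")
    bgp <- list()
    filters <- list()
    services <- list()
    repeat {
      if (peek() == "}") { advance(); break }
      check_supported()
      if (peek_kw() == "FILTER") {
        advance()
        filters[[length(filters) + 1L]] <- parse_filter()
        if (peek() == ".") advance()
        next
      }
      if (peek_kw() == "SERVICE") {
        if (in_service) stop("unsupported feature: nested SERVICE",
                             call. = FALSE)
        advance()
        ep <- next_term()
        if (!is_iri(ep)) stop("SPARQL: SERVICE endpoint must be an IRI",
                              call. = FALSE)
        sub <- parse_group(TRUE)
        services[[length(services) + 1L]] <-
          list(endpoint = ep, bgp = sub$bgp)
        filters <- c(filters, sub$filters)
        if (peek() == ".") advance()
        next
      }
      subj <- next_term()
      pred <- if (peek() == "a" && ptype() == "word") {
        advance(); iri(paste0(NS$rdf, "type"))
      } else {
        check_supported()
        next_term()
      }
      obj <- next_term()
      repeat {
        bgp[[length(bgp) + 1L]] <- c(subj, pred, obj)
        if (peek() == ",") {
          advance()
          obj <- next_term()
          next
        }
        break
      }
      if (peek() == ";") {
        # predicate-object list continuation
        while (peek() == ";") {
          advance()
          if (peek() %in% c(".", "}")) break
          pred <- if (peek() == "a" && ptype() == "word") {
            advance(); iri(paste0(NS$rdf, "type"))
          } else {
            next_term()
          }
          obj <- next_term()
          repeat {
            bgp[[length(bgp) + 1L]] <- c(subj, pred, obj)
            if (peek() == ",") {
              advance()
              obj <- next_term()
              next
            }
            break
          }
        }
      }
      if (peek() == ".") advance()
    }
    list(bgp = bgp, filters = filters, services = services)
  }

  grp <- parse_group(FALSE)
  limit <- NULL
  if (peek_kw() == "LIMIT") {
    advance()
    if (ptype() != "number") stop("SPARQL: LIMIT expects an integer",
                                  call. = FALSE)
    limit <- as.integer(advance())
  }
  check_supported()
  if (st$i <= st$n) stop("SPARQL: trailing content after query: '",
                         peek(), "'", call. = FALSE)
  sparql_query(vars = vars, bgp = grp$bgp, filters = grp$filters,
               distinct = distinct, limit = limit, services = grp$services)
}

tokenize_sparql <- function(doc) {
  pats <- c(
    ws      = "[ \t\r\n]+",
    comment = "#[^\n]*",
    iriref  = "<[^<>\"{}|^`\\\\ \t\r\n]*>",
    literal = '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^(?:<[^>]*>)|@[A-Za-z]+(?:-[A-Za-z0-9]+)*)?',
    var     = "\\?[A-Za-z0-9_]+",
    number  = "[0-9]+(?:\\.[0-9]+)?",
    pname_ns = "[A-Za-z][A-Za-z0-9_.-]*:(?![A-Za-z0-9_%(:-])",
    pname   = "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_.%-]*|:[A-Za-z0-9_][A-Za-z0-9_.%-]*",
    word    = "[A-Za-z][A-Za-z0-9_]*",
    op      = "!=|=|<|>",
    punct   = "[{}().,;]"
  )
  types <- character(0); texts <- character(0)
  pos <- 1L; len <- nchar(doc)
  while (pos <= len) {
    rest <- substr(doc, pos, len)
    matched <- FALSE
    for (nm in names(pats)) {
      m <- regexpr(paste0("^(?:", pats[[nm]], ")"), rest, perl = TRUE)
      if (m == 1L) {
        tk <- substr(rest, 1L, attr(m, "match.length"))
        pos <- pos + attr(m, "match.length")
        if (!nm %in% c("ws", "comment")) {
          types <- c(types, nm)
          texts <- c(texts, tk)
        }
        matched <- TRUE
        break
      }
    }
    if (!matched) stop("SPARQL: cannot tokenize near: ",
                       substr(rest, 1L, 30L), call. = FALSE)
  }
  list(type = types, text = texts)
}
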