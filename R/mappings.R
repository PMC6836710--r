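#' @title Relational-to-RDF mappings (ontology-based data access)
#'
#' @description
#' A mapping rule pairs a relational SELECT statement (the *source*) with a
#' list of triple templates (the *target*). Placeholders `{col}` in a
#' template are filled from the source's projected columns; `{fn(col)}`
#' first applies a registered, named transformation. The rules as a whole
#' induce a virtual RDF graph over the database, which can be materialized
#' or queried directly with triple-pattern pushdown.
#'
#' @name obda
NULL

# Registered named transformations (finite set). Each entry has the forward
# function and, when invertible, its inverse; inversion lets a constant in a
# query pattern be pushed down as a relational constraint.
TRANSFORMS <- list(
  uberon_local = list(
    fn = function(x) sub(":", "_", x, fixed = TRUE),
    inv = function(x) sub("_", ":", x, fixed = TRUE)
  ),
  lower = list(fn = tolower, inv = NULL),
  upper = list(fn = toupper, inv = NULL)
)

#' Map an ontology CURIE to its term IRI
#'
#' Anatomical-entity identifiers are stored as CURIEs (`UBERON:0000955`);
#' the ontology's term IRIs use `_` instead of `:` in the local name.
#'
#' @param curie identifier of the form `PREFIX:digits`.
#' @param base ontology IRI base (default: the OBO PURL base).
#' @return encoded IRI term.
#' @export
#' @examples
#' transform_uberon("UBERON:0000955")
transform_uberon <- function(curie, base = NS$obo) {
  stopifnot(is.character(curie), length(curie) >= 1L)
  if (any(!grepl(":", curie, fixed = TRUE))) {
    stop("not a CURIE (missing ':'): ", curie[!grepl(":", curie, fixed = TRUE)][1],
         call. = FALSE)
  }
  iri(paste0(base, TRANSFORMS$uberon_local$fn(curie)))
}

#' Inverse of [transform_uberon()] on the local name
#' @param local a local name such as `"UBERON_0000955"`.
#' @return the CURIE form.
#' @export
uberon_curie <- function(local) TRANSFORMS$uberon_local$inv(local)

#' Form a taxon scientific-name literal
#'
#' The scientific name is the concatenation `genus + " " + species`,
#' byte-identical to the scientific-name literals of the protein store
#' (this is the literal-level join contract for organisms).
#'
#' @param genus,species non-empty character scalars/vectors.
#' @return encoded literal term(s).
#' @export
#' @examples
#' transform_scientific_name("Homo", "sapiens")
transform_scientific_name <- function(genus, species) {
  if (any(!nzchar(genus)) || any(!nzchar(species))) {
    stop("genus and species must both be non-empty", call. = FALSE)
  }
  literal(paste(genus, species))
}

# ---- mapping file dialect ----------------------------------------------

#' Load mapping rules from a mapping document
#'
#' The dialect is block-oriented: a `[PrefixDeclaration]` section of
#' `prefix: iri` lines, then a `[MappingDeclaration]` section of blocks
#'
#' ```
#' mappingId  expressed-in
#' source     SELECT geneId, anatEntityId, stageId FROM expression
#'            WHERE callType = 'present'
#' target     gene:{geneId} genex:isExpressedIn cond:{uberon_local(anatEntityId)}-{stageId} .
#' ```
#'
#' separated by blank lines. Every `{col}`/`{fn(col)}` placeholder must be
#' a projected column of the source; transformations must be registered.
#'
#' @param text document text, or a path when `file = TRUE`.
#' @param file read `text` as a path.
#' @return list of mapping rules.
#' @export
load_mappings <- function(text, file = FALSE) {
  lines <- read_doc_lines(text, file)
  lines <- lines[!grepl("^\\s*#", lines)]
  section <- ""
  prefixes <- list()
  blocks <- list()
  cur <- NULL
  curkey <- NULL
  flush <- function() {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- NULL
    curkey <<- NULL
  }
  for (line in lines) {
    if (grepl("^\\[.*\\]", line)) {
      flush()
      section <- sub("^\\[([^]]*)\\].*$", "\\1", line)
      next
    }
    if (section == "PrefixDeclaration") {
      if (grepl("^\\s*$", line)) next
      m <- regmatches(line, regexec("^\\s*([A-Za-z][A-Za-z0-9_.-]*):\\s+(\\S+)\\s*$",
                                    line))[[1]]
      if (length(m) == 0L) stop("mapping file: malformed prefix line: ", line,
                                call. = FALSE)
      prefixes[[m[2]]] <- m[3]
    } else if (section == "MappingDeclaration") {
      if (grepl("^\\s*$", line)) { flush(); next }
      m <- regmatches(line, regexec("^(mappingId|source|target)\\s+(.*)$",
                                    line))[[1]]
      if (length(m) > 0L) {
        if (is.null(cur)) cur <- list()
        curkey <- m[2]
        cur[[curkey]] <- paste(c(cur[[curkey]], trimws(m[3])), collapse = " ")
      } else if (!is.null(curkey) && grepl("^\\s", line)) {
        cur[[curkey]] <- paste(cur[[curkey]], trimws(line))
      } else {
        stop("mapping file: unexpected line: ", line, call. = FALSE)
      }
    } else if (!grepl("^\\s*$", line)) {
      stop("mapping file: content outside a declared section: ", line,
           call. = FALSE)
    }
  }
  flush()
  rules <- lapply(blocks, function(b) {
    for (k in c("mappingId", "source", "target")) {
      if (is.null(b[[k]])) stop("mapping block missing '", k, "'",
                                call. = FALSE)
    }
    build_mapping_rule(b$mappingId, b$source, b$target, prefixes)
  })
  ids <- vapply(rules, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate mapping rule id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  rules
}

#' Construct a single mapping rule
#'
#' @param id rule identifier.
#' @param source SELECT statement text (see [parse_sql()]).
#' @param target Turtle-like template text with `{col}` placeholders.
#' @param prefixes named list of prefix expansions for the target.
#' @return a `mapping_rule` object.
#' @export
build_mapping_rule <- function(id, source, target, prefixes = list()) {
  ast <- parse_sql(source)
  proj <- sql_projection(ast)
  templates <- parse_target_templates(target, prefixes)
  for (t in templates) {
    for (slot in t) {
      if (slot$kind == "const") next
      for (part in slot$parts) {
        if (!is.null(part$col)) {
          if (!part$col %in% proj) {
            stop("mapping rule '", id, "': placeholder {", part$col,
                 "} is not a projected source column", call. = FALSE)
          }
          if (!is.null(part$fn) && !part$fn %in% names(TRANSFORMS)) {
            stop("mapping rule '", id, "': unknown transformation '",
                 part$fn, "'", call. = FALSE)
          }
        }
      }
    }
    if (t[[2]]$kind != "const") {
      stop("mapping rule '", id, "': predicate templates must be constant IRIs",
           call. = FALSE)
    }
  }
  structure(list(id = id, source = source, source_ast = ast,
                 projection = proj, targets = templates),
            class = "mapping_rule")
}

# Parse the Turtle-like target text into a list of triple templates
# (subject/predicate/object slot templates).
parse_target_templates <- function(target, prefixes) {
  toks <- tokenize_target(target)
  i <- 1L; n <- length(toks$type)
  peek <- function() if (i <= n) toks$text[i] else ""
  ttype <- function() if (i <= n) toks$type[i] else "eof"
  advance <- function() { tk <- peek(); i <<- i + 1L; tk }
  slot_of <- function() {
    type <- ttype()
    tok <- advance()
    if (type == "a") {
      return(list(kind = "const", term = iri(paste0(NS$rdf, "type"))))
    }
    if (type == "iriref") {
      return(template_slot_iri(substr(tok, 2L, nchar(tok) - 1L)))
    }
    if (type == "pname") {
      j <- regexpr(":", tok, fixed = TRUE)
      pfx <- substr(tok, 1L, j - 1L)
      base <- prefixes[[pfx]]
      if (is.null(base)) base <- NS[[pfx]]
      if (is.null(base)) stop("target template: unknown prefix '", pfx, ":'",
                              call. = FALSE)
      return(template_slot_iri(paste0(base, substr(tok, j + 1L, nchar(tok)))))
    }
    if (type == "literal") {
      m <- regmatches(tok, regexec(
        '^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(<[^>]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_]+))?$',
        tok))[[1]]
      dt <- NULL
      if (nzchar(m[3])) {
        dt <- if (startsWith(m[3], "<")) {
          substr(m[3], 2L, nchar(m[3]) - 1L)
        } else {
          j <- regexpr(":", m[3], fixed = TRUE)
          pfx <- substr(m[3], 1L, j - 1L)
          base <- prefixes[[pfx]]
          if (is.null(base)) base <- NS[[pfx]]
          if (is.null(base)) stop("target template: unknown prefix '", pfx,
                                  ":'", call. = FALSE)
          paste0(base, substr(m[3], j + 1L, nchar(m[3])))
        }
      }
      return(template_slot_literal(unescape_nt(m[2]), dt))
    }
    stop("target template: unexpected token '", tok, "'", call. = FALSE)
  }
  out <- list()
  while (i <= n) {
    s <- slot_of()
    repeat {
      p <- slot_of()
      repeat {
        o <- slot_of()
        out[[length(out) + 1L]] <- list(s, p, o)
        if (peek() == ",") { advance(); next }
        break
      }
      if (peek() == ";") {
        while (peek() == ";") advance()
        if (peek() == ".") break
        next
      }
      break
    }
    if (peek() != ".") stop("target template: expected '.'", call. = FALSE)
    advance()
  }
  out
}

tokenize_target <- function(doc) {
  pats <- c(
    ws      = "[ \t\r\n]+",
    iriref  = "<[^<> \t\r\n]*>",
    literal = '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^(?:<[^>]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_]+))?',
    a       = "a(?![A-Za-z0-9_:{-])",
    pname   = "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_{][A-Za-z0-9_.{}()%-]*",
    punct   = "[;,.]"
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
        if (nm != "ws") { types <- c(types, nm); texts <- c(texts, tk) }
        matched <- TRUE
        break
      }
    }
    if (!matched) stop("target template: cannot tokenize near: ",
                       substr(rest, 1L, 30L), call. = FALSE)
  }
  list(type = types, text = texts)
}

PLACEHOLDER_RE <- "\\{(?:([A-Za-z_][A-Za-z0-9_]*)\\()?([A-Za-z_][A-Za-z0-9_]*)\\)?\\}"

split_template_parts <- function(str) {
  parts <- list()
  pos <- 1L
  repeat {
    m <- regexpr(PLACEHOLDER_RE, substr(str, pos, nchar(str)), perl = TRUE)
    if (m == -1L) {
      if (pos <= nchar(str)) {
        parts[[length(parts) + 1L]] <- list(text = substr(str, pos, nchar(str)))
      }
      break
    }
    start <- pos + m - 1L
    if (start > pos) {
      parts[[length(parts) + 1L]] <- list(text = substr(str, pos, start - 1L))
    }
    tok <- substr(str, start, start + attr(m, "match.length") - 1L)
    g <- regmatches(tok, regexec(PLACEHOLDER_RE, tok, perl = TRUE))[[1]]
    fn <- if (nzchar(g[2])) g[2] else NULL
    if (!is.null(fn) && !grepl("\\)\\}$", tok)) {
      stop("malformed placeholder: ", tok, call. = FALSE)
    }
    parts[[length(parts) + 1L]] <- list(col = g[3], fn = fn)
    pos <- start + attr(m, "match.length")
    if (pos > nchar(str)) break
  }
  parts
}

template_slot_iri <- function(str) {
  if (!grepl("{", str, fixed = TRUE)) {
    return(list(kind = "const", term = iri(str)))
  }
  list(kind = "iri", parts = split_template_parts(str))
}

template_slot_literal <- function(str, datatype = NULL) {
  if (!grepl("{", str, fixed = TRUE)) {
    return(list(kind = "const", term = literal(str, datatype = datatype)))
  }
  list(kind = "literal", parts = split_template_parts(str),
       datatype = datatype)
}

# Expand one slot template over the rows of a source result.
# Returns encoded terms with NA where any referenced column is NULL.
expand_slot <- function(slot, rows) {
  n <- nrow(rows)
  if (slot$kind == "const") return(rep(slot$term, n))
  ok <- rep(TRUE, n)
  pieces <- lapply(slot$parts, function(part) {
    if (!is.null(part$text)) return(rep(part$text, n))
    v <- as.character(rows[[part$col]])
    ok <<- ok & !is.na(v)
    v[is.na(v)] <- ""
    if (!is.null(part$fn)) v <- TRANSFORMS[[part$fn]]$fn(v)
    if (slot$kind == "iri") v <- percent_encode(v)
    v
  })
  raw <- do.call(paste0, pieces)
  out <- rep(NA_character_, n)
  if (any(ok)) {
    out[ok] <- if (slot$kind == "iri") {
      iri(raw[ok])
    } else {
      literal(raw[ok], datatype = slot$datatype)
    }
  }
  out
}

#' Instantiate a mapping rule's templates for one row
#'
#' Templates whose placeholders hit a `NULL` (`NA`) column yield no triple
#' (skip, not error); IRI-template values are percent-encoded.
#'
#' @param rule a mapping rule from [build_mapping_rule()].
#' @param row named list/one-row data frame covering the source projection.
#' @return list of length-3 character vectors (encoded triples).
#' @export
expand_rule <- function(rule, row) {
  row <- as.data.frame(as.list(row), stringsAsFactors = FALSE)
  missing <- setdiff(needed_columns(rule), names(row))
  if (length(missing) > 0L) {
    stop("expand_rule: row is missing column '", missing[1], "'",
         call. = FALSE)
  }
  out <- list()
  for (t in rule$targets) {
    s <- expand_slot(t[[1]], row)
    p <- expand_slot(t[[2]], row)
    o <- expand_slot(t[[3]], row)
    if (!is.na(s) && !is.na(p) && !is.na(o)) {
      out[[length(out) + 1L]] <- c(s, p, o)
    }
  }
  out
}

needed_columns <- function(rule) {
  cols <- character(0)
  for (t in rule$targets) {
    for (slot in t) {
      if (slot$kind == "const") next
      for (part in slot$parts) if (!is.null(part$col)) cols <- c(cols, part$col)
    }
  }
  unique(cols)
}

# ---- virtual graph ------------------------------------------------------

#' Bind mappings to a database as a virtual RDF graph
#'
#' @param db a [rel_db()].
#' @param mappings list of mapping rules (see [load_mappings()]).
#' @param name optional graph name.
#' @return object of class `virtual_graph`.
#' @export
virtual_graph <- function(db, mappings, name = NULL) {
  stopifnot(inherits(db, "rel_db"))
  structure(list(db = db, mappings = mappings, name = name),
            class = "virtual_graph")
}

#' Materialize a virtual graph
#'
#' Runs every rule's source query and expands every template over every
#' row; the result is the set union (duplicates collapse). Deterministic
#' for a fixed database state.
#'
#' @param v a [virtual_graph()].
#' @return an [rdf_graph()].
#' @export
materialize <- function(v) {
  s <- p <- o <- character(0)
  for (rule in v$mappings) {
    rows <- tryCatch(execute_sql(v$db, rule$source_ast),
                     error = function(e) {
                       stop("mapping rule '", rule$id, "': ",
                            conditionMessage(e), call. = FALSE)
                     })
    if (nrow(rows) == 0L) next
    for (t in rule$targets) {
      sv <- expand_slot(t[[1]], rows)
      pv <- expand_slot(t[[2]], rows)
      ov <- expand_slot(t[[3]], rows)
      keep <- !is.na(sv) & !is.na(pv) & !is.na(ov)
      s <- c(s, sv[keep]); p <- c(p, pv[keep]); o <- c(o, ov[keep])
    }
  }
  rdf_graph(s, p, o, name = v$name)
}

# Attempt to invert a slot template against a constant term.
# Returns list(status = "const_ok" | "unsat" | "constraint" | "postfilter",
#              col =, value =).
invert_slot <- function(slot, const) {
  if (slot$kind == "const") {
    return(list(status = if (slot$term == const) "const_ok" else "unsat"))
  }
  if (slot$kind == "iri") {
    if (!is_iri(const)) return(list(status = "unsat"))
    target <- iri_value(const)
  } else {
    if (!is_literal(const)) return(list(status = "unsat"))
    lp <- literal_parts(const)
    dt <- if (is.null(slot$datatype)) NA_character_ else slot$datatype
    if (!identical(lp$datatype, dt) && !(is.na(lp$datatype) && is.na(dt))) {
      return(list(status = "unsat"))
    }
    if (!is.na(lp$lang)) return(list(status = "unsat"))
    target <- lp$lex
  }
  ph <- Filter(function(p) !is.null(p$col), slot$parts)
  if (length(ph) != 1L) return(list(status = "postfilter"))
  fn <- ph[[1]]$fn
  if (!is.null(fn) && is.null(TRANSFORMS[[fn]]$inv)) {
    return(list(status = "postfilter"))
  }
  # build ^text (capture) text$ regex
  rx <- paste0("^", paste(vapply(slot$parts, function(p) {
    if (!is.null(p$text)) regex_escape(p$text) else "(.*)"
  }, character(1)), collapse = ""), "$")
  m <- regmatches(target, regexec(rx, target))[[1]]
  if (length(m) == 0L) return(list(status = "unsat"))
  val <- m[2]
  if (slot$kind == "iri") val <- percent_decode(val)
  if (!is.null(fn)) val <- TRANSFORMS[[fn]]$inv(val)
  list(status = "constraint", col = ph[[1]]$col, value = val)
}

regex_escape <- function(x) {
  gsub("([.\\\\+*?\\[^\\]$(){}=!<>|:#-])", "\\\\\\1", x, perl = TRUE)
}

#' Answer a BGP query directly against the virtual graph
#'
#' For each triple pattern, every triple template of every rule is unified
#' with the pattern: constants against constant slots must match; constants
#' against template slots become relational constraints (after inverting
#' the transformation when invertible, with a post-filter fallback);
#' variable slots become column selections. Candidate bindings per pattern
#' are unioned over rules and joined on shared variables. The result equals
#' `match_bgp(materialize(v), q)`.
#'
#' @param v a [virtual_graph()].
#' @param q a [sparql_query()] without service blocks.
#' @return a solution data frame.
#' @export
answer_bgp_virtual <- function(v, q) {
  if (length(q$services) > 0L) {
    stop("answer_bgp_virtual evaluates local queries only", call. = FALSE)
  }
  sols <- unit_solutions()
  for (pat in q$bgp) {
    psol <- virtual_pattern_solutions(v, pat)
    sols <- join_solutions(sols, psol)
    if (nrow(sols) == 0L && ncol(sols) > 0L) break
  }
  finalize_solutions(sols, q)
}

virtual_pattern_solutions <- function(v, pat) {
  varmask <- is_variable(pat)
  vnames <- sub("^\\?", "", pat[varmask])
  frames <- list()
  for (rule in v$mappings) {
    for (t in rule$targets) {
      constraints <- list()
      postfilter <- integer(0)
      unsat <- FALSE
      for (k in 1:3) {
        if (varmask[k]) next
        res <- invert_slot(t[[k]], pat[k])
        if (res$status == "unsat") { unsat <- TRUE; break }
        if (res$status == "constraint") {
          constraints[[length(constraints) + 1L]] <-
            list(col = res$col, values = res$value)
        } else if (res$status == "postfilter") {
          postfilter <- c(postfilter, k)
        }
      }
      if (unsat) next
      rows <- execute_sql(v$db, rule$source_ast, extra = constraints)
      if (nrow(rows) == 0L) next
      expanded <- lapply(1:3, function(k) expand_slot(t[[k]], rows))
      keep <- !is.na(expanded[[1]]) & !is.na(expanded[[2]]) &
        !is.na(expanded[[3]])
      for (k in postfilter) keep <- keep & expanded[[k]] == pat[k]
      if (!any(keep)) next
      cols <- list()
      ok <- keep
      for (k in which(varmask)) {
        vn <- sub("^\\?", "", pat[k])
        if (!is.null(cols[[vn]])) {
          ok <- ok & cols[[vn]] == expanded[[k]]
        } else {
          cols[[vn]] <- expanded[[k]]
        }
      }
      if (!any(ok)) next
      frame <- as.data.frame(lapply(cols, function(cl) cl[ok]),
                             stringsAsFactors = FALSE, optional = TRUE)
      if (length(cols) == 0L) frame <- unit_solutions()[rep(1L, sum(ok)), ,
                                                        drop = FALSE]
      frames[[length(frames) + 1L]] <- frame
    }
  }
  uv <- unique(vnames)
  if (length(uv) == 0L) {
    # no variables in the pattern: any surviving candidate proves the triple
    if (length(frames) > 0L) return(unit_solutions())
    return(empty_solutions())
  }
  if (length(frames) == 0L) {
    return(empty_solutions(uv))
  }
  unique_rows(do.call(rbind, frames))
}
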