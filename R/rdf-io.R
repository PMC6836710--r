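#' Parse an N-Triples document
#'
#' Line-oriented parser for the N-Triples format. Full-line and trailing
#' `#` comments are tolerated; literals are re-encoded canonically.
#'
#' @param text a character scalar (whole document) or vector of lines, or a
#'   file path when `file = TRUE`.
#' @param file read `text` as a path.
#' @param name optional graph name.
#' @return an [rdf_graph()].
#' @export
parse_ntriples <- function(text, file = FALSE, name = NULL) {
  lines <- read_doc_lines(text, file)
  nt_re <- paste0(
    '^\\s*',
    '(<[^>]*>|_:[A-Za-z0-9][A-Za-z0-9_.-]*)\\s+',       # subject
    '(<[^>]*>)\\s+',                                     # predicate
    '(<[^>]*>|_:[A-Za-z0-9][A-Za-z0-9_.-]*|',            # object: iri/bnode
    '"(?:[^"\\\\]|\\\\.)*"',                             # literal
    '(?:\\^\\^<[^>]*>|@[A-Za-z]+(?:-[A-Za-z0-9]+)*)?)',  # datatype/lang
    '\\s*\\.\\s*(?:#.*)?$'
  )
  s <- p <- o <- character(0)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*(#.*)?$", line)) next
    m <- regmatches(line, regexec(nt_re, line, perl = TRUE))[[1]]
    if (length(m) == 0L) {
      stop("malformed N-Triples statement at line ", ln, ": ", trimws(line),
           call. = FALSE)
    }
    s <- c(s, recode_term(m[2], ln))
    p <- c(p, recode_term(m[3], ln))
    o <- c(o, recode_term(m[4], ln))
  }
  rdf_graph(s, p, o, name = name)
}

read_doc_lines <- function(text, file) {
  if (file) {
    readLines(text, warn = FALSE, encoding = "UTF-8")
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
}

# Validate + canonicalize a single already-delimited term.
recode_term <- function(tok, ln) {
  if (startsWith(tok, "<")) {
    val <- substr(tok, 2L, nchar(tok) - 1L)
    tryCatch(iri(val), error = function(e) {
      stop("line ", ln, ": ", conditionMessage(e), call. = FALSE)
    })
  } else if (startsWith(tok, "_:")) {
    tok
  } else {
    m <- regmatches(tok, regexec(
      '^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^<([^>]*)>|@([A-Za-z]+(?:-[A-Za-z0-9]+)*))?$',
      tok))[[1]]
    if (length(m) == 0L) stop("line ", ln, ": malformed literal ", tok,
                              call. = FALSE)
    literal(unescape_nt(m[2]),
            datatype = if (nzchar(m[3])) m[3] else NULL,
            lang = if (nzchar(m[4])) m[4] else NULL)
  }
}

#' Serialize a graph
#'
#' N-Triples output is canonical: one statement per line, sorted
#' byte-lexicographically, so equal graphs serialize to identical documents.
#' Turtle output groups statements by subject with `;` lists and uses the
#' package's common prefixes.
#'
#' @param g an [rdf_graph()].
#' @param format `"ntriples"` (canonical) or `"turtle"`.
#' @return a single character scalar (the document).
#' @export
serialize_graph <- function(g, format = c("ntriples", "turtle")) {
  if (!format[1] %in% c("ntriples", "turtle")) {
    stop("unknown serialization format: ", format[1], call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "ntriples") {
    lines <- canonical_lines(g)
    if (length(lines) == 0L) return("")
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  serialize_turtle(g)
}

serialize_turtle <- function(g) {
  if (graph_size(g) == 0L) return("")
  pfx <- unlist(NS)
  shorten <- function(t) {
    if (!is_iri(t)) return(t)
    v <- iri_value(t)
    for (nm in names(pfx)) {
      base <- pfx[[nm]]
      if (startsWith(v, base)) {
        local <- substr(v, nchar(base) + 1L, nchar(v))
        if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local)) {
          return(paste0(nm, ":", local))
        }
      }
    }
    t
  }
  df <- g$triples[order(g$triples$s, g$triples$p, g$triples$o, method = "radix"), ]
  header <- paste0("@prefix ", names(pfx), ": <", pfx, "> .")
  body <- character(0)
  for (subj in unique(df$s)) {
    rows <- df[df$s == subj, ]
    po <- vapply(seq_len(nrow(rows)), function(i) {
      p <- rows$p[i]
      pshort <- if (p == iri(paste0(NS$rdf, "type"))) "a" else shorten(p)
      paste(pshort, shorten(rows$o[i]))
    }, character(1))
    body <- c(body, paste0(shorten(subj), " ",
                           paste(po, collapse = " ;\n    "), " ."))
  }
  paste0(paste(header, collapse = "\n"), "\n\n",
         paste(body, collapse = "\n"), "\n")
}

# ---- Turtle-subset reader ----------------------------------------------

#' Parse a Turtle document (subset)
#'
#' Accepts `@prefix`/`PREFIX` declarations, prefixed names, `a`,
#' object lists (`,`) and predicate-object lists (`;`). Relative IRIs,
#' `@base`, collections and numeric/boolean shorthand are not supported.
#'
#' @inheritParams parse_ntriples
#' @return an [rdf_graph()].
#' @export
parse_turtle <- function(text, file = FALSE, name = NULL) {
  doc <- if (file) {
    paste(readLines(text, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    paste(read_doc_lines(text, FALSE), collapse = "\n")
  }
  toks <- tokenize_turtle(doc)
  prefixes <- list()
  s <- p <- o <- character(0)
  i <- 1L
  n <- length(toks$type)
  peek <- function() if (i <= n) toks$text[i] else ""
  ttype <- function() if (i <= n) toks$type[i] else "eof"
  advance <- function() {
    tk <- toks$text[i]; i <<- i + 1L; tk
  }
  expect <- function(txt) {
    if (peek() != txt) stop("Turtle parse error near token ", i,
                            " ('", peek(), "'): expected '", txt, "'",
                            call. = FALSE)
    advance()
  }
  resolve <- function(tok, type) {
    force(tok)
    if (type == "iriref") {
      tryCatch(iri(substr(tok, 2L, nchar(tok) - 1L)),
               error = function(e) stop("Turtle: ", conditionMessage(e),
                                        call. = FALSE))
    } else if (type == "pname") {
      expand_pname(tok, prefixes)
    } else if (type == "bnode") {
      tok
    } else if (type == "literal") {
      recode_term(tok, NA)
    } else {
      stop("Turtle parse error: unexpected token '", tok, "'", call. = FALSE)
    }
  }
  next_node <- function() {
    type <- ttype()
    tok <- advance()
    resolve(tok, type)
  }
  while (i <= n) {
    if (toks$type[i] == "kw_prefix") {
      at_form <- peek() == "@prefix"
      advance()
      if (ttype() != "pname_ns") stop("Turtle: expected prefix name",
                                      call. = FALSE)
      pn <- advance()
      pfx <- substr(pn, 1L, nchar(pn) - 1L)
      if (ttype() != "iriref") stop("Turtle: expected IRI in prefix declaration",
                                    call. = FALSE)
      base <- substr(peek(), 2L, nchar(peek()) - 1L); advance()
      prefixes[[pfx]] <- base
      if (at_form) expect(".")
      next
    }
    subj <- next_node()
    repeat {
      # predicate
      pr <- if (peek() == "a") {
        advance(); iri(paste0(NS$rdf, "type"))
      } else {
        next_node()
      }
      if (!is_iri(pr)) stop("Turtle: predicate must be an IRI", call. = FALSE)
      repeat {
        ob <- next_node()
        s <- c(s, subj); p <- c(p, pr); o <- c(o, ob)
        if (peek() == ",") { advance(); next }
        break
      }
      if (peek() == ";") {
        while (peek() == ";") advance()
        if (peek() == ".") break  # tolerate trailing ;
        next
      }
      break
    }
    expect(".")
  }
  rdf_graph(s, p, o, name = name)
}

tokenize_turtle <- function(doc) {
  pats <- c(
    ws       = "[ \t\r\n]+",
    comment  = "#[^\n]*",
    iriref   = "<[^<>\"{}|^`\\\\ \t\r\n]*>",
    literal  = '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^(?:<[^>]*>)|@[A-Za-z]+(?:-[A-Za-z0-9]+)*)?',
    kw_prefix = "@prefix|PREFIX",
    bnode    = "_:[A-Za-z0-9][A-Za-z0-9_.-]*",
    a_kw     = "a(?![A-Za-z0-9_:-])",
    pname_ns = "[A-Za-z][A-Za-z0-9_.-]*:(?![A-Za-z0-9_%(:-])",
    pname    = "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_.%-]*|:[A-Za-z0-9_][A-Za-z0-9_.%-]*",
    punct    = "[;,.]"
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
          types <- c(types, if (nm == "a_kw") "kw" else nm)
          texts <- c(texts, tk)
        }
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop("Turtle: cannot tokenize near: ",
           substr(rest, 1L, 30L), call. = FALSE)
    }
  }
  list(type = types, text = texts)
}
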