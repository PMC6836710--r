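#' @title RDF terms
#'
#' @description
#' Terms are interned as canonical N-Triples-encoded strings:
#' IRIs as `<iri>`, literals as `"lex"`, `"lex"@lang` or `"lex"^^<datatype>`,
#' blank nodes as `_:label`, and (in patterns only) variables as `?name`.
#' Interning makes term equality plain string equality, graphs become
#' unique-row data frames, and canonical serialization is a sort.
#'
#' @name rdf-terms
NULL

# Common namespaces used throughout the package.
NS <- list(
  rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
  xsd   = "http://www.w3.org/2001/XMLSchema#",
  owl   = "http://www.w3.org/2002/07/owl#",
  void  = "http://rdfs.org/ns/void#",
  up    = "http://purl.uniprot.org/core/",
  orth  = "http://purl.org/net/orth#",
  genex = "http://purl.org/genex#",
  obo   = "http://purl.obolibrary.org/obo/",
  lscr  = "http://purl.org/lscr#",
  taxon = "http://purl.uniprot.org/taxonomy/",
  gene  = "http://purl.example.org/vlink/gene/",
  cond  = "http://purl.example.org/vlink/condition/",
  stage = "http://purl.example.org/vlink/stage/",
  prot  = "http://purl.example.org/vlink/protein/",
  voidext = "http://purl.example.org/vlink/voidext#",
  meta  = "http://purl.example.org/vlink/metadata/"
)

escape_nt <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_nt <- function(x) {
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0); i <- 1L; n <- length(chars)
    while (i <= n) {
      ch <- chars[i]
      if (ch == "\\" && i < n) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t", "\"" = "\"", "\\" = "\\",
          stop("invalid escape sequence: \\", nxt, call. = FALSE)))
        i <- i + 2L
      } else {
        out <- c(out, ch); i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct an IRI term
#'
#' IRIs must be absolute (have a scheme) and contain no whitespace or
#' characters forbidden in N-Triples IRI references.
#'
#' @param x character vector of absolute IRI strings (without angle brackets).
#' @return encoded term vector.
#' @export
#' @examples
#' iri("http://purl.uniprot.org/taxonomy/9606")
iri <- function(x) {
  stopifnot(is.character(x))
  bad <- !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)
  if (any(bad)) {
    stop("relative or schemeless IRI: ", x[bad][1], call. = FALSE)
  }
  bad <- grepl("[\x01-\x20<>\"{}|^`\\\\]", x)
  if (any(bad)) {
    stop("IRI contains forbidden character: ", x[bad][1], call. = FALSE)
  }
  paste0("<", x, ">")
}

#' Construct a literal term
#'
#' @param lex lexical form (character vector).
#' @param datatype optional datatype IRI string (not encoded). Plain
#'   `xsd:string` is the implicit default and is stored without a datatype.
#' @param lang optional BCP47-ish language tag; mutually exclusive with
#'   `datatype`.
#' @return encoded term vector.
#' @export
literal <- function(lex, datatype = NULL, lang = NULL) {
  stopifnot(is.character(lex))
  if (!is.null(datatype) && !is.null(lang)) {
    stop("a literal cannot carry both a datatype and a language tag", call. = FALSE)
  }
  out <- paste0("\"", escape_nt(lex), "\"")
  if (!is.null(lang)) {
    if (!grepl("^[A-Za-z]+(-[A-Za-z0-9]+)*$", lang)) {
      stop("invalid language tag: ", lang, call. = FALSE)
    }
    out <- paste0(out, "@", lang)
  } else if (!is.null(datatype) && datatype != paste0(NS$xsd, "string")) {
    out <- paste0(out, "^^", iri(datatype))
  }
  out
}

#' Construct a blank node term
#'
#' @param label local blank node label.
#' @return encoded term vector.
#' @export
bnode <- function(label) {
  stopifnot(is.character(label))
  if (any(!grepl("^[A-Za-z0-9][A-Za-z0-9_.-]*$", label))) {
    stop("invalid blank node label", call. = FALSE)
  }
  paste0("_:", label)
}

#' Term kind predicates and accessors
#'
#' @param x encoded term vector.
#' @return logical vector / decoded component.
#' @name term-accessors
NULL

#' @rdname term-accessors
#' @export
is_iri <- function(x) startsWith(x, "<")

#' @rdname term-accessors
#' @export
is_literal <- function(x) startsWith(x, "\"")

#' @rdname term-accessors
#' @export
is_bnode <- function(x) startsWith(x, "_:")

#' @rdname term-accessors
#' @export
is_variable <- function(x) startsWith(x, "?")

#' @rdname term-accessors
#' @export
iri_value <- function(x) {
  stopifnot(all(is_iri(x)))
  substr(x, 2L, nchar(x) - 1L)
}

#' Decompose a literal term
#'
#' @param x a single encoded literal term.
#' @return list with `lex`, `datatype` (IRI string or NA), `lang` (or NA).
#' @export
literal_parts <- function(x) {
  stopifnot(length(x) == 1L, is_literal(x))
  m <- regmatches(x, regexec(
    '^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^<([^>]*)>|@([A-Za-z]+(?:-[A-Za-z0-9]+)*))?$',
    x))[[1]]
  if (length(m) == 0L) stop("malformed literal: ", x, call. = FALSE)
  list(
    lex = unescape_nt(m[2]),
    datatype = if (nzchar(m[3])) m[3] else NA_character_,
    lang = if (nzchar(m[4])) m[4] else NA_character_
  )
}

#' Lexical value used for comparisons
#'
#' Literals compare on their lexical form, IRIs on the IRI string, blank
#' nodes on the label.
#'
#' @param x encoded term vector.
#' @return character vector of comparison keys.
#' @export
term_value <- function(x) {
  out <- x
  li <- is_literal(x)
  if (any(li)) {
    out[li] <- vapply(x[li], function(t) literal_parts(t)$lex, character(1),
                      USE.NAMES = FALSE)
  }
  ir <- is_iri(x)
  out[ir] <- substr(x[ir], 2L, nchar(x[ir]) - 1L)
  bn <- is_bnode(x)
  out[bn] <- substr(x[bn], 3L, nchar(x[bn]))
  out
}

# Percent-encode a value for use inside an IRI template. Conservative
# RFC 3986 unreserved set plus a few safe IRI path characters.
percent_encode <- function(x) {
  safe <- grepl("^[A-Za-z0-9_.~:-]*$", x)
  if (all(safe)) return(x)
  x[!safe] <- percent_encode_slow(x[!safe])
  x
}

percent_encode_slow <- function(x) {
  vapply(x, function(s) {
    if (grepl("^[A-Za-z0-9_.~:-]*$", s)) return(s)
    raw <- charToRaw(enc2utf8(s))
    keep <- rawToChar(raw, multiple = TRUE) %in%
      c(letters, LETTERS, as.character(0:9), "_", ".", "~", "-", ":")
    enc <- toupper(as.character(raw))
    paste(ifelse(keep, rawToChar(raw, multiple = TRUE), paste0("%", enc)),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

percent_decode <- function(x) utils::URLdecode(x)

# Expand a prefixed name against a prefix map; errors on unknown prefix.
expand_pname <- function(pname, prefixes) {
  i <- regexpr(":", pname, fixed = TRUE)
  pfx <- substr(pname, 1L, i - 1L)
  local <- substr(pname, i + 1L, nchar(pname))
  base <- prefixes[[pfx]]
  if (is.null(base)) stop("unknown prefix: '", pfx, ":'", call. = FALSE)
  iri(paste0(base, local))
}

default_prefixes <- function() {
  c(NS, list(xsd = NS$xsd))
}
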