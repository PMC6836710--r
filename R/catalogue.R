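#' @title Natural-language query templates
#'
#' @description
#' The application layer: a catalogue of representative federated queries
#' in plain English with editable parameter slots, each paired with the
#' equivalent SPARQL-subset text. Slots are named placeholders (`{slot}`)
#' shared between the sentence and the query; rendering escapes values by
#' slot kind (labels and keywords become quoted literals, ontology terms
#' must be IRIs) so user input cannot change the query shape.
#'
#' @name catalogue
NULL

SLOT_KINDS <- c("gene_label", "keyword", "taxon", "anatomical_entity",
                "stage", "clade")
IRI_SLOT_KINDS <- c("taxon", "anatomical_entity", "stage", "clade")

TEMPLATE_SLOT_RE <- "\\{([A-Za-z_][A-Za-z0-9_]*)\\}"

template_placeholders <- function(text) {
  m <- gregexpr(TEMPLATE_SLOT_RE, text, perl = TRUE)
  unique(sub("^\\{", "", sub("\\}$", "", unlist(regmatches(text, m)))))
}

#' Load a query-template catalogue
#'
#' @param path YAML catalogue file (or a YAML string with `text = TRUE`).
#' @param text treat `path` as YAML text.
#' @return list of `query_template` objects.
#' @export
load_catalogue <- function(path, text = FALSE) {
  raw <- if (text) yaml::yaml.load(path) else yaml::read_yaml(path)
  if (length(raw) == 0L) return(list())
  lapply(raw, function(entry) {
    for (k in c("id", "nl", "sparql")) {
      if (is.null(entry[[k]])) {
        stop("catalogue entry missing field '", k, "'", call. = FALSE)
      }
    }
    slots <- lapply(entry$slots, function(s) {
      if (is.null(s$name) || is.null(s$kind) || is.null(s$default)) {
        stop("template ", entry$id,
             ": slots need name, kind and default", call. = FALSE)
      }
      if (!s$kind %in% SLOT_KINDS) {
        stop("template ", entry$id, ": unknown slot kind '", s$kind, "'",
             call. = FALSE)
      }
      s
    })
    declared <- vapply(slots, `[[`, "", "name")
    in_nl <- template_placeholders(entry$nl)
    in_q <- template_placeholders(entry$sparql)
    if (!setequal(declared, in_nl) || !setequal(declared, in_q)) {
      stop("template ", entry$id, ": slot mismatch between declaration (",
           paste(declared, collapse = ","), "), sentence (",
           paste(in_nl, collapse = ","), ") and query (",
           paste(in_q, collapse = ","), ")", call. = FALSE)
    }
    structure(list(id = entry$id, nl = entry$nl, sparql = entry$sparql,
                   slots = slots, tags = unlist(entry$tags) %||% character(0),
                   group = entry$group %||% NA_character_,
                   cost = entry$cost %||% "fast"),
              class = "query_template")
  })
}

#' @export
print.query_template <- function(x, ...) {
  cat("<query_template>", x$id, "-", x$nl, "\n")
  invisible(x)
}

escape_slot_value <- function(value, kind) {
  value <- as.character(value)
  if (kind %in% IRI_SLOT_KINDS) {
    # validates; errors on non-IRI input
    return(iri(value))
  }
  literal(value)
}

#' Render a template into an executable query
#'
#' Missing parameters fall back to the slot defaults. A default result
#' limit is attached unless the caller turns limiting off.
#'
#' @param t a `query_template`.
#' @param params named list of slot values (plain strings; IRI-kind slots
#'   take plain IRI strings).
#' @param default_limit limit attached when the query text has none.
#' @param no_limit disable result limiting.
#' @return a [sparql_query()].
#' @export
render_template <- function(t, params = list(), default_limit = 1000L,
                            no_limit = FALSE) {
  text <- t$sparql
  for (s in t$slots) {
    value <- params[[s$name]] %||% s$default
    enc <- escape_slot_value(value, s$kind)
    text <- gsub(paste0("{", s$name, "}"), enc, text, fixed = TRUE)
  }
  q <- parse_query(text)
  if (is.null(q$limit) && !no_limit) {
    q$limit <- as.integer(default_limit)
  }
  q
}

#' Render the natural-language sentence with parameter values
#'
#' @inheritParams render_template
#' @return character scalar.
#' @export
render_sentence <- function(t, params = list()) {
  text <- t$nl
  for (s in t$slots) {
    value <- params[[s$name]] %||% s$default
    text <- gsub(paste0("{", s$name, "}"), as.character(value), text,
                 fixed = TRUE)
  }
  text
}

#' Filter templates by keyword
#'
#' Case-insensitive substring match over the sentence and the tags.
#'
#' @param catalogue list of templates from [load_catalogue()].
#' @param keyword search string; the empty string matches everything.
#' @return the matching sub-list.
#' @export
search_templates <- function(catalogue, keyword) {
  if (!nzchar(keyword)) return(catalogue)
  kw <- tolower(keyword)
  Filter(function(t) {
    grepl(kw, tolower(t$nl), fixed = TRUE) ||
      any(grepl(kw, tolower(t$tags), fixed = TRUE))
  }, catalogue)
}

#' Path of the catalogue shipped with the package
#' @return file path.
#' @export
default_catalogue_path <- function() {
  system.file("extdata", "catalogue.yaml", package = "vlink", mustWork = TRUE)
}
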