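#' Solution sets
#'
#' A solution set is a data frame whose columns are variable names and whose
#' cells are encoded terms; each row is one solution mapping. The row order
#' is unspecified — compare with [solutions_equal()].
#'
#' @name solution-sets
NULL

# The algebraic identity: a single empty solution mapping (join unit).
unit_solutions <- function() {
  as.data.frame(matrix(nrow = 1L, ncol = 0L))
}

empty_solutions <- function(vars = character()) {
  df <- as.data.frame(matrix(character(0), nrow = 0L, ncol = length(vars)),
                      stringsAsFactors = FALSE)
  names(df) <- vars
  df
}

#' Multiset equality of two solution sets
#'
#' @param a,b data frames of solutions.
#' @return `TRUE` iff both have the same columns and the same rows with the
#'   same multiplicities (row order ignored).
#' @export
solutions_equal <- function(a, b) {
  if (!setequal(names(a), names(b))) return(FALSE)
  if (nrow(a) != nrow(b)) return(FALSE)
  if (nrow(a) == 0L) return(TRUE)
  cols <- sort(names(a))
  key <- function(df) {
    if (length(cols) == 0L) return(rep("", nrow(df)))
    sort(do.call(paste, c(df[cols], sep = "")), method = "radix")
  }
  identical(key(a), key(b))
}

# Inner natural join of two solution frames; cross join when no shared
# vars. Hand-rolled (match/split index join over plain column vectors):
# merge()'s row-name bookkeeping dominates runtime on wide intermediate
# results.
join_solutions <- function(a, b) {
  if (ncol(a) == 0L) {
    if (nrow(a) == 0L) return(b[0L, , drop = FALSE])
    return(b)
  }
  if (ncol(b) == 0L) {
    if (nrow(b) == 0L) return(a[0L, , drop = FALSE])
    return(a)
  }
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) {
    ia <- rep(seq_len(nrow(a)), each = nrow(b))
    jb <- rep(seq_len(nrow(b)), times = nrow(a))
  } else {
    ka <- do.call(paste, c(a[shared], list(sep = "\r")))
    kb <- do.call(paste, c(b[shared], list(sep = "\r")))
    ub <- unique(kb)
    grp <- split(seq_len(nrow(b)),
                 factor(match(kb, ub), levels = seq_along(ub)))
    m <- grp[match(ka, ub)]
    ia <- rep(seq_len(nrow(a)), lengths(m))
    jb <- unlist(m, use.names = FALSE)
    if (is.null(jb)) jb <- integer(0)
  }
  cols <- c(lapply(a, `[`, ia),
            lapply(b[setdiff(names(b), shared)], `[`, jb))
  out <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  names(out) <- c(names(a), setdiff(names(b), shared))
  out
}

# Match one triple pattern against a triple frame; returns a solution frame
# over the pattern's variables (unique rows, since the graph is a set).
match_pattern <- function(triples, pat) {
  keep <- rep(TRUE, nrow(triples))
  slots <- c("s", "p", "o")
  for (k in 1:3) {
    if (!is_variable(pat[k])) keep <- keep & (triples[[slots[k]]] == pat[k])
  }
  rows <- triples[keep, , drop = FALSE]
  varmask <- is_variable(pat)
  if (!any(varmask)) {
    if (nrow(rows) > 0L) return(unit_solutions())
    return(empty_solutions())
  }
  vnames <- sub("^\\?", "", pat[varmask])
  vslots <- slots[varmask]
  if (anyDuplicated(vnames)) {
    # repeated variable within the pattern: enforce slot equality
    for (v in unique(vnames[duplicated(vnames)])) {
      sl <- vslots[vnames == v]
      for (j in seq_along(sl)[-1]) {
        rows <- rows[rows[[sl[1]]] == rows[[sl[j]]], , drop = FALSE]
      }
    }
  }
  first <- !duplicated(vnames)
  out <- rows[, vslots[first], drop = FALSE]
  names(out) <- vnames[first]
  unique_rows(out)
}

unique_rows <- function(df) {
  out <- unique(df)
  rownames(out) <- NULL
  out
}

#' Evaluate a BGP query against a single graph
#'
#' Pattern-at-a-time evaluation with natural joins; filters, DISTINCT and
#' LIMIT applied afterwards; the result is projected to the query's
#' variables. Used directly as the in-memory store and as the correctness
#' oracle for the OBDA and federation engines.
#'
#' @param g an [rdf_graph()].
#' @param q a [sparql_query()] without service blocks (service blocks are
#'   refused: a single graph has no endpoints).
#' @return a solution data frame (see [solution-sets]).
#' @export
match_bgp <- function(g, q) {
  if (length(q$services) > 0L) {
    stop("match_bgp evaluates local queries only (query has SERVICE blocks)",
         call. = FALSE)
  }
  sols <- unit_solutions()
  for (pat in q$bgp) {
    psol <- match_pattern(g$triples, pat)
    sols <- join_solutions(sols, psol)
    if (nrow(sols) == 0L && ncol(sols) > 0L) break
  }
  finalize_solutions(sols, q)
}

# Shared tail of query evaluation: VALUES join, filters, distinct, limit,
# projection.
finalize_solutions <- function(sols, q) {
  if (!is.null(q$values) && ncol(q$values) > 0L) {
    sols <- join_solutions(sols, unique_rows(q$values))
  }
  for (f in q$filters) {
    if (!f$var %in% names(sols)) next
    sols <- sols[eval_filter(f, sols), , drop = FALSE]
  }
  proj <- intersect(q$vars, names(sols))
  sols <- sols[, proj, drop = FALSE]
  missing <- setdiff(q$vars, proj)
  for (v in missing) sols[[v]] <- rep(NA_character_, nrow(sols))
  sols <- sols[, q$vars, drop = FALSE]
  if (q$distinct) sols <- unique_rows(sols)
  if (!is.null(q$limit)) sols <- utils::head(sols, q$limit)
  rownames(sols) <- NULL
  sols
}

# Evaluate one filter over a solution frame -> logical vector.
eval_filter <- function(f, sols) {
  lhs <- sols[[f$var]]
  if (f$op == "contains") {
    ok <- is_literal(lhs) &
      grepl(tolower(f$value), tolower(term_value(lhs)), fixed = TRUE)
    return(ok & !is.na(lhs))
  }
  rhs <- if (is_variable(f$value)) {
    v <- sub("^\\?", "", f$value)
    if (!v %in% names(sols)) return(rep(FALSE, nrow(sols)))
    sols[[v]]
  } else {
    rep(f$value, length(lhs))
  }
  lv <- term_value(lhs)
  rv <- term_value(rhs)
  ln <- suppressWarnings(as.numeric(lv))
  rn <- suppressWarnings(as.numeric(rv))
  num <- !is.na(ln) & !is.na(rn)
  out <- logical(length(lv))
  cmp <- function(a, b, op) switch(op,
    "=" = a == b, "!=" = a != b, "<" = a < b, ">" = a > b)
  if (f$op %in% c("=", "!=")) {
    # term equality, except numeric literals compare by value
    out <- cmp(lhs, rhs, f$op)
    out[num] <- cmp(ln[num], rn[num], f$op)
  } else {
    out[num] <- cmp(ln[num], rn[num], f$op)
    out[!num] <- cmp(lv[!num], rv[!num], f$op)
  }
  out & !is.na(out)
}
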