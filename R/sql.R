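#' An embedded relational database
#'
#' Tables are plain data frames held in memory; `NA` plays the role of SQL
#' `NULL`. The ANSI-subset SELECT interpreter below is the execution target
#' of the relational-to-RDF mapping engine.
#'
#' @param tables named list of data frames.
#' @return object of class `rel_db`.
#' @export
rel_db <- function(tables = list()) {
  stopifnot(is.list(tables))
  if (length(tables) > 0L) {
    stopifnot(!is.null(names(tables)), all(nzchar(names(tables))))
    lapply(tables, function(t) stopifnot(is.data.frame(t)))
  }
  structure(list(tables = tables), class = "rel_db")
}

#' @export
print.rel_db <- function(x, ...) {
  cat("<rel_db>", length(x$tables), "tables\n")
  for (nm in names(x$tables)) {
    cat("  ", nm, ": ", nrow(x$tables[[nm]]), " rows (",
        paste(names(x$tables[[nm]]), collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Parse an ANSI-subset SELECT statement
#'
#' Supports `SELECT [DISTINCT] cols FROM t [JOIN t2 ON a = b ...]`
#' `[WHERE cond [AND cond ...]]` with conditions `col = value`,
#' `col <> value`, `col IS [NOT] NULL`; column references may be qualified
#' (`table.col`) and aliased (`AS alias`).
#'
#' @param sql the statement text.
#' @return a parsed statement (list) for [execute_sql()].
#' @export
parse_sql <- function(sql) {
  toks <- tokenize_sql(sql)
  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[i] else ""
  kw <- function() toupper(peek())
  advance <- function() { tk <- peek(); i <<- i + 1L; tk }
  expect_kw <- function(w) {
    if (kw() != w) stop("SQL parse error: expected ", w, " near '", peek(),
                        "'", call. = FALSE)
    advance()
  }
  expect_kw("SELECT")
  distinct <- FALSE
  if (kw() == "DISTINCT") { distinct <- TRUE; advance() }
  cols <- list()
  repeat {
    ref <- advance()
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*(\\.[A-Za-z_][A-Za-z0-9_]*)?$", ref)) {
      stop("SQL: invalid column reference '", ref, "'", call. = FALSE)
    }
    alias <- if (kw() == "AS") { advance(); advance() } else {
      sub("^.*\\.", "", ref)
    }
    cols[[length(cols) + 1L]] <- list(ref = ref, alias = alias)
    if (peek() == ",") { advance(); next }
    break
  }
  expect_kw("FROM")
  from <- advance()
  joins <- list()
  while (kw() %in% c("JOIN", "INNER", "LEFT")) {
    if (kw() == "LEFT") stop("SQL: only inner joins are supported",
                             call. = FALSE)
    if (kw() == "INNER") advance()
    expect_kw("JOIN")
    tbl <- advance()
    expect_kw("ON")
    lhs <- advance()
    if (advance() != "=") stop("SQL: JOIN ... ON expects an equality",
                               call. = FALSE)
    rhs <- advance()
    joins[[length(joins) + 1L]] <- list(table = tbl, lhs = lhs, rhs = rhs)
  }
  where <- list()
  if (kw() == "WHERE") {
    advance()
    repeat {
      lhs <- advance()
      if (kw() == "IS") {
        advance()
        neg <- FALSE
        if (kw() == "NOT") { neg <- TRUE; advance() }
        expect_kw("NULL")
        where[[length(where) + 1L]] <-
          list(op = if (neg) "notnull" else "isnull", lhs = lhs)
      } else {
        op <- advance()
        if (!op %in% c("=", "<>", "!=")) {
          stop("SQL: unsupported operator '", op, "'", call. = FALSE)
        }
        rhs <- advance()
        where[[length(where) + 1L]] <-
          list(op = if (op == "=") "=" else "!=", lhs = lhs, rhs = rhs)
      }
      if (kw() == "AND") { advance(); next }
      break
    }
  }
  if (i <= n) stop("SQL: trailing content near '", peek(), "'", call. = FALSE)
  list(distinct = distinct, cols = cols, from = from, joins = joins,
       where = where)
}

tokenize_sql <- function(sql) {
  sql <- gsub("[ \t\r\n]+", " ", sql)
  pat <- paste0(
    "'(?:[^']|'')*'",                                    # string literal
    "|[A-Za-z_][A-Za-z0-9_]*(?:\\.[A-Za-z_][A-Za-z0-9_]*)?", # identifier
    "|[0-9]+(?:\\.[0-9]+)?",                              # number
    "|<>|!=|=|,|\\(|\\)"
  )
  m <- gregexpr(pat, sql, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("SQL: empty statement", call. = FALSE)
  toks <- regmatches(sql, gregexpr(pat, sql, perl = TRUE))[[1]]
  rest <- gsub(pat, " ", sql, perl = TRUE)
  if (grepl("[^ ]", rest)) {
    stop("SQL: cannot tokenize near '",
         trimws(sub("^ *", "", rest)), "'", call. = FALSE)
  }
  toks
}

#' Execute a parsed SELECT against an embedded database
#'
#' @param db a [rel_db()].
#' @param ast a statement from [parse_sql()] (or a statement string).
#' @param extra optional list of extra equality constraints pushed down by
#'   the OBDA rewriter: each `list(col = <output column>, values = <character
#'   vector>)` keeps only rows whose column is in `values`.
#' @return data frame with one column per selected output column.
#' @export
execute_sql <- function(db, ast, extra = list()) {
  if (is.character(ast)) ast <- parse_sql(ast)
  tabs <- c(ast$from, vapply(ast$joins, `[[`, "", "table"))
  for (t in tabs) {
    if (!t %in% names(db$tables)) stop("SQL: unknown table '", t, "'",
                                       call. = FALSE)
  }
  qualify <- function(tbl) {
    df <- db$tables[[tbl]]
    names(df) <- paste0(tbl, ".", names(df))
    df
  }
  work <- qualify(ast$from)
  resolve <- function(ref, cols) {
    if (grepl(".", ref, fixed = TRUE)) {
      if (!ref %in% cols) stop("SQL: unknown column '", ref, "'",
                               call. = FALSE)
      return(ref)
    }
    hits <- cols[sub("^[^.]*\\.", "", cols) == ref]
    if (length(hits) == 0L) stop("SQL: unknown column '", ref, "'",
                                 call. = FALSE)
    if (length(hits) > 1L) stop("SQL: ambiguous column '", ref, "'",
                                call. = FALSE)
    hits
  }
  for (j in ast$joins) {
    right <- qualify(j$table)
    lref <- resolve(j$lhs, c(names(work), names(right)))
    rref <- resolve(j$rhs, c(names(work), names(right)))
    if (lref %in% names(right) && rref %in% names(work)) {
      tmp <- lref; lref <- rref; rref <- tmp
    }
    work <- merge(work, right, by.x = lref, by.y = rref, sort = FALSE)
    # merge drops the by.y column; restore it under its qualified name
    work[[rref]] <- work[[lref]]
  }
  is_str <- function(x) grepl("^'.*'$", x)
  unquote <- function(x) gsub("''", "'", substr(x, 2L, nchar(x) - 1L))
  for (w in ast$where) {
    col <- resolve(w$lhs, names(work))
    v <- work[[col]]
    keep <- switch(w$op,
      isnull = is.na(v),
      notnull = !is.na(v),
      {
        rhs <- if (is_str(w$rhs)) unquote(w$rhs) else w$rhs
        r <- if (w$op == "=") v == rhs else v != rhs
        r & !is.na(r)
      })
    work <- work[keep, , drop = FALSE]
  }
  out <- data.frame(row.names = seq_len(nrow(work)))
  for (c_ in ast$cols) {
    ref <- resolve(c_$ref, names(work))
    out[[c_$alias]] <- work[[ref]]
  }
  if (ast$distinct) out <- unique(out)
  for (ex in extra) {
    if (!ex$col %in% names(out)) {
      stop("SQL: pushdown constraint on unprojected column '", ex$col, "'",
           call. = FALSE)
    }
    v <- out[[ex$col]]
    out <- out[!is.na(v) & v %in% ex$values, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Projected output column names of a parsed statement
#' @param ast result of [parse_sql()].
#' @return character vector of aliases.
#' @export
sql_projection <- function(ast) {
  vapply(ast$cols, `[[`, "", "alias")
}

#' Serialize a database as a plain-text SQL dump
#'
#' Deterministic: tables in name order, `CREATE TABLE` followed by one
#' `INSERT` per row in stored row order. Used for the byte-identical
#' reproducibility contract of the fixture generator.
#'
#' @param db a [rel_db()].
#' @return character scalar (the dump document).
#' @export
db_dump_sql <- function(db) {
  esc <- function(x) {
    ifelse(is.na(x), "NULL", paste0("'", gsub("'", "''", as.character(x)), "'"))
  }
  out <- character(0)
  for (nm in sort(names(db$tables), method = "radix")) {
    df <- db$tables[[nm]]
    df[] <- lapply(df, as.character)
    out <- c(out, paste0("CREATE TABLE ", nm, " (",
                         paste(names(df), "TEXT", collapse = ", "), ");"))
    if (nrow(df) > 0L) {
      vals <- apply(df, 1L, function(r) paste(esc(r), collapse = ", "))
      out <- c(out, paste0("INSERT INTO ", nm, " (",
                           paste(names(df), collapse = ", "),
                           ") VALUES (", vals, ");"))
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
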