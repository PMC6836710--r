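# Independent oracles used by the property tests. They deliberately share
# no code with the engines they check.

# Exhaustive BGP evaluation: enumerate every assignment of graph terms to
# the query's variables and keep those under which every pattern is a
# triple of the graph. Only feasible on tiny graphs / few variables.
exhaustive_answers <- function(g, q) {
  vars <- query_variables(q)
  terms <- unique(c(g$triples$s, g$triples$p, g$triples$o))
  if (length(vars) == 0L) stop("exhaustive oracle needs variables")
  grid <- expand.grid(rep(list(terms), length(vars)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  keep <- rep(TRUE, nrow(grid))
  for (pat in q$bgp) {
    slot <- function(x) {
      if (is_variable(x)) grid[[sub("^[?]", "", x)]] else rep(x, nrow(grid))
    }
    keep <- keep & graph_contains(g, slot(pat[1]), slot(pat[2]), slot(pat[3]))
  }
  sols <- grid[keep, q$vars, drop = FALSE]
  rownames(sols) <- NULL
  sols
}

# Random small graphs for round-trip and evaluator properties.
random_graph <- function(n_triples = 15L, n_nodes = 8L, n_preds = 4L) {
  nodes <- iri(paste0("http://example.org/node/", seq_len(n_nodes)))
  preds <- iri(paste0("http://example.org/pred/", seq_len(n_preds)))
  lits <- c(literal(c("alpha", "beta", "10", "2.5")),
            literal("gamma", lang = "en"),
            literal("42", datatype = "http://www.w3.org/2001/XMLSchema#integer"))
  s <- sample(nodes, n_triples, replace = TRUE)
  p <- sample(preds, n_triples, replace = TRUE)
  o <- sample(c(nodes, lits), n_triples, replace = TRUE)
  rdf_graph(s, p, o)
}

# Brute-force lowest-common-ancestor classification of every leaf pair of
# a HOG, via root-to-leaf position paths (independent of the recursive
# cross-product derivation in the package).
lca_oracle_pairs <- function(h) {
  events <- list()
  paths <- list()
  taxa <- list()
  walk <- function(node, path) {
    if (inherits(node, "hog_leaf")) {
      paths[[node$gene]] <<- path
      taxa[[node$gene]] <<- node$taxon
      return(invisible(NULL))
    }
    id <- paste0("n", paste(path, collapse = "."))
    events[[id]] <<- node$event
    for (i in seq_along(node$children)) walk(node$children[[i]], c(path, i))
  }
  walk(h, integer(0))
  genes <- names(paths)
  if (length(genes) < 2L) {
    return(data.frame(geneA = character(), geneB = character(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (i in seq_along(genes)[-1]) {
    for (j in seq_len(i - 1L)) {
      pa <- paths[[genes[j]]]; pb <- paths[[genes[i]]]
      k <- 0L
      while (k < min(length(pa), length(pb)) && pa[k + 1L] == pb[k + 1L]) {
        k <- k + 1L
      }
      ev <- events[[paste0("n", paste(pa[seq_len(k)], collapse = "."))]]
      a <- sort(c(genes[j], genes[i]), method = "radix")
      out[[length(out) + 1L]] <- data.frame(
        geneA = a[1], geneB = a[2],
        relation = if (ev == "speciation") "ortholog" else "paralog",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Random valid HOG over <= max_leaves leaves: speciation nodes partition
# taxa disjointly, duplications split genes arbitrarily.
random_hog <- function(max_leaves = 12L, taxa_pool = 5L) {
  n <- sample(seq_len(max_leaves), 1L)
  genes <- iri(paste0("http://example.org/gene/", sample(1e6, n)))
  taxa <- iri(paste0("http://example.org/taxon/",
                     sample(seq_len(taxa_pool), n, replace = TRUE)))
  build <- function(idx) {
    if (length(idx) == 1L) return(hog_leaf(genes[idx], taxa[idx]))
    utaxa <- unique(taxa[idx])
    speciation_ok <- length(utaxa) >= 2L
    if (speciation_ok && stats::runif(1) < 0.6) {
      grp <- sample(c(1L, 2L), length(utaxa), replace = TRUE)
      if (length(unique(grp)) == 1L) grp[1L] <- 3L - grp[1L]
      sideA <- idx[taxa[idx] %in% utaxa[grp == 1L]]
      sideB <- idx[taxa[idx] %in% utaxa[grp == 2L]]
      return(hog_node("speciation", list(build(sideA), build(sideB)),
                      taxon = iri("http://example.org/taxon/anc")))
    }
    grp <- sample(c(1L, 2L), length(idx), replace = TRUE)
    if (length(unique(grp)) == 1L) grp[1L] <- 3L - grp[1L]
    hog_node("duplication", list(build(idx[grp == 1L]),
                                 build(idx[grp == 2L])))
  }
  if (n == 1L) return(hog_leaf(genes, taxa))
  build(seq_len(n))
}

normalize_pairs <- function(df) {
  df <- df[, c("geneA", "geneB", "relation")]
  df <- df[order(df$geneA, df$geneB, method = "radix"), ]
  rownames(df) <- NULL
  df
}
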