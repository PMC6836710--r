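#' @title Hierarchical orthologous groups (HOGs)
#'
#' @description
#' A HOG is a tree: internal nodes carry an evolutionary event — a
#' speciation (labelled with the taxon of the ancestral species) or a
#' duplication — and leaves carry a gene with its taxon. Pairwise homology
#' falls out of the tree shape: two genes are orthologs when their lowest
#' common ancestor is a speciation, paralogs when it is a duplication.
#'
#' @name hogs
NULL

#' Construct a HOG internal node
#'
#' @param event `"speciation"` or `"duplication"`.
#' @param children list of child nodes ([hog_node()] or [hog_leaf()]).
#' @param taxon taxon IRI term of the ancestral species (speciation nodes).
#' @return a `hog_node`.
#' @export
hog_node <- function(event = c("speciation", "duplication"), children,
                     taxon = NULL) {
  event <- match.arg(event)
  stopifnot(is.list(children), length(children) >= 1L)
  if (event == "speciation" && !is.null(taxon)) stopifnot(is_iri(taxon))
  structure(list(event = event, taxon = taxon, children = children),
            class = "hog_node")
}

#' Construct a HOG leaf (an extant gene)
#'
#' @param gene gene IRI term.
#' @param taxon taxon IRI term of the gene's species.
#' @return a `hog_leaf`.
#' @export
hog_leaf <- function(gene, taxon) {
  stopifnot(is_iri(gene), is_iri(taxon))
  structure(list(gene = gene, taxon = taxon), class = "hog_leaf")
}

is_leaf <- function(x) inherits(x, "hog_leaf")

#' All leaves of a HOG
#' @param h a HOG node.
#' @return data frame with columns `gene`, `taxon`.
#' @export
hog_leaves <- function(h) {
  if (is_leaf(h)) {
    return(data.frame(gene = h$gene, taxon = h$taxon,
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(h$children, hog_leaves))
}

#' Validate HOG invariants
#'
#' Checks that no gene occurs in more than one leaf and that the children
#' of every speciation node cover pairwise disjoint taxon sets (a
#' speciation separates lineages; the same species cannot sit on both
#' sides, whereas duplication children may share taxa).
#'
#' @param h a HOG node.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_hog <- function(h) {
  lv <- hog_leaves(h)
  if (anyDuplicated(lv$gene)) {
    stop("gene occurs in more than one HOG leaf: ",
         lv$gene[duplicated(lv$gene)][1], call. = FALSE)
  }
  walk <- function(node) {
    if (is_leaf(node)) return(invisible(NULL))
    if (node$event == "speciation" && length(node$children) > 1L) {
      sets <- lapply(node$children, function(ch) unique(hog_leaves(ch)$taxon))
      for (i in seq_along(sets)[-1]) {
        for (j in seq_len(i - 1L)) {
          shared <- intersect(sets[[i]], sets[[j]])
          if (length(shared) > 0L) {
            stop("speciation node has the same taxon on two branches: ",
                 shared[1], call. = FALSE)
          }
        }
      }
    }
    lapply(node$children, walk)
    invisible(NULL)
  }
  walk(h)
  invisible(TRUE)
}

#' Derive pairwise ortholog/paralog relations from a HOG
#'
#' Every unordered pair of leaves is classified exactly once, by the event
#' at the pair's lowest common ancestor: speciation gives an ortholog
#' pair, duplication a paralog pair.
#'
#' @param h a HOG (see [hog_node()]).
#' @return data frame with columns `geneA`, `taxonA`, `geneB`, `taxonB`,
#'   `relation` (`"ortholog"`/`"paralog"`); pairs are unordered and stored
#'   with `geneA < geneB` byte order.
#' @export
derive_pairwise <- function(h) {
  validate_hog(h)
  out <- list()
  walk <- function(node) {
    if (is_leaf(node)) {
      return(data.frame(gene = node$gene, taxon = node$taxon,
                        stringsAsFactors = FALSE))
    }
    kids <- lapply(node$children, walk)
    rel <- if (node$event == "speciation") "ortholog" else "paralog"
    for (i in seq_along(kids)[-1]) {
      for (j in seq_len(i - 1L)) {
        a <- kids[[j]]; b <- kids[[i]]
        ia <- rep(seq_len(nrow(a)), each = nrow(b))
        ib <- rep(seq_len(nrow(b)), times = nrow(a))
        out[[length(out) + 1L]] <<- data.frame(
          geneA = a$gene[ia], taxonA = a$taxon[ia],
          geneB = b$gene[ib], taxonB = b$taxon[ib],
          relation = rel, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, kids)
  }
  walk(h)
  if (length(out) == 0L) {
    return(data.frame(geneA = character(), taxonA = character(),
                      geneB = character(), taxonB = character(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  swap <- df$geneA > df$geneB
  tmp <- df[swap, c("geneB", "taxonB", "geneA", "taxonA")]
  df[swap, c("geneA", "taxonA", "geneB", "taxonB")] <- tmp
  rownames(df) <- NULL
  df
}

#' Restrict pairwise relations to a clade
#'
#' Keeps the pairs whose partner gene (the `geneB` slot) belongs to one of
#' the given taxa. Used by the federation planner's specificity lesson:
#' restricting the clade shrinks intermediate results.
#'
#' @param relations data frame from [derive_pairwise()] (or a union of
#'   such frames).
#' @param taxa character vector of taxon IRI terms defining the clade.
#' @return the filtered data frame.
#' @export
restrict_to_clade <- function(relations, taxa) {
  if (length(taxa) > 0L && any(!is_iri(taxa))) {
    stop("unknown taxon IRI in clade set: ", taxa[!is_iri(taxa)][1],
         call. = FALSE)
  }
  if (any(is.na(relations$taxonB))) {
    stop("relation partner lacks a taxon annotation", call. = FALSE)
  }
  out <- relations[relations$taxonB %in% taxa, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit an ORTH-style RDF graph from HOGs
#'
#' Per gene: class membership, optional label, taxon link (the taxon
#' instance IRI is shared verbatim with the expression and protein
#' stores), optional cross-reference to its protein. Per pairwise
#' relation: a symmetric property assertion in both directions.
#'
#' @param hogs list of HOGs.
#' @param labels named character vector: gene IRI -> label.
#' @param proteins named character vector: gene IRI -> protein IRI term
#'   (genes absent from the vector get no cross-reference).
#' @param sci_names named character vector: taxon IRI -> scientific-name
#'   literal term.
#' @param name optional graph name.
#' @return an [rdf_graph()].
#' @export
emit_orth_graph <- function(hogs, labels = character(),
                            proteins = character(),
                            sci_names = character(), name = NULL) {
  voc <- genex_vocabulary()
  s <- p <- o <- character(0)
  add <- function(ss, pp, oo) {
    s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo)
  }
  for (h in hogs) {
    lv <- hog_leaves(h)
    add(lv$gene, rep(voc$rdf_type, nrow(lv)), rep(voc$gene_class, nrow(lv)))
    add(lv$gene, rep(voc$in_taxon, nrow(lv)), lv$taxon)
    add(lv$taxon, rep(voc$rdf_type, nrow(lv)), rep(voc$taxon_class, nrow(lv)))
    lab <- labels[lv$gene]
    got <- !is.na(lab)
    if (any(got)) {
      add(lv$gene[got], rep(voc$rdfs_label, sum(got)),
          literal(unname(lab[got])))
    }
    pr <- proteins[lv$gene]
    got <- !is.na(pr)
    if (any(got)) {
      add(lv$gene[got], rep(voc$xref_protein, sum(got)), unname(pr[got]))
      add(unname(pr[got]), rep(voc$rdf_type, sum(got)),
          rep(voc$protein_class, sum(got)))
    }
    rel <- derive_pairwise(h)
    if (nrow(rel) > 0L) {
      prop <- ifelse(rel$relation == "ortholog", voc$has_ortholog,
                     voc$has_paralog)
      add(rel$geneA, prop, rel$geneB)
      add(rel$geneB, prop, rel$geneA)
    }
  }
  sn <- sci_names[unique(s[is_iri(s) & s %in% names(sci_names)])]
  sn <- sn[!is.na(sn)]
  if (length(sn) > 0L) {
    add(names(sn), rep(voc$scientific_name, length(sn)), unname(sn))
  }
  rdf_graph(s, p, o, name = name)
}

# ---- serialization ------------------------------------------------------

hog_to_list <- function(node) {
  if (is_leaf(node)) {
    return(list(gene = iri_value(node$gene), taxon = iri_value(node$taxon)))
  }
  out <- list(event = node$event,
              children = lapply(node$children, hog_to_list))
  if (!is.null(node$taxon)) out$taxon <- iri_value(node$taxon)
  out
}

hog_from_list <- function(x) {
  if (!is.null(x$gene)) {
    return(hog_leaf(iri(x$gene), iri(x$taxon)))
  }
  hog_node(event = x$event,
           children = lapply(x$children, hog_from_list),
           taxon = if (!is.null(x$taxon)) iri(x$taxon) else NULL)
}

#' Write / read HOGs as JSON
#'
#' The JSON schema is a list of objects; internal nodes have `event`
#' (`"speciation"`/`"duplication"`), optional `taxon` (plain IRI string)
#' and `children`; leaves have `gene` and `taxon`.
#'
#' @param hogs list of HOGs.
#' @param path file path.
#' @return `read_hogs_json` returns a list of HOGs.
#' @export
write_hogs_json <- function(hogs, path) {
  jsonlite::write_json(lapply(hogs, hog_to_list), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_hogs_json
#' @export
read_hogs_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(lst, hog_from_list)
}

#' Read an OrthoXML-subset document as HOGs
#'
#' Understands the `species/database/genes/gene` header (gene and species
#' identity) and nested `orthologGroup` (speciation; taxon taken from a
#' `TaxRange`/`TaxId` property when present) / `paralogGroup`
#' (duplication) / `geneRef` group structure.
#'
#' @param path path to an OrthoXML file.
#' @param gene_base IRI base under which gene identifiers are minted.
#' @param taxon_base IRI base under which NCBI taxon identifiers are minted.
#' @return list of HOGs.
#' @export
read_orthoxml <- function(path, gene_base = NS$gene, taxon_base = NS$taxon) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_strip(doc)
  gene_taxon <- character(0)
  gene_id <- character(0)
  for (sp in xml2::xml_find_all(doc, ".//species")) {
    tax <- xml2::xml_attr(sp, "NCBITaxId")
    for (gn in xml2::xml_find_all(sp, ".//gene")) {
      gid <- xml2::xml_attr(gn, "id")
      gname <- xml2::xml_attr(gn, "geneId")
      if (is.na(gname)) gname <- gid
      gene_id[gid] <- gname
      gene_taxon[gid] <- tax
    }
  }
  parse_group <- function(node, event) {
    children <- list()
    taxon <- NULL
    for (ch in xml2::xml_children(node)) {
      nm <- xml2::xml_name(ch)
      if (nm == "property") {
        if (xml2::xml_attr(ch, "name") %in% c("TaxId", "TaxRange")) {
          val <- xml2::xml_attr(ch, "value")
          if (grepl("^[0-9]+$", val)) taxon <- iri(paste0(taxon_base, val))
        }
      } else if (nm == "geneRef") {
        gid <- xml2::xml_attr(ch, "id")
        if (!gid %in% names(gene_taxon)) {
          stop("orthoxml: geneRef to undeclared gene id '", gid, "'",
               call. = FALSE)
        }
        children[[length(children) + 1L]] <- hog_leaf(
          iri(paste0(gene_base, percent_encode(gene_id[[gid]]))),
          iri(paste0(taxon_base, gene_taxon[[gid]])))
      } else if (nm == "orthologGroup") {
        children[[length(children) + 1L]] <- parse_group(ch, "speciation")
      } else if (nm == "paralogGroup") {
        children[[length(children) + 1L]] <- parse_group(ch, "duplication")
      }
    }
    if (length(children) == 1L && event == "speciation") {
      return(children[[1L]])
    }
    hog_node(event = event, children = children, taxon = taxon)
  }
  groups <- xml2::xml_find_all(doc, "./groups/orthologGroup")
  lapply(groups, parse_group, event = "speciation")
}
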