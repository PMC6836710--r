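#' @title Seeded synthetic data stores
#'
#' @description
#' Generates the three coupled stores the federation integrates: a
#' relational gene-expression database (queried through the OBDA
#' mappings), an orthology store derived from hierarchical orthologous
#' groups, and a protein store with organism, existence and annotation
#' facts. Gene and taxon IRIs are minted once and reused verbatim across
#' stores — the virtual-link contract — and a handful of deterministic
#' anchor gene families (INS, HBB-Y, Tp53, a fly-brain family, EGFR with
#' a glioblastoma annotation) guarantees every catalogue query a
#' non-empty answer by construction.
#'
#' @name fixtures
NULL

# Fixed species pool: the organisms the catalogue's questions mention.
SPECIES_POOL <- data.frame(
  speciesId = c("9606", "10090", "10116", "7955", "7227", "9986"),
  genus = c("Homo", "Mus", "Rattus", "Danio", "Drosophila", "Oryctolagus"),
  species = c("sapiens", "musculus", "norvegicus", "rerio", "melanogaster",
              "cuniculus"),
  code = c("HSA", "MMU", "RNO", "DRE", "DME", "OCU"),
  stringsAsFactors = FALSE
)

ANAT_POOL <- data.frame(
  anatEntityId = c("UBERON:0000955", "UBERON:0002107", "UBERON:0001264",
                   "UBERON:0000948", "UBERON:0002113", "UBERON:0002048",
                   "UBERON:0000178", "UBERON:0002097"),
  name = c("brain", "liver", "pancreas", "heart", "kidney", "lung",
           "blood", "skin of body"),
  stringsAsFactors = FALSE
)

STAGE_POOL <- data.frame(
  stageId = c("embryo", "infant", "juvenile", "adult"),
  name = c("embryo stage", "infant stage", "juvenile stage", "adult stage"),
  stringsAsFactors = FALSE
)

#' Taxonomic clades of the fixture species tree
#'
#' Lineage is encoded as `rdfs:subClassOf` triples from each species taxon
#' to all its ancestor clades (as the protein store's taxonomy does), so a
#' clade restriction is a single extra pattern.
#'
#' @return named list of clade taxon IRI terms.
#' @export
clade_taxa <- function() {
  tx <- function(id) iri(paste0(NS$taxon, id))
  list(primates = tx("9443"), murinae = tx("39107"), glires = tx("314147"),
       euarchontoglires = tx("314146"), vertebrata = tx("7742"),
       bilateria = tx("33213"))
}

# species taxon -> ancestor clade ids, innermost first
SPECIES_LINEAGE <- list(
  `9606` = c("9443", "314146", "7742", "33213"),
  `10090` = c("39107", "314147", "314146", "7742", "33213"),
  `10116` = c("39107", "314147", "314146", "7742", "33213"),
  `7955` = c("7742", "33213"),
  `7227` = c("33213"),
  `9986` = c("314147", "314146", "7742", "33213")
)

# Deterministic anchor gene families: species code -> gene name, plus the
# forced facts each catalogue question needs.
ANCHOR_FAMILIES <- list(
  INS = list(members = c(HSA = "INS", MMU = "Ins2", RNO = "Ins1",
                         DRE = "ins", OCU = "INS"),
             duplication = FALSE),
  HBB = list(members = c(HSA = "HBB", MMU = "HBB-Y", OCU = "HBB1"),
             duplication = FALSE),
  TP53 = list(members = c(HSA = "TP53", RNO = "Tp53"),
              members2 = c(HSA = "TP63", RNO = "Tp63"),
              duplication = TRUE),
  GLI = list(members = c(DME = "ci", HSA = "GLI3", MMU = "Gli3",
                         RNO = "Gli3", DRE = "gli3", OCU = "GLI3"),
             duplication = FALSE),
  EGFR = list(members = c(HSA = "EGFR", RNO = "Egfr", MMU = "Egfr"),
              duplication = FALSE)
)

# Expression calls forced into the database (gene name @ species code).
FORCED_CALLS <- data.frame(
  code = c("MMU", "DRE", "HSA", "DME", "RNO", "HSA", "HSA"),
  geneName = c("Ins2", "ins", "INS", "ci", "Egfr", "EGFR", "EGFR"),
  anatEntityId = c("UBERON:0002107", "UBERON:0001264", "UBERON:0001264",
                   "UBERON:0000955", "UBERON:0000955", "UBERON:0000955",
                   "UBERON:0000955"),
  stageId = c("adult", "adult", "adult", "adult", "adult", "infant",
              "adult"),
  callType = "present",
  level = c("high", "low", "high", "low", "high", "low", "high"),
  stringsAsFactors = FALSE
)

#' Specify a synthetic-fixture configuration
#'
#' Defaults are the package's study conditions: the six catalogue
#' organisms, six anatomical entities (brain, liver, pancreas among them),
#' four developmental stages including infancy, 24 genes per species in
#' ten random families plus the anchors.
#'
#' @param seed integer RNG seed; identical seed and spec give
#'   byte-identical outputs.
#' @param n_species number of species (prefix of the fixed pool, max 6).
#' @param n_genes_per_species genes per species: 0 (an empty gene table)
#'   or >= 6 (so the deterministic anchor families fit).
#' @param n_anat_entities anatomical entities (>= 3, max 8).
#' @param n_stages developmental stages (>= 2, max 4).
#' @param n_hogs number of random gene families.
#' @param p_expressed,p_absent per (gene, anatomical entity, stage)
#'   probabilities of a present/absent expression call
#'   (`p_expressed + p_absent <= 1`).
#' @param p_high overall probability of a high-level present call
#'   (`p_high <= p_expressed`).
#' @param p_disease_annotated probability a protein carries a disease
#'   annotation.
#' @param p_protein probability a gene has a protein entry (the protein
#'   store does not cover all orthology-store genes).
#' @param disease_vocabulary disease names for annotations.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_species = 6L,
                         n_genes_per_species = 24L, n_anat_entities = 6L,
                         n_stages = 4L, n_hogs = 10L,
                         p_expressed = 0.25, p_absent = 0.10,
                         p_high = 0.08, p_disease_annotated = 0.15,
                         p_protein = 0.8,
                         disease_vocabulary = c(
                           "glioblastoma", "type 2 diabetes mellitus",
                           "beta thalassemia", "Li-Fraumeni syndrome",
                           "retinitis pigmentosa")) {
  stopifnot(n_species >= 1L, n_species <= nrow(SPECIES_POOL),
            n_genes_per_species == 0L || n_genes_per_species >= 6L,
            n_anat_entities >= 3L, n_anat_entities <= nrow(ANAT_POOL),
            n_stages >= 2L, n_stages <= nrow(STAGE_POOL),
            n_hogs >= 1L)
  if (p_expressed + p_absent > 1) {
    stop("p_expressed + p_absent must not exceed 1", call. = FALSE)
  }
  if (p_high > p_expressed) {
    stop("p_high must not exceed p_expressed", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_genes_per_species = as.integer(n_genes_per_species),
                 n_anat_entities = as.integer(n_anat_entities),
                 n_stages = as.integer(n_stages), n_hogs = as.integer(n_hogs),
                 p_expressed = p_expressed, p_absent = p_absent,
                 p_high = p_high, p_disease_annotated = p_disease_annotated,
                 p_protein = p_protein,
                 disease_vocabulary = disease_vocabulary),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Mint the store-shared identifiers
#'
#' Gene, taxon and protein IRIs are minted once, under a single namespace
#' each, and reused verbatim across the three stores (no sameAs bridging).
#'
#' @param geneId,speciesId identifier strings.
#' @return encoded IRI term vector.
#' @export
gene_iri <- function(geneId) iri(paste0(NS$gene, geneId))

#' @rdname gene_iri
#' @export
taxon_iri <- function(speciesId) iri(paste0(NS$taxon, speciesId))

#' @rdname gene_iri
#' @export
protein_iri <- function(geneId) iri(paste0(NS$prot, "P_", geneId))

#' Build the relational gene-expression database
#'
#' Tables: `species`, `gene`, `anatEntity`, `stage`, `expression`
#' (`callType` in present/absent; `level` high/low for present calls, SQL
#' `NULL` for absent calls). Anchor genes and their expression calls are
#' deterministic; the remaining calls are sampled per (gene, anatomical
#' entity, stage).
#'
#' @param spec a [fixture_spec()].
#' @return a [rel_db()].
#' @export
build_expression_db <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, build_expression_db_impl(spec))
}

anchor_gene_table <- function(spec) {
  sp <- SPECIES_POOL[seq_len(spec$n_species), ]
  rows <- list()
  for (fam in names(ANCHOR_FAMILIES)) {
    af <- ANCHOR_FAMILIES[[fam]]
    sets <- list(af$members)
    if (!is.null(af$members2)) sets <- c(sets, list(af$members2))
    for (si in seq_along(sets)) {
      mem <- sets[[si]]
      for (code in names(mem)) {
        if (!code %in% sp$code) next
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, subtree = si, code = code, geneName = mem[[code]],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

build_expression_db_impl <- function(spec) {
  sp <- SPECIES_POOL[seq_len(spec$n_species), ]
  anat <- ANAT_POOL[seq_len(spec$n_anat_entities), ]
  stg <- STAGE_POOL[seq_len(spec$n_stages), ]
  anchors <- if (spec$n_genes_per_species == 0L) {
    anchor_gene_table(spec)[0L, , drop = FALSE]
  } else {
    anchor_gene_table(spec)
  }

  genes <- list()
  if (spec$n_genes_per_species > 0L) for (i in seq_len(nrow(sp))) {
    code <- sp$code[i]
    a <- anchors[anchors$code == code, , drop = FALSE]
    n_fill <- spec$n_genes_per_species - nrow(a)
    if (n_fill < 0L) {
      stop("n_genes_per_species too small for the anchor families",
           call. = FALSE)
    }
    nm <- c(a$geneName,
            if (n_fill > 0L) paste0(tolower(code), "-", sprintf("%03d",
                                                                seq_len(n_fill))))
    genes[[i]] <- data.frame(
      geneId = paste0(code, sprintf("%04d", seq_along(nm))),
      geneName = nm,
      speciesId = sp$speciesId[i],
      stringsAsFactors = FALSE)
  }
  gene <- if (length(genes) == 0L) {
    data.frame(geneId = character(), geneName = character(),
               speciesId = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, genes)
  }
  rownames(gene) <- NULL

  # random expression calls
  ng <- nrow(gene)
  combos <- expand.grid(gi = seq_len(ng), ai = seq_len(nrow(anat)),
                        si = seq_len(nrow(stg)), KEEP.OUT.ATTRS = FALSE)
  u <- stats::runif(nrow(combos))
  present <- u < spec$p_expressed
  high <- u < spec$p_high
  absent <- !present & u < spec$p_expressed + spec$p_absent
  keep <- present | absent
  expression <- data.frame(
    geneId = gene$geneId[combos$gi[keep]],
    anatEntityId = anat$anatEntityId[combos$ai[keep]],
    stageId = stg$stageId[combos$si[keep]],
    callType = ifelse(present[keep], "present", "absent"),
    level = ifelse(present[keep], ifelse(high[keep], "high", "low"),
                   NA_character_),
    stringsAsFactors = FALSE)

  # forced anchor calls override whatever was sampled for the same cell
  fc <- FORCED_CALLS
  fc <- fc[fc$code %in% sp$code &
             fc$anatEntityId %in% anat$anatEntityId &
             fc$stageId %in% stg$stageId, , drop = FALSE]
  if (nrow(fc) > 0L) {
    code_of <- stats::setNames(sp$code, sp$speciesId)
    gid <- mapply(function(code, nm) {
      hit <- gene$geneId[gene$geneName == nm &
                           code_of[gene$speciesId] == code]
      hit[1]
    }, fc$code, fc$geneName)
    forced <- data.frame(geneId = unname(gid),
                         anatEntityId = fc$anatEntityId,
                         stageId = fc$stageId, callType = fc$callType,
                         level = fc$level, stringsAsFactors = FALSE)
    forced <- forced[!is.na(forced$geneId), , drop = FALSE]
    key <- function(df) paste(df$geneId, df$anatEntityId, df$stageId)
    expression <- expression[!key(expression) %in% key(forced), ,
                             drop = FALSE]
    expression <- rbind(expression, forced)
  }
  expression <- expression[order(expression$geneId, expression$anatEntityId,
                                 expression$stageId, method = "radix"), ]
  rownames(expression) <- NULL

  rel_db(list(
    species = sp[, c("speciesId", "genus", "species")],
    gene = gene,
    anatEntity = anat,
    stage = stg,
    expression = expression
  ))
}

# ---- HOGs and proteins --------------------------------------------------

# Nested species tree over the pool, with ancestral taxon ids.
species_tree <- function(codes) {
  node <- function(tax, kids) list(tax = tax, kids = kids)
  full <- node("33213", list(
    "DME",
    node("7742", list(
      "DRE",
      node("314146", list(
        "HSA",
        node("314147", list(
          "OCU",
          node("39107", list("MMU", "RNO"))))))))))
  prune <- function(nd) {
    if (is.character(nd)) {
      if (nd %in% codes) return(nd)
      return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(nd$kids, prune))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    node(nd$tax, kids)
  }
  prune(full)
}

# Build one HOG tree for genes_by_code (code -> character vector of gene
# IRIs), guided by the species tree; within-species multi-copy sets become
# duplication nodes.
build_family_tree <- function(genes_by_code, tree, taxon_of_code) {
  build <- function(nd) {
    if (is.character(nd)) {
      gs <- genes_by_code[[nd]]
      if (is.null(gs) || length(gs) == 0L) return(NULL)
      leaves <- lapply(gs, hog_leaf, taxon = taxon_of_code[[nd]])
      if (length(leaves) == 1L) return(leaves[[1L]])
      return(hog_node("duplication", leaves))
    }
    kids <- Filter(Negate(is.null), lapply(nd$kids, build))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    hog_node("speciation", kids, taxon = iri(paste0(NS$taxon, nd$tax)))
  }
  build(tree)
}

#' Build HOGs and the protein store coupled to an expression database
#'
#' Every database gene lands in exactly one HOG leaf (the orthology store
#' covers the expression store's genes completely); a `p_protein`
#' fraction of genes gets a protein entry (the protein store does not
#' cover all orthology genes), with organism, scientific name, existence
#' evidence, a function annotation and — for a `p_disease_annotated`
#' fraction, and always for the glioblastoma anchor — a disease
#' annotation. Taxon IRIs and scientific-name literals are byte-identical
#' across the three stores.
#'
#' @param spec a [fixture_spec()].
#' @param db the matching [build_expression_db()] result.
#' @return list with `hogs`, `oma_graph`, `protein_graph`, `proteins`
#'   (named vector gene IRI -> protein IRI).
#' @export
build_hogs_and_proteins <- function(spec, db) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!all(c("gene", "species") %in% names(db$tables))) {
    stop("database does not match the fixture schema", call. = FALSE)
  }
  with_seed(spec$seed + 1L, build_hogs_and_proteins_impl(spec, db))
}

build_hogs_and_proteins_impl <- function(spec, db) {
  voc <- genex_vocabulary()
  sp <- db$tables$species
  gene <- db$tables$gene
  code_of <- stats::setNames(SPECIES_POOL$code, SPECIES_POOL$speciesId)
  gene$code <- unname(code_of[gene$speciesId])
  taxon_of_code <- as.list(stats::setNames(taxon_iri(sp$speciesId),
                                           code_of[sp$speciesId]))
  tree <- species_tree(unique(gene$code))
  anchors <- anchor_gene_table(spec)
  anchors$key <- paste(anchors$code, anchors$geneName)
  gene$key <- paste(gene$code, gene$geneName)
  gene$iri <- gene_iri(gene$geneId)

  hogs <- list()
  # anchor families (deterministic; the TP53 family has a duplication root)
  for (fam in unique(anchors$family)) {
    af <- anchors[anchors$family == fam, , drop = FALSE]
    subtrees <- list()
    for (si in sort(unique(af$subtree))) {
      part <- af[af$subtree == si, , drop = FALSE]
      genes_by_code <- split(gene$iri[match(part$key, gene$key)], part$code)
      sub <- build_family_tree(genes_by_code, tree, taxon_of_code)
      if (!is.null(sub)) subtrees[[length(subtrees) + 1L]] <- sub
    }
    if (length(subtrees) == 0L) next
    hogs[[length(hogs) + 1L]] <- if (length(subtrees) == 1L) {
      subtrees[[1L]]
    } else {
      hog_node("duplication", subtrees)
    }
  }
  # random fill families
  fill <- gene[!gene$key %in% anchors$key, , drop = FALSE]
  if (nrow(fill) > 0L) {
    fam_of <- sample.int(spec$n_hogs, nrow(fill), replace = TRUE)
    for (f in sort(unique(fam_of))) {
      part <- fill[fam_of == f, , drop = FALSE]
      split_root <- stats::runif(1) < 0.25 && nrow(part) >= 3L
      groups <- if (split_root) {
        side <- sample(c(1L, 2L), nrow(part), replace = TRUE)
        list(part[side == 1L, , drop = FALSE],
             part[side == 2L, , drop = FALSE])
      } else {
        list(part)
      }
      subtrees <- list()
      for (g in groups) {
        if (nrow(g) == 0L) next
        genes_by_code <- split(g$iri, g$code)
        sub <- build_family_tree(genes_by_code, tree, taxon_of_code)
        if (!is.null(sub)) subtrees[[length(subtrees) + 1L]] <- sub
      }
      if (length(subtrees) == 0L) next
      hogs[[length(hogs) + 1L]] <- if (length(subtrees) == 1L) {
        subtrees[[1L]]
      } else {
        hog_node("duplication", subtrees)
      }
    }
  }

  # proteins: all anchor genes, plus a p_protein fraction of the rest
  has_protein <- gene$key %in% anchors$key |
    stats::runif(nrow(gene)) < spec$p_protein
  prot <- gene[has_protein, , drop = FALSE]
  proteins <- stats::setNames(protein_iri(prot$geneId), prot$iri)

  # protein store triples
  sci <- stats::setNames(
    transform_scientific_name(sp$genus, sp$species),
    taxon_iri(sp$speciesId))
  existence_pool <- c("Evidence at protein level",
                      "Evidence at transcript level",
                      "Inferred from homology")
  function_pool <- c("Predicted intracellular enzyme",
                     "Putative membrane receptor",
                     "DNA-binding regulatory protein",
                     "Secreted peptide hormone",
                     "Cytoskeletal structural protein")
  s <- p <- o <- character(0)
  add <- function(ss, pp, oo) {
    s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo)
  }
  np <- nrow(prot)
  prot_iris <- unname(proteins)
  add(prot_iris, rep(voc$rdf_type, np), rep(voc$protein_class, np))
  add(prot_iris, rep(voc$organism, np), taxon_iri(prot$speciesId))
  add(prot_iris, rep(voc$rdfs_label, np),
      literal(paste0(toupper(prot$geneName), "_", prot$code)))
  add(prot_iris, rep(voc$existence, np),
      literal(sample(existence_pool, np, replace = TRUE)))
  add(prot_iris, rep(voc$annotation, np),
      literal(sample(function_pool, np, replace = TRUE)))
  diseased <- stats::runif(np) < spec$p_disease_annotated
  dtext <- sample(spec$disease_vocabulary, np, replace = TRUE)
  if (spec$p_disease_annotated > 0) {
    # the motivating example's anchor: human EGFR is glioblastoma-annotated
    forced_egfr <- prot$key == "HSA EGFR"
    diseased <- diseased | forced_egfr
    dtext[forced_egfr] <- "glioblastoma"
  }
  if (any(diseased)) {
    add(prot_iris[diseased], rep(voc$disease_annotation, sum(diseased)),
        literal(paste0("Involved in ", dtext[diseased])))
  }
  tax <- taxon_iri(sp$speciesId)
  add(tax, rep(voc$rdf_type, length(tax)),
      rep(voc$taxon_class, length(tax)))
  add(tax, rep(voc$scientific_name, length(tax)), unname(sci[tax]))
  add(lineage_triples(sp$speciesId)$s, lineage_triples(sp$speciesId)$p,
      lineage_triples(sp$speciesId)$o)
  protein_graph <- rdf_graph(s, p, o, name = iri(paste0(NS$meta,
                                                        "graph/uniprot")))

  labels <- stats::setNames(gene$geneName, gene$iri)
  oma_graph <- emit_orth_graph(hogs, labels = labels, proteins = proteins,
                               sci_names = sci,
                               name = iri(paste0(NS$meta, "graph/oma")))
  lt <- lineage_triples(sp$speciesId)
  oma_graph <- graph_add(oma_graph, lt$s, lt$p, lt$o)

  list(hogs = hogs, oma_graph = oma_graph, protein_graph = protein_graph,
       proteins = proteins)
}

# rdfs:subClassOf closure from each species taxon to its ancestor clades.
lineage_triples <- function(speciesIds) {
  voc <- genex_vocabulary()
  s <- o <- character(0)
  for (id in speciesIds) {
    anc <- SPECIES_LINEAGE[[id]]
    chain <- c(id, anc)
    # species to every ancestor, and each clade to its own ancestors
    for (i in seq_along(chain)[-length(chain)]) {
      for (j in seq((i + 1L), length(chain))) {
        s <- c(s, paste0(NS$taxon, chain[i]))
        o <- c(o, paste0(NS$taxon, chain[j]))
      }
    }
  }
  s <- iri(s); o <- iri(o)
  list(s = s, p = rep(voc$subclass_of, length(s)), o = o)
}

# ---- assembled stores ---------------------------------------------------

#' Build every store plus the federation over them
#'
#' Convenience wrapper: expression database + OBDA virtual graph (using
#' the shipped mapping file), orthology and protein graphs, dataset
#' descriptions (derived from the materialized graphs), discovered
#' virtual links, and a ready [federation_system()] with the expression
#' store answering virtually.
#'
#' @param spec a [fixture_spec()].
#' @return list with `spec`, `db`, `mappings`, `vg`, `bgee_graph`, `hogs`,
#'   `oma_graph`, `protein_graph`, `proteins`, `datasets`, `links`, `fed`.
#' @export
fixture_stores <- function(spec = fixture_spec()) {
  db <- build_expression_db(spec)
  mappings <- load_mappings(system.file("extdata", "bgee_mappings.obda",
                                        package = "vlink", mustWork = TRUE),
                            file = TRUE)
  vg <- virtual_graph(db, mappings,
                      name = iri(paste0(NS$meta, "graph/bgee")))
  bgee_graph <- materialize(vg)
  hp <- build_hogs_and_proteins(spec, db)
  describe <- function(id, endpoint, g) {
    voc <- genex_vocabulary()
    dataset_description(
      id = iri(paste0(NS$meta, "dataset/", id)), endpoint = endpoint,
      classes = unique(g$triples$o[g$triples$p == voc$rdf_type]),
      predicates = unique(g$triples$p))
  }
  datasets <- list(
    bgee = describe("bgee", "bgee", bgee_graph),
    oma = describe("oma", "oma", hp$oma_graph),
    uniprot = describe("uniprot", "uniprot", hp$protein_graph))
  links <- c(
    discover_links(bgee_graph, hp$oma_graph, datasets$bgee, datasets$oma),
    discover_links(bgee_graph, hp$protein_graph, datasets$bgee,
                   datasets$uniprot),
    discover_links(hp$oma_graph, hp$protein_graph, datasets$oma,
                   datasets$uniprot))
  endpoints <- list(
    bgee = virtual_endpoint("bgee", vg,
                            service_iri = iri("https://sparql.example.org/bgee")),
    oma = graph_endpoint("oma", hp$oma_graph,
                         service_iri = iri("https://sparql.example.org/oma")),
    uniprot = graph_endpoint("uniprot", hp$protein_graph,
                             service_iri = iri("https://sparql.example.org/uniprot")))
  fed <- federation_system(endpoints, datasets, links)
  c(list(spec = spec, db = db, mappings = mappings, vg = vg,
         bgee_graph = bgee_graph), hp,
    list(datasets = datasets, links = links, fed = fed))
}

#' Union of the three materialized store graphs
#'
#' The centralized view federated execution must agree with.
#'
#' @param stores a [fixture_stores()] (or [worked_example()]) result.
#' @return an [rdf_graph()].
#' @export
union_graph <- function(stores) {
  graph_union(stores$bgee_graph, stores$oma_graph, stores$protein_graph)
}

# ---- independent brute-force evaluator ----------------------------------

#' Brute-force query answering (ground-truth oracle)
#'
#' Answers a query by recursive enumeration with binding substitution —
#' an independent code path from both the BGP evaluator and the OBDA and
#' federation engines, used to compute by-construction ground truth.
#'
#' @param g an [rdf_graph()].
#' @param q a [sparql_query()] (SERVICE blocks are flattened).
#' @return a solution data frame.
#' @export
brute_force_answers <- function(g, q) {
  pats <- all_patterns(q)
  t <- g$triples
  recurse <- function(pats, binding) {
    if (length(pats) == 0L) return(list(binding))
    pat <- pats[[1L]]
    # substitute already-bound variables
    for (k in 1:3) {
      if (is_variable(pat[k])) {
        v <- sub("^\\?", "", pat[k])
        if (!is.null(binding[[v]])) pat[k] <- binding[[v]]
      }
    }
    keep <- rep(TRUE, nrow(t))
    if (!is_variable(pat[1])) keep <- keep & t$s == pat[1]
    if (!is_variable(pat[2])) keep <- keep & t$p == pat[2]
    if (!is_variable(pat[3])) keep <- keep & t$o == pat[3]
    rows <- which(keep)
    out <- list()
    for (r in rows) {
      b2 <- binding
      ok <- TRUE
      for (k in 1:3) {
        if (is_variable(pat[k])) {
          v <- sub("^\\?", "", pat[k])
          val <- t[[c("s", "p", "o")[k]]][r]
          if (!is.null(b2[[v]]) && b2[[v]] != val) { ok <- FALSE; break }
          b2[[v]] <- val
        }
      }
      if (ok) out <- c(out, recurse(pats[-1L], b2))
    }
    out
  }
  sols <- recurse(pats, list())
  # filters
  passes <- function(b, f) {
    val <- b[[f$var]]
    if (is.null(val)) return(FALSE)
    if (f$op == "contains") {
      return(is_literal(val) &&
               grepl(tolower(f$value), tolower(term_value(val)),
                     fixed = TRUE))
    }
    rhs <- if (is_variable(f$value)) b[[sub("^\\?", "", f$value)]] else f$value
    if (is.null(rhs)) return(FALSE)
    a <- term_value(val); bb <- term_value(rhs)
    an <- suppressWarnings(as.numeric(a))
    bn <- suppressWarnings(as.numeric(bb))
    if (!is.na(an) && !is.na(bn)) { a <- an; bb <- bn }
    else if (f$op %in% c("=", "!=")) { a <- val; bb <- rhs }
    switch(f$op, "=" = a == bb, "!=" = a != bb, "<" = a < bb, ">" = a > bb)
  }
  for (f in q$filters) sols <- Filter(function(b) passes(b, f), sols)
  rows <- lapply(sols, function(b) {
    vapply(q$vars, function(v) b[[v]] %||% NA_character_, character(1))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                       optional = TRUE)
  if (length(rows) == 0L) out <- empty_solutions(q$vars)
  names(out) <- q$vars
  if (q$distinct) out <- unique_rows(out)
  if (!is.null(q$limit)) out <- utils::head(out, q$limit)
  rownames(out) <- NULL
  out
}

#' Ground truth for a template catalogue
#'
#' Renders each template with its defaults and answers it by brute force
#' over the union of the materialized stores.
#'
#' @param stores a [fixture_stores()] result.
#' @param catalogue templates from [load_catalogue()].
#' @return named list of solution data frames (one per template id).
#' @export
compute_ground_truth <- function(stores, catalogue) {
  g <- union_graph(stores)
  out <- list()
  for (t in catalogue) {
    q <- render_template(t)
    out[[t$id]] <- brute_force_answers(g, q)
  }
  out
}

# ---- randomized query generators ---------------------------------------

#' Generate a random BGP query grounded in a graph
#'
#' Samples a connected set of triples (a path/star in the graph) and
#' replaces nodes by variables — shared nodes become shared variables, so
#' the query exercises joins without degenerate cross products, and at
#' least one solution exists by construction. Occasionally a predicate
#' becomes a variable.
#'
#' @param g an [rdf_graph()].
#' @param npat number of triple patterns (1–4).
#' @param p_var probability a node is replaced by a variable.
#' @param max_product resample while the product of per-pattern candidate
#'   counts exceeds this bound (keeps the generated workload away from
#'   degenerate star queries whose answer is itself astronomically large).
#' @return a [sparql_query()] projecting every variable used.
#' @export
random_bgp_query <- function(g, npat = 2L, p_var = 0.7,
                             max_product = 5e4) {
  for (attempt in 1:25) {
    q <- random_bgp_query_once(g, npat, p_var)
    counts <- vapply(q$bgp, function(pat) {
      keep <- rep(TRUE, nrow(g$triples))
      if (!is_variable(pat[1])) keep <- keep & g$triples$s == pat[1]
      if (!is_variable(pat[2])) keep <- keep & g$triples$p == pat[2]
      if (!is_variable(pat[3])) keep <- keep & g$triples$o == pat[3]
      sum(keep)
    }, 1)
    if (prod(counts) <= max_product) return(q)
  }
  q
}

random_bgp_query_once <- function(g, npat = 2L, p_var = 0.7) {
  t <- g$triples
  stopifnot(nrow(t) > 0L)
  idx <- sample.int(nrow(t), 1L)
  rows <- t[idx, , drop = FALSE]
  nodes <- unique(c(rows$s, rows$o))
  for (j in seq_len(npat - 1L)) {
    adj <- which(t$s %in% nodes | t$o %in% nodes)
    idx <- adj[sample.int(length(adj), 1L)]
    rows <- rbind(rows, t[idx, , drop = FALSE])
    nodes <- unique(c(nodes, t$s[idx], t$o[idx]))
  }
  uniq <- unique(c(rows$s, rows$o))
  varname <- stats::setNames(paste0("?v", seq_along(uniq)), uniq)
  isvar <- stats::setNames(stats::runif(length(uniq)) < p_var, uniq)
  bgp <- lapply(seq_len(nrow(rows)), function(i) {
    s <- if (isvar[[rows$s[i]]]) varname[[rows$s[i]]] else rows$s[i]
    o <- if (isvar[[rows$o[i]]]) varname[[rows$o[i]]] else rows$o[i]
    p <- if (stats::runif(1) < 0.1) paste0("?p", i) else rows$p[i]
    c(s, p, o)
  })
  slots <- unlist(bgp)
  vars <- unique(sub("^[?]", "", slots[is_variable(slots)]))
  if (length(vars) == 0L) {
    # force at least one variable so the query projects something
    bgp[[1L]][1L] <- "?v1"
    vars <- "v1"
  }
  sparql_query(vars = vars, bgp = bgp)
}

#' Generate a random link-covered federated query
#'
#' Builds a 2- or 3-dataset conjunctive query whose join variables are
#' covered by the discovered virtual links: a gene variable (typed into
#' the gene class) joining expression and orthology, and optionally a
#' protein variable (typed into the protein class) joining orthology and
#' the protein store. Constants (anatomical entity, taxon, relation) are
#' drawn at random from the fixture pools.
#'
#' @param stores a [fixture_stores()] result.
#' @param n_datasets 2 or 3.
#' @return a [sparql_query()].
#' @export
random_federated_query <- function(stores, n_datasets = 2L) {
  voc <- genex_vocabulary()
  anat <- transform_uberon(stores$db$tables$anatEntity$anatEntityId)
  taxa <- taxon_iri(stores$db$tables$species$speciesId)
  rel <- sample(c(voc$has_ortholog, voc$has_paralog), 1L)
  bgp <- list(
    c("?g", voc$rdf_type, voc$gene_class),
    c("?g", voc$is_expressed_in, "?c"),
    c("?g", rel, "?h"))
  if (stats::runif(1) < 0.7) {
    bgp <- c(bgp, list(c("?c", voc$has_anat_entity,
                         anat[sample.int(length(anat), 1L)])))
  }
  if (stats::runif(1) < 0.5) {
    bgp <- c(bgp, list(c("?h", voc$in_taxon,
                         taxa[sample.int(length(taxa), 1L)])))
  }
  if (n_datasets >= 3L) {
    bgp <- c(bgp, list(
      c("?h", voc$xref_protein, "?prot"),
      c("?prot", voc$rdf_type, voc$protein_class),
      c("?prot", voc$annotation, "?ann")))
  }
  slots <- unlist(bgp)
  vars <- unique(sub("^[?]", "", slots[is_variable(slots)]))
  sparql_query(vars = vars, bgp = bgp, distinct = TRUE)
}

# ---- the worked example -------------------------------------------------

#' The hand-written worked example
#'
#' A fixed, seed-free instance of the motivating question ("human genes
#' associated with glioblastoma whose ortholog is expressed in the rat
#' brain"): exactly three human genes carry a glioblastoma annotation,
#' exactly two of them have rat orthologs, and exactly one of those
#' orthologs has a present call in the rat brain — so the expected answer
#' is that single human–rat pair, declared in the returned object.
#'
#' @return like [fixture_stores()], plus `expected` (the single-pair
#'   solution) and `query` (the rendered worked-example query).
#' @export
worked_example <- function() {
  sp <- SPECIES_POOL[SPECIES_POOL$speciesId %in% c("9606", "10116"), ]
  human_names <- c("EGFRw", "PTENw", "NF1w", "ACTBw")
  rat_names <- c("Egfrw", "Ptenw", "Actbw")
  gene <- data.frame(
    geneId = c(paste0("WEH", 1:4), paste0("WER", 1:3)),
    geneName = c(human_names, rat_names),
    speciesId = c(rep("9606", 4), rep("10116", 3)),
    stringsAsFactors = FALSE)
  db <- rel_db(list(
    species = sp[, c("speciesId", "genus", "species")],
    gene = gene,
    anatEntity = ANAT_POOL[1:2, ],
    stage = STAGE_POOL[STAGE_POOL$stageId == "adult", ],
    expression = data.frame(
      geneId = c("WER1", "WER2", "WER3", "WEH1"),
      anatEntityId = c("UBERON:0000955", "UBERON:0000955",
                       "UBERON:0000955", "UBERON:0000955"),
      stageId = "adult",
      callType = c("present", "absent", "present", "present"),
      level = c("high", NA, "low", "low"),
      stringsAsFactors = FALSE)))
  tax <- function(id) taxon_iri(id)
  leaf <- function(gid, sp) hog_leaf(gene_iri(gid), tax(sp))
  pair <- function(h, r) {
    hog_node("speciation", list(leaf(h, "9606"), leaf(r, "10116")),
             taxon = iri(paste0(NS$taxon, "314146")))
  }
  hogs <- list(
    pair("WEH1", "WER1"),        # glioblastoma gene; rat ortholog in brain
    pair("WEH2", "WER2"),        # glioblastoma gene; rat ortholog in liver
    leaf("WEH3", "9606"),        # glioblastoma gene; no rat ortholog
    pair("WEH4", "WER3"))        # no disease annotation; rat gene in brain
  proteins <- stats::setNames(protein_iri(gene$geneId),
                              gene_iri(gene$geneId))
  voc <- genex_vocabulary()
  s <- p <- o <- character(0)
  add <- function(ss, pp, oo) {
    s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo)
  }
  pri <- unname(proteins)
  n <- length(pri)
  add(pri, rep(voc$rdf_type, n), rep(voc$protein_class, n))
  add(pri, rep(voc$organism, n), tax(gene$speciesId))
  add(pri, rep(voc$annotation, n), rep(literal("Annotated protein"), n))
  dis <- gene$geneId %in% c("WEH1", "WEH2", "WEH3")
  add(pri[dis], rep(voc$disease_annotation, sum(dis)),
      rep(literal("Involved in glioblastoma"), sum(dis)))
  sci <- stats::setNames(transform_scientific_name(sp$genus, sp$species),
                         tax(sp$speciesId))
  add(names(sci), rep(voc$rdf_type, 2), rep(voc$taxon_class, 2))
  add(names(sci), rep(voc$scientific_name, 2), unname(sci))
  protein_graph <- rdf_graph(s, p, o)
  labels <- stats::setNames(gene$geneName, gene_iri(gene$geneId))
  oma_graph <- emit_orth_graph(hogs, labels = labels, proteins = proteins,
                               sci_names = sci)
  lt <- lineage_triples(sp$speciesId)
  oma_graph <- graph_add(oma_graph, lt$s, lt$p, lt$o)
  mappings <- load_mappings(system.file("extdata", "bgee_mappings.obda",
                                        package = "vlink", mustWork = TRUE),
                            file = TRUE)
  vg <- virtual_graph(db, mappings)
  bgee_graph <- materialize(vg)
  describe <- function(id, endpoint, g) {
    dataset_description(
      id = iri(paste0(NS$meta, "dataset/", id)), endpoint = endpoint,
      classes = unique(g$triples$o[g$triples$p == voc$rdf_type]),
      predicates = unique(g$triples$p))
  }
  datasets <- list(bgee = describe("bgee", "bgee", bgee_graph),
                   oma = describe("oma", "oma", oma_graph),
                   uniprot = describe("uniprot", "uniprot", protein_graph))
  links <- c(
    discover_links(bgee_graph, oma_graph, datasets$bgee, datasets$oma),
    discover_links(bgee_graph, protein_graph, datasets$bgee,
                   datasets$uniprot),
    discover_links(oma_graph, protein_graph, datasets$oma,
                   datasets$uniprot))
  endpoints <- list(
    bgee = virtual_endpoint("bgee", vg,
                            service_iri = iri("https://sparql.example.org/bgee")),
    oma = graph_endpoint("oma", oma_graph,
                         service_iri = iri("https://sparql.example.org/oma")),
    uniprot = graph_endpoint("uniprot", protein_graph,
                             service_iri = iri("https://sparql.example.org/uniprot")))
  fed <- federation_system(endpoints, datasets, links)
  catalogue <- load_catalogue(default_catalogue_path())
  we <- Filter(function(t) t$id == "WE", catalogue)[[1L]]
  expected <- data.frame(humanGene = gene_iri("WEH1"),
                         ratGene = gene_iri("WER1"),
                         stringsAsFactors = FALSE)
  list(db = db, mappings = mappings, vg = vg, bgee_graph = bgee_graph,
       hogs = hogs, oma_graph = oma_graph, protein_graph = protein_graph,
       proteins = proteins, datasets = datasets, links = links, fed = fed,
       template = we, query = render_template(we), expected = expected)
}

# ---- file outputs -------------------------------------------------------

#' Write the fixture stores to disk
#'
#' Outputs are deterministic for a fixed (seed, spec): a plain-text SQL
#' dump of the expression database, canonical N-Triples for the three
#' graphs, the VoIDext metadata, and tab-separated ground-truth files for
#' the shipped catalogue.
#'
#' @param dir output directory (created if needed).
#' @param spec a [fixture_spec()].
#' @return invisibly, the list of files written.
#' @export
make_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ground_truth"), showWarnings = FALSE)
  stores <- fixture_stores(spec)
  files <- character(0)
  put <- function(name, content) {
    path <- file.path(dir, name)
    con <- file(path, open = "wb")
    writeBin(charToRaw(enc2utf8(content)), con)
    close(con)
    files <<- c(files, path)
  }
  put("bgee_dump.sql", db_dump_sql(stores$db))
  put("bgee.nt", serialize_graph(stores$bgee_graph))
  put("oma.nt", serialize_graph(stores$oma_graph))
  put("uniprot.nt", serialize_graph(stores$protein_graph))
  put("voidext.nt",
      serialize_graph(serialize_voidext(stores$links, stores$datasets)))
  catalogue <- load_catalogue(default_catalogue_path())
  gt <- compute_ground_truth(stores, catalogue)
  for (id in names(gt)) {
    put(file.path("ground_truth", paste0(id, ".tsv")),
        solutions_tsv(gt[[id]]))
  }
  invisible(files)
}

#' Canonical TSV form of a solution set
#'
#' Columns in name order, rows byte-sorted: equal solution sets produce
#' identical documents.
#'
#' @param sols a solution data frame.
#' @return character scalar.
#' @export
solutions_tsv <- function(sols) {
  cols <- sort(names(sols))
  sols <- sols[, cols, drop = FALSE]
  lines <- if (nrow(sols) == 0L) character(0) else {
    sort(do.call(paste, c(sols, sep = "\t")), method = "radix")
  }
  paste0(paste(c(paste(cols, collapse = "\t"), lines), collapse = "\n"),
         "\n")
}
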