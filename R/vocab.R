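#' Gene-expression (GenEx-style) and companion vocabulary
#'
#' The fixed term set the three stores share: the gene class and label from
#' the orthology (ORTH) schema, taxa and scientific names from the protein
#' store's core schema, UBERON anatomical-entity IRIs, developmental
#' stages, and the three expression relations (*is expressed in*, *is
#' absent in*, *is highly expressed in*), each pointing at an expression
#' condition node that pairs an anatomical entity with a developmental
#' stage.
#'
#' @return named list of encoded IRI terms.
#' @export
genex_vocabulary <- function() {
  list(
    rdf_type            = iri(paste0(NS$rdf, "type")),
    rdfs_label          = iri(paste0(NS$rdfs, "label")),
    gene_class          = iri(paste0(NS$orth, "Gene")),
    taxon_class         = iri(paste0(NS$up, "Taxon")),
    protein_class       = iri(paste0(NS$up, "Protein")),
    scientific_name     = iri(paste0(NS$up, "scientificName")),
    in_taxon            = iri(paste0(NS$obo, "RO_0002162")),
    anat_entity_class   = iri(paste0(NS$genex, "AnatomicalEntity")),
    dev_stage_class     = iri(paste0(NS$genex, "DevelopmentalStage")),
    condition_class     = iri(paste0(NS$genex, "ExpressionCondition")),
    has_anat_entity     = iri(paste0(NS$genex, "hasAnatomicalEntity")),
    has_dev_stage       = iri(paste0(NS$genex, "hasDevelopmentalStage")),
    is_expressed_in     = iri(paste0(NS$genex, "isExpressedIn")),
    is_absent_in        = iri(paste0(NS$genex, "isAbsentIn")),
    is_highly_expressed_in = iri(paste0(NS$genex, "isHighlyExpressedIn")),
    has_ortholog        = iri(paste0(NS$orth, "hasOrtholog")),
    has_paralog         = iri(paste0(NS$orth, "hasParalog")),
    xref_protein        = iri(paste0(NS$lscr, "xrefUniprot")),
    organism            = iri(paste0(NS$up, "organism")),
    annotation          = iri(paste0(NS$up, "annotation")),
    disease_annotation  = iri(paste0(NS$up, "diseaseAnnotation")),
    subclass_of         = iri(paste0(NS$rdfs, "subClassOf")),
    existence           = iri(paste0(NS$up, "existence"))
  )
}
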