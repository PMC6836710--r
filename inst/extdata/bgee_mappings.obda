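# Relational-to-RDF mappings exposing the embedded gene-expression
# database as a virtual RDF graph. Gene and taxon IRIs deliberately reuse
# the orthology store's identifiers (no sameAs bridging): they are the
# virtual links between the stores.

[PrefixDeclaration]
orth:  http://purl.org/net/orth#
up:    http://purl.uniprot.org/core/
genex: http://purl.org/genex#
obo:   http://purl.obolibrary.org/obo/
rdfs:  http://www.w3.org/2000/01/rdf-schema#
taxon: http://purl.uniprot.org/taxonomy/
gene:  http://purl.example.org/vlink/gene/
cond:  http://purl.example.org/vlink/condition/
stage: http://purl.example.org/vlink/stage/

[MappingDeclaration]

mappingId  gene-class
source     SELECT geneId FROM gene
target     gene:{geneId} a orth:Gene .

mappingId  gene-label
source     SELECT geneId, geneName FROM gene
target     gene:{geneId} rdfs:label "{geneName}" .

mappingId  gene-taxon
source     SELECT geneId, speciesId FROM gene
target     gene:{geneId} obo:RO_0002162 taxon:{speciesId} .

mappingId  taxon-class
source     SELECT speciesId FROM species
target     taxon:{speciesId} a up:Taxon .

mappingId  taxon-scientific-name
source     SELECT speciesId, genus, species FROM species
target     taxon:{speciesId} up:scientificName "{genus} {species}" .

mappingId  anat-entity
source     SELECT anatEntityId, name FROM anatEntity
target     obo:{uberon_local(anatEntityId)} a genex:AnatomicalEntity ;
           rdfs:label "{name}" .

mappingId  dev-stage
source     SELECT stageId, name FROM stage
target     stage:{stageId} a genex:DevelopmentalStage ; rdfs:label "{name}" .

mappingId  expression-condition
source     SELECT anatEntityId, stageId FROM expression
target     cond:{uberon_local(anatEntityId)}-{stageId} a genex:ExpressionCondition ;
           genex:hasAnatomicalEntity obo:{uberon_local(anatEntityId)} ;
           genex:hasDevelopmentalStage stage:{stageId} .

mappingId  expressed-in
source     SELECT geneId, anatEntityId, stageId FROM expression WHERE callType = 'present'
target     gene:{geneId} genex:isExpressedIn cond:{uberon_local(anatEntityId)}-{stageId} .

mappingId  absent-in
source     SELECT geneId, anatEntityId, stageId FROM expression WHERE callType = 'absent'
target     gene:{geneId} genex:isAbsentIn cond:{uberon_local(anatEntityId)}-{stageId} .

mappingId  highly-expressed-in
source     SELECT geneId, anatEntityId, stageId FROM expression WHERE callType = 'present' AND level = 'high'
target     gene:{geneId} genex:isHighlyExpressedIn cond:{uberon_local(anatEntityId)}-{stageId} .
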