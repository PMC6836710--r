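# Shared fixtures, built once per test run.
.vlink_cache <- new.env(parent = emptyenv())

get_stores <- function() {
  if (is.null(.vlink_cache$stores)) {
    .vlink_cache$stores <- fixture_stores(fixture_spec())
  }
  .vlink_cache$stores
}

get_worked <- function() {
  if (is.null(.vlink_cache$worked)) .vlink_cache$worked <- worked_example()
  .vlink_cache$worked
}

get_catalogue <- function() {
  if (is.null(.vlink_cache$catalogue)) {
    .vlink_cache$catalogue <- load_catalogue(default_catalogue_path())
  }
  .vlink_cache$catalogue
}

get_ground_truth <- function() {
  if (is.null(.vlink_cache$gt)) {
    .vlink_cache$gt <- compute_ground_truth(get_stores(), get_catalogue())
  }
  .vlink_cache$gt
}

template_by_id <- function(id) {
  hit <- Filter(function(t) t$id == id, get_catalogue())
  stopifnot(length(hit) == 1L)
  hit[[1L]]
}

# A federation clone with the intermediate-result cap disabled (the cap is
# a safety valve for interactive use; equivalence checks need full results).
uncapped <- function(fed) {
  fed$cap <- Inf
  fed
}

# Small deterministic demo graph used across rdf-core tests.
demo_graph <- function() {
  voc <- genex_vocabulary()
  g1 <- iri("http://example.org/g1")
  g2 <- iri("http://example.org/g2")
  rdf_graph(
    s = c(g1, g1, g2, g2),
    p = c(voc$rdf_type, voc$rdfs_label, voc$rdf_type, voc$rdfs_label),
    o = c(voc$gene_class, literal("HBB-Y"), voc$gene_class, literal("INS"))
  )
}
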