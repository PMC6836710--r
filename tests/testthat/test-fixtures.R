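test_that("fixture specifications validate their probabilities and sizes", {
  expect_error(fixture_spec(p_expressed = 0.8, p_absent = 0.3), "exceed 1")
  expect_error(fixture_spec(p_expressed = 0.1, p_high = 0.2), "p_high")
  expect_error(fixture_spec(n_genes_per_species = 3L))
  expect_error(fixture_spec(n_species = 99L))
  expect_s3_class(fixture_spec(), "fixture_spec")
})

test_that("the expression database realizes the spec arithmetic", {
  spec <- fixture_spec()
  db <- build_expression_db(spec)
  expect_equal(nrow(db$tables$species), spec$n_species)
  expect_equal(nrow(db$tables$gene),
               spec$n_species * spec$n_genes_per_species)
  expect_equal(nrow(db$tables$anatEntity), spec$n_anat_entities)
  expect_equal(nrow(db$tables$stage), spec$n_stages)
  expect_true(all(c("UBERON:0000955", "UBERON:0002107", "UBERON:0001264")
                  %in% db$tables$anatEntity$anatEntityId))
  expect_true("infant" %in% db$tables$stage$stageId)
  # absent calls carry a NULL level
  ex <- db$tables$expression
  expect_true(all(is.na(ex$level[ex$callType == "absent"])))
  expect_true(all(ex$callType %in% c("present", "absent")))
  # a zero gene budget gives an empty gene table
  db0 <- build_expression_db(fixture_spec(n_genes_per_species = 0L))
  expect_equal(nrow(db0$tables$gene), 0L)
  expect_equal(nrow(db0$tables$expression), 0L)
})

test_that("coverage asymmetry matches the integration scenario", {
  st <- get_stores()
  voc <- genex_vocabulary()
  # the orthology store covers every expression-store gene...
  oma_genes <- class_instances(st$oma_graph, voc$gene_class)
  db_genes <- gene_iri(st$db$tables$gene$geneId)
  expect_setequal(oma_genes, db_genes)
  # ...but some orthology genes have no protein entry
  expect_true(length(st$proteins) < length(db_genes))
  expect_true(length(st$proteins) > 0L)
  # shared taxon IRIs across all three stores equal the species count
  taxa_bgee <- class_instances(st$bgee_graph, voc$taxon_class)
  taxa_oma <- class_instances(st$oma_graph, voc$taxon_class)
  taxa_up <- class_instances(st$protein_graph, voc$taxon_class)
  expect_length(intersect(intersect(taxa_bgee, taxa_oma), taxa_up),
                st$spec$n_species)
})

test_that("a zero disease-annotation rate produces zero disease annotations", {
  hp <- build_hogs_and_proteins(
    fixture_spec(p_disease_annotated = 0),
    build_expression_db(fixture_spec(p_disease_annotated = 0)))
  voc <- genex_vocabulary()
  expect_equal(sum(hp$protein_graph$triples$p == voc$disease_annotation), 0L)
})

test_that("identical seeds give byte-identical outputs, different seeds differ", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  make_fixtures(d1, fixture_spec(seed = 42L))
  make_fixtures(d2, fixture_spec(seed = 42L))
  make_fixtures(d3, fixture_spec(seed = 43L))
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     info = f)
  }
  expect_false(identical(readBin(file.path(d1, "bgee_dump.sql"), "raw", 5e6),
                         readBin(file.path(d3, "bgee_dump.sql"), "raw", 5e6)))
})

test_that("the worked example is exactly its constructed instance", {
  we <- get_worked()
  expect_lte(nrow(we$db$tables$gene), 30L)
  voc <- genex_vocabulary()
  # three glioblastoma-annotated human proteins by construction
  t <- we$protein_graph$triples
  expect_equal(sum(t$p == voc$disease_annotation), 3L)
  res <- federate(we$fed, we$query)
  expect_true(solutions_equal(res, we$expected))
  # swapping the anatomical term empties the answer
  liver <- render_template(
    we$template,
    params = list(anat = "http://purl.obolibrary.org/obo/UBERON_0002107"))
  expect_equal(nrow(federate(we$fed, liver)), 0L)
  # a disease absent from the vocabulary empties the answer
  absent <- render_template(we$template,
                            params = list(disease = "kuru zzz"))
  expect_equal(nrow(federate(we$fed, absent)), 0L)
})

test_that("ground truth is computed independently and regressions are frozen", {
  expect_length(compute_ground_truth(get_stores(), list()), 0L)
  gt <- get_ground_truth()
  # every catalogue query has at least one solution on default fixtures
  expect_true(all(vapply(gt, nrow, 1L) > 0L))
  # frozen counts for the default spec (seed 42); computed by the
  # brute-force oracle and pinned as a regression contract
  counts <- vapply(gt, nrow, 1L)
  expect_equal(counts[["Q1"]], 1L)
  expect_equal(counts[["Q4"]], 1L)
  expect_equal(counts[["Q5"]], 80L)
  expect_equal(counts[["Q6"]], 16L)
  expect_equal(counts[["Q10"]], 60L)
  expect_equal(counts[["Q11"]], 11L)
  expect_equal(counts[["WE"]], 1L)
  # the worked-example entry on its own fixture equals the declared pair
  we <- get_worked()
  gt_we <- brute_force_answers(union_graph(we), we$query)
  expect_true(solutions_equal(gt_we, we$expected))
})
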