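empty_classification <- function() {
  structure(tibble::tibble(
    transcript_id = character(), code = character(),
    overlapping_gene_ids = list(), n_genes = integer(),
    matched_reference_transcript = character(),
    seqid = character(), start = integer(), strand = character()
  ), class = c("tx_classification", "tbl_df", "tbl", "data.frame"))
}

test_that("integrating nothing is the identity", {
  fx <- generate_fixture(fixture_config(seed = 51, with_genome = FALSE))
  res <- integrate_annotation(fx$reference, empty_classification(),
                              fx$candidates)
  expect_true(ann_equal(res$updated, fx$reference))
  expect_equal(nrow(res$id_map), 0)
  expect_true(all(res$provenance$status == "reference_retained"))
})

test_that("a lone novel transcript becomes the first scheme gene", {
  ref <- toy_annotation(list(
    list(tx = "gA.t1", gene = "gA", exons = list(c(100, 500)))
  ))
  cand <- toy_annotation(list(
    list(tx = "STRG.1.1", gene = "STRG.1", seqid = "chr9",
         exons = list(c(1000, 1400)))
  ), source = "candidate")
  cls <- classify_transcripts(cand, ref)
  res <- integrate_annotation(ref, cls, cand)
  expect_true("GBIG_G_000001" %in% res$updated$genes$gene_id)
  expect_true("GBIG_G_000001.t1" %in% res$updated$transcripts$transcript_id)
  expect_equal(res$scheme$next_serial, 2L)
})

test_that("prefix and padding of the identifier scheme are configurable", {
  ref <- toy_annotation(list(
    list(tx = "gA.t1", gene = "gA", exons = list(c(100, 500)))
  ))
  cand <- toy_annotation(list(
    list(tx = "n1", gene = "cg", seqid = "chr9", exons = list(c(10, 50)))
  ), source = "candidate")
  cls <- classify_transcripts(cand, ref)
  res <- integrate_annotation(ref, cls, cand,
                              scheme = id_scheme("NEW_", 3, next_serial = 41))
  expect_true("NEW_041" %in% res$updated$genes$gene_id)
  # collisions with existing identifiers are refused
  ref2 <- toy_annotation(list(
    list(tx = "x", gene = "NEW_041", exons = list(c(100, 500)))
  ))
  cls2 <- classify_transcripts(cand, ref2)
  expect_error(
    integrate_annotation(ref2, cls2, cand,
                         scheme = id_scheme("NEW_", 3, next_serial = 41)),
    "identifier collision")
})

test_that("novel isoforms attach to their gene, which keeps id and attributes", {
  ref_gtf <- c(
    'chr1\tref\tgene\t100\t800\t.\t+\t.\tgene_id "gA"; note "keepme";',
    'chr1\tref\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\tref\texon\t400\t500\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'chr1\tref\texon\t700\t800\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";'
  )
  ref <- read_gtf(ref_gtf)
  cand <- toy_annotation(list(
    list(tx = "c1", gene = "cg", exons = list(c(100, 200), c(700, 800)))
  ), source = "candidate")
  cls <- classify_transcripts(cand, ref)
  res <- integrate_annotation(ref, cls, cand)
  g <- res$updated$genes
  expect_equal(nrow(g), 1)
  expect_equal(g$gene_id, "gA")
  expect_identical(g$attributes[[1]][["note"]], "keepme")
  expect_setequal(res$updated$transcripts$transcript_id, c("gA.t1", "c1"))
  expect_equal(
    res$provenance$status[res$provenance$transcript_id == "c1"],
    "isoform_added")
  # exact-match candidates contribute nothing
  exact <- toy_annotation(list(
    list(tx = "dup", gene = "cg",
         exons = list(c(100, 200), c(400, 500), c(700, 800)))
  ), source = "candidate")
  cls2 <- classify_transcripts(exact, ref)
  expect_equal(cls2$code, "exact_match")
  res2 <- integrate_annotation(ref, cls2, exact)
  expect_true(ann_equal(res2$updated, ref))
})

test_that("merge components fuse genes under a fresh id with merged_from", {
  ref <- toy_annotation(list(
    list(tx = "gA.t1", gene = "gA", exons = list(c(100, 300))),
    list(tx = "gB.t1", gene = "gB", exons = list(c(1000, 1300)))
  ))
  cand <- toy_annotation(list(
    list(tx = "span", gene = "cg", exons = list(c(200, 300), c(1000, 1100)))
  ), source = "candidate")
  cls <- classify_transcripts(cand, ref)
  res <- integrate_annotation(ref, cls, cand)
  g <- res$updated$genes
  expect_equal(nrow(g), 1)
  expect_equal(g$gene_id, "GBIG_G_000001")
  expect_identical(g$attributes[[1]][["merged_from"]], "gA,gB")
  # member transcripts keep their original ids under the new gene
  tx <- res$updated$transcripts
  expect_setequal(tx$transcript_id, c("gA.t1", "gB.t1", "span"))
  expect_true(all(tx$gene_id == "GBIG_G_000001"))
  expect_setequal(res$id_map$old_gene_id, c("gA", "gB"))
  expect_true(all(res$id_map$new_gene_id == "GBIG_G_000001"))
  # span covers all member exons
  expect_equal(g$start, 100L)
  expect_equal(g$end, 1300L)
  # and re-classifying the evidence against the update finds one gene only
  # (no further join evidence survives integration)
  again <- classify_transcripts(cand, res$updated)
  expect_equal(again$n_genes, 1L)
  expect_equal(again$code, "exact_match")
})

test_that("an isoform of a consumed gene outside its component errors", {
  ref <- toy_annotation(list(
    list(tx = "gA.t1", gene = "gA", exons = list(c(100, 300), c(500, 700))),
    list(tx = "gB.t1", gene = "gB", exons = list(c(1000, 1300)))
  ))
  cand <- toy_annotation(list(
    list(tx = "span", gene = "cg1", exons = list(c(200, 300), c(1000, 1100))),
    list(tx = "iso", gene = "cg2", exons = list(c(100, 300)))
  ), source = "candidate")
  cls <- classify_transcripts(cand, ref)
  expect_error(integrate_annotation(ref, cls, cand), "consistency error")
})

test_that("fixture integration conserves reference transcripts and counts", {
  fx <- generate_fixture(fixture_config(seed = 57, with_genome = FALSE))
  cls <- classify_transcripts(fx$candidates, fx$reference)
  comps <- build_merge_components(cls, fx$reference)
  res <- integrate_annotation(fx$reference, cls, fx$candidates,
                              components = comps)
  # every reference transcript id survives exactly once
  upd_ids <- res$updated$transcripts$transcript_id
  expect_true(all(table(upd_ids) == 1))
  expect_true(all(fx$reference$transcripts$transcript_id %in% upd_ids))
  # no dangling gene references
  expect_true(all(res$updated$transcripts$gene_id %in%
                    res$updated$genes$gene_id))
  # gene arithmetic: ref - consumed members + components + novel clusters
  truth <- fx$truth
  n_novel_clusters <- sum(truth$category == "novel_gene")  # one tx per cluster
  expect_equal(
    nrow(res$updated$genes),
    nrow(fx$reference$genes) - sum(lengths(comps$member_gene_ids)) +
      nrow(comps) + n_novel_clusters)
  # transcript arithmetic: ref + all non-exact candidates
  expect_equal(
    nrow(res$updated$transcripts),
    nrow(fx$reference$transcripts) + sum(truth$category != "exact_match"))
  # determinism: identical inputs give byte-identical output
  res2 <- integrate_annotation(fx$reference, cls, fx$candidates,
                               components = comps)
  expect_identical(write_gtf(res$updated), write_gtf(res2$updated))
  # idempotence: integrating the update against itself with no survivors
  res3 <- integrate_annotation(res$updated, empty_classification(),
                               fx$candidates, scheme = res$scheme)
  expect_true(ann_equal(res3$updated, res$updated))
})

test_that("soft-mask fractions match the per-base count", {
  ann <- toy_annotation(list(
    list(tx = "up", gene = "g1", exons = list(c(1, 10), c(21, 30))),
    list(tx = "down", gene = "g2", exons = list(c(41, 60)))
  ))
  genome <- c(chr1 = paste0(strrep("A", 40), strrep("a", 40)))
  sm <- softmask_fractions(ann, genome)
  expect_equal(sm$masked_fraction[sm$transcript_id == "up"], 0)
  expect_equal(sm$masked_fraction[sm$transcript_id == "down"], 1)

  fx <- generate_fixture(fixture_config(seed = 61, n_genes = 15,
                                        n_candidates = 8))
  sm <- softmask_fractions(fx$reference, fx$genome)
  ex_by_tx <- split(fx$reference$exons, fx$reference$exons$transcript_id)
  for (tid in sample(names(ex_by_tx), 10)) {
    expect_equal(sm$masked_fraction[sm$transcript_id == tid],
                 oracle_softmask(ex_by_tx[[tid]], fx$genome))
  }
  # out-of-bounds exons are coordinate errors
  tiny <- c(chr1 = "ACGT")
  expect_error(softmask_fractions(ann, tiny), "coordinate error")
})
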