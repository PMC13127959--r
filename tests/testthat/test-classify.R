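ref_two_genes <- toy_annotation(list(
  list(tx = "gA.t1", gene = "gA",
       exons = list(c(100, 200), c(400, 500), c(700, 800))),
  list(tx = "gA.t2", gene = "gA", exons = list(c(100, 200), c(400, 500))),
  list(tx = "gB.t1", gene = "gB", exons = list(c(2000, 2200), c(2500, 2700))),
  list(tx = "gC.t1", gene = "gC", strand = "-",
       exons = list(c(5000, 5300)))
))

test_that("a structurally identical candidate is an exact match", {
  cand <- toy_annotation(list(
    # same intron chain as gA.t1 but different terminal extents
    list(tx = "c1", gene = "cg1",
         exons = list(c(150, 200), c(400, 500), c(700, 760)))
  ), source = "candidate")
  got <- classify_transcripts(cand, ref_two_genes)
  expect_equal(got$code, "exact_match")
  expect_equal(got$matched_reference_transcript, "gA.t1")
  expect_equal(got$overlapping_gene_ids[[1]], "gA")
})

test_that("overlap with two same-strand genes is join evidence", {
  cand <- toy_annotation(list(
    list(tx = "c1", gene = "cg1",
         exons = list(c(700, 800), c(2000, 2100)))
  ), source = "candidate")
  got <- classify_transcripts(cand, ref_two_genes)
  expect_equal(got$code, "join_evidence")
  expect_equal(got$overlapping_gene_ids[[1]], c("gA", "gB"))
})

test_that("intronic and antisense candidates are novel genes", {
  cand <- toy_annotation(list(
    # entirely inside gA's first intron: zero exonic overlap
    list(tx = "intronic", gene = "cg1", exons = list(c(250, 350))),
    # overlaps gC's exon but on the opposite strand
    list(tx = "anti", gene = "cg2", strand = "+",
         exons = list(c(5000, 5300)))
  ), source = "candidate")
  got <- classify_transcripts(cand, ref_two_genes)
  expect_equal(got$code[got$transcript_id == "intronic"], "novel_gene")
  expect_equal(got$code[got$transcript_id == "anti"], "novel_gene")
})

test_that("a different intron chain in one gene is a novel isoform", {
  cand <- toy_annotation(list(
    # skips the middle exon of gA.t1
    list(tx = "skip", gene = "cg1",
         exons = list(c(100, 200), c(700, 800)))
  ), source = "candidate")
  got <- classify_transcripts(cand, ref_two_genes)
  expect_equal(got$code, "novel_isoform")
  expect_equal(got$n_genes, 1L)
})

test_that("single-exon matching uses the reciprocal-overlap threshold", {
  ref <- toy_annotation(list(
    list(tx = "s.t1", gene = "gS", exons = list(c(1000, 1999)))
  ))
  hi <- toy_annotation(list(   # 900/1000 both ways
    list(tx = "c_hi", gene = "c1", exons = list(c(1100, 2099)))
  ), source = "candidate")
  lo <- toy_annotation(list(   # 500/1000: below 0.8
    list(tx = "c_lo", gene = "c2", exons = list(c(1500, 2499)))
  ), source = "candidate")
  expect_equal(classify_transcripts(hi, ref)$code, "exact_match")
  expect_equal(classify_transcripts(lo, ref)$code, "novel_isoform")
  # the threshold is a parameter
  expect_equal(classify_transcripts(lo, ref,
                                    min_reciprocal_overlap = 0.4)$code,
               "exact_match")
})

test_that("unstranded candidates hitting both strands keep the best gene", {
  ref <- toy_annotation(list(
    list(tx = "p.t1", gene = "gP", strand = "+", exons = list(c(100, 400))),
    list(tx = "m.t1", gene = "gM", strand = "-", exons = list(c(380, 700)))
  ))
  cand <- toy_annotation(list(
    # overlaps gP by 101 bases and gM by 221: gM wins
    list(tx = "c1", gene = "c1", strand = ".",
         exons = list(c(300, 600)))
  ), source = "candidate")
  got <- classify_transcripts(cand, ref)
  expect_equal(got$n_genes, 1L)
  expect_equal(got$overlapping_gene_ids[[1]], "gM")
})

test_that("classification codes satisfy their cardinality invariants", {
  fx <- generate_fixture(fixture_config(seed = 17, with_genome = FALSE))
  got <- classify_transcripts(fx$candidates, fx$reference)
  expect_setequal(got$code, intersect(unique(got$code),
                                      c("exact_match", "novel_isoform",
                                        "join_evidence", "novel_gene")))
  expect_true(all(got$n_genes[got$code %in%
                                c("exact_match", "novel_isoform")] == 1))
  expect_true(all(got$n_genes[got$code == "join_evidence"] >= 2))
  expect_true(all(got$n_genes[got$code == "novel_gene"] == 0))
  expect_true(all(is.na(
    got$matched_reference_transcript[got$code != "exact_match"])))
})

test_that("classification recovers planted labels and ignores input order", {
  fx <- generate_fixture(fixture_config(seed = 23, with_genome = FALSE))
  got <- classify_transcripts(fx$candidates, fx$reference)
  truth <- fx$truth
  expect_identical(
    got$code[match(truth$transcript_id, got$transcript_id)],
    truth$category)
  # permuting candidate exon-row order leaves the output identical
  ex <- fx$candidates$exons
  shuffled <- annotation(
    ex[sample.int(nrow(ex)), c("transcript_id", "gene_id", "seqid", "start",
                               "end", "strand")],
    source = "candidate")
  got2 <- classify_transcripts(shuffled, fx$reference)
  expect_identical(got$transcript_id, got2$transcript_id)
  expect_identical(got$code, got2$code)
})

test_that("classifier agrees with the quadratic exon-pair oracle", {
  fx <- generate_fixture(fixture_config(
    seed = 29, n_genes = 40, n_candidates = 30, with_genome = FALSE))
  # add adversarial unplanted candidates around gene boundaries
  set.seed(30)
  extra <- lapply(1:90, function(i) {
    g <- fx$reference$genes[sample.int(nrow(fx$reference$genes), 1), ]
    offset <- sample(-800:800, 1)
    len <- sample(80:900, 1)
    start <- max(1, g$start + offset)
    list(tx = sprintf("adv%03d", i), gene = sprintf("advg%03d", i),
         seqid = g$seqid, strand = sample(c("+", "-", "."), 1),
         exons = list(c(start, start + len)))
  })
  cands <- annotation(dplyr::bind_rows(
    fx$candidates$exons[, c("transcript_id", "gene_id", "seqid", "start",
                            "end", "strand")],
    toy_annotation(extra, source = "candidate")$exons[
      , c("transcript_id", "gene_id", "seqid", "start", "end", "strand")]),
    source = "candidate")
  got <- classify_transcripts(cands, fx$reference)
  want <- oracle_classify(cands, fx$reference)
  merged <- dplyr::left_join(tidy(got), want, by = "transcript_id")
  expect_identical(merged$code.x, merged$code.y)
  expect_identical(merged$overlapping_gene_ids, merged$genes)
  expect_identical(merged$matched_reference_transcript, merged$matched)
})
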