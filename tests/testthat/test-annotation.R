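toy_gtf <- c(
  'chr1\ttoy\tgene\t100\t900\t.\t+\t.\tgene_id "gA"; name "alpha";',
  'chr1\ttoy\ttranscript\t100\t500\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
  'chr1\ttoy\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
  'chr1\ttoy\texon\t400\t500\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
  'chr1\ttoy\ttranscript\t100\t900\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
  'chr1\ttoy\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
  'chr1\ttoy\texon\t700\t900\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t2";',
  'chr2\ttoy\ttranscript\t50\t300\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";',
  'chr2\ttoy\texon\t50\t120\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";',
  'chr2\ttoy\texon\t250\t300\t.\t-\t.\tgene_id "gB"; transcript_id "gB.t1";'
)

test_that("empty input yields an empty annotation", {
  ann <- read_gtf(character())
  expect_s3_class(ann, "tx_annotation")
  expect_equal(glance(ann)$n_genes, 0)
  expect_equal(glance(ann)$n_transcripts, 0)
  expect_identical(write_gtf(ann), character())
})

test_that("a hand-counted toy GTF parses to the expected model", {
  ann <- read_gtf(toy_gtf)
  expect_equal(nrow(ann$genes), 2)
  expect_equal(nrow(ann$transcripts), 3)
  expect_equal(nrow(ann$exons), 6)
  expect_setequal(
    ann$transcripts$transcript_id[ann$transcripts$gene_id == "gA"],
    c("gA.t1", "gA.t2"))
  # gene gB was synthesized from its transcripts
  expect_true("gB" %in% ann$genes$gene_id)
  # attributes preserved verbatim on the explicit gene record
  a <- ann$genes$attributes[[match("gA", ann$genes$gene_id)]]
  expect_identical(a[["name"]], "alpha")
  # gene span is the minimal interval over member exons
  expect_equal(ann$genes$start[ann$genes$gene_id == "gA"], 100L)
  expect_equal(ann$genes$end[ann$genes$gene_id == "gA"], 900L)
})

test_that("write -> read round trip is the identity and deterministic", {
  ann <- read_gtf(toy_gtf)
  out1 <- write_gtf(ann)
  out2 <- write_gtf(ann)
  expect_identical(out1, out2)
  ann2 <- read_gtf(out1)
  expect_true(ann_equal(ann, ann2))
  # and across fixture annotations
  fx <- generate_fixture(fixture_config(seed = 11, with_genome = FALSE))
  for (a in list(fx$reference, fx$candidates)) {
    expect_true(ann_equal(a, read_gtf(write_gtf(a),
                                      dialect = a$transcripts$source[1])))
  }
})

test_that("both attribute dialects are accepted on read", {
  gff_style <- c(
    "chr1\ttoy\texon\t10\t50\t.\t+\t.\tgene_id=gX;transcript_id=gX.t1;note=hi"
  )
  ann <- read_gtf(gff_style)
  expect_equal(nrow(ann$exons), 1)
  expect_identical(ann$exons$attributes[[1]][["note"]], "hi")
  # re-emitted in GTF2.2 syntax with gene_id/transcript_id first
  line <- write_gtf(ann)[3]
  expect_match(line, 'gene_id "gX"; transcript_id "gX.t1"; note "hi";',
               fixed = TRUE)
})

test_that("non-core features pass through untouched", {
  with_cds <- c(
    toy_gtf,
    'chr1\ttoy\tCDS\t120\t190\t.\t+\t0\tgene_id "gA"; transcript_id "gA.t1";'
  )
  ann <- read_gtf(with_cds)
  expect_equal(nrow(ann$extras), 1)
  out <- write_gtf(ann)
  expect_true(any(grepl("\tCDS\t", out)))
  expect_true(ann_equal(ann, read_gtf(out)))
})

test_that("malformed input produces named parse errors", {
  expect_error(read_gtf(c(toy_gtf, "chr1\tonly\tthree")),
               "malformed GTF line 11")
  bad_coord <- 'chr1\ttoy\texon\t500\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";'
  expect_error(read_gtf(bad_coord), "coordinate error at line 1")
  dup <- c(
    'chr1\ttoy\ttranscript\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr1\ttoy\ttranscript\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr1\ttoy\texon\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t1";'
  )
  expect_error(read_gtf(dup), "duplicate transcript id 't1'")
  # same transcript id reused on another seqid is a duplication error too
  dup2 <- c(
    'chr1\ttoy\texon\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr2\ttoy\texon\t1\t10\t.\t+\t.\tgene_id "g2"; transcript_id "t1";'
  )
  expect_error(read_gtf(dup2), "duplicate transcript id 't1'")
})

test_that("spliced length is the exon-length sum, not the genomic span", {
  ann <- toy_annotation(list(
    list(tx = "t1", gene = "g1", exons = list(c(101, 200))),
    list(tx = "t2", gene = "g2", exons = list(c(1, 100), c(201, 250)))
  ))
  len <- transcript_lengths(ann)
  expect_equal(len$length[len$transcript_id == "t1"], 100L)
  expect_equal(len$length[len$transcript_id == "t2"], 150L)

  fx <- generate_fixture(fixture_config(seed = 3, with_genome = FALSE))
  got <- transcript_lengths(fx$reference)
  ex_by_tx <- split(fx$reference$exons, fx$reference$exons$transcript_id)
  for (tid in sample(names(ex_by_tx), 25)) {
    expect_equal(got$length[got$transcript_id == tid],
                 length(tx_positions(ex_by_tx[[tid]])))
  }
  # spliced length >= exon count; equals span only when single-exon
  tx <- fx$reference$transcripts
  expect_true(all(got$length[match(tx$transcript_id, got$transcript_id)] >=
                    tx$n_exons))
  span <- tx$end - tx$start + 1L
  eq <- got$length[match(tx$transcript_id, got$transcript_id)] == span
  expect_true(all(eq == (tx$n_exons == 1L)))
})

test_that("intron chains order junctions and skip single-exon transcripts", {
  ann <- toy_annotation(list(
    list(tx = "s", gene = "g1", exons = list(c(1, 100))),
    list(tx = "m", gene = "g2", seqid = "chr2",
         exons = list(c(1, 100), c(201, 300), c(401, 500)))
  ))
  ic <- intron_chains(ann)
  expect_false("s" %in% ic$transcript_id)
  mm <- ic[ic$transcript_id == "m", ]
  expect_equal(mm$donor_end, c(100L, 300L))
  expect_equal(mm$acceptor_start, c(201L, 401L))
})

test_that("interval index agrees with exhaustive scan on random queries", {
  fx <- generate_fixture(fixture_config(seed = 5, with_genome = FALSE))
  ann <- fx$reference
  ex <- ann$exons
  set.seed(99)
  for (i in 1:1000) {
    seqid <- sample(unique(ex$seqid), 1)
    a <- sample.int(60000, 1)
    b <- a + sample.int(3000, 1)
    got <- query_exons(ann, seqid, a, b)
    want <- ex[ex$seqid == seqid & ex$start <= b & ex$end >= a, ]
    expect_setequal(paste(got$transcript_id, got$rank),
                    paste(want$transcript_id, want$rank))
  }
})

test_that("written GTF is read identically by an independent parser", {
  skip_if_not_installed("rtracklayer")
  fx <- generate_fixture(fixture_config(seed = 2, n_genes = 20,
                                        n_candidates = 10,
                                        with_genome = FALSE))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(fx$reference, path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  ours <- fx$reference$exons
  expect_equal(length(ex), nrow(ours))
  key_them <- sort(paste(GenomicRanges::seqnames(ex),
                         GenomicRanges::start(ex), GenomicRanges::end(ex),
                         ex$transcript_id))
  key_us <- sort(paste(ours$seqid, ours$start, ours$end, ours$transcript_id))
  expect_identical(key_them, key_us)
})
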