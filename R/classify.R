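# Four-way classification of candidate transcripts against a reference
# annotation, driven by same-strand exonic overlap and intron-chain identity:
#   novel_gene     no reference gene shares exonic sequence on the strand
#   join_evidence  exonic overlap with >= 2 reference genes (merge evidence)
#   exact_match    one gene, and an isoform with an identical intron chain
#                  (single-exon: reciprocal overlap >= the threshold)
#   novel_isoform  one gene, but no structurally identical isoform
# Overlap is exon-level, never span-level, so a candidate inside an intron is
# novel_gene; antisense-only overlap never links a candidate to a gene.

COMPARISON_CODES <- c("exact_match", "novel_isoform", "join_evidence",
                      "novel_gene")

# reduced (unioned) exon ranges per reference gene, plus lookup tables
build_ref_index <- function(reference) {
  ex <- reference$exons
  gr <- GenomicRanges::GRanges(ex$seqid, IRanges::IRanges(ex$start, ex$end))
  S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(gr)$strand_chr <- ex$strand
  list(
    gr = gr,
    gene_strand = setNames(reference$genes$strand, reference$genes$gene_id),
    gene_start = setNames(reference$genes$start, reference$genes$gene_id),
    sigs = intron_chain_signatures(reference)
  )
}

# overlap in bases between a candidate's exons and the union of a gene's exons
gene_overlap_bases <- function(cand_ir, gene_ex) {
  red <- IRanges::reduce(IRanges::IRanges(gene_ex$start, gene_ex$end))
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(cand_ir), red)))
}

#' Classify candidate transcripts against a reference annotation
#'
#' Assigns each candidate one of four comparison codes (`exact_match`,
#' `novel_isoform`, `join_evidence`, `novel_gene`) from same-strand exonic
#' overlap with reference genes and intron-chain comparison. Unstranded
#' (`"."`) candidates match genes on either strand; if genes on both strands
#' overlap, the gene with the largest exonic overlap wins (ties broken by
#' smaller gene start, then gene id).
#'
#' @param candidates Candidate `tx_annotation`.
#' @param reference Reference `tx_annotation`.
#' @param min_reciprocal_overlap Single-exon exact-match threshold: fraction
#'   of each transcript's length that the overlap must cover (default 0.8).
#' @return Tibble (class `tx_classification`), one row per candidate in
#'   deterministic genomic order: `transcript_id`, `code`,
#'   `overlapping_gene_ids` (list column, genomic order), `n_genes`,
#'   `matched_reference_transcript`, `seqid`, `start`, `strand`.
#' @export
classify_transcripts <- function(candidates, reference,
                                 min_reciprocal_overlap = 0.8) {
  stopifnot(inherits(candidates, "tx_annotation"),
            inherits(reference, "tx_annotation"))
  txs <- candidates$transcripts |>
    arrange(.data$seqid, .data$start, .data$transcript_id)
  out <- tibble(
    transcript_id = txs$transcript_id,
    code = character(nrow(txs)),
    overlapping_gene_ids = vector("list", nrow(txs)),
    n_genes = integer(nrow(txs)),
    matched_reference_transcript = NA_character_,
    seqid = txs$seqid, start = txs$start, strand = txs$strand
  )
  if (nrow(txs) == 0) {
    return(structure(out, class = c("tx_classification", class(out))))
  }

  idx <- build_ref_index(reference)
  ref_ex <- reference$exons
  ref_tx <- reference$transcripts
  cand_ex_all <- candidates$exons
  ex_by_tx <- split(cand_ex_all, cand_ex_all$transcript_id)
  ref_ex_by_gene <- split(ref_ex, ref_ex$gene_id)
  ref_tx_by_gene <- split(ref_tx$transcript_id, ref_tx$gene_id)
  cand_sigs <- intron_chain_signatures(candidates)

  # one overlap query for all candidate exons at once; shared seqlevels keep
  # the overlap engine quiet when scaffold sets differ
  all_seq <- sort(unique(c(cand_ex_all$seqid, ref_ex$seqid)))
  cand_gr <- GenomicRanges::GRanges(
    factor(cand_ex_all$seqid, levels = all_seq),
    IRanges::IRanges(cand_ex_all$start, cand_ex_all$end))
  ref_gr <- GenomicRanges::GRanges(
    factor(ref_ex$seqid, levels = all_seq),
    IRanges::IRanges(ref_ex$start, ref_ex$end))
  S4Vectors::mcols(ref_gr) <- S4Vectors::mcols(idx$gr)
  hits <- GenomicRanges::findOverlaps(cand_gr, ref_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  cand_strand_hit <- cand_ex_all$strand[qh]
  ref_strand_hit <- S4Vectors::mcols(idx$gr)$strand_chr[sh]
  ok <- cand_strand_hit == "." | ref_strand_hit == "." |
    cand_strand_hit == ref_strand_hit
  hit_tab <- tibble(
    transcript_id = cand_ex_all$transcript_id[qh][ok],
    gene_id = S4Vectors::mcols(idx$gr)$gene_id[sh][ok]
  ) |> distinct()
  genes_by_cand <- split(hit_tab$gene_id, hit_tab$transcript_id)

  for (i in seq_len(nrow(txs))) {
    tid <- txs$transcript_id[i]
    cstrand <- txs$strand[i]
    cex <- ex_by_tx[[tid]]
    cand_ir <- IRanges::IRanges(cex$start, cex$end)
    genes <- genes_by_cand[[tid]] %||% character()

    if (cstrand == "." && length(genes) > 1) {
      strands <- idx$gene_strand[genes]
      if (length(unique(strands[strands %in% c("+", "-")])) > 1) {
        ov <- map_dbl(genes, function(g) {
          gene_overlap_bases(cand_ir, ref_ex_by_gene[[g]])
        })
        ordv <- order(-ov, idx$gene_start[genes], genes)
        genes <- genes[ordv[1]]
      }
    }

    genes <- genes[order(idx$gene_start[genes], genes)]
    n <- length(genes)
    out$overlapping_gene_ids[[i]] <- genes
    out$n_genes[i] <- n

    if (n == 0) {
      out$code[i] <- "novel_gene"
    } else if (n >= 2) {
      out$code[i] <- "join_evidence"
    } else {
      g <- genes
      isoforms <- ref_tx_by_gene[[g]]
      matched <- NA_character_
      if (nrow(cex) > 1) {
        same <- isoforms[idx$sigs[isoforms] == cand_sigs[[tid]] &
                           nzchar(idx$sigs[isoforms])]
        if (length(same)) matched <- sort(same)[1]
      } else {
        single <- isoforms[!nzchar(idx$sigs[isoforms])]
        if (length(single)) {
          clen <- sum(IRanges::width(cand_ir))
          ovs <- map_dbl(single, function(s) {
            gene_overlap_bases(cand_ir, ref_ex_by_gene[[g]] |>
                                 filter(.data$transcript_id == s))
          })
          lens <- map_dbl(single, function(s) {
            e <- ref_ex_by_gene[[g]] |> filter(.data$transcript_id == s)
            sum(e$end - e$start + 1)
          })
          recip <- ovs / clen >= min_reciprocal_overlap &
            ovs / lens >= min_reciprocal_overlap
          if (any(recip)) {
            cand_iso <- single[recip]
            ordv <- order(-ovs[recip], cand_iso)
            matched <- cand_iso[ordv[1]]
          }
        }
      }
      if (!is.na(matched)) {
        out$code[i] <- "exact_match"
        out$matched_reference_transcript[i] <- matched
      } else {
        out$code[i] <- "novel_isoform"
      }
    }
  }
  structure(out, class = c("tx_classification", class(out)))
}

#' @export
tidy.tx_classification <- function(x, ...) {
  x |>
    mutate(overlapping_gene_ids = map_chr(.data$overlapping_gene_ids,
                                          paste, collapse = ",")) |>
    as_tibble()
}

#' Per-code classification counts
#'
#' @param x A `tx_classification`.
#' @param ... Unused.
#' @return One-row tibble with candidate totals per comparison code.
#' @export
glance.tx_classification <- function(x, ...) {
  counts <- table(factor(x$code, levels = COMPARISON_CODES))
  tibble(
    n_candidates = nrow(x),
    exact_match = as.integer(counts[["exact_match"]]),
    novel_isoform = as.integer(counts[["novel_isoform"]]),
    join_evidence = as.integer(counts[["join_evidence"]]),
    novel_gene = as.integer(counts[["novel_gene"]])
  )
}
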