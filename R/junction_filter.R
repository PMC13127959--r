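# Junction-support pre-filter: candidate transcripts must have every novel
# splice junction (one absent from the reference annotation) supported by
# spliced reads with sufficient anchor length, and sufficient transcript
# coverage where the assembler reported one. Defaults mirror common
# assembly-stage thresholds (4 supporting reads, 15 anchor bases, coverage 10).

#' Splice junctions of a reference annotation
#'
#' Union of the intron chains of all reference transcripts, keyed with strand.
#'
#' @param reference A `tx_annotation`.
#' @return Tibble: `seqid`, `donor_end`, `acceptor_start`, `strand` (distinct
#'   rows).
#' @export
reference_junctions <- function(reference) {
  intron_chains(reference) |>
    distinct(.data$seqid, .data$donor_end, .data$acceptor_start, .data$strand)
}

junction_key <- function(seqid, donor_end, acceptor_start) {
  paste(seqid, donor_end, acceptor_start, sep = ":")
}

#' Filter candidate transcripts by novel-junction support and coverage
#'
#' A candidate passes iff every junction of its intron chain that is not in
#' the reference junction set has evidence with `read_count >=
#' min_junction_reads` and `min_anchor >= min_anchor`, and (when the candidate
#' carries a coverage value) `coverage >= min_coverage`. A novel junction with
#' no evidence row counts as 0 supporting reads. Strand matching requires
#' agreement, except strand `"."` (unknown) on either side matches anything.
#'
#' @param candidates A candidate `tx_annotation`.
#' @param ref_junctions Tibble from [reference_junctions()].
#' @param evidence Tibble with columns `seqid`, `donor_end`, `acceptor_start`,
#'   `strand`, `read_count`, `min_anchor` (one row per observed junction).
#' @param min_junction_reads Minimum spliced reads supporting each novel
#'   junction (default 4).
#' @param min_anchor Minimum anchor alignment length in bases (default 15).
#' @param min_coverage Minimum assembler-reported transcript coverage
#'   (default 10); transcripts without a coverage value skip this rule.
#' @return Tibble (class `tx_junction_filter`): `transcript_id`, `pass`,
#'   `reason` (`NA` for passing transcripts; otherwise names the first
#'   violated junction or the coverage rule).
#' @export
filter_by_junctions <- function(candidates, ref_junctions, evidence,
                                min_junction_reads = 4, min_anchor = 15,
                                min_coverage = 10) {
  stopifnot(inherits(candidates, "tx_annotation"))
  if (min_junction_reads < 0 || min_anchor < 0 || min_coverage < 0) {
    abort("thresholds must be nonnegative")
  }
  evidence <- as_tibble(evidence)
  if (nrow(evidence)) {
    if (any(evidence$acceptor_start <= evidence$donor_end)) {
      abort("junction evidence with acceptor_start <= donor_end")
    }
    if (any(evidence$read_count < 0) || any(evidence$min_anchor < 0)) {
      abort("junction evidence with negative read_count or min_anchor")
    }
  }

  txs <- candidates$transcripts
  res <- tibble(transcript_id = txs$transcript_id, pass = TRUE,
                reason = NA_character_)
  if (nrow(txs) == 0) {
    return(structure(res, class = c("tx_junction_filter", class(res))))
  }

  ref_keys <- character()
  ref_strand <- character()
  if (nrow(ref_junctions)) {
    ref_keys <- junction_key(ref_junctions$seqid, ref_junctions$donor_end,
                             ref_junctions$acceptor_start)
    ref_strand <- ref_junctions$strand
  }
  ev_keys <- character()
  if (nrow(evidence)) {
    ev_keys <- junction_key(evidence$seqid, evidence$donor_end,
                            evidence$acceptor_start)
  }

  cand_j <- intron_chains(candidates)
  j_by_tx <- split(cand_j, cand_j$transcript_id)

  strand_ok <- function(a, b) a == "." | b == "." | a == b

  for (i in seq_len(nrow(txs))) {
    tx <- txs[i, ]
    jj <- j_by_tx[[tx$transcript_id]]
    fail <- NA_character_
    if (!is.null(jj) && nrow(jj)) {
      jj <- jj |> arrange(.data$donor_end)
      for (k in seq_len(nrow(jj))) {
        key <- junction_key(jj$seqid[k], jj$donor_end[k], jj$acceptor_start[k])
        in_ref <- any(ref_keys == key & strand_ok(ref_strand, jj$strand[k]))
        if (in_ref) next
        hit <- which(ev_keys == key &
                       strand_ok(evidence$strand, jj$strand[k]))
        reads <- if (length(hit)) max(evidence$read_count[hit]) else 0
        anchors <- if (length(hit)) {
          max(evidence$min_anchor[hit][evidence$read_count[hit] == reads])
        } else 0
        supported <- length(hit) > 0 &&
          any(evidence$read_count[hit] >= min_junction_reads &
                evidence$min_anchor[hit] >= min_anchor)
        if (!supported) {
          fail <- sprintf(
            "junction %s:%d-%d: read_count %d, min_anchor %d (need >= %g reads, >= %g anchor)",
            jj$seqid[k], jj$donor_end[k], jj$acceptor_start[k],
            as.integer(reads), as.integer(anchors),
            min_junction_reads, min_anchor)
          break
        }
      }
    }
    if (is.na(fail) && !is.na(tx$coverage) && tx$coverage < min_coverage) {
      fail <- sprintf("coverage %g < %g", tx$coverage, min_coverage)
    }
    if (!is.na(fail)) {
      res$pass[i] <- FALSE
      res$reason[i] <- fail
    }
  }
  structure(res, class = c("tx_junction_filter", class(res)))
}
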