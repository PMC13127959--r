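# Annotation data model: a gene -> transcript -> exon hierarchy held as three
# tibbles. Coordinates follow GTF convention throughout (1-based, closed).
# Strand is one of "+", "-", "." (unknown).

STRANDS <- c("+", "-", ".")
DEFAULT_GTF_SOURCE <- "txrefine"

empty_exon_table <- function() {
  tibble(
    transcript_id = character(), gene_id = character(), seqid = character(),
    start = integer(), end = integer(), strand = character(),
    rank = integer(), gtf_source = character(), attributes = list()
  )
}

empty_transcript_table <- function() {
  tibble(
    transcript_id = character(), gene_id = character(), seqid = character(),
    strand = character(), start = integer(), end = integer(),
    n_exons = integer(), coverage = double(), source = character(),
    gtf_source = character(), attributes = list()
  )
}

empty_gene_table <- function() {
  tibble(
    gene_id = character(), seqid = character(), strand = character(),
    start = integer(), end = integer(), n_transcripts = integer(),
    gtf_source = character(), attributes = list()
  )
}

empty_extra_table <- function() {
  tibble(
    transcript_id = character(), seqid = character(), gtf_source = character(),
    feature = character(), start = integer(), end = integer(),
    score = character(), strand = character(), frame = character(),
    attributes = list(), line_order = integer()
  )
}

new_annotation <- function(genes, transcripts, exons,
                           extras = empty_extra_table()) {
  structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         extras = extras),
    class = "tx_annotation"
  )
}

#' Build an annotation from an exon table
#'
#' Constructs the package's annotation container (genes, transcripts, exons)
#' from a tibble of exon records. Transcript and gene records are derived:
#' transcript spans cover their exons, gene spans cover all member exons, exon
#' ranks are assigned 5'->3' in genome coordinates.
#'
#' @param exons Tibble with columns `transcript_id`, `gene_id`, `seqid`,
#'   `start`, `end`, `strand`. Optional: `gtf_source`, `attributes`
#'   (list column of named character vectors).
#' @param transcript_meta Optional tibble keyed by `transcript_id` with any of
#'   `coverage`, `gtf_source`, `attributes` to attach to transcript records.
#' @param gene_meta Optional tibble keyed by `gene_id` with any of
#'   `gtf_source`, `attributes`.
#' @param source Provenance of the transcripts: `"reference"` or
#'   `"candidate"`.
#' @param extras Pass-through feature table (non gene/transcript/exon GTF
#'   records attached to a transcript), normally only populated by
#'   [read_gtf()].
#' @return A `tx_annotation` object.
#' @export
annotation <- function(exons, transcript_meta = NULL, gene_meta = NULL,
                       source = c("reference", "candidate"),
                       extras = empty_extra_table()) {
  source <- match.arg(source)
  exons <- as_tibble(exons)
  if (nrow(exons) == 0) {
    return(new_annotation(empty_gene_table(), empty_transcript_table(),
                          empty_exon_table(), extras))
  }
  required <- c("transcript_id", "gene_id", "seqid", "start", "end", "strand")
  missing <- setdiff(required, names(exons))
  if (length(missing)) {
    abort(paste0("exon table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (!"gtf_source" %in% names(exons)) exons$gtf_source <- DEFAULT_GTF_SOURCE
  if (!"attributes" %in% names(exons)) {
    exons$attributes <- rep(list(character()), nrow(exons))
  }
  check_coords(exons)
  if (!all(exons$strand %in% STRANDS)) {
    abort("exon strand must be one of '+', '-', '.'")
  }

  exons <- exons |>
    arrange(.data$seqid, .data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("transcript_id", "gene_id", "seqid", "start", "end", "strand",
           "rank", "gtf_source", "attributes")

  check_transcript_consistency(exons)

  transcripts <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1], seqid = .data$seqid[1],
      strand = .data$strand[1],
      start = min(.data$start), end = max(.data$end),
      n_exons = dplyr::n(), .groups = "drop"
    ) |>
    mutate(coverage = NA_real_, source = source,
           gtf_source = DEFAULT_GTF_SOURCE,
           attributes = rep(list(character()), dplyr::n()))
  if (!is.null(transcript_meta)) {
    transcripts <- merge_meta(transcripts, as_tibble(transcript_meta),
                              "transcript_id")
  }

  genes <- transcripts |>
    group_by(.data$gene_id) |>
    summarise(
      seqid = .data$seqid[1],
      strand = if (length(unique(.data$strand)) == 1) .data$strand[1] else ".",
      start = min(.data$start), end = max(.data$end),
      n_transcripts = dplyr::n(), .groups = "drop"
    ) |>
    mutate(gtf_source = DEFAULT_GTF_SOURCE,
           attributes = rep(list(character()), dplyr::n()))
  if (!is.null(gene_meta)) {
    genes <- merge_meta(genes, as_tibble(gene_meta), "gene_id")
  }

  bad <- transcripts |>
    group_by(.data$gene_id) |>
    summarise(k = length(unique(.data$seqid)), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(bad)) {
    abort(paste0("gene '", bad$gene_id[1],
                 "' has member transcripts on more than one seqid"))
  }

  ann <- new_annotation(arrange(genes, .data$seqid, .data$start, .data$gene_id),
                        arrange(transcripts, .data$seqid, .data$start,
                                .data$transcript_id),
                        exons, extras)
  ann
}

# overwrite coverage/gtf_source/attributes columns from a metadata tibble
merge_meta <- function(base, meta, key) {
  idx <- match(base[[key]], meta[[key]])
  for (col in intersect(c("coverage", "gtf_source", "attributes"), names(meta))) {
    hit <- !is.na(idx)
    if (col == "attributes") {
      base[[col]][hit] <- meta[[col]][idx[hit]]
    } else {
      base[[col]][hit] <- meta[[col]][idx[hit]]
    }
  }
  base
}

check_coords <- function(tab, line = NULL) {
  if (any(is.na(tab$start) | is.na(tab$end))) {
    abort("non-numeric start/end coordinate")
  }
  if (any(tab$start < 1)) abort("coordinate error: start < 1")
  bad <- which(tab$end < tab$start)
  if (length(bad)) {
    where <- if (!is.null(line)) paste0(" at line ", line[bad[1]]) else ""
    abort(paste0("coordinate error: end < start", where))
  }
  invisible(TRUE)
}

check_transcript_consistency <- function(exons) {
  per_tx <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      n_gene = length(unique(.data$gene_id)),
      n_seq = length(unique(.data$seqid)),
      n_strand = length(unique(.data$strand)),
      overlapping = dplyr::n() > 1 &&
        any(.data$start[-1] <= cummax(.data$end)[-dplyr::n()]),
      .groups = "drop"
    )
  bad <- per_tx |> filter(.data$n_gene > 1 | .data$n_seq > 1)
  if (nrow(bad)) {
    abort(paste0("duplicate transcript id '", bad$transcript_id[1],
                 "': used with more than one gene_id or seqid"))
  }
  bad <- per_tx |> filter(.data$n_strand > 1)
  if (nrow(bad)) {
    abort(paste0("transcript '", bad$transcript_id[1],
                 "' mixes strands across exons"))
  }
  bad <- per_tx |> filter(.data$overlapping)
  if (nrow(bad)) {
    abort(paste0("transcript '", bad$transcript_id[1],
                 "' has overlapping exons"))
  }
  invisible(TRUE)
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat("<tx_annotation> ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts, ", nrow(x$exons), " exons\n",
      sep = "")
  if (nrow(x$genes)) {
    cat("  seqids: ", paste(unique(x$genes$seqid), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
tidy.tx_annotation <- function(x, ...) x$exons

#' Annotation-level counts
#'
#' @param x A `tx_annotation`.
#' @param ... Unused.
#' @return One-row tibble with gene/transcript/exon counts.
#' @export
glance.tx_annotation <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_transcripts = nrow(x$transcripts),
    n_exons = nrow(x$exons),
    n_seqids = length(unique(x$genes$seqid))
  )
}

#' Spliced transcript lengths
#'
#' Sum of exon lengths (end - start + 1) per transcript: the mature transcript
#' length, not the genomic span.
#'
#' @param ann A `tx_annotation`.
#' @return Tibble with `transcript_id` and `length` (bases).
#' @export
transcript_lengths <- function(ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  if (nrow(ann$exons) == 0) {
    return(tibble(transcript_id = character(), length = integer()))
  }
  ann$exons |>
    group_by(.data$transcript_id) |>
    summarise(length = sum(.data$end - .data$start + 1L), .groups = "drop")
}

#' Intron chains of all transcripts
#'
#' For a transcript of n exons returns its n - 1 splice junctions as
#' (donor_end, acceptor_start) pairs ordered by coordinate; single-exon
#' transcripts contribute no rows.
#'
#' @param ann A `tx_annotation`.
#' @return Tibble: `transcript_id`, `seqid`, `strand`, `donor_end`,
#'   `acceptor_start`.
#' @export
intron_chains <- function(ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  ex <- ann$exons
  if (nrow(ex) == 0) {
    return(tibble(transcript_id = character(), seqid = character(),
                  strand = character(), donor_end = integer(),
                  acceptor_start = integer()))
  }
  ex |>
    arrange(.data$transcript_id, .data$rank) |>
    group_by(.data$transcript_id) |>
    summarise(
      seqid = .data$seqid[1], strand = .data$strand[1],
      donor_end = list(.data$end[-dplyr::n()]),
      acceptor_start = list(.data$start[-1]),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("donor_end", "acceptor_start")) |>
    arrange(.data$seqid, .data$donor_end, .data$acceptor_start)
}

# string signature of a transcript's intron chain ("" for single-exon)
intron_chain_signatures <- function(ann) {
  tx <- ann$transcripts$transcript_id
  sig <- setNames(rep("", length(tx)), tx)
  ic <- intron_chains(ann)
  if (nrow(ic)) {
    s <- ic |>
      arrange(.data$transcript_id, .data$donor_end) |>
      group_by(.data$transcript_id) |>
      summarise(sig = paste(.data$donor_end, .data$acceptor_start,
                            sep = "-", collapse = "|"),
                .groups = "drop")
    sig[s$transcript_id] <- s$sig
  }
  sig
}

#' Query exons overlapping an interval
#'
#' Interval lookup over an annotation's exons, backed by an IRanges overlap
#' index.
#'
#' @param ann A `tx_annotation`.
#' @param seqid Scaffold identifier.
#' @param start,end Query interval (1-based, closed).
#' @param strand Optional strand filter; `"."` (and exons stored as `"."`)
#'   match either strand.
#' @return The matching rows of the exon table.
#' @export
query_exons <- function(ann, seqid, start, end, strand = NULL) {
  stopifnot(inherits(ann, "tx_annotation"))
  ex <- ann$exons
  if (nrow(ex) == 0) return(ex)
  gr <- GenomicRanges::GRanges(
    ex$seqid, IRanges::IRanges(ex$start, ex$end)
  )
  q <- GenomicRanges::GRanges(seqid, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  out <- ex[S4Vectors::subjectHits(hits), ]
  if (!is.null(strand) && strand %in% c("+", "-")) {
    out <- out |> filter(.data$strand %in% c(!!strand, "."))
  }
  out
}
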