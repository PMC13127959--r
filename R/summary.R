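# Reporting: assembly summary statistics, and gene-level BUSCO
# reconciliation. Rounding is half-up at the stated precision (1 decimal for
# transcripts-per-gene ratios, 2 decimals for percentages, integer for mean
# and median lengths); R's round() is round-half-even, so a dedicated helper
# is used.

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used by all reported statistics in this package (R's `round()` rounds half
#' to even).
#'
#' @param x Numeric vector (nonnegative in all package uses).
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage with fixed rounding
#'
#' `100 * count / total`, rounded half-up to 2 decimals.
#'
#' @param count Integer count, `0 <= count <= total`.
#' @param total Positive total.
#' @return Percentage (2 decimals).
#' @export
percentage <- function(count, total) {
  if (any(total <= 0)) abort("percentage: total must be > 0")
  if (any(count < 0) || any(count > total)) {
    abort("percentage: count must be within [0, total]")
  }
  round_half_up(100 * count / total, 2)
}

#' Mean transcripts per gene with fixed rounding
#'
#' `n_transcripts / n_genes`, rounded half-up to 1 decimal — the convention
#' used in assembly summary tables.
#'
#' @param n_transcripts,n_genes Counts.
#' @return Ratio (1 decimal).
#' @export
transcripts_per_gene <- function(n_transcripts, n_genes) {
  if (any(n_genes <= 0)) abort("transcripts_per_gene: n_genes must be > 0")
  round_half_up(n_transcripts / n_genes, 1)
}

#' Assembly summary statistics
#'
#' Gene and transcript counts, transcripts-per-gene statistics, and spliced
#' transcript-length statistics for an annotation. Mean transcripts per gene
#' is rounded half-up to 1 decimal; mean length is rounded half-up to an
#' integer; the median of an even count is the mean of the central pair,
#' rounded half-up to an integer.
#'
#' @param ann A `tx_annotation`.
#' @return One-row tibble (class `tx_assembly_summary`): `n_genes`,
#'   `n_transcripts`, `mean_tx_per_gene`, `max_tx_per_gene`,
#'   `mean_tx_length`, `median_tx_length`, `max_tx_length`.
#' @export
assembly_summary <- function(ann) {
  stopifnot(inherits(ann, "tx_annotation"))
  ng <- nrow(ann$genes)
  nt <- nrow(ann$transcripts)
  if (nt == 0) {
    out <- tibble(n_genes = 0L, n_transcripts = 0L, mean_tx_per_gene = 0,
                  max_tx_per_gene = 0L, mean_tx_length = 0L,
                  median_tx_length = 0L, max_tx_length = 0L)
    return(structure(out, class = c("tx_assembly_summary", class(out))))
  }
  lens <- transcript_lengths(ann)$length
  out <- tibble(
    n_genes = ng,
    n_transcripts = nt,
    mean_tx_per_gene = transcripts_per_gene(nt, ng),
    max_tx_per_gene = max(ann$genes$n_transcripts),
    mean_tx_length = as.integer(round_half_up(mean(lens))),
    median_tx_length = as.integer(round_half_up(median(lens))),
    max_tx_length = max(lens)
  )
  structure(out, class = c("tx_assembly_summary", class(out)))
}

BUSCO_CATEGORIES <- c("complete_total", "complete_single",
                      "complete_duplicated", "fragmented", "missing")

#' Gene-level BUSCO reconciliation
#'
#' Collapses per-transcript BUSCO hits to gene level: for each ortholog,
#' multiple complete hits on isoforms of one gene count as a single complete
#' gene; complete hits on two or more distinct genes are duplicated; an
#' ortholog with only fragmented hits is fragmented; orthologs absent from
#' the hit table are missing. Complete takes precedence over fragmented
#' within one ortholog.
#'
#' @param hits Tibble with columns `busco_id`, `transcript_id`, `status`
#'   (`"complete"` or `"fragmented"`).
#' @param tx_to_gene Transcript-to-gene mapping (named character vector or a
#'   tibble with `transcript_id`, `gene_id`) covering every hit transcript.
#' @param total_orthologs Size of the ortholog set assessed (e.g. 1013 for
#'   arthropoda_odb10).
#' @return Tibble (class `tx_busco_table`): `category`, `count`, `percent`
#'   (half-up, 2 decimals) over the five categories; `complete_total` always
#'   equals single + duplicated and the exclusive categories sum to
#'   `total_orthologs`.
#' @export
busco_gene_reconcile <- function(hits, tx_to_gene, total_orthologs) {
  hits <- as_tibble(hits)
  if (nrow(hits) && !all(hits$status %in% c("complete", "fragmented"))) {
    abort("BUSCO hit status must be 'complete' or 'fragmented'")
  }
  if (is.data.frame(tx_to_gene)) {
    tx_to_gene <- setNames(tx_to_gene$gene_id, tx_to_gene$transcript_id)
  }
  unknown <- setdiff(hits$transcript_id, names(tx_to_gene))
  if (length(unknown)) {
    abort(paste0("BUSCO hit on unknown transcript '", unknown[1], "'"))
  }
  n_observed <- length(unique(hits$busco_id))
  if (total_orthologs < n_observed) {
    abort("total_orthologs smaller than the number of distinct busco_ids")
  }

  if (nrow(hits)) {
    per <- hits |>
      mutate(gene_id = unname(tx_to_gene[.data$transcript_id])) |>
      group_by(.data$busco_id) |>
      summarise(
        n_complete_genes = length(unique(
          .data$gene_id[.data$status == "complete"])),
        any_fragmented = any(.data$status == "fragmented"),
        .groups = "drop"
      )
    single <- sum(per$n_complete_genes == 1)
    duplicated <- sum(per$n_complete_genes >= 2)
    fragmented <- sum(per$n_complete_genes == 0 & per$any_fragmented)
  } else {
    single <- duplicated <- fragmented <- 0L
  }
  missing <- total_orthologs - n_observed
  counts <- c(
    complete_total = single + duplicated,
    complete_single = single,
    complete_duplicated = duplicated,
    fragmented = fragmented,
    missing = missing
  )
  out <- tibble(
    category = BUSCO_CATEGORIES,
    count = as.integer(counts[BUSCO_CATEGORIES]),
    percent = percentage(as.integer(counts[BUSCO_CATEGORIES]),
                         total_orthologs)
  )
  attr(out, "total_orthologs") <- total_orthologs
  structure(out, class = c("tx_busco_table", class(out)))
}

#' Read a minimal BUSCO hit table
#'
#' Tab-delimited with header `busco_id`, `transcript_id`, `status`. (An
#' adapter for full BUSCO `full_table.tsv` output is deliberately out of
#' scope; reduce that format to these three columns upstream.)
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_busco_hits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    busco_id = readr::col_character(),
                    transcript_id = readr::col_character(),
                    status = readr::col_character()
                  ))
}
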