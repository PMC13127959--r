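# Three-rule expression filter for novel transcripts, applied to an
# expected-count matrix (transcripts x samples, RSEM-style fractional counts).
# A novel transcript is eliminated if it fails ANY of:
#   1. expressed (count > 0) in fewer than `min_sample_fraction` of samples
#   2. summed reads across all samples fewer than `min_total_reads`
#   3. its share of its gene's summed reads less than `min_gene_fraction`
# Boundary semantics are strict-less-than failure: a value exactly at a
# threshold passes. Gene totals pool all transcripts mapped to the same
# (post-integration) gene over all samples jointly; a zero gene total gives
# gene fraction 1 by convention. Reference transcripts are never filtered.

#' Apply the three-rule expression filter to novel transcripts
#'
#' @param expr Expression matrix as a tibble: first column `transcript_id`,
#'   remaining columns one per sample (nonnegative expected counts).
#' @param novel_ids Character vector of transcript ids subject to filtering;
#'   all must be present in `expr`.
#' @param gene_of Transcript-to-gene mapping covering every matrix
#'   transcript: a named character vector, or a tibble with columns
#'   `transcript_id` and `gene_id`. Use post-integration gene membership
#'   (merged units pool their member transcripts).
#' @param min_sample_fraction Fail rule 1 below this fraction of samples with
#'   nonzero expression (default 0.30).
#' @param min_total_reads Fail rule 2 below this summed count (default 10).
#' @param min_gene_fraction Fail rule 3 below this share of the gene total
#'   (default 0.10).
#' @return Tibble (class `tx_filter_report`), one row per matrix transcript:
#'   `transcript_id`, `novel`, `kept`, `fail_sample_fraction`,
#'   `fail_total_reads`, `fail_gene_fraction`, `failed_rules`,
#'   `expressed_sample_count`, `total_reads`, `gene_fraction`.
#' @export
expression_filter <- function(expr, novel_ids, gene_of,
                              min_sample_fraction = 0.30,
                              min_total_reads = 10,
                              min_gene_fraction = 0.10) {
  expr <- as_tibble(expr)
  if (!"transcript_id" %in% names(expr)) {
    abort("expression matrix must have a transcript_id column")
  }
  if (min_sample_fraction < 0 || min_sample_fraction > 1 ||
      min_gene_fraction < 0 || min_gene_fraction > 1 || min_total_reads < 0) {
    abort("filter thresholds out of bounds")
  }
  if (anyDuplicated(expr$transcript_id)) {
    abort("duplicate transcript_id rows in expression matrix")
  }
  vals <- as.matrix(expr[setdiff(names(expr), "transcript_id")])
  if (!is.numeric(vals)) abort("expression values must be numeric")
  if (any(vals < 0)) abort("expression matrix has negative entries")
  n_samples <- ncol(vals)
  tx <- expr$transcript_id

  missing <- setdiff(novel_ids, tx)
  if (length(missing)) {
    abort(paste0("novel transcript '", missing[1],
                 "' absent from the expression matrix"))
  }

  if (is.data.frame(gene_of)) {
    gene_of <- setNames(gene_of$gene_id, gene_of$transcript_id)
  }
  unmapped <- setdiff(tx, names(gene_of))
  if (length(unmapped)) {
    abort(paste0("transcript '", unmapped[1], "' has no gene mapping"))
  }
  gene <- unname(gene_of[tx])

  expressed <- rowSums(vals > 0)
  total <- rowSums(vals)
  gene_total <- as.vector(tapply(total, gene, sum)[gene])
  gene_fraction <- ifelse(gene_total > 0, total / gene_total, 1)

  novel <- tx %in% novel_ids
  fail1 <- novel & (expressed / n_samples < min_sample_fraction)
  fail2 <- novel & (total < min_total_reads)
  fail3 <- novel & (gene_fraction < min_gene_fraction)

  failed_rules <- pmap(list(fail1, fail2, fail3), function(a, b, c) {
    c("sample_fraction", "total_reads", "gene_fraction")[c(a, b, c)]
  })

  out <- tibble(
    transcript_id = tx,
    novel = novel,
    kept = !(fail1 | fail2 | fail3),
    fail_sample_fraction = fail1,
    fail_total_reads = fail2,
    fail_gene_fraction = fail3,
    failed_rules = map_chr(failed_rules, paste, collapse = ","),
    expressed_sample_count = as.integer(expressed),
    total_reads = total,
    gene_fraction = unname(gene_fraction)
  )
  structure(out, class = c("tx_filter_report", class(out)))
}

#' Filter-report totals
#'
#' @param x A `tx_filter_report`.
#' @param ... Unused.
#' @return One-row tibble: novel transcripts in, kept, removed, and per-rule
#'   failure counts.
#' @export
glance.tx_filter_report <- function(x, ...) {
  nv <- x |> filter(.data$novel)
  tibble(
    n_novel = nrow(nv),
    n_kept = sum(nv$kept),
    n_removed = sum(!nv$kept),
    fail_sample_fraction = sum(nv$fail_sample_fraction),
    fail_total_reads = sum(nv$fail_total_reads),
    fail_gene_fraction = sum(nv$fail_gene_fraction)
  )
}

#' @export
autoplot.tx_filter_report <- function(object, ...) {
  nv <- as_tibble(object) |> filter(.data$novel)
  counts <- tibble(
    rule = factor(c("sample_fraction", "total_reads", "gene_fraction", "kept"),
                  levels = c("kept", "sample_fraction", "total_reads",
                             "gene_fraction")),
    n = c(sum(nv$fail_sample_fraction), sum(nv$fail_total_reads),
          sum(nv$fail_gene_fraction), sum(nv$kept))
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$rule, y = .data$n)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::labs(x = NULL, y = "novel transcripts",
                  title = "Expression-filter outcomes") +
    ggplot2::theme_minimal()
}

#' Read a tab-delimited expression matrix
#'
#' First column `transcript_id`, remaining columns samples.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_expression_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "transcript_id"
  out
}

#' Read a tab-delimited splice-junction evidence table
#'
#' Expects header columns `seqid`, `donor_end`, `acceptor_start`, `strand`,
#' `read_count`, `min_anchor`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_junction_evidence <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    seqid = readr::col_character(),
                    donor_end = readr::col_integer(),
                    acceptor_start = readr::col_integer(),
                    strand = readr::col_character(),
                    read_count = readr::col_double(),
                    min_anchor = readr::col_double()
                  ))
}
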