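# End-to-end refinement driver: junction filter -> classification -> merge
# components -> expression filter -> integration -> summaries. Merge
# components are rebuilt from the expression-surviving join transcripts so
# every merge in the output is backed by retained evidence.

#' Run the full annotation-refinement pipeline
#'
#' Chains all stages and (optionally) writes the artifact set: `updated.gtf`,
#' `provenance.tsv`, `classified.tsv`, `merges.tsv`, `filter_report.tsv`,
#' `junction_filter.tsv`, `summary.txt` (and `intermediate.gtf` with
#' `emit_intermediate`). Per-stage counts are collected in a log and printed
#' when `verbose`.
#'
#' @param reference Reference annotation: a `tx_annotation` or a GTF path.
#' @param candidates Candidate annotation: a `tx_annotation` or a GTF path
#'   (candidate dialect).
#' @param expression Expression matrix: tibble or TSV path (first column
#'   `transcript_id`).
#' @param junctions Junction evidence: tibble or TSV path.
#' @param genome Optional soft-masked genome (named character vector or FASTA
#'   path) for soft-mask QC columns in the summary.
#' @param busco Optional BUSCO hit table (tibble or TSV path with `busco_id`,
#'   `transcript_id`, `status`) evaluated against the updated annotation.
#' @param out_dir Optional output directory for the artifact set.
#' @param min_junction_reads,min_anchor,min_coverage Junction-filter
#'   thresholds (defaults 4, 15, 10).
#' @param min_sample_fraction,min_total_reads,min_gene_fraction
#'   Expression-filter thresholds (defaults 0.30, 10, 0.10).
#' @param min_reciprocal_overlap Single-exon exact-match threshold.
#' @param scheme Identifier scheme for new genes.
#' @param total_orthologs Ortholog-set size for the BUSCO table (required
#'   when `busco` is given).
#' @param emit_intermediate Also write the pre-expression-filter intermediate
#'   annotation.
#' @param verbose Print per-stage counts.
#' @return A `tx_refinement` list: `updated`, `integration`, `classified`,
#'   `junction_filter`, `filter_report`, `components`, `summary` (reference
#'   and updated assembly summaries), `busco` (or `NULL`), `log` (tibble of
#'   per-stage counts).
#' @export
run_pipeline <- function(reference, candidates, expression, junctions,
                         genome = NULL, busco = NULL, out_dir = NULL,
                         min_junction_reads = 4, min_anchor = 15,
                         min_coverage = 10,
                         min_sample_fraction = 0.30, min_total_reads = 10,
                         min_gene_fraction = 0.10,
                         min_reciprocal_overlap = 0.8,
                         scheme = id_scheme(), total_orthologs = NULL,
                         emit_intermediate = FALSE, verbose = FALSE) {
  if (is.character(reference)) reference <- read_gtf(reference, "reference")
  if (is.character(candidates)) candidates <- read_gtf(candidates, "candidate")
  if (is.character(expression)) expression <- read_expression_matrix(expression)
  if (is.character(junctions)) junctions <- read_junction_evidence(junctions)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  if (is.character(busco)) busco <- read_busco_hits(busco)

  log <- list()
  note <- function(stage, count) {
    log[[length(log) + 1]] <<- tibble(stage = stage, count = as.integer(count))
    if (verbose) message(sprintf("[%s] %d", stage, count))
  }
  note("candidates_in", nrow(candidates$transcripts))

  # 1. junction/coverage filter
  jf <- filter_by_junctions(candidates, reference_junctions(reference),
                            junctions,
                            min_junction_reads = min_junction_reads,
                            min_anchor = min_anchor,
                            min_coverage = min_coverage)
  pass_ids <- jf$transcript_id[jf$pass]
  note("junction_pass", length(pass_ids))
  note("junction_fail", sum(!jf$pass))

  passing <- subset_annotation(candidates, pass_ids)

  # 2. classification
  cls <- classify_transcripts(passing, reference,
                              min_reciprocal_overlap = min_reciprocal_overlap)
  for (code in COMPARISON_CODES) {
    note(paste0("classified_", code), sum(cls$code == code))
  }

  # 3. provisional gene membership (merged units pool their transcripts) for
  #    the expression-filter denominators
  comp0 <- build_merge_components(cls, reference)
  gene_of <- pipeline_gene_membership(reference, candidates, cls, comp0,
                                      expression$transcript_id)

  # 4. expression filter on novel (non-exact) junction survivors
  novel_ids <- cls$transcript_id[cls$code != "exact_match"]
  fr <- expression_filter(expression, novel_ids, gene_of,
                          min_sample_fraction = min_sample_fraction,
                          min_total_reads = min_total_reads,
                          min_gene_fraction = min_gene_fraction)
  kept_novel <- fr$transcript_id[fr$novel & fr$kept]
  note("expression_kept", length(kept_novel))
  note("expression_removed", length(novel_ids) - length(kept_novel))

  survivors <- cls |>
    filter(.data$code == "exact_match" |
             .data$transcript_id %in% kept_novel)

  # 5. merge components from surviving evidence, then integration
  comps <- build_merge_components(survivors, reference)
  note("merge_components", nrow(comps))
  res <- integrate_annotation(reference, survivors, candidates,
                              components = comps, scheme = scheme)
  note("final_genes", nrow(res$updated$genes))
  note("final_transcripts", nrow(res$updated$transcripts))

  summary_tbl <- bind_rows(
    assembly_summary(reference) |> mutate(annotation = "reference",
                                          .before = 1),
    assembly_summary(res$updated) |> mutate(annotation = "updated",
                                            .before = 1)
  )

  busco_tbl <- NULL
  if (!is.null(busco)) {
    if (is.null(total_orthologs)) {
      abort("total_orthologs is required when a BUSCO hit table is supplied")
    }
    busco_tbl <- busco_gene_reconcile(
      busco,
      setNames(res$updated$transcripts$gene_id,
               res$updated$transcripts$transcript_id),
      total_orthologs)
  }

  softmask <- NULL
  if (!is.null(genome) && length(genome)) {
    novel_tx <- res$provenance$transcript_id[
      res$provenance$status %in% c("novel", "isoform_added")]
    softmask <- bind_rows(
      softmask_fractions(reference, genome) |> mutate(set = "reference"),
      softmask_fractions(res$updated, genome, novel_tx) |>
        mutate(set = "novel")
    )
  }

  out <- structure(
    list(updated = res$updated, integration = res, classified = cls,
         junction_filter = jf, filter_report = fr, components = comps,
         summary = summary_tbl, busco = busco_tbl, softmask = softmask,
         log = bind_rows(log)),
    class = "tx_refinement"
  )

  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir,
                                                  emit_intermediate,
                                                  reference, candidates,
                                                  cls)
  out
}

# restrict a candidate annotation to a transcript subset
subset_annotation <- function(ann, transcript_ids) {
  keep_tx <- ann$transcripts |>
    filter(.data$transcript_id %in% transcript_ids)
  ex <- ann$exons |> filter(.data$transcript_id %in% transcript_ids)
  src <- if (nrow(keep_tx)) keep_tx$source[1] else "candidate"
  annotation(
    ex |> select("transcript_id", "gene_id", "seqid", "start", "end",
                 "strand", "gtf_source", "attributes"),
    transcript_meta = keep_tx |>
      select("transcript_id", "coverage", "gtf_source", "attributes"),
    source = src,
    extras = ann$extras |> filter(.data$transcript_id %in% transcript_ids)
  )
}

# transcript -> pooled gene key for every matrix transcript: merged members
# share a component key, candidates map through their classification, and
# anything else (e.g. junction-failed candidates) is its own unit
pipeline_gene_membership <- function(reference, candidates, cls, comps,
                                     matrix_ids) {
  comp_of_gene <- character()
  if (nrow(comps)) {
    for (i in seq_len(nrow(comps))) {
      comp_of_gene[comps$member_gene_ids[[i]]] <- sprintf("merge_%d", i)
    }
  }
  pool_key <- function(gid) {
    ifelse(gid %in% names(comp_of_gene), unname(comp_of_gene[gid]), gid)
  }
  map_ref <- setNames(pool_key(reference$transcripts$gene_id),
                      reference$transcripts$transcript_id)
  cand_gene <- setNames(candidates$transcripts$gene_id,
                        candidates$transcripts$transcript_id)
  map_cand <- cand_gene
  if (nrow(cls)) {
    cls_gene <- map_chr(seq_len(nrow(cls)), function(i) {
      code <- cls$code[i]
      gs <- cls$overlapping_gene_ids[[i]]
      if (code %in% c("exact_match", "novel_isoform")) pool_key(gs[1])
      else if (code == "join_evidence") pool_key(gs[1])
      else cand_gene[[cls$transcript_id[i]]]
    })
    map_cand[cls$transcript_id] <- cls_gene
    # novel candidates that overlap each other share a unit
    novel_ids <- cls$transcript_id[cls$code == "novel_gene"]
    if (length(novel_ids)) {
      clusters <- cluster_novel_survivors(novel_ids, candidates)
      key <- sprintf("novel_%d", clusters$cluster)
      map_cand[clusters$transcript_id] <- key
    }
  }
  full <- c(map_ref, map_cand)
  missing <- setdiff(matrix_ids, names(full))
  if (length(missing)) {
    full[missing] <- missing   # unknown rows count only against themselves
  }
  full
}

write_pipeline_artifacts <- function(out, out_dir, emit_intermediate,
                                     reference, candidates, cls) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(out$updated, file.path(out_dir, "updated.gtf"))
  readr::write_tsv(out$integration$provenance,
                   file.path(out_dir, "provenance.tsv"), progress = FALSE)
  readr::write_tsv(tidy(out$classified),
                   file.path(out_dir, "classified.tsv"), progress = FALSE)
  merges <- as_tibble(out$components) |>
    mutate(member_gene_ids = map_chr(.data$member_gene_ids, paste,
                                     collapse = ","),
           evidence_transcript_ids = map_chr(.data$evidence_transcript_ids,
                                             paste, collapse = ","))
  if (nrow(out$integration$id_map)) {
    first_member <- map_chr(strsplit(merges$member_gene_ids, ","), 1)
    idm <- setNames(out$integration$id_map$new_gene_id,
                    out$integration$id_map$old_gene_id)
    merges <- merges |> mutate(new_gene_id = unname(idm[first_member]),
                               .before = 1)
  } else if (nrow(merges)) {
    merges <- merges |> mutate(new_gene_id = NA_character_, .before = 1)
  }
  readr::write_tsv(merges, file.path(out_dir, "merges.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(out$filter_report),
                   file.path(out_dir, "filter_report.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(out$junction_filter),
                   file.path(out_dir, "junction_filter.tsv"),
                   progress = FALSE)
  if (emit_intermediate) {
    inter <- subset_annotation(candidates, cls$transcript_id)
    write_gtf(inter, file.path(out_dir, "intermediate.gtf"))
  }
  lines <- c(
    "annotation refinement summary",
    "=============================",
    utils::capture.output(as.data.frame(out$summary)),
    "",
    "stage counts:",
    utils::capture.output(as.data.frame(out$log))
  )
  if (!is.null(out$busco)) {
    lines <- c(lines, "", "gene-level BUSCO table:",
               utils::capture.output(as.data.frame(out$busco)))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.tx_refinement <- function(x, ...) {
  cat("<tx_refinement>\n")
  print(as.data.frame(x$log), row.names = FALSE)
  invisible(x)
}

#' @export
glance.tx_refinement <- function(x, ...) {
  wide <- setNames(as.list(x$log$count), x$log$stage)
  as_tibble(wide)
}

#' @export
autoplot.tx_classification <- function(object, ...) {
  counts <- as_tibble(object) |>
    dplyr::count(code = factor(.data$code, levels = COMPARISON_CODES))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$code, y = .data$n)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "candidate transcripts",
                  title = "Candidate classification against the reference") +
    ggplot2::theme_minimal()
}
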