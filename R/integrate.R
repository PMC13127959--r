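# The integration step: fuse surviving candidate transcripts and merge
# components into the reference annotation.
#   exact_match    candidates contribute nothing (no duplicate isoforms)
#   novel_isoform  attached to their single host gene, which keeps its id and
#                  attributes
#   merge component  member genes are replaced by one new gene (fresh scheme
#                  id); member transcripts keep their original ids, evidence
#                  transcripts are added; members recorded in a merged_from
#                  attribute and in the id map
#   novel_gene     survivors are clustered by same-strand exonic overlap;
#                  each cluster becomes a fresh gene, transcripts renamed
#                  <gene_id>.t<n> in genomic order
# Identifier assignment order: merge components first, then novel genes, both
# in genomic order (seqid lexicographic, then leftmost start).

#' Deterministic identifier scheme for new genes
#'
#' Generates zero-padded serial gene identifiers (e.g. `GBIG_G_000001`).
#' Serials are strictly increasing in assignment order and collisions with
#' existing identifiers are an error.
#'
#' @param gene_prefix Prefix for generated gene ids (default `"GBIG_G_"`).
#' @param pad_width Zero-padding width of the serial (default 6).
#' @param next_serial First serial to assign (default 1).
#' @return A `tx_id_scheme` object.
#' @export
id_scheme <- function(gene_prefix = "GBIG_G_", pad_width = 6,
                      next_serial = 1) {
  stopifnot(pad_width >= 1, next_serial >= 1)
  structure(list(gene_prefix = gene_prefix, pad_width = as.integer(pad_width),
                 next_serial = as.integer(next_serial)),
            class = "tx_id_scheme")
}

scheme_take <- function(scheme, k, existing) {
  if (k == 0) return(list(ids = character(), scheme = scheme))
  serials <- seq(scheme$next_serial, length.out = k)
  ids <- sprintf(paste0("%s%0", scheme$pad_width, "d"),
                 scheme$gene_prefix, serials)
  clash <- intersect(ids, existing)
  if (length(clash)) {
    abort(paste0("identifier collision: generated id '", clash[1],
                 "' already exists"))
  }
  scheme$next_serial <- scheme$next_serial + as.integer(k)
  list(ids = ids, scheme = scheme)
}

# cluster novel_gene survivors into genes: connected components of
# same-strand exonic overlap ("." matches either strand)
cluster_novel_survivors <- function(novel_ids, candidates) {
  if (!length(novel_ids)) {
    return(tibble(transcript_id = character(), cluster = integer()))
  }
  ex <- candidates$exons |> filter(.data$transcript_id %in% novel_ids)
  gr <- GenomicRanges::GRanges(ex$seqid, IRanges::IRanges(ex$start, ex$end))
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  s1 <- ex$strand[qh]
  s2 <- ex$strand[sh]
  ok <- s1 == "." | s2 == "." | s1 == s2
  edges <- tibble(a = ex$transcript_id[qh][ok], b = ex$transcript_id[sh][ok]) |>
    distinct()
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sort(unique(novel_ids))))
  memb <- igraph::components(g)$membership
  tibble(transcript_id = names(memb), cluster = as.integer(memb))
}

#' Integrate surviving candidates and merge components into the reference
#'
#' Produces the updated annotation together with per-transcript provenance
#' (`reference_retained`, `isoform_added`, `join_member`, `novel`) and the
#' old-to-new gene id map for merged members. Reference transcript ids and
#' attributes are carried over unchanged; every reference transcript appears
#' exactly once in the result.
#'
#' @param reference Reference `tx_annotation`.
#' @param survivors A `tx_classification` restricted to candidates that
#'   passed the junction and expression filters (plus any `exact_match`
#'   records, which are dropped here).
#' @param candidates Candidate `tx_annotation` holding the survivors'
#'   transcript models.
#' @param components Optional `tx_merge_components`; defaults to components
#'   built from the survivors' join-evidence records.
#' @param scheme A [id_scheme()] for new gene identifiers.
#' @return A `tx_integration` list: `updated` (annotation), `provenance`
#'   (tibble: `transcript_id`, `status`, `old_gene_id`, `new_gene_id`),
#'   `id_map` (tibble: `old_gene_id`, `new_gene_id`), `scheme` (advanced
#'   scheme state).
#' @export
integrate_annotation <- function(reference, survivors, candidates,
                                 components = NULL, scheme = id_scheme()) {
  stopifnot(inherits(reference, "tx_annotation"),
            inherits(candidates, "tx_annotation"),
            inherits(scheme, "tx_id_scheme"))
  cls <- as_tibble(survivors)
  if (is.null(components)) {
    components <- build_merge_components(cls, reference)
  }
  comp <- as_tibble(components)

  missing <- setdiff(cls$transcript_id,
                     candidates$transcripts$transcript_id)
  if (length(missing)) {
    abort(paste0("survivor '", missing[1],
                 "' has no transcript model in the candidate annotation"))
  }

  consumed <- unlist(comp$member_gene_ids)
  if (anyDuplicated(consumed)) {
    abort("merge components are not disjoint")
  }
  iso <- cls |> filter(.data$code == "novel_isoform")
  iso_gene <- map_chr(iso$overlapping_gene_ids, 1)
  bad <- iso$transcript_id[iso_gene %in% consumed]
  if (length(bad)) {
    abort(paste0("consistency error: survivor '", bad[1],
                 "' references gene consumed by a merge component it is not part of"))
  }
  join <- cls |> filter(.data$code == "join_evidence")
  if (nrow(join)) {
    comp_members <- comp$member_gene_ids
    ok <- map_lgl(seq_len(nrow(join)), function(i) {
      gs <- join$overlapping_gene_ids[[i]]
      any(map_lgl(comp_members, function(m) all(gs %in% m)))
    })
    if (!all(ok)) {
      abort(paste0("consistency error: survivor '",
                   join$transcript_id[!ok][1],
                   "' spans genes not grouped into a single merge component"))
    }
  }

  existing_ids <- c(reference$genes$gene_id,
                    reference$transcripts$transcript_id)

  ref_ex <- reference$exons
  ref_tx <- reference$transcripts
  ref_gn <- reference$genes
  cand_tx <- candidates$transcripts
  cand_ex <- candidates$exons

  provenance <- tibble(
    transcript_id = ref_tx$transcript_id,
    status = "reference_retained",
    old_gene_id = ref_tx$gene_id,
    new_gene_id = ref_tx$gene_id
  )

  # --- merge components -> new genes, ids assigned in genomic order ---------
  take <- scheme_take(scheme, nrow(comp),
                      c(existing_ids, cand_tx$transcript_id))
  scheme <- take$scheme
  id_map <- tibble(old_gene_id = character(), new_gene_id = character())
  gene_rename <- character()   # old gene id -> new gene id
  merged_attrs <- list()
  if (nrow(comp)) {
    for (i in seq_len(nrow(comp))) {
      m <- comp$member_gene_ids[[i]]
      gene_rename[m] <- take$ids[i]
      merged_attrs[[take$ids[i]]] <-
        c(merged_from = paste(m, collapse = ","))
    }
    id_map <- tibble(old_gene_id = unlist(comp$member_gene_ids),
                     new_gene_id = gene_rename[unlist(comp$member_gene_ids)])
  }

  new_ref_gene <- ifelse(ref_tx$gene_id %in% names(gene_rename),
                         unname(gene_rename[ref_tx$gene_id]),
                         ref_tx$gene_id)
  provenance$new_gene_id <- new_ref_gene
  provenance$status[provenance$old_gene_id %in% names(gene_rename)] <-
    "join_member"

  upd_tx <- ref_tx |> mutate(gene_id = new_ref_gene)
  upd_ex <- ref_ex |>
    mutate(gene_id = ifelse(.data$gene_id %in% names(gene_rename),
                            unname(gene_rename[.data$gene_id]),
                            .data$gene_id))

  add_candidate <- function(tid, new_gene, new_tid, status) {
    t <- cand_tx[cand_tx$transcript_id == tid, ]
    e <- cand_ex[cand_ex$transcript_id == tid, ]
    if (new_tid %in% c(upd_tx$transcript_id)) {
      abort(paste0("identifier collision: transcript id '", new_tid,
                   "' already present"))
    }
    t$transcript_id <- new_tid
    t$gene_id <- new_gene
    e$transcript_id <- new_tid
    e$gene_id <- new_gene
    upd_tx <<- bind_rows(upd_tx, t)
    upd_ex <<- bind_rows(upd_ex, e)
    provenance <<- bind_rows(provenance, tibble(
      transcript_id = new_tid, status = status,
      old_gene_id = NA_character_, new_gene_id = new_gene))
  }

  # evidence transcripts join their component's new gene, keeping their ids
  if (nrow(join)) {
    join <- join |> arrange(.data$seqid, .data$start, .data$transcript_id)
    for (i in seq_len(nrow(join))) {
      gs <- join$overlapping_gene_ids[[i]]
      add_candidate(join$transcript_id[i], unname(gene_rename[gs[1]]),
                    join$transcript_id[i], "join_member")
    }
  }

  # --- novel isoforms -------------------------------------------------------
  if (nrow(iso)) {
    iso <- iso |> arrange(.data$seqid, .data$start, .data$transcript_id)
    for (i in seq_len(nrow(iso))) {
      add_candidate(iso$transcript_id[i],
                    iso$overlapping_gene_ids[[i]][1],
                    iso$transcript_id[i], "isoform_added")
    }
  }

  # --- novel genes ----------------------------------------------------------
  novel <- cls |> filter(.data$code == "novel_gene")
  if (nrow(novel)) {
    clusters <- cluster_novel_survivors(novel$transcript_id, candidates)
    cl_tx <- split(clusters$transcript_id, clusters$cluster)
    pos <- cand_tx[match(novel$transcript_id, cand_tx$transcript_id), ]
    pos_key <- setNames(seq_len(nrow(pos)), pos$transcript_id)
    cl_pos <- map(cl_tx, function(ids) {
      p <- cand_tx[match(ids, cand_tx$transcript_id), ]
      o <- order(p$seqid, p$start, p$transcript_id)
      list(ids = ids[o], seqid = p$seqid[o][1], start = p$start[o][1])
    })
    ord <- order(map_chr(cl_pos, "seqid"), map_dbl(cl_pos, "start"),
                 map_chr(cl_pos, function(x) x$ids[1]))
    take <- scheme_take(scheme, length(ord),
                        c(existing_ids, upd_tx$transcript_id))
    scheme <- take$scheme
    for (i in seq_along(ord)) {
      cl <- cl_pos[[ord[i]]]
      gid <- take$ids[i]
      for (k in seq_along(cl$ids)) {
        add_candidate(cl$ids[k], gid, paste0(gid, ".t", k), "novel")
      }
    }
  }

  # rebuild gene table: recompute spans, carry reference attributes over
  gene_meta <- tibble(
    gene_id = ref_gn$gene_id,
    gtf_source = ref_gn$gtf_source,
    attributes = ref_gn$attributes
  ) |> filter(!.data$gene_id %in% names(gene_rename))
  if (length(merged_attrs)) {
    gene_meta <- bind_rows(gene_meta, tibble(
      gene_id = names(merged_attrs),
      gtf_source = DEFAULT_GTF_SOURCE,
      attributes = unname(merged_attrs)
    ))
  }

  tx_meta <- tibble(
    transcript_id = upd_tx$transcript_id,
    coverage = upd_tx$coverage,
    gtf_source = upd_tx$gtf_source,
    attributes = upd_tx$attributes
  )
  extras <- reference$extras

  updated <- annotation(
    upd_ex |> select("transcript_id", "gene_id", "seqid", "start", "end",
                     "strand", "gtf_source", "attributes"),
    transcript_meta = tx_meta, gene_meta = gene_meta,
    source = "reference", extras = extras
  )
  # preserve candidate/reference provenance per transcript
  src <- setNames(upd_tx$source, upd_tx$transcript_id)
  updated$transcripts$source <-
    unname(src[updated$transcripts$transcript_id])

  structure(
    list(updated = updated,
         provenance = arrange(provenance, .data$transcript_id),
         id_map = id_map, scheme = scheme),
    class = "tx_integration"
  )
}

#' @export
print.tx_integration <- function(x, ...) {
  g <- glance(x)
  cat("<tx_integration> updated annotation: ", g$n_genes, " genes, ",
      g$n_transcripts, " transcripts\n", sep = "")
  cat("  isoforms added: ", g$n_isoforms_added,
      "; merged units: ", g$n_merged_units,
      "; novel genes: ", g$n_novel_genes, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.tx_integration <- function(x, ...) x$provenance

#' Integration totals
#'
#' @param x A `tx_integration`.
#' @param ... Unused.
#' @return One-row tibble: updated gene/transcript counts and per-status
#'   additions.
#' @export
glance.tx_integration <- function(x, ...) {
  p <- x$provenance
  novel_genes <- x$updated$transcripts |>
    filter(.data$transcript_id %in%
             p$transcript_id[p$status == "novel"]) |>
    pull("gene_id")
  tibble(
    n_genes = nrow(x$updated$genes),
    n_transcripts = nrow(x$updated$transcripts),
    n_reference_retained = sum(p$status == "reference_retained"),
    n_isoforms_added = sum(p$status == "isoform_added"),
    n_join_members = sum(p$status == "join_member"),
    n_merged_units = length(unique(x$id_map$new_gene_id)),
    n_novel_transcripts = sum(p$status == "novel"),
    n_novel_genes = length(unique(novel_genes))
  )
}

#' Soft-masked fraction of transcripts
#'
#' Fraction of each transcript's exonic bases that are lowercase in a
#' soft-masked genome: a repeat/transposable-element contamination signal for
#' QC of novel models.
#'
#' @param ann A `tx_annotation`.
#' @param genome Named character vector of scaffold sequences, or a
#'   `Biostrings::BStringSet` as returned by [read_genome()] (case
#'   preserved).
#' @param transcript_ids Optional subset of transcripts to score.
#' @return Tibble: `transcript_id`, `length`, `masked_bases`,
#'   `masked_fraction` (in `[0, 1]`).
#' @export
softmask_fractions <- function(ann, genome, transcript_ids = NULL) {
  stopifnot(inherits(ann, "tx_annotation"))
  if (methods::is(genome, "XStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  ex <- ann$exons
  if (!is.null(transcript_ids)) {
    ex <- ex |> filter(.data$transcript_id %in% transcript_ids)
  }
  if (nrow(ex) == 0) {
    return(tibble(transcript_id = character(), length = integer(),
                  masked_bases = integer(), masked_fraction = double()))
  }
  bad <- setdiff(unique(ex$seqid), names(genome))
  if (length(bad)) {
    abort(paste0("coordinate error: seqid '", bad[1],
                 "' absent from the genome"))
  }
  lens <- nchar(genome)
  oob <- ex$end > lens[ex$seqid]
  if (any(oob)) {
    abort(paste0("coordinate error: exon beyond end of seqid '",
                 ex$seqid[oob][1], "'"))
  }
  seqs <- substring(genome[ex$seqid], ex$start, ex$end)
  masked <- nchar(gsub("[^a-z]", "", seqs))
  ex |>
    mutate(.masked = masked, .len = .data$end - .data$start + 1L) |>
    group_by(.data$transcript_id) |>
    summarise(length = sum(.data$.len),
              masked_bases = as.integer(sum(.data$.masked)),
              .groups = "drop") |>
    mutate(masked_fraction = .data$masked_bases / .data$length)
}

#' Read a soft-masked genome FASTA
#'
#' Reads sequences with case preserved (lowercase = soft-masked).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @param width Line width (default 70).
#' @return The path, invisibly.
#' @export
write_genome <- function(genome, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
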