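# Evidence-based merging of reference genes: transcripts classified as
# join_evidence define edges between the genes they span; connected
# components of that graph are the transcription units to be fused. Connected
# components (not pairwise merging) are required because chained evidence can
# link genes no single transcript spans.

#' Build merge components from join-evidence classifications
#'
#' Nodes are the reference gene ids referenced by `join_evidence` records;
#' edges link genes co-occurring in one transcript's overlapping gene set.
#' Each connected component becomes one candidate transcription unit carrying
#' all contributing transcript ids.
#'
#' @param classified A `tx_classification` (rows with other codes are
#'   ignored).
#' @param reference Optional reference `tx_annotation`; when supplied,
#'   components are ordered by the genomic position of their leftmost member
#'   and member ids are listed in genomic order (otherwise lexicographic).
#' @return Tibble (class `tx_merge_components`): `component`,
#'   `member_gene_ids` (list), `evidence_transcript_ids` (list),
#'   `cardinality`.
#' @export
build_merge_components <- function(classified, reference = NULL) {
  joins <- as_tibble(classified) |> filter(.data$code == "join_evidence")
  out <- tibble(component = integer(), member_gene_ids = list(),
                evidence_transcript_ids = list(), cardinality = integer())
  if (nrow(joins) == 0) {
    return(structure(out, class = c("tx_merge_components", class(out))))
  }
  sizes <- lengths(joins$overlapping_gene_ids)
  if (any(sizes < 2)) {
    bad <- joins$transcript_id[sizes < 2][1]
    abort(paste0("join_evidence record '", bad,
                 "' references fewer than 2 genes"))
  }

  nodes <- sort(unique(unlist(joins$overlapping_gene_ids)))
  edges <- unlist(map(joins$overlapping_gene_ids, function(g) {
    g <- sort(g)
    rbind(g[-length(g)], g[-1])
  }))
  em <- matrix(edges, ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2]), directed = FALSE,
    vertices = data.frame(name = nodes))
  memb <- igraph::components(g)$membership
  comp_of <- setNames(memb[nodes], nodes)

  members <- split(nodes, comp_of[nodes])
  tx_comp <- map_int(joins$overlapping_gene_ids,
                     function(gs) as.integer(comp_of[gs[1]]))
  ev <- split(joins$transcript_id, tx_comp)

  gene_pos <- NULL
  if (!is.null(reference)) {
    gene_pos <- reference$genes |>
      select("gene_id", "seqid", "start")
  }

  comp_ids <- names(members)
  order_key <- map(comp_ids, function(cid) {
    m <- members[[cid]]
    if (!is.null(gene_pos)) {
      pos <- gene_pos[match(m, gene_pos$gene_id), ]
      if (anyNA(pos$gene_id)) {
        abort(paste0("merge component references gene '",
                     m[is.na(pos$gene_id)][1],
                     "' absent from the reference"))
      }
      o <- order(pos$seqid, pos$start, m)
      list(members = m[o], key_seq = pos$seqid[o][1], key_pos = pos$start[o][1])
    } else {
      list(members = sort(m), key_seq = "", key_pos = 0L)
    }
  })
  ord <- order(map_chr(order_key, "key_seq"),
               map_dbl(order_key, "key_pos"),
               map_chr(order_key, function(k) k$members[1]))

  out <- tibble(
    component = seq_along(ord),
    member_gene_ids = map(order_key[ord], "members"),
    evidence_transcript_ids = map(comp_ids[ord],
                                  function(cid) sort(unique(ev[[cid]]))),
    cardinality = lengths(map(order_key[ord], "members"))
  )
  structure(out, class = c("tx_merge_components", class(out)))
}

#' Distribution of merge-component cardinalities
#'
#' Counts components by the number of reference genes they join.
#'
#' @param components A `tx_merge_components`.
#' @return Tibble (class `tx_merge_distribution`): `cardinality`, `n`;
#'   `sum(n)` is the total number of merge instances.
#' @export
merge_distribution <- function(components) {
  tab <- as_tibble(components)
  if (nrow(tab) == 0) {
    out <- tibble(cardinality = integer(), n = integer())
  } else {
    out <- tab |>
      dplyr::count(.data$cardinality, name = "n") |>
      arrange(.data$cardinality)
  }
  structure(out, class = c("tx_merge_distribution", class(out)))
}

#' @export
autoplot.tx_merge_distribution <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$cardinality), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "reference genes joined per merged unit",
                  y = "merged units",
                  title = "Evidence-based gene merges by cardinality") +
    ggplot2::theme_minimal()
}
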