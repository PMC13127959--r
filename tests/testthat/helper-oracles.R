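# Independent oracles used across the suite. These deliberately avoid the
# package's index/graph machinery: classification is checked by a quadratic
# exon-pair scan over per-base position sets, components by a hand-written
# breadth-first search, filters by per-rule loops.

# compact annotation builder: ex is a list of lists
#   list(tx, gene, seqid, strand, exons = list(c(start, end), ...))
toy_annotation <- function(specs, source = "reference", coverage = NULL) {
  rows <- lapply(specs, function(s) {
    m <- do.call(rbind, s$exons)
    tibble::tibble(
      transcript_id = s$tx, gene_id = s$gene,
      seqid = s$seqid %||% "chr1", start = as.integer(m[, 1]),
      end = as.integer(m[, 2]), strand = s$strand %||% "+"
    )
  })
  ex <- dplyr::bind_rows(rows)
  meta <- NULL
  if (!is.null(coverage)) {
    ids <- unique(ex$transcript_id)
    meta <- tibble::tibble(transcript_id = ids,
                           coverage = rep(coverage, length(ids)))
  }
  txrefine::annotation(ex, transcript_meta = meta, source = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

strand_compatible <- function(a, b) a == "." || b == "." || a == b

# exonic position set of a transcript (per-base, brute force)
tx_positions <- function(exons_tab) {
  unlist(mapply(seq, exons_tab$start, exons_tab$end, SIMPLIFY = FALSE))
}

# quadratic brute-force classifier over every (candidate exon x reference
# exon) pair
oracle_classify_one <- function(cand_ex, ref, min_recip = 0.8) {
  genes <- ref$genes
  ref_ex <- ref$exons
  cstrand <- cand_ex$strand[1]
  cseq <- cand_ex$seqid[1]
  cpos <- tx_positions(cand_ex)

  overlap_by_gene <- numeric(0)
  for (g in genes$gene_id) {
    ge <- ref_ex[ref_ex$gene_id == g & ref_ex$seqid == cseq, ]
    if (nrow(ge) == 0) next
    linked <- FALSE
    for (i in seq_len(nrow(cand_ex))) {
      for (j in seq_len(nrow(ge))) {
        if (!strand_compatible(cstrand, ge$strand[j])) next
        if (cand_ex$start[i] <= ge$end[j] && ge$start[j] <= cand_ex$end[i]) {
          linked <- TRUE
        }
      }
    }
    if (linked) {
      gpos <- unique(tx_positions(ge))
      overlap_by_gene[g] <- length(intersect(cpos, gpos))
    }
  }
  hit <- names(overlap_by_gene)
  if (is.null(hit)) hit <- character()

  if (cstrand == "." && length(hit) > 1) {
    strands <- genes$strand[match(hit, genes$gene_id)]
    if (length(unique(strands[strands %in% c("+", "-")])) > 1) {
      ov <- overlap_by_gene[hit]
      st <- genes$start[match(hit, genes$gene_id)]
      o <- order(-ov, st, hit)
      hit <- hit[o[1]]
    }
  }
  st <- genes$start[match(hit, genes$gene_id)]
  hit <- hit[order(st, hit)]

  if (length(hit) == 0) {
    return(list(code = "novel_gene", genes = character(), matched = NA_character_))
  }
  if (length(hit) >= 2) {
    return(list(code = "join_evidence", genes = hit, matched = NA_character_))
  }
  g <- hit
  iso_ids <- ref$transcripts$transcript_id[ref$transcripts$gene_id == g]
  cand_junc <- if (nrow(cand_ex) > 1) {
    o <- order(cand_ex$start)
    paste(cand_ex$end[o][-nrow(cand_ex)], cand_ex$start[o][-1],
          sep = "-", collapse = "|")
  } else ""
  matched <- NA_character_
  if (nrow(cand_ex) > 1) {
    for (iso in sort(iso_ids)) {
      ie <- ref_ex[ref_ex$transcript_id == iso, ]
      if (nrow(ie) < 2) next
      o <- order(ie$start)
      ij <- paste(ie$end[o][-nrow(ie)], ie$start[o][-1],
                  sep = "-", collapse = "|")
      if (identical(ij, cand_junc)) { matched <- iso; break }
    }
  } else {
    best_ov <- -1
    for (iso in sort(iso_ids)) {
      ie <- ref_ex[ref_ex$transcript_id == iso, ]
      if (nrow(ie) != 1) next
      ipos <- tx_positions(ie)
      ov <- length(intersect(cpos, ipos))
      if (ov / length(cpos) >= min_recip && ov / length(ipos) >= min_recip) {
        if (ov > best_ov) { best_ov <- ov; matched <- iso }
      }
    }
  }
  if (!is.na(matched)) {
    list(code = "exact_match", genes = g, matched = matched)
  } else {
    list(code = "novel_isoform", genes = g, matched = NA_character_)
  }
}

oracle_classify <- function(candidates, ref, min_recip = 0.8) {
  ex_by_tx <- split(candidates$exons, candidates$exons$transcript_id)
  res <- lapply(names(ex_by_tx), function(tid) {
    r <- oracle_classify_one(ex_by_tx[[tid]], ref, min_recip)
    tibble::tibble(transcript_id = tid, code = r$code,
                   genes = paste(r$genes, collapse = ","),
                   matched = r$matched)
  })
  dplyr::bind_rows(res)
}

# breadth-first-search connected components over explicit adjacency lists;
# `sets` is a list of character vectors (each a join record's gene set)
oracle_components <- function(sets) {
  nodes <- sort(unique(unlist(sets)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (s in sets) {
    for (i in seq_along(s)) {
      for (j in seq_along(s)) {
        if (i != j) adj[[s[i]]] <- union(adj[[s[i]]], s[j])
      }
    }
  }
  seen <- character()
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    queue <- n
    comp <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

# per-junction brute-force pass/fail check
oracle_junction_pass <- function(candidates, reference, evidence,
                                 min_reads = 4, min_anchor = 15,
                                 min_cov = 10) {
  ref_j <- txrefine::intron_chains(reference)
  cand_j <- txrefine::intron_chains(candidates)
  txs <- candidates$transcripts
  pass <- logical(nrow(txs))
  for (i in seq_len(nrow(txs))) {
    tid <- txs$transcript_id[i]
    jj <- cand_j[cand_j$transcript_id == tid, ]
    ok <- TRUE
    for (k in seq_len(nrow(jj))) {
      in_ref <- FALSE
      for (r in seq_len(nrow(ref_j))) {
        if (ref_j$seqid[r] == jj$seqid[k] &&
            ref_j$donor_end[r] == jj$donor_end[k] &&
            ref_j$acceptor_start[r] == jj$acceptor_start[k] &&
            strand_compatible(ref_j$strand[r], jj$strand[k])) {
          in_ref <- TRUE
        }
      }
      if (in_ref) next
      supported <- FALSE
      for (r in seq_len(nrow(evidence))) {
        if (evidence$seqid[r] == jj$seqid[k] &&
            evidence$donor_end[r] == jj$donor_end[k] &&
            evidence$acceptor_start[r] == jj$acceptor_start[k] &&
            strand_compatible(evidence$strand[r], jj$strand[k]) &&
            evidence$read_count[r] >= min_reads &&
            evidence$min_anchor[r] >= min_anchor) {
          supported <- TRUE
        }
      }
      if (!supported) ok <- FALSE
    }
    if (ok && !is.na(txs$coverage[i]) && txs$coverage[i] < min_cov) {
      ok <- FALSE
    }
    pass[i] <- ok
  }
  stats::setNames(pass, txs$transcript_id)
}

# per-rule brute-force expression filter
oracle_expression_kept <- function(expr, novel_ids, gene_of,
                                   f_sample = 0.30, f_total = 10,
                                   f_gene = 0.10) {
  vals <- as.matrix(expr[setdiff(names(expr), "transcript_id")])
  tx <- expr$transcript_id
  if (is.data.frame(gene_of)) {
    gene_of <- stats::setNames(gene_of$gene_id, gene_of$transcript_id)
  }
  kept <- character()
  for (t in novel_ids) {
    i <- match(t, tx)
    v <- vals[i, ]
    r1 <- sum(v > 0) / length(v) < f_sample
    r2 <- sum(v) < f_total
    sib <- tx[gene_of[tx] == gene_of[[t]]]
    gt <- sum(vals[match(sib, tx), , drop = FALSE])
    frac <- if (gt > 0) sum(v) / gt else 1
    r3 <- frac < f_gene
    if (!r1 && !r2 && !r3) kept <- c(kept, t)
  }
  kept
}

# per-base soft-mask count
oracle_softmask <- function(exons_tab, genome) {
  chars <- strsplit(genome[[exons_tab$seqid[1]]], "")[[1]]
  pos <- tx_positions(exons_tab)
  sum(chars[pos] %in% letters) / length(pos)
}

# model-level annotation equality via the deterministic writer
ann_equal <- function(a, b) {
  identical(txrefine::write_gtf(a), txrefine::write_gtf(b))
}
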