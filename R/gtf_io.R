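# GTF reading and writing. Both GTF2.2 (`key "value";`) and GFF3-style
# (`key=value`) attributes are accepted on read; GTF2.2 is emitted on write.
# Features other than gene/transcript/exon are passed through untouched,
# attached to their transcript, and never interpreted.

parse_gtf_attributes <- function(s) {
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character())
  keys <- character(length(toks))
  vals <- character(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    m <- regmatches(t, regexec('^(\\S+)\\s+"(.*)"\\s*$', t))[[1]]
    if (length(m) == 3) {
      keys[i] <- m[2]; vals[i] <- m[3]
      next
    }
    m <- regmatches(t, regexec("^([^=[:space:]]+)=(.*)$", t))[[1]]
    if (length(m) == 3) {
      keys[i] <- m[2]; vals[i] <- gsub('^"|"$', "", m[3])
      next
    }
    m <- regmatches(t, regexec("^(\\S+)\\s+(.*)$", t))[[1]]
    if (length(m) == 3) {
      keys[i] <- m[2]; vals[i] <- gsub('^"|"$', "", m[3])
    } else {
      keys[i] <- t; vals[i] <- ""
    }
  }
  setNames(vals, keys)
}

format_gtf_attributes <- function(gene_id, transcript_id = NULL, attrs = character()) {
  kv <- c(gene_id = unname(gene_id))
  if (!is.null(transcript_id) && !is.na(transcript_id)) {
    kv <- c(kv, transcript_id = unname(transcript_id))
  }
  attrs <- attrs[!names(attrs) %in% c("gene_id", "transcript_id")]
  kv <- c(kv, attrs)
  paste0(names(kv), ' "', kv, '";', collapse = " ")
}

#' Read a GTF file into an annotation
#'
#' Parses gene, transcript and exon records into a [annotation()] container.
#' Genes without explicit gene records are synthesized from their
#' transcripts' `gene_id`. Attributes on retained features are preserved
#' verbatim (in stored key order); any other feature carrying a
#' `transcript_id` (CDS, UTR, ...) is passed through untouched and re-emitted
#' by [write_gtf()].
#'
#' @param file Path to a GTF file, or a character vector of GTF lines.
#' @param dialect `"reference"` for a curated annotation, `"candidate"` for
#'   assembler output (StringTie-style); the candidate dialect reads a `cov`
#'   attribute into the transcript `coverage` field.
#' @return A `tx_annotation`.
#' @export
read_gtf <- function(file, dialect = c("reference", "candidate")) {
  dialect <- match.arg(dialect)
  if (is.character(file) && length(file) == 1 && !grepl("\n", file) &&
      file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) {
    return(annotation(empty_exon_table(), source = dialect))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 9)
  if (length(bad)) {
    abort(paste0("malformed GTF line ", lineno[bad[1]], ": expected 9 columns, got ",
                 nf[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(paste0("malformed GTF line ", lineno[bad], ": non-numeric coordinate"))
  }
  bad <- which(end < start)
  if (length(bad)) {
    abort(paste0("coordinate error at line ", lineno[bad[1]], ": end < start"))
  }
  if (any(start < 1)) {
    bad <- which(start < 1)[1]
    abort(paste0("coordinate error at line ", lineno[bad], ": start < 1"))
  }
  strand <- m[, 7]
  strand[!strand %in% c("+", "-")] <- "."

  attrs <- lapply(m[, 9], parse_gtf_attributes)
  pick <- function(a, key) {
    if (key %in% names(a)) a[[key]] else NA_character_
  }
  gene_id <- map_chr(attrs, pick, "gene_id")
  transcript_id <- map_chr(attrs, pick, "transcript_id")
  feature <- m[, 3]

  tab <- tibble(
    lineno = lineno, seqid = m[, 1], gtf_source = m[, 2], feature = feature,
    start = start, end = end, score = m[, 6], strand = strand,
    frame = m[, 8], gene_id = gene_id, transcript_id = transcript_id,
    attributes = lapply(attrs, function(a) {
      a[!names(a) %in% c("gene_id", "transcript_id")]
    })
  )

  ex <- tab |> filter(.data$feature == "exon")
  if (nrow(ex)) {
    bad <- which(is.na(ex$gene_id) | is.na(ex$transcript_id))
    if (length(bad)) {
      abort(paste0("malformed GTF line ", ex$lineno[bad[1]],
                   ": exon lacks gene_id or transcript_id attribute"))
    }
  }

  tx_rec <- tab |> filter(.data$feature == "transcript")
  if (nrow(tx_rec) && anyDuplicated(tx_rec$transcript_id)) {
    dup <- tx_rec$transcript_id[duplicated(tx_rec$transcript_id)][1]
    abort(paste0("duplicate transcript id '", dup, "'"))
  }
  gene_rec <- tab |> filter(.data$feature == "gene")
  if (nrow(gene_rec) && anyDuplicated(gene_rec$gene_id)) {
    dup <- gene_rec$gene_id[duplicated(gene_rec$gene_id)][1]
    abort(paste0("duplicate gene id '", dup, "'"))
  }

  extras <- tab |>
    filter(!.data$feature %in% c("gene", "transcript", "exon"),
           !is.na(.data$transcript_id)) |>
    mutate(line_order = row_number()) |>
    select("transcript_id", "seqid", "gtf_source", "feature", "start", "end",
           "score", "strand", "frame", "attributes", "line_order")

  if (nrow(ex) == 0) {
    # transcripts with no exon records are not representable
    return(annotation(empty_exon_table(), source = dialect, extras = extras))
  }

  tx_meta <- NULL
  if (nrow(tx_rec)) {
    cov <- rep(NA_real_, nrow(tx_rec))
    if (dialect == "candidate") {
      cov <- map_dbl(tx_rec$attributes, function(a) {
        suppressWarnings(as.numeric(pick(a, "cov")))
      })
    }
    tx_meta <- tibble(
      transcript_id = tx_rec$transcript_id,
      coverage = cov,
      gtf_source = tx_rec$gtf_source,
      attributes = tx_rec$attributes
    )
  }
  gene_meta <- NULL
  if (nrow(gene_rec)) {
    gene_meta <- tibble(
      gene_id = gene_rec$gene_id,
      gtf_source = gene_rec$gtf_source,
      attributes = gene_rec$attributes
    )
  }

  exons <- ex |>
    select("transcript_id", "gene_id", "seqid", "start", "end", "strand",
           "gtf_source", "attributes")
  annotation(exons, transcript_meta = tx_meta, gene_meta = gene_meta,
             source = dialect, extras = extras)
}

#' Write an annotation as GTF
#'
#' Emits gene, transcript and exon lines in deterministic order (seqid
#' lexicographic, then start, then identifier), with attributes in GTF2.2
#' syntax, `gene_id` and `transcript_id` first. Two calls on the same
#' annotation produce byte-identical output.
#'
#' @param ann A `tx_annotation`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of GTF lines, invisibly when `path` is given.
#' @export
write_gtf <- function(ann, path = NULL) {
  stopifnot(inherits(ann, "tx_annotation"))
  out <- character()
  genes <- ann$genes |> arrange(.data$seqid, .data$start, .data$gene_id)
  txs <- ann$transcripts
  exs <- ann$exons
  extras <- ann$extras
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    out <- c(out, paste(
      g$seqid, g$gtf_source, "gene", g$start, g$end, ".", g$strand, ".",
      format_gtf_attributes(g$gene_id, NULL, g$attributes[[1]]),
      sep = "\t"
    ))
    gt <- txs |>
      filter(.data$gene_id == g$gene_id) |>
      arrange(.data$start, .data$transcript_id)
    for (ti in seq_len(nrow(gt))) {
      t <- gt[ti, ]
      out <- c(out, paste(
        t$seqid, t$gtf_source, "transcript", t$start, t$end, ".", t$strand, ".",
        format_gtf_attributes(g$gene_id, t$transcript_id, t$attributes[[1]]),
        sep = "\t"
      ))
      te <- exs |>
        filter(.data$transcript_id == t$transcript_id) |>
        arrange(.data$start)
      out <- c(out, paste(
        te$seqid, te$gtf_source, "exon", te$start, te$end, ".", te$strand, ".",
        map_chr(seq_len(nrow(te)), function(i) {
          format_gtf_attributes(g$gene_id, t$transcript_id,
                                te$attributes[[i]])
        }),
        sep = "\t"
      ))
      if (nrow(extras)) {
        xe <- extras |>
          filter(.data$transcript_id == t$transcript_id) |>
          arrange(.data$line_order)
        if (nrow(xe)) {
          out <- c(out, paste(
            xe$seqid, xe$gtf_source, xe$feature, xe$start, xe$end, xe$score,
            xe$strand, xe$frame,
            map_chr(seq_len(nrow(xe)), function(i) {
              format_gtf_attributes(g$gene_id, t$transcript_id,
                                    xe$attributes[[i]])
            }),
            sep = "\t"
          ))
        }
      }
    }
  }
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
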