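#' Assemble primary operons from junction-spanning reads
#'
#' Walks the genes in genome order and joins each adjacent same-strand pair
#' whose junction-spanning read count reaches `min_spanning` (>= 3 by
#' default); maximal joined runs become primary operons and unjoined genes
#' are monocistronic. Adjacent genes separated by an opposite-strand gene are
#' never joined, and every gene belongs to exactly one operon.
#'
#' @param annotation A [genome_annotation].
#' @param junctions data.frame with `upstream_gene`, `downstream_gene` and
#'   `spanning_reads` for adjacent same-strand gene pairs (either gene order
#'   is accepted); pairs absent from the table count as zero spanning reads.
#' @param min_spanning Minimum spanning reads to join a pair.
#' @return data.frame of class `operon_set`: `operon_id`, `strand`,
#'   `n_genes`, `monocistronic`, `first_gene`/`last_gene` (transcription
#'   order), `start`/`end` (genome coordinates) and `genes` (list column,
#'   transcription order).
#' @export
assemble_primary_operons <- function(annotation, junctions, min_spanning = 3L) {
  g <- annotation$genes
  n <- nrow(g)
  jkey <- character(0)
  if (nrow(junctions) > 0L) {
    a <- pmin(junctions$upstream_gene, junctions$downstream_gene)
    b <- pmax(junctions$upstream_gene, junctions$downstream_gene)
    jkey <- stats::setNames(junctions$spanning_reads, paste(a, b, sep = "\r"))
    if (anyDuplicated(names(jkey))) {
      jkey <- tapply(junctions$spanning_reads, paste(a, b, sep = "\r"), sum)
    }
  }
  lookup <- function(x, y) {
    k <- paste(min(x, y), max(x, y), sep = "\r")
    v <- jkey[k]
    if (is.na(v)) 0L else as.integer(v)
  }
  joined <- logical(max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    joined[i] <- g$strand[i] == g$strand[i + 1L] &&
      lookup(g$gene_id[i], g$gene_id[i + 1L]) >= min_spanning
  }
  run <- cumsum(c(1L, !joined))
  rows <- lapply(split(seq_len(n), run), function(i) {
    strand <- g$strand[i[1L]]
    ids <- if (strand == "+") g$gene_id[i] else rev(g$gene_id[i])
    data.frame(
      strand = strand, n_genes = length(i),
      monocistronic = length(i) == 1L,
      first_gene = ids[1L], last_gene = ids[length(ids)],
      start = min(g$start[i]), end = max(g$stop[i]),
      genes = I(list(ids)), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(operon_id = sprintf("OP%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  class(out) <- c("operon_set", "data.frame")
  out
}

#' Assign condition-specific sub-operons from internal TSS
#'
#' A sub-operon is anchored at a pTSS or iTSS lying on the operon strand
#' strictly downstream of the first gene's translation start and upstream of
#' the operon's 3' end. Its gene set is the contiguous suffix of the operon
#' starting at the first gene whose TLS lies at or downstream of the anchor
#' (so an iTSS inside gene g starts the suffix at g's successor). Distinct
#' anchors yielding the same suffix are kept as distinct sub-operons;
#' monocistronic operons never spawn sub-operons.
#'
#' @param operons An `operon_set` from [assemble_primary_operons()].
#' @param classified_tss Output of [classify_tss()] for one condition.
#' @param annotation The [genome_annotation].
#' @param condition Condition label stored with the result (defaults to the
#'   TSS table's `condition` column when present).
#' @return data.frame of class `suboperon_set`: `suboperon_id`, `operon_id`,
#'   `condition`, `anchor_position`, `anchor_class`, `strand`, `n_genes`,
#'   `first_gene` and `genes` (list column, transcription-order suffix).
#' @export
assign_suboperons <- function(operons, classified_tss, annotation,
                              condition = NULL) {
  if (is.null(condition)) {
    condition <- if ("condition" %in% names(classified_tss) &&
                     nrow(classified_tss) > 0L)
      classified_tss$condition[1L] else NA_character_
  }
  g <- annotation$genes
  tls <- stats::setNames(ifelse(g$strand == "+", g$start, g$stop), g$gene_id)
  eligible <- classified_tss[classified_tss$tss_class %in% c("pTSS", "iTSS"), ,
                             drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(operons))) {
    op <- operons[k, ]
    if (op$monocistronic) next
    ids <- op$genes[[1L]]
    first_tls <- tls[[ids[1L]]]
    hits <- eligible[eligible$strand == op$strand &
                       eligible$position >= op$start &
                       eligible$position <= op$end, , drop = FALSE]
    if (nrow(hits) == 0L) next
    for (r in seq_len(nrow(hits))) {
      pos <- hits$position[r]
      # internal anchors only: strictly downstream of the primary TLS and
      # upstream of the operon 3' end, in transcription direction
      if (op$strand == "+") {
        if (pos <= first_tls || pos >= op$end) next
        suffix_from <- which(tls[ids] >= pos)
      } else {
        if (pos >= first_tls || pos <= op$start) next
        suffix_from <- which(tls[ids] <= pos)
      }
      if (length(suffix_from) == 0L) next
      suffix <- ids[seq.int(min(suffix_from), length(ids))]
      rows[[length(rows) + 1L]] <- data.frame(
        operon_id = op$operon_id, condition = condition,
        anchor_position = pos, anchor_class = hits$tss_class[r],
        strand = op$strand, n_genes = length(suffix),
        first_gene = suffix[1L], genes = I(list(suffix)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(operon_id = character(0), condition = character(0),
               anchor_position = integer(0), anchor_class = character(0),
               strand = character(0), n_genes = integer(0),
               first_gene = character(0), genes = I(list()))
  out <- cbind(suboperon_id = if (nrow(out))
    sprintf("SUB%04d", seq_len(nrow(out))) else character(0), out)
  rownames(out) <- NULL
  class(out) <- c("suboperon_set", "data.frame")
  out
}

#' Operon size distribution
#'
#' Counts operons by gene number, reporting monocistronic transcripts
#' separately from polycistronic operons (shares are percentages within the
#' polycistronic set), and optionally the sub-operon size distribution per
#' condition.
#'
#' @param operons An `operon_set`.
#' @param suboperons Optional `suboperon_set` (one or several conditions
#'   row-bound together).
#' @return List with `monocistronic` (count), `polycistronic` (data.frame
#'   `size`, `count`, `share_pct`) and `suboperons` (data.frame `condition`,
#'   `size`, `count`, `share_pct`, or NULL).
#' @export
operon_size_distribution <- function(operons, suboperons = NULL) {
  poly <- operons[!operons$monocistronic, , drop = FALSE]
  tab <- table(poly$n_genes)
  poly_df <- data.frame(size = as.integer(names(tab)),
                        count = as.integer(tab),
                        share_pct = percent_share(as.integer(tab),
                                                  max(nrow(poly), 1L)))
  sub_df <- NULL
  if (!is.null(suboperons) && nrow(suboperons) > 0L) {
    parts <- split(suboperons, suboperons$condition)
    sub_df <- do.call(rbind, lapply(names(parts), function(cc) {
      t2 <- table(parts[[cc]]$n_genes)
      data.frame(condition = cc, size = as.integer(names(t2)),
                 count = as.integer(t2),
                 share_pct = percent_share(as.integer(t2), nrow(parts[[cc]])))
    }))
  }
  list(monocistronic = sum(operons$monocistronic),
       polycistronic = poly_df,
       suboperons = sub_df)
}
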