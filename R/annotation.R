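#' Genome annotation container
#'
#' Holds the coordinate frame for a single bacterial replicon together with an
#' ordered, strand-aware gene table. All positional operations in the package
#' (TSS classification, promoter window extraction, operon assembly) use this
#' object as the coordinate authority. Coordinates are 1-based inclusive, the
#' native GFF3 convention.
#'
#' @param replicon_id Single replicon (chromosome) identifier.
#' @param length Replicon length in bp.
#' @param genes data.frame with columns `gene_id`, `start`, `stop`, `strand`
#'   (`"+"`/`"-"`) and optionally `product`. Coordinates 1-based inclusive.
#' @param circular Treat the replicon as circular (bacterial chromosome
#'   default)? Upstream windows wrap across the origin iff `TRUE`.
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `replicon_id`, `length`, `circular` and `genes` (sorted by `start`).
#' @export
genome_annotation <- function(replicon_id, length, genes, circular = TRUE) {
  stopifnot(is.character(replicon_id), length(replicon_id) == 1L)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("replicon length must be a positive integer")
  if (!is.data.frame(genes)) stop("`genes` must be a data.frame")
  needed <- c("gene_id", "start", "stop", "strand")
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0L) stop("`genes` lacks columns: ", paste(missing, collapse = ", "))
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$stop <- as.integer(genes$stop)
  genes$gene_id <- as.character(genes$gene_id)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start > genes$stop)) {
    bad <- genes$gene_id[genes$start > genes$stop][1L]
    stop("gene '", bad, "' has stop < start")
  }
  if (any(genes$start < 1L) || any(genes$stop > length)) {
    stop("gene coordinates outside replicon [1, ", length, "]")
  }
  genes <- genes[order(genes$start, genes$stop), , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(replicon_id = replicon_id, length = length,
         circular = isTRUE(circular),
         genes = genes[, c("gene_id", "start", "stop", "strand", "product")]),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d bp (%s), %d genes\n",
              x$replicon_id, x$length,
              if (x$circular) "circular" else "linear",
              nrow(x$genes)))
  invisible(x)
}

#' Translation start sites
#'
#' The translation start (TLS, first base of the start codon) is the gene
#' `start` on the plus strand and the gene `stop` on the minus strand.
#'
#' @param annotation A [genome_annotation].
#' @return Integer vector of TLS positions, named by gene id.
#' @export
tls_positions <- function(annotation) {
  g <- annotation$genes
  out <- ifelse(g$strand == "+", g$start, g$stop)
  names(out) <- g$gene_id
  as.integer(out)
}

# minimal structural validation so parse failures point at the offending line
validate_gff3_lines <- function(lines) {
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (i in body) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 8L) {
      stop("malformed GFF3 at line ", i, ": expected >= 8 tab-separated fields")
    }
    s <- suppressWarnings(as.integer(fields[[4L]]))
    e <- suppressWarnings(as.integer(fields[[5L]]))
    if (is.na(s) || is.na(e)) {
      stop("malformed GFF3 at line ", i, ": non-numeric coordinates")
    }
    if (e < s) stop("malformed GFF3 at line ", i, ": end < start")
  }
  body
}

#' Read a genome annotation from GFF3
#'
#' Parses `gene` (preferred) or `CDS` features into a [genome_annotation].
#' The replicon length is taken from the `##sequence-region` pragma when
#' present, otherwise from the right-most feature end.
#'
#' @param path Path to a GFF3 file.
#' @param circular Passed through to [genome_annotation()].
#' @param feature_types Feature types considered, in order of preference.
#' @return A [genome_annotation].
#' @export
read_gff3 <- function(path, circular = TRUE, feature_types = c("gene", "CDS")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- validate_gff3_lines(lines)
  if (length(body) == 0L) stop("empty annotation: no features in ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  use <- character(0)
  for (ft in feature_types) {
    if (any(type == ft)) { use <- ft; break }
  }
  if (length(use) == 0L) {
    stop("empty annotation: no ", paste(feature_types, collapse = "/"),
         " features in ", path)
  }
  gr <- gr[type == use]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    alt <- gr$locus_tag
    if (!is.null(alt) && !anyNA(alt)) ids <- alt else
      ids <- sprintf("gene_%04d", seq_along(gr))
  }
  product <- if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  replicon <- as.character(GenomicRanges::seqnames(gr))[1L]
  len <- NA_integer_
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr) > 0L) {
    parts <- strsplit(trimws(sr[[1L]]), "\\s+")[[1L]]
    if (length(parts) >= 4L) len <- as.integer(parts[[4L]])
  }
  if (is.na(len)) len <- max(GenomicRanges::end(gr))
  genome_annotation(
    replicon_id = replicon,
    length = len,
    genes = data.frame(
      gene_id = as.character(ids),
      start = GenomicRanges::start(gr),
      stop = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      product = product,
      stringsAsFactors = FALSE
    ),
    circular = circular
  )
}

#' Write a genome annotation to GFF3
#'
#' @param annotation A [genome_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$replicon_id,
    ranges = IRanges::IRanges(start = g$start, end = g$stop),
    strand = g$strand
  )
  gr$type <- "gene"
  gr$ID <- g$gene_id
  if (!all(is.na(g$product))) gr$product <- g$product
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <-
    stats::setNames(annotation$length, annotation$replicon_id))
  rtracklayer::export(gr, path, format = "gff3")
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "##sequence-region"))) {
    pragma <- sprintf("##sequence-region %s 1 %d",
                      annotation$replicon_id, annotation$length)
    writeLines(append(lines, pragma, after = 1L), path)
  }
  invisible(path)
}

#' Read a genome sequence from FASTA
#'
#' @param path FASTA file with a single replicon sequence.
#' @return A `Biostrings::DNAStringSet` of length one.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  if (length(seqs) > 1L) stop("multi-replicon FASTA not supported")
  # keep only the identifier token of the header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Upstream window of an anchor position
#'
#' Returns the genomic interval of the `width` bases immediately upstream of
#' `anchor` in the direction of transcription: `[anchor - width, anchor - 1]`
#' on the plus strand, `[anchor + 1, anchor + width]` on the minus strand. On
#' a circular replicon the window wraps across the origin; on a linear one it
#' is truncated at the replicon edge and flagged.
#'
#' @param anchor Anchor position (1-based), e.g. a TSS or a TLS.
#' @param strand `"+"` or `"-"`.
#' @param width Window width in bp (>= 1).
#' @param annotation A [genome_annotation] providing length and circularity.
#' @return A list with `segments` (data.frame of `start`,`end` pieces ordered
#'   5' to 3' along the strand), `strand`, `width` (realized), `truncated`
#'   and `wrapped`.
#' @export
upstream_window <- function(anchor, strand, width, annotation) {
  stopifnot(width >= 1L)
  L <- annotation$length
  anchor <- as.integer(anchor)
  if (is.na(anchor) || anchor < 1L || anchor > L) {
    stop("anchor ", anchor, " outside replicon [1, ", L, "]")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  width <- as.integer(width)
  wrapped <- FALSE
  truncated <- FALSE
  if (strand == "+") {
    lo <- anchor - width
    hi <- anchor - 1L
    if (lo >= 1L) {
      seg <- data.frame(start = lo, end = hi)
    } else if (annotation$circular) {
      wrapped <- TRUE
      seg <- data.frame(start = c(L + lo, 1L), end = c(L, hi))
      if (hi < 1L) seg <- data.frame(start = L + lo, end = L + hi)
    } else {
      truncated <- TRUE
      seg <- if (hi >= 1L) data.frame(start = 1L, end = hi)
             else data.frame(start = integer(0), end = integer(0))
    }
  } else {
    lo <- anchor + 1L
    hi <- anchor + width
    if (hi <= L) {
      seg <- data.frame(start = lo, end = hi)
    } else if (annotation$circular) {
      wrapped <- TRUE
      seg <- data.frame(start = c(lo, 1L), end = c(L, hi - L))
      if (lo > L) seg <- data.frame(start = lo - L, end = hi - L)
    } else {
      truncated <- TRUE
      seg <- if (lo <= L) data.frame(start = lo, end = L)
             else data.frame(start = integer(0), end = integer(0))
    }
  }
  realized <- if (nrow(seg)) sum(seg$end - seg$start + 1L) else 0L
  list(segments = seg, strand = strand, width = realized,
       truncated = truncated, wrapped = wrapped)
}

#' Sequence of an upstream window
#'
#' Extracts the window sequence 5' to 3' on the anchor's own strand (i.e.
#' reverse-complemented for minus-strand anchors).
#'
#' @param window A window from [upstream_window()].
#' @param genome A `DNAStringSet` of length one (see [read_genome_fasta()]).
#' @return A single character string (possibly empty if fully truncated).
#' @export
window_sequence <- function(window, genome) {
  seq <- genome[[1L]]
  seg <- window$segments
  if (nrow(seg) == 0L) return("")
  parts <- vapply(seq_len(nrow(seg)), function(i) {
    as.character(Biostrings::subseq(seq, start = seg$start[i], end = seg$end[i]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (window$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
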