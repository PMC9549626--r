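#' 5'-UTR category from length
#'
#' Closed-interval categories: `leaderless` 0-9 nt (too short to harbor an
#' RBS with its spacer), `short` 25-35 nt (long enough for an RBS plus
#' spacer), `long` 150-300 nt (long enough for cis-regulatory structures
#' such as riboswitches), `other` everything else.
#'
#' @param length Integer vector of 5'-UTR lengths in nt.
#' @return Character vector of categories.
#' @export
utr_category <- function(length) {
  out <- rep("other", base::length(length))
  out[length >= 0L & length <= 9L] <- "leaderless"
  out[length >= 25L & length <= 35L] <- "short"
  out[length >= 150L & length <= 300L] <- "long"
  out[is.na(length)] <- NA_character_
  out
}

#' Extract 5'-UTR records from classified TSS
#'
#' One record per pTSS: the UTR length is the pTSS-to-TLS distance, counting
#' the transcribed bases strictly before the start codon (TSS base included,
#' TLS base excluded), so a pTSS at the TLS gives length 0 (leaderless). A
#' gene with several pTSS contributes one record per pTSS unless
#' `primary_only` keeps only the highest-RRS pTSS per gene.
#'
#' @param classified Output of [classify_tss()].
#' @param primary_only Keep only the strongest (highest RRS) pTSS per gene.
#' @return data.frame `gene_id`, `tss_position`, `strand`, `length`,
#'   `category` (plus `condition` when present in the input).
#' @export
extract_utrs <- function(classified, primary_only = FALSE) {
  p <- classified[classified$tss_class == "pTSS", , drop = FALSE]
  if (primary_only && nrow(p) > 1L) {
    keep <- unlist(lapply(split(seq_len(nrow(p)), p$assigned_gene),
                          function(i) i[which.max(p$rrs[i])]))
    p <- p[sort(keep), , drop = FALSE]
  }
  out <- data.frame(
    gene_id = p$assigned_gene,
    tss_position = p$position,
    strand = p$strand,
    length = p$distance_to_tls,
    category = utr_category(p$distance_to_tls),
    stringsAsFactors = FALSE
  )
  if ("condition" %in% names(p)) out$condition <- p$condition
  rownames(out) <- NULL
  out
}

#' 5'-UTR length histogram and category fractions
#'
#' @param records Output of [extract_utrs()]; must be non-empty.
#' @param bin_width Histogram bin width in nt.
#' @return List with `histogram` (data.frame `bin_start`, `bin_end`,
#'   `count`, `fraction`), `category_counts` and `category_fractions`
#'   (fractions over all records, summing to 1).
#' @export
utr_histogram <- function(records, bin_width = 10L) {
  if (nrow(records) == 0L) stop("no UTR records to histogram")
  len <- records$length
  top <- max(len)
  breaks <- seq.int(0L, (top %/% bin_width + 1L) * bin_width, by = bin_width)
  h <- hist(len, breaks = breaks, right = FALSE, plot = FALSE)
  lv <- c("leaderless", "short", "long", "other")
  cc <- table(factor(records$category, levels = lv))
  list(
    histogram = data.frame(bin_start = breaks[-base::length(breaks)],
                           bin_end = breaks[-1L] - 1L,
                           count = h$counts,
                           fraction = h$counts / nrow(records)),
    category_counts = stats::setNames(as.integer(cc), lv),
    category_fractions = stats::setNames(as.numeric(cc) / nrow(records), lv)
  )
}

#' Percentage share of a count within a total
#'
#' Tiny convenience for reporting category and operon-size shares as
#' percentages (e.g. 317 of 1522 -> 20.8).
#'
#' @param count,total Non-negative numbers, `total > 0`.
#' @return `count / total * 100` (unrounded).
#' @export
percent_share <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  count / total * 100
}
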