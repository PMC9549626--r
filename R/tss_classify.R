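#' Classify TSS positions relative to the annotation
#'
#' Assigns each called TSS one of four positional classes with the precedence
#' pTSS > iTSS > asTSS > oTSS:
#'
#' * **pTSS** (primary): on the same strand within `upstream_window` nt
#'   upstream of a gene's translation start (TLS), distance 0 allowed. The
#'   closest TLS wins; ties go to the gene with the smaller start. A TSS
#'   inside the upstream gene of an operon still counts as pTSS for the
#'   downstream gene (internal promoters create sub-operons).
#' * **iTSS** (intragenic): inside a same-strand gene body.
#' * **asTSS** (antisense): inside an opposite-strand gene body extended by
#'   `antisense_margin` nt on both sides.
#' * **oTSS** (other): none of the above.
#'
#' @param tss TSS table from [call_tss()] (`position`, `strand` required).
#' @param annotation A [genome_annotation].
#' @param upstream_window pTSS capture window upstream of the TLS, nt.
#' @param antisense_margin Extension of opposite-strand gene bodies, nt.
#' @return The input with columns `tss_class`, `assigned_gene` and
#'   `distance_to_tls` (NA unless pTSS) appended; class `classified_tss`.
#' @export
classify_tss <- function(tss, annotation, upstream_window = 300L,
                         antisense_margin = 100L) {
  g <- annotation$genes
  tls <- ifelse(g$strand == "+", g$start, g$stop)
  n <- nrow(tss)
  tss_class <- rep("oTSS", n)
  assigned <- rep(NA_character_, n)
  dist_tls <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pos <- tss$position[i]; s <- tss$strand[i]
    same <- g$strand == s
    d <- if (s == "+") tls - pos else pos - tls
    ok <- same & d >= 0L & d <= upstream_window
    if (any(ok)) {
      cand <- which(ok)
      cand <- cand[order(d[cand], g$start[cand])]
      tss_class[i] <- "pTSS"
      assigned[i] <- g$gene_id[cand[1L]]
      dist_tls[i] <- d[cand[1L]]
      next
    }
    inside <- same & pos >= g$start & pos <= g$stop
    if (any(inside)) {
      tss_class[i] <- "iTSS"
      assigned[i] <- g$gene_id[which(inside)[1L]]
      next
    }
    anti <- !same & pos >= (g$start - antisense_margin) &
      pos <= (g$stop + antisense_margin)
    if (any(anti)) {
      tss_class[i] <- "asTSS"
      assigned[i] <- g$gene_id[which(anti)[1L]]
    }
  }
  out <- tss
  out$tss_class <- tss_class
  out$assigned_gene <- assigned
  out$distance_to_tls <- dist_tls
  class(out) <- unique(c("classified_tss", class(out)))
  out
}

#' Count TSS per positional class
#'
#' @param classified Output of [classify_tss()].
#' @param by_condition Split counts by the `condition` column when present.
#' @return A named integer vector over `pTSS`, `iTSS`, `asTSS`, `oTSS`
#'   (summing to the number of input TSS), or a matrix with one row per
#'   condition when `by_condition = TRUE`.
#' @export
class_distribution <- function(classified, by_condition = FALSE) {
  lv <- c("pTSS", "iTSS", "asTSS", "oTSS")
  f <- factor(classified$tss_class, levels = lv)
  if (by_condition && "condition" %in% names(classified)) {
    tab <- table(classified$condition, f)
    return(as.matrix(unclass(tab)))
  }
  out <- table(f)
  stats::setNames(as.integer(out), lv)
}
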