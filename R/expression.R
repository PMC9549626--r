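#' Transcripts per kilobase million (TPM)
#'
#' `tpm_g = (count_g / length_kb_g) / sum_g(count_g / length_kb_g) * 1e6`,
#' per column; every column sums to 1e6.
#'
#' @param counts Gene x sample matrix of raw counts.
#' @param lengths Gene lengths in bp (recycled over columns).
#' @return Numeric matrix of TPM values with the input dimnames.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) {
    stop("`lengths` must have one entry per gene")
  }
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / (lengths / 1000)
  denom <- colSums(rate)
  if (any(denom == 0)) stop("zero library: a sample has no counts")
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Replicate concordance (squared Pearson correlation)
#'
#' @param tpm_mat TPM matrix (genes x samples), e.g. from [tpm()].
#' @param conditions Optional factor per column; when given, a warning is
#'   emitted if any within-condition sample pair has R^2 below `floor`.
#' @param floor Concordance floor used for the warning.
#' @return Symmetric sample x sample matrix of squared Pearson correlations
#'   (diagonal 1).
#' @export
replicate_r2 <- function(tpm_mat, conditions = NULL, floor = 0.8) {
  r2 <- stats::cor(tpm_mat)^2
  if (!is.null(conditions)) {
    conditions <- as.factor(conditions)
    for (lv in levels(conditions)) {
      j <- which(conditions == lv)
      if (length(j) < 2L) next
      sub <- r2[j, j]
      low <- sub[upper.tri(sub)] < floor
      if (any(low)) {
        warning("replicate concordance below ", floor,
                " within condition '", lv, "'")
      }
    }
  }
  r2
}

# DESeq-style median-of-ratios size factors over genes with all-positive counts
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has positive counts in every sample")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2L, function(col) exp(stats::median(col - ref)))
}

#' M/A statistics per gene
#'
#' Size factors are estimated by median-of-ratios over genes with
#' all-positive counts; the base mean is the mean of normalized counts over
#' all samples (A = log2 base mean) and M is the log2 ratio of the two
#' condition means of normalized counts (condition of interest over
#' reference).
#'
#' @param counts Gene x sample count matrix.
#' @param conditions Factor per column with two levels; the first level is
#'   the reference (denominator of the fold change).
#' @param pseudocount Added to both condition means before the log ratio;
#'   with the default 0, genes with a zero mean in either condition get
#'   `m_value = NA`.
#' @return data.frame `gene_id`, `base_mean`, `a_value`, `m_value`.
#' @export
ma_statistics <- function(counts, conditions, pseudocount = 0) {
  counts <- as.matrix(counts)
  conditions <- as.factor(conditions)
  if (nlevels(conditions) != 2L) stop("exactly two conditions required")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  ref <- levels(conditions)[1L]
  alt <- levels(conditions)[2L]
  mean_ref <- rowMeans(norm[, conditions == ref, drop = FALSE])
  mean_alt <- rowMeans(norm[, conditions == alt, drop = FALSE])
  base_mean <- rowMeans(norm)
  m <- log2(mean_alt + pseudocount) - log2(mean_ref + pseudocount)
  m[!is.finite(m)] <- NA_real_
  data.frame(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    base_mean = base_mean,
    a_value = log2(base_mean),
    m_value = m,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed linear fold change from an M-value
#'
#' `|fc| = 2^|m|` with the sign of `m`; the inverse of the log2 fold change
#' on magnitudes, so `m = 8.32` gives a 319.6-fold change and negative M
#' report the down-fold with a negative sign.
#'
#' @param m Numeric vector of M-values (log2 fold changes).
#' @return Signed linear fold changes (`m = 0` -> 1).
#' @export
fold_change_from_m <- function(m) {
  ifelse(m == 0, 1, sign(m) * 2^abs(m))
}

#' Negative-binomial Wald test for differential expression
#'
#' A transparent two-group NB test: median-of-ratios size factors, per-gene
#' dispersion by method-of-moments on normalized counts (floored at the
#' genome-wide median estimate, and at 1e-8), a Wald statistic on the log2
#' fold change of condition means via the delta method, and
#' Benjamini-Hochberg correction over the tested genes. Genes
#' with zero counts in every sample are excluded before size-factor
#' estimation and testing. This is a calibration-oriented stand-in for a
#' full GLM framework: no dispersion shrinkage, no LFC shrinkage, no outlier
#' filtering.
#'
#' @param counts Gene x sample count matrix.
#' @param conditions Factor per column, two levels, first level = reference;
#'   at least two replicates per condition.
#' @param mean_pseudocount Small normalized-count offset stabilizing the log
#'   ratio and its variance when one condition mean is near zero.
#' @return data.frame `gene_id`, `base_mean`, `m_value`, `dispersion`,
#'   `stat`, `pvalue`, `padj` (NA rows for all-zero genes are kept so the
#'   output aligns with the input genes).
#' @export
nb_test <- function(counts, conditions, mean_pseudocount = 0.5) {
  counts <- as.matrix(counts)
  conditions <- as.factor(conditions)
  if (nlevels(conditions) != 2L) stop("exactly two conditions required")
  if (any(table(conditions) < 2L)) {
    stop("at least two replicates per condition are required")
  }
  gene_id <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  expressed <- rowSums(counts) > 0
  sub <- counts[expressed, , drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2L, sf, "/")
  ref <- levels(conditions)[1L]; alt <- levels(conditions)[2L]
  jr <- conditions == ref; ja <- conditions == alt
  nr <- sum(jr); na <- sum(ja)
  m_ref <- rowMeans(norm[, jr, drop = FALSE])
  m_alt <- rowMeans(norm[, ja, drop = FALSE])
  v_ref <- apply(norm[, jr, drop = FALSE], 1L, stats::var)
  v_alt <- apply(norm[, ja, drop = FALSE], 1L, stats::var)
  # method-of-moments dispersion, averaged over the two conditions; with few
  # replicates the per-gene estimate is noisy and underestimates inflate the
  # Wald statistic, so each gene is floored at the genome-wide median
  # (a crude form of information sharing across genes)
  mom <- function(v, m) ifelse(m > 0, (v - m) / m^2, 0)
  disp_gene <- (mom(v_ref, m_ref) + mom(v_alt, m_alt)) / 2
  disp_floor <- stats::median(disp_gene[disp_gene > 0])
  if (!is.finite(disp_floor)) disp_floor <- 0
  disp <- pmax(disp_gene, disp_floor, 1e-8)
  pc <- mean_pseudocount
  m <- log2(m_alt + pc) - log2(m_ref + pc)
  # delta method: Var(log2 mean) = Var(mean) / ((mean+pc)^2 * ln(2)^2)
  var_mean <- function(mu, n) (mu + disp * mu^2) / n
  se2 <- var_mean(m_ref, nr) / ((m_ref + pc)^2 * log(2)^2) +
    var_mean(m_alt, na) / ((m_alt + pc)^2 * log(2)^2)
  stat <- ifelse(se2 > 0, m / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(stat))
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene_id = gene_id, base_mean = NA_real_, m_value = NA_real_,
    dispersion = NA_real_, stat = NA_real_, pvalue = NA_real_,
    padj = NA_real_, stringsAsFactors = FALSE
  )
  out$base_mean[expressed] <- rowMeans(norm)
  out$m_value[expressed] <- m
  out$dispersion[expressed] <- disp
  out$stat[expressed] <- stat
  out$pvalue[expressed] <- p
  out$padj[expressed] <- padj
  out
}

#' Regulation class from M-value and significance
#'
#' Mirrors an MA-plot's color classes: `highly_up` (M >= `m_high_up`),
#' `highly_down` (M <= `m_high_down`), `up`/`down` (|M| >= 1), `ns`
#' otherwise; any non-`ns` class additionally requires `padj < alpha`.
#'
#' @param m,padj Numeric vectors.
#' @param m_high_up,m_high_down Thresholds of the extreme classes (the
#'   asymmetric defaults 4 and -3 follow an MA-plot reading where
#'   upregulation under the condition of interest is stronger than
#'   downregulation).
#' @param alpha Adjusted-p significance cutoff.
#' @return Character vector over `highly_up`, `up`, `ns`, `down`,
#'   `highly_down`.
#' @export
regulation_class <- function(m, padj, m_high_up = 4, m_high_down = -3,
                             alpha = 0.01) {
  out <- rep("ns", length(m))
  sig <- !is.na(padj) & padj < alpha & !is.na(m)
  out[sig & m >= 1] <- "up"
  out[sig & m <= -1] <- "down"
  out[sig & m >= m_high_up] <- "highly_up"
  out[sig & m <= m_high_down] <- "highly_down"
  out
}

#' Full differential-expression summary table
#'
#' Convenience wrapper combining [tpm()], [ma_statistics()], [nb_test()],
#' [fold_change_from_m()] and [regulation_class()] into one per-gene table.
#'
#' @param counts Gene x sample count matrix.
#' @param lengths Gene lengths in bp.
#' @param conditions Factor per column, two levels, first = reference.
#' @param ... Passed to [regulation_class()].
#' @return data.frame `gene_id`, `length`, `base_mean`, `a_value`,
#'   `m_value`, `fold_change`, `pvalue`, `padj`, `regulation`.
#' @export
expression_table <- function(counts, lengths, conditions, ...) {
  ma <- ma_statistics(counts, conditions)
  nb <- nb_test(counts, conditions)
  data.frame(
    gene_id = ma$gene_id,
    length = as.integer(lengths),
    base_mean = ma$base_mean,
    a_value = ma$a_value,
    m_value = ma$m_value,
    fold_change = fold_change_from_m(ma$m_value),
    pvalue = nb$pvalue,
    padj = nb$padj,
    regulation = regulation_class(ma$m_value, nb$padj, ...),
    stringsAsFactors = FALSE
  )
}
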