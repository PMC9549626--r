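#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run with the package
#' defaults. Unknown parameters are rejected.
#'
#' @param seed Master seed; all stage randomness derives from it.
#' @param simulation A [simulation_config] for the synthetic study (its seed
#'   is overridden by `seed`).
#' @param threshold,min_rrs,cluster_window,pseudocount,threshold_space TSS
#'   calling parameters, see [call_tss()].
#' @param match_tolerance Cross-condition TSS matching tolerance, bp.
#' @param upstream_window,antisense_margin Classification windows, nt, see
#'   [classify_tss()].
#' @param promoter_window Promoter window width upstream of pTSS, bp.
#' @param rbs_window RBS window width upstream of the TLS, bp.
#' @param motif_width Width of the discovered motifs.
#' @param min_spanning Operon joining threshold, spanning reads.
#' @param de_alpha Adjusted-p cutoff for differential expression.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulation = simulation_config(seed = seed),
                            threshold = 2.5,
                            min_rrs = 1,
                            cluster_window = 5L,
                            pseudocount = 0.5,
                            threshold_space = "log2",
                            match_tolerance = 3L,
                            upstream_window = 300L,
                            antisense_margin = 100L,
                            promoter_window = 70L,
                            rbs_window = 20L,
                            motif_width = 6L,
                            min_spanning = 3L,
                            de_alpha = 0.01) {
  simulation$seed <- as.integer(seed)
  structure(list(
    seed = as.integer(seed), simulation = simulation,
    threshold = threshold, min_rrs = min_rrs,
    cluster_window = as.integer(cluster_window),
    pseudocount = pseudocount, threshold_space = threshold_space,
    match_tolerance = as.integer(match_tolerance),
    upstream_window = as.integer(upstream_window),
    antisense_margin = as.integer(antisense_margin),
    promoter_window = as.integer(promoter_window),
    rbs_window = as.integer(rbs_window),
    motif_width = as.integer(motif_width),
    min_spanning = as.integer(min_spanning),
    de_alpha = de_alpha
  ), class = "pipeline_config")
}

#' TSS recovery against a ground truth
#'
#' Matches called TSS to true TSS on the same strand within `tolerance` bp
#' (greedy nearest matching, each TSS used once) and reports sensitivity,
#' precision and F1.
#'
#' @param calls TSS table from [call_tss()].
#' @param truth_tss data.frame with `position` and `strand` of true TSS.
#' @param tolerance Matching tolerance, bp.
#' @return List with `sensitivity`, `precision`, `f1`, `n_true`, `n_called`,
#'   `n_matched`.
#' @export
tss_recovery <- function(calls, truth_tss, tolerance = 3L) {
  cmp <- compare_conditions(calls, truth_tss, match_tolerance = tolerance)
  n_matched <- nrow(cmp$shared)
  sens <- if (nrow(truth_tss)) n_matched / nrow(truth_tss) else NA_real_
  prec <- if (nrow(calls)) n_matched / nrow(calls) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  list(sensitivity = sens, precision = prec, f1 = f1,
       n_true = nrow(truth_tss), n_called = nrow(calls),
       n_matched = n_matched)
}

#' Operon recovery against a ground truth
#'
#' Fraction of true operons whose assembled counterpart contains exactly the
#' same ordered gene run.
#'
#' @param operons An `operon_set` from [assemble_primary_operons()].
#' @param true_operons Named list of true gene runs (transcription order).
#' @return List with `exact_match` (fraction of true operons recovered
#'   exactly), `n_true`, `n_assembled`.
#' @export
operon_recovery <- function(operons, true_operons) {
  sig <- vapply(operons$genes, paste, character(1), collapse = "|")
  true_sig <- vapply(true_operons, paste, character(1), collapse = "|")
  list(exact_match = mean(true_sig %in% sig),
       n_true = length(true_operons), n_assembled = nrow(operons))
}

#' Run the full annotation pipeline on a simulated study
#'
#' Generates a ground-truthed synthetic study, then runs TSS calling per
#' condition, positional classification, promoter and RBS motif discovery,
#' 5'-UTR categorization, operon and sub-operon reconstruction and the
#' differential-expression summary, and scores every stage against the
#' simulation's ground truth. When `out_dir` is given, the study inputs and
#' all result tables are written as TSV/GFF3/FASTA/bedGraph files.
#'
#' @param config A [pipeline_config].
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_result` with elements `study`, `tss`
#'   (per condition, classified), `comparison` (shared/exclusive TSS),
#'   `motifs`, `rbs`, `utr` (per condition), `operons`, `suboperons` (per
#'   condition), `expression`, `summary` and `scorecard`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_study(config$simulation, out_dir = out_dir)
  ann <- study$annotation
  conds <- config$simulation$conditions

  classified <- list()
  for (cond in conds) {
    calls <- call_tss(study$profiles[[cond]]$enriched,
                      study$profiles[[cond]]$control,
                      threshold = config$threshold, min_rrs = config$min_rrs,
                      cluster_window = config$cluster_window,
                      pseudocount = config$pseudocount,
                      threshold_space = config$threshold_space)
    classified[[cond]] <- classify_tss(calls, ann,
                                       upstream_window = config$upstream_window,
                                       antisense_margin = config$antisense_margin)
  }
  comparison <- compare_conditions(classified[[conds[1L]]],
                                   classified[[conds[2L]]],
                                   match_tolerance = config$match_tolerance)

  # promoter + RBS motifs from the first condition's pTSS
  ptss <- classified[[conds[1L]]]
  ptss <- ptss[ptss$tss_class == "pTSS", , drop = FALSE]
  prom_windows <- extract_windows(ptss, config$promoter_window,
                                  study$genome, ann)
  motifs <- discover_promoter_motifs(prom_windows, width = config$motif_width,
                                     seed = config$seed)
  prom_scan <- two_box_promoter_scan(prom_windows, motifs$pwm10, motifs$pwm35)
  tls_anchors <- data.frame(
    position = tls_positions(ann),
    strand = ann$genes$strand
  )
  rbs_windows <- extract_windows(tls_anchors, config$rbs_window,
                                 study$genome, ann)
  rbs_fit <- find_motif_em(rbs_windows, width = config$motif_width,
                           seed = config$seed + 2L)
  rbs <- rbs_report(rbs_windows, rbs_fit$pwm)

  utr <- lapply(classified, extract_utrs)
  operons <- assemble_primary_operons(ann, study$junctions,
                                      min_spanning = config$min_spanning)
  suboperons <- lapply(classified, function(cl)
    assign_suboperons(operons, cl, ann))

  expr <- expression_table(study$expression$counts,
                           study$expression$lengths,
                           study$expression$conditions,
                           alpha = config$de_alpha)

  sizes <- operon_size_distribution(operons, do.call(rbind, suboperons))
  summary <- list(
    tss_counts = vapply(classified, nrow, integer(1)),
    class_counts = lapply(classified, class_distribution),
    shared_tss = nrow(comparison$shared),
    exclusive_tss = c(stats::setNames(nrow(comparison$exclusive_a), conds[1L]),
                      stats::setNames(nrow(comparison$exclusive_b), conds[2L])),
    promoter_consensus = c(minus10 = pwm_consensus(motifs$pwm10),
                           minus35 = pwm_consensus(motifs$pwm35)),
    rbs_consensus = rbs$consensus,
    utr_fractions = lapply(utr, function(u) utr_histogram(u)$category_fractions),
    operon_sizes = sizes,
    suboperon_counts = vapply(suboperons, nrow, integer(1)),
    regulation_counts = table(expr$regulation)
  )

  truth <- study$truth
  scorecard <- list()
  for (cond in conds) {
    tt <- truth$tss[truth$tss$condition %in% c("both", cond), ]
    scorecard[[cond]] <- tss_recovery(classified[[cond]], tt,
                                      tolerance = config$match_tolerance)
    cl <- classified[[cond]]
    mt <- merge(data.frame(position = cl$position, strand = cl$strand,
                           called_class = cl$tss_class),
                tt[, c("position", "strand", "class")],
                by = c("position", "strand"))
    scorecard[[cond]]$class_agreement <-
      if (nrow(mt)) mean(mt$called_class == mt$class) else NA_real_
    # recovered UTR category fractions vs the truth-realized fractions of
    # the same active TSS set (internal anchors shift the realized mixture)
    lv <- c("leaderless", "short", "long", "other")
    truth_frac <- table(factor(utr_category(tt$utr_length), levels = lv)) /
      max(nrow(tt), 1L)
    scorecard[[cond]]$utr_max_abs_diff <-
      max(abs(summary$utr_fractions[[cond]][lv] - as.numeric(truth_frac)))
    # planted sub-operon anchors recovered as sub-operons (same operon gene
    # suffix, matched on first gene and suffix length)
    ts <- truth$suboperons[truth$suboperons$condition %in% c("both", cond), ,
                           drop = FALSE]
    got <- suboperons[[cond]]
    key <- paste(got$first_gene, got$n_genes)
    scorecard[[cond]]$suboperon_recovery <- if (nrow(ts))
      mean(paste(ts$first_gene, ts$n_genes) %in% key) else NA_real_
  }
  scorecard$operons <- operon_recovery(operons, truth$operons)
  scorecard$minus10_edit_distance <- as.integer(utils::adist(
    toupper(pwm_consensus(motifs$pwm10)),
    config$simulation$minus10_consensus))

  result <- list(study = study, tss = classified, comparison = comparison,
                 motifs = motifs, promoter_scan = prom_scan, rbs = rbs,
                 utr = utr, operons = operons, suboperons = suboperons,
                 expression = expr, summary = summary, scorecard = scorecard,
                 config = config)
  class(result) <- "pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in conds) {
      tab <- classified[[cond]]
      tab$cluster_members <- vapply(tab$cluster_members, paste,
                                    character(1), collapse = ",")
      utils::write.table(tab, file.path(out_dir, paste0("tss_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_tss_bed(classified[[cond]], ann$replicon_id,
                    file.path(out_dir, paste0("tss_", cond, ".bed")))
      utils::write.table(utr[[cond]],
                         file.path(out_dir, paste0("utr_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sub <- suboperons[[cond]]
      sub$genes <- vapply(sub$genes, paste, character(1), collapse = ",")
      utils::write.table(sub,
                         file.path(out_dir, paste0("suboperons_", cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    ops <- operons
    ops$genes <- vapply(ops$genes, paste, character(1), collapse = ",")
    utils::write.table(ops, file.path(out_dir, "operons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expr, file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_meme(list(minus10 = motifs$pwm10, minus35 = motifs$pwm35,
                    rbs = rbs_fit$pwm),
               file.path(out_dir, "motifs.meme"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat("  TSS called:", paste(names(s$tss_counts), s$tss_counts,
                             sep = "=", collapse = ", "), "\n")
  cat("  shared TSS:", s$shared_tss, "; exclusive:",
      paste(names(s$exclusive_tss), s$exclusive_tss,
            sep = "=", collapse = ", "), "\n")
  cat("  promoter consensus: -35", s$promoter_consensus["minus35"],
      "/ -10", s$promoter_consensus["minus10"],
      "; RBS", s$rbs_consensus, "\n")
  cat("  operons:", s$operon_sizes$monocistronic, "monocistronic +",
      sum(s$operon_sizes$polycistronic$count), "polycistronic\n")
  cat("  sub-operons:", paste(names(s$suboperon_counts), s$suboperon_counts,
                              sep = "=", collapse = ", "), "\n")
  for (cond in names(x$scorecard)[names(x$scorecard) %in%
                                  names(s$tss_counts)]) {
    sc <- x$scorecard[[cond]]
    cat(sprintf("  recovery %s: sens %.3f prec %.3f F1 %.3f\n",
                cond, sc$sensitivity, sc$precision, sc$f1))
  }
  cat(sprintf("  operon exact match: %.3f\n", x$scorecard$operons$exact_match))
  invisible(x)
}
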