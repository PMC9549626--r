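#' Configuration of the synthetic study generator
#'
#' Bundles every parameter of the ground-truthed simulation: operon-structured
#' gene layout, sigma-70 style promoters (-35 box, 11-20 bp spacer, -10 box,
#' 6-9 bp spacer, TSS starting on A), Shine-Dalgarno-like ribosome binding
#' sites with a spacer mode of 8 nt, a 5'-UTR length mixture including
#' leaderless transcripts, Poisson read-start noise for the 5'-enriched and
#' control libraries, junction-spanning coverage, and negative-binomial
#' replicate count tables with planted condition effects.
#'
#' @param seed Integer master seed; each generator stage derives its own
#'   stream from it (genome: `seed`, read starts: `seed + 1000 + condition`,
#'   junctions: `seed + 2000`, counts: `seed + 3000`), so a fixed seed gives
#'   byte-identical outputs.
#' @param n_genes Number of genes to lay out.
#' @param operon_size_distribution Named probability vector over operon sizes
#'   `1..K` (names are the sizes).
#' @param gene_length_range,intergenic_range,operon_gap_range bp ranges for
#'   gene lengths, within-operon gaps and between-operon gaps.
#' @param minus10_consensus,minus35_consensus,rbs_consensus Planted 6-mer
#'   motif consensi.
#' @param motif_mismatch_rate Per-base probability that a planted motif base
#'   deviates from its consensus.
#' @param spacer_35_10,spacer_10_tss,rbs_spacer Integer ranges (bp) for the
#'   -35/-10 interspacer, the -10-to-TSS spacer, and the RBS-to-start-codon
#'   spacer; `rbs_spacer_mode` peaks the RBS spacer distribution.
#' @param utr_length_mixture Named weights over the 5'-UTR categories
#'   `leaderless` (0-9 nt), `short` (25-35 nt), `long` (150-300 nt) and
#'   `other` (10-24 or 36-149 nt).
#' @param tss_signal_mean Expected 5'-enriched read starts at a true TSS.
#' @param background_rate Expected read starts per background base (both
#'   libraries).
#' @param control_flatness Control-library rate at a TSS relative to
#'   background (1 = perfectly flat control).
#' @param library_size Total mapped reads recorded for each simulated library
#'   (normalization denominator; exceeds the retained start counts, as in
#'   real libraries where most reads are not retained 5' ends).
#' @param junction_read_mean Expected junction-spanning reads within operons;
#'   `junction_noise_rate` the between-operon (false join) rate.
#' @param suboperon_fraction Fraction of multi-gene operons that receive one
#'   internal (sub-operon) TSS, assigned to `both`, `anoxic` or `oxic`.
#' @param nb_dispersion NB size parameter for replicate gene counts
#'   (dispersion alpha = 1/size).
#' @param n_replicates Replicates per condition (biological triplicates by
#'   default).
#' @param de_fraction,de_log2fc_range Fraction of genes with a condition
#'   effect and the |log2 fold change| range of planted effects.
#' @param mu_log10_range log10 range of baseline gene expression means.
#' @param conditions Two condition labels; the second is the reference
#'   (fold changes are condition 1 over condition 2).
#' @param circular Simulated replicon circularity.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 150L,
    operon_size_distribution = c(`1` = 0.43, `2` = 0.24, `3` = 0.13,
                                 `4` = 0.09, `5` = 0.06, `6` = 0.05),
    gene_length_range = c(300L, 900L),
    intergenic_range = c(40L, 120L),
    operon_gap_range = c(400L, 700L),
    minus10_consensus = "TATAAT",
    minus35_consensus = "CTTGCC",
    rbs_consensus = "AAGGAG",
    motif_mismatch_rate = 0.1,
    spacer_35_10 = c(11L, 20L),
    spacer_10_tss = c(6L, 9L),
    rbs_spacer = c(2L, 19L),
    rbs_spacer_mode = 8L,
    utr_length_mixture = c(leaderless = 0.05, short = 0.25,
                           long = 0.25, other = 0.45),
    tss_signal_mean = 200,
    background_rate = 0.05,
    control_flatness = 1,
    library_size = 2e6,
    junction_read_mean = 30,
    junction_noise_rate = 0.05,
    suboperon_fraction = 0.5,
    nb_dispersion = 20,
    n_replicates = 3L,
    de_fraction = 0.1,
    de_log2fc_range = c(1, 5),
    mu_log10_range = c(1, 3.5),
    conditions = c("anoxic", "oxic"),
    circular = TRUE) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    operon_size_distribution = operon_size_distribution,
    gene_length_range = as.integer(gene_length_range),
    intergenic_range = as.integer(intergenic_range),
    operon_gap_range = as.integer(operon_gap_range),
    minus10_consensus = toupper(minus10_consensus),
    minus35_consensus = toupper(minus35_consensus),
    rbs_consensus = toupper(rbs_consensus),
    motif_mismatch_rate = motif_mismatch_rate,
    spacer_35_10 = as.integer(spacer_35_10),
    spacer_10_tss = as.integer(spacer_10_tss),
    rbs_spacer = as.integer(rbs_spacer),
    rbs_spacer_mode = as.integer(rbs_spacer_mode),
    utr_length_mixture = utr_length_mixture,
    tss_signal_mean = tss_signal_mean,
    background_rate = background_rate,
    control_flatness = control_flatness,
    library_size = library_size,
    junction_read_mean = junction_read_mean,
    junction_noise_rate = junction_noise_rate,
    suboperon_fraction = suboperon_fraction,
    nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    de_fraction = de_fraction,
    de_log2fc_range = de_log2fc_range,
    mu_log10_range = mu_log10_range,
    conditions = conditions,
    circular = isTRUE(circular)
  )
  probs <- cfg$operon_size_distribution
  if (is.null(names(probs)) || anyNA(suppressWarnings(as.integer(names(probs))))) {
    stop("operon_size_distribution must be named by operon size")
  }
  if (any(probs < 0) || sum(probs) <= 0) stop("invalid operon size distribution")
  cfg$operon_size_distribution <- probs / sum(probs)
  mix <- cfg$utr_length_mixture
  if (!setequal(names(mix), c("leaderless", "short", "long", "other"))) {
    stop("utr_length_mixture must be named leaderless/short/long/other")
  }
  if (any(mix < 0) || sum(mix) <= 0) stop("invalid UTR mixture weights")
  cfg$utr_length_mixture <- mix / sum(mix)
  for (nm in c("gene_length_range", "intergenic_range", "operon_gap_range",
               "spacer_35_10", "spacer_10_tss", "rbs_spacer",
               "de_log2fc_range", "mu_log10_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || anyNA(r) || r[1L] > r[2L]) stop("invalid range: ", nm)
  }
  for (nm in c("motif_mismatch_rate", "de_fraction", "suboperon_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0,1]")
  }
  if (length(cfg$conditions) != 2L) stop("exactly two conditions required")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(cfg, class = "simulation_config")
}

# base sampling helpers -------------------------------------------------------

.BASES <- c("A", "C", "G", "T")

sample_range <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

# plant a motif with per-base mismatches; returns a character vector of bases
mutate_motif <- function(consensus, rate) {
  bases <- strsplit(consensus, "")[[1L]]
  flip <- stats::runif(length(bases)) < rate
  if (any(flip)) {
    bases[flip] <- vapply(bases[flip],
                          function(b) sample(setdiff(.BASES, b), 1L),
                          character(1))
  }
  bases
}

sample_utr_length <- function(category) {
  switch(category,
    leaderless = sample(0:9, 1L),
    short = sample(25:35, 1L),
    long = sample(150:300, 1L),
    other = sample(c(10:24, 36:149), 1L)
  )
}

# RBS spacer: discrete distribution over rbs_spacer range peaked at the mode
sample_rbs_spacer <- function(range, mode) {
  support <- seq.int(range[1L], range[2L])
  if (length(support) == 1L) return(support)
  w <- 1 / (1 + abs(support - mode))^2
  support[sample.int(length(support), 1L, prob = w / sum(w))]
}

#' Simulate an operon-structured genome with planted regulatory elements
#'
#' Lays out genes in operon runs on random strands, plants a full promoter
#' (-35 box, interspacer, -10 box, spacer, TSS on an A) upstream of each
#' operon's first gene and of each internal sub-operon anchor, plants an RBS
#' upstream of every translation start and an ATG start codon at it, and
#' fills the rest of the replicon with i.i.d. uniform ACGT sequence.
#'
#' @param config A [simulation_config].
#' @return A list with `annotation` ([genome_annotation]), `genome`
#'   (`DNAStringSet`) and `truth` (class `ground_truth`; see Details).
#' @details The `truth` object carries `tss` (position, strand, gene, UTR
#'   length, class, condition, role, operon), `operons` (named list of gene
#'   runs in transcription order), `genes` (layout table with operon
#'   membership), `suboperons` (anchor and gene-suffix per condition) and
#'   `promoters`/`rbs` manifests of every planted element.
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  # operon sizes until n_genes is covered; trim the last run to fit exactly
  sizes <- integer(0)
  supp <- as.integer(names(config$operon_size_distribution))
  while (sum(sizes) < config$n_genes) {
    sizes <- c(sizes, supp[sample.int(length(supp), 1L,
                                      prob = config$operon_size_distribution)])
  }
  excess <- sum(sizes) - config$n_genes
  if (excess > 0L) sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes <- sizes[sizes > 0L]
  n_op <- length(sizes)
  strands <- sample(c("+", "-"), n_op, replace = TRUE)

  # left-to-right layout in genome coordinates
  genes <- vector("list", n_op)
  cursor <- 0L
  for (k in seq_len(n_op)) {
    gap <- sample_range(config$operon_gap_range)
    cursor <- cursor + gap
    m <- sizes[k]
    glen <- sample_range(config$gene_length_range, m)
    igap <- if (m > 1L) sample_range(config$intergenic_range, m - 1L) else integer(0)
    start <- integer(m); stop <- integer(m)
    for (j in seq_len(m)) {
      start[j] <- cursor + 1L
      stop[j] <- cursor + glen[j]
      cursor <- stop[j] + if (j < m) igap[j] else 0L
    }
    ord <- if (strands[k] == "+") seq_len(m) else rev(seq_len(m))
    genes[[k]] <- data.frame(
      operon_id = sprintf("op%04d", k),
      strand = strands[k],
      start = start, stop = stop,
      tx_order = order(ord),  # position within operon in transcription order
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, genes)
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  L <- as.integer(ceiling((cursor + config$operon_gap_range[2L]) * 1.1))
  if (max(genes$stop) > L) stop("layout overflow: increase the replicon size")

  seq_chars <- sample(.BASES, L, replace = TRUE)
  plant <- function(bases, start, end, strand) {
    # bases given 5'->3' on `strand`; write into genome coordinates
    if (strand == "-") {
      bases <- rev(chartr("ACGT", "TGCA", bases))
    }
    idx <- start:end
    ok <- idx >= 1L & idx <= L
    seq_chars[idx[ok]] <<- bases[ok]
  }

  tls <- ifelse(genes$strand == "+", genes$start, genes$stop)

  # plant a promoter whose TSS sits `utr` bases upstream of `anchor_tls`
  promoter_rows <- list()
  plant_promoter <- function(anchor_tls, strand, utr) {
    s10 <- sample_range(config$spacer_10_tss)
    s3510 <- sample_range(config$spacer_35_10)
    if (strand == "+") {
      tss <- anchor_tls - utr
      e10 <- tss - s10 - 1L; b10 <- e10 - 5L
      e35 <- b10 - s3510 - 1L; b35 <- e35 - 5L
      plant(mutate_motif(config$minus10_consensus, config$motif_mismatch_rate),
            b10, e10, "+")
      plant(mutate_motif(config$minus35_consensus, config$motif_mismatch_rate),
            b35, e35, "+")
      seq_chars[tss] <<- "A"
    } else {
      tss <- anchor_tls + utr
      e10 <- tss + s10 + 1L; b10 <- e10 + 5L
      e35 <- b10 + s3510 + 1L; b35 <- e35 + 5L
      plant(mutate_motif(config$minus10_consensus, config$motif_mismatch_rate),
            e10, b10, "-")
      plant(mutate_motif(config$minus35_consensus, config$motif_mismatch_rate),
            e35, b35, "-")
      seq_chars[tss] <<- "T"  # A on the minus strand
    }
    promoter_rows[[length(promoter_rows) + 1L]] <<- data.frame(
      tss = tss, strand = strand, spacer_35_10 = s3510, spacer_10_tss = s10,
      stringsAsFactors = FALSE
    )
    tss
  }

  # primary promoters: one per operon, upstream of the first gene in
  # transcription order, with a UTR drawn from the category mixture
  op_first <- genes[genes$tx_order == 1L, ]
  utr_cat <- sample(names(config$utr_length_mixture), n_op, replace = TRUE,
                    prob = config$utr_length_mixture)
  tss_rows <- vector("list", n_op)
  for (k in seq_len(n_op)) {
    row <- op_first[op_first$operon_id == sprintf("op%04d", k), ]
    utr <- sample_utr_length(utr_cat[k])
    anchor <- if (row$strand == "+") row$start else row$stop
    tss <- plant_promoter(anchor, row$strand, utr)
    tss_rows[[k]] <- data.frame(
      position = tss, strand = row$strand, gene_id = row$gene_id,
      utr_length = utr, class = "pTSS", condition = "both",
      role = "primary", operon_id = row$operon_id, stringsAsFactors = FALSE
    )
  }

  # internal sub-operon anchors: planted as condition-specific internal pTSS
  sub_rows <- list()
  for (k in seq_len(n_op)) {
    if (sizes[k] < 2L || stats::runif(1L) > config$suboperon_fraction) next
    opid <- sprintf("op%04d", k)
    og <- genes[genes$operon_id == opid, ]
    og <- og[order(og$tx_order), ]
    j <- if (sizes[k] == 2L) 2L else sample(2:sizes[k], 1L)
    target <- og[j, ]
    prev <- og[j - 1L, ]
    gap <- if (target$strand == "+") target$start - prev$stop - 1L
           else prev$start - target$stop - 1L
    utr <- min(sample(15:35, 1L), max(gap - 1L, 1L))
    anchor <- if (target$strand == "+") target$start else target$stop
    cond <- sample(c("both", config$conditions), 1L)
    tss <- plant_promoter(anchor, target$strand, utr)
    tss_rows[[length(tss_rows) + 1L]] <- data.frame(
      position = tss, strand = target$strand, gene_id = target$gene_id,
      utr_length = utr, class = "pTSS", condition = cond,
      role = "internal", operon_id = opid, stringsAsFactors = FALSE
    )
    sub_rows[[length(sub_rows) + 1L]] <- data.frame(
      operon_id = opid, anchor_position = tss, strand = target$strand,
      condition = cond, first_gene = target$gene_id,
      n_genes = sizes[k] - j + 1L, stringsAsFactors = FALSE
    )
  }

  # RBS + start codon for every gene
  rbs_rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    r <- sample_rbs_spacer(config$rbs_spacer, config$rbs_spacer_mode)
    if (genes$strand[i] == "+") {
      e <- genes$start[i] - r - 1L
      plant(mutate_motif(config$rbs_consensus, config$motif_mismatch_rate),
            e - 5L, e, "+")
      plant(c("A", "T", "G"), genes$start[i], genes$start[i] + 2L, "+")
    } else {
      e <- genes$stop[i] + r + 1L
      plant(mutate_motif(config$rbs_consensus, config$motif_mismatch_rate),
            e, e + 5L, "-")
      plant(c("A", "T", "G"), genes$stop[i] - 2L, genes$stop[i], "-")
    }
    rbs_rows[[i]] <- data.frame(gene_id = genes$gene_id[i], spacer = r,
                                stringsAsFactors = FALSE)
  }

  annotation <- genome_annotation(
    replicon_id = "simchr", length = L,
    genes = data.frame(gene_id = genes$gene_id, start = genes$start,
                       stop = genes$stop, strand = genes$strand,
                       product = paste0("simulated protein ", genes$gene_id),
                       stringsAsFactors = FALSE),
    circular = config$circular
  )
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "simchr"

  operons <- lapply(split(genes, genes$operon_id), function(og) {
    og$gene_id[order(og$tx_order)]
  })
  truth <- structure(list(
    replicon_id = "simchr", replicon_length = L, circular = config$circular,
    genes = genes[, c("gene_id", "operon_id", "start", "stop", "strand",
                      "tx_order")],
    tss = do.call(rbind, tss_rows),
    operons = operons,
    suboperons = if (length(sub_rows)) do.call(rbind, sub_rows) else
      data.frame(operon_id = character(0), anchor_position = integer(0),
                 strand = character(0), condition = character(0),
                 first_gene = character(0), n_genes = integer(0)),
    promoters = do.call(rbind, promoter_rows),
    rbs = do.call(rbind, rbs_rows)
  ), class = "ground_truth")

  list(annotation = annotation, genome = genome, truth = truth)
}

#' Simulate 5'-enriched and control read-start libraries
#'
#' Background read starts are Poisson(`background_rate`) at every base of
#' both strands in both libraries. At each true TSS active under `condition`
#' the enriched library draws Poisson(`tss_signal_mean`) starts and the
#' control draws Poisson(`background_rate * control_flatness`), emulating the
#' 5'-triphosphate enrichment contrast.
#'
#' @param truth `ground_truth` from [simulate_genome()].
#' @param config The [simulation_config].
#' @param condition Which condition's TSS set is active (TSS planted as
#'   `"both"` are always active).
#' @return List with `enriched` and `control` [read_start_profile]s.
#' @export
simulate_readstarts <- function(truth, config, condition = config$conditions[1L]) {
  stopifnot(inherits(truth, "ground_truth"))
  cond_idx <- match(condition, config$conditions)
  if (is.na(cond_idx)) stop("unknown condition: ", condition)
  set.seed(config$seed + 1000L + cond_idx)
  L <- truth$replicon_length
  active <- truth$tss[truth$tss$condition %in% c("both", condition), ]

  draw <- function(signal_mean) {
    fwd <- stats::rpois(L, config$background_rate)
    rev <- stats::rpois(L, config$background_rate)
    pf <- active$position[active$strand == "+"]
    pr <- active$position[active$strand == "-"]
    fwd[pf] <- stats::rpois(length(pf), signal_mean)
    rev[pr] <- stats::rpois(length(pr), signal_mean)
    list(fwd = fwd, rev = rev)
  }
  enr <- draw(config$tss_signal_mean)
  ctl <- draw(config$background_rate * config$control_flatness)
  list(
    enriched = read_start_profile(
      library_id = paste0("enriched_", condition), condition = condition,
      counts_fwd = enr$fwd, counts_rev = enr$rev,
      total_mapped = max(config$library_size, max(enr$fwd), max(enr$rev))),
    control = read_start_profile(
      library_id = paste0("control_", condition), condition = condition,
      counts_fwd = ctl$fwd, counts_rev = ctl$rev,
      total_mapped = max(config$library_size, max(ctl$fwd), max(ctl$rev)))
  )
}

#' Simulate junction-spanning read counts
#'
#' Adjacent same-strand gene pairs inside a true operon receive
#' Poisson(`junction_read_mean`) spanning reads; adjacent same-strand pairs
#' across operon boundaries receive Poisson(`junction_noise_rate`).
#'
#' @param truth `ground_truth` from [simulate_genome()].
#' @param config The [simulation_config].
#' @return data.frame with one row per adjacent same-strand pair in genome
#'   order: `upstream_gene`, `downstream_gene` (transcription order),
#'   `strand`, `spanning_reads`.
#' @export
simulate_junctions <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(config$seed + 2000L)
  g <- truth$genes[order(truth$genes$start), ]
  n <- nrow(g)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    if (g$strand[i] != g$strand[i + 1L]) next
    same_op <- g$operon_id[i] == g$operon_id[i + 1L]
    lambda <- if (same_op) config$junction_read_mean else config$junction_noise_rate
    up <- if (g$strand[i] == "+") i else i + 1L
    dn <- if (g$strand[i] == "+") i + 1L else i
    rows[[length(rows) + 1L]] <- data.frame(
      upstream_gene = g$gene_id[up], downstream_gene = g$gene_id[dn],
      strand = g$strand[i], spanning_reads = stats::rpois(1L, lambda),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(upstream_gene = character(0),
                      downstream_gene = character(0), strand = character(0),
                      spanning_reads = integer(0)))
  }
  do.call(rbind, rows)
}

#' Simulate a replicate gene-count table with condition effects
#'
#' Baseline gene means are log-uniform; a `de_fraction` of genes receives a
#' planted log2 fold change (condition 1 relative to condition 2, random
#' sign). Counts are negative-binomial with size `nb_dispersion`.
#'
#' @param truth `ground_truth` from [simulate_genome()], or a data.frame with
#'   columns `gene_id`, `start`, `stop` (lengths are `stop - start + 1`).
#' @param config The [simulation_config].
#' @return List with `counts` (gene x sample integer matrix, columns named
#'   `<condition>_<replicate>`), `lengths` (bp, named by gene),
#'   `conditions` (factor per column, reference = second condition) and
#'   `de` (data.frame `gene_id`, `log2fc`; zero for unaffected genes).
#' @export
simulate_counts <- function(truth, config) {
  g <- if (inherits(truth, "ground_truth")) truth$genes else truth
  stopifnot(all(c("gene_id", "start", "stop") %in% names(g)))
  set.seed(config$seed + 3000L)
  n <- nrow(g)
  mu <- 10^stats::runif(n, config$mu_log10_range[1L], config$mu_log10_range[2L])
  lfc <- numeric(n)
  n_de <- round(config$de_fraction * n)
  if (n_de > 0L) {
    idx <- sample.int(n, n_de)
    lfc[idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, config$de_log2fc_range[1L], config$de_log2fc_range[2L])
  }
  conds <- rep(config$conditions, each = config$n_replicates)
  counts <- matrix(0L, nrow = n, ncol = length(conds),
                   dimnames = list(g$gene_id,
                                   paste0(conds, "_", rep(seq_len(config$n_replicates), 2L))))
  for (j in seq_along(conds)) {
    m <- if (conds[j] == config$conditions[1L]) mu * 2^lfc else mu
    counts[, j] <- stats::rnbinom(n, mu = m, size = config$nb_dispersion)
  }
  list(
    counts = counts,
    lengths = stats::setNames(g$stop - g$start + 1L, g$gene_id),
    conditions = factor(conds, levels = rev(config$conditions)),
    de = data.frame(gene_id = g$gene_id, log2fc = lfc,
                    stringsAsFactors = FALSE)
  )
}

#' Simulate a complete ground-truthed study
#'
#' Convenience wrapper running [simulate_genome()], [simulate_readstarts()]
#' for both conditions, [simulate_junctions()] and [simulate_counts()].
#' Optionally writes every artifact in the formats the readers of this
#' package consume (GFF3, FASTA, bedGraph per strand per library, junction
#' and count TSVs).
#'
#' @param config A [simulation_config].
#' @param out_dir Optional directory to write the study files into.
#' @return List with `annotation`, `genome`, `truth`, `profiles` (per
#'   condition: `enriched`, `control`), `junctions`, `expression` (the
#'   [simulate_counts()] result) and, when written, `files`.
#' @export
simulate_study <- function(config = simulation_config(), out_dir = NULL) {
  sim <- simulate_genome(config)
  profiles <- lapply(stats::setNames(nm = config$conditions), function(cond) {
    simulate_readstarts(sim$truth, config, condition = cond)
  })
  junctions <- simulate_junctions(sim$truth, config)
  expression <- simulate_counts(sim$truth, config)
  out <- list(annotation = sim$annotation, genome = sim$genome,
              truth = sim$truth, profiles = profiles,
              junctions = junctions, expression = expression,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      gff3 = file.path(out_dir, "annotation.gff3"),
      fasta = file.path(out_dir, "genome.fasta"),
      junctions = file.path(out_dir, "junctions.tsv"),
      counts = file.path(out_dir, "counts.tsv")
    )
    write_gff3(sim$annotation, files$gff3)
    Biostrings::writeXStringSet(sim$genome, files$fasta)
    utils::write.table(junctions, files$junctions, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cnt <- data.frame(gene_id = rownames(expression$counts),
                      length = as.integer(expression$lengths),
                      expression$counts, check.names = FALSE)
    utils::write.table(cnt, files$counts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (cond in config$conditions) {
      for (lib in c("enriched", "control")) {
        fwd <- file.path(out_dir, sprintf("%s_%s_fwd.bedgraph", lib, cond))
        rev <- file.path(out_dir, sprintf("%s_%s_rev.bedgraph", lib, cond))
        write_bedgraph_pair(profiles[[cond]][[lib]], sim$annotation$replicon_id,
                            fwd, rev)
        files[[sprintf("%s_%s", lib, cond)]] <- c(fwd = fwd, rev = rev)
      }
    }
    out$files <- files
  }
  out
}
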