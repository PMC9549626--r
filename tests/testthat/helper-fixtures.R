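# shared fixtures and independent oracle implementations

# small linear/circular annotation with explicit genes
make_annotation <- function(genes, length = 10000L, circular = TRUE,
                            replicon_id = "chr") {
  genome_annotation(replicon_id, length, genes, circular = circular)
}

two_gene_annotation <- function(circular = TRUE) {
  make_annotation(data.frame(
    gene_id = c("geneA", "geneB"),
    start = c(101L, 501L), stop = c(400L, 900L),
    strand = c("+", "-"),
    product = c("alpha", "beta")
  ), length = 1000L, circular = circular)
}

# profile with counts planted at given positions (fwd/rev), rest zero
make_profile <- function(length, fwd = integer(0), rev = integer(0),
                         total_mapped = 1e6, library_id = "lib",
                         condition = "test") {
  cf <- integer(length); cr <- integer(length)
  if (length(fwd)) cf[as.integer(names(fwd))] <- as.integer(fwd)
  if (length(rev)) cr[as.integer(names(rev))] <- as.integer(rev)
  read_start_profile(library_id, condition, cf, cr, total_mapped)
}

# ---- independent oracle: exhaustive per-base TSS scan -----------------------
# evaluates the score definition at every base and clusters candidates by
# connected components of the |pos_i - pos_j| <= window graph (union-find),
# picking the max-rrs member (ties -> smaller coordinate)
oracle_call_tss <- function(enriched, control, threshold = 2.5, min_rrs = 1,
                            cluster_window = 5L, pseudocount = 0.5) {
  out <- list()
  for (strand in c("+", "-")) {
    ec <- if (strand == "+") enriched$counts_fwd else enriched$counts_rev
    cc <- if (strand == "+") control$counts_fwd else control$counts_rev
    cand <- integer(0); rrs <- numeric(0); sc <- numeric(0)
    for (p in seq_along(ec)) {
      r_e <- ec[p] / enriched$total_mapped * 1e6
      r_c <- cc[p] / control$total_mapped * 1e6
      s <- log2((r_e + pseudocount) / (r_c + pseudocount))
      if (s >= threshold && r_e >= min_rrs) {
        cand <- c(cand, p); rrs <- c(rrs, r_e); sc <- c(sc, s)
      }
    }
    if (length(cand) == 0L) next
    parent <- seq_along(cand)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (i < j && abs(cand[i] - cand[j]) <= cluster_window) {
          parent[find(j)] <- find(i)
        }
      }
    }
    comp <- vapply(seq_along(cand), find, integer(1))
    for (cp in unique(comp)) {
      members <- which(comp == cp)
      best <- members[order(-rrs[members], cand[members])][1L]
      out[[length(out) + 1L]] <- data.frame(
        position = cand[best], strand = strand, rrs = rrs[best],
        enrichment_score = sc[best],
        cluster_size = length(members)
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(position = integer(0), strand = character(0),
                      rrs = numeric(0), enrichment_score = numeric(0),
                      cluster_size = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(match(res$strand, c("+", "-")), res$position), , drop = FALSE]
}

# ---- independent oracle: operon assembly by union-find ----------------------
oracle_assemble_operons <- function(annotation, junctions, min_spanning = 3L) {
  g <- annotation$genes
  n <- nrow(g)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  jc <- function(x, y) {
    hit <- (junctions$upstream_gene == x & junctions$downstream_gene == y) |
      (junctions$upstream_gene == y & junctions$downstream_gene == x)
    if (!any(hit)) 0L else sum(junctions$spanning_reads[hit])
  }
  for (i in seq_len(max(n - 1L, 0L))) {
    if (g$strand[i] == g$strand[i + 1L] &&
        jc(g$gene_id[i], g$gene_id[i + 1L]) >= min_spanning) {
      parent[find(i + 1L)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lapply(unname(split(seq_len(n), comp)), function(i) {
    i <- sort(i)
    if (g$strand[i[1L]] == "+") g$gene_id[i] else rev(g$gene_id[i])
  })
}

# windows with an exact planted motif at known offsets in uniform background
planted_motif_windows <- function(n, width = 40L, motif = "TATAAT",
                                  seed = 42L) {
  set.seed(seed)
  m <- nchar(motif)
  offs <- sample.int(width - m + 1L, n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    s[offs[i]:(offs[i] + m - 1L)] <- strsplit(motif, "")[[1L]]
    paste(s, collapse = "")
  }, character(1))
  list(seqs = seqs, offsets = offs)
}

# near-deterministic pwm concentrated on a consensus
consensus_pwm <- function(consensus, p = 0.91) {
  bases <- strsplit(consensus, "")[[1L]]
  probs <- matrix((1 - p) / 3, nrow = 4L, ncol = length(bases),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) probs[bases[j], j] <- p
  pwm(probs)
}
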