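#' Relative read score (RRS)
#'
#' Depth-normalizes the per-base read-start counts of a library to reads per
#' million mapped reads: `RRS(pos) = counts(pos) / total_mapped * 1e6`.
#'
#' @param profile A [read_start_profile].
#' @return List with numeric vectors `fwd` and `rev`.
#' @export
compute_rrs <- function(profile) {
  stopifnot(inherits(profile, "read_start_profile"))
  if (profile$total_mapped <= 0) stop("total_mapped must be > 0")
  list(fwd = profile$counts_fwd / profile$total_mapped * 1e6,
       rev = profile$counts_rev / profile$total_mapped * 1e6)
}

#' Log2 enrichment score
#'
#' `log2((rrs + pc) / (rrs_control + pc))`: the per-base contrast between the
#' 5'-enriched library and the unenriched control, with a pseudocount
#' guarding zero-control positions. Swapping the arguments negates the score.
#'
#' @param rrs,rrs_control Non-negative RRS values (vectorized).
#' @param pseudocount Positive pseudocount in RRS units (reads per million).
#' @return Numeric vector of scores.
#' @export
enrichment_score <- function(rrs, rrs_control, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2((rrs + pseudocount) / (rrs_control + pseudocount))
}

# cluster candidate positions on one strand: runs whose consecutive gaps are
# <= window collapse to the member with maximal rrs (ties -> smaller coord)
cluster_candidates <- function(pos, rrs, rrs_control, score, window) {
  if (length(pos) == 0L) {
    return(data.frame(position = integer(0), rrs = numeric(0),
                      rrs_control = numeric(0), enrichment_score = numeric(0),
                      cluster_size = integer(0),
                      cluster_members = I(list())))
  }
  o <- order(pos)
  pos <- pos[o]; rrs <- rrs[o]; rrs_control <- rrs_control[o]; score <- score[o]
  grp <- cumsum(c(1L, diff(pos) > window))
  idx <- split(seq_along(pos), grp)
  rows <- lapply(idx, function(i) {
    best <- i[which.max(rrs[i])]  # which.max returns the first (smallest coord) tie
    data.frame(position = pos[best], rrs = rrs[best],
               rrs_control = rrs_control[best],
               enrichment_score = score[best],
               cluster_size = length(i),
               cluster_members = I(list(pos[i])))
  })
  do.call(rbind, rows)
}

#' Call transcription start sites
#'
#' Every base whose enrichment score reaches `threshold` and whose enriched
#' RRS reaches `min_rrs` is a TSS candidate; same-strand candidates within
#' `cluster_window` bp of each other are merged to the candidate with the
#' highest RRS (ties resolved to the smaller coordinate).
#'
#' @param enriched,control [read_start_profile]s sharing the replicon layout.
#' @param threshold Calling threshold. Interpreted in `threshold_space`:
#'   `"log2"` (default) cuts the log2 enrichment score at `threshold`;
#'   `"linear"` treats `threshold` as a linear enrichment factor and cuts the
#'   score at `log2(threshold)`.
#' @param min_rrs Minimum enriched RRS (reads per million) of a candidate,
#'   suppressing single-read artifacts.
#' @param cluster_window Merge window in bp.
#' @param pseudocount Passed to [enrichment_score()].
#' @param threshold_space `"log2"` or `"linear"` (see `threshold`).
#' @return A data.frame of class `tss_set`, sorted by (strand, position),
#'   with columns `position`, `strand`, `rrs`, `rrs_control`,
#'   `enrichment_score`, `cluster_size`, `cluster_members` (list) and
#'   `condition` (taken from the enriched profile).
#' @export
call_tss <- function(enriched, control, threshold = 2.5, min_rrs = 1,
                     cluster_window = 5L, pseudocount = 0.5,
                     threshold_space = c("log2", "linear")) {
  stopifnot(inherits(enriched, "read_start_profile"),
            inherits(control, "read_start_profile"))
  if (length(enriched$counts_fwd) != length(control$counts_fwd)) {
    stop("enriched and control profiles have mismatched replicon lengths")
  }
  threshold_space <- match.arg(threshold_space)
  cut <- if (threshold_space == "log2") threshold else log2(threshold)
  rrs_e <- compute_rrs(enriched)
  rrs_c <- compute_rrs(control)
  per_strand <- function(strand) {
    key <- if (strand == "+") "fwd" else "rev"
    score <- enrichment_score(rrs_e[[key]], rrs_c[[key]], pseudocount)
    cand <- which(score >= cut & rrs_e[[key]] >= min_rrs)
    df <- cluster_candidates(cand, rrs_e[[key]][cand], rrs_c[[key]][cand],
                             score[cand], cluster_window)
    if (nrow(df)) df$strand <- strand else df$strand <- character(0)
    df
  }
  out <- rbind(per_strand("+"), per_strand("-"))
  out <- out[, c("position", "strand", "rrs", "rrs_control",
                 "enrichment_score", "cluster_size", "cluster_members")]
  out <- out[order(match(out$strand, c("+", "-")), out$position), , drop = FALSE]
  rownames(out) <- NULL
  out$condition <- rep(enriched$condition, nrow(out))
  class(out) <- c("tss_set", "data.frame")
  out
}

#' Compare TSS sets between two conditions
#'
#' Greedy nearest matching of same-strand TSS within `match_tolerance` bp:
#' candidate pairs are ranked by distance and accepted while both partners
#' are unmatched, so each TSS matches at most once.
#'
#' @param a,b TSS tables (from [call_tss()]) with `position` and `strand`.
#' @param match_tolerance Maximum |distance| in bp for a match.
#' @return List with `shared` (data.frame `position_a`, `position_b`,
#'   `strand`, `distance`), `exclusive_a` and `exclusive_b` (row subsets of
#'   the inputs).
#' @export
compare_conditions <- function(a, b, match_tolerance = 3L) {
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  pairs <- list()
  for (s in c("+", "-")) {
    ia <- which(a$strand == s); ib <- which(b$strand == s)
    if (length(ia) == 0L || length(ib) == 0L) next
    d <- abs(outer(a$position[ia], b$position[ib], "-"))
    hit <- which(d <= match_tolerance, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    ord <- order(d[hit], a$position[ia][hit[, 1L]])
    for (h in ord) {
      qi <- ia[hit[h, 1L]]; si <- ib[hit[h, 2L]]
      if (used_a[qi] || used_b[si]) next
      used_a[qi] <- TRUE; used_b[si] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        position_a = a$position[qi], position_b = b$position[si],
        strand = s, distance = abs(a$position[qi] - b$position[si]))
    }
  }
  shared <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(position_a = integer(0), position_b = integer(0),
               strand = character(0), distance = integer(0))
  list(shared = shared,
       exclusive_a = a[!used_a, , drop = FALSE],
       exclusive_b = b[!used_b, , drop = FALSE])
}

#' Export called TSS as BED6
#'
#' One BED line per TSS: name = class (if classified, else "TSS"), score =
#' enrichment score times 100, rounded.
#'
#' @param tss A TSS table; if classified (see [classify_tss()]) the class
#'   labels are used as names.
#' @param replicon_id Chromosome name for column 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, replicon_id, path) {
  name <- if ("tss_class" %in% names(tss)) tss$tss_class else
    rep("TSS", nrow(tss))
  bed <- data.frame(
    chrom = replicon_id,
    start = tss$position - 1L,   # BED is 0-based half-open
    end = tss$position,
    name = name,
    score = round(tss$enrichment_score * 100),
    strand = tss$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
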