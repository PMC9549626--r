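#' Read-start profile for one sequencing library
#'
#' Dense per-base counts of read 5' ends on both strands of a replicon, plus
#' the library's total mapped-read count used for depth normalization. A
#' read's start is the genomic coordinate of its 5'-most base on its own
#' strand (minus-strand reads anchor at their alignment end), so that a
#' 5'-enriched protocol marks transcript 5' ends.
#'
#' `total_mapped` is the library's mapped-read count; it may exceed the sum of
#' the retained start counts (not every mapped read yields a retained 5' end)
#' but must be at least the largest per-base count.
#'
#' @param library_id Library identifier.
#' @param condition Growth condition label for the library.
#' @param counts_fwd,counts_rev Non-negative integer vectors of per-base
#'   5'-end counts, one entry per replicon base.
#' @param total_mapped Positive integer, mapped reads in the library.
#' @return An object of class `read_start_profile`.
#' @export
read_start_profile <- function(library_id, condition, counts_fwd, counts_rev,
                               total_mapped) {
  if (length(counts_fwd) != length(counts_rev)) {
    stop("forward and reverse count vectors must have equal length")
  }
  counts_fwd <- as.integer(counts_fwd)
  counts_rev <- as.integer(counts_rev)
  if (anyNA(counts_fwd) || anyNA(counts_rev) ||
      any(counts_fwd < 0L) || any(counts_rev < 0L)) {
    stop("counts must be non-negative integers")
  }
  total_mapped <- as.numeric(total_mapped)
  if (is.na(total_mapped) || total_mapped <= 0) {
    stop("total_mapped must be positive")
  }
  if (total_mapped < max(c(counts_fwd, counts_rev, 0L))) {
    stop("total_mapped smaller than the largest per-base count")
  }
  structure(
    list(library_id = library_id, condition = condition,
         counts_fwd = counts_fwd, counts_rev = counts_rev,
         total_mapped = total_mapped),
    class = "read_start_profile"
  )
}

#' @export
print.read_start_profile <- function(x, ...) {
  cat(sprintf(
    "<read_start_profile> %s (%s): %d bp, %d fwd / %d rev starts, %g mapped reads\n",
    x$library_id, x$condition, length(x$counts_fwd),
    sum(x$counts_fwd), sum(x$counts_rev), x$total_mapped))
  invisible(x)
}

# bedGraph file -> dense 1-based per-base vector of length `length`
bedgraph_to_vector <- function(path, length) {
  out <- integer(length)
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) return(out)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(out)
  s <- GenomicRanges::start(gr)  # rtracklayer converts to 1-based inclusive
  e <- GenomicRanges::end(gr)
  v <- as.numeric(gr$score)
  if (any(v < 0)) stop("negative values in bedGraph: ", path)
  if (any(e > length)) stop("bedGraph interval beyond replicon length in ", path)
  seen <- integer(length)
  for (i in seq_along(gr)) {
    idx <- s[i]:e[i]
    clash <- seen[idx] > 0L & out[idx] != v[i]
    if (any(clash)) {
      stop("overlapping bedGraph intervals with conflicting values at position ",
           idx[which(clash)[1L]], " in ", path)
    }
    out[idx] <- v[i]
    seen[idx] <- seen[idx] + 1L
  }
  out
}

#' Read a strand pair of bedGraph read-start tracks
#'
#' bedGraph intervals are 0-based half-open (the format's native convention);
#' they are converted to this package's 1-based frame at the boundary, so a
#' line `chr 9 10 42` places 42 counts at model position 10.
#'
#' @param fwd,rev Paths to the forward/reverse strand bedGraph files.
#' @param library_size Total mapped reads of the library.
#' @param length Replicon length in bp.
#' @param library_id,condition Labels stored in the profile.
#' @return A [read_start_profile].
#' @export
read_bedgraph_pair <- function(fwd, rev, library_size, length,
                               library_id = basename(fwd),
                               condition = NA_character_) {
  read_start_profile(
    library_id = library_id, condition = condition,
    counts_fwd = bedgraph_to_vector(fwd, length),
    counts_rev = bedgraph_to_vector(rev, length),
    total_mapped = library_size
  )
}

# dense vector -> bedGraph (nonzero runs only), 0-based half-open
vector_to_bedgraph <- function(counts, replicon_id, path) {
  nz <- which(counts != 0L)
  if (length(nz) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  runs <- split(nz, cumsum(c(1L, diff(nz) != 1L | diff(counts[nz]) != 0L)))
  # split runs further where the value changes
  starts <- integer(0); ends <- integer(0); vals <- numeric(0)
  for (r in runs) {
    brk <- cumsum(c(1L, diff(counts[r]) != 0L))
    for (p in split(r, brk)) {
      starts <- c(starts, p[1L]); ends <- c(ends, p[length(p)])
      vals <- c(vals, counts[p[1L]])
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = replicon_id,
    ranges = IRanges::IRanges(start = starts, end = ends),
    score = vals
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a read-start profile as a bedGraph strand pair
#'
#' @param profile A [read_start_profile].
#' @param replicon_id Replicon name written to the first column.
#' @param fwd,rev Output paths for the two strands.
#' @return Character vector of the two paths, invisibly.
#' @export
write_bedgraph_pair <- function(profile, replicon_id, fwd, rev) {
  vector_to_bedgraph(profile$counts_fwd, replicon_id, fwd)
  vector_to_bedgraph(profile$counts_rev, replicon_id, rev)
  invisible(c(fwd, rev))
}
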