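#' Position weight matrix
#'
#' @param probs 4 x width matrix of base probabilities, rows A, C, G, T;
#'   columns must each sum to 1.
#' @param background Named background base frequencies (A, C, G, T).
#' @param n_sites Number of (effective) sites supporting the matrix.
#' @return An object of class `pwm`.
#' @export
pwm <- function(probs, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                n_sites = 0) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A, C, G, T)")
  rownames(probs) <- c("A", "C", "G", "T")
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("pwm columns must sum to 1")
  }
  background <- background[c("A", "C", "G", "T")]
  structure(list(width = ncol(probs), probs = probs,
                 background = background / sum(background),
                 n_sites = n_sites),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, %s sites, consensus %s\n",
              x$width, format(x$n_sites), pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM
#'
#' Majority base per column; uppercase where the probability reaches
#' `upper`, lowercase otherwise (the field's "TATaaT" convention).
#'
#' @param x A [pwm].
#' @param upper Probability above which a base is written uppercase.
#' @return A single character string.
#' @export
pwm_consensus <- function(x, upper = 0.7) {
  idx <- apply(x$probs, 2L, which.max)
  p <- x$probs[cbind(idx, seq_len(x$width))]
  ch <- rownames(x$probs)[idx]
  ch[p < upper] <- tolower(ch[p < upper])
  paste(ch, collapse = "")
}

#' Per-column information content of a PWM
#'
#' `2 + sum(p * log2(p))` bits per column (uniform background), in `[0, 2]`.
#'
#' @param x A [pwm].
#' @return Numeric vector, one value per column.
#' @export
pwm_information_content <- function(x) {
  apply(x$probs, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

# log-odds matrix vs the pwm's background
pwm_log_odds <- function(x) {
  log(x$probs) - log(x$background)
}

seqs_to_int <- function(seqs) {
  lapply(strsplit(toupper(seqs), ""), function(b) match(b, .BASES))
}

# sliding log-odds score of a pwm over one integer-coded sequence;
# ambiguous (non-ACGT) positions score 0
score_pwm_sliding <- function(x_int, lodds) {
  w <- ncol(lodds)
  m <- length(x_int) - w + 1L
  if (m < 1L) return(numeric(0))
  out <- numeric(m)
  for (j in seq_len(w)) {
    b <- x_int[j:(j + m - 1L)]
    contrib <- lodds[cbind(b, j)]
    contrib[is.na(contrib)] <- 0
    out <- out + contrib
  }
  out
}

#' Ungapped motif discovery by ZOOPS expectation-maximization
#'
#' Fits the zero-or-one-occurrence-per-sequence (ZOOPS) model: each sequence
#' harbors at most one occurrence of a width-`width` motif at a uniform
#' unknown offset, against a 0-order background estimated from the input.
#' The E-step computes the posterior over offsets (and absence), the M-step
#' re-estimates the matrix with Dirichlet(0.25) smoothing and the occurrence
#' probability. Because of the smoothing this is MAP-EM; the objective that
#' provably never decreases (and is checked at every iteration) is the
#' penalized log-likelihood, i.e. the log posterior. The run is restarted
#' `n_restarts` times from seeded initializations and the restart with the
#' highest objective wins; results are deterministic given `seed`.
#'
#' @param seqs Character vector of DNA sequences, each at least `width` long
#'   (lengths may differ).
#' @param width Motif width.
#' @param n_restarts Number of seeded restarts (>= 1).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param seed Integer seed for the restart initializations.
#' @return List of class `motif_em` with `pwm` (a [pwm]), `offsets` (MAP
#'   motif start per sequence, NA where absence is the MAP state), `gamma`
#'   (fitted occurrence probability), `loglik` (final penalized
#'   log-likelihood) and `loglik_trace` (its per-iteration values,
#'   non-decreasing).
#' @export
find_motif_em <- function(seqs, width = 6L, n_restarts = 5L, max_iter = 100L,
                          tol = 1e-6, seed = 1L) {
  width <- as.integer(width)
  if (length(seqs) == 0L) stop("no sequences")
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  if (any(nchar(seqs) < width)) stop("motif width exceeds the shortest sequence")
  xs <- seqs_to_int(seqs)
  ns <- length(xs)
  base_tab <- tabulate(unlist(xs)[!is.na(unlist(xs))], nbins = 4L) + 0.25
  bg <- stats::setNames(base_tab / sum(base_tab), .BASES)
  lbg <- log(bg)
  # background log-likelihood of each full sequence (constant over iterations)
  B <- vapply(xs, function(x) {
    v <- lbg[x]; sum(v[!is.na(v)])
  }, numeric(1))
  m <- vapply(xs, length, integer(1)) - width + 1L
  # group sequences by length for vectorized E/M-steps; ambiguous (non-ACGT)
  # bases are coded 5 and contribute background-neutral scores
  xs5 <- lapply(xs, function(x) { x[is.na(x)] <- 5L; x })
  groups <- split(seq_len(ns), vapply(xs5, length, integer(1)))
  Xmats <- lapply(groups, function(idx) {
    matrix(unlist(xs5[idx]), nrow = length(idx), byrow = TRUE)
  })

  run_em <- function(probs0) {
    probs <- probs0
    gamma <- 0.5
    trace <- numeric(0)
    prev <- -Inf
    offsets <- rep(NA_integer_, ns)
    for (iter in seq_len(max_iter)) {
      lodds <- rbind(log(probs) - lbg, 0)   # row 5: ambiguous base, neutral
      counts <- matrix(0.25, nrow = 4L, ncol = width)
      occ_total <- 0
      ll <- 0
      for (gidx in seq_along(groups)) {
        idx <- groups[[gidx]]
        X <- Xmats[[gidx]]
        mg <- ncol(X) - width + 1L
        S <- matrix(0, nrow = nrow(X), ncol = mg)
        for (o in seq_len(mg)) {
          for (j in seq_len(width)) {
            S[, o] <- S[, o] + lodds[cbind(X[, o + j - 1L], j)]
          }
        }
        lo <- log(gamma) - log(mg) + S     # log joint, occurrence per offset
        la <- log1p(-gamma)                # log joint, absence
        row_max <- pmax(la, apply(lo, 1L, max))
        lse <- row_max + log(exp(la - row_max) + rowSums(exp(lo - row_max)))
        ll <- ll + sum(B[idx] + lse)
        post <- exp(lo - lse)
        p0 <- exp(la - lse)
        occ_total <- occ_total + sum(1 - p0)
        for (o in seq_len(mg)) {
          w_o <- post[, o]
          for (j in seq_len(width)) {
            b <- X[, o + j - 1L]
            for (bb in 1:4) {
              sel <- b == bb
              if (any(sel)) counts[bb, j] <- counts[bb, j] + sum(w_o[sel])
            }
          }
        }
        best_o <- max.col(lo, ties.method = "first")
        absent <- la >= lo[cbind(seq_len(nrow(lo)), best_o)]
        offsets[idx] <- ifelse(absent, NA_integer_, best_o)
      }
      # the Dirichlet(0.25) smoothing makes this MAP-EM: the monotone
      # objective is the penalized log-likelihood (log posterior)
      obj <- ll + 0.25 * sum(log(probs))
      if (obj < prev - 1e-8 * (1 + abs(prev))) {
        stop("internal error: EM objective decreased")
      }
      trace <- c(trace, obj)
      probs <- sweep(counts, 2L, colSums(counts), "/")
      gamma <- min(max(occ_total / ns, 1e-6), 1 - 1e-6)
      if (is.finite(prev) && (obj - prev) < tol) { prev <- obj; break }
      prev <- obj
    }
    list(probs = probs, gamma = gamma, loglik = prev, trace = trace,
         offsets = offsets, n_sites = occ_total)
  }

  # shift a PWM by delta columns, padding with background
  shift_probs <- function(probs, delta) {
    out <- matrix(bg, nrow = 4L, ncol = width)
    src <- seq_len(width) + delta
    ok <- src >= 1L & src <= width
    out[, ok] <- probs[, src[ok]]
    out
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    i <- sample.int(ns, 1L)
    o <- sample.int(m[i], 1L)
    site <- xs[[i]][o:(o + width - 1L)]
    probs0 <- matrix(0.1, nrow = 4L, ncol = width)
    for (j in seq_len(width)) {
      if (is.na(site[j])) probs0[, j] <- 0.25 else probs0[site[j], j] <- 0.7
    }
    fit <- run_em(probs0)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # phase-shift refinement: EM often locks into a register one or two
  # columns off the optimum; restart from shifted matrices while the
  # objective improves
  repeat {
    improved <- FALSE
    for (delta in c(-2L, -1L, 1L, 2L)) {
      cand <- run_em(shift_probs(best$probs, delta))
      if (cand$loglik > best$loglik + 1e-6) {
        best <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  structure(list(
    pwm = pwm(best$probs, background = bg, n_sites = round(best$n_sites)),
    offsets = best$offsets,
    gamma = best$gamma,
    loglik = best$loglik,
    loglik_trace = best$trace
  ), class = "motif_em")
}

#' Extract strand-aware upstream sequence windows
#'
#' Pulls the `width` bases upstream of each anchor (a TSS for promoter
#' analysis, a TLS for RBS analysis), reverse-complemented for minus-strand
#' anchors so all windows read 5' to 3' into the anchor. Windows truncated at
#' the edge of a linear replicon are dropped (with a message).
#'
#' @param anchors data.frame with columns `position` and `strand` (e.g. a
#'   classified TSS table, or TLS positions assembled by the caller).
#' @param width Window width in bp.
#' @param genome `DNAStringSet` of the replicon (see [read_genome_fasta()]).
#' @param annotation The [genome_annotation].
#' @return Character vector of windows; `attr(, "kept")` gives the row
#'   indices of `anchors` that survived truncation filtering.
#' @export
extract_windows <- function(anchors, width, genome, annotation) {
  n <- nrow(anchors)
  out <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    win <- upstream_window(anchors$position[i], anchors$strand[i], width,
                           annotation)
    if (win$truncated || win$width < width) next
    out[i] <- window_sequence(win, genome)
    keep[i] <- TRUE
  }
  if (any(!keep)) {
    message(sum(!keep), " window(s) truncated at the replicon edge and dropped")
  }
  res <- out[keep]
  attr(res, "kept") <- which(keep)
  res
}

#' Scan promoter windows for a -35/-10 two-box architecture
#'
#' For each window (read 5' to 3' ending immediately before the TSS) the scan
#' maximizes the summed log-odds of a -35 site and a -10 site subject to an
#' interspacer within `spacer_range` bp. Windows whose best combined score
#' falls below `score_floor` are reported unmatched.
#'
#' @param windows Character vector of equal-width promoter windows (e.g. 70
#'   bp upstream of pTSS, from [extract_windows()]).
#' @param pwm10,pwm35 [pwm]s of the -10 and -35 boxes.
#' @param spacer_range Allowed bp between the 3' end of the -35 match and
#'   the 5' end of the -10 match.
#' @param score_floor Minimum combined log-odds score of a match.
#' @return List with `calls` (per window: offsets, matched sequences, both
#'   spacers, score, matched flag), `spacer_35_10` and `spacer_10_tss`
#'   (histogram tables over matched windows). `spacer_10_tss` is the bp
#'   between the 3' end of the -10 box and the TSS base.
#' @export
two_box_promoter_scan <- function(windows, pwm10, pwm35,
                                  spacer_range = c(11L, 20L),
                                  score_floor = 0) {
  xs <- seqs_to_int(windows)
  lo10 <- pwm_log_odds(pwm10)
  lo35 <- pwm_log_odds(pwm35)
  w10 <- pwm10$width; w35 <- pwm35$width
  rows <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    W <- length(xs[[i]])
    s10 <- score_pwm_sliding(xs[[i]], lo10)
    s35 <- score_pwm_sliding(xs[[i]], lo35)
    best <- list(score = -Inf)
    for (o35 in seq_along(s35)) {
      lo_o10 <- o35 + w35 + spacer_range[1L]
      hi_o10 <- o35 + w35 + spacer_range[2L]
      if (lo_o10 > length(s10)) next
      cand <- seq.int(lo_o10, min(hi_o10, length(s10)))
      sc <- s35[o35] + s10[cand]
      k <- which.max(sc)
      if (sc[k] > best$score) {
        best <- list(score = sc[k], o35 = o35, o10 = cand[k])
      }
    }
    matched <- is.finite(best$score) && best$score >= score_floor
    rows[[i]] <- data.frame(
      window = i,
      matched = matched,
      minus35_offset = if (matched) best$o35 else NA_integer_,
      minus35_seq = if (matched)
        substr(windows[i], best$o35, best$o35 + w35 - 1L) else NA_character_,
      minus10_offset = if (matched) best$o10 else NA_integer_,
      minus10_seq = if (matched)
        substr(windows[i], best$o10, best$o10 + w10 - 1L) else NA_character_,
      spacer_35_10 = if (matched) best$o10 - (best$o35 + w35) else NA_integer_,
      spacer_10_tss = if (matched) W - (best$o10 + w10 - 1L) else NA_integer_,
      score = if (matched) best$score else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, rows)
  list(calls = calls,
       spacer_35_10 = table(calls$spacer_35_10[calls$matched]),
       spacer_10_tss = table(calls$spacer_10_tss[calls$matched]))
}

#' Ribosome binding site report
#'
#' Scans windows upstream of translation starts for the best RBS site and
#' reports the recovered consensus (rebuilt from the matched sites) and the
#' spacer-to-start-codon histogram. The spacer is the number of bases between
#' the 3' end of the RBS match and the first base of the start codon.
#'
#' @param utr_windows Character windows immediately upstream of TLS (e.g. 20
#'   bp, from [extract_windows()]).
#' @param rbs_pwm [pwm] of the RBS motif.
#' @param score_floor Minimum log-odds score of a match; windows below it are
#'   excluded from the histogram and counted unmatched.
#' @return List with `consensus`, `spacer_hist` (table), `matches`
#'   (data.frame `window`, `offset`, `site`, `spacer`, `score`) and
#'   `n_unmatched`.
#' @export
rbs_report <- function(utr_windows, rbs_pwm, score_floor = 0) {
  xs <- seqs_to_int(utr_windows)
  lo <- pwm_log_odds(rbs_pwm)
  w <- rbs_pwm$width
  rows <- list()
  unmatched <- 0L
  for (i in seq_along(xs)) {
    s <- score_pwm_sliding(xs[[i]], lo)
    if (length(s) == 0L) { unmatched <- unmatched + 1L; next }
    k <- which.max(s)
    if (s[k] < score_floor) { unmatched <- unmatched + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      window = i, offset = k,
      site = substr(utr_windows[i], k, k + w - 1L),
      spacer = length(xs[[i]]) - (k + w - 1L),
      score = s[k], stringsAsFactors = FALSE
    )
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window = integer(0), offset = integer(0), site = character(0),
               spacer = integer(0), score = numeric(0))
  consensus <- NA_character_
  if (nrow(matches) > 0L) {
    counts <- matrix(0.25, nrow = 4L, ncol = w,
                     dimnames = list(.BASES, NULL))
    for (site in matches$site) {
      b <- match(strsplit(toupper(site), "")[[1L]], .BASES)
      ok <- !is.na(b)
      counts[cbind(b[ok], seq_len(w)[ok])] <-
        counts[cbind(b[ok], seq_len(w)[ok])] + 1
    }
    site_pwm <- pwm(sweep(counts, 2L, colSums(counts), "/"),
                    n_sites = nrow(matches))
    consensus <- pwm_consensus(site_pwm)
  }
  list(consensus = consensus,
       spacer_hist = table(matches$spacer),
       matches = matches,
       n_unmatched = unmatched)
}

#' Discover the -10 and -35 promoter boxes in pTSS windows
#'
#' Two-stage discovery mirroring the reported two-box architecture without a
#' joint model: the -10 box is discovered first on the 3'-most `tail_region`
#' nt of each window (where it must lie given the 6-9 nt spacer to the TSS);
#' the matched region is then masked by truncation and the -35 box is
#' discovered on the upstream remainder.
#'
#' @param windows Equal-width promoter windows (70 bp recommended).
#' @param width Motif width for both boxes.
#' @param tail_region 3' window region searched for the -10 box, nt.
#' @param seed Seed for the EM restarts.
#' @param ... Passed to [find_motif_em()].
#' @return List with `pwm10`, `pwm35`, the two `motif_em` fits, and the
#'   window coordinates of the -10 offsets.
#' @export
discover_promoter_motifs <- function(windows, width = 6L, tail_region = 25L,
                                     seed = 1L, ...) {
  W <- unique(nchar(windows))
  if (length(W) != 1L) stop("promoter windows must share one width")
  if (tail_region > W) stop("tail_region exceeds the window width")
  tail_start <- W - tail_region + 1L
  tails <- substr(windows, tail_start, W)
  fit10 <- find_motif_em(tails, width = width, seed = seed, ...)
  # offset of the -10 box in full-window coordinates (NA where absent)
  off10 <- ifelse(is.na(fit10$offsets), NA_integer_,
                  tail_start - 1L + fit10$offsets)
  # -35 search space: everything strictly upstream of the matched -10 box
  prefix_end <- ifelse(is.na(off10), tail_start - 1L, off10 - 1L)
  prefixes <- substr(windows, 1L, prefix_end)
  usable <- nchar(prefixes) >= width
  fit35 <- find_motif_em(prefixes[usable], width = width, seed = seed + 1L, ...)
  list(pwm10 = fit10$pwm, pwm35 = fit35$pwm,
       em10 = fit10, em35 = fit35, minus10_offsets = off10)
}

#' Export PWMs in MEME minimal text format
#'
#' @param pwms Named list of [pwm] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1L]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       p$width, max(1L, round(p$n_sites))), con)
    for (j in seq_len(p$width)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         p$probs["A", j], p$probs["C", j],
                         p$probs["G", j], p$probs["T", j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
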