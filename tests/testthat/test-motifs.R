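test_that("pwm objects validate and summarize correctly", {
  uni <- matrix(0.25, 4, 6)
  p <- pwm(uni)
  expect_equal(p$width, 6L)
  expect_equal(pwm_information_content(p), rep(0, 6))
  one_hot <- consensus_pwm("TATAAT", p = 1 - 3e-12)
  expect_equal(pwm_consensus(one_hot), "TATAAT")
  expect_equal(pwm_information_content(one_hot), rep(2, 6), tolerance = 1e-9)
  expect_error(pwm(matrix(0.3, 4, 6)), "sum to 1")
  ic <- pwm_information_content(consensus_pwm("ACGTAC", 0.6))
  expect_true(all(ic >= 0 & ic <= 2))
})

test_that("EM recovers an exactly planted motif and its offsets", {
  pl <- planted_motif_windows(200, width = 40, motif = "TATAAT", seed = 42)
  fit <- find_motif_em(pl$seqs, width = 6, seed = 1)
  expect_equal(toupper(pwm_consensus(fit$pwm)), "TATAAT")
  # objective never decreases, at any iteration
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # MAP offsets point at the planted sites for nearly all sequences
  expect_gte(mean(fit$offsets == pl$offsets, na.rm = TRUE), 0.9)
})

test_that("EM on pure noise yields low information content", {
  set.seed(300)
  noise <- vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1))
  fit <- find_motif_em(noise, width = 6, seed = 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # calibrated null level: ZOOPS-EM on 200 x 40 nt uniform noise settles at
  # ~0.35-0.42 bits/column of selection bias, far below planted motifs (>1.5)
  expect_lte(mean(pwm_information_content(fit$pwm)), 0.5)
  planted <- find_motif_em(planted_motif_windows(200, seed = 301)$seqs,
                           width = 6, seed = 2)
  expect_gte(mean(pwm_information_content(planted$pwm)), 1.2)
})

test_that("EM degenerate case: single sequence, width equal to length", {
  fit <- find_motif_em("ACGTT", width = 5, seed = 3)
  idx <- apply(fit$pwm$probs, 2, which.max)
  expect_equal(rownames(fit$pwm$probs)[idx], c("A", "C", "G", "T", "T"))
  # Dirichlet(0.25) smoothing keeps all probabilities strictly positive
  expect_true(all(fit$pwm$probs > 0))
  expect_error(find_motif_em("ACG", width = 6), "width exceeds")
})

test_that("EM is deterministic given its seed", {
  pl <- planted_motif_windows(60, motif = "AAGGAG", seed = 8)
  f1 <- find_motif_em(pl$seqs, width = 6, seed = 9)
  f2 <- find_motif_em(pl$seqs, width = 6, seed = 9)
  expect_identical(f1$pwm$probs, f2$pwm$probs)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("two-box scan recovers planted spacers and rejects out-of-range ones", {
  build_window <- function(spacer, tail_spacer = 7L, width = 70L, seed) {
    set.seed(seed)
    s <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    e10 <- width - tail_spacer
    s[(e10 - 5L):e10] <- strsplit("TATAAT", "")[[1L]]
    e35 <- e10 - 6L - spacer
    s[(e35 - 5L):e35] <- strsplit("CTTGCC", "")[[1L]]
    paste(s, collapse = "")
  }
  # floor between the one-box score (~7.7 for an exact 6-mer at p = 0.91)
  # and the two-box score (~15.5), so only genuine pairs match
  wins <- vapply(1:40, function(i) build_window(17L, seed = i), character(1))
  scan <- two_box_promoter_scan(wins, consensus_pwm("TATAAT"),
                                consensus_pwm("CTTGCC"),
                                spacer_range = c(11L, 20L), score_floor = 11)
  expect_true(all(scan$calls$matched))
  sp <- as.integer(names(which.max(scan$spacer_35_10)))
  expect_equal(sp, 17L)
  expect_gte(mean(scan$calls$spacer_35_10 == 17L), 0.9)
  expect_equal(as.integer(names(which.max(scan$spacer_10_tss))), 7L)

  far <- vapply(41:60, function(i) build_window(25L, seed = i), character(1))
  scan2 <- two_box_promoter_scan(far, consensus_pwm("TATAAT"),
                                 consensus_pwm("CTTGCC"),
                                 spacer_range = c(11L, 20L), score_floor = 11)
  expect_true(mean(scan2$calls$matched) <= 0.2)
})

test_that("RBS spacer is the gap between the match 3' end and the start codon", {
  set.seed(77)
  win <- function(spacer) {
    s <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
    e <- 20L - spacer
    s[(e - 5L):e] <- strsplit("AAGGAG", "")[[1L]]
    paste(s, collapse = "")
  }
  wins <- vapply(rep(8L, 30), win, character(1))
  rep8 <- rbs_report(wins, consensus_pwm("AAGGAG"), score_floor = 5)
  expect_equal(as.integer(names(which.max(rep8$spacer_hist))), 8L)
  expect_true(grepl("^AAGGAG$", toupper(rep8$consensus)))
  expect_equal(rep8$n_unmatched, 0L)

  noise <- vapply(1:10, function(i)
    paste(sample(c("C", "T"), 20, replace = TRUE), collapse = ""), character(1))
  repn <- rbs_report(noise, consensus_pwm("AAGGAG"), score_floor = 5)
  expect_equal(repn$n_unmatched, 10L)
})

test_that("planted promoter windows drive full motif discovery", {
  cfg <- simulation_config(seed = 61, n_genes = 60, motif_mismatch_rate = 0.1)
  sim <- simulate_genome(cfg)
  wins <- extract_windows(sim$truth$tss, 70L, sim$genome, sim$annotation)
  disc <- discover_promoter_motifs(wins, seed = 4)
  d10 <- utils::adist(toupper(pwm_consensus(disc$pwm10)), "TATAAT")
  expect_lte(as.integer(d10), 1L)
  expect_true(all(diff(disc$em10$loglik_trace) >= -1e-8))
  expect_true(all(diff(disc$em35$loglik_trace) >= -1e-8))
})

test_that("RBS mode of 8 nt is recovered from simulated TLS windows", {
  cfg <- simulation_config(seed = 71, n_genes = 150, motif_mismatch_rate = 0.05)
  sim <- simulate_genome(cfg)
  anchors <- data.frame(position = tls_positions(sim$annotation),
                        strand = sim$annotation$genes$strand)
  wins <- extract_windows(anchors, 20L, sim$genome, sim$annotation)
  fit <- find_motif_em(wins, width = 6, seed = 5)
  rep <- rbs_report(wins, fit$pwm)
  expect_equal(as.integer(names(which.max(rep$spacer_hist))), 8L)
  expect_lte(as.integer(utils::adist(toupper(rep$consensus), "AAGGAG")), 1L)
})

test_that("MEME export writes a parseable minimal motif file", {
  p <- consensus_pwm("TATAAT")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(minus10 = p), path)
  lines <- readLines(path)
  expect_true(any(grepl("^MOTIF minus10$", lines)))
  expect_true(any(grepl("letter-probability matrix", lines)))
  mat <- read.table(text = lines[grep("^ ", lines)])
  expect_equal(rowSums(mat), rep(1, 6), tolerance = 1e-5,
               ignore_attr = TRUE)
})
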