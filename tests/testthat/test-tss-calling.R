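test_that("RRS is depth normalization in reads per million", {
  p <- make_profile(100L, fwd = c(`10` = 5L), total_mapped = 1e6)
  rrs <- compute_rrs(p)
  expect_equal(rrs$fwd[10L], 5)
  expect_equal(sum(rrs$rev), 0)

  # scale invariance: doubling counts and depth leaves RRS unchanged
  p2 <- make_profile(100L, fwd = c(`10` = 10L), total_mapped = 2e6)
  expect_equal(compute_rrs(p2)$fwd, rrs$fwd)
})

test_that("enrichment score is zero at parity and antisymmetric", {
  expect_equal(enrichment_score(7, 7), 0)
  expect_equal(enrichment_score(10, 10 / 5.66, pseudocount = 1e-9), 2.5,
               tolerance = 1e-3)
  set.seed(17)
  a <- runif(200, 0, 50); b <- runif(200, 0, 50)
  expect_equal(enrichment_score(a, b), -enrichment_score(b, a))
  expect_error(enrichment_score(1, 1, pseudocount = 0), "pseudocount")
})

test_that("single peaks are called once and flat contrasts yield nothing", {
  enr <- make_profile(1000L, fwd = c(`500` = 200L), total_mapped = 1e6)
  ctl <- make_profile(1000L, total_mapped = 1e6)
  calls <- call_tss(enr, ctl)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 500L)
  expect_equal(calls$strand, "+")

  same <- call_tss(enr, enr)
  expect_equal(nrow(same), 0L)

  short <- make_profile(500L, total_mapped = 1e6)
  expect_error(call_tss(enr, short), "mismatched replicon")
})

test_that("nearby candidates merge to the strongest, ties to the smaller coordinate", {
  enr <- make_profile(1000L, fwd = c(`500` = 120L, `502` = 200L),
                      total_mapped = 1e6)
  ctl <- make_profile(1000L, total_mapped = 1e6)
  calls <- call_tss(enr, ctl, cluster_window = 5L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 502L)
  expect_equal(calls$cluster_size, 2L)
  expect_equal(calls$cluster_members[[1L]], c(500L, 502L))

  tie <- make_profile(1000L, fwd = c(`500` = 200L, `502` = 200L),
                      total_mapped = 1e6)
  expect_equal(call_tss(tie, ctl)$position, 500L)
})

test_that("linear threshold space cuts at log2 of the factor", {
  enr <- make_profile(100L, fwd = c(`50` = 40L), total_mapped = 1e6)
  ctl <- make_profile(100L, fwd = c(`50` = 10L), total_mapped = 1e6)
  # score = log2(40.5/10.5) ~ 1.95: fails the 2.5 log2 cut,
  # passes a linear factor cut of 2.5 (log2(2.5) ~ 1.32)
  expect_equal(nrow(call_tss(enr, ctl, threshold = 2.5)), 0L)
  expect_equal(nrow(call_tss(enr, ctl, threshold = 2.5,
                             threshold_space = "linear")), 1L)
})

test_that("caller equals the exhaustive per-base oracle on a small replicon", {
  cfg <- simulation_config(seed = 19, n_genes = 8, gene_length_range = c(200, 400),
                           operon_gap_range = c(300, 400))
  sim <- simulate_genome(cfg)
  expect_lte(sim$annotation$length, 10000L)
  rs <- simulate_readstarts(sim$truth, cfg)
  fast <- call_tss(rs$enriched, rs$control)
  slow <- oracle_call_tss(rs$enriched, rs$control)
  expect_equal(fast$position, slow$position)
  expect_equal(fast$strand, slow$strand)
  expect_equal(fast$rrs, slow$rrs)
  expect_equal(fast$enrichment_score, slow$enrichment_score)
  expect_equal(fast$cluster_size, slow$cluster_size)
})

test_that("raising the threshold never admits new candidate bases", {
  cfg <- simulation_config(seed = 23, n_genes = 20, tss_signal_mean = 20,
                           background_rate = 0.2)
  sim <- simulate_genome(cfg)
  rs <- simulate_readstarts(sim$truth, cfg)
  # the candidate set shrinks monotonically; clustered call counts can
  # transiently rise when a removed candidate splits a cluster in two
  candidates <- vapply(seq(0, 9), function(th) {
    calls <- call_tss(rs$enriched, rs$control, threshold = th, min_rrs = 0)
    sum(calls$cluster_size)
  }, integer(1))
  expect_true(all(diff(candidates) <= 0))
})

test_that("condition comparison matches greedily within tolerance", {
  a <- data.frame(position = c(100L, 200L, 300L), strand = c("+", "+", "-"))
  b <- a
  cmp <- compare_conditions(a, b)
  expect_equal(nrow(cmp$shared), 3L)
  expect_equal(nrow(cmp$exclusive_a), 0L)

  b2 <- data.frame(position = c(100L, 200L, 300L), strand = c("-", "-", "+"))
  cmp2 <- compare_conditions(a, b2)
  expect_equal(nrow(cmp2$shared), 0L)
  expect_equal(nrow(cmp2$exclusive_a), 3L)
  expect_equal(nrow(cmp2$exclusive_b), 3L)

  # each TSS matches at most once: two near b-sites compete for one a-site
  a3 <- data.frame(position = 100L, strand = "+")
  b3 <- data.frame(position = c(99L, 101L), strand = c("+", "+"))
  cmp3 <- compare_conditions(a3, b3)
  expect_equal(nrow(cmp3$shared), 1L)
  expect_equal(cmp3$shared$position_b, 99L)
  expect_equal(nrow(cmp3$exclusive_b), 1L)
  expect_equal(nrow(cmp3$shared) + nrow(cmp3$exclusive_a), nrow(a3))
})

test_that("condition-specific planted TSS surface as exclusive sets", {
  cfg <- simulation_config(seed = 29, n_genes = 60)
  sim <- simulate_genome(cfg)
  prof <- lapply(c(anoxic = "anoxic", oxic = "oxic"), function(cc)
    simulate_readstarts(sim$truth, cfg, condition = cc))
  calls <- lapply(prof, function(p) call_tss(p$enriched, p$control))
  cmp <- compare_conditions(calls$anoxic, calls$oxic)
  tt <- sim$truth$tss
  expect_setequal(cmp$exclusive_a$position,
                  tt$position[tt$condition == "anoxic"])
  expect_setequal(cmp$exclusive_b$position,
                  tt$position[tt$condition == "oxic"])
  expect_equal(nrow(cmp$shared), sum(tt$condition == "both"))
})
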