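chain_annotation <- function(strands = c("+", "+", "+")) {
  n <- length(strands)
  make_annotation(data.frame(
    gene_id = LETTERS[seq_len(n)],
    start = seq(1000L, by = 2000L, length.out = n),
    stop = seq(2500L, by = 2000L, length.out = n),
    strand = strands
  ), length = 2000L * n + 2000L, circular = FALSE)
}

junc <- function(pairs) {
  data.frame(upstream_gene = vapply(pairs, `[[`, character(1), 1L),
             downstream_gene = vapply(pairs, `[[`, character(1), 2L),
             strand = rep("+", length(pairs)),
             spanning_reads = vapply(pairs, function(p) as.integer(p[[3L]]),
                                     integer(1)))
}

test_that("joining follows the spanning-read threshold transitively", {
  ann <- chain_annotation()
  ops <- assemble_primary_operons(ann, junc(list(c("A", "B", 5), c("B", "C", 2))))
  expect_equal(lapply(ops$genes, identity), list(c("A", "B"), "C"),
               ignore_attr = TRUE)
  expect_equal(ops$monocistronic, c(FALSE, TRUE))

  # the threshold is >= 3: exactly 3 spanning reads joins
  ops3 <- assemble_primary_operons(ann, junc(list(c("A", "B", 3), c("B", "C", 3))))
  expect_equal(nrow(ops3), 1L)
  expect_equal(ops3$genes[[1L]], c("A", "B", "C"))
  expect_equal(ops3$n_genes, 3L)

  ops2 <- assemble_primary_operons(ann, junc(list(c("A", "B", 2), c("B", "C", 2))))
  expect_true(all(ops2$monocistronic))
})

test_that("strand breaks end the walk regardless of junction counts", {
  ann <- chain_annotation(c("+", "-", "+"))
  ops <- assemble_primary_operons(ann, junc(list(c("A", "B", 50), c("B", "C", 50))))
  expect_equal(nrow(ops), 3L)
  expect_true(all(ops$monocistronic))
})

test_that("minus-strand operons list genes in transcription order", {
  ann <- chain_annotation(c("-", "-"))
  ops <- assemble_primary_operons(ann, junc(list(c("B", "A", 10))))
  expect_equal(ops$genes[[1L]], c("B", "A"))
  expect_equal(ops$first_gene, "B")
})

test_that("assembly partitions the gene set and is monotone in the threshold", {
  cfg <- simulation_config(seed = 47, n_genes = 50)
  sim <- simulate_genome(cfg)
  jn <- simulate_junctions(sim$truth, cfg)
  sizes <- integer(0)
  for (th in c(1L, 3L, 10L, 30L, 100L)) {
    ops <- assemble_primary_operons(sim$annotation, jn, min_spanning = th)
    expect_equal(sum(ops$n_genes), 50L)
    expect_equal(anyDuplicated(unlist(ops$genes)), 0L)
    sizes <- c(sizes, nrow(ops))
  }
  expect_true(all(diff(sizes) >= 0))  # raising the threshold never merges more
})

test_that("assembly equals a union-find oracle on random fixtures", {
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(10:40, 1L)
    ann <- make_annotation(data.frame(
      gene_id = sprintf("g%02d", seq_len(n)),
      start = seq(1000L, by = 1500L, length.out = n),
      stop = seq(2200L, by = 1500L, length.out = n),
      strand = sample(c("+", "-"), n, replace = TRUE, prob = c(0.6, 0.4))
    ), length = 1500L * n + 2000L, circular = FALSE)
    g <- ann$genes
    jn <- data.frame(
      upstream_gene = g$gene_id[-n], downstream_gene = g$gene_id[-1L],
      strand = g$strand[-n],
      spanning_reads = sample(0:6, n - 1L, replace = TRUE))
    fast <- assemble_primary_operons(ann, jn)
    slow <- oracle_assemble_operons(ann, jn)
    sig <- sort(vapply(fast$genes, paste, character(1), collapse = "|"))
    sig_o <- sort(vapply(slow, paste, character(1), collapse = "|"))
    expect_equal(sig, sig_o)
  }
})

test_that("sub-operons are suffixes anchored at internal TSS", {
  ann <- chain_annotation(c("+", "+", "+", "+"))
  ops <- assemble_primary_operons(
    ann, junc(list(c("A", "B", 9), c("B", "C", 9), c("C", "D", 9))))
  expect_equal(nrow(ops), 1L)

  # internal pTSS in the intergenic gap ahead of gene C -> suffix [C, D]
  tss <- data.frame(position = 4900L, strand = "+", tss_class = "pTSS",
                    condition = "anoxic")
  sub <- assign_suboperons(ops, tss, ann)
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$genes[[1L]], c("C", "D"))
  expect_equal(sub$first_gene, "C")
  expect_equal(sub$condition, "anoxic")

  # iTSS inside gene B starts the suffix at B's successor
  itss <- data.frame(position = 3500L, strand = "+", tss_class = "iTSS",
                     condition = "x")
  sub2 <- assign_suboperons(ops, itss, ann)
  expect_equal(sub2$genes[[1L]], c("C", "D"))

  # the operon's own primary TSS never spawns a sub-operon
  prim <- data.frame(position = 950L, strand = "+", tss_class = "pTSS",
                     condition = "x")
  expect_equal(nrow(assign_suboperons(ops, prim, ann)), 0L)

  # an iTSS in the last gene has no downstream suffix
  last <- data.frame(position = 7500L, strand = "+", tss_class = "iTSS",
                     condition = "x")
  expect_equal(nrow(assign_suboperons(ops, last, ann)), 0L)

  # monocistronic operons never spawn sub-operons
  mono <- assemble_primary_operons(chain_annotation("+"), junc(list()))
  expect_equal(nrow(assign_suboperons(mono, tss, chain_annotation("+"))), 0L)
})

test_that("condition-specific planted anchors yield per-condition sub-operons", {
  cfg <- simulation_config(seed = 59, n_genes = 80, suboperon_fraction = 0.8)
  sim <- simulate_genome(cfg)
  jn <- simulate_junctions(sim$truth, cfg)
  ops <- assemble_primary_operons(sim$annotation, jn)
  for (cond in c("anoxic", "oxic")) {
    rs <- simulate_readstarts(sim$truth, cfg, condition = cond)
    cl <- classify_tss(call_tss(rs$enriched, rs$control), sim$annotation)
    sub <- assign_suboperons(ops, cl, sim$annotation, condition = cond)
    ts <- sim$truth$suboperons
    ts <- ts[ts$condition %in% c("both", cond), ]
    expect_setequal(paste(sub$first_gene, sub$n_genes),
                    paste(ts$first_gene, ts$n_genes))
  }
})

test_that("size distributions separate monocistrons and report shares", {
  ann <- chain_annotation(rep("+", 10L))
  jn <- junc(lapply(1:9, function(i)
    c(LETTERS[i], LETTERS[i + 1L], if (i %% 2 == 0) 0 else 9)))
  ops <- assemble_primary_operons(ann, jn)
  dist <- operon_size_distribution(ops)
  expect_equal(dist$polycistronic$size, 2L)
  expect_equal(dist$polycistronic$count, 5L)
  expect_equal(sum(dist$polycistronic$share_pct), 100)
  expect_equal(dist$monocistronic, 0L)
})
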