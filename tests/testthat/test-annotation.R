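test_that("GFF3 reading preserves coordinates and strands", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 1000",
    "chr\tsim\tgene\t101\t400\t.\t+\t.\tID=geneA;product=alpha",
    "chr\tsim\tgene\t501\t900\t.\t-\t.\tID=geneB;product=beta"
  ), path)
  ann <- read_gff3(path)
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(ann$genes$gene_id, c("geneA", "geneB"))
  expect_equal(ann$genes$start, c(101L, 501L))
  expect_equal(ann$genes$stop, c(400L, 900L))
  expect_equal(ann$genes$strand, c("+", "-"))
  expect_equal(ann$length, 1000L)
})

test_that("malformed GFF3 fails with the offending line; empty files error", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsim\tgene\t400\t101\t.\t+\t.\tID=geneA"
  ), bad)
  expect_error(read_gff3(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_error(read_gff3(empty), "empty annotation")

  expect_error(
    genome_annotation("chr", 1000, data.frame(
      gene_id = "x", start = 10, stop = 5, strand = "+")),
    "stop < start")
})

test_that("simulated annotation round-trips through GFF3", {
  sim <- simulate_genome(simulation_config(seed = 11, n_genes = 20))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$annotation, path)
  back <- read_gff3(path, circular = sim$annotation$circular)
  expect_equal(back$genes$gene_id, sim$annotation$genes$gene_id)
  expect_equal(back$genes$start, sim$annotation$genes$start)
  expect_equal(back$genes$stop, sim$annotation$genes$stop)
  expect_equal(back$genes$strand, sim$annotation$genes$strand)
  expect_equal(back$length, sim$annotation$length)
})

test_that("bedGraph positions convert 0-based half-open to 1-based", {
  fwd <- withr::local_tempfile(fileext = ".bedgraph")
  rev <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr\t9\t10\t42", fwd)
  file.create(rev)
  prof <- read_bedgraph_pair(fwd, rev, library_size = 1e6, length = 100L)
  expect_equal(prof$counts_fwd[10L], 42L)
  expect_equal(sum(prof$counts_fwd), 42L)
  expect_equal(prof$counts_rev, integer(100))
})

test_that("bedGraph errors on conflicts and out-of-range intervals", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  r <- withr::local_tempfile(fileext = ".bedgraph")
  file.create(r)
  writeLines(c("chr\t5\t8\t3", "chr\t6\t7\t9"), f)
  expect_error(read_bedgraph_pair(f, r, 1e6, 100L), "conflicting")
  writeLines("chr\t95\t105\t2", f)
  expect_error(read_bedgraph_pair(f, r, 1e6, 100L), "beyond replicon")
})

test_that("read-start profiles round-trip through bedGraph pairs", {
  sim <- simulate_genome(simulation_config(seed = 3, n_genes = 10))
  rs <- simulate_readstarts(sim$truth, simulation_config(seed = 3, n_genes = 10))
  dir <- withr::local_tempdir()
  fwd <- file.path(dir, "f.bedgraph"); rev <- file.path(dir, "r.bedgraph")
  write_bedgraph_pair(rs$enriched, "simchr", fwd, rev)
  back <- read_bedgraph_pair(fwd, rev, rs$enriched$total_mapped,
                             sim$annotation$length)
  expect_identical(back$counts_fwd, rs$enriched$counts_fwd)
  expect_identical(back$counts_rev, rs$enriched$counts_rev)
})

test_that("profile validation enforces the count invariants", {
  expect_error(read_start_profile("x", "c", c(1L, 2L), c(1L), 10),
               "equal length")
  expect_error(read_start_profile("x", "c", c(-1L, 0L), c(0L, 0L), 10),
               "non-negative")
  expect_error(read_start_profile("x", "c", c(5L, 0L), c(0L, 0L), 3),
               "total_mapped")
})

test_that("upstream windows follow strand, wrap when circular, truncate when not", {
  circ <- two_gene_annotation(circular = TRUE)
  lin <- two_gene_annotation(circular = FALSE)

  w <- upstream_window(1000L, "+", 70L, circ)
  expect_equal(w$segments, data.frame(start = 930L, end = 999L))
  expect_false(w$truncated)

  w <- upstream_window(5L, "+", 10L, circ)
  expect_equal(w$width, 10L)
  expect_true(w$wrapped)
  expect_equal(w$segments$start, c(995L, 1L))
  expect_equal(w$segments$end, c(1000L, 4L))

  w <- upstream_window(5L, "+", 10L, lin)
  expect_true(w$truncated)
  expect_equal(w$segments, data.frame(start = 1L, end = 4L))
  expect_equal(w$width, 4L)

  w <- upstream_window(998L, "-", 10L, lin)
  expect_true(w$truncated)
  expect_equal(w$segments, data.frame(start = 999L, end = 1000L))

  expect_error(upstream_window(0L, "+", 10L, circ), "outside replicon")
  expect_error(upstream_window(1001L, "+", 10L, circ), "outside")
})

test_that("circular windows always have the requested width", {
  ann <- two_gene_annotation(circular = TRUE)
  set.seed(99)
  for (i in 1:50) {
    a <- sample.int(1000L, 1L)
    s <- sample(c("+", "-"), 1L)
    w <- sample.int(200L, 1L)
    expect_equal(upstream_window(a, s, w, ann)$width, w)
  }
})

test_that("window sequences are strand-aware", {
  genome <- Biostrings::DNAStringSet("ACGTACGTAC")
  names(genome) <- "chr"
  ann <- make_annotation(data.frame(gene_id = "g", start = 2L, stop = 9L,
                                    strand = "+"),
                         length = 10L, circular = FALSE)
  wp <- upstream_window(5L, "+", 4L, ann)
  expect_equal(window_sequence(wp, genome), "ACGT")
  wm <- upstream_window(5L, "-", 4L, ann)
  # bases 6..9 are CGTA; read 5'->3' on the minus strand
  expect_equal(window_sequence(wm, genome), "TACG")
})
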