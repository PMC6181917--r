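test_that("read_gtf converts 1-based inclusive coordinates to 0-based half-open", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "x", "exon", 1, 100, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "x", "exon", 201, 300, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "x", "exon", 1, 300, ".", "+", ".",
          'gene_id "g1"; transcript_id "t2";', sep = "\t")
  ), gtf)
  m <- read_gtf(gtf)
  t1 <- dplyr::filter(m, transcript_id == "t1")
  expect_equal(t1$start, c(0L, 200L))
  expect_equal(t1$end, c(100L, 300L))
  expect_equal(dplyr::n_distinct(m$transcript_id), 2L)
})

test_that("read_gtf rejects malformed lines with a line number", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "x", "exon", 1, 100, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("chr1", "x", "exon", 500, 400, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t")
  ), gtf)
  expect_error(read_gtf(gtf), "line 2")
})

test_that("read_gtf validates features against chromosome bounds", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "x", "exon", 1, 100, ".", "+", ".",
                   'gene_id "g"; transcript_id "t";', sep = "\t"), gtf)
  genome <- make_genome(strrep("A", 50))
  expect_error(read_gtf(gtf, genome = genome), "bounds")
})

test_that("extract_introns returns the gaps between consecutive exons", {
  m <- make_models(t1 = ex(0, 100, 200, 300, 400, 500))
  intr <- extract_introns(m)
  expect_equal(intr$start, c(100L, 300L))
  expect_equal(intr$end, c(200L, 400L))
  expect_equal(intr$length, c(100L, 100L))
  # single exon -> no introns
  expect_equal(nrow(extract_introns(make_models(t1 = ex(0, 100)))), 0L)
  # abutting exons -> degenerate zero-length intron
  expect_error(extract_introns(make_models(t1 = ex(0, 100, 100, 200))),
               "zero-length")
})

test_that("exons and introns tile the transcript span on simulated genes", {
  sim <- simulate_annotation(simulation_config(n_genes = 10, seed = 42))
  exons <- dplyr::filter(sim$models, feature == "exon")
  intr <- extract_introns(sim$models)
  for (tx in unique(exons$transcript_id)) {
    e <- dplyr::filter(exons, transcript_id == tx)
    i <- dplyr::filter(intr, transcript_id == tx)
    expect_equal(nrow(i), nrow(e) - 1L)
    covered <- sum(e$end - e$start) + sum(i$end - i$start)
    expect_equal(covered, max(e$end) - min(e$start))
  }
})

test_that("intron status follows the containment-restricted universality rule", {
  # single isoform: its introns are constitutive
  one <- classify_intron_status(make_models(t1 = ex(0, 100, 200, 300)))
  expect_equal(one$status, "constitutive")

  # skipped-exon gene: all three intron spans are alternative
  se <- classify_intron_status(make_models(
    t1 = ex(0, 100, 200, 300, 400, 500), t2 = ex(0, 100, 400, 500)))
  expect_equal(sort(se$start), c(100L, 100L, 300L))
  expect_true(all(se$status == "alternative"))

  # isoforms differing only beyond the last intron keep shared introns
  # constitutive (hand enumeration of the containment rule)
  tr <- classify_intron_status(make_models(
    t1 = ex(0, 100, 200, 300), t2 = ex(0, 100, 200, 350)))
  expect_equal(tr$status, "constitutive")
})

test_that("longest isoform maximises exonic length with deterministic ties", {
  m <- make_models(tA = ex(0, 500, 600, 1000), tB = ex(0, 300))
  expect_equal(longest_isoform(m)$transcript_id, "tA")
  # tie on exonic length: smaller start coordinate wins
  tie <- make_models(tA = ex(50, 550), tB = ex(0, 500))
  expect_equal(longest_isoform(tie)$transcript_id, "tB")
  single <- make_models(only = ex(0, 100))
  expect_equal(longest_isoform(single)$transcript_id, "only")
})

test_that("region partition is strand-aware and tiles the gene span", {
  plus <- make_models(t1 = ex(0, 1000))
  plus_cds <- tibble::tibble(chrom = "chr1", start = 150L, end = 450L,
                             strand = "+", feature = "CDS", gene_id = "g1",
                             transcript_id = "t1", novelty = "known")
  p <- partition_regions(dplyr::bind_rows(plus, plus_cds))
  expect_equal(p$region[p$start == 0], "5UTR")
  expect_equal(p[p$region == "CDS", c("start", "end")],
               tibble::tibble(start = 150L, end = 450L))
  expect_equal(p$region[p$start == 450], "3UTR")
  expect_equal(sum(p$end - p$start), 1000L)

  minus <- dplyr::mutate(dplyr::bind_rows(plus, plus_cds), strand = "-")
  pm <- partition_regions(minus)
  expect_equal(pm$region[pm$start == 0], "3UTR")
  expect_equal(pm$region[pm$start == 450], "5UTR")

  # no CDS -> no partition rows
  expect_equal(nrow(partition_regions(plus)), 0L)
})

test_that("GTF write/read round trip preserves models", {
  sim <- simulate_annotation(simulation_config(n_genes = 8, seed = 5))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$models, path)
  back <- read_gtf(path)
  cols <- c("chrom", "start", "end", "strand", "feature", "gene_id",
            "transcript_id", "novelty")
  ord <- function(d) dplyr::arrange(d[, cols], chrom, gene_id,
                                    transcript_id, feature, start)
  expect_equal(ord(back), ord(sim$models))
})
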