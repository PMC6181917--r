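test_that("psi and as_score implement the defining ratios", {
  expect_equal(psi(6, 2), 0.75)
  expect_equal(psi(0, 5), 0)
  expect_equal(psi(7, 0), 1)
  expect_true(is.na(psi(0, 0)))
  expect_error(psi(-1, 2), "negative")

  expect_equal(as_score(c(0, 0.5, 1)), c(-1, 0, 1))
  expect_error(as_score(1.2), "outside")
  # monotone in psi, endpoints at +/- 1 for any positive count
  for (c0 in c(1, 7, 100)) {
    expect_equal(as_score(psi(c0, 0)), 1)
    expect_equal(as_score(psi(0, c0)), -1)
  }
  p <- seq(0, 1, by = 0.1)
  expect_true(all(diff(as_score(p)) > 0))
})

test_that("fpkm follows the closed form and scales with library size", {
  expect_equal(fpkm(100, 1000, 1e6), 100)
  expect_equal(fpkm(0, 500, 1e6), 0)
  expect_equal(fpkm(100, 1000, 2e6), fpkm(100, 1000, 1e6) / 2)
  expect_error(fpkm(1, 0, 1e6), "positive")
})

test_that("event support sums junction reads by role", {
  se <- tibble::tibble(
    event_id = "SE|chr1|+|100|200|300|400", event_type = "SE",
    gene_id = "g1", chrom = "chr1", strand = "+",
    defining_start = 200L, defining_end = 300L, anchors = "",
    inclusion_junctions = "100-200;300-400", exclusion_junctions = "100-400")
  j <- dplyr::bind_rows(jrow(100, 200, 4), jrow(300, 400, 2),
                        jrow(100, 400, 3))
  q <- count_event_support(se, j)
  expect_equal(q$counts_EII, 6L)
  expect_equal(q$counts_EEI, 3L)
  expect_equal(q$psi, 6 / 9)

  # no overlapping junctions: zero counts, undefined PSI
  far <- dplyr::mutate(se, event_id = "x",
                       inclusion_junctions = "900-950;960-990",
                       exclusion_junctions = "900-990")
  q2 <- count_event_support(far, j)
  expect_equal(c(q2$counts_EII, q2$counts_EEI), c(0L, 0L))
  expect_true(is.na(q2$psi))
})

test_that("MXE support follows the genomic exon order", {
  mxe <- tibble::tibble(
    event_id = "MXE|chr1|+|100|150|180|250|300|400", event_type = "MXE",
    gene_id = "g1", chrom = "chr1", strand = "+",
    defining_start = 150L, defining_end = 300L, anchors = "",
    inclusion_junctions = "100-150;180-400",
    exclusion_junctions = "100-250;300-400")
  j <- dplyr::bind_rows(jrow(100, 150, 5), jrow(180, 400, 5),
                        jrow(100, 250, 2), jrow(300, 400, 2))
  q <- count_event_support(mxe, j)
  expect_equal(q$counts_EII, 10L)
  expect_equal(q$counts_EEI, 4L)
})

test_that("RI inclusion evidence comes from retention counts", {
  ri <- tibble::tibble(
    event_id = "RI|chr1|+|0|100|200|300", event_type = "RI",
    gene_id = "g1", chrom = "chr1", strand = "+",
    defining_start = 100L, defining_end = 200L, anchors = "",
    inclusion_junctions = "", exclusion_junctions = "100-200")
  j <- jrow(100, 200, 8)
  ret <- tibble::tibble(sample_id = "s1", chrom = "chr1", strand = "+",
                        start = 100L, end = 200L, count = 24L)
  q <- count_event_support(ri, j, retention = ret)
  expect_equal(q$counts_EII, 24L)
  expect_equal(q$counts_EEI, 8L)
  expect_equal(q$psi, 0.75)
})

test_that("samples missing from the junction table get zero counts with warning", {
  se <- tibble::tibble(
    event_id = "e", event_type = "SE", gene_id = "g", chrom = "chr1",
    strand = "+", defining_start = 1L, defining_end = 2L, anchors = "",
    inclusion_junctions = "100-200", exclusion_junctions = "100-400")
  sheet <- tibble::tibble(sample_id = c("s1", "s2"))
  expect_warning(q <- count_event_support(se, jrow(100, 200, 3), samples = sheet),
                 "s2")
  expect_equal(q$counts_EII[q$sample_id == "s2"], 0L)
})

test_that("psi is an unbiased binomial estimator of planted PSI", {
  set.seed(31)
  for (n in c(10L, 100L, 1000L)) {
    pi0 <- 0.3
    reps <- 3000L
    I <- rbinom(reps, n, pi0)
    est <- psi(I, n - I)
    se_mean <- sqrt(pi0 * (1 - pi0) / n) / sqrt(reps)
    expect_lt(abs(mean(est) - pi0), 4 * se_mean)
    expect_lt(abs(sd(est) / sqrt(pi0 * (1 - pi0) / n) - 1), 0.1)
  }
})

test_that("transcript filter applies intronic and relative-expression rules", {
  ab <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"), gene_id = "g1",
    fpkm = c(100, 5, 50, 40),
    intronic_read_fraction = c(0.05, 0.05, 0.20, 0.10))
  out <- filter_transcripts(ab)
  expect_true(out$kept[out$transcript_id == "a"])     # major isoform
  expect_equal(out$reason[out$transcript_id == "b"], "relative")  # 5% < 10%
  expect_equal(out$reason[out$transcript_id == "c"], "intronic")  # 20% > 15%
  expect_true(out$kept[out$transcript_id == "d"])
})

test_that("the major isoform of an expressed gene is never lost entirely", {
  # all isoforms fail the intronic rule: the major one is rescued
  ab <- tibble::tibble(transcript_id = c("a", "b"), gene_id = "g1",
                       fpkm = c(10, 8),
                       intronic_read_fraction = c(0.3, 0.4))
  out <- filter_transcripts(ab)
  expect_true(out$rescued[out$transcript_id == "a"])
  expect_true(out$kept[out$transcript_id == "a"])
  expect_false(out$kept[out$transcript_id == "b"])
  # property over random tables
  set.seed(8)
  for (i in 1:20) {
    tab <- tibble::tibble(
      transcript_id = paste0("t", 1:12),
      gene_id = sample(c("g1", "g2", "g3"), 12, replace = TRUE),
      fpkm = runif(12, 0, 50),
      intronic_read_fraction = runif(12))
    res <- filter_transcripts(tab) %>%
      dplyr::group_by(gene_id) %>%
      dplyr::summarise(any_kept = any(kept), expressed = max(fpkm) > 0)
    expect_true(all(res$any_kept[res$expressed]))
  }
})
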