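test_that("au_richness counts A and T/U over non-N bases", {
  expect_equal(au_richness(c("ATAT", "GCGC", "GTAG")), c(1, 0, 0.5))
  expect_equal(au_richness("ANTN"), 1)      # N excluded both sides
  expect_error(au_richness(""), "empty")
  # complement identity with GC fraction for N-free sequence
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  gc <- stringr::str_count(s, "[GC]") / nchar(s)
  expect_equal(au_richness(s) + gc, 1)
})

test_that("border dinucleotides are strand-corrected", {
  # forward: GT...AG intron at (10, 30) inside a padded sequence
  fwd <- paste0(strrep("C", 10), "GT", strrep("A", 16), "AG", strrep("C", 10))
  g <- make_genome(fwd)
  intr <- tibble::tibble(chrom = "chr1", strand = "+", start = 10L, end = 30L)
  out <- border_dinucleotides(intr, g)
  expect_equal(out$border, "GT-AG")

  # minus strand: genomic forward CT...AC reads GT-AG after reverse complement
  rev <- paste0(strrep("G", 10), "CT", strrep("T", 16), "AC", strrep("G", 10))
  out2 <- border_dinucleotides(
    dplyr::mutate(intr, strand = "-"), make_genome(rev))
  expect_equal(out2$border, "GT-AG")

  # minor-class borders pass through unchanged
  gc_intron <- paste0(strrep("C", 10), "GC", strrep("A", 16), "AG", strrep("C", 10))
  out3 <- border_dinucleotides(intr, make_genome(gc_intron))
  expect_equal(out3$border, "GC-AG")

  expect_error(border_dinucleotides(
    tibble::tibble(chrom = "chr1", strand = "+", start = 10L, end = 13L), g),
    "4 nt")
})

test_that("PWM training recovers closed-form frequencies", {
  # genome where every intron has identical windows: frequencies hit the
  # (count + 1) / (count + 4) pseudocount closed form at consensus positions
  n <- 60L
  unit <- paste0("CCC", "GTAAGT", strrep("G", 30),
                 "TTTTTTTTTTTTTTTTTTAG", "CCC")  # 3 exonic+6 intronic ... 20+3
  g <- make_genome(strrep(unit, n))
  w <- nchar(unit)
  starts <- (seq_len(n) - 1L) * w + 3L
  ends <- starts + (w - 6L)
  intr <- tibble::tibble(chrom = "chr1", strand = "+", start = starts,
                         end = ends)
  pwm <- suppressMessages(train_pwm(intr, g, pseudocount = 1))
  # donor window is "CCCGTAAGT": position 4 is G in all n sites
  expect_equal(unname(pwm$donor["G", 4]), (n + 1) / (n + 4))
  expect_equal(unname(colSums(pwm$donor)), rep(1, 9))
  expect_equal(unname(colSums(pwm$acceptor)), rep(1, 23))
  expect_true(all(pwm$donor > 0))
})

test_that("PWM trained on uniform random sites is near-uniform", {
  set.seed(77)
  n <- 1000L
  w <- 80L
  g <- make_genome(paste(sample(c("A", "C", "G", "T"), n * w, replace = TRUE),
                         collapse = ""))
  starts <- (seq_len(n) - 1L) * w + 10L
  intr <- tibble::tibble(chrom = "chr1", strand = "+", start = starts,
                         end = starts + 40L)
  pwm <- train_pwm(intr, g)
  expect_true(all(abs(pwm$donor - 0.25) < 0.06))
  expect_true(all(abs(pwm$background - 0.25) < 0.02))
})

test_that("splice-site scoring has the analytic log-odds properties", {
  uniform <- matrix(0.25, nrow = 4, ncol = 9,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  uniform23 <- matrix(0.25, nrow = 4, ncol = 23,
                      dimnames = list(c("A", "C", "G", "T"), NULL))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  # PWM equal to background scores 0 for any sequence
  flat <- structure(list(donor = uniform, acceptor = uniform23,
                         background = bg, pseudocount = 1, n_train = 100),
                    class = "splice_pwm")
  g <- make_genome(paste(rep("ACGT", 40), collapse = ""))
  intr <- tibble::tibble(chrom = "chr1", strand = "+", start = 30L, end = 90L)
  out <- splice_site_score(intr, flat, g)
  expect_equal(out$donor_score, 0)
  expect_equal(out$acceptor_score, 0)
  expect_equal(out$site_score, 0)

  # p = 0.5 at every position vs background 0.25 gives exactly 1 bit per
  # matching position: log2(0.5 / 0.25) * 9 for a full donor match
  # donor window spans 0-based [27, 36) = 1-based characters 28..36
  seqs <- strsplit(substr(paste(rep("ACGT", 40), collapse = ""), 28, 36),
                   "")[[1]]
  half <- uniform
  half[] <- (1 - 0.5) / 3
  for (j in 1:9) half[seqs[j], j] <- 0.5
  biased <- structure(list(donor = half, acceptor = uniform23,
                           background = bg, pseudocount = 1, n_train = 100),
                      class = "splice_pwm")
  out2 <- splice_site_score(intr, biased, g)
  expect_equal(out2$donor_score, 9)

  # consensus maximises the score over all single-base changes
  n_seq <- out2$donor_score
  for (j in 1:9) {
    for (b in setdiff(c("A", "C", "G", "T"), seqs[j])) {
      alt <- log2(half[b, j] / 0.25) - log2(half[seqs[j], j] / 0.25)
      expect_lt(n_seq + alt, n_seq)
    }
  }
})

test_that("group comparison reproduces exact Wilcoxon behaviour", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)  # most extreme of the 20 rank assignments
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_warning(const <- compare_groups(c(2, 2), c(2, 2)), "constant")
  expect_equal(const$p_value, 1)
  set.seed(5)
  shifted <- compare_groups(rnorm(200), rnorm(200, mean = 1))
  expect_lt(shifted$p_value, 0.001)
})

test_that("intron summaries count enormous introns and border classes", {
  f <- tibble::tibble(length = c(10L, 60000L, 200L),
                      au_fraction = c(0.5, 0.6, 0.4),
                      border = c("GT-AG", "GT-AG", "GT-AG"))
  s <- summarize_introns(f)
  expect_equal(s$n_enormous, 1L)
  expect_equal(s$gt_ag_fraction, 1)
  expect_warning(summarize_introns(f[0, ], border), "no groups")
})

test_that("simulated borders recover the planted canonical fraction", {
  sim <- simulate_annotation(simulation_config(n_genes = 60, seed = 13))
  intr <- dplyr::distinct(extract_introns(sim$models),
                          chrom, strand, start, end)
  bd <- border_dinucleotides(intr, sim$genome)
  frac <- mean(bd$border == "GT-AG")
  se3 <- 3 * sqrt(0.98 * 0.02 / nrow(bd))
  expect_gt(frac, 0.98 - se3 - 0.01)
})
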