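test_that("tau matches hand-computed values and its invariances", {
  expect_equal(tau(c(10, 0, 0, 0, 0)), 1)
  expect_equal(tau(c(4, 4, 4, 4)), 0)
  expect_equal(tau(c(8, 4)), 0.5)          # x_hat = (1, 0.5)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(5), "2 groups")
  expect_error(tau(c(-1, 2)), "negative")
  set.seed(4)
  for (i in 1:25) {
    x <- rgamma(sample(2:8, 1), 2)
    expect_equal(tau(3.7 * x), tau(x))            # scale invariance
    expect_equal(tau(sample(x)), tau(x))          # permutation equivariance
    expect_gte(tau(x), 0); expect_lte(tau(x), 1)
  }
})

test_that("group aggregation sums within groups and normalises to CPM", {
  sheet <- tidyr::expand_grid(tissue = c("muscle", "liver"),
                              stage = c("s1", "s2"), replicate = 1:3) %>%
    dplyr::mutate(sample_id = paste(tissue, stage, replicate, sep = "_"))
  quants <- tidyr::expand_grid(event_id = "e1", sample_id = sheet$sample_id) %>%
    dplyr::mutate(counts_EII = 2L, counts_EEI = 1L)
  prof <- aggregate_groups(quants, sheet, mode = "tissue")
  # 6 samples per tissue summed
  expect_equal(prof$count[prof$side == "EII"], c(12L, 12L))
  expect_equal(prof$count[prof$side == "EEI"], c(6L, 6L))

  # explicit library sizes: counts proportional to depth give equal CPM
  sheet2 <- tibble::tibble(sample_id = c("a", "b"), tissue = c("t1", "t2"),
                           stage = "s", replicate = 1L)
  q2 <- tibble::tibble(event_id = "e", sample_id = c("a", "b"),
                       counts_EII = c(10L, 20L), counts_EEI = 0L)
  libs <- tibble::tibble(sample_id = c("a", "b"), lib_size = c(1e6, 2e6))
  p2 <- aggregate_groups(q2, sheet2, lib_sizes = libs)
  cpm <- p2$cpm[p2$side == "EII"]
  expect_equal(cpm[1], cpm[2])

  # unknown sample errors; stage mode crosses tissue and stage
  expect_error(aggregate_groups(dplyr::mutate(q2, sample_id = "zz"), sheet2),
               "absent")
  p3 <- aggregate_groups(quants, sheet, mode = "stage_within_tissue")
  expect_equal(dplyr::n_distinct(p3$group), 4L)
})

test_that("coverage filter keeps sides whose max group count reaches 3", {
  prof <- tibble::tibble(
    event_id = "e", side = rep(c("EII", "EEI"), each = 2),
    group = rep(c("g1", "g2"), 2),
    count = c(2L, 2L, 3L, 0L), cpm = c(2, 2, 3, 0))
  out <- coverage_filter(prof)
  expect_equal(unique(out$side), "EEI")   # max 2 < 3 removes EII rows
  expect_equal(nrow(coverage_filter(dplyr::mutate(prof, count = 0L))), 0L)
})

test_that("specificity calls follow the single-group rule and tau threshold", {
  mk <- function(counts) {
    tibble::tibble(event_id = "e", side = "EII",
                   group = c("muscle", "heart", "liver", "spleen", "kidney"),
                   count = as.integer(counts), cpm = counts)
  }
  hit <- call_specific(mk(c(9, 0, 0, 0, 0)))
  expect_true(hit$specific)
  expect_equal(hit$specific_group, "muscle")

  miss <- call_specific(mk(c(9, 1, 0, 0, 0)))
  expect_false(miss$specific)

  # tau = ((1-1) + (1-1/9) + 3) / 4 = 0.9722 >= 0.9 under a relaxed threshold
  soft <- call_specific(mk(c(9, 1, 0, 0, 0)), tau_threshold = 0.9)
  expect_equal(soft$tau, (8 / 9 + 3) / 4)
  expect_true(soft$specific)
  expect_equal(soft$specific_group, "muscle")
})

test_that("threshold-1 calls equal the brute-force single-group rule", {
  set.seed(12)
  prof <- tidyr::expand_grid(event_id = paste0("e", 1:150), side = "EII",
                             group = paste0("g", 1:5)) %>%
    dplyr::mutate(count = rpois(dplyr::n(), 1.2), cpm = count * 1.0)
  called <- call_specific(prof)
  oracle <- prof %>%
    dplyr::group_by(event_id) %>%
    dplyr::summarise(specific = sum(count > 0) == 1L)
  expect_equal(called$specific[order(called$event_id)],
               oracle$specific[order(oracle$event_id)])
})

test_that("planted specific events are recovered from simulated counts", {
  cfg <- simulation_config(n_genes = 40, seed = 17,
                           fraction_specific_events = 0.2)
  sim <- simulate_annotation(cfg)
  counts <- simulate_junction_counts(sim)
  q <- count_event_support(detect_events(sim$models), counts$junctions,
                           retention = counts$retention,
                           samples = counts$samples)
  spec <- aggregate_groups(q, counts$samples) %>%
    coverage_filter() %>%
    call_specific()
  truth <- counts$truth %>%
    dplyr::distinct(event_id, specific_tissue)
  called <- spec %>% dplyr::filter(side == "EII")
  joined <- dplyr::inner_join(called, truth, by = "event_id")
  planted <- !is.na(joined$specific_tissue)
  expect_true(all(joined$specific[planted]))
  expect_equal(joined$specific_group[planted],
               joined$specific_tissue[planted])
  expect_true(all(!joined$specific[!planted]))

  # no planted specificity -> no calls at threshold 1
  cfg0 <- simulation_config(n_genes = 25, seed = 18,
                            fraction_specific_events = 0)
  sim0 <- simulate_annotation(cfg0)
  c0 <- simulate_junction_counts(sim0)
  q0 <- count_event_support(detect_events(sim0$models), c0$junctions,
                            retention = c0$retention, samples = c0$samples)
  s0 <- aggregate_groups(q0, c0$samples) %>%
    coverage_filter() %>%
    call_specific()
  expect_equal(sum(s0$specific), 0L)
})
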