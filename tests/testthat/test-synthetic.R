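# a reduced configuration that keeps the full geometry but runs fast
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed,
                   n_loops_per_resolution = 20,
                   n_decoys = 6, n_genes = 60, n_has = 10,
                   n_orphan_peaks = 20, n_rdd_background = 15, ...)
}

test_that("the generator is deterministic given a seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(small_config(seed = 7), d1)
  simulate_study(small_config(seed = 7), d2)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
})

test_that("generated inputs pass the package validators and match counts", {
  d <- withr::local_tempdir()
  sim <- simulate_study(small_config(seed = 3), d)
  cs <- read_chromsizes(sim$files$chromsizes)
  n_sig <- 0
  for (key in grep("^(clamp|gaf)_(up|down)_\\d+$", names(sim$files),
                   value = TRUE)) {
    res <- as.numeric(sub(".*_", "", key))
    ls <- read_bedpe(sim$files[[key]], default_resolution = res,
                     p_value_col = 10, effect_col = 11, direction_col = 9,
                     chromsizes = cs)
    expect_true(all(ls$records$end1 - ls$records$start1 == res))
    n_sig <- n_sig + length(filter_significant(ls, 0.01))
  }
  expect_equal(n_sig, 4 * 60)   # four comparisons at config counts
  states <- read_state_bed(sim$files$states, chromsizes = cs)
  expect_true(all(states$chrom[states$state == 5] == "chrX"))
  genes <- read_bed(sim$files$genes, cs)
  dcg <- dc_genes_from_states(states, genes)
  expect_setequal(dcg$name, sim$truth$dc_genes)
})

test_that("count-level truth is stable across seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  t1 <- simulate_study(small_config(seed = 11), d1)$truth
  t2 <- simulate_study(small_config(seed = 12), d2)$truth
  expect_equal(length(t1$comparisons$clamp_down$direct),
               length(t2$comparisons$clamp_down$direct))
  expect_equal(length(t1$comparisons$gaf_down$indirect),
               length(t2$comparisons$gaf_down$indirect))
  expect_equal(length(t1$dc_genes), length(t2$dc_genes))
  # coordinates do change
  r1 <- read_bedpe(file.path(d1, "hichip_clamp.bedpe"))
  r2 <- read_bedpe(file.path(d2, "hichip_clamp.bedpe"))
  expect_false(identical(r1$records$start1, r2$records$start1))
})

test_that("fraction_direct = 0 yields an all-indirect classification", {
  d <- withr::local_tempdir()
  sim <- simulate_study(small_config(seed = 5, fraction_direct = 0), d)
  cs <- read_chromsizes(sim$files$chromsizes)
  down <- lapply(c(1000, 5000, 10000), function(res)
    filter_significant(read_bedpe(sim$files[[sprintf("clamp_down_%d", res)]],
                                  default_resolution = res,
                                  p_value_col = 10, direction_col = 9),
                       0.01))
  cons <- merge_multiresolution(down, cs)
  hc <- read_bedpe(sim$files$hichip_clamp, default_resolution = 1000)
  lab <- classify_direct_indirect(cons, hc, cs)
  expect_true(all(lab$label == "indirect"))
})

test_that("no planted enrichment means a flat APA readout", {
  fx <- simulate_apa_fixture(n_loops = 30, e = 1, resolution = 1000,
                             chromsizes = c(chrX = 6e5))
  st <- pileup_loops(fx$matrices$chrX, fx$loops, flank = 10)
  expect_equal(enrichment_score(st, 3)$ratio, 1, tolerance = 1e-12)
})

test_that("truth_report scores label recovery and flags id mismatches", {
  d <- withr::local_tempdir()
  sim <- simulate_study(small_config(seed = 9), d)
  cmp <- sim$truth$comparisons$clamp_down
  perfect <- data.frame(name = c(cmp$direct, cmp$indirect),
                        label = rep(c("direct", "indirect"),
                                    c(length(cmp$direct),
                                      length(cmp$indirect))))
  rep1 <- truth_report(sim$truth, labels = list(clamp = perfect))
  expect_equal(rep1$value[rep1$metric == "clamp_precision"], 1)
  expect_equal(rep1$value[rep1$metric == "clamp_recall"], 1)
  flipped <- perfect
  flipped$label <- rev(flipped$label)
  rep2 <- truth_report(sim$truth, labels = list(clamp = flipped))
  expect_lt(rep2$value[rep2$metric == "clamp_recall"], 1)
  bogus <- data.frame(name = "nope", label = "direct")
  expect_error(truth_report(sim$truth, labels = list(clamp = bogus)),
               "unknown loop ids")
})
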