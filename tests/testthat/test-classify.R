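test_that("classification matches brute-force window overlap on toy loops", {
  cs <- demo_chromsizes
  down <- toy_loopset(c(100000, 300000, 500000),
                      c(150000, 350000, 550000), width = 1000,
                      resolution = 1000)
  hichip <- toy_loopset(100000 + 800, 150000 - 900, width = 1000,
                        resolution = 1000, p_value = NA_real_)
  lab <- classify_direct_indirect(down, hichip, cs)
  expect_equal(lab$label, c("direct", "indirect", "indirect"))
  expect_equal(lab$n_matches, c(1, 0, 0))
  # brute force on the harmonized windows agrees
  wmc <- harmonize_anchors(down, 10000, cs)
  whc <- harmonize_anchors(hichip, 10000, cs)
  want <- brute_pair_to_pair(wmc$records, whc$records)
  expect_equal(lab$label == "direct", seq_len(3) %in% want$a)
})

test_that("every loop gets exactly one label; empty evidence means indirect", {
  cs <- demo_chromsizes
  down <- toy_loopset(c(100000, 300000), c(150000, 350000),
                      width = 5000, resolution = 5000)
  lab <- classify_direct_indirect(down, toy_loopset(numeric(0), numeric(0)),
                                  cs)
  expect_equal(nrow(lab), 2)
  expect_true(all(lab$label == "indirect"))
  expect_equal(sum(lab$label == "direct") + sum(lab$label == "indirect"),
               length(down))
})

test_that("classification rejects non-down loops and odd resolutions", {
  cs <- demo_chromsizes
  up <- toy_loopset(100000, 150000, direction = "up")
  hc <- toy_loopset(500000, 550000)
  expect_error(classify_direct_indirect(up, hc, cs), "downregulated")
  odd <- toy_loopset(100000, 150000, width = 2000, resolution = 2000)
  expect_error(classify_direct_indirect(odd, hc, cs),
               "unsupported resolution")
})

test_that("adding Hi-ChIP evidence never demotes a direct call", {
  cs <- demo_chromsizes
  set.seed(21)
  down <- rand_loopset(40, chroms = "chrX", len = 1.5e6)
  hc1 <- rand_loopset(15, chroms = "chrX", len = 1.5e6)
  hc2 <- rand_loopset(15, chroms = "chrX", len = 1.5e6)
  l1 <- classify_direct_indirect(down, hc1, cs)
  both <- loopset(rbind(hc1$records, hc2$records))
  l2 <- classify_direct_indirect(down, both, cs)
  expect_true(all(l2$label[l1$label == "direct"] == "direct"))
  # swapping Hi-ChIP anchor order changes nothing
  sw <- hc1$records
  sw[c("start1", "end1", "start2", "end2")] <-
    sw[c("start2", "end2", "start1", "end1")]
  l3 <- classify_direct_indirect(down, loopset(sw), cs)
  expect_equal(l1$label, l3$label)
})

test_that("TF-bound anchor flags match a brute-force scan", {
  ls <- toy_loopset(c(10000, 50000), c(30000, 70000))
  pk <- data.frame(chrom = "chrX", start = 10200, end = 10400)
  got <- tf_bound_anchors(ls, pk)
  expect_equal(got$flags$anchor1_bound, c(TRUE, FALSE))
  expect_equal(got$flags$anchor2_bound, c(FALSE, FALSE))
  expect_equal(nrow(got$anchors), 1)
  none <- tf_bound_anchors(ls, pk[0, ])
  expect_equal(nrow(none$anchors), 0)

  set.seed(33)
  ls <- rand_loopset(40)
  pk <- rand_intervals(60)
  got <- tf_bound_anchors(ls, pk)
  r <- ls$records
  b1 <- vapply(seq_len(40), function(i)
    any(ivl_overlaps(r$chrom[i], r$start1[i], r$end1[i],
                     pk$chrom, pk$start, pk$end)), logical(1))
  b2 <- vapply(seq_len(40), function(i)
    any(ivl_overlaps(r$chrom[i], r$start2[i], r$end2[i],
                     pk$chrom, pk$start, pk$end)), logical(1))
  expect_equal(got$flags$anchor1_bound, b1)
  expect_equal(got$flags$anchor2_bound, b2)
})

test_that("peak participation reports the share of loop-free peaks", {
  ls <- toy_loopset(c(10000, 50000), c(30000, 70000))
  pk <- data.frame(chrom = "chrX",
                   start = c(10200, 30100, 90000), end = c(10400, 30300, 90200))
  got <- peak_loop_participation(pk, ls)
  expect_equal(got$n_in_loops, 2)
  expect_equal(got$n_total, 3)
  expect_equal(got$percent_without, percentage(1, 3, 1))
  expect_error(peak_loop_participation(pk[0, ], ls), "empty peak set")
})
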