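make_states <- function(...) {
  segs <- list(...)
  df <- do.call(rbind, lapply(segs, function(s)
    data.frame(chrom = s[[1]], start = as.numeric(s[[2]]),
               end = as.numeric(s[[3]]), state = as.integer(s[[4]]))))
  df$name <- as.character(df$state)
  df$score <- NA_real_
  df$strand <- "."
  df[c("chrom", "start", "end", "name", "score", "strand", "state")]
}

test_that("either-anchor state annotation deduplicates within a loop", {
  states <- make_states(list("chrX", 0, 50000, 4))
  ls <- toy_loopset(1000, 21000)
  got <- annotate_states_either(ls, states)
  expect_equal(nrow(got), 1)                 # both anchors in state 4
  expect_equal(got$state, 4)

  # anchor spanning a 1|3 boundary contributes both states
  states2 <- make_states(list("chrX", 0, 1500, 1),
                         list("chrX", 1500, 20000, 3),
                         list("chrX", 20000, 50000, 3))
  got2 <- annotate_states_either(ls, states2)
  expect_equal(got2$state, c(1, 3))
})

test_that("state annotation is restricted to 1 kb calls unless forced", {
  states <- make_states(list("chrX", 0, 50000, 2))
  coarse <- toy_loopset(1000, 21000, width = 5000, resolution = 5000)
  expect_error(annotate_states_either(coarse, states), "1 kb")
  expect_silent(annotate_states_either(coarse, states, force = TRUE))
})

test_that("state pairs are the unordered product of anchor state sets", {
  states <- make_states(list("chrX", 0, 2000, 5),
                        list("chrX", 20000, 50000, 9))
  ls <- toy_loopset(1000, 21000)
  got <- annotate_state_pairs(ls, states)
  expect_equal(got[c("state1", "state2")],
               data.frame(state1 = 5L, state2 = 9L))

  # anchor1 in {1,3}, anchor2 in {5}: enumerated product
  states2 <- make_states(list("chrX", 0, 1500, 3),
                         list("chrX", 1500, 2000, 1),
                         list("chrX", 20000, 50000, 5))
  got2 <- annotate_state_pairs(ls, states2)
  expect_equal(got2[c("state1", "state2")],
               data.frame(state1 = c(1L, 3L), state2 = c(5L, 5L)))

  # an uncovered anchor yields the reserved unassigned label (0)
  states3 <- make_states(list("chrX", 0, 2000, 7))
  got3 <- annotate_state_pairs(ls, states3)
  expect_equal(got3[c("state1", "state2")],
               data.frame(state1 = 0L, state2 = 7L))
})

test_that("either-mode and pair annotations are mutually consistent", {
  set.seed(14)
  segs <- rand_intervals(60, max_width = 5000)
  segs$state <- sample(1:9, 60, replace = TRUE)
  ls <- rand_loopset(25)
  either <- annotate_states_either(ls, segs)
  pairs <- annotate_state_pairs(ls, segs)
  for (i in unique(pairs$loop)) {
    in_pairs <- setdiff(unique(c(pairs$state1[pairs$loop == i],
                                 pairs$state2[pairs$loop == i])), 0L)
    in_either <- either$state[either$loop == i]
    expect_setequal(in_pairs, in_either)
  }
})

test_that("DC genes are the deduplicated state-5 overlappers", {
  states <- make_states(list("chrX", 0, 5000, 5),
                        list("chrX", 5000, 9000, 1),
                        list("chrX", 9000, 12000, 5))
  genes <- data.frame(chrom = "chrX",
                      start = c(4000, 6000, 8500), end = c(6000, 7000, 13000),
                      name = c("gA", "gB", "gC"))
  got <- dc_genes_from_states(states, genes)
  expect_equal(got$name, c("gA", "gC"))   # gC overlaps two segments, once
  none <- dc_genes_from_states(make_states(list("chrX", 0, 5000, 1)), genes)
  expect_equal(nrow(none), 0)
  genes$name <- c("g", "g", "gC")
  expect_error(dc_genes_from_states(states, genes), "duplicate gene name")
  # order invariance
  set.seed(2)
  states_r <- make_states(list("chrX", 9000, 12000, 5),
                          list("chrX", 5000, 9000, 1),
                          list("chrX", 0, 5000, 5))
  genes$name <- c("gA", "gB", "gC")
  expect_equal(sort(dc_genes_from_states(states_r, genes)$name),
               sort(got$name))
})

test_that("DC-gene association uses span containment and HAS anchoring", {
  ls <- toy_loopset(c(10000, 100000), c(40000, 130000))
  dcg <- data.frame(chrom = "chrX", start = c(20000, 500000),
                    end = c(22000, 502000), name = c("gIn", "gOut"))
  has <- data.frame(chrom = "chrX", start = 130200, end = 130800)
  got <- associate_dc_genes(ls, dcg, has)
  expect_equal(got$per_loop$n_dc_genes, c(1, 0))
  expect_equal(got$per_loop$dc_genes[1], "gIn")   # inside span, off-anchor
  expect_equal(got$per_loop$has_anchored, c(FALSE, TRUE))
  expect_equal(got$summary$n_in_any_loop, 1)
  expect_equal(got$summary$pct_in_any_loop, 50)
  expect_equal(got$summary$n_in_has_loop, 0)
})

test_that("RDD overlap demands uniform bins and honours site filters", {
  cs <- demo_chromsizes
  raw <- toy_loopset(c(100000, 300000), c(150000, 350000),
                     width = 1000, resolution = 1000)
  norm <- normalize_bins(raw, 5000, cs)
  expect_error(rdd_overlap(raw, norm), "normalized")
  # RDD = copy of the input -> 100 %
  got <- rdd_overlap(norm, norm)
  expect_equal(got$percent, 100)
  # disjoint chromosomes -> 0 %
  far <- normalize_bins(toy_loopset(c(100000, 300000), c(150000, 350000),
                                    chrom = "chr2L"), 5000, cs)
  expect_equal(rdd_overlap(norm, far)$percent, 0)
  expect_equal(rdd_overlap(far, norm, site_filter = "chrX")$n_total, 0)
})
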