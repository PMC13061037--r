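test_that("BED parsing maps fields, skips headers, and flags bad lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo",
               "chrX\t100\t200\tHAS1",
               "chr2L\t0\t50",
               "# a comment",
               "chrX\t500\t900\tpk\t7.5\t+"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 3)
  expect_equal(x$chrom[1], "chrX")
  expect_equal(x$start[1], 100)
  expect_equal(x$end[1], 200)
  expect_equal(x$name[1], "HAS1")
  expect_true(is.na(x$name[2]))
  expect_equal(x$score[3], 7.5)

  writeLines("chrX\t200\t100", f)
  expect_error(read_bed(f), "start >= end at line 1")
  writeLines("chrX\t100", f)
  expect_error(read_bed(f), "fewer than 3 columns")
})

test_that("chromsizes binding validates chromosome names and bounds", {
  cs <- c(chrX = 1000)
  expect_error(genomic_intervals("chr9", 0, 10, chromsizes = cs),
               "absent from chromsizes")
  expect_error(genomic_intervals("chrX", 0, 2000, chromsizes = cs),
               "exceeds chromosome length")
  expect_silent(genomic_intervals("chrX", 0, 1000, chromsizes = cs))
})

test_that("BED and BEDPE round-trip field-for-field", {
  set.seed(7)
  x <- rand_intervals(25)
  x <- x[order(x$chrom, x$start, x$end), ]
  rownames(x) <- NULL
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  expect_equal(read_bed(f), x)

  ls <- rand_loopset(20)
  g <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(ls, g)
  back <- read_bedpe(g, default_resolution = 1000, p_value_col = 10,
                     effect_col = 11, direction_col = 9)
  r <- ls$records
  r <- r[order(r$chrom, r$start1, r$start2, r$end1, r$end2,
               method = "radix"), ]    # the writer's deterministic order
  rownames(r) <- NULL
  expect_equal(back$records, r)
})

test_that("BEDPE reader canonicalizes, rejects trans pairs, deduplicates", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chrX\t5000\t6000\tchrX\t1000\t2000\tL1", f)
  ls <- read_bedpe(f)
  expect_lt(ls$records$start1, ls$records$start2)

  writeLines("chrX\t1000\t2000\tchr2L\t5000\t6000\tL1", f)
  expect_error(read_bedpe(f), "trans pair at line 1")

  rows <- sprintf("chrX\t%d\t%d\tchrX\t%d\t%d\tL%d", (1:8) * 1000,
                  (1:8) * 1000 + 500, (1:8) * 1000 + 5000,
                  (1:8) * 1000 + 5500, 1:8)
  writeLines(c(rows, rows[1], rows[5]), f)   # 10 rows, 2 exact duplicates
  expect_equal(nrow(read_bedpe(f)$records), 8)
})

test_that("slop extends symmetrically and clips at chromosome bounds", {
  cs <- c(chrX = 5e6)
  s <- slop_intervals(data.frame(chrom = "chrX", start = 5000, end = 6000),
                      4500, cs)
  expect_equal(c(s$start, s$end), c(500, 10500))
  expect_equal(s$end - s$start, 10000)

  s0 <- slop_intervals(data.frame(chrom = "chrX", start = 1000, end = 2000),
                       0, cs)
  expect_equal(c(s0$start, s0$end), c(1000, 2000))

  sc <- slop_intervals(data.frame(chrom = "chrX", start = 1000, end = 2000),
                       4500, c(chrX = 5000))
  expect_equal(c(sc$start, sc$end), c(0, 5000))
  expect_equal(attr(sc, "n_clipped"), 1)
})

test_that("slop is monotone in the extension amount", {
  set.seed(11)
  x <- rand_intervals(50)
  cs <- c(chrX = 1e5, chr2L = 1e5)
  for (rep in 1:20) {
    a <- sort(runif(2, 0, 20000))
    s1 <- slop_intervals(x, a[1], cs)
    s2 <- slop_intervals(x, a[2], cs)
    expect_true(all(s2$start <= s1$start & s1$end <= s2$end))
  }
})

test_that("canonicalization is idempotent and preserves loop span", {
  set.seed(3)
  r <- rand_loopset(30)$records
  swapped <- r
  swapped[c("start1", "end1", "start2", "end2")] <-
    r[c("start2", "end2", "start1", "end1")]
  ls1 <- loopset(r)
  ls2 <- loopset(swapped)
  expect_equal(ls1$records[1:5], ls2$records[1:5])
  expect_equal(sort(loop_span(ls1)), sort(loop_span(ls2)))
  expect_equal(loopset(ls1$records)$records, ls1$records)
})

test_that("loop span is the midpoint distance (outer span optional)", {
  ls <- toy_loopset(1000, 11000)
  expect_equal(loop_span(ls), 10000)
  expect_equal(loop_span(ls, "ospan"), 11000)
  same <- loopset(data.frame(chrom = "chrX", start1 = 1000, end1 = 2000,
                             start2 = 1000, end2 = 2000))
  expect_equal(loop_span(same), 0)
})
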