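const_cm <- function(n = 30, value = 2, chrom = "chrX", res = 5000)
  contact_matrix(chrom, res, matrix(value, n, n))

test_that("contact matrices enforce symmetry and round-trip exactly", {
  m <- matrix(runif(9), 3, 3)
  expect_error(contact_matrix("chrX", 1000, m), "asymmetry")
  m <- (m + t(m)) / 2
  cm <- contact_matrix("chrX", 1000, m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(cm, f)
  back <- read_contact_matrix(f)
  expect_equal(back$chrom, "chrX")
  expect_equal(back$resolution, 1000)
  expect_lt(max(abs(back$mat - m)), 1e-12)
  expect_error(read_contact_matrix(f, resolution = 5000), "mismatch")

  writeLines(c("# chrom=chrX resolution=1000",
               "1\t2\t3", "9\t1\t2", "3\t2\t1"), f)
  expect_error(read_contact_matrix(f), "asymmetry")
  expect_error(contact_matrix("chrX", 1000, matrix(4, 5, 5),
                              chrom_length = 1000), "bin count")
})

test_that("expected-by-distance recovers per-diagonal profiles", {
  cm <- const_cm(20, 3)
  expect_equal(expected_by_distance(cm, "mean"), rep(3, 20))
  expect_equal(expected_by_distance(cm, "median"), rep(3, 20))

  n <- 25
  sep <- abs(outer(1:n, 1:n, "-"))
  cm2 <- contact_matrix("chrX", 1000, 1 / (1 + sep))
  expect_equal(expected_by_distance(cm2, "mean"), 1 / (1 + 0:(n - 1)))

  one <- contact_matrix("chrX", 1000, matrix(5, 1, 1))
  expect_equal(expected_by_distance(one), 5)
})

test_that("pile-up of a constant matrix is all ones after normalization", {
  cm <- const_cm(60, 7)
  sites <- data.frame(chrom = "chrX",
                      start = c(50000, 120000, 200000) - 500,
                      end = c(50000, 120000, 200000) + 500)
  st <- pileup_sites(cm, sites, flank = 3, min_sep = 10000, max_sep = 3e5)
  expect_equal(st$mean, matrix(1, 7, 7))
  expect_equal(length(st$windows), 3)
  # scale invariance of the score
  sc1 <- enrichment_score(st, corner_block = 2)
  st2 <- pileup_sites(const_cm(60, 70), sites, flank = 3,
                      min_sep = 10000, max_sep = 3e5)
  expect_equal(enrichment_score(st2, 2)$ratio, sc1$ratio)
})

test_that("windows near matrix edges are skipped, not padded", {
  cm <- const_cm(40)
  sites <- data.frame(chrom = "chrX",
                      start = c(5000, 55000, 120000) - 500,
                      end = c(5000, 55000, 120000) + 500)
  st <- pileup_sites(cm, sites, flank = 4, min_sep = 10000, max_sep = 2e5)
  expect_gt(st$n_skipped, 0)
  expect_true(all(vapply(st$windows, function(w) all(dim(w) == 9),
                         logical(1))))
  expect_error(pileup_sites(cm, sites, flank = 4, min_sep = 1e6,
                            max_sep = 2e6), "no site pairs")
})

test_that("loop pile-up recovers a planted bump at the central pixel", {
  n <- 80
  sep <- abs(outer(1:n, 1:n, "-"))
  base <- 100 * (1 + sep)^-0.8
  b1 <- 20; b2 <- 50
  base[b1, b2] <- base[b1, b2] * 4
  base[b2, b1] <- base[b1, b2]
  cm <- contact_matrix("chrX", 5000, base)
  ls <- loopset(data.frame(chrom = "chrX",
                           start1 = (b1 - 1) * 5000, end1 = b1 * 5000,
                           start2 = (b2 - 1) * 5000, end2 = b2 * 5000))
  st <- pileup_loops(cm, ls, flank = 6)
  expect_equal(st$mean[7, 7], 4, tolerance = 1e-12)
  expect_equal(enrichment_score(st, 2)$ratio, 4, tolerance = 1e-12)
  expect_error(pileup_loops(cm, ls[0], flank = 6), "no loops")
})

test_that("enrichment score is the centre over the corner-block mean", {
  w <- matrix(1, 11, 11)
  expect_equal(enrichment_score(w, 3)$ratio, 1)
  expect_equal(enrichment_score(w, 3)$log_ratio, 0)
  w[6, 6] <- 2
  expect_equal(enrichment_score(w, 3)$ratio, 2)
  expect_error(enrichment_score(matrix(0, 11, 11), 3), "zero background")
  expect_error(enrichment_score(matrix(1, 5, 5), 3), "too small")
})

test_that("planted APA enrichment is recovered exactly without noise", {
  fx <- simulate_apa_fixture(n_loops = 40, e = 3, resolution = 1000,
                             chromsizes = c(chrX = 6e5, chr2L = 6e5))
  stacks <- lapply(fx$matrices, function(cm)
    tryCatch(pileup_loops(cm, fx$loops, flank = 10),
             error = function(e) NULL))
  stacks <- stacks[!vapply(stacks, is.null, logical(1))]
  windows <- do.call(c, lapply(stacks, function(s) s$windows))
  mean_w <- Reduce(`+`, windows) / length(windows)
  sc <- enrichment_score(mean_w, 3)
  expect_equal(sc$ratio, 3, tolerance = 1e-12)
})
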