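test_that("Fisher exact matches enumeration on hand-derived tables", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1.0)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3)$p, 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10)$p, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  set.seed(8)
  for (i in 1:50) {
    t4 <- rpois(4, 6)
    p0 <- fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4])$p
    expect_equal(fisher_exact_2x2(t4[1], t4[3], t4[2], t4[4])$p, p0)
    expect_equal(fisher_exact_2x2(t4[4], t4[3], t4[2], t4[1])$p, p0)
    # independent implementation agrees
    expect_equal(p0, fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U and exact p match enumeration", {
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$U, 0)
  expect_equal(got$p, 2 / 20)              # full separation, both tails
  expect_equal(got$method, "exact")

  same <- mann_whitney(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(same$U, 16 / 2)             # n^2 / 2 under symmetry
  expect_equal(same$p, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "empty sample")
})

test_that("Mann-Whitney is symmetric and agrees with wilcox.test", {
  set.seed(19)
  for (i in 1:20) {
    pool <- sample(1:100, 13)          # tie-free: wilcox.test stays exact
    x <- pool[1:6]
    y <- pool[7:13]
    a <- mann_whitney(x, y)
    b <- mann_whitney(y, x)
    expect_equal(a$p, b$p)
    expect_equal(a$U + b$U, length(x) * length(y))
    # tie-free exact case: wilcox.test computes the same distribution
    expect_equal(a$p, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("normal-approximation branch tracks wilcox.test with ties", {
  set.seed(23)
  x <- sample(1:10, 30, replace = TRUE)
  y <- sample(1:10, 35, replace = TRUE)
  got <- mann_whitney(x, y)
  expect_equal(got$method, "normal")
  expect_equal(got$p,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("printed-percentage rounding is half-away-from-zero", {
  expect_equal(percentage(1218, 3852, 2), 31.62)
  expect_equal(percentage(1044, 1218, 2), 85.71)
  expect_equal(percentage(0, 7, 1), 0)
  expect_equal(percentage(1, 8, 1), 12.5)
  expect_equal(percentage(1, 16, 1), 6.3)   # 6.25 rounds away from zero
  expect_error(percentage(1, 0), "zero denominator")
  set.seed(4)
  for (i in 1:50) {
    d <- sample(1:5000, 1); n <- sample(0:d, 1)
    expect_lte(abs(percentage(n, d, 2) + percentage(d - n, d, 2) - 100),
               0.01 + 1e-9)
  }
})

test_that("union-overlap percentage follows the shared-over-union rule", {
  expect_equal(union_overlap_percentage(1366, 1679, 7, 2), 0.23)
  expect_equal(union_overlap_percentage(15150, 3870, 39, 2), 0.21)
  for (n in c(1, 5, 400))
    expect_equal(union_overlap_percentage(n, n, n), 100)
  expect_error(union_overlap_percentage(5, 5, 6), "exceeds")
})

test_that("size summaries interpolate quartiles per group", {
  ls <- loopset(data.frame(chrom = "chrX", start1 = 0, end1 = 1000,
                           start2 = c(10000, 20000, 30000, 8000),
                           end2 = c(11000, 21000, 31000, 9000)))
  # note: loopset sorts records by coordinates; group accordingly
  got <- size_summary(ls, c("a", "a", "a", "b")[order(c(10000, 20000,
                                                        30000, 8000))])
  a <- got[got$group == "a", ]
  expect_equal(c(a$median_kb, a$q1_kb, a$q3_kb), c(20, 15, 25))
  b <- got[got$group == "b", ]
  expect_equal(c(b$median_kb, b$q1_kb, b$q3_kb), c(8, 8, 8))
  expect_warning(size_summary(ls, factor(rep("a", 4), levels = c("a", "z"))),
                 "empty group")
})

test_that("per-state enrichment tests build the right 2x2 tables", {
  up <- c(10, 10, 10, 10, 10, 10, 10, 10, 10)
  down <- up * 3
  flat <- state_enrichment_test(up, down)
  expect_equal(flat$p, rep(1, 9), tolerance = 1e-12)
  toy_up <- c(90, rep(10 / 8, 8)); toy_up[2:9] <- c(2, 2, 2, 1, 1, 1, 1, 0)
  toy_down <- c(10, rep(90 / 8, 8)); toy_down[2:9] <- c(12, 12, 12, 11, 11,
                                                        11, 11, 10)
  got <- state_enrichment_test(toy_up, toy_down)
  expect_equal(got$p[1],
               brute_fisher(90, sum(toy_up) - 90, 10, sum(toy_down) - 10),
               tolerance = 1e-9)
  # permutation equivariance
  perm <- c(3, 1, 2, 9, 8, 7, 4, 5, 6)
  expect_equal(state_enrichment_test(toy_up[perm], toy_down[perm])$p,
               got$p[perm])
  expect_error(state_enrichment_test(rep(0, 9), toy_down), "zero total")
})
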