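# Brute-force quadratic oracles and random-fixture builders shared by the
# unit and acceptance suites.  All oracles work straight off data.frames,
# independent of the IRanges-backed overlap machinery they check.

ivl_overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

# all-pairs pair_to_bed predicate, evaluated on the full cross product
brute_pair_to_bed <- function(records, features, mode) {
  ij <- expand.grid(i = seq_len(nrow(records)),
                    j = seq_len(nrow(features)))
  r <- records[ij$i, ]; f <- features[ij$j, ]
  ok <- if (mode == "either") {
    ivl_overlaps(r$chrom, r$start1, r$end1, f$chrom, f$start, f$end) |
      ivl_overlaps(r$chrom, r$start2, r$end2, f$chrom, f$start, f$end)
  } else {
    ivl_overlaps(r$chrom, r$start1, r$end2, f$chrom, f$start, f$end)
  }
  out <- data.frame(loop = ij$i[ok], feature = ij$j[ok])
  out[order(out$loop, out$feature), , drop = FALSE]
}

# all-pairs both-ends pair_to_pair predicate
brute_pair_to_pair <- function(ra, rb) {
  ij <- expand.grid(i = seq_len(nrow(ra)), j = seq_len(nrow(rb)))
  a <- ra[ij$i, ]; b <- rb[ij$j, ]
  straight <-
    ivl_overlaps(a$chrom, a$start1, a$end1, b$chrom, b$start1, b$end1) &
    ivl_overlaps(a$chrom, a$start2, a$end2, b$chrom, b$start2, b$end2)
  crossed <-
    ivl_overlaps(a$chrom, a$start1, a$end1, b$chrom, b$start2, b$end2) &
    ivl_overlaps(a$chrom, a$start2, a$end2, b$chrom, b$start1, b$end1)
  ok <- straight | crossed
  out <- data.frame(a = ij$i[ok], b = ij$j[ok])
  out[order(out$a, out$b), , drop = FALSE]
}

# two-sided Fisher p by explicit enumeration with choose() ratios
brute_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp)
  sum(p[p <= p[x == a] * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by enumeration of all group assignments
brute_mw <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  stat <- function(idx) sum(rk[idx])
  obs <- stat(seq_len(n1))
  all_sets <- utils::combn(length(pooled), n1)
  sums <- apply(all_sets, 2, stat)
  min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
}

# random fixtures -------------------------------------------------------

rand_intervals <- function(n, chroms = c("chrX", "chr2L"), len = 1e5,
                           max_width = 3000) {
  start <- floor(runif(n, 0, len - max_width))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + ceiling(runif(n, 1, max_width)),
             name = sprintf("f%04d", seq_len(n)),
             score = NA_real_, strand = ".",
             stringsAsFactors = FALSE)
}

rand_loopset <- function(n, chroms = c("chrX", "chr2L"), len = 1e5,
                         width = 1000, dedup = FALSE) {
  s1 <- floor(runif(n, 0, len - 30000))
  gap <- floor(runif(n, 0, 20000))
  r <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                  start1 = s1, end1 = s1 + width,
                  start2 = s1 + width + gap, end2 = s1 + 2 * width + gap,
                  name = sprintf("L%04d", seq_len(n)),
                  resolution = width, direction = "down",
                  p_value = signif(runif(n), 6), effect = -1,
                  stringsAsFactors = FALSE)
  loopset(r, dedup = dedup)
}

toy_loopset <- function(start1, start2, width = 1000, chrom = "chrX",
                        resolution = width, direction = "down",
                        p_value = 0.001) {
  if (!length(start1))
    return(loopset(data.frame(chrom = character(), start1 = numeric(),
                              end1 = numeric(), start2 = numeric(),
                              end2 = numeric())))
  loopset(data.frame(chrom = chrom, start1 = start1,
                     end1 = start1 + width, start2 = start2,
                     end2 = start2 + width,
                     name = sprintf("T%03d", seq_along(start1)),
                     resolution = resolution, direction = direction,
                     p_value = p_value, effect = -1))
}

demo_chromsizes <- c(chrX = 2e6, chr2L = 2e6)
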