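#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7, the convention of \code{stats::fisher.test}).
#' A doubling-rule alternative (twice the smaller one-sided tail, capped at
#' 1) is available behind \code{alternative_rule}.
#'
#' @param a,b,c,d Non-negative counts of the table \code{[[a, b], [c, d]]}.
#' @param alternative_rule \code{"mass"} (default) or \code{"doubling"}.
#' @return List with \code{p} (two-sided p-value in (0, 1]), \code{table}
#'   (the 2x2 matrix, echoed for auditability) and \code{odds_ratio} (the
#'   sample odds ratio).
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative_rule = c("mass", "doubling")) {
  alternative_rule <- match.arg(alternative_rule)
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("negative count")
  if (any(counts != round(counts))) stop("non-integer count")
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  if ((m + n) == 0) stop("all-zero table")
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  dens <- stats::dhyper(x, m, n, k)
  d_obs <- dens[x == a]
  p <- if (alternative_rule == "mass") {
    sum(dens[dens <= d_obs * (1 + 1e-7)])
  } else {
    lower <- sum(dens[x <= a])
    upper <- sum(dens[x >= a])
    min(1, 2 * min(lower, upper))
  }
  list(p = min(1, p),
       table = matrix(counts, 2, 2, byrow = TRUE),
       odds_ratio = (a * d) / (b * c))
}

#' Mann-Whitney U test
#'
#' U is computed from midranks (average ranks for ties).  The two-sided
#' p-value is exact -- by the distribution of the rank sum over all
#' \code{choose(n1+n2, n1)} group assignments of the pooled sample, computed
#' with a Streitberg-Roehmel style generating-function recursion that
#' handles ties -- whenever \code{n1 * n2 <= exact_limit}; otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.  The exact two-sided p doubles the smaller tail (including the
#' observed value) and is capped at 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Exact enumeration is used when \code{n1 * n2} does not
#'   exceed this (default 400).
#' @return List with \code{U} (statistic for \code{x}), \code{p}
#'   (two-sided), \code{method} (\code{"exact"} or \code{"normal"}) and
#'   \code{n} (the two sample sizes).
#' @export
mann_whitney <- function(x, y, exact_limit = 400) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)           # midranks
  r1 <- sum(rk[seq_len(n1)])
  U <- r1 - n1 * (n1 + 1) / 2
  if (n1 * n2 <= exact_limit) {
    # distribution of the x rank-sum over all subsets of size n1,
    # on doubled midranks so weights are integers
    w <- as.integer(round(2 * rk))
    smax <- sum(sort(w, decreasing = TRUE)[seq_len(n1)])
    # f[k+1, s+1] = number of size-k subsets with doubled-rank-sum s
    f <- matrix(0, n1 + 1, smax + 1)
    f[1, 1] <- 1
    for (wi in w) {
      for (k in seq(n1, 1)) {           # descending: each item used once
        idx <- seq_len(smax + 1 - wi)
        f[k + 1, idx + wi] <- f[k + 1, idx + wi] + f[k, idx]
      }
    }
    dist <- f[n1 + 1, ]
    total <- sum(dist)
    s_obs <- as.integer(round(2 * r1))
    lower <- sum(dist[seq_len(s_obs + 1)]) / total
    upper <- sum(dist[seq(s_obs + 1, smax + 1)]) / total
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = p, method = method, n = c(n1 = n1, n2 = n2))
}

# half-away-from-zero rounding (printed-percentage convention)
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5) / scale * sign(x)
}

#' Percentage with printed-table rounding
#'
#' \code{100 * numerator / denominator}, rounded half-away-from-zero to the
#' requested number of decimals (the convention that reproduces printed
#' values such as 31.62 and 85.71 from their counts).
#'
#' @param numerator,denominator Counts; \code{denominator > 0}.
#' @param decimals Decimal places (default 1).
#' @return The rounded percentage.
#' @export
percentage <- function(numerator, denominator, decimals = 1) {
  if (any(denominator == 0)) stop("zero denominator")
  round_half_away(100 * numerator / denominator, decimals)
}

#' Overlap percentage on the union of two sets
#'
#' \code{100 * nAB / (nA + nB - nAB)}: the shared count over the union size,
#' the convention behind printed loop-set overlap percentages such as 0.23
#' (7 shared of 1,366 and 1,679).
#'
#' @param nA,nB Set sizes.
#' @param nAB Shared count; must not exceed \code{min(nA, nB)}.
#' @param decimals Decimal places (default 2).
#' @return The rounded percentage.
#' @export
union_overlap_percentage <- function(nA, nB, nAB, decimals = 2) {
  if (nAB > min(nA, nB)) stop("shared count exceeds a set size")
  u <- nA + nB - nAB
  if (u <= 0) stop("empty union")
  round_half_away(100 * nAB / u, decimals)
}

#' Per-group loop-size summaries
#'
#' Median and quartiles (linear interpolation between order statistics) of
#' the loop span in kb, per group.
#'
#' @param loops A [loopset()].
#' @param groups Vector (or data.frame of vectors) of group keys, one per
#'   record.
#' @param method Span definition passed to [loop_span()].
#' @return data.frame with one row per group: group key(s), \code{n},
#'   \code{median_kb}, \code{q1_kb}, \code{q3_kb}.  Empty groups are
#'   omitted with a warning.
#' @export
size_summary <- function(loops, groups, method = "midpoint") {
  spans_kb <- loop_span(loops, method) / 1000
  if (is.data.frame(groups)) {
    key <- interaction(groups, drop = FALSE, sep = " / ")
  } else if (is.factor(groups)) {
    key <- groups
  } else {
    key <- factor(groups)
  }
  if (length(key) != length(spans_kb))
    stop("group keys must cover every record")
  empty <- setdiff(levels(key), unique(as.character(key)))
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(split(spans_kb, key, drop = TRUE),
                               function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), median_kb = q[2], q1_kb = q[1], q3_kb = q[3])
  }))
  out <- cbind(data.frame(group = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Per-state enrichment test between two loop classes
#'
#' For each chromatin state s, tests the 2x2 table \code{[[up_s, up_total -
#' up_s], [down_s, down_total - down_s]]} with the two-sided Fisher exact
#' test.  Raw p-values are the primary readout (the study thresholds raw
#' p), with Benjamini-Hochberg adjusted q-values co-reported.
#'
#' @param counts_up,counts_down Numeric vectors of per-state counts (same
#'   length, nine states in the standard segmentation).
#' @return data.frame with \code{state}, the four table cells, \code{p} and
#'   \code{q} (BH).
#' @export
state_enrichment_test <- function(counts_up, counts_down) {
  if (length(counts_up) != length(counts_down))
    stop("count vectors differ in length")
  tot_up <- sum(counts_up)
  tot_down <- sum(counts_down)
  if (tot_up == 0 || tot_down == 0) stop("zero total counts")
  p <- vapply(seq_along(counts_up), function(s)
    fisher_exact_2x2(counts_up[s], tot_up - counts_up[s],
                     counts_down[s], tot_down - counts_down[s])$p,
    numeric(1))
  data.frame(state = seq_along(counts_up),
             up = counts_up, up_rest = tot_up - counts_up,
             down = counts_down, down_rest = tot_down - counts_down,
             p = p, q = stats::p.adjust(p, "BH"))
}
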