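#' Associate loops with BED features (pairToBed-style)
#'
#' Two modes mirror the bedtools pairToBed semantics used throughout the
#' integration:
#' \describe{
#'   \item{either}{a feature is associated with a loop when it overlaps
#'     anchor 1 or anchor 2 by at least 1 bp (TAD, HAS and state
#'     integration);}
#'   \item{ospan}{a feature is associated when it overlaps the outer span
#'     \code{[start1, end2)} by at least 1 bp, which captures genes lying
#'     entirely between the two anchors (dosage-compensated gene
#'     containment).}
#' }
#' A loop may match many features and vice versa.
#'
#' @param loops A [loopset()].
#' @param features Interval data.frame (may be empty: no associations).
#' @param mode \code{"either"} or \code{"ospan"}.
#' @return A data.frame with columns \code{loop} (row index into the loop
#'   records), \code{feature} (row index into \code{features}) and, for
#'   either-mode, \code{anchor1}/\code{anchor2} logical flags saying which
#'   anchor(s) produced the overlap.  One row per distinct (loop, feature)
#'   pair, sorted.
#' @export
pair_to_bed <- function(loops, features, mode = c("either", "ospan")) {
  mode <- match.arg(mode)
  r <- loops$records
  if (!nrow(r) || !nrow(features)) {
    out <- data.frame(loop = integer(), feature = integer())
    if (mode == "either") {
      out$anchor1 <- logical()
      out$anchor2 <- logical()
    }
    return(out)
  }
  validate_intervals(features)
  if (mode == "either") {
    h1 <- interval_hits(loop_anchors(loops, 1), features)
    h2 <- interval_hits(loop_anchors(loops, 2), features)
    key1 <- paste(h1$query, h1$subject)
    key2 <- paste(h2$query, h2$subject)
    all_pairs <- unique(rbind(h1, h2))
    key <- paste(all_pairs$query, all_pairs$subject)
    out <- data.frame(loop = all_pairs$query, feature = all_pairs$subject,
                      anchor1 = key %in% key1, anchor2 = key %in% key2)
  } else {
    span <- data.frame(chrom = r$chrom, start = r$start1, end = r$end2)
    h <- interval_hits(span, features)
    out <- data.frame(loop = h$query, feature = h$subject)
  }
  out <- out[order(out$loop, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match loops between two sets (pairToPair-style, both ends)
#'
#' A loop in \code{loopsA} matches a loop in \code{loopsB} when both anchor
#' pairs overlap on the same chromosome, in either orientation: (A1 with B1
#' and A2 with B2) or (A1 with B2 and A2 with B1), overlap meaning >= 1
#' shared bp.  This is the "both" mode used to intersect differential
#' Micro-C loops with TF Hi-ChIP loops and with roX2-RDD loops.
#'
#' @param loopsA,loopsB [loopset()] objects (canonicalized).
#' @return A data.frame with columns \code{a}, \code{b}: row indices of
#'   matching records, one row per distinct pair, sorted by (a, b).
#' @export
pair_to_pair <- function(loopsA, loopsB) {
  ra <- loopsA$records
  rb <- loopsB$records
  if (!nrow(ra) || !nrow(rb))
    return(data.frame(a = integer(), b = integer()))
  a1 <- loop_anchors(loopsA, 1); a2 <- loop_anchors(loopsA, 2)
  b1 <- loop_anchors(loopsB, 1); b2 <- loop_anchors(loopsB, 2)
  joint <- function(hx, hy) {
    # pairs (a,b) present in both hit lists
    kx <- paste(hx$query, hx$subject)
    ky <- paste(hy$query, hy$subject)
    hx[kx %in% ky, , drop = FALSE]
  }
  straight <- joint(interval_hits(a1, b1), interval_hits(a2, b2))
  crossed <- joint(interval_hits(a1, b2), interval_hits(a2, b1))
  out <- unique(rbind(straight, crossed))
  out <- data.frame(a = out$query, b = out$subject)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonize loop anchors onto uniform windows
#'
#' Symmetrically extends each anchor by \code{(width - anchor width) / 2} so
#' that every anchor becomes a window of the requested width (clipped at
#' chromosome ends).  This reproduces the slop-based harmonization used to
#' compare 1 kb / 5 kb / 10 kb loop calls on uniform 10 kb windows: a 1 kb
#' anchor is slopped by 4500 bp and a 5 kb anchor by 2500 bp.
#'
#' @param loops A loopset whose anchor widths are all <= \code{width}.
#' @param width Target window width in bp.
#' @param chromsizes Named vector of chromosome lengths.
#' @return A loopset with widened anchors (same order, names and metadata).
#' @export
harmonize_anchors <- function(loops, width, chromsizes) {
  r <- loops$records
  if (!nrow(r)) return(loops)
  w1 <- r$end1 - r$start1
  w2 <- r$end2 - r$start2
  if (any(w1 > width) || any(w2 > width))
    stop("anchor wider than the target window (", width, " bp)")
  a1 <- slop_intervals(data.frame(chrom = r$chrom, start = r$start1,
                                  end = r$end1),
                       (width - w1) / 2, chromsizes)
  a2 <- slop_intervals(data.frame(chrom = r$chrom, start = r$start2,
                                  end = r$end2),
                       (width - w2) / 2, chromsizes)
  r$start1 <- a1$start; r$end1 <- a1$end
  r$start2 <- a2$start; r$end2 <- a2$end
  structure(list(records = r, meta = loops$meta), class = "loopset")
}
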