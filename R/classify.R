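#' Classify downregulated loops as direct or indirect
#'
#' A knockdown-lost (downregulated) loop is called \emph{direct} when it
#' coincides with at least one loop from the factor's own Hi-ChIP set under
#' harmonized 10 kb windows, and \emph{indirect} otherwise.  Micro-C anchors
#' called at 1 kb / 5 kb / 10 kb are slopped by 4500 / 2500 / 0 bp; the 1 kb
#' Hi-ChIP anchors are slopped by 4500 bp, so that every comparison uses
#' uniform 10 kb windows.  Coincidence is the both-ends pair overlap of
#' [pair_to_pair()].
#'
#' @param down_loops [loopset()] of downregulated loops; resolutions must be
#'   1000, 5000 or 10000 and every record's direction must be \code{"down"}.
#' @param hichip_loops [loopset()] of TF Hi-ChIP loops (1 kb anchors).
#' @param chromsizes Named vector of chromosome lengths.
#' @param window Harmonized window width in bp (default 10000).
#' @param slop_hichip Slop the Hi-ChIP anchors up to \code{window} too?
#'   (default \code{TRUE}; set \code{FALSE} to keep them at native width).
#' @return A data.frame with one row per input loop: \code{loop} (row
#'   index), \code{name}, \code{label} (\code{"direct"}/\code{"indirect"}),
#'   \code{n_matches} and \code{matches} (comma-separated Hi-ChIP record
#'   names); attribute \code{"window"} records the harmonized width.
#' @export
classify_direct_indirect <- function(down_loops, hichip_loops, chromsizes,
                                     window = 10000, slop_hichip = TRUE) {
  r <- down_loops$records
  if (nrow(r)) {
    bad <- which(r$direction != "down")
    if (length(bad))
      stop("direct/indirect classification is only defined for ",
           "downregulated loops (record ", r$name[bad[1]], " is '",
           r$direction[bad[1]], "')")
    bad <- which(!r$resolution %in% c(1000, 5000, 10000))
    if (length(bad))
      stop("unsupported resolution ", r$resolution[bad[1]],
           " on record ", r$name[bad[1]])
  }
  wide_mc <- harmonize_anchors(down_loops, window, chromsizes)
  wide_hc <- if (slop_hichip)
    harmonize_anchors(hichip_loops, window, chromsizes)
  else hichip_loops
  hits <- pair_to_pair(wide_mc, wide_hc)
  n <- nrow(r)
  n_matches <- tabulate(hits$a, nbins = n)
  match_names <- rep("", n)
  if (nrow(hits)) {
    nm <- split(hichip_loops$records$name[hits$b], hits$a)
    match_names[as.integer(names(nm))] <-
      vapply(nm, paste, character(1), collapse = ",")
  }
  out <- data.frame(loop = seq_len(n),
                    name = r$name,
                    label = ifelse(n_matches > 0, "direct", "indirect"),
                    n_matches = n_matches,
                    matches = match_names,
                    stringsAsFactors = FALSE)
  attr(out, "window") <- window
  out
}

#' Flag TF-bound loop anchors
#'
#' An anchor is bound when at least one ChIP peak overlaps it by >= 1 bp (at
#' native anchor width, no slop).  Used to retain only TF-bound anchors,
#' e.g. for downstream motif discovery.
#'
#' @param loops A [loopset()].
#' @param peaks Interval data.frame of ChIP peaks.
#' @return A list with \code{flags}: data.frame(loop, name, anchor1_bound,
#'   anchor2_bound); and \code{anchors}: the retained bound anchors as an
#'   interval data.frame (columns chrom/start/end plus \code{loop} and
#'   \code{side}).
#' @export
tf_bound_anchors <- function(loops, peaks) {
  r <- loops$records
  n <- nrow(r)
  if (n == 0 || nrow(peaks) == 0) {
    return(list(flags = data.frame(loop = seq_len(n), name = r$name,
                                   anchor1_bound = logical(n),
                                   anchor2_bound = logical(n)),
                anchors = loop_anchors(loops)[0, , drop = FALSE]))
  }
  validate_intervals(peaks)
  h1 <- interval_hits(loop_anchors(loops, 1), peaks)
  h2 <- interval_hits(loop_anchors(loops, 2), peaks)
  b1 <- seq_len(n) %in% h1$query
  b2 <- seq_len(n) %in% h2$query
  anchors <- rbind(loop_anchors(loops, 1)[b1, , drop = FALSE],
                   loop_anchors(loops, 2)[b2, , drop = FALSE])
  rownames(anchors) <- NULL
  list(flags = data.frame(loop = seq_len(n), name = r$name,
                          anchor1_bound = b1, anchor2_bound = b2),
       anchors = anchors)
}

#' ChIP peak participation in Hi-ChIP loops
#'
#' A peak participates when it overlaps either anchor of at least one
#' Hi-ChIP loop (native widths, >= 1 bp).  The headline quantity is the
#' percentage of peaks \emph{not} associated with any loop, reported to one
#' decimal.
#'
#' @param peaks Interval data.frame of ChIP peaks (non-empty).
#' @param hichip_loops [loopset()] of Hi-ChIP loops.
#' @return List with \code{n_in_loops}, \code{n_total},
#'   \code{percent_without} (one decimal, half-away-from-zero).
#' @export
peak_loop_participation <- function(peaks, hichip_loops) {
  if (nrow(peaks) == 0) stop("empty peak set")
  assoc <- pair_to_bed(hichip_loops, peaks, mode = "either")
  n_in <- length(unique(assoc$feature))
  list(n_in_loops = n_in,
       n_total = nrow(peaks),
       percent_without = percentage(nrow(peaks) - n_in, nrow(peaks), 1))
}
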