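#' Read a chromatin-state segmentation BED
#'
#' BED whose 4th column is an integer state label (1-9 in the standard
#' 9-state segmentation of the Drosophila S2 genome, where state 5 marks
#' dosage-compensated active exons on chrX and state 9 transcriptionally
#' silent intergenic/insulator euchromatin).
#'
#' @param path Path to the BED file.
#' @param n_states Number of states permitted (default 9).
#' @param chromsizes Optional named vector for coordinate validation.
#' @return Interval data.frame with an integer \code{state} column.
#' @export
read_state_bed <- function(path, n_states = 9, chromsizes = NULL) {
  x <- read_bed(path, chromsizes)
  st <- suppressWarnings(as.integer(x$name))
  if (anyNA(st))
    stop("non-integer state label at row ", which(is.na(st))[1])
  if (any(st < 1 | st > n_states))
    stop("state label out of 1..", n_states,
         " at row ", which(st < 1 | st > n_states)[1])
  x$state <- st
  x
}

# state label used for anchors covering no segment
STATE_UNASSIGNED <- 0L

check_state_resolution <- function(loops, force) {
  res <- unique(loops$records$resolution)
  res <- res[!is.na(res)]
  if (!force && length(res) && any(res != 1000))
    stop("chromatin-state annotation is restricted to 1 kb loop calls ",
         "(found resolution ", res[res != 1000][1],
         "); pass force = TRUE to override")
}

#' Annotate loops with chromatin states (either-anchor rule)
#'
#' A state is associated with a loop when either anchor overlaps a segment
#' of that state by >= 1 bp; a loop overlapping several states appears once
#' per distinct state.  State annotation is meaningful at anchor widths
#' comparable to segment size, so only 1 kb loop calls are accepted unless
#' \code{force = TRUE}.
#'
#' @param loops A [loopset()] at 1 kb resolution.
#' @param states State segmentation (see [read_state_bed()]).
#' @param force Allow non-1 kb records.
#' @return data.frame(loop, name, state), one row per distinct
#'   (loop, state), sorted.
#' @export
annotate_states_either <- function(loops, states, force = FALSE) {
  check_state_resolution(loops, force)
  stopifnot("state" %in% names(states))
  r <- loops$records
  h <- pair_to_bed(loops, states, mode = "either")
  out <- unique(data.frame(loop = h$loop, state = states$state[h$feature]))
  out <- out[order(out$loop, out$state), , drop = FALSE]
  rownames(out) <- NULL
  data.frame(loop = out$loop, name = r$name[out$loop], state = out$state)
}

#' Annotate loops with chromatin-state pairs
#'
#' Each anchor is independently annotated with the states it overlaps; the
#' loop's state pairs are the Cartesian product of the two anchor state
#' sets, stored unordered (min first) and deduplicated per loop.  Anchors
#' covering no segment contribute the reserved unassigned label (state 0).
#'
#' @inheritParams annotate_states_either
#' @return data.frame(loop, name, state1, state2) with
#'   \code{state1 <= state2}; 0 denotes an unassigned anchor.
#' @export
annotate_state_pairs <- function(loops, states, force = FALSE) {
  check_state_resolution(loops, force)
  stopifnot("state" %in% names(states))
  r <- loops$records
  n <- nrow(r)
  h1 <- interval_hits(loop_anchors(loops, 1), states)
  h2 <- interval_hits(loop_anchors(loops, 2), states)
  sets <- function(h) {
    out <- rep(list(STATE_UNASSIGNED), n)
    if (nrow(h)) {
      sp <- split(states$state[h$subject], h$query)
      out[as.integer(names(sp))] <- lapply(sp, function(s) sort(unique(s)))
    }
    out
  }
  s1 <- sets(h1); s2 <- sets(h2)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    g <- expand.grid(a = s1[[i]], b = s2[[i]])
    pr <- unique(data.frame(state1 = pmin(g$a, g$b),
                            state2 = pmax(g$a, g$b)))
    pr <- pr[order(pr$state1, pr$state2), , drop = FALSE]
    cbind(loop = i, pr)
  }))
  rownames(out) <- NULL
  data.frame(loop = out$loop, name = r$name[out$loop],
             state1 = out$state1, state2 = out$state2)
}

#' Derive dosage-compensated genes from the state segmentation
#'
#' Genes overlapping any state-5 segment (dosage-compensated active exons)
#' by >= 1 bp, deduplicated by gene name.
#'
#' @param states State segmentation (see [read_state_bed()]).
#' @param genes Interval data.frame of genes with unique names.
#' @return The subset of \code{genes} designated dosage-compensated, in
#'   gene-table order.
#' @export
dc_genes_from_states <- function(states, genes) {
  stopifnot("state" %in% names(states))
  if (anyNA(genes$name)) stop("genes must be named")
  if (anyDuplicated(genes$name))
    stop("duplicate gene name: ",
         genes$name[duplicated(genes$name)][1])
  s5 <- states[states$state == 5, , drop = FALSE]
  if (!nrow(s5)) return(genes[0, , drop = FALSE])
  h <- interval_hits(genes, s5)
  genes[sort(unique(h$query)), , drop = FALSE]
}

#' Associate dosage-compensated genes and HAS with loops
#'
#' Genes are assigned to a loop when they overlap its outer span (ospan
#' containment test); a loop is HAS-anchored when a High-Affinity Site
#' overlaps either anchor.  The summary reports, for both denominators
#' (all DC genes, and DC genes encompassed by any loop), the share
#' encompassed by HAS-anchored loops.
#'
#' @param loops A [loopset()].
#' @param dcg DC gene table (from [dc_genes_from_states()]).
#' @param has Interval data.frame of High-Affinity Sites.
#' @return List with \code{per_loop} (data.frame: loop, name, n_dc_genes,
#'   dc_genes, has_anchored) and \code{summary} (named list of counts and
#'   percentages).
#' @export
associate_dc_genes <- function(loops, dcg, has) {
  r <- loops$records
  n <- nrow(r)
  span_hits <- pair_to_bed(loops, dcg, mode = "ospan")
  has_hits <- pair_to_bed(loops, has, mode = "either")
  has_anchored <- seq_len(n) %in% has_hits$loop
  genes_by_loop <- rep("", n)
  if (nrow(span_hits)) {
    sp <- split(dcg$name[span_hits$feature], span_hits$loop)
    genes_by_loop[as.integer(names(sp))] <-
      vapply(sp, paste, character(1), collapse = ",")
  }
  per_loop <- data.frame(loop = seq_len(n), name = r$name,
                         n_dc_genes = tabulate(span_hits$loop, nbins = n),
                         dc_genes = genes_by_loop,
                         has_anchored = has_anchored)
  g_any <- unique(span_hits$feature)
  g_has <- unique(span_hits$feature[has_anchored[span_hits$loop]])
  n_dcg <- nrow(dcg)
  summary <- list(
    n_dc_genes = n_dcg,
    n_in_any_loop = length(g_any),
    n_in_has_loop = length(g_has),
    pct_in_any_loop = if (n_dcg) percentage(length(g_any), n_dcg, 1) else NA,
    pct_in_has_loop_of_all = if (n_dcg)
      percentage(length(g_has), n_dcg, 1) else NA,
    pct_in_has_loop_of_looped = if (length(g_any))
      percentage(length(g_has), length(g_any), 1) else NA)
  list(per_loop = per_loop, summary = summary)
}

#' Overlap of a loop set with roX2-RDD loops
#'
#' Both sets must first be normalized to uniform 5 kb bins (see
#' [normalize_bins()]); overlap is then the both-ends pair overlap at 5 kb.
#' Reports what share of the input set coincides with at least one RDD
#' loop, optionally after restricting the input set to HAS-anchored loops
#' or to chrX.
#'
#' @param loops Input [loopset()] (e.g. direct or indirect loops),
#'   normalized to 5 kb.
#' @param rdd roX2-RDD [loopset()], normalized to 5 kb.
#' @param site_filter \code{"none"}, \code{"has"} (either anchor overlaps a
#'   High-Affinity Site) or \code{"chrX"}.
#' @param has HAS interval table (required for \code{site_filter = "has"}).
#' @param resolution Expected uniform anchor width (default 5000).
#' @return List with \code{n_overlapping}, \code{n_total}, \code{percent}
#'   (one decimal).
#' @export
rdd_overlap <- function(loops, rdd, site_filter = c("none", "has", "chrX"),
                        has = NULL, resolution = 5000) {
  site_filter <- match.arg(site_filter)
  widths <- function(s) {
    r <- s$records
    c(r$end1 - r$start1, r$end2 - r$start2)
  }
  if (any(widths(loops) != resolution) || any(widths(rdd) != resolution))
    stop("inputs must be normalized to uniform ", resolution,
         " bp anchors (see normalize_bins)")
  keep <- switch(site_filter,
    none = rep(TRUE, nrow(loops$records)),
    chrX = loops$records$chrom == "chrX",
    has = {
      if (is.null(has)) stop("site_filter = 'has' needs a HAS table")
      seq_len(nrow(loops$records)) %in%
        pair_to_bed(loops, has, mode = "either")$loop
    })
  sub <- loops[keep]
  n_total <- nrow(sub$records)
  if (n_total == 0)
    return(list(n_overlapping = 0L, n_total = 0L, percent = NA_real_))
  hits <- pair_to_pair(sub, rdd)
  n_over <- length(unique(hits$a))
  list(n_overlapping = n_over, n_total = n_total,
       percent = percentage(n_over, n_total, 1))
}
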