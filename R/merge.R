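#' Filter a loop set on significance
#'
#' Retains records with \code{p_value < alpha} (strictly).  The applied
#' threshold is recorded in the returned set's metadata.
#'
#' @param loops A [loopset()]; every record must carry a p-value.
#' @param alpha Significance threshold in (0, 1]; the consensus differential
#'   sets use 0.01.
#' @return A loopset with the retained records.
#' @export
filter_significant <- function(loops, alpha = 0.01) {
  stopifnot(alpha > 0, alpha <= 1)
  r <- loops$records
  if (nrow(r) && anyNA(r$p_value))
    stop("missing p_value on record ",
         r$name[which(is.na(r$p_value))[1]])
  out <- loops[!nrow(r) | r$p_value < alpha]
  out$meta$alpha <- alpha
  out
}

# minimal union-find over 1..n
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges))
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  vapply(seq_len(n), find, integer(1))
}

#' Merge loop sets called at multiple resolutions into a consensus set
#'
#' Every anchor is symmetrically expanded to the coarsest input resolution,
#' loops are clustered by transitive both-ends overlap of the expanded
#' windows (connected components of the overlap graph), and each cluster is
#' represented by its finest-resolution member (ties: smallest p-value, then
#' leftmost coordinates).  The representative keeps its original, unexpanded
#' coordinates; the resolutions contributing to its cluster are recorded in
#' a \code{resolutions} column.
#'
#' @param loopsets List of single-resolution [loopset()] objects from the
#'   same comparison, at pairwise distinct resolutions.
#' @param chromsizes Named vector of chromosome lengths (for window
#'   clipping).
#' @return A consensus loopset; \code{meta$resolutions} lists the input
#'   resolutions and each record's \code{resolutions} column the ones
#'   present in its cluster.
#' @export
merge_multiresolution <- function(loopsets, chromsizes) {
  stopifnot(is.list(loopsets), length(loopsets) >= 1)
  res <- vapply(loopsets, function(s) {
    u <- unique(s$records$resolution)
    u <- u[!is.na(u)]
    if (length(u) > 1)
      stop("input set is not single-resolution: ",
           paste(u, collapse = ", "))
    if (length(u)) u else NA_real_
  }, numeric(1))
  if (anyNA(res)) stop("every input set needs a resolution")
  if (anyDuplicated(res)) stop("duplicate resolutions across inputs")
  cmp <- unique(unlist(lapply(loopsets, function(s) s$meta$comparison)))
  if (length(cmp) > 1)
    stop("inputs belong to different comparisons: ",
         paste(cmp, collapse = ", "))
  combined <- do.call(rbind, lapply(loopsets, function(s) {
    r <- s$records
    r[intersect(names(r), c("chrom", "start1", "end1", "start2", "end2",
                            "name", "resolution", "direction", "p_value",
                            "effect"))]
  }))
  pooled <- loopset(combined,
                    meta = list(comparison = if (length(cmp)) cmp else NULL))
  n <- nrow(pooled$records)
  if (n == 0) {
    pooled$meta$resolutions <- sort(res)
    return(pooled)
  }
  coarse <- max(res)
  wide <- harmonize_anchors(pooled, coarse, chromsizes)
  m <- pair_to_pair(wide, wide)
  m <- m[m$a < m$b, , drop = FALSE]
  comp <- uf_components(n, as.matrix(m[c("a", "b")]))
  r <- pooled$records
  # representative: finest resolution, then smallest p, then leftmost
  o <- order(comp, r$resolution, r$p_value, r$chrom, r$start1, r$start2,
             method = "radix", na.last = TRUE)
  rep_rows <- o[!duplicated(comp[o])]
  out <- r[rep_rows, , drop = FALSE]
  out$resolutions <- vapply(comp[rep_rows], function(cc)
    paste(sort(unique(r$resolution[comp == cc])), collapse = ","),
    character(1))
  out <- out[order(out$chrom, out$start1, out$start2, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(list(records = out,
                 meta = c(pooled$meta, list(resolutions = sort(res)))),
            class = "loopset")
}

#' Normalize loop anchors to a uniform bin size
#'
#' Replaces each anchor by the fixed-resolution grid bin (grid aligned at
#' coordinate 0) containing its midpoint.  Needed before comparing
#' variable-anchor loop sets (such as roX2-RDD calls) with fixed-resolution
#' calls; the uniform resolution used for that integration is 5 kb.  Records
#' whose two anchors collapse into the same bin are dropped, and duplicates
#' arising from the snapping are collapsed; both counts are reported as
#' attributes.
#'
#' @param loops A [loopset()].
#' @param target_resolution Bin size in bp (> 0).
#' @param chromsizes Optional named vector; bins are clipped to chromosome
#'   ends when given.
#' @return A loopset at the target resolution with attributes
#'   \code{"n_dropped"} (same-bin collapses) and \code{"n_duplicates"}
#'   (records merged by deduplication).
#' @export
normalize_bins <- function(loops, target_resolution, chromsizes = NULL) {
  stopifnot(target_resolution > 0)
  r <- loops$records
  if (!nrow(r)) {
    out <- loops
    attr(out, "n_dropped") <- 0L
    attr(out, "n_duplicates") <- 0L
    return(out)
  }
  bin <- function(mid) floor(mid / target_resolution) * target_resolution
  b1 <- bin((r$start1 + r$end1) / 2)
  b2 <- bin((r$start2 + r$end2) / 2)
  collide <- b1 == b2
  n_dropped <- sum(collide)
  r <- r[!collide, , drop = FALSE]
  b1 <- b1[!collide]; b2 <- b2[!collide]
  r$start1 <- b1; r$end1 <- b1 + target_resolution
  r$start2 <- b2; r$end2 <- b2 + target_resolution
  if (!is.null(chromsizes)) {
    lim <- unname(chromsizes[r$chrom])
    r$end1 <- pmin(r$end1, lim)
    r$end2 <- pmin(r$end2, lim)
  }
  r$resolution <- rep(target_resolution, nrow(r))
  n_before <- nrow(r)
  out <- loopset(r, meta = c(loops$meta,
                             list(normalized_resolution = target_resolution)))
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_duplicates") <- n_before - nrow(out$records)
  out
}
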