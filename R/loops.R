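#' Construct a loop set
#'
#' A loop set holds cis anchor pairs (chromatin loops) together with the
#' comparison metadata they came from.  Records are canonicalized so that
#' \code{start1 <= start2} and exact coordinate duplicates are collapsed,
#' keeping the record with the smallest p-value.
#'
#' @param records A data.frame with columns \code{chrom}, \code{start1},
#'   \code{end1}, \code{start2}, \code{end2} and optionally \code{name},
#'   \code{resolution}, \code{direction} (\code{"up"}, \code{"down"},
#'   \code{"none"}), \code{p_value}, \code{effect}.
#' @param meta Named list of provenance labels (condition, comparison,
#'   resolutions present, significance threshold applied, ...).
#' @param dedup Collapse exact coordinate duplicates? (default \code{TRUE})
#' @param chrom2 Optional second-anchor chromosome vector; must equal
#'   \code{chrom} (trans pairs are rejected).
#' @return An object of class \code{"loopset"}: a list with elements
#'   \code{records} (data.frame) and \code{meta} (list).
#' @export
loopset <- function(records, meta = list(), dedup = TRUE, chrom2 = NULL) {
  stopifnot(is.data.frame(records))
  r <- records
  if (!is.null(chrom2) && nrow(r)) {
    bad <- which(as.character(chrom2) != as.character(r$chrom))
    if (length(bad))
      stop("trans pair at row ", bad[1],
           " (", r$chrom[bad[1]], " / ", chrom2[bad[1]], ")")
  }
  for (col in c("chrom", "start1", "end1", "start2", "end2"))
    if (!col %in% names(r)) stop("records lack column ", col)
  defaults <- list(name = NA_character_, resolution = NA_real_,
                   direction = "none", p_value = NA_real_, effect = NA_real_)
  for (col in names(defaults))
    if (!col %in% names(r)) r[[col]] <- rep(defaults[[col]], nrow(r))
  canon <- c("chrom", "start1", "end1", "start2", "end2", "name",
             "resolution", "direction", "p_value", "effect")
  r <- r[c(canon, setdiff(names(r), canon))]
  r$chrom <- as.character(r$chrom)
  if (nrow(r)) {
    if (any(r$start1 >= r$end1) || any(r$start2 >= r$end2))
      stop("degenerate anchor (start >= end)")
    if (any(r$start1 < 0) || any(r$start2 < 0))
      stop("negative anchor coordinate")
    if (!all(r$direction %in% c("up", "down", "none")))
      stop("direction must be 'up', 'down' or 'none'")
    swap <- r$start2 < r$start1 |
      (r$start2 == r$start1 & r$end2 < r$end1)
    if (any(swap)) {
      tmp <- r[swap, c("start1", "end1")]
      r[swap, c("start1", "end1")] <- r[swap, c("start2", "end2")]
      r[swap, c("start2", "end2")] <- tmp
    }
    if (dedup) {
      key <- paste(r$chrom, r$start1, r$end1, r$start2, r$end2)
      o <- order(key, r$p_value, method = "radix", na.last = TRUE)
      r <- r[o, , drop = FALSE]
      r <- r[!duplicated(key[o]), , drop = FALSE]
      r <- r[order(r$chrom, r$start1, r$start2, r$end1, r$end2,
                   method = "radix"), , drop = FALSE]
    }
    rownames(r) <- NULL
    if (all(is.na(r$name)))
      r$name <- sprintf("loop_%05d", seq_len(nrow(r)))
  }
  structure(list(records = r, meta = meta), class = "loopset")
}

#' @export
print.loopset <- function(x, ...) {
  cat("<loopset> ", nrow(x$records), " loops", sep = "")
  res <- sort(unique(x$records$resolution))
  if (length(res) && !all(is.na(res)))
    cat(" | resolutions:", paste(res, collapse = "/"))
  if (!is.null(x$meta$comparison)) cat(" |", x$meta$comparison)
  cat("\n")
  if (nrow(x$records)) print(utils::head(x$records, 6))
  invisible(x)
}

#' @export
length.loopset <- function(x) nrow(x$records)

#' @export
as.data.frame.loopset <- function(x, ...) x$records

#' Subset a loop set
#' @param x A loopset.
#' @param i Row index/logical vector into the records.
#' @param ... Ignored.
#' @return A loopset with the selected records and unchanged meta.
#' @export
`[.loopset` <- function(x, i, ...) {
  structure(list(records = x$records[i, , drop = FALSE], meta = x$meta),
            class = "loopset")
}

#' Read a BEDPE file into a loop set
#'
#' Standard 6+-column tab-separated BEDPE (\code{chrom1 start1 end1 chrom2
#' start2 end2 [name score strand1 strand2 ...]}), \code{"."} for missing.
#' Additional numeric columns can be mapped onto the p-value and signed
#' effect fields by 1-based position.
#'
#' @param path Path to a BEDPE file.
#' @param default_resolution Resolution (bin size, bp) assigned to every
#'   record when the file carries none.
#' @param p_value_col,effect_col,direction_col Optional 1-based column
#'   indices holding the p-value, signed fold-change and direction
#'   (up/down).
#' @param chromsizes Optional named vector for coordinate validation.
#' @param meta Metadata list stored on the returned loopset.
#' @return A [loopset()] with canonicalized, deduplicated records.  Trans
#'   rows (different anchor chromosomes) are an error.
#' @export
read_bedpe <- function(path, default_resolution = NA_real_,
                       p_value_col = NULL, effect_col = NULL,
                       direction_col = NULL, chromsizes = NULL,
                       meta = list()) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(loopset(data.frame(chrom = character(), start1 = numeric(),
                              end1 = numeric(), start2 = numeric(),
                              end2 = numeric()), meta = meta))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("fewer than 6 columns at line ", lineno[which(nf < 6)[1]],
         " of ", path)
  get_col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else ".", character(1))
  num <- function(i, what) {
    v <- get_col(i)
    out <- suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
    bad <- which(!is.na(v) & v != "." & is.na(out))
    if (length(bad))
      stop("unparseable ", what, " at line ", lineno[bad[1]], " of ", path)
    out
  }
  chrom1 <- get_col(1); chrom2 <- get_col(4)
  bad <- which(chrom1 != chrom2)
  if (length(bad))
    stop("trans pair at line ", lineno[bad[1]], " of ", path,
         " (", chrom1[bad[1]], " / ", chrom2[bad[1]], ")")
  r <- data.frame(chrom = chrom1,
                  start1 = num(2, "start1"), end1 = num(3, "end1"),
                  start2 = num(5, "start2"), end2 = num(6, "end2"),
                  stringsAsFactors = FALSE)
  nm <- get_col(7)
  r$name <- ifelse(nm == "." | nm == "", NA, nm)
  r$resolution <- default_resolution
  r$direction <- "none"
  r$p_value <- NA_real_
  r$effect <- NA_real_
  if (!is.null(p_value_col)) r$p_value <- num(p_value_col, "p-value")
  if (!is.null(effect_col)) r$effect <- num(effect_col, "effect")
  if (!is.null(direction_col)) {
    d <- get_col(direction_col)
    if (!all(d %in% c("up", "down", "none")))
      stop("bad direction value at line ",
           lineno[which(!d %in% c("up", "down", "none"))[1]], " of ", path)
    r$direction <- d
  }
  if (!is.null(chromsizes)) {
    validate_intervals(data.frame(chrom = r$chrom, start = r$start1,
                                  end = r$end1), chromsizes)
    validate_intervals(data.frame(chrom = r$chrom, start = r$start2,
                                  end = r$end2), chromsizes)
  }
  loopset(r, meta = meta)
}

#' Write a loop set as BEDPE
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name resolution direction
#' p_value effect.  Rows are emitted in deterministic (chrom, start1,
#' start2) order.
#'
#' @param loops A loopset.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  r <- loops$records
  if (nrow(r))
    r <- r[order(r$chrom, r$start1, r$start2, r$end1, r$end2,
                 method = "radix"), , drop = FALSE]
  dot <- function(v) ifelse(is.na(v), ".", as.character(v))
  out <- data.frame(r$chrom, format_bp(r$start1), format_bp(r$end1),
                    r$chrom, format_bp(r$start2), format_bp(r$end2),
                    dot(r$name), dot(r$resolution), dot(r$direction),
                    dot(r$p_value), dot(r$effect))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Loop size
#'
#' Distance in bp between the two anchor midpoints (the default) or the
#' outer span \code{end2 - start1}.  Midpoint distance is insensitive to the
#' calling resolution; the outer-span alternative adds one bin width and is
#' provided for sensitivity checks.
#'
#' @param loops A loopset.
#' @param method \code{"midpoint"} (default) or \code{"ospan"}.
#' @return Numeric vector of spans in bp (one per record), always >= 0.
#' @export
loop_span <- function(loops, method = c("midpoint", "ospan")) {
  method <- match.arg(method)
  r <- loops$records
  if (method == "midpoint")
    (r$start2 + r$end2) / 2 - (r$start1 + r$end1) / 2
  else
    r$end2 - r$start1
}

# anchors of a loopset as an interval table; which = 1, 2 or "both"
# ("both" stacks anchor1 rows then anchor2 rows, loop index in $loop)
loop_anchors <- function(loops, which = "both") {
  r <- loops$records
  a1 <- data.frame(chrom = r$chrom, start = r$start1, end = r$end1,
                   loop = seq_len(nrow(r)), side = 1L)
  a2 <- data.frame(chrom = r$chrom, start = r$start2, end = r$end2,
                   loop = seq_len(nrow(r)), side = 2L)
  if (identical(which, 1) || identical(which, 1L)) a1
  else if (identical(which, 2) || identical(which, 2L)) a2
  else rbind(a1, a2)
}
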