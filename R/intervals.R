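#' Construct a table of genomic intervals
#'
#' Intervals are the atom of every BED-side feature handled by the package
#' (TADs, High-Affinity Sites, ChIP peaks, genes, chromatin-state segments).
#' Coordinates follow the BED convention: 0-based, half-open \code{[start,
#' end)}; an overlap means at least one shared base pair.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer-like vector of 0-based inclusive start positions.
#' @param end Integer-like vector of exclusive end positions.
#' @param name Optional labels (recycled; default \code{NA}).
#' @param score Optional numeric scores.
#' @param strand Optional strand, one of \code{"+"}, \code{"-"}, \code{"."}.
#' @param chromsizes Optional named numeric vector of chromosome lengths; when
#'   supplied, every \code{chrom} must be present and \code{end} must not
#'   exceed the chromosome length.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score}, \code{strand}.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".",
                              chromsizes = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df, chromsizes = chromsizes)
  df
}

#' Validate an interval table
#'
#' @param x A data.frame with at least \code{chrom}, \code{start}, \code{end}.
#' @param chromsizes Optional named vector of chromosome lengths.
#' @return \code{x}, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(x, chromsizes = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    stop("non-finite interval coordinates")
  if (any(x$start < 0))
    stop("negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("start >= end at row ", bad[1])
  if (!is.null(chromsizes)) {
    unknown <- setdiff(unique(x$chrom), names(chromsizes))
    if (length(unknown))
      stop("chromosome(s) absent from chromsizes: ",
           paste(unknown, collapse = ", "))
    over <- which(x$end > chromsizes[x$chrom])
    if (length(over))
      stop("interval end exceeds chromosome length at row ", over[1])
  }
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chromsizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (anyDuplicated(df$chrom))
    stop("duplicate chromosome name in ", path)
  if (any(df$length <= 0))
    stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Write a chrom.sizes file
#' @param chromsizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_chromsizes <- function(chromsizes, path) {
  utils::write.table(data.frame(names(chromsizes),
                                format_bp(chromsizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# integers-as-text without scientific notation
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BED file
#'
#' Accepts 3-6 column BED; \code{track}, \code{browser} and \code{#} comment
#' lines are skipped.  Missing fields are returned as \code{NA} (\code{"."}
#' in the file maps to \code{NA} for name/score).
#'
#' @param path Path to a BED file.
#' @param chromsizes Optional named vector; when given, intervals are
#'   validated against it.
#' @return Interval data.frame (see [genomic_intervals()]); input order is
#'   preserved.
#' @export
read_bed <- function(path, chromsizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("fewer than 3 columns at line ", lineno[which(nf < 3)[1]],
         " of ", path)
  get_col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else ".", character(1))
  num_or_na <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed coordinates at line ", lineno[bad[1]], " of ", path)
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", lineno[bad[1]], " of ", path)
  nm <- get_col(4)
  df <- genomic_intervals(get_col(1), start, end,
                          name = ifelse(nm == ".", NA, nm),
                          score = num_or_na(get_col(5)),
                          strand = get_col(6),
                          chromsizes = chromsizes)
  df
}

#' Write intervals as BED
#'
#' Emits deterministic ordering (chrom, start, end) when \code{sort = TRUE}.
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @param sort Sort rows by (chrom, start, end) before writing?
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path, sort = TRUE) {
  validate_intervals(x)
  if (!"name" %in% names(x)) x$name <- NA_character_
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"strand" %in% names(x)) x$strand <- "."
  if (sort && nrow(x))
    x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out <- data.frame(x$chrom, format_bp(x$start), format_bp(x$end),
                    ifelse(is.na(x$name), ".", x$name),
                    ifelse(is.na(x$score), ".", as.character(x$score)),
                    ifelse(is.na(x$strand), ".", x$strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Symmetrically extend intervals (bedtools-style slop)
#'
#' Extends every interval by \code{amount} bp on both sides, clipping at 0
#' and at the chromosome length.  Used to harmonize loop anchors called at
#' different resolutions onto uniform windows.
#'
#' @param x Interval data.frame.
#' @param amount Non-negative extension in bp (scalar or per-row vector).
#' @param chromsizes Named vector of chromosome lengths (required for
#'   right-side clipping).
#' @return The extended interval table; the number of rows whose bounds were
#'   clipped is attached as attribute \code{"n_clipped"}.
#' @export
slop_intervals <- function(x, amount, chromsizes) {
  validate_intervals(x)
  if (any(amount < 0)) stop("slop amount must be >= 0")
  unknown <- setdiff(unique(x$chrom), names(chromsizes))
  if (length(unknown))
    stop("chromosome(s) absent from chromsizes: ",
         paste(unknown, collapse = ", "))
  lo <- x$start - amount
  hi <- x$end + amount
  lim <- unname(chromsizes[x$chrom])
  clipped <- sum(lo < 0 | hi > lim)
  x$start <- pmax(0, lo)
  x$end <- pmin(lim, hi)
  attr(x, "n_clipped") <- clipped
  x
}

# Hits between two interval tables (>=1 bp shared), via IRanges.
# Returns data.frame(query, subject) of row indices.
interval_hits <- function(a, b) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(query = integer(), subject = integer()))
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
  # disjoint chromosome sets are a legitimate no-hit case, not a warning
  h <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L,
                                                    ignore.strand = TRUE))
  data.frame(query = S4Vectors::queryHits(h),
             subject = S4Vectors::subjectHits(h))
}
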