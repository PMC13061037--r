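#' Construct a per-chromosome contact matrix
#'
#' Symmetric binned matrix of (balanced) contact values for one chromosome
#' at a fixed resolution.  Bin i covers \code{[(i-1)*resolution,
#' i*resolution)}.
#'
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @param mat Square numeric matrix; must be symmetric within 1e-9 and
#'   non-negative.
#' @param chrom_length Optional chromosome length; when given,
#'   \code{nrow(mat)} must equal \code{ceiling(chrom_length / resolution)}.
#' @return Object of class \code{"contact_matrix"}.
#' @export
contact_matrix <- function(chrom, resolution, mat, chrom_length = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), resolution > 0)
  if (any(mat < 0)) stop("negative contact value")
  asym <- max(abs(mat - t(mat)))
  if (asym > 1e-9) stop("matrix asymmetry ", signif(asym, 3),
                        " exceeds tolerance")
  if (!is.null(chrom_length) &&
      nrow(mat) != ceiling(chrom_length / resolution))
    stop("bin count does not match ceiling(chrom_length / resolution)")
  structure(list(chrom = chrom, resolution = resolution, mat = mat),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", x$chrom, ": ", nrow(x$mat), " x ", nrow(x$mat),
      " bins at ", x$resolution, " bp\n", sep = "")
  invisible(x)
}

#' Read a dense contact matrix TSV
#'
#' Dense symmetric text format: a header line \code{"# chrom=<name>
#' resolution=<bp>"} followed by the tab-separated matrix.  Slight
#' asymmetry (up to 1e-6, e.g. from truncated text output) is repaired by
#' averaging with the transpose; larger asymmetry is an error.
#'
#' @param path Path to the TSV.
#' @param resolution Optional expected resolution; mismatch is an error.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, resolution = NULL) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("^#\\s*chrom=(\\S+)\\s+resolution=(\\d+)", header))[[1]]
  if (length(m) != 3)
    stop("missing '# chrom=... resolution=...' header in ", path)
  chrom <- m[2]
  res <- as.numeric(m[3])
  if (!is.null(resolution) && res != resolution)
    stop("resolution mismatch: file has ", res, ", requested ", resolution)
  mat <- as.matrix(utils::read.table(path, sep = "\t", skip = 1,
                                     header = FALSE))
  dimnames(mat) <- NULL
  asym <- max(abs(mat - t(mat)))
  if (asym > 1e-6) stop("matrix asymmetry ", signif(asym, 3),
                        " exceeds tolerance in ", path)
  contact_matrix(chrom, res, (mat + t(mat)) / 2)
}

#' Write a contact matrix as dense TSV
#' @param cm A [contact_matrix()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s resolution=%s", cm$chrom,
                     format_bp(cm$resolution)), con)
  utils::write.table(format(cm$mat, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Expected contact by distance
#'
#' Per-separation summary of the contact signal: for each separation s (in
#' bins) a location estimate over all diagonal-s entries.  The default is
#' the per-diagonal median, which tracks the distance-decay background
#' exactly when loop pixels occupy a minority of a diagonal; the
#' per-diagonal mean is available but is inflated by enriched pixels when
#' the matrix is small relative to the number of loops.
#'
#' @param cm A [contact_matrix()].
#' @param stat \code{"median"} (default) or \code{"mean"}.
#' @return Numeric vector of length \code{nbins}; element s+1 is the
#'   expected value at separation s.
#' @export
expected_by_distance <- function(cm, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  m <- cm$mat
  n <- nrow(m)
  f <- if (stat == "median") stats::median else mean
  vapply(0:(n - 1), function(s) {
    i <- seq_len(n - s)
    f(m[cbind(i, i + s)])
  }, numeric(1))
}

# shared window-extraction core; centers = 2-column matrix of bin indices
extract_windows <- function(cm, centers, flank, normalize, expected_stat) {
  n <- nrow(cm$mat)
  exp_vec <- if (normalize == "expected")
    expected_by_distance(cm, expected_stat)
  else NULL
  windows <- list()
  prov <- list()
  skipped <- 0L
  for (k in seq_len(nrow(centers))) {
    bi <- centers[k, 1]; bj <- centers[k, 2]
    if (bi - flank < 1 || bj - flank < 1 ||
        bi + flank > n || bj + flank > n) {
      skipped <- skipped + 1L
      next
    }
    w <- cm$mat[(bi - flank):(bi + flank), (bj - flank):(bj + flank),
                drop = FALSE]
    if (!is.null(exp_vec)) {
      # per-pixel separation: |row_bin - col_bin|
      sep_abs <- abs(outer((bi - flank):(bi + flank),
                           (bj - flank):(bj + flank), "-"))
      e <- matrix(exp_vec[sep_abs + 1], nrow(w), ncol(w))
      if (any(e <= 0)) stop("non-positive expected value inside window")
      w <- w / e
    }
    windows[[length(windows) + 1]] <- w
    prov[[length(prov) + 1]] <- c(bin1 = bi, bin2 = bj,
                                  separation = abs(bj - bi))
  }
  if (!length(windows))
    stop("no usable windows (", skipped, " skipped at matrix edges)")
  mean_window <- Reduce(`+`, windows) / length(windows)
  structure(list(mean = mean_window, windows = windows,
                 provenance = as.data.frame(do.call(rbind, prov)),
                 flank = flank, n_skipped = skipped,
                 normalize = normalize),
            class = "window_stack")
}

#' @export
print.window_stack <- function(x, ...) {
  cat("<window_stack> ", length(x$windows), " windows of ",
      2 * x$flank + 1, " x ", 2 * x$flank + 1, " bins (",
      x$n_skipped, " skipped)\n", sep = "")
  invisible(x)
}

#' Aggregate pile-up over pairs of sites
#'
#' For every unordered pair of sites on the matrix chromosome whose midpoint
#' separation lies in \code{[min_sep, max_sep]} bp, extracts the
#' \code{(2*flank+1)}-square window centered at the pair's (bin, bin) pixel;
#' windows crossing the matrix edge are skipped (never padded).  With
#' \code{normalize = "expected"} each pixel is divided by the expected value
#' at its own separation.  The aggregate plot of the mean window is the
#' classic APA readout over a site class (e.g. High-Affinity Sites versus
#' random GA-repeats).
#'
#' @param cm A [contact_matrix()].
#' @param sites Interval data.frame; only rows on \code{cm$chrom} are used.
#' @param flank Flank in bins (>= 1).
#' @param min_sep,max_sep Midpoint separation band in bp.
#' @param normalize \code{"expected"} or \code{"none"}.
#' @param expected_stat Passed to [expected_by_distance()].
#' @return A \code{window_stack}: list with \code{mean} (mean window),
#'   \code{windows}, \code{provenance}, \code{n_skipped}.
#' @export
pileup_sites <- function(cm, sites, flank = 10, min_sep = 0,
                         max_sep = Inf, normalize = c("expected", "none"),
                         expected_stat = "median") {
  normalize <- match.arg(normalize)
  stopifnot(flank >= 1, min_sep < max_sep)
  s <- sites[sites$chrom == cm$chrom, , drop = FALSE]
  mid <- (s$start + s$end) / 2
  bins <- floor(mid / cm$resolution) + 1
  pairs <- which(outer(mid, mid, function(a, b) {
    d <- b - a
    d >= min_sep & d <= max_sep
  }) & upper.tri(matrix(0, length(mid), length(mid))), arr.ind = TRUE)
  if (!nrow(pairs))
    stop("no site pairs with separation in [", min_sep, ", ", max_sep,
         "] bp on ", cm$chrom)
  centers <- cbind(bins[pairs[, 1]], bins[pairs[, 2]])
  extract_windows(cm, centers, flank, normalize, expected_stat)
}

#' Aggregate pile-up over a loop set
#'
#' As [pileup_sites()] but with one window per loop, centered at the pixel
#' (anchor-1 midpoint bin, anchor-2 midpoint bin); the central pixel is the
#' bin pair containing the called chromatin contact.
#'
#' @param cm A [contact_matrix()].
#' @param loops A [loopset()]; only records on \code{cm$chrom} are used.
#' @inheritParams pileup_sites
#' @return A \code{window_stack}.
#' @export
pileup_loops <- function(cm, loops, flank = 10,
                         normalize = c("expected", "none"),
                         expected_stat = "median") {
  normalize <- match.arg(normalize)
  stopifnot(flank >= 1)
  r <- loops$records[loops$records$chrom == cm$chrom, , drop = FALSE]
  if (!nrow(r)) stop("no loops on ", cm$chrom)
  b1 <- floor((r$start1 + r$end1) / 2 / cm$resolution) + 1
  b2 <- floor((r$start2 + r$end2) / 2 / cm$resolution) + 1
  extract_windows(cm, cbind(b1, b2), flank, normalize, expected_stat)
}

#' Central-pixel enrichment score of a mean APA window
#'
#' Ratio of the central pixel to the mean of the four corner blocks (the
#' least loop-contaminated region of the window), plus its natural log.
#'
#' @param mean_window Square numeric matrix of odd side length (the
#'   \code{$mean} of a pile-up), or a \code{window_stack}.
#' @param corner_block Corner block side in bins (default 3); the window
#'   side must be at least \code{2 * corner_block + 1}.
#' @return List with \code{ratio} and \code{log_ratio}.
#' @export
enrichment_score <- function(mean_window, corner_block = 3) {
  if (inherits(mean_window, "window_stack"))
    mean_window <- mean_window$mean
  n <- nrow(mean_window)
  stopifnot(n == ncol(mean_window), n %% 2 == 1)
  if (n < 2 * corner_block + 1)
    stop("window side ", n, " too small for corner blocks of ",
         corner_block)
  ctr <- (n + 1) / 2
  lo <- seq_len(corner_block)
  hi <- seq(n - corner_block + 1, n)
  bg <- mean(c(mean_window[lo, lo], mean_window[lo, hi],
               mean_window[hi, lo], mean_window[hi, hi]))
  if (bg <= 0) stop("zero background")
  ratio <- mean_window[ctr, ctr] / bg
  list(ratio = ratio, log_ratio = log(ratio))
}
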