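#' Configuration for the synthetic study generator
#'
#' Defines the desk-scale study conditions emulated by [simulate_study()]:
#' two 2 Mb chromosomes (an X and an autosome), four differential loop sets
#' (two factors x up/down) called at 1/5/10 kb, factor-specific Hi-ChIP
#' loops and ChIP peaks for the control condition, a 9-state chromatin
#' tiling with state 5 restricted to chrX, genes with a configured
#' dosage-compensated subset, High-Affinity Sites on chrX, variable-anchor
#' RDD loops with a planted overlap fraction, TAD tilings, and binned
#' contact matrices with power-law distance decay plus planted loop
#' enrichments.
#'
#' Geometry is ambiguity-free by construction: anchors sit on lattice sites
#' spaced at least 11 kb apart, direct loops receive a Hi-ChIP twin
#' jittered by less than 4.5 kb plus a ChIP peak inside an anchor, and
#' indirect loops keep at least 15 kb clear of any Hi-ChIP anchor or peak,
#' so that direct/indirect recovery is exact under the harmonized 10 kb
#' windows.  \code{hard = TRUE} shrinks that separation for stress testing.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param chromsizes Named lengths of the simulated chromosomes.
#' @param n_loops_per_resolution Significant loops per comparison per
#'   resolution (default 100, i.e. 300 down-loops per factor).
#' @param resolutions Calling resolutions in bp.
#' @param fraction_direct Fraction of down-loops that are direct.
#' @param n_decoys Non-significant decoy loops per comparison (p >= 0.02).
#' @param n_has High-Affinity Sites on chrX.
#' @param n_genes Genes (split evenly between chromosomes).
#' @param fraction_dc Fraction of chrX genes planted onto state-5 segments.
#' @param n_orphan_peaks ChIP peaks per factor placed away from any Hi-ChIP
#'   anchor.
#' @param peak_width ChIP peak width in bp.
#' @param rdd_overlap_fraction Fraction of chrX direct loops given an RDD
#'   partner loop.
#' @param n_rdd_background Additional chrX RDD loops matching no
#'   differential loop.
#' @param rdd_anchor_width Range of variable RDD anchor widths in bp.
#' @param decay_alpha Distance-decay exponent of the contact model
#'   \code{base * (1 + |i - j|)^-alpha}.
#' @param base_contacts Contact level at zero separation.
#' @param loop_enrichment Multiplicative enrichment planted at loop pixels
#'   (>= 1).
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param matrix_resolution Contact-matrix bin size in bp.
#' @param margin Keep-out distance from chromosome ends for loop anchors.
#' @param pitch Range of lattice site spacing in bp (minimum > 10 kb).
#' @param hard Shrink the direct/indirect exclusion radius (stress mode).
#' @return A list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(seed = 1,
                             chromsizes = c(chrX = 2e6, chr2L = 2e6),
                             n_loops_per_resolution = 100,
                             resolutions = c(1000, 5000, 10000),
                             fraction_direct = 0.4,
                             n_decoys = 30,
                             n_has = 24,
                             n_genes = 200,
                             fraction_dc = 0.4,
                             n_orphan_peaks = 60,
                             peak_width = 400,
                             rdd_overlap_fraction = 0.2,
                             n_rdd_background = 60,
                             rdd_anchor_width = c(2000, 12000),
                             decay_alpha = 0.85,
                             base_contacts = 1000,
                             loop_enrichment = 3,
                             noise = c("none", "poisson"),
                             matrix_resolution = 5000,
                             margin = 50000,
                             pitch = c(11000, 11800),
                             hard = FALSE) {
  noise <- match.arg(noise)
  stopifnot(fraction_direct >= 0, fraction_direct <= 1,
            fraction_dc >= 0, fraction_dc <= 1,
            rdd_overlap_fraction >= 0, rdd_overlap_fraction <= 1,
            loop_enrichment >= 1, decay_alpha > 0,
            pitch[1] > 10000, all(chromsizes > 0))
  structure(as.list(environment()), class = "synthetic_config")
}

# lattice of anchor sites, pitch drawn per gap
make_sites <- function(chromsizes, margin, pitch) {
  out <- lapply(names(chromsizes), function(ch) {
    len <- chromsizes[[ch]]
    pos <- numeric(0)
    p <- margin
    while (p <= len - margin) {
      pos <- c(pos, p)
      p <- p + round(stats::runif(1, pitch[1], pitch[2]))
    }
    data.frame(chrom = ch, pos = pos)
  })
  do.call(rbind, out)
}

# cis edges (site index pairs) walked along the lattice
build_edges <- function(sites, start_row, quota,
                        kprobs = c(0.7, 0.2, 0.1)) {
  n <- nrow(sites)
  j <- start_row
  out <- matrix(NA_integer_, quota, 2)
  got <- 0L
  while (got < quota) {
    if (j >= n)
      stop("infeasible placement: too many loops for the genome size")
    k <- sample.int(3, 1, prob = kprobs)
    if (j + k <= n && sites$chrom[j] == sites$chrom[j + k]) {
      got <- got + 1L
      out[got, ] <- c(j, j + k)
    }
    j <- j + 1L
  }
  list(edges = out, reach = max(out[, 2]))
}

# brute-force anchor -> state-set scan (generator-side oracle, kept
# independent of the package's IRanges-backed overlap path)
brute_anchor_states <- function(chrom, start, end, states) {
  hit <- states$chrom == chrom & states$start < end & start < states$end
  s <- sort(unique(states$state[hit]))
  if (!length(s)) STATE_UNASSIGNED else s
}

#' Generate a synthetic study with recorded ground truth
#'
#' Writes every input the pipeline consumes (chrom.sizes, per-resolution
#' differential BEDPE, Hi-ChIP BEDPE, ChIP peak BED, 9-state BED, gene BED,
#' HAS BED, TAD BEDs, RDD BEDPE, dense contact-matrix TSVs) into
#' \code{dir}, plus a \code{truth.json} tracing every planted feature.
#' Deterministic given \code{config$seed}.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with \code{dir}, \code{files} (named paths)
#'   and \code{truth} (the ground-truth list, also written as JSON).
#' @export
simulate_study <- function(config = synthetic_config(), dir = tempfile("sim_")) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  path <- function(f) file.path(dir, f)
  cs <- cfg$chromsizes
  files$chromsizes <- write_chromsizes(cs, path("chrom.sizes"))

  tfs <- c("clamp", "gaf")
  n_res <- length(cfg$resolutions)
  n_per_cmp <- cfg$n_loops_per_resolution * n_res
  n_direct <- round(cfg$fraction_direct * n_per_cmp)
  gap_sites <- if (cfg$hard) 1L else 2L
  jit_max <- if (cfg$hard) 4400 else 4000

  truth <- list(seed = cfg$seed,
                n_per_comparison = n_per_cmp,
                fraction_direct = cfg$fraction_direct,
                loop_enrichment = cfg$loop_enrichment,
                comparisons = list())
  loops_all <- list()     # per comparison: records df with site columns
  hichip <- list()
  peaks <- list()

  for (tf in tfs) {
    for (dirn in c("down", "up")) {
      cmp <- paste(tf, dirn, sep = "_")
      # quotas split across chromosomes so direct loops exist on both
      chroms <- names(cs)
      split_quota <- function(q)
        diff(round(seq(0, q, length.out = length(chroms) + 1)))
      qd <- split_quota(if (dirn == "down") n_direct else 0L)
      qi <- split_quota(n_per_cmp - (if (dirn == "down") n_direct else 0L))
      dir_rows <- list(); ind_rows <- list(); dsite_pos <- list()
      for (ci in seq_along(chroms)) {
        s <- make_sites(cs[chroms[ci]], cfg$margin, cfg$pitch)
        nxt <- 1L
        if (qd[ci] > 0) {
          ed <- build_edges(s, 1L, qd[ci])
          dir_rows[[ci]] <- data.frame(chrom = chroms[ci],
                                       sa = s$pos[ed$edges[, 1]],
                                       sb = s$pos[ed$edges[, 2]])
          dsite_pos[[ci]] <- data.frame(chrom = chroms[ci],
                                        pos = s$pos[seq_len(ed$reach)])
          nxt <- ed$reach + gap_sites + 1L
        }
        if (qi[ci] > 0) {
          ei <- build_edges(s, nxt, qi[ci])
          ind_rows[[ci]] <- data.frame(chrom = chroms[ci],
                                       sa = s$pos[ei$edges[, 1]],
                                       sb = s$pos[ei$edges[, 2]])
        }
      }
      placed <- rbind(do.call(rbind, dir_rows), do.call(rbind, ind_rows))
      n_dir_here <- if (dirn == "down") n_direct else 0L
      label <- if (dirn == "down")
        rep(c("direct", "indirect"), c(n_dir_here, n_per_cmp - n_dir_here))
      else rep(NA_character_, n_per_cmp)
      res <- cfg$resolutions[(seq_len(n_per_cmp) - 1) %% n_res + 1]
      sa <- placed$sa
      sb <- placed$sb
      r <- data.frame(chrom = placed$chrom,
                      start1 = round(sa - res / 2), end1 = round(sa + res / 2),
                      start2 = round(sb - res / 2), end2 = round(sb + res / 2),
                      name = sprintf("%s_%05d", cmp, seq_len(n_per_cmp)),
                      resolution = res, direction = dirn,
                      p_value = stats::runif(n_per_cmp, 1e-6, 0.009),
                      effect = (if (dirn == "up") 1 else -1) *
                        round(stats::runif(n_per_cmp, 0.5, 3), 3),
                      label = label, site1 = sa, site2 = sb,
                      stringsAsFactors = FALSE)
      loops_all[[cmp]] <- r

      if (dirn == "down") {
        dr <- r[r$label == "direct", , drop = FALSE]
        if (nrow(dr)) {
          j1 <- round(stats::runif(nrow(dr), -jit_max, jit_max))
          j2 <- round(stats::runif(nrow(dr), -jit_max, jit_max))
          hichip[[tf]] <- data.frame(
            chrom = dr$chrom,
            start1 = dr$site1 + j1 - 500, end1 = dr$site1 + j1 + 500,
            start2 = dr$site2 + j2 - 500, end2 = dr$site2 + j2 + 500,
            name = sprintf("hichip_%s_%05d", tf, seq_len(nrow(dr))),
            resolution = 1000, direction = "none",
            p_value = NA_real_, effect = NA_real_,
            stringsAsFactors = FALSE)
          pk_center <- dr$site1 + round(stats::runif(nrow(dr), -100, 100))
          bound_peaks <- data.frame(chrom = dr$chrom,
                                    start = pk_center - cfg$peak_width / 2,
                                    end = pk_center + cfg$peak_width / 2)
          # orphan peaks at midpoints between consecutive direct sites:
          # inside the direct blocks but clear of every Hi-ChIP anchor
          dsites <- do.call(rbind, dsite_pos)
          mids <- do.call(rbind, lapply(split(dsites, dsites$chrom),
                                        function(s) {
            if (nrow(s) < 2) return(NULL)
            data.frame(chrom = s$chrom[-1],
                       center = (s$pos[-1] + s$pos[-nrow(s)]) / 2)
          }))
          mids <- mids[seq_len(min(nrow(mids), cfg$n_orphan_peaks)), ,
                       drop = FALSE]
          orphan <- data.frame(chrom = mids$chrom,
                               start = round(mids$center) - cfg$peak_width / 2,
                               end = round(mids$center) + cfg$peak_width / 2)
          pk <- rbind(bound_peaks, orphan)
          pk$name <- sprintf("peak_%s_%05d", tf, seq_len(nrow(pk)))
          peaks[[tf]] <- pk
          truth$comparisons[[cmp]] <- list(
            direct = dr$name,
            indirect = r$name[r$label == "indirect"],
            n_orphan_peaks = nrow(orphan),
            n_bound_peaks = nrow(bound_peaks))
        } else {
          hichip[[tf]] <- loops_all[[cmp]][0, 1:10]
          peaks[[tf]] <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), name = character())
          truth$comparisons[[cmp]] <- list(direct = character(),
                                           indirect = r$name,
                                           n_orphan_peaks = 0L,
                                           n_bound_peaks = 0L)
        }
      } else {
        truth$comparisons[[cmp]] <- list(n = n_per_cmp)
      }
    }
  }

  # decoy (non-significant) loops, random placement
  decoys <- function(cmp, dirn) {
    n <- cfg$n_decoys
    if (n == 0) return(NULL)
    ch <- sample(names(cs), n, replace = TRUE)
    len <- unname(cs[ch])
    res <- cfg$resolutions[(seq_len(n) - 1) %% n_res + 1]
    m1 <- round(stats::runif(n, cfg$margin, len - cfg$margin - 250000))
    span <- round(stats::runif(n, 20000, 200000))
    data.frame(chrom = ch,
               start1 = round(m1 - res / 2), end1 = round(m1 + res / 2),
               start2 = round(m1 + span - res / 2),
               end2 = round(m1 + span + res / 2),
               name = sprintf("%s_decoy_%03d", cmp, seq_len(n)),
               resolution = res, direction = dirn,
               p_value = stats::runif(n, 0.02, 0.9),
               effect = round(stats::runif(n, -1, 1), 3),
               label = NA_character_, site1 = m1, site2 = m1 + span,
               stringsAsFactors = FALSE)
  }

  # write per-resolution differential BEDPE
  for (cmp in names(loops_all)) {
    dirn <- sub("^[a-z]+_", "", cmp)
    dc <- decoys(cmp, dirn)
    all_r <- rbind(loops_all[[cmp]], dc)
    for (res in cfg$resolutions) {
      sub <- all_r[all_r$resolution == res,
                   c("chrom", "start1", "end1", "start2", "end2", "name",
                     "resolution", "direction", "p_value", "effect")]
      f <- sprintf("loops_%s_%d.bedpe", cmp, res)
      files[[sprintf("%s_%d", cmp, res)]] <-
        write_bedpe(loopset(sub, meta = list(comparison = cmp)), path(f))
    }
  }
  for (tf in tfs) {
    files[[paste0("hichip_", tf)]] <-
      write_bedpe(loopset(hichip[[tf]],
                          meta = list(comparison = paste0("hichip_", tf))),
                  path(sprintf("hichip_%s.bedpe", tf)))
    files[[paste0("peaks_", tf)]] <-
      write_bed(genomic_intervals(peaks[[tf]]$chrom, peaks[[tf]]$start,
                                  peaks[[tf]]$end, name = peaks[[tf]]$name),
                path(sprintf("peaks_%s.bed", tf)))
  }

  # 9-state tiling; state 5 only on chrX
  states <- do.call(rbind, lapply(names(cs), function(ch) {
    len <- cs[[ch]]
    starts <- c()
    p <- 0
    while (p < len) {
      starts <- c(starts, p)
      p <- p + round(stats::runif(1, 2000, 10000))
    }
    ends <- c(starts[-1], len)
    pool <- if (ch == "chrX") 1:9 else c(1:4, 6:9)
    data.frame(chrom = ch, start = starts, end = ends,
               state = sample(pool, length(starts), replace = TRUE))
  }))
  files$states <- write_bed(
    genomic_intervals(states$chrom, states$start, states$end,
                      name = as.character(states$state)),
    path("states.bed"))

  # genes: a planted dosage-compensated subset overlaps state 5 on chrX
  n_per_chrom <- round(cfg$n_genes / length(cs))
  s5 <- states[states$state == 5 & states$chrom == "chrX", , drop = FALSE]
  if (cfg$fraction_dc > 0 && nrow(s5) == 0)
    stop("infeasible placement: no state-5 segment on chrX")
  genes <- list()
  gid <- 0
  for (ch in names(cs)) {
    n_dc <- if (ch == "chrX") round(cfg$fraction_dc * n_per_chrom) else 0L
    glen <- round(stats::runif(n_per_chrom, 1000, 3000))
    gstart <- numeric(n_per_chrom)
    for (i in seq_len(n_per_chrom)) {
      if (i <= n_dc) {
        seg <- s5[sample.int(nrow(s5), 1), ]
        gstart[i] <- round(stats::runif(1, seg$start, seg$end - 1))
      } else {
        cand <- states[states$chrom == ch & states$state != 5 &
                         (states$end - states$start) >= glen[i] + 2, ]
        seg <- cand[sample.int(nrow(cand), 1), ]
        gstart[i] <- seg$start +
          floor(stats::runif(1, 1, seg$end - seg$start - glen[i]))
      }
    }
    g <- data.frame(chrom = ch, start = gstart,
                    end = pmin(gstart + glen, cs[[ch]]),
                    name = sprintf("gene_%s_%04d", ch, seq_len(n_per_chrom)),
                    dc = seq_len(n_per_chrom) <= n_dc)
    gid <- gid + n_per_chrom
    genes[[ch]] <- g
  }
  genes <- do.call(rbind, genes)
  files$genes <- write_bed(
    genomic_intervals(genes$chrom, genes$start, genes$end,
                      name = genes$name),
    path("genes.bed"))
  truth$dc_genes <- sort(genes$name[genes$dc])

  # HAS: half at chrX clamp-direct anchor-1 sites, half elsewhere on chrX
  cl_dir <- loops_all$clamp_down[loops_all$clamp_down$label == "direct" &
                                   loops_all$clamp_down$chrom == "chrX", ]
  n_at <- min(nrow(cl_dir), floor(cfg$n_has / 2))
  has_at <- if (n_at > 0) cl_dir$site1[seq_len(n_at)] else numeric(0)
  has_free <- round(stats::runif(cfg$n_has - n_at, cfg$margin,
                                 cs[["chrX"]] - cfg$margin))
  has_pos <- c(has_at, has_free)
  files$has <- write_bed(
    genomic_intervals("chrX", round(has_pos - 300), round(has_pos + 300),
                      name = sprintf("HAS%03d", seq_along(has_pos))),
    path("has.bed"))
  truth$n_has_at_direct_anchors <- n_at

  # TAD tilings and per-factor differential subsets
  tads <- do.call(rbind, lapply(names(cs), function(ch) {
    len <- cs[[ch]]
    starts <- c(); p <- 0
    while (p < len) {
      starts <- c(starts, p)
      p <- p + round(stats::runif(1, 40000, 100000))
    }
    data.frame(chrom = ch, start = starts, end = c(starts[-1], len))
  }))
  tads$name <- sprintf("TAD%04d", seq_len(nrow(tads)))
  files$tads <- write_bed(genomic_intervals(tads$chrom, tads$start,
                                            tads$end, name = tads$name),
                          path("tads.bed"))
  for (tf in tfs) {
    idx <- sort(sample.int(nrow(tads), round(0.3 * nrow(tads))))
    dtf <- tads[idx, ]
    files[[paste0("diff_tads_", tf)]] <-
      write_bed(genomic_intervals(dtf$chrom, dtf$start, dtf$end,
                                  name = dtf$name),
                path(sprintf("diff_tads_%s.bed", tf)))
    truth$comparisons[[paste0(tf, "_down")]]$n_diff_tads <- nrow(dtf)
  }

  # roX2-RDD loops: variable anchors; partners sit on direct-loop bins
  bin5 <- function(x) floor(x / 5000)
  down_pairs <- lapply(tfs, function(tf) {
    r <- loops_all[[paste0(tf, "_down")]]
    paste(r$chrom, pmin(bin5(r$site1), bin5(r$site2)),
          pmax(bin5(r$site1), bin5(r$site2)))
  })
  names(down_pairs) <- tfs
  rdd <- list()
  for (tf in tfs) {
    r <- loops_all[[paste0(tf, "_down")]]
    dx <- r[r$label == "direct" & r$chrom == "chrX", , drop = FALSE]
    other <- setdiff(tfs, tf)
    key <- paste(dx$chrom, pmin(bin5(dx$site1), bin5(dx$site2)),
                 pmax(bin5(dx$site1), bin5(dx$site2)))
    eligible <- which(!key %in% unlist(down_pairs[other]))
    n_part <- min(length(eligible),
                  round(cfg$rdd_overlap_fraction * nrow(dx)))
    pick <- sort(eligible[sample.int(length(eligible), n_part)])
    if (n_part > 0) {
      w1 <- 2 * round(stats::runif(n_part, cfg$rdd_anchor_width[1],
                                   cfg$rdd_anchor_width[2]) / 2)
      w2 <- 2 * round(stats::runif(n_part, cfg$rdd_anchor_width[1],
                                   cfg$rdd_anchor_width[2]) / 2)
      rdd[[tf]] <- data.frame(chrom = dx$chrom[pick],
                              start1 = dx$site1[pick] - w1 / 2,
                              end1 = dx$site1[pick] + w1 / 2,
                              start2 = dx$site2[pick] - w2 / 2,
                              end2 = dx$site2[pick] + w2 / 2)
    }
    truth$rdd[[tf]] <- list(n_direct_chrX = nrow(dx),
                            n_partnered = n_part,
                            partnered = dx$name[pick])
  }
  # background RDD loops matching no differential down-loop bin pair
  all_down_keys <- unlist(down_pairs)
  bg <- list()
  used_keys <- unlist(lapply(rdd, function(d)
    paste(d$chrom, pmin(bin5((d$start1 + d$end1) / 2),
                        bin5((d$start2 + d$end2) / 2)),
          pmax(bin5((d$start1 + d$end1) / 2),
               bin5((d$start2 + d$end2) / 2)))))
  tries <- 0
  while (length(bg) < cfg$n_rdd_background && tries < 10000) {
    tries <- tries + 1
    m1 <- round(stats::runif(1, cfg$margin, cs[["chrX"]] - cfg$margin - 250000))
    m2 <- m1 + round(stats::runif(1, 20000, 200000))
    key <- paste("chrX", min(bin5(m1), bin5(m2)), max(bin5(m1), bin5(m2)))
    if (key %in% all_down_keys || key %in% used_keys) next
    used_keys <- c(used_keys, key)
    w1 <- 2 * round(stats::runif(1, cfg$rdd_anchor_width[1],
                                 cfg$rdd_anchor_width[2]) / 2)
    w2 <- 2 * round(stats::runif(1, cfg$rdd_anchor_width[1],
                                 cfg$rdd_anchor_width[2]) / 2)
    bg[[length(bg) + 1]] <- data.frame(chrom = "chrX",
                                       start1 = m1 - w1 / 2, end1 = m1 + w1 / 2,
                                       start2 = m2 - w2 / 2, end2 = m2 + w2 / 2)
  }
  rdd_df <- do.call(rbind, c(unname(rdd), bg))
  rdd_df$start1 <- pmax(0, rdd_df$start1)
  rdd_df$name <- sprintf("rdd_%05d", seq_len(nrow(rdd_df)))
  files$rdd <- write_bedpe(loopset(rdd_df, meta = list(source = "rdd")),
                           path("rdd.bedpe"))
  truth$n_rdd <- nrow(rdd_df)

  # contact matrices: power-law decay with planted loop enrichments
  res_m <- cfg$matrix_resolution
  sig <- do.call(rbind, lapply(loops_all, function(r)
    r[c("chrom", "site1", "site2")]))
  for (ch in names(cs)) {
    n_bins <- ceiling(cs[[ch]] / res_m)
    sep <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
    m <- cfg$base_contacts * (1 + sep)^(-cfg$decay_alpha)
    s <- sig[sig$chrom == ch, ]
    b1 <- floor(s$site1 / res_m) + 1
    b2 <- floor(s$site2 / res_m) + 1
    px <- unique(cbind(pmin(b1, b2), pmax(b1, b2)))
    m[px] <- m[px] * cfg$loop_enrichment
    m[px[, c(2, 1), drop = FALSE]] <- m[px]
    if (cfg$noise == "poisson") {
      up <- upper.tri(m, diag = TRUE)
      noisy <- m
      noisy[up] <- stats::rpois(sum(up), m[up])
      noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
      m <- noisy
    }
    files[[paste0("matrix_", ch)]] <-
      write_contact_matrix(contact_matrix(ch, res_m, m, cs[[ch]]),
                           path(sprintf("matrix_%s.tsv", ch)))
  }

  # state-pair ground truth for the 1 kb down-loops (brute-force scan)
  for (tf in tfs) {
    r <- loops_all[[paste0(tf, "_down")]]
    r1k <- r[r$resolution == 1000, , drop = FALSE]
    tab <- do.call(rbind, lapply(seq_len(nrow(r1k)), function(i) {
      s1 <- brute_anchor_states(r1k$chrom[i], r1k$start1[i], r1k$end1[i],
                                states)
      s2 <- brute_anchor_states(r1k$chrom[i], r1k$start2[i], r1k$end2[i],
                                states)
      g <- expand.grid(a = s1, b = s2)
      unique(data.frame(name = r1k$name[i],
                        state1 = pmin(g$a, g$b), state2 = pmax(g$a, g$b)))
    }))
    tab <- tab[order(tab$name, tab$state1, tab$state2), ]
    rownames(tab) <- NULL
    truth$state_pairs[[tf]] <-
      sprintf("%s:%d-%d", tab$name, tab$state1, tab$state2)
  }

  truth_path <- path("truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files$truth <- truth_path
  invisible(list(dir = dir, files = files, truth = truth))
}

#' Simulate one loop set called at several resolutions
#'
#' Plants \code{k} loops and emits each at every requested resolution with
#' independent anchor-centre jitter below \code{jitter / 2} bp, so that the
#' copies coincide under windows harmonized to the coarsest resolution
#' while distinct planted loops stay well separated.  Used to validate
#' consensus merging: the consensus must contain exactly \code{k} loops,
#' each represented by its finest-resolution copy.
#'
#' @param k Number of planted loops.
#' @param chromsizes Named chromosome lengths.
#' @param resolutions Calling resolutions (bp).
#' @param jitter Total jitter width in bp (< coarsest resolution).
#' @param spacing Site spacing in bp (default 30000).
#' @param margin Keep-out from chromosome ends.
#' @return List with \code{loopsets} (one [loopset()] per resolution) and
#'   \code{truth} (data.frame of planted anchor centres and names).
#' @export
simulate_multires_loops <- function(k = 100,
                                    chromsizes = c(chrX = 2e6, chr2L = 2e6),
                                    resolutions = c(1000, 5000, 10000),
                                    jitter = 9000, spacing = 30000,
                                    margin = 20000) {
  stopifnot(jitter < max(resolutions))
  sites <- do.call(rbind, lapply(names(chromsizes), function(ch) {
    pos <- seq(margin, chromsizes[[ch]] - margin, by = spacing)
    data.frame(chrom = ch, pos = pos)
  }))
  edges <- do.call(rbind, lapply(split(sites, sites$chrom), function(s)
    if (nrow(s) >= 2) data.frame(chrom = s$chrom[-nrow(s)],
                                 a = s$pos[-nrow(s)], b = s$pos[-1])))
  if (nrow(edges) < k)
    stop("infeasible placement: at most ", nrow(edges), " loops fit")
  edges <- edges[seq_len(k), ]
  truth <- data.frame(name = sprintf("planted_%04d", seq_len(k)),
                      chrom = edges$chrom, a = edges$a, b = edges$b)
  loopsets <- lapply(resolutions, function(res) {
    ja <- round(stats::runif(k, -jitter / 2, jitter / 2))
    jb <- round(stats::runif(k, -jitter / 2, jitter / 2))
    loopset(data.frame(chrom = edges$chrom,
                       start1 = edges$a + ja - res / 2,
                       end1 = edges$a + ja + res / 2,
                       start2 = edges$b + jb - res / 2,
                       end2 = edges$b + jb + res / 2,
                       name = sprintf("%s_res%d", truth$name, res),
                       resolution = res, direction = "down",
                       p_value = stats::runif(k, 1e-6, 0.009),
                       effect = -1),
            meta = list(comparison = "multires"))
  })
  names(loopsets) <- as.character(resolutions)
  list(loopsets = loopsets, truth = truth)
}

#' Simulate a dedicated APA fixture
#'
#' Contact matrices with power-law decay and \code{n_loops} planted loops,
#' all at the same bin separation, positioned so that no planted pixel
#' falls inside another loop's pile-up window.  With noise off and
#' median-based expected normalization the mean-window central pixel equals
#' the planted enrichment exactly.
#'
#' @param n_loops Number of planted loops.
#' @param e Planted multiplicative enrichment (>= 1).
#' @param resolution Matrix bin size (bp).
#' @param sep_bins Loop separation in bins.
#' @param stride_bins Spacing between successive loops, in bins; must
#'   exceed \code{flank} so windows stay uncontaminated.
#' @param chromsizes Named chromosome lengths.
#' @param alpha,base Decay exponent and zero-separation contact level.
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param flank Intended pile-up flank (bins), used for edge margins.
#' @return List with \code{matrices} (list of [contact_matrix()]),
#'   \code{loops} (a [loopset()]) and \code{e}.
#' @export
simulate_apa_fixture <- function(n_loops = 200, e = 3, resolution = 1000,
                                 sep_bins = 40, stride_bins = 11,
                                 chromsizes = c(chrX = 2e6, chr2L = 2e6),
                                 alpha = 0.85, base = 1000,
                                 noise = c("none", "poisson"),
                                 flank = 10) {
  noise <- match.arg(noise)
  stopifnot(e >= 1, stride_bins > flank)
  placements <- do.call(rbind, lapply(names(chromsizes), function(ch) {
    n_bins <- ceiling(chromsizes[[ch]] / resolution)
    a <- seq(flank + 2, n_bins - sep_bins - flank - 2, by = stride_bins)
    data.frame(chrom = ch, a = a, b = a + sep_bins, n_bins = n_bins)
  }))
  if (nrow(placements) < n_loops)
    stop("infeasible placement: at most ", nrow(placements), " loops fit")
  placements <- placements[seq_len(n_loops), ]
  matrices <- lapply(names(chromsizes), function(ch) {
    n_bins <- ceiling(chromsizes[[ch]] / resolution)
    sep <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
    m <- base * (1 + sep)^(-alpha)
    p <- placements[placements$chrom == ch, ]
    px <- cbind(p$a, p$b)
    m[px] <- m[px] * e
    m[px[, c(2, 1), drop = FALSE]] <- m[px]
    if (noise == "poisson") {
      up <- upper.tri(m, diag = TRUE)
      noisy <- m
      noisy[up] <- stats::rpois(sum(up), m[up])
      noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
      m <- noisy
    }
    contact_matrix(ch, resolution, m, chromsizes[[ch]])
  })
  names(matrices) <- names(chromsizes)
  loops <- loopset(data.frame(
    chrom = placements$chrom,
    start1 = (placements$a - 1) * resolution,
    end1 = placements$a * resolution,
    start2 = (placements$b - 1) * resolution,
    end2 = placements$b * resolution,
    name = sprintf("apa_%04d", seq_len(n_loops)),
    resolution = resolution, direction = "down",
    p_value = 0.001, effect = -1),
    meta = list(comparison = "apa_fixture"))
  list(matrices = matrices, loops = loops, e = e)
}

#' Compare pipeline outputs with synthetic ground truth
#'
#' @param truth Truth list from [simulate_study()].
#' @param labels Named list (per factor) of classification tables from
#'   [classify_direct_indirect()].
#' @param dc_genes Character vector of recovered dosage-compensated gene
#'   names (optional).
#' @param state_pairs Named list (per factor) of tables from
#'   [annotate_state_pairs()] (optional).
#' @param apa_ratio Recovered APA enrichment ratio (optional).
#' @return data.frame with one row per checked quantity: \code{metric},
#'   \code{value}.  Precision/recall are for the "direct" label; set
#'   comparisons yield exact-match flags (1/0); APA yields the relative
#'   recovery error.
#' @export
truth_report <- function(truth, labels = NULL, dc_genes = NULL,
                         state_pairs = NULL, apa_ratio = NULL) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, value = value)
  for (tf in names(labels)) {
    cmp <- truth$comparisons[[paste0(tf, "_down")]]
    if (is.null(cmp)) stop("no truth for factor ", tf)
    lab <- labels[[tf]]
    known <- lab$name %in% c(cmp$direct, cmp$indirect)
    if (!all(known))
      stop("label table for ", tf, " contains unknown loop ids: ",
           lab$name[!known][1])
    pred_dir <- lab$name[lab$label == "direct"]
    tp <- sum(pred_dir %in% cmp$direct)
    add(paste0(tf, "_precision"),
        if (length(pred_dir)) tp / length(pred_dir) else NA_real_)
    add(paste0(tf, "_recall"),
        if (length(cmp$direct)) tp / length(cmp$direct) else NA_real_)
  }
  if (!is.null(dc_genes))
    add("dc_genes_exact", as.numeric(setequal(dc_genes, truth$dc_genes)))
  for (tf in names(state_pairs)) {
    got <- sprintf("%s:%d-%d", state_pairs[[tf]]$name,
                   state_pairs[[tf]]$state1, state_pairs[[tf]]$state2)
    add(paste0(tf, "_state_pairs_exact"),
        as.numeric(setequal(got, truth$state_pairs[[tf]])))
  }
  if (!is.null(apa_ratio))
    add("apa_recovery_error",
        abs(apa_ratio - truth$loop_enrichment) / truth$loop_enrichment)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
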