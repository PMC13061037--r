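# stage-ordered orchestration: filter -> merge -> classify -> annotate ->
# stats -> APA, with report tables mirroring the figure-panel families.

default_pipeline_config <- function() {
  list(seed = 1,
       alpha = 0.01,
       window = 10000,          # harmonized overlap window (bp)
       rdd_resolution = 5000,   # uniform bin size for RDD integration
       apa_flank = 10,          # pile-up flank in bins
       apa_corner = 3,          # corner block for enrichment scores
       simulate = TRUE,
       simulate_args = list())
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  cfg
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

# mean window pooled over several window stacks (e.g. one per chromosome)
pool_stacks <- function(stacks) {
  stacks <- stacks[!vapply(stacks, is.null, logical(1))]
  if (!length(stacks)) stop("no windows to pool")
  windows <- do.call(c, lapply(stacks, function(s) s$windows))
  list(mean = Reduce(`+`, windows) / length(windows),
       n = length(windows),
       n_skipped = sum(vapply(stacks, function(s) s$n_skipped, numeric(1))))
}

#' Run the integration pipeline end-to-end
#'
#' Executes the full stage order -- significance filtering, multi-resolution
#' consensus merging, direct/indirect classification against Hi-ChIP,
#' chromatin-state and state-pair annotation, dosage-compensated-gene / HAS
#' / TAD association, roX2-RDD integration at uniform 5 kb bins, the
#' enrichment and size statistics, and APA scoring -- and writes one TSV
#' per report family plus a manifest into \code{out_dir}.
#'
#' @param config A named list (or path to a YAML file) overriding the
#'   defaults: \code{seed}, \code{alpha} (loop significance, default 0.01),
#'   \code{window} (harmonized overlap window, 10 kb), \code{rdd_resolution}
#'   (5 kb), \code{apa_flank}, \code{apa_corner}, and either
#'   \code{simulate: true} (with optional \code{simulate_args}) or an
#'   \code{inputs} list naming every input file (chromsizes, loops_<tf>_
#'   <direction>_<resolution>, hichip_<tf>, peaks_<tf>, states, genes, has,
#'   tads, diff_tads_<tf>, rdd, matrix_<chrom>).
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with the output directory, the report table
#'   paths, and the in-memory results (consensus loop sets, classification
#'   tables, annotation tables, scores).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("run_")) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  tfs <- c("clamp", "gaf")
  resolutions <- c(1000, 5000, 10000)

  # ---- inputs ---------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate_args)
    sim <- stage("simulate",
                 simulate_study(do.call(synthetic_config, sim_args),
                                file.path(out_dir, "inputs")))
    inputs <- sim$files
    say("simulate: wrote ", length(inputs), " input files")
  } else {
    inputs <- cfg$inputs
    if (is.null(inputs$chromsizes))
      stop("config lacks inputs$chromsizes")
    missing <- !vapply(inputs, file.exists, logical(1))
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(inputs[missing]), collapse = ", "))
  }
  chromsizes <- read_chromsizes(inputs$chromsizes)
  states <- read_state_bed(inputs$states, chromsizes = chromsizes)
  genes <- read_bed(inputs$genes, chromsizes)
  has <- read_bed(inputs$has, chromsizes)
  tads <- read_bed(inputs$tads, chromsizes)
  matrices <- lapply(names(chromsizes), function(ch) {
    key <- paste0("matrix_", ch)
    if (is.null(inputs[[key]])) NULL else read_contact_matrix(inputs[[key]])
  })
  names(matrices) <- names(chromsizes)
  rdd_raw <- read_bedpe(inputs$rdd, chromsizes = chromsizes,
                        meta = list(source = "rdd"))

  # ---- filter + merge -------------------------------------------------
  consensus <- list()
  loop_count_rows <- list()
  for (tf in tfs) for (dirn in c("up", "down")) {
    cmp <- paste(tf, dirn, sep = "_")
    sets <- lapply(resolutions, function(res) {
      key <- sprintf("%s_%d", cmp, res)
      if (is.null(inputs[[key]]))
        stop("config lacks inputs$", key)
      raw <- read_bedpe(inputs[[key]], default_resolution = res,
                        p_value_col = 10, effect_col = 11,
                        direction_col = 9, chromsizes = chromsizes,
                        meta = list(comparison = cmp))
      sig <- filter_significant(raw, cfg$alpha)
      loop_count_rows[[length(loop_count_rows) + 1]] <<-
        data.frame(comparison = cmp, resolution = res,
                   n_input = length(raw), n_significant = length(sig))
      sig
    })
    consensus[[cmp]] <- stage("merge", merge_multiresolution(sets, chromsizes))
    say("merge ", cmp, ": ",
        sum(vapply(sets, length, numeric(1))), " significant -> ",
        length(consensus[[cmp]]), " consensus loops")
  }

  # ---- TAD integration ------------------------------------------------
  diff_tads <- lapply(tfs, function(tf)
    read_bed(inputs[[paste0("diff_tads_", tf)]], chromsizes))
  names(diff_tads) <- tfs
  loop_counts <- do.call(rbind, loop_count_rows)
  cons_rows <- do.call(rbind, lapply(names(consensus), function(cmp) {
    tf <- sub("_.*", "", cmp)
    ls <- consensus[[cmp]]
    data.frame(comparison = cmp, resolution = NA,
               n_input = NA, n_significant = NA,
               n_consensus = length(ls),
               n_tad_associated =
                 length(unique(pair_to_bed(ls, tads, "either")$loop)),
               n_diff_tad_associated =
                 length(unique(pair_to_bed(ls, diff_tads[[tf]],
                                           "either")$loop)))
  }))
  loop_counts$n_consensus <- NA
  loop_counts$n_tad_associated <- NA
  loop_counts$n_diff_tad_associated <- NA
  loop_counts <- rbind(loop_counts, cons_rows)

  # ---- classification -------------------------------------------------
  hichip <- lapply(tfs, function(tf)
    read_bedpe(inputs[[paste0("hichip_", tf)]], default_resolution = 1000,
               chromsizes = chromsizes,
               meta = list(comparison = paste0("hichip_", tf))))
  names(hichip) <- tfs
  peaks <- lapply(tfs, function(tf) read_bed(inputs[[paste0("peaks_", tf)]],
                                             chromsizes))
  names(peaks) <- tfs
  labels <- list()
  di_rows <- list()
  for (tf in tfs) {
    down <- consensus[[paste0(tf, "_down")]]
    labels[[tf]] <- stage("classify",
                          classify_direct_indirect(down, hichip[[tf]],
                                                   chromsizes,
                                                   window = cfg$window))
    n <- nrow(labels[[tf]])
    nd <- sum(labels[[tf]]$label == "direct")
    di_rows[[tf]] <- data.frame(tf = tf, n_down = n, n_direct = nd,
                                n_indirect = n - nd,
                                pct_direct = percentage(nd, n, 1),
                                pct_indirect = percentage(n - nd, n, 1))
    say("classify ", tf, ": ", nd, " direct / ", n - nd, " indirect")
  }
  direct_indirect <- do.call(rbind, di_rows)
  rownames(direct_indirect) <- NULL

  split_by_label <- function(tf) {
    down <- consensus[[paste0(tf, "_down")]]
    lab <- labels[[tf]]$label
    list(direct = down[lab == "direct"], indirect = down[lab == "indirect"])
  }
  parts <- lapply(tfs, split_by_label)
  names(parts) <- tfs

  # ---- cross-factor union overlaps ------------------------------------
  union_row <- function(what, a, b) {
    wa <- harmonize_anchors(a, cfg$window, chromsizes)
    wb <- harmonize_anchors(b, cfg$window, chromsizes)
    nAB <- length(unique(pair_to_pair(wa, wb)$a))
    nA <- length(a); nB <- length(b)
    total <- sum(vapply(consensus, length, numeric(1)))
    fp <- fisher_exact_2x2(nAB, nA - nAB, nB - nAB,
                           max(0, total - nA - nB + nAB))$p
    data.frame(pair = what, nA = nA, nB = nB, n_shared = nAB,
               union_pct = union_overlap_percentage(nA, nB, nAB, 2),
               fisher_p = fp)
  }
  overlap_union <- rbind(
    union_row("up_clamp_vs_up_gaf", consensus$clamp_up, consensus$gaf_up),
    union_row("down_clamp_vs_down_gaf", consensus$clamp_down,
              consensus$gaf_down),
    union_row("direct_clamp_vs_direct_gaf", parts$clamp$direct,
              parts$gaf$direct),
    union_row("indirect_clamp_vs_indirect_gaf", parts$clamp$indirect,
              parts$gaf$indirect))

  # ---- chromatin states (1 kb calls only) -----------------------------
  at_res <- function(ls, res) ls[ls$records$resolution == res]
  state_rows <- list()
  state_pair_tabs <- list()
  enr_rows <- list()
  for (tf in tfs) {
    up1 <- at_res(consensus[[paste0(tf, "_up")]], 1000)
    down1 <- at_res(consensus[[paste0(tf, "_down")]], 1000)
    su <- annotate_states_either(up1, states)
    sd <- annotate_states_either(down1, states)
    cu <- tabulate(su$state, nbins = 9)
    cd <- tabulate(sd$state, nbins = 9)
    enr <- state_enrichment_test(cu, cd)
    enr_rows[[tf]] <- cbind(tf = tf, enr)
    state_pair_tabs[[tf]] <- annotate_state_pairs(down1, states)
    sp <- state_pair_tabs[[tf]]
    lab1k <- labels[[tf]]$label[match(sp$name, labels[[tf]]$name)]
    chrom1k <- down1$records$chrom[sp$loop]
    grp <- data.frame(
      tf = tf,
      chrom_class = ifelse(chrom1k == "chrX", "chrX", "autosome"),
      label = lab1k, state1 = sp$state1, state2 = sp$state2)
    agg <- stats::aggregate(list(n = rep(1, nrow(grp))),
                            grp, FUN = sum)
    tot <- stats::ave(agg$n, agg$tf, agg$chrom_class, agg$label,
                      FUN = sum)
    agg$pct <- percentage(agg$n, tot, 1)
    state_rows[[tf]] <- agg
  }
  state_enrichment <- do.call(rbind, enr_rows)
  rownames(state_enrichment) <- NULL
  state_pairs <- do.call(rbind, state_rows)
  state_pairs <- state_pairs[order(state_pairs$tf, state_pairs$chrom_class,
                                   state_pairs$label, state_pairs$state1,
                                   state_pairs$state2), ]
  rownames(state_pairs) <- NULL

  # ---- loop sizes -----------------------------------------------------
  size_rows <- list()
  for (tf in tfs) {
    down <- consensus[[paste0(tf, "_down")]]
    lab <- labels[[tf]]$label
    cc <- ifelse(down$records$chrom == "chrX", "chrX", "autosome")
    ss <- size_summary(down, data.frame(label = lab, chrom_class = cc))
    ss <- cbind(tf = tf, ss)
    mw <- vapply(unique(cc), function(ch) {
      x <- loop_span(down)[lab == "direct" & cc == ch]
      y <- loop_span(down)[lab == "indirect" & cc == ch]
      if (!length(x) || !length(y)) return(NA_real_)
      mann_whitney(x, y)$p
    }, numeric(1))
    ss$mw_p_direct_vs_indirect <-
      mw[match(sub(".* / ", "", ss$group), names(mw))]
    size_rows[[tf]] <- ss
  }
  size_tab <- do.call(rbind, size_rows)
  rownames(size_tab) <- NULL

  # ---- DC genes / HAS -------------------------------------------------
  dcg <- dc_genes_from_states(states, genes)
  dcg_rows <- list()
  for (cmp in names(consensus)) {
    assoc <- associate_dc_genes(consensus[[cmp]], dcg, has)
    s <- assoc$summary
    dcg_rows[[cmp]] <- data.frame(comparison = cmp,
                                  n_dc_genes = s$n_dc_genes,
                                  n_in_any_loop = s$n_in_any_loop,
                                  n_in_has_loop = s$n_in_has_loop,
                                  pct_in_any_loop = s$pct_in_any_loop,
                                  pct_in_has_loop_of_all =
                                    s$pct_in_has_loop_of_all,
                                  pct_in_has_loop_of_looped =
                                    s$pct_in_has_loop_of_looped)
  }
  dcg_has <- do.call(rbind, dcg_rows)
  rownames(dcg_has) <- NULL

  # ---- roX2-RDD integration -------------------------------------------
  rdd_norm <- normalize_bins(rdd_raw, cfg$rdd_resolution, chromsizes)
  say("rdd normalize: ", length(rdd_raw), " -> ", length(rdd_norm),
      " (", attr(rdd_norm, "n_dropped"), " dropped, ",
      attr(rdd_norm, "n_duplicates"), " duplicates)")
  rdd_rows <- list()
  for (tf in tfs) for (filt in c("chrX", "has")) {
    ov <- lapply(parts[[tf]], function(ls) {
      norm <- normalize_bins(ls, cfg$rdd_resolution, chromsizes)
      rdd_overlap(norm, rdd_norm, site_filter = filt, has = has,
                  resolution = cfg$rdd_resolution)
    })
    fp <- if (ov$direct$n_total > 0 && ov$indirect$n_total > 0)
      fisher_exact_2x2(ov$direct$n_overlapping,
                       ov$direct$n_total - ov$direct$n_overlapping,
                       ov$indirect$n_overlapping,
                       ov$indirect$n_total - ov$indirect$n_overlapping)$p
    else NA_real_
    rdd_rows[[paste(tf, filt)]] <- do.call(rbind, lapply(
      names(ov), function(lb)
        data.frame(tf = tf, site_filter = filt, label = lb,
                   n_overlapping = ov[[lb]]$n_overlapping,
                   n_total = ov[[lb]]$n_total,
                   percent = ov[[lb]]$percent, fisher_p = fp)))
  }
  rdd_tab <- do.call(rbind, rdd_rows)
  rownames(rdd_tab) <- NULL

  # ---- APA ------------------------------------------------------------
  apa_rows <- list()
  have_mat <- !vapply(matrices, is.null, logical(1))
  if (any(have_mat)) {
    apa_for <- function(what, loops_or_sites, type) {
      stacks <- lapply(matrices[have_mat], function(cm) {
        tryCatch(
          if (type == "loops") pileup_loops(cm, loops_or_sites,
                                            flank = cfg$apa_flank)
          else pileup_sites(cm, loops_or_sites, flank = cfg$apa_flank,
                            min_sep = 20000, max_sep = 500000),
          error = function(e) NULL)
      })
      pooled <- tryCatch(pool_stacks(stacks), error = function(e) NULL)
      if (is.null(pooled)) return(NULL)
      sc <- enrichment_score(pooled$mean, cfg$apa_corner)
      data.frame(set = what, n_windows = pooled$n,
                 n_skipped = pooled$n_skipped,
                 ratio = sc$ratio, log_ratio = sc$log_ratio)
    }
    for (cmp in names(consensus))
      apa_rows[[cmp]] <- apa_for(cmp, consensus[[cmp]], "loops")
    apa_rows$has <- apa_for("has_sites", has, "sites")
  }
  apa_tab <- do.call(rbind, apa_rows)
  if (!is.null(apa_tab)) rownames(apa_tab) <- NULL

  # ---- write reports --------------------------------------------------
  reports <- list(loop_counts = loop_counts,
                  direct_indirect = direct_indirect,
                  overlap_union = overlap_union,
                  state_enrichment = state_enrichment,
                  state_pairs = state_pairs,
                  size_summary = size_tab,
                  dcg_has = dcg_has,
                  rdd_overlap = rdd_tab,
                  apa_scores = apa_tab)
  report_paths <- list()
  for (nm in names(reports)) {
    if (is.null(reports[[nm]])) next
    report_paths[[nm]] <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(reports[[nm]], report_paths[[nm]])
  }
  manifest <- list(
    package = "loopweaver",
    version = as.character(utils::packageVersion("loopweaver")),
    seed = cfg$seed, alpha = cfg$alpha, window = cfg$window,
    rdd_resolution = cfg$rdd_resolution,
    inputs = lapply(inputs, function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(out_dir = out_dir, reports = report_paths,
                 tables = reports, consensus = consensus, labels = labels,
                 parts = parts, dc_genes = dcg$name,
                 state_pairs_raw = state_pair_tabs,
                 truth = if (isTRUE(cfg$simulate)) sim$truth else NULL))
}

#' Summarize a completed pipeline run directory
#'
#' @param out_dir Directory produced by [run_pipeline()].
#' @return Named list of report data.frames (one per table family).
#' @export
pipeline_report <- function(out_dir) {
  expect <- c("loop_counts", "direct_indirect", "overlap_union",
              "state_enrichment", "state_pairs", "size_summary",
              "dcg_has", "rdd_overlap", "apa_scores")
  paths <- file.path(out_dir, paste0(expect, ".tsv"))
  missing <- expect[!file.exists(paths)]
  if (length(missing))
    stop("incomplete run: missing ", paste(missing, collapse = ", "))
  out <- lapply(paths, utils::read.delim)
  names(out) <- expect
  out
}
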