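#' Read a dataset directory written by [write_dataset()]
#'
#' Expects per-strand bedGraphs (`<lib>.plus/minus.bedGraph` for libraries
#' csrna, input, rnaseq, groseq), `genome.fa`, `genes.gtf`, `starr.tsv`,
#' `atac.bed`, `totals.tsv`, and optionally `truth.tsv`. Missing optional
#' layers are returned as `NULL`.
#'
#' @param dir dataset directory.
#' @return list mirroring [simulate_dataset()] output.
#' @export
read_dataset <- function(dir) {
  tot_path <- file.path(dir, "totals.tsv")
  totals <- if (file.exists(tot_path)) {
    t <- utils::read.delim(tot_path)
    stats::setNames(t$total_reads, t$library)
  } else c(csrna = NA, input = NA, rnaseq = NA, groseq = NA)
  read_lib <- function(lib) {
    pp <- file.path(dir, sprintf("%s.plus.bedGraph", lib))
    pm <- file.path(dir, sprintf("%s.minus.bedGraph", lib))
    if (!file.exists(pp) && !file.exists(pm)) return(NULL)
    tr <- totals[lib]
    parts <- list()
    if (file.exists(pp)) parts$p <- read_bedgraph(pp, "+", total_reads = tr)
    if (file.exists(pm)) parts$m <- read_bedgraph(pm, "-", total_reads = tr)
    cnt <- data.table::rbindlist(lapply(parts, function(x) x$counts))
    tr_eff <- if (is.na(tr)) max(sum(cnt$value), 1) else tr
    end_profile(cnt, total_reads = tr_eff)
  }
  out <- list(
    genome = if (file.exists(file.path(dir, "genome.fa")))
      read_genome(file.path(dir, "genome.fa")) else NULL,
    annotation = if (file.exists(file.path(dir, "genes.gtf")))
      read_gtf(file.path(dir, "genes.gtf")) else NULL,
    truth = if (file.exists(file.path(dir, "truth.tsv")))
      utils::read.delim(file.path(dir, "truth.tsv")) else NULL,
    starr = if (file.exists(file.path(dir, "starr.tsv")))
      read_region_table(file.path(dir, "starr.tsv"), "tsv") else NULL,
    atac = if (file.exists(file.path(dir, "atac.bed")))
      read_region_table(file.path(dir, "atac.bed"), "bed6") else NULL)
  for (lib in c("csrna", "input", "rnaseq", "groseq")) out[[lib]] <- read_lib(lib)
  out
}

#' Run the full TSR classification pipeline
#'
#' Orchestrates every stage on one or more samples: TSR calling with
#' input filtering, stability classification, genomic-context annotation,
#' bidirectional pairing and initiation styles, pausing indices, hexamer
#' ranking, nucleotide metaplot, STARR-seq integration, and (with two or
#' more samples) cross-sample stability switching. Each stage's table is
#' written as TSV under `outdir/<sample>/`, and a machine-readable
#' `summary.json` gathers the headline counts and fractions.
#'
#' @param sample_dirs named character vector/list of dataset directories
#'   (see [read_dataset()]); a single unnamed path is treated as sample
#'   `"sample1"`.
#' @param outdir output directory.
#' @param params [caller_params()] for TSS/TSR calling.
#' @param stability_threshold stability threshold (per 10^7 reads).
#' @param pair_window bidirectional pairing window in bp.
#' @param hexamer_window inclusive downstream offsets for hexamer windows.
#' @param stages stages to run; default `NULL` selects every stage whose
#'   inputs exist (switch only with >= 2 samples). Requesting `"switch"`
#'   with one sample is an error.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(sample_dirs, outdir,
                         params = caller_params(),
                         stability_threshold = 2.0,
                         pair_window = 275L,
                         hexamer_window = c(1000L, 3000L),
                         stages = NULL) {
  sample_dirs <- as.list(sample_dirs)
  if (is.null(names(sample_dirs)) || any(!nzchar(names(sample_dirs))))
    names(sample_dirs) <- paste0("sample", seq_along(sample_dirs))
  if (!is.null(stages) && "switch" %in% stages && length(sample_dirs) < 2L)
    stop("stage 'switch' requires at least 2 samples")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  all_tsrs <- list(); all_calls <- list()
  summary <- list(parameters = list(
    tss_min_norm = params$tss_min_norm, tsr_min_norm = params$tsr_min_norm,
    cluster_dist = params$cluster_dist, input_fold = params$input_fold,
    stability_threshold = stability_threshold, pair_window = pair_window,
    hexamer_window = hexamer_window))
  want <- function(s) is.null(stages) || s %in% stages

  for (sn in names(sample_dirs)) {
    d <- read_dataset(sample_dirs[[sn]])
    if (is.null(d$csrna) || is.null(d$input))
      stop("stage 'calltsr': sample '", sn, "' lacks csRNA or input profiles")
    sdir <- file.path(outdir, sn)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    tsrs <- call_tsrs(d$csrna, d$input, params)
    mem <- attr(tsrs, "members")
    smry <- list(n_tsr = nrow(tsrs), n_tss = nrow(mem))

    if (is.null(d$rnaseq)) stop("stage 'classify': sample '", sn, "' lacks RNA-seq")
    calls <- classify_stability(tsrs, d$rnaseq, threshold = stability_threshold)
    smry$n_stable <- sum(calls$class == "stable")
    smry$n_unstable <- sum(calls$class == "unstable")
    smry$pct_unstable <- if (nrow(calls) > 0) 100 * smry$n_unstable / nrow(calls) else NA

    ctx <- classify_context(tsrs, d$annotation)
    smry$context_counts <- as.list(table(ctx$context))
    if (!is.null(d$annotation) && nrow(d$annotation) > 0L && nrow(tsrs) > 0L) {
      bins <- distance_bin_ratios(tsrs, calls, d$annotation)
      data.table::fwrite(bins, file.path(sdir, "distance_bins.tsv"), sep = "\t")
      smry$antisense_ratio <- as.numeric(antisense_ratio(tsrs, d$annotation))
    }
    partners <- pair_bidirectional(tsrs, pair_window)
    styles <- assign_styles(tsrs, partners, calls)
    smry$style_counts <- as.list(table(styles$style))
    bf <- bidirectional_unstable_fraction(styles, ctx)
    smry$pct_uu <- bf$pct_uu
    smry$pct_uu_distal <- bf$pct_uu_distal

    tab <- merge(merge(merge(tsrs, calls, by.x = "id", by.y = "tsr_id"),
                       ctx, by.x = "id", by.y = "tsr_id"),
                 styles[, c("tsr_id", "style", "partner_id", "bidirectional")],
                 by.x = "id", by.y = "tsr_id")
    tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
    data.table::fwrite(tab, file.path(sdir, "tsr.tsv"), sep = "\t")
    data.table::fwrite(mem, file.path(sdir, "tss.tsv"), sep = "\t")

    if (want("pausing") && !is.null(d$groseq) && nrow(tsrs) > 0L) {
      mt <- data.frame(id = tsrs$id, chrom = tsrs$chrom, strand = tsrs$strand,
                       pos = tsrs$major_tss)
      pi_tab <- pausing_index(mt, normalize_profile(d$groseq))
      pi_tab$class <- calls$class[match(pi_tab$id, calls$tsr_id)]
      data.table::fwrite(pi_tab, file.path(sdir, "pausing.tsv"), sep = "\t")
      smry$median_pausing_stable <- stats::median(pi_tab$index[pi_tab$class == "stable"])
      smry$median_pausing_unstable <- stats::median(pi_tab$index[pi_tab$class == "unstable"])
    }

    if (want("hexamer") && !is.null(d$genome) && nrow(tsrs) > 0L &&
        smry$n_stable > 0L && smry$n_unstable > 0L) {
      anch <- data.frame(chrom = tsrs$chrom, strand = tsrs$strand,
                         pos = tsrs$major_tss, id = tsrs$id)
      cls <- calls$class[match(tsrs$id, calls$tsr_id)]
      ws <- suppressWarnings(extract_windows(d$genome, anch[cls == "stable", ],
                                             hexamer_window[1], hexamer_window[2]))
      wu <- suppressWarnings(extract_windows(d$genome, anch[cls == "unstable", ],
                                             hexamer_window[1], hexamer_window[2]))
      if (length(ws) > 0L && length(wu) > 0L) {
        hx <- hexamer_stability_ranks(ws, wu)
        data.table::fwrite(hx, file.path(sdir, "hexamer.tsv"), sep = "\t")
      }
    }

    if (want("ntmeta") && !is.null(d$genome) && nrow(tsrs) > 0L) {
      anch <- data.frame(chrom = tsrs$chrom, strand = tsrs$strand,
                         pos = tsrs$major_tss)
      nm <- suppressWarnings(nucleotide_metaplot(anch, d$genome, flank = 50L))
      utils::write.table(data.frame(base = rownames(nm), nm, check.names = FALSE),
                         file.path(sdir, "nt_metaplot.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }

    if (want("starr") && !is.null(d$starr)) {
      act_col <- if ("activity" %in% names(d$starr)) "activity" else "score"
      pk <- filter_fragments(d$starr)
      ms <- merge_and_score(tsrs, d$atac, pk, calls = calls, styles = styles)
      data.table::fwrite(ms, file.path(sdir, "starr_merged.tsv"), sep = "\t")
      cov <- ms[ms$covered, , drop = FALSE]
      smry$starr_tsr_coverage_pct <-
        if (nrow(tsrs) > 0) 100 * mean(!is.na(ms$tsr_id[ms$covered])) else NA
      if (length(unique(cov$class)) >= 2L && all(table(cov$class) >= 2L)) {
        gc <- group_compare(cov$per_bp_activity, cov$class)
        smry$starr_anova_F <- gc$F
        smry$starr_anova_p <- gc$p
        smry$starr_group_means <- as.list(gc$group_means)
        smry$starr_tukey <- gc$tukey
        data.table::fwrite(gc$tukey, file.path(sdir, "starr_tukey.tsv"), sep = "\t")
      }
      tx <- cov[!is.na(cov$tsr_norm), , drop = FALSE]
      if (nrow(tx) >= 3L) {
        r <- activity_correlation(tx$tsr_norm, tx$per_bp_activity)
        smry$starr_activity_correlation <- as.numeric(r)
      }
    }
    all_tsrs[[sn]] <- tsrs
    all_calls[[sn]] <- calls
    summary$samples[[sn]] <- smry
  }

  if ((is.null(stages) && length(sample_dirs) >= 2L) ||
      (!is.null(stages) && "switch" %in% stages)) {
    sw <- switch_analysis(all_tsrs, all_calls)
    data.table::fwrite(sw$table, file.path(outdir, "switch.tsv"), sep = "\t")
    summary$pct_switching <- sw$pct_switching
    summary$n_switch_regions <- sw$n_multi
  }
  summary$starr_tukey <- NULL  # data.frame not JSON-scalar; kept per sample file
  for (sn in names(summary$samples)) summary$samples[[sn]]$starr_tukey <- NULL
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
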