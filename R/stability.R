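#' Classify TSRs as initiating stable or unstable transcripts
#'
#' The stability score of a TSR is the normalized (per 10^7) total RNA-seq
#' signal on the TSR's own (sense) strand within -100..+500 bp of its major
#' TSS, oriented along transcription. A TSR is called `unstable` when the
#' score is strictly below `threshold` (default 2): nascent initiation seen
#' by csRNA-seq with essentially no steady-state RNA downstream. The window
#' is clipped implicitly at chromosome edges (positions outside the
#' chromosome carry no signal).
#'
#' @param tsrs TSR table (needs `chrom,strand,major_tss`; `id` used if
#'   present).
#' @param rnaseq total RNA-seq [end_profile()] (read 5'-end counts by
#'   default; a per-base coverage track works identically since both are
#'   summed over the window). Will be normalized if raw.
#' @param threshold stability threshold in per-10^7 units.
#' @param window inclusive offsets around the major TSS, default
#'   `c(-100, 500)`.
#' @return data.frame `tsr_id,score,class` with `class` in
#'   `{"stable","unstable"}`.
#' @export
classify_stability <- function(tsrs, rnaseq, threshold = 2.0,
                               window = c(-100L, 500L)) {
  if (any(is.na(tsrs$major_tss))) stop("every TSR needs a major TSS")
  rn <- if (rnaseq$normalized) rnaseq else normalize_profile(rnaseq)
  anchors <- data.frame(chrom = tsrs$chrom, strand = tsrs$strand,
                        pos = tsrs$major_tss)
  score <- window_sums(rn, anchors, window[1], window[2], same_strand = TRUE)
  ids <- if ("id" %in% names(tsrs)) tsrs$id else as.character(seq_len(nrow(tsrs)))
  data.frame(tsr_id = ids, score = score,
             class = ifelse(score < threshold, "unstable", "stable"))
}

#' Histogram of stability scores on the log10(x + 1) scale
#'
#' @param calls output of [classify_stability()].
#' @param binwidth width of histogram bins in log10 units.
#' @return data.frame `bin_lo,bin_mid,class,count`; the bimodal stable /
#'   unstable structure shows as two modes.
#' @export
stability_distribution <- function(calls, binwidth = 0.1) {
  stopifnot(nrow(calls) >= 1L)
  x <- log10(calls$score + 1)
  bin <- floor(x / binwidth + 1e-9)
  dt <- data.table::data.table(bin = bin, class = calls$class)
  out <- dt[, list(count = .N), by = c("bin", "class")]
  out[, "bin_lo" := out$bin * binwidth]
  out[, "bin_mid" := out$bin_lo + binwidth / 2]
  data.table::setorderv(out, c("bin", "class"))
  as.data.frame(out[, c("bin_lo", "bin_mid", "class", "count")])
}

#' Cross-sample stability switch analysis
#'
#' Builds a union TSR set across samples by strand-aware overlap merging
#' (same-strand overlapping TSRs unify), assigns each sample's stability
#' call to the union regions, and reports the percentage of regions —
#' among those detected in at least two samples — classified stable in one
#' sample and unstable in another. A TSR absent from a sample contributes
#' no class there: absence of detection is not evidence of instability.
#'
#' @param per_sample_tsrs named list of TSR tables (one per sample).
#' @param per_sample_calls named list of matching [classify_stability()]
#'   outputs.
#' @param merge_dist maximum gap in bp for two TSRs to be merged into the
#'   same union region (0 = require overlap).
#' @return list with `table` (per union region: per-sample class columns,
#'   `n_detected`, `switch`), `pct_switching` (over regions detected in
#'   >= 2 samples), and `n_multi`.
#' @export
switch_analysis <- function(per_sample_tsrs, per_sample_calls, merge_dist = 0L) {
  if (length(per_sample_tsrs) < 2L) stop("switch analysis requires >= 2 samples")
  stopifnot(length(per_sample_tsrs) == length(per_sample_calls))
  samples <- names(per_sample_tsrs)
  if (is.null(samples)) samples <- paste0("sample", seq_along(per_sample_tsrs))
  all_gr <- do.call(c, unname(lapply(per_sample_tsrs, function(t)
    GenomicRanges::GRanges(t$chrom, IRanges::IRanges(t$start + 1L, t$end),
                           strand = t$strand))))
  union_gr <- GenomicRanges::reduce(all_gr, min.gapwidth = merge_dist + 1L,
                                    ignore.strand = FALSE)
  n_u <- length(union_gr)
  cls <- matrix(NA_character_, nrow = n_u, ncol = length(samples),
                dimnames = list(NULL, samples))
  for (k in seq_along(samples)) {
    t <- per_sample_tsrs[[k]]
    if (nrow(t) == 0L) next
    calls <- per_sample_calls[[k]]
    gr <- GenomicRanges::GRanges(t$chrom, IRanges::IRanges(t$start + 1L, t$end),
                                 strand = t$strand)
    hits <- GenomicRanges::findOverlaps(gr, union_gr)
    if (length(hits) == 0L) next
    h <- data.table::data.table(u = S4Vectors::subjectHits(hits),
                                q = S4Vectors::queryHits(hits))
    h[, "norm" := t$total_norm[h$q]]
    data.table::setorderv(h, c("u", "norm"), order = c(1L, -1L))
    h <- h[!duplicated(h$u)]       # strongest TSR represents the sample
    cls[h$u, k] <- calls$class[match(t$id[h$q], calls$tsr_id)]
  }
  n_det <- rowSums(!is.na(cls))
  sw <- apply(cls, 1L, function(r) any(r == "stable", na.rm = TRUE) &&
                                   any(r == "unstable", na.rm = TRUE))
  tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(union_gr)),
    start = GenomicRanges::start(union_gr) - 1L,
    end = GenomicRanges::end(union_gr),
    strand = as.character(GenomicRanges::strand(union_gr)),
    cls, n_detected = n_det, switch = sw, check.names = FALSE)
  multi <- n_det >= 2L
  pct <- if (any(multi)) 100 * mean(sw[multi]) else NA_real_
  list(table = tab, pct_switching = pct, n_multi = sum(multi))
}
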