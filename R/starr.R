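#' Remove short STARR-seq library fragments
#'
#' Fragments of 1-50 bp are dropped: in the source assay these short
#' fragments disproportionately showed no enhancer activity even when
#' longer fragments of the same locus did.
#'
#' @param peaks region table with `chrom,start,end` (0-based half-open)
#'   and an activity column.
#' @param min_keep_len minimum retained length in bp (default 51).
#' @return Filtered region table.
#' @export
filter_fragments <- function(peaks, min_keep_len = 51L) {
  len <- peaks$end - peaks$start
  out <- peaks[len >= min_keep_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge TSRs with open-chromatin regions and score per-bp STARR activity
#'
#' TSR spans and assayed open-chromatin regions are unified
#' (strand-agnostic overlap merging). Each STARR peak is assigned to the
#' merged region containing its midpoint (so a peak straddling two
#' regions is counted once), activities of contained peaks are summed,
#' and the per-bp activity of a merged region is
#' `100 * sum(activities) / region_length`. Each merged region is then
#' labelled by the transcription initiating in it: `no_transcription`
#' when no TSR overlaps (strand ignored — reporter activity has no
#' strand), otherwise the stability class of the strongest overlapping
#' TSR, with the initiation style of that TSR as substyle for unstable
#' regions.
#'
#' @param tsrs TSR table (may be empty).
#' @param open_chromatin region table of assayed regions (may be NULL).
#' @param peaks filtered STARR peak table with an `activity` column (the
#'   `score` column is used when `activity` is absent).
#' @param calls stability calls for `tsrs` (optional; without it classes
#'   are `transcribed`/`no_transcription`).
#' @param styles initiation styles for `tsrs` (optional).
#' @return data.frame `region_id,chrom,start,end,length,n_peaks,
#'   activity_sum,per_bp_activity,covered,class,substyle`.
#' @export
merge_and_score <- function(tsrs, open_chromatin, peaks,
                            calls = NULL, styles = NULL) {
  grl <- list()
  if (!is.null(tsrs) && nrow(tsrs) > 0L)
    grl$tsr <- GenomicRanges::GRanges(tsrs$chrom,
      IRanges::IRanges(tsrs$start + 1L, tsrs$end))
  if (!is.null(open_chromatin) && nrow(open_chromatin) > 0L)
    grl$oc <- GenomicRanges::GRanges(open_chromatin$chrom,
      IRanges::IRanges(open_chromatin$start + 1L, open_chromatin$end))
  if (length(grl) == 0L) stop("nothing to merge: no TSRs and no open-chromatin regions")
  merged <- GenomicRanges::reduce(do.call(c, unname(grl)), ignore.strand = TRUE)
  act <- if ("activity" %in% names(peaks)) peaks$activity else peaks$score
  n_m <- length(merged)
  asum <- numeric(n_m); npk <- integer(n_m)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    mid <- floor((peaks$start + peaks$end) / 2)
    midp <- GenomicRanges::GRanges(peaks$chrom,
      IRanges::IRanges(mid + 1L, width = 1L))
    ov <- GenomicRanges::findOverlaps(midp, merged, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      dt <- data.table::data.table(m = S4Vectors::subjectHits(ov),
                                   a = act[S4Vectors::queryHits(ov)])
      agg <- dt[, list(s = sum(a), n = .N), by = "m"]
      asum[agg$m] <- agg$s; npk[agg$m] <- agg$n
    }
  }
  len <- GenomicRanges::width(merged)
  cls <- rep("no_transcription", n_m)
  sub <- rep("none", n_m)
  tsr_id <- rep(NA_character_, n_m)
  tsr_norm <- rep(NA_real_, n_m)
  if (!is.null(tsrs) && nrow(tsrs) > 0L) {
    tsr_gr <- GenomicRanges::GRanges(tsrs$chrom,
      IRanges::IRanges(tsrs$start + 1L, tsrs$end))
    ov2 <- GenomicRanges::findOverlaps(tsr_gr, merged, ignore.strand = TRUE)
    if (length(ov2) > 0L) {
      h <- data.table::data.table(m = S4Vectors::subjectHits(ov2),
                                  q = S4Vectors::queryHits(ov2))
      h[, "norm" := tsrs$total_norm[h$q]]
      data.table::setorderv(h, c("m", "norm"), order = c(1L, -1L))
      h <- h[!duplicated(h$m)]    # strongest overlapping TSR labels the region
      tsr_id[h$m] <- tsrs$id[h$q]
      tsr_norm[h$m] <- tsrs$total_norm[h$q]
      if (is.null(calls)) {
        cls[h$m] <- "transcribed"
      } else {
        cls[h$m] <- calls$class[match(tsrs$id[h$q], calls$tsr_id)]
      }
      if (!is.null(styles)) {
        st <- styles$style[match(tsrs$id[h$q], styles$tsr_id)]
        sub[h$m] <- ifelse(cls[h$m] == "unstable", st, "none")
      }
    }
  }
  data.frame(
    region_id = sprintf("%s:%d-%d",
                        as.character(GenomicRanges::seqnames(merged)),
                        GenomicRanges::start(merged) - 1L,
                        GenomicRanges::end(merged)),
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    length = len, n_peaks = npk, activity_sum = asum,
    per_bp_activity = 100 * asum / len,
    covered = npk > 0L, class = cls, substyle = sub,
    tsr_id = tsr_id, tsr_norm = tsr_norm, row.names = NULL)
}

#' One-way ANOVA with Tukey HSD across activity groups
#'
#' Compares per-bp STARR activities between groups (e.g. no_transcription
#' / stable / unstable classes, or U / UU / US substyles) by one-way
#' ANOVA followed by Tukey's honestly significant difference test for all
#' pairwise comparisons. If every observation is identical the comparison
#' is degenerate and `F = 0`, `p = 1` is reported with all pairwise
#' adjusted p-values 1.
#'
#' @param values numeric vector of per-bp activities.
#' @param groups group label per value (>= 2 groups with >= 2 values each).
#' @return list `F`, `p`, `tukey` (data.frame `pair,diff,lwr,upr,p_adj`),
#'   `group_means`.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least two values")
  gm <- tapply(values, groups, mean)
  if (stats::var(values) == 0) {
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2L)
    tk <- data.frame(pair = paste(pairs[2L, ], pairs[1L, ], sep = "-"),
                     diff = 0, lwr = 0, upr = 0, p_adj = 1)
    return(list(F = 0, p = 1, tukey = tk, group_means = gm))
  }
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  s <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       group_means = gm)
}

#' Correlation between transcription initiation and enhancer activity
#'
#' Pearson correlation of TSR csRNA-seq signal with per-bp STARR activity
#' after a `log10(x + 1)` transform of both sides (transform
#' configurable).
#'
#' @param tsr_signal numeric vector (normalized TSR csRNA signal).
#' @param activity numeric vector (per-bp STARR activity), same length.
#' @param method correlation method, default `"pearson"`.
#' @param transform function applied to both vectors first.
#' @return Correlation coefficient; `NA` with attribute
#'   `undefined = TRUE` when either side has zero variance.
#' @export
activity_correlation <- function(tsr_signal, activity, method = "pearson",
                                 transform = function(x) log10(x + 1)) {
  stopifnot(length(tsr_signal) == length(activity), length(activity) >= 3L)
  x <- transform(tsr_signal); y <- transform(activity)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(x, y, method = method)
}
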