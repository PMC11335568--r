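#' Promoter-proximal pausing index
#'
#' Ratio of sense-strand signal near the TSS (offsets -100..+300,
#' inclusive, 401 bases) to downstream gene-body signal (+301..+3000,
#' 2,700 bases), with a pseudocount of 1 read added to both numerator and
#' denominator so TSSs with empty gene bodies remain defined.
#'
#' @param tss data.frame with `chrom,strand,pos` (major TSSs; an `id`
#'   column is carried through).
#' @param track strand-specific [end_profile()] (e.g. GRO-seq).
#' @param proximal,distal inclusive offset windows.
#' @return data.frame `id,proximal,distal,index`.
#' @export
pausing_index <- function(tss, track,
                          proximal = c(-100L, 300L), distal = c(301L, 3000L)) {
  anchors <- data.frame(chrom = tss$chrom, strand = tss$strand, pos = tss$pos)
  p <- window_sums(track, anchors, proximal[1], proximal[2])
  d <- window_sums(track, anchors, distal[1], distal[2])
  ids <- if ("id" %in% names(tss)) tss$id else as.character(seq_len(nrow(tss)))
  data.frame(id = ids, proximal = p, distal = d,
             index = (p + 1) / (d + 1))
}

#' Aggregate signal metaplot around reference positions
#'
#' Signal within `half_width` bp of each reference position is assigned a
#' strand-oriented offset (positive downstream) and summed into bins of
#' `bin_size` bp across all references. In `percent_total` mode the bins
#' are rescaled so the whole curve sums to 100.
#'
#' @param refs data.frame `chrom,strand,pos`.
#' @param profile [end_profile()].
#' @param half_width half-width of the window in bp.
#' @param bin_size bin width in bp; must divide `2 * half_width`.
#' @param normalize `"percent_total"` or `"raw"`.
#' @param same_strand aggregate signal on the reference's strand (sense)
#'   or the opposite strand.
#' @return data.frame `offset` (bin left edge, strand-oriented), `signal`.
#' @export
signal_metaplot <- function(refs, profile, half_width = 1000L, bin_size = 10L,
                            normalize = c("percent_total", "raw"),
                            same_strand = TRUE) {
  normalize <- match.arg(normalize)
  if ((2L * half_width) %% bin_size != 0L)
    stop("bin_size must divide 2 * half_width")
  edges <- seq(-half_width, half_width, by = bin_size)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  cnt <- profile$counts
  if (nrow(cnt) > 0L && nrow(refs) > 0L) {
    qs <- refs$strand
    if (!same_strand) qs <- ifelse(qs == "+", "-", "+")
    q <- data.table::data.table(
      chrom = refs$chrom, strand = qs,
      lo = refs$pos - half_width, hi = refs$pos + half_width,
      rpos = refs$pos, rstrand = refs$strand)
    hits <- cnt[q, on = c("chrom", "strand", "pos>=lo", "pos<=hi"),
                nomatch = NULL,
                list(off = ifelse(rstrand == "+", x.pos - rpos, rpos - x.pos),
                     value = value)]
    if (nrow(hits) > 0L) {
      b <- findInterval(hits$off, edges, rightmost.closed = TRUE)
      ok <- b >= 1L & b <= nb
      acc <- as.numeric(tapply(hits$value[ok], factor(b[ok], levels = seq_len(nb)), sum))
      acc[is.na(acc)] <- 0
    }
  }
  if (normalize == "percent_total" && sum(acc) > 0) acc <- 100 * acc / sum(acc)
  data.frame(offset = edges[-length(edges)], signal = acc)
}

#' Windowed log2 ratio between two tracks
#'
#' `log2((A + 1) / (B + 1))` of the summed sense-strand signal of two
#' tracks over an inclusive offset window downstream of each TSS (default
#' +1..+600, the region just downstream of the TSS used for
#' histone-modification quantification). The pseudocount of 1 read on
#' both sides avoids division by zero and buffers low signal.
#'
#' @param tss data.frame `chrom,strand,pos`.
#' @param track_a,track_b comparably normalized [end_profile()]s.
#' @param window inclusive offsets, default `c(1, 600)`.
#' @return Numeric vector of log2 ratios, one per TSS.
#' @export
window_log_ratio <- function(tss, track_a, track_b, window = c(1L, 600L)) {
  anchors <- data.frame(chrom = tss$chrom, strand = tss$strand, pos = tss$pos)
  a <- window_sums(track_a, anchors, window[1], window[2])
  b <- window_sums(track_b, anchors, window[1], window[2])
  log2((a + 1) / (b + 1))
}
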