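# Nearest annotated transcript 5' end for each TSR major TSS.
# Signed distance is oriented by the *annotation's* strand: positive means
# the TSR lies downstream of the annotated TSS in its direction of
# transcription, negative upstream.

#' Nearest annotated 5' end
#'
#' @param tsrs TSR table (`chrom,strand,major_tss`).
#' @param annotation data.frame from [read_gtf()].
#' @return data.frame with `nearest_tx`, `ann_strand`, `same_strand`,
#'   `distance` (signed, annotation-oriented) and `abs_distance`; all-`NA`
#'   rows when the annotation is empty.
#' @export
nearest_five_prime <- function(tsrs, annotation) {
  n <- nrow(tsrs)
  out <- data.frame(nearest_tx = rep(NA_character_, n),
                    ann_strand = NA_character_, same_strand = NA,
                    distance = NA_real_, abs_distance = NA_real_)
  if (is.null(annotation) || nrow(annotation) == 0L || n == 0L) return(out)
  ann <- data.table::as.data.table(annotation)
  data.table::setorderv(ann, c("chrom", "five_prime_end", "transcript_id"))
  for (ch in unique(tsrs$chrom)) {
    a <- ann[ann$chrom == ch]
    ix <- which(tsrs$chrom == ch)
    if (nrow(a) == 0L || length(ix) == 0L) next
    apos <- a$five_prime_end
    p <- tsrs$major_tss[ix]
    right <- findInterval(p, apos) # last apos <= p (apos sorted, ties fine)
    left <- pmax(right, 1L)
    nxt <- pmin(right + 1L, nrow(a))
    d_left <- abs(p - apos[left])
    d_right <- abs(p - apos[nxt])
    use_right <- (right == 0L) | (d_right < d_left)
    best <- ifelse(use_right, nxt, left)
    out$nearest_tx[ix] <- a$transcript_id[best]
    out$ann_strand[ix] <- a$strand[best]
    out$same_strand[ix] <- a$strand[best] == tsrs$strand[ix]
    out$distance[ix] <- ifelse(a$strand[best] == "+",
                               p - apos[best], apos[best] - p)
    out$abs_distance[ix] <- abs(p - apos[best])
  }
  out
}

#' Genomic-context classification of TSRs
#'
#' Each TSR is classified relative to the nearest annotated transcript 5'
#' end, with mutually exclusive classes assigned in priority order:
#' \enumerate{
#'   \item `tss_sense` — same strand, within `sense_window` bp (default
#'     +/-275) of the annotated TSS;
#'   \item `tss_divergent` — opposite strand, initiating from -1 to
#'     -275 bp upstream of the annotated TSS;
#'   \item `tss_antisense` — opposite strand, 0 to +300 bp downstream;
#'   \item `single_exon_gene` / `exonic` — major TSS inside a same-strand
#'     transcript span (single- vs multi-exon);
#'   \item `mirna_proximal` — within `mirna_window` bp of an annotated
#'     miRNA gene (heuristic window, flagged in output);
#'   \item `distal` — none of the above.
#' }
#'
#' @param tsrs TSR table.
#' @param annotation data.frame from [read_gtf()]; empty/NULL means every
#'   TSR is `distal`.
#' @param sense_window,divergent_window,antisense_window,mirna_window
#'   class windows in bp (divergent/antisense as inclusive signed ranges).
#' @return data.frame `tsr_id,context,distance,nearest_tx` plus logical
#'   `mirna_heuristic` marking class-5 calls.
#' @export
classify_context <- function(tsrs, annotation,
                             sense_window = 275L,
                             divergent_window = c(-275L, -1L),
                             antisense_window = c(0L, 300L),
                             mirna_window = 1000L) {
  ids <- if ("id" %in% names(tsrs)) tsrs$id else as.character(seq_len(nrow(tsrs)))
  nf <- nearest_five_prime(tsrs, annotation)
  ctx <- rep("distal", nrow(tsrs))
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    d <- nf$distance
    same <- nf$same_strand
    ctx[!same & d >= antisense_window[1] & d <= antisense_window[2]] <- "tss_antisense"
    ctx[!same & d >= divergent_window[1] & d <= divergent_window[2]] <- "tss_divergent"
    ctx[same & abs(d) <= sense_window] <- "tss_sense"
    rest <- which(ctx == "distal")
    if (length(rest) > 0L) {
      ann_gr <- GenomicRanges::GRanges(annotation$chrom,
        IRanges::IRanges(annotation$start + 1L, annotation$end),
        strand = annotation$strand)
      pt <- GenomicRanges::GRanges(tsrs$chrom[rest],
        IRanges::IRanges(tsrs$major_tss[rest] + 1L, width = 1L),
        strand = tsrs$strand[rest])
      ov <- GenomicRanges::findOverlaps(pt, ann_gr, ignore.strand = FALSE)
      if (length(ov) > 0L) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        first <- !duplicated(qh)
        ne <- annotation$n_exons[sh[first]]
        ctx[rest[qh[first]]] <- ifelse(!is.na(ne) & ne == 1L,
                                       "single_exon_gene", "exonic")
      }
      mir <- annotation[!is.na(annotation$biotype) & annotation$biotype == "miRNA", , drop = FALSE]
      rest2 <- which(ctx == "distal")
      if (nrow(mir) > 0L && length(rest2) > 0L) {
        mgr <- GenomicRanges::GRanges(mir$chrom,
          IRanges::IRanges(mir$start + 1L, mir$end))
        pt2 <- GenomicRanges::GRanges(tsrs$chrom[rest2],
          IRanges::IRanges(tsrs$major_tss[rest2] + 1L, width = 1L))
        dd <- GenomicRanges::distanceToNearest(pt2, mgr, ignore.strand = TRUE)
        hit <- S4Vectors::queryHits(dd)[S4Vectors::mcols(dd)$distance <= mirna_window]
        ctx[rest2[hit]] <- "mirna_proximal"
      }
    }
  }
  data.frame(tsr_id = ids, context = ctx, distance = nf$distance,
             nearest_tx = nf$nearest_tx,
             mirna_heuristic = ctx == "mirna_proximal")
}

#' Unstable/stable TSR ratios by distance to annotated 5' ends
#'
#' TSRs are binned by absolute distance of their major TSS to the nearest
#' annotated transcript 5' end: `<=100`, `101-1000`, `1001-2000` and
#' `>2000` bp. Within each bin the ratio of unstable to stable TSRs is
#' reported; when either count is zero, a pseudocount of 1 is added to
#' both before dividing.
#'
#' @param tsrs TSR table.
#' @param calls stability calls from [classify_stability()] (every TSR
#'   must have one).
#' @param annotation data.frame from [read_gtf()]; must be non-empty.
#' @return data.frame `bin,n_stable,n_unstable,ratio`.
#' @export
distance_bin_ratios <- function(tsrs, calls, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L)
    stop("distance bins require a non-empty annotation")
  ids <- if ("id" %in% names(tsrs)) tsrs$id else as.character(seq_len(nrow(tsrs)))
  cls <- calls$class[match(ids, calls$tsr_id)]
  if (any(is.na(cls))) stop("every TSR needs a stability call")
  nf <- nearest_five_prime(tsrs, annotation)
  breaks <- c(-1, 100, 1000, 2000, Inf)
  labels <- c("<=100", "101-1000", "1001-2000", ">2000")
  bin <- cut(nf$abs_distance, breaks = breaks, labels = labels)
  ns <- tapply(cls == "stable", bin, sum)
  nu <- tapply(cls == "unstable", bin, sum)
  ns[is.na(ns)] <- 0L; nu[is.na(nu)] <- 0L
  pseud <- ns == 0L | nu == 0L
  ratio <- ifelse(pseud, (nu + 1) / (ns + 1), nu / ns)
  data.frame(bin = labels, n_stable = as.integer(ns), n_unstable = as.integer(nu),
             ratio = as.numeric(ratio), row.names = NULL)
}

#' Promoter-proximal antisense-to-sense TSR ratio
#'
#' Counts TSRs whose major TSS lies within `window` bp (default +/-275) of
#' any annotated transcript 5' end, split by whether the TSR is on the
#' annotated gene's strand (sense-mapped) or the opposite strand
#' (antisense-mapped), and returns antisense / sense.
#'
#' @param tsrs TSR table.
#' @param annotation data.frame from [read_gtf()].
#' @param window half-width in bp around annotated 5' ends.
#' @return Single numeric ratio; `NA` with attribute `undefined = TRUE`
#'   when no TSR maps in sense.
#' @export
antisense_ratio <- function(tsrs, annotation, window = 275L) {
  if (nrow(tsrs) == 0L || is.null(annotation) || nrow(annotation) == 0L)
    return(structure(NA_real_, undefined = TRUE))
  # expand each annotated 5' end to [pos - window, pos + window] so plain
  # overlap means |TSS - annotated 5' end| <= window exactly
  five <- GenomicRanges::GRanges(annotation$chrom,
    IRanges::IRanges(pmax(annotation$five_prime_end + 1L - window, 1L),
                     annotation$five_prime_end + 1L + window),
    strand = annotation$strand)
  tsr_gr <- GenomicRanges::GRanges(tsrs$chrom,
    IRanges::IRanges(tsrs$major_tss + 1L, width = 1L), strand = tsrs$strand)
  sense_hit <- GenomicRanges::countOverlaps(tsr_gr, five,
                                            ignore.strand = FALSE) > 0L
  flip <- tsr_gr
  GenomicRanges::strand(flip) <- ifelse(tsrs$strand == "+", "-", "+")
  anti_hit <- GenomicRanges::countOverlaps(flip, five,
                                           ignore.strand = FALSE) > 0L
  n_sense <- sum(sense_hit)
  if (n_sense == 0L) return(structure(NA_real_, undefined = TRUE))
  sum(anti_hit) / n_sense
}
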