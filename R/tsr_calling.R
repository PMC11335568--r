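#' Parameters for TSS/TSR calling
#'
#' Defaults follow the published csRNA-seq calling procedure: a candidate
#' TSS needs at least 7 reads per 10^7 aligned reads, a TSR at least 10,
#' TSSs are clustered within 200 bp, and any position or region where the
#' short-RNA input library has higher normalized density than csRNA-seq is
#' discarded as a likely non-initiating contaminant.
#'
#' @param tss_min_norm minimum normalized (per 10^7) signal for a single
#'   TSS position.
#' @param tsr_min_norm minimum summed normalized signal for a reported TSR.
#' @param cluster_dist maximum span of one TSS cluster in bp; the greedy
#'   seed claims members within `cluster_dist / 2` on either side.
#' @param input_fold a TSS/TSR is discarded when input density exceeds
#'   `input_fold` times the csRNA density (1 = strictly higher input).
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(tss_min_norm = 7, tsr_min_norm = 10,
                          cluster_dist = 200, input_fold = 1.0) {
  stopifnot(tss_min_norm > 0, tsr_min_norm > 0, cluster_dist > 0, input_fold > 0)
  structure(list(tss_min_norm = tss_min_norm, tsr_min_norm = tsr_min_norm,
                 cluster_dist = cluster_dist, input_fold = input_fold),
            class = "caller_params")
}

#' Call candidate single-nucleotide TSSs
#'
#' Keeps positions where the normalized csRNA-seq signal reaches
#' `tss_min_norm` and the short-RNA input signal at the same position does
#' not exceed `input_fold` times the csRNA signal (positions dominated by
#' the input are typically miRNAs and other abundant non-initiating RNAs
#' surviving cap enrichment).
#'
#' @param cs normalized csRNA-seq [end_profile()].
#' @param input normalized short-RNA input [end_profile()].
#' @param params [caller_params()].
#' @return data.frame of TSS records: `chrom,strand,pos,norm,input_norm`.
#' @export
call_candidate_tss <- function(cs, input, params = caller_params()) {
  stopifnot(inherits(cs, "end_profile"), inherits(input, "end_profile"))
  if (!cs$normalized || !input$normalized)
    stop("profiles must be normalized to per-10^7 before TSS calling")
  cand <- cs$counts[cs$counts$value >= params$tss_min_norm]
  if (nrow(cand) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      pos = integer(), norm = numeric(), input_norm = numeric()))
  }
  inp <- profile_value_at(input, cand)
  keep <- inp <= params$input_fold * cand$value
  out <- data.frame(chrom = cand$chrom, strand = cand$strand, pos = cand$pos,
                    norm = cand$value, input_norm = inp)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Deterministic calling order: strongest first; ties resolved to the
# 5'-most position relative to the strand, then lexicographic chromosome.
tss_calling_order <- function(tss) {
  pos5 <- ifelse(tss$strand == "+", tss$pos, -tss$pos)
  order(-tss$norm, pos5, tss$chrom)
}

#' Cluster TSSs into transcription start regions (TSRs)
#'
#' Greedy strongest-first clustering: the strongest unclaimed TSS seeds a
#' TSR and claims all unclaimed same-strand TSSs within `cluster_dist / 2`
#' bp on either side; the next strongest unclaimed TSS seeds the next TSR,
#' and so on. Seeding in strength order with a fixed claim window (rather
#' than single-linkage gap merging) guarantees that no reported TSR spans
#' more than `cluster_dist` bp. The TSR span is the tight hull of its
#' member TSSs; its major TSS is the seed; its signal is the sum of member
#' normalized counts. TSRs below `tsr_min_norm` are discarded.
#'
#' @param tss data.frame from [call_candidate_tss()].
#' @param params [caller_params()].
#' @return data.frame of TSRs: `id,chrom,strand,start,end,major_tss,
#'   total_norm,n_tss`, with the member TSS table (plus `tsr_id`) in
#'   `attr(, "members")`.
#' @export
cluster_tsrs <- function(tss, params = caller_params()) {
  half <- floor(params$cluster_dist / 2)
  empty <- data.frame(id = character(), chrom = character(), strand = character(),
                      start = integer(), end = integer(), major_tss = integer(),
                      total_norm = numeric(), n_tss = integer())
  if (nrow(tss) == 0L) {
    attr(empty, "members") <- cbind(tss, tsr_id = character(0))
    return(empty)
  }
  tss <- as.data.frame(tss)
  ord <- tss_calling_order(tss)
  key <- paste(tss$chrom, tss$strand)
  claimed <- logical(nrow(tss))
  assign_id <- integer(nrow(tss))
  seeds <- integer(0)
  # per-group position-sorted index for fast window lookup
  groups <- split(seq_len(nrow(tss)), key)
  groups <- lapply(groups, function(ix) ix[order(tss$pos[ix])])
  n_tsr <- 0L
  for (i in ord) {
    if (claimed[i]) next
    n_tsr <- n_tsr + 1L
    seeds[n_tsr] <- i
    g <- groups[[key[i]]]
    gpos <- tss$pos[g]
    lo <- findInterval(tss$pos[i] - half - 1L, gpos) + 1L
    hi <- findInterval(tss$pos[i] + half, gpos)
    if (hi >= lo) {
      mem <- g[lo:hi]
      mem <- mem[!claimed[mem]]
      claimed[mem] <- TRUE
      assign_id[mem] <- n_tsr
    }
  }
  res <- data.table::data.table(tsr = assign_id, pos = tss$pos, norm = tss$norm)
  agg <- res[, list(start = min(pos), end = max(pos) + 1L,
                    total_norm = sum(norm), n_tss = .N), by = "tsr"]
  data.table::setorderv(agg, "tsr")
  out <- data.frame(
    chrom = tss$chrom[seeds[agg$tsr]],
    strand = tss$strand[seeds[agg$tsr]],
    start = agg$start, end = agg$end,
    major_tss = tss$pos[seeds[agg$tsr]],
    total_norm = agg$total_norm, n_tss = agg$n_tss)
  out$id <- sprintf("%s:%d-%d:%s", out$chrom, out$start, out$end, out$strand)
  keep <- out$total_norm >= params$tsr_min_norm
  members <- cbind(tss, tsr_id = out$id[assign_id])
  out <- out[keep, c("id", "chrom", "strand", "start", "end",
                     "major_tss", "total_norm", "n_tss")]
  ord2 <- order(out$chrom, out$start, out$strand)
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  members <- members[members$tsr_id %in% out$id, , drop = FALSE]
  rownames(members) <- NULL
  attr(out, "members") <- members
  out
}

#' Major TSS of each TSR
#'
#' The member TSS with the highest normalized count; ties resolve to the
#' 5'-most member relative to the TSR's strand.
#'
#' @param tsrs TSR table from [cluster_tsrs()] (must carry its `members`
#'   attribute), or a member table with a `tsr_id` column passed via
#'   `members`.
#' @param members optional explicit member table.
#' @return data.frame `tsr_id,chrom,strand,pos,norm` (one row per TSR).
#' @export
major_tss <- function(tsrs, members = attr(tsrs, "members")) {
  if (is.null(members)) stop("no member TSS table available")
  if (nrow(members) == 0L) stop("TSR has no member TSSs")
  m <- data.table::as.data.table(members)
  m[, "pos5" := ifelse(m$strand == "+", m$pos, -m$pos)]
  data.table::setorderv(m, c("tsr_id", "norm", "pos5"), order = c(1L, -1L, 1L))
  top <- m[!duplicated(m$tsr_id)]
  out <- as.data.frame(top[, c("tsr_id", "chrom", "strand", "pos", "norm")])
  rownames(out) <- NULL
  out
}

#' Remove TSRs dominated by the short-RNA input library
#'
#' A TSR is discarded when the summed normalized input density over its
#' span exceeds `input_fold` times the summed csRNA density there —
#' the region-level version of the per-position false-positive filter.
#'
#' @param tsrs TSR table.
#' @param cs,input normalized [end_profile()]s.
#' @param params [caller_params()].
#' @return Filtered TSR table (members attribute subset accordingly).
#' @export
filter_tsr_by_input <- function(tsrs, cs, input, params = caller_params()) {
  if (nrow(tsrs) == 0L) return(tsrs)
  if (!cs$normalized || !input$normalized) stop("profiles must be normalized")
  q <- data.table::data.table(chrom = tsrs$chrom, strand = tsrs$strand,
                              lo = tsrs$start, hi = tsrs$end - 1L)
  span_sum <- function(p) {
    cnt <- p$counts
    if (nrow(cnt) == 0L) return(numeric(nrow(tsrs)))
    hits <- cnt[q, on = c("chrom", "strand", "pos>=lo", "pos<=hi"),
                list(s = sum(value, na.rm = TRUE)), by = .EACHI]
    s <- hits$s; s[is.na(s)] <- 0
    s
  }
  cs_sum <- span_sum(cs)
  in_sum <- span_sum(input)
  keep <- in_sum <= params$input_fold * cs_sum
  out <- tsrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  mem <- attr(tsrs, "members")
  if (!is.null(mem)) attr(out, "members") <- mem[mem$tsr_id %in% out$id, , drop = FALSE]
  out
}

#' Full TSR calling from raw profiles
#'
#' Convenience wrapper: normalize both libraries, call candidate TSSs,
#' cluster into TSRs, and apply the region-level input filter.
#'
#' @param cs_raw,input_raw raw [end_profile()]s.
#' @param params [caller_params()].
#' @return TSR table (see [cluster_tsrs()]).
#' @export
call_tsrs <- function(cs_raw, input_raw, params = caller_params()) {
  cs <- if (cs_raw$normalized) cs_raw else normalize_profile(cs_raw)
  input <- if (input_raw$normalized) input_raw else normalize_profile(input_raw)
  tss <- call_candidate_tss(cs, input, params)
  tsrs <- cluster_tsrs(tss, params)
  filter_tsr_by_input(tsrs, cs, input, params)
}
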