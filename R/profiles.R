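#' Strand-specific sparse 5'-end / coverage profile
#'
#' The central signal container: a sparse map from (chromosome, strand,
#' position) to a non-negative value, plus the library's total aligned read
#' count used for per-10^7 normalization. The same structure serves both
#' single-nucleotide 5'-end count profiles (csRNA-seq, short-RNA input,
#' RNA-seq read starts) and per-base coverage tracks (GRO-seq); the only
#' difference is whether `value` holds integer counts or float coverage.
#'
#' All coordinates are 0-based; a stored position refers to the single base
#' `[pos, pos + 1)`. Duplicate (chrom, strand, pos) rows are summed on
#' construction and zero-value rows are dropped, so two profiles with the
#' same sparse content are identical objects.
#'
#' @param counts data.frame with columns `chrom` (character), `strand`
#'   ("+" or "-"), `pos` (0-based integer), `value` (non-negative numeric).
#' @param total_reads total aligned reads in the library that produced the
#'   profile (metadata reported by the aligner, not recomputed from the
#'   stored positions). Must be positive.
#' @param normalized logical; `TRUE` if `value` is already on the
#'   per-10^7-aligned-reads scale.
#' @return An object of class `end_profile`.
#' @seealso [normalize_profile()], [read_bedgraph()], [window_sums()]
#' @export
end_profile <- function(counts, total_reads, normalized = FALSE) {
  if (is.null(counts) || nrow(counts) == 0L) {
    dt <- data.table::data.table(chrom = character(), strand = character(),
                                 pos = integer(), value = numeric())
  } else {
    dt <- data.table::as.data.table(counts)[, c("chrom", "strand", "pos", "value")]
    if (any(dt$value < 0)) stop("profile values must be non-negative")
    if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(dt$pos < 0)) stop("positions must be >= 0 (0-based)")
    dt <- dt[, list(value = sum(value)), by = c("chrom", "strand", "pos")]
    dt <- dt[dt$value > 0]
    data.table::setorderv(dt, c("chrom", "strand", "pos"))
  }
  if (!is.numeric(total_reads) || length(total_reads) != 1L ||
      is.na(total_reads) || total_reads <= 0) {
    stop("total_reads must be a single positive number")
  }
  structure(list(counts = dt, total_reads = as.numeric(total_reads),
                 normalized = isTRUE(normalized)),
            class = "end_profile")
}

#' @export
print.end_profile <- function(x, ...) {
  cat(sprintf("<end_profile> %d positions on %d chromosome(s); total_reads=%g; %s\n",
              nrow(x$counts), length(unique(x$counts$chrom)), x$total_reads,
              if (x$normalized) "normalized (per 10^7)" else "raw counts"))
  invisible(x)
}

#' Scale a profile to reads per 10^7 aligned reads
#'
#' Every stored value is multiplied by `10^7 / total_reads`, the unit in
#' which all calling and classification thresholds of this package are
#' expressed (TSS >= 7, TSR >= 10, stability < 2).
#'
#' @param profile an [end_profile()] with raw values.
#' @return The profile with values on the per-10^7 scale and
#'   `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "end_profile"))
  if (profile$normalized) stop("profile is already normalized")
  if (profile$total_reads <= 0) stop("total_reads must be positive")
  out <- profile
  out$counts <- data.table::copy(profile$counts)
  out$counts[, "value" := out$counts$value * 1e7 / profile$total_reads]
  out$normalized <- TRUE
  out
}

#' Sum profile values over strand-oriented windows around anchor positions
#'
#' For each anchor the window `[off_lo, off_hi]` is interpreted in
#' transcription direction: on the plus strand it covers genomic positions
#' `pos + off_lo .. pos + off_hi` (inclusive), on the minus strand
#' `pos - off_hi .. pos - off_lo`. Windows extending past a chromosome end
#' simply find no stored positions there, which is equivalent to clipping.
#'
#' @param profile an [end_profile()].
#' @param anchors data.frame with columns `chrom`, `strand`, `pos` (anchor
#'   positions, e.g. major TSSs).
#' @param off_lo,off_hi inclusive window offsets in bp relative to the
#'   anchor (negative = upstream).
#' @param same_strand if `TRUE` (default) sum signal on the anchor's strand
#'   (sense); if `FALSE`, on the opposite strand.
#' @return Numeric vector of window sums, one per anchor row.
#' @export
window_sums <- function(profile, anchors, off_lo, off_hi, same_strand = TRUE) {
  stopifnot(inherits(profile, "end_profile"), off_lo <= off_hi)
  a <- data.table::as.data.table(anchors)
  if (nrow(a) == 0L) return(numeric(0))
  qs <- a$strand
  if (!same_strand) qs <- ifelse(qs == "+", "-", "+")
  lo <- ifelse(a$strand == "+", a$pos + off_lo, a$pos - off_hi)
  hi <- ifelse(a$strand == "+", a$pos + off_hi, a$pos - off_lo)
  q <- data.table::data.table(chrom = a$chrom, strand = qs,
                              lo = as.integer(lo), hi = as.integer(hi))
  cnt <- profile$counts
  if (nrow(cnt) == 0L) return(numeric(nrow(a)))
  hits <- cnt[q, on = c("chrom", "strand", "pos>=lo", "pos<=hi"),
              list(s = sum(value, na.rm = TRUE)), by = .EACHI]
  s <- hits$s
  s[is.na(s)] <- 0
  s
}

#' Look up the profile value at exact positions
#'
#' @param profile an [end_profile()].
#' @param at data.frame with `chrom`, `strand`, `pos`.
#' @return Numeric vector (0 where no signal is stored).
#' @export
profile_value_at <- function(profile, at) {
  a <- data.table::as.data.table(at)[, c("chrom", "strand", "pos")]
  if (nrow(a) == 0L) return(numeric(0))
  a[, "idx" := seq_len(nrow(a))]
  m <- profile$counts[a, on = c("chrom", "strand", "pos")]
  v <- m$value
  v[is.na(v)] <- 0
  v
}
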