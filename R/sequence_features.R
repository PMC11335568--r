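#' All 4,096 hexamers in lexicographic order
#' @return Character vector of length 4096, `"AAAAAA"` first.
#' @export
enumerate_hexamers <- function() {
  sort(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 6L))
}

#' Extract strand-oriented sequence windows around anchor positions
#'
#' For a plus-strand anchor at `pos`, offsets `from..to` (inclusive, 0 =
#' the anchor base) give genomic positions `pos+from .. pos+to`; for a
#' minus-strand anchor the mirror-image window is taken and
#' reverse-complemented, so returned sequences always read in
#' transcription direction. Anchors whose window would run off the
#' chromosome are dropped (with a warning).
#'
#' @param genome `DNAStringSet` (or named character vector).
#' @param anchors data.frame with `chrom,strand,pos` (0-based).
#' @param from,to inclusive offsets in bp.
#' @return `DNAStringSet`, one entry per retained anchor, named by anchor
#'   row (or `id` column if present).
#' @export
extract_windows <- function(genome, anchors, from, to) {
  stopifnot(from <= to)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  lens <- chrom_lengths(genome)
  plus <- anchors$strand == "+"
  g_lo <- ifelse(plus, anchors$pos + from, anchors$pos - to)
  g_hi <- ifelse(plus, anchors$pos + to, anchors$pos - from)
  ok <- g_lo >= 0 & g_hi < lens[anchors$chrom] & anchors$chrom %in% names(lens)
  if (any(!ok)) warning(sum(!ok), " anchor window(s) outside chromosome bounds dropped")
  a <- anchors[ok, , drop = FALSE]
  if (nrow(a) == 0L) return(Biostrings::DNAStringSet())
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(a)), function(i) {
    as.character(Biostrings::subseq(genome[[a$chrom[i]]],
                                    start = g_lo[ok][i] + 1L,
                                    end = g_hi[ok][i] + 1L))
  }, character(1)))
  minus <- a$strand == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- if ("id" %in% names(a)) a$id else as.character(which(ok))
  seqs
}

#' Hexamer stability-ratio ranking
#'
#' Counts overlapping hexamer occurrences in downstream windows (the
#' intended windows are +1 kb..+3 kb of each major TSS, extracted with
#' [extract_windows()]) of TSRs initiating stable versus unstable
#' transcripts, normalizes each count by the number of TSRs in its class,
#' and ranks all 4,096 hexamers by the stability ratio
#' `(norm_stable + 1) / (norm_unstable + 1)` in ascending order: rank 1 is
#' the most unstable-enriched hexamer, rank 4,096 the most
#' stable-enriched. Rank ties are broken lexicographically.
#'
#' @param stable_windows,unstable_windows `DNAStringSet`s (or character
#'   vectors) of class windows; both must be non-empty.
#' @return data.frame `hexamer,count_stable,count_unstable,norm_stable,
#'   norm_unstable,ratio,rank` with exactly 4,096 rows in lexicographic
#'   hexamer order.
#' @export
hexamer_stability_ranks <- function(stable_windows, unstable_windows) {
  if (length(stable_windows) == 0L || length(unstable_windows) == 0L)
    stop("both stability classes need at least one sequence")
  hx <- enumerate_hexamers()
  count_class <- function(x) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    m <- Biostrings::oligonucleotideFrequency(x, width = 6L, step = 1L)
    colSums(m)[hx]
  }
  cs <- count_class(stable_windows)
  cu <- count_class(unstable_windows)
  ns <- cs / length(stable_windows)
  nu <- cu / length(unstable_windows)
  ratio <- (ns + 1) / (nu + 1)
  rk <- integer(4096L)
  rk[order(ratio, hx)] <- seq_len(4096L)
  data.frame(hexamer = hx, count_stable = as.numeric(cs),
             count_unstable = as.numeric(cu), norm_stable = ns,
             norm_unstable = nu, ratio = ratio, rank = rk, row.names = NULL)
}

#' Scan sequences for an IUPAC consensus pattern
#'
#' Overlapping matches of a degenerate consensus (e.g. `TATAWAAR`,
#' `AATAAA`) are located on the given sequences; with `sense_only = TRUE`
#' (default) only the forward orientation is scanned, matching how
#' RNA-processing motifs are counted on the transcribed strand. The
#' summary `per_seq` is total matches divided by the number of sequences
#' (motif occurrences per TSS when windows are one-per-TSS).
#'
#' @param sequences `DNAStringSet` or character vector.
#' @param pattern IUPAC consensus string.
#' @param sense_only if `FALSE`, matches on the reverse complement are
#'   added (positions reported on the forward sequence).
#' @return list `counts` (per sequence), `positions` (list of 0-based
#'   match start offsets per sequence), `total`, `per_seq`.
#' @export
scan_consensus <- function(sequences, pattern, sense_only = TRUE) {
  if (!grepl("^[ACGTUWSMKRYBDHVN]+$", toupper(pattern)))
    stop("invalid IUPAC letter in pattern '", pattern, "'")
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  pat <- Biostrings::DNAString(toupper(chartr("U", "T", pattern)))
  find <- function(seqs, p) {
    m <- Biostrings::vmatchPattern(p, seqs,
                                   fixed = c(pattern = FALSE, subject = TRUE))
    lapply(m, function(ir) IRanges::start(ir) - 1L)
  }
  pos <- find(sequences, pat)
  if (!sense_only) {
    rc <- find(sequences, Biostrings::reverseComplement(pat))
    pos <- Map(function(a, b) sort(unique(c(a, b))), pos, rc)
  }
  counts <- vapply(pos, length, integer(1))
  list(counts = counts, positions = pos, total = sum(counts),
       per_seq = if (length(sequences) > 0L) sum(counts) / length(sequences) else NA_real_)
}

#' Nucleotide-frequency metaplot around TSSs
#'
#' Per-offset A/C/G/T frequencies over all TSS-centred windows, read in
#' transcription direction (minus-strand windows reverse-complemented).
#' Frequencies at each offset sum to 1 over A/C/G/T (Ns are ignored in
#' the denominator). TSSs too close to a chromosome end are dropped.
#'
#' @param tss data.frame with `chrom,strand,pos`.
#' @param genome `DNAStringSet` or named character vector.
#' @param flank half-width in bp (window = offset -flank..+flank).
#' @return Numeric matrix, 4 rows (`A,C,G,T`) by `2*flank+1` columns named
#'   by offset.
#' @export
nucleotide_metaplot <- function(tss, genome, flank = 50L) {
  wins <- extract_windows(genome, tss, -flank, flank)
  if (length(wins) == 0L) stop("no TSS windows inside chromosome bounds")
  cm <- Biostrings::consensusMatrix(wins)[c("A", "C", "G", "T"), , drop = FALSE]
  tot <- colSums(cm)
  tot[tot == 0] <- 1
  freq <- sweep(cm, 2L, tot, "/")
  colnames(freq) <- as.character(seq(-flank, flank))
  freq
}
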