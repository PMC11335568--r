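# Strand-mirroring utilities.
#
# Mirroring maps every 0-based position p on a chromosome of length L to
# L - 1 - p, flips strands, and reverse-complements the sequence. A
# correct strand-aware pipeline must produce identical counts, fractions,
# ratios and rank tables on a mirrored dataset — these helpers exist so
# tests (and users) can assert that symmetry.

#' Strand-mirror a profile
#' @param profile an [end_profile()].
#' @param lengths named chromosome lengths ([chrom_lengths()]).
#' @return The mirrored profile.
#' @export
mirror_profile <- function(profile, lengths) {
  out <- profile
  dt <- data.table::copy(profile$counts)
  if (nrow(dt) > 0L) {
    dt[, "pos" := as.integer(lengths[dt$chrom] - 1L - dt$pos)]
    dt[, "strand" := ifelse(dt$strand == "+", "-", "+")]
    data.table::setorderv(dt, c("chrom", "strand", "pos"))
  }
  out$counts <- dt
  out
}

#' Strand-mirror a gene annotation
#' @param annotation data.frame from [read_gtf()].
#' @param lengths named chromosome lengths.
#' @return The mirrored annotation (5' ends recomputed).
#' @export
mirror_annotation <- function(annotation, lengths) {
  a <- annotation
  if (nrow(a) == 0L) return(a)
  L <- lengths[a$chrom]
  new_start <- as.integer(L - a$end)
  a$end <- as.integer(L - a$start)
  a$start <- new_start
  a$strand <- ifelse(a$strand == "+", "-", "+")
  a$five_prime_end <- ifelse(a$strand == "+", a$start, a$end - 1L)
  a
}

#' Strand-mirror a region table
#' @param regions data.frame with `chrom,start,end` (and optional strand).
#' @param lengths named chromosome lengths.
#' @return The mirrored region table.
#' @export
mirror_regions <- function(regions, lengths) {
  r <- regions
  if (nrow(r) == 0L) return(r)
  L <- lengths[r$chrom]
  new_start <- as.integer(L - r$end)
  r$end <- as.integer(L - r$start)
  r$start <- new_start
  if ("strand" %in% names(r))
    r$strand <- ifelse(r$strand == "+", "-", ifelse(r$strand == "-", "+", r$strand))
  r
}

#' Strand-mirror a genome
#' @param genome `DNAStringSet` or named character vector.
#' @return Reverse-complemented `DNAStringSet`.
#' @export
mirror_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::reverseComplement(genome)
}

#' Strand-mirror a simulated dataset
#' @param sim output of [simulate_dataset()].
#' @return The dataset with every coordinate, strand and sequence
#'   mirrored (truth positions included).
#' @export
mirror_dataset <- function(sim) {
  lens <- chrom_lengths(sim$genome)
  out <- sim
  out$genome <- mirror_genome(sim$genome)
  out$annotation <- mirror_annotation(sim$annotation, lens)
  for (lib in c("csrna", "input", "rnaseq", "groseq"))
    out[[lib]] <- mirror_profile(sim[[lib]], lens)
  out$starr <- mirror_regions(sim$starr, lens)
  out$atac <- mirror_regions(sim$atac, lens)
  tr <- sim$truth
  if (nrow(tr) > 0L) {
    tr$pos <- as.integer(lens[tr$chrom] - 1L - tr$pos)
    tr$strand <- ifelse(tr$strand == "+", "-", "+")
  }
  out$truth <- tr
  out
}
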