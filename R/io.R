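#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique, named sequences,
#'   uppercased.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicate sequence names in FASTA")
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome FASTA
#' @param genome named `DNAStringSet` (or named character vector).
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome `DNAStringSet` or named character vector.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  if (is.character(genome)) return(setNames(nchar(genome), names(genome)))
  setNames(Biostrings::width(genome), names(genome))
}

#' Read gene annotations from GTF
#'
#' Parses transcript features into a transcript 5'-end catalogue. The 5'
#' end is the interval start for plus-strand transcripts and the interval
#' end for minus-strand transcripts, reported in 0-based coordinates.
#'
#' @param path GTF file (GTF2.2 attribute syntax).
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open transcript span),
#'   `five_prime_end` (0-based), `n_exons`, `biotype`.
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  tx <- gr[type == "transcript"]
  if (length(tx) == 0L) {
    # fall back to exon rows grouped by transcript
    ex <- gr[type == "exon"]
    if (length(ex) == 0L) stop("GTF contains no transcript or exon features")
    dt <- data.table::data.table(
      transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
      gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
      chrom = as.character(GenomicRanges::seqnames(ex)),
      strand = as.character(GenomicRanges::strand(ex)),
      start = GenomicRanges::start(ex) - 1L,
      end = GenomicRanges::end(ex))
    ann <- dt[, list(gene_id = gene_id[1L], chrom = chrom[1L],
                     strand = strand[1L], start = min(start), end = max(end),
                     n_exons = .N), by = "transcript_id"]
    ann[, "biotype" := NA_character_]
  } else {
    mtx <- S4Vectors::mcols(tx)
    bio <- if ("gene_biotype" %in% names(mtx)) as.character(mtx$gene_biotype)
           else if ("transcript_biotype" %in% names(mtx)) as.character(mtx$transcript_biotype)
           else NA_character_
    ann <- data.table::data.table(
      transcript_id = as.character(mtx$transcript_id),
      gene_id = as.character(mtx$gene_id),
      chrom = as.character(GenomicRanges::seqnames(tx)),
      strand = as.character(GenomicRanges::strand(tx)),
      start = GenomicRanges::start(tx) - 1L,
      end = GenomicRanges::end(tx),
      n_exons = NA_integer_,
      biotype = bio)
    ex <- gr[type == "exon"]
    if (length(ex) > 0L) {
      ne <- table(as.character(S4Vectors::mcols(ex)$transcript_id))
      ann[, "n_exons" := as.integer(ne[ann$transcript_id])]
    }
    ann$n_exons[is.na(ann$n_exons)] <- 1L
  }
  if (!all(ann$strand %in% c("+", "-"))) stop("GTF transcripts must be stranded")
  ann[, "five_prime_end" := ifelse(ann$strand == "+", ann$start, ann$end - 1L)]
  data.table::setorderv(ann, c("chrom", "start", "transcript_id"))
  as.data.frame(ann)
}

#' Write gene annotations as GTF
#' @param annotation data.frame as returned by [read_gtf()].
#' @param path output file.
#' @param source source field for column 2.
#' @export
write_gtf <- function(annotation, path, source = "tsrkit") {
  a <- as.data.frame(annotation)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                     a$gene_id[i], a$transcript_id[i],
                     if (!is.null(a$biotype) && !is.na(a$biotype[i]))
                       sprintf(' gene_biotype "%s";', a$biotype[i]) else "")
    for (feat in c("transcript", "exon")) {
      writeLines(paste(a$chrom[i], source, feat, a$start[i] + 1L, a$end[i],
                       ".", a$strand[i], ".", attrs, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Extract one TSS record per transcript
#'
#' @param annotation data.frame from [read_gtf()].
#' @param dedup collapse transcripts sharing an identical 5' end position
#'   and strand to one record.
#' @return A region table (0-based half-open, width-1 intervals at the 5'
#'   ends), columns `chrom,start,end,name,score,strand`.
#' @export
extract_tss <- function(annotation, dedup = FALSE) {
  a <- data.table::as.data.table(annotation)
  out <- data.table::data.table(chrom = a$chrom,
                                start = as.integer(a$five_prime_end),
                                end = as.integer(a$five_prime_end) + 1L,
                                name = a$transcript_id, score = 0,
                                strand = a$strand)
  if (dedup) out <- unique(out, by = c("chrom", "start", "strand"))
  data.table::setorderv(out, c("chrom", "start", "name"))
  as.data.frame(out)
}

#' Read a strand's bedGraph into a profile
#'
#' bedGraph intervals are 0-based half-open; each interval is expanded to
#' its constituent single-base positions carrying the interval's value.
#' Overlapping intervals are rejected because the per-position count would
#' be ambiguous.
#'
#' @param path bedGraph file (4 columns, optional `track` header line).
#' @param strand strand this file carries ("+" or "-").
#' @param total_reads total aligned reads of the library; default: the sum
#'   of the values read (adequate for single-base 5'-end files that store
#'   every read).
#' @return An [end_profile()] with raw values.
#' @export
read_bedgraph <- function(path, strand, total_reads = NULL) {
  stopifnot(strand %in% c("+", "-"))
  lines_exist <- file.exists(path) && file.size(path) > 0
  has_data <- FALSE
  if (lines_exist) {
    first <- readLines(path, n = 50L)
    has_data <- any(!grepl("^(track|#|browser)", first) & nzchar(first))
  }
  if (!has_data) {
    return(end_profile(NULL, total_reads = if (is.null(total_reads)) 1 else total_reads))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!IRanges::isDisjoint(GenomicRanges::ranges(gr)) &&
      any(vapply(split(GenomicRanges::ranges(gr), GenomicRanges::seqnames(gr)),
                 function(r) !IRanges::isDisjoint(r), logical(1)))) {
    stop("overlapping intervals in bedGraph '", path, "' (ambiguous counts)")
  }
  w <- GenomicRanges::width(gr)
  starts0 <- GenomicRanges::start(gr) - 1L
  dt <- data.table::data.table(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
    strand = strand,
    pos = unlist(lapply(seq_along(gr), function(i)
      seq.int(starts0[i], length.out = w[i]))),
    value = rep(S4Vectors::mcols(gr)$score, w))
  dt <- dt[dt$value != 0]
  if (is.null(total_reads)) total_reads <- max(sum(dt$value), 1)
  end_profile(dt, total_reads = total_reads)
}

#' Write one strand of a profile as bedGraph
#'
#' One line per covered position (single-base intervals, `fragLength 1`
#' semantics), ordered by chromosome then position, so output is
#' deterministic and round-trips through [read_bedgraph()].
#'
#' @param profile an [end_profile()].
#' @param path output file.
#' @param strand which strand of the profile to write.
#' @export
write_bedgraph <- function(profile, path, strand) {
  stopifnot(inherits(profile, "end_profile"), strand %in% c("+", "-"))
  want_strand <- strand
  dt <- profile$counts[which(profile$counts$strand == want_strand)]
  out <- data.table::data.table(chrom = dt$chrom, start = dt$pos,
                                end = dt$pos + 1L, value = dt$value)
  data.table::setorderv(out, c("chrom", "start"))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a region table (BED6 / HOMER pos / headered TSV)
#'
#' All dialects are converted to 0-based half-open coordinates:
#' \describe{
#'   \item{bed6}{`chrom start end name score strand`, no header, already
#'     0-based half-open.}
#'   \item{homer_pos}{`name chrom start end strand` (comment lines with
#'     `#` skipped), 1-based inclusive.}
#'   \item{tsv}{header line naming at least `chrom,start,end`; 0-based
#'     half-open; extra columns preserved.}
#' }
#' @param path input file.
#' @param dialect one of `"bed6"`, `"homer_pos"`, `"tsv"`.
#' @return data.frame with `chrom,start,end,name,score,strand` plus any
#'   extra columns.
#' @export
read_region_table <- function(path, dialect = c("bed6", "homer_pos", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed6") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    data.table::setnames(dt, seq_len(min(6L, ncol(dt))),
                         c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(dt)))])
    if (!"name" %in% names(dt)) dt[, "name" := sprintf("region_%d", .I)]
    if (!"score" %in% names(dt)) dt[, "score" := 0]
    if (!"strand" %in% names(dt)) dt[, "strand" := "*"]
  } else if (dialect == "homer_pos") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "")
    dt <- dt[!grepl("^#", dt[[1]])]
    data.table::setnames(dt, 1:5, c("name", "chrom", "start", "end", "strand"))
    dt[, "start" := as.integer(dt$start) - 1L]   # 1-based inclusive -> 0-based half-open
    dt[, "end" := as.integer(dt$end)]
    dt[, "score" := 0]
    dt <- dt[, c("chrom", "start", "end", "name", "score", "strand")]
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    if (!all(c("chrom", "start", "end") %in% names(dt)))
      stop("TSV region table must have chrom/start/end columns")
    if (!"name" %in% names(dt)) dt[, "name" := sprintf("region_%d", seq_len(nrow(dt)))]
    if (!"score" %in% names(dt)) dt[, "score" := 0]
    if (!"strand" %in% names(dt)) dt[, "strand" := "*"]
  }
  dt[, "start" := as.integer(dt$start)]
  dt[, "end" := as.integer(dt$end)]
  if (any(dt$start >= dt$end)) stop("region with start >= end after conversion")
  as.data.frame(dt)
}

#' Write a region table
#' @param regions data.frame with `chrom,start,end,name,score,strand`.
#' @param path output file.
#' @param dialect `"bed6"` (no header, six columns) or `"tsv"` (headered,
#'   all columns).
#' @export
write_region_table <- function(regions, path, dialect = c("bed6", "tsv")) {
  dialect <- match.arg(dialect)
  dt <- data.table::as.data.table(regions)
  data.table::setorderv(dt, c("chrom", "start"))
  if (dialect == "bed6") {
    data.table::fwrite(dt[, c("chrom", "start", "end", "name", "score", "strand")],
                       path, sep = "\t", col.names = FALSE)
  } else {
    data.table::fwrite(dt, path, sep = "\t", col.names = TRUE)
  }
  invisible(path)
}

# GRanges view of a region table (internal glue for overlap operations)
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = if ("strand" %in% names(regions)) regions$strand else "*")
}
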