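#' Configuration for the synthetic csRNA-seq study generator
#'
#' Describes a planted genome-wide initiation landscape: how many
#' elements, what fraction initiate unstable transcripts, how many are
#' bidirectional or promoter-distal, sequencing depths, the TSS shape,
#' short-RNA-input contamination, background noise, and STARR-seq effect
#' sizes per transcription class. One seed fixes all randomness of all
#' stages.
#'
#' @param genome_length chromosome length in bp.
#' @param n_elements number of planted initiating elements (TSRs).
#' @param n_genes number of annotated genes; defaults to
#'   `round(n_elements * (1 - fraction_distal))`, the remaining elements
#'   being promoter-distal. Set 0 for an annotation-free genome.
#' @param fraction_unstable probability an element initiates an unstable
#'   transcript.
#' @param fraction_bidirectional fraction of elements given a divergent
#'   opposite-strand partner 80-250 bp upstream.
#' @param fraction_distal fraction of elements placed away from any
#'   annotated gene (used only when `n_genes` is not given).
#' @param csrna_depth,input_depth,rna_depth,groseq_depth total aligned
#'   reads per library.
#' @param input_contaminant_rate number of non-initiating contaminant
#'   loci (miRNA-like pileups with higher input than csRNA density), as a
#'   fraction of `n_elements`.
#' @param tss_shape `"sharp"` (>= 80 percent of reads at the mode) or
#'   `"dispersed"` (discretized Laplace over +/-50 bp).
#' @param dispersion_width Laplace scale in bp for dispersed initiation.
#' @param signal_mean geometric-mean planted csRNA signal per element, in
#'   per-10^7 units.
#' @param noise_rate background 5'-end rate per bp per strand.
#' @param starr_effects named mean activities for groups
#'   `no_transcription,U,UU,US,stable`.
#' @param starr_noise_sd activity noise SD.
#' @param starr_region_halfwidth half-width in bp of assayed regions.
#' @param starr_n_no_txn number of transcription-free open-chromatin
#'   regions.
#' @param starr_short_frac fraction of extra 20-50 bp library fragments
#'   (exercises the short-fragment filter).
#' @param plant_tata plant a TATA box (TATAAAAG) at -30 and a C/A
#'   initiator at -1/+1 of every element.
#' @param chrom_name chromosome name.
#' @param seed integer seed fixing all randomness.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 6.5e6,
                              n_elements = 1000L,
                              n_genes = NULL,
                              fraction_unstable = 0.3,
                              fraction_bidirectional = 0.1,
                              fraction_distal = 0.2,
                              csrna_depth = 1e7,
                              input_depth = 1e7,
                              rna_depth = 1e7,
                              groseq_depth = 1e7,
                              input_contaminant_rate = 0.05,
                              tss_shape = c("sharp", "dispersed"),
                              dispersion_width = 20L,
                              signal_mean = 100,
                              noise_rate = 1e-5,
                              starr_effects = c(no_transcription = 0.5, U = 1.4,
                                                UU = 2.0, US = 2.6, stable = 3.2),
                              starr_noise_sd = 0.2,
                              starr_region_halfwidth = 150L,
                              starr_n_no_txn = 200L,
                              starr_short_frac = 0.1,
                              plant_tata = TRUE,
                              chrom_name = "chr1",
                              seed = 1L) {
  tss_shape <- match.arg(tss_shape)
  stopifnot(fraction_unstable >= 0, fraction_unstable <= 1,
            fraction_bidirectional >= 0, fraction_bidirectional <= 1,
            fraction_distal >= 0, fraction_distal <= 1,
            csrna_depth > 0, rna_depth > 0, input_depth > 0, groseq_depth > 0,
            genome_length > 0, n_elements >= 0)
  if (is.null(n_genes)) n_genes <- as.integer(round(n_elements * (1 - fraction_distal)))
  if (n_genes > n_elements) stop("n_genes cannot exceed n_elements")
  req <- setdiff(c("no_transcription", "U", "UU", "US", "stable"),
                 names(starr_effects))
  if (length(req) > 0L) stop("starr_effects missing groups: ",
                             paste(req, collapse = ", "))
  structure(as.list(environment()), class = "simulation_config")
}

# element spacing of the placement grid (keeps neighbouring 5' ends far
# enough apart that context windows and distal calls never interact)
.slot_spacing <- 4000L

# 1-based indices and bases for an oriented motif: s occupies offsets
# off .. off+nchar(s)-1 downstream of a TSS at pos (strand-aware, with
# complementation on the minus strand). Returned as a list so edits from
# many elements can be applied to the genome vector in one assignment.
.motif_edits <- function(pos, strand, s, off) {
  b <- strsplit(s, "")[[1L]]
  n <- length(b)
  if (strand == "+") {
    list(idx = pos + off + seq_len(n), base = b)
  } else {
    list(idx = pos - off - seq_len(n) + 2L, base = chartr("ACGT", "TGCA", b))
  }
}

#' Simulate a genome with planted initiation elements
#'
#' Places `n_elements` initiating elements (plus divergent partners,
#' non-initiating contaminant loci and transcription-free open-chromatin
#' regions) on a uniform-random chromosome, at grid positions at least
#' ~3.2 kb apart so context classes are unambiguous. Genic elements get a
#' 2-kb single-exon transcript annotation starting at their TSS; distal
#' elements get none. Stability, bidirectionality and the STARR activity
#' group of each element are drawn per the config fractions and recorded
#' in the truth table.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (`DNAStringSet`), `annotation` (data.frame
#'   as from [read_gtf()]), `truth` (data.frame: `id,chrom,strand,pos,
#'   class,context,partner_id,csrna_norm,rna_window_norm,starr_group,
#'   starr_mean`), and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- as.integer(config$genome_length)
  n <- as.integer(config$n_elements)
  n_genes <- as.integer(config$n_genes)
  n_contam <- as.integer(round(config$input_contaminant_rate * n))
  n_open <- as.integer(config$starr_n_no_txn)
  centers <- seq.int(.slot_spacing, L - .slot_spacing, by = .slot_spacing)
  needed <- n + n_contam + n_open
  if (length(centers) < needed)
    stop("genome too short to place ", needed, " elements at ",
         .slot_spacing, " bp spacing")
  slots <- sample(centers, needed)
  jitter <- sample(-400:400, needed, replace = TRUE)
  pos_all <- slots + jitter

  mk_truth <- function(id, strand, pos, class, context, partner_id,
                       csrna_norm, rna_window_norm, starr_group) {
    data.frame(id = id, chrom = config$chrom_name, strand = strand,
               pos = as.integer(pos), class = class, context = context,
               partner_id = partner_id, csrna_norm = csrna_norm,
               rna_window_norm = rna_window_norm, starr_group = starr_group,
               stringsAsFactors = FALSE)
  }

  truth <- NULL
  annotation <- data.frame(transcript_id = character(), gene_id = character(),
                           chrom = character(), strand = character(),
                           start = integer(), end = integer(),
                           n_exons = integer(), biotype = character(),
                           five_prime_end = integer())
  if (n > 0L) {
    pos <- pos_all[seq_len(n)]
    strand <- sample(c("+", "-"), n, replace = TRUE)
    unstable <- stats::runif(n) < config$fraction_unstable
    genic <- seq_len(n) <= n_genes
    csn <- exp(stats::rnorm(n, log(config$signal_mean), 0.4))
    rnw <- ifelse(unstable, stats::runif(n, 0, 1), stats::runif(n, 5, 50))
    ids <- sprintf("el%04d", seq_len(n))
    n_bi <- round(config$fraction_bidirectional * n)
    bi <- rep(FALSE, n); if (n_bi > 0L) bi[sample.int(n, n_bi)] <- TRUE
    pd <- sample(80:250, n, replace = TRUE)
    ppos <- ifelse(strand == "+", pos - pd, pos + pd)
    pstrand <- ifelse(strand == "+", "-", "+")
    punstable <- stats::runif(n) < config$fraction_unstable
    pcsn <- exp(stats::rnorm(n, log(config$signal_mean), 0.4))
    prnw <- ifelse(punstable, stats::runif(n, 0, 1), stats::runif(n, 5, 50))

    style_of <- function(self_un, paired, partner_un) {
      ifelse(!self_un, "stable",
      ifelse(!paired, "U", ifelse(partner_un, "UU", "US")))
    }
    grp <- style_of(unstable, bi, punstable)
    pgrp <- style_of(punstable, TRUE, unstable)

    truth <- mk_truth(ids, strand, pos,
                      ifelse(unstable, "unstable", "stable"),
                      ifelse(genic, "promoter_sense", "distal"),
                      ifelse(bi, paste0(ids, "b"), NA_character_),
                      csn, rnw, grp)
    if (any(bi)) {
      tp <- mk_truth(paste0(ids[bi], "b"), pstrand[bi], ppos[bi],
                     ifelse(punstable[bi], "unstable", "stable"),
                     ifelse(genic[bi], "divergent", "distal"),
                     ids[bi], pcsn[bi], prnw[bi], pgrp[bi])
      truth <- rbind(truth, tp)
    }
    if (n_genes > 0L) {
      gi <- seq_len(n_genes)
      annotation <- data.frame(
        transcript_id = paste0("t_", ids[gi]),
        gene_id = paste0("g_", ids[gi]),
        chrom = config$chrom_name, strand = strand[gi],
        start = ifelse(strand[gi] == "+", pos[gi], pos[gi] - 1999L),
        end = ifelse(strand[gi] == "+", pos[gi] + 2000L, pos[gi] + 1L),
        n_exons = 1L, biotype = "protein_coding",
        five_prime_end = pos[gi], stringsAsFactors = FALSE)
    }
  }
  if (n_contam > 0L) {
    cpos <- pos_all[n + seq_len(n_contam)]
    tc <- mk_truth(sprintf("contam%03d", seq_len(n_contam)),
                   sample(c("+", "-"), n_contam, replace = TRUE), cpos,
                   "contaminant", "contaminant", NA_character_,
                   exp(stats::rnorm(n_contam, log(config$signal_mean), 0.4)),
                   0, "no_transcription")
    truth <- rbind(truth, tc)
  }
  if (n_open > 0L) {
    opos <- pos_all[n + n_contam + seq_len(n_open)]
    to <- mk_truth(sprintf("open%03d", seq_len(n_open)),
                   sample(c("+", "-"), n_open, replace = TRUE), opos,
                   "open_chromatin", "open_chromatin", NA_character_,
                   0, 0, "no_transcription")
    truth <- rbind(truth, to)
  }
  if (is.null(truth)) truth <- mk_truth(character(), character(), integer(),
                                        character(), character(), character(),
                                        numeric(), numeric(), character())
  rownames(truth) <- NULL

  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  init <- truth[truth$class %in% c("stable", "unstable"), , drop = FALSE]
  if (config$plant_tata && nrow(init) > 0L) {
    edits <- lapply(seq_len(nrow(init)), function(i) {
      a <- .motif_edits(init$pos[i], init$strand[i], "TATAAAAG", -32L)
      b <- .motif_edits(init$pos[i], init$strand[i], "CA", -1L)
      list(idx = c(a$idx, b$idx), base = c(a$base, b$base))
    })
    chars[unlist(lapply(edits, `[[`, "idx"))] <- unlist(lapply(edits, `[[`, "base"))
  }
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- config$chrom_name
  list(genome = genome, annotation = annotation, truth = truth, config = config)
}

# multinomial 5'-end placement around a mode position
.shape_offsets <- function(config) {
  if (config$tss_shape == "sharp") {
    list(off = -3:3, w = c(0.01, 0.02, 0.04, 0.85, 0.05, 0.02, 0.01))
  } else {
    off <- -50:50
    list(off = off, w = exp(-abs(off) / config$dispersion_width))
  }
}

.scatter_reads <- function(chrom, strand, mode_pos, n_reads, off, w) {
  if (n_reads <= 0L) return(NULL)
  cnt <- as.integer(stats::rmultinom(1L, n_reads, w))
  keep <- cnt > 0L
  if (!any(keep)) return(NULL)
  gpos <- if (strand == "+") mode_pos + off[keep] else mode_pos - off[keep]
  data.table::data.table(chrom = chrom, strand = strand,
                         pos = as.integer(gpos), value = cnt[keep])
}

.uniform_reads <- function(chrom, strand, tss, n_reads, off_lo, off_hi) {
  if (n_reads <= 0L) return(NULL)
  offs <- sample(off_lo:off_hi, n_reads, replace = TRUE)
  gpos <- if (strand == "+") tss + offs else tss - offs
  data.table::data.table(chrom = chrom, strand = strand,
                         pos = as.integer(gpos), value = 1)
}

.background_reads <- function(config, depth_scale = 1) {
  n_bg <- stats::rpois(1L, config$noise_rate * config$genome_length * 2)
  if (n_bg == 0L) return(NULL)
  data.table::data.table(chrom = config$chrom_name,
                         strand = sample(c("+", "-"), n_bg, replace = TRUE),
                         pos = sample.int(as.integer(config$genome_length), n_bg,
                                          replace = TRUE) - 1L,
                         value = 1)
}

#' Simulate all sequencing-signal inputs from a truth table
#'
#' Generates the four signal layers the pipeline consumes:
#' \itemize{
#'   \item csRNA-seq 5' ends, multinomially scattered around each planted
#'     TSS per the configured shape, plus Poisson background;
#'   \item short-RNA input: contaminant loci receive pileups at 3x their
#'     csRNA density (so the input filter removes them), true elements
#'     essentially none;
#'   \item total RNA-seq read starts: each element receives exactly
#'     `round(rna_window_norm)` sense reads in +1..+500 of its TSS (the
#'     planted stability score) plus 3x that over +501..+2000 —
#'     unstable elements therefore stay below 2 per 10^7 in the
#'     stability window, stable ones at or above 5;
#'   \item GRO-seq sense coverage over -100..+3000 at class-dependent
#'     levels.
#' }
#'
#' @param truth truth table from [simulate_genome()].
#' @param config the same [simulation_config()].
#' @return list of raw [end_profile()]s: `csrna`, `input`, `rnaseq`,
#'   `groseq`.
#' @export
simulate_signals <- function(truth, config) {
  set.seed(config$seed + 1L)
  sh <- .shape_offsets(config)
  cs_parts <- list(.background_reads(config))
  in_parts <- list(.background_reads(config))
  rn_parts <- list()
  gr_parts <- list()
  gro_levels <- list(stable = c(prox = 40, dist = 80),
                     unstable = c(prox = 30, dist = 10))
  for (i in seq_len(nrow(truth))) {
    cl <- truth$class[i]
    if (!cl %in% c("stable", "unstable", "contaminant")) next
    ch <- truth$chrom[i]; st <- truth$strand[i]; p <- truth$pos[i]
    n_cs <- round(truth$csrna_norm[i] * config$csrna_depth / 1e7)
    cs_parts[[length(cs_parts) + 1L]] <- .scatter_reads(ch, st, p, n_cs, sh$off, sh$w)
    if (cl == "contaminant") {
      n_in <- round(3 * truth$csrna_norm[i] * config$input_depth / 1e7)
      in_parts[[length(in_parts) + 1L]] <- .scatter_reads(ch, st, p, n_in, sh$off, sh$w)
      next
    }
    n_win <- round(truth$rna_window_norm[i] * config$rna_depth / 1e7)
    rn_parts[[length(rn_parts) + 1L]] <- .uniform_reads(ch, st, p, n_win, 1L, 500L)
    rn_parts[[length(rn_parts) + 1L]] <- .uniform_reads(ch, st, p, 3L * n_win, 501L, 2000L)
    lv <- gro_levels[[cl]]
    n_px <- round(lv["prox"] * config$groseq_depth / 1e7)
    n_dx <- round(lv["dist"] * config$groseq_depth / 1e7)
    gr_parts[[length(gr_parts) + 1L]] <- .uniform_reads(ch, st, p, n_px, -100L, 300L)
    gr_parts[[length(gr_parts) + 1L]] <- .uniform_reads(ch, st, p, n_dx, 301L, 3000L)
  }
  bind <- function(parts) {
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) NULL else data.table::rbindlist(parts)
  }
  list(csrna = end_profile(bind(cs_parts), config$csrna_depth),
       input = end_profile(bind(in_parts), config$input_depth),
       rnaseq = end_profile(bind(rn_parts), config$rna_depth),
       groseq = end_profile(bind(gr_parts), config$groseq_depth))
}

#' Assayed-region table around planted elements
#' @param truth truth table.
#' @param halfwidth region half-width in bp.
#' @param include which truth classes to include.
#' @return region table (`chrom,start,end,name,score,strand`).
#' @export
truth_regions <- function(truth, halfwidth = 150L,
                          include = c("stable", "unstable", "open_chromatin")) {
  t <- truth[truth$class %in% include, , drop = FALSE]
  data.frame(chrom = t$chrom, start = as.integer(t$pos - halfwidth),
             end = as.integer(t$pos + halfwidth), name = t$id, score = 0,
             strand = "*", stringsAsFactors = FALSE)
}

#' Simulate STARR-seq peak activities
#'
#' Emits one assayed region per initiating element and per
#' transcription-free open-chromatin locus, with activity drawn from a
#' normal around the element's group mean (`starr_effects`), plus a
#' configurable fraction of short 20-50 bp library fragments (at no-
#' transcription activity) that the fragment filter is expected to
#' remove.
#'
#' @param truth truth table from [simulate_genome()].
#' @param config the same [simulation_config()].
#' @return Region table with extra columns `activity`, `group`,
#'   `is_short_fragment`.
#' @export
simulate_starr <- function(truth, config) {
  set.seed(config$seed + 2L)
  hw <- as.integer(config$starr_region_halfwidth)
  t <- truth[truth$class %in% c("stable", "unstable", "open_chromatin"), , drop = FALSE]
  if (nrow(t) == 0L) stop("truth table has no assayable elements")
  mu <- config$starr_effects[t$starr_group]
  act <- pmax(stats::rnorm(nrow(t), mu, config$starr_noise_sd), 0.01)
  out <- data.frame(chrom = t$chrom, start = as.integer(t$pos - hw),
                    end = as.integer(t$pos + hw), name = paste0("peak_", t$id),
                    score = 0, strand = "*", activity = act,
                    group = t$starr_group, is_short_fragment = FALSE,
                    stringsAsFactors = FALSE)
  n_short <- round(config$starr_short_frac * nrow(out))
  if (n_short > 0L) {
    src <- sample.int(nrow(t), n_short, replace = TRUE)
    len <- sample(20:50, n_short, replace = TRUE)
    st <- as.integer(t$pos[src] - floor(len / 2))
    short <- data.frame(chrom = t$chrom[src], start = st, end = st + len,
                        name = sprintf("frag_%03d", seq_len(n_short)),
                        score = 0, strand = "*",
                        activity = pmax(stats::rnorm(
                          n_short, config$starr_effects["no_transcription"],
                          config$starr_noise_sd), 0.01),
                        group = "short_fragment", is_short_fragment = TRUE,
                        stringsAsFactors = FALSE)
    out <- rbind(out, short)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a complete study dataset
#'
#' Runs [simulate_genome()], [simulate_signals()] and [simulate_starr()]
#' under one config/seed.
#'
#' @param config a [simulation_config()].
#' @return list `genome, annotation, truth, csrna, input, rnaseq, groseq,
#'   starr, atac, config`.
#' @export
simulate_dataset <- function(config) {
  g <- simulate_genome(config)
  sig <- simulate_signals(g$truth, config)
  starr <- simulate_starr(g$truth, config)
  c(g, sig, list(starr = starr,
                 atac = truth_regions(g$truth, config$starr_region_halfwidth)))
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits the same formats the readers consume: genome FASTA, GTF
#' annotation, one bedGraph per strand per library, a headered STARR TSV,
#' an open-chromatin BED, the truth table TSV, and a library-totals TSV
#' (bedGraph carries no read-total metadata).
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "genes.gtf"),
             truth = file.path(dir, "truth.tsv"),
             starr = file.path(dir, "starr.tsv"),
             atac = file.path(dir, "atac.bed"),
             totals = file.path(dir, "totals.tsv"))
  write_genome(sim$genome, paths["genome"])
  write_gtf(sim$annotation, paths["gtf"])
  data.table::fwrite(sim$truth, paths["truth"], sep = "\t")
  write_region_table(sim$starr, paths["starr"], dialect = "tsv")
  write_region_table(sim$atac, paths["atac"], dialect = "bed6")
  libs <- c("csrna", "input", "rnaseq", "groseq")
  for (lib in libs) {
    for (s in c("+", "-")) {
      p <- file.path(dir, sprintf("%s.%s.bedGraph", lib,
                                  if (s == "+") "plus" else "minus"))
      write_bedgraph(sim[[lib]], p, s)
      paths[paste0(lib, if (s == "+") "_plus" else "_minus")] <- p
    }
  }
  tot <- data.frame(library = libs,
                    total_reads = vapply(libs, function(l) sim[[l]]$total_reads,
                                         numeric(1)))
  data.table::fwrite(tot, paths["totals"], sep = "\t")
  invisible(paths)
}
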