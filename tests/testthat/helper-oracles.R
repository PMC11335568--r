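# Independent straight-line reference implementations used as oracles.
# These deliberately share no code with the package internals.

# greedy strongest-first clustering, written as a direct O(n^2) transcription
# of the rule: strongest unclaimed TSS seeds, claims within +/- half window
oracle_cluster <- function(tss, cluster_dist = 200, tsr_min = 10) {
  half <- floor(cluster_dist / 2)
  ord <- order(-tss$norm, ifelse(tss$strand == "+", tss$pos, -tss$pos), tss$chrom)
  tss <- tss[ord, , drop = FALSE]
  claimed <- rep(FALSE, nrow(tss))
  res <- list()
  for (i in seq_len(nrow(tss))) {
    if (claimed[i]) next
    mem <- which(!claimed & tss$chrom == tss$chrom[i] &
                 tss$strand == tss$strand[i] &
                 abs(tss$pos - tss$pos[i]) <= half)
    claimed[mem] <- TRUE
    res[[length(res) + 1L]] <- data.frame(
      chrom = tss$chrom[i], strand = tss$strand[i],
      start = min(tss$pos[mem]), end = max(tss$pos[mem]) + 1L,
      major_tss = tss$pos[i], total_norm = sum(tss$norm[mem]),
      n_tss = length(mem))
  }
  out <- do.call(rbind, res)
  out <- out[out$total_norm >= tsr_min, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive per-position IUPAC consensus scan; returns 0-based match offsets
.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               W = c("A", "T"), S = c("C", "G"), M = c("A", "C"),
               K = c("G", "T"), R = c("A", "G"), Y = c("C", "T"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
oracle_scan <- function(seq, pattern) {
  pc <- strsplit(toupper(pattern), "")[[1L]]
  sc <- strsplit(toupper(seq), "")[[1L]]
  k <- length(pc); n <- length(sc)
  hits <- integer(0)
  if (n >= k) {
    for (i in 0:(n - k)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!(sc[i + j] %in% .iupac[[pc[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# brute-force hexamer counting by explicit substring extraction
oracle_hexamer_counts <- function(seqs) {
  hx <- character(0)
  for (s in seqs) {
    if (nchar(s) >= 6L) {
      hx <- c(hx, substring(s, 1:(nchar(s) - 5L), 6:nchar(s)))
    }
  }
  tab <- table(hx)
  all_h <- tsrkit::enumerate_hexamers()
  out <- stats::setNames(numeric(4096L), all_h)
  keep <- intersect(names(tab), all_h)
  out[keep] <- as.numeric(tab[keep])
  out
}

# two-group Tukey HSD adjusted p from the studentized range distribution
oracle_tukey2_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  mse <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  q <- abs(mean(x1) - mean(x2)) / sqrt(mse / 2 * (1 / n1 + 1 / n2))
  stats::ptukey(q, nmeans = 2, df = n1 + n2 - 2, lower.tail = FALSE)
}

# profile construction shorthand
prof <- function(chrom, strand, pos, value, total = 1e7, normalized = FALSE) {
  end_profile(data.frame(chrom = chrom, strand = strand, pos = pos,
                         value = value),
              total_reads = total, normalized = normalized)
}

# minimal TSR table builder (one row per major TSS)
mk_tsrs <- function(major, strand = "+", chrom = "chr1", norm = 50,
                    start = NULL, end = NULL) {
  n <- length(major)
  strand <- rep(strand, length.out = n)
  chrom <- rep(chrom, length.out = n)
  norm <- rep(norm, length.out = n)
  if (is.null(start)) start <- major
  if (is.null(end)) end <- major + 1L
  data.frame(id = sprintf("tsr%02d", seq_len(n)), chrom = chrom,
             strand = strand, start = as.integer(start), end = as.integer(end),
             major_tss = as.integer(major), total_norm = norm, n_tss = 1L)
}

# annotation row builder
mk_ann <- function(five_prime, strand = "+", chrom = "chr1", span = 2000L,
                   biotype = "protein_coding", n_exons = 1L) {
  n <- length(five_prime)
  strand <- rep(strand, length.out = n)
  data.frame(transcript_id = sprintf("t%02d", seq_len(n)),
             gene_id = sprintf("g%02d", seq_len(n)),
             chrom = rep(chrom, length.out = n), strand = strand,
             start = ifelse(strand == "+", five_prime, five_prime - span + 1L),
             end = ifelse(strand == "+", five_prime + span, five_prime + 1L),
             n_exons = rep(n_exons, length.out = n),
             biotype = rep(biotype, length.out = n),
             five_prime_end = as.integer(five_prime))
}

# shared small simulated dataset, memoised per seed so several test files
# can reuse it without re-simulating
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 7, ...) {
  key <- paste0("s", seed, paste(c(...), collapse = "_"))
  if (is.null(.sim_cache[[key]])) {
    cfg <- simulation_config(genome_length = 1.2e6, n_elements = 100,
                             starr_n_no_txn = 50, seed = seed, ...)
    .sim_cache[[key]] <- simulate_dataset(cfg)
  }
  .sim_cache[[key]]
}

# match called TSRs to planted elements within a tolerance (bp)
match_to_truth <- function(tsrs, truth, tol = 100) {
  init <- truth[truth$class %in% c("stable", "unstable"), , drop = FALSE]
  vapply(seq_len(nrow(tsrs)), function(i) {
    j <- which(init$chrom == tsrs$chrom[i] & init$strand == tsrs$strand[i] &
               abs(init$pos - tsrs$major_tss[i]) <= tol)
    if (length(j) > 0L) init$id[j[1L]] else NA_character_
  }, character(1))
}
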