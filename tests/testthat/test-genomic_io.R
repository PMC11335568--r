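test_that("per-10^7 normalization scales linearly and preserves positions", {
  p <- prof("chr1", "+", c(10L, 20L), c(5, 4), total = 1e7)
  n <- normalize_profile(p)
  expect_equal(n$counts$value, c(5, 4))   # identity scaling at depth 1e7
  p2 <- prof("chr1", "+", c(10L, 20L), c(5, 4), total = 2e7)
  n2 <- normalize_profile(p2)
  expect_equal(n2$counts$value, c(2.5, 2))
  expect_equal(n2$counts$pos, p2$counts$pos)
  # brute-force sum oracle: total normalized mass = 1e7 * stored fraction
  set.seed(42)
  raw <- data.frame(chrom = "chr1", strand = sample(c("+", "-"), 50, TRUE),
                    pos = sample.int(1e5, 50), value = rpois(50, 8) + 1)
  total <- 3.7e6
  np <- normalize_profile(end_profile(raw, total))
  expect_equal(sum(np$counts$value), 1e7 * sum(raw$value) / total)
  # linearity: k-scaled counts with k-scaled total normalize identically
  for (k in c(2L, 5L)) {
    rawk <- transform(raw, value = value * k)
    npk <- normalize_profile(end_profile(rawk, total * k))
    expect_equal(npk$counts$value, np$counts$value)
  }
  expect_error(end_profile(raw, 0), "positive")
  expect_error(normalize_profile(np), "already")
})

test_that("bedGraph reader/writer round-trips sparse content and rejects overlaps", {
  # empty file -> empty profile
  f0 <- withr::local_tempfile(fileext = ".bedGraph")
  file.create(f0)
  expect_equal(nrow(read_bedgraph(f0, "+")$counts), 0L)
  # one record
  f1 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chr1\t10\t11\t7", f1)
  p1 <- read_bedgraph(f1, "+")
  expect_equal(p1$counts$pos, 10L)
  expect_equal(p1$counts$value, 7)
  # random sparse fixture: write o read o write is identity
  set.seed(1)
  p <- prof("chr1", rep(c("+", "-"), each = 30),
            c(sample.int(5e4, 30), sample.int(5e4, 30)),
            rpois(60, 5) + 1)
  fp <- withr::local_tempfile(); fm <- withr::local_tempfile()
  write_bedgraph(p, fp, "+"); write_bedgraph(p, fm, "-")
  back <- end_profile(rbind(read_bedgraph(fp, "+")$counts,
                            read_bedgraph(fm, "-")$counts), p$total_reads)
  expect_equal(as.data.frame(back$counts), as.data.frame(p$counts))
  # multi-base intervals expand to per-position values
  f2 <- withr::local_tempfile()
  writeLines(c("chr1\t5\t8\t2", "chr1\t20\t21\t1"), f2)
  p2 <- read_bedgraph(f2, "-")
  expect_equal(p2$counts$pos, c(5L, 6L, 7L, 20L))
  expect_equal(p2$counts$value, c(2, 2, 2, 1))
  # overlapping intervals are ambiguous
  f3 <- withr::local_tempfile()
  writeLines(c("chr1\t5\t8\t2", "chr1\t7\t9\t1"), f3)
  expect_error(read_bedgraph(f3, "+"), "overlap")
})

test_that("GTF transcript 5' ends are strand-correct and round-trip", {
  ann <- data.frame(
    transcript_id = c("tA", "tB", "tC"), gene_id = c("gA", "gB", "gC"),
    chrom = "chr1", strand = c("+", "-", "+"),
    start = c(100L, 100L, 900L), end = c(500L, 500L, 1400L),
    n_exons = 1L, biotype = "protein_coding",
    five_prime_end = c(100L, 499L, 900L))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  got <- read_gtf(f)
  got <- got[order(got$transcript_id), ]
  expect_equal(got$five_prime_end, c(100L, 499L, 900L))  # minus strand flips
  expect_equal(got$strand, c("+", "-", "+"))
  expect_equal(nrow(got), 3L)
  tss <- extract_tss(got)
  expect_equal(nrow(tss), 3L)
  expect_equal(tss$end - tss$start, rep(1L, 3L))
  expect_setequal(tss$start, c(100L, 499L, 900L))
  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines("chr1\tsrc\ttranscript\tnotanumber\t500\t.\t+\t.\tgene_id \"g\";", bad)
  expect_error(suppressWarnings(read_gtf(bad)), "parse|features")
})

test_that("region-table dialects all land on 0-based half-open coordinates", {
  fb <- withr::local_tempfile()
  writeLines("chr1\t0\t200\tx\t0\t+", fb)
  rb <- read_region_table(fb, "bed6")
  expect_equal(c(rb$start, rb$end), c(0L, 200L))
  fh <- withr::local_tempfile()
  writeLines(c("# header comment", "x\tchr1\t1\t200\t+"), fh)
  rh <- read_region_table(fh, "homer_pos")
  expect_equal(c(rh$start, rh$end), c(0L, 200L))   # 1-based inclusive converted
  expect_equal(rb[, c("chrom", "start", "end", "strand")],
               rh[, c("chrom", "start", "end", "strand")])
  # 5-row mixed TSV keeps rows and extra columns
  ft <- withr::local_tempfile()
  df <- data.frame(chrom = "chr1", start = c(0, 10, 30, 70, 150),
                   end = c(5, 20, 60, 80, 151), name = letters[1:5],
                   score = 0, strand = c("+", "-", "+", "*", "-"),
                   activity = 1:5 / 2)
  write_region_table(df, ft, "tsv")
  rt <- read_region_table(ft, "tsv")
  expect_equal(nrow(rt), 5L)
  expect_equal(rt$activity, df$activity)
  # double conversion 1-based <-> 0-based is identity
  expect_equal(rt$start, df$start)
  bad <- withr::local_tempfile()
  writeLines("chr1\t5\t5\tx\t0\t+", bad)
  expect_error(read_region_table(bad, "bed6"), "start")
})

test_that("FASTA round-trips with uppercase unique names", {
  g <- Biostrings::DNAStringSet(c(chrA = "ACGTACGTNN", chrB = "TTTTGGGGCC"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, f)
  back <- read_genome(f)
  expect_equal(as.character(back), as.character(g))
  expect_equal(chrom_lengths(back), c(chrA = 10L, chrB = 10L))
})
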