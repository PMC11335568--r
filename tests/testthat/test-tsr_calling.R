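test_that("TSS calling applies the 7-per-10^7 threshold and the input rule", {
  cs <- prof("chr1", "+", c(100L, 200L, 300L, 400L),
             c(7.0, 6.99, 20, 50), normalized = TRUE)
  inp <- prof("chr1", "+", c(100L, 300L), c(0, 25), normalized = TRUE)
  got <- call_candidate_tss(cs, inp)
  # 7.0 kept; 6.99 below threshold; 20-vs-25 input-dominated; 50 clean
  expect_setequal(got$pos, c(100L, 400L))
  # input equal to csRNA is not *higher*: kept at default input_fold = 1
  cs2 <- prof("chr1", "-", 500L, 10, normalized = TRUE)
  in2 <- prof("chr1", "-", 500L, 10, normalized = TRUE)
  expect_equal(nrow(call_candidate_tss(cs2, in2)), 1L)
  # strand-specific: input on the other strand does not mask
  in3 <- prof("chr1", "+", 500L, 99, normalized = TRUE)
  expect_equal(nrow(call_candidate_tss(cs2, in3)), 1L)
  expect_error(call_candidate_tss(prof("chr1", "+", 1L, 9), inp), "normalized")
})

test_that("greedy clustering window arithmetic matches the hand-traced cases", {
  mk <- function(pos, norm, strand = "+") {
    data.frame(chrom = "chr1", strand = strand, pos = as.integer(pos),
               norm = norm, input_norm = 0)
  }
  # 80 bp apart -> one TSR (within +/-100 claim window)
  one <- cluster_tsrs(mk(c(1000, 1080), c(20, 20)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$end - one$start, 81L)
  # 150 bp apart -> second TSS outside +/-100 window seeds its own TSR
  two <- cluster_tsrs(mk(c(1000, 1150), c(20, 20)))
  expect_equal(nrow(two), 2L)
  # 250 bp apart -> always two (beyond the 200 bp TSR definition)
  expect_equal(nrow(cluster_tsrs(mk(c(1000, 1250), c(20, 20)))), 2L)
  # single TSS at 9.9 < tsr_min_norm 10 -> nothing reported
  expect_equal(nrow(cluster_tsrs(mk(1000, 9.9))), 0L)
  expect_equal(nrow(cluster_tsrs(mk(1000, 10))), 1L)
})

test_that("major TSS is the strongest member with strand-aware tie-break", {
  mk_mem <- function(pos, norm, strand) {
    data.frame(chrom = "chr1", strand = strand, pos = as.integer(pos),
               norm = norm, input_norm = 0, tsr_id = "t1")
  }
  expect_equal(major_tss(NULL, mk_mem(c(100, 120), c(50, 10), "+"))$pos, 100L)
  expect_equal(major_tss(NULL, mk_mem(c(100, 110), c(20, 20), "+"))$pos, 100L)
  expect_equal(major_tss(NULL, mk_mem(c(100, 110), c(20, 20), "-"))$pos, 110L)
  empty <- mk_mem(c(100, 110), c(20, 20), "+")[0, ]
  expect_error(major_tss(NULL, empty), "no member")
})

test_that("region-level input filter removes contaminant-dominated TSRs", {
  tss <- data.frame(chrom = "chr1", strand = "+", pos = c(1000L, 5000L),
                    norm = c(20, 20), input_norm = 0)
  tsrs <- cluster_tsrs(tss)
  cs <- prof("chr1", "+", c(1000L, 5000L), c(20, 20), normalized = TRUE)
  inp <- prof("chr1", "+", 1000L, 60, normalized = TRUE)   # 3x csRNA there
  kept <- filter_tsr_by_input(tsrs, cs, inp)
  expect_equal(kept$major_tss, 5000L)
})

test_that("reported TSRs satisfy the width, signal and non-overlap invariants", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 200
    tss <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      strand = sample(c("+", "-"), n, TRUE),
                      pos = sample.int(20000L, n),
                      norm = runif(n, 7, 60), input_norm = 0)
    tsrs <- cluster_tsrs(tss)
    expect_true(all(tsrs$end - tsrs$start <= 200))
    expect_true(all(tsrs$total_norm >= 10))
    expect_true(all(tsrs$major_tss >= tsrs$start & tsrs$major_tss < tsrs$end))
    # same-strand TSRs never overlap
    by_gs <- split(tsrs, paste(tsrs$chrom, tsrs$strand))
    for (g in by_gs) {
      g <- g[order(g$start), ]
      if (nrow(g) > 1L) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
})

test_that("greedy clustering equals the straight-line oracle on small instances", {
  set.seed(123)
  for (rep in 1:40) {
    n <- sample(1:10, 1)
    tss <- data.frame(chrom = "chr1",
                      strand = sample(c("+", "-"), n, TRUE),
                      pos = sample.int(600L, n),
                      norm = round(runif(n, 7, 40), 2), input_norm = 0)
    tss <- tss[!duplicated(tss[, c("strand", "pos")]), , drop = FALSE]
    got <- cluster_tsrs(tss)
    ref <- oracle_cluster(tss)
    expect_equal(got[, c("chrom", "strand", "start", "end", "major_tss",
                         "total_norm", "n_tss")],
                 ref, ignore_attr = TRUE)
  }
})

test_that("TSR counts are robust to cluster_dist on dispersed initiation", {
  cfg <- simulation_config(genome_length = 1.2e6, n_elements = 100,
                           tss_shape = "dispersed", signal_mean = 400,
                           starr_n_no_txn = 5, seed = 21)
  sim <- simulate_dataset(cfg)
  counts <- vapply(c(150, 200, 250, 300), function(cd) {
    nrow(call_tsrs(sim$csrna, sim$input, caller_params(cluster_dist = cd)))
  }, numeric(1))
  expect_lt(diff(range(counts)) / max(counts), 0.15)
})

test_that("planted TSRs are recovered at single-nucleotide precision", {
  sim <- small_sim(7)
  tsrs <- call_tsrs(sim$csrna, sim$input)
  tr <- sim$truth[sim$truth$class %in% c("stable", "unstable"), ]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(tsrs$chrom == tr$chrom[i] & tsrs$strand == tr$strand[i] &
        abs(tsrs$major_tss - tr$pos[i]) <= 10)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  # all planted contaminants rejected
  con <- sim$truth[sim$truth$class == "contaminant", ]
  near_con <- vapply(seq_len(nrow(con)), function(i) {
    any(tsrs$chrom == con$chrom[i] & abs(tsrs$major_tss - con$pos[i]) <= 100)
  }, logical(1))
  expect_true(!any(near_con))
})
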