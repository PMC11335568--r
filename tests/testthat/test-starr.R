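mk_peaks <- function(start, end, activity, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = sprintf("p%02d", seq_along(start)), score = 0,
             strand = "*", activity = activity)
}

test_that("the 1-50 bp fragment filter removes exactly the short fragments", {
  pk <- mk_peaks(c(0, 100, 300, 500), c(50, 151, 350, 800), activity = 1:4)
  kept <- filter_fragments(pk)
  # lengths 50 and 50 removed, 51 and 300 kept
  expect_equal(kept$name, c("p02", "p04"))
  expect_equal(nrow(filter_fragments(pk[0, ])), 0L)
  # boundary: length 51 kept
  expect_equal(nrow(filter_fragments(mk_peaks(0, 51, 1))), 1L)
  expect_equal(nrow(filter_fragments(mk_peaks(0, 50, 1))), 0L)
})

test_that("per-bp activity is 100 x summed contained activity over length", {
  oc <- data.frame(chrom = "chr1", start = 1000L, end = 1200L, name = "oc1",
                   score = 0, strand = "*")
  one <- merge_and_score(NULL, oc, mk_peaks(1050, 1150, 2.0))
  expect_equal(one$per_bp_activity, 100 * 2 / 200)
  expect_equal(one$length, 200L)
  # two peaks 1 + 3 in a 400-bp region -> 100*4/400 = 1
  oc4 <- transform(oc, end = 1400L)
  two <- merge_and_score(NULL, oc4, mk_peaks(c(1050, 1200), c(1150, 1300), c(1, 3)))
  expect_equal(two$per_bp_activity, 1)
  expect_equal(two$n_peaks, 2L)
  # region without contained peaks -> activity 0, flagged uncovered
  none <- merge_and_score(NULL, oc, mk_peaks(5000, 5100, 9))
  got <- none[none$start == 1000L, ]
  expect_equal(got$per_bp_activity, 0)
  expect_false(got$covered)
  # doubling the region length with the same peaks halves per-bp activity
  oc2 <- transform(oc, end = 1400L)
  half <- merge_and_score(NULL, oc2, mk_peaks(1050, 1150, 2.0))
  expect_equal(half$per_bp_activity, one$per_bp_activity / 2)
  # midpoint assignment counts a straddling peak exactly once, in the
  # region holding its midpoint
  oc_two <- data.frame(chrom = "chr1", start = c(1000L, 1250L),
                       end = c(1248L, 1500L), name = c("a", "b"), score = 0,
                       strand = "*")
  straddle <- merge_and_score(NULL, oc_two, mk_peaks(1150, 1350, 4))
  straddle <- straddle[order(straddle$start), ]
  expect_equal(straddle$n_peaks, c(0L, 1L))
  expect_equal(straddle$activity_sum, c(0, 4))
})

test_that("merged regions inherit class and substyle from the strongest TSR", {
  tsrs <- mk_tsrs(c(1100L, 3100L), norm = c(50, 80))
  tsrs$start <- tsrs$major_tss - 50L; tsrs$end <- tsrs$major_tss + 50L
  calls <- data.frame(tsr_id = tsrs$id, score = c(0, 10),
                      class = c("unstable", "stable"))
  styles <- data.frame(tsr_id = tsrs$id, style = c("UU", "S"),
                       partner_id = NA, bidirectional = c(TRUE, FALSE))
  oc <- data.frame(chrom = "chr1", start = c(1000L, 3000L, 5000L),
                   end = c(1200L, 3200L, 5200L), name = c("a", "b", "c"),
                   score = 0, strand = "*")
  pk <- mk_peaks(c(1050, 3050, 5050), c(1150, 3150, 5150), c(1, 2, 3))
  ms <- merge_and_score(tsrs, oc, pk, calls = calls, styles = styles)
  ms <- ms[order(ms$start), ]
  expect_equal(ms$class, c("unstable", "stable", "no_transcription"))
  expect_equal(ms$substyle, c("UU", "none", "none"))
  expect_equal(ms$tsr_id, c("tsr01", "tsr02", NA))
})

test_that("filter-then-merge equals merge-then-filter for contained peaks", {
  set.seed(17)
  oc <- data.frame(chrom = "chr1", start = seq(0L, 9000L, by = 1000L),
                   end = seq(0L, 9000L, by = 1000L) + 400L,
                   name = letters[1:10], score = 0, strand = "*")
  st <- seq(50L, 9050L, by = 1000L)
  len <- sample(c(20:50, 60:300), 10, replace = TRUE)
  pk <- mk_peaks(st, st + len, runif(10, 0.5, 3))
  a <- merge_and_score(NULL, oc, filter_fragments(pk))
  keep_long <- len >= 51
  # regions whose only peaks are short lose their activity; others keep
  # the sum over their long peaks
  manual <- vapply(seq_len(nrow(oc)), function(i) {
    inside <- st >= oc$start[i] & st < oc$end[i] & keep_long
    sum(pk$activity[inside])
  }, numeric(1))
  expect_equal(a$activity_sum, manual)
})

test_that("group comparison matches the studentized-range closed form", {
  # degenerate: identical values everywhere
  g0 <- group_compare(rep(1, 10), rep(c("a", "b"), each = 5))
  expect_equal(g0$F, 0); expect_equal(g0$p, 1)
  expect_true(all(g0$tukey$p_adj == 1))
  # two-group Tukey equals the closed-form studentized-range p
  set.seed(23)
  for (rep in 1:5) {
    x1 <- rnorm(12, 0, 1); x2 <- rnorm(15, 0.8, 1)
    gc <- group_compare(c(x1, x2), rep(c("a", "b"), c(12, 15)))
    expect_equal(gc$tukey$p_adj, oracle_tukey2_p(x1, x2), tolerance = 1e-8)
  }
  # all pairwise adjusted p in [0, 1]
  set.seed(24)
  v <- rnorm(60); g <- rep(c("a", "b", "c"), 20)
  gc3 <- group_compare(v, g)
  expect_true(all(gc3$tukey$p_adj >= 0 & gc3$tukey$p_adj <= 1))
  expect_equal(nrow(gc3$tukey), 3L)
  expect_error(group_compare(v, rep("a", 60)), "two groups")
})

test_that("correlation recovers planted linear dependence at the closed-form level", {
  expect_equal(activity_correlation(1:10, 1:10), 1)
  expect_lt(activity_correlation(1:10, 10:1), 0)
  r0 <- activity_correlation(rep(2, 5), 1:5)
  expect_true(is.na(r0) && attr(r0, "undefined"))
  # rho = 1/sqrt(1 + sigma^2/var(x)) for y = x + noise (identity transform)
  set.seed(25)
  n <- 4000; sigma <- 0.8
  x <- rnorm(n, 0, 1)
  y <- x + rnorm(n, 0, sigma)
  rho <- 1 / sqrt(1 + sigma^2 / 1)
  r <- activity_correlation(x, y, transform = identity)
  expect_equal(r, rho, tolerance = 0.05)
})
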