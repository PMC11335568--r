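test_that("context classes honor the printed windows and priorities", {
  ann <- mk_ann(10000L, strand = "+")
  cases <- list(
    list(pos = 10000L, strand = "+", want = "tss_sense"),     # exactly at 5' end
    list(pos = 10275L, strand = "+", want = "tss_sense"),     # +275 boundary in
    list(pos = 9725L,  strand = "+", want = "tss_sense"),     # -275 boundary in
    list(pos = 9900L,  strand = "-", want = "tss_divergent"), # d = -100 opposite
    list(pos = 9725L,  strand = "-", want = "tss_divergent"), # d = -275 boundary
    list(pos = 9724L,  strand = "-", want = "distal"),        # d = -276 outside
    list(pos = 10150L, strand = "-", want = "tss_antisense"), # d = +150 opposite
    list(pos = 10300L, strand = "-", want = "tss_antisense"), # +300 boundary
    list(pos = 10276L, strand = "+", want = "single_exon_gene"), # past sense win, in 1-exon gene body
    list(pos = 15000L, strand = "+", want = "distal"))        # 5 kb away
  for (cs in cases) {
    tsr <- mk_tsrs(cs$pos, strand = cs$strand)
    got <- classify_context(tsr, ann)
    expect_equal(got$context, cs$want,
                 label = sprintf("pos=%d strand=%s -> %s (got %s)",
                                 cs$pos, cs$strand, cs$want, got$context))
  }
  # single-exon annotation marks gene-body hits as single_exon_gene when
  # the transcript has one exon; the builder above uses n_exons = 1, so
  # check the multi-exon variant flips to exonic
  ann2 <- mk_ann(10000L, strand = "+", n_exons = 3L)
  got2 <- classify_context(mk_tsrs(10276L), ann2)
  expect_equal(got2$context, "exonic")
  got1 <- classify_context(mk_tsrs(10276L), mk_ann(10000L, n_exons = 1L))
  expect_equal(got1$context, "single_exon_gene")
  # miRNA proximity is a flagged heuristic
  mir <- mk_ann(10000L, strand = "+", span = 100L, biotype = "miRNA")
  gotm <- classify_context(mk_tsrs(10500L), mir)
  expect_equal(gotm$context, "mirna_proximal")
  expect_true(gotm$mirna_heuristic)
  # empty annotation -> everything distal
  got0 <- classify_context(mk_tsrs(10000L), NULL)
  expect_equal(got0$context, "distal")
})

test_that("context classes partition the TSR set on simulated data", {
  sim <- small_sim(7)
  tsrs <- call_tsrs(sim$csrna, sim$input)
  ctx <- classify_context(tsrs, sim$annotation)
  expect_equal(nrow(ctx), nrow(tsrs))
  expect_true(all(!is.na(ctx$context)))
  # planted context labels recovered
  truth_id <- match_to_truth(tsrs, sim$truth)
  planted <- sim$truth$context[match(truth_id, sim$truth$id)]
  map <- c(promoter_sense = "tss_sense", divergent = "tss_divergent",
           distal = "distal")
  ok <- !is.na(planted)
  expect_gte(mean(ctx$context[ok] == map[planted[ok]]), 0.95)
})

test_that("distance-bin ratios use pseudocounts only when a class is empty", {
  ann <- mk_ann(10000L)
  # constructed 7-TSR instance with hand-binned distances
  # 50, 80 -> bin 1; 500, 800 -> bin 2; 1500, 1900 -> bin 3; 3000 -> bin 4
  tsrs <- mk_tsrs(c(10050L, 10080L, 10500L, 10800L, 11500L, 11900L, 13000L))
  calls <- data.frame(tsr_id = tsrs$id, score = 0,
                      class = c("stable", "unstable", "stable", "unstable",
                                "stable", "unstable", "unstable"))
  bins <- distance_bin_ratios(tsrs, calls, ann)
  expect_equal(bins$n_stable, c(1L, 1L, 1L, 0L))
  expect_equal(bins$n_unstable, c(1L, 1L, 1L, 1L))
  expect_equal(bins$ratio, c(1, 1, 1, (1 + 1) / (0 + 1)))
  expect_equal(sum(bins$n_stable) + sum(bins$n_unstable), 7L)
  # all stable -> (0+1)/(n_b+1) per occupied bin
  calls2 <- transform(calls, class = "stable")
  bins2 <- distance_bin_ratios(tsrs, calls2, ann)
  expect_equal(bins2$ratio, (0 + 1) / (bins2$n_stable + 1))
})

test_that("antisense ratio divides antisense-mapped by sense-mapped TSRs", {
  ann <- mk_ann(seq(10000L, 130000L, by = 10000L))
  # 10 sense TSRs at annotated 5' ends, 2 antisense within the window
  sense <- mk_tsrs(seq(10000L, 100000L, by = 10000L), strand = "+")
  anti <- mk_tsrs(c(110100L, 120200L), strand = "-")
  anti$id <- paste0("a", anti$id)
  both <- rbind(sense, anti)
  expect_equal(antisense_ratio(both, ann), 0.2)
  expect_equal(antisense_ratio(sense, ann), 0)
  # no sense-mapped TSRs -> undefined, not an exception
  far <- mk_tsrs(500000L)
  r <- antisense_ratio(far, ann)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))
})

test_that("antisense window boundary is inclusive at exactly 275 bp", {
  ann <- mk_ann(10000L, strand = "+")
  onsense <- mk_tsrs(10000L, strand = "+")
  at275 <- mk_tsrs(10275L, strand = "-"); at275$id <- "a1"
  at276 <- mk_tsrs(10276L, strand = "-"); at276$id <- "a2"
  expect_equal(antisense_ratio(rbind(onsense, at275), ann), 1)
  expect_equal(antisense_ratio(rbind(onsense, at276), ann), 0)
})

test_that("distance sign convention survives strand mirroring", {
  sim <- small_sim(7)
  tsrs <- call_tsrs(sim$csrna, sim$input)
  ctx <- classify_context(tsrs, sim$annotation)
  m <- mirror_dataset(sim)
  mtsrs <- call_tsrs(m$csrna, m$input)
  mctx <- classify_context(mtsrs, m$annotation)
  expect_equal(sort(table(mctx$context)), sort(table(ctx$context)))
  expect_equal(sort(mctx$distance), sort(ctx$distance))
  expect_equal(antisense_ratio(mtsrs, m$annotation),
               antisense_ratio(tsrs, sim$annotation))
})
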