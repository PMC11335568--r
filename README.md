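# tsrkit

Classify transcription start regions (TSRs) from nascent 5′-end
sequencing by transcript stability, genomic context and initiation
directionality, and relate those classes to enhancer activity measured
by STARR-seq.

Capped small RNA sequencing (csRNA-seq) captures the 5′ ends of short,
capped nascent RNA polymerase II transcripts at single-nucleotide
resolution, so it detects *all* initiation events — including transcripts
that are degraded too quickly to appear in steady-state RNA-seq (the
hallmark of vertebrate enhancer RNAs). `tsrkit` implements the analysis
stack that turns strand-specific 5′-end count profiles into a classified
TSR atlas:

- **TSS/TSR calling.** Positions with csRNA-seq signal ≥ 7 reads per 10⁷
  aligned reads are candidate TSSs; positions where the short-RNA input
  library has higher normalized density are discarded as non-initiating
  contaminants (miRNAs and other abundant RNAs surviving cap enrichment).
  TSSs are clustered greedily (strongest seed first, ±100 bp claim
  window) into strand-specific TSRs of span ≤ 200 bp with total signal
  ≥ 10 per 10⁷.
- **Stability.** A TSR initiates an *unstable* transcript when the sense
  total RNA-seq signal within −100..+500 bp of its major TSS is
  < 2 per 10⁷ aligned reads.
- **Context.** Each TSR is classified against the nearest annotated gene
  5′ end: sense promoter (±275 bp), divergent (−275..−1 bp, opposite
  strand), TSS-antisense (0..+300 bp, opposite strand), gene-body
  (exonic / single-exon), miRNA-proximal, or distal; distance-bin
  unstable/stable ratios and the promoter antisense/sense ratio are
  reported.
- **Directionality.** Divergent sense/antisense TSR pairs (major TSSs
  within 275 bp) are matched nearest-first and every TSR gets an
  initiation style: **S** stable, **U** unstable unidirectional, **US**
  unstable with a stable divergent partner, **UU** unstable in both
  directions — the vertebrate-enhancer-like configuration.
- **Sequence & signal features.** Hexamer stability-ratio ranking over
  +1..+3 kb windows (4,096 hexamers, rank 1 = most unstable-enriched),
  IUPAC consensus scanning, nucleotide metaplots, pausing index
  ((reads in −100..+300) + 1) / ((reads in +301..+3,000) + 1), signal
  metaplots, and windowed log₂ ratios.
- **STARR-seq integration.** Library fragments of 1–50 bp are removed,
  assayed regions are merged with TSRs, per-bp activity is
  100 × Σ(contained peak activities) / region length, and activity is
  compared between no-transcription / stable / unstable regions (and U /
  UU / US substyles) by one-way ANOVA with Tukey's HSD.
- **Synthetic data.** A seeded generator plants a full study — genome,
  annotations, TSRs with known stability/context/directionality labels,
  csRNA/input/RNA-seq/GRO-seq signal and STARR activities — so every
  stage is verifiable against ground truth without any download.

## Worked example

```r
library(tsrkit)
cfg <- simulation_config(genome_length = 1.2e6, n_elements = 100,
                         starr_n_no_txn = 50, seed = 7)
sim <- simulate_dataset(cfg)

tsrs   <- call_tsrs(sim$csrna, sim$input)          # TSS calling + clustering + input filter
calls  <- classify_stability(tsrs, sim$rnaseq)     # stable / unstable at 2 per 10^7
styles <- assign_styles(tsrs, pair_bidirectional(tsrs), calls)

nrow(tsrs)            # 110
table(calls$class)    #   stable unstable
                      #       81       29
table(styles$style)   #  S  U US UU
                      # 81 22  5  2

ms  <- merge_and_score(tsrs, sim$atac, filter_fragments(sim$starr),
                       calls = calls, styles = styles)
cov <- ms[ms$covered, ]
gc  <- group_compare(cov$per_bp_activity, cov$class)
round(gc$group_means, 3)
# no_transcription           stable         unstable
#            0.162            1.079            0.593
gc$tukey[, c("pair", "diff", "p_adj")]
#                        pair       diff        p_adj
# 1   stable-no_transcription  0.9175544 2.997602e-15
# 2 unstable-no_transcription  0.4316761 4.551914e-15
# 3           unstable-stable -0.4858783 2.997602e-15
```

The 110 called TSRs recover the 100 planted elements plus their
divergent partners; planted contaminant loci are removed by the input
filter. The STARR group means reproduce the planted ordering
no-transcription < unstable < stable in per-bp activity units, with all
pairwise Tukey-adjusted p-values far below 0.0005.

`run_pipeline()` orchestrates all stages over one or more sample
directories (written by `write_dataset()`), emits per-stage TSV tables
and a `summary.json` of counts and fractions, and adds a cross-sample
stability-switch analysis when given two or more samples.

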