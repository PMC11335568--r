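---
title: "Classifying transcription start regions from nascent 5'-end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcription start regions from nascent 5'-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrkit)
```

## The model

Capped small RNA sequencing (csRNA-seq) selects short, 5'-capped nascent
transcripts and reports the genomic position of their first base, so the
signal is a strand-specific map of read 5'-end counts at single-nucleotide
resolution. Because capping happens at initiation, the assay sees every
initiation event regardless of the transcript's fate; total RNA-seq, by
contrast, sees only transcripts that survive to steady state. `tsrkit`
exploits that asymmetry: initiation without downstream steady-state RNA
defines an *unstable* transcript, the defining property of vertebrate
enhancer RNAs.

All thresholds are expressed in reads per 10^7 aligned reads. The
normalization denominator is the producer-reported number of uniquely
aligned reads, carried as metadata on each profile — the package never
recomputes it from the stored sparse positions, since multi-locus totals
legitimately exceed the stored sum.

The pipeline proceeds in layers, each an exported function:

1. **TSS calling** (`call_candidate_tss`): positions with csRNA signal
   >= `tss_min_norm` (default 7 per 10^7) are kept unless the short-RNA
   input library has strictly higher normalized density at the same
   position and strand (`input_fold = 1`; "higher than" is read as a
   strict comparison). The input library is sequenced before cap
   enrichment, so abundant non-initiating species (miRNAs and other
   processed small RNAs) pile up there and are removed here.
2. **TSR clustering** (`cluster_tsrs`): greedy strongest-first. The
   strongest unclaimed TSS seeds a TSR and claims unclaimed same-strand
   TSSs within +/- `cluster_dist/2` (default +/-100 bp); iterate. This
   guarantees the defining invariant that no TSR spans more than
   `cluster_dist` (200 bp), which single-linkage gap merging cannot
   (chains can grow unboundedly). The TSR span is the tight hull of its
   members, the major TSS is the seed, and TSRs with summed signal below
   `tsr_min_norm` (10) are dropped. A region-level input filter
   (`filter_tsr_by_input`) then removes TSRs whose span-summed input
   density exceeds the csRNA density.
3. **Stability** (`classify_stability`): the score is the sense-strand
   total RNA-seq signal within -100..+500 bp of the major TSS, oriented
   along transcription; class `unstable` iff score < 2 (strict). RNA-seq
   is quantified as read 5'-end counts in the window rather than a
   per-base coverage integral — both reduce to the same window sum on the
   sparse representation, and end counts keep the score in read units.
   Antisense coverage is ignored: stability is a property of the sense
   transcript.
4. **Context** (`classify_context`): evaluated against the nearest
   annotated transcript 5' end, with mutually exclusive classes in
   priority order: sense promoter (same strand, |d| <= 275), divergent
   (opposite strand, d in [-275, -1]), TSS-antisense (opposite strand,
   d in [0, +300]), gene-body (single-exon vs multi-exon), miRNA-proximal,
   distal. The divergent and antisense windows reconcile two printed
   conventions — "within the TSS region" (+/-275) and "within 300 bp
   downstream" — by giving the upstream side to the divergent class and
   capping the downstream side at +300; both windows are arguments.
5. **Directionality** (`pair_bidirectional`, `assign_styles`): a
   plus-strand TSR pairs with a minus-strand TSR whose major TSS lies
   1..`pair_window` bp upstream (divergent geometry; convergent pairs
   never match). No pairing distance is canonical in the field, so the
   default (275 bp) mirrors the divergent context window; it is
   configurable over 100-1000 bp. Matching is nearest-first with ties
   broken by combined signal then id, each TSR taking at most one
   partner, which makes `partner(partner(x)) = x` an invariant. Styles:
   unpaired stable S, unpaired unstable U, paired unstable with unstable
   partner UU, with stable partner US; the stable side of any pair stays
   S with its `bidirectional` flag set (there is no SS style; the flag
   preserves the information).
6. **STARR-seq integration** (`filter_fragments`, `merge_and_score`,
   `group_compare`): fragments of 1-50 bp are removed (they show
   systematically depressed activity for technical reasons). TSR spans
   and assayed open-chromatin regions are merged strand-agnostically;
   each surviving peak is assigned to the merged region containing its
   midpoint so a peak straddling two regions is counted exactly once;
   per-bp activity is 100 x (sum of contained activities) / region
   length. Regions are labelled by the strongest overlapping TSR's
   stability (reporter activity has no strand, so overlap ignores
   strand). Group comparison is one-way ANOVA with Tukey HSD from the
   base stats machinery; the two-group case is cross-checked in the test
   suite against the studentized-range closed form, and a fully
   degenerate input (all values identical) short-circuits to F = 0,
   p = 1 rather than a NaN from a zero residual variance.

### Sequence and signal metrics

- `hexamer_stability_ranks` counts overlapping hexamers in +1..+3 kb
  windows downstream of major TSSs (strand-aware, reverse-complemented on
  minus), normalizes by the number of TSRs per class, and ranks all 4,096
  hexamers by `(stable + 1) / (unstable + 1)` ascending — rank 1 is the
  most unstable-enriched. The pseudocount mirrors the "1 read" pseudocount
  used for log ratios and keeps empty cells defined; ties break
  lexicographically so the rank vector is always a permutation. The window
  is anchored at the major TSS (a single-nucleotide anchor) rather than a
  TSR edge, for determinism.
- `pausing_index` is (proximal + 1)/(distal + 1) with inclusive windows
  -100..+300 (401 bases) and +301..+3000 (2,700 bases). Endpoints are
  inclusive on both sides in base terms; the uniform-coverage oracle value
  (401+1)/(2700+1) is frozen in the tests. The pseudocount extends the
  log-ratio convention to TSSs with empty gene bodies.
- `window_log_ratio` computes log2((A+1)/(B+1)) over +1..+600, the
  just-downstream window used for chromatin-mark quantification.
- Windows that would cross a chromosome edge contribute nothing there
  (sparse positions outside the chromosome simply do not exist), which is
  equivalent to clipping; sequence windows (`extract_windows`) instead
  drop out-of-bounds anchors with a warning, since a truncated sequence
  window would bias k-mer counts.

## The synthetic-data generator

`simulation_config()` + `simulate_dataset()` plant a complete study with
known labels, which is what makes every stage testable without external
data. Defaults are the study conditions used throughout the test suite:
1,000 initiating elements on a 6.5 Mb chromosome, 30% unstable, 10% with
a divergent partner 80-250 bp upstream, 20% promoter-distal, all four
libraries at 10^7 aligned reads.

Choices a user should know:

- Elements sit on a ~4 kb grid (+/-400 bp jitter), so neighbouring
  elements never interact through any analysis window and "distal" is
  unambiguous (> 2 kb from any annotated 5' end by construction).
- Initiation shape: `sharp` puts >= 80% of 5'-ends at the planted mode
  (+/-3 bp spread); `dispersed` is a discretized Laplace over +/-50 bp
  with scale `dispersion_width` (default 20 bp), emulating the dispersed
  initiation typical of plant promoters. Dispersed simulations need a
  higher `signal_mean` for single positions to clear the 7-per-10^7 TSS
  threshold; the robustness test uses 400.
- Stability planting is separated from the threshold: unstable elements
  receive uniform [0, 1) normalized reads in the stability window, stable
  ones uniform [5, 50] — deliberately clear of the boundary at 2 so that
  classification accuracy measures the pipeline, not threshold noise.
  Boundary behaviour is exercised separately by explicit sweeps.
- Contaminant loci receive input pileups at 3x their csRNA density, so
  both the per-position and the region-level input filters must remove
  them; transcription-free open-chromatin regions carry STARR activity but
  no initiation.
- STARR activities are drawn per element as N(group mean, 0.2) with
  default means no_transcription 0.5 < U 1.4 < UU 2.0 < US 2.6 < stable
  3.2 — consecutive gaps of >= 3 SD — plus a 10% admixture of 20-50 bp
  fragments that the length filter must remove. Because activity depends
  only on the class, the simulated csRNA-to-activity correlation is near
  zero; real data couple activity to initiation strength within classes,
  a feature this generator intentionally does not model.
- GRO-seq levels are stylized (stable: 40 proximal / 80 body per 10^7;
  unstable: 30 / 10): they produce class-separated pausing indices for
  the metrics to chew on but encode no quantitative claim about polymerase
  kinetics.
- A TATA box (TATAAAAG) at -30 and a C/A initiator at -1/+1 are planted
  for every element (`plant_tata`), giving the nucleotide metaplot a known
  landmark. Background 5' ends arrive at `noise_rate` = 1e-5 per bp per
  strand — single reads, far below the TSS threshold at default depth.
- One integer seed fixes the genome, the signals and the STARR draw
  (stage-offset seeds keep the stages independently reproducible).

What passing tests on this generator do **not** show: robustness to
mappability artifacts, GC bias, replicate variance, annotation errors,
overlapping genes, or initiation shapes beyond sharp/Laplace. The
generator verifies the logic of the pipeline, not the messiness of real
libraries.

## Verification strategy

Every non-trivial computation has an independent oracle in the test
suite: greedy clustering against a straight-line O(n^2) reference on
all instances of <= 10 TSSs; IUPAC scanning against a naive
per-position scan; hexamer counts against brute-force substring
extraction; two-group Tukey HSD against the studentized-range closed
form; window metrics against direct formula evaluation. Printed
procedural constants are verified by boundary sweeps (6.99/7.00,
9.99/10, 1.99/2.00, +/-275 vs 276, +3000 vs +3001, 50 vs 51 bp).
Strand-mirroring the entire dataset (reverse-complement genome,
reflected coordinates, flipped strands) must leave every count,
fraction, ratio and rank table invariant, which pins down all
orientation conventions at once. The end-to-end suite simulates 1,000
elements at 10^7 reads and requires >= 95% planted-TSR recovery within
+/-10 bp, >= 95% stability accuracy away from the boundary, and class
fractions inside binomial 99% intervals; the STARR recovery suite
requires the planted ordering and a significant stable-vs-unstable
Tukey pair at alpha = 0.0005 in >= 19 of 20 seeds.

## Limitations

- The caller implements the printed rules only; production TSS callers
  apply additional fold-enrichment heuristics against RNA-seq that are
  not part of this package.
- The miRNA-proximal context window (1 kb) is a heuristic with no
  printed counterpart and is flagged as such in the output.
- Differential TSR analysis across conditions (count modelling,
  shrinkage) is out of scope; `switch_analysis` reports simple
  class-discordance percentages over TSRs detected in >= 2 samples,
  with absence of detection deliberately not treated as instability.
- The csRNA-to-STARR correlation transform (log10(x+1), Pearson) is a
  configurable default; the choice is not canonical.
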