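# teregulome

Transposable elements (TEs) supply a substantial share of the
transcription-factor binding sites (TFBSs) and promoters operating in
human cancer cells. `teregulome` is an R package for quantifying that
contribution from standard regulatory-genomics inputs — ChIP-seq peak
calls, a RepeatMasker-style TE annotation, aligned-tag tracks, CAGE
clusters, transcript models and paired count tables — and for
validating every stage against synthetic data with known ground truth.

It is aimed at computational biologists studying TE exaptation in
cancer (or any system where repeat subfamilies may have been co-opted
as regulatory elements), and implements four connected analyses:

1. **TE-subfamily enrichment in TFBSs.** For subfamily *s* with
   observed count *O* (distinct peaks overlapping ≥ 1 copy of *s*) and
   a circular-rotation permutation expectation *E* over *B* rotations,

   *p*₀ = *E*/*n*,  *p* = P(*X* ≥ *O*), *X* ~ Binomial(*n*, *p*₀),

   one-sided, Bonferroni-corrected over the subfamily universe, with
   enrichment ratio ER = *O*/*E*. The rotation null shifts each
   chromosome's peaks by an independent uniform offset modulo the
   chromosome length, splitting (not discarding) peaks that wrap.
2. **Epigenetic metaprofiles.** Mark coverage in 200 × 50 bp bins over
   10 kb windows centred on TE copies, as RPKM, replicate-averaged,
   control-subtracted, averaged over bound vs unbound copies and
   smoothed with an Epanechnikov kernel; plus truncation profiles in
   consensus coordinates.
3. **TE-derived promoter discovery.** The funnel CAGE ∩ TFBS
   (±300 bp) ∩ TE ∩ strand-matched promoter (TSS ± 1 kb), after
   hierarchical probe annotation (mRNA > lncRNA tier 1 > tier 2,
   strand-matched and exon-aware).
4. **Subfamily-normalised statistics.** Methylation and DNase levels
   as candidate/subfamily count ratios over consensus-homologous
   regions, tested with a paired lower-tail t-test and a one-tailed
   Yates-corrected proportion test; dual-luciferase relative activities
   with a one-tailed equal-variance t-test for TE deletions.

A seeded synthetic-data generator (`sim_config()`, `simulate_*`,
`simulate_dataset()`) emits every input format the pipeline reads, with
planted enrichment, planted promoter positives plus single-violation
decoys, and known effect sizes — so the whole pipeline is testable
offline. See `vignettes/te-regulatory-analysis.Rmd` for the model
details and design decisions.

## Worked example

```r
library(teregulome)

cfg <- sim_config(planted_enrichment = c(MIRb = 5, LTR7C = 5))
gen <- simulate_genome(cfg, seed = 1)
pk  <- simulate_peaks(cfg, gen$te, gen$genome, seed = 2)
res <- te_enrichment(pk$peaks, gen$te, gen$genome, n_perm = 1000, seed = 3)
res[res$significant == 1,
    c("subfamily", "te_class", "observed", "expected_mean", "p_adj",
      "enrichment_ratio")]
#>  subfamily te_class observed expected_mean        p_adj enrichment_ratio
#>      LTR7C      LTR       81        16.645 1.133070e-28         4.866326
#>       MIRb     SINE      255        52.779 4.459347e-92         4.831467
```

The two subfamilies planted at 5× their background overlap probability
are the only ones flagged at the Bonferroni level, with enrichment
ratios close to the planted fold; the run's accounting
(`attr(res, "n_peaks_in_te")`) shows 1303 of 2000 peaks (65.2%)
overlapping a TE on this TE-dense synthetic genome.

```r
lv <- paired_levels(simulate_paired_counts(cfg, seed = 4))
paired_methylation_test(lv$tumour, lv$normal)
#> one-sample one-tailed t-test (paired differences)
#>   statistic = -1.747  df = 5  tail = lower  p = 0.0705
```

Six simulated tumour/normal pairs at the configured mean difference of
−0.2 give a lower-tail t of −1.75 — a reminder that n = 6 pairs has
limited power for a single draw (the calibration tests average over
thousands of such draws).

A thin command-line wrapper over the same functions is included at
`inst/scripts/teregulome-cli.R`, with subcommands `enrich`, `profile`,
`discover`, `methylation`, `dnase`, `luciferase` and `simulate`.

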