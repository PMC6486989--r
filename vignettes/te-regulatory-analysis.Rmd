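---
title: "Quantifying transposable-element contributions to TF binding and promoter activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transposable-element contributions to TF binding and promoter activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teregulome)
library(GenomicRanges)
```

## The scientific problem

Transposable elements (TEs) make up roughly half of the human genome and,
far from being inert, supply a large reservoir of cis-regulatory
sequence: transcription-factor binding sites (TFBSs), internal promoters
(notably the RNA-Pol-II promoters in LTR retrotransposon long terminal
repeats and the L1 antisense promoter) and enhancer-like elements. In
somatic tissue most TE copies are silenced by DNA methylation and
repressive histone marks, but that repression is frequently relaxed in
epithelial cancers, where individual TE copies have been shown to drive
oncogene expression. `teregulome` implements the computational side of a
breast-cancer-oriented analysis of this phenomenon:

1. **Enrichment** — which TE *subfamilies* are over-represented in the
   ChIP-seq binding sites of oncogenic TFs (C/EBPβ, E2F1, MYC), relative
   to a circular-rotation permutation null?
2. **Metaprofiles** — do TF-bound copies of a subfamily carry active
   histone marks (H3K27ac, H3K4me1/3, ...) that unbound copies of the
   same subfamily lack?
3. **Promoter discovery** — which genes have a CAGE-defined
   transcription start site that sits inside a TE, near a TFBS, within
   the gene's promoter — i.e. a putative TE-derived promoter?
4. **Epigenetic statistics** — are candidate TEs hypomethylated in
   tumours, DNase-accessible in cancer cells, and do reporter-assay
   deletions of the TE reduce promoter activity?

All four stages run end-to-end on synthetic data with known ground
truth (the `simulate_*` family), which is how the package tests itself.

## The enrichment model

For a peak set of $n$ peaks and a subfamily $s$, the observed statistic
is the number of *distinct* peaks overlapping at least one genomic copy
of $s$ (a peak overlapping two copies counts once; a peak overlapping
copies of two subfamilies counts once for each). The null preserves the
joint structure of both the peak set and the TE annotation by circular
rotation: each chromosome's peaks are shifted by an independent uniform
integer offset modulo the chromosome length; a peak wrapping past the
end is split into two segments that share one peak identity, so peak
count and peak bp are conserved exactly. Averaging the per-subfamily
count over $B$ rotations gives `expected_mean`, and

$$p_0 = \frac{\text{expected\_mean}}{n}, \qquad
  p = \Pr\{X \ge \text{observed}\},\; X \sim \mathrm{Bin}(n, p_0),$$

one-sided because the hypothesis is *enrichment*. P-values are
Bonferroni-corrected over the full subfamily universe (every subfamily
present in the annotation, not only those with non-zero overlap), and
the enrichment ratio is observed / expected\_mean.

Numerical choices:

* **Rotation granularity.** Rotation is per chromosome, not on a
  concatenated genome: it preserves per-chromosome peak and TE
  densities and avoids an arbitrary concatenation order.
* **Zero-expectation floor.** When no rotation ever produces an
  overlap, $p_0$ is floored at $1 / (B \cdot n)$ — the resolution limit
  of the permutation estimate — so finite sampling cannot manufacture
  $p = 0$. The enrichment ratio is reported as `Inf` in that case.
* **Sidedness.** Upper-tail only; a depletion analysis would flip the
  tail and is deliberately not bundled.
* **Determinism.** All rotation offsets come from a seeded RNG scoped
  to the call (`seed =`), and the seed is recorded in the result
  attributes and output headers.

```{r enrichment-demo}
cfg <- sim_config(planted_enrichment = c(MIRb = 5, LTR7C = 5))
gen <- simulate_genome(cfg, seed = 1)
pk <- simulate_peaks(cfg, gen$te, gen$genome, seed = 2)
res <- te_enrichment(pk$peaks, gen$te, gen$genome, n_perm = 500, seed = 3)
res[res$significant == 1,
    c("subfamily", "observed", "expected_mean", "p_adj",
      "enrichment_ratio")]
```

## Metaprofiles

A 10 kb window centred on each TE copy is divided into 200 bins of
50 bp. Per bin, tags overlapping by at least 1 bp are counted (so one
tag can increment adjacent bins, as in a `bedtools coverage` workflow)
and scaled to RPKM, $c \cdot 10^9 / (50 \cdot N)$ with $N$ the track's
mapped-read total. The aggregation order is fixed: mean across
replicates per anchor and bin, minus the pooled-control mean per anchor
and bin, then mean across anchors; bins clipped at a chromosome end are
missing and drop out of the anchor mean (the per-bin effective $n$ is
reported). Curves are smoothed by a Nadaraya–Watson smoother with the
Epanechnikov kernel $K(u) = 0.75\,(1-u^2)$, $|u| \le 1$.

* **Window anchor** is the element midpoint — the only reading of a
  fixed 10 kb window "centred on" elements of variable length.
* **Strand.** Windows are not flipped for minus-strand copies; profiles
  are in genomic orientation, matching a plain coverage workflow.
* **Bandwidth** defaults to 150 bp (three bins) — a light smoothing
  scale chosen once for visual continuity; it is a reported parameter,
  not an inference.
* **Truncation profiles** use the RepeatMasker-style consensus
  coordinates: position $j$ of the subfamily consensus scores the
  fraction of group copies whose alignment covers $j$, giving a
  coverage-of-consensus curve in $[0, 1]$ for bound vs unbound groups.

## Promoter discovery

The discovery funnel is deterministic geometry, applied in fixed order
to CAGE clusters: (1) keep clusters within 300 bp of any TFBS peak
(strand-blind; the window matches a `bedtools window -w 300` contract:
a cluster exactly 300 bp away is excluded, 299 bp is kept); (2) keep
clusters overlapping a TE copy by ≥ 1 bp; (3) keep clusters lying
*fully inside* a strand-matched promoter, defined as TSS ± 1 kb of an
annotated transcript. Candidates are emitted per (cluster, transcript,
TE, TF) combination, with a gene-level deduplicated summary and the
funnel of stage counts.

Probe annotation is hierarchical: a probe is annotated with all
strand-matched, exon-aware (`-split`-style) transcript hits from the
highest-priority tier that yields any hit — mRNA, then lncRNA tier 1,
then tier 2 — and never from more than one tier.

Two genuinely open design points are resolved as follows, each with the
alternative exposed as an argument:

* "the 2 kb region around the 5′ end" is read as TSS ± 1000 bp
  (`mode = "centered"`); an upstream-anchored 2 kb is
  `mode = "upstream"`.
* Stage 1 pools all TF peak sets, recording which TFs matched, rather
  than running per-TF funnels; per-TF candidacy is recoverable from the
  `tf` column.

## Subfamily-normalised statistics

Read-depth differences between samples are normalised away by dividing
the tag count in a candidate TE's TFBS footprint by the count over the
*homologous regions* of every copy of the subfamily. Homology is
defined through consensus coordinates: the footprint is projected onto
the consensus via the candidate's (`rep_start`, `rep_end`) alignment
and lifted back into every copy whose alignment covers ≥ 1 bp of it
(linear interpolation; exact whenever the genomic and consensus spans
are equal length, which the simulator guarantees). The tests are:

* **Methylation** — one-sample, lower-tail t-test on paired
  tumour − normal differences of normalised levels.
* **DNase sensitivity** — two-sample proportion test
  (Yates-corrected χ², df 1) of candidate/subfamily counts between
  cell lines; the one-tailed p is half the upper χ² tail when the
  observed direction matches the alternative, and the complement when
  it does not, so equal proportions give exactly p = 0.5.
* **Luciferase** — firefly:Renilla per well, triplicate means per
  construct, normalised to the positive control within each experiment
  and then to mean wild-type across experiments; TE deletions are
  tested with a one-tailed pooled-variance t-test (deleted <
  wild-type).

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: 4 chromosomes of
2 Mb, ~5000 non-overlapping TE copies drawn from a 30-subfamily
catalogue spanning LINE/SINE/LTR/DNA classes with field-typical
consensus lengths (Alu ≈ 300 bp ... L1 ≈ 6 kb) and ~45% genomic
density; 2000 ChIP-seq peaks of 150–400 bp; Poisson tag tracks at
0.02 tags/bp with a 5× fold inside ±500 bp of bound copies; a tiered
transcriptome; six tumour/normal pairs with a −0.2 mean difference of
normalised methylation levels at SD 0.15. Enrichment is planted by
giving configured subfamilies a peak-overlap probability `fold` times
the background overlap probability of a random peak. Each
transcript and each planted promoter construction occupies a disjoint
25 kb slot, so ground truth is exact: positives satisfy all discovery
predicates, decoys violate exactly one (window distance / TE overlap /
promoter containment / strand), and background CAGE clusters sit in
peak-free slots.

The generator does *not* emulate: nested or interrupted repeats
(readers accept them; the generator places disjoint copies), sequence
content (no FASTA, hence no GC or mappability structure), fragment-size
and read-pairing effects, copy-number variation, or correlated
biological replicates. Passing tests therefore demonstrate the
*correctness of the computations and the calibration of the tests under
the stated model*, not robustness to alignment artefacts or
composition biases of real data.

## Problem sizes and runtime

The shipped tests and the acceptance script run the permutation null at
1000 rotations over 2000 peaks × ~4900 copies (seconds per run; the
10,000-rotation default is intended for genome-scale analyses),
metaprofiles over 200 + 200 anchors, discovery over 20 positives + 200
decoys, and test calibration with 2000 null replicates and 1000 power
replicates — sizes at which every Monte-Carlo acceptance band is several
standard errors wide.

## Known limitations

* The binomial test treats peaks as exchangeable Bernoulli trials; peak
  width heterogeneity enters only through the rotation expectation.
* RPKM totals include planted signal (no depth renormalisation), so
  control-subtracted flanks can sit slightly below zero — visible only
  when bound windows are a non-trivial fraction of the library.
* Consensus liftover assumes an indel-free linear alignment between a
  copy and its consensus; real RepeatMasker alignments bend this, which
  only degrades the homologous-region projection gracefully.
* The subfamily universe (Bonferroni divisor) is taken from the TE
  annotation supplied; analyses of annotation subsets change the
  correction accordingly.
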