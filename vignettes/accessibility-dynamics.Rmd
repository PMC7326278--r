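---
title: "Methods: modeling chromatin accessibility dynamics with accessdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling chromatin accessibility dynamics with accessdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

accessdyn analyzes how chromatin accessibility changes across an
experimental time course measured by ATAC-seq — the motivating setting is a
baculovirus infection course in insect cells (four conditions, two
replicates each), where infection progressively opens most of the host
genome while a minority of regions close. This vignette explains the models
and procedures the package implements, the choices made where the design
was genuinely open, and what the synthetic-data generator does and does not
emulate.

## Coordinate conventions

All internal coordinates are 0-based half-open (`[start, end)`, the BED
convention); GTF's 1-based inclusive coordinates are converted at the I/O
boundary. The TSS and TTS are stored as single-base positions: a `+` gene
at `[a, b)` has `tss = a`, `tts = b - 1`; a `-` gene the reverse. Fragments
(sequenced Tn5 inserts) carry no strand and no Tn5 9-bp shift is applied —
the analyses here (coverage, spectra, V-plots) are insensitive to a
constant sub-10-bp offset. Scaffold names match by exact string equality.

## Peak calling

`call_peaks()` is a deliberately simple stand-in for a full local-background
caller such as MACS2 (whose model-building and local lambda are out of
scope). Windows of 200 bp slide by 50 bp across each scaffold. The window
statistic is the summed depth mass divided by the expected fragment length
(`frag_len`, default 200 bp): per-bp depth mass itself is overdispersed
under a Poisson model because each fragment paints ~200 correlated bases,
whereas the number of fragments touching a window is Poisson under uniform
background, and mass/`frag_len` approximates that count. The background
rate is the *median* window count genome-wide: on signal-sparse genomes it
coincides with the mean, while on the generator's deliberately peak-dense
toy genome the mean would fold several-fold enrichment into the null and
cost most of the caller's sensitivity. P-values are Poisson upper tails,
corrected by Benjamini-Hochberg over all windows with significance called
at q < 0.01; overlapping significant windows are merged, the summit is the
leftmost maximal-depth base, and peaks shorter than 150 bp are dropped.

## Consensus peaks

Replicate and cross-sample peak sets are merged by interval union where two
intervals join iff the distance between their proximal ends is less than
1 bp — in half-open coordinates, iff they overlap or are exactly
book-ended. This is the only reading under which a "< 1 bp" gap rule is
non-vacuous. The merged score is the maximum of the constituents. The
operation is idempotent, commutative and associative, so merging all
samples at once equals any iterated pairwise merge; tests assert this
against a per-base painting oracle.

## Normalization

Two routes, matching two assay types:

* **Stable-gene scaling (ATAC).** `select_stable_genes()` ranks genes by
  the coefficient of variation of RPKM across all samples, after an
  expression floor (mean RPKM >= 1) so that near-zero genes with unstable
  CVs cannot enter; CV rather than raw variance is used so highly expressed
  genes do not dominate the "low variance" screen. Fragments whose
  midpoints fall within 1 kb of the selected TSSs are counted per sample
  (midpoint rather than any-overlap: deterministic and symmetric), and
  `stable_gene_scale_factors()` sets `factor_s = mean(counts)/counts_s`, so
  scaled counts equal the cross-sample mean *exactly* — equalization to the
  mean is a concrete choice where only "basically the same" is required,
  made for testability. Scaling is by weight (lossless), not read
  subsampling.
* **Spike-in scaling (ChIP).** Factors proportional to the inverse
  exogenous-chromatin read count, normalized to mean 1. A 1:4
  exogenous:target chromatin mix corresponds to an expected spike read
  share of 1/5 before immunoprecipitation-efficiency noise.

## Differential accessibility

`moderated_t_test()` works on `x = log2(signal + 1)` (the linear-model
machinery assumes roughly additive noise; the pseudocount handles empty
peaks). Per peak it computes group means, the pooled residual variance
`s2_g` on `d_g = n1 + n2 - 2` df, then shrinks variances with an
empirical-Bayes prior `(d0, s0_sq)` fitted to the whole ensemble by
closed-form moment matching on `log s2` under the scaled-F model
`s2_g ~ s0_sq F(d_g, d0)`:

* `trigamma(d0/2) = var(e) - trigamma(d_g/2)` with
  `e_g = log s2_g - digamma(d_g/2) + log(d_g/2)`,
* `log s0_sq = mean(e) + digamma(d0/2) - log(d0/2)`,

solved with a Newton inverse of the trigamma function. Moment matching
(rather than the full marginal MLE) keeps the fit closed-form; on simulated
ensembles it agrees with the reference eBayes implementation to within a
few percent on the prior and > 0.9999 correlation on the statistics, and a
dedicated test asserts exact reduction to the classical pooled t at
`d0 = 0`. A non-positive excess variance gives `d0 = Inf` (Normal
reference distribution); `d0` above 1e6 is treated as infinite. The
moderated statistic uses posterior variance
`(d0 s0_sq + d_g s2_g)/(d0 + d_g)` and `d0 + d_g` df.

DAP status applies fold change > 2 and **raw** p < 0.05 — no
multiple-testing correction is applied to DAP calls, mirroring the
threshold convention of the motivating analysis (correction there is
reserved for GO enrichment); an optional BH mode exists but is off by
default. Only two-group contrasts are supported; there is no design-matrix
language, no voom-style weights, and no trend/robust variants.

## PCA and K-means archetypes

PCA treats samples as observations and peaks as features, centers each
peak across samples, and decomposes by SVD (`stats::prcomp`, unscaled, on
all merged peaks); PC signs follow the convention that each component's
largest-magnitude loading is positive. `kmeans_cluster()` z-scores each
peak's profile across samples — so clusters reflect the *shape* of the
accessibility trajectory, not its amplitude — and runs `stats::kmeans`
with 10 random restarts and up to 300 iterations, seeded, which is
deterministic per seed. k defaults to 4 (the four archetypes) but is a
parameter. The recommended input is `log2(signal + 1)`, the same scale the
differential model uses: on the raw scale a gradual-gain and a late-gain
trajectory are nearly collinear after z-scoring and the archetypes blur
together; the log scale separates them cleanly. Reference k-means rather
than a hand-rolled k-means++ loop is a deliberate build-on-base-R choice;
with 10 restarts on these well-separated profiles initialization is not a
practical concern.

## Annotation and enrichment

`annotate_peaks()` reduces each peak to an anchor (summit when present,
else midpoint — simpler than HOMER's exact anchor logic, a documented
divergence) and classifies by fixed priority: promoter-TSS (within 3 kb of
any TSS) > TTS (within 1 kb, a HOMER-like default where no definition is
given) > exon > intron > intergenic. The nearest gene minimizes
`|anchor - tss|` on the same scaffold (HOMER's TSS-distance convention),
ties broken lexicographically; distances are signed by gene orientation
(negative = upstream). `overlap_sets()` reports the count-based
(asymmetric) percentage of A peaks sharing >= 1 bp with B, plus the
symmetric base-pair Jaccard index — both, because summary percentages of
this kind are ambiguous between the two readings. `go_enrichment()` is the
one-sided Fisher exact test (hypergeometric upper tail) per term with BH
adjustment across tested terms, terms without study hits skipped; the
background is the supplied gene universe, term sets are taken as given (no
GO-DAG propagation).

## Nucleosome landscape

Fragment-length bands: NFR < 140 bp, mono-nucleosomal 150-200 bp
(inclusive), multi-nucleosomal >= 250 bp; lengths in the gaps (140-149,
201-249) are classed "other" rather than forced into a band, since the
bands as stated leave gaps. The multi-nucleosome index,
`multi / (nfr + mono)`, scalarizes the collapse of the multi-nucleosomal
component. V-plots bin (signed midpoint-to-center distance, insert length)
over all qualifying (fragment, peak) pairs; a fragment near two peak
centers counts once per peak. Midpoint positioning is the standard V-plot
convention; signed distance retains left/right asymmetry. Normalization
modes: raw counts, per-peak mean, or density — the reference figures'
normalization is not stated, so both normalized modes are provided.

## The synthetic-data generator

`simulate_experiment()` is first-class, tested code, and every output is a
pure function of the configuration (including its seed). It emulates:

* a toy genome of 5 x 200 kb scaffolds with 300 non-overlapping genes
  (1-4 exons), of which 30 are stable (housekeeping-like: high, tight
  expression — NB dispersion 0.01 versus 0.1 plus a lognormal per-group
  wobble, sd 0.2, for the rest);
* 160 truth peaks (40 per archetype), 400 bp wide, >= 1 kb apart, placed
  outside exons and outside stable-gene TSS +-1.5 kb neighborhoods — the
  latter so that differential peak signal cannot contaminate the
  normalization windows, which would otherwise make depth-factor recovery
  structurally impossible;
* per-group accessibility multipliers I (1, 2.5, 5, 10) gradual gain,
  II (0.05, 0.05, 0.05, 6) near-closed until a final-condition jump,
  III (10, 5, 2.5, 1) gradual loss, IV (1, 1, 4, 8) late gain beginning
  mid-course. The shapes are chosen to be separable after per-peak
  z-scoring at the generator's replicate noise (NB dispersion 0.05); II's
  near-zero baseline is what makes cluster-II regions invisible to the
  caller in the control state, reproducing the open/closed chromatin
  dichotomy that the ChIP-overlap analysis contrasts;
* ~200,000 fragments per sample: uniform background at 0.05 fragments/bp,
  NB per-peak counts with mean proportional to multiplier x per-sample
  depth factor (depth factors uniform in 0.7-1.3), and Poisson
  stable-gene TSS pileups (expectation 200 per gene) equal across samples
  before depth scaling;
* insert lengths from a three-component mixture — NFR Normal(80, 20),
  mono Normal(180, 15), multi `k x 200 + Normal(0, 15)` with
  `k = 2 + min(Geom(1/2), 3)` — with the multi weight 0.25 in all groups
  except 0.05 in the final condition (the multi-nucleosomal collapse).
  NFR fragments center tightly on the summit (sd 30 bp); nucleosomal
  fragments sit +-1 period from it, which is what produces the V-plot
  flanking-nucleosome pattern;
* RNA-seq NB counts whose promoter coupling acts only in the final
  condition: genes owning a truth promoter peak get a lift
  `(multiplier_last / multiplier_first)^0.6`, renormalized across owned
  genes so total expression mass is conserved. The renormalization models
  a transcriptome that redistributes rather than inflates; without it,
  library totals in the final condition blow up and RPKM's library
  normalization corrupts the CV screen for every gene — a composition
  bias that is an artifact of a toy genome where a large share of genes
  owns a peak;
* ChIP marks as jittered (sd 20 bp) copies of the truth peaks of the
  clusters each mark occupies, with spike read counts around
  `target x f/(1-f)` for spike share f = 0.2, +-20% noise.

What it does **not** emulate: sequence (no FASTA/FASTQ, no Tn5 or GC
bias), duplicate fragments, local background structure
(mappability, copy number), gene-length biases in RNA-seq, or the scale of
a real genome. Passing recovery tests therefore demonstrates the
*pipeline's* correctness under the assumed signal structure, not
performance on real libraries — in particular the caller's genome-wide
background is easier here than on a genome with chromosome-scale coverage
waves.

## Problem sizes and numerical choices

The test suite runs the full default generator (8 samples x ~200k
fragments) for the archetype-recovery and depth-recovery checks (20 seeds
each), a scaled-down configuration (2 x 100 kb scaffolds, 32 truth peaks,
30k fragments) for the other Monte-Carlo property checks, 100 replicates
of a 2,000-peak null for type-I calibration, and >= 100 randomized small
instances per interval primitive against per-base brute-force oracles.
Ties everywhere are broken deterministically (leftmost summit,
lexicographic gene and term ids). K-means convergence follows
`stats::kmeans` defaults with `iter.max = 300`; the trigamma inverse
iterates Newton steps to relative 1e-10. Degenerate inputs are defined,
not accidental: empty fragment files parse to empty tables, zero-signal
tracks call no peaks, zero-variance rows z-score to zero vectors,
zero-variance ensembles take the `d0 = Inf` path, and a zero stable-gene
count or an empty ECDF set is an error.

## Known limitations

The caller has no local lambda and will underperform MACS2 on real data
with non-uniform background. The moderated t supports only two-group
contrasts. GO enrichment assumes the term map is already propagated.
Overlap percentages are count-based by default and can differ sharply from
the bp-based Jaccard on fragmented interval sets. The generator's group
labels are ordinal with the last group treated as the remodeled state; the
ChIP model has no background peaks, so overlap contrasts are cleaner than
real immunoprecipitation would give.
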