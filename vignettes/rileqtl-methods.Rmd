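---
title: "Methods and design notes for rileqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rileqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rileqtl)
```

# The experimental design being modelled

`rileqtl` analyzes a biparental recombinant inbred line (RIL) panel profiled
by RNA-seq under two environments. Each RIL is near-fully homozygous: its
genome is a mosaic of the two parental genomes ("MM" and "PI") delimited by
historical crossovers. Each line is sequenced once, in one of the two
environments (the sub-panels are disjoint), and the parental lines are
sequenced in replicate under both environments. RNA-seq provides both the
genotypes — SNPs segregating in transcribed genes — and the phenotypes —
transcript abundances — so a single experiment supports genetic-map
construction, differential expression, genetic-architecture statistics and
eQTL mapping.

# Genotyping and map construction

**Consistency filter.** A SNP site is usable when every replicate of each
parent carries the same allele, the two parents differ, and every RIL has a
call. The all-RILs requirement is strict but removes the need for any
imputation model downstream.

**Sliding-bin genotyping.** Individual RNA-seq SNP calls are noisy and
sparse, so genotypes are called per sliding window of `bin_size = 100`
consecutive SNPs (step 1 SNP). The per-cell genotype probability is the
fraction of non-missing window SNPs matching MM; the reported code takes the
most likely genotype, with an exact 0.5 tie or fewer than 10% informative
SNPs giving NA. Both the tie rule and the 10% informativeness floor are
conservative choices: an ambiguous cell should not contribute recombinations
or map distance. The marker's physical position is the arithmetic mean of
its member SNP positions.

**Collapse and maps.** Sliding windows produce long runs of identical
columns between breakpoints; consecutive markers identical across all lines
(including their NA pattern) are merged (idempotent, by construction). A
recombination is a code change between consecutive non-NA markers; NA cells
are skipped and the breakpoint interval spans the gap. The genetic map uses
direct Morgan mapping — the cM increment between adjacent markers is 100
times the recombination fraction across informative lines, accumulated from
0 per chromosome. No Haldane/Kosambi correction is applied by default
(adjacent-marker fractions are small after collapsing; a `mapping =
"haldane"` switch exists).

Each collapsed marker represents a genomic *block* of SNP bins. Two
coordinates summarize it: the mean position (`pos`, the marker position
used for peaks, bins and the cM map) and the block span
(`span_left`/`span_right`, the first and last member-SNP positions). The
distinction matters for confidence intervals (below).

# Expression layers

Counts are converted to TPM with annotated gene lengths (quantification from
alignments is out of scope; lengths are inputs). Two transforms serve
different purposes: `TPM_log = log2(TPM + 1)` is the response in every
linear model, and `TPM_rat = log2(TPM / per-gene mean TPM)` places genes on
a common scale for the sample PCA (computed with `stats::prcomp`, centered
and unscaled — the ratio transform already normalizes per gene). The
`TPM_rat` mean is taken over the full analysis sample set; the
expressed-gene filter (`TPM > 0` in *every* sample) is likewise applied
jointly across both environments, so all stages share one gene universe.

# Linear models and multiple testing

The treatment model is a per-gene one-factor least-squares fit over all
samples of both environments, RILs and parental replicates alike, with the
F-test p value Bonferroni-adjusted: with m genes the −log10(p) cutoff at
family-wise level α is −log10(α/m). The parental G×E model is the two-way
fit `T + L + T×L` on parental replicates with sequential F tests, per-term
Benjamini–Hochberg control, and one shared significance threshold — the most
stringent of the three realized per-term cutoffs. Realized BH cutoffs depend
on the observed p-value distribution and are reported, not hard-coded. Sign
conventions: positive treatment effects mean higher abundance under HP,
positive line/eQTL effects mean the MM allele raises abundance.

# Heritability, transgression and permutation thresholds

Broad-sense heritability is estimated as H² = (V_RIL − V_e)/V_RIL, with
V_RIL the sample variance over RILs and V_e the pooled variance of the
parental replicates (n−1 denominators throughout). This is an upper-bound
style estimator; it can be negative when parental replicates are noisier
than the RIL spread, and is reported as computed. Transgression counts RILs
strictly beyond (min parental mean) − 3σ or (max parental mean) + 3σ, σ
being the pooled parental SD; σ = 0 collapses the bounds and is flagged
degenerate.

Significance uses a per-transcript permutation scheme: trait values are
reshuffled over the line designations (group sizes preserved), the statistic
recomputed, and after `n_perm = 1000` rounds the 50th-highest value is the
threshold; the observed statistic must strictly exceed it. The 50/1000 rank
is nominally an FDR = 0.05 label but operates per transcript, i.e. close to
a per-test α = 0.05 — on null data about 5% of transcripts pass, which the
test suite verifies (within ±2 percentage points at 1000 genes, for both
statistics). In the genome-wide scans one permutation of samples is applied
to all genes jointly per round; per-gene thresholds are still individually
valid (marginally each gene sees 1000 exchangeable reshuffles), and the
joint scheme preserves gene–gene correlation at a fraction of the cost.

# eQTL mapping

Per environment, each transcript is regressed on each marker (genotype coded
0/1, NA lines dropped marker-wise; markers with a single genotype class
score 0). The genome-wide significance threshold searches an ascending grid
of −log10(p) cutoffs (step 0.1) for the smallest cutoff with RDS > 0
satisfying `FDS/RDS ≤ (m0/m)·q·log(m)`, where RDS counts transcripts whose
real profile maximum exceeds the cutoff, FDS the mean of that count over
`n_perm = 10` full permutation remappings, m0 = m − RDS, and the log is
natural (the bound echoes the harmonic-sum inflation used for FDR control
under dependency; a base-10 switch exists). If no cutoff satisfies the
bound, a sentinel (NA cutoff, "no significant eQTLs") is returned rather
than an error. Cross-environment comparisons use the most stringent of the
two cutoffs when `harmonize = TRUE` (the default in the pipeline).

**Peaks and intervals.** Per chromosome whose maximum exceeds the threshold,
one record is emitted (secondary within-chromosome peaks are out of scope):
the leftmost maximal marker is the peak, and the confidence interval is the
contiguous marker run around the peak scoring within 1.5 −log10(p) units of
it. The CI is reported in bp as the *genomic span* of that run — from the
first member SNP of its leftmost marker to the last member SNP of its
rightmost marker — rather than the outer markers' mean positions. This is a
deliberate design choice: a collapsed marker stands for a 0.5–2 Mb block in
a ~100-line panel, and mean positions systematically under-cover the region
the markers actually represent; with single-marker CIs they would degenerate
to a point. Measured on simulated panels (100 genes, 50 RILs, cis effects of
two residual SDs), span-based CIs cover the true locus for ≍92–95% of
recovered genes versus ≍86% for mean-position CIs.

**cis/trans.** An eQTL is trans when the peak is at least 1 Mb from the gene
(distance to the nearest edge of the gene interval; infinite across
chromosomes) *and* the gene interval does not intersect the CI; otherwise
cis. Both conditions being required makes the trans call conservative.

# Trans-band detection

Trans-eQTL peaks are assigned to 2-Mb bins on a 0-based half-open grid per
chromosome. The null is a uniform distribution of trans-eQTLs over the bin
universe: λ = total trans count / number of bins, and each bin's enrichment
p is the upper-tail Poisson probability P(X ≥ observed). The default
universe is the set of bins containing at least one marker — only
marker-bearing regions can carry a peak, and including empty bins would
deflate λ and overcall enrichment; a whole-genome universe is available.
Bins with p < 1e-4 are significant, and runs of significant bins bridging at
most one non-significant bin merge into a trans-band whose counts sum over
the whole merged span. Bins never span chromosome boundaries.

# The synthetic population generator

The generator emulates the post-alignment data of the design: 12
tomato-scale chromosomes; disjoint RIL sub-panels of 49 (HP) and 52 (LN)
lines plus 3 parental replicates per parent per environment; crossover
counts Poisson with mean 2 per chromosome per line, placed with 80% of
events in the distal thirds (arm bias mimicking suppressed pericentromeric
recombination); biallelic parental SNPs scattered proportionally to
chromosome length, with configurable per-call missingness in RILs (default
1%) and perfectly consistent parents. Optional segregation distortion on one
chromosome draws that chromosome's mosaic from a stationary two-state Markov
process with the requested PI frequency — a Poisson-plus-alternation scheme
cannot reach a 0.7 marginal frequency, the Markov construction matches both
the marginal and the expected switch count exactly.

Expression follows a latent log2 model per gene and sample: baseline
(uniform 3–8) + cis effect × genotype at the gene's own locus + hotspot
effects × genotype at the hotspot locus (active only in the hotspot's
environment) + treatment effect + G×E term + Normal residual (SD 0.25).
Counts are negative-binomial around TPM-consistent expectations at a 2e6
library size (dispersion 0.05; dispersion 0 gives the deterministic
noise-free limit used by exact oracles). Ground truth — crossovers, per-gene
effects, hotspot targets — is returned alongside, so recovery is measurable.

What the generator does *not* emulate: read-level sequencing error and
mapping bias, residual heterozygosity, selfing-generation pedigree structure
(the crossover rate absorbs the F generation), expression-level outliers,
batch effects, and realistic gene-gene co-expression beyond what genetics
and library-size coupling induce. Passing tests therefore demonstrate
correctness of the algorithms under the stated stochastic model, not
robustness to every artifact of real RNA-seq.

One emergent feature deserves emphasis because it is realistic:
**compositional coupling**. TPM is a relative measure, so a hotspot that
up-regulates many targets in one genotype class depresses every other
gene's TPM in those samples, creating genuine (not artifactual-to-the-code)
trans associations at the hotspot locus for genes with no simulated effect.
The validation suites account for this — false-discovery accounting against
ground truth is done in the hotspot-free environment.

# Numerical and testing choices

* Zero-variance genes: p = 1, effect 0 (never NaN). Zero-total-count
  samples: error naming the sample.
* −log10(p) values are computed via `pf(..., log.p = TRUE)` to stay finite
  and accurate far beyond double-precision p values.
* Ties at peaks resolve to the leftmost marker; probability-0.5 genotype
  cells are NA; NA never contributes to recombination counts or cM.
* Permutation seeds: every stochastic stage takes a seed; the pipeline
  derives fixed per-stage offsets from one master seed, so stages can be
  re-run in isolation and whole runs are bit-reproducible.
* Problem sizes in the test-suite: calibration suites use 1000 null genes
  with the full 1000-permutation scheme; eQTL recovery 100 genes × 50 RILs
  on a 5×50 Mb genome; FDR calibration 5 seeds × 200 genes; hotspot
  recovery 20 seeds × 400 genes with a 50-target hotspot at 52 LN lines;
  recombination recovery 16,000 SNPs over two chromosomes. These sizes give
  stable rates while keeping the whole suite around a minute.
* The hotspot-recovery suite maps at the fixed harmonized threshold 3.9:
  with only a few hundred transcripts the permutation bound admits lenient
  cutoffs (≈2.7), at which chance inter-chromosome genotype correlations
  (|r| ≈ 0.4 at n = 52) let strong hotspot targets emit correlated secondary
  peaks and satellite bands. The FDR machinery is validated separately on
  mixed simulations, where ground-truth false-discovery proportions stay
  within the declared bound on average over seeds.

# Known limitations

* Single-marker mapping only: no composite-interval or multi-QTL models, no
  kinship correction; with strong population structure the FDR bound is the
  only guard.
* One record per chromosome per transcript; linked secondary peaks on the
  same chromosome are absorbed into one CI.
* The cM map reflects detectable recombinations; closely spaced double
  crossovers within one genotype block are invisible, so map length is a
  slight underestimate at realistic SNP densities.
* The per-transcript 50/1000 permutation threshold controls a per-test
  error rate, not a genome-wide FDR, and is labelled accordingly in outputs.
* TPM compositionality is not corrected (no size-factor alternatives by
  design); strong hotspots induce trans associations through the library
  itself, as discussed above.
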