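---
title: "Quantifying spike-in normalized transcription and occupancy changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spike-in normalized transcription and occupancy changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikequant)
```

## The problem

Rapid-depletion (auxin-degron) experiments in budding yeast can collapse
transcription globally within minutes. Conventional per-library
normalization (RPM, TMM, quantile) silently erases such global shifts
because it assumes most signal is unchanged. The experiments this package
quantifies therefore carry a dual-genome spike-in: a fixed amount of
foreign material — *S. pombe* cells mixed 1:8 with the *S. cerevisiae*
culture for 4-thiouracil nascent RNA-seq and ChIP-seq, or MNase-digested
*D. melanogaster* chromatin for ChEC-seq — so that absolute signal changes
between the vehicle control (DMSO) and the depletion condition (IAA) remain
measurable.

`spikequant` implements the quantification layer that sits downstream of
alignment and counting: normalization, filtering, promoter-level peak
analysis, occupancy change, Pol II traveling ratio and metagene profiles,
ratio statistics normalized to total polymerase, and the comparative
statistics used to summarize them. A synthetic-data generator with known
ground truth stands in for deposited sequencing data, so every pipeline
stage is exercised by parameter-recovery tests.

## Normalization models

Three normalization modes, each leaving per-base or per-gene values on an
arbitrary but condition-comparable scale (scale factor 10,000 throughout):

* **Nascent RNA-seq** (`normalize_counts`): gene count divided by the
  sample's total *S. pombe* reads, times 10,000.
* **ChEC-seq coverage** (`normalize_chec`): per-base coverage divided by
  the sample's total *D. melanogaster* reads, times 10,000.
* **ChIP-seq coverage** (`normalize_chip`): per-base coverage divided by
  the IP sample's *S. pombe* reads, multiplied by the input sample's
  *S. pombe*:*S. cerevisiae* read ratio, times 10,000. The input ratio
  corrects for the spike fraction actually present in each IP; with a unit
  input ratio the formula degenerates to the ChEC formula, which the test
  suite checks explicitly.
* `normalize_rpm` covers re-analyzed public datasets that carry no
  spike-in.

Counts and tracks carry a normalization state (`raw` → `normalized` →
`averaged` for tables; `raw` → `*_normalized` for tracks) and refuse to be
normalized twice — a cheap state machine that catches a common scripting
error.

The order of operations is fixed: normalize, filter, average replicates,
log2 change. The detectability filter removes any gene with a zero raw
count in at least one sample, which is why the default pseudocount for
`log2_change` is 0; a positive pseudocount is available for exploratory
use.

## Coordinates

All internal coordinates are 0-based, half-open (the bedGraph convention);
GFF3 input is converted from 1-based inclusive on read. For minus-strand
genes, TSS and PAS are stored as half-open boundary coordinates — the exact
mirror image of plus-strand coordinates — so that every windowed operation
(promoter windows, TR anchor windows, metagene offsets) is a strict
reflection of its plus-strand counterpart. The test suite verifies this
mirror symmetry on reversed tracks.

Promoter windows span −300..+100 bp around the TSS in the transcription
direction. Genes lacking a TSS annotation receive a fallback TSS 100 bp
upstream of the start codon. Windows clipped at a chromosome edge record
the clipping.

## TATA classification

Promoters are classified by the presence of at least one TATAWAW match
(W ∈ {A, T}) on the sense strand. The scan window and strand are not fully
determined by the source analyses, so they are configuration with
documented defaults: −200..TSS, sense strand only. Ambiguous genome bases
(N) never match. The scan is implemented with `Biostrings` pattern matching
(`fixed = "subject"`, so IUPAC codes in the motif are interpreted but
subject ambiguity codes are not) and is cross-checked in the tests against
an independent character-level regular-expression oracle.

## Peak calling

The published analyses delegate peak calling to HOMER with settings whose
stated content is: a 0.1% FDR, twofold enrichment over the control track
(free MNase for ChEC, input for ChIP), and twofold enrichment over the
local background. This package implements those stated criteria directly
rather than reproducing HOMER's internals:

1. Slide a window (default 200 bp, step 100 bp) along each chromosome.
2. Score each window by a Poisson upper-tail probability of the IP signal
   given the larger of (a) the depth-scaled control expectation and (b) the
   local background expectation (IP signal in a surrounding 10 kb span,
   excluding the window itself).
3. Benjamini–Hochberg across all windows; keep windows with q ≤ 0.001 and
   both fold enrichments ≥ 2; merge overlapping survivors.

Because the input tracks are normalized onto an arbitrary scale, Poisson
scoring uses a fixed pseudo-depth (`effective_reads`, default 10^6): the IP
track is rescaled to that total before scoring, which makes the calls
exactly invariant to any rescaling of the inputs — a property the tests
check. The twofold filters, not the tail probability, dominate the
operating point, so the pseudo-depth choice has little effect on calls at
realistic enrichment levels. Exact HOMER concordance is a non-goal; the
thresholds are exposed so the caller can be calibrated against real peak
lists if needed.

The peak summit is the mid-range of the peak borders. A summit is assigned
to a promoter when it falls inside the −300..+100 window; if several peaks
land in one window the summit closest to the TSS wins, with exact-distance
ties resolved to the upstream peak, so assignment is deterministic. A
promoter counts as consensus-bound when bound in at least k of n replicates
(presets: 4 of 6 for ChEC, 1 of 2 for ChIP).

Promoter occupancy is the sum of normalized signal in a 200 bp window
centered on the summit. Promoters without an assigned peak fall back to the
strongest-signal position inside the promoter window, found on a 21-bp
running mean of the per-base signal; within a smoothed plateau the raw
maximum is preferred, then the position closest to the TSS, then the
upstream one. Occupancy change is computed per replicate pair as
log2(IAA/DMSO) and then averaged across pairs. If any occupancy is zero, a
pseudocount of half the smallest positive occupancy in the experiment is
applied — scale-aware and infinity-free.

## Elongation analyses

The traveling ratio (TR) is the ratio of polymerase signal in a 100 bp
window at the start of the transcribed region to a 100 bp window at its
end. The source analyses state the window width but not the exact anchors;
this package anchors at `[TSS, TSS+100)` and `[PAS−100, PAS)` in the
transcription direction, exposed as configuration. Genes shorter than
300 bp, lacking TSS/PAS, or with zero 3′ signal are excluded and counted.
TR is invariant to global track scaling, and the log2 TR change is
invariant to independent per-condition scaling, so it is insensitive to
normalization errors — a deliberate strength of the ratio-of-ratios design.

Metagene profiles average per-base normalized coverage across a gene group
at each TSS-relative offset (−200..+1000 bp, strand-resolved; genes ≥ 1 kb)
per condition, then take log2 of the ratio of group means. Log2-of-means
(rather than mean-of-log2s) tolerates per-gene zeros; a per-gene mode with
a scale-aware pseudocount is provided for sensitivity analysis. An offset
whose group mean is zero yields a non-finite value that downstream
summaries must exclude.

Gene dependence quintiles are formed by sorting the transcriptional log2
change ascending and splitting into five groups of equal size (±1), ties
broken by stable order. Orientation is a documented constant: **Q5 holds
the most depletion-dependent (most negative) genes**, Q1 the least.

Phospho-CTD and kinase analyses reuse one statistic:
`log2[(P_IAA/R_IAA) / (P_DMSO/R_DMSO)]`, where P is the gene-body signal of
the mark or factor and R the matched total Rpb1 signal. The same code path
serves Ser2P/Ser5P, Bur1, Ctk1, and Spt5 — there is no separate kinase
implementation.

## Comparative statistics

Welch's unequal-variance t-test (two-sided, Welch–Satterthwaite df),
Spearman rank correlation (average ranks on ties), and the one-sided
hypergeometric over-representation tail for promoter-set overlaps, all
mapped to significance stars at the conventional cutoffs (≤ 0.0001 → ****,
≤ 0.001 → ***, ≤ 0.01 → **, ≤ 0.05 → *, else ns). These standard tests are
delegated to base R (`t.test`, `cor`, `phyper`); the test suite
cross-checks the hypergeometric tail against exact combinatorial
enumeration for universes up to 25 and calibrates the Welch type-I error
empirically. Degenerate inputs have defined behavior: both-constant samples
with equal means give p = 1; a constant vector makes Spearman undefined
(NA with a warning); a forced maximal overlap is flagged as degenerate.
The hypergeometric universe defaults to whatever promoter set the caller
supplies — the annotated, filtered promoter universe is the sensible
choice — because the original Venn analyses do not state it explicitly;
one-sided over-representation was chosen as the only direction those
analyses interpret.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; its defaults are the
conditions the quantified experiments describe, not tuning knobs:

* Two gene classes, TFIID-dependent and coactivator-redundant (CR), at
  fractions 0.73/0.27 — the approximate genome-wide split established for
  these classes in yeast.
* Injected transcriptional responses: median 4.0-fold decrease (TFIID
  class) and 1.3-fold (CR), normally distributed on the log2 scale with
  spreads 0.4 and 0.3.
* Negative-binomial counts with gene dispersion 0.05 and lognormal
  per-replicate depth factors at CV 0.2, consistent with replicate
  variation under 30%. The count dispersion of nascent RNA-seq is not
  stated anywhere authoritative; 0.05 is a typical technical+labeling
  value and is exposed in the configuration. With `replicate_cv = 0` the
  generator returns the exact zero-noise limit (counts equal rounded
  means), which makes degenerate-case tests deterministic.
* Spike totals drawn as Binomial(total reads, spike fraction) with the
  spike expectation tied to cell-equivalents (constant per cell, not per
  experimental read), so spike counts co-vary with sequencing depth but do
  **not** track the transcriptional collapse — exactly the property that
  makes a cell-mix spike-in informative. The expected spike:experimental
  ratio in the control condition is 1:8.
* Promoter peaks as discretized Gaussians (σ = 75 bp, matching the broad
  −1/+1 nucleosome span), 8-fold high over a Poisson background, on 70% of
  promoters, dropping 1.7-fold under depletion.
* Polymerase tracks spanning TSS..PAS with a 5′ accumulation that decays
  exponentially (length scale 130 bp, so the excess is spent by ~400 bp
  downstream of the TSS); depletion scales the body by the gene's true
  fold change and can add extra 5′ accumulation in proportion to the
  gene's dependence rank.
* TATA-positive promoters (10% of the TFIID class, 60% of CR — TATA boxes
  are strongly enriched among CR/SAGA-type promoters) carry a planted
  TATAWAW in the scan window; TATA-negative windows are scrubbed of chance
  matches so the flags are exact ground truth.

The generator emulates the statistical structure the pipeline assumes —
spike-in arithmetic, class structure, replicate noise, peak shape,
elongation profiles — and deliberately omits read-level artifacts:
sequence-composition bias, mappability, fragment-size effects, alignment
errors. Passing recovery tests therefore demonstrates that the
quantification is correct given correctly aligned, counted data; they say
nothing about upstream alignment quality.

Determinism: one seed in the configuration drives every stage
(annotation, counts, and tracks use fixed offsets of it), and identical
configurations reproduce every output byte for byte, including the written
TSV/bedGraph/FASTA/JSON artifacts.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so a
full run completes comfortably on one CPU: 2,000 genes × 3 replicates for
fold-change recovery (recovered class medians must land within ±10% of the
injected 4.0/1.3), 200 planted peaks for caller recovery (≥95% recovered,
≤1 false peak), and 300 genes for occupancy and elongation runs. These
sizes are statements of the package's test design, and the recovery
tolerances are fixed properties of those designs.

Other numerical choices: CV uses the n−1 sample standard deviation (the
source analyses do not specify; documented); class "fold decrease" medians
are computed as `2^(−median log2fc)`, which equals the median of per-gene
linear folds because the median commutes with monotone transforms; the
Poisson tail in the peak caller uses the continuous extension
`P[X ≥ x] = pgamma(λ, x)` so normalized (non-integer) signals need no
rounding.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_genes = 2000, n_replicates = 3, seed = 1)
ann <- simulate_annotation(cfg)
sim <- simulate_counts(cfg, ann)
est <- rnaseq_log2fc(sim$counts, sim$meta)
class_summary(est, setNames(ann$genes$class, ann$genes$gene_id))
```

## Known limitations

* The peak caller implements the stated enrichment criteria, not HOMER's
  internals; bound-promoter counts on real data may differ from published
  peak lists, and the thresholds are exposed for calibration.
* One TSS per gene; no isoforms, UTR models, or multiple TSS clusters.
* The generator's single-chromosome layout has no centromeres, repeats, or
  intergenic structure; peak assignment ambiguity from genuinely
  overlapping promoter windows is rare by construction and resolved
  deterministically rather than modeled.
* Differential-expression inference with shrinkage (DESeq2-style) is out
  of scope: the quantification reports medians, ratios and correlations,
  matching the analyses it implements.
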