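---
title: "Methods: designing and using synthetic rRNA-operon spike-in standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing and using synthetic rRNA-operon spike-in standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemimic)
```

# Overview

`spikemimic` covers the full life cycle of synthetic spike-in standards for
quantitative amplicon sequencing: design of artificial variable-region
sequences under hard screening constraints, assembly of full mimic
constructs around natural primer-binding regions, conversion of spiked ASV
count tables into absolute microbial loads, quality control, and a
simulator that provides ground truth for all of it. This vignette explains
the models and algorithms, the tunable parameters and their defaults, the
numerical choices, and what the simulation-based validation does and does
not demonstrate about real data.

# The design model

## Why these screens

A spike-in variable region must be (i) sequenceable and amplifiable without
artifacts and (ii) unambiguously distinguishable from natural sequences and
from the other panel members. The designer therefore enforces, on every
returned sequence:

| screen | threshold (default) | rationale |
|---|---|---|
| homopolymer run | ≤ 3 bp | synthesis and Illumina error hotspots |
| direct repeat | ≤ 8 bp | polymerase slippage, chimera formation |
| inverted repeat | ≤ 8 bp | hairpins; proxy for secondary structure |
| windowed GC deviation | ≤ 2.5 points | uniform amplification and coverage |
| prohibited primer 8-mers | 0 hits | no spurious internal primer sites |
| composition balance | \|f(A)−f(T)\|, \|f(G)−f(C)\| ≤ 0.05 | no strand skew at a fixed GC target |
| pairwise local alignment | ≤ 16 columns | unambiguous read assignment |

Thermodynamic secondary-structure prediction and novelty screening against
public databases (BLAST) are deliberately out of scope: the inverted-repeat
screen acts as a conservative, parameter-free hairpin proxy, and candidate
panels can be exported as FASTA for external novelty checks.

## Assembly algorithm

Sequences are grown from random seed k-mers (default 20 bp) that carry the
GC target exactly: each k-mer contains `round(target_gc × k)` G/C bases and
no homopolymer longer than 3 bp. Assembly is greedy append-with-rejection:

1. draw a candidate k-mer, append it (truncating at the target length),
2. re-run *all* screens on the extended sequence,
3. accept on pass; otherwise resample (up to 200 candidates per step),
4. if no candidate passes, backtrack by removing the previous extension
   (up to 5 consecutive steps), then restart from scratch,
5. a global `max_attempts` budget (default 200 000 draws) bounds the run;
   exhausting it raises a "design failed" error naming the most frequently
   violated constraint.

Screening the whole growing sequence at each step (rather than the new
k-mer alone) is what keeps junction-spanning violations out: a homopolymer
or repeat formed at the boundary between two k-mers is caught immediately.

Within-sequence similarity is controlled by the repeat screen: a local
self-alignment longer than a few bases requires an exact repeat of
comparable length, and those are capped at 8 bp, far below the 16-column
between-sequence limit. Between sequences, each new panel member is aligned
against all accepted members (both orientations) and regenerated from a
deterministically bumped seed if any alignment exceeds 16 columns or any
shared exact substring exceeds 16 bp. Each panel member draws from its own
fresh k-mer stream; members share nothing but the screening thresholds.

## Numerical and algorithmic choices

- **Local alignment scoring**: match +1, mismatch −3, affine gaps costing
  5 + 2k for a gap of length k (BLAST-like defaults). "Alignment length" is
  the number of aligned columns of the best-scoring alignment; among
  score-optimal alignments the longest is reported, making the screen
  conservative and deterministic. The kernel is a small Rcpp Gotoh DP; for
  self-comparison the main-diagonal match move is forbidden, which removes
  the trivial full-length self-hit. Because alignment length under these
  scores can miss long, poorly scoring exact words in principle, the panel
  screen additionally enforces the parameter-free longest-shared-substring
  bound — the stricter union of both definitions is applied.
- **GC windows**: 100 bp windows at 10 bp steps, the standard scale for
  uniformity scans; the last window is anchored at the 3' end so the tail
  is always covered. While the sequence is shorter than one window, the
  whole-sequence GC is compared to the target instead.
- **Composition balance** at 0.05 is the only balance notion compatible
  with a fixed GC target: A/T and G/C totals are fixed by the target, so
  only the within-pair split is constrained.
- **Repeat scans** find exact maxima by binary search over the repeat
  length; existence of a length-L repeat implies existence at L−1, so the
  predicate is monotone. The assembly hot loop only tests existence at
  threshold + 1, which is equivalent for pass/fail and much faster.
- **Determinism**: every sampling step flows from one recorded seed
  (`rng_seed`); identical configurations yield byte-identical panels.
  Panel regeneration seeds are derived as `seed + 7919 × retry`.
- **Coordinates** are 1-based inclusive throughout (the IRanges/Biostrings
  convention this package is built on); GFF3 output is 1-based inclusive
  per the standard either way.

## Scaffolding

Conserved blocks are anchored at primer sites located with IUPAC-aware
matching (default 0 mismatches — reference primer sites are exact by
construction; degenerate third-party primers can relax this). A primer with
zero or multiple sites is a hard error: silently picking a site would
corrupt the construct. Each block retains the primer footprint plus a
configurable flank (default 20 bp) *toward the amplicon interior*,
preserving annealing context while maximizing artificial content. The
published panels of this kind span roughly 1.3–1.9 kb for a full
V9–ITS1–ITS2–D1D2 layout; `in_silico_pcr` lets users verify amplicon
lengths for their own primer sets before synthesis.

# The quantification model

Let a sample contain environmental rRNA-operon copies $E^*$ and receive $c$
copies of a spike-in mimic. After amplification and sequencing, read counts
$E$ (environmental, summed over all non-mimic ASVs) and $M$ (mimic) are
observed. Under competitive amplification, $E/M \approx E^*/c$, so

$$\mathrm{ALR} = \log_{10}(E/M), \qquad
  \widehat{E^*} = 10^{\mathrm{ALR}} \cdot c,$$

and the normalized load divides by the sample amount (e.g. mg of soil). In
a dilution series with fixed $E^*$ and varying $c$, plotting ALR against
$\log_{10} c$ must give a slope of −1 by design; this is the primary
self-check of a spike-in experiment.

Differential load between samples 1 and 2 is
$\Delta = \mathrm{ALR}_1 - \mathrm{ALR}_2 + \log_{10}(c_1/c_2)$,
antisymmetric by construction. Agreement statistics use the geometric mean
of absolute fold differences,
$\mathrm{gmAFD} = \exp(\tfrac1n \sum_i |\ln(m_i/e_i)|) \ge 1$,
which is base-invariant (internally computed in natural log, reported
identically to a log10 formulation).

Choices worth knowing:

- **Feature→mimic assignment** uses deterministic glocal alignment identity
  (feature global within mimic reference, threshold 0.97) instead of a
  naive-Bayes classifier: panels are designed to be mutually dissimilar, so
  the threshold is uncritical and the rule is auditably exact. A feature
  matching two mimics indicates a broken panel and errors out.
- **Zero mimic counts** are an error with a QC flag by default (mirroring
  sample exclusion); an explicit `pseudocount` argument enables a labeled
  +0.5 path.
- **`min_mimic_reads` defaults to 50**: spike-in experiments in this
  domain exclude samples in the 10–25-read range, and 50 leaves comfortable
  margin; affected samples are flagged, not silently dropped.
- **Spike copies are declared per PCR or per extraction**
  (`amount_basis`); a mismatch is an error, never a silent conversion.
- **Rarefaction** (when a depth is set) happens before load estimation and
  is delegated to `vegan::rrarefy` behind an explicit seed; loads are
  invariant to rarefaction in expectation.

# Quality control

The staggered standard curve regresses log10 of each mimic's percentage
*within the mimic subcomposition* on log10 of its spike copies, by ordinary
least squares on the log-log scale. Using the subcomposition removes the
environmental background from the response, so a slope of 1 with high
R² certifies the whole measurement chain. Mimics with zero counts are
excluded (with a record) and fits with fewer than 3 usable points are
flagged rather than fitted. Per-fit exclusion lists express locus-specific
exceptions (e.g. constructs whose primer-binding sites differ for one
primer set) without hard-coding taxonomy.

The dose-response of mimic reads at fixed depth versus spike level follows
a two-parameter rectangular hyperbola $y = a x/(b + x)$, fit by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), which converges on
exactly-generated zero-residual data where plain Gauss–Newton fails.
Degenerate inputs (constant reads) and non-convergence yield flagged
results, not errors. Fits on raw or subsampled counts are both supported.

QC flags (`low_spike_reads` below 50 mimic reads, `spike_saturation` above
95% mimic fraction, slope/R² bands) are pure functions of their inputs.

# The simulator

`simulate_counts` draws, per sample, multinomial reads at fixed depth with
probabilities proportional to copy number × per-feature efficiency bias.
Defaults encode a realistic desk-scale experiment: 50 environmental taxa
with lognormal copy numbers (meanlog = log 2000, sdlog = 1, i.e. a pool of
~1.6 × 10^5 copies, commensurate with the 10^3–10^6 spike range of the
dilution design), depth 2 × 10^5 reads, and per-feature bias lognormal with
sdlog 0.5 — a several-fold spread, drawn once and held constant across
samples. That constancy is deliberate: it encodes the empirical observation
that spike-in detection bias is consistent across samples and therefore
cancels in differential analyses, which is the central mechanism the
framework relies on. Scenario wrappers emulate the standard experimental
designs: a dilution series against a fixed pool (expected ALR slope −1), a
staggered mix (expected standard-curve slope 1) and a BF-ratio series with
a cross-domain construct spiked at fixed copies.

What the simulator does *not* emulate: PCR-cycle-explicit amplification,
chimeras, sequencing errors and denoising artifacts, primer-binding-site
mismatches, amplicon-length bias, or taxon-specific bias that varies
*between* samples. Passing the simulation-based tests therefore
demonstrates that the estimators are correct and unbiased given
multinomial sampling with consistent efficiency bias — it does not certify
accuracy on real sequencing runs, where the wet-lab factors above dominate.
Real-data validation requires mock communities and defined spike-in
series.

# Validation problem sizes

The test suite verifies every screen against independent brute-force
oracles (position loops, shift scans, regex scans, a pure-R alignment DP,
and Biostrings as a library cross-check) on 200 random sequences up to
500 bp; designer invariants on a 9-member default panel (GC 40/50/60% ×
300/450/600 bp); and estimator recovery on simulated experiments at depths
10^3–10^6 with 4-level dilution series, 8-mimic staggered pools and
7-sample BF series spanning ratios 0.025–40. These sizes were chosen to
make sampling noise small relative to the acceptance bands while keeping
the full suite fast enough to run routinely.

# Known limitations

- The designer's assembly is stochastic search; extreme configurations
  (very tight GC windows, very low/high GC with strict balance) can be
  infeasible and fail explicitly after the attempt budget.
- Assignment by alignment identity assumes the panel was designed with
  this package's dissimilarity screens (or equivalent); for arbitrary
  reference panels the 0.97 threshold may need review.
- Amplicon-length detection bias is observable in QC output (staggered
  curves) but no adjustment factor is estimated or applied.
- BF ratios from a single cross-domain construct inherit its fixed 1:1
  fungal:bacterial calibration; samples with extremely unbalanced domains
  may leave one domain's mimic reads below the QC threshold.
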