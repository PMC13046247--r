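---
title: "Spike-in calibrated ChIP-seq of meiotic protein binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated ChIP-seq of meiotic protein binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiocal)
```

## The experiment this package models

During budding-yeast meiosis, crossover-pathway proteins are recruited to
programmed DNA double-strand-break (DSB) hotspots, to the Red1/Hop1-marked
chromosome axis, and to centromeres. Mapping where such a protein sits —
and whether it favors strong or weak hotspots, axis sites, or regions of
high heterozygosity — requires ChIP-seq that is *calibrated*: cells of a
related species (*S. mikatae*) are mixed with the experimental culture at
a fixed 1:10 cell ratio before immunoprecipitation, so cross-species read
ratios normalize IP efficiency between samples. An isogenic untagged
strain provides the nonspecific background.

`meiocal` implements the full downstream computation: scaling-factor
calibration, binned coverage tracks, untagged subtraction, replicate
averaging, kernel smoothing, local-Poisson peak calling, Venn-style
classification of peaks against feature maps, and the comparative
statistics (rank-sum contrasts of hotspot strength, chromosome-size
binding density, SNP-density and crossover co-occupancy analyses, qPCR
normalization). Because the computation starts *after* read alignment,
the package consumes mapped-read records carrying a mapping-status label
(`target_unique`, `spike_unique`, `ambiguous`, `unmapped`) rather than
raw sequences; a synthetic generator produces such records with the
statistical structure of the real experiment, so every stage is testable
at desk scale.

## The calibration model

For each sample, with $N_t$ uniquely mapped target-genome reads and $N_s$
uniquely mapped spike-in reads:

$$\mathrm{SF1} = \frac{N_t}{N_s}, \qquad
  \mathrm{SF2} = \frac{\mathrm{SF1}}{c_u},$$

where $c_u$ is the untagged sample's coverage, interpreted here as its
genome-wide mean raw reads per 10-bp bin (the published description does
not define "coverage"; mean per-bin depth makes SF2 dimensionally a
per-bin normalizer, and since $c_u$ is one shared constant it cancels in
every within-study comparison). The genome is partitioned into 10-bp
bins; the calibrated track is

$$\text{cal}[b] = \tilde{x}_\text{chip}[b]\,\mathrm{SF2}_\text{chip}
                 - \tilde{x}_\text{unt}[b]\,\mathrm{SF2}_\text{unt},$$

with the untagged sample scaled by its own SF2. Negative values are
retained — clamping would bias genome-wide means — and peak calling does
not consume calibrated tracks at all (see below).

**Depth invariance.** Applying SF2 to raw bin counts would make the
result scale with sequencing depth (both the counts and SF1 grow with
depth). `calibrate()` therefore first places each track on a
reads-per-million-target-reads scale (the `normalized` track state)
before applying SF2. Algebraically this makes the calibrated chip term
proportional to $x[b]/N_s$ — counts per spike-in read, the canonical
spike-in (ChIP-Rx) normalization — so tracks from libraries sequenced to
different depths are directly comparable, while the SF1/SF2 arithmetic
itself is untouched. A `scale = "none"` option reproduces the literal
counts-times-SF2 arithmetic for depth-matched libraries.

Replicate averaging operates on calibrated tracks, and smoothing is
applied after averaging, matching the stated processing order of the
experiment.

## Smoothing

Tracks are smoothed with a Nadaraya–Watson estimator at each bin center
using a Gaussian kernel whose quartiles sit at $\pm 0.25\,h$ for
bandwidth $h$ (i.e. $\sigma = 0.25\,h/\Phi^{-1}(0.75) \approx 0.3707\,h$,
the convention of R's classic `ksmooth` interface, so results are
comparable to tracks produced with that smoother), default $h$ = 1 kb.
Kernel weights are renormalized over the available bins at chromosome
ends, so constant tracks are exact fixed points.

Numerically, the estimator is computed by FFT convolution with the
kernel truncated at 8 standard deviations; the truncation error is below
$10^{-13}$ relative, and the unit tests verify agreement with a direct
full-kernel summation oracle to $10^{-9}$. The interface named above
truncates its kernel much earlier (deviations around $4\times10^{-5}$),
which is why the estimator is computed in-package; a cross-check against
it at tolerance $10^{-3}$ is part of the test suite. The final bin of a
chromosome may be shorter than 10 bp; its true center is used, with the
affected kernel-range tail recomputed by direct summation.

## Peak calling

Peaks are called from the *raw pooled counts* of the two ChIP replicates
with the untagged sample as control — the Poisson model needs counts,
not calibrated depths. For each bin, the local background is

$$\lambda_\text{local}[b] = r \cdot \max\left(
  \bar{c}_{1\text{kb}}[b], \bar{c}_{5\text{kb}}[b],
  \bar{c}_{10\text{kb}}[b], \bar{c}_\text{genome}\right),$$

where $\bar{c}_w[b]$ is the control's mean count in a $w$-wide window
centered on $b$ and $r$ scales the control to the ChIP depth. The bin
p-value is the Poisson upper tail $P(X \ge x[b] \mid
\lambda_\text{local}[b])$; bins with $p \le 10^{-5}$ (the published
retention rule) within 100 bp of each other are merged, peaks narrower
than 50 bp are dropped, the summit is the highest-count bin, and
q-values come from Benjamini–Hochberg correction over all bins. This is
a deliberate self-contained re-implementation of the algorithmic core of
model-based peak callers; since the original study's caller options are
not recorded, no attempt is made to reproduce its exact published peak
counts — the caller's operating characteristics (false-positive rate at
most twice nominal on null data, >95% recovery of 10×/500-bp planted
peaks with covering spans) are verified instead.

Without a control track, a uniform background equal to the ChIP track's
genome-wide mean is used.

## Classification and comparative statistics

*Venn classification.* A peak receives every feature class it overlaps
by ≥ 1 bp (hotspot → `Spo11`, axis → `Red1`, centromere →
`Centromere`), or `Nil`; the category counts partition the peak set
exactly. Overlap machinery uses `GenomicRanges`; the tests verify it
against a brute-force all-pairs oracle on random interval sets.

*Rank-sum testing.* All distributional contrasts route through one
Wilcoxon rank-sum implementation. The exact two-sided p-value is
computed from the full Mann–Whitney $U$ null distribution (dynamic
programming over rank subsets) when $n_a + n_b \le 12$ with no ties;
otherwise a normal approximation with tie and continuity corrections is
used. The tests enumerate every tie-free configuration up to $n = 10$
against an independent oracle and verify 5%-level type-I calibration.

*Hotspot binding classes.* A hotspot is bound by a protein iff it
overlaps that protein's peak set by ≥ 1 bp; hotspots split into
`both` / `A_only` / `B_only` / `neither`, and strengths of the two
specific classes are compared by rank sum. One peak spanning two
hotspots marks both. When a specific class is empty the comparison is
reported as undefined rather than forced.

*Chromosome-size density.* Per-chromosome binding density is reads per
million mapped per kb of usable sequence, with exclusion intervals
(e.g. the chromosome XII rDNA array at published coordinates
451418–489465, converted to 0-based half-open on ingestion) removed
from both the read counts and the lengths. The size–density association
uses Pearson's correlation with the usual t-transform p-value.

*SNP density.* Peak SNP densities (markers per kb within each peak) are
compared to 1-kb non-overlapping genome tiles (full tiles only,
exclusion-overlapping tiles dropped; the per-kb unit motivates the 1-kb
tiling, which the source description leaves unstated). The display
scalings used in genome-browser-style figures (SNP counts per 100-bp bin
×2; crossover counts ÷ tetrad count × 200) are writer-side options of
`write_bedgraph()` only and never enter statistics.

*Crossover co-occupancy.* A crossover site is its midpoint ± half of
`site_window` (default 2 kb — tetrad crossover resolution is not stated,
so this is exposed as a parameter), classified by ≥ 1-bp overlap with
each protein's peaks into `both` / `A_only` / `B_only` / `neither`,
fractions summing to 1.

*qPCR.* Fold enrichment consumes standard-curve quantities (not raw
Ct): IP/input ratios, normalized to the coldspot locus and then to the
untagged control, so the coldspot is exactly 1.

## The synthetic generator

`simulate_experiment()` draws fragment midpoints from a mixture of a
uniform background over the genome and one enrichment component per
feature, with per-feature rate multiplier

$$M_f = E_{\text{class}(f)} \cdot
        (s_f/s_0)^{\alpha} \cdot (d_f/d_0)^{\beta}$$

for hotspots, where $s_f$ is the hotspot strength (default sampler
log-normal, meanlog 5, sdlog 1.2, capturing the heavy tail of
Spo11-oligo counts), $d_f$ the local SNP density, and $s_0, d_0$
geometric means. Normalizing by $s_0$ and $d_0$ keeps the overall
enrichment mass comparable when the coupling exponents $\alpha, \beta$
change sign — the couplings redistribute signal across hotspots rather
than rescaling the experiment. The true coupling between occupancy and
hotspot strength is unknown for this protein family, so both exponents
are free parameters with default 0. Multipliers below 1 are clamped to
1: depletion below the nonspecific background is not modelled.

Fragment lengths are normal (mean 350 bp, sd 25) truncated to
[100, 1000] bp, emulating sonication to ~300–400 bp; the read 5′
position is the fragment end chosen by a fair-coin strand. Mapping
ambiguity is a label applied at rate `ambiguous_rate` (default 0.05);
ambiguous reads keep positions but are excluded from unique-read
counting, as in the real unique-extraction procedure.

**Spike-in physics.** `spike_fraction` (default 1/11, the 1:10 cell
mixture with equal nonspecific recovery) is the expected spike read
share of an *enrichment-free* sample. Spike chromatin mass is fixed
relative to the target *background* mass, so a tagged sample — whose
specific enrichment adds target material — realizes a lower spike share.
This is precisely what lets SF1 report occupancy rather than depth, and
it is why the simulator defines the fraction this way rather than as a
fixed per-sample read share. The `occupancy_scale` argument multiplies
the specific (above-background) mass, emulating genuine biological
occupancy differences that the calibration must recover.

Each sample carries a ground-truth sidecar (expected and observed
per-feature midpoint counts, expected spike share) used by the
parameter-recovery tests. Expectations are stated for fragment
*midpoints* because the planted rates govern midpoints; 5′ positions are
deterministic transforms of them, smeared by about half a fragment
length past feature edges.

Crossovers are drawn per tetrad at a genome-wide rate of 7.5 per Mb per
tetrad (the budding-yeast average of ~90 crossovers over ~12 Mb), landing
in hotspots with probability proportional to
$s^{\text{weighting}}$ plus a 10% uniform component.

## Numerical and design choices

- **Coordinates** are 0-based half-open everywhere internally
  (BED-native); readers accept `one_based = TRUE` for published 1-based
  inclusive coordinates and shift starts by −1.
- **Seeds**: every generator takes a seed and restores the caller's RNG
  state; the pipeline derives per-stage seeds from one global seed by a
  stable 31-bit hash of the stage name, so stage outputs are
  individually reproducible.
- **Determinism**: rerunning `run_pipeline()` with the same
  configuration and seed is byte-identical, including provenance
  headers (package version, configuration hash, seed; the output
  directory is excluded from the hash so relocation does not change
  identity).
- **Degenerate inputs**: zero spike reads, zero untagged coverage,
  empty peak/crossover sets, constant correlation input, chromosomes
  without centromere records, zero-width peaks and out-of-bounds
  records all raise immediate, specific errors rather than propagating.
- **Tie-breaks**: peak summits take the leftmost maximal bin; Venn
  labels use the fixed order Spo11, Red1, Centromere.

## Problem sizes in the test suite

The shipped tests exercise the pipeline at desk scale, chosen to give
the statistical checks comfortable resolution: calibration recovery on a
2-Mb genome at 2–6 × 10⁵ reads per sample; peak-caller null
characteristics over twenty 10-Mb genomes at ~1 read per bin and power
on one hundred 500-bp 10× regions at ~3 reads per bin (above the ≥2
reads/bin regime the operating-characteristic guarantees assume, giving
edge bins detection margin under the strict reading that a recovered
span must fully contain its planted region); the directional
strength-coupling contrast over 100 seeded runs of 200 hotspots at
2 × 10⁵ reads per sample; SNP neutrality/depletion over 100 seeded SNP
maps at 4 markers per kb. `scripts/acceptance.R` recomputes the same
quantities at somewhat smaller replicate counts and records each
problem size alongside each value.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis
assumes: mixture enrichment at planted features, fixed-ratio spike-in
mass, fragment-scale smearing, Poisson-level count noise, tunable
couplings. It does not model sequence content, mappability structure,
GC or accessibility biases, duplicate reads, or aligner artifacts —
mapping ambiguity is an exchangeable label, not a genomic property. The
acceptance properties therefore certify that the implementation
faithfully computes the published procedure and recovers planted truths
under its assumptions; they cannot certify published point estimates
(peak counts, Venn percentages, specific medians), which derive from
sequencing data for which no accession is available and which are
additionally sensitive to unrecorded caller options.
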