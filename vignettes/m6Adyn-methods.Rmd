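---
title: "Methods: models, parameters and design choices in m6Adyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in m6Adyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

N6-methyladenosine (m6A) is the most prevalent internal mRNA modification.
In m6A-IP-seq (MeRIP-seq), methylated RNA fragments are immunoprecipitated
with an anti-m6A antibody and sequenced; methylation shows up as coverage
peaks in the IP library relative to a non-IP input library. m6Adyn analyses
how the m6A landscape changes between two conditions — a copper-induced
oxidative stress and an untreated control in the motivating system,
*Arabidopsis* seedlings — and how those changes relate to transcript
abundance and polysome occupancy. Because antibody enrichment has
~100–200 nt resolution, the unit of analysis is the peak region, not the
single nucleotide.

The pipeline starts from windowed coverage tracks and count matrices, not
reads: alignment, trimming and QC are upstream concerns that carry no
statistical content for the questions addressed here.

# The peak caller

## Model

For each strand of each chromosome, coverage is summarised in fixed
25-nt windows. Within a condition the three input replicates are pooled
into one background library. For window $i$ the expected IP count is

$$\lambda_i = \mathrm{smooth}_3(\text{input}_i) \cdot
  \frac{N_\mathrm{IP}}{N_\mathrm{input}},$$

where $\mathrm{smooth}_3$ is a centred running mean over 3 windows and the
ratio scales the pooled input to IP sequencing depth. Where the local
estimate is zero, a genome-wide floor (mean input rate scaled to IP depth,
`lambda_floor()`) is substituted so that stray IP reads over empty input
can never reach $p = 0$. The window p-value is the upper Poisson tail
$P(X \ge k_\mathrm{IP} \mid \lambda_i)$. Windows with $p < 0.05$ are merged
into peaks when separated by at most one non-significant window; runs with
fewer than two significant windows are dropped. Each peak reports the
summit (midpoint of its max-count window), an enrichment score
($\sum k_\mathrm{IP} / \sum \lambda$ over the run) and its minimum window
p-value. No multiple-testing correction is applied at this stage — the
p < 0.05 filter is deliberate, and the confidence filter is replicate
consensus (below).

## Why the background is pooled and smoothed

A per-window plug-in $\hat\lambda$ from a single input library is far too
noisy to be calibrated: numerically, with IP and input both Poisson at 30
reads/window, the fraction of windows passing $p < 0.05$ is ~0.12 (no
floor) or ~0.03 (flooring every window at the global mean), both far from
the nominal 0.05. Pooling the three input replicates and smoothing over
three windows brings the effective number of draws behind $\hat\lambda$ to
nine and the measured null rate to ~0.052 at depth 30 (~0.051 at depth
20), which is within three binomial standard deviations of 0.05 at
$10^4$ windows. The floor is applied only where the local estimate is
zero, because flooring everywhere at the global mean makes the caller
conservative in every below-average-coverage region.

## Calibration limits

Two caveats are measured and documented rather than hidden:

* **Coverage boundaries.** At transcript edges and where coverage levels
  step (e.g. CDS→UTR), the smoothed $\hat\lambda$ borrows from
  lower-coverage neighbours and the test becomes anticonservative
  (~0.15 locally, ~18% of covered windows in the default synthetic
  transcriptome; overall rate ~0.07). These false windows do not
  replicate at the same locus across three independent IP libraries, so
  replicate consensus absorbs them: at study-default conditions the
  consensus false-peak rate is 0%.
* **Overdispersion.** The Poisson test is exactly calibrated only for
  Poisson counts. The generator's default negative-binomial dispersion
  (0.02) inflates the per-window false rate to ~0.10; again the consensus
  step is the control. Calibration itself is therefore verified on a
  uniform Poisson null track, the sampling model of the statistic.

# Consensus and classification

A *high-confidence* peak must be supported by every replicate of its
condition. Pairwise-overlapping 1D intervals always share a common base
(Helly's theorem), so the consensus seeds are exactly the runs of bases
covered by all three replicates. Each seed takes the union of its member
peaks as the consensus interval; members join at most one consensus (seeds
processed left to right). The overlap rule everywhere is >= 1 nt on the
same strand — peaks are called strand-split and strand is honoured in all
downstream comparisons. A stricter minimum-overlap fraction is exposed as
a parameter for sensitivity analysis but is not the default, since the
underlying study states none.

Stress-side consensus peaks overlapping any control-side consensus peak
are `shared` (reported once, stress-side coordinates, to avoid double
counting); the remainder are `stress-enriched` or `control-enriched`. A
transcript inherits labels from all peaks overlapping its exons with
precedence stress > control > shared; the precedence rule is a declared
choice for the (rare) transcripts hosting peaks of multiple categories.
Swapping condition labels swaps the condition-specific sets exactly; the
shared *count* is side-dependent by construction because several stress
peaks may overlap one control peak.

# Metagene and positional profiles

**Binned density.** Each coding transcript with nonzero 5'UTR, CDS and
3'UTR is mapped window-by-window into per-nucleotide density, normalised
by the transcript's total density, split into 20 bins per region with
fractional-nt edge weighting, and averaged across transcripts. A fixed
bin *count* (rather than width) is the default because variable-length
UTRs cannot share a fixed-width axis; width-derived bin counts are
available via `bin_mode = "width"`. The profile is exactly flat under
uniform coverage and invariant to transcript order and global count
scaling.

**Positional frequency.** For each category and each position $p$ within
±100 nt of the start or stop codon (transcript coordinates, position 0 =
first codon nucleotide),

$$\mathrm{raw}(p) = \frac{\#\{\text{unique peaks of the category
overlapping } p\}}{\#\{\text{methylated transcripts in the category}\}},$$

then each category's profile is normalised to its maximum over the
window. The denominator population is the category's own methylated
coding transcripts (`frequency_denominator = "category"`); the
alternative reading — all methylated transcripts — is available via
`denominator = "all"`. Empty categories yield flagged all-zero profiles,
never a division by zero.

**Feature breakdown.** Each peak votes once by the feature at its summit
(5'UTR, the 3-nt start codon, CDS, the 3-nt stop codon, 3'UTR of the host
transcript whose exons contain the summit). Full-overlap multi-voting is
available via `rule = "overlap"`. Percentages sum to 100 within each
category.

# Quantification

* **Size factors** are median-of-ratios over features positive in all
  samples, rescaled to geometric mean 1 (cross-checked in the test suite
  against the DESeq2 estimator).
* **Fold change** is `log2((mean normalised copper + 1) / (mean
  normalised control + 1))`; the pseudocount of 1 keeps logs finite and
  is config-exposed. The per-transcript test is deliberately a simplified
  stand-in — Welch t on log2 normalised counts with Benjamini–Hochberg
  adjustment, significance at padj < 0.05 — because the category-level
  conclusions rest on the rank-sum comparisons, which are implemented
  exactly. BH is the default adjustment (Bonferroni available), matching
  the default behaviour of the negative-binomial package the full-scale
  analysis would use.
* **Polysome occupancy** is `log2(RPM_polysome / RPM_RNA)` per condition
  with RPM averaged over replicates within assay × condition, and the
  occupancy change is the exact difference copper − control. Transcripts
  with RPM < 1 in any of the four cells are excluded (floor
  config-exposed).
* **Category comparisons** are pairwise two-sided Wilcoxon rank-sum tests
  (Welch t available, and used for the non-coding groups per the
  underlying study's methods), with medians and group sizes reported.
* **Threshold counts** declare a ">50% increase/decrease" as a normalised
  ratio > 1.5 / < 0.5.

A property worth knowing: global RPM normalisation is compositional. If a
large minority of transcripts is shifted, library totals move and *every*
occupancy change is offset (−0.18 log2 with 25% of transcripts shifted;
−0.05 with ~6% shifted). Median-of-ratios is robust to a shifted
minority, which is why abundance fold changes do not show the effect. The
effect-recovery checks therefore embed the ~500 transcripts per category
in a realistic total (8000 transcripts, ~6% shifted), mirroring the scale
of the real experiment (thousands of changed peaks among tens of
thousands).

# Motif enrichment

Peak sequences are extracted by mapping each peak's genomic interval onto
its host transcript and slicing the transcript sequence, so minus-strand
peaks are reverse-complemented and junction-spanning peaks are spliced
automatically. Enrichment is a site-level binomial test per k-mer
(k = 4–6): the foreground occurrence count over foreground positions
against the rate estimated from 100 dinucleotide-preserving
(Altschul–Erickson) shuffles of the same sequences, with a 0.5 pseudocount
on background counts, BH adjustment, and deterministic ranking (p-value,
then enrichment fold, then lexicographic). This is a declared simplified
stand-in for de novo motif discovery: it answers the same enrichment
question without position-weight-matrix optimisation. Dinucleotide
shuffling preserves mono- and di-nucleotide composition exactly (verified
per sequence in the tests), which is the composition-matched background
the enrichment question needs.

# The synthetic data generator

The generator emulates the study design: 3 IP + 3 input replicates × 2
conditions as windowed counts, 3 × 2 RNA-seq and 2 × 2 polysome-seq count
matrices, with full ground truth (planted peaks with classes, motif
positions, per-transcript effect sizes). Key defaults and why:

| Parameter | Default | Rationale |
|---|---|---|
| transcripts | 2000 | enough peaks (~1200) for stable rates at desk scale |
| 5'UTR / CDS / 3'UTR means | 150 / 1200 / 300 nt | Arabidopsis-like transcript anatomy |
| non-coding fraction | 10% (lncRNA half of it) | lncRNA is the largest polyadenylated ncRNA class |
| peak length | uniform 150–200 nt | the antibody-fragment peak regime |
| class shares | 13 / 15 / 72% of methylated | mirrors the ~2.6k / 3.1k / 14.7k split of condition-specific and shared peaks |
| shared-class position bias | (0.02, 0.03, 0.15, 0.10, 0.70) over 5'UTR/start/CDS/stop/3'UTR | canonical stop-codon/3'UTR concentration of plant m6A |
| changed-class position bias | (0.20, 0.20, 0.25, 0.10, 0.25) | stress-responsive peaks shift toward 5'UTR/start |
| input region weights | 0.8 / 1.3 / 0.8 | mild CDS enrichment of background polyA+ RNA-seq |
| IP enrichment | 8× | detectable but not degenerate at depth 30 |
| depth | 30 reads/window | typical MeRIP windowed coverage |
| dispersion | 0.02 (NB inverse size) | mild replicate overdispersion; 0 gives the Poisson limit |
| motif | DNA `TGTA` (RNA UGUA), 0.8/peak | the plant m6A motif planted on the sense strand |
| effect sizes | ±0.5 log2 abundance, +0.5 log2 occupancy, −0.5 for stress-methylated lncRNA | free parameters chosen for detectability; the study reports directions, not magnitudes |

Placement semantics: peaks of the pure-region classes lie fully inside
their region when it is long enough (centre-and-clip when it is not);
codon-proximal classes centre within ±50 nt of the codon and straddle the
boundary. The ±50 nt window keeps planted signal inside the ±100 nt
plotted range. One peak is planted per methylated transcript so that
category ground truth is unambiguous; multi-peak transcripts are handled
(and tested) in the assignment code, they are just not part of the
default truth. A planted peak's nucleotides always lie in exons; its
genomic span may bridge an intron.

What the generator does *not* emulate — and hence what green tests do not
show about real data: read-level effects (fragment-length bias, PCR
duplicates, mappability), isoform mixtures, overlapping genes,
non-uniform base composition (sequences are i.i.d. with the motif planted
explicitly), antibody off-target binding, and batch effects between
replicates beyond NB dispersion. Transcripts are also non-overlapping by
construction so that truth scoring is exact.

Determinism: every stage derives its RNG stream from `cfg$seed` (fixed
offsets per stage), so `simulate` and `run_all` outputs are byte-identical
across runs with the same config.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF/GFF3 converts at the
  file boundary. NarrowPeak column 8 stores −log10 p at 4 decimal places
  (capped at 400), so p-values round-trip to ~1e-4 relative precision;
  all other fields round-trip exactly.
* Poisson tails are computed with `ppois(k − 1, λ, lower.tail = FALSE)`
  and agree with direct pmf summation to 1e−12 for λ ≤ 50, k ≤ 200.
* Malformed annotation records (start > end) are rejected individually
  with a warning; a transcript without exons is an error. Empty peak
  lists, empty categories and all-zero tracks are defined no-ops or
  flagged outputs, never crashes.
* Multi-isoform genes are represented by the longest transcript
  (`collapse_to_longest()`, ties by id) — a declared deterministic rule;
  the generator emits one isoform per gene.
* k-mer ties are broken by enrichment fold then lexicographically, so
  motif rankings are reproducible.

# Problem sizes used in the checks

The automated checks run the generator at 2000 transcripts (peak
recovery, metagene, motif and end-to-end determinism; consensus oracles
use 100 randomised small instances), 8000 transcripts for effect-size
recovery, and $10^4$-window uniform tracks for caller calibration. These
sizes give stable rates (binomial standard errors well inside the
asserted margins) while keeping a full run of the suite within a few
minutes on one CPU. On the 25-nt grid a fully covered 150–200 nt peak
spans six to nine windows, so called peak lengths snap to 150–225 nt;
the "predominantly 150–200 nt" check reads median length in [150, 225]
and at least 80% of lengths in [125, 250].

# Known limitations

* The caller is windowed: boundaries are resolved to 25 nt and summits to
  window midpoints. MACS2-specific machinery (fragment-shift model,
  duplicate filtering, tiered local λ, q-values) is intentionally out of
  scope; exact concordance with MACS2 output is not a goal.
* The per-transcript DE test is a simplified stand-in (see above); its
  p-values are calibrated under the null in the tests but do not model NB
  dispersion shrinkage.
* Polysome occupancy inherits the compositional property of RPM
  normalisation discussed above.
* The motif stage scores exact k-mers, not degenerate position-weight
  matrices; a motif family with high internal variability would be
  under-ranked relative to dedicated de novo discovery.
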