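---
title: "Measuring ter-region enrichment in vesicle DNA: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ter-region enrichment in vesicle DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terenrich)
```

## The problem

DNA recovered from the lumen of bacterial outer membrane vesicles is, in
several species, strongly enriched for the chromosomal region around the
terminus of replication (*ter*), with the coverage maximum at the *dif*
site where the XerC/XerD recombinases act. `terenrich` turns mapped reads
into three quantities: a per-nucleotide coverage profile, an integer
enrichment statistic for the *ter* window against a random-window null,
and a TMM-normalized per-window log2 fold-change between strains.

## Coordinate model

All internal coordinates are 1-based and inclusive, so published *ter*
bounds can be used verbatim in `replicon_spec()`; conversion to 0-based
half-open happens only when reading or writing BED and bedGraph.
Circular replicons are first-class: intervals and reads may wrap through
the origin (`end < start`), window means wrap, and rotating all
coordinates by a constant offset provably changes nothing (a tested
invariant). Because neither SAM nor BED can express a wrap, the writers
emit wrapping reads with their end running past the reference length and
`read_alignments()` folds them back; round trips are exact.

Reads are represented by their mapped reference interval only. Mate
pairing is ignored (each mate counts as one read, matching how published
totals are reported) and strand is recorded but unused, since no step of
the analysis is strand-specific.

## The enrichment statistic

A read is assigned to a region by its start coordinate. This makes
region counts a partition: counts over any disjoint cover of the
replicon sum to the total read count exactly, so "inside *ter*" and
"outside *ter*" are unambiguous and the statistic is insensitive to read
length. (Assignment by overlap would double-count boundary reads; for
windows of thousands of bases versus 50 bp reads the numerical
difference is negligible either way.)

The null treats the chromosome minus *ter* as one contiguous arc, splits
it into 10 equal segments (remainder bases go to the last segment), and
draws 20 uniform window starts per segment such that each window fits
inside its segment — 200 windows, all wholly outside *ter*, possibly
overlapping within a segment (20 multi-kilobase windows often cannot be
disjoint in a segment). The enrichment is the ratio of the *ter* count
to the null median, rounded to the nearest integer with halves away from
zero; when the median is zero the *ter* count itself is reported. Both
conventions are pinned down by the shipped published count table
(`published_ter_counts()`), which the rounding reproduces row for row —
including ratios at .56 and .84 and the two median-zero rows.

The default null-window width equals the *ter* interval length
(6,001–7,001 bp for the shipped replicons — printed *ter* bounds are
inclusive, hence the +1). Source descriptions of the procedure vary
between ~6 kb and 8 kb windows; the width is therefore always an explicit
parameter, with the *ter*-length default and 8,000 bp as the common
alternative. Stratifying 20 draws within each of 10 segments rather than
200 free draws keeps the null spatially balanced; medians over the even
sample count use the standard midpoint convention. All sampling is
seeded (`withr::with_seed`, leaving the session RNG untouched), making
every result a pure function of its inputs.

## Coverage

Per-base depth adds one unit for every mapped base
(`IRanges::coverage` underneath), so total depth equals total mapped
bases exactly — an integer conservation law the tests assert.
Sliding-window means are computed by cumulative sums (arithmetically
identical to a rolling mean), wrap on circular replicons, and truncate
to the actual overlap at linear ends. Analysis-scale summaries use 8 kb
windows, display-scale profiles 0.5 kb; step defaults to 1.

## Differential comparison

`build_count_matrix()` tiles a region flanking *ter* (for the E. coli
chromosome the 1.3–1.9 Mb span, inside which windowed counts are
approximately normal) into non-overlapping 500 bp windows by default —
tiling rather than sliding, because overlapping windows would correlate
the observations normalization relies on. TMM factors follow the
published procedure exactly: reference = sample whose upper-quartile/
library-size ratio is closest to the mean; M and A per window over
doubly-positive windows; 30% two-sided trim on M, 5% on A; factor =
2^(inverse-variance weighted mean of retained M) with binomial
delta-method weights; rescaled to geometric mean 1. The in-package
implementation is cross-checked against edgeR's independent one in the
test suite to 1e-6. A caveat the tests document: the precision weights
are not scale-free, so multiplying one sample's counts by a constant
reproduces the factors only approximately (~1e-4 relative at typical
counts, identical in edgeR); the exact invariant is that a
composition-identical scaled sample gets identical normalized counts.

Log2 fold-changes divide counts by effective library size (library ×
factor), rescale to the mean effective library so values stay in read
units, and compare group means with a 0.5-read pseudocount on that
scale; identical groups give exactly 0 and swapping groups flips the
sign exactly. Dispersion estimation and significance testing are
deliberately out of scope — only the descriptive fold-change profile is
produced.

## The simulator: a stated world

`simulate_reads()` draws read starts i.i.d. from a four-component
mixture: uniform background, a *dif*-centred peak (rectangular,
triangular or Laplace kernel; width, centre and asymmetry tunable), a
linear ori-to-ter gradient (mimicking replication skew in DNA released
from exponentially growing or lysed cells), and a uniform phage-hotspot
interval. For a rectangular peak inside *ter* the pre-rounding
enrichment has the closed form `1 + pi_ter * G / ((1 - pi_ter) * w)`,
inverted by `enrichment_target_params()` to calibrate presets; other
mixtures are integrated numerically from the per-base density
(`expected_enrichment()`), which Monte-Carlo simulation matches within
2%.

Defaults are fixed once and not tuned: 50 bp reads (typical short-read
runs), 200,000 reads per sample (desk-scale yet within the depth range
of the published samples), a 1 Mb circular replicon with *dif* at
500,000 and a 6,001 bp *ter* window (`sim_replicon()`; real replicon
specs drop in unchanged). Preset choices: `wt_ecoli` targets
pre-rounding enrichment 14 (the first published wild-type replicate);
`xer_mutant` widens the peak 3.5-fold with asymmetry 0.3 and weight
0.0582, chosen so the shoulder outside *ter* sits ~4-fold above
background and the central maximum drops ~3-fold — the qualitative
knockout signature (asymmetrically broadened peak, reduced *dif*
maximum); `pmarinus` is a broad 100 kb Laplace peak; `paeruginosa_lysis`
is gradient-dominated (weight 0.75); `vcholerae_phage` combines a
9-fold *ter* peak with a 15 kb hotspot carrying 15% of reads. The
Laplace scale is width/8 (~98% of mass within the nominal width); the
asymmetry parameter moves the stated fraction of peak mass to the right
flank.

What the simulator does *not* model: sequencing error, base quality,
mappability, alignment ambiguity, GC bias, paired-end fragment geometry,
or DNase-digestion efficiency. A green simulation test therefore
establishes the correctness of the statistics pipeline, not the
biological interpretation of any real dataset.

## Numerical conventions and degenerate inputs

Rounding is half-away-from-zero (`floor(x + 0.5)` for non-negative x),
the only convention consistent with every published row. Null standard
deviations use the n−1 denominator. Empty mapping sets give all-zero
tracks; an all-unmapped alignment file gives an empty set, not an error.
Infeasible null sampling (segment shorter than the window) and wrapping
intervals on linear replicons raise typed conditions. Windows with zero
counts in either sample are excluded from TMM (as in the original
method); a count matrix with no doubly-positive windows raises a
degenerate-normalization error rather than returning factors.

## Known limitations

Full reproduction of published per-sample enrichment values from raw
archived reads requires multi-gigabyte downloads and alignment and is
outside the package's desk-scale test surface; the arithmetic is instead
verified exhaustively against the published count summaries, and the
statistical machinery against simulations with known ground truth.
Multi-mapping reads are counted as whatever primary alignments the input
file contains, mirroring common practice upstream.
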