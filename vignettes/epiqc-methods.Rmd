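---
title: "Quality-control metrics for ChIP-seq and DNase-seq: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-control metrics for ChIP-seq and DNase-seq: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epiqc` computes quality metrics for ChIP-seq and DNase-seq experiments in
three layers — read, ChIP and annotation — plus a historical atlas for
percentile context. This vignette documents the models behind the metrics,
the parameters that matter, the design choices made where conventions were
genuinely open, what the synthetic generator does and does not emulate, and
the known limitations.

## Coordinates and the interval engine

All intervals are 0-based half-open (`[start, end)`, BED-style); SAM's
1-based positions are converted on ingest. Overlap means at least one
shared base, so touching half-open intervals (`[0,10)` vs `[10,20)`) do
*not* overlap — but they *do* merge, because the union-DHS construction
needs maximal covered blocks. Interval operations are executed through
GenomicRanges/IRanges internally; the test suite checks them against
brute-force all-pairs and per-base bitmap oracles.

The 5′ position of a minus-strand read is the 3′ reference end of its
alignment, computed from the reference-consuming CIGAR operations
(M, D, N, =, X). This matches the duplicate-location semantics of
alignment-based deduplication: two reads are "the same location" when
they share (chromosome, stranded 5′ position, strand). Including strand in
the location key follows common practice for complexity metrics; a
strand-blind variant would merge sense/antisense stacks and report
slightly lower NRF.

## Read layer

**Median base quality.** The median is taken over all base calls of up to
`quality_sample_n` (default 100 000) reads, drawn uniformly without
replacement. Even-sized multisets use the lower median (the element at
index `floor((k-1)/2)` of the sorted values) so the result is always an
attained Phred score. Per-base and per-sequence medians differ in
principle; the per-base median is reported because it is the more
conservative summary for downstream base-resolution analyses.

**Uniquely mapped.** MAPQ strictly greater than 1 (`mapq_gt = 1`,
configurable). A MAPQ of 255 means "unavailable" in the SAM specification
and is treated as passing any threshold rather than failing it.

**Fixed-depth complexity.** NRF (distinct locations / uniquely mapped
reads) and PBC (single-read locations / distinct locations) both fall as
depth grows — deeper sequencing revisits the same positions — so both are
computed on a fixed subsample of `subsample_depth` = 4 000 000 uniquely
mapped reads. Shallower libraries are evaluated with all reads and the
record carries `below_subsample_depth = TRUE`; such values are biased high
relative to 4 M-depth values and should be compared with care. The
subsampler is index sampling without replacement (`sample.int` under a
locally-seeded RNG that is restored afterwards): deterministic for a fixed
seed, no reliance on hash ordering, and stable across platforms.

**Contamination screen.** The screen subsamples `contam_sample` = 100 000
reads once and applies every species mapper to the same subsample, so the
per-species fractions are comparable. Mappers are injected functions
(sequences → logical); `make_exact_mapper()` provides the exact-substring
mapper used with synthetic fixtures, and users with aligners available can
inject a wrapper instead. Bundling a real aligner is out of scope.

## ChIP layer

**FRiP.** The fraction of non-mitochondrial uniquely mapped reads whose 5′
base lies inside a peak, at the same fixed 4 M subsample. Two conventions
matter:

* membership is tested with the read's 5′ position only (not the whole
  span), consistent with the location-based read-layer metrics;
* the peak set should be called from *all* reads. Under that convention
  the subsampled FRiP is approximately depth-stable, which is what makes
  it comparable across libraries; peaks re-called from the subsample
  would make FRiP fall with depth.

Mitochondrial chromosomes default to `chrM`, `MT`, `chrMT`. An empty peak
set yields FRiP 0 with a warning; a library with only mitochondrial reads
is an error rather than a silent 0/0.

**Peak census.** Fold-enrichment cutoffs are applied inclusively
(≥ 10, ≥ 20); the boundary convention is configurable via
`fc_thresholds` because published usage mixes strict and inclusive
phrasing and the difference only matters for peaks sitting exactly on the
cutoff.

**Replicate consistency.** Signal correlation is Pearson's r over the
concatenated bins (default `corr_bin` = 1000 bp) of all shared
chromosomes after scaling each track to reads per million — the metric is
therefore invariant to sequencing-depth differences and to positive
rescaling. A flat (zero-variance) track gives NaN with a warning; NaN is
reported, not dropped, because a flat track is itself a quality signal.
The peak-overlap ratio counts peaks of the *larger* set overlapping the
smaller and divides by the larger peak number: numerator and denominator
then refer to the same set, the ratio is guaranteed to lie in [0, 1], and
the unordered pair is well defined (equal sizes fall back to the first
argument). Counting the smaller set's overlaps against the larger
denominator would be an alternative reading; it can only lower the ratio
and is not used here.

## Annotation layer

**Summits.** narrowPeak summits are `start + summit_offset`; peaks
without a summit (broadPeak, BED) use the interval midpoint
`floor((start+end)/2)` so every peak has a summit for the summit-based
metrics.

**Meta-regions.** Each summit receives exactly one label with precedence
promoter > exon > intron > intergenic. The promoter is TSS ±
`promoter_flank` (default 2000 bp, matching the conservation flank);
"intron" is inside a transcript body but neither exon nor promoter. The
distribution uses *all* summits rather than the top-5000 subset: the
meta-region profile is a property of the whole peak set, while the
DHS/blacklist ratios deliberately use the top peaks to characterise the
confident calls.

**Conservation profile.** Mean per-base conservation in windows of ±
`conservation_flank` (2000 bp) around summits, binned at
`conservation_bin` (50 bp). Bases missing from the track read as 0 and
are tallied with a warning; summits within a flank of a chromosome edge
are zero-padded and counted in `n_truncated`. Per-base expansion is
restricted to the summit windows so memory stays bounded by
`n_summits × 2·flank`.

**Regulatory potential.** For gene *g*,
`RP(g) = Σ w(d)` over peak summits with summit-to-TSS distance
`d ≤ max_dist` (default 100 kb), with default weight
`w(d) = exp(−(0.5 + 4·d/max_dist))` — a smooth exponential decay giving
`e^{−0.5} ≈ 0.607` for a peak directly at the TSS and `e^{−4.5} ≈ 0.011`
at the cutoff. The exact decay used by published regulatory-potential
rankings is defined only by citation in most descriptions, so this
default is an informed reconstruction and the weight is pluggable
(`"exp2"` for `2^{−d/d₀}`, `"uniform"`, or any non-increasing function).
Genes with several transcripts score each transcript's TSS and keep the
maximum, so a gene is ranked by its best-supported promoter.

## Atlas and flags

Percentiles are mid-rank: `100·(#{x < v} + 0.5·#{x = v})/N`. Mid-rank is
symmetric (the percentile of a value in its own single-row table is 50)
and stable under ties, which matters because metrics like peak counts are
heavily tied. Input-control samples are stored with `is_input_control`
and excluded from ChIP-enrichment pools (FRiP, peak counts) by default,
since input and ChIP distributions differ systematically.

Flag thresholds default to quality > 25, uniquely mapped ratio > 0.5,
PBC > 0.8, FRiP ≥ 1 % and replicate consistency > 0.6; all strict except
FRiP, where the 1 % reference is inclusive. FRiP is not applicable to
input controls (low enrichment there is expected). A missing metric is
`not_applicable`, never silently good or bad. Assay categories are a free
label set defaulting to eight literature-based classes (transcription
factor, narrow/broad histone mark, chromatin regulator, chromatin
accessibility, RNA polymerase, CTCF/insulator, other) and are
configurable.

## The synthetic generator

`simulate_library()` draws per-location read counts from a zero-truncated
Poisson with rate λ, which has closed forms for both complexity metrics:

* expected PBC = `λ·e^{−λ}/(1−e^{−λ})`,
* expected NRF ≈ `(1−e^{−λ})/λ` (the reciprocal of the mean truncated
  count).

Exact numbers of in-peak and mitochondrial reads are placed
(`round(q·n)`), so FRiP truth is exact, and the truth record is bookkept
during generation — it never calls the metric implementations it is used
to test. Defaults emulate a reasonable transcription-factor ChIP library:
70 % uniquely mapped, λ = 0.5 (analytic PBC ≈ 0.771, deliberately near
the 0.8 flag boundary), 5 % of reads in 200 peaks of 500 bp, 1 %
mitochondrial, on a 3 Mb + chrM toy genome. `simulate_replicates()`
shares a fraction ρ of read positions between replicates (expected binned
correlation increases monotonically with ρ, equalling 1 at ρ = 1) and an
exact fraction of peaks (disjoint grid placement makes the expected
overlap ratio exactly the shared fraction).
`simulate_annotation_and_tracks()` builds a toy transcriptome, a
triangular-bump conservation track with closed-form window means, and
DHS/blacklist sets containing exact fractions of the top peaks.

What the generator does *not* emulate: base-composition and GC bias,
mappability structure, fragment-length effects, chromatin-state-dependent
duplication, and broad-mark signal shapes. Tests passing on these
fixtures therefore validate the *metric computations* — definitions,
conventions, determinism, analytic limits — not the biological
interpretability of any particular threshold on real data.

## Numerical and reproducibility choices

* All sampling uses an explicit seed; internal seeding saves and restores
  the caller's RNG state, so library calls never perturb a session's
  random stream.
* The metrics JSON rounds floats to 1e−6 and keeps a stable key order, so
  reruns are byte-identical and diffs are meaningful.
* Ties in `top_peaks()` break by (chrom, start) so the top-N selection is
  deterministic.
* Degenerate inputs fail loudly: empty libraries, empty summit sets,
  all-mitochondrial read sets and unknown atlas pools raise errors;
  empty peak sets (FRiP 0) and flat tracks (NaN correlation) warn.
* When a dataset has replicates, the flattened sample record reports the
  first replicate's read/ChIP/annotation scalars (the per-pair
  consistency metrics cover all pairs; their mean fills the atlas row's
  consistency columns). Per-replicate records can be produced by running
  each replicate as its own sample.
* Test and acceptance problem sizes: most unit fixtures use 10³–10⁵
  reads; the analytic PBC check uses ~10⁵ locations (binomial 3σ ≈
  0.004), and the FRiP depth-stability check uses an 8 M-read library
  subsampled to 4 M (4σ ≈ 4·10⁻⁴). These sizes make the sampling-noise
  tolerances tight enough to catch convention errors (e.g. an off-by-one
  in the half-open boundary shifts FRiP by whole read-counts).

## Known limitations

* No BAM/BigWig binary parsing: alignments are consumed as SAM text and
  signal as bedGraph. Convert with samtools/UCSC tools upstream.
* Peak calling, fragment-size estimation and motif enrichment are
  upstream/downstream tools' jobs; `epiqc` consumes their outputs.
* Paired-end mates are treated as independent reads; fragment-level
  deduplication would require mate pairing.
* The regulatory-potential weight is a reconstruction (see above); rank
  orderings are robust to monotone reweighting but absolute scores are
  weight-specific.
* The shipped atlas machinery is the container and query logic; a useful
  reference distribution still requires compiling one's own collection of
  processed samples.
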