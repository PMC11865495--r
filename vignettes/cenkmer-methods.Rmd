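---
title: "Reference-free k-mer enrichment analysis of centromeric chromatin profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free k-mer enrichment analysis of centromeric chromatin profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenkmer)
```

## The problem

Centromeres and pericentromeres are built from satellite repeats —
alpha-satellite higher-order repeat (HOR) arrays carrying the CENP-B box,
monomeric alpha satellite, human satellites (Hsat1, Hsat2, ...) and
transition (ct) regions mixing unique and repetitive sequence. Short reads
from chromatin profiling assays such as CUT&RUN cannot be uniquely aligned
inside these arrays, so conventional peak calling is blind exactly where
centromere biology happens. `cenkmer` implements the reference-free
alternative: compare the *k-mer composition* of a target antibody's
library against a nonspecific IgG control, call individual k-mers
enriched, and only then place those k-mers back onto an assembly to ask
*which satellite class* they came from.

## The k-mer enrichment model

For each replicate, every 51 bp window of every read contributes one count
to its **canonical** k-mer (the lexicographic minimum of the k-mer and its
reverse complement, so counting is strand-neutral); windows containing `N`
are skipped, and k-mers seen fewer than `min_count = 2` times are dropped,
mirroring a `kmc -k51 -ci2` run. Counts are then normalised:

* **Missing floor.** When replicates are joined over the union of their
  k-mers, a k-mer absent from a replicate is assigned a raw count of 1
  *before* normalisation. Absence only means the true count was 0 or 1, so
  the floor deliberately underestimates enrichment while keeping every
  fold change defined. Because the floor is applied on raw counts, the
  floored *rate* differs between replicates with different sequencing
  depths — each normalised table therefore carries its own floor value,
  which later unions (salt pooling, control averaging, the final join)
  re-use.
* **Depth normalisation.** Counts are divided by the replicate's total
  base count over its full read set (both mates), giving a rate per
  sequenced base.
* **Salt pooling.** Low- and high-salt fractions of one replicate are
  normalised separately (each by its own base count) and summed.

The control is the arithmetic mean of the normalised IgG replicates over
the union of their k-mers. The enrichment call is then per replicate: a
k-mer is *eligible* in a replicate iff its normalised count exceeds
`norm_threshold = 5e-9` (the filter acts per replicate — a replicate below
the threshold cannot support a call, which is our reading of applying the
filter "for each replicate individually"; the stricter alternative of
requiring all replicates to pass is not implemented because it would
silently discard k-mers robust in a subset of replicates), its fold change
is its value over the averaged control, and the k-mer is **enriched** when
at least `min_enriched_replicates = 2` replicates are both eligible and
above `fc_threshold = 2`.

At desk scale the 5e-9 threshold is easily cleared (it corresponds to ~5
copies in a billion sequenced bases); its role in the tests is structural
— the third worked example of `call_enrichment()` shows a replicate below
threshold failing to support a call regardless of its fold change.

## Mapping enriched k-mers back

`map_exact()` reports every exact occurrence of each k-mer on both strands
(emulating an exact `-k 5000` alignment), truncating at 5000 sites per
k-mer with truncated k-mers flagged; coincident +/− hits of
reverse-complement palindromes collapse to one + hit. Attribution then
collapses each censat-style annotation name at its first underscore
(`ct_1_1(p_arm)` → `ct`) and pivots hits into a k-mer × class matrix; a
hit straddling a boundary counts once per overlapped interval (the
bedtools-intersect convention). `region_percentages()` reports, per class,
the percentage of enriched k-mers with at least one hit in that class —
k-mers hitting several classes count toward each, so columns may sum above
100%; a `majority` attribution and a mapped-only denominator are available
by flag since the original figure convention is not stated.

## The synthetic world

Real centromeric datasets are terabytes; every stage here is instead
exercised on simulators whose ground truth is known exactly.

**Toy genome.** A single chromosome laid out as unique arms, ct segments
(unique sequence with recorded promoter-like windows), an Hsat1-like
AT-rich block, monomeric alpha satellite, a HOR array, a short divergent
HOR and an Hsat2-like 5-mer tandem block (~59.5 kb by default; segment
plan, monomer length 171 bp and the 17 bp degenerate CENP-B-box-like
motif `NTTCGNNNNANNCGGGN` are configurable, with degenerate positions
resolved per genome under the seed). The HOR array is built as tandem
copies of a **higher-order unit** of `hor_unit = 6` distinct monomers,
each carrying the motif once. This is a deliberate design choice: a
single-monomer array contains only ~171 distinct 51-mers, the same order
of magnitude as the genuinely enriched "spillover" k-mers created where
fragments that start inside the weighted array extend past its edge, so
class attribution on such an array would be dominated by a boundary
artefact rather than signal. Multi-monomer units are also what makes real
alpha-satellite arrays higher-order repeats in the first place. Setting
`hor_unit = 1` restores the single-monomer construction.

**Reads.** Paired-end fragments with truncated-normal lengths (mean 180
bp, s.d. 30 bp — typical mononucleosomal CUT&RUN), 2 × 75 bp mates (long
enough to host 51-mer windows), fragment *start* positions drawn with
per-base weight 1 outside the enrichment intervals and `w` inside, and a
default sequencing error rate of 0 so exact-match k-mer tests are
noise-free. With one enriched interval of genome fraction `f` and weight
`w`, the expected fraction of fragment starts inside it is
`f·w / (1 − f + f·w)` — the closed form the simulator is tested against at
n = 50,000.

What the generator does **not** emulate: PCR duplicates, adapter
contamination, GC or mappability bias, spike-in chromatin, chromatin
three-dimensional structure, or the extreme array lengths of real
centromeres. A green planted-recovery test therefore establishes the
*statistical machinery* (counting, flooring, normalisation, calling,
mapping, attribution), not robustness to library artefacts — those are
assumed removed upstream, as the pipeline starts from cleaned reads.

**Default planted experiment.** Three target replicates with `w = 10`
over the HOR array versus three uniform IgG replicates, 50,000 pairs
each. With the array at fraction ~0.29 of the genome, the expected in-array
fold change is `10 / (1 − f + 10f)` ≈ 2.8 — comfortably above the 2×
threshold — while arm k-mers sit near 0.28, far below it; the acceptance
suite verifies ≥ 90% sensitivity on array-unique k-mers, < 1% false calls
on arm-unique k-mers and ≥ 90% `hor` attribution.

## Interval statistics

* **Consensus.** `consensus_intervals()` returns maximal intervals over
  bases covered by ≥ 2 replicate sets (each set reduced first), the
  interval algebra behind multiinter-then-merge consensus peaks. Verified
  against a per-base coverage sweep on random instances.
* **Venn counts.** Many-to-many overlaps are collapsed to connected
  components of the bipartite overlap graph (one "shared" event per
  component), avoiding double counting; the raw per-set overlap counts are
  also emitted because plotting tools differ in convention.
* **Categorisation.** Primary-factor peaks split by overlap with the
  knockout set; knockout-specific peaks must by default avoid *both*
  parental sets (they should "appear only when the primary factor is
  lost"); a flag relaxes this to the second factor's parental set only.
* **Relative distance.** For each query location strictly between two
  flanking reference locations, `reldist = min(d1, d2)/(d1 + d2)` — a
  statistic uniform on [0, 0.5] under independence. Locations are interval
  midpoints (`use = "start"` switches to start coordinates, since the
  original computation's choice for k-mer hits is unstated); queries
  outside the outermost reference locations are skipped rather than
  wrapped; a query coincident with a reference location scores 0. The
  cumulative fraction is reported on a 0.01 grid up to 0.5.
* **Signal matrices.** Fragment-depth coverage averaged in bins across
  interval centre ± 5 kb, rows ordered by descending row sum of a
  designated ordering matrix (so heatmaps of several tracks can share the
  ordering of the left-most one). Bases beyond chromosome ends count as
  zero coverage.
* **Feature distribution.** Each peak is assigned the single
  highest-priority feature overlapping its centre (promoter > exon >
  intron > downstream, then intergenic); the toy feature builder uses a
  ±3000 bp promoter window by default.

## Radial ring quantification

The imaging pipeline mirrors ring-based quantification of a chromatin
mark around centromere foci: segment nuclei from the DNA channel (global
Otsu threshold, hole filling, 4-connected labeling, minimum-area filter —
or pass through provided label masks), detect foci as local maxima above
background + k·s.d. (median/MAD estimates; candidates are nucleus pixels,
so foci cannot fall outside nuclei), then expand rings to `max_radius = 4`
µm in `n_rings = 8` steps of 0.5 µm around each focus centre. Every
in-nucleus pixel is assigned to its *nearest* focus (ties to the lower
focus id) — this resolves collisions between the 4 µm disks of
neighbouring foci, which the original pipeline leaves unstated — and
joins ring `⌈d/0.5 µm⌉` (centre pixel in ring 1). The per-ring statistic
defaults to the mean over assigned pixels clipped to the nucleus mask
(mean is stable across foci whose outer rings are clipped differently);
integrated intensity is a flag. Empty rings are reported as missing, not
zero. Analysis is 2-D, intended for maximum-intensity projections.

Shape metrics use the mask's second central moment matrix: eccentricity
`sqrt(1 − λ2/λ1)` is 0 for a disk and `sqrt(3)/2 ≈ 0.866` for a 2:1
ellipse. Mutual-nearest-neighbour pairing gives centre-to-centre distances
for paired foci (e.g. sister-kinetochore signals). Per-nucleus intensities
are normalised to the median of a designated reference cohort.

Numerical conventions worth knowing: images are matrices indexed
[row = y, col = x] with pixel centres at integer coordinates; all
distances are computed between pixel centres, which is why ring-boundary
pixels (a pixel exactly 1.0 µm from an on-grid centre) can disagree with a
continuous ground truth — the tests use off-grid focus centres where
exactness is asserted, and a 2% tolerance where boundaries can coincide.
Rasterized disk areas deviate from `πr²` by O(1/r), so the 2%
area-recovery tolerance applies to radii ≳ 15 px.

## Protein-panel statistics

Abundances (positive, sum-normalised upstream) are expressed per knockout
clone as log2 ratios to the *mean* of the parental samples (the exact
parental aggregation being unstated, the arithmetic mean is used);
proteins quantified in under half the samples are excluded and remaining
missing values propagate without imputation. Each clone column is centered
by subtracting its median — idempotent, and the natural null for panels
that are small relative to the proteome. Per-protein significance is the
two-sided one-sample t-test of the centered values against zero computed
from its formula (`t = mean/(sd/√n)`, df = n − 1); "unpaired one-sample"
in the original description is read as the standard one-sample test. The
panel summary is the median centered log2FC over the panel's proteins per
clone; the planted-shift recovery test aggregates replicate clones by
their median, because a single clone's panel median carries both sampling
noise (~0.015 s.d. for a 100-protein panel) and a small centering bias
(the panel itself drags the column median when it is 10% of the
proteome), and the study's own summaries likewise aggregate replicate
clones.

## Known limitations

* Exact counting and exact mapping only: no mismatch tolerance, no
  quality model, no probabilistic sketches. This is intentional (the
  contract is exactness) but limits inputs to cleaned reads.
* The k-mer counter materialises all windows of a replicate in memory;
  fine for simulated replicates (millions of windows), not for real
  lanes.
* Single-chromosome toy genomes; the interval and mapping code is
  multi-chromosome-aware, the simulator is not.
* Segmentation is threshold-based and will merge touching nuclei; the
  simulators only generate disjoint ones.
* Image file interchange is plain-text PGM; no TIFF/PNG reader is
  assumed.
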