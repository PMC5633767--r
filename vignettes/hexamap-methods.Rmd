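---
title: "Detecting and mapping homoeologous exchanges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and mapping homoeologous exchanges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hexamap detects homoeologous exchanges (HE), segmental deletions and
duplications in an allopolyploid genome — the A/C subgenome situation of
*Brassica napus* is the motivating case — and links them to quantitative
trait variation in doubled-haploid (DH) populations. An HE replaces a
chromosome segment by its counterpart from the other subgenome, so its
molecular signature is a *linked pair*: a deletion on one homoeologue and a
duplication of the corresponding segment on the other. The package works
from two independent evidence streams, read-depth coverage of the parents
and SNP-array segregation in the DH progeny, and calls an event "validated"
only when both agree.

This vignette explains the models behind each stage, the parameters that
matter, what the bundled simulator does and does not emulate, and the design
choices made where more than one convention was defensible.

## Read-depth segmentation

Per-chromosome depth tracks are reduced to the median depth of 1000-bp bins
(`bin_median()`); bins with no aligned data become gap bins, which are
excluded from all statistics and break the track into independently
segmented runs. Binned tracks are partitioned into constant-mean segments by
circular binary segmentation (`segment_track()`): within each current
segment, the circular arc `(i, j]` maximising the two-sample |t| statistic
against its complement is split off if a permutation test supports it. Two
implementation facts are worth knowing:

* For a fixed arc width the |t| statistic is monotone in
  `u = D^2 w (n - w) / n` (`D` = difference of means), and `u` can be
  compared against a fixed threshold without computing `t`; since the total
  sum of squares is permutation-invariant, each permutation scan reduces to
  "does any arc reach the observed `u`", which allows the scan to abort
  early. The permutation loop additionally stops as soon as the exceedance
  count makes `p <= alpha` statistically implausible, and overwhelming
  observed statistics (Bonferroni bound far below `alpha`) are accepted
  without permutations. Defaults: `alpha = 0.01`, 1000 permutations,
  minimum segment width 2 bins.
* Runs longer than 6000 bins are first segmented on averaged coarse bins
  (targeting ~2000) and every breakpoint is then re-estimated at full
  resolution in a local window. This multiscale pass keeps the search
  quadratic cost bounded while preserving single-bin boundary precision;
  tracks at or below the threshold are always processed at full resolution.

Segments are post-processed by the 50-kb rules
(`merge_filter_segments()`): adjacent segments whose means agree within 10%
of the chromosome mean merge unless separated by a gap larger than 50 kb,
and segments shorter than 50 kb are dissolved into the nearest compatible
neighbour or dropped. Mean "equality" needs a tolerance for real data; 10%
relative to the chromosome mean is the package default and configurable.
After merging, each boundary between touching segments is re-estimated by
maximum likelihood with side-specific variances (`refine_boundaries()`):
read-count variance grows with copy number, and a plain least-squares cut
systematically misassigns edge bins of the higher-coverage side.

Classification (`classify_segments()`) follows the 1-SD convention: a
segment is a segmental duplication if its mean exceeds the chromosome mean
by more than `k = 1` population standard deviation, a deletion if it falls
more than `k` SDs below, and normal otherwise. The SD estimator is the
population SD (divisor `n`) over non-gap bins, stated here so that
classification is deterministic. The chromosome-mean normalisation is known
to be biased when a large fraction of the chromosome is rearranged; we keep
it for fidelity to the standard protocol and expose `k` for sensitivity
analyses. Segmentation runs per chromosome, matching the per-chromosome
statistics.

## Marker scoring in DH populations

Infinium-style calls (AA/BB/AB/NC) for two parents and the DH lines are
classified per marker (`classify_markers()`):

* **simple** — parents opposite homozygotes, lines AA/BB;
* **het** — one parent heterozygous-appearing (hemi-SNP: the probe also
  samples a duplicated locus carrying the alternative allele), the other
  homozygous; lines segregate AB vs that homozygous call, and AB is scored
  as the hemi-SNP parent's allele;
* **PA** — one parent gives no call because the probe site is deleted;
  lines split called/NC near 1:1 and NC is scored as the null-allele
  parent (dominant presence-absence recoding);
* **monomorphic** / **rejected** otherwise, with a reason code.

Class assignment is structural: PA status requires the NC fraction to fall
in a wide presence-absence band (0.2-0.8 by default) rather than to pass a
significance test, because a test calibrated to level alpha would
misclassify that fraction of genuinely 1:1 markers by construction. The
chi-square 1:1 test `chi2 = (c1 - c2)^2 / (c1 + c2)` is computed for every
marker and reported at `alpha = 0.05` (`pass_1to1`). Up to 10% sporadic NC
is treated as technical missingness, and up to 5% of lines may carry calls
outside the expected pattern (they are set to missing) before a marker is
rejected; both thresholds are configurable. Isolated PA/het markers are
kept and tiered down later rather than discarded.

In a DH population every line is homozygous, so the dominant PA recoding
carries exactly the same information as a codominant marker; PA and het
markers therefore enter recombination-fraction estimation on equal terms
with simple markers, and their scored vectors equal the carrier indicator of
the underlying rearranged haplotype.

Physical anchors are accepted when the marker's flanking-sequence hit has
at least 50 bp overlap, at least 95% identity, no gaps, and is unique
(`filter_anchors()`); only uniquely anchored markers enter the map.

## Linkage-map construction

Markers are first collapsed into cosegregation bins (identical scored
vectors; missing values must match too, because wildcard matching is not
transitive — `bin_cosegregating()`). Pairwise recombination fractions are
the discordance rate over jointly scored lines, truncated at 0.5, with
pairs below 20 informative lines flagged uninformative. Linkage groups are
the connected components at recombination fraction below 0.2
(`group_markers()`), so grouping is
monotone in the cut-off by construction.

Admission to the map uses a *distortion* threshold of `p >= 0.001` on the
1:1 test rather than the reporting level 0.05. The reason is statistical,
not cosmetic: along a 164-line chromosome the parental-origin count is a
slowly mixing random walk, and pure sampling drift regularly pushes
contiguous multi-cM regions beyond a marginal 5% test. Excluding those
markers would carve gaps wider than the rf-0.2 cut-off distance
(~25.5 cM) and fragment linkage groups of perfectly normal chromosomes;
excluding only strongly distorted markers is the usual practice in map
construction and keeps the control group count equal to the chromosome
count.

Within a group, ordering minimises the sum of adjacent recombination
fractions (a travelling-salesman path). Groups of up to 8 bins are solved
exhaustively; larger groups are seeded by the first principal coordinate of
classical MDS on Haldane-transformed distances plus greedy
nearest-neighbour starts, then refined by alternating 2-opt (reversals) and
Or-opt (segment relocations) to convergence. The MDS seed provides global
coherence; Or-opt repairs single misplaced bins that 2-opt cannot move.
JoinMap's maximum-likelihood ordering is deliberately not re-implemented;
the seriation objective plus the exhaustive small-group oracle is the
package's documented substitute.

Before computing map distances, apparent tight double crossovers are
masked (`clean_singletons`): a non-missing bin score differing from both
agreeing flanks of the same line would require two crossovers within one
bin interval, which at the simulated marker density is overwhelmingly a
genotyping error; retaining such calls inflates Haldane map length by
roughly 1 cM per error. Distances are Haldane,
`d = -50 ln(1 - 2r)` cM, consistent with the interference-free Poisson
crossover model (Kosambi is not offered because the simulator has no
interference). Groups are named by the majority anchor chromosome of their
markers (ties: smallest anchor position; multiple groups per chromosome get
`_1`, `_2`, ...) and oriented so cM increases with physical position.

## Calling rearrangements

`find_blocks()` scans each group in map order for maximal runs of
same-class markers: PA-runs (deletion evidence), het-runs (in-place
duplication evidence) and translocated-runs — markers anchored on a
different chromosome than their linkage group, the signature of a
duplicated fragment mapping to its homoeologous position. Runs of three or
more markers are validation-grade; shorter runs are retained at the
`single-marker` tier because isolated PA/het markers can still mark real
events.

`pair_homoeologues()` clusters loss-side evidence (PA-runs, deletion
segments) and gain-side evidence (het/translocated runs, duplication
segments) by physical overlap, projects each loss cluster through the
homoeology table (piecewise-linear within blocks, so inversions are
encodable by reversed block coordinates), and calls an HE when the
projected image overlaps a gain cluster with interval Jaccard >= 0.25.
The Jaccard threshold is an explicit stand-in for the visual
"corresponding segment" judgement of coverage-plot figures; no quantitative
rule exists in the protocol this package systematises. Unpaired losses
become deletions, unpaired gains duplications. Physical extents prefer
coverage-segment boundaries (bin precision) over marker footprints (marker
spacing precision). Evidence that contradicts itself — loss and gain
overlapping on the same chromosome — is flagged `conflict` and surfaced,
never silently resolved.

`reconcile_evidence()` assigns tiers: **validated** requires at least one
marker block *and* one coverage segment; **putative** is a single evidence
kind with a run of >= 3 or a segment of >= 50 kb; anything weaker is
**single-marker**. The caller has no random state.

## QTL scanning

`scan_qtl()` performs Haley-Knott regression of the (unit-variance
standardized) phenotype on the expected parental dosage at a 1-cM grid,
`LOD = (n/2) log10(RSS_0 / RSS_1)`. Dosage is imputed from the nearest
informative flanking markers under Haldane probabilities
(`expected_genotype()`); at an informative marker it is exactly 0 or 1,
and lines with no informative flank get 0.5 with a flag. Composite interval
mapping is approximated by forward-selected marker cofactors (at most 5,
entry p < 0.001) excluded within +/-10 cM of the test position. QTL are
reported above LOD 5 (`report_qtl()`), with 1-LOD support intervals
expanded to the nearest flanking map markers (the usual convention; on a
1-cM grid the raw interval of a strong QTL can be artificially narrow),
peaks closer than 10 cM merged (a plateau carved by cofactor switching is
one QTL), and each QTL annotated with the rearrangement event whose cM span
overlaps its support interval — the colocalization call. A permutation
null (`scan_permutations()`) is available for genome-wide thresholds.

## The synthetic-data generator

The simulator exists so that every stage is testable end to end with known
truth. Its defaults describe a desk-scale caricature of a natural x
synthetic *B. napus* cross: 2 homoeologous pairs of 20 Mb with
whole-chromosome co-linear homoeology, 164 DH lines, Poisson(2) crossovers
per chromosome with uniform positions and no interference, 50-kb marker
spacing, 2% missing calls, 0.5% miscalls, and all rearrangements carried by
parent P2 (the synthetic donor). Coverage is negative binomial per 1000-bp
bin with mean `200 x copy number / 2` and size 50; 200 reads per bin
corresponds to ~20x depth with 100-bp reads, and size 50 gives a ~16%
coefficient of variation, a realistic WGS bin-coverage noise level.
Parents carry events hemizygously (copy number 1 or 3), DH lines
homozygously (0 or 4) — DH biology makes every line fully homozygous.

Three modelling choices deserve emphasis. First, calls inside event
intervals follow the event's carrier status, never a within-event
crossover: hemizygous rearranged regions cannot pair and recombine, which
also makes the lost and gained sides of an HE cosegregate perfectly.
Second, hemi-SNP markers are emitted as AB in carriers and as the other
parent's homozygous call elsewhere, i.e. the resident locus is taken
monomorphic and the duplicated copy contributes the alternative allele;
raw Infinium intensity semantics (theta/R clusters) are not modelled.
Third, the NC code doubles as deletion signal and technical failure, as on
a real array; the truth table disambiguates for tests only.

What passing tests therefore do *not* show about real data: robustness to
intensity-cluster miscalling of hemi-SNPs, GC and mappability bias in
coverage, paralogous mis-anchoring, segregation distortion with a
biological cause, or interference. The generator also does not simulate
reads (no FASTQ) or aneuploidy beyond whole-chromosome loss/gain flags.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and in BED-family output.
* Noiseless flat segments have an undefined t statistic and are never
  split; a degenerate chromosome SD of 0 warns and classifies by strict
  inequality.
* Adjacent recombination fractions >= 0.5 make Haldane distance infinite;
  the group is rejected with advice to split.
* Cosegregation-bin ties (r = 0) leave ordering among tied bins arbitrary
  but deterministic.
* All stochastic stages take explicit seeds and restore the caller's RNG
  state; reruns are bit-identical.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate the pipeline at the
simulator's default scale: 50 noiseless tracks of up to 100 bins against an
exhaustive-search changepoint oracle; 50 seeded 5-Mb replicates for
100-300 kb deletion/duplication recovery at 20x; one clean and 25 noisy
toy crosses for marker-class recovery; 10,000 null markers for chi-square
calibration; 3 control crosses plus one suppressed-recombination cross for
map properties; and 20 end-to-end crosses (3 HEs + 2 deletions, additive
QTL with `a = 2`, `sigma = 1`, expected R^2 ~ 0.5) for HE calling and QTL
colocalization, with a 200-permutation null for the LOD-5 false-positive
rate. These sizes were chosen as the smallest at which the binomial success
criteria are meaningful.

## Known limitations

Reciprocal-translocation phasing and whole-chromosome replacement calling
are out of scope (a chromosome-wide deletion pattern is visible in the
segment output but not specially flagged). The chromosome-mean
normalisation biases classification when rearrangement is extensive; the
median/MAD mode (`robust = TRUE` in `chrom_stats()`/`segment_coverage()`)
mitigates this but is off by default for protocol fidelity. LOD/R^2 values from the regression approximation are not
expected to equal those of likelihood-based composite interval mapping
software on the same data, and no attempt is made to reproduce JoinMap
orders.
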