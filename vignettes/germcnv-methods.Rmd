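---
title: "Methods: classifying germline CNVs versus somatic CNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying germline CNVs versus somatic CNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germcnv)
```

# The model and its assumptions

`germcnv` treats the classification of a short copy-number segment as a
supervised problem. The unit of analysis is the *candidate CNV*: a
segment of constant copy number, produced by any external segmentation
algorithm, that (a) is called a gain or loss, (b) spans at most 2.3 Mb,
and (c) has a normal segment on at least one side. The length cap
reflects the empirical size range of germline variants — variants beyond
a few megabases exist but are rare and atypical — and the flank condition
reproduces the situation in which the CNV/CNA question actually arises:
a short aberration standing out of a quiet background. A short gain
inside a chromosome-arm-level gain is not a candidate, because nothing
local distinguishes it from its somatic surroundings.

Calling uses robust statistics of the probe log-ratios: a segment is a
gain (loss) when its mean is at least one median absolute deviation
above (below) the array median. Both statistics are *unscaled* — no
1.4826 normal-consistency factor anywhere — so the threshold is the
literal MAD of the data. Two consequences matter downstream:

* **Scale invariance.** Multiplying all log-ratios of an array by a
  positive constant changes neither the calls nor any of the scale-free
  features (relative height, break score), so arrays of different
  dynamic range are comparable.
* **Degenerate noise.** If the array MAD is zero (constant profile),
  every off-median segment is called, with a warning; this only occurs
  in synthetic or corrupted data.

Consecutive same-sign gain (or loss) runs are merged when their combined
span is strictly under 2.3 Mb, with the merged mean the marker-weighted
average of the members — the mean that re-segmenting the union would
give under constant probe density. Merging is idempotent, and runs at or
over the cap are left untouched. Candidate admission then uses an
*inclusive* cap (span ≤ 2.3 Mb): both boundary conventions follow the
wording of the respective rules and are asserted in tests. Chromosome
edges do **not** count as normal flanks (the conservative reading), and
candidates touching a physiological rearrangement region (immunoglobulin
/ T-cell receptor loci) by even one base are excluded, as such exclusion
lists are deliberately broad. No minimum length is imposed: with ~9 kb
probe spacing, segment lengths are underestimated and sub-kilobase
segments are legitimate candidates.

# Coordinates and formats

Internally every interval is 0-based half-open; SEG and DGV-style tables
(1-based inclusive) are converted on ingest and back on output, BED is
taken as-is, and `chr` prefixes are stripped. A probe is *in* an
interval iff `start <= pos < end`; in particular a probe exactly at a
variant's converted end is outside it. Having exactly one convention
confined to two conversion functions removes the usual off-by-one family
of overlap bugs; the conversion round-trip is property-tested.

# Database scores

For each probe we count the distinct catalogue variation ids covering it
(`n_variants`) and the summed reported individuals (`n_individuals`,
with absent counts contributing 0). A candidate's *Database score* is
the mean of `n_variants` over its probes; *Database score II* averages
`n_individuals`. Averaging over probes (rather than testing interval
overlap) makes the score robust to the endpoint uncertainty of catalogue
records: a candidate half-covered by reported variants scores half of a
fully covered one. Both scores are checked against a brute-force
per-probe recount oracle on random toy catalogues.

# Truth labels from the paired normal

When a matched normal hybridization exists, each candidate is labeled:

1. **Segment overlap.** If the candidate intersects (≥ 1 bp) a called
   gain/loss *of the same sign* in the normal sample, it is a CNV.
   Breakpoints need not match — segmentation estimates them with error.
   Sign agreement is our reading of "overlaps a gain or loss": opposite-
   sign overlap is evidence of two different events, not of a germline
   variant, and the sign-matched convention is what the paired examples
   in the source analyses show.
2. **Conditional segmentation test.** Normal-sample events too weak for
   the segmenter are caught by a permutation test. Let the candidate
   cover `k` normal probes with mean μ. The null pool is the normal
   log-ratios over the candidate plus its immediate left and right
   *tumor* segments — a local null that inherits whatever regional trend
   or noise level the neighborhood has. We draw `k` values from the pool
   **without replacement** `R = 1000` times (the permutation-test
   convention for resampling observed values), compute each mean μ\*,
   and set `p = #(s·μ* ≥ s·μ)/R` with `s` the candidate sign — one-sided
   in the candidate's direction, ties counting as extreme (both
   conservative choices). The candidate is declared a CNV iff μ also
   clears the gain/loss threshold of the **normal** array
   (`s·(μ − median) ≥ MAD`, using the normal array's own statistics,
   since the question is about the normal sample's signal) and
   `p < α = 0.01`.
3. Otherwise the candidate is a CNA.

The threshold conjunction makes the test strictly conservative: under an
i.i.d. null its declaration rate is far below α (the mean of 20
null probes rarely exceeds one probe-level MAD), which is what the
calibration tests and the acceptance script measure. Exhaustive
enumeration over all `C(pool, k)` subsets on small pools provides an
independent oracle for the sampled p-value. Per-candidate RNG streams
are derived from the base seed plus the candidate's sample, chromosome
and start, so relabeling is order-independent and bit-reproducible.

# The feature set

Eighteen columns in a fixed order (`feature_columns()`): 16 predictors
plus the two Database scores. Percentages are stored as fractions in
[0, 1]. Choices where the definitions left room:

* **Break score** with a missing neighbor (chromosome edge) is 0 — the
  natural null, avoiding missing values in the model matrix. The same
  logic sets **Database score of other candidates** to 0 for a lone
  candidate: 0 is the score of a catalogue-absent region.
* **Telomere proximity** uses positions 0 and the chromosome length as
  telomere proxies (no telomere table is bundled); centromere and
  telomere windows are 2 Mb, the nearby-candidate window 500 kb.
* **Overlap pattern**: GG/LL when all other patients' overlapping
  candidates share one sign; GL requires mixed signs from at least two
  distinct patients. The corner case of a *single* other patient
  carrying both an overlapping gain and loss is resolved by majority
  sign (ties to the candidate's own sign) rather than GL — the stated
  GL definition requires two patients, and the case is vanishingly rare.
* **Percent of normal** uses all markers on the chromosome in its
  denominator, including the candidate's own.
* **Exact breakpoint matching** compares internal coordinates for
  equality; interval overlap anywhere else means ≥ 1 bp intersection.
* A cohort of one patient gets zero/None cohort features, with a
  warning, so single-array classification still works.

# Classifiers

The five published trees are hard-coded from their printed split rules,
with "at least / or more" inclusive and "shorter / greater / more than"
strict. Only the CNV paths were printed; every unprinted complement
branch predicts CNA (e.g. GLAD's Database score ≥ 3 with relative height
≤ 1.5). Percentage thresholds (37 %, 38 %, 1.2 %) are stored as
fractions to match the feature units. One genuine ambiguity remains: the
smoothed-CBS tree's third split, "matching candidate segments in 37 % or
more of the other patients", could denote the overlap percentage or the
exact-breakpoint percentage. We default to `overlap_pct` — the named
predictor list for that model includes *Overlap with other patients -
percent* — and expose `overlap_feature = "matching_bkpt_pct"` to rebind
it. Branch order beyond the printed splits is unknowable from prose; the
encoded trees are flat rule lists equivalent to any branch order.

Trainable models delegate the generic machinery to the field's standard
implementations behind the package's interface: `rpart` grows the Gini
tree (10-fold cross-validation, minimum leaf 5, then our 1-SE pruning:
the smallest subtree whose cross-validated error is within one standard
error of the minimum), and `randomForest` fits the forest (500 trees,
`floor(sqrt(p))` features per split, Gini-decrease importances). The
univariate logistic screen fits one `glm` per feature with a
likelihood-ratio p-value against the intercept-only model; multi-level
factors contribute one coefficient per level and a single p. Perfect
separation is flagged (glm warning, or any |linear predictor| > 15)
rather than raised; constant features get p = 1. Train/test splits are
always by patient — candidates of one tumor are correlated, and a
candidate-level split would leak cohort features across partitions.
Evaluation treats CNV as the positive class and reports confusion
counts, pooled accuracy, both standard recalls *and* both predictive
values, labeled unambiguously, plus per-tumor accuracies and their
median.

# The synthetic cohort generator

`cohort_spec()` plants three kinds of events on a probe grid with 9 kb
spacing (the density of a 244K-feature array on a genome-scale target):
germline CNV loci, present in tumor **and** normal of each carrier
patient at the locus's population frequency; recurrent somatic loci and
private somatic events (Poisson count per patient, log-uniform lengths
50 kb – 8 Mb so both under- and over-cap spans occur), tumor only; and
optional reference-sample variants present in every genome — these
surface as candidates in every tumor and are *correctly* labeled CNV by
paired logic, reproducing the known blind spot for variants carried by a
pooled reference. Probe values are the sum of active shifts plus
`N(0, noise_sd)`; isolated outlier probes are spiked at ±5 noise SDs.
Overlapping planted events within one genome resolve by dropping the
later-listed event (germline loci are listed before somatic ones, so
germline wins), keeping the ground truth consistent with the signal.

The oracle segmentation uses the true breakpoints snapped to the probe
grid, each independently jittered by up to `breakpoint_jitter_probes`
probes in tumor and normal, emulating segmentation error without running
a segmenter — the tests stay download-free and deterministic, and real
CBS/GLAD output can be substituted through the SEG reader. Default
conditions (40 patients, four 60 Mb chromosomes, noise SD 0.12, jitter
2, outlier rate 0.002) put planted shifts of 0.35–0.6 at 4–7 calling
MADs — clearly callable single-copy-like events over realistic array
noise. The `small` preset (6 patients, two 30 Mb chromosomes) is the
smoke scale used throughout the unit tests; the `default` preset is the
benchmark scale for the labeling-recovery and held-out-accuracy checks.

What passing on synthetic data shows — and does not. The generator
exercises every code path the classifier depends on: MAD calling,
merging, flank logic, catalogue redundancy, paired labeling including
permutation rescue, cohort features, training and evaluation. It does
**not** emulate GC waves, probe-specific response, tumor purity dilution
of somatic shifts, allele-specific states, or the heavy-tailed noise of
real hybridizations; accuracies obtained on synthetic cohorts
characterize the implementation, not expected performance on real
arrays, and the published-tree thresholds are validated as constants,
not re-derived.

# Numerical and scale choices

* Boundary calls are inclusive (`mean = median ± MAD` is a call).
* Merging uses strict `< 2.3 Mb`; admission uses `≤ 2.3 Mb`.
* The permutation p-value has resolution 1/R; with R = 1000 and
  α = 0.01 a declaration needs at most 9 of 1000 draws as extreme.
* Published-tree threshold scans in the acceptance script step on exact
  rational grids (multiples of 0.01 or 0.1) to avoid floating-point
  drift at the split points.
* Problem sizes in the test suite — 1000 null candidates for
  calibration, 100 cohorts for candidate-rule conformance, 50 toy
  catalogues for the score oracle, 20 seeds for CART recovery, one
  default-preset cohort for end-to-end recovery — were chosen as the
  smallest sizes at which the binomial/Monte-Carlo error of each check
  is clearly below its margin.

# Known limitations

Segmentation quality bounds everything: candidates are only as good as
the segments supplied. Stromal contamination can push true somatic
events below the calling threshold in impure tumors, and copy-neutral
LOH is invisible to total-copy-number log-ratios. The truth labels
derived from paired normals are themselves a silver standard — a
sufficiently weak germline variant can fail both the segmentation
overlap and the permutation test and be mislabeled CNA.
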