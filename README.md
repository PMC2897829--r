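# germcnv

Classify short gain/loss segments on tumor copy-number arrays as germline
**copy number variants (CNVs)** or somatic **copy number alterations
(CNAs)**.

## The problem

CNVs — inherited gains and losses of 1 kb to a few Mb carried by healthy
individuals — are present in every cell of a tumor, so an array-CGH
profile of a tumor mixes them with the somatic alterations that cancer
studies actually care about. When no paired normal sample is available
the two are hard to tell apart, and recurrent CNVs (including variants
carried by a pooled reference sample) masquerade as recurrent cancer
events. `germcnv` implements a classification framework for this
problem, aimed at anyone analyzing segmented array (or array-like)
copy-number data for tumor cohorts.

## What it does

1. **Candidate extraction.** Segments (from any external segmenter; CBS-
   or GLAD-style output is consumed via SEG files) are called gain/loss
   when the segment mean lies at least one unscaled MAD from the array
   median. Consecutive same-sign runs under 2.3 Mb are merged; a
   *candidate CNV* is any called gain/loss with span ≤ 2.3 Mb flanked by
   at least one normal segment, off chromosomes X/Y and outside
   physiological rearrangement regions.
2. **Database scores.** For each probe, the number of distinct catalogue
   variants (DGV-style table) covering it, `n(p)`, and the total
   individuals reported for them, `m(p)`. A candidate's *Database score*
   is `mean(n(p))` over its probes, *Database score II* is `mean(m(p))`.
3. **Truth labels from paired normals.** A candidate is a true CNV if it
   overlaps a same-sign called gain/loss in the matched normal, or if
   the normal-sample probes under it are significant by a *conditional
   segmentation test*: with `k` normal probes of mean μ under the
   candidate, draw `k` values (without replacement, R = 1000 times) from
   the normal log-ratios spanning the candidate and its two neighboring
   tumor segments; declare a CNV when μ clears the normal array's
   gain/loss threshold and fewer than α = 1% of draws are as extreme.
4. **A 16-predictor feature set** per candidate: length, height and
   relative height (|mean| / residual MAD), break score, sign, flank
   and segmental-duplication/centromere/telomere indicators, cohort
   overlap pattern and percentages, exact-breakpoint matches, nearby
   candidates, fraction of normal markers on the chromosome, Database
   score of other candidates, overlap with other patients' non-candidate
   same-sign segments, and both Database scores.
5. **Classifiers.** The five published decision trees are hard-coded
   (e.g. the smoothed-CBS tree: CNV if Database score ≥ 2.45, else if
   length < 30 kb, else if ≥ 37 % of other patients have an overlapping
   candidate), alongside the ad-hoc two-study rule, trainable CART with
   1-SE pruning, random forests with Gini importances, a univariate
   logistic screen, and evaluation reports (confusion counts, pooled and
   per-tumor accuracy, predictive values).
6. **Synthetic cohorts.** A generator plants germline CNV loci (in tumor
   *and* normal), recurrent and private somatic events (tumor only),
   reference-sample variants, Gaussian probe noise, outlier spikes and
   oracle segmentations with optional breakpoint jitter — so the whole
   pipeline runs and is tested without any external data.

## Worked example

```r
library(germcnv)

fx  <- end_to_end_fixture("small", seed = 1)     # 6 synthetic patients
out <- classify_cohort(fx$tumor_profiles, fx$tumor_segments,
                       fx$dgv, fx$annotation,
                       model = published_tree("cbs_smoothed_full"))
table(out$predictions)
#> CNA CNV
#>  12  36

# paired-normal truth labels, then evaluate the published tree
labs <- label_cohort(out$calls, fx$normal_profiles, fx$normal_segments,
                     rng_seed = 1)
evaluate(out$predictions, labs$label, labs$patient)
#> CNV/CNA classification evaluation (positive class: CNV)
#>   counts: TN 12  FN 0  FP 5  TP 31
#>   accuracy 0.896  sens 1.000  spec 0.706  ppv 0.861  npv 1.000
#>   per-tumor median accuracy 0.962 over 6 tumors
```

The 48 candidates split into 36 predicted CNVs and 12 CNAs; against the
paired-normal labels the published tree classifies 89.6 % of them
correctly, missing no true CNV and over-calling five CNAs as CNVs — the
same error asymmetry the model family shows on real cohorts, because
catalogue overlap is strong evidence *for* a CNV but weak evidence
against one. Training your own models on a labeled cohort:

```r
tp <- train_pipeline(fx, seed = 1)   # patient-level 60/40 split
tp$eval_rf                            # held-out random-forest report
gini_importance(tp$rf)                # per-feature Gini decreases
```

A command-line wrapper with `simulate`, `classify` and `train`
subcommands lives at `inst/cli/cnvclass.R`.

## Limitations

- Segmentation itself (CBS, GLAD) is out of scope: segments are inputs.
- No modelling of tumor purity / stromal contamination or allele-specific
  copy number.
- The synthetic cohorts use additive fixed-shift events with Gaussian
  noise; see the methods vignette for what that does and does not
  establish about real arrays.
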