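---
title: "Methods: the serumiR circulating-miRNA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the serumiR circulating-miRNA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumiR)
```

## The measurement model

A qPCR array reports, per well, a quantification cycle Cq; abundance is
proportional to 2^(−Cq), so a difference of one cycle is a two-fold
difference in template. Serum profiling adds three complications that shape
everything in this package: there are no accepted endogenous reference RNAs
in cell-free samples, the low miRNA amounts force a pre-amplification step
(shifting all Cq values and motivating a conservative detection cutoff),
and blood-cell material — from hemolysis or incomplete cell removal — can
contribute miRNAs that were never secreted.

All internal computation is on Cq (cycles) and temperatures (degrees
Celsius); relative expression is 2^(−ΔCq), dimensionless, with an assumed
amplification efficiency of exactly 2 (per-assay efficiencies are not
modeled — the platform does not report them).

## Sample QC

Three per-sample checks produce an include/exclude verdict
(`qc_verdict()`); a sample fails iff at least one check fails, and failing
is data, not an error.

* **Hemolysis**: ΔCq = Cq(miR-23a-5p) − Cq(miR-451a), computed on raw Cq
  (per-sample calibration constants cancel in the within-sample
  difference). miR-451a is strongly erythrocyte-enriched, miR-23a-5p is
  serum-stable. Threshold: delta > 5 cycles fails; (5, 7] is additionally
  reported as borderline. The threshold follows the convention of the
  indicator's source literature; it is a configurable parameter.
* **Contamination**: the SNORDs and RNU6-2 are abundant in blood cells and
  normally absent from serum; any of them detected below Cq 32 counts as a
  hit. The bound is a design choice ("normally absent" is not a number);
  32 sits two cycles beyond the detection cutoff so that borderline noise
  does not flag clean samples.
* **Spike recovery**: per spike-in, |Cq − batch median| > 2 cycles, or an
  undetected spike, fails. The batch median is the only way batch
  composition enters any verdict; verdicts are otherwise independent of
  sample order.

## Calibration, censoring, normalization

`calibrate_cel39()` implements anchor calibration: compute each sample's
cel-39 mean, find the batch maximum, and add the per-sample difference
(correction factor ≥ 0) to every Cq of that sample. The operation is
idempotent, preserves within-sample contrasts, and equalizes all cel-39
means at the batch maximum.

`censor_cq()` masks calibrated Cq strictly greater than 30 (the boundary
value is kept) and any well whose melt curve is bad — regardless of Cq,
since a low Cq on an unspecific product is not a measurement of the target.
The mask is sticky downstream.

`global_mean_normalize()` computes ΔCq against the sample's detected target
mean; by construction the geometric mean of each sample's expressions is 1.
A `common_only` flag restricts the reference to assays detected in *every*
sample: when sample means are compared directly (the circadian analysis),
the default per-sample detected set is a liability, because censoring near
the cutoff removes different wells from different samples and shifts their
means by different amounts.

`stability_rank()` scores candidate references with four classical
measures — geNorm M (mean across-sample SD of pairwise differences),
comparative ΔCt (the same quantity, kept as its own report column by
convention), BestKeeper (plain Cq SD), and NormFinder in its single-group
variance-decomposition form (normalization precedes any group comparison
here, so the multi-group variance term is out of scope). The consensus is
the geometric mean of the four per-method ranks — the documented convention
of consensus reference tools, whose exact aggregation is otherwise
unpublished — with ties broken by assay name. `stable_reference_normalize()`
then uses the five top-consensus assays as the reference mean.

## Melt-curve classification

`extract_features()` reduces each −dF/dT curve to the features a reviewer
inspects: associated Cq, Tm (global maximum, ties broken toward the lower
temperature), peak height, grid endpoints, secondary-peak count (local
maxima of the lightly smoothed signal at ≥ 30% of the main peak), width at
half height, and the shape itself resampled to 32 points and
max-normalized. An all-zero curve is flagged degenerate with peak height 0.

The classifier is an RBF-kernel SVM with Platt-style probability estimates
on standardized features. Classification adds the *questionable* rule: over
the classified batch, curves whose prediction probability is strictly below
mean − SD of all prediction probabilities are labeled questionable for
manual inspection. The threshold is computed batch-wise (it is a symmetric
function, so labels are order-invariant); the conservative downstream
default treats questionable as bad. Efficiency is evaluated by stratified
repeated splits: hold out one third, train on the rest, compute the
rank-statistic ROC AUC of the good-class probabilities on the holdout, and
average over 100 repeats.

## The healthy miRNome

`categorize_mirnome()` assigns each target miRNA exactly one of five
categories, in a fixed precedence chosen to make the summary pie disjoint:
not expressed (undetected or Cq > 30 in all samples) → bad melt curves
(> 80% of samples) → unstable (raw Cq SD > 1 over detected samples,
requiring ≥ 50% detection so absent miRNAs cannot be "unstable") → high
expression (Cq < 27 in > 80%) → low expression (the remainder). SD is
computed on raw (calibrated, uncensored) Cq.

`circadian_analysis()` flags miRNAs with a single-timepoint deviation: the
midday mean ΔCq must differ from both the morning and the evening mean by
at least δ with the same sign, while morning and evening agree within δ/2.
Two choices deserve justification:

* δ defaults to 1.25 cycles (≈ 2.4-fold). With four donors and 0.3-cycle
  noise, a timepoint mean has SE ≈ 0.15 and a between-timepoint contrast
  SE ≈ 0.21. The binding constraint is the morning/evening consistency
  gate at δ/2: at δ near 0.6 that gate sits within 1.5 SE of its own null
  and candidate recovery is a coin flip; at δ = 1.25 both the detection
  gates and the consistency gate are ≈ 3 SE from their boundaries.
* a stability gate: assays whose across-sample SD outside the midday
  timepoint exceeds the instability cutoff are never circadian candidates.
  Inter-individual fluctuation otherwise mimics single-timepoint deviations;
  the catalog itself warns that fluctuating miRNAs must not be read as
  differential signals.

## Biomarker signatures

For each of the nine comparisons (healthy vs all-melanoma, vs each stage
0–IV, vs early 0+I+II, vs late III+IV, and early vs late), `build_dataset()`
restricts the normalized custom-panel expression to the two groups, pools
multi-stage groups under a common label, log2-transforms, drops assays
undetected in more than 20% of the selected samples and imputes the
remaining gaps at the censoring bound (the expression a Cq-30 well would
have in that sample — row deletion would discard most late-stage samples
exactly where the signal is).

`rank_svmrfe()` is recursive feature elimination with a linear SVM on
standardized features, removing one feature per iteration (88 features make
chunked elimination unnecessary); ranking is the reverse elimination order,
weight ties break by fixed feature order, and constant features leave
first. Nested signatures of sizes 2–10 are scored by leave-one-out accuracy
with an RBF SVM retrained per fold (linear weights for ranking, RBF for
classification, both configurable); the best signature maximizes accuracy
with ties toward fewer miRNAs. The chosen signature gets a stratified
half-split ROC AUC (rank statistic on SVM decision values) with a 95%
stratified-bootstrap CI (2000 resamples of the test half; bootstrap rather
than an asymptotic variance because it is exactly specifiable at these
sample sizes). Rankings are computed independently per comparison and never
cached across comparisons — a ranking is specific to its training set.

`signature_null_band()` re-runs the *entire* selection (ranking + nested
evaluation) on label-permuted data; comparing an observed best accuracy
against this band guards against selection-bias optimism. The scientific
claim for comparisons with no effect is one-sided: the observed accuracy
must not beat the upper null quantile.

Candidate flags annotate, never remove: whole-blood-high (mean whole-blood
Cq < 15 — the miRNA may derive from contaminating blood cells) and
membership in the catalog's unstable list.

## Tissue vs serum

On matched serum / normal-skin / primary / metastasis quadruples,
`compare_compartments()` makes panel-level calls: tissue-exclusive
(detected in at least one tissue sample, undetected in every serum sample),
serum-exclusive (symmetric), and serum-higher (mean serum / mean pooled
tissue expression > 3, averaged over individuals). `stage_gradient()` flags
strictly increasing normal → primary → metastasis means with each step
at least 1.5-fold (a progression gradient is usually judged by eye; 1.5 is
the package's operationalization). These comparisons are semi-quantitative:
serum input amounts vary more than tissue input amounts, which the report
carries as a footnote, not a correction.

## Embeddings

PCA is the eigendecomposition of the covariance of centered log2
expression, with the sign convention that each component's
largest-magnitude loading is positive (fully deterministic). t-SNE is the
exact (non-approximated) algorithm — adequate for qPCR-scale cohorts of
tens of samples — on PCA-whitened input at perplexity 10. Whitening is
capped at 30 retained components: whitening every component up to n − 1
when there are at least as many assays as samples places all points on a
regular simplex (all pairwise distances equal) and the perplexity
calibration diverges. Gradient descent uses the reference schedule (early
exaggeration 4 for 100 iterations, momentum 0.5 → 0.8, adaptive gains, 600
iterations, learning rate 100), recorded in the embedding's attributes.

## The synthetic cohorts

The generator is a first-class module: it draws the study conditions with
planted, recoverable ground truth, and its defaults *are* the fixture
definitions used by the tests.

* **Healthy cohort**: 19 single-draw donors plus 4 circadian donors at
  three timepoints (31 samples, 1066-target panel). 63% of targets absent
  (never at or below Cq 30; half the wells not detected at all), 82 high
  (baseline Cq 20–25.5, comfortably below the 27-cycle bound even after
  calibration shifts), 30 unstable, 7 circadian, remainder low expression.
  Measurement noise is a single additive Gaussian on Cq, SD 0.3 — the
  variance structure of biological vs technical replication is not
  separable from the study design, so one term carries both.
* **Unstable miRNAs** carry an inter-individual fluctuation whose realized
  SD is fixed at exactly 1.3 cycles (offsets are rescaled after drawing):
  a fluctuation merely *drawn* at that SD would fall below the SD-1
  detection cutoff for roughly one miRNA in ten at this cohort size, which
  would make planted category counts irrecoverable in principle. Fixing
  the realized amplitude makes the planted category unambiguous ground
  truth while leaving every individual value noisy.
* **Circadian miRNAs** shift −1.9 cycles at midday only. The shift is
  bounded above by the instability cutoff — a midday shift much past 2
  cycles lifts the across-sample SD of a 31-sample cohort with 4 midday
  draws above 1 and the miRNA leaks into the unstable category — and
  bounded below by detection power; −1.9 with δ = 1.25 leaves both
  category and candidate counts recoverable with ≈ 95% probability per
  seed. Baselines sit at Cq 26.5–28 so morning/evening wells stay below
  the censoring cutoff after calibration.
* **QC stream**: 131 serum samples, 31 planted failures (11 hemolytic:
  miR-451a shifted −8 cycles; 10 contaminated: SNORDs at Cq 25–29 where
  clean serum has none; 10 poor-recovery: all spikes shifted +4 ± 1.5
  cycles). Each failure mode is decisive by design, so the verdict and its
  reasons are exactly recoverable.
* **Patients**: 30 healthy plus 4/11/17/11/9 patients of stages 0–IV on
  the 88-target custom panel. Late-stage effects are planted on the
  melanoma-associated assays (2–2.5-cycle shifts in stages III+IV in both
  directions; miR-211-5p at −6.09 cycles in stage IV, i.e. 2^6.09 ≈
  68-fold overexpression). No early-stage effects are planted: early
  comparisons must stay at permutation-null accuracy.
* **Matched plan**: 6 individuals × (serum, normal skin, primary,
  metastasis); 15 tissue-exclusive, 2 serum-exclusive (miR-3201,
  miR-122-5p), 12 serum-higher (−2.5 cycles in serum) and 5 stage-gradient
  (−1.5 cycles per step) miRNAs.
* **Melt curves**: −dF/dT profiles on a 65–95 °C grid at 0.5 °C (a common
  instrument export; the grid is configurable). Good: single Gaussian, Tm
  74–84 °C, height 0.8–1.2. Bad: low-Tm primer-dimer (Tm ≤ 72), multi-peak,
  and flat archetypes in even thirds. Signal noise SD 0.02.

What the generator does *not* emulate — and hence what passing recovery
tests do and do not show: real plates have per-assay amplification
efficiencies, position effects, correlated technical drift, heavy-tailed
noise and melt-curve shapes far richer than three archetypes. Recovery of
planted structure demonstrates that the pipeline's logic is correct and its
thresholds behave as specified, not that the same thresholds are optimal on
any particular instrument's data. Category assignment depends only on seed
and configuration (never on noise draws), and all outputs are bit-identical
given a seed.

## Numerical and policy choices

* Not-detected wells are `NA` internally; files carry a Cq-35 sentinel plus
  a `detected` flag, and readers map "N/A"/blank to not-detected.
* Censoring is strict: Cq 30.0 is kept, anything greater is masked.
* The questionable threshold uses the sample (n − 1) SD; a zero-SD batch
  leaves nothing "strictly below" the threshold.
* The melt SVM uses C = 1 and the 1/p gamma default; the signature SVMs use
  a linear kernel for RFE weights and RBF for evaluation. Hyperparameters
  are fixed in the function signatures and reported in results.
* Half-split ROC uses a single seeded split per call; multi-seed averaging
  is the caller's loop (as in the acceptance script, 10 seeds).
* Problem sizes in the shipped tests (cohort sizes above, 1000 melt curves,
  100 evaluation repeats, 20-cohort fold-change averages, 25-permutation
  null bands) were chosen so the full verification runs in a few minutes on
  a single core while keeping every recovery criterion's sampling error
  well inside its tolerance.

## Known limitations

Efficiency-corrected (Pfaffl-type) quantification, inter-plate calibrators
beyond cel-39, absorbance-based hemolysis detection, multi-group NormFinder
and multi-class staging are out of scope. The consensus-stability
aggregation reproduces the geometric-mean-of-ranks convention, not any
proprietary implementation. The circadian rule assumes the midday timepoint
is the only candidate deviation, mirroring the study design it emulates.
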