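---
title: "Methods: serum glycoprotein biomarker discovery and validation with glycomark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum glycoprotein biomarker discovery and validation with glycomark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomark)
```

## The scientific setting

Serum glycoproteins captured by lectin-affinity pulldown are a rich
source of candidate cancer biomarkers: a carbohydrate-binding lectin
(AAL, SNA, STL, ...) enriches the subset of serum proteins carrying its
preferred glycan, so each lectin pulldown yields an independent feature
space of *glycoforms* — a protein as captured by a specific lectin.
glycomark implements a two-phase case-control analysis over such data:

1. **Discovery** on data-dependent-acquisition (DDA) shotgun
   proteomics: per lectin, a protein-group intensity matrix over cases
   (high-grade serous ovarian carcinoma in the motivating design),
   benign-neoplasm controls and healthy controls, filtered, imputed and
   tested for differential abundance to shortlist candidate glycoforms
   and rank lectins.
2. **Validation** on multiple-reaction-monitoring (MRM) targeted
   proteomics for the shortlisted lectins: transition peak areas are
   aggregated to peptides, internal-standard quality control is run,
   peptides are tested with false-discovery-rate control, proteins are
   validated by a peptide-consistency rule, and multi-peptide
   classification panels are built with penalized logistic regression
   under leave-one-out cross-validation (LOOCV).

A seeded synthetic-cohort generator with planted effects makes the
whole chain testable: every statistical property asserted in the test
suite is measured on data whose ground truth is known by construction.

## Discovery stage

### Filtering and quantification

Protein groups are dropped when flagged as contaminant or
reverse-database hits, supported by fewer than `min_peptides` (default
2) peptide identifications, or scored below `min_score` (default 5).
Protein quantity per sample is the **sum of observed peptide
intensities**; a protein is missing in a sample only when all of its
peptides are missing there. Zero or blank intensity cells in DDA
exports are treated as missing, following the label-free convention
that a zero records a non-detection rather than a measured abundance.

### Missingness-routed imputation

Imputation operates on the log2 scale and is routed per feature by its
missingness fraction against `missing_frac_boundary` (default 0.25):

* **Below the boundary** the feature is treated as missing at random
  and imputed by *local least squares*: its `lls_k` (default 10) most
  correlated fully observed neighbour features (absolute Pearson over
  the feature's observed samples) are used as regressors, with an
  intercept, and the missing entries are the linear predictions. The
  intercept is deliberate: it lets the regression invert an exact
  affine relation between a feature and its neighbour, which a
  through-the-origin fit cannot. Rank-deficient systems are solved by
  the Moore–Penrose pseudoinverse. With fewer than `lls_k` eligible
  neighbours the largest available number is used; with none, the
  feature falls through to the minimum-value route (recorded per row).
* **At or above the boundary** the feature is treated as left-censored
  (missing because it sat near or below the detection limit) and each
  missing entry is drawn from a normal distribution centred at the
  per-sample minimum of observed log2 values, with SD estimated as the
  square root of the mean within-row variance over fully observed rows
  (a scalar override is available). Exactly-at-boundary rows take this
  route on purpose: the boundary case is ambiguous, and the
  distribution-free draw is the conservative choice.

Observed entries are never altered, and the route taken for every row
is recorded. Imputation on the log2 scale (rather than linear) is
itself a decision: minimum-centred Gaussian draws are only well formed
there, and local linearity is more plausible after variance
stabilisation.

### Testing and shortlisting

The default test is the pooled-variance two-sided Student *t* per
feature, computed in closed form over matrix rows; an empirical-Bayes
moderated *t* (limma) is available as a variant and agrees with the
pooled test in effect ranking on well-behaved data. The log2 fold
change is mean(case) − mean(control). At the discovery stage q-values
are intentionally absent: with small group sizes and a downstream
targeted assay to confirm candidates, shortlisting is on unadjusted p.

Two shortlist modes exist: **strict** (p < `p_discovery` = 0.05 and
|log2FC| > `fc_discovery_log2` = 1) and **expanded**
(p < `p_expanded` = 0.1, no fold-change condition) for assembling a
larger assay target list. Cross-cohort concordance keeps features
exceeding `concordance_fc_log2` = 0.5 in both cohorts with matching
sign. Candidate summaries count *distinct* proteins per lectin
(overlapping cells counted once), and lectin ranking offers two
metrics — distinct-protein union count, or count of proteins found in
both cohorts — because candidate totals alone do not determine a
unique ordering; ties break lexicographically and are logged.

## MRM stage

Peptide quantity is the **sum of transition peak areas,
log2-transformed after summing**. Internal-standard QC computes the
percent coefficient of variation (100·SD/mean) of each ovalbumin and
spiked stable-isotope-standard peptide on **linear-scale** summed
areas — a CV of log-transformed values is not a CV — against
`cv_limit_pct` (default 10%). Outlier samples are scored by a robust z
on their mean log2 standard level: |level − batch median| / (1.4826 ·
MAD), flagged above `outlier_robust_z` (default 3.5). The flags are
advisory; removal is an explicit, logged step, because the rule is a
reconstruction — instrument-failure batches are usually known from run
records, and the robust z formalises "visibly aberrant standards"
without a published numeric criterion. When the MAD is zero and any
sample deviates, the deviating samples are flagged with a warning.

No global normalisation is applied by default (the QC design already
verifies low technical variance); an ovalbumin-standardisation option
subtracts the per-sample mean of the ovalbumin peptides from every
log2 entry, removing sample-level loading shifts, and is off by
default.

## Validation stage

Peptides are tested per comparison with the pooled *t* and adjusted by
Benjamini–Hochberg **within each (lectin, comparison) family**,
matching the design in which each lectin's assay is analysed
independently. A peptide is *significant* when, in either comparison,
q < `q_validation` (0.05) and |log2FC| > `fc_validation_log2` (0.5). A
protein **validates** under the default `direction` rule when at least
one peptide is significant and *all* of its measured peptides agree in
fold-change sign; the `strict` rule additionally requires every
peptide to be significant itself. Both rules are implemented because
the two published phrasings of the filter differ, and the strict set
is provably a subset of the direction set. When a peptide's two
comparisons disagree in sign, its direction is taken from the
comparison with the larger |log2FC| and the disagreement is flagged.
Reported percentages are consistent-protein counts over
any-significant counts, rounded to one decimal.

## Panel stage

The design matrix holds lectin-qualified peptide features
("AAL-peptide"); cases are labelled 1 and the benign and healthy
groups are pooled as 0. Samples missing any in-scope feature are
dropped with a logged count, and QC-flagged outliers are excluded by
default (an option retains them for sensitivity analysis).

For each left-out sample the training split is standardized (its mean
and SD only), the L1 penalty is chosen by inner 5-fold cross-validated
binomial deviance with the one-standard-error rule (fold assignment is
stratified and seeded), the lasso-penalized logistic model is fitted,
and the selected features and the left-out sample's predicted
probability are recorded. Nothing about the left-out sample enters its
own fold's standardization or penalty choice; the test suite asserts
this by corrupting a held-out sample and checking its fold's selection
is unchanged. The one-standard-error rule was preferred after
comparing both: on the package's own synthetic validation cohorts the
deviance-minimising penalty overfits noise features at these sample
sizes.

**Per-fold baseline centring.** Pooled raw LOOCV probabilities carry a
known pessimistic artifact: when the inner lasso shrinks to the
intercept, the training set of a left-out case holds one fewer case,
so its predicted probability is systematically *below* that of a
left-out control, driving the pooled AUC toward zero on null data.
glycomark therefore centres each fold's linear predictor on its
training-prevalence logit and re-anchors at the full-data prevalence.
Within-fold rankings are untouched; null data recover a pooled AUC
near 0.5, as a permutation null should.

AUC is the Mann–Whitney probability with half credit for ties;
sensitivity and specificity are reported both at the fixed
`classification_threshold` (0.5) and at the Youden-optimal threshold,
because lasso-shrunk LOOCV probabilities concentrate near the
prevalence and a fixed 0.5 cut can sit outside their range. Intervals
are stratified bootstrap percentile intervals (`n_boot` = 2000
resamples of the pooled left-out predictions); they describe resampling
uncertainty of the pooled predictions and are not comparable to
intervals produced by other software's internal methods. Stability is
the fraction of LOOCV fits selecting each peptide; the stable set
keeps fractions ≥ `stability_frac` (0.5), the boundary included, sorted
by fraction then name.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
at the motivating study's scale: three age-matched groups (10/10/10
per discovery cohort; 39/28/28 for validation), several lectin
pulldowns per sample, log2-normal protein abundance (per-protein
baseline drawn once per cohort, default mean 20, SD 2 on the log2
scale), within-group noise SD 1, peptide-level tables with 2–6
peptides per protein, and MRM tables with 4–5 transitions per peptide
whose areas split each peptide's abundance by fixed weights plus small
multiplicative noise. Planted effects are registered per (lectin,
protein, comparison); an effect Δ is realised by shifting the named
control group by −Δ, so case-minus-control equals Δ for that
comparison while the other comparison is untouched — this keeps the
two contrasts independently controllable.

Missingness combines left-censoring (deletion probability
`plogis((mnar_midpoint − log2 intensity) · mnar_slope)`, defaults 17
and 1 against the baseline of 20) with a uniform 2% missing-completely-
at-random component. The censoring mechanism is an assumption made for
testing — it is what justifies a minimum-value imputation branch — not
a claim about any particular instrument. Internal standards (three
ovalbumin-like and three spiked stable-isotope peptides) are present
in every sample, drawn group-independent and log-normal with an 8%
target linear CV, and are never deleted. Decoy rows (5% contaminant,
5% reverse, 10% low-evidence) give the filter real work. An optional
instrument-failure batch perturbs one lectin's named samples by a log2
location shift and a variance inflation about per-peptide means, so
that a shift of 0 with inflation 1 is exactly the identity.

All randomness flows from one root seed through named streams (per
lectin and stage), so identical configuration and seed reproduce
byte-identical tables and any stage can be regenerated independently.

What the generator does **not** emulate: raw spectra, chromatography,
retention-time drift, peptide-specific ionisation efficiency shared
across samples, batch effects beyond the explicit outlier batch,
correlated protein modules, or non-Gaussian abundance distributions.
Passing tests therefore demonstrate that the pipeline's statistics
behave as designed under its own model assumptions — calibrated null
p-values, controlled false-discovery proportions, unbiased effect
recovery, signal recovery in panels — not that those properties hold
on any real cohort.

## Numerical choices and degenerate inputs

* Exactly-at-boundary missingness routes to minimum-value draws.
* A constant imputation target returns its own constant; zero-variance
  neighbours get correlation 0 rather than NA.
* Zero pooled variance with zero mean difference yields t = 0, p = 1;
  p-values are floored at the smallest positive double so BH input
  stays in (0, 1].
* Direction "flat" applies only at log2FC exactly 0 (no tolerance):
  candidates are threshold-selected anyway, so a tolerance would only
  blur the bookkeeping.
* BH adjustment validates p ∈ (0, 1] and otherwise errors — malformed
  inputs are never silently coerced, in files or in memory.
* The lasso penalty is parameterised on the sum-deviance scale, so
  duplicating every observation while doubling the penalty provably
  leaves the solution unchanged; the unpenalized limit matches a
  generic maximum-likelihood fit to ≤ 1e−4.
* Lectin-ranking ties break lexicographically and are logged; asking
  for more lectins than exist returns all with a warning.

## Problem sizes used by the test suite

The suite measures: null calibration on 1000 features at 10 samples
per group (3 binomial SE band around 0.05); false-discovery proportion
over 50 replicates of 200 features with 10% planted effects of 2 log2
units at 30 per group; effect recovery to within ±0.1 over 100
planted-feature estimates; LOOCV panel recovery on 60 samples with 3
informative peptides at 2 SD among 30 noise peptides, plus a
permuted-label null; internal-standard CV pass rates over 100
validation-scale replicates at the 8% target; exact flagging of a
constructed −1 log2 unit outlier batch; and byte-identical reruns of
the full pipeline. These sizes were chosen as the smallest at which
the binomial/Monte-Carlo error bands in the assertions are meaningful.

## Known limitations

* The consistency rule treats peptides as exchangeable evidence;
  proteoform-specific peptide behaviour (real and common) will fail
  the all-peptides-consistent filter by design.
* Local least squares assumes the correlated-neighbour structure
  survives missingness; with few fully observed rows it degrades to
  small neighbour sets and, at the limit, to minimum-value draws.
* Bootstrap percentile intervals on LOOCV predictions ignore the
  dependence between folds; they are honest about resampling noise,
  not about model-selection variability.
* The pipeline consumes tidied tabular exports; parsing the full
  dialect variety of real search-engine or MRM-software outputs is out
  of scope.
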