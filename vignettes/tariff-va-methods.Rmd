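---
title: "Tariff-based verbal autopsy analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tariff-based verbal autopsy analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tariffva)
library(dplyr)
```

## The problem

In countries where most deaths happen outside health facilities, no physician
certifies a cause of death, and civil registration and vital statistics (CRVS)
systems cannot say what people die of. Verbal autopsy (VA) fills the gap: a
trained interviewer asks the family a fixed, structured set of yes/no symptom
questions about the terminal illness, and an algorithm converts those answers
into (a) a probable cause per death and (b) population-level cause-specific
mortality fractions (CSMFs), the quantity health policy actually consumes.

`tariffva` implements that full analytic chain — tariff training, individual
assignment with an explicit *undetermined* category, population-level
redistribution of undetermined deaths, CSMF estimation with bootstrap
uncertainty, and plausibility assessment against a modelled reference — plus a
synthetic-data generator so every stage can be exercised and validated without
access to restricted gold-standard or country data.

## The tariff model

Training data is a *gold-standard database*: deaths with a reliably known
cause and the same symptom questionnaire. For cause $c$ and symptom $s$, let
$x_{cs}$ be the endorsement rate — the fraction of gold-standard deaths of
cause $c$ whose interview answered "yes" to $s$. The tariff standardises the
rate against the spread of that symptom across causes:

$$ t_{cs} \;=\; \frac{x_{cs} - \operatorname{median}_{c'}(x_{c's})}
                     {\operatorname{IQR}_{c'}(x_{c's})} $$

A symptom endorsed equally often for every cause carries no diagnostic
information; its IQR is 0 and its tariff column is set to 0 by rule. A
record's score for cause $c$ is $\sum_{s \in \text{endorsed}} t_{cs}$: only
"yes" answers contribute, so a missing response scores exactly like a "no"
while remaining missing in the stored data (the records stay auditable).

Two standard post-processing steps, both on by default and recorded in the
tariff metadata, make scores robust and sparse:

* rounding to the nearest 0.5 (`round_to = 0.5`), exact midpoints away from
  zero for determinism;
* per-cause truncation to the `top_k = 40` largest-magnitude tariffs, ties at
  the cut broken by schema symptom order.

Quantiles use inclusive linear interpolation between order statistics
(R's type 7), stated in the metadata so independent reimplementations can
match it exactly. Bootstrap significance filtering of tariffs, a refinement
some tariff implementations apply before truncation, is deliberately not
implemented; the metadata marks it `unavailable`.

## Individual assignment and the undetermined category

Raw tariff scores are not comparable across causes, so assignment is done by
*ranking*. A baseline pool is built by resampling, with replacement,
`per_cause_n` (default 100) gold-standard records of **each** cause — a
uniform cause composition, so the baseline cannot leak the gold standard's
cause mix into field estimates — and scoring the pool against every cause. A
field record's rank for cause $c$ is one plus the number of pool scores for
$c$ strictly above its own (ties favour the record). The candidate cause is
the eligible cause with the lowest rank; ties break by higher score, then
cause-list order, so results are invariant to cause-list permutation except
through that final documented tie-break.

The candidate is demoted to `undetermined` when the evidence is weak:

* rank above `rank_quantile_cutoff` × pool size (default 0.89),
* score below `minimum_score` (default 0),
* rank above `overall_rank_cap` × pool size (default 1, inactive).

These thresholds are deployment calibrations, not constants of the method;
the defaults mirror the public adult configuration of the tariff method and
everything is overridable per run. Undetermined rules are applied uniformly
across causes; demographic eligibility (e.g. maternal causes restricted to
women aged 12–49) ships as an editable CSV table
(`inst/extdata/cause_restrictions.csv`), data rather than code, and records
of unknown sex or age remain eligible everywhere so they are never silently
dropped.

## Redistribution of undetermined deaths

Undetermined deaths are reallocated **only at the population level** —
individual predictions are never edited. Within each (sex, age-group)
stratum the weight for cause $c$ averages two components:

$$ w_c = \lambda\, w^{\text{frac}}_c + (1-\lambda)\, w^{\text{ref}}_c,
   \qquad \lambda = 0.5 \text{ by default.} $$

$w^{\text{frac}}$ is the *undetermined propensity*: run the gold standard
back through the trained pipeline and count, per true cause, how often it
comes back undetermined (causes that are inherently hard to diagnose from
symptoms, such as pneumonia, pick up more of the undetermined mass). By
default this uses 5-fold cross-validation so each record is assigned by a
pipeline trained without it, avoiding resubstitution bias; an in-sample mode
exists for small databases. If nothing is ever undetermined the weights fall
back to uniform with a warning. The propensity is estimated globally (not
per stratum): per-stratum estimates would be extremely noisy at realistic
gold-standard sizes, and the stratum specificity enters through the second
component.

$w^{\text{ref}}$ comes from a reference age-sex cause distribution (GBD
style): the stratum's cause fractions renormalised over the causes the VA
cause list can assign. Unknown sex averages the male and female strata;
unknown age uses the all-age marginal (unweighted mean over age bins, since
the package does not model population denominators).

The averaging weight $\lambda$ is configurable because the published
description of the method says the two weights are "averaged" without giving
proportions; $\lambda = 0.5$ (unweighted mean) is the natural reading,
$\lambda = 1$ is pure propensity, $\lambda = 0$ pure reference. Mass is
conserved to $10^{-6}$ by construction and verified by test.

## CSMF estimation and uncertainty

The before-redistribution CSMF keeps undetermined as its own category; the
after-redistribution CSMF adds each cause's allocated fractional counts and
zeroes the undetermined row. Uncertainty is a percentile bootstrap over
deaths (`B = 1000` by default, seeded): each replicate resamples records
with replacement and redoes the stratified redistribution arithmetic, so
every replicate's fractions sum to 1 — conservation holds for the
uncertainty, not just the point estimate. The combined stratum weights are
fixed across replicates (they depend on the trained pipeline and the
reference, not on the resampled counts). Broad-group CIs reuse the same
replicate matrix, so cause and group intervals are mutually consistent. The
CI method is recorded in the table's metadata.

Population agreement is measured by chance-corrected CSMF accuracy,

$$ 1 - \frac{\sum_c |\text{true}_c - \text{pred}_c|}{2\,(1 - \min_c \text{true}_c)}, $$

the field-standard metric: 1 iff the distributions agree, 0 for the worst
possible prediction (all mass on the rarest true cause), invariant to
relabelling. The degenerate single-cause case (denominator 0) is defined as
1 when the prediction matches exactly.

## Plausibility assessment

The reference distribution is a modelled comparator, **not** a gold
standard, so the plausibility stage reports quantitative triggers and leaves
interpretation to the analyst:

* the age distribution of VA deaths per bin (12–19 through 80+, Unknown),
  with the index of dissimilarity ($\tfrac{1}{2}\sum|\Delta\%|$) against a
  reference age pattern;
* broad-group (communicable/maternal/nutritional, NCD, injury) fractions
  with a flag wherever the reference lies outside the VA 95% CI;
* the undetermined fraction (field programmes typically see roughly 5–20%,
  falling with interviewer experience) and the sex ratio;
* a ranking-stability check: whether the cause ordering is the same before
  and after redistribution is *verified* on each run, never assumed.

Registration-completeness assessment needs population denominators the
package does not model; the report prints an explicit placeholder asking for
an external estimate. Report generation is pure — identical inputs give a
byte-identical body — so reports diff cleanly across monthly batches.

## The synthetic-data generator

The generator defines the study conditions the package is validated under.
Each cause owns a disjoint block of `signature_size = 3` signature symptoms
endorsed with probability `signal = 0.95`; all other symptoms are endorsed
at `background_rate = 0.05`; symptoms are independent given cause. Defaults:
10 causes, 40 symptoms (30 signature, 10 pure noise), 500 gold-standard
deaths per cause, 5,000 field deaths, and a geometric-decay true CSMF
(`exp(-0.35 k)`, normalised — leading cause ≈ 30%, rarest ≈ 2%), chosen to
resemble the skewed cause distributions of real adult mortality rather than
an unrealistic uniform. Causes rotate through three demographic archetypes
(old-NCD, mid-age infectious, young injury, with male shares 0.45/0.50/0.70)
so age-by-cause gradients and the broad-group structure arise naturally; the
broad-group map follows the archetypes. The reference generator returns the
exactly truth-implied stratified distribution, optionally distorted by
seeded log-normal noise or by shifting a share of mass between broad groups
to build scenarios where the reference genuinely disagrees with the truth.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: symptom dependence within a cause (real symptoms
cluster in syndromes), overlapping symptom profiles between causes,
interviewer and recall error, free-text narratives, and secular change in
cause composition. Conditional independence makes the strong-signal setting
close to best-case for any endorsement-based classifier; the accuracy
figures from synthetic runs are a correctness check of the machinery, not a
field-performance claim. Published validation of the tariff method against a
physician-reviewed gold standard puts population-level CSMF accuracy near
77%; nothing at desk scale can reproduce that number because the underlying
database is restricted, which is exactly why the synthetic recovery property
is stated against the generator's known truth instead.

One consequence worth spelling out: in the deterministic limit
(`signal = 1, background = 0`) each signature symptom has one cause at rate
1 and all others at an identical 0, so the inclusive IQR across causes is 0
and the zero-IQR rule blanks the entire tariff column. That limit is
therefore only used to validate the generator's record patterns; pipeline
validation uses stochastic signal, where sampling jitter keeps the
cross-cause IQR positive and the signature tariffs large.

## Numerical choices and degenerate inputs

* Ages are integer years; bins are closed integer ranges (12–19 means
  $12 \le a \le 19$); fractional ages are floored; ages under 12 error (the
  adult questionnaire's floor, taken from the first reporting bin).
* Fewer than 3 causes error out of tariff training: the per-symptom
  median/IQR is degenerate below that.
* IQR = 0 columns are zeroed rather than producing infinities.
* Rounding ties go away from zero; truncation ties break by symptom order —
  both fully deterministic.
* Empty prediction sets abort aggregation; an all-undetermined set
  redistributes to exactly the combined weight vector.
* Every stochastic step (baseline resample, CV folds, bootstrap, generators)
  is seed-controlled; the batch pipeline stamps its outputs with the config
  hash and seed, and a rerun is byte-identical apart from timestamps.

## Problem sizes used in the shipped validation

The test suite validates modules on small handmade fixtures plus simulated
studies of 150–500 training records per cause and 300–5,000 field deaths;
the full-scale recovery property runs the default configuration (10 causes ×
500 training records, 5,000 field deaths) over five seeds, and the CI
sample-size contrast compares programmes of 612 and 10,000 deaths at
B = 500. These sizes are representative of small-to-mid VA programmes while
keeping the whole suite fast enough to run on every change.

## Known limitations

* Free-text narrative processing, child/neonate questionnaire modules, and
  physician-review workflows are out of scope.
* Garbage-code redistribution of physician-certified deaths is only counted
  (as an exclusion category in tallies), not modelled.
* The propensity weights assume the gold-standard symptom–cause relationship
  transfers to the field population; when it does not, redistribution is
  systematically biased in ways no internal check can detect — which is why
  the plausibility stage exists.
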