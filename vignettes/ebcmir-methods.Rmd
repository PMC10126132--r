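---
title: "Methods: qualitative exhaled-breath microRNA analysis with ebcmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qualitative exhaled-breath microRNA analysis with ebcmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebcmir)
```

## The problem

Exhaled breath condensate (EBC) carries trace amounts of airway microRNA —
far too little for reliable quantitative RT-qPCR, but enough for a
qualitative present/absent readout per microRNA when an intercalating-dye
(SYBR) assay is gated on both the cycle threshold (Ct) and the melt
temperature (Tm) of the product. `ebcmir` implements the full analysis chain
around that readout:

1. **Scoring** — well-level Ct/Tm records become binary microRNA calls.
2. **Topography** — a Hamming-distance permutation test asks whether EBC
   profiles resemble deep-lung profiles of the *same* person more than those
   of random people.
3. **Discrimination** — covariate-adjusted logistic regression per microRNA,
   and random-forest models quantifying what the microRNA panel adds to a
   clinical lung-cancer risk model.
4. **Simulation** — generators for qPCR plates, multi-tissue profile sets
   and case-control cohorts, so every stage can be exercised and validated
   without clinical data.

## Qualitative scoring

A well is called positive when it satisfies both gates simultaneously:
the melt temperature lies within `tm_tolerance` (default 1.5 °C, inclusive)
of the positive-control Tm for the primerset, and the Ct is strictly below
`ct_positive_max` (default 44, of 45 cycles run). Either a missing melt
curve or missing amplification forces a negative. A (sample, microRNA) pair
is positive when **at least one** replicate well is positive; the replicate
count is recorded so designs other than duplicates work unchanged.

Two boundary conventions deserve a note, since they are easy to get
backwards: the Ct gate is *strict* (`Ct = 44.0` exactly is negative) while
the Tm gate is *inclusive* (`|ΔTm| = 1.5` exactly is positive — only a
deviation *greater than* 1.5 °C disqualifies). Non-amplified wells are
encoded as missing Ct, never as `Ct = total_cycles`; the single exception is
the primerset-specificity contrast `specificity_delta_ct()`, where a
non-amplified condition is censored at `total_cycles` and the result carries
an explicit `censored` flag.

Delta-Ct normalisation (`delta_ct_matrix()`) uses the housekeeper
miR-423-3p by default. The temporal-stability regime (40 cycles,
housekeeper Ct cutoff 35) is expressed as
`scoring_config(total_cycles = 40, housekeeper_ct_max = 35)` rather than a
separate code path. Because the housekeeper is reported under both the
-3p and -5p arm labels in different places, either id is recognised when
excluding it from analysis panels; replicate Cts are averaged before
normalising, a choice the qualitative pipeline never depends on.

## The topography statistic

For two tissue types, the statistic is

$$S_H = \sum_i H(d_i, d_i'),$$

the sum over individuals of the Hamming distance between the individual's
binary profiles in the two tissues. Small values mean within-individual
similarity. Its null distribution is obtained by permuting the assignment
of one tissue's profiles to individual labels while holding the other
fixed; permuting both tissues independently gives the same distribution
after relabelling, so the one-sided permutation is used for efficiency.
The test is one-sided toward small $S_H$, and permuted values *equal* to
the observed one count against it (conservative tie handling).

Numerical conventions:

* With up to 7 usable individuals (5 040 relabellings) the test enumerates
  all permutations and reports the exact fraction; above that it uses
  Monte-Carlo draws (default 1 000) with the add-one estimator
  $(b+1)/(B+1)$, so the reported p-value can never be zero. The plain
  proportion is retained alongside.
* Missing calls are excluded pairwise per individual; `strict = TRUE`
  instead drops any individual with a missing call. An individual lacking a
  whole profile in either tissue is skipped and listed in the result.
* All permutations come from R's own Fisher–Yates `sample.int()` under a
  caller-supplied seed, so results are bit-reproducible.

Internally the test precomputes the cross-individual distance matrix
$D_{ij} = H(d_i, d_j')$ once; each permutation is then just a trace along a
permuted diagonal, which is what makes thousands of simulated tests cheap.

## Case-control discrimination

`fit_univariate_lr()` regresses case-control status on one binary microRNA
call, optionally adjusted for age, gender, smoking status
(never/former/current), pack-years, quit-years, and underlying lung disease
trichotomised into carcinogenesis-risk (COPD/fibrosis/inflammation/asthma),
granulomatous-airway (sarcoid/bronchiectasis) and none/other. Reference
levels are fixed (female, never-smoker, none/other) so coefficients are
comparable across runs. The reported p-value is the Wald p of the microRNA
term; the two columns of `run_panel_lr()` are the *unadjusted* and
*covariate-adjusted* model p-values — they are **not** multiple-testing
corrected values, which is why the adjusted column can be smaller than the
raw one. Separation is flagged (`unreliable`), never silently printed, and
a degenerate microRNA fails its own row without aborting the panel.
Pack-years and quit-years are zero (not missing) for never- and non-former
smokers, both in the models and in the generator.

The random-forest comparison follows the resampled-ROC design: for each of
`n_splits` (default 100) stratified 50/50 train/test splits, forests for
both feature sets are trained on the identical training half and score the
identical testing half; the per-split ROC AUCs form two samples compared by
a Welch two-independent-sample t-test, and the increment is reported in
percentage points. Two caveats are documented deliberately. First, the
t-test treats the 100 AUCs as independent although the splits overlap; the
result object therefore also carries a paired t-test on the per-split
differences as a sensitivity check. Second, tumour histology and stage are
case-only variables and hence label-leaking in a case-control model; the
clinical feature set excludes them by design (stage is still available to
`subgroup_view()`, which keeps all controls when filtering cases by stage).

Forests use 500 trees, the implementation default feature subsampling and
no class weighting (the cohort is near-balanced); these are configuration,
not tuning — nothing is ever adjusted on test data. Missing microRNA calls
are mode-imputed per column using the *training half only*, so no
information leaks into the testing half; logistic models instead drop the
affected subject for that microRNA. The engine is `ranger`, and every fit
receives a seed derived from the caller's master seed, making AUC vectors
bit-reproducible. AUC itself comes from `pROC` with an explicitly fixed
direction (cases score higher), so a worse-than-chance model is reported
below 0.5 rather than silently flipped.

## What the generators emulate — and what they do not

`generate_cohort()` reproduces the *marginal* clinical structure of a
351-subject bronchoscopy/surgery series: 166 cases / 185 controls, case and
control mean ages 66.93 and 56.40 years, smoking mixes
(current/former/never) of 43.4/47.6/9.0% versus 20.5/41.6/37.8%, mean
pack-years 43.43 versus 19.21 among ever-smokers and mean quit-years 7.33
versus 9.40 among former smokers. Dispersions are not part of those
marginals, so they are explicit parameters chosen once as realistic for
such a series: ages normal with SD 10 years; pack- and quit-years
gamma-shaped with coefficient of variation 0.8. The underlying-lung-disease
trichotomy is drawn from per-arm mixes obtained by summing the component
diagnosis rates and renormalising (diagnoses overlap, so the raw
percentages exceed 100%): approximately 67/3/30% in cases and 45/10/45% in
controls for risk/granulomatous/none. MicroRNA calls follow a per-microRNA
logistic model with control-arm prevalence 0.3 and a planted case odds
ratio of 2.5 on the miR-21, miR-33b and miR-212 analogues (1.0 elsewhere),
2% missingness completely at random. Covariate–microRNA confounding is off
by default so planted odds ratios stay interpretable; a
`smoking_mir_log_or` switch exists to stress-test the adjustment.

`generate_tissue_profiles()` gives each individual a latent binary lung
profile; each tissue copies each latent call with its concordance
probability and otherwise draws independently at the population prevalence.
The default concordances (EBC 0.9, BAL 0.9, MW 0.2, SP 0.1, BB 0.1) were
chosen once so that the *expected* similarity gradient of generated sets —
EBC–BAL strongly similar, EBC–MW weakly, EBC–SP/BB near chance — matches
the ordering the airway pilot sub-study reported; they are generator
parameters, not measured biology.

What the generators do **not** emulate: correlation between microRNAs,
covariate-driven microRNA presence (unless switched on), informative
missingness, batch or plate effects, and any sequence-level content.
Passing tests on this synthetic data therefore validate the *procedures* —
scoring rules, the permutation test's calibration and power, covariate
adjustment, leakage-free model comparison — not the clinical effect sizes,
which only the real (undeposited) cohort could speak to.

## Validation summary

The test suite checks, among others:

* scoring boundary behaviour and exact truth recovery on noiseless plates;
* $S_H$ against a brute-force double-loop oracle, and Monte-Carlo versus
  exhaustive p-values (within 0.02 at $B = 10{,}000$, $n = 5$);
* permutation-test level on 2 000 null profile sets (12 donors, 13
  microRNAs, $B = 999$) against the 99% binomial band around 0.05,
  super-uniformity of the null p-values at $\alpha \in \{0.05, 0.10\}$
  (the conservative tie convention can only *deflate* the rejection rate —
  with 13 binary markers the null $S_H$ distribution has sizeable atoms, so
  some deficit below nominal is expected by design), and power monotone in
  the planted concordance;
* logistic null calibration (600 null fits) and per-marker recovery of the
  planted odds ratios in 100 replicated cohorts;
* ROC AUC against the Mann–Whitney identity to $10^{-12}$ and the Welch
  test against its closed form to $10^{-10}$;
* a positive, significant combined-minus-clinical AUC increment in planted
  cohorts (50 runs of 100 splits), and no significantly positive increment
  when the 24 microRNAs are pure noise (200 null runs of 30 splits at a
  reduced forest size and cohort, sized to keep the suite fast).

Problem sizes in the heavy simulations (replicate counts, splits, trees)
were scaled to keep the default test run quick; the properties they check
are size-stable, and each test states its own sizes.

## Interface note

The package is used from R: the exported functions are the interface, and
`run_pipeline()` ties the stages together for a scripted end-to-end run,
writing per-stage CSV outputs, a MANIFEST and a JSON report that embeds the
exact configuration and seeds. `scripts/acceptance.R` in the source
repository recomputes the headline quantities from scratch for a given
seed.

## Known limitations

* The qualitative readout discards quantitative information by design; the
  package deliberately offers no ΔΔCt expression analysis for the clinical
  panel.
* The permutation test conditions on the observed profiles; with very few
  individuals its resolution is limited to multiples of $1/n!$, and the
  conservative tie convention makes it run somewhat below nominal level on
  small discrete panels.
* The resampled-AUC t-test inherits the optimism of treating overlapping
  splits as independent; the paired alternative is reported but the
  headline number keeps the conventional form.
* Mode imputation of missing calls is simplistic; with the low default
  missingness it is immaterial, but heavy missingness would warrant a
  proper missing-data model.
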