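---
title: "Methods: protein-source diversity, amino acid adequacy and survey weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-source diversity, amino acid adequacy and survey weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protdiv)
library(dplyr)
```

protdiv analyses protein nutrition in population dietary surveys built on
single 24-hour recalls, in the setting of the South-East Asian protein
transition: as incomes rise, plant protein from rice and legumes is
progressively complemented by animal protein from poultry, eggs, meat and
dairy, and the question is how the *diversity* of protein food sources
relates to protein and essential amino acid (EAA) adequacy across
socio-economic groups. This vignette documents the models and the design
decisions; the README shows the worked example.

## From recall rows to daily intakes

A recall is a set of (food, grams) rows per participant. Each food in the
food composition table (FCT) carries an energy density (kcal/100 g), a
protein density (g/100 g) and exactly one protein-source label from the
closed set {cereals, legumes, eggs, dairy, beef, pork, poultry, fish},
or the sentinel `non_protein_source` for foods counted for energy only.
Nutrient contributions are linear in amount. Composite dishes are entered
as one row per component; the package deliberately has no disaggregation
model for mixed dishes. Meats outside the eight categories (goat, mutton)
are folded into a category by a configurable alias map, defaulting to
beef, keeping the source set closed.

The study design this mirrors uses one recall day per person, so a second
recall day for the same id is an error, never an average: averaging would
smuggle in a usual-intake model the data cannot support. Protein from
non-source foods (vegetables, tubers) counts toward total protein and the
adequacy denominator but never toward the diversity score or the
animal/plant split, which are defined on the eight listed sources.

EAA intakes are reconstructed at the protein-source level: each source
has a profile of the nine EAAs (histidine, isoleucine, leucine, lysine,
threonine, tryptophan, valine, methionine+cysteine,
phenylalanine+tyrosine) in mg per g protein, and
`eaa[k] = sum_s protein_by_source[s] * profile[s, k]`. National FCTs in
this region list no amino acids, so a per-food reconstruction is not
possible; per-source profiles are the coarsest model consistent with
a source-resolved recall, and they are shipped as data
(`eaa_profiles_synthetic.csv`, representative values constructed from
typical published compositions of rice, soy, egg, milk and muscle
proteins) so users can substitute measured ones.

## Scores and adequacy

The **protein diversity score** counts the sources with any intake
(> 0 g/d); 0.001 g counts, which is the score's known weakness
(over-counting trace amounts) as much as its definition. The theoretical
range is 1-8 for anyone who ate a listed source; a zero score (protein
only from non-source foods) is retained and flagged rather than dropped.
Scores are analysed in four ordered strata, by default 1-3, 4, 5, 6-8:
the published four-group stratification does not state its cut-points, so
we chose the split that keeps all four groups populated in a population
whose mean score is near 4.8, and made it configurable.

The **protein requirement** is 0.83 g protein per kg body weight per day
(adult value), so a 60 kg adult requires 49.8 g/d. The **protein
adequacy ratio** is intake over requirement, dichotomised at 1 (primary)
and 0.7 (secondary), both with >= semantics.

Each **EAA adequacy ratio** divides intake (mg/d) by the adult
requirement in mg per kg body weight per day (2007 FAO/WHO/UNU adult
pattern: histidine 10, isoleucine 20, leucine 39, lysine 30, threonine
15, tryptophan 4, valine 26, SAA 15, AAA 25) times body weight. The
phrase "requirements given each individual's protein adequacy
requirements" admits a second reading — scaling a per-g-protein pattern
by the 0.83 g/kg requirement — but the per-kg × weight reading matches
the reference's units and is the default. The **MAR** is the arithmetic
mean of the nine ratios, dichotomised at 1. Classical MAR truncates each
ratio at 1 before averaging; the description we follow says only
"arithmetic mean of nine ratios", so ratios are untruncated by default
and `truncate_ratios = TRUE` restores the classical behaviour. Untruncated
ratios make the MAR interpretable as an average surplus/deficit but mean
a high ratio on one EAA can mask a shortfall on another — the per-EAA
ratios are always reported alongside.

## Socio-economic indices

The **wealth index** follows the DHS convention: thirteen asset/housing
variables (five categoricals one-hot encoded, eight 0/1 ownerships),
standardised; principal components with eigenvalue > 1 retained and
varimax-rotated; the first rotated factor's regression-method score is
the index, sign-oriented so car ownership loads positively. "Principal
component factor analysis with varimax rotation" is operationalised this
way because it is the most common reading of that phrase; retention rule,
rotation and scoring are all visible in one function for auditability.
The one-hot design is rank-deficient (complete dummy sets), so regression
scores use the pseudo-inverse via the PCA basis — identical to the
Moore-Penrose form. Scores are cut into weighted tertiles (T1 = least
wealth) with ties broken by stable row order for determinism.

**Urbanisation** maps (province, district class): urban districts of the
Java-island provinces (Jakarta, West Java, East Java) and Bali are
"urban", urban districts of West Sumatra and South Sulawesi "suburban",
everything else "rural". The **modernisation index** scores wealth
tertile (10/30/50), urbanisation (10/30/50) and number of children
(0-2: 50, 3-4: 30, 5+: 0) and sums, ranging 20-150; analysis strata are
weighted tertiles of the points by default because the published banding
is not stated, and a fixed banding can be supplied instead.

## Weighting and tests

**Post-stratification weights** equalise sample and population margins
over cells (urbanisation × sex × age group by default — whatever columns
the margins table shares with the sample): weight ∝ population share /
sample share, normalised to sum to n. Weighted margins then reproduce
population margins exactly; a sampled cell with no population mass is an
error, an unsampled population cell is dropped with a warning and the
shares renormalised.

Group comparisons use **frequency-weight semantics**, matching the
SPSS-style workflow this reproduces: the weighted one-way ANOVA
decomposes weighted sums of squares with df = (k−1, Σw−k) and reduces
exactly to the textbook F at unit weights; the chi-square test is
Pearson's on the weighted cross-tabulation. No design-effect or
cluster-robust correction is applied — a known limitation, inherited
deliberately from the analysis being modelled.

**Odds ratios** come from bivariate logistic regressions of an
inadequacy indicator on one categorical exposure, fitted by IRLS
(`stats::glm`, binomial family, convergence tightened to 1e-12) with
Wald 95 % intervals; with one categorical exposure and unit weights each
OR equals the contingency cross-product ratio, which the test suite
verifies to 1e-6 on random tables. The lowest-diversity stratum is
compared against the highest as reference. Separated levels (all-0 or
all-1 outcomes) are reported as flagged infinite sentinels, not errors.
Whether to weight the OR models is switchable (`weighted_or`), defaulting
to weighted.

## The synthetic survey

No microdata are deposited for the survey this package is built around,
so `simulate_survey()` generates a study-shaped dataset: n = 1665 adults
over six provinces sampled roughly equally with one urban and one rural
district each; a standard-normal latent wealth factor, shifted by
urbanicity, drives both asset ownership (logistic/ordered models) and
the consumption probability of animal protein sources; body weight is
normal by sex (62/55 kg, sd 10, truncated to 35-120 kg); the sampled age
distribution deliberately skews younger than the population margins so
the weighting step has real work to do.

The diet model consumes each source with a wealth- and urbanicity-
dependent probability and log-normal grams (male amounts ×1.17, the
ratio of the target energy means). Rice and legumes are near-universal
staples with no wealth terms, so plant protein is flat across the wealth
and diversity gradients; fish is common and wealth-flat; eggs, poultry,
beef and dairy rise with wealth; pork is negligible outside Bali and
dairy amounts are small everywhere. The gram medians were calibrated
once, by simulation, to the study conditions — weighted mean energy near
1678 kcal/d (men) and 1435 kcal/d (women), mean diversity near 4.8, and
mean protein near 59/51 g/d as a secondary guide — and then frozen; the
tests assert the ±5 % / ±0.3 calibration bands. With these defaults
about 45 % of participants fall below the protein requirement and the
MAR-inadequacy prevalence declines monotonically across diversity
strata.

What the generator does *not* emulate: intra-household correlation and
cluster sampling, portion-size measurement error, seasonal and weekday
effects, mixed dishes, and any joint distribution of the
socio-demographics beyond the margins stated above. Passing tests on
synthetic data therefore demonstrate the *pipeline's* correctness and
the qualitative SES-diet patterns, not findings about any real
population.

For parameter-recovery testing the generator has a calibration mode
(`adequacy_probs`): after recalls are drawn, each participant's amounts
are rescaled multiplicatively so that P(protein ratio < 1 | diversity
stratum) equals configured probabilities. Rescaling preserves which
sources are positive — the diversity score is untouched — so the implied
stratum-wise inadequacy odds ratio is a known truth the pipeline must
recover; the acceptance suite checks unbiasedness over 200 replicates at
n = 1665.

## Numerical choices and degenerate inputs

Tolerances: adequacy arithmetic is exact to floating point (tests at
1e-9); logistic fits converge at 1e-12 relative deviance, max 100
iterations. Tie-breaks: weighted tertiles assign ties by stable row
order. Degenerate inputs: an empty recall yields a zero-intake row with
a warning flag; an asset table with no variation yields a degenerate
all-T2 wealth index with a warning; a zero-variance asset column is
dropped with a warning; an all-zero diversity score is flagged
out-of-theoretical-range and placed in the lowest stratum. Missing
required participant fields cause complete-case exclusion before
weighting, with the excluded count reported in the run manifest.

## Problem sizes used in the test suite

Unit and property tests run on fixtures of 10-400 records; the
statistical acceptance checks run at the study's own scale — single runs
at n = 1665 for the structural and calibration checks, 200 replicates of
n = 1665 for parameter recovery, and 1000 random tables for the
odds-ratio identity.
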