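---
title: "Developing word-recognition literacy scales with wordlit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing word-recognition literacy scales with wordlit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordlit)
library(dplyr)
```

## The measurement problem

Word-recognition (pronunciation) tests are a standard rapid screen for print
health literacy: a person reads a list of domain words aloud, the
administrator marks each word correct (`+`) or not (`-`, covering
mispronounced, skipped after about five seconds, and never-attempted words),
and the sum of correct words is the score. `wordlit` implements the full
psychometric workflow for building such an instrument with multiple language
forms: expert content-validity screening, classical item analysis,
two-parameter logistic (2PL) item response theory, cross-language equating
and differential item functioning (DIF) tests, stratified short-form
selection, and convergent-validity / intervention-sensitivity analyses. A
seeded generator produces synthetic studies with the same statistical
structure, so every stage can be exercised and tested without access to any
participant data.

The canonical design the defaults encode is an 82-word diabetes vocabulary
split into three expert-assigned difficulty strata (29 low, 28 medium, 25
high) administered in English, Spanish and Korean to groups of roughly
261/128/245 respondents, with a two-arm longitudinal sub-study measured at
baseline and months 3, 6 and 12.

## Content-validity screening

Experts rate each candidate word's relevance on a 4-point scale; the item
content validity index (I-CVI) is the proportion rating 3 or 4, and items
with I-CVI above .80 are retained (`compute_cvi()`, Lynn's criterion); in
the canonical design this screening narrows a pool of 120 candidate words to
82. The same experts categorise difficulty into three levels;
`assign_difficulty()` uses the modal vote and resolves ties to the *medium*
stratum — no tie rule is canonical, and the middle category is the least
selection-distorting default because quota allocation is least sensitive to
it. An alternative mean-rating retention rule and an optional percentile
trim for words that are too easy or too hard relative to the pool are
provided as configuration — expert-retention criteria are sometimes phrased
as mean-rating rather than proportion rules, and screens for extreme words
rarely come with numeric cutoffs; no trim is applied by default.

## Classical test theory

`item_statistics()` reports each item's percent correct (difficulty; higher
means easier) and its *corrected* item-total correlation — Pearson
correlation with the rest-score, i.e. the total over the remaining items
(discrimination). The corrected form is the default because the uncorrected
version inflates every correlation by the item's own contribution; with 82
items the difference is small, and a switch provides the uncorrected
variant. `cronbach_alpha()` uses the variance decomposition
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_j s_j^2 / s_T^2\bigr)$ with $n-1$
variances. Alpha needs complete total scores, so rows with any missing
response are dropped there (listwise); per-item statistics use each item's
available responses (pairwise). On dichotomous data alpha equals KR-20, so
no separate code path exists.

## The 2PL engine

The response model is the two-parameter logistic,
$P(X_{ij}=1\mid\theta_i) = \text{logit}^{-1}\{a_j(\theta_i - b_j)\}$, with
discrimination $a_j$, difficulty $b_j$ and ability $\theta_i$. `fit_2pl()`
estimates items by Bock–Aitkin marginal maximum likelihood: abilities are
integrated out over a fixed N(0,1) prior on 61 equally spaced quadrature
nodes spanning $[-6, 6]$ (normal weights renormalised on the grid), and an
EM iteration alternates expected per-node counts with a safeguarded Newton
maximisation of each item's expected complete-data log-likelihood (compiled;
step-halving keeps the update monotone, a bounded quasi-Newton cleans up any
item left off a stationary point). Choices, all exposed as arguments:

* **Parameterisation** $a(\theta - b)$ rather than slope–intercept, because
  equating operates on $b$ directly.
* **Bounds** $a \in [0.05, 6]$, $b \in [-6, 6]$; estimates on a bound are
  flagged `boundary`. Items answered all-correct or all-incorrect carry no
  information and are excluded as `excluded_degenerate`.
* **Convergence**: maximum parameter change $< 10^{-4}$ and relative
  log-likelihood change $< 10^{-7}$, at most 500 EM cycles.
* **No prior on $a$** by default (pure MML); a log-normal penalty is
  available for very small samples.
* **Standard errors** from the outer product of per-person scores of the
  marginal likelihood (BHHH), per-item 2×2 blocks.

Fixing the latent scale through the N(0,1) prior makes refits bit-for-bit
reproducible. `eap_scores()` returns posterior-mean abilities on the same
grid; a person with no scored responses gets the prior (0, 1) back, flagged.

## Cross-language comparison

Forms in different languages are calibrated separately and placed on a
common metric by mean/sigma equating (`mean_sigma_equate()`):
$A = s_{b,\text{ref}}/s_{b,\text{focal}}$,
$B = \bar b_{\text{ref}} - A\,\bar b_{\text{focal}}$, $b' = Ab + B$,
$a' = a/A$, which forces the focal difficulties to match the reference mean
and standard deviation exactly and leaves every item response function
unchanged under $\theta' = A\theta + B$. Equating uses difficulty moments
only (not characteristic-curve criteria) because moment matching is the
stated goal of the rescaling.

DIF is tested per item with the IRT likelihood-ratio method
(`dif_test()`): a constrained two-group 2PL holding every item equal across
groups is compared against a model freeing the studied item's $(a_j, b_j)$,
with all other items anchoring the metric in both fits and the focal group's
ability mean and variance estimated (reference fixed at N(0,1)), so genuine
group ability differences are not mistaken for DIF. The statistic is
referred to $\chi^2_2$. A model freeing *all* items in both fits is not
identified (the focal metric would be undetermined), which is why anchoring
is required. Benjamini–Hochberg adjustment across items is the default
flagging rule — dozens of simultaneous tests need multiplicity control —
with raw p-values always reported. Anchor purification (one pass) is off by
default: at a few hundred persons per group it adds instability for little
gain. `difficulty_separation()` summarises stratum difficulty structure via
$(\bar b_\text{high} - \bar b_\text{low+med})/s_\text{pooled}$, the index
used to contrast deep-orthography forms (distinct high stratum) with
shallow-orthography forms (compressed).

## Short-form selection

The item-reduction procedure plots item-total correlation against percent
correct, fits a mean curve through the scatter with a cubic smoothing
spline (`fit_mean_curve()`; `stats::smooth.spline` with generalized
cross-validation, falling back to a fixed 4 effective degrees of freedom
below 15 points, where GCV is unreliable), and prefers items *above* the
curve: better discrimination than expected at their difficulty.
`allocate_quotas()` preserves the full scale's difficulty distribution by
largest-remainder apportionment — floor the proportional share, then hand
leftover seats to the largest fractional remainders (ties resolved in
stratum order low, medium, high). For sizes (29, 28, 25) this produces
exactly (14, 14, 12) at length 40 and (7, 7, 6) at length 20 —
largest-remainder is the standard apportionment that reproduces this nested
pair. `select_items()` ranks candidates within stratum by residual above the
curve (ties: higher item-total correlation, then earlier bank position —
documented and deterministic), restricts to a percent-correct window
(default 5–95%, configurable; no numeric bounds are canonical, so the window
is configuration), and fills quotas top-down, flagging any stratum that needed
below-curve items. Passing the 40-item result as `parent` restricts the
20-item search to those items, giving nested forms; candidates are
restricted but statistics are not recomputed. Selection is driven by the
reference language, after which `multi_language_review()` recomputes each
selected item's residual under every other language's curve and lists
below-curve items for review — advisory only, no automatic swaps, matching
the staged procedure in which the English form led and the Spanish and
Korean forms informed later rounds.

## Validity and sensitivity

`convergent_validity()` computes pairwise-complete Pearson correlations
between form scores and external criteria with
$t = r\sqrt{(n-2)/(1-r^2)}$ two-sided p-values.
`sensitivity_analysis()` reproduces the intervention-evaluation layout: per
timepoint, mean percent score and standard error overall and per arm; the
baseline row reports the raw between-arm gap, and each follow-up reports the
between-arm difference in mean change from baseline with a Welch two-sample
test on person-level change scores (stars at .05 and .01). No single
inferential model is canonical for this table layout; Welch on change
scores is the transparent default, and the estimates rather than the
p-values are the quantity of interest.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all values are generator
configuration, chosen once to mirror the described structure qualitatively,
never estimates of real data:

* **Bank**: strata (29, 28, 25); placeholder word tokens per language.
* **Truth**: discriminations $a \sim U(0.8, 2)$ shared across languages. In
  *separated* (deep-orthography, English-like) mode, low/medium difficulties
  draw from N(−0.7, 0.5²) and high from N(+1.3, 0.4²), a clearly harder
  high stratum. *Compressed* (shallow-orthography) forms move each stratum's
  centre toward the grand mean by factor λ (default 0.5) while keeping
  within-stratum spread, so the standardized separation genuinely shrinks;
  λ = 1 reproduces the separated difficulties exactly.
* **Responses**: $\theta \sim N(\mu, \sigma^2)$ per language group (default
  standard normal; group sizes 261/128/245), responses Bernoulli draws from
  the 2PL.
* **DIF**: explicit per-item shifts (`dif_spec`), so tests can verify that
  flagged items are exactly the shifted ones.
* **Longitudinal**: person ability $\theta_i + \delta_{\text{arm}}(t) +
  \varepsilon_{it}$, $\varepsilon \sim N(0, \tau^2)$ with $\tau = 0.3$; the
  default drift gives the intervention arm +0.45/+0.35/+0.5 logits at months
  3/6/12 against a flat control, which maps to roughly a ten
  percentage-point score gain — the magnitude the instrument is meant to
  detect.
* **Covariates**: $\rho\theta + \sqrt{1-\rho^2}\,z$ with loadings 0.5
  (functional-literacy proxy), 0.5 (education, discretised to 4 levels) and
  0.3 (disease knowledge) — moderate positive convergent correlations.

Everything is a deterministic function of the seed. What the generator does
*not* emulate: pronunciation phonetics and orthographic depth beyond the
single compression parameter, item-level guessing, administration-order
effects, dropout, and real covariate distributions. Tests passing on this
generator therefore demonstrate that the algorithms recover known structure
under the model's own assumptions — not that any particular real population
satisfies those assumptions.

## Numerical choices and verification scale

Problem sizes used by the test-suite and the acceptance script were chosen
to verify each claim at the scale it concerns while keeping full runs
routine on a single core: parameter recovery at n = 1000 persons × 40
items; DIF null calibration over several hundred replicates at n = 300 per
group and 20 items, with power replicates at n = 500 per group; sensitivity
recovery at 500 persons per arm. Cronbach's alpha is checked against a
brute-force variance-of-sums oracle to machine precision; EAP scores against
a 10×-resolution quadrature oracle; the EM solution against coordinate-wise
likelihood grids; and the EM log-likelihood trace is asserted non-decreasing
on every run.

Degenerate inputs are handled explicitly rather than silently: perfect
items are excluded and flagged before calibration, constant items report
percent correct but an undefined item-total correlation, a zero-variance
total score makes alpha undefined (flagged), equating refuses item sets
that disagree or focal difficulties with zero spread, and empty
administrations score zero but are flagged when a whole row is missing.

## Known limitations

* Only the 2PL is implemented — no 1PL/3PL or graded models, and no MCMC.
* The DIF suite offers only the likelihood-ratio test (no Mantel–Haenszel,
  logistic-regression or SIBTEST variants) and the joint 2-df test, without
  a uniform/nonuniform decomposition.
* BHHH standard errors are a first-order approximation; they ignore
  cross-item information and can understate uncertainty for boundary items.
* Results from real administrations cannot be reproduced here because no
  participant-level data are distributed; the synthetic studies validate
  the machinery, not any particular sample.
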