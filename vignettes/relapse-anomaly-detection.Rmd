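---
title: "Detecting relapse periods in social-media timelines by one-class anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting relapse periods in social-media timelines by one-class anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relapsewatch)
```

## The problem and the modelling stance

Psychotic relapse is rare relative to time spent relatively well, and every
relapse can look different — even within one person — while healthy posting
behavior is comparatively stable. That asymmetry makes ordinary binary
classification awkward (severe class imbalance, heterogeneous positive
class) and motivates the one-class stance taken here: learn the boundary of
*healthy* posting from health periods only, and flag anything outside it as
a potential relapse period. Under this convention health is the positive
(inlier) class, so **sensitivity** measures how often health is recognized
and **specificity** measures how often relapse is caught; clinically the
emphasis falls on specificity.

The unit of analysis is the *period*, a half-open date interval
`[start, end)` labelled `relapse` or `health`:

* the study window runs from the day of the first hospitalization to the day
  of the most recent relapse admission; a participant with a single
  admission has no relapse and is excluded;
* the 30 days before every subsequent admission are a relapse period,
  clipped so the window never reaches back into the previous inpatient stay;
* everything else — minus inpatient days, by default — is cut into maximal
  healthy runs, and each run is tiled left-to-right with fixed-length health
  periods (30, 60 or 90 days); a trailing remainder shorter than the
  granularity is dropped so that all health periods of one configuration
  have identical length.

"One month" is fixed at 30 days everywhere. Calendar months vary in length,
which would make period features subtly incommensurable; a fixed 30-day
month keeps rates and proportions comparable across periods and
configurations. Timestamps are treated as participant-local wall-clock
times and never timezone-converted, because the diurnal features below only
make sense on the local clock.

Two degenerate-input rules worth stating: events exactly on a period's start
date belong to it, events on the end date do not (half-open convention,
applied uniformly); and a missing discharge date is imputed as
admit + 13 days — the cohort's median inpatient stay — and flagged, rather
than dropped.

## Features

**Psycholinguistic categories.** Tokens are lowercased maximal runs of
letters, digits and apostrophes; URLs and @-handles are stripped first. Each
lexicon category is a word list whose entries are literals or prefix
patterns (`hate*`), the classic dictionary-lookup mechanism; a category's
feature is the fraction of the period's pooled tokens matching it. Pronoun,
tense and function-word classes are closed-class word lists inside the same
lexicon — no POS tagging. The shipped mini-lexicon (36 categories, roughly
10–30 entries each) is a small open stand-in for proprietary dictionaries;
`load_lexicon()` accepts a full user-supplied dictionary in the same
format. Period text is pooled before counting (not averaged per post):
social-media posts are short enough that per-post proportions would be
dominated by quantization noise.

**Structural measures.** Readability is Flesch Reading Ease with a
vowel-group syllable heuristic (any standard readability index would serve;
Flesch is the most widely reported and needs no external resources);
repeatability is `1 − distinct/total` tokens; word length is mean characters
per token. All three are 0 on empty text rather than undefined.

**Unigram usage.** "Word usage" features are proportions over the top-*k*
unigrams (default *k* = 200) of the *training* periods — the vocabulary
never sees held-out data, which would otherwise leak test information into
the feature space. Frequency ties break lexicographically so the vocabulary
is deterministic.

**Behavioral rates.** Events of each kind (status, comment, share, like,
photo, check-in, friending, co-tagging, app use — plus a derived co-tagging
family that also counts tagged statuses/photos) are counted overall and per
diurnal bin, then normalized to a 30-day equivalent. The bins are morning
[05:00, 12:00), noon [12:00, 17:00), night [17:00, 22:00) and midnight
[22:00, 05:00); morning and midnight boundaries follow the windows in which
significant pre-relapse activity shifts are reported, and noon/night are
chosen to complete the partition symmetrically. Normalization matters: raw
counts scale with period length, so an unnormalized model comparing 30-day
relapse windows against 60- or 90-day health periods would simply learn
period length.

## Screening and selection

The exploratory screen pairs, per participant, one uniformly drawn relapse
period with one health period and applies a paired Wilcoxon signed-rank test
per feature. Zero differences are discarded (the classic convention; Pratt's
treatment is deliberately not used), tied absolute differences receive
mid-ranks, and the statistic is W+, the rank sum of positive differences.
Up to 25 effective pairs the two-sided p-value is exact — the null
distribution of W+ is built by convolution over the doubled (hence integer)
ranks, equivalent to enumerating all 2^n sign assignments — and beyond that
a normal approximation with tie correction and continuity correction takes
over; the two agree to within 0.01 at the crossover. One draw per
participant (not all pairs) keeps the pairs independent across participants,
which the signed-rank test assumes. p-values are reported raw, with
Benjamini–Hochberg q-values available as an option.

Feature selection uses the coefficient of variation, `sd/|mean|` per feature
across training periods (0 by convention for zero-mean columns). The default
rule retains a feature iff its CoV lies within one standard deviation of the
mean CoV across features — i.e. it *eliminates* the dispersion outliers in
both tails. This is the literal reading of the published procedure, but note
that under typical CoV distributions it retains most features (~70–90%); a
reduction to ~13% of features, as reported for the original cohort, would
require keeping only the *outlying* CoVs, so the inverted rule is provided
as `mode = "keep_outside"`. Both modes are deterministic and recomputable
from the returned report. Selection and the subsequent z-standardization use
training inliers only.

## The one-class models

The base model is a ν-parameterized one-class SVM (RBF kernel by default).
ν = 0.1 bounds the fraction of training inliers rejected; it is a project
default chosen so that roughly one health period in ten is sacrificed to
tighten the boundary.

The kernel width γ defaults to the **median heuristic**: γ = 1 / median of
pairwise squared distances among training rows. The more common
`1/(p·Var(x))` rule ("scale") is also available, but on this feature space —
standardized, high-dimensional, with many sparse zero-inflated columns such
as rare-category proportions and per-bin rates of rare activities — it
over-sharpens the kernel: the model then memorizes training points and
rejects 2–4× ν of *held-out* inliers drawn from the same distribution. The
median heuristic restores the calibration that makes ν interpretable (on
null synthetic cohorts, held-out inlier rejection stays within ±0.08 of ν;
this is asserted in the test suite).

The ensemble is a bagging construction: 25 members, each a one-class SVM fit
on a seeded 80% row subsample (without replacement) and 70% feature
subsample; a point is an inlier iff the fraction of members voting inlier
strictly exceeds 0.5, and an exact tie is an outlier. The tie-break
direction favors flagging relapse, consistent with the emphasis on
specificity. These ensemble hyperparameters are this package's documented
reconstruction — the original supplement describing them is not available —
and they follow standard bagging practice for subspace ensembles.

Training uses 90% of health periods; the remaining 10% plus *all* relapse
periods form the test set. The held-out count uses round-half-up, which is
what reproduces the published held-out sizes 72/42/31 from 719/421/312
inliers. The default split is period-level (a participant's periods may land
on both sides, as the published period counts imply); participant-level
grouping is available to measure the leakage this choice admits.
`reconstruct_counts()` rebuilds integer confusion matrices from printed
rates and class counts with the same rounding convention, which is how the
package verifies the published PPV/NPV values and the 45-false-negative
error-analysis count without any patient data. (The published table's
predictive values for the 1-month row reconcile with 71 held-out inliers
while the stated split yields 72 — an internal inconsistency of one period
in the source reporting; the reconstruction accepts either, and the
error-analysis count requires 72.)

## The synthetic cohort generator

`generate_cohort()` produces the inputs the analysis assumes, plus a truth
log (hospitalization dates, planted relapse-window intervals, realized
per-window event counts, the multiplier map) so that segmentation and
effect-recovery can be tested exactly.

Per participant: 2–4 hospitalizations (an approximation of the reported
average of 2.4 relapse admissions per participant) spaced Uniform(90, 300)
days apart — wide enough that every gap yields several 1-, 2- and 3-month
health periods; a 13-day inpatient stay; and a Poisson event stream at 2
posts/day over a 720-day follow-up. Post text is drawn token-by-token: with
per-category emission probabilities of the order seen in social-media text
(function-word classes ~1–5%, topical classes ~0.2–1%), a token comes from
that category's word list, otherwise from a neutral filler vocabulary that
is filtered against the lexicon at run time so fillers never collide with a
category. Inside each pre-relapse window the configured multipliers scale
category emissions (swear, anger, death, hear, feel and pronouns up;
work, friends, health, achievement, body down), the co-tag/friending share
of events, and the midnight diurnal weight, each renormalized — multiplicative
effects are the simplest mechanism that is monotone in effect size and
faithful to the reported directions. All randomness flows from one seed;
the same seed reproduces the cohort bit-for-bit.

What the generator does *not* emulate: real language (tokens are exchangeable
draws, so there is no syntax, topic drift or code-switching), per-participant
heterogeneity in posting style, platform dialect quirks, comment threads, or
gradual prodromes (the planted shift is a step function at the window edge).
Consequently, passing tests demonstrate that the pipeline recovers planted
structure of the assumed form — they say nothing about effect sizes or
operating points on real archives, where the published specificity of 0.71
(rather than the ~0.85–0.9 typical on these synthetic cohorts) is the more
realistic anchor.

## Test problem sizes and numerical conventions

The test-suite property checks run at deliberately modest sizes: 50 random
cohorts of 4 participants for the segmentation partition/conservation
invariants; 20 seeds at the generator's default scale (50 participants) for
null calibration of held-out rejection; one 40-participant null cohort with
~290 features for p-value uniformity (Kolmogorov–Smirnov distance < 0.1);
20 seeds of 60 participants for screen-based recovery of ×3 planted
effects; and 20 seeds × 4 multiplier levels of 25-participant cohorts for
the monotonicity of ensemble specificity in effect size. Exact oracles
(sign-flip enumeration for the Wilcoxon test, hand-computed CoV examples,
brute-force confusion-matrix round-trips) are checked to 1e-12.

Other conventions: proportions over empty token lists are 0; repeatability
of a single token is 0; sample (n−1) standard deviations throughout;
CoV uses |mean|; columns with zero training sd standardize to 0; undefined
evaluation rates (empty denominators) are reported as `NA`, never 0.

## Limitations

Relapse is operationalized as hospitalization, which misses exacerbations
managed without admission and inherits the multifactorial nature of
admission decisions; the fixed 30-day window is a convention, not a clinical
boundary, and real prodromes vary in length; tokenization and the lexicon
are English-centric; and the CoV selection rule's direction cannot be
settled from the available description (see above). The pipeline makes
global, not per-participant, boundaries — "personalized" prediction here
means per-period prediction for an individual from a model trained on the
cohort's healthy behavior.
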