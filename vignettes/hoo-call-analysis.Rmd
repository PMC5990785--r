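---
title: "Classifying context-specific hoo call variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying context-specific hoo call variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoovar)
```

## The problem

Wild chimpanzees produce quiet "hoo" calls in at least three behavioural
contexts — rest, travel and alert (a hidden threat such as a snake). The
scientific question is whether the three variants are acoustically
distinguishable, and which acoustic properties carry the contextual
information. Two statistical obstacles shape the whole analysis:

1. **Repeated measures.** Field recordings yield many calls per caller,
   unbalanced across contexts (some callers appear in one context only).
   Naive discriminant analysis would partly classify caller identity, and
   its permutation test would be wildly anti-conservative.
2. **Observational confounding.** Different observers, using different
   recording devices, recorded different contexts: in the emulated design
   one observer recorded essentially all alert bouts and the other all
   travel bouts. Any acoustic effect of observer or device therefore rides
   along with context.

The package addresses the first problem with a *crossed permuted
discriminant function analysis* (pDFA) and the second with Gaussian linear
mixed models (LMMs) that estimate context effects while controlling for
observer, device, sex and age.

## Acoustic measurement

A call is represented by its fundamental-frequency (F0) contour (sample
spacing at most 0.01 s) and, optionally, framewise spectra (256-point
analysis of 44.1 kHz audio, 0.05 s Gaussian window, 1000 frames per call
by default). `measure_call()` computes: call duration; maximum F0 (with
the earliest attaining sample on ties); start and end F0 as the **median**
of contour samples in the first/last 0.05 s — the window statistic is a
design choice, chosen for robustness to edge jitter; F0 drop
(max − end); slope steepness (drop divided by the time from the maximum to
the call end, defined as 0 for flat contours so the function is total);
peak frequency as the maximum-amplitude bin in the single frame nearest
the maximum-intensity time; and the positions of maximum F0 and peak
frequency as proportions of call duration. Calls shorter than 0.1 s have
their edge windows truncated at the midpoint, with a warning.
Inter-call intervals are offsets-to-onsets gaps within an unbroken
same-type bout.

## Variable screening

Nine candidate predictors enter screening: duration, start/end/maximum F0,
F0 drop, slope steepness, the two position variables and the inter-call
interval. (Peak frequency in Hz is measured and stored but serves only to
derive its position.) Transformations are applied first: natural log for
duration, maximum F0 and position of maximum F0; square root for F0 drop,
position of peak frequency and the interval. The position variables are
also described as untransformed in part of the original methods text;
`default_transforms("untransformed")` supports that reading, and the
default follows the annotations of the published loading table, since
those reflect the variables as they entered the analysis.

Screening is two-stage (`screen_correlations()`): pairs with Pearson
|r| > 0.7 are resolved by discarding one member — preferentially a member
of a configurable victim list defaulting to slope steepness and start/end
F0, otherwise the member with the larger mean absolute correlation —
and the survivors must all have variance inflation factors below 2,
largest-first removal otherwise. In the pipeline the pairwise rule runs
once over **all** calls on the eight single-call candidates; the interval
then joins the retained set and only the VIFs are re-checked over the
interval-bearing calls. Re-running the pairwise rule on the two-context
bout subset would mistake context separation (pooled between-group
correlation) for collinearity.

## The crossed pDFA

Callers contributing calls to every analysed context are *eligible*; the
training set is exactly one uniformly chosen call per eligible caller per
context, so every context contributes the same number of training calls
and no caller dominates. Linear discriminant functions are fitted to the
training calls (`fit_lda()`: pooled within-group covariance with divisor
N − g, coefficients from the whitened between/within eigenproblem, scaled
to unit within-group score variance), and **all** remaining calls — the
held-out calls of training callers and every call of the other callers —
are classified by the Gaussian equal-covariance posterior. Because one
random selection is arbitrary, the observed rate is the mean over 100
selections (default).

The null distribution permutes context labels **within callers**,
preserving each caller's label multiset and hence all caller-level
structure; each of the 10 000 permutations (default) is evaluated with one
fresh balanced selection. The choice of one selection per permutation
(rather than re-averaging 100 selections inside every permutation) is a
deliberate design decision: permutation variance dominates selection
variance, and the million-fit alternative buys nothing. The p-value is the
add-one estimator (1 + #{null ≥ observed})/(1 + m), never exactly zero.
Eligibility is computed once from the observed labels; since the shuffle
conserves per-caller context counts, it is permutation-invariant (the code
asserts this on every draw).

With the full selection average the observed statistic has smaller
variance than each single-selection null draw, which makes the test
mildly conservative, never liberal. The calibration experiment in the test
suite therefore runs with one selection for the observed statistic too,
making observed and null draws exchangeable under the null and the
p-value exactly uniform up to ties in the discrete rate; it uses a
doubled roster so the rate grid is fine enough for tie effects to be
small. Measured rejection at nominal 0.05 falls within [0.02, 0.09] over
200 replicate null tables.

Two analyses are run: the three-context analysis on the five retained
single-call variables, and a travel/alert analysis that adds the
inter-call interval (rest hoos are nearly always single calls and carry no
interval; interval-less calls are excluded, mirroring the original
exclusion of single calls and unmeasurable bouts).

## Context mixed models

For each influential variable (maximum F0 and duration over all 271
calls; inter-call interval over the travel/alert bout calls) the package
fits `response ~ context + controls + (1 | caller)` by **maximum
likelihood** (not REML — the likelihood-ratio tests compare models
differing in fixed effects), with treatment contrasts and alert as the
reference context. Controls are sex, age, observer and device; the
interval model uses only sex and age, because observer and device separate
almost completely from context once rest calls are gone. Significance of
the context effect is the full-versus-null LRT on a central chi-square
(identical random structure in both models, so no boundary correction),
Bonferroni-gated at 0.05/3 ≈ 0.017 with a strict inequality. The
fixed-effects design is rank-checked before fitting; aliasing is an
explicit identifiability error, never a silent column drop. Model
stability is assessed by refitting with each caller excluded
(`stability_check()`); changes are scaled by the larger of the estimate's
magnitude and a tenth of the response SD so near-zero estimates do not
explode the ratio, with a 50% default influence threshold.

The mixed model is what disentangles observer from context: the pDFA
cannot (and should not) — any acoustic consequence of the observer
allocation is classifiable signal to it. The package's confound-scenario
generator exists precisely to demonstrate, by simulation, that the LMM
context estimates remain unbiased under the study's allocation as long as
at least one context is shared between observers (complete confounding is
detected by a rank check and warned about).

## The synthetic generator

`synthetic_truth()` / `generate_feature_table()` emulate the study design:
29 callers (14 males: 9 adult, 5 subadult; 15 females: 11 adult, 4
subadult) with unbalanced per-context call counts totalling 271 calls
(alert 40 / rest 137 / travel 94), 11 callers present in all three
contexts; rest hoos single calls in 134/137 cases while travel (79/94) and
alert (38/40) hoos come in bouts, with 5 intervals unmeasurable — all
allocated by exact quota so the design counts are reproduced exactly at
the default roster. Observer allocation (alert → CC, travel → TG, rest
split) and device-given-observer probabilities reproduce the
observer-by-context imbalance.

Continuous variables are Gaussian **on the transformed scale** — so the
LMM stage's assumptions hold by construction — with context, observer,
device and sex effects set to the published fixed-effect estimates
(e.g. log duration: rest +0.63, travel −0.28 versus alert; log maximum
F0: rest −0.31, travel −0.42; intercepts −1.62 and 5.74). Between-caller
and residual SDs are not published anywhere; they are plausibility choices
(duration 0.15/0.40, maximum F0 0.08/0.17 on the log scale), calibrated
once so that the generator reproduces the reported *data properties*:
start/end F0 correlate above 0.7 with maximum F0, slope steepness is
collinear with F0 drop (log-scale correlation above 0.7; its raw-scale
Pearson correlation fluctuates across seeds because slope is untransformed
and heavy-tailed, but screening removes it in either case via the pair
rule or the VIF stage), and the six retained variables keep VIF < 2.
Inter-call gaps are Gamma (shape 2 — positive and right-skewed) with
per-context means matching the published interval contrast and a
log-normal caller factor. Derived fields are constructed to satisfy the
record invariants exactly (end F0 = max − drop; event times = position ×
duration).

`generate_call_bout()` additionally produces measurable signals: rise–fall
piecewise-linear F0 contours snapped to the 5 ms sampling grid with the
peak kept clear of the 0.05 s edge windows, and harmonic-stack spectra
whose per-frame power is normalized to a smooth envelope — both choices
exist so the generator can state the *exact* value every measurement
should recover (edge-window medians analytically, peak frequency to one
FFT bin, times to one sampling step). `bout_audio()`/`write_wav()` render
bouts as deterministic 16-bit 44.1 kHz PCM.

What the generator does **not** emulate: real chimpanzee voice quality,
individual vocal signatures, pitch-tracking noise, or any dependence
between a caller's acoustics and its age beyond the configured linear
terms. Passing tests therefore demonstrate that the *statistical
machinery* behaves correctly under the study's design and the stated
effect structure — not that the numbers from any particular field data set
are reproduced.

## Numerical choices and problem sizes

* Covariance condition number above 1e10 in `fit_lda()` is a degeneracy
  error naming the collinear variables; there is no silent ridge.
* Posterior ties in classification break to the first context in declared
  order and are flagged.
* A single master seed drives everything; selections, permutations and
  generator components use independently derived child streams, so
  changing one count never reshuffles another. A pipeline run is a pure
  function of (input, config, seed).
* Derived-field consistency checks on file input use a tolerance of 1e-6
  in the variable's units.
* The test suite runs the full pDFA at 100 selections × 1000 permutations,
  the type-I calibration at 200 replicate tables × 200 permutations, and
  the recovery experiments at 200 mixed-model replicates; the shipped
  defaults (100 × 10 000) match the original analysis and run in about a
  minute per analysis.

## Known limitations

* The LDA is strictly linear with a shared covariance; no quadratic or
  shrinkage variants, and no nested (caller-level) pDFA designs.
* The interval model's identifiability depends on the observer allocation;
  fully confounded allocations are refused rather than estimated.
* Start/end F0 medians are a reading of an underspecified manual
  procedure; the package documents, rather than claims to reproduce, the
  original cursor-based measurements.
* With two contexts, pooled correlations between strongly separated
  variables are large by construction; collinearity decisions are
  therefore made on the full data, never on a two-context subset.
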