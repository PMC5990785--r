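# hoovar

Repeated-measures classification and mixed-model analysis of
context-specific chimpanzee "hoo" call variants.

Wild chimpanzees produce quiet hoos when resting, when initiating or
during travel, and when alerting others to hidden threats. Whether these
are acoustically distinct call variants is a repeated-measures problem:
many calls per caller, unbalanced across contexts, recorded by different
observers on different devices. This package implements the full analysis
chain for that problem, for bioacousticians and behavioural ecologists
working with any comparable call data set:

* **Acoustic measurement** (`measure_call`, `inter_call_intervals`) from
  F0 contours and framewise spectra: duration, start/end/maximum F0,
  F0 drop, slope steepness, peak frequency, event positions, inter-call
  intervals.
* **Transformation and collinearity screening** (`apply_transforms`,
  `screen_correlations`): log/sqrt transforms, pairwise |r| > 0.7
  resolution, variance inflation factors below 2.
* **Crossed permuted discriminant function analysis** (`run_pdfa`). A
  linear DFA is trained on a balanced subset — one random call per
  eligible caller per context, eligible meaning the caller appears in
  every context — and all remaining calls are cross-classified. The
  observed rate averages 100 such random selections. Significance comes
  from a permutation null that shuffles context labels *within* callers
  (10 000 permutations), preserving every caller's label multiset:

  observed rate = mean over selections of P(correct | held-out calls),
  p = (1 + #{null ≥ observed}) / (1 + n_perm).

* **Gaussian linear mixed models** (`fit_lmm`, `context_lmm`, `lrt`):
  `response ~ context + sex + age + observer + device + (1 | caller)`,
  fitted by maximum likelihood, with full-vs-null likelihood-ratio tests
  of the context effect, Bonferroni control at 0.05/3 ≈ 0.017, and
  leave-one-caller-out stability checks. The mixed models are what
  separate context from the observer/device confound that the
  classification analysis cannot address.
* **A synthetic call generator with ground truth** (`synthetic_truth`,
  `generate_feature_table`, `generate_call_bout`): emulates the study
  design (29 callers, 271 calls, observer-by-context imbalance, bout
  structure) with known effects, for calibration and recovery testing —
  including audio rendering of synthetic bouts.
* **One-call orchestration** (`run_pipeline`) from a config object or
  YAML/JSON file, writing JSON results, CSV screening reports and a
  Markdown report. A thin CLI wrapper ships in `inst/scripts/pdfa.R`.

## Worked example

Generate a study-like synthetic table, screen the single-call variables,
and run the three-context pDFA and a duration mixed model:

```r
library(hoovar)
tab <- generate_feature_table(synthetic_truth(seed = 42))$table
vars <- setdiff(candidate_variables(), "inter_call_interval_s")
fm <- apply_transforms(feature_matrix(tab, vars))
scr <- screen_correlations(fm)
print(scr)
#> screening: retained 5 of 8 variables (|r| <= 0.7, VIF < 2)
#>   discarded: f0_start_hz, f0_end_hz, slope_steepness_hz_per_s
#>   duration_s                 VIF 1.064
#>   f0_max_hz                  VIF 1.069
#>   f0_drop_hz                 VIF 1.022
#>   pos_f0max                  VIF 1.043
#>   pos_peakfreq               VIF 1.028

fm <- subset_variables(fm, scr$retained)
run_pdfa(fm, config = pdfa_config(n_selections = 100,
                                  n_permutations = 1000, seed = 42))
#> crossed pDFA over {rest, travel, alert}
#>   observed cross-classification: 80.8%
#>   permutation-expected:          33.1%
#>   p = 0.000999  (1000 permutations, 100 selections)
#>   per-context:  rest 77.6%, travel 86.0%, alert 79.8%
#>   calls: 33 training, 129 held-out, 109 novel (11 eligible callers)

context_lmm(fm, lmm_spec("duration_s"))
#> LMM for duration_s (ML, random intercept per caller, n = 271)
#>   full vs null: chi^2 = 195.43, d.f. = 2, p = 3.66e-43  (significant at Bonferroni 0.017)
#>   (Intercept)            beta =  -1.787  se =  0.133  t = -13.40
#>   contextrest            beta =   0.669  se =  0.086  t =   7.81
#>   contexttravel          beta =  -0.309  se =  0.108  t =  -2.87
#>   ...
```

Reading the output: held-out and novel-caller calls are classified to
the correct context 80.8% of the time against a within-caller permutation
baseline of 33.1% (chance for three contexts), with the add-one
permutation p at its minimum for 1000 permutations. The mixed model
recovers the planted context effects on log duration (rest hoos longer,
travel hoos shorter than alert) with the context LRT far below the
Bonferroni threshold. The generator's 33/129/109 training/held-out/novel
split reflects the emulated study design: 11 of 29 callers contribute
calls to all three contexts.

The full pipeline, end to end:

```r
run_pipeline(pipeline_config(input = list(type = "synthetic", seed = 1),
                             seed = 1, out_dir = "results"))
```

or from a shell, for a CSV call table with the canonical columns:

```sh
Rscript inst/scripts/pdfa.R --input calls.csv --out results --seed 1
```

## Vignette

`vignettes/hoo-call-analysis.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
design choices (tie-breaking, degeneracy thresholds, seed policy).
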