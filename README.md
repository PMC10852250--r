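# sensbias

Decomposing self-evaluation bias under sequential evaluative feedback.

## The problem

People revising a self-evaluation `a` (on a 1–100 scale) after receiving a
feedback `f` tend to move a fraction of the way towards it:

    a[t+1] = a[t] + h(a[t]) * (f[t] - a[t])

where `h` is the *sensitivity to feedback*. Two distinct mechanisms bias the
long-run self-evaluation:

* **Self-enhancement** — reacting more strongly to positive than to negative
  feedback (`h_p > h_n`); with the opposite asymmetry, self-derogation.
* **Bias from decreasing sensitivity** — even with perfectly symmetric
  reactions, if `h` *decreases* in `a` (`h' < 0`), a balanced pair of
  opposite feedbacks `±δ` leaves the agent slightly higher than it started:
  the downward step happens at a higher `a`, where sensitivity is lower.
  To second order the drift is `S(a) ≈ −h'(a) h(a) δ²` for either order of
  the pair, and `−h'(a) h²(a) var(θ)` under random mean-zero feedback noise
  θ. It is purely statistical: no motivation involved.

The package implements the full chain used to detect and separate these
biases in a balanced-feedback experiment:

1. **Protocol simulation** (`simulate_cohort`): synthetic participants get an
   anchor (low `[15,40]` w.p. 1/3 / high `[60,85]` w.p. 2/3), then four
   feedbacks `f_t = a_t ± δ ± ε` (δ = 13, ε = 1) in one of the six balanced
   sign sequences, responding between their previous evaluation and the
   feedback; feedbacks truncated at the 1–100 bounds flag the series for
   exclusion.
2. **Result treatment** (`rank_to_score`, `filter_excluded`,
   `subset_frame`): map decreasing-scale (rank) values to `100 − r`, drop
   unbalanced series, and build subsets by trust, time-step range, scale,
   gender, self-esteem or interview time.
3. **Sensitivity regressions** (`fit_sensitivity`,
   `fit_sensitivity_mixed`): OLS of the realized sensitivity
   `|a[t+1] − a[t]| / δ_t` on `a_t/100` — slope `c`, intercept `b` — for
   all/positive/negative feedbacks, plus an lme4 random-intercept variant
   for sets spanning ≥ 3 time steps.
4. **Bias decomposition** (`decompose_bias`), all in percent of the feedback
   intensity:
   * total bias `B = mean_i (a_5 − a_1) / (½ Σ_t δ_t) × 100`,
   * self-enhancement `E = mean[(c_p−c_n) a_t/100 + b_p−b_n] × 100`,
   * measured sensitivity bias `S = B − E`,
   * its closed-form estimate `S' = mean[−c_m (c_m a_t/100 + b_m) δ_t]`,
     with `c_m, b_m` the averages of the positive/negative fits.
5. **Uncertainty** (`bootstrap_participants`, `bootstrap_triples`,
   `effect_size`): 200-sample bootstrap, resampling whole participants so
   series-level measures stay computable, and effect sizes
   `s = |m₁ − m₂| / σ₁`.

## Worked example

```r
library(sensbias)

co <- simulate_cohort(cohort_config(n_participants = 1500), seed = 42)
co
#> <cohort> 1500 participants, 6000 triples (91 flagged for exclusion)

fr <- filter_excluded(rank_to_score(sample_frame(co$triples, co$participants)))
#> removed 91 participant(s) with truncated feedback series

hi <- subset_frame(fr, trust = c(7, 10), timesteps = 1:4)
fit_sensitivity(hi)
#> <sensitivity_fit ols/all> h(a) ~ 0.6485 -0.1002 * a/100  (n = 2116, p[slope] = 4.8e-08)
fit_sensitivity_mixed(hi)
#> <sensitivity_fit lmer/all> h(a) ~ 0.6394 -0.0846 * a/100  (n = 2116)

cmp <- subset_frame(hi, require_complete_series = TRUE)
decompose_bias(cmp)
#> <bias_estimates> (percent of delta; n = 2116 triples, 529 participants)
#>   B  total bias            :  -1.926
#>   E  self-enhancement      :  -2.478
#>   S  = B - E (measured)    :   0.552
#>   S' (theoretical)         :   0.844

bo <- bootstrap_participants(cmp,
  list(S = function(f) total_bias(f) - enhancement_bias(f)),
  n_samples = 200, seed = 7)
bo$S
#> <bootstrap_summary S> mean = 0.544, sd = 0.2764 (200 participant-level samples)
```

Reading: the fitted slope is significantly negative (sensitivity declines as
self-evaluation rises). The cohort's default configuration mixes a mild
rank-condition self-enhancement with a stronger score-condition
self-derogation, so `E < 0` overall; the decreasing-sensitivity bias
`S ≈ 0.5–0.8%` of the feedback intensity is positive and distinguishable
from zero (bootstrap sd ≈ 0.28), and the closed-form `S'` agrees with the
measured `S` within the combined bootstrap error.

## Command line

```sh
Rscript -e 'sensbias::sensbias_main()' simulate --out data --seed 7
Rscript -e 'sensbias::sensbias_main()' validate --data data
Rscript -e 'sensbias::sensbias_main()' analyze  --data data --out results --seed 7
```

`simulate` writes `triples.csv`, `participants.csv` and a `manifest.json`
(config, seed, checksums); `analyze` writes slope tables by trust interval ×
time-step range (OLS + mixed model), per-step slopes, and the bias
decomposition with bootstrap summaries (`analysis.json`); `validate` reports
invariant violations and exclusion counts. JSON configuration keys mirror
`cohort_config()` arguments.

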