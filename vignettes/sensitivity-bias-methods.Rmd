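---
title: "Models and methods: separating self-enhancement from the decreasing-sensitivity bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensbias)
```

## The update model

An agent holds a self-evaluation $a_t$ on a 1–100 scale and receives a
feedback $f_t$. The update is proportional to the gap:

$$a_{t+1} = a_t + h(a_t)\,(f_t - a_t),$$

with $h$ the *sensitivity to feedback*, a positive function of the current
self-evaluation. The model's central assumption is that $h$ is
**decreasing**: agents who already evaluate themselves highly are less
influenced by further evaluation. This is the constant-source special case
of a more general two-agent influence model; we deliberately implement only
this case (the source of feedback is fixed, as in the experiment the
package emulates).

Curves are parameterized as $h(a) = b + c\,a/100$ (`linear_curve`), so the
**slope convention** is: $c$ is the change of sensitivity per unit of
*normalized* self-evaluation $a/100$, and the derivative per raw unit is
$c/100$. Every closed-form formula in the package uses the raw-unit
derivative internally. A `logistic_curve` family is provided to probe
non-linearity; a `constant_curve` is the degenerate control.

### Two bias mechanisms

**Self-enhancement** is an asymmetry of reactions: sensitivity $h_p$ to
positive feedback differs from $h_n$ to negative feedback. At
self-evaluation $a$ and intensity $\delta$ the induced change is
$E(a) = (h_p(a) - h_n(a))\,\delta$ (`enhancement_at`); negative values are
self-derogation.

**The decreasing-sensitivity bias** needs no asymmetry. After a balanced
pair of feedbacks $+\delta$, $-\delta$ (either order), the exact net change
is $(h(a_1) - h(a_2))\,\delta > 0$ whenever $h$ is positive and decreasing:
the downward step is taken from a higher self-evaluation, where sensitivity
is lower, so it does not fully undo the upward step. The second-order
expansion gives

$$S(a_1) \approx -h'(a_1)\,h(a_1)\,\delta^2,$$

which is *exact* for linear curves (`pair_bias_exact` vs
`pair_bias_first_order`). Under random mean-zero feedback noise
($f_t = a_1 + \theta_t$) the expected drift after two feedbacks is
$-h'(a_1)\,h^2(a_1)\,\overline{\theta^2}$ (`random_bias_theory`), checked
against a brute-force Monte-Carlo oracle
(`simulate_random_feedback_series`). For balanced four-feedback series with
asymmetric curves, averaging the four order-specific cross terms yields
$-h_m'\,h_m\,\delta^2$ with $h_m = (h_p + h_n)/2$ (`avg_pair_bias`).

Analytic formulas always use the *unclipped* curve (the derivations assume
a smooth $h$); simulation clips realized sensitivities to $[0,1]$, because
the emulated protocol forces responses between the previous evaluation and
the feedback.

### Numerical note

The pair bias is a difference of two $O(h\delta)$ updates, so computing it
as $a_3 - a_1$ loses up to $\sim 10^{-14}$ absolute to cancellation around
$a \approx 50$. `pair_bias_exact` therefore accumulates the per-step
*increments*; agreement with the closed form is then at the $10^{-12}$
relative level whenever the bias is not itself vanishing. A second pitfall:
for the logistic family the first-order error is $O(\delta^3)$ with
coefficient $\propto h''$, and the logistic inflection sits at the
midpoint — testing the $\delta^3$ decay at the midpoint would measure the
$O(\delta^4)$ term instead (ratio 16, not 8, on halving). The tests probe
$a = 65$ with midpoint 0.5.

## The emulated protocol

`simulate_cohort` reproduces the experiment's structure exactly:

* **Anchor** $f_0$: integer uniform on $[15, 40]$ with probability $1/3$,
  on $[60, 85]$ with probability $2/3$ (the high-anchor condition is
  over-sampled because the sensitivity decline is expected mainly there).
* **Sequences**: one of the six orderings of two positive and two negative
  feedbacks, uniformly (`feedback_sequences`).
* **Feedbacks**: $f_t = a_t \pm \delta \pm \epsilon$ with $\delta = 13$,
  $\epsilon = 1$; the jitter is an equiprobable fair draw each step (the
  protocol only requires that it avoids too-regular series). Values
  leaving $[1, 100]$ are truncated and flag the participant's series as
  unbalanced; `filter_excluded` later removes such participants entirely.
* **Responses**: the latent curve evaluated at $a_t$ plus Gaussian noise on
  the sensitivity scale, clamped to $[0,1]$, then rounded
  (half-away-from-zero) to the integer on-screen scale — responses never
  leave the closed interval between $a_t$ and $f_t$, by construction.
* **Scales**: behavior is simulated on the increasing (score) scale;
  rank-condition participants have recorded values mirrored to $100 - v$,
  and `rank_to_score` undoes the mirror at analysis time. Simulated ranks
  therefore live in $[0, 99]$; the real instrument's rank 101 edge
  ($\mapsto -1$) is clamped to 0 with a message, since the transform is
  not defined for it.

### Choices the protocol does not specify

* **First self-evaluation**: participants are told the anchor is their
  evaluation and know nothing else, so $a_1$ = anchor + $N(0, 5)$ rounded
  and clamped to $[1,100]$. The sd of 5 is a package default (a plausible
  spread for "restate a number you were just shown").
* **Interview time**: log-normal around 7 minutes (median ≈ 420 s, log-sd
  0.55), so a realistic minority falls under the 3-minute
  attention filter.
* **Trust**: uniform integers 0–10, independent of behavior by default.
  With `trust_coupling = TRUE` the common slope interpolates linearly from
  $-0.04$ at trust 0 to $-0.20$ at trust 10, reproducing the qualitative
  trust gradient of the reported slope tables.
* **Group-level defaults** (explicitly *not* measured quantities): base
  curves $b = 0.65$, $c = -0.12$; participant-level random intercept sd
  0.1 shared by $h_p$ and $h_n$; response noise sd 0.15; enhancement
  offsets $+0.05$ (rank scale), $-0.10$ (score scale), $\pm 0.02$ by
  gender, $0.03\,(\mathrm{SE}-3)$ by self-esteem. These produce the
  qualitative pattern the human data showed — decreasing mean sensitivity,
  rank-condition enhancement, score-condition derogation, slightly higher
  male/high-self-esteem enhancement — at plausible magnitudes.

What a green test on this generator establishes is **internal
consistency**: the estimators recover what the generator put in, at the
design's sample sizes. It does not establish anything about human
behavior; features of real data that the generator does not emulate
include participant-specific *slopes*, non-linear individual sensitivity,
attention loss at the fourth step, and any dependence of trust on the
experienced feedback series.

## Result treatment

Given a frame of triples $(a_t^i, f_t^i, a_{t+1}^i)$ joined to covariates:

1. **Sensitivity regressions** (`fit_sensitivity`): OLS of
   $|a_{t+1}^i - a_t^i| / \delta_t^i$ on $a_t^i/100$, over all, positive
   or negative feedbacks, giving $(c, b)$, $(c_p, b_p)$, $(c_n, b_n)$.
   The absolute value relies on the protocol constraint that responses
   never overshoot the feedback; violating rows are rejected upstream by
   validation. Slope p-values are two-sided (the star convention used in
   reports does not state sidedness; two-sided is the conservative R
   default).
2. **Mixed model** (`fit_sensitivity_mixed`): the same regression with a
   participant random intercept, fit by ML via lme4, restricted to frames
   spanning ≥ 3 time steps. Random intercept only: the reference analysis
   is not fully specified on this point, a random slope is weakly
   identified with ≤ 4 observations per participant, and the pooled and
   mixed slopes are expected (and observed) to be close anyway. No
   p-value is reported for the mixed slope.
3. **Bias measures**, all in percent of feedback intensity:
   $B$ (net change over complete series, normalized by half the summed
   intensities), $E$ (fitted asymmetry averaged over triples, ×100),
   $S = B - E$ (exact by construction), and the closed-form
   $S' = \mathrm{mean}[-c_m(c_m a_t/100 + b_m)\,\delta_t]$. The unit
   harmonization is worth spelling out: the $E$ sum is a fraction of
   $\delta$ (so ×100), while the $S'$ summand is the raw second-order
   drift divided by $\delta_t$ and multiplied by 100 — the surviving
   factor $\delta_t$ in the formula is exactly that conversion.
4. **Bootstrap**: 200 samples by default (doubling to 1000 moves means
   and sds by ≲ 20% on reference frames, which we consider sufficient —
   and test). Triple-level resampling serves measures defined on
   arbitrary row sets; measures needing complete series ($B$, hence $S$)
   are refused there and use the participant-level scheme, which redraws
   whole participants with all four triples (a drawn participant is
   relabeled per draw so duplicated clusters stay distinct). Effect sizes
   $s = |m_1 - m_2| / \sigma_1$ take $\sigma_1$ from the *first* set —
   the definition is asymmetric and kept that way; when group order is
   not obvious, report both orderings.

### Interpreting $S$ vs $S'$ on synthetic data

With exact intensities (no $\pm\epsilon$ jitter) and no response noise,
$S$ and $S'$ agree to a fraction of a percent, the residual being the
higher-order trajectory effect, which shrinks linearly as $\delta$ is
reduced. The $\pm\epsilon$ jitter adds per-participant noise of order
$h \cdot 2\epsilon / (2\delta) \approx 5$ percentage points to individual
$B$ terms: on realistic cohort sizes this sampling noise — not expansion
error — dominates the observed $S - S'$ gap, which is why the agreement
criterion is stated against the combined bootstrap error.

## Exclusion rule

"Series too close to the bounds" is operationalized as *any truncated
feedback*: truncation is the mechanism that breaks the balanced design,
and it is detectable from the data ($\delta_t \notin \{\delta-\epsilon,
\delta+\epsilon\}$). A pre-computed `truncated`/`excluded` column is
honored when present (for externally deposited data whose exclusion flags
were computed upstream). At the default configuration this removes ~6–9%
of participants, consistent with the design's ~30% over-recruitment
margin for all loss sources.

## Known limitations

* The generator's covariate effects are additive intercept shifts; it
  cannot express, e.g., trust affecting only $h_n$.
* `fit_sensitivity` treats triples as exchangeable within the frame; the
  mixed model corrects only the intercept-level clustering.
* Four observations per participant make individual curves unidentifiable
  by design; all estimates are set-level averages, and subset comparisons
  are descriptive (no multiple-testing correction, mirroring the
  reference treatment).
* The CLI's `analyze` computes the bias decomposition only for subsets
  spanning all four time steps; $S'$ remains available for shorter
  ranges through the API.
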