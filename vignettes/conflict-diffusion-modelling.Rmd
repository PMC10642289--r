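---
title: "Conflict diffusion modelling of flanker-task data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conflict diffusion modelling of flanker-task data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

In a flanker task, a central target is accompanied by distractors that call
for the same (congruent) or the opposite (incongruent) response. The
congruency effect (CE) — slower and less accurate responding on incongruent
trials — arises from the interplay of target- and distractor-driven response
activation over time. The diffusion model for conflict tasks (DMC) captures
this interplay in a single Wiener diffusion process between two absorbing
boundaries, $+b$ (correct) and $-b$ (error), with diffusion constant
$\sigma$ and time-varying drift

$$\mu(t) \;=\; \mu_t \;+\; \frac{d}{dt}\,E[X_d](t),$$

the superposition of a constant, controlled target drift $\mu_t$ and the
derivative of the expected automatic distractor activation

$$E[X_d](t) \;=\; A\, e^{-t/\tau}
  \left(\frac{t\,e}{(a-1)\,\tau}\right)^{a-1},$$

a rescaled gamma density that rises to its single maximum $A$ at
$t_{\text{peak}} = (a-1)\tau$ and then decays to zero. On congruent trials
the distractor term is added with positive sign (it initially pushes toward
the correct boundary), on incongruent trials with negative sign. This form
is the standard one for the model family: it is the unique rescaling of the
gamma density for which the amplitude parameter is exactly the peak value
and the peak sits at $(a-1)\tau$, so with the conventional $a = 2$ the scale
$\tau$ can be read directly as the peak time of distractor influence.

The starting point is drawn from a symmetric beta$(\alpha_s, \alpha_s)$
distribution rescaled to the open interval $(-b, b)$; observed RT is the
first-passage time plus a normally distributed residual (nondecision) time
with mean $\mu_r$ and SD $\sigma_r$.

Three parameters are held at the conventional fixed values throughout:
$\sigma = 4$, $\alpha_s = 3$ and $a = 2$. The six estimated parameters and
their search ranges are

| parameter | meaning | units | bounds |
|---|---|---|---|
| $\mu_t$ | target drift rate | evidence/ms | 0.1–1.5 |
| $A$ | distractor peak amplitude | evidence | 0–40 |
| $\tau$ | distractor timing (peak time for $a=2$) | ms | 1–500 |
| $b$ | decision boundary | evidence | 20–100 |
| $\mu_r$ | mean residual time | ms | 200–500 |
| $\sigma_r$ | SD of residual time | ms | 5–50 |

## Numerical choices in the simulator

`simulate_condition()` integrates the process by Euler–Maruyama with step
`dt = 1` ms: $X(t+dt) = X(t) + \mu(t)\,dt + \sigma\sqrt{dt}\,\varepsilon$.
The drift is evaluated at step midpoints $t = (s + 0.5)\,dt$. Besides being
the usual second-order-accurate choice for a smoothly varying drift, this
keeps $t$ strictly positive: the distractor drift has a finite limit at
$t \to 0^+$ only for $a \ge 2$ and diverges for $1 < a < 2$, so the
left-endpoint rule would be undefined on the first step.

Walks not absorbed within `t_max_decision = 5000` ms are flagged
`nonresponse` rather than forced to a boundary — mirroring the behavioural
"too slow" category, these trials are removed by the exclusion stage.
Responses slower than the 2000 ms deadline are `too_slow`, faster than the
150 ms floor `too_fast`. Negative residual draws are redrawn until
nonnegative; with $\mu_r \ge 200$ and $\sigma_r \le 50$ the truncated mass
is below $3\times10^{-5}$, so the distortion is negligible. The error
boundary is placed symmetrically at $-b$.

## The fitting target and G²

`summarize_observed()` reduces each congruency's included trials to the two
conventional summaries: six CDF bins of correct RTs induced by the
percentile cuts at 0.1, 0.3, 0.5, 0.7, 0.9, and a five-bin conditional
accuracy function (CAF) over all included trials with bin edges at the
sample's quintiles. All quantiles in the package use type-7 linear
interpolation; the convention is applied uniformly (deciles, CAF edges,
CDF cuts) since nothing in the method depends on the particular type.

`g2()` evaluates the likelihood-ratio statistic

$$G^2 = 2 \sum_{\text{congruency}} \Bigl[\, \sum_{j=1}^{6} n_j
  \ln\frac{p_j}{\hat p_j} + \sum_{b=1}^{5} n_b \Bigl( pc_b
  \ln\frac{pc_b}{\hat{pc}_b} + (1-pc_b)
  \ln\frac{1-pc_b}{1-\hat{pc}_b} \Bigr) \Bigr],$$

where hats denote proportions of a model-simulated trial table computed **in
the observed cut points and bin edges**. Re-quantiling the predictions would
make the statistic insensitive to location shifts; using the observed cuts
is also what makes $G^2(\text{obs}, \text{obs}) = 0$ exactly. Predicted
proportions entering a log denominator are floored at the simulation's
resolution, half a count ($1/2m$ for a proportion estimated from $m$
simulated trials). The floor matters: the model predicts near-ceiling
accuracy in the slow CAF bins, so a finite simulation returns a predicted
proportion of exactly 1 with appreciable probability, and a hard constant
floor (e.g. $10^{-10}$) then adds tens of spurious $G^2$ units exactly at
good parameter values — a bias that systematically drives the fitted
distractor timing $\tau$ up its trade-off ridge with $A$. The half-count
continuity correction removes this pathology while leaving the
perfect-prediction identity exact. A predicted CAF bin that receives no
simulated trials contributes an uninformative predicted accuracy of 0.5
(this occurs only for pathological parameter sets that the search discards
anyway).

## Fitting, the model ladder and BIC

The object-membership manipulation can in principle act on target strength
($\mu_t$), distractor strength ($A$) or distractor timing ($\tau$); the
boundary and residual parameters cannot produce a condition-specific CE and
are always shared. `model_spec()` therefore spans the power set of
$\{\mu_t, A, \tau\}$ — eight models from $M_0$ (nothing varies between the
two object conditions) to $M_{\mu_t+A+\tau}$.

`dmc_fit()` fits one specification **jointly** to both object conditions by
minimising the summed G² — equality constraints on shared parameters are
only enforceable in a joint fit. The optimizer is a standard differential
evolution (DE/rand/1/bin; population $10\times$ dimension, crossover 0.9,
mutation factor dithered in (0.5, 1)), with the conventional stopping rule:
terminate when the last 50 iterations have not reduced the best G² by at
least 1%, or after 500 iterations (the fitting examples in this package use
a reduced 150-iteration budget). Each candidate is scored on freshly
simulated trials (default 2,000 per congruency and condition), which makes
the objective stochastic. A common-random-numbers option
(`de_options(crn = TRUE)`) scores every candidate on one fixed noise
substream instead; it reduces optimizer chatter at the cost of conditioning
the fit on that substream, and is off by default.

The search cannot, even in principle, place the distractor parameters
precisely: at 2,000 simulated trials per cell the Monte-Carlo noise floor
of G² is far larger than the true G² differences along the $(A, \tau)$
trade-off ridge, so where the population settles on that ridge is
arbitrary. `dmc_fit()` therefore finishes with a final-selection stage at
`n_sim_final` (default 10,000) simulated trials: every candidate evaluated
during the search is archived; the best archived candidates, plus a
coarse-then-fine grid over $(A, \tau)$ spliced into the best vector, enter
a two-round tournament in which all scores are *paired* — every candidate
is evaluated on the same fixed noise substreams, so simulation noise
largely cancels out of score differences — and the leaders are separated
with three-fold more paired evaluations. The reported parameters are the
tournament winner's; reported G² values come from fresh evaluations at the
winner.

BIC bookkeeping: with $k = 6 + |\text{free}|$ estimated values in total,
each condition's BIC is $G^2_c + k \ln N_c$ with $N_c$ that condition's
included trial count, and models are ranked by the mean across conditions.
Attributing the full $k$ to each condition is a deliberate convention: in a
joint fit all estimated parameters co-determine each condition's solution,
and a penalty that did not grow with model size would make the ladder
ranking equivalent to raw G² comparison, defeating the purpose of BIC.

## The synthetic cohort generator

No raw behavioural data ship with the package, so `generate_cohort()`
emulates the study design: congruency × object membership within
participants, 112 trials per cell, 2000 ms deadline, 150 ms floor, 40
participants. Group-level means default to the reference parameter rows in
`dmc_defaults()` — fits in which only $\mu_t$ differs between object
conditions (e.g. Experiment 1: $\mu_t$ 0.58/0.62, $A$ 13.8, $\tau$ 249 ms,
$b$ 74.5, $\mu_r$ 408 ms, $\sigma_r$ 38 ms). Participant-level parameters
are drawn independently per parameter from truncated normals with a 15%
coefficient of variation; parameters in the effect structure (default:
$\mu_t$ only) are drawn per condition, all others once per participant. The
published dispersion of the intercept effect (a 9 ms mean difference with
$d_z \approx 0.44$ implies an SD of roughly 20 ms across participants) is
reproduced well by this choice.

Under these defaults cohorts land in the realistic regime — mean correct RT
around 520 ms, 3–5% choice errors, essentially no deadline violations —
without any further calibration.

What the generator does **not** emulate: stimulus-level structure (line
types, displays, block order), response-key mappings, practice and fatigue
effects, contaminant processes (fast guesses, attentional lapses), and
parameter covariance across participants. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline recovers the structure the
generator puts in, under realistic trial counts and noise — not that real
data are free of the omitted complications.

A note on effect sizes: group-mean fitted parameters understate individual
condition effects (the mean of per-participant fits is not the fit of the
mean data). With the reference rows as generating truth, the $\mu_t$
difference of 0.04 produces a mean delta-function intercept difference of
only ~2.5 ms — much smaller than the ~9 ms dissociation reported for the
empirical data. Property tests of the signature dissociation ("intercepts
move, slopes do not") therefore use a $\mu_t$ contrast sized to the
reported intercept effect ($\mu_t$ 0.48 vs 0.67, other parameters at the
reference row; calibrated so cohorts show the reported ~9 ms intercept
difference, $d_z \approx 0.44$), so that a 40-participant cohort has the
power the published analysis had. Direction-only checks keep the reference
contrast.

## Distributional analyses

RT delta functions (`delta_function_rt()`) difference the nine deciles of
correct incongruent and congruent RTs; `delta_regression()` fits a line to
the nine CE values against the per-decile mean RT centred at the
participant's mean RT, so the intercept is the predicted CE at that mean RT
and the slope the CE growth per ms of response slowness. The centring RT
defaults to the participant's mean correct RT over the two congruency cells
entering that delta function (the most local reading of "mean RT across
conditions"); any other centring value can be passed explicitly, which
covers the grand-mean variant. CAFs bin each congruency by its **own**
quintiles (the standard construction); pooled edges can be supplied via the
`edges` argument of `caf()`.

## Behavioural statistics

`cell_summaries()` computes PC over all included trials and mean RT over
correct trials only. `paired_t()` adds $d_z$; an all-zero difference vector
is reported as $t = 0$, $p = 1$ (no evidence, not an error), while a
constant nonzero difference — zero variance with a nonzero mean — is a
degenerate input and raises an error. `rm_anova()` delegates to
`stats::aov()` with the participant error strata and adds partial eta
squared; all factors in the emulated designs have two levels, where
sphericity holds exactly, so no sphericity correction is implemented — a
documented limitation for designs with factors of three or more levels.
`within_subject_se()` implements participant-mean centring with the
$\sqrt{C/(C-1)}$ bias correction.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely from
simulation, at sizes chosen to keep each property sharply testable while a
full run stays comfortably interactive: recovery checks simulate 10,000
trials per congruency and condition and refit with the 2,000-trial /
150-iteration search budget; the model-selection smoke check uses five
replicate synthetic participants at 224 trials per cell with a
common-random-numbers search at a reduced budget and a 2 ms integration
step for both generation and fitting (a small search budget cannot drive a
stochastic objective close enough to its optimum for BIC differences to
reflect model structure, so the smoke check fixes the simulation noise);
cohort-level properties use 40-participant cohorts at the study's 112
trials per cell, pooled across replicate cohorts where a single-cohort
direction check would be underpowered. The one-percent/50-iteration
stopping rule and all seeds are fixed in the scripts, so every reported
number is reproducible.

## Known limitations

- Estimation is simulation-based throughout; no closed-form first-passage
  densities are provided, and fitted G² values carry Monte-Carlo noise of a
  few units at the default evaluation sizes.
- The distractor amplitude $A$ and timing $\tau$ are recovered to roughly
  ±35% at 10,000 trials per cell with the reduced search budget (target
  drift and the nuisance parameters to a few percent) — the quantile/CAF
  summaries simply carry limited information about the distractor pulse,
  and the G²-optimal $(A, \tau)$ of a finite data set can itself sit 15%
  or more from the generating values. Reference fits of the same data at
  different simulation sizes shift these two parameters by comparable
  amounts. Conclusions about distractor strength or timing should rest on
  condition contrasts, not point values.
- The eight-model ladder at realistic single-participant trial counts (224
  per condition) operates near the resolution limit of BIC for small
  $\mu_t$ effects; selection-consistency checks use larger simulated trial
  counts, and cohort-level inference (paired tests on per-participant
  estimates) is the more sensitive instrument, as in the motivating
  analyses.
- Time-varying target drift, single-process spotlight models and race-model
  alternatives are out of scope.
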