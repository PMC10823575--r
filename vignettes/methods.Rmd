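---
title: "Methods: response bias, informed-prior Bayes factors, and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response bias, informed-prior Bayes factors, and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardbf)
```

# Scope

`rewardbf` implements the full analysis chain of a registered crossover study
of reward responsiveness under active versus sham excitatory prefrontal
stimulation (iTBS): a probabilistic learning task (PLT) quantifies each
participant's drift toward the more frequently rewarded stimulus, and the
analysis asks whether stimulation moves that drift, using informed-prior
Bayes factors as the primary decision statistics. Because studies of this
kind rarely deposit trial-level data, the package also ships a generative
model of the whole study, so every stage — filtering, response bias,
contrasts, Bayes factors, ANOVA — can be exercised end to end on data with
known ground truth.

# The task and the response-bias statistic

Each task application has three blocks of 100 trials; each block presents 50
"long" and 50 "short" mouths in shuffled order. One stimulus is designated
*rich* and is scheduled to be rewarded on 30 trials per block; the other,
*lean*, on 10. Rewards are delivered only on correct responses. The
signal-detection response bias for a block is

$$RB = \tfrac{1}{2}\,
\ln\frac{\mathrm{Rich}_{correct}\,\mathrm{Lean}_{incorrect}}
        {\mathrm{Rich}_{incorrect}\,\mathrm{Lean}_{correct}},$$

the log-odds preference for the rich response irrespective of accuracy. We
use the natural logarithm; the statistic is antisymmetric under a rich/lean
relabelling and exactly zero whenever the two correct/incorrect odds are
equal. When any cell count is zero, 0.5 is added to all four cells (the
standard log-linear continuity correction) and the value is flagged
`corrected`; the study protocols we follow are silent on this case, and the
correction only arises for near-perfect or near-empty blocks.

Trial retention follows the registered rules: responses faster than 200 ms or
slower than 2000 ms are dropped (boundary values retained), missing responses
are dropped and count toward the same violation budget, and a participant is
excluded when more than 10% of their trials are unusable, when any session
was answered with a single key, or when a session is missing entirely.

# One-degree-of-freedom reductions

Every hypothesis is carried by an `effect_summary` triple $(M, SE, df)$
computed from *per-participant* contrast scores, so that $SE = sd/\sqrt{n}$
and $df = n-1$ are always well defined and the Bayes tests below apply
uniformly:

* **Primary effect** — block-1 response bias, post-active minus post-sham.
* **Mood indices** — PANAS PA and NA are double-baselined:
  $(post-pre)_{active} - (post-pre)_{sham}$; the NA index is sign-flipped so
  positive values mean negative mood *decreased*, matching the orientation of
  its prior.
* **Stimulation-by-block interaction** — per-participant active−sham
  differences per block reduced by the linear contrast
  $B_1 - \tfrac12 B_2 - \tfrac12 B_3$.
* **Three-way interaction** — the same block contrast computed at each level
  of time, then differenced (post − pre), after covariate adjustment: within
  every design cell the values are regressed on the grand-mean-centred
  TEPS-consummatory score and replaced by $v - b_{cell}(x - \bar x)$, so cell
  means equal ANCOVA-adjusted means. Grand-mean centring is our choice; the
  source analyses do not state theirs, and the convention is pinned by
  reproducing their reduced summaries.

Zero-variance contrast scores yield a `degenerate` flag and are refused by
the test layer rather than producing infinite statistics.

# Informed-prior Bayes factors

For data summary $(M, SE, df)$ the likelihood of the observed mean given a
true effect $\delta$ is a scaled, shifted t density with the data's degrees
of freedom. H1 is a shifted, scaled t prior $\pi(\delta)$; H0 is the point
null:

$$BF_{10} \;=\; \frac{\int f_t(M \mid \delta, SE, df)\,\pi(\delta)\,d\delta}
                     {f_t(M \mid 0, SE, df)}.$$

Two conventions matter and are fixed package-wide:

* **Two-sided versus directional.** The "two-tailed" prior is the untruncated
  shifted t itself; a directional test truncates the same t at zero on the
  predicted side and renormalises.
* **Prior scale.** The registry priors used against observed data take their
  scale from the original study's sample SD ($SE\sqrt{n}$), i.e. the prior
  expresses the spread of effects seen in the original sample; the
  prospective *design analysis* instead uses the original SE as scale,
  expressing only the sampling uncertainty of the original mean. Both
  variants are exposed; the registry records location, SD, SE, $n$ and $df$
  for each source effect so either can be formed.

The registry ships seven source effects: the primary block-1 effect
(location .14, SD .26, df 17), the stimulation-by-block contrast (.16,
.08·√18, 17), the covariate-adjusted three-way contrast (.14, .33, 20), the
PA and NA treatment effects (4.91 and 5.92, SDs .82·√96 and .94·√96, df 95;
the NA location is mapped onto the "decrease" direction), and the two
block-3 manipulation-check effects (.19, .26, 17 and .26, .32, 20).

The default-prior complement is the JZS one-sample Bayes factor: a
zero-centred Cauchy prior (scale $\sqrt2/2$ unless stated) on the
standardised effect against the point null, computed by integrating the
noncentral-t likelihood of the observed t statistic over the prior.

**Quadrature.** Marginals use adaptive quadrature (`integrate`) with
relative tolerance 1e-10 over a window spanning the prior location and the
data mean by 12 of the wider of (prior scale, data SE), clipped to the
truncation support — wide enough that the heavy t tails carry negligible
mass outside. The reported error bound must stay below 1e-6 of the Bayes
factor or the call fails rather than returning a doubtful number. The test
suite cross-checks the adaptive result against an independent 1e5-point
trapezoid grid to 0.1% on randomised cases.

# Design analysis and stopping rule

Planning uses SE scaling: at planned size $n_t$, the expected SE is
$SE\sqrt{n_o/n_t}$, and the expected Bayes factor under the null is the
informed BF evaluated at an observed mean of exactly zero with that SE. Data
collection stops when all monitored BFs exceed 6, all fall below 1/6, or 30
participants have been collected; thresholds and cap are configurable.

# Frequentist complements

`paired_t`/`one_sample_t` apply $t = M/SE$, two-sided p, and $d = t/\sqrt n$.
The repeated-measures ANOVA/ANCOVA are type-III partitions on the within-cell
matrix (via the standard multivariate linear model machinery), with Mauchly's
test per multi-df effect and the Greenhouse-Geisser corrected p substituted
when Mauchly's p < .05. Partial eta squared is $F\,df_1/(F\,df_1+df_2)$ and
its d equivalent $2\sqrt{\eta^2/(1-\eta^2)}$ — a nonstandard but fixed
conversion that reproduces the conventions of the analyses this package
mirrors. Bonferroni post-hocs cover the pairwise comparisons of significant
main effects with more than two levels (a family of 3 for the block factor).
ANCOVA enters the grand-mean-centred covariate as a between-subject
regressor, so its interactions with every within-subject effect are
estimated.

# The synthetic study

`simulate_participant` is a criterion-learning signal-detection agent. On a
trial with role sign $s$ (+1 rich-role stimulus, −1 lean), the probability of
choosing the rich response is $\mathrm{logit}^{-1}(d'\,s/2 + c)$, so the
expected block response bias equals the criterion $c$ in log-odds units. A
logistic (rather than probit) choice rule keeps closed-form expectations for
tests. After every delivered reward the criterion moves toward the rich
response by `learn_rate`, saturating at ±3 log-odds; with the 3:1 reward
asymmetry this produces the rising bias across blocks that the task is
designed to elicit. The per-application reward quota is tracked: a planned
reward falling on an incorrect trial is re-queued to the next correct
same-role trial and dropped at block end, preserving the 30/10 asymmetry
approximately for accurate responders. Each of the four task applications
restarts the criterion (the rich pairing reverses between pre and post, so
learning restarts); `stim_effect` adds to the criterion in the post-active
application only and is the injectable ground truth for power properties.
Reaction times are lognormal (meanlog log 500, sdlog 0.3) truncated to
[1, 5000] ms by inverse-CDF sampling.

Defaults were chosen once to sit in the reported regime of such studies:
`dprime = 2.2` (≈75% accuracy at a neutral criterion), `learn_rate = 0.002`
per reward (block-3 bias around .2), `lapse = 0.05`, population spread
`dprime_sd = 0.3`, `learn_rate_sd = 0.001` (truncated at 0), `criterion0_sd
= 0.2`. Questionnaire items come from latent normal mood: a participant
trait, an administration-level state fluctuation (sd 0.3, shared by the ten
items of a scale — this term dominates the variance of change scores), and
item noise (sd 0.6), rounded and clipped to the 1–5 response scale. The PA
latent item mean (2.9) puts sums near 29; the NA item mean (0.6) puts sums
near 11 with a large share of administrations at the scale floor of 10,
reproducing the floor-limited character of negative affect in non-clinical
samples. Injected mood effects are specified in sum-scale points at the post
administration of a condition. TEPS items (1–6) are generated at baseline
only. Randomisation uses one root seed with per-participant streams at fixed
offsets (`seed + 1000 i`), so any participant regenerates identically in
isolation.

**What the generator does not emulate:** response-key laterality and its
counterbalancing (responses are recorded as stimulus choices), sequential
constraints on the "pseudo-random" stimulus order beyond shuffling (an
unconstrained shuffle is used), session-order effects, fatigue and dropout,
or any neurophysiology of stimulation — `stim_effect` is a phenomenological
criterion shift. Passing tests therefore validate the analysis chain and its
calibration, not claims about real stimulation physiology. Real data are
also noisier between participants than the default population (the study we
mirror shows block-level SDs several times larger), so synthetic power
figures are optimistic for equally sized real samples. The allocation of
stimulation order is balanced (alternating), matching the reported 15/15
split rather than literal coin-flip allocation, which the source protocol
describes both ways.

# Test problem sizes

The property suite runs at sizes chosen to keep the full check fast while
leaving comfortable statistical margins: 200 task applications for the
unbiased-agent and learning-curve properties, a 200-agent grid for
learning-rate recovery, 1000 replicates for the ANOVA type-I calibration, 50
studies of 12 participants for the null behaviour of the primary test, 30
studies of 30 participants for detection of an injected +0.3 criterion
shift, and 2000 simulated summaries for the Bayes-factor null calibration.

# Known limitations

* The informed-prior convention (prior scale = original SD for observed-data
  tests) follows the analyses this package reproduces; readers who prefer
  SE-scaled priors can pass any `prior_model` explicitly.
* The ANCOVA adjustment is the simple per-cell regression form; it is not a
  mixed-model formulation and assumes homogeneous slopes only within cells.
* The JZS integrand underflows for |t| beyond roughly 25 at moderate n;
  evidence that overwhelming is outside the calibrated range.
* Bayes factors are reported without posterior summaries; the package takes
  no position on estimation.
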