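---
title: "Robust Bayesian estimation for picture-word interference designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Bayesian estimation for picture-word interference designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwibayes)
```

## The design and the data

The picture-word interference (PWI) task crosses a between-participant factor
(patient vs. control group) with a within-participant factor (distractor
condition: neutral XXX, unrelated word, semantically related word,
phonologically related word). Each of 22 pictures appears once with each
distractor, so each participant contributes 88 experimental trials
(`build_design()`).

Naming latencies are strongly right-skewed, and three kinds of trials carry
no usable latency signal: overt speech errors, voice-key trigger failures
(no RT at all), and artifactual responses faster than 200 ms.
`exclude_trials()` removes these with a fixed precedence (error > voice-key >
fast) so that each trial is counted exactly once in the exclusion report; the
operation is idempotent. The unit of all inference is then the
per-participant **median** RT in each condition (`condition_medians()`) —
medians, not means, because the median is the better location summary under
skew. Even-count cells use the mean of the two central order statistics (a
convention this package fixes; either convention changes medians by well
under the trial-level noise). Missing cells propagate as `NA` and are never
imputed.

## The hierarchical model

`fit_splitplot()` models each participant-condition median as

$$y_{sc} \sim t_\nu\!\left(\mu_{sc},\ \sigma\right), \qquad
\mu_{sc} = \beta_0 + \beta^G_{g(s)} + \beta^D_{c} + \beta^{GD}_{g(s),c} + \beta^S_s,$$

a split-plot decomposition into a grand baseline, group and distractor
deflections, their interaction, and a per-participant deflection nested in
group. The deflections satisfy sum-to-zero constraints: $\sum_g \beta^G_g =
0$, $\sum_c \beta^D_c = 0$, interaction deflections sum to zero across every
row and column of the group × condition grid, and participant deflections sum
to zero within each group. The scale $\sigma$ and the degrees of freedom
$\nu$ are shared by all cells, so their estimation pools information across
groups and conditions; small $\nu$ means heavy tails, which is how the model
absorbs outlying medians without letting them drag cell locations around
(robust estimation).

Participant deflections are not optional decoration: without them, every
within-participant contrast would carry the full between-participant variance
(hundreds of ms here), and the model would no longer be a split-plot at all.
With them, condition contrasts are informed by within-participant differences
only, exactly as the paired error strata of a repeated-measures ANOVA.

### Priors

All priors are vague and located at broad data summaries
(`build_priors()`):

| parameter | prior | default location |
|---|---|---|
| baseline $\beta_0$ | Normal | mean of pooled medians; precision $10^{-6}\times$ pooled precision |
| scale $\sigma$ | Uniform | pooled SD ÷ 1000 to pooled SD × 1000 |
| normality $\nu$ | Exponential | mean 29 (balances near-normal and heavy-tailed regimes) |
| deflections | Normal(0, $\tau$) | shared $\tau \sim$ Gamma, moment-matched |

The gamma hyperprior on the common deflection precision is parameterized by
moment matching (`gamma_from_mean_sd()`: shape $= m^2/s^2$, rate $= m/s^2$)
to the mean of the observed per-cell precisions and an SD inflated by a
factor of $10^6$ — the inflation is what makes the prior effectively flat.
For a typical RT dataset this yields shape $\approx 2\times10^{-12}$ and rate
$\approx 4.6\times10^{-8}$; at such values the deflection prior exerts
essentially no shrinkage, and posterior results are insensitive to the exact
hyperparameter values. Participant deflections receive their own precision
parameter under the same gamma hyperprior by default
(`subject_precision = "separate"`); tying it to the effect-deflection
precision is a configuration switch, and with hyperpriors this flat the
choice is immaterial in practice.

The $\nu$ prior is an unshifted exponential on $\nu > 0$ with mean 29; a
shifted variant ($\nu \ge 1$) would change nothing detectable here because
the likelihood keeps $\nu$ comfortably positive.

### Sampling, identification and diagnostics

The model is sampled with JAGS through `rjags`. Chains are initialized at
data summaries (pooled mean, group/condition means, subject means, pooled
SD), and per-chain RNG seeds are derived deterministically from the
configuration seed, so a fit is exactly reproducible. Defaults follow the
settings the model was designed with — 100,000 retained draws, thinning 50,
burn-in 2,000 — but reduced settings (a few thousand retained draws, light
thinning) are adequate for the simulation studies in the test suite, which
use 1,500–4,000 retained draws to keep the whole suite inside a practical
runtime at the documented problem sizes (10–40 participants per group).

The sampler works on an *unconstrained* parameterization (independent normal
deflections). That parameterization contains flat ridges — adding a constant
to all group deflections and subtracting it from the baseline changes
nothing — so raw-parameter trace diagnostics are meaningless. Every retained
draw is therefore swept into the sum-to-zero decomposition (participant
deflections centered within group, then the 2 × 4 grid of cell means swept
into baseline + row + column + interaction parts; the sweep never moves a
cell mean), and split-$\hat R$ and effective sample size are computed on the
*identified* quantities: baseline, all swept deflections, $\sigma$, $\nu$. A
fit with max $\hat R$ above 1.1 is returned with a prominent warning flag
rather than an error.

### What the cell means estimate

The swept cell means are fixed-effect (conditional) estimands: the average
fitted location of the *sampled* participants in a cell. Within-participant
contrasts (the lexical, semantic, phonological effects and their group
differences) are insensitive to this distinction because participant offsets
cancel. For purely between-group quantities (the `group_main` contrast), the
posterior is conditional on the recruited participants and is therefore much
tighter than a Welch-type interval that generalizes to new participants —
the same behavior visible in published HDIs from this model class. Users who
need population-level group inference should read the split-plot ANOVA's
group test, which uses the between-participant error stratum.

## Decisions from the posterior

`hdi()` computes the shortest interval containing the requested mass as a
window of consecutive order statistics, with ties broken toward the smallest
lower bound; for skewed posteriors it is shorter than the equal-tailed
interval and need not contain the mean. `contrast()` turns any linear
combination of the eight cell means into a posterior distribution and reports
mean, 95% HDI, tail masses and a decision: `credible_positive` if the HDI
lies above zero, `credible_negative` if below, otherwise
`credibly_null_candidate`. The third label deliberately avoids claiming
evidence *for* the null: with no region of practical equivalence defined, an
HDI containing zero only fails to exclude it, and the `narrow_hdi` annotation
(default half-width < 25 ms, a magnitude below which distractor effects in
this paradigm are rarely interpreted) marks the cases where the posterior is
concentrated enough for the null reading to be interesting.

`standard_contrasts()` packages the ten contrasts of scientific interest:
overall group slowing, the three distractor effects per group, and each
effect's group difference signed so that negative values mean *larger
interference* (decreased performance) in patients and, for the phonological
contrast, positive values mean larger facilitation in patients.

## Single-case scores and general slowing

`standardized_scores()` expresses each patient's effect in SD units of the
control sample, $(x - \bar x_{ctrl}) / s_{ctrl}$ with the $n-1$ sample SD
(the package's convention; with 13 controls the population-SD variant would
shrink scores by ~4%, never changing a 2 SD flag in practice). Two SDs
approximate the 95th percentile under normality. Controls are standardized
against their own group, so their scores have sample mean 0 and SD 1 by
construction — a property the tests verify.

Because patients are globally slower, a larger raw effect can be a
multiplicative-scaling artifact. `rt_ratios()` divides each effect by the
participant's unrelated-condition median (the condition common to all three
effects); a purely multiplicative slowing cancels exactly in these ratios, so
group differences that survive the ratio transform cannot be explained by
general slowing alone.

## The synthetic-data generator

`simulate_trials()` emulates the study conditions so that the entire pipeline
can be exercised against known ground truth. Correct-trial RTs are drawn from
a **shifted lognormal**, $rt = 250 + (\ell - 250)\,e^{\sigma Z}$, chosen
because it is positive, right-skewed, and — parameterized this way — has
*median exactly* $\ell$, making effect injection additive on the median scale
(the estimand of the whole pipeline). The family is pluggable behind
`rt_noise$family`.

The paper-like preset (`paper_like_config()`) fixes the study conditions: 13
controls and 6 patients; control neutral location 750 ms; patient slowing
400 ms; control effects 80 / 46 / −18 ms and patient effects 332 / 75 /
−172 ms (lexical / semantic / phonological); error rates 2% / 3%, voice-key
failure rates 3% / 5.3%, fast-guess rate 0.1%. The dispersion parameters were
calibrated once from the printed inferential statistics of the study this
design emulates: lognormal $\sigma$ of 0.2 (controls) and 0.45 (patients)
reproduce the reported within-group effect SDs (~33–47 ms for controls,
~140–230 ms for patients at 22 trials per cell), and stable participant
offsets with SD 100 ms (controls) / 200 ms (patients) reproduce the reported
between-participant spread. Errors carry an RT (a voice key logs one);
voice-key failures do not; fast guesses are uniform on 80–199 ms. Trial order
is shuffled per participant, which is cosmetic since the analysis is
order-insensitive. Exclusion-class probabilities are uniform over conditions
(no per-condition loss rates are specified anywhere, so none are modeled).

What the generator does **not** emulate — and hence what passing tests do not
certify about real data: item-level variation (conditions are opaque labels;
no lexical frequency or phoneme-overlap structure), per-participant
variation in *effect size* (patient effect heterogeneity is represented
through trial noise, not random effect slopes), sequential effects (fatigue,
practice), and any dependence of artifact rates on condition.

## Numerical and design choices

- **Heteroscedasticity.** The shared-$\sigma$, shared-$\nu$ likelihood is the
  model's stated assumption. Under the paper-like preset the patient group's
  trial noise is ~4× the controls', and simulation shows the consequence:
  HDIs for patient-side contrasts undercover slightly (pooled coverage ~0.89
  instead of 0.95 at 10 + 10 participants), while control-side HDIs are
  conservative. The HDI-calibration test in the suite therefore generates
  data under the model's own assumptions (equal noise in both groups), which
  is the standard simulation-based-calibration design; the heteroscedastic
  behavior is a known limitation of this model class, inherited by design.
- **Detecting small effects.** A −18 ms phonological effect against a ~37 ms
  within-participant effect SD at n = 13 has low power/credibility
  probability (~15% of replicates yield an HDI excluding zero). A single
  dataset can land on the credible side; most will not. This is a property of
  the design, not of the estimator.
- **Exclusion precedence** (error > voice-key > fast) makes the report a
  partition; the classes are reported separately without overlap.
- **Degenerate inputs.** Zero pooled variance rejects prior construction; a
  zero control SD yields explicitly undefined standardized scores; a
  condition with no errors in either group is flagged degenerate in the
  error-rate comparison rather than fitted; a contrast of a cell with itself
  returns a degenerate flagged result.
- **ANOVA conventions.** The split-plot ANOVA reports uncorrected p-values
  (each effect is read off one model, mirroring the Bayesian analysis's
  single posterior); a Greenhouse-Geisser option exists but is off by
  default. Between-group comparisons of effects use Welch's unequal-variance
  t with Satterthwaite df — the appropriate choice for a 6 vs. 13 split with
  unequal variances — and 95% CIs use the same df as the accompanying t.

## Problem sizes used in the shipped simulations

The test suite runs: generator oracles at 10,000 trials/condition; HDI
oracles at 10^6 draws; parameter recovery at 40 participants/group; HDI
calibration over 200 replicates at 10 participants/group; the qualitative
effect-pattern study over 50 replicates at the design's 13 + 6 sample sizes;
all MCMC at 1,500–4,000 retained draws. These sizes were chosen so each check
has the Monte-Carlo resolution its tolerance requires.
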