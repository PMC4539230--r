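---
title: "Models and methods behind sexdisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexdisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexdisc)
```

## The measurement problem

The Sexual Discounting Task (SDT) measures willingness to delay sexual
gratification for safety: a participant repeatedly chooses, on a
visual-analog scale (VAS) from 0 ("sex now without a condom") to 100
("sex after a delay with a condom"), across seven delays from 1 hour to
3 months plus a zero-delay anchor trial, and under four partner
conditions (the partner they find most and least attractive, and the
partner they judge most and least likely to carry a sexually
transmitted infection). A companion monetary task (DDT) titrates an
immediate amount against $1000 delayed at six delays from 1 day to 5
years. Cohorts are assigned to one of three narrative scenarios about a
friend's unprotected-sex experience — a positive health outcome, a
negative outcome (HIV seroconversion), or the negative outcome with an
explicit expression of regret — and the scientific question is whether
the scenario framing shifts discounting of delayed condom-protected
sex, selectively (i.e., without shifting monetary discounting).

`sexdisc` implements the complete analysis chain for such cohorts, and
a cohort simulator rich enough that every stage of the chain can be
exercised and calibrated without human data.

## Area under the discounting curve

Each participant x condition yields indifference points $y_i \in [0,1]$
at delays $D_i$ (VAS/100 for the SDT; titrated amount/1000 for the
DDT). Delays are normalized to $x_i = D_i / \max_i D_i$ and the curve
is summarised by the trapezoidal area

$$\mathrm{AUC} = \sum_{i} (x_{i+1} - x_i)\,\frac{y_i + y_{i+1}}{2},$$

so $\mathrm{AUC} \in [0,1]$ with lower values meaning steeper
discounting. Label durations use round calendar conversions (1 month =
720 h, 1 year = 8760 h) purely so positions are reproducible.

Two anchoring decisions are genuinely open and are surfaced as options:

* **Zero-delay SDT trial.** The task's first trial ("sex now with a
  condom" vs "now without") sits at position 0. Whether it should enter
  the AUC is not self-evident; `compute_auc(auc_anchor = "measured")`
  (the default) keeps it, `"exclude-zero"` drops it, and the choice is
  recorded in every report's metadata. When the zero-delay point is
  excluded, the integral is renormalized by the remaining position span
  so a constant curve still integrates to its constant.
* **Monetary anchor.** The undelayed $1000 is worth $1000 by
  definition, so monetary curves receive a synthetic (0, 1) anchor
  before integration, the common convention for trapezoidal AUC on
  titrated indifference points.

Curves containing any missing response are excluded from that
condition's analysis and counted (no imputation); out-of-range VAS
values error in strict mode or are clipped-and-counted in lenient mode.

## Rank-based inference

AUC distributions carry point masses at 0 and 1 (always-immediate and
always-delayed responders), so group comparisons are rank-based
throughout and no distributional model is fit to AUC.

**Wilcoxon rank-sum Z.** With joint midranks, rank sum $W$ of the
first-listed group, and tie groups of size $t$,

$$Z = \frac{W - n_a(n+1)/2}{\sqrt{\dfrac{n_a n_b}{12}\left[(n+1) -
\dfrac{\sum (t^3 - t)}{n(n-1)}\right]}},$$

with a two-sided normal p. The default applies **no continuity
correction**, matching the convention under which the published Z
values in this literature are reported; `continuity = TRUE` is
available. The uncorrected approximation is coarse at very small
samples (its two-sided p can differ from the exact enumeration by up to
about 0.19 at $n_a = n_b = 3$; the corrected variant stays within about
0.04), which is immaterial at cohort sizes but is why the test suite
checks the small-sample accuracy property on the corrected variant and
cross-checks the default against `wilcox.test(correct = FALSE)`.
A zero-variance pooled sample returns the defined result $Z = 0$,
$p = 1$ with a warning. The reported `mean_rank_diff` (difference in
mean joint ranks) is a descriptive effect direction only.

**Spearman correlation.** Product-moment correlation of midranks, with
the $t$ approximation on $n - 2$ degrees of freedom for the two-sided
p. Zero rank variance in either margin yields a flagged, undefined
correlation rather than a silent `NA`.

**Permutation test for correlation differences.** To compare the
*strength* of the AUC-HRBS relationship between two scenario groups
without distributional assumptions, pairs $(x, y)$ are kept intact and
only group labels are reassigned, preserving group sizes. The observed
statistic is $\rho_a - \rho_b$; the two-sided p is the plain proportion
of resampled differences with $|\Delta\rho^*| \ge |\Delta\rho|$ over
$B = 100{,}000$ relabelings by default. Choices worth stating:

* "at least as extreme" is implemented as $\ge$ on absolute values
  (conservative, stable when the observed difference is exactly 0);
* the plain proportion $\#\{|\Delta\rho^*| \ge |\Delta\rho|\}/B$ is the
  default estimator, with the $(\#+1)/(B+1)$ variant behind a flag;
* a resample in which a relabeled group has zero rank variance
  contributes a difference of 0 and is tallied in `n_degenerate`;
* every stochastic result stores its seed, and the resampling loop is
  compiled (C++) but drives R's RNG, so results are bit-reproducible
  from `set.seed()`;
* `exhaustive_corr_diff_null()` enumerates all
  $\binom{n_a+n_b}{n_a} \le 10^6$ relabelings exactly and serves as the
  small-sample oracle for the Monte-Carlo path.

No multiple-testing adjustment is applied anywhere; tables report
unadjusted p values with significance markers as presentation only.
Quantiles (demographic medians/IQRs) use linear interpolation between
order statistics (`type = 7`), one stated convention for
reproducibility.

## Questionnaire scoring

Four instruments are scored from item responses: HRBS (11 items, 0-5,
sum), the ZTPI future-orientation subscale (12 retained items of 13 —
one item was not recorded in the motivating dataset — 1-5, mean after
reversals), SSS (21 items, 1-5, sum), and CFC (12 items, 1-5, mean by
default, sum by flag, after reversals). Reverse-scored positions are
configuration (`questionnaire_key()`), not hard-coded: the instruments'
published keys are the defaults, the active key travels with the run,
and reversal maps $r \mapsto 6 - r$. Precomputed totals in a loaded
dataset can bypass the scorers entirely via the column mapping.

## The cohort simulator

`generate_cohort()` draws agents from a generative model chosen to
reproduce the *structure* the analysis has to survive, with every
parameter in `sim_config()`:

* **Hyperbolic valuation.** $V(D) = A/(1 + kD)$, $k$ in 1/h (an
  exponential form is available for robustness checks). Regular agents
  answer the SDT with $\mathrm{clip}(100\,V(D) + \varepsilon, 0, 100)$,
  $\varepsilon \sim N(0, \sigma_\mathrm{VAS})$, $\sigma_\mathrm{VAS} =
  7$ VAS points by default.
* **One discounting propensity, many curves.** Each agent has a latent
  $z_\mathrm{disc} \sim N(0,1)$; per condition,
  $\log k = \mu[\mathrm{scenario}, \mathrm{condition}] +
  \mathrm{gender\ shift} + \sigma\,(\sqrt{1-w^2}\, z_\mathrm{disc} +
  w\,\epsilon_c)$ with $\sigma = 2$ and condition-noise fraction
  $w = 0.3$: discounting is strongly but not perfectly consistent
  across partner conditions.
* **Point masses.** Agents in the upper $p_\mathrm{floor} = 0.15$ tail
  of $z_\mathrm{disc}$ are always-immediate responders (AUC exactly 0);
  the lower $p_\mathrm{ceiling} = 0.15$ tail are always-delayed (AUC
  exactly 1). Tying extremity to the discounting latent (rather than an
  independent coin flip) keeps the marginal rates binomial while
  preserving the rank coupling between AUC and the trait layer.
* **Trait copula.** Questionnaire totals, image count and the monetary
  rate are coupled to $z_\mathrm{disc}$ through a single-factor
  Gaussian copula. Spearman targets $\rho_S$ are converted to latent
  Pearson correlations by $\rho_P = 2\sin(\pi\rho_S/6)$ and inflated by
  a single calibration scalar (default 1.25) that offsets the known
  attenuation from VAS noise, condition noise and discretization; with
  it, realized correlations land within about 0.02 of target at
  $n = 5000$. Totals are produced by mapping each trait latent through
  its instrument's range with uniform bins (HRBS 0-55, SSS 21-105,
  ZTPI/CFC on the 1-5 grid of attainable 12-item means, images 2-20).
  Default targets (monetary +0.04, ZTPI +0.08, images -0.20, HRBS
  -0.15, SSS -0.14, CFC -0.20) are weak negative rank correlations of
  the size typical for this construct family.
* **Scenario effect preset.** Printed effect magnitudes do not exist
  for this manipulation, so the preset $\mu$ shifts were calibrated
  once, analytically and by simulation, to reproduce the qualitative
  detection pattern at 135 per group: the regret scenario discounts
  least in the most-attractive and least-STI conditions (shifts -2.1
  and -1.8 log units vs the positive scenario), both negative scenarios
  sit together below the positive one in the least-attractive and
  most-STI conditions (-1.7/-2.0 and -1.2/-1.2), and monetary
  discounting is untouched by scenario. `scenario_effects = "none"`
  zeroes all shifts for null calibration.
* **Gender preset.** Male agents receive condition-dependent positive
  shifts of $\log k$ (steepest in the most-attractive condition),
  reproducing the observation that males wait less for condom-protected
  sex; set `gender_effect = 0` to remove it.
* **Titration.** The DDT ladder starts the immediate offer at $500
  with a $250 adjustment halving over 8 choices, so a deterministic
  agent ends within the final step (about $2) of $1000/(1+kD)$ on the
  attainable range of roughly $2-$998; logistic choice noise is
  available behind a temperature parameter (default 0).
* **Demographics.** Marginals resemble an online adult US sample:
  log-normal age (median 30, IQR about 25-37), days since last sexual
  encounter (median 6, heavily right-skewed), household income (median
  $37k), 44% female, 90% with college exposure, 43% single. These are
  scenery for the reporting stage, not part of the inferential model.

**What the simulator does not emulate.** Real item-level response
styles (totals come from a smooth copula, not item processes), partner
image selection (only its count), attrition or inconsistent responders
(the DDT consistency checker exists but the generator produces orderly
curves), within-participant order effects, and any dependence of the
extreme-responder rates on scenario. Passing tests on synthetic cohorts
therefore demonstrate that the statistical machinery is correct and
calibrated — not that the generative model is a faithful model of human
sexual decision making.

## Numerical and design notes

* Trapezoidal integration on sorted normalized positions; curves are
  validated to lie in $[0,1]$.
* Ranking uses midranks everywhere; tie counts enter the Wilcoxon
  variance through exact value matching, not string rounding.
* Degenerate inputs have defined outcomes: zero-variance Wilcoxon
  returns $Z = 0, p = 1$ with a warning; zero rank variance flags the
  Spearman result; degenerate permutation resamples count as 0 and are
  tallied; analysis rows with empty cells are flagged, never dropped.
* Row order never matters: table analyses sort participants into a
  canonical order before any seeded resampling.
* Per-row permutation seeds are derived deterministically from the
  master seed, so a 12-row table is reproducible as a whole and row by
  row.
* Foreign file layouts are adapted declaratively (`column_mapping()`),
  including an AUC-bypass path for datasets that archive AUC values
  rather than trial-level responses.

## Problem sizes used by the shipped checks

The test suite and the acceptance script exercise, as the package's own
choices: the full pipeline at the study's 136/137/135 group sizes with
$B = 100{,}000$ permutation resamples; power over 100 replicate cohorts
at 135 per group; null calibration over 500 replicate 30-per-group
cohorts; copula recovery at 5,000 participants per scenario; and exact
enumeration oracles at $n \le 6$ per group. On one CPU the whole
acceptance run takes on the order of three minutes.

## Known limitations

* The Wilcoxon "score mean difference" column of the motivating
  reports follows an unnamed implementation's internal formula; the
  package's `mean_rank_diff` is a documented descriptive analogue, not
  a reproduction, and only Z and p are comparable surfaces.
* The normal-approximation Z is not trustworthy below about 8
  observations per group; use the exact enumeration oracle there.
* Monte-Carlo permutation p values below about $10/B$ are resolution
  limited; raise `n_resamples` or use the exhaustive path.
* The simulator's effect presets encode a sign/significance pattern,
  not published effect magnitudes (none are printed); quantitative
  agreement of Z values with any specific dataset is out of scope
  without that dataset.
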