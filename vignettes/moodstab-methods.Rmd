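---
title: "Methods: mood-stability monitoring from passive sensing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mood-stability monitoring from passive sensing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(moodstab)
```

This vignette is the package's own account of its modeling choices: the
procedure and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the decisions made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The procedure

The unit of analysis is a **data sample**: three consecutive PHQ-9
submissions at times $t_1 < t_2 < t_3$ with total scores
$s_1, s_2, s_3 \in [0, 27]$, defining period 1 $= [t_1, t_2)$ and period 2
$= [t_2, t_3)$. A candidate sample is discarded when either period is
shorter than 7 days (7 × 24 h between submission timestamps — the PHQ-9
reflects roughly the past week, so shorter periods double-count state), or
when a required stream has fewer than 3 *effective days* in either period.
Windows slide with stride 1, so one submission can serve up to three
samples; this overlap is deliberate — with roughly five scheduled
submissions per participant, disjoint triples could not produce cohorts of
realistic size.

**Labels.** With $R = \max(s) - \min(s)$: Swing-drastic ($R \ge 10$),
Swing-moderate ($R \ge 5$), Steady-remission (all $\le 5$), Steady-depressed
(all $\ge 11$, $R < 5$). These criteria overlap — $(0, 5, 3)$ is both "all
≤ 5" and "range ≥ 5", and every drastic triple is also moderate — so a
precedence is unavoidable. We apply **Drastic → Moderate → Remission →
Depressed**: instability (range) takes priority over level, and drastic
before moderate makes Moderate mean $5 \le R < 10$, keeping the four classes
disjoint as the benchmark tasks require. Triples matching no rule (e.g.
$(8, 9, 8)$: mid-range level, small range) are `unlabeled` and excluded from
benchmarking. The label function is total and deterministic; the acceptance
suite proves equivalence with an independently coded oracle over all
$28^3$ triples.

**Effective days.** The source protocol never defines "effective data". We
chose: a phone stream (calls, screen, apps) has an effective day when at
least one record falls on that local calendar day; the wristband when at
least 240 worn minute-packets (4 h) do. Both thresholds are config-exposed
(`min_events`, `min_worn_minutes`). The discard is evaluated **per
data-type combination**: a sample can be usable for a sleep-only analysis
while failing the call-log one, which is why sample counts legitimately
differ across the six experiment tables.

## Feature battery

All clock-time computations (3-hour bins, morning/afternoon/night windows,
call hours, sleep onset/wake) run on a single participant-local timezone
fixed at load (`tz`, default UTC). Features with no basis — entropy of zero
calls, session SD of one session — are **NaN, never zero**: a zero would
conflate "no calls" with "instantaneous calls". Imputation is deferred to
the benchmark's training folds.

* **Calls.** Per type (incoming, outgoing, rejected, all): count, total and
  mean duration (NaN for rejected — a rejected call has none), distinct
  peers, caller entropy $H = -\sum p \log_2 p$ with $p$ the per-peer share
  of calls, and the circular mean/SD of call clock hour. The circular
  summary (rather than a 24-bin histogram per type) keeps the battery near
  the source's size; `call_hour_histogram`-style expansion was considered
  and rejected as quadrupling the call block.
* **Screen.** Sessions are on→off spans after repair to strict alternation
  (duplicates collapsed keeping the first; a leading `off` and trailing
  `on` dropped — both are unmatched fragments). Daily count and duration
  statistics are computed over days *with data only*: a non-compliant day
  is missingness, not inactivity. Sessions crossing a window boundary are
  split proportionally so the morning/afternoon/night shares and the eight
  3-hour bins conserve total duration exactly (a tested invariant).
* **Apps.** Eight groups — seven assignable categories plus `all` (their
  union; the source's own category table lists the aggregate as its eighth
  row). Per group: session-duration mean/SD, duration and count per 3-hour
  bin (duration split at boundaries; a session *counted* in its start bin,
  since counts cannot be fractional). Cross-category entropy is computed
  twice, weighting events by session counts and by durations — the
  per-category-sessions reading of "entropy of app usage duration" was
  rejected because the category-as-event construction is the one the
  formula's accompanying text describes. Plus the instant-messaging share
  of total duration.
* **Sleep.** Nights are maximal runs of sleep-typed minutes; gaps up to
  `bridge_min` (60 min — a bathroom trip should not split a night) are
  merged; runs under `min_night_min` (180 min) are naps, flagged invalid.
  A night belongs to the calendar date of its onset. Summaries: mean /
  median / SD of light, deep and total minutes; mean light/total and
  deep/total ratios; circular mean onset and wake clock times (linear
  averaging of 23:30 and 00:30 gives noon; the circular mean gives
  midnight).
* **Steps.** Period total; mean/median/SD of daily totals and of the daily
  totals within each 3-hour bin, over days with worn packets.
* **Heart rate.** Present only during sleep minutes (the device's design).
  One cosinor per valid night: least squares of
  $y = M + \beta_1 \cos \omega t + \beta_2 \sin \omega t$, $\omega = 2\pi/24$
  with $t$ the local clock hour, then $A = \sqrt{\beta_1^2 + \beta_2^2}$,
  $\phi = \mathrm{atan2}(\beta_2, \beta_1)/\omega \bmod 24$,
  $r^2 = 1 - SSE/SST$. Fitting a 24-h cosine to a < 24-h window is
  ill-conditioned by construction — that is what per-night cosinor means —
  so `n_points` and $r^2$ are retained for downstream discounting, and the
  test suite derives its noise tolerances from the actual design matrix
  rather than the full-period $\sigma\sqrt{2/n}$ formula, which
  underestimates the SE badly on short windows. Nights with under 10 HR
  points are not fit. Flat signals get amplitude 0 and $r^2$ defined as 0.
  Nightly parameters are summarized by mean/median/SD; acrophase circularly
  (median and SD on values unwrapped around the circular mean). Clock time,
  not time-since-onset, is the regressor: acrophase is then a clock time
  comparable across nights.

**Aggregation.** Each per-period feature $f$ with values $a, b$ yields
$f.\mathrm{diff} = b - a$, $f.\mathrm{mean} = (a+b)/2$, and
$f.\mathrm{sd} = |b - a|/\sqrt{2}$ (two-point sample SD, $n-1$ convention —
a convention had to be fixed; either choice is monotone in $|b-a|$). The
$sd \equiv |diff|/\sqrt 2$ redundancy is documented and tested rather than
hidden: it mirrors the source battery. NaN in either period propagates to
all three.

## Selection and benchmarking

Per CV fold the pipeline is impute → standardize → select → fit, all fit on
the training fold only. Imputation is the training-fold median (robust,
config-exposed); standardization parameters likewise come from the training
fold. Selection inside the fold is the defensible default — selecting on
the full data leaks test labels into the feature set — while the single
"features selected, n" the report quotes is the selection size on the full
set, matching how such tables are usually printed. Two selectors are
implemented, exactly the two the source methods describe (its abstract's
count of four is not substantiated there, so nothing was invented): lasso
logistic regression at penalty `l1_strength` (default 0.05), and random
forest mean-impurity-decrease importance at threshold `tree_threshold`
(default: mean importance).

The classifier battery is SVM, KNN, decision tree, naive Bayes, random
forest, logistic regression. The environment provides none of the standard
R implementations for four of these, so they are implemented in-package:
greedy Gini CART (depth ≤ 6, minimum split 8, minimum leaf 4), bagged CART
random forest (`ntree`, `mtry` $= \lfloor\sqrt p\rfloor$) whose accumulated
impurity decreases double as the tree-selection scores, Gaussian naive
Bayes with a variance floor, and a linear L2 SVM with squared hinge loss
fit by BFGS ($\lambda = 0.1$). Hyperparameters are fixed at these recorded
defaults — the source gives none, and searching them would change the
question. Folds are stratified (class ratios within one sample per fold,
tested); a class smaller than $k$ reduces $k$ with a warning, never
silently. Accuracy is correct over total; recall is **positive-class
(Swing) recall** — this reading, not macro-averaging, reproduces the
recall ≫ accuracy pattern that Swing-majority imbalance forces on
majority-leaning classifiers, a degeneracy the acceptance suite asserts is
detectable rather than pretends is absent.

## The synthetic cohort: what it is and is not

The generator is a stated world, not a tuning dial. Each participant has a
baseline profile (defaults: ~5 calls/day across types, 40 screen unlocks,
IM-dominated app use, 6000 daily steps, sleep 23:30–07:30 with 30% deep
sleep, nocturnal HR cosinor with mesor 62 bpm, amplitude 6 bpm, acrophase
4 h, per-stream daily compliance 0.85–0.95) randomized across participants
with ~30% lognormal heterogeneity. Event times are drawn from
inhomogeneous Poisson processes with clock-hour intensity profiles (calls
and screen use by day, steps with commute peaks); the wristband emits
exactly one packet per minute with 90-minute sleep cycles containing deep
blocks, heart rate only during sleep minutes, and random daytime not-worn
gaps that exercise the effective-day logic.

Scenarios condition the PHQ-9 triple, drawn uniformly from the integer set
earning the scenario's label under the documented precedence (no score
distribution is stated anywhere, so uniform is the assumption-free choice).
Swing scenarios apply one multiplicative changepoint at $t_2$ — matching
the two-period difference statistic the pipeline computes — with effect
sizes 0.45 (drastic) and 0.7 (moderate) on call/screen/app/step rates,
deep-sleep fraction and HR amplitude, and a $2 - e$ stretch of time in bed
(hypersomnia under worsening). Submissions default to a biweekly cadence
(day 0/14/28) with ±12 h uniform jitter; the cadence variance is a free
parameter since only "biweekly, at any time" is stated.

What a green pipeline test establishes: the machinery — sampling, discard,
features, leakage-free CV — carries a planted two-period behavioral shift
through to classification, and carries *no* signal when the shift is
removed (the permutation-null check). What it does not establish: anything
about real patients. The generator has no autocorrelated mood dynamics, no
weekday/weekend structure, no gradual drift (the changepoint is sharp), no
measurement error model for the wristband's sleep staging, and its
within-scenario score draws are independent of behavior given the scenario.
Classification accuracies on synthetic cohorts are therefore not
comparable to the source study's clinical values and are never asserted
against them.

## Numerical choices and degenerate inputs

* Two-point SD and single-observation SD use $n-1$; SD of one value is NaN.
* Circular means snap the $2\pi$ wrap so $24 - \varepsilon$ reports as 0;
  circular SD is $\sqrt{-2\log R}$ scaled to hours.
* Entropy of an all-zero count vector is NaN with a warning.
* glmnet's binomial lasso needs two observations per class; on degenerate
  training folds the selector returns the empty set and the fold falls back
  to all features.
* Ties in best-model choice break alphabetically; duplicate timestamps keep
  file order.
* Bin-splitting conservation is exact in math; tests allow ~1e-7 relative
  slack for double rounding at epoch-seconds magnitude.

## Known limitations

Sliding windows make samples statistically dependent, and CV folds split
samples, not participants — a participant's samples can appear in both
train and test folds. Both mirror the source design; participant-grouped
folding would be the stricter alternative and is a natural extension.
The cosinor's 24-h period on sub-8-h windows yields wide amplitude
confidence regions; downstream consumers should weight by $r^2$ or
`n_points`. The CLI and JSONL schemas cover the synthetic interchange
format only — vendor-native exports are out of scope.
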