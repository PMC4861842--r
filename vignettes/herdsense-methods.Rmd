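---
title: "Methods: sensor-based feeding and rumination phenotyping"
author: "herdsense authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-based feeding and rumination phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lameness is one of the most costly and welfare-relevant conditions in dairy
herds, and it changes how cows eat long before a herdsman scores them lame.
Automatic feed stations record every visit (who, where, when, how long, how
much fresh matter), and neck-mounted tri-axial accelerometers sampling at
12 Hz carry enough signal to classify rumination. `herdsense` implements the
full computation from those raw streams to behavioural phenotypes and
mixed-model estimates of lameness effects: visit cleaning, daily
characteristics, inter-/intra-individual coefficients of variation, and three
families of linear mixed models. Because barn data of this kind are rarely
public, the package ships a first-class synthetic-barn generator calibrated
to published group-level values, so every estimator can be exercised against
known truth.

## The synthetic barn

`barn_config()` describes a 16-cow loose-housed herd (7 non-lame, 9 lame by
the majority-of-four locomotion-score rule), 12 feed stations, 22 study days,
three daily milkings (0730-1000, 1430-1630, 2130-2330, with a 40-min absence
per cow per milking) and a 30-min daily station-reset window (1145-1215)
during which eaten feed is never assigned to a cow.

Distributional choices (the sources print means and SDs, not families):

* per-cow feeding **rate** and visit **frequency**: lognormal, moment-matched
  to the group mean and between-cow SD — positive support and right skew are
  the natural choices for rates and counts of events;
* per-cow daily **intake** and **milk level**: normal truncated at a low
  floor;
* per-day visit **counts**: Poisson around the cow's frequency;
* visit **durations**: a gamma-proportioned split of the cow-day's feeding
  time budget;
* rumination **event durations**: gamma (shape 4), normalised to the day's
  rumination-time target.

Group means are the published least-square means (feeding frequency
60.3/33.9 visits/day, feeding rate 206/289 g/min, intake 39.4/33.8 kg/day,
milk 18.8/25.9 l/day for non-lame/lame); SDs are the published inter- and
intra-individual spreads. Two published days-in-milk trends are injected as
centred linear effects (feeding time +0.32 min/day per DIM, milk -0.05 l/day
per DIM); the intake trend (+0.07 kg/day per DIM) is deliberately **not**
injected because it already emerges as rate x time-trend (0.32 min/day x
~0.25 kg/min), and injecting it twice would double-count. A lame-only
frequency trend (+0.136 visits/day per DIM) induces the published
lameness-by-DIM interaction on mean intake per visit (-0.004 kg/visit per
day) through mvFMI = dFMI/dFfreq.

Daily **rumination time** is generated structurally, not as an independent
trait: `461 - 0.24 x dFR + 3.57 x dMY - 1.66 x lame + cow effect + day
noise` (min/day), the fitted rumination-association model of the source
study. This single mechanism reproduces both the published near-null
lameness contrast on rumination (implied group means 482/479 min/day) and
the -0.24 min/day-per-g/min coefficient that the M2-family fit must
recover, without either being set directly.

Two worlds, one generator. The published daily-level results (group LSMs)
and the published visit-level slope model (baseline 119 g/min, +36 g/min per
locomotion unit, +0.32 g/min per litre milk) are *not* mutually consistent
as one mechanism: the linear predictor gives a lame-group rate near 250
g/min, not 289. The package therefore exposes both calibrations:
`barn_config()` (rates drawn per lameness group; used for daily-model
recovery) and `m3_truth_config()` (rates built from locomotion and milk;
used for visit-level slope recovery). In the second world the cow's feeding
time is drawn independently of its rate (intake emerges as their product):
if time were intake/rate, fast cows would have systematically shorter visits
and the cow random slope would correlate with the design — an endogeneity
that biases *any* estimator of the no-intercept slope model by around -10%
on the baseline. Unbiased recovery presumes an exogenous design, so the M3
world is built exogenous.

The cap at 5 kg/visit is modelled as visit-ending (the station door rises;
duration and intake truncate together, so the implied rate is preserved)
with a 5% override probability — the publication states that overrides
happened but not how often; the value is configurable and was fixed before
any acceptance measurement.

What a green test does **not** establish: the generator has no social
dominance, station competition, estrus cyclicity, feed sorting, meal-level
ultradian structure, or autocorrelated day-to-day behaviour; visit counts
being Poisson makes the within-cow CV of daily feeding frequency (~17%)
larger than the published ~9%. Recovery tests validate the estimators
against this stated world, not the biology of any real herd.

## Feed-visit cleaning

Visits with zero duration are excluded. Per cow, intake is regressed on
visit duration through the origin (`slope = sum(d*f)/sum(d^2)`); the first
check flags visits more than 5 residual SDs off the line and visits shorter
than 4 s with more than 0.1 kg intake; the line is refit without them; the
second check repairs every flagged visit and every visit more than 5
residual SDs off the refit line. Repair is case-based: short visits with
real intake and long visits with low intake get a new duration
(`fmi/slope2`), large or negative intakes get a new intake
(`slope2 x duration`). "SD units" are read as residual standard deviations
of the relevant per-cow regression — the publication names the unit but
does not define it. Two boundaries the publication names but does not
quantify were fixed as: "large FMI" = above the 5-kg cap or above-line by
more than 5 SDs; "long visit with low FMI" = below-line by more than 5 SDs.
One deliberate extension: a *negative* intake is always repaired even when
inside the 5-SD band, because contaminated data inflate the per-cow SD
enough to hide small negative intakes, and a negative intake is physically
impossible. Pass-2 replacements are not themselves re-checked ("immediately
replaced" reads as a single second pass).

On contaminated synthetic data about 3.4% of visits are affected —
coincidentally and reassuringly the fraction the source study reports.

## Rumination classification

The published pipeline (windowed signal variance plus Fourier-spectrum
content, classified by a hidden Markov model, validated at 86.1%
sensitivity / 98.7% PPV against a pressure-sensor halter) cites an internal
reference for its details, so this module *reconstructs the stated design*
rather than re-implements a printed algorithm: 30-s windows on the 3-axis
resultant magnitude; per-window sample variance and band powers
(`sum |X_k|^2 / N^2` over band bins, DC excluded) in a 0.5-2 Hz chew band
and a 2-6 Hz broadband; natural-log transform (emission normality); a 2-3
state Gaussian-emission HMM fitted by EM with 5 restarts (forward-backward
and Viterbi in C++); the state with the highest mean log chew-to-broadband
ratio labelled rumination — a rule invariant to state permutation across
restarts. Consecutive rumination windows become events; gaps under 60 s are
merged; events under 120 s dropped. Every number above is a configurable
default, not a claim about the original device. Window length and state
count are knobs precisely because the publication does not state them.

The signal synthesiser gives rumination a ~1.1 Hz chew rhythm (plus a weak
second harmonic) mostly along the gravity axis — placed there so the rhythm
survives linearly in the resultant magnitude, where off-axis components
enter only quadratically — feeding a higher-variance broadband signature,
and everything else the noise floor; `snr` scales the signatures relative
to the floor.

## Mixed models

All three model families use a single random term per cow, so each cow's
covariance block is a rank-1 update `sigma^2 (I + lambda z z')`. The
deviance is profiled over `lambda` (Sherman-Morrison per block, O(n) per
evaluation), minimised on a log grid refined by Brent search (relative
tolerance 1e-9, boundary `lambda = 0` checked), with fixed effects by GLS
at the optimum. The engine reproduces lme4 log-likelihoods, estimates, SEs
and variance components to numerical precision on both random-intercept and
no-intercept random-slope models (oracle-tested; lme4 is used only as a
test oracle, never in the implementation path).

Conventions, chosen where the source is silent:

* Likelihood-ratio tests of fixed effects use **ML** fits (REML likelihoods
  are not comparable across fixed structures); reported coefficients and
  LSMs use **REML**. `lrt()` refits automatically.
* DIM enters as a continuous linear covariate (the published slopes imply
  linearity).
* RSS is the sum of squared **conditional** (BLUP-adjusted) residuals; the
  R-squared is `(RSS_null - RSS_model)/RSS_null` against the intercept +
  random-cow null. With conditional residuals a purely between-cow
  predictor (lameness) explains almost nothing beyond the cow effect, so
  single-effect R-squared values are smaller than the published ones —
  consistent with the definitional ambiguity noted as an open question.
* Least-square means hold continuous covariates at their fitted-row means
  (interactions at level x mean), random effects at zero, delta-method SEs.
* Stepwise reduction drops the highest-order non-significant interaction
  (largest p first) under marginality, never a main effect.
* AIC/BIC use `k = p + 2` (fixed effects + two variance parameters),
  matching lme4's counting. Model comparison tables are ML-fitted on the
  common complete-case rows (milk-recorded cow-days).
* The visit-level model is fitted with intake in grams and duration in
  minutes so the slope is g/min as published; no intercept (zero duration
  implies zero intake), random slope on duration per cow.

Intra-individual "mean" columns in the CV table are cow-day-weighted pooled
means while inter-individual means weight cows equally — with 8-22 days per
cow the two genuinely differ, which reproduces the published table's
apparent inconsistency; the convention is documented, not asserted against
the published numbers.

## Numerical and degenerate-input choices

Zero-SD generator configs degenerate exactly (no jitter). A residual SD of
exactly zero in cleaning flags every off-line point. Cows with fewer than
two usable visits, or a non-positive refit slope, pass through cleaning
unchanged with a warning. EM non-convergence after all restarts warns and
returns the best fit. Cow-days with no visits report zero sums and missing
per-visit means. An empty truth set makes sensitivity undefined (`NA`).
Log-features add an epsilon of 1e-12 before the log; emission variances are
floored at 1e-6.

## Reproducibility

Every generator takes a seed; a fixed seed fixes every output byte.
`run_pipeline()` writes CSV artifacts, model JSONs, a YAML config copy and a
manifest with a config checksum; rerunning with the same config and seed
reproduces the tables byte for byte. `scripts/acceptance.R` recomputes all
acceptance quantities from scratch: 50-seed recovery suites for the daily
and visit-level models, a 10-seed classifier suite, and the closed-form
worked examples.

## Known limitations

The classifier is validated against synthetic signals whose regimes are by
construction separable at the default SNR; real collar data add posture
drift, collar rotation and inter-cow variation that this module does not
model. The LMM engine supports exactly one random term (the study's
designs) — no crossed or nested structures, no Kenward-Roger or
Satterthwaite corrections (the likelihood-ratio test with 16 cows is
slightly anticonservative, visible in its type-I simulation sitting near
the top of the binomial band). The CV table's intra/inter conventions are
one defensible reading of an under-specified table.
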