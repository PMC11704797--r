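---
title: "Modelling long-term disability progression in PPMS from short-term trial data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term disability progression in PPMS from short-term trial data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Primary progressive multiple sclerosis (PPMS) accrues disability over
decades, but any one clinical trial observes each participant for only two
to three years, at an uncertain and self-reported point of their disease
course.  `ppmsprog` reconstructs the long-term, population-level timeline of
disability accrual from such short, irregular, multimodal series — EDSS,
timed walk, 9-hole peg test, SDMT, brain volume and lesion volumes — and
simultaneously estimates where on that timeline each individual sits.  The
per-subject discrepancy between observed disease duration and model-assigned
disease time then stratifies the cohort into slow, normative and fast
progressors, which feed confirmed-disability-progression (CDP) survival
analyses.

## Model

For subject $s$ with visits at observed disease duration $t$ (years since
reported symptom onset) and marker vector $y_s(t) \in [0,1]^K$ on the
quantile-score scale,

$$ y_s(t) = f(t - d_s) + \eta_s + \varepsilon, $$

where

* $f = (f_1, \dots, f_K)$ are population trajectories, one independent
  Gaussian process per marker with squared-exponential kernel, constrained
  to be monotone in each marker's declared direction;
* $d_s \sim N(0, \sigma_d^2)$ is the subject's time-shift: the visit at
  observed duration $t$ is modelled as occurring at the *reparametrized
  disease duration* (RDD) $\tau = t - d_s$;
* $\eta_s$ are per-subject, per-marker Gaussian random intercepts with
  variance $\rho_k^2$;
* $\varepsilon$ is heteroskedastic Gaussian noise with per-marker scale
  $\sigma_k$.

Monotonicity of the population curves is what makes the decomposition into
a common timeline plus individual shifts identifiable; the residual
translation invariance (shifting $f$ and all $d_s$ together) is fixed by
centring the shifts to mean zero.  The reparametrization parameter reported
per subject is $\delta_s = \mathrm{RDD} - \mathrm{ODD} = -d_s$: positive
$\delta$ means the subject carries more disability than their reported
duration suggests (fast progression).

### Inference

The trajectories are represented on $M$ inducing points spanning the
disease-time axis (subset-of-regressors: $f_k(\tau) =
k(\tau,Z)K_{ZZ}^{-1}u_k$, $u_k \sim N(0, K_{ZZ})$).  Monotonicity is a soft
constraint: virtual derivative observations on a dense grid are pushed
through a steep logistic link, so the posterior pays a rapidly growing
price for a wrong-signed derivative of the *population* curve (subject-level
data are not constrained).  Estimation alternates:

1. MAP update of each $u_k$ by BFGS on the penalized Gaussian likelihood;
2. per-subject shift update on the subject's *marginal* likelihood, with
   the random intercepts integrated out analytically (per marker the
   residual covariance is compound-symmetric, $\sigma_k^2 I + \rho_k^2 J$,
   so the profile is closed-form): a global grid search over the shift
   window followed by local refinement, with the shift prior as penalty;
3. recentring of the shifts (the identifiability gauge);
4. EM-style updates of $\sigma_k^2$, $\rho_k^2$ and $\sigma_d^2$ that
   include the intercepts' posterior variances, which prevents the
   variance-component collapse that plain MAP updates exhibit.

Convergence is declared when the relative change of the full negative log
posterior falls below `tol` (default `1e-5`) and is flagged — never silent —
otherwise.  After convergence one final shift pass runs through exactly the
same routine used by `stage_new_subjects()`, which is why self-staging of
the training cohort reproduces the fitted shifts exactly (up to the gauge).
Posterior uncertainty is Laplace-based: a Gaussian on $u_k$ at the MAP
(used by `sample_trajectories()`, `peak_rate_ordering()` and
`percent_change()`), and a one-dimensional curvature SD per shift.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_inducing` | 25 | – | ~2-year spacing over a ~50-year axis, well below the kernel lengthscale |
| `lengthscale` | range/4, clamped 2–15 | years | disability trajectories are smooth at the 5–10 year scale; the steepest plausible sigmoid has a feature width of ~5 years |
| `amplitude` | 0.6 | score units | prior SD of a curve around the marker mean; scores live in [0,1] |
| `mono_lambda` | 1000 | – | steep enough that the observed derivative-sign violations on a 200-point grid are zero at machine level; cheaper than a hard constraint |
| `shift_prior_sd` | 5 (then estimated) | years | weakly-informative start; the empirical update recovers the true spread within ~5% on the benchmark |
| `shift_max` | 3 × prior SD | years | global search window for shifts |
| `grid_step` | 0.05 | years | shift-search interpolation error ≪ noise scale |
| `noise_floor` | 1e-3 | score units | keeps noise-free synthetic fits well-posed |

All randomness in a fit flows from the single `seed` entry of
`gppm_control()`.

## The synthetic cohort generator

Because the motivating clinical-trial data are access-controlled, the
package ships a first-class generator whose defaults encode the study
conditions the pipeline is meant to face: visits every 2.76 months (with
0.15-month jitter) over follow-ups of mean 28.2 (SD 10.8) months; baseline
disease duration log-normal with median 6.3 years and IQR 3.7–9.8 years,
truncated at 45 years (longer durations are inconsistent with typical onset
ages and trial-entry ages); Gaussian time-shifts of SD 3 years, centred;
monotone sigmoid population trajectories on the score scale with staggered
midpoints (disability scales first, brain volume last, shallow lesion-volume
slopes); per-subject random intercepts (SD 0.04) and per-marker Gaussian
noise (SD 0.06 score units, a visually realistic scatter for quantile-scored
clinical measures); and trial-blocked missingness (SDMT only in one trial,
~24% of subjects; T1 lesion volume absent in another) mirroring how marker
availability differs across pooled trials.  The EDSS-like marker is also
emitted on the ordinal 0–10 half-point raw scale so CDP detection sees
realistic step data; the other markers get plausible raw-scale mappings
(seconds, points, ml).

What the generator does *not* emulate — and what green tests therefore do
not establish about real data: visit dropout correlated with disability,
relapse-associated fluctuations, non-monotone individual courses,
time-varying subject effects, floor/ceiling measurement artefacts beyond
simple clamping, and between-trial calibration differences in the assays
themselves.

## Preprocessing

Raw values are log-transformed for the right-skewed measures (lesion
volumes, timed walk, peg test) and converted to empirical quantile scores.
The convention is the mid-distribution CDF, $q(x) = (\#\{x_i < x\} +
\tfrac12\#\{x_i = x\})/n$, which handles ties symmetrically, gives exactly
0.5 at an odd-sample median, and clamps to $[0,1]$ out of sample.  With the
default `abnormal_high` orientation every marker's score runs 0 (normal) to
1 (most abnormal), and all fitted trajectories are non-decreasing; with the
`native` orientation the declining measures (SDMT, brain volume) keep their
direction and carry non-increasing constraints, matching the clinical
description of those markers.  Quantile maps are fitted on all pooled
visits (a baseline-only mode exists as sensitivity), serialized to JSON,
and re-applied — never refitted — to held-out cohorts.

## Subgrouping and outcomes

`classify_progressors()` applies the ±k·SD rule to the $\delta$
distribution (k = 1 default; 1.5 and 2 as sensitivity): G1 slow below,
G2 normative within, G3 fast above.  The SD is the plain sample SD of the
posterior-mean $\delta$; posterior uncertainty is deliberately not
propagated into the cutoff, the simplest reading of an SD-rule on estimated
parameters.  `null_classify()` is the ODD-only comparator: the same rule on
baseline observed duration (upper tail labelled G3).  Because the verbal
conventions for the sign of $\delta$ are ambiguous in the field, a
`flip_sign` flag is exposed; the default (fast = staged further along than
duration suggests) reproduces the clinical picture of fast progressors:
more disability at shorter duration.

CDP detection implements four rule families on raw scales: EDSS step
(1.0 point for baselines 3.0–5.0, 0.5 for 5.5–6.5; out-of-band baselines
get 1.0 below 3.0 and 0.5 at 7.0+, flagged and configurable), ≥20%
worsening for timed tests (equality qualifies), SDMT ≥3 points *or* ≥10%
with 6-month confirmation, and the confirmed-EDSS-6 milestone timed from
symptom onset (prevalent confirmed baselines count as events at baseline).
Confirmation means the first scheduled visit at least 3 (or 6) months after
the candidate also meets the criterion; in the default strict mode every
intermediate visit must too (sustained worsening), with a lenient mode by
flag.  The study baseline is fixed (no re-baselining; relapse rates in this
population are negligible).  Cox models use Efron tie handling — the right
choice for interval-scheduled, heavily tied visit data — with age at onset,
sex and treatment as multivariable covariates and an optional
treatment-by-subgroup interaction; Kaplan–Meier medians use log-log CIs and
the log-rank test is two-sided and uncorrected.

## Numerical choices and degenerate inputs

Kernel matrices carry a $10^{-6}$ relative jitter; the trajectory
derivative used by `peak_rate_ordering()` is analytic (kernel derivative),
not finite-differenced.  A marker whose posterior-mean total change is
below 0.05 score units has no meaningful peak: it is flagged undefined,
ordered last, and given an infinite-width interval (the threshold is the
scale at which constraint-induced drift on a flat marker becomes
indistinguishable from signal).  Markers with zero observations are dropped
with a warning; a subject with no usable observations makes staging error
(or is skipped by option); zero-variance $\delta$ distributions and empty
risk sets raise classed errors rather than propagating NaNs; an
all-tied-event log-rank variance (singular) yields an `NA` statistic with
the medians still reported.

## Problem sizes

The test-suite and acceptance benchmark sizes were chosen so the whole
pipeline exercises realistic structure at desk scale: the standard
parameter-recovery benchmark uses 150 subjects × 4 markers (~6 600
observations, fitting in under a minute), held-out staging 100 subjects,
ordering recovery 20 replicates of 120 subjects × 3 markers, survival
calibration 200 replicates of 1 000 subjects, and the CDP oracle an
exhaustive 31 200-series enumeration.

## Known limitations

The random effects are intercepts, not time-varying subject processes; the
noise is heteroskedastic across markers but not across time; trajectories
are strictly monotone at the population level, which oversimplifies
fluctuating courses; shift uncertainty is a Laplace approximation and is
optimistic in flat likelihood regions; and subgroup labels reuse the same
markers (notably EDSS) that drive the downstream endpoint analyses, a
circularity inherited from the analysis design itself.
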