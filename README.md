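# ppmsprog

Data-driven modelling of disability progression in primary progressive
multiple sclerosis (PPMS).

Clinical trials observe each PPMS participant for only ~2–3 years, at a
self-reported and uncertain point of a disease that unfolds over decades.
`ppmsprog` reconstructs the long-term population timeline of disability
accrual from such short multimodal series, and places every individual on
it.  It is aimed at biostatisticians and MS researchers analysing pooled
longitudinal trial data (EDSS, timed 25-foot walk, 9-hole peg test, SDMT,
normalized brain volume, T1/T2 lesion volumes), and at methodologists who
need a fully synthetic, ground-truthed sandbox for disease-progression
methods.

## The model

Measurements on the quantile-score scale are modelled as

$$ y_s(t) \;=\; f(t - d_s) \;+\; \eta_s \;+\; \varepsilon $$

* $f = (f_1,\dots,f_K)$ — monotone population trajectories, one Gaussian
  process per marker over a common disease-time axis;
* $d_s \sim N(0,\sigma_d^2)$ — a subject-specific time-shift mapping
  observed disease duration (ODD, years since symptom onset) to
  reparametrized disease duration (RDD $= t - d_s$);
* $\eta_s$ — per-subject random intercepts; $\varepsilon$ — per-marker
  Gaussian noise.

Monotonicity (enforced softly through virtual-derivative observations)
makes the timeline identifiable; shifts are centred as the gauge.  The
per-subject reparametrization parameter $\delta_s = \mathrm{RDD} -
\mathrm{ODD}$ classifies progressors by a ±k·SD rule: slow (G1), normative
(G2), fast (G3).  Downstream, confirmed-disability-progression (CDP)
events (EDSS step rules, ≥20% timed-test worsening, SDMT points-or-percent,
confirmed EDSS 6) feed Cox proportional-hazards contrasts and
Kaplan–Meier/log-rank comparisons between the subgroups.

Because the motivating trial datasets are access-controlled, the package
ships a seeded synthetic-cohort generator with known ground truth
(trajectories, shifts, subgroup labels, hazards) that emulates the pooled
trial setting: 2.76-month visit schedules, ~28-month follow-ups, log-normal
baseline durations (median 6.3 y), trial-blocked marker missingness.
Everything downstream is testable end to end against that truth.

## Worked example

```r
library(ppmsprog)

## synthetic PPMS-like cohort with known truth: 150 subjects, 4 markers
gen <- generate_cohort(sim_config(n_subjects = 150,
                                  specs = default_marker_specs()[1:4, ],
                                  shift_sd = 3, seed = 42))
gen$cohort
#> <ppms_cohort> 150 subjects, 4 markers, 6008 observations (native scale)

fit <- gppm_fit(gen$cohort, default_marker_specs()[1:4, ],
                gppm_control(max_iter = 30, seed = 1))
fit
#> <gppm_model> 4 markers, 150 subjects, timeline span 49.0 years
#>   markers: EDSS, T25FW, HPT9_D, HPT9_ND
#>   shift-prior SD 2.93 y; noise SD 0.057/0.060/0.062/0.060

cor(gen$truth$shifts[fit$shifts$subject_id], fit$shifts$d_mean)
#> [1] 0.891
```

The model compresses 150 short follow-ups into a 49-year disease timeline;
the estimated time-shifts correlate 0.89 with the generator's truth (whose
prior SD, 3 y, is re-estimated at 2.93 y).  The subgroup rule and the
temporal ordering of peak change follow:

```r
classify_progressors(fit, k_sd = 1)
#> <subgroup_assignment> k = 1 SD, n = 150
#>   G1 (slow) 26 (17.3%) | G2 (normative) 100 (66.7%) | G3 (fast) 24 (16.0%)

peak_rate_ordering(fit, n_samples = 100, seed = 2)
#>    marker tau_peak    lower    upper undefined
#> 1    EDSS     11.9     10.1     13.1     FALSE
#> 2   T25FW     18.0     13.5     21.1     FALSE
#> 3  HPT9_D     23.9     17.9     47.1     FALSE
#> 4 HPT9_ND     26.1     23.1     29.2     FALSE
```

The recovered ordering (EDSS first, then walking speed, then upper-limb
function) matches the generator's sigmoid midpoints at 12/18/24/26 years.
Overlaying shift-driven hazards and contrasting subgroups:

```r
ev <- generate_survival_overlay(gen$cohort, gen$truth,
                                c(G1 = 0.4, G3 = 2.5), seed = 3)
fit_cox(ev)
#> <cox_result>
#>  contrast         model               hr      p n_events
#>  G1 vs G2   univariable 0.44 (0.17-1.12) 0.0862        5
#>  G3 vs G2   univariable 2.13 (1.24-3.66) 0.0065       20
#>  G1 vs G2 multivariable 0.39 (0.15-1.01) 0.0519        5
#>  G3 vs G2 multivariable 2.52 (1.42-4.47) 0.0016       20
```

Fast progressors show roughly the doubled progression hazard that was
simulated.  `run_pipeline(run_config(...))` chains all of the above —
simulate/load, preprocess, fit, subgroup, outcomes, figures, tables — into
one seeded, reproducible run, and `stage_external()` scores held-out
cohorts against a trained model (missing markers tolerated).  A thin
command-line wrapper lives at `inst/cli/ppmsprog.R`.

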