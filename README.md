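# tinnitraj

Latent-class trajectory analysis of daily tinnitus symptom diaries.

## What problem this solves

Tinnitus treatment studies typically compare arms on pre/post
questionnaires, which hides how differently individual patients actually
evolve: some deteriorate, some never change, some improve early, some
late. Daily ecological momentary assessment (EMA) diaries — smartphone
prompts answered every evening on 0–100 visual analogue scales — capture
each patient's 12-week course day by day. `tinnitraj` is for
biostatisticians and digital-phenotyping researchers who want to ask
whether such individual trajectories cluster into a small number of
latent classes, and to characterise those classes.

At its core is a latent-class linear mixed model (growth mixture model):
subject *i* in latent class *g* (mixing proportions π_g) has

    y_ij = β_g0 + s(t_ij)' β_g + b_i + ε_ij,
    b_i ~ N(0, σ_b²),  ε_ij ~ N(0, σ²),

with s(·) a natural cubic spline of time in days (3 df), a random
intercept shared across classes and a residual variance constrained equal
across classes. Estimation is multi-start EM on the marginal likelihood
(30 starts × 30 burn-in iterations, best start run to convergence), with
posterior class probabilities, relative entropy and posterior probability
of membership (PPM) as classification diagnostics, and an explicit,
configurable triangulation rule (class sizes, entropy, PPM, BIC) for
choosing the number of classes.

Around the model, the package provides the full pipeline:

* a **synthetic-data generator** emulating the motivating 12-week study
  (147 subjects × 84 days, four trajectory classes, 22.5% raw
  missingness, five linked secondary symptom items, baseline/outcome
  tables) with full ground truth for recovery testing;
* **preprocessing**: long-CSV validation, compliance filtering
  (50% ⇒ 42 observations; 10% ⇒ 8), centred seven-day moving averages,
  robust outlier flagging, missingness reports;
* **class contrasts**: chi-square / one-way ANOVA across classes with
  Holm–Bonferroni adjustment, and pre/post questionnaire changes against
  minimal clinically important differences (THI = 11, TFI = 9, PHQ-9 = 6);
* **symptom dynamics**: per-class mean trajectories with confidence
  bands, weekly within-class loudness–distress correlations, and the
  intra-individually standardized loudness–distress difference.

Everything takes and returns tibbles, fitted models have `tidy()`,
`glance()`, `augment()` and `autoplot()` methods, and `run_pipeline()`
drives the whole chain from one configuration object.

## Worked example

Simulate the study-scale default panel, preprocess it as the analysis
prescribes, and fit the four-class model:

```r
library(tinnitraj)
library(dplyr)

sim <- simulate_ema(default_study_config(seed = 42))
sim
#> <ema_sim> 147 subjects, 57420 observed rows (6 items), 4 classes

filt <- compliance_filter(sim$panel, "tinnitus_related_thoughts", 0.5, 84)
sm   <- moving_average(filter(filt$panel, item == "tinnitus_related_thoughts"), 84)
missingness_report(filter(filt$panel, item == "tinnitus_related_thoughts"), sm, 84)
#> $raw_fraction       0.2250425
#> $smoothed_fraction  0.0001619695
#> $n_subjects         147

outcome <- filter(sm, !is.na(value)) |> select(subject_id, day, value)
fit <- lcgmm(outcome, G = 4, seed = 1)
fit
#> <lcgmm_fit> G = 4 classes, 147 subjects, 12346 observations
#>   loglik -30124.52 (npar 21), converged after 1 iterations
#>   proportions: 0.238, 0.347, 0.224, 0.190
#>   sigma_b 8.219, sigma_eps 2.625
```

The raw panel is 22.5% missing; the seven-day moving average all but
removes that missingness. The fitted mixing proportions are the seed-42
realisation of the generating proportions (18.4/40.1/20.4/21.1%), and the
variance components recover the generating σ_b = 8 (σ is smaller than the
generating residual SD 6 because the likelihood sees the smoothed series).
Classes are labelled by day-0 level, descending:

```r
predict_class_trajectory(fit, days = c(0, 42, 83))
#>    class   day estimate    se conf_low conf_high
#>  1     1     0     58.8  1.40     56.1      61.5   # early improvement
#>  2     1    42     34.6  1.39     31.9      37.4
#>  3     1    83     30.9  1.40     28.2      33.7
#>  4     2     0     41.2  1.16     39.0      43.5   # stable course
#>  5     2    42     34.0  1.15     31.7      36.2
#>  6     2    83     38.7  1.16     36.4      41.0
#>  7     3     0     37.8  1.44     34.9      40.6   # deterioration
#>  8     3    42     46.0  1.43     43.2      48.8
#>  9     3    83     55.0  1.44     52.2      57.8
#> 10     4     0     33.6  1.56     30.5      36.6   # late improvement
#> 11     4    42     35.4  1.56     32.4      38.5
#> 12     4    83     22.4  1.56     19.3      25.4
```

The four generating shapes come back clearly: a high-start early
improver (60 → 32), a stable course, a deteriorating class (38 → 56) and
a late improver (36 → 25). `glance(fit)` adds AIC/BIC, entropy and PPM;
`autoplot(fit)` draws the curves with their 95% bands;
`enumerate_classes()` + `select_model()` reproduce the class-count
triangulation; `augment(fit)` yields per-subject posteriors for the
contrast and dynamics modules. See the vignette
(`vignettes/trajectory-analysis.Rmd`) for the model, every default and
the design decisions behind them.

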