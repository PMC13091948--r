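---
title: "Latent-class trajectory analysis of daily tinnitus diaries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class trajectory analysis of daily tinnitus diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinnitraj)
library(dplyr)
```

## The scientific problem

Clinical tinnitus studies usually compare treatments on group-level changes
in retrospective questionnaires, which can mask large differences in how
individual patients evolve.  Daily ecological momentary assessment (EMA)
diaries -- smartphone prompts answered every evening on 0--100 visual
analogue scales (VAS) -- record each patient's symptom course at a
resolution where such heterogeneity becomes visible.  This package provides
the full analysis chain for asking whether individual 12-week symptom
trajectories cluster into a small number of latent classes: simulation of
realistic EMA panels with known class structure, preprocessing, latent-class
mixed-model estimation, class enumeration, baseline contrasts and
symptom-dynamics summaries.

## The model

For subject $i$ with (preprocessed) outcome values $y_{ij}$ at days
$t_{ij}$, the latent-class linear mixed model assumes an unobserved class
$c_i \in \{1,\dots,G\}$ with mixing proportions $\pi_g$ and, conditional on
$c_i = g$,

$$ y_{ij} = \beta_{g0} + \mathbf{s}(t_{ij})^\top \boldsymbol\beta_g
   + b_i + \varepsilon_{ij}, \qquad
   b_i \sim N(0, \sigma_b^2), \quad \varepsilon_{ij} \sim N(0, \sigma^2), $$

where $\mathbf{s}(\cdot)$ is a natural cubic spline basis of time in days
with three degrees of freedom (so each class mean is a smooth, possibly
non-linear curve), $b_i$ is a subject-level random intercept shared across
classes, and the residual variance is constrained equal across classes.
Marginally, a subject's observation vector is multivariate normal with
compound-symmetry covariance
$\Sigma_i = \sigma_b^2 \mathbf{J} + \sigma^2 \mathbf{I}$, and the
observed-data log-likelihood is the usual mixture form
$\sum_i \log \sum_g \pi_g \, \phi(\mathbf y_i; X_i \boldsymbol\beta_g, \Sigma_i)$.
The class-membership model is intercept-only: no covariates enter either
the trajectories or the mixing proportions.

`cs_loglik()` evaluates the per-subject Gaussian density through the
rank-one closed form
$\Sigma_i^{-1} = \sigma^{-2}[\mathbf I - \tfrac{\sigma_b^2}{\sigma^2 + n_i\sigma_b^2}\mathbf J]$,
$\det \Sigma_i = (\sigma^2)^{n_i-1}(\sigma^2 + n_i\sigma_b^2)$, never a
dense factorisation; the unit tests verify it against an explicit
matrix-inverse oracle to $10^{-8}$.

### Estimation

Estimation is by EM on the marginal likelihood:

* **E-step** -- posterior class probabilities
  $p_{ig} \propto \pi_g \phi(\mathbf y_i; X_i\boldsymbol\beta_g, \Sigma_i)$,
  computed with log-sum-exp stabilisation.
* **M-step** -- a weighted generalised-least-squares update of each
  $\boldsymbol\beta_g$ under the compound-symmetry covariance,
  $\pi_g$ as mean posterior, and Nelder-Mead maximisation of the expected
  complete-data likelihood over $(\log\sigma_b, \log\sigma)$.

Because the variance update only improves (rather than globally maximises)
its conditional objective, the algorithm is a generalised ECM; the
observed-data log-likelihood is still non-decreasing at every iteration,
which the test suite asserts on every simulated panel.  The reference
estimation tradition for these models uses a quasi-Newton (Marquardt)
optimiser instead; the contract here is "stationary point of the marginal
likelihood", verified through the ascent property and agreement of the
$G=1$ case with an independent mixed-model implementation (`lme4`) to
$10^{-6}$ in log-likelihood.

Multi-start estimation (`grid_search_fit()`) mirrors the standard protocol:
30 starts, each run for 30 EM iterations, the best continued to
convergence (relative log-likelihood change below $10^{-8}$), with one
retry at 50 starts after non-convergence.  Starts perturb the one-class
solution: $\boldsymbol\beta_g^{(0)} = \hat{\boldsymbol\beta}_1 +
c\,\mathrm{SE}(\hat{\boldsymbol\beta}_1)\,z$, $z \sim N(0,1)$, with
$c = 1$ by default, uniform mixing proportions, and -- an important detail
-- the starting random-intercept SD deflated to $\hat\sigma_b^{(1)}/G$.
The one-class $\hat\sigma_b$ absorbs exactly the between-class spread the
mixture is supposed to explain; started at that value, the posteriors stay
flat and EM can settle on a local maximum in which two classes share one
level (we observed a ~115-point log-likelihood deficit in a flat two-class
benchmark).  Deflating the start lets level differences be attributed to
classes first and to the random intercept only as needed.

Two numerical guards: $\sigma$ is floored at $10^{-4}$ to avoid degenerate
likelihood spikes, and a class whose total posterior mass falls below one
subject-equivalent marks the run as non-converged with a diagnostic rather
than returning a silently collapsed fit.

### Identifiability and labels

Mixture labels are arbitrary; after fitting, classes are reported ordered
by fitted mean at day 0 (descending) and the applied permutation is stored
in `$relabeling`.  Comparisons against ground truth or between runs use
explicit alignment: `align_labels()` maximises agreement over label
permutations, and `sensitivity_compare()` minimises summed curve distance
(exact enumeration up to 7 classes, greedy beyond).

### Spline basis

With `df = 3` the basis has two interior knots, placed at the terciles of
pooled observed days (boundary knots at the observed range); the reference
implementations do not publish their knot rule, so the knots are stored
with every fit.  Days are rescaled to $[0,1]$ before basis construction
for conditioning; predictions apply the stored transform, so curves are
always reported on the day scale.  Confidence bands for class curves are
pointwise delta-method intervals,
$\pm 1.96\,\mathrm{se}$, with $\mathrm{se}$ from the inverse of the
posterior-weighted GLS information block for that class -- a pragmatic
choice (the bands ignore uncertainty in the classification itself) made
explicit because the published figures do not state their CI construction.

## Preprocessing

The raw diary is long-format `(subject_id, day, item, value)` with missing
subject-days simply absent.  The pipeline applies, in order:

1. **Compliance filter**: retain subjects with at least
   `floor(fraction * days_total)` observed outcome days.  Rounding down is
   what reconciles the two published thresholds (50% of 84 days = 42
   observations, 10% = 8).  The default analysis uses 50%; 10% is the
   sensitivity setting.
2. **Seven-day moving average** per subject and item: a *centred* window
   (days $t-3$ to $t+3$, truncated at the study edges), mean of whatever
   raw values the window contains, undefined only if it contains none.
   Centred (not trailing) smoothing is chosen because the stated purpose is
   removing weekly periodicity symmetrically; the window width is the one
   design constant users should not change casually, since the fitted
   residual variance depends on it.  Edge days with partial windows are
   kept (truncation, not dropping) -- the alternative would shorten every
   series by six days.
3. **Outlier screening**: the published analysis removed one subject after
   visual inspection, which is not reproducible; the package instead flags
   subjects whose per-subject median of the smoothed outcome lies more than
   `k = 4` scaled median-absolute-deviations from the cohort median.
   Flags are reported, never auto-removed.
4. **Missingness accounting**: fractions of undefined subject-days before
   and after smoothing.  No imputation anywhere.

Smoothing before fitting has a knowable cost: it averages over overlapping
windows, so the residuals of the smoothed series are serially correlated
while the model assumes independence given the random intercept.  The
consequence shows up in class enumeration (below).

## Class enumeration and triangulated selection

`enumerate_classes()` fits $G = 1 \dots 10$ (configurable) and tabulates
log-likelihood, AIC, BIC (sample size = number of subjects, the convention
for subject-level mixtures), relative entropy
$1 - \sum_{ig} -p_{ig}\log p_{ig} / (N \log G)$, per-class mean posterior
of assigned members (PPM), and class sizes.  The entropy and PPM variants
are stated choices; "entropy" is used ambiguously in the literature.

On smoothed panels AIC and BIC keep decreasing past the generating class
count -- the ignored serial correlation overstates the information in each
subject, so extra classes keep "paying" for themselves.  The motivating
study saw exactly this on real data (no usable AIC/BIC minimum) and put
more weight on classification quality; on raw (unsmoothed) simulated
panels, where the model is correctly specified, BIC recovers the
generating $G$ -- the test suite checks both behaviours.

`select_model()` encodes the published judgment sequence as an explicit
rule set.  Solutions are flagged when they contain a class below 5%, did
not converge, or contain a *redundant* class pair -- two classes whose
fitted mean curves lie within each other's pointwise 95% bands on more
than 90% of study days.  The redundancy flag is the conservative
"avoid overfitting" judgment made operational: when a solution splits a
true class, the resulting twin curves sit a couple of VAS points apart
with strongly overlapping bands (in the study-scale simulations the
spurious split pair is typically ~2--3 points apart while genuinely
distinct classes stay 6+ apart), exactly the configuration the motivating
analysis used to dismiss its five-class solution.  Among unflagged
candidates with a preferred class count (default 3--5, following the
comparable literature), the rule keeps those within 0.01 of the best
entropy, among them those within 0.01 of the best mean PPM, and breaks
the remaining tie by BIC.  The tolerances exist because entropy and PPM
of well-separated solutions differ in the third decimal; a strict
lexicographic rule would reduce the triangulation to "highest entropy
wins" and never consult the other criteria.  Without the redundancy flag
the BIC tie-break systematically favours the larger near-tied solution on
smoothed data (where BIC has no interior minimum), which inverts the
published conservatism.  Every parameter of the rule is configurable and
the report lists all candidates with reasons.

## The synthetic-data generator

Since the patient-level diaries are not publicly deposited, the generator
is the package's study stand-in, with the study's printed design as
defaults (`default_study_config()`): 147 subjects, 84 days, four classes
with proportions (18.4%, 40.1%, 20.4%, 21.1%) and anchor points
deterioration (0, 38) to (83, 56); stable (0, 41), (34, 34), (83, 39);
early improvement (0, 60), (42, 36), (83, 32); late improvement (0, 36),
(26, 40), (83, 25); and 22.5% raw missingness.  Between anchors the class
mean is a shape-preserving monotone cubic (Fritsch--Carlson), which passes
exactly through the anchors and cannot overshoot the 0--100 scale; only
start/turning/end values are published, so any interpolant is a choice and
this one is the most conservative.

Two generating parameters are not published anywhere: the random-intercept
and residual SDs.  The defaults $\sigma_b = 8$, $\sigma_\varepsilon = 6$
VAS points were fixed once as a realistic regime for daily VAS diaries --
subject-level heterogeneity comparable to but not dwarfing the class
separations (which span roughly 15--25 points), day-to-day noise large
enough that single days are uninformative, and implied class-trajectory
confidence bands of the same order as the published ones.

Secondary items (daily tinnitus distress, maximum and momentary tinnitus
loudness, jaw tension, negative emotion -- the emotion item is emitted
already reverse-coded) are linear in the primary outcome plus Gaussian
noise, with offsets/slopes chosen to reproduce the qualitative published
pattern: distress tracks the outcome closely, loudness sits high with a
weak link, jaw tension low.  The published relationships are figures, not
tables, so these links are qualitative by construction.

Missingness removes whole subject-days: MCAR draws the target number of
cells uniformly (realised fraction within rounding of the target); MAR-age
weights cells by $\exp\{0.06\,(\text{age}_i - \bar{\text{age}})\}$,
emulating the reported weak positive association of missingness with age
and nothing else.  Day 0 is the first treatment day; days run 0--83.
A single seed governs every draw, so panels are byte-reproducible.

What the generator deliberately does not emulate: streaky (burst-like)
missingness -- under MCAR, seven-day windows are almost never empty, so
smoothing removes nearly *all* missingness rather than leaving the ~3%
reported for real diaries; bounded-scale censoring (values are clamped,
the fitted model ignores bounds -- tolerable because the default class
means stay 20+ points away from both bounds); within-day timing structure;
treatment-arm effects; and dropout processes.  Passing recovery tests
therefore demonstrate correctness of the estimation machinery under the
stated generative model, not robustness to everything real EMA data can
do.

The baseline table generator draws demographics, questionnaire scores
(THI/TFI 0--100, PHQ-9 0--27), personality and history variables in their
published ranges, independent of class by default -- the null scenario
matching the study's finding that baseline variables do not predict class
membership -- with optional class-linked shifts for power studies.
Post-treatment scores add class-specific mean changes chosen so that the
MCID pattern of the published PROM analysis can be reproduced on synthetic
data (e.g. the stable class improves clinically on TFI but not THI).

## Contrasts and dynamics

`contrast_baseline()` runs one chi-square test per categorical variable
(Pearson, no continuity correction) and one classical one-way ANOVA per
continuous variable (the published table does not state Welch vs classical;
classical is the default here), with a single Holm family across all
testable variables, matching the 15-test family of the published baseline
table.  `holm_adjust()` is the plain step-down rule; it reproduces the
published family (15 p values between 0.09 and 0.94) adjusting to all 1s,
and agrees with `p.adjust(method = "holm")` on random inputs.

`prom_change_by_class()` evaluates pre-to-post changes per class against
MCID thresholds THI = 11, TFI = 9, PHQ-9 = 6, using a paired t-test
against zero change (the published analysis reports significance without
naming the test) with Holm families per instrument.  A mean improvement
exactly at the MCID counts as clinically relevant (documented boundary
rule, configurable).

`weekly_class_correlation()` pools all subject-days within a class-week
(the published text does not say pooled vs per-subject-averaged; the
averaged variant is available via `by_subject = TRUE`), on smoothed values
by default.  `standardized_difference()` computes
$d = \text{max loudness} - \text{distress}$ per day and standardises it
within subject with the sample (n-1) SD; subjects with constant $d$ are
reported and excluded from class summaries.  The class-level daily mean of
$z$ is accompanied by a loess trend (span 0.75, stated rather than hidden,
since the published figure names only a generic smoother).

## Problem sizes and tolerances used in the tests

The test suite runs the full study-scale recovery (147 subjects, 84 days,
22.5% MCAR, $G = 4$, 30 starts) and a ten-replicate enumeration study at
$G = 1\dots6$ with 10 starts per fit -- sizes chosen so the whole suite
completes in about a minute while leaving the study conditions themselves
untouched.  Analytical identities are tested to $10^{-8}$ or tighter;
stochastic recovery checks use the pre-stated bands (mixing proportions
within 0.05, class curves within 3 VAS points RMSE, assignment accuracy at
least 0.90, type-I error within 0.03--0.07 at $\alpha = .05$ over 1000
null cohorts).

## Known limitations

* The model ignores the serial correlation induced by smoothing; fitted
  $\sigma$ is a property of the smoothed series, not the raw diary, and
  information criteria on smoothed data overstate evidence for more
  classes (see above).
* Classes that differ only in *level* (identical shapes) are weakly
  identified against the shared random intercept, especially on smoothed
  panels of modest size, where the likelihood can genuinely prefer a
  large-$\sigma_b$ solution with nearly coincident class curves; the
  redundancy flag marks such solutions.  Classes that differ in shape --
  the situation the trajectory analysis targets -- are identified through
  the whole curve and recover reliably.
* Confidence bands condition on the estimated classification.
* No random slopes, class-specific variances, membership covariates, MNAR
  mechanisms, or bounded-outcome likelihoods; these are out of scope by
  design.
* The triangulation rule makes the published judgment reproducible but is
  still a rule; its tolerances are reportable parameters, not truths.
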