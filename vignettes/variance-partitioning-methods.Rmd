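---
title: "Partitioning trait (co)variation between and within individuals under treatment structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait (co)variation between and within individuals under treatment structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Ecotoxicological experiments increasingly ask not only whether a stressor
shifts the *average* of a trait, but whether it reshapes variation *between*
individuals (individuality), variation *within* individuals across repeated
measures (plasticity/predictability), and the between-individual
*correlations* that link behaviour, life history and reproductive allocation
into a pace-of-life syndrome (POLS). `polsvar` implements the full analysis
path for the canonical design behind these questions: `K` exposure
treatments, replicate mesocosms (semi-natural housing populations) nested in
treatment, individuals nested in mesocosm, a pair of behavioural traits
measured on repeated trials, and a set of morphological and ejaculate traits
measured once per individual.

## The model

For individual $i$ in treatment $k$ and mesocosm $m$, the value of trait $t$
on occasion $o$ is modelled as

$$y_{itmo} = \mu_t + \beta_{kt} + \gamma_t\,(o - 1) + b_{mt} + u_{it} +
\varepsilon_{itmo},$$

with

* $\mu_t$: per-trait intercept (reference treatment, first trial);
* $\beta_{kt}$: treatment offsets under reference coding;
* $\gamma_t$: a linear trial slope, present only for the repeated
  (behavioural) traits, acting on the left-centred occasion index so the
  intercept sits at the first trial. One slope per behaviour, shared across
  treatments, because habituation across an open-field trial series is a
  population-level process and the design (three trials) cannot support a
  slope-by-treatment interaction of useful precision;
* $b_{mt} \sim N(0, \sigma^2_{\text{meso},t})$: mesocosm random intercepts,
  independent across traits with a common per-trait SD across treatments —
  with only four mesocosms per treatment, a treatment-specific or
  cross-trait-correlated mesocosm structure is not estimable, so we do not
  pretend to estimate it;
* $u_i \sim \mathrm{MVN}(0, \Sigma_B^{(k)})$: the individual
  random-intercept vector, with one full $T \times T$ between-individual
  covariance matrix per treatment. This is the object of scientific
  interest: its diagonal gives treatment-specific individuality, and its
  off-diagonal the syndrome correlations;
* $\varepsilon$: residuals, independent across traits within an occasion.
  Repeated traits get a treatment-specific residual variance
  $\sigma^2_{W,kt}$ — the within-individual (plasticity) component. Traits
  measured once cannot separate a residual from $u$, so their residual
  variance is pinned to the small reference value $0.01$ and their
  between-individual variance absorbs essentially all non-mesocosm
  variation.

Residual correlations across traits are deliberately excluded: for the
once-measured traits a residual correlation matrix is ill-posed (their
residuals are pinned), and between-trait association is then carried
entirely — and interpretably — by $\Sigma_B^{(k)}$.

All responses are z-scored (one global mean/SD per trait, pooled over
treatments and trials) before fitting; `standardize_traits()` records the
per-trait parameters for exact back-transformation. Pooling is intentional:
standardizing within treatment would erase the very mean differences the
model estimates.

## Priors and sampling

The sampler is a fully conjugate block Gibbs scheme written for this model:

* fixed effects: joint Gaussian conditional under a $N(0, 1)$ prior
  (standardized scale);
* mesocosm and within-individual variances: inverse-gamma$(1, 0.1)$ priors
  and conditionals. The shape/rate were chosen once for z-scored traits: the
  prior is diffuse above $0.05$ and does not pull a 12-mesocosm variance
  estimate upward the way a sharper inverse-gamma would;
* each $\Sigma_B^{(k)}$: inverse-Wishart with $T + 2$ degrees of freedom and
  scale $0.5\,I$ (prior mean $0.5\,I$, correlations centred on zero),
  giving an inverse-Wishart conditional. Posterior draws are reported as SD
  vectors plus correlation matrices, so syndrome correlations come straight
  out of the chain.

We chose the inverse-gamma/inverse-Wishart family over half-Exponential SDs
with an LKJ correlation prior so that *every* full conditional stays in
closed form: a Metropolis layer over three $8\times8$ correlation matrices
mixes poorly at this scale, whereas the conjugate chain is exact,
reproducible and fast. The practical prior weight is similar (about
$T+2$ pseudo-individuals against 48 real ones per treatment), and the
`"flat"` flavour ($N(0, 100)$ fixed effects, inverse-gamma$(0.001, 0.001)$,
inverse-Wishart $df = T+1$, scale $0.1 I$) exists precisely to verify that
conclusions do not ride on this choice — on study-size synthetic data the
fixed-effect posterior means move by less than $0.1$ SD units between
flavours (checked in the test suite).

Two implementation points matter for correctness and speed:

1. **Partial collapsing.** With residual variance pinned at $0.01$, a naive
   Gibbs sweep barely moves the fixed effects: $u_i$ tracks the data almost
   exactly and the chain crawls (we observed split-Rhat near 1.9). The
   sampler therefore updates the fixed effects and the mesocosm effects from
   the likelihood with $u$ *integrated out* (each individual's rows have
   marginal covariance $\Sigma_B^{(k)}[t, t'] + \mathrm{diag}(r)$), then
   regenerates $u$ from its exact conditional before the variance updates.
   The composite kernel leaves the joint posterior invariant and restores
   honest mixing (split-Rhat $\le 1.01$ at the reference settings).
2. **Pattern sharing.** Individuals with the same treatment and the same
   trait/occasion layout share one Cholesky factorization per sweep, so the
   per-iteration cost stays a few milliseconds for 1728 observations.

Reference sampler settings are 4 chains of 8000 iterations, 3000 warmup,
thinning 2 — 10000 retained draws. Chain $c$ is seeded `seed + c - 1`;
identical seeds give bit-identical draws, and the input row order is
canonicalized so permuting the data changes nothing. Convergence is checked
with split-chain Rhat (flag above 1.01) and bulk effective sample size
(flag below 400); a flagged fit warns and records the state in its
metadata — never silently.

## Posterior summaries

All intervals are equal-tailed posterior quantiles, reported at both 89% and
95%; the package's "supported" flag means the 89% interval excludes zero.
Equal-tailed intervals (rather than highest-density ones) match the summary
convention of the mixed-model software ecosystem this analysis style comes
from.

* `delta_v()` — the variance contrast $\Delta V$: the draw-wise difference
  between two posterior variance-component distributions (between-individual
  for any trait, within-individual for repeated traits). Because published
  $\Delta V$ signs are notoriously ambiguous about which group is the
  minuend, the output always labels both groups and the sign convention is
  explicit: `V(group_a) - V(group_b)`.
* `between_individual_correlations()` — the posterior of each unique pair of
  $\Sigma_B^{(k)}$ correlations, per treatment.
* `repeatability()` — draw-wise $V_B / (V_B + V_W)$ for repeated traits.
* `summarize_fixed_effects()` / `summarize_variances()` — the full effect
  and variance-component tables.

No multiplicity correction is applied across the 28 correlation pairs; the
reporting convention is estimation-based (CIs), not hypothesis testing.

## Trait derivation

The raw-measurement helpers implement the standard phenotype definitions:

* body condition as the scaled mass index
  $SMI = M (L_0/L)^{\beta}$, with $\beta$ the standardized-major-axis slope
  of $\ln M$ on $\ln L$ computed as OLS slope divided by the Pearson
  correlation (the Peig–Green estimator; `fit_sma_slope()` reproduces a
  brute-force first-principles regression to machine precision, and equals
  3 exactly on cubic data). Defaults in `smi_params()` are $\beta = 3.203$
  and $L_0 = 17.43$ mm;
* coloration as (orange + black patch area) / body area;
* sperm vitality as pooled live / (live + dead) over counting subsamples;
* sperm count as the subsample mean of (live + dead) scaled by an explicit
  dilution factor and chamber-volume scale — explicit because haemocytometer
  geometry and extender volume vary between protocols and the counting
  formula should never be implicit;
* sperm velocity as the tracked-count-weighted mean of per-sample VCL.
  "Accounting for the number of sperm tracked" is read as weighting (a
  sample in which twice as many cells were tracked carries twice the
  weight); `mean_vcl(weighting = "equal")` is the switch for the unweighted
  reading.

## The synthetic-data generator

`generate_population()` is the exact generative mirror of the fitted model —
same linear predictor, same random-effect structure, same residual rules —
so parameter-recovery tests are well-posed. The built-in `"paper-like"`
scenario encodes the study conditions: 3 treatments x 4 mesocosms x 12
males, three trials on two behaviours; treatment effects, trial slopes and
within-individual variances at the reported posterior means of the exposure
study (e.g. control-minus-low within-individual variance contrasts of 0.307
for activity and 0.259 for refuge use); a negative activity/refuge
between-individual correlation (-0.4 in the control group); and
dose-specific between-individual variance in body condition (highest under
high exposure) and sperm count (highest under low exposure). Mesocosm SD is
set to 0.25 on the standardized scale — a modest housing effect of the size
one expects from replicate tank systems; the study reports no value for it.
The `"null"` scenario zeroes all effects and correlations for calibration
checks, and `"strong-syndrome"` exaggerates the fast–slow axis for power
demonstrations.

What the generator does *not* emulate: non-Gaussian trait distributions
(raw activity and refuge-use times are bounded and skewed before
standardization), missing-not-at-random ejaculate failures, observation-level
correlation between the two behaviours scored in the same trial, and any
mesocosm-by-trait covariance. Passing recovery tests therefore show the
inference machinery is correct for the stated model, not that the model is
true of real fish.

## Validation summary (what the tests compute)

* the joint log posterior matches an independently coded brute-force
  term-by-term sum to $10^{-10}$ on random tiny instances;
* on a conjugate toy model the sampler matches the closed-form posterior
  mean and SD within three Monte-Carlo standard errors;
* over 20 replicate study-size populations under the `"paper-like"` truth
  (shortened chains: 2 x 700 iterations), pooled 95% credible-interval
  coverage of all 148 generating parameters is at least 90%, and the
  negative control-group activity/refuge correlation is recovered with the
  correct sign in at least 18 of 20 replicates;
* under the `"null"` scenario the 89% intervals of treatment effects
  exclude zero in no more than the nominal 11% of cases plus simulation
  error;
* same-seed refits are bit-identical, and prior-only sampling reproduces the
  stated prior distributions (Kolmogorov–Smirnov checks at 5000 draws).

The replicate counts and shortened chain lengths above are the problem sizes
the test suite uses; the acceptance script refits one study-size population
at the full reference settings (4 x 8000 / 3000 / thin 2).

## Known limitations

* The Gaussian likelihood is assumed, not checked; heavy-tailed or bounded
  traits should be transformed before standardization.
* Once-measured traits cannot separate within-individual variance from
  between-individual variance; the 0.01 pinned residual is a convention, and
  their "between-individual variance" is really total non-mesocosm variance.
* With four mesocosms per treatment, treatment effects and mesocosm effects
  are weakly separated; treatment CIs are honest about this (they are wide),
  and the null-scenario calibration is conservative.
* The inverse-Wishart prior shrinks large correlations toward zero by the
  equivalent of about ten pseudo-individuals; with 48 individuals per
  treatment this is visible (a true correlation of -0.4 posterior-means
  around -0.33) but the sign and interval behaviour are unaffected.
* Missing cells are skipped in the likelihood under an ignorability
  assumption, not imputed.
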