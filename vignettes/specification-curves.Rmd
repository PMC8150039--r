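---
title: "Specification curves for dysregulated gaming and well-being: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specification curves for dysregulated gaming and well-being: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analytic problem

Survey studies of dysregulated ("problematic") gaming face a garden of
forking paths: several competing severity instruments exist (full scales,
core-criteria subsets, single diagnostic items), well-being can be
operationalized as general mental health, depressive mood, or life
satisfaction, many covariates have literature precedent, and extreme-playtime
respondents can be justifiably kept or excluded. Any single published model
is one draw from this space. `specwell` implements the multiverse
(specification curve) approach: enumerate *every* justifiable specification,
fit them all, and base inference on the distribution of effect sizes rather
than on a single model.

The default space crosses

* 3 well-being outcomes (general mental health; absence of depressive mood,
  i.e. the reversed depressive-mood score; life satisfaction),
* 9 dysregulated-gaming operationalizations (five instruments, two of them in
  9-/11-item and core-criteria variants, plus a composite covering both the
  DSM-5 and ICD-11 criterion sets),
* 18 covariate sets (none, each of 16 single covariates, all 16), and
* 2 subsample rules (playtime outliers kept or excluded),

for 3 × 9 × 18 × 2 = 972 ordinary least-squares models. An item-level mode
replaces the nine scale scores with the 15 single DSM-5/ICD-11 items
(1620 models).

## Per-model estimator

Each specification is the linear model
$z(y) = \beta\, z(x) + \sum_k \gamma_k c_k + \varepsilon$
fitted on the subsample implied by the outlier choice. The outcome, the focal
severity score and all continuous covariates are z-scored **within that
subsample** (the alternative, standardizing once globally, is available by
pre-standardizing the input; results are identical when the subsample is the
full sample). Gender (three levels, reference: female) and education (two
levels, reference: tertiary) enter as unstandardized indicator contrasts;
only the male and secondary-education contrasts are summarized, the sparse
"other gender" level stays in the model but is not reported. With no
covariates, $\hat\beta$ is exactly the Pearson correlation and the
semipartial $\Delta R^2$ is exactly $\hat\beta^2$; both identities are kept
as numerical tests. $\Delta R^2$ is always computed by a full refit without
the focal variable (entire factors are dropped for categorical variables)
rather than by an analytic shortcut, so it remains exact under collinearity.
Two-sided p-values come from the t distribution; no multiple-testing
correction is applied, because the curve, not any single model, is the unit
of inference.

### Curve summaries and the median-model interval

For a variable's distribution over the models containing it we report the
median, minimum and maximum point estimate, the median semipartial
$\Delta R^2$, and a confidence interval taken from the *model holding the
central-most estimate*. With an even model count the interval is built from
the mean of the two central estimates and the mean of their standard errors,
with the t quantile at the (rounded) mean of the two residual degrees of
freedom — a choice the even-count rule leaves open; the effect of the
rounding is far below reporting precision. Specifications with a
zero-variance focal predictor are retained as flagged rows and excluded from
summaries with a message, never silently dropped.

## Decomposed variance

To attribute curve variance to decision classes we fit the crossed
random-effects null model
$\beta_i = \mu + u_{\text{outcome}(i)} + u_{\text{predictor}(i)} +
u_{\text{covariates}(i)} + u_{\text{subset}(i)} + e_i$
with independent zero-mean random effects, by REML (`lme4::lmer`). Each
class's intraclass correlation is $\sigma^2_k / (\sum_j \sigma^2_j +
\sigma^2_e)$; the headline output renormalizes over the four decision
classes so the shares sum to 100% (the residual-inclusive ICCs are also
reported, since with fine-grained decision grids the residual is not always
negligible). Negative component estimates are truncated at zero. On balanced
grids REML coincides with the Henderson/ANOVA method-of-moments estimator
(expected mean square $\sigma^2_e + (N/a_k)\sigma^2_k$ per main effect); the
package carries that estimator both as an independent cross-check (agreement
to 1e−3 is asserted in the tests) and as the fallback when REML errors.
Classes with a single level are fixed at zero; an all-constant curve returns
an all-zero, flagged decomposition.

## Scale psychometrics

Each operationalization is examined as a one-factor model. The maximum
likelihood discrepancy
$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$
is minimized over loadings $\lambda$ and uniquenesses $\theta \ge 0$ with
unit factor variance, using analytic gradients from a principal-axis start
plus three random restarts (best solution kept, tie tolerance 1e−10;
convergence tolerance well below 1e−8 on $F_{ML}$). Reverse-worded items are
recoded to the scored direction before factoring — skipping this produces
mixed-sign loadings and a collapsed omega, which is asserted in the tests.
Then $\chi^2 = (n-1)F_{ML}$ with $df = p(p+1)/2 - 2p$, and:

* CFI against the independence baseline ($\Sigma_b = \mathrm{diag}(S)$,
  $df_b = p(p-1)/2$);
* RMSEA $= \sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$ with a 90% interval from
  inverting the noncentral $\chi^2$ distribution in its noncentrality
  parameter (root-finding; a grid-search inversion serves as the test
  oracle). Four-item scales have $df = 2$ and wide intervals; with $df = 0$
  the RMSEA is reported as 0 with a caution flag;
* SRMR over standardized residuals including the diagonal.

Reliability is coefficient omega,
$\omega = (\sum\lambda)^2 / ((\sum\lambda)^2 + \sum\theta)$ — for a
unidimensional model this is the only omega variant defined, and it is how
the "hierarchical omega" of common reporting reduces under one factor. Its
confidence interval is a bias-corrected and accelerated (BCa) bootstrap over
respondents: $z_0$ from the fraction of bootstrap statistics below the
observed value, acceleration from the jackknife third-moment formula,
endpoints at the adjusted quantiles. Degenerate bootstrap distributions
collapse to a point interval with a warning. Estimation is plain ML
throughout: the package's validation data are generated multivariate normal
before discretization, where robust (sandwich-corrected) ML and plain ML
agree asymptotically; a robust correction is a natural extension point but
is not implemented, and comparisons against robust-ML results on real Likert
data should expect small differences in $\chi^2$-based indices. Items are
treated as continuous (no polychoric option), matching common practice of
running ML on raw 1–5 scores.

Two estimator facts worth knowing: (i) at the independence null the
one-factor model is unidentified — a single-item "spike" factor fits exactly
as well as all-zero loadings, and the sample MLE typically is such a spike
(so do not read individual loadings of a non-correlating item set; the
model-implied shared covariances are the identified quantity); (ii) the
reported solution is normalized to a positive loading sum, resolving the
global sign indeterminacy.

## The synthetic survey generator

The generator defines the study conditions the pipeline is validated under;
it is first-class, tested code.

**Mechanism.** Four latent constructs — dysregulation $D$ and well-being
$W_1$ (general mental health), $W_2$ (absence of depressive mood), $W_3$
(life satisfaction) — are drawn multivariate normal. Each item is
$y^* = g_j \lambda_j F + \sqrt{1-\lambda_j^2}\,\epsilon$, discretized at four
thresholds into 1–5 responses (graded-response-style, matching the
one-factor CFA assumption). Items worded against the scored direction
($g_j = -1$: the negatively-phrased behavioural-addiction items, the
distress-worded mental-health items, and the whole depressive-mood scale,
whose *scale score* is reversed) use mirrored thresholds $-\mathrm{rev}(\tau)$,
which makes the reverse-coded response exactly equal in distribution to a
positively worded item — so reverse-coding logic is exercised without
distorting the marginals.

**Attenuation compensation.** Mean scores over discretized items correlate
with their factor at $a < 1$. The generator computes $a$ analytically —
univariate item moments are exact; cross-item covariances use the Hermite
expansion $\mathrm{cov} = \sum_m \rho^m/m!\, A_m(\tau_j)A_m(\tau_k)$
truncated at $m = 3$ (omitted terms $< 10^{-3}$ at the default loadings) —
and, by default (`effects_are_observed = TRUE`), inflates the latent
correlations so that the *observed* score correlations land on the
configured targets for a reference operationalization (the 11-item DSM-5
scale). Other operationalizations then differ by their attenuation ratios,
which is precisely the realistic between-scale variation the predictor
decision class measures. In latent mode the entries are used directly and
the recorded attenuation factors let tests verify the disattenuated
correlation. Positive definiteness is re-checked after compensation.

**Defaults as study conditions.** 743 starters; 38.9% abandon at a
page sampled with heavy early weights (most dropout within the first three
measures); 6.6% of completers respond carelessly (constant or repeating
1-2-3 patterns, always failing at least one of the two attention checks);
~5% of attentive completers get extreme playtime implanted so they exceed
the 3-SD flag with certainty. Counts are deterministic
(`round(rate * n)`); membership is random under the seed. Observed effect
targets default to −0.40/−0.47/−0.33 (general mental health / absence of
depressive mood / life satisfaction), the per-outcome medians of the
emulated study. Gaming items use thresholds (−0.5, 0.5, 1.5, 2.5) — mean
scores near 2, matching low symptom endorsement in community samples —
and well-being items (−2.2, −1.2, −0.3, 0.7), means near 3.7; real
item-level distributions are not published, so these are stated conventions,
not reproductions. Loadings default to 0.65–0.75 with the
"conscious choice" behavioural-addiction item at 0.28, reproducing that
scale's known weak item. Age is 16 + gamma (mean ≈ 24); gender proportions
307:113:4 (female reference; a small male shift on the well-being latents
mirrors the emulated male contrast and exercises sparse-category handling);
weekly playtime and session length are lognormal (right-skewed, so the 3-SD
rule flags a nonempty set) with weak loadings on $D$; the eight gaming
motivations and three need satisfactions are generated directly as 1–5
scale scores with weak configured loadings on $D$ and mean well-being —
no analysis in scope consumes their item responses, so item-level generation
is not simulated for them.

**What the generator does not emulate.** Real response styles
(acquiescence, midpoint preference), item-level missingness (only page-level
dropout), multidimensional gaming scales (every instrument loads one common
factor, so the full-scale vs core-criteria contrast and the scale-fit
differences seen in real data are compressed), cultural/language effects,
and zero-playtime respondents (the flag rule handles them; the generator
never produces them). Passing recovery tests therefore shows the *pipeline*
is correct and calibrated under its assumed measurement model — not that
real instruments are unidimensional or that real effects equal the defaults.

## Cleaning and scoring rules

The cascade removes incomplete respondents first, then attention-check
failers, and reports counts at each stage with exact conservation
($n_{initial} = n_{incomplete} + n_{careless} + n_{retained}$). Sensitivity
mode disables both removals (incomplete respondents then drop out of
individual models listwise). Scores are item means after reverse coding
(reverse item $r$ contributes $6-r$); depressive mood is reversed at the
scale level into absence of depressive mood. Weekly game time is
$5\times$ weekday $+\ 2\times$ weekend hours. Outliers are respondents at or
above mean + 3 SD in weekly hours *or* session minutes — SDs computed on the
cleaned sample before any outlier removal — plus anyone reporting zero
weekly hours; the zero-hours case is grouped with the high-playtime outliers
(the emulated study discusses them as one in/exclusion set; treating the
zero-hours case separately would change at most one respondent's flag). A
zero SD disables the corresponding rule rather than flagging everyone.
Education is collapsed to two levels (secondary vs tertiary) at ingestion.
Scores are carried at full precision; rounding happens only in reports.

## Numerical choices and degenerate inputs

* CFA optimization: `nlminb` with analytic gradients, $\theta \ge 10^{-8}$,
  relative tolerance 1e−14, four starts, tie tolerance 1e−10.
* Noncentrality inversion: bracketed root-finding to 1e−9, doubling upper
  bracket; noncentrality 0 returned when the observed $\chi^2$ is below the
  target percentile at zero.
* BCa: the bootstrap-below-observed proportion is clipped to
  $[1/2B,\ 1-1/2B]$ so $z_0$ stays finite; an optional grouped jackknife
  (`jack_groups`) trades a little accuracy in the acceleration constant for
  large savings with expensive statistics.
* Curve ordering for figures: ascending $\hat\beta$, ties broken by
  enumeration index, so figures are deterministic.
* Box plots use standard 1.5 × IQR whiskers for fliers; the
  "±1.58 × IQR/√n" formula sometimes quoted in figure captions is the notch
  half-width, not a flier rule, and is not used.
* Rank-deficient models raise an error naming the collinear columns.

## Simulation sizes used by the test suite

Chosen as the smallest sizes at which each property is sharply testable:
marginal calibration at $10^6$ draws (±0.005 on category frequencies);
effect calibration at $n = 5\times10^4$–$10^5$; parameter recovery as the
mean of curve medians over 20 seeds at $n = 424$ (±0.03); decomposition
recovery over 50 replicates of 10×10×10 grids (±0.05 on shares); omega
recovery at $n = 10^4$ (±0.02); BCa coverage for omega over 500 simulations
at $n = 424$, $B = 500$ bootstrap replicates and a 40-group jackknife
(coverage asserted within [0.91, 0.99]).

## Known limitations

No permutation-based joint inference on the curve (descriptive summaries
only, deliberately); no Satorra–Bentler robust corrections, polychoric
correlations, multi-factor or bifactor models, measurement invariance, or
IRT; no imputation or weighting; no interactions between decision classes in
the variance decomposition; single-item "predictors" inherit single-item
reliability, so item-level curves sit closer to zero than scale-level curves
by construction.
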