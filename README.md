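# specwell

Specification curve (multiverse) analysis of the relationship between
dysregulated-gaming severity and mental well-being in Likert survey data —
for researchers who want the *distribution* of justifiable estimates rather
than one model's coefficient, and a fully synthetic, ground-truthed testbed
to validate the pipeline end to end.

Any single regression of well-being on a gaming-disorder score embodies a
chain of debatable choices: which severity instrument (or core-criteria
subset, or single diagnostic item), which well-being outcome, which
covariates, whether to exclude extreme-playtime respondents. `specwell`
enumerates the full cross of those decisions — by default

3 outcomes × 9 severity operationalizations × 18 covariate sets ×
2 outlier rules = **972 models**

— fits every OLS specification

  z(wellbeing) = β·z(severity) + Σ γ_k·covariate_k + ε,

and summarizes the curve: median/min/max β, the confidence interval of the
model holding the central-most estimate, the semipartial ΔR² of the focal
predictor (R² drop on refit without it), and the share of models significant
at 0.05. A crossed random-effects null model
(β_i = μ + u_outcome + u_predictor + u_covariates + u_subset + e_i, REML)
decomposes between-specification variance into intraclass shares per
decision class. Scale quality is assessed with one-factor maximum-likelihood
CFA (F_ML = log|Σ| + tr(SΣ⁻¹) − log|S| − p), CFI / RMSEA (90% CI by
noncentral-χ² inversion) / SRMR, and coefficient omega
ω = (Σλ)² / ((Σλ)² + Σθ) with BCa bootstrap intervals.

A synthetic survey generator with known ground truth drives validation:
latent constructs with configurable true associations, Likert items via
factor loadings and threshold discretization (attenuation compensated
analytically so configured effects land on the observed scale), page-level
dropout, careless patterned responders failing attention checks, and
implanted playtime outliers.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic
conditions (743 survey starters, 38.9% dropout, 6.6% careless completers,
~5% playtime outliers, observed effect targets −0.40/−0.47/−0.33 per
outcome):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_clean_score.R
Rscript analysis/03_psychometrics.R
Rscript analysis/04_curve.R
Rscript analysis/05_decompose.R
Rscript analysis/06_figures.R
```

which prints, among other things:

```
<cleaning_report> 743 began; removed 289 incomplete (38.9%), 30 careless (6.6% of completers); retained 424
972 models: median beta -0.350 [-0.450, -0.251], range -0.486 to -0.067; 99.8% significant
predictor share 27.7% -> 3.2% after removing ODBA
```

Read: after the cleaning cascade, all 972 justifiable models agree the
association is negative (median standardized β ≈ −0.35 at this seed; the
bracket is the median model's 95% CI). Dropping the one anomalous severity
operationalization (the behavioural-addiction-definition scale, whose
weakest item loads at 0.28) collapses the predictor decision's variance
share — most remaining spread comes from *which well-being outcome* you
pick, since the generator's true effects differ by outcome. Tables land in
`results/` (`curve_results.csv`, `curve_summary.csv`, `psychometrics.csv`,
`variance_decomposition.csv`, `item_curve_summary.csv`) along with the
specification-curve, box-plot and variance-share figures.

The same run is available programmatically:

```r
library(specwell)
m <- run_pipeline(pipeline_config(seed = 1, out_dir = "results/run1"))
m$stages$curve$median_beta
```

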